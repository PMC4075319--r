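# Shared fixtures: built once per test run.

cml_registry <- load_cml_fixture()
cml_timeline <- build_timeline(cml_registry)
cml_2012 <- network_at(cml_timeline, 2012)

# a minimal registry built in code: two 2-arm trials and one 3-arm trial
make_tiny_registry <- function() {
  as_trial_registry(tibble::tibble(
    trial_id = c("T1", "T2", "T3", "T3", "T3"),
    year = c(2000L, 2001L, 2003L, 2003L, 2003L),
    regimen_a = c("A", "A", "A", "A", "B"),
    n_a = c(50L, 60L, 40L, 40L, 45L),
    regimen_b = c("B", "B", "B", "C", "C"),
    n_b = c(55L, 52L, 45L, 30L, 30L),
    outcome_class = c("os", "strong", "weak", "os", "strong"),
    verdict = c("a", "tie", "b", "tie", "b"),
    basis = c("sig", "ns", "sig", "noninf", "sig")
  ))
}

# independent brute-force re-evaluation of the contest formula:
# plain loop, no vectorization shared with the implementation
oracle_vertex_value <- function(E, rv, n_compared, log_base = 10) {
  m <- length(E)
  N <- 0
  for (n in n_compared) N <- N + ifelse(is.na(n), 0, n)
  if (m == 0 || N <= 1) return(0)
  s <- 0
  for (i in seq_len(m)) s <- s + rv[i] * E[i]
  (s / m) * log(N) / log(log_base)
}

# brute-force multigraph degree from an edge list
oracle_degree <- function(edges, regimen) {
  cnt <- 0L
  for (i in seq_len(nrow(edges))) {
    if (edges$regimen_a[i] == regimen) cnt <- cnt + 1L
    if (edges$regimen_b[i] == regimen) cnt <- cnt + 1L
  }
  cnt
}
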