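test_that("fixture snapshot at 2012 has the published structure", {
  expect_identical(nrow(cml_2012$vertices), 17L)
  expect_identical(nrow(cml_2012$edges), 40L)
  d <- regimen_degree(cml_2012, c("Imatinib", "Busulfan"))
  expect_identical(d$degree, c(13L, 13L))
  sc <- singly_connected(cml_2012)
  expect_identical(length(sc), 5L)
  expect_setequal(sc, canonicalize_regimen(
    c("Radiation", "MRD allo-SCT", "IFNA/HiDAC", "Nilotinib", "Bosutinib")))
  # DBM has a single neighbour but two parallel edges: not singly connected
  expect_false("DBM" %in% sc)
  expect_identical(regimen_degree(cml_2012, "DBM")$degree, 2L)
})

test_that("a single 2-arm trial builds a 2-vertex, 1-edge network", {
  reg <- as_trial_registry(tibble::tibble(
    trial_id = "T1", year = 2000L, regimen_a = "A", n_a = 10L,
    regimen_b = "B", n_b = 12L, outcome_class = "os", verdict = "a",
    basis = "sig"))
  net <- build_network(reg, 2000)
  expect_identical(nrow(net$vertices), 2L)
  expect_identical(nrow(net$edges), 1L)
  expect_setequal(singly_connected(net), c("A", "B"))
  expect_error(build_network(reg, 1999), "no evidence yet")
})

test_that("degree matches a brute-force count and the handshake identity holds", {
  withr::with_seed(31, {
    for (i in 1:5) {
      cfg <- synthesis_config(n_regimens = 6, years = c(2000L, 2004L),
                              trials_per_year = 3, seed = sample.int(1e6, 1))
      net <- build_network(generate_trials(cfg))
      d <- regimen_degree(net)
      for (r in d$regimen) {
        expect_identical(d$degree[d$regimen == r], oracle_degree(net$edges, r))
      }
      expect_identical(sum(d$degree), 2L * nrow(net$edges))
    }
  })
  d <- regimen_degree(cml_2012)
  expect_identical(sum(d$degree), 80L)
  expect_error(regimen_degree(cml_2012, "NoSuchDrug"), "unknown regimen")
})

test_that("vertex and edge sets grow monotonically with the as-of year", {
  yrs <- c(1970L, 1994L, 2003L, 2012L)
  nets <- lapply(yrs, network_at, timeline = cml_timeline)
  for (k in seq_along(nets)[-1]) {
    expect_true(all(nets[[k - 1]]$vertices$regimen %in%
                      nets[[k]]$vertices$regimen))
    key <- function(e) paste(e$trial_id, e$regimen_a, e$regimen_b)
    expect_true(all(key(nets[[k - 1]]$edges) %in% key(nets[[k]]$edges)))
  }
  # edge count equals the sum of k(k-1)/2 over included trials
  arm_counts <- trial_arms(cml_registry) |> dplyr::count(trial_id, year)
  for (net in nets) {
    k <- arm_counts$n[arm_counts$year <= net$as_of_year]
    expect_identical(nrow(net$edges), as.integer(sum(k * (k - 1) / 2)))
  }
})

test_that("patient totals accumulate over a regimen's arms and flag unknowns", {
  reg <- as_trial_registry(tibble::tibble(
    trial_id = c("T1", "T2", "T3"), year = c(2000L, 2001L, 2002L),
    regimen_a = "A", n_a = c(50L, 70L, NA),
    regimen_b = c("B", "C", "B"), n_b = c(20L, 30L, 40L),
    outcome_class = "os", verdict = "tie", basis = "ns"))
  tot <- vertex_patient_total(reg, "A", 2001)
  expect_identical(as.integer(tot), 120L)
  expect_identical(attr(tot, "n_unknown"), 0L)
  tot3 <- vertex_patient_total(reg, "A", 2002)
  expect_identical(as.integer(tot3), 120L)   # unknown arm contributes 0
  expect_identical(attr(tot3, "n_unknown"), 1L)
  expect_identical(as.integer(vertex_patient_total(reg, "C", 2000)), 0L)
  # independent spreadsheet-style sum over the fixture
  manual <- trial_arms(cml_registry)
  manual <- sum(manual$n[manual$regimen == "Imatinib" & manual$year <= 2012])
  expect_identical(as.integer(vertex_patient_total(cml_registry, "Imatinib", 2012)),
                   as.integer(manual))
})

test_that("summary statistics are cumulative, monotone, and normalized to 100", {
  stats_tbl <- summary_stats(cml_registry)
  expect_identical(stats_tbl$trials[stats_tbl$year == 2012], 24L)
  expect_identical(stats_tbl$regimens[stats_tbl$year == 2012], 17L)
  expect_true(all(diff(stats_tbl$regimens) >= 0))
  expect_true(all(diff(stats_tbl$trials) >= 0))
  expect_true(all(diff(stats_tbl$patients) >= 0))
  expect_equal(stats_tbl$patients_normalized[nrow(stats_tbl)], 100)
  # a single trial jumps the regimen count from 0 to its arm count
  reg <- make_tiny_registry()
  s1 <- summary_stats(reg, year_range = 2000:2003)
  expect_identical(s1$regimens, c(2L, 2L, 2L, 3L))
})

test_that("GraphML and GML export preserve attributes and parallel edges", {
  gml_path <- withr::local_tempfile(fileext = ".graphml")
  write_network(cml_2012, gml_path, format = "graphml")
  g <- igraph::read_graph(gml_path, format = "graphml")
  expect_identical(as.integer(igraph::vcount(g)), 17L)
  expect_identical(as.integer(igraph::ecount(g)), 40L)   # duplicates preserved
  expect_setequal(igraph::vertex_attr(g, "canonical_name"),
                  cml_2012$vertices$regimen)
  a <- igraph::vertex_attr(g, "alpha")[match(cml_2012$vertices$regimen,
                                             igraph::vertex_attr(g, "name"))]
  expect_equal(a, cml_2012$vertices$alpha)
  expect_true(all(grepl("^#[0-9A-F]{6}$", igraph::vertex_attr(g, "color"))))

  gml2 <- withr::local_tempfile(fileext = ".gml")
  write_network(cml_2012, gml2, format = "gml")
  g2 <- igraph::read_graph(gml2, format = "gml")
  expect_identical(as.integer(igraph::ecount(g2)), 40L)
})
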