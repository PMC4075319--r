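test_that("alpha decays 0.1/year to the 0.2 floor and validates its input", {
  expect_equal(decay_alpha(1.0), 0.9)
  expect_equal(decay_alpha(0.25), 0.2)
  expect_equal(decay_alpha(0.2), 0.2)
  expect_error(decay_alpha(1.5), "out of range")
  expect_error(decay_alpha(0.05), "out of range")
})

test_that("closed-form aging agrees exactly with iterated decay over 50 years", {
  a <- 1.0
  for (k in 1:50) {
    a <- decay_alpha(a)
    expect_identical(a, alpha_after(k))
  }
  expect_identical(alpha_after(8), 0.2)
  expect_identical(alpha_after(100), 0.2)
  expect_identical(alpha_after(0), 1.0)
})

test_that("a year without new trials decays every alpha and changes no value", {
  net <- build_network(make_tiny_registry(), 2001)
  nxt <- advance_year(net, net$records[0, ])
  expect_identical(nxt$as_of_year, 2002L)
  expect_equal(nxt$vertices$alpha, decay_alpha(net$vertices$alpha))
  expect_equal(nxt$edges$alpha, decay_alpha(net$edges$alpha))
  expect_identical(nxt$vertices$value, net$vertices$value)
  expect_identical(nxt$vertices$classification, net$vertices$classification)
  expect_error(advance_year(net, net$records), "other years")
})

test_that("new trials refresh their nodes to alpha 1.0, even from the floor", {
  # A and B compared in 2000; nothing until 2010, so both sit at the floor;
  # a 2010 trial touching A refreshes A but not B
  rows <- tibble::tibble(
    trial_id = c("T1", "T2"), year = c(2000L, 2010L),
    regimen_a = c("A", "A"), n_a = c(50L, 60L),
    regimen_b = c("B", "C"), n_b = c(55L, 65L),
    outcome_class = "weak", verdict = "tie", basis = "ns")
  tl <- build_timeline(as_trial_registry(rows))
  v09 <- network_at(tl, 2009)$vertices
  expect_equal(v09$alpha[v09$regimen %in% c("A", "B")], c(0.2, 0.2))
  v10 <- network_at(tl, 2010)$vertices
  expect_equal(v10$alpha[v10$regimen == "A"], 1.0)
  expect_equal(v10$alpha[v10$regimen == "B"], 0.2)
  expect_equal(v10$alpha[v10$regimen == "C"], 1.0)
  # edges never refresh: the 2000 edge stays at its own trial's age
  e10 <- network_at(tl, 2010)$edges
  expect_equal(e10$alpha[e10$trial_id == "T1"], 0.2)
  expect_equal(e10$alpha[e10$trial_id == "T2"], 1.0)
})

test_that("a superior-to-inferior flip refreshes every adjacent node", {
  # X beats A (2000) and B (2001): superior. In 2008 a large OS trial has
  # X losing to C twice over -> X flips to inferior; A and B (adjacent,
  # aged to the floor) must be refreshed to 1.0.
  rows <- tibble::tibble(
    trial_id = c("T1", "T2", "T3", "T4"),
    year = c(2000L, 2001L, 2008L, 2008L),
    regimen_a = c("X", "X", "X", "X"),
    n_a = c(50L, 50L, 400L, 400L),
    regimen_b = c("A", "B", "C", "C"),
    n_b = c(50L, 50L, 400L, 410L),
    outcome_class = c("weak", "weak", "os", "os"),
    verdict = c("a", "a", "b", "b"),
    basis = "sig")
  reg <- as_trial_registry(rows)
  tl <- build_timeline(reg)
  v07 <- network_at(tl, 2007)$vertices
  expect_identical(v07$classification[v07$regimen == "X"], "superior")
  expect_equal(v07$alpha[v07$regimen %in% c("A", "B")], c(0.3, 0.4))

  v08 <- network_at(tl, 2008)$vertices
  expect_identical(v08$classification[v08$regimen == "X"], "inferior")
  expect_equal(v08$alpha[v08$regimen == "A"], 1.0)
  expect_equal(v08$alpha[v08$regimen == "B"], 1.0)

  fl <- flip_events(tl)
  expect_identical(nrow(fl), 1L)
  expect_identical(fl$year, 2008L)
  expect_identical(fl$regimen, "X")
  expect_identical(fl$old_class, "superior")
  expect_identical(fl$new_class, "inferior")
})

test_that("transitions through equivocal do not trigger the cascade", {
  # X ties A in 2000 (equivocal), then beats B in 2008 (equivocal ->
  # superior): not a flip, so aged neighbour A must stay at the floor
  rows <- tibble::tibble(
    trial_id = c("T1", "T2"), year = c(2000L, 2008L),
    regimen_a = c("X", "X"), n_a = c(50L, 60L),
    regimen_b = c("A", "B"), n_b = c(52L, 61L),
    outcome_class = c("weak", "weak"),
    verdict = c("tie", "a"), basis = c("ns", "sig"))
  tl <- build_timeline(as_trial_registry(rows))
  v08 <- network_at(tl, 2008)$vertices
  expect_identical(v08$classification[v08$regimen == "X"], "superior")
  expect_equal(v08$alpha[v08$regimen == "A"], 0.2)
  expect_identical(nrow(flip_events(tl)), 0L)
})

test_that("the fixture timeline spans the full history and accrues monotonically", {
  expect_identical(cml_timeline$first_year, 1968L)
  expect_identical(cml_timeline$last_year, 2012L)
  expect_identical(length(cml_timeline$snapshots), 45L)
  expect_false("Imatinib" %in% network_at(cml_timeline, 2002)$vertices$regimen)
  expect_true("Imatinib" %in% network_at(cml_timeline, 2003)$vertices$regimen)
  for (y in 1969:2012) {
    prev <- network_at(cml_timeline, y - 1L)
    cur <- network_at(cml_timeline, y)
    expect_true(all(prev$vertices$regimen %in% cur$vertices$regimen))
    expect_true(all(cur$vertices$alpha >= 0.2 & cur$vertices$alpha <= 1.0))
    if (nrow(cur$edges)) {
      expect_true(all(cur$edges$alpha >= 0.2 & cur$edges$alpha <= 1.0))
    }
  }
  expect_error(build_timeline(cml_registry[0, ]), "empty registry")
  expect_error(network_at(cml_timeline, 1950), "outside the timeline")
})

test_that("the fixture records the narrative era overturnings", {
  fl <- flip_events(cml_timeline)
  expect_identical(fl$regimen, c("Busulfan", "Hydrea", "Imatinib"))
  expect_identical(fl$year, c(1994L, 1995L, 2010L))
  expect_true(all(fl$old_class == "superior" & fl$new_class == "inferior"))
  # busulfan is still superior in the 1992 snapshot
  v92 <- network_at(cml_timeline, 1992)$vertices
  expect_identical(v92$classification[v92$regimen == "Busulfan"], "superior")
})

test_that("timelines are deterministic and export per-year graph files", {
  reg <- make_tiny_registry()
  t1 <- build_timeline(reg)
  t2 <- build_timeline(reg)
  expect_identical(t1, t2)
  dir <- withr::local_tempdir()
  files <- write_timeline(t1, dir)
  expect_identical(nrow(files), length(t1$snapshots) + 1L)
  expect_true(file.exists(file.path(dir, "flip_events.csv")))
  g <- igraph::read_graph(file.path(dir, "network_2003.graphml"),
                          format = "graphml")
  expect_identical(as.integer(igraph::vcount(g)), 3L)
})
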