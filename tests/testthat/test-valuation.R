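test_that("contest outcomes are antisymmetric and viewpoint-checked", {
  ann <- list(regimen_a = "A", regimen_b = "B", verdict = "a")
  expect_identical(contest_outcome(ann, "A"), 1L)
  expect_identical(contest_outcome(ann, "B"), -1L)
  tie <- list(regimen_a = "A", regimen_b = "B", verdict = "tie")
  expect_identical(contest_outcome(tie, "A"), 0L)
  expect_identical(contest_outcome(tie, "B"), 0L)
  expect_error(contest_outcome(ann, "C"), "not part of the comparison")
  # every fixture annotation: the two viewpoints sum to zero
  for (i in seq_len(nrow(cml_registry))) {
    row <- cml_registry[i, ]
    expect_identical(contest_outcome(row, row$regimen_a) +
                       contest_outcome(row, row$regimen_b), 0L)
  }
})

test_that("relative values map outcome quality to 1.0 / 1.25 / 1.5", {
  expect_identical(relative_value(c("weak", "strong", "os")),
                   c(1.0, 1.25, 1.5))
  expect_identical(relative_value("overall_survival"), 1.5)
  expect_error(relative_value("bogus"), "outcome_class")
})

test_that("vertex_value matches direct evaluation and its degenerate guards", {
  contests <- tibble::tibble(E = c(1, 0), rv = c(1.5, 1.25),
                             n_compared = c(600, 400))
  expect_equal(vertex_value(contests, n_total = 1000, log_base = 10), 2.25)
  expect_equal(vertex_value(tibble::tibble(E = -1, rv = 1.0, n_compared = 10),
                            log_base = 10), -1.0)
  # all ties: zero regardless of patients
  ties <- tibble::tibble(E = c(0, 0, 0), rv = c(1, 1.25, 1.5),
                         n_compared = c(100, 200, 300))
  expect_identical(vertex_value(ties), 0)
  expect_identical(vertex_value(ties[0, ]), 0)
  expect_identical(vertex_value(tibble::tibble(E = 1, rv = 1.5, n_compared = 1)), 0)
})

test_that("vertex_value equals the brute-force oracle on random contest lists", {
  withr::with_seed(99, {
    for (i in seq_len(1000)) {
      m <- sample(1:12, 1)
      E <- sample(c(-1L, 0L, 1L), m, replace = TRUE)
      rv <- sample(c(1.0, 1.25, 1.5), m, replace = TRUE)
      n <- sample(c(NA, 0:500), m, replace = TRUE)
      base <- sample(c(10, exp(1), 2), 1)
      got <- vertex_value(tibble::tibble(E = E, rv = rv, n_compared = n),
                          log_base = base)
      expect_equal(got, oracle_vertex_value(E, rv, n, base), tolerance = 1e-12)
    }
  })
})

test_that("valuation is linear in the relative-value weights", {
  reg <- make_tiny_registry()
  base <- vertex_values(reg, params = valuation_params())
  scaled <- vertex_values(reg, params = valuation_params(
    rv = 3 * c(weak = 1.0, strong = 1.25, os = 1.5)))
  expect_equal(scaled$value, 3 * base$value, tolerance = 1e-12)
})

test_that("a single comparison yields zero-sum values for its two regimens", {
  withr::with_seed(5, {
    for (i in 1:25) {
      verdict <- sample(c("a", "b", "tie"), 1)
      reg <- as_trial_registry(tibble::tibble(
        trial_id = "T1", year = 2000L,
        regimen_a = "A", n_a = sample(2:500, 1),
        regimen_b = "B", n_b = sample(2:500, 1),
        outcome_class = sample(c("weak", "strong", "os"), 1),
        verdict = verdict,
        basis = if (verdict == "tie") "ns" else "sig"))
      vals <- vertex_values(reg)
      expect_equal(sum(vals$value), 0, tolerance = 1e-12)
    }
  })
})

test_that("classification follows the sign rule with an optional equivocal band", {
  expect_identical(classify_vertex(c(2.25, 0, -1)),
                   c("superior", "equivocal", "inferior"))
  expect_identical(classify_vertex(c(0.05, -0.05), epsilon = 0.1),
                   c("equivocal", "equivocal"))
  expect_error(classify_vertex(1, epsilon = -1))
})

test_that("value colors hit the anchors, interpolate, and are channel-monotone", {
  expect_identical(value_to_color(0, 1), "#FFFF00")
  expect_identical(value_to_color(-1, 1), "#FF0000")
  expect_identical(value_to_color(1, 1), "#00A000")
  # midpoint of the yellow-to-green segment
  expect_identical(value_to_color(0.5, 1), "#80D000")
  expect_identical(grDevices::col2rgb("#80D000")[, 1],
                   c(red = 128L, green = 208L, blue = 0L))
  # clamped outside the domain
  expect_identical(value_to_color(10, 1), value_to_color(1, 1))
  expect_identical(value_to_color(-10, 1), value_to_color(-1, 1))
  # monotone toward green: red channel never increases with v, and the
  # green channel never decreases across the red-to-yellow half
  vs <- seq(-1.5, 1.5, by = 0.05)
  ch <- t(grDevices::col2rgb(value_to_color(vs, 1)))
  expect_true(all(diff(ch[, "red"]) <= 0))
  expect_true(all(diff(ch[vs <= 0, "green"]) >= 0))
  expect_true(all(ch[, "blue"] == 0))
})

test_that("edge colors are the discrete three-class scale", {
  expect_identical(edge_color(c("weak", "strong", "os")),
                   c("#FF0000", "#FFFF00", "#00A000"))
  expect_error(edge_color("bogus"), "outcome_class")
})

test_that("node area is proportional to patients and edge width to comparisons, with clamps", {
  p <- valuation_params()
  a1 <- node_display_size(500); a2 <- node_display_size(1000)
  expect_equal(a2 / a1, 2)
  expect_identical(node_display_size(0), unname(p$node_area[["min"]]))
  expect_identical(node_display_size(1e9), unname(p$node_area[["max"]]))

  w <- edge_display_width(c(200, 600))
  expect_equal(w[2] / w[1], 3)
  expect_identical(edge_display_width(0), unname(p$edge_width[["min"]]))
  n <- sort(sample(0:5000, 50))
  expect_true(!is.unsorted(edge_display_width(n)))
})
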