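# Trial registry: read, validate, and canonicalize the table of randomized
# head-to-head comparisons that drives the evidence network.

REGISTRY_COLS <- c("trial_id", "year", "regimen_a", "n_a", "regimen_b", "n_b",
                   "outcome_class", "verdict", "basis")

OUTCOME_CLASSES <- c("weak", "strong", "os")
VERDICTS <- c("a", "b", "tie")
BASES <- c("sig", "noninf", "ns")

# long-form synonyms accepted on input
.class_aliases <- c(
  weak = "weak", weak_surrogate = "weak",
  strong = "strong", strong_surrogate = "strong",
  os = "os", overall_survival = "os"
)
.verdict_aliases <- c(
  a = "a", a_superior = "a",
  b = "b", b_superior = "b",
  tie = "tie"
)
.basis_aliases <- c(
  sig = "sig", significant = "sig",
  noninf = "noninf", noninferiority = "noninf",
  ns = "ns", nonsignificant = "ns"
)

#' Canonicalize a regimen label
#'
#' A regimen is a slash-separated list of drug/modality components. Two labels
#' naming the same component set in different order (or through synonyms)
#' denote a substantively identical regimen and must map to the same vertex.
#' Components are mapped through the synonym table, then sorted case-folded
#' lexicographically and re-joined with `/`, so canonicalization is idempotent
#' and order-invariant.
#'
#' @param name Character vector of regimen labels, components separated by `/`.
#' @param synonyms Named character vector mapping alias component -> canonical
#'   token. The default maps nothing: which labels are "substantively
#'   identical" is a curation judgment carried by data, not code.
#' @return Character vector of canonical regimen names.
#' @examples
#' canonicalize_regimen("IFNA/Imatinib") == canonicalize_regimen("Imatinib/IFNA")
#' @export
canonicalize_regimen <- function(name, synonyms = character()) {
  if (length(name) == 0L) return(character())
  if (any(is.na(name)) || any(!nzchar(trimws(name)))) {
    rlang::abort("regimen labels must be non-empty and non-missing")
  }
  vapply(name, function(nm) {
    comps <- trimws(strsplit(nm, "/", fixed = TRUE)[[1]])
    if (length(comps) == 0L || any(!nzchar(comps))) {
      rlang::abort(sprintf("regimen label '%s' has an empty component", nm))
    }
    if (length(synonyms)) {
      hit <- match(comps, names(synonyms))
      comps[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
    }
    comps <- comps[order(tolower(comps), method = "radix")]
    paste(comps, collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

#' Split a canonical regimen name into its components
#' @param name Character vector of regimen names.
#' @return List of character vectors, one per name.
#' @export
regimen_components <- function(name) {
  strsplit(name, "/", fixed = TRUE)
}

# sort an unordered pair of names deterministically (byte order)
pair_sorted <- function(a, b) {
  swap <- vapply(seq_along(a), function(i) {
    order(c(a[[i]], b[[i]]), method = "radix")[1] == 2L
  }, logical(1))
  tibble::tibble(
    lo = ifelse(swap, b, a),
    hi = ifelse(swap, a, b)
  )
}

map_token <- function(x, aliases, what, context = "") {
  out <- unname(aliases[match(tolower(trimws(x)), names(aliases))])
  if (any(is.na(out) & !is.na(x))) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    rlang::abort(sprintf("unknown %s token%s: %s", what, context,
                         paste(sQuote(bad), collapse = ", ")))
  }
  out
}

#' Coerce a data frame to a validated trial registry
#'
#' The registry is a tibble with one row per (trial, unordered comparison):
#' `trial_id`, `year`, `regimen_a`, `n_a`, `regimen_b`, `n_b`,
#' `outcome_class` (`weak`/`strong`/`os`), `verdict` (`a`/`b`/`tie`),
#' `basis` (`sig`/`noninf`/`ns`). Regimen labels are canonicalized, rows are
#' sorted by (year, trial_id, pair), and all registry invariants are checked.
#'
#' @param x Data frame with the registry columns (long token forms such as
#'   `overall_survival` are accepted and normalized).
#' @param synonyms Passed to [canonicalize_regimen()].
#' @param validate If `TRUE` (default), abort with the full violation report
#'   when [validate_trials()] finds problems.
#' @return A `trial_registry` tibble.
#' @export
as_trial_registry <- function(x, synonyms = character(), validate = TRUE) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(REGISTRY_COLS, names(x))
  if (length(missing_cols)) {
    rlang::abort(sprintf("registry is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  x <- x[REGISTRY_COLS]
  x$trial_id <- as.character(x$trial_id)
  x$year <- as.integer(x$year)
  x$n_a <- as.integer(x$n_a)
  x$n_b <- as.integer(x$n_b)
  x$regimen_a <- canonicalize_regimen(x$regimen_a, synonyms)
  x$regimen_b <- canonicalize_regimen(x$regimen_b, synonyms)
  x$outcome_class <- map_token(x$outcome_class, .class_aliases, "outcome_class")
  x$verdict <- map_token(x$verdict, .verdict_aliases, "verdict")
  x$basis <- map_token(x$basis, .basis_aliases, "basis")

  keys <- pair_sorted(x$regimen_a, x$regimen_b)
  x <- x[order(x$year, x$trial_id, keys$lo, keys$hi, method = "radix"), ]
  x <- tibble::as_tibble(x)
  class(x) <- c("trial_registry", class(x))

  if (validate) {
    report <- validate_trials(x)
    if (nrow(report)) {
      rlang::abort(c("invalid trial registry",
                     stats::setNames(paste0(report$trial_id, ": ", report$detail),
                                     rep("x", nrow(report)))))
    }
  }
  x
}

#' Read a trial registry from CSV or JSON
#'
#' CSV: one row per (trial, comparison) with the registry columns; `#` lines
#' are comments; blank `n_a`/`n_b` mean the enrollment was not reported.
#' JSON: an array of trial objects `{trial_id, year, arms: [{regimen, n}],
#' comparisons: [{regimen_a, regimen_b, outcome_class, verdict, basis}]}`,
#' accepted interchangeably.
#'
#' @param path File path (`.json` selects the JSON dialect).
#' @inheritParams as_trial_registry
#' @return A `trial_registry` tibble sorted by (year, trial_id, pair).
#' @export
read_trial_table <- function(path, synonyms = character(), validate = TRUE) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    trials <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- purrr::map_dfr(trials, function(tr) {
      arms <- purrr::map_dfr(tr$arms, function(a) {
        tibble::tibble(regimen = a$regimen,
                       n = if (is.null(a$n)) NA_integer_ else as.integer(a$n))
      })
      purrr::map_dfr(tr$comparisons, function(cmp) {
        tibble::tibble(
          trial_id = tr$trial_id, year = as.integer(tr$year),
          regimen_a = cmp$regimen_a,
          n_a = arms$n[match(cmp$regimen_a, arms$regimen)],
          regimen_b = cmp$regimen_b,
          n_b = arms$n[match(cmp$regimen_b, arms$regimen)],
          outcome_class = cmp$outcome_class, verdict = cmp$verdict,
          basis = cmp$basis
        )
      })
    })
  } else {
    rows <- readr::read_csv(
      path, comment = "#", na = c("", "NA"), show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  as_trial_registry(rows, synonyms = synonyms, validate = validate)
}

#' Write a trial registry to CSV or JSON
#'
#' Round-trips exactly through [read_trial_table()].
#'
#' @param registry A `trial_registry`.
#' @param path Output path (`.json` selects the JSON dialect).
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(registry, path) {
  registry <- as_trial_registry(registry, validate = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    arms <- trial_arms(registry)
    trials <- registry |>
      dplyr::distinct(.data$trial_id, .data$year) |>
      purrr::pmap(function(trial_id, year) {
        a <- arms[arms$trial_id == trial_id, ]
        cmp <- registry[registry$trial_id == trial_id, ]
        list(
          trial_id = trial_id, year = year,
          arms = purrr::map2(a$regimen, a$n, function(r, n) {
            if (is.na(n)) list(regimen = r) else list(regimen = r, n = n)
          }),
          comparisons = purrr::pmap(
            cmp[c("regimen_a", "regimen_b", "outcome_class", "verdict", "basis")],
            function(regimen_a, regimen_b, outcome_class, verdict, basis) {
              list(regimen_a = regimen_a, regimen_b = regimen_b,
                   outcome_class = outcome_class, verdict = verdict,
                   basis = basis)
            })
        )
      })
    jsonlite::write_json(trials, path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  } else {
    readr::write_csv(as.data.frame(registry), path, na = "")
  }
  invisible(path)
}

#' Per-arm view of a registry
#'
#' Derives each trial's arm list as the union of regimens over its comparison
#' rows, with the enrollment reported for that arm (`NA` if never reported).
#'
#' @param registry A `trial_registry` (or compatible data frame).
#' @return Tibble with columns `trial_id`, `year`, `regimen`, `n`.
#' @export
trial_arms <- function(registry) {
  long <- dplyr::bind_rows(
    dplyr::transmute(registry, trial_id = .data$trial_id, year = .data$year,
                     regimen = .data$regimen_a, n = .data$n_a),
    dplyr::transmute(registry, trial_id = .data$trial_id, year = .data$year,
                     regimen = .data$regimen_b, n = .data$n_b)
  )
  long |>
    dplyr::group_by(.data$trial_id, .data$year, .data$regimen) |>
    dplyr::summarise(
      n = if (all(is.na(.data$n))) NA_integer_ else
        as.integer(unique(stats::na.omit(.data$n)))[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year, .data$trial_id, .data$regimen)
}

#' Validate registry invariants
#'
#' Report-only: returns one row per violation (empty tibble iff the registry
#' is valid). Checks: no self-comparison; verdicts `a`/`b` require basis
#' `sig` and `tie` requires `noninf`/`ns`; non-negative enrollments, reported
#' consistently across a trial's rows; no duplicate (trial, pair); a single
#' year per trial; all-pairwise completeness (a k-arm trial must carry exactly
#' k(k-1)/2 comparisons, one per unordered arm pair).
#'
#' @param registry A `trial_registry` or any data frame with the registry
#'   columns (tokens already normalized).
#' @return Tibble with columns `trial_id`, `rule`, `detail`.
#' @export
validate_trials <- function(registry) {
  registry <- tibble::as_tibble(registry)
  out <- list()
  bad <- function(trial_id, rule, detail) {
    tibble::tibble(trial_id = as.character(trial_id), rule = rule,
                   detail = detail)
  }

  self <- registry$regimen_a == registry$regimen_b
  if (any(self)) {
    out <- c(out, list(bad(registry$trial_id[self], "self_comparison",
                           paste0("comparison of ", registry$regimen_a[self],
                                  " with itself"))))
  }
  vb_bad <- (registry$verdict %in% c("a", "b") & registry$basis != "sig") |
    (registry$verdict == "tie" & !registry$basis %in% c("noninf", "ns"))
  if (any(vb_bad)) {
    out <- c(out, list(bad(registry$trial_id[vb_bad], "verdict_basis",
                           paste0("verdict '", registry$verdict[vb_bad],
                                  "' incompatible with basis '",
                                  registry$basis[vb_bad], "'"))))
  }
  neg <- (!is.na(registry$n_a) & registry$n_a < 0) |
    (!is.na(registry$n_b) & registry$n_b < 0)
  if (any(neg)) {
    out <- c(out, list(bad(registry$trial_id[neg], "negative_enrollment",
                           "negative enrollment count")))
  }

  keys <- pair_sorted(registry$regimen_a, registry$regimen_b)
  pair_id <- paste(registry$trial_id, keys$lo, keys$hi, sep = "\r")
  dup <- duplicated(pair_id) | duplicated(pair_id, fromLast = TRUE)
  if (any(dup)) {
    dups <- unique(registry$trial_id[dup])
    out <- c(out, list(bad(dups, "duplicate_pair",
                           "duplicate (trial, regimen pair) annotation")))
  }

  per_trial <- split(seq_len(nrow(registry)), registry$trial_id)
  for (tid in names(per_trial)) {
    idx <- per_trial[[tid]]
    yrs <- unique(registry$year[idx])
    if (length(yrs) > 1) {
      out <- c(out, list(bad(tid, "year_conflict",
                             "trial rows disagree on publication year")))
    }
    arms <- unique(c(registry$regimen_a[idx], registry$regimen_b[idx]))
    k <- length(arms)
    expected <- k * (k - 1) / 2
    n_pairs <- length(unique(pair_id[idx]))
    if (n_pairs != expected) {
      out <- c(out, list(bad(tid, "pairwise_completeness",
                             sprintf("%d arms need %d pairwise comparisons, found %d",
                                     k, expected, n_pairs))))
    }
    # enrollment consistency across rows mentioning the same arm
    long_n <- rbind(
      data.frame(regimen = registry$regimen_a[idx], n = registry$n_a[idx]),
      data.frame(regimen = registry$regimen_b[idx], n = registry$n_b[idx])
    )
    conflict <- tapply(long_n$n, long_n$regimen, function(v) {
      length(unique(stats::na.omit(v))) > 1
    })
    if (any(conflict, na.rm = TRUE)) {
      out <- c(out, list(bad(tid, "enrollment_conflict",
                             paste0("inconsistent enrollment for arm(s): ",
                                    paste(names(conflict)[which(conflict)],
                                          collapse = ", ")))))
    }
  }

  if (length(out)) {
    dplyr::arrange(dplyr::bind_rows(out), .data$trial_id, .data$rule)
  } else {
    tibble::tibble(trial_id = character(), rule = character(),
                   detail = character())
  }
}

#' @export
print.trial_registry <- function(x, ...) {
  arms <- trial_arms(x)
  cat(sprintf("<trial_registry> %d comparisons, %d trials, %d regimens, years %d-%d\n",
              nrow(x), dplyr::n_distinct(x$trial_id),
              dplyr::n_distinct(arms$regimen), min(x$year), max(x$year)))
  NextMethod()
}
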