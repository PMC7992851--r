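#' Specification for the synthetic-data generators
#'
#' Bundles and validates the parameters shared by [gen_analogue_db()] and
#' [gen_prediction_table()]. The defaults emulate a typical baseline
#' (narcosis-type) aquatic-toxicity dataset: log10 LC50 declines linearly
#' with hydrophobicity at about -0.7 log units per log Kow unit around an
#' intercept of 2 log10 mg/L, with lognormal biological scatter of 0.3
#' log10 units; tool predictions carry multiplicative lognormal error of
#' 0.5 log10 units, a 10% missing-prediction rate and a 20%
#' outside-domain rate, in line with the spread observed across the
#' benchmark fixtures.
#'
#' @param n_chemicals number of chemicals to generate.
#' @param kow_range numeric length-2, low < high, range of log Kow.
#' @param slope trend slope, log10 mg/L per log Kow unit.
#' @param intercept trend intercept, log10 mg/L at log Kow 0.
#' @param noise_sd biological scatter around the trend, log10 units.
#' @param group_vocabulary labels to sample functional groups from.
#' @param n_groups_per_chemical groups per chemical.
#' @param tool_error_sd lognormal prediction error, log10 units.
#' @param tool_bias systematic prediction bias, log10 units.
#' @param missing_prob probability a prediction is missing.
#' @param ad_out_prob probability a prediction is flagged outside the AD.
#' @param seed integer seed; every draw is reproducible from it.
#' @return a validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_chemicals = 100,
                           kow_range = c(-1, 6),
                           slope = -0.7,
                           intercept = 2,
                           noise_sd = 0.3,
                           group_vocabulary = c("aryl", "phenol", "alkane",
                                                "ester", "amine", "halide"),
                           n_groups_per_chemical = 2,
                           tool_error_sd = 0.5,
                           tool_bias = 0,
                           missing_prob = 0.1,
                           ad_out_prob = 0.2,
                           seed = 1L) {
  if (n_chemicals < 1) rlang::abort("`n_chemicals` must be >= 1")
  if (length(kow_range) != 2 || kow_range[1] >= kow_range[2]) {
    rlang::abort("`kow_range` must be c(low, high) with low < high")
  }
  if (noise_sd < 0 || tool_error_sd < 0) {
    rlang::abort("standard deviations must be >= 0")
  }
  for (p in c(missing_prob, ad_out_prob)) {
    if (p < 0 || p > 1) rlang::abort("probabilities must lie in [0, 1]")
  }
  if (n_groups_per_chemical < 1 ||
      n_groups_per_chemical > length(group_vocabulary)) {
    rlang::abort("`n_groups_per_chemical` must fit the vocabulary")
  }
  structure(
    list(
      n_chemicals = as.integer(n_chemicals), kow_range = kow_range,
      slope = slope, intercept = intercept, noise_sd = noise_sd,
      group_vocabulary = group_vocabulary,
      n_groups_per_chemical = as.integer(n_groups_per_chemical),
      tool_error_sd = tool_error_sd, tool_bias = tool_bias,
      missing_prob = missing_prob, ad_out_prob = ad_out_prob,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Deterministic per-row substream: row i of a given stream always sees the
# same seed, so extending n_chemicals never reshuffles earlier rows.
row_seed <- function(seed, i, stream = 0L) {
  (as.double(seed) * 69069 + stream * 7919 + i * 104729) %% 2147483647
}

with_row_seed <- function(seed, i, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(row_seed(seed, i, stream))
  expr
}

#' Generate a synthetic analogue database
#'
#' Draws log Kow uniformly over `kow_range` and experimental log10 LC50 as
#' `intercept + slope * kow + Normal(0, noise_sd)`, with functional-group
#' labels sampled from the vocabulary. Fully reproducible from the spec's
#' seed; each chemical has its own deterministic substream.
#'
#' @param spec a [synthetic_spec()].
#' @return analogue tibble: `cas`, `name`, `log_kow`, `groups`
#'   (semicolon-delimited), `lc50`, `source_db`.
#' @export
gen_analogue_db <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_chemicals
  kow <- numeric(n)
  noise <- numeric(n)
  groups <- character(n)
  for (i in seq_len(n)) {
    with_row_seed(spec$seed, i, 0L, {
      kow[i] <- stats::runif(1, spec$kow_range[1], spec$kow_range[2])
      noise[i] <- stats::rnorm(1, 0, spec$noise_sd)
      groups[i] <- paste(
        sort(sample(spec$group_vocabulary, spec$n_groups_per_chemical)),
        collapse = ";"
      )
    })
  }
  tibble::tibble(
    cas = sprintf("SYN-%06d", seq_len(n)),
    name = sprintf("synthetic analogue %d", seq_len(n)),
    log_kow = kow,
    groups = groups,
    lc50 = 10^(spec$intercept + spec$slope * kow + noise),
    source_db = "synthetic"
  )
}

#' Generate a synthetic tool-prediction table
#'
#' Emulates a prediction tool with multiplicative lognormal error:
#' `log10 pred = log10 exp + tool_bias + Normal(0, tool_error_sd)`.
#' Each prediction is independently dropped with probability
#' `missing_prob` and flagged outside the applicability domain with
#' probability `ad_out_prob`.
#'
#' @param spec a [synthetic_spec()].
#' @param experiments tibble with columns `cas` and `lc50` (positive).
#' @param tool tool label for the generated records.
#' @return long prediction tibble: `cas`, `tool`, `lc50`, `ad_status`.
#' @export
gen_prediction_table <- function(spec, experiments, tool = "SYNTH") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(experiments) || nrow(experiments) == 0) {
    rlang::abort("`experiments` must be non-empty")
  }
  if (any(!is.finite(experiments$lc50) | experiments$lc50 <= 0)) {
    rlang::abort("all experimental LC50 must be positive")
  }
  n <- nrow(experiments)
  err <- numeric(n)
  missing <- logical(n)
  out_ad <- logical(n)
  for (i in seq_len(n)) {
    with_row_seed(spec$seed, i, 1L, {
      err[i] <- stats::rnorm(1, 0, spec$tool_error_sd)
      missing[i] <- stats::runif(1) < spec$missing_prob
      out_ad[i] <- stats::runif(1) < spec$ad_out_prob
    })
  }
  pred <- 10^(log10(experiments$lc50) + spec$tool_bias + err)
  tibble::tibble(
    cas = experiments$cas,
    tool = tool,
    lc50 = ifelse(missing, NA_real_, pred),
    ad_status = dplyr::case_when(
      missing ~ "unknown",
      out_ad ~ "outside",
      TRUE ~ "inside"
    )
  )
}
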