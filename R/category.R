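#' Split a semicolon-delimited group string into a set
#' @keywords internal
group_set <- function(x) {
  if (is.list(x)) return(lapply(x, group_set))
  sort(unique(trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1]])))
}

set_equal <- function(a, b) length(a) == length(b) && all(a == b)

#' Build a chemical category for a target
#'
#' Selects, from an analogue database, the records whose organic
#' functional-group set matches the target's. The default `"strict"` mode
#' requires set equality (the nested-group categorisation yields one label
#' set per chemical); `"subset"` mode accepts analogues whose groups
#' contain the target's. The target itself is excluded by CAS.
#'
#' @param target list or one-row tibble with `cas`, `log_kow`,
#'   `functional_groups` (character vector or semicolon-delimited string).
#' @param db analogue tibble with columns `cas`, `log_kow`, `groups`
#'   (semicolon-delimited), `lc50`, optionally `source_db`.
#' @param mode `"strict"` or `"subset"`.
#' @return the matching rows of `db`.
#' @export
build_category <- function(target, db, mode = c("strict", "subset")) {
  mode <- rlang::arg_match(mode)
  tgt <- sort(unique(unlist(lapply(target$functional_groups, group_set))))
  if (length(tgt) == 0) rlang::abort("target has no functional groups")
  if (is.null(db) || nrow(db) == 0) return(db[0, ])
  keep <- vapply(db$groups, function(g) {
    gs <- group_set(g)
    if (mode == "strict") set_equal(gs, tgt) else all(tgt %in% gs)
  }, logical(1))
  db[keep & db$cas != target$cas, ]
}

#' Applicability-domain check for a category prediction
#'
#' A category prediction is inside its domain when the target's log Kow
#' lies within the range spanned by the collected analogues and every
#' functional group of the target occurs among the analogues' groups.
#'
#' @inheritParams build_category
#' @param analogues analogue tibble (as `db` in [build_category()]).
#' @return `"inside"` or `"outside"`.
#' @export
category_ad_check <- function(target, analogues) {
  if (is.null(analogues) || nrow(analogues) == 0) {
    rlang::abort("`analogues` must be non-empty")
  }
  kow_in <- target$log_kow >= min(analogues$log_kow) &&
    target$log_kow <= max(analogues$log_kow)
  tgt <- sort(unique(unlist(lapply(target$functional_groups, group_set))))
  pool <- unique(unlist(lapply(analogues$groups, group_set)))
  if (kow_in && all(tgt %in% pool)) "inside" else "outside"
}

category_prediction <- function(lc50, method, ad_status, analogue_ids,
                                slope = NA_real_, intercept = NA_real_,
                                r2 = NA_real_) {
  tibble::tibble(
    lc50 = lc50, method = method, ad_status = ad_status,
    analogue_ids = list(analogue_ids),
    slope = slope, intercept = intercept, r2 = r2
  )
}

#' Read-across prediction from nearest analogues
#'
#' Averages the experimental LC50 of the `k` analogues nearest to the
#' target in log Kow (ties broken by CAS, ascending, for determinism).
#' The default average is geometric (mean of log10 LC50), consistent with
#' the log-linear structure of baseline aquatic toxicity; an arithmetic
#' mode is available.
#'
#' @inheritParams category_ad_check
#' @param k number of analogues to average (uses all when fewer exist).
#' @param averaging `"geometric"` or `"arithmetic"`.
#' @return one-row category-prediction tibble; missing `lc50` when no
#'   usable analogue exists.
#' @export
read_across <- function(target, analogues, k = 5,
                        averaging = c("geometric", "arithmetic")) {
  averaging <- rlang::arg_match(averaging)
  usable <- analogues[!is.na(analogues$lc50) & analogues$lc50 > 0, ]
  if (nrow(usable) == 0) {
    return(category_prediction(NA_real_, "read_across", "outside",
                               character(0)))
  }
  ord <- order(abs(usable$log_kow - target$log_kow), usable$cas)
  sel <- usable[ord[seq_len(min(k, nrow(usable)))], ]
  pred <- if (averaging == "geometric") {
    10^mean(log10(sel$lc50))
  } else {
    mean(sel$lc50)
  }
  category_prediction(pred, "read_across",
                      category_ad_check(target, analogues), sel$cas)
}

#' Trend-analysis prediction from a category regression
#'
#' Fits an ordinary least-squares regression of toxicity on log Kow over
#' the category members and evaluates it at the target's log Kow. The
#' default regression space is log10 LC50 (predictions always positive);
#' `space = "linear"` regresses LC50 itself, which can extrapolate to
#' non-positive values exactly as reported by linear-space trend tools.
#'
#' @inheritParams category_ad_check
#' @param space `"log10"` or `"linear"`.
#' @return one-row category-prediction tibble with regression
#'   diagnostics; missing when fewer than 3 analogues or no Kow variance.
#' @export
trend_analysis <- function(target, analogues, space = c("log10", "linear")) {
  space <- rlang::arg_match(space)
  usable <- analogues[!is.na(analogues$lc50), ]
  if (space == "log10") usable <- usable[usable$lc50 > 0, ]
  if (nrow(usable) < 3 || length(unique(usable$log_kow)) < 2 ||
      stats::var(usable$log_kow) == 0) {
    return(category_prediction(NA_real_, "trend_analysis", "outside",
                               character(0)))
  }
  y <- if (space == "log10") log10(usable$lc50) else usable$lc50
  fit <- stats::lm(y ~ log_kow, data = data.frame(y = y,
                                                  log_kow = usable$log_kow))
  yhat <- unname(stats::predict(fit,
                                newdata = data.frame(log_kow = target$log_kow)))
  pred <- if (space == "log10") 10^yhat else yhat
  category_prediction(
    pred, "trend_analysis", category_ad_check(target, analogues), usable$cas,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = suppressWarnings(summary(fit))$r.squared
  )
}

#' Remove expert-excluded analogues
#'
#' Outlier removal in category refinement is an expert decision: this
#' function only drops the explicitly listed CAS numbers. Use
#' [flag_outliers()] to obtain data-driven suggestions; nothing is ever
#' removed silently.
#'
#' @param analogues analogue tibble.
#' @param exclude character vector of CAS numbers to drop.
#' @return the filtered tibble.
#' @export
remove_outliers <- function(analogues, exclude = character(0)) {
  analogues[!(analogues$cas %in% exclude), ]
}

#' Suggest regression outliers in a category
#'
#' Fits the trend regression (log10 LC50 on log Kow) and flags analogues
#' whose externally studentized residual exceeds the threshold. The
#' output is advisory: pass the CAS numbers you accept to
#' [remove_outliers()].
#'
#' @param analogues analogue tibble with at least 4 usable rows.
#' @param threshold absolute studentized-residual cutoff.
#' @return character vector of flagged CAS numbers.
#' @export
flag_outliers <- function(analogues, threshold = 3) {
  usable <- analogues[!is.na(analogues$lc50) & analogues$lc50 > 0, ]
  if (nrow(usable) < 4) return(character(0))
  fit <- stats::lm(log10(lc50) ~ log_kow, data = usable)
  rs <- stats::rstudent(fit)
  res <- stats::residuals(fit)
  # a non-finite studentized residual with a real raw residual means the
  # leave-one-out fit is (near-)perfect: the most extreme outlier of all
  hit <- (is.finite(rs) & abs(rs) > threshold) |
    (!is.finite(rs) & abs(res) > 1e-8)
  usable$cas[hit]
}

#' Water-solubility plausibility of an LC50
#'
#' An acute LC50 above the substance's water solubility cannot be realised
#' in a test medium, so the experimental value is suspect. The rule is a
#' strict inequality: an LC50 equal to the solubility is plausible.
#'
#' @param lc50 LC50 values, mg/L, positive.
#' @param water_solubility water solubility, mg/L, positive or `NA`.
#' @return character vector: `"plausible"`, `"implausible"` or
#'   `"unknown"` (missing solubility).
#' @examples
#' solubility_check(68, 0.106)     # implausible
#' solubility_check(0.0356, 0.047) # plausible
#' @export
solubility_check <- function(lc50, water_solubility) {
  if (any(!is.na(lc50) & lc50 <= 0) ||
      any(!is.na(water_solubility) & water_solubility <= 0)) {
    rlang::abort("`lc50` and `water_solubility` must be positive")
  }
  dplyr::case_when(
    is.na(water_solubility) | is.na(lc50) ~ "unknown",
    lc50 > water_solubility ~ "implausible",
    TRUE ~ "plausible"
  )
}
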