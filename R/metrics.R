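#' Total accuracy of qualitative category assignment
#'
#' Fraction of chemicals with a prediction whose predicted LC50 falls in the
#' same GHS category as the measured LC50:
#' `100 * n_correct / (n_all - n_missing)`.
#'
#' @param n_correct number of correct category assignments.
#' @param n_all number of chemicals in the dataset.
#' @param n_missing number of chemicals the tool could not predict.
#' @return percentage in `[0, 100]`, or `NA` when every prediction is missing.
#' @examples
#' total_accuracy(21, 37, 12) # 84
#' @export
total_accuracy <- function(n_correct, n_all, n_missing) {
  check_counts(n_correct, n_all, n_missing)
  denom <- n_all - n_missing
  if (denom == 0) return(NA_real_)
  100 * n_correct / denom
}

#' Predictive power of qualitative category assignment
#'
#' Like [total_accuracy()] but a missing prediction is treated as an
#' incorrect assignment: `100 * n_correct / n_all`.
#'
#' @inheritParams total_accuracy
#' @return percentage in `[0, 100]`.
#' @examples
#' predictive_power(21, 37) # 56.76
#' @export
predictive_power <- function(n_correct, n_all) {
  if (n_all <= 0) rlang::abort("`n_all` must be positive")
  check_counts(n_correct, n_all, 0)
  100 * n_correct / n_all
}

check_counts <- function(n_correct, n_all, n_missing) {
  if (n_missing < 0 || n_missing > n_all) {
    rlang::abort("`n_missing` must lie in [0, n_all]")
  }
  if (n_correct < 0 || n_correct > n_all - n_missing) {
    rlang::abort("`n_correct` must lie in [0, n_all - n_missing]")
  }
  invisible(NULL)
}

#' Fold error between predicted and measured LC50
#'
#' Absolute difference on the log10 scale, `|log10(pred) - log10(exp)|`.
#' A fold error of 1 means the prediction is within a factor of 10 of the
#' measurement. Non-positive predictions have no log and get `Inf`, so they
#' fail every fold criterion.
#'
#' @param exp_lc50 experimental LC50, mg/L, positive.
#' @param pred_lc50 predicted LC50, mg/L.
#' @return numeric vector of fold errors in log10 units.
#' @examples
#' fold_error(1.68, 1.88)
#' @export
fold_error <- function(exp_lc50, pred_lc50) {
  if (any(!is.finite(exp_lc50) | exp_lc50 <= 0)) {
    rlang::abort("`exp_lc50` must be positive and finite")
  }
  out <- rep(Inf, length(pred_lc50))
  ok <- !is.na(pred_lc50) & is.finite(pred_lc50) & pred_lc50 > 0
  out[ok] <- abs(log10(pred_lc50[ok]) - log10(exp_lc50[ok]))
  out[is.na(pred_lc50)] <- NA_real_
  out
}

#' Accuracy within a fold factor
#'
#' Percentage of non-missing predictions whose fold error does not exceed
#' `log10(factor)`. Non-positive predictions count in the denominator and
#' always fail; missing predictions are excluded entirely.
#'
#' @param pairs tibble with columns `exp_lc50` and `pred_lc50`.
#' @param factor fold factor, typically 10, 100 or 1000.
#' @return percentage, or `NA` when there is no non-missing prediction.
#' @export
fold_accuracy <- function(pairs, factor) {
  stopifnot(factor > 1)
  present <- !is.na(pairs$pred_lc50)
  if (!any(present)) return(NA_real_)
  fe <- fold_error(pairs$exp_lc50[present], pairs$pred_lc50[present])
  100 * mean(fe <= log10(factor))
}

#' Root mean square error on the log10 scale
#'
#' Computed over pairs with a positive prediction; missing and non-positive
#' predictions are excluded (their log is undefined).
#'
#' @inheritParams fold_accuracy
#' @return RMSE in log10 units, or `NA` when no pair is usable.
#' @export
rmse_log10 <- function(pairs) {
  use <- usable_pairs(pairs)
  if (!any(use)) return(NA_real_)
  err <- log10(pairs$pred_lc50[use]) - log10(pairs$exp_lc50[use])
  sqrt(mean(err^2))
}

usable_pairs <- function(pairs) {
  !is.na(pairs$pred_lc50) & is.finite(pairs$pred_lc50) & pairs$pred_lc50 > 0
}

#' Squared Pearson correlation
#'
#' The R-squared used throughout the evaluation: the square of the Pearson
#' correlation coefficient of the two vectors, computed over pairwise
#' complete finite pairs. Applied to GHS class codes for the qualitative
#' R-squared and to log10 LC50 for the quantitative one.
#'
#' @param xs,ys numeric vectors of equal length.
#' @return squared correlation, or `NA` with fewer than 3 complete pairs or
#'   zero variance in either vector.
#' @export
r_squared <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  ok <- is.finite(xs) & is.finite(ys)
  if (sum(ok) < 3) return(NA_real_)
  x <- xs[ok]
  y <- ys[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Signed prediction error distribution
#'
#' Sample mean and standard deviation (n - 1 denominator) of
#' `log10(pred) - log10(exp)`. Positive errors mean the predicted LC50 is
#' above the experimental one, i.e. toxicity was underestimated. Missing
#' and non-positive predictions are excluded.
#'
#' @inheritParams fold_accuracy
#' @return one-row tibble with columns `mean`, `sd`, `n`.
#' @export
error_distribution <- function(pairs) {
  use <- usable_pairs(pairs)
  if (!any(use)) {
    return(tibble::tibble(mean = NA_real_, sd = NA_real_, n = 0L))
  }
  err <- log10(pairs$pred_lc50[use]) - log10(pairs$exp_lc50[use])
  tibble::tibble(
    mean = mean(err),
    sd = if (length(err) > 1) stats::sd(err) else 0,
    n = length(err)
  )
}

#' Evaluate one tool on one endpoint
#'
#' Computes the full panel of qualitative and quantitative performance
#' statistics for a set of paired observations belonging to a single tool
#' and endpoint. With `scope = "inside_ad"` all statistics are computed on
#' the subset of chemicals flagged inside the tool's applicability domain;
#' predictive power, whose denominator is the whole dataset, is reported
#' only for the entire-dataset scope.
#'
#' @param pairs tibble with columns `cas`, `exp_lc50`, `pred_lc50`,
#'   `ad_status` (`"inside"`, `"outside"` or `"unknown"`); optionally
#'   `tool` and `endpoint` (carried through to the report).
#' @param scope `"entire"` or `"inside_ad"`.
#' @param factors fold factors for quantitative accuracy.
#' @return a one-row tibble (an evaluation report).
#' @export
evaluate_tool <- function(pairs, scope = c("entire", "inside_ad"),
                          factors = c(10, 100, 1000)) {
  scope <- rlang::arg_match(scope)
  if (nrow(pairs) == 0) rlang::abort("`pairs` must contain at least one row")
  if (any(!is.finite(pairs$exp_lc50) | pairs$exp_lc50 <= 0)) {
    rlang::abort("all `exp_lc50` must be positive")
  }

  n_all <- nrow(pairs)
  n_inside <- sum(pairs$ad_status == "inside", na.rm = TRUE)
  used <- pairs
  if (scope == "inside_ad") {
    used <- dplyr::filter(pairs, .data$ad_status == "inside")
    if (nrow(used) == 0) rlang::abort("no observations inside the AD")
  }

  missing <- is.na(used$pred_lc50)
  agree <- qualitative_agreement(used$exp_lc50, used$pred_lc50)
  n_correct <- sum(agree, na.rm = TRUE)
  n_incorrect <- sum(!agree, na.rm = TRUE)
  n_missing <- sum(missing)

  cls_exp <- classify_ghs(used$exp_lc50)
  cls_pred <- classify_ghs(used$pred_lc50)

  folds <- vapply(factors, function(f) fold_accuracy(used, f), numeric(1))
  names(folds) <- paste0("fold", factors, "_pct")
  dist <- error_distribution(used)
  use <- usable_pairs(used)

  tibble::tibble(
    tool = if ("tool" %in% names(pairs)) pairs$tool[[1]] else NA_character_,
    endpoint = if ("endpoint" %in% names(pairs)) pairs$endpoint[[1]] else NA_character_,
    scope = scope,
    n_all = n_all,
    n_used = nrow(used),
    n_missing = n_missing,
    n_inside_ad = n_inside,
    n_correct = n_correct,
    n_incorrect = n_incorrect,
    total_accuracy_pct = total_accuracy(n_correct, nrow(used), n_missing),
    predictive_power_pct = if (scope == "entire") {
      predictive_power(n_correct, n_all)
    } else {
      NA_real_
    },
    !!!as.list(folds),
    r2_class = r_squared(as.numeric(cls_exp), as.numeric(cls_pred)),
    r2_log10 = r_squared(
      replace(log10(used$exp_lc50), !use, NA_real_),
      replace(rep(NA_real_, nrow(used)), use, log10(used$pred_lc50[use]))
    ),
    rmse_log10 = rmse_log10(used),
    error_mean = dist$mean,
    error_sd = dist$sd,
    error_n = dist$n
  )
}
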