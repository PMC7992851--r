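#' @keywords internal
consolidated <- function(lc50 = NA_real_, ad_status = "unknown",
                         provenance = NA_character_) {
  tibble::tibble(lc50 = lc50, ad_status = ad_status, provenance = provenance)
}

#' Select the experimental value used for validation
#'
#' When several experimental LC50 values exist for one chemical the lowest
#' reasonable value is used (conservative, worst-case).
#'
#' @param values numeric vector of positive LC50 values, mg/L.
#' @return the minimum value.
#' @examples
#' select_experimental(c(5.3, 83, 542))
#' @export
select_experimental <- function(values) {
  if (length(values) == 0) rlang::abort("`values` must be non-empty")
  if (any(!is.finite(values) | values <= 0)) {
    rlang::abort("all experimental values must be positive")
  }
  min(values)
}

#' Consolidate KATE multi-class output
#'
#' KATE can match a chemical to several structural classes; the lowest
#' predicted value is used for validation.
#'
#' @param values numeric vector of predicted LC50 values (may be empty).
#' @param ad_status AD flag to attach to the result.
#' @return one-row tibble `lc50`, `ad_status`, `provenance`; missing value
#'   when `values` is empty.
#' @export
consolidate_kate <- function(values, ad_status = "unknown") {
  if (length(values) == 0) return(consolidated(ad_status = ad_status))
  consolidated(min(values), ad_status, "KATE: lowest of matched classes")
}

#' Consolidate Danish QSAR Database output
#'
#' The Battery estimate combines the component model systems and is used
#' first; without it, the lower (more toxic) of the Leadscope and SciQSAR
#' estimates is selected.
#'
#' @param battery,leadscope,sciqsar optional LC50 values, mg/L (`NA` or
#'   `NULL` = not given).
#' @param ad_status AD flag to attach.
#' @return one-row tibble `lc50`, `ad_status`, `provenance`.
#' @examples
#' consolidate_danish(NA, 0.00636, 354065) # Leadscope wins
#' @export
consolidate_danish <- function(battery = NA, leadscope = NA, sciqsar = NA,
                               ad_status = "unknown") {
  battery <- battery %||% NA_real_
  leadscope <- leadscope %||% NA_real_
  sciqsar <- sciqsar %||% NA_real_
  if (!is.na(battery)) {
    return(consolidated(battery, ad_status, "Danish: battery"))
  }
  rest <- c(leadscope = leadscope, sciqsar = sciqsar)
  rest <- rest[!is.na(rest)]
  if (length(rest) == 0) return(consolidated(ad_status = ad_status))
  consolidated(min(rest), ad_status,
               paste0("Danish: lowest of ", paste(names(rest), collapse = "/")))
}

#' Consolidate T.E.S.T. consensus output
#'
#' The consensus value averages the component QSAR methodologies and is
#' only reliable when at least two methods contributed; with fewer the
#' prediction is discarded. A usable consensus value is by definition
#' inside the applicability domain.
#'
#' @param consensus consensus LC50, mg/L, or `NA`.
#' @param n_contributing_methods number of methods behind the consensus.
#' @return one-row tibble `lc50`, `ad_status`, `provenance`.
#' @export
consolidate_test <- function(consensus, n_contributing_methods) {
  if (n_contributing_methods < 0) rlang::abort("negative method count")
  if (is.na(consensus) || n_contributing_methods < 2) {
    return(consolidated(ad_status = "unknown"))
  }
  consolidated(consensus, "inside",
               paste0("TEST: consensus of ", n_contributing_methods, " methods"))
}

#' Consolidate ECOSAR multi-class output
#'
#' ECOSAR reports one estimate per matched structural class and medium;
#' only freshwater estimates are used, and across classes the minimum
#' (most conservative) value is taken by default.
#'
#' @param class_predictions tibble with columns `class_name`, `medium`
#'   (`"fresh"` or `"salt"`), `lc50`.
#' @param resolution `"min"` (default) or `"first"` (first listed class).
#' @param ad_status AD flag to attach.
#' @return one-row tibble `lc50`, `ad_status`, `provenance`.
#' @export
consolidate_ecosar <- function(class_predictions,
                               resolution = c("min", "first"),
                               ad_status = "unknown") {
  resolution <- rlang::arg_match(resolution)
  if (is.null(class_predictions) || nrow(class_predictions) == 0) {
    return(consolidated(ad_status = ad_status))
  }
  fresh <- class_predictions[class_predictions$medium %in%
                               c("fresh", "freshwater"), ]
  if (nrow(fresh) == 0) return(consolidated(ad_status = ad_status))
  i <- if (resolution == "min") which.min(fresh$lc50) else 1L
  consolidated(fresh$lc50[i], ad_status,
               paste0("ECOSAR: ", resolution, " freshwater class '",
                      fresh$class_name[i], "'"))
}

# band lower limits in mg/L for GHS-like classes 1-4
ghs_band_lower <- c(0, 1, 10, 100)

class_to_value <- function(tox_class, offset = 0.1) {
  code <- suppressWarnings(
    as.integer(sub("^.*?(\\d)$", "\\1", as.character(tox_class)))
  )
  if (any(is.na(code) | code < 1 | code > 4)) {
    rlang::abort("`tox_class` must end in a band code 1-4, e.g. 'toxic-3'")
  }
  ghs_band_lower[code] + offset
}

#' Integrated selection across multi-model output
#'
#' Implements the stepwise strategy for combining several sub-models each
#' reporting a reliability score (0-3 stars) and an Applicability Domain
#' Index (ADI, 0-1 global plus similarity / accuracy / concordance /
#' fragment sub-indices):
#'
#' 1. a single model with 3 stars and every ADI equal to 1 wins outright;
#' 2. otherwise the model with the highest global ADI wins;
#' 3. ties are broken by comparing the sub-indices lexicographically in
#'    the order similarity, accuracy, concordance, fragment coverage;
#' 4. if all indices tie, the lowest (most toxic) LC50 is used.
#'
#' Classification-only sub-models are converted to a value at the lower
#' limit of their toxicity band plus 0.1 mg/L (e.g. the 10-100 mg/L band
#' becomes 10.1 mg/L). The winning prediction is flagged inside the AD
#' when its reliability is good (`stars >= star_threshold`).
#'
#' @param models tibble with columns `model_name`, `output_kind`
#'   (`"value"`/`"class"`), `lc50`, `tox_class`, `reliability_stars`,
#'   `adi_global`, `adi_similarity`, `adi_accuracy`, `adi_concordance`,
#'   `adi_acf`.
#' @param star_threshold minimum stars deemed "good reliability".
#' @return one-row tibble `lc50`, `ad_status`, `provenance`.
#' @export
vega_integrate <- function(models, star_threshold = 2) {
  if (is.null(models) || nrow(models) == 0) {
    rlang::abort("`models` must contain at least one model output")
  }
  stopifnot(all(models$reliability_stars %in% 0:3))
  adi_cols <- c("adi_global", "adi_similarity", "adi_accuracy",
                "adi_concordance", "adi_acf")
  adi <- as.matrix(models[adi_cols])
  if (any(adi < 0 | adi > 1, na.rm = TRUE)) {
    rlang::abort("all ADI values must lie in [0, 1]")
  }

  value_of <- function(i) {
    if (models$output_kind[i] == "class") {
      class_to_value(models$tox_class[i])
    } else {
      models$lc50[i]
    }
  }

  perfect <- which(models$reliability_stars == 3 &
                     rowSums(adi == 1) == ncol(adi))
  if (length(perfect) == 1) {
    win <- perfect
    why <- "step 2: 3 stars with all ADI = 1"
  } else {
    cand <- seq_len(nrow(models))
    cand <- cand[models$adi_global[cand] == max(models$adi_global[cand])]
    if (length(cand) == 1) {
      win <- cand
      why <- "step 3: highest global ADI"
    } else {
      # step 4: lexicographic on the sub-indices, listed order
      for (col in c("adi_similarity", "adi_accuracy", "adi_concordance",
                    "adi_acf")) {
        if (length(cand) == 1) break
        cand <- cand[models[[col]][cand] == max(models[[col]][cand])]
      }
      if (length(cand) == 1) {
        win <- cand
        why <- "step 4: sub-index comparison"
      } else {
        vals <- vapply(cand, value_of, numeric(1))
        win <- cand[which.min(vals)]
        why <- "tie: lowest toxicity value"
      }
    }
  }

  lc50 <- value_of(win)
  if (models$output_kind[win] == "class") {
    why <- paste0(why, "; class '", models$tox_class[win],
                  "' transformed to band lower limit + 0.1")
  }
  consolidated(
    lc50,
    ifelse(models$reliability_stars[win] >= star_threshold,
           "inside", "outside"),
    paste0(models$model_name[win], " (", why, ")")
  )
}
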