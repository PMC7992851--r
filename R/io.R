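#' Tools covered by the benchmark fixtures
#' @export
ecotox_tools <- c(
  "ECOSAR", "TEST", "DANISH", "VEGA", "READ_ACROSS", "TREND_ANALYSIS", "KATE"
)

#' Path to a packaged fixture
#'
#' @param name one of `"pcc_daphnia"`, `"pcc_fish"`, `"ghs_criteria"`,
#'   `"solubility"`, `"reference_summary"`.
#' @return path to the installed CSV file.
#' @export
ecotox_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".csv"), package = "ecotoxeval")
  if (path == "") rlang::abort(paste0("no packaged fixture named '", name, "'"))
  path
}

ad_levels <- c("inside", "outside", "unknown")

parse_ad <- function(x) {
  out <- dplyr::case_match(
    trimws(x),
    "In" ~ "inside",
    "Out" ~ "outside",
    .default = "unknown"
  )
  out[is.na(x)] <- "unknown"
  out
}

format_ad <- function(x) {
  dplyr::case_match(x, "inside" ~ "In", "outside" ~ "Out", .default = "")
}

parse_numeric_cell <- function(x, column, path) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "NA" & x != "" & is.na(out))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "non-numeric value '", x[bad[1]], "' in column '", column,
      "', row ", bad[1], " of ", path
    ))
  }
  out
}

#' Read a prediction table
#'
#' Reads a wide CSV with one row per chemical: columns `cas`, `name`,
#' `exp_lc50`, then for each tool a value column and an `_ad` column
#' holding `"In"`/`"Out"` (empty = unknown), plus an optional free-text
#' `note` column for transcription ambiguities. Empty or `NA` value cells
#' become missing predictions.
#'
#' @param path CSV file path.
#' @param endpoint endpoint label attached to the records.
#' @return list with `experimental` (tibble: cas, name, endpoint, lc50)
#'   and `predictions` (long tibble: cas, tool, endpoint, lc50, ad_status).
#' @examples
#' pcc <- load_predictions(ecotox_fixture("pcc_daphnia"), "daphnia_48h")
#' nrow(pcc$experimental)
#' @export
load_predictions <- function(path, endpoint = c("daphnia_48h", "fish_96h")) {
  endpoint <- rlang::arg_match(endpoint)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  required <- c("cas", "name", "exp_lc50")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    rlang::abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  tools <- intersect(ecotox_tools, names(raw))
  if (length(tools) == 0) rlang::abort("no known tool columns found")
  unknown <- setdiff(
    names(raw),
    c(required, "note", tools, paste0(tools, "_ad"))
  )
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "unknown column(s): ", paste(unknown, collapse = ", "),
      "; known tools are ", paste(ecotox_tools, collapse = ", ")
    ))
  }
  if (any(raw$cas == "" | is.na(raw$cas))) {
    rlang::abort(paste0("empty cas in ", path))
  }
  if (anyDuplicated(raw$cas) > 0) {
    rlang::abort(paste0("duplicated cas '", raw$cas[duplicated(raw$cas)][1],
                        "' in ", path))
  }

  experimental <- tibble::tibble(
    cas = raw$cas,
    name = raw$name,
    endpoint = endpoint,
    lc50 = parse_numeric_cell(raw$exp_lc50, "exp_lc50", path)
  )
  if (nrow(experimental) > 0 &&
      any(!is.finite(experimental$lc50) | experimental$lc50 <= 0)) {
    rlang::abort(paste0("non-positive experimental LC50 in ", path))
  }

  predictions <- purrr::map_dfr(tools, function(tl) {
    ad_col <- paste0(tl, "_ad")
    lc50 <- parse_numeric_cell(raw[[tl]], tl, path)
    ad <- if (ad_col %in% names(raw)) parse_ad(raw[[ad_col]]) else "unknown"
    tibble::tibble(
      cas = raw$cas,
      tool = tl,
      endpoint = endpoint,
      lc50 = lc50,
      ad_status = ad,
      note = if ("note" %in% names(raw)) raw$note else ""
    )
  })
  list(experimental = experimental, predictions = predictions)
}

#' Write a prediction table
#'
#' Inverse of [load_predictions()]: lays the long prediction tibble back
#' out as the wide one-row-per-chemical CSV. Values and AD flags
#' round-trip exactly.
#'
#' @param data list with `experimental` and `predictions` as returned by
#'   [load_predictions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(data, path) {
  preds <- data$predictions
  wide <- data$experimental["cas"]
  wide$name <- data$experimental$name
  wide$exp_lc50 <- data$experimental$lc50
  for (tool in intersect(ecotox_tools, unique(preds$tool))) {
    sub <- preds[preds$tool == tool, ]
    idx <- match(wide$cas, sub$cas)
    wide[[tool]] <- sub$lc50[idx]
    wide[[paste0(tool, "_ad")]] <- format_ad(sub$ad_status[idx])
  }
  if ("note" %in% names(preds)) {
    sub <- preds[preds$tool == preds$tool[1], ]
    wide$note <- sub$note[match(wide$cas, sub$cas)]
  }
  readr::write_csv(wide, path, na = "NA")
  invisible(path)
}

#' Join experimental values to predictions
#'
#' @param data list as returned by [load_predictions()].
#' @return long tibble of paired observations: `cas`, `tool`, `endpoint`,
#'   `exp_lc50`, `pred_lc50`, `ad_status`.
#' @export
paired_observations <- function(data) {
  dplyr::inner_join(
    dplyr::rename(data$experimental, exp_lc50 = "lc50"),
    dplyr::rename(data$predictions, pred_lc50 = "lc50"),
    by = c("cas", "endpoint")
  )
}

round_half_up <- function(x, digits = 0) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}

#' Write evaluation reports as a summary table
#'
#' Lays reports out tool-per-column, metric-per-row, in the shape of the
#' printed benchmark tables. Percentages are rounded half-up to integers,
#' RMSE and R-squared to two decimals; full precision is kept internally
#' and only presentation is rounded.
#'
#' @param reports tibble of evaluation reports (rows from
#'   [evaluate_tool()]), one tool each, same endpoint and scope.
#' @param path output CSV path.
#' @return the formatted tibble, invisibly.
#' @export
write_report <- function(reports, path) {
  if (is.null(reports) || nrow(reports) == 0) {
    rlang::abort("`reports` must be non-empty")
  }
  fmt_int <- function(x) ifelse(is.na(x), "NA", sprintf("%d", as.integer(x)))
  fmt_pct <- function(x) ifelse(is.na(x), "NA",
                                sprintf("%d", as.integer(round_half_up(x))))
  fmt_2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

  rows <- list(
    c("Number of inside AD", fmt_int(reports$n_inside_ad)),
    c("Number of missing predictions", fmt_int(reports$n_missing)),
    c("Number of correct", fmt_int(reports$n_correct)),
    c("Number of incorrect", fmt_int(reports$n_incorrect)),
    c("Total accuracy (%)", fmt_pct(reports$total_accuracy_pct)),
    c("Predictive power (%)", fmt_pct(reports$predictive_power_pct)),
    c("R2 (toxicity class)", fmt_2(reports$r2_class)),
    c("Accuracy within a factor of 10 (%)", fmt_pct(reports$fold10_pct)),
    c("Accuracy within a factor of 100 (%)", fmt_pct(reports$fold100_pct)),
    c("Accuracy within a factor of 1000 (%)", fmt_pct(reports$fold1000_pct)),
    c("RMSE (log10 scale)", fmt_2(reports$rmse_log10)),
    c("R2 (log10 LC50)", fmt_2(reports$r2_log10))
  )
  out <- tibble::as_tibble(
    stats::setNames(
      as.data.frame(do.call(rbind, lapply(rows, function(r) r[-1]))),
      reports$tool
    )
  )
  out <- dplyr::bind_cols(
    tibble::tibble(metric = vapply(rows, `[[`, character(1), 1)), out
  )
  readr::write_csv(out, path)
  invisible(out)
}
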