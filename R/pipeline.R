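#' Evaluation run configuration
#'
#' Collects inputs, tool list, scopes and mode flags for a full
#' evaluation run. Paths default to the packaged benchmark fixtures;
#' pass `NULL` for an endpoint to skip it.
#'
#' @param daphnia,fish paths to wide prediction CSVs (see
#'   [load_predictions()]), or `NULL` to skip the endpoint.
#' @param scopes evaluation scopes, subset of `c("entire", "inside_ad")`.
#' @param tools tool columns to evaluate.
#' @param factors fold factors for quantitative accuracy.
#' @param out_dir directory for the report CSVs.
#' @param seed integer seed for synthetic subcommands.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(daphnia = ecotox_fixture("pcc_daphnia"),
                       fish = ecotox_fixture("pcc_fish"),
                       scopes = c("entire", "inside_ad"),
                       tools = ecotox_tools,
                       factors = c(10, 100, 1000),
                       out_dir = tempdir(),
                       seed = 1L) {
  scopes <- match.arg(scopes, c("entire", "inside_ad"), several.ok = TRUE)
  if (is.null(daphnia) && is.null(fish)) {
    rlang::abort("at least one endpoint input is required")
  }
  bad <- setdiff(tools, ecotox_tools)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown tool(s): ", paste(bad, collapse = ", "),
                        "; known tools are ",
                        paste(ecotox_tools, collapse = ", ")))
  }
  structure(
    list(daphnia = daphnia, fish = fish, scopes = scopes, tools = tools,
         factors = factors, out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

config_inputs <- function(config) {
  inputs <- list(daphnia_48h = config$daphnia, fish_96h = config$fish)
  inputs[!vapply(inputs, is.null, logical(1))]
}

#' Evaluate every tool in a loaded dataset
#'
#' @param data list as returned by [load_predictions()].
#' @param scope `"entire"` or `"inside_ad"`.
#' @param tools tools to evaluate.
#' @param factors fold factors.
#' @return tibble of evaluation reports, one row per tool.
#' @export
evaluate_dataset <- function(data, scope = "entire", tools = ecotox_tools,
                             factors = c(10, 100, 1000)) {
  pairs <- paired_observations(data)
  purrr::map_dfr(tools, function(t) {
    evaluate_tool(dplyr::filter(pairs, .data$tool == t), scope = scope,
                  factors = factors)
  })
}

#' Run the full benchmark evaluation
#'
#' For each configured endpoint and scope, evaluates every tool and
#' writes one summary CSV laid out like the printed benchmark tables
#' (tool per column, metric per row).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `reports` (all evaluation rows) and
#'   `files` (paths written).
#' @export
run_evaluation <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  inputs <- config_inputs(config)
  all_reports <- list()
  files <- character(0)
  for (ep in names(inputs)) {
    data <- load_predictions(inputs[[ep]], endpoint = ep)
    for (scope in config$scopes) {
      reports <- evaluate_dataset(data, scope = scope, tools = config$tools,
                                  factors = config$factors)
      path <- file.path(config$out_dir,
                        sprintf("summary_%s_%s.csv", ep, scope))
      write_report(reports, path)
      files <- c(files, path)
      all_reports[[paste(ep, scope, sep = "_")]] <- reports
    }
  }
  invisible(list(reports = dplyr::bind_rows(all_reports), files = files))
}

#' Per-tool signed error distribution summary
#'
#' One row per tool and endpoint with the mean, standard deviation and
#' count of `log10(pred) - log10(exp)` (positive = toxicity
#' underestimated), as displayed alongside the error histograms.
#'
#' @param config a [run_config()].
#' @param write whether to also write `error_distribution_<endpoint>.csv`
#'   files to the configured output directory.
#' @return tibble with columns `endpoint`, `tool`, `mean`, `sd`, `n`.
#' @export
run_distribution_summary <- function(config = run_config(), write = FALSE) {
  stopifnot(inherits(config, "run_config"))
  inputs <- config_inputs(config)
  out <- purrr::map_dfr(names(inputs), function(ep) {
    data <- load_predictions(inputs[[ep]], endpoint = ep)
    pairs <- paired_observations(data)
    purrr::map_dfr(config$tools, function(t) {
      dplyr::bind_cols(
        tibble::tibble(endpoint = ep, tool = t),
        error_distribution(dplyr::filter(pairs, .data$tool == t))
      )
    })
  })
  if (write) {
    if (!dir.exists(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE)
    }
    for (ep in unique(out$endpoint)) {
      readr::write_csv(out[out$endpoint == ep, ],
                       file.path(config$out_dir,
                                 sprintf("error_distribution_%s.csv", ep)))
    }
  }
  out
}

#' GHS category distribution of experimental values
#'
#' @param experimental tibble with a positive `lc50` column.
#' @return tibble with one row per GHS category present: `class`,
#'   `label`, `n`, `pct`.
#' @export
category_distribution <- function(experimental) {
  cls <- classify_ghs(experimental$lc50)
  tab <- table(factor(cls, levels = 1:4))
  tibble::tibble(
    class = 1:4,
    label = ghs_label(1:4),
    n = as.integer(tab),
    pct = 100 * as.integer(tab) / length(cls)
  )
}

#' The benchmark's printed summary statistics
#'
#' @return long tibble of the published per-tool summary values:
#'   `endpoint`, `scope`, `tool`, `metric`, `value`.
#' @export
load_reference_summary <- function() {
  readr::read_csv(ecotox_fixture("reference_summary"),
                  col_types = readr::cols(
                    endpoint = "c", scope = "c", tool = "c",
                    metric = "c", value = "d"
                  ))
}

#' Compare recomputed summaries with the printed reference
#'
#' Joins evaluation reports recomputed from the fixtures against the
#' published summary tables, cell by cell, and flags each cell as inside
#' or outside tolerance. Counts carry a tolerance of one chemical;
#' percentages three points (one chemical out of ~33); unit-scale values
#' (R-squared, RMSE) 0.1, the movement a single-chemical perturbation
#' induces at this dataset size. The function never hides a discrepancy:
#' every compared cell is returned with its deviation.
#'
#' @param reports tibble of evaluation reports (all endpoints/scopes),
#'   with `endpoint`, `scope`, `tool` and metric columns.
#' @param reference long reference tibble, by default the packaged one.
#' @param count_tol,pct_tol,value_tol tolerances per metric family; one
#'   chemical out of the smallest evaluated subset (~25) is 4 points.
#' @return tibble with `endpoint`, `scope`, `tool`, `metric`, `computed`,
#'   `reference`, `deviation`, `tolerance`, `within`.
#' @export
compare_to_reference <- function(reports,
                                 reference = load_reference_summary(),
                                 count_tol = 1, pct_tol = 4,
                                 value_tol = 0.1) {
  long <- tidyr::pivot_longer(
    reports[c("endpoint", "scope", "tool", "n_missing", "n_inside_ad",
              "n_correct", "n_incorrect", "total_accuracy_pct",
              "predictive_power_pct", "fold10_pct", "fold100_pct",
              "fold1000_pct", "r2_class", "r2_log10", "rmse_log10")],
    cols = -c("endpoint", "scope", "tool"),
    names_to = "metric", values_to = "computed"
  )
  merged <- dplyr::inner_join(
    reference, long, by = c("endpoint", "scope", "tool", "metric")
  )
  tol <- dplyr::case_when(
    grepl("^n_", merged$metric) ~ count_tol,
    grepl("_pct$", merged$metric) ~ pct_tol,
    TRUE ~ value_tol
  )
  dplyr::mutate(
    dplyr::rename(merged, reference = "value"),
    deviation = .data$computed - .data$reference,
    tolerance = tol,
    within = !is.na(.data$computed) &
      abs(.data$computed - .data$reference) <= tol
  )
}
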