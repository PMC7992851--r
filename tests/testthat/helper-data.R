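# small builders shared across tests

make_pairs <- function(exp_lc50, pred_lc50,
                       ad_status = rep("inside", length(exp_lc50)),
                       tool = "TOOL", endpoint = "daphnia_48h") {
  tibble::tibble(
    cas = sprintf("C-%03d", seq_along(exp_lc50)),
    tool = tool,
    endpoint = endpoint,
    exp_lc50 = exp_lc50,
    pred_lc50 = pred_lc50,
    ad_status = ad_status
  )
}

make_target <- function(cas = "T-1", log_kow = 2,
                        functional_groups = "aryl;phenol") {
  list(cas = cas, log_kow = log_kow, functional_groups = functional_groups)
}

make_analogues <- function(log_kow, lc50, groups = "aryl;phenol",
                           cas = sprintf("A-%03d", seq_along(log_kow))) {
  tibble::tibble(
    cas = cas,
    name = cas,
    log_kow = log_kow,
    groups = groups,
    lc50 = lc50,
    source_db = "test"
  )
}

load_benchmark <- function(endpoint = c("daphnia_48h", "fish_96h")) {
  endpoint <- match.arg(endpoint)
  fixture <- if (endpoint == "daphnia_48h") "pcc_daphnia" else "pcc_fish"
  load_predictions(ecotox_fixture(fixture), endpoint)
}
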