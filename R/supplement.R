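#' Summary statistics from a printed catalog summary table
#'
#' Computes per-batch averages (mean herbs per prescription, mean triplets
#' per prescription) from a catalog summary table of printed counts, such as
#' the one shipped at `system.file("extdata", "acfp_catalog_summary.csv",
#' package = "pccmm")` for the two government catalog batches.
#'
#' @param path CSV with columns `batch`, `selected_prescriptions`,
#'   `total_cmm_occurrences`, `total_pccmm_occurrences` (extra columns are
#'   kept), or a data frame in that shape.
#' @return The table with added columns `mean_cmms_per_prescription` and
#'   `mean_pccmms_per_prescription`.
#' @export
catalog_summary_stats <- function(path = system.file("extdata", "acfp_catalog_summary.csv",
                                    package = "pccmm"
                                  )) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  needed <- c("batch", "selected_prescriptions", "total_cmm_occurrences")
  if (!all(needed %in% names(df))) {
    stop("summary table needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  df$mean_cmms_per_prescription <- df$total_cmm_occurrences / df$selected_prescriptions
  if ("total_pccmm_occurrences" %in% names(df)) {
    df$mean_pccmms_per_prescription <-
      df$total_pccmm_occurrences / df$selected_prescriptions
  }
  df
}

#' Checklist against the full reference tables
#'
#' Runs the pipeline on user-supplied full-scale input tables (a complete
#' monograph table, formula catalog, incompatible pairs, and optional
#' syndrome labels -- none of which are bundled with the package) and
#' returns the headline quantities for comparison with published values:
#' matrix shape and nonzero count, batch-average max-Jaccard at omega1 = 0.5
#' (weighted), high-frequency item selections, rule counts at the standard
#' thresholds, the strongest item correlations, and (when labels are given)
#' the bootstrap classification accuracies on both encodings.
#'
#' This is deliberately a reporting function, not a test: it needs external
#' reference data and can take tens of minutes at full scale.
#'
#' @param cmm_table,catalog,pairs Paths or parsed objects for the three
#'   inputs.
#' @param labels Optional data frame with columns `formula_id`, `syndrome`.
#' @param omega1 Reconstruction weight for the rebuild check.
#' @param seed Seed for the stochastic stages.
#' @param cap Pool cap for the rebuild check.
#' @param trials Bootstrap trials.
#' @return A named list of computed quantities.
#' @export
supplement_checks <- function(cmm_table, catalog, pairs = NULL, labels = NULL,
                              omega1 = 0.5, seed = 1L, cap = 15000L,
                              trials = 5000L) {
  records <- if (inherits(cmm_table, "pcmm_table")) cmm_table else parse_cmm_table(cmm_table)
  spaces <- build_spaces(records)
  P <- build_pccmm_matrix(records, spaces)
  Q <- if (is.null(pairs)) {
    NULL
  } else if (inherits(pairs, "incompatible_pairs")) {
    pairs
  } else {
    load_incompatible_pairs(pairs, spaces)
  }
  cat_obj <- if (inherits(catalog, "formula_catalog")) {
    catalog
  } else {
    parse_formula_catalog(catalog, spaces)
  }
  out <- list(
    N = spaces$N, m = spaces$m, nnz = Matrix::nnzero(P),
    density = Matrix::nnzero(P) / (spaces$N * spaces$m),
    n_formulas = nrow(cat_obj),
    mean_formula_size = mean(lengths(cat_obj$cmm_ids)),
    n_pairs = if (is.null(Q)) 0L else nrow(Q)
  )
  rebuild <- rebuild_catalog(cat_obj, P, spaces,
    pairs = Q, omega1_grid = omega1,
    modes = "weighted", cap = cap
  )
  out$avg_max_jaccard <- rebuild$summary
  tx_cmm <- catalog_transactions(cat_obj, "cmm")
  tx_pccmm <- catalog_transactions(cat_obj, "pccmm", P = P, spaces = spaces)
  freq_cmm <- item_frequency(tx_cmm)
  freq_pccmm <- item_frequency(tx_pccmm)
  hf_cmm <- high_frequency_items(freq_cmm, 10L)
  hf_pccmm <- high_frequency_items(freq_pccmm, 50L)
  out$high_freq_cmm <- list(
    n = length(hf_cmm$items),
    cumulative_pct = 100 * hf_cmm$cumulative_proportion
  )
  out$high_freq_pccmm <- list(
    n = length(hf_pccmm$items),
    cumulative_pct = 100 * hf_pccmm$cumulative_proportion
  )
  out$n_rules_cmm <- nrow(mine_rules(tx_cmm))
  out$n_rules_pccmm <- nrow(mine_rules(tx_pccmm))
  if (length(hf_cmm$items) >= 2L) {
    R <- phi_correlation_matrix(tx_cmm, hf_cmm$items)
    diag(R) <- NA
    out$max_cmm_correlation <- max(R, na.rm = TRUE)
  }
  if (length(hf_pccmm$items) >= 2L) {
    R <- phi_correlation_matrix(tx_pccmm, hf_pccmm$items)
    diag(R) <- NA
    out$max_pccmm_correlation <- max(R, na.rm = TRUE)
  }
  if (!is.null(labels)) {
    lab <- labels[match(cat_obj$formula_id, labels$formula_id), "syndrome"]
    keep <- !is.na(lab) & nzchar(lab)
    sub <- cat_obj[keep, , drop = FALSE]
    X <- t(vapply(sub$cmm_ids, encode_formula, integer(spaces$N), space = spaces))
    YW <- t(apply(X, 1L, measure, P = P, weighted = TRUE))
    out$bootstrap_accuracy <- list(
      pccmm = bootstrap_classify(YW, lab[keep], trials = trials, seed = seed)$mean,
      cmm = bootstrap_classify(X, lab[keep], trials = trials, seed = seed)$mean
    )
  }
  out
}
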