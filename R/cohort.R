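# Cohort pipeline: read compositions, apply inclusion filters, simulate
# every subject with and without the PC pathway, summarize by group.

#' Read a cohort composition table
#'
#' Accepts either the molar dialect (columns `fII_uM`, `fV_nM`, `fVII_nM`,
#' `fVIII_nM`, `fIX_nM`, `fX_nM`, `AT_uM`, `TFPI_nM`, `PC_nM`) or the
#' percent-of-mean dialect (`fII_pct` ... `PC_pct`, converted through
#' [percent_to_molar()] with the physiologic means as 100%).  Mixing
#' dialects is an error.
#'
#' @param path CSV path with a `subject_id` column, the nine factor
#'   columns in one dialect, and optionally sex, age, group labels and
#'   exclusion-flag columns.
#' @return a `cohort_table` data frame in molar units.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) stop("cohort CSV needs a subject_id column")
  molar_cols <- paste0(FACTOR_NAMES, "_", FACTOR_UNITS[FACTOR_NAMES])
  pct_cols <- paste0(FACTOR_NAMES, "_pct")
  has_molar <- any(molar_cols %in% names(df))
  has_pct <- any(pct_cols %in% names(df))
  if (has_molar && has_pct)
    stop("mixed unit dialects: both *_uM/_nM and *_pct columns present")
  if (!has_molar && !has_pct)
    stop("no factor columns found (expected *_uM/_nM or *_pct)")
  if (has_pct) {
    miss <- setdiff(pct_cols, names(df))
    if (length(miss)) stop("missing percent column(s): ",
                           paste(miss, collapse = ", "))
    means <- physiologic_means()
    for (i in seq_along(FACTOR_NAMES)) {
      f <- FACTOR_NAMES[i]
      pct <- df[[paste0(f, "_pct")]]
      if (any(!is.finite(pct) | pct <= 0))
        stop("nonpositive percent value for ", f)
      df[[molar_cols[i]]] <- pct / 100 * means[[f]]
    }
    df <- df[, setdiff(names(df), pct_cols)]
  } else {
    miss <- setdiff(molar_cols, names(df))
    if (length(miss)) stop("missing factor column(s): ",
                           paste(miss, collapse = ", "))
  }
  class(df) <- c("cohort_table", "data.frame")
  attr(df, "provenance") <- list(source = path, n_read = nrow(df))
  df
}

#' Convert percent-of-mean factor levels to molar concentrations
#'
#' `concentration = percent / 100 * physiologic mean`, per factor.
#'
#' @param percent_values named numeric vector of percentages for the nine
#'   factors (`fII` ... `PC`).
#' @param mean_table named vector of physiologic means (assay units);
#'   defaults to [physiologic_means()].
#' @param subject_id id for the returned composition.
#' @return a `plasma_composition`.
#' @examples
#' pc <- percent_to_molar(setNames(rep(100, 9),
#'   c("fII","fV","fVII","fVIII","fIX","fX","AT","TFPI","PC")))
#' pc$PC_nM  # 65
#' @export
percent_to_molar <- function(percent_values, mean_table = physiologic_means(),
                             subject_id = "subject") {
  miss <- setdiff(FACTOR_NAMES, names(percent_values))
  if (length(miss)) stop("missing factor(s): ", paste(miss, collapse = ", "))
  miss2 <- setdiff(FACTOR_NAMES, names(mean_table))
  if (length(miss2)) stop("mean table missing factor(s): ",
                          paste(miss2, collapse = ", "))
  p <- percent_values[FACTOR_NAMES]
  if (any(!is.finite(p) | p <= 0)) stop("nonpositive percent value")
  conc <- p / 100 * mean_table[FACTOR_NAMES]
  suppressWarnings(plasma_composition(
    subject_id, conc[["fII"]], conc[["fV"]], conc[["fVII"]], conc[["fVIII"]],
    conc[["fIX"]], conc[["fX"]], conc[["AT"]], conc[["TFPI"]], conc[["PC"]]))
}

#' Apply the study inclusion filters
#'
#' Removes every row with any exclusion flag set (anticoagulant use, unknown
#' anticoagulant status, self-reported unconfirmed DVT/PE, superficial-only
#' venous thrombosis, insufficient sample, insufficient composition data).
#' A multiply-flagged row is removed once but tallied in each category.
#'
#' @param raw a `cohort_table` carrying the six `excl_*` logical columns.
#' @return the filtered `cohort_table`; the per-category tallies and
#'   before/after counts are in `attr(, "filter_report")`.
#' @export
apply_inclusion_filters <- function(raw) {
  miss <- setdiff(EXCLUSION_FLAGS, names(raw))
  if (length(miss)) stop("missing exclusion-flag column(s): ",
                         paste(miss, collapse = ", "))
  flags <- as.matrix(as.data.frame(lapply(raw[EXCLUSION_FLAGS], as.logical)))
  drop <- rowSums(flags, na.rm = TRUE) > 0
  out <- raw[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "provenance") <- attr(raw, "provenance")
  tallies <- colSums(flags, na.rm = TRUE)
  storage.mode(tallies) <- "integer"
  attr(out, "filter_report") <- list(
    n_before = nrow(raw), n_removed = sum(drop), n_after = nrow(out),
    category_tallies = tallies)
  out
}

cohort_row_composition <- function(row) {
  suppressWarnings(plasma_composition(
    row$subject_id, row$fII_uM, row$fV_nM, row$fVII_nM, row$fVIII_nM,
    row$fIX_nM, row$fX_nM, row$AT_uM, row$TFPI_nM, row$PC_nM,
    sex = if ("sex" %in% names(row)) row$sex else NA,
    age = if ("age" %in% names(row)) row$age else NA,
    pc_mutation = if ("pc_mutation" %in% names(row)) row$pc_mutation else NA,
    pt_g20210a = if ("pt_g20210a" %in% names(row)) row$pt_g20210a else NA,
    thrombosis_history = if ("thrombosis_history" %in% names(row))
      row$thrombosis_history else NA))
}

#' Simulate a whole cohort with and without the PC pathway
#'
#' Runs every subject twice (PC pathway on and off), computes the six
#' thrombogram parameters per run, and attaches per-parameter
#' exceeds-control flags against the mean physiologic control simulated
#' under the matching pathway setting.  Individual integration failures are
#' logged and reported; more than 10% of subjects failing aborts the run.
#'
#' @param cohort a filtered `cohort_table`.
#' @param model a `coag_model` (default the packaged model).
#' @param config a `sim_config`; its `include_pc` is overridden per arm.
#' @param keep_thrombin keep the thrombin traces (for [envelope_curves()])?
#' @param progress emit per-subject progress via `message()`?
#' @return a `cohort_metrics` data frame (two rows per subject: pathway
#'   `with_pc` / `without_pc`) with metric columns and `exceeds_*` flags.
#'   Attributes: `control` (per-pathway control metrics), `failures`,
#'   `thrombin` (per-pathway trace matrices), `time`.
#' @export
run_cohort <- function(cohort, model = default_model(), config = sim_config(),
                       keep_thrombin = TRUE, progress = FALSE) {
  stopifnot(nrow(cohort) > 0)
  arms <- c(with_pc = TRUE, without_pc = FALSE)
  ctrl <- mean_physiologic_composition()
  times <- seq(0, config$duration_s, by = config$report_interval_s)
  control <- list(); rows <- list(); failures <- list()
  thrombin <- list()
  for (arm in names(arms)) {
    cfg <- config
    cfg$include_pc <- arms[[arm]]
    ctc <- simulate_subject(model, ctrl, cfg)
    control[[arm]] <- compute_metrics(ctc)
    tr <- if (keep_thrombin)
      matrix(NA_real_, nrow(cohort), length(times),
             dimnames = list(cohort$subject_id, NULL)) else NULL
    for (i in seq_len(nrow(cohort))) {
      comp <- cohort_row_composition(cohort[i, ])
      res <- tryCatch({
        tc <- simulate_subject(model, comp, cfg)
        if (keep_thrombin) tr[i, ] <- tc$thrombin
        m <- compute_metrics(tc)
        ex <- exceeds_control(m, control[[arm]])
        cbind(as_metrics_row(m, comp$subject_id, arm),
              exceeds_CT = ex[["CT"]], exceeds_MaxL = ex[["MaxL"]],
              exceeds_MaxR = ex[["MaxR"]], exceeds_AUC = ex[["AUC"]])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(subject_id = comp$subject_id, pathway = arm,
               message = conditionMessage(res))
        warning("simulation failed for ", comp$subject_id, " (", arm, "): ",
                conditionMessage(res), call. = FALSE)
      } else rows[[length(rows) + 1L]] <- res
      if (progress && i %% 25 == 0)
        message(sprintf("[%s] %d/%d subjects", arm, i, nrow(cohort)))
    }
    if (keep_thrombin) thrombin[[arm]] <- tr
  }
  if (length(failures) > 0.1 * nrow(cohort) * 2)
    stop("more than 10% of subject simulations failed (",
         length(failures), " failures)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_metrics", "data.frame")
  attr(out, "control") <- control
  attr(out, "failures") <- failures
  attr(out, "thrombin") <- thrombin
  attr(out, "time") <- times
  out
}

#' Group-stratified summary of thrombogram parameters
#'
#' Mean (SD) and n of clot time, maximum rate, maximum level and AUC per
#' group of the chosen stratifier, overall and (optionally) within each sex
#' stratum; layout matches the grouped summary tables of this model
#' lineage's cohort studies.  The `p_value` column is left `NA` for
#' [lrt_group_effect()] to fill.
#'
#' @param metrics a `cohort_metrics` table from [run_cohort()].
#' @param cohort the matching `cohort_table` (provides labels and sex).
#' @param stratifier `"pc_mutation"`, `"pt_g20210a"` or
#'   `"thrombosis_history"`.
#' @param by_sex also summarize within the F and M strata?
#' @param pathway which simulation arm to summarize.
#' @param metric_cols metric columns to summarize.
#' @return long-format data frame: stratifier, stratum, group, n, metric,
#'   mean, sd, p_value.
#' @export
summarize_groups <- function(metrics, cohort,
                             stratifier = c("pc_mutation", "pt_g20210a",
                                            "thrombosis_history"),
                             by_sex = FALSE, pathway = "with_pc",
                             metric_cols = c("CT_s", "MaxR_nM_per_s",
                                             "MaxL_nM", "AUC_uM_s")) {
  stratifier <- match.arg(stratifier)
  if (!stratifier %in% names(cohort)) stop("cohort lacks label column ",
                                           stratifier)
  df <- merge(metrics[metrics$pathway == pathway, ],
              cohort[, c("subject_id", stratifier,
                         intersect("sex", names(cohort)))],
              by = "subject_id")
  strata <- list(all = rep(TRUE, nrow(df)))
  if (by_sex) {
    strata$F <- df$sex == "F"
    strata$M <- df$sex == "M"
  }
  groups <- sort(unique(stats::na.omit(df[[stratifier]])))
  out <- list()
  for (s in names(strata)) for (g in groups) {
    sel <- strata[[s]] & !is.na(df[[stratifier]]) & df[[stratifier]] == g
    n <- sum(sel)
    for (mc in metric_cols) {
      v <- df[[mc]][sel]
      v <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.frame(
        stratifier = stratifier, stratum = s, group = g, n = n, metric = mc,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) sd(v) else NA_real_,
        p_value = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(stratifier = character(0), stratum = character(0),
                      group = character(0), n = integer(0),
                      metric = character(0), mean = numeric(0),
                      sd = numeric(0), p_value = numeric(0)))
  do.call(rbind, out)
}

#' Pointwise mean and SD thrombin envelopes per group
#'
#' @param traces matrix of thrombin traces (subjects x time points) on a
#'   common grid, e.g. `attr(run_cohort(...), "thrombin")$with_pc`.
#' @param groups per-subject group labels (length `nrow(traces)`).
#' @param time time grid (defaults to 1 s from 0).
#' @param control optional control trace to append as group `"control"`.
#' @return long data frame: time_s, group, mean_nM, sd_nM.
#' @export
envelope_curves <- function(traces, groups, time = NULL, control = NULL) {
  stopifnot(is.matrix(traces), length(groups) == nrow(traces))
  if (is.null(time)) time <- seq_len(ncol(traces)) - 1
  if (length(time) != ncol(traces)) stop("grid mismatch")
  if (!is.null(control) && length(control) != ncol(traces))
    stop("grid mismatch for control trace")
  out <- list()
  for (g in sort(unique(stats::na.omit(groups)))) {
    m <- traces[!is.na(groups) & groups == g, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      time_s = time, group = g, mean_nM = colMeans(m),
      sd_nM = apply(m, 2, sd), stringsAsFactors = FALSE)
  }
  if (!is.null(control))
    out[[length(out) + 1L]] <- data.frame(
      time_s = time, group = "control", mean_nM = as.numeric(control),
      sd_nM = 0, stringsAsFactors = FALSE)
  do.call(rbind, out)
}

#' Write a cohort metrics table to CSV
#'
#' Empty `CT_s` cells encode a clot time that was never reached.
#'
#' @param metrics a `cohort_metrics` data frame.
#' @param path output CSV path.
#' @export
write_metrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}
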