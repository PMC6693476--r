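# Treatment-adjusted and treatment-stratified analyses: does the disease
# signature survive adjustment for therapy, and which probes show effects
# only in treated or only in untreated patients?

#' Treatment-adjusted differential methylation scan
#'
#' Re-runs the DMS model with treatment indicator covariates (constant
#' columns are dropped with a warning) and reports the Pearson correlation
#' between adjusted and unadjusted effects over the supplied call set.
#'
#' @inheritParams run_dms_scan
#' @param treatments character vector of treatment columns to adjust for
#'   (default all three flags).
#' @param dms probe ids over which to compute the effect concordance
#'   (default: all probes).
#' @return list: `records` (adjusted scan), `unadjusted` (plain scan
#'   records), `concordance` (Pearson r of the two effect vectors).
#' @export
ewas_treatment_adjusted <- function(m, sheet, cells = NULL, alpha = 0.05,
                                    case = "MCTD", control = "CTRL",
                                    treatments = TREATMENT_COLS,
                                    dms = NULL) {
  extra <- sheet[, treatments, drop = FALSE]
  adj <- run_dms_scan(m, sheet, cells, alpha, case, control, extra = extra)
  unadj <- run_dms_scan(m, sheet, cells, alpha, case, control)
  ids <- if (is.null(dms)) adj$records$probe_id else dms
  a <- adj$records$effect[match(ids, adj$records$probe_id)]
  u <- unadj$records$effect[match(ids, unadj$records$probe_id)]
  ok <- !is.na(a) & !is.na(u)
  list(records = adj$records, unadjusted = unadj$records,
       threshold = adj$threshold,
       concordance = stats::cor(a[ok], u[ok]))
}

#' Treatment-stratified differential methylation
#'
#' Fits the EWAS model separately in treated cases + controls and untreated
#' cases + controls (controls are shared by both strata), restricted to a
#' call set.
#'
#' @inheritParams run_dms_scan
#' @param treatment one of "steroid", "antimalarial", "immunosuppressant".
#' @param calls probe ids to evaluate (typically the DMS set); NULL = all.
#' @param min_stratum minimum number of cases required per stratum
#'   (default 3).
#' @return data.frame per probe: treated_effect, treated_p,
#'   untreated_effect, untreated_p, plus stratum case counts as attributes
#'   `n_treated` / `n_untreated`.
#' @export
stratified_scan <- function(m, sheet, cells = NULL, treatment, calls = NULL,
                            case = "MCTD", control = "CTRL",
                            min_stratum = 3) {
  stopifnot(treatment %in% TREATMENT_COLS)
  if (!is.null(calls)) m <- subset_probes(m, m$probes$probe_id %in% calls)
  sh <- scan_sheet(m, sheet, case, control)
  treated_cases <- sh$sample_id[sh$diagnosis == case & sh[[treatment]] == 1]
  untreated_cases <- sh$sample_id[sh$diagnosis == case & sh[[treatment]] == 0]
  controls <- sh$sample_id[sh$diagnosis == control]
  if (length(treated_cases) < min_stratum ||
      length(untreated_cases) < min_stratum)
    stop(sprintf("stratum too small: %d treated, %d untreated cases (min %d)",
                 length(treated_cases), length(untreated_cases), min_stratum))
  run_stratum <- function(case_ids) {
    ids <- c(case_ids, controls)
    run_dms_scan(subset_samples(m, ids), sh[sh$sample_id %in% ids, ],
                 cells, case = case, control = control)$records
  }
  tr <- run_stratum(treated_cases)
  un <- run_stratum(untreated_cases)
  out <- data.frame(probe_id = tr$probe_id,
                    treated_effect = tr$effect, treated_p = tr$p,
                    untreated_effect = un$effect, untreated_p = un$p,
                    stringsAsFactors = FALSE)
  attr(out, "n_treated") <- length(treated_cases)
  attr(out, "n_untreated") <- length(untreated_cases)
  out
}

#' Call treatment-specific effects
#'
#' A probe is treatment-specific when, in the discovery stratified results,
#' one stratum is significant at `alpha_one` while the other shows little
#' evidence (p > `p_other_floor`), AND the same stratum replicates
#' (p < `p_rep`, same effect direction) in the replication stratified
#' results.
#'
#' @param discovery,replication stratified result tables from
#'   [stratified_scan()] on the two cohorts.
#' @param alpha_one per-stratum significance level; defaults to
#'   0.05 / number of probes in `discovery` (Bonferroni over the call set).
#' @param p_other_floor "little evidence" floor for the other stratum
#'   (default 0.01).
#' @param p_rep replication level (default 0.05).
#' @return data.frame of called probes: `specific_to` ("treated" or
#'   "untreated") plus the discovery/replication effects and p-values.
#' @export
call_treatment_specific <- function(discovery, replication,
                                    alpha_one = NULL, p_other_floor = 0.01,
                                    p_rep = 0.05) {
  if (is.null(alpha_one))
    alpha_one <- bonferroni_threshold(0.05, nrow(discovery))
  ri <- replication[match(discovery$probe_id, replication$probe_id), ]
  call_side <- function(p_this, p_other, eff_d, p_r, eff_r) {
    p_this < alpha_one & p_other > p_other_floor &
      !is.na(p_r) & p_r < p_rep &
      !is.na(eff_r) & sign(eff_r) == sign(eff_d)
  }
  tr <- call_side(discovery$treated_p, discovery$untreated_p,
                  discovery$treated_effect, ri$treated_p, ri$treated_effect)
  un <- call_side(discovery$untreated_p, discovery$treated_p,
                  discovery$untreated_effect, ri$untreated_p,
                  ri$untreated_effect)
  keep <- which(tr | un)
  out <- data.frame(
    probe_id = discovery$probe_id[keep],
    specific_to = ifelse(tr[keep], "treated", "untreated"),
    discovery_effect = ifelse(tr[keep], discovery$treated_effect[keep],
                              discovery$untreated_effect[keep]),
    discovery_p = ifelse(tr[keep], discovery$treated_p[keep],
                         discovery$untreated_p[keep]),
    replication_effect = ifelse(tr[keep], ri$treated_effect[keep],
                                ri$untreated_effect[keep]),
    replication_p = ifelse(tr[keep], ri$treated_p[keep],
                           ri$untreated_p[keep]),
    stringsAsFactors = FALSE)
  attr(out, "alpha_one") <- alpha_one
  out
}
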