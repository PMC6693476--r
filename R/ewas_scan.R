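# Per-CpG differential methylation (DMS) and differential variability (VMS)
# scanning. Betas are regressed directly (not M-values) so the diagnosis
# coefficient is the adjusted beta-scale difference reported in study
# tables; variability uses the Brown-Forsythe (median-centred Levene) test
# on covariate residuals.

scan_sheet <- function(m, sheet, case, control) {
  sheet <- sheet[sheet$sample_id %in% sample_ids(m), , drop = FALSE]
  sheet[sheet$diagnosis %in% c(case, control), , drop = FALSE]
}

#' Fit the per-CpG linear model at a single probe
#'
#' OLS of beta on the diagnosis indicator plus the standard covariates; the
#' diagnosis coefficient is the covariate-adjusted beta-scale difference
#' (case minus control), with its SE and two-sided t-test p-value, and the
#' raw per-group means attached.
#'
#' @param y named numeric vector of betas (names = sample ids).
#' @param sheet validated sample sheet.
#' @param cells cell proportions (or NULL).
#' @param case,control diagnosis labels contrasted.
#' @param covariates standard covariates to include (see [build_design()]);
#'   use `character(0)` for a diagnosis-only model.
#' @param extra optional extra covariates (see [build_design()]).
#' @return one-row data.frame: effect, se, p, n, case_mean, control_mean.
#' @export
fit_cpg_model <- function(y, sheet, cells = NULL, case = "MCTD",
                          control = "CTRL",
                          covariates = c("age", "sex", "batch"),
                          extra = NULL) {
  sheet <- sheet[sheet$sample_id %in% names(y) &
                 sheet$diagnosis %in% c(case, control), , drop = FALSE]
  d <- build_design(sheet, cells, case, control, covariates = covariates,
                    extra = extra)
  yv <- y[d$sample_ids]
  if (sum(!is.na(yv)) <= ncol(d$X) + 1)
    stop("too few complete cases for the model")
  fit <- ols_scan(matrix(yv, 1, dimnames = list("y", names(yv))), d$X, "case")
  if (fit$skipped[1] && !is.na(fit$effect[1]) && fit$effect[1] == 0)
    warning("zero-variance probe: effect 0, p 1 by convention")
  is_case <- sheet$diagnosis[match(d$sample_ids, sheet$sample_id)] == case
  data.frame(effect = fit$effect[1], se = fit$se[1], p = fit$p[1],
             n = fit$n[1],
             case_mean = mean(yv[is_case], na.rm = TRUE),
             control_mean = mean(yv[!is_case], na.rm = TRUE))
}

#' Genome-wide differential methylation scan
#'
#' Fits the per-CpG model at every probe and calls differentially methylated
#' sites (DMS) at the Bonferroni threshold `alpha / m`, where `m` is the
#' number of probes actually tested (zero-variance and n-deficient probes
#' are skipped and listed, never called).
#'
#' @param m autosomal [methylation_matrix()].
#' @param sheet,cells as in [fit_cpg_model()].
#' @param alpha family-wise level (default 0.05).
#' @param case,control diagnosis labels contrasted.
#' @param include_sex set FALSE for single-sex scans.
#' @param extra optional extra covariates (data.frame indexed like `sheet`
#'   restricted to the modelled samples, e.g. treatment flags).
#' @return list: `records` (one row per probe: effect, se, p, n, group
#'   means/variances, significant flag), `threshold`, `m_tests`, `dms`
#'   (called probe ids), `skipped` (probe ids not tested).
#' @export
run_dms_scan <- function(m, sheet, cells = NULL, alpha = 0.05,
                         case = "MCTD", control = "CTRL",
                         include_sex = TRUE, extra = NULL) {
  sh <- scan_sheet(m, sheet, case, control)
  if (nrow(sh) == 0) stop("no samples for the requested contrast")
  ex <- if (!is.null(extra))
    extra[match(sh$sample_id, sheet$sample_id), , drop = FALSE] else NULL
  d <- build_design(sh, cells, case, control, include_sex = include_sex,
                    extra = ex)
  Y <- m$beta[, d$sample_ids, drop = FALSE]
  fit <- ols_scan(Y, d$X, "case")
  is_case <- sh$diagnosis[match(d$sample_ids, sh$sample_id)] == case
  gs <- group_stats(Y, is_case)
  tested <- !fit$skipped
  m_tests <- sum(tested)
  thr <- bonferroni_threshold(alpha, max(1, m_tests))
  records <- data.frame(
    probe_id = rownames(Y), effect = fit$effect, se = fit$se, p = fit$p,
    n = fit$n, case_mean = gs$case_mean, control_mean = gs$control_mean,
    case_var = gs$case_var, control_var = gs$control_var,
    skipped = fit$skipped,
    significant = tested & !is.na(fit$p) & fit$p < thr,
    stringsAsFactors = FALSE)
  list(records = records, threshold = thr, m_tests = m_tests,
       dms = records$probe_id[records$significant],
       skipped = records$probe_id[fit$skipped])
}

#' Residualise methylation on the covariates
#'
#' Per probe, OLS residuals on the covariate-only design (no diagnosis
#' term): age, sex, batch and cell proportions.
#'
#' @inheritParams run_dms_scan
#' @param covariates standard covariates (see [build_design()]).
#' @return matrix of residuals, probes x samples.
#' @export
residualize <- function(m, sheet, cells = NULL,
                        covariates = c("age", "sex", "batch"),
                        include_sex = TRUE) {
  sh <- sheet[sheet$sample_id %in% sample_ids(m), , drop = FALSE]
  d <- build_design(sh, cells, case = NULL, include_sex = include_sex,
                    covariates = covariates)
  Y <- m$beta[, d$sample_ids, drop = FALSE]
  fit <- ols_scan(Y, d$X, term = NULL, want_residuals = TRUE)
  fit$residuals
}

#' Brown-Forsythe test for unequal spread
#'
#' Levene's test with group-median centring: absolute deviations from each
#' group's median are compared by one-way ANOVA, so mean differences between
#' groups do not masquerade as variance differences.
#'
#' @param x numeric values (e.g. covariate residuals at one probe).
#' @param g group labels (2 or more groups, each n >= 2).
#' @return list: `W` (the F statistic), `p` (F(k-1, N-k) upper tail), and
#'   per-group residual variances `group_var`. Degenerate inputs (all
#'   deviations zero) give W = NA with a warning.
#' @export
levene_bf <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("each group needs n >= 2")
  d <- abs(x - stats::ave(x, g, FUN = stats::median))
  gv <- tapply(x, g, stats::var)
  if (all(d == 0)) {
    warning("all absolute deviations zero; test degenerate")
    return(list(W = NA_real_, p = NA_real_, group_var = gv))
  }
  k <- nlevels(g); N <- length(x)
  dbar <- mean(d)
  gm <- tapply(d, g, mean)
  gn <- tabulate(g)
  ssb <- sum(gn * (gm - dbar)^2)
  ssw <- sum((d - gm[g])^2)
  if (ssw == 0) {
    # deviations constant within groups: equal constants mean equal spread
    W <- if (ssb == 0) 0 else Inf
    return(list(W = W, p = if (ssb == 0) 1 else 0, group_var = gv))
  }
  W <- (ssb / (k - 1)) / (ssw / (N - k))
  list(W = W, p = stats::pf(W, k - 1, N - k, lower.tail = FALSE),
       group_var = gv)
}

# vectorised two-group Brown-Forsythe over the rows of a residual matrix
levene_bf_rows <- function(Y, is_case) {
  med1 <- apply(Y[, is_case, drop = FALSE], 1, stats::median, na.rm = TRUE)
  med0 <- apply(Y[, !is_case, drop = FALSE], 1, stats::median, na.rm = TRUE)
  D <- abs(Y - outer(med1, as.numeric(is_case)) -
             outer(med0, as.numeric(!is_case)))
  n1 <- sum(is_case); n0 <- sum(!is_case); N <- n1 + n0
  m1 <- rowMeans(D[, is_case, drop = FALSE], na.rm = TRUE)
  m0 <- rowMeans(D[, !is_case, drop = FALSE], na.rm = TRUE)
  mall <- (n1 * m1 + n0 * m0) / N
  ssb <- n1 * (m1 - mall)^2 + n0 * (m0 - mall)^2
  ssw <- rowSums((D - outer(m1, as.numeric(is_case)) -
                    outer(m0, as.numeric(!is_case)))^2, na.rm = TRUE)
  W <- ssb / (ssw / (N - 2))
  degenerate <- ssw == 0 & ssb == 0
  W[degenerate] <- NA_real_
  p <- stats::pf(W, 1, N - 2, lower.tail = FALSE)
  list(W = W, p = p,
       case_var = apply(Y[, is_case, drop = FALSE], 1, stats::var),
       control_var = apply(Y[, !is_case, drop = FALSE], 1, stats::var))
}

#' Genome-wide differential variability scan
#'
#' Residualises methylation on the covariates, then tests case/control
#' differences in residual spread per probe with the Brown-Forsythe test.
#' Variable methylated sites (VMS) are called at the Bonferroni threshold,
#' and the overlap with a supplied DMS call set is reported.
#'
#' @inheritParams run_dms_scan
#' @param dms optional character vector of DMS probe ids for the overlap
#'   count.
#' @return list: `records` (probe_id, levene_W, p, case_var, control_var,
#'   significant), `threshold`, `m_tests`, `vms` (called probe ids),
#'   `dms_overlap` (count, NA when no DMS set given), `skipped`.
#' @export
run_vms_scan <- function(m, sheet, cells = NULL, alpha = 0.05,
                         case = "MCTD", control = "CTRL",
                         include_sex = TRUE, dms = NULL) {
  sh <- scan_sheet(m, sheet, case, control)
  res <- residualize(subset_samples(m, sh$sample_id), sh, cells,
                     include_sex = include_sex)
  is_case <- sh$diagnosis[match(colnames(res), sh$sample_id)] == case
  lv <- levene_bf_rows(res, is_case)
  tested <- !is.na(lv$W)
  m_tests <- sum(tested)
  thr <- bonferroni_threshold(alpha, max(1, m_tests))
  records <- data.frame(
    probe_id = rownames(res), levene_W = lv$W, p = lv$p,
    case_var = lv$case_var, control_var = lv$control_var,
    significant = tested & !is.na(lv$p) & lv$p < thr,
    stringsAsFactors = FALSE)
  vms <- records$probe_id[records$significant]
  list(records = records, threshold = thr, m_tests = m_tests, vms = vms,
       dms_overlap = if (is.null(dms)) NA_integer_
                     else length(intersect(vms, dms)),
       skipped = records$probe_id[!tested])
}

#' Replication of discovery calls in an independent cohort
#'
#' A call is testable when the probe was scanned (not skipped) in the
#' replication cohort; it replicates when the replication effect has the
#' same direction and p < `p_rep`.
#'
#' @param discovery,replication `records` data.frames from the same scan run
#'   on the two cohorts (must share effect/p columns).
#' @param calls character vector of called probe ids from the discovery
#'   cohort.
#' @param p_rep replication significance level (default 0.05).
#' @return list: per-call table (`testable`, `replicated`), counts, and
#'   `percent` = replicated / testable x 100 rounded to integer.
#' @export
replicate_calls <- function(discovery, replication, calls, p_rep = 0.05) {
  eff_col <- if ("effect" %in% names(discovery)) "effect" else "levene_W"
  di <- discovery[match(calls, discovery$probe_id), ]
  ri <- replication[match(calls, replication$probe_id), ]
  skipped_rep <- if ("skipped" %in% names(replication))
    ri$skipped else is.na(ri$p)
  testable <- !is.na(ri$probe_id) & !is.na(ri$p) &
    !(!is.na(skipped_rep) & skipped_rep)
  same_dir <- if (eff_col == "effect")
    sign(di$effect) == sign(ri$effect)
  else  # variability calls: variance contrast on the same side
    sign(di$case_var - di$control_var) == sign(ri$case_var - ri$control_var)
  replicated <- testable & !is.na(same_dir) & same_dir & ri$p < p_rep
  tab <- data.frame(probe_id = calls, testable = testable,
                    replicated = replicated, stringsAsFactors = FALSE)
  n_testable <- sum(testable)
  n_replicated <- sum(replicated)
  list(table = tab, n_calls = length(calls), n_testable = n_testable,
       n_replicated = n_replicated,
       percent = if (n_testable > 0)
         as.integer(round(100 * n_replicated / n_testable)) else NA_integer_)
}

#' X-chromosome scan in females
#'
#' The autosomal model without the sex term, run on the female subset only;
#' males present in the input are excluded with a message.
#'
#' @param mX X-chromosome [methylation_matrix()].
#' @inheritParams run_dms_scan
#' @return as [run_dms_scan()], plus `n_excluded_males`.
#' @export
x_chromosome_scan <- function(mX, sheet, cells = NULL, alpha = 0.05,
                              case = "MCTD", control = "CTRL") {
  sh <- scan_sheet(mX, sheet, case, control)
  males <- sh$sample_id[sh$sex == "male"]
  if (length(males) > 0)
    message(length(males), " male sample(s) excluded from the X scan")
  sh <- sh[sh$sex == "female", , drop = FALSE]
  if (sum(sh$diagnosis == case) < 2 || sum(sh$diagnosis == control) < 2)
    stop("fewer than 2 female cases or controls")
  out <- run_dms_scan(subset_samples(mX, sh$sample_id), sh, cells, alpha,
                      case, control, include_sex = FALSE)
  out$n_excluded_males <- length(males)
  out
}

#' Genomic inflation factor
#'
#' Lambda = median observed 1-df chi-square / its null median (0.4549...),
#' with QQ-plot coordinates alongside.
#'
#' @param p p-values in \[0,1\].
#' @return list: `lambda` and `qq` (data.frame of expected and observed
#'   -log10 p, sorted).
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  chisq <- stats::qchisq(1 - p, df = 1)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  obs <- sort(-log10(pmax(p, 1e-300)))
  exp_ <- sort(-log10(stats::ppoints(length(p))))
  list(lambda = lambda, qq = data.frame(expected = exp_, observed = obs))
}
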