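# Cross-disease comparison of the MCTD methylation signature, case-vs-case
# differential methylation, ROC/AUC biomarker evaluation of CpG panels, and
# a hypergeometric gene-set over-representation test.

#' Default biomarker panels
#'
#' The two standing panels: the top 10 discriminating CpGs and the six
#' IFI44L-region CpGs.
#' @return named list of probe-id character vectors.
#' @export
panel_specs <- function() {
  list(
    top10 = c("cg22930808", "cg03607951", "cg13452062", "cg22862003",
              "cg06981309", "cg05552874", "cg07839457", "cg24678928",
              "cg00959259", "cg05696877"),
    IFI44L6 = c("cg13452062", "cg05696877", "cg03607951", "cg13304609",
                "cg17980508", "cg00458211"))
}

#' Cross-disease scan at the DMS set
#'
#' Fits the EWAS model for every other disease versus the shared control
#' pool, restricted to the supplied DMS probes, and correlates each
#' disease's effect vector with the MCTD one. The heat-map subset applies
#' the |MCTD effect| > `heat_threshold` rule to the MCTD effects only.
#'
#' @inheritParams run_dms_scan
#' @param dms character vector of DMS probe ids.
#' @param diseases disease labels to compare (default all non-control
#'   labels present in the sheet).
#' @param heat_threshold absolute MCTD effect cut for the heat-map subset
#'   (default 0.15).
#' @return list: `effects` (diseases x probes matrix of adjusted effects),
#'   `records` (per-disease scan records), `correlations` (Pearson r of
#'   each disease's effects with MCTD's), `heatmap_probes`.
#' @export
cross_disease_scan <- function(m, sheet, cells = NULL, dms,
                               diseases = NULL, control = "CTRL",
                               heat_threshold = 0.15) {
  if (length(dms) == 0)
    return(list(effects = matrix(numeric(0), 0, 0), records = list(),
                correlations = numeric(0), heatmap_probes = character(0)))
  msub <- subset_probes(m, m$probes$probe_id %in% dms)
  present <- unique(sheet$diagnosis[sheet$sample_id %in% sample_ids(m)])
  if (is.null(diseases))
    diseases <- setdiff(DIAGNOSIS_LEVELS, control)
  missing <- setdiff(diseases, present)
  if (length(missing) > 0) {
    warning("diagnoses absent from the sheet, skipped: ",
            paste(missing, collapse = ", "))
    diseases <- intersect(diseases, present)
  }
  records <- list()
  effects <- matrix(NA_real_, length(diseases), nrow(msub$beta),
                    dimnames = list(diseases, rownames(msub$beta)))
  for (d in diseases) {
    sc <- run_dms_scan(msub, sheet, cells, case = d, control = control)
    records[[d]] <- sc$records
    effects[d, sc$records$probe_id] <- sc$records$effect
  }
  cors <- stats::setNames(rep(NA_real_, length(diseases)), diseases)
  if ("MCTD" %in% diseases) {
    ref <- effects["MCTD", ]
    for (d in diseases) {
      ok <- !is.na(ref) & !is.na(effects[d, ])
      cors[d] <- stats::cor(ref[ok], effects[d, ok])
    }
  }
  heat <- if ("MCTD" %in% diseases)
    colnames(effects)[!is.na(effects["MCTD", ]) &
                        abs(effects["MCTD", ]) > heat_threshold]
  else character(0)
  list(effects = effects, records = records, correlations = cors,
       heatmap_probes = heat)
}

#' Case-vs-case differential methylation
#'
#' Same covariate model with a diseaseA-vs-diseaseB indicator, restricted
#' to the DMS set and Bonferroni-corrected at 0.05 / |DMS|.
#'
#' @inheritParams run_dms_scan
#' @param dms DMS probe ids defining the test set.
#' @param diseaseA,diseaseB the two case groups contrasted (A coded 1).
#' @return as [run_dms_scan()]; `dms` holds the differential set.
#' @export
case_vs_case_scan <- function(m, sheet, cells = NULL, dms,
                              diseaseA = "MCTD", diseaseB = "SLE",
                              alpha = 0.05) {
  msub <- subset_probes(m, m$probes$probe_id %in% dms)
  run_dms_scan(msub, sheet, cells, alpha, case = diseaseA,
               control = diseaseB)
}

#' Area under the ROC curve
#'
#' Mann-Whitney U identity: the fraction of (case, control) score pairs
#' won by the case, ties counting 1/2; identical to the trapezoidal area
#' under the empirical ROC.
#'
#' @param scores numeric risk scores.
#' @param labels case indicator (logical, or coercible 0/1).
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

logistic_score <- function(y, Z) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = as.data.frame(Z), family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # under separation the fitted probabilities saturate but the linear score
  # still orders the samples; AUC is computed from it and flagged
  list(score = stats::predict(fit, type = "link"), separation = sep)
}

#' Evaluate a CpG biomarker panel
#'
#' Logistic regression of case (default MCTD) versus a comparator group on
#' the panel's beta values (optionally plus the standard covariates), with
#' in-sample fitted probabilities scored by [roc_auc()]. Per-probe
#' single-CpG AUCs are computed the same way on one probe at a time.
#'
#' @param m [methylation_matrix()].
#' @param sheet validated sample sheet.
#' @param panel character vector of probe ids (see [panel_specs()]).
#' @param comparator comparison group: "CTRL" or another disease label.
#' @param case case label (default "MCTD").
#' @param cells cell proportions for the covariate-adjusted mode.
#' @param adjust_covariates include age/sex/batch/cells alongside the
#'   panel betas (default TRUE).
#' @return list: `auc`, `n_case`, `n_comparator`, `separation` flag,
#'   `single` (data.frame of per-probe AUCs), `panel`, `comparator`.
#' @export
evaluate_panel <- function(m, sheet, panel, comparator = "CTRL",
                           case = "MCTD", cells = NULL,
                           adjust_covariates = TRUE) {
  miss <- setdiff(panel, m$probes$probe_id)
  if (length(miss) > 0)
    stop("panel probes absent from the matrix: ",
         paste(miss, collapse = ", "))
  sh <- scan_sheet(m, sheet, case, comparator)
  if (!any(sh$diagnosis == case) || !any(sh$diagnosis == comparator))
    stop("need samples in both the case and comparator groups")
  y <- as.numeric(sh$diagnosis == case)
  covs <- NULL
  if (adjust_covariates) {
    d <- build_design(sh, cells, case = NULL)
    covs <- d$X[, -1, drop = FALSE]       # glm supplies its own intercept
  }
  panel_beta <- t(m$beta[panel, sh$sample_id, drop = FALSE])
  fit_auc <- function(B) {
    Z <- if (is.null(covs)) B else cbind(B, covs)
    ls <- logistic_score(y, Z)
    list(auc = roc_auc(ls$score, y == 1), separation = ls$separation)
  }
  full <- fit_auc(panel_beta)
  single <- data.frame(
    probe_id = panel,
    auc = vapply(panel, function(p)
      fit_auc(panel_beta[, p, drop = FALSE])$auc, numeric(1)),
    stringsAsFactors = FALSE)
  list(auc = full$auc, n_case = sum(y == 1), n_comparator = sum(y == 0),
       separation = full$separation, single = single, panel = panel,
       comparator = comparator)
}

#' Gene-set over-representation test
#'
#' One-sided hypergeometric tail of the hit/set overlap against the
#' background, BH-adjusted across sets.
#'
#' @param hits character vector of hit genes (must be a subset of
#'   `background`).
#' @param background character vector of background genes (e.g. all genes
#'   on the filtered array).
#' @param sets named list of gene sets.
#' @return data.frame per set: overlap, set size (in background), p,
#'   q (BH), and the overlapping genes.
#' @export
gene_set_enrichment <- function(hits, background, sets) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  hits <- unique(hits)
  if (!all(hits %in% background))
    stop("hits must be a subset of the background")
  N <- length(background); n <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), background)
    ov <- intersect(hits, set)
    K <- length(set); k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, p = p,
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p), ]
}
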