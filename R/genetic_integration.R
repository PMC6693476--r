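# cis-meQTL scanning, case/control genetic association under the additive
# model, and the SNP-methylation-disease mediation-triangle intersection.

#' Enumerate cis SNP-probe pairs
#'
#' Pairs on the same chromosome with |SNP position - CpG position| <=
#' `window` (boundary inclusive; both coordinate systems 1-based).
#'
#' @param probes probe annotation (probe_id, chrom, pos).
#' @param variants variant table (snp_id, chrom, pos).
#' @param window window in bp (default 1 Mb).
#' @return data.frame: probe_id, snp_id, distance (snp pos - cpg pos).
#' @export
enumerate_cis_pairs <- function(probes, variants, window = 1e6) {
  out <- lapply(split(seq_len(nrow(variants)), variants$chrom), function(vi) {
    pi <- which(probes$chrom == variants$chrom[vi[1]])
    if (length(pi) == 0) return(NULL)
    d <- outer(variants$pos[vi], probes$pos[pi], "-")
    hit <- which(abs(d) <= window, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    data.frame(probe_id = probes$probe_id[pi[hit[, 2]]],
               snp_id = variants$snp_id[vi[hit[, 1]]],
               distance = d[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(probe_id = character(0), snp_id = character(0),
                      distance = numeric(0)))
  rownames(out) <- NULL
  out
}

#' First genetic principal component
#'
#' Scores on the leading eigenvector of the standardised-dosage covariance;
#' missing dosages are mean-imputed, monomorphic variants dropped. The sign
#' is fixed by making the loading of the first retained variant
#' non-negative.
#'
#' @param g [genotype_table()].
#' @return named numeric vector of PC1 scores (one per sample), with the
#'   proportion of variance explained as attribute `var_explained`.
#' @export
genotype_pc1 <- function(g) {
  D <- g$dosage
  for (i in seq_len(nrow(D))) {
    miss <- is.na(D[i, ])
    if (any(miss)) D[i, miss] <- mean(D[i, ], na.rm = TRUE)
  }
  poly <- apply(D, 1, stats::var) > 0
  if (sum(poly) < 2) stop("need at least 2 polymorphic variants")
  Z <- t(D[poly, , drop = FALSE])
  pc <- stats::prcomp(Z, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  if (pc$rotation[1, 1] < 0) scores <- -scores
  attr(scores, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  scores
}

#' cis-meQTL scan
#'
#' For every cis pair, OLS of probe beta on additive dosage adjusted for
#' sex, age, batch, cell proportions, disease status and the first genetic
#' principal component. BH-FDR is applied jointly across all tested pairs;
#' pairs are significant at `q < q_level`. SNPs monomorphic or below the
#' MAF floor (computed on the analysis samples after complete-case
#' reduction) are skipped and counted.
#'
#' @param m [methylation_matrix()].
#' @param g [genotype_table()].
#' @param sheet,cells as elsewhere.
#' @param window cis window in bp (default 1 Mb, boundary inclusive).
#' @param maf_floor minor-allele-frequency floor (default 0.05).
#' @param q_level FDR level (default 0.05).
#' @param case diagnosis coded as the disease-status covariate.
#' @return list: `records` (probe_id, snp_id, distance, effect = beta change
#'   per alt allele, se, p, q, maf, n, significant), `significant` subset,
#'   `n_pairs_tested`, `n_snps_skipped`, `lambda` (genomic inflation of the
#'   pair p-values).
#' @export
run_meqtl_scan <- function(m, g, sheet, cells = NULL, window = 1e6,
                           maf_floor = 0.05, q_level = 0.05,
                           case = "MCTD") {
  ids <- Reduce(intersect, list(sample_ids(m), colnames(g$dosage),
                                sheet$sample_id))
  if (length(ids) == 0) stop("no overlapping samples between inputs")
  sh <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  pc1 <- genotype_pc1(
    genotype_table(g$dosage[, ids, drop = FALSE], g$variants))
  d <- build_design(sh, cells, case = NULL)
  X0 <- cbind(d$X, disease = as.numeric(sh$diagnosis == case),
              geno_pc1 = as.numeric(pc1[ids]))
  pairs <- enumerate_cis_pairs(m$probes, g$variants, window)
  n_skipped <- 0L
  recs <- list()
  for (sid in unique(pairs$snp_id)) {
    dos <- g$dosage[sid, ids]
    ok <- !is.na(dos)
    af <- mean(dos[ok]) / 2
    maf <- min(af, 1 - af)
    if (sum(ok) < ncol(X0) + 3 || maf < maf_floor || stats::var(dos[ok]) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    pp <- pairs[pairs$snp_id == sid, , drop = FALSE]
    X <- cbind(X0[ok, , drop = FALSE], dosage = dos[ok])
    Y <- m$beta[pp$probe_id, ids[ok], drop = FALSE]
    fit <- ols_scan(matrix(Y, nrow(pp),
                           dimnames = list(pp$probe_id, ids[ok])),
                    X, "dosage")
    recs[[sid]] <- data.frame(
      probe_id = pp$probe_id, snp_id = sid, distance = pp$distance,
      effect = fit$effect, se = fit$se, p = fit$p, maf = maf, n = fit$n,
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(probe_id = character(0), snp_id = character(0),
               distance = numeric(0), effect = numeric(0), se = numeric(0),
               p = numeric(0), maf = numeric(0), n = integer(0))
  rownames(records) <- NULL
  records$q <- bh_fdr(records$p)
  records$significant <- !is.na(records$q) & records$q < q_level
  list(records = records,
       significant = records[records$significant, , drop = FALSE],
       n_pairs_tested = nrow(records), n_snps_skipped = n_skipped,
       lambda = if (nrow(records) > 0) genomic_inflation(records$p)$lambda
                else NA_real_)
}

#' Replicate meQTL hits in an independent cohort
#'
#' A discovery hit replicates when the same pair shows a consistent effect
#' direction at p < `p_rep` (default 0.001) in the replication scan.
#'
#' @param discovery significant records from [run_meqtl_scan()].
#' @param replication full records from the replication scan.
#' @param p_rep replication significance level.
#' @return the discovery records with `testable` and `replicated` flags.
#' @export
replicate_meqtl <- function(discovery, replication, p_rep = 0.001) {
  key_d <- paste(discovery$probe_id, discovery$snp_id)
  key_r <- paste(replication$probe_id, replication$snp_id)
  idx <- match(key_d, key_r)
  discovery$testable <- !is.na(idx)
  rp <- replication$p[idx]
  re <- replication$effect[idx]
  discovery$replicated <- discovery$testable & !is.na(rp) & rp < p_rep &
    sign(re) == sign(discovery$effect)
  discovery
}

#' Best meQTL per gene
#'
#' One row per annotated gene: the record with the smallest p; ties broken
#' by larger |effect|, then lexicographic snp_id.
#'
#' @param records (significant) meQTL records.
#' @param annotation probe annotation supplying the gene labels.
#' @return data.frame, one row per gene.
#' @export
top_meqtl_per_gene <- function(records, annotation) {
  gene <- annotation$gene[match(records$probe_id, annotation$probe_id)]
  records$gene <- gene
  ord <- order(gene, records$p, -abs(records$effect), records$snp_id)
  records <- records[ord, , drop = FALSE]
  out <- records[!duplicated(records$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# score-test chi-square for dosage effect on a binary outcome (null: no
# covariates beyond the intercept)
score_chisq <- function(y, dos) {
  ok <- !is.na(dos)
  y <- y[ok]; dos <- dos[ok]
  yb <- mean(y)
  num <- sum((y - yb) * dos)^2
  den <- yb * (1 - yb) * sum((dos - mean(dos))^2)
  if (den == 0) return(NA_real_)
  num / den
}

#' Case/control genetic association under the additive model
#'
#' Per SNP, logistic regression (IRLS via [stats::glm()], tolerance 1e-8,
#' up to 100 iterations) of case status on additive dosage; OR =
#' exp(coefficient). Complete separation is flagged and no OR reported for
#' that SNP. The genomic-control lambda of the per-SNP score-test
#' chi-squares is attached for the scan.
#'
#' @param g [genotype_table()].
#' @param sheet validated sample sheet.
#' @param case diagnosis label(s) coded 1 (default "MCTD").
#' @param control diagnosis label coded 0.
#' @return list: `records` (snp_id, log_or, or, se, p, n, af_case, af_ctrl,
#'   separation) and `lambda_gc`.
#' @export
case_control_assoc <- function(g, sheet, case = "MCTD", control = "CTRL") {
  sh <- sheet[sheet$sample_id %in% colnames(g$dosage) &
              sheet$diagnosis %in% c(case, control), , drop = FALSE]
  if (!any(sh$diagnosis %in% case) || !any(sh$diagnosis == control))
    stop("both cases and controls are required")
  y <- as.numeric(sh$diagnosis %in% case)
  D <- g$dosage[, sh$sample_id, drop = FALSE]
  n_snps <- nrow(D)
  rec <- data.frame(snp_id = g$variants$snp_id,
                    log_or = NA_real_, or = NA_real_, se = NA_real_,
                    p = NA_real_, n = NA_integer_,
                    af_case = NA_real_, af_ctrl = NA_real_,
                    separation = FALSE, stringsAsFactors = FALSE)
  chisqs <- rep(NA_real_, n_snps)
  for (i in seq_len(n_snps)) {
    dos <- D[i, ]
    ok <- !is.na(dos)
    rec$n[i] <- sum(ok)
    rec$af_case[i] <- mean(dos[ok & y == 1]) / 2
    rec$af_ctrl[i] <- mean(dos[ok & y == 0]) / 2
    if (stats::var(dos[ok]) == 0) next
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y[ok] ~ dos[ok], family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    if (sep || abs(co[2, 1]) > 15) {
      rec$separation[i] <- TRUE
      next
    }
    rec$log_or[i] <- co[2, 1]
    rec$or[i] <- exp(co[2, 1])
    rec$se[i] <- co[2, 2]
    rec$p[i] <- co[2, 4]
    chisqs[i] <- score_chisq(y, dos)
  }
  ok_chi <- !is.na(chisqs)
  lambda <- if (any(ok_chi))
    stats::median(chisqs[ok_chi]) / stats::qchisq(0.5, 1) else NA_real_
  list(records = rec, lambda_gc = lambda)
}

#' SNP-methylation-disease mediation triangle
#'
#' Intersects three scans: a SNP appears with a CpG when (1) the pair is a
#' significant meQTL, (2) the CpG is a called DMS, and (3) the SNP's
#' case/control association has p < `p_assoc`. The `direction_consistent`
#' flag records whether the risk allele moves methylation toward the case
#' profile (sign(meQTL effect) x sign(log OR) equals the EWAS effect sign);
#' it is reported, not filtered on.
#'
#' @param meqtl significant meQTL records.
#' @param ewas EWAS records (for effects at the CpGs).
#' @param dms character vector of called DMS probe ids.
#' @param assoc association `records` from [case_control_assoc()].
#' @param p_assoc suggestive association level (default 0.05).
#' @return data.frame, one row per (snp, probe): the three effects and
#'   p-values plus `direction_consistent`.
#' @export
mediation_triangle <- function(meqtl, ewas, dms, assoc, p_assoc = 0.05) {
  hit <- meqtl[meqtl$probe_id %in% dms, , drop = FALSE]
  ai <- assoc[match(hit$snp_id, assoc$snp_id), ]
  keep <- !is.na(ai$p) & ai$p < p_assoc & !ai$separation
  hit <- hit[keep, , drop = FALSE]
  ai <- ai[keep, , drop = FALSE]
  ei <- ewas[match(hit$probe_id, ewas$probe_id), ]
  out <- data.frame(
    snp_id = hit$snp_id, probe_id = hit$probe_id,
    meqtl_effect = hit$effect, meqtl_p = hit$p,
    ewas_effect = ei$effect, ewas_p = ei$p,
    or = ai$or, assoc_p = ai$p,
    direction_consistent =
      sign(hit$effect) * sign(ai$log_or) == sign(ei$effect),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
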