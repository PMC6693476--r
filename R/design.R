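# Design-matrix construction and the vectorised per-probe OLS engine shared
# by the EWAS, variability, treatment and meQTL scans.

#' Build an EWAS design matrix
#'
#' Encodes the standard covariate set: intercept, diagnosis indicator (case
#' vs control), age, sex, batch (one-hot, first level dropped) and five cell
#' proportions (neutrophils, the largest compartment, is dropped to avoid
#' collinearity with the intercept).
#'
#' @param sheet validated sample sheet restricted to the samples to model.
#' @param cells data.frame of cell proportions with a sample_id column, or
#'   NULL to omit cell covariates.
#' @param case diagnosis label coded 1 (NULL for a covariate-only design,
#'   e.g. for residualisation).
#' @param control diagnosis label coded 0 (default "CTRL").
#' @param include_sex drop the sex column (e.g. female-only X-chromosome
#'   scans) by setting FALSE.
#' @param extra optional data.frame of additional numeric covariates (e.g.
#'   treatment flags), matched to `sheet$sample_id` by row order.
#' @param covariates which of the standard covariates to include; defaults
#'   to all of age, sex, batch (sex is additionally controlled by
#'   `include_sex` for female-only scans).
#' @return list with the design matrix `X` (rownames = sample ids), the name
#'   of the term of interest `term` (NULL for covariate-only designs), and
#'   the sample ids used.
#' @export
build_design <- function(sheet, cells = NULL, case = "MCTD",
                         control = "CTRL", include_sex = TRUE,
                         extra = NULL,
                         covariates = c("age", "sex", "batch")) {
  if (!is.null(case)) {
    keep <- sheet$diagnosis %in% c(case, control)
    sheet <- sheet[keep, , drop = FALSE]
    if (!is.null(extra)) extra <- extra[keep, , drop = FALSE]
  }
  n <- nrow(sheet)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(case)) X <- cbind(X, case = as.numeric(sheet$diagnosis == case))
  if ("age" %in% covariates) X <- cbind(X, age = sheet$age)
  if ("sex" %in% covariates && include_sex &&
      length(unique(sheet$sex)) > 1)
    X <- cbind(X, sex_male = as.numeric(sheet$sex == "male"))
  bl <- sort(unique(sheet$batch))
  if ("batch" %in% covariates && length(bl) > 1) {
    B <- vapply(bl[-1], function(b) as.numeric(sheet$batch == b), numeric(n))
    B <- matrix(B, nrow = n,
                dimnames = list(NULL, paste0("batch_", bl[-1])))
    X <- cbind(X, B)
  }
  if (!is.null(cells)) {
    idx <- match(sheet$sample_id, cells$sample_id)
    if (any(is.na(idx)))
      stop("cell proportions missing for samples: ",
           paste(sheet$sample_id[is.na(idx)], collapse = ", "))
    keep_cells <- setdiff(CELL_TYPES, "neutrophils")
    X <- cbind(X, as.matrix(cells[idx, keep_cells, drop = FALSE]))
  }
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    const <- vapply(extra, function(v) stats::var(as.numeric(v)) == 0,
                    logical(1))
    if (any(const)) {
      warning("constant covariate(s) dropped: ",
              paste(names(extra)[const], collapse = ", "))
      extra <- extra[, !const, drop = FALSE]
    }
    if (ncol(extra) > 0) X <- cbind(X, as.matrix(extra))
  }
  rownames(X) <- sheet$sample_id
  check_full_rank(X)
  list(X = X, term = if (!is.null(case)) "case" else NULL,
       sample_ids = sheet$sample_id)
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

# Vectorised OLS of every row of Y (probes x samples) on X (samples x p).
# Returns effect/se/p for `term` plus residual matrix if requested.
# Probes with missing values are refit by complete cases; zero-variance or
# n-deficient probes are flagged `skipped`.
ols_scan <- function(Y, X, term, want_residuals = FALSE) {
  stopifnot(ncol(Y) == nrow(X))
  p <- ncol(X)
  tcol <- if (!is.null(term)) which(colnames(X) == term) else NA_integer_
  n_probes <- nrow(Y)
  effect <- se <- pval <- rep(NA_real_, n_probes)
  nn <- integer(n_probes)
  skipped <- logical(n_probes)
  res_mat <- if (want_residuals)
    matrix(NA_real_, n_probes, ncol(Y), dimnames = dimnames(Y)) else NULL

  fit_block <- function(Yb, Xb) {
    qrX <- qr(Xb)
    coefs <- qr.coef(qrX, t(Yb))                     # p x probes
    fitted <- Xb %*% coefs
    resid <- t(Yb) - fitted                          # n x probes
    dfres <- nrow(Xb) - p
    sigma2 <- colSums(resid^2) / dfres
    XtXinv <- chol2inv(qr.R(qrX))
    list(coefs = coefs, resid = resid, sigma2 = sigma2,
         vtt = if (!is.na(tcol)) XtXinv[tcol, tcol] else NA_real_,
         dfres = dfres)
  }

  complete <- !apply(is.na(Y), 1, any)
  if (any(complete)) {
    fb <- fit_block(Y[complete, , drop = FALSE], X)
    idx <- which(complete)
    if (!is.na(tcol)) {
      effect[idx] <- fb$coefs[tcol, ]
      se[idx] <- sqrt(fb$sigma2 * fb$vtt)
      pval[idx] <- 2 * stats::pt(abs(fb$coefs[tcol, ] / se[idx]),
                                 fb$dfres, lower.tail = FALSE)
    }
    nn[idx] <- nrow(X)
    if (want_residuals) res_mat[idx, ] <- t(fb$resid)
  }
  for (j in which(!complete)) {
    ok <- !is.na(Y[j, ])
    if (sum(ok) < p + 2) { skipped[j] <- TRUE; next }
    Xj <- X[ok, , drop = FALSE]
    if (qr(Xj)$rank < p) { skipped[j] <- TRUE; next }
    fb <- fit_block(Y[j, ok, drop = FALSE], Xj)
    if (!is.na(tcol)) {
      effect[j] <- fb$coefs[tcol, 1]
      se[j] <- sqrt(fb$sigma2[1] * fb$vtt)
      pval[j] <- 2 * stats::pt(abs(effect[j] / se[j]), fb$dfres,
                               lower.tail = FALSE)
    }
    nn[j] <- sum(ok)
    if (want_residuals) res_mat[j, ok] <- fb$resid[, 1]
  }
  # zero-variance probes: effect 0, p 1 by convention, flagged
  zv <- apply(Y, 1, function(y) {
    y <- y[!is.na(y)]; length(y) > 0 && stats::var(y) == 0
  })
  if (any(zv)) {
    effect[zv] <- 0; se[zv] <- NA_real_; pval[zv] <- 1
    skipped[zv] <- TRUE
  }
  list(effect = effect, se = se, p = pval, n = nn, skipped = skipped,
       residuals = res_mat)
}

group_stats <- function(Y, is_case) {
  list(case_mean = rowMeans(Y[, is_case, drop = FALSE], na.rm = TRUE),
       control_mean = rowMeans(Y[, !is_case, drop = FALSE], na.rm = TRUE),
       case_var = apply(Y[, is_case, drop = FALSE], 1, stats::var,
                        na.rm = TRUE),
       control_var = apply(Y[, !is_case, drop = FALSE], 1, stats::var,
                           na.rm = TRUE))
}
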