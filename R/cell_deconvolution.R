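# Reference-based leukocyte deconvolution: project each sample's methylation
# at discriminating reference probes onto cell-type reference profiles under
# simplex constraints, yielding the mixture proportions the EWAS adjusts for.

# Equality-constrained non-negative least squares:
#   min ||b - R w||^2  s.t.  w >= 0, sum(w) = 1
# Active-set iteration on the KKT system of the equality-constrained
# subproblem; deterministic.
eq_nnls <- function(R, b, tol = 1e-9, max_iter = 200) {
  k <- ncol(R)
  RtR <- crossprod(R)
  Rtb <- crossprod(R, b)
  passive <- rep(TRUE, k)
  solve_passive <- function(pas) {
    p <- sum(pas)
    K <- rbind(cbind(RtR[pas, pas, drop = FALSE], 1), c(rep(1, p), 0))
    sol <- solve(K, c(Rtb[pas], 1))
    list(w = sol[1:p], lambda = sol[p + 1])
  }
  for (it in seq_len(max_iter)) {
    sp <- solve_passive(passive)
    w <- rep(0, k)
    w[passive] <- sp$w
    if (any(sp$w < -tol)) {
      drop <- which(passive)[which.min(sp$w)]
      passive[drop] <- FALSE
      if (sum(passive) == 0) stop("active-set solver emptied the passive set")
      next
    }
    # KKT multipliers of the zeroed coordinates; free the most violating one
    mu <- RtR %*% w - Rtb + sp$lambda
    viol <- !passive & (mu < -tol)
    if (!any(viol)) {
      w[w < 0] <- 0
      return(w / sum(w))
    }
    passive[which.min(replace(mu, passive, Inf))] <- TRUE
  }
  stop("equality-constrained NNLS did not converge")
}

#' Estimate leukocyte proportions from reference-probe methylation
#'
#' For each sample solves the constrained projection
#' `min_w ||beta_s - R w||^2` subject to `w >= 0` and `sum(w) = 1`, where
#' `R` holds the cell-type reference profiles at discriminating probes.
#' The default solver enforces the simplex exactly (active-set NNLS with the
#' equality constraint in the KKT system); `method = "truncate"` gives the
#' classical unconstrained-then-truncate-and-renormalise variant for
#' comparison.
#'
#' @param m [methylation_matrix()] restricted to the reference probes, or a
#'   plain matrix (probes x samples). Rows are matched to `ref` by rowname
#'   when both are named.
#' @param ref reference matrix (probes x cell types), full column rank.
#' @param method "constrained" (default) or "truncate".
#' @return data.frame with `sample_id` and one proportion column per cell
#'   type.
#' @export
estimate_cell_proportions <- function(m, ref,
                                      method = c("constrained", "truncate")) {
  method <- match.arg(method)
  B <- if (inherits(m, "methylation_matrix")) m$beta else as.matrix(m)
  if (!is.null(rownames(B)) && !is.null(rownames(ref))) {
    common <- intersect(rownames(B), rownames(ref))
    if (length(common) < ncol(ref))
      stop("fewer shared reference probes than cell types")
    B <- B[common, , drop = FALSE]
    ref <- ref[common, , drop = FALSE]
  }
  if (nrow(B) != nrow(ref)) stop("probe dimension mismatch with reference")
  if (qr(ref)$rank < ncol(ref))
    stop("reference matrix is rank deficient; supply more discriminating ",
         "probes or remove collinear cell types")
  W <- matrix(NA_real_, ncol(B), ncol(ref),
              dimnames = list(colnames(B), colnames(ref)))
  for (s in seq_len(ncol(B))) {
    b <- B[, s]
    if (method == "constrained") {
      W[s, ] <- eq_nnls(ref, b)
    } else {
      w <- solve(crossprod(ref), crossprod(ref, b))
      w[w < 0] <- 0
      W[s, ] <- w / sum(w)
    }
  }
  out <- data.frame(sample_id = colnames(B), W, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
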