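# independent normal-equations oracle for OLS
ols_oracle <- function(y, X, term) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  t_idx <- which(colnames(X) == term)
  se <- sqrt(s2 * XtXi[t_idx, t_idx])
  tval <- b[t_idx] / se
  list(effect = b[t_idx], se = se, p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}

test_that("a diagnosis-only model returns the difference of group means", {
  sheet <- toy_sheet(2, 2)
  y <- c(S01 = 0.30, S02 = 0.40, S03 = 0.81, S04 = 0.91)
  fit <- fit_cpg_model(y, sheet, covariates = character(0))
  expect_equal(fit$effect, -0.51)
  expect_equal(fit$case_mean, 0.35)
  expect_equal(fit$control_mean, 0.86)
})

test_that("a zero-variance probe yields effect 0 and p 1 with a warning", {
  sheet <- toy_sheet(5, 5)
  y <- setNames(rep(0.5, 10), sheet$sample_id)
  expect_warning(fit <- fit_cpg_model(y, sheet), "zero-variance")
  expect_equal(fit$effect, 0)
  expect_equal(fit$p, 1)
})

test_that("per-probe OLS matches the normal-equations oracle on random
           designs", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(15:40, 1)
    X <- cbind(`(Intercept)` = 1, case = rbinom(n, 1, 0.4),
               age = runif(n, 20, 70), z = rnorm(n))
    y <- 0.5 + 0.1 * X[, "case"] + rnorm(n, 0, 0.05)
    Y <- matrix(y, 1, dimnames = list("p1", paste0("S", 1:n)))
    rownames(X) <- colnames(Y)
    fit <- sadewas:::ols_scan(Y, X, "case")
    orc <- ols_oracle(y, X, "case")
    expect_equal(fit$effect[1], unname(orc$effect), tolerance = 1e-8)
    expect_equal(fit$se[1], unname(orc$se), tolerance = 1e-8)
    expect_equal(fit$p[1], unname(orc$p), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs are rejected naming the aliased column", {
  sheet <- toy_sheet(6, 6)
  extra <- data.frame(dup_age = sheet$age)
  expect_error(build_design(sheet, extra = extra), "dup_age")
})

test_that("residualisation removes covariates exactly", {
  m <- toy_methylation(4, 20)
  sheet <- toy_sheet(10, 10)
  # covariate-free design: residuals are the centred values
  sheet0 <- sheet; sheet0$age <- 1; sheet0$sex <- "female"
  sheet0$batch <- "b1"
  res0 <- residualize(m, sheet0, covariates = character(0))
  expect_equal(res0, sweep(m$beta, 1, rowMeans(m$beta)), tolerance = 1e-12)
  # a probe exactly linear in age residualises to zero
  m2 <- m
  m2$beta[1, ] <- 0.2 + 0.005 * sheet$age[match(colnames(m2$beta),
                                                sheet$sample_id)]
  res <- residualize(m2, sheet)
  expect_lt(max(abs(res[1, ])), 1e-10)
  # residuals are orthogonal to every design column
  d <- build_design(sheet, case = NULL)
  for (j in seq_len(ncol(d$X)))
    expect_lt(max(abs(res %*% d$X[, j])), 1e-8)
})

test_that("the Brown-Forsythe statistic matches an independent ANOVA on
           absolute deviations and is scale-stable", {
  x <- c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10)
  g <- rep(c("a", "b"), each = 5)
  lv <- levene_bf(x, g)
  # oracle: |x - group median| fed to stats::oneway.test (equal variances)
  d <- abs(x - ave(x, g, FUN = median))
  orc <- oneway.test(d ~ factor(g), var.equal = TRUE)
  expect_equal(lv$W, unname(orc$statistic), tolerance = 1e-12)
  expect_equal(lv$p, orc$p.value, tolerance = 1e-12)
  # equal spread gives W = 0, p = 1
  lv0 <- levene_bf(c(-1, 1, -1, 1), rep(c("a", "b"), each = 2))
  expect_equal(lv0$W, 0)
  expect_equal(lv0$p, 1)
  # common scaling of both groups leaves the F ratio unchanged
  lv10 <- levene_bf(10 * x, g)
  expect_equal(lv10$p, lv$p, tolerance = 1e-12)
  # degenerate input is flagged
  expect_warning(levene_bf(rep(1, 6), rep(c("a", "b"), 3)), "degenerate")
})

test_that("the vectorised variability scan agrees with the single-probe
           test", {
  sim <- simulate_cohort(small_cfg(seed = 21))
  sh <- sim$sheet[sim$sheet$sample_id %in% colnames(sim$discovery$beta) &
                    sim$sheet$diagnosis %in% c("MCTD", "CTRL"), ]
  res <- residualize(sadewas:::subset_samples(sim$discovery, sh$sample_id),
                     sh)
  is_case <- sh$diagnosis[match(colnames(res), sh$sample_id)] == "MCTD"
  rows <- sadewas:::levene_bf_rows(res, is_case)
  for (j in c(1, 7, 30)) {
    single <- levene_bf(res[j, ], ifelse(is_case, "case", "ctrl"))
    expect_equal(unname(rows$W[j]), single$W, tolerance = 1e-10)
    expect_equal(unname(rows$p[j]), single$p, tolerance = 1e-10)
  }
})

test_that("scans are invariant to joint sample reordering", {
  sim <- simulate_cohort(small_cfg(seed = 22))
  ids <- sample_ids(sim$discovery)
  perm <- sample(length(ids))
  m_perm <- sadewas:::subset_samples(sim$discovery, ids[perm])
  s1 <- run_dms_scan(sim$discovery, sim$sheet)
  s2 <- run_dms_scan(m_perm, sim$sheet)
  expect_equal(s1$records, s2$records, tolerance = 1e-12)
})

test_that("the DMS scan has power against a -0.3 shift at the study's
           sample sizes", {
  detected <- sapply(1:5, function(s) {
    sim <- simulate_cohort(small_cfg(
      seed = 300 + s, n_probes = 120, n_ifn_probes = 50,
      delta_range = c(-0.3, -0.3), prop_hyper = 0,
      treatment_attenuation = 0, vms_frac_of_dms = 0, n_vms_only = 0,
      other_sads = c(SLE = 0, SjS = 0, RA = 0, SSc = 0)))
    scan <- run_dms_scan(sim$discovery, sim$sheet)
    sum(sim$truth$probes$probe_id[sim$truth$probes$is_dms] %in% scan$dms)
  })
  expect_gte(mean(detected), 45)
})

test_that("probes with variance inflation but no mean shift appear in VMS
           and not in DMS", {
  sim <- simulate_cohort(small_cfg(seed = 23, n_ifn_probes = 0,
                                   n_vms_only = 10, var_inflation = 10,
                                   other_sads = c(SLE = 0, SjS = 0,
                                                  RA = 0, SSc = 0)))
  scan <- run_dms_scan(sim$discovery, sim$sheet)
  vms <- run_vms_scan(sim$discovery, sim$sheet, dms = scan$dms)
  truth_vms <- sim$truth$probes$probe_id[sim$truth$probes$vms]
  expect_gte(mean(truth_vms %in% vms$vms), 0.7)
  # plain OLS pools residual variance across groups, so its t-test is
  # anticonservative at strongly variance-inflated probes; variance-only
  # probes therefore sometimes reach the mean-difference threshold too,
  # but at most a minority of them
  expect_lte(length(scan$dms), 0.5 * length(truth_vms))
  expect_gte(length(vms$vms) - vms$dms_overlap, 0.7 * length(truth_vms))
})

test_that("replication logic applies the direction + p rule and reports an
           integer percentage", {
  disc <- data.frame(probe_id = paste0("cg", 1:3),
                     effect = c(-0.3, -0.3, -0.2), p = rep(1e-10, 3),
                     case_var = 1, control_var = 1, skipped = FALSE)
  repl <- data.frame(probe_id = paste0("cg", 1:3),
                     effect = c(-0.1, 0.2, -0.1),
                     p = c(0.01, 0.001, 0.2),
                     case_var = 1, control_var = 1, skipped = FALSE)
  out <- replicate_calls(disc, repl, disc$probe_id)
  expect_equal(out$table$replicated, c(TRUE, FALSE, FALSE))
  expect_equal(out$percent, 33L)
  # 99 of 100 testable -> "99%"
  disc2 <- data.frame(probe_id = paste0("cg", 1:100), effect = -0.3,
                      p = 1e-10, case_var = 1, control_var = 1,
                      skipped = FALSE)
  repl2 <- data.frame(probe_id = paste0("cg", 1:100),
                      effect = c(0.2, rep(-0.1, 99)), p = 0.001,
                      case_var = 1, control_var = 1, skipped = FALSE)
  expect_equal(replicate_calls(disc2, repl2, disc2$probe_id)$percent, 99L)
  # percentage does not depend on probe order
  perm <- sample(100)
  expect_equal(replicate_calls(disc2[perm, ], repl2, disc2$probe_id[perm])$percent,
               99L)
})

test_that("the X-chromosome scan runs in females only and excludes males", {
  sim <- simulate_cohort(small_cfg(seed = 24, n_x_probes = 30,
                                   other_sads = c(SLE = 0, SjS = 0,
                                                  RA = 0, SSc = 0)))
  split <- filter_probes(sim$discovery)
  expect_equal(nrow(split$x$beta), 30)
  expect_message(xs <- x_chromosome_scan(split$x, sim$sheet), "male")
  expect_gt(xs$n_excluded_males, 0)
  expect_equal(length(xs$dms), 0)          # no X effects simulated
  # all-male input has too few female cases
  sh_m <- sim$sheet
  sh_m$sex[sh_m$diagnosis == "MCTD"] <- "male"
  expect_error(suppressMessages(x_chromosome_scan(split$x, sh_m)),
               "fewer than 2")
})

test_that("genomic inflation equals 1 at the null median and grows when
           p-values shrink", {
  expect_equal(genomic_inflation(rep(0.5, 11))$lambda, 1.0)
  set.seed(30)
  p <- runif(10000)
  lam <- genomic_inflation(p)$lambda
  expect_gt(lam, 0.95)
  expect_lt(lam, 1.05)
  expect_gt(genomic_inflation(p / 2)$lambda, lam)
  expect_error(genomic_inflation(c(0.5, 1.2)), "\\[0,1\\]")
})
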