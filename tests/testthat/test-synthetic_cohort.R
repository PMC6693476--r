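test_that("the same seed reproduces the cohort bit for bit", {
  s1 <- simulate_cohort(small_cfg(seed = 9))
  s2 <- simulate_cohort(small_cfg(seed = 9))
  expect_identical(s1$discovery$beta, s2$discovery$beta)
  expect_identical(s1$replication$beta, s2$replication$beta)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$truth, s2$truth)
})

test_that("simulated betas stay strictly inside (0,1) and cell proportions
           lie on the simplex", {
  sim <- simulate_cohort(small_cfg(seed = 2))
  expect_true(all(sim$discovery$beta > 0 & sim$discovery$beta < 1))
  expect_true(all(sim$replication$beta > 0 & sim$replication$beta < 1))
  w <- as.matrix(sim$cells[, CELL_TYPES])
  expect_true(all(w >= 0))
  expect_equal(unname(rowSums(w)), rep(1, nrow(w)), tolerance = 1e-12)
})

test_that("reference profiles are reproducible and separated", {
  r1 <- simulate_reference_profiles(6, 120, seed = 4)
  r2 <- simulate_reference_profiles(6, 120, seed = 4)
  expect_identical(r1$profiles, r2$profiles)
  expect_gt(r1$min_pairwise_mad, 0.2)
  # two fully separated profiles give a well-conditioned reference
  R <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_lt(kappa(R), 10)
})

test_that("the truth ledger covers every probe and SNP exactly once", {
  sim <- simulate_cohort(small_cfg(seed = 3))
  expect_equal(sort(sim$truth$probes$probe_id),
               sort(sim$discovery$probes$probe_id))
  expect_false(anyDuplicated(sim$truth$probes$probe_id) > 0)
  expect_equal(sort(sim$truth$snps$snp_id),
               sort(sim$genotypes$variants$snp_id))
  # wired loci appear in the ledger with their cis SNP
  wired <- sim$truth$probes[sim$truth$probes$gamma != 0, ]
  expect_equal(nrow(wired), 5)
  expect_true(all(wired$cis_snp %in% sim$truth$snps$snp_id))
  expect_equal(sum(sim$truth$snps$is_mediated), 1)
})

test_that("the realized case-control beta difference converges to the
           ledger delta at large n", {
  cfg <- sim_config(seed = 11, n_cases = 2500, n_controls = 2500,
                    n_cases_rep = 5, n_controls_rep = 5,
                    other_sads = c(SLE = 0, SjS = 0, RA = 0, SSc = 0),
                    n_probes = 6, n_ifn_probes = 6,
                    delta_range = c(-0.3, -0.3), prop_hyper = 0,
                    treatment_counts = c(steroid = 0, antimalarial = 0,
                                         immunosuppressant = 0),
                    vms_frac_of_dms = 0, n_vms_only = 0,
                    n_snps = 10, n_meqtl = 1, n_risk_snps = 1,
                    n_assoc_extra_cases = 0, n_assoc_extra_controls = 0,
                    n_ref_probes = 30)
  sim <- simulate_cohort(cfg)
  sh <- sim$sheet[sim$sheet$cohort == "discovery", ]
  is_case <- sh$diagnosis == "MCTD"
  diff <- rowMeans(sim$discovery$beta[, sh$sample_id[is_case]]) -
    rowMeans(sim$discovery$beta[, sh$sample_id[!is_case]])
  # skip the wired meQTL probe: its group means also move with dosage
  plain <- is.na(sim$truth$probes$cis_snp)
  expect_equal(unname(diff[plain]),
               sim$truth$probes$delta[plain], tolerance = 0.01 / 0.3)
})

test_that("detection rates rise with effect size and with variance
           inflation", {
  rates_d <- sapply(c(0.02, 0.05, 0.2), function(d) {
    hits <- sapply(1:4, function(s) {
      sim <- simulate_cohort(small_cfg(
        seed = 100 + s, delta_range = c(-d, -d), prop_hyper = 0,
        other_sads = c(SLE = 0, SjS = 0, RA = 0, SSc = 0),
        treatment_attenuation = 0, vms_frac_of_dms = 0, n_vms_only = 0))
      scan <- run_dms_scan(sim$discovery, sim$sheet)
      mean(sim$truth$probes$probe_id[sim$truth$probes$is_dms] %in% scan$dms)
    })
    mean(hits)
  })
  expect_true(all(diff(rates_d) >= 0))
  expect_gt(rates_d[3], rates_d[1])
  rates_v <- sapply(c(1.5, 4, 10), function(v) {
    hits <- sapply(1:4, function(s) {
      sim <- simulate_cohort(small_cfg(
        seed = 200 + s, n_ifn_probes = 0, n_vms_only = 12, var_inflation = v,
        other_sads = c(SLE = 0, SjS = 0, RA = 0, SSc = 0)))
      scan <- run_vms_scan(sim$discovery, sim$sheet)
      mean(sim$truth$probes$probe_id[sim$truth$probes$vms] %in% scan$vms)
    })
    mean(hits)
  })
  expect_true(all(diff(rates_v) >= 0))
  expect_gt(rates_v[3], rates_v[1])
})

test_that("non-risk SNP allele frequencies are equal between cases and
           controls within sampling error", {
  sim <- simulate_cohort(small_cfg(seed = 5))
  sh <- sim$sheet[match(colnames(sim$genotypes$dosage),
                        sim$sheet$sample_id), ]
  is_case <- sh$diagnosis == "MCTD"
  tsnp <- sim$truth$snps
  z <- sapply(which(!tsnp$is_risk), function(i) {
    d <- sim$genotypes$dosage[i, ]
    p1 <- mean(d[is_case]) / 2; p0 <- mean(d[!is_case]) / 2
    n1 <- 2 * sum(is_case); n0 <- 2 * sum(!is_case)
    pp <- (p1 * n1 + p0 * n0) / (n1 + n0)
    (p1 - p0) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n0))
  })
  # z-scores behave like standard normals: no |z| beyond Bonferroni-ish 4
  expect_true(all(abs(z) < 4))
  expect_lt(abs(mean(z)), 0.5)
})

test_that("truth_report scores perfect, empty and inverted callers
           correctly", {
  truth <- data.frame(probe_id = paste0("cg", 1:6),
                      delta = c(-0.3, -0.2, 0, 0, 0.1, 0),
                      is_dms = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  perfect <- data.frame(probe_id = truth$probe_id, effect = truth$delta,
                        significant = truth$is_dms)
  r <- truth_report(truth, perfect)
  expect_equal(r$bias, 0)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$realized_fdr, 0)
  empty <- transform(perfect, significant = FALSE)
  r <- truth_report(truth, empty)
  expect_equal(r$sensitivity, 0)
  expect_equal(r$realized_fdr, 0)
  all_nulls <- transform(perfect, significant = !truth$is_dms)
  expect_equal(truth_report(truth, all_nulls)$realized_fdr, 1)
  bad <- transform(perfect, probe_id = paste0("xx", 1:6))
  expect_error(truth_report(truth, bad), "absent")
})

test_that("replication platform mask keeps roughly the configured probe
           fraction", {
  sim <- simulate_cohort(sim_config(seed = 8, n_probes = 800,
                                    other_sads = c(SLE = 0, SjS = 0,
                                                   RA = 0, SSc = 0)))
  frac <- nrow(sim$replication$beta) / nrow(sim$discovery$beta)
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.62)
  expect_true(all(rownames(sim$replication$beta) %in%
                    rownames(sim$discovery$beta)))
})

test_that("configurations round-trip through YAML files", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_probes: 40", "n_ifn_probes: 5", "seed: 7"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_probes, 40)
  expect_equal(cfg$n_ifn_probes, 5)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$var_inflation, sim_config()$var_inflation)
})

test_that("configuration validation rejects inconsistent settings before
           sampling", {
  expect_error(sim_config(bogus_field = 1), "unknown")
  expect_error(simulate_cohort(small_cfg(n_ifn_probes = 500)),
               "exceeds n_probes")
  expect_error(simulate_cohort(small_cfg(n_snps = 3)), "too small")
})
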