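test_that("cis-pair enumeration matches brute force and treats the window
           boundary inclusively", {
  probes <- cpg_annotation(c("p1", "p2"), c("1", "2"),
                           c(5e6, 5e6), c("A", "B"))
  vars <- data.frame(snp_id = c("s1", "s2", "s3"),
                     chrom = c("1", "1", "2"),
                     pos = c(5e6 + 1e6, 5e6 + 1e6 + 1, 5e6),
                     ref = "A", alt = "G")
  pairs <- enumerate_cis_pairs(probes, vars, window = 1e6)
  # exactly-1Mb SNP included; 1 bp past excluded; cross-chromosome excluded
  expect_true(any(pairs$probe_id == "p1" & pairs$snp_id == "s1"))
  expect_false(any(pairs$snp_id == "s2"))
  expect_false(any(pairs$probe_id == "p1" & pairs$snp_id == "s3"))
  expect_true(any(pairs$probe_id == "p2" & pairs$snp_id == "s3"))
  # random maps against an all-pairs filter oracle
  set.seed(50)
  for (i in 1:20) {
    np <- sample(3:8, 1); nv <- sample(3:10, 1)
    pr <- cpg_annotation(paste0("p", 1:np),
                         sample(c("1", "2", "3"), np, TRUE),
                         sample.int(1e7, np), "G")
    vr <- data.frame(snp_id = paste0("s", 1:nv),
                     chrom = sample(c("1", "2", "3"), nv, TRUE),
                     pos = sample.int(1e7, nv), ref = "A", alt = "G")
    w <- sample.int(3e6, 1)
    got <- enumerate_cis_pairs(pr, vr, w)
    want <- expand.grid(pi = 1:np, vi = 1:nv)
    want <- want[pr$chrom[want$pi] == vr$chrom[want$vi] &
                   abs(pr$pos[want$pi] - vr$pos[want$vi]) <= w, ]
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$probe_id, got$snp_id),
                    paste(pr$probe_id[want$pi], vr$snp_id[want$vi]))
  }
})

test_that("genotype PC1 matches a brute-force eigendecomposition and is
           sign-anchored", {
  set.seed(51)
  D <- matrix(rbinom(60, 2, 0.4), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("S", 1:10)))
  g <- genotype_table(D, data.frame(snp_id = paste0("s", 1:6), chrom = "1",
                                    pos = 1:6, ref = "A", alt = "G"))
  pc1 <- genotype_pc1(g)
  Z <- scale(t(D))
  ev <- eigen(cov(Z))
  v1 <- ev$vectors[, 1]
  if (v1[1] < 0) v1 <- -v1
  expect_equal(unname(as.numeric(pc1)), unname(as.numeric(Z %*% v1)),
               tolerance = 1e-8)
  # two perfectly correlated variants: PC1 carries all the variance
  D2 <- rbind(s1 = c(0, 1, 2, 1, 0, 2), s2 = c(0, 1, 2, 1, 0, 2))
  colnames(D2) <- paste0("S", 1:6)
  g2 <- genotype_table(D2, data.frame(snp_id = c("s1", "s2"), chrom = "1",
                                      pos = 1:2, ref = "A", alt = "G"))
  expect_equal(attr(genotype_pc1(g2), "var_explained"), 1)
  # all-monomorphic input is an error
  D3 <- rbind(s1 = rep(1, 6), s2 = rep(2, 6))
  colnames(D3) <- paste0("S", 1:6)
  g3 <- genotype_table(D3, data.frame(snp_id = c("s1", "s2"), chrom = "1",
                                      pos = 1:2, ref = "A", alt = "G"))
  expect_error(genotype_pc1(g3), "polymorphic")
})

test_that("the meQTL scan recovers wired effects and a label permutation
           destroys them", {
  sim <- simulate_cohort(small_cfg(seed = 52))
  mq <- run_meqtl_scan(sim$discovery, sim$genotypes, sim$sheet)
  tp <- sim$truth$probes
  wired <- tp[tp$gamma != 0, ]
  key <- paste(mq$records$probe_id, mq$records$snp_id)
  est <- mq$records[match(paste(wired$probe_id, wired$cis_snp), key), ]
  expect_true(all(!is.na(est$effect)))
  expect_gte(sum(est$significant), nrow(wired) - 1)
  expect_lt(mean(abs(est$effect - wired$gamma)), 0.02)
  # permuting the genotype sample labels removes the signal
  g_perm <- sim$genotypes
  colnames(g_perm$dosage) <- sample(colnames(g_perm$dosage))
  mq_perm <- run_meqtl_scan(sim$discovery, g_perm, sim$sheet)
  expect_lte(nrow(mq_perm$significant), 1)
})

test_that("best-per-gene selection uses p, then |effect|, then snp id", {
  ann <- cpg_annotation(c("p1", "p2", "p3"), "1", 1:3,
                        c("GENEA", "GENEA", "GENEB"))
  rec <- data.frame(probe_id = c("p1", "p2", "p2", "p3"),
                    snp_id = c("s_b", "s_a", "s_c", "s_d"),
                    effect = c(0.05, 0.05, 0.02, 0.01),
                    p = c(1e-4, 1e-10, 1e-10, 1e-3))
  top <- top_meqtl_per_gene(rec, ann)
  expect_equal(nrow(top), 2)
  # GENEA: p tie broken by |effect| (0.05 beats 0.02)
  expect_equal(top$snp_id[top$gene == "GENEA"], "s_a")
  rec2 <- rec
  rec2$effect[2:3] <- 0.05               # full tie: lexicographic snp id
  expect_equal(top_meqtl_per_gene(rec2, ann)$snp_id[1], "s_a")
})

test_that("the additive logistic association reproduces the 2x2 odds ratio
           and flags separation", {
  y <- c(rep(1, 30), rep(0, 30))
  dos <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  ids <- sprintf("S%03d", seq_along(y))
  g <- genotype_table(matrix(dos, 1, dimnames = list("s1", ids)),
                      data.frame(snp_id = "s1", chrom = "1", pos = 1,
                                 ref = "A", alt = "G"))
  sheet <- validate_sample_sheet(data.frame(
    sample_id = ids, diagnosis = ifelse(y == 1, "MCTD", "CTRL"),
    age = 50, sex = "female", batch = "b1", steroid = 0, antimalarial = 0,
    immunosuppressant = 0, cohort = "discovery"))
  out <- case_control_assoc(g, sheet)
  expect_equal(out$records$or[1], (20 / 10) / (10 / 20), tolerance = 1e-6)
  # complete separation: all cases carry the allele, no controls do
  g2 <- g
  g2$dosage[1, ] <- c(rep(2, 30), rep(0, 30))
  out2 <- case_control_assoc(g2, sheet)
  expect_true(out2$records$separation[1])
  expect_true(is.na(out2$records$or[1]))
})

test_that("IRLS lands on the grid-search maximum of the single-SNP
           likelihood", {
  set.seed(53)
  dos <- rbinom(200, 2, 0.3)
  y <- rbinom(200, 1, plogis(-1 + 0.6 * dos))
  ids <- sprintf("S%03d", 1:200)
  g <- genotype_table(matrix(dos, 1, dimnames = list("s1", ids)),
                      data.frame(snp_id = "s1", chrom = "1", pos = 1,
                                 ref = "A", alt = "G"))
  sheet <- validate_sample_sheet(data.frame(
    sample_id = ids, diagnosis = ifelse(y == 1, "MCTD", "CTRL"),
    age = 50, sex = "female", batch = "b1", steroid = 0, antimalarial = 0,
    immunosuppressant = 0, cohort = "discovery"))
  fit <- case_control_assoc(g, sheet)$records
  loglik <- function(a, b) sum(y * (a + b * dos) -
                                 log1p(exp(a + b * dos)))
  bs <- seq(fit$log_or - 0.3, fit$log_or + 0.3, length.out = 241)
  prof <- sapply(bs, function(b) {
    optimize(function(a) -loglik(a, b), c(-5, 5))$objective
  })
  expect_lt(abs(bs[which.min(prof)] - fit$log_or), 1e-4 + diff(bs)[1])
})

test_that("the mediation triangle returns exactly the wired locus and
           respects its gates", {
  sim <- simulate_cohort(small_cfg(seed = 54))
  scan <- run_dms_scan(sim$discovery, sim$sheet)
  mq <- run_meqtl_scan(sim$discovery, sim$genotypes, sim$sheet)
  assoc <- case_control_assoc(sim$genotypes, sim$sheet)
  tri <- mediation_triangle(mq$significant, scan$records, scan$dms,
                            assoc$records)
  tsnp <- sim$truth$snps
  tp <- sim$truth$probes
  wired_snp <- tsnp$snp_id[tsnp$is_mediated]
  wired_probe <- tp$probe_id[!is.na(tp$cis_snp) & tp$cis_snp == wired_snp]
  expect_true(any(tri$snp_id == wired_snp & tri$probe_id == wired_probe))
  expect_true(all(tri$probe_id %in% scan$dms))
  # triangle rows are a subset of the significant meQTL pairs
  expect_true(all(paste(tri$probe_id, tri$snp_id) %in%
                    paste(mq$significant$probe_id, mq$significant$snp_id)))
  # a failing association gate removes the row
  assoc_null <- assoc$records
  assoc_null$p[assoc_null$snp_id == wired_snp] <- 0.4
  tri2 <- mediation_triangle(mq$significant, scan$records, scan$dms,
                             assoc_null)
  expect_false(any(tri2$snp_id == wired_snp))
  # an empty DMS set empties the triangle
  expect_equal(nrow(mediation_triangle(mq$significant, scan$records,
                                       character(0), assoc$records)), 0)
})
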