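# Shared fixture builders: everything is generated in code at test time.

# a reduced cohort configuration that keeps the full study structure but
# runs in well under a second per draw
small_cfg <- function(...) {
  args <- utils::modifyList(list(
    n_probes = 60L, n_ifn_probes = 15L, n_vms_only = 4L,
    other_sads = c(SLE = 40L, SjS = 40L, RA = 40L, SSc = 40L),
    n_snps = 30L, n_meqtl = 5L, n_risk_snps = 2L,
    n_assoc_extra_cases = 40L, n_assoc_extra_controls = 200L,
    n_ref_probes = 60L, seed = 1L), list(...))
  do.call(sim_config, args)
}

# a cohort with no disease signal at all (for calibration checks)
null_cfg <- function(...) {
  small_cfg(n_ifn_probes = 0L, n_vms_only = 0L, n_meqtl = 0L,
            n_risk_snps = 0L,
            other_sads = c(SLE = 0L, SjS = 0L, RA = 0L, SSc = 0L), ...)
}

rdirichlet_test <- function(n, alpha = c(30, 5, 3, 9, 6, 4)) {
  g <- matrix(rgamma(n * length(alpha), alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

toy_annotation <- function(n = 3, chrom = rep("1", n)) {
  cpg_annotation(sprintf("cg%07d", seq_len(n)), chrom,
                 seq_len(n) * 1000L, paste0("GENE", seq_len(n)))
}

toy_methylation <- function(n_probes = 3, n_samples = 2, seed = 42,
                            chrom = rep("1", n_probes)) {
  set.seed(seed)
  beta <- matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes,
                 dimnames = list(sprintf("cg%07d", seq_len(n_probes)),
                                 sprintf("S%02d", seq_len(n_samples))))
  methylation_matrix(beta, toy_annotation(n_probes, chrom))
}

toy_sheet <- function(n_case = 10, n_ctrl = 10, seed = 42) {
  set.seed(seed)
  n <- n_case + n_ctrl
  validate_sample_sheet(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    diagnosis = c(rep("MCTD", n_case), rep("CTRL", n_ctrl)),
    age = runif(n, 20, 70),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(.8, .2)),
    batch = sample(c("b1", "b2"), n, replace = TRUE),
    steroid = rbinom(n, 1, 0.3) * (seq_len(n) <= n_case),
    antimalarial = 0L, immunosuppressant = 0L,
    cohort = "discovery", stringsAsFactors = FALSE))
}

# minimal VCF text for the genotype reader
write_toy_vcf <- function(path, gts, ids = sprintf("S%02d", seq_len(ncol(gts))),
                          chrom = "1", pos = seq_len(nrow(gts)) * 100L,
                          alt = rep("G", nrow(gts))) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(gts)), function(i) {
    paste(c(chrom, pos[i], paste0("rs", i), "A", alt[i], ".", "PASS", ".",
            "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
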