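#' @keywords internal
"_PACKAGE"

DIAGNOSIS_LEVELS <- c("CTRL", "MCTD", "SLE", "SjS", "RA", "SSc")
SEX_LEVELS <- c("female", "male")
#' Treatment flag column names
#' @export
TREATMENT_COLS <- c("steroid", "antimalarial", "immunosuppressant")

#' The six leukocyte compartments of the blood reference panel
#' @export
CELL_TYPES <- c("neutrophils", "monocytes", "B", "CD4", "CD8", "NK")

chrom_class <- function(chrom) {
  cc <- sub("^chr", "", as.character(chrom))
  ifelse(cc == "X", "X", ifelse(cc == "Y", "Y", "autosome"))
}

#' Probe annotation constructor
#'
#' Builds and validates a CpG probe annotation table. Coordinates are 1-based
#' and fully closed throughout the package; BED input is converted at the
#' reader boundary.
#'
#' @param probe_id character probe identifiers, unique.
#' @param chrom chromosome labels ("1".."22", "X", "Y", with or without a
#'   "chr" prefix).
#' @param pos 1-based genomic position of the interrogated CpG.
#' @param gene gene label; may list several genes ("PARP9; DTX3L") or be
#'   "Intergenic".
#' @return data.frame with columns probe_id, chrom, pos, gene, chrom_class.
#' @export
cpg_annotation <- function(probe_id, chrom, pos, gene) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id))
    stop("duplicated probe ids: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("probe positions must be integers >= 1")
  chrom <- sub("^chr", "", as.character(chrom))
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
             gene = as.character(gene), chrom_class = chrom_class(chrom),
             stringsAsFactors = FALSE)
}

#' Methylation matrix constructor
#'
#' The central observable: beta values (fraction of methylated molecules,
#' in \[0,1\]) for probes x samples. Probes are stored in rows, samples in
#' columns, matching the on-disk layout.
#'
#' @param beta numeric matrix, probes in rows, samples in columns; rownames
#'   are probe ids, colnames sample ids.
#' @param probes annotation as returned by [cpg_annotation()], covering every
#'   row of `beta` (same order).
#' @param detection_p optional matrix of detection p-values, same shape.
#' @param tol tolerance for the \[0,1\] bound check.
#' @return object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(beta, probes, detection_p = NULL, tol = 1e-9) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta))) rownames(beta) <- probes$probe_id
  if (is.null(colnames(beta))) stop("beta must have sample ids as colnames")
  if (anyDuplicated(colnames(beta)))
    stop("duplicated sample ids in methylation matrix")
  if (nrow(beta) != nrow(probes) || !all(rownames(beta) == probes$probe_id))
    stop("annotation does not match beta rows")
  bad <- which(!is.na(beta) & (beta < -tol | beta > 1 + tol), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value outside [0,1] at probe %s, sample %s (value %g)",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                 beta[bad[1, 1], bad[1, 2]]))
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!all(dim(detection_p) == dim(beta)))
      stop("detection_p dimensions do not match beta")
  }
  structure(list(beta = beta, probes = probes, detection_p = detection_p),
            class = "methylation_matrix")
}

#' @exportS3Method base::print
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d probes x %d samples (%s)\n",
              nrow(x$beta), ncol(x$beta),
              paste(sprintf("%s=%d", names(table(x$probes$chrom_class)),
                            table(x$probes$chrom_class)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$beta)

sample_ids <- function(m) colnames(m$beta)

subset_probes <- function(m, keep) {
  methylation_matrix(m$beta[keep, , drop = FALSE],
                     m$probes[keep, , drop = FALSE],
                     if (!is.null(m$detection_p))
                       m$detection_p[keep, , drop = FALSE])
}

subset_samples <- function(m, ids) {
  methylation_matrix(m$beta[, ids, drop = FALSE], m$probes,
                     if (!is.null(m$detection_p))
                       m$detection_p[, ids, drop = FALSE])
}

#' Genotype table constructor
#'
#' @param dosage numeric matrix of additive alt-allele dosages (variants in
#'   rows, samples in columns); values in \[0,2\] or NA.
#' @param variants data.frame with columns snp_id, chrom, pos (1-based),
#'   ref, alt.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  variants$chrom <- sub("^chr", "", as.character(variants$chrom))
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  if (nrow(dosage) != nrow(variants))
    stop("dosage rows do not match variant table")
  if (is.null(rownames(dosage))) rownames(dosage) <- variants$snp_id
  if (is.null(colnames(dosage))) stop("dosage must have sample ids as colnames")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0,2] or be NA")
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_table")
}

#' @exportS3Method base::print
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d variants x %d samples\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Validate a sample sheet
#'
#' Checks the closed vocabularies (diagnosis, sex), positive ages, presence of
#' the treatment flags and the cohort label.
#'
#' @param sheet data.frame with columns sample_id, diagnosis, age, sex,
#'   batch, steroid, antimalarial, immunosuppressant, cohort.
#' @return the sheet, with diagnosis/sex/batch as character and treatment
#'   flags coerced to 0/1 integers.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "diagnosis", "age", "sex", "batch",
            TREATMENT_COLS, "cohort")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0)
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample ids in sheet")
  sheet$diagnosis <- as.character(sheet$diagnosis)
  bad <- setdiff(unique(sheet$diagnosis), DIAGNOSIS_LEVELS)
  if (length(bad) > 0) stop("unknown diagnosis labels: ",
                            paste(bad, collapse = ", "))
  sheet$sex <- as.character(sheet$sex)
  bad <- setdiff(unique(sheet$sex), SEX_LEVELS)
  if (length(bad) > 0) stop("unknown sex labels: ", paste(bad, collapse = ", "))
  if (any(!is.finite(sheet$age)) || any(sheet$age <= 0))
    stop("ages must be positive")
  for (tc in TREATMENT_COLS) sheet[[tc]] <- as.integer(sheet[[tc]] > 0)
  sheet$batch <- as.character(sheet$batch)
  sheet$cohort <- as.character(sheet$cohort)
  sheet
}

# ---------------------------------------------------------------------------
# Readers / writers. Methylation travels as a probes x samples TSV plus a
# separate annotation file (native 4-column TSV or 5-column BED-like TSV).

read_annotation <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- any(c("probe_id", "chrom") %in% first)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 5) {
    # BED-like: chrom, start (0-based), end, probe_id, gene
    names(tab) <- c("chrom", "start", "end", "probe_id", "gene")
    cpg_annotation(tab$probe_id, tab$chrom, tab$start + 1L, tab$gene)
  } else if (ncol(tab) == 4) {
    names(tab) <- c("probe_id", "chrom", "pos", "gene")
    cpg_annotation(tab$probe_id, tab$chrom, tab$pos, tab$gene)
  } else {
    stop("annotation must have 4 (native) or 5 (BED-like) columns")
  }
}

#' Read a methylation matrix from delimited text
#'
#' @param path TSV of beta values: first column probe ids, remaining columns
#'   one per sample with sample ids in the header.
#' @param annotation path to a probe annotation file: native 4-column TSV
#'   (probe_id, chrom, pos, gene) or BED-like 5-column TSV (chrom, 0-based
#'   start, end, probe_id, gene).
#' @param detection_p optional path to a detection p-value TSV of the same
#'   layout as the beta file.
#' @return [methylation_matrix()]; probes missing from the annotation are
#'   dropped with a message, and the drop count is available as
#'   `attr(, "n_unannotated")`.
#' @export
read_methylation <- function(path, annotation, detection_p = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  probe_ids <- as.character(tab[[1]])
  beta <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(beta)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(beta), nrow(beta)))) & !is.na(beta), arr.ind = TRUE)
    stop(sprintf("malformed numeric cell at probe %s, sample %s",
                 probe_ids[bad[1, 1]], colnames(beta)[bad[1, 2]]))
  }
  rownames(beta) <- probe_ids
  ann <- read_annotation(annotation)
  known <- probe_ids %in% ann$probe_id
  n_drop <- sum(!known)
  if (n_drop > 0) {
    message(n_drop, " probe(s) lacked annotation and were dropped")
    beta <- beta[known, , drop = FALSE]
    probe_ids <- probe_ids[known]
  }
  ann <- ann[match(probe_ids, ann$probe_id), ]
  rownames(ann) <- NULL
  dp <- NULL
  if (!is.null(detection_p)) {
    dtab <- utils::read.delim(detection_p, check.names = FALSE)
    dp <- as.matrix(dtab[, -1, drop = FALSE])
    rownames(dp) <- as.character(dtab[[1]])
    dp <- dp[probe_ids, colnames(beta), drop = FALSE]
  }
  out <- methylation_matrix(beta, ann, dp)
  attr(out, "n_unannotated") <- n_drop
  out
}

#' Write a methylation matrix (and its annotation) to delimited text
#'
#' @param m [methylation_matrix()].
#' @param path output TSV for the beta matrix.
#' @param annotation output TSV for the native 4-column annotation.
#' @export
write_methylation <- function(m, path, annotation = NULL) {
  tab <- data.frame(probe_id = rownames(m$beta), m$beta,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation)) {
    ann <- m$probes[, c("probe_id", "chrom", "pos", "gene")]
    utils::write.table(ann, annotation, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path CSV or TSV (by extension) with the mandated columns.
#' @return validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  reader <- if (grepl("\\.csv$", path)) utils::read.csv else utils::read.delim
  validate_sample_sheet(reader(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  writer <- if (grepl("\\.csv$", path)) {
    function(x, p) utils::write.csv(x, p, row.names = FALSE, quote = FALSE)
  } else {
    function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE)
  }
  writer(sheet, path)
  invisible(path)
}

gt_to_dosage <- function(gt) {
  # diploid GT string ("0/1", "1|1", "./.") -> additive alt count
  if (is.na(gt) || gt %in% c("./.", ".|.", ".")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

read_genotypes_vcf <- function(path, multiallelic = c("split", "reject")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)          # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi) && multiallelic == "reject")
    stop("multi-allelic records present: ",
         paste(fix$ID[multi], collapse = ", "))
  fmt <- strsplit(unname(v@gt[, 1]), ":")
  has_ds <- vapply(fmt, function(f) "DS" %in% f, logical(1))
  samples <- colnames(v@gt)[-1]
  rows <- list(); vars <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    if (has_ds[i] && length(alts) == 1) {
      ds <- suppressWarnings(as.numeric(
        vcfR::extract.gt(v, "DS", as.numeric = FALSE)[i, ]))
      dos <- list(ds)
    } else {
      gts <- vcfR::extract.gt(v, "GT")[i, ]
      dos <- lapply(seq_along(alts), function(k) {
        vapply(gts, function(g) {
          if (is.na(g)) return(NA_real_)
          a <- strsplit(g, "[/|]")[[1]]
          if (any(a == ".")) return(NA_real_)
          sum(a == as.character(k))
        }, numeric(1))
      })
    }
    for (k in seq_along(dos)) {
      id <- fix$ID[i]
      if (length(alts) > 1) id <- paste0(id, "_", alts[k])
      vars[[length(vars) + 1]] <- data.frame(
        snp_id = id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- dos[[k]]
    }
  }
  dosage <- do.call(rbind, rows)
  colnames(dosage) <- samples
  genotype_table(dosage, do.call(rbind, vars))
}

#' Read genotypes from a VCF or a dosage table
#'
#' VCF input uses the DS FORMAT field when present, otherwise counts alt
#' alleles in GT; "./." becomes NA. A dosage table is a TSV with columns
#' snp_id, chrom, pos, ref, alt followed by one column per sample.
#'
#' @param path input file (".vcf" extension selects the VCF parser).
#' @param sheet optional sample sheet; genotype samples absent from it raise
#'   an error listing the offenders.
#' @param multiallelic "split" (one variant per alt allele, ids suffixed with
#'   the allele) or "reject".
#' @return [genotype_table()].
#' @export
read_genotypes <- function(path, sheet = NULL,
                           multiallelic = c("split", "reject")) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    g <- read_genotypes_vcf(path, multiallelic)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    meta <- c("snp_id", "chrom", "pos", "ref", "alt")
    dosage <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
    rownames(dosage) <- tab$snp_id
    g <- genotype_table(dosage, tab[, meta])
  }
  if (!is.null(sheet)) {
    extra <- setdiff(colnames(g$dosage), sheet$sample_id)
    if (length(extra) > 0)
      stop("genotype samples not in sample sheet: ",
           paste(extra, collapse = ", "))
  }
  g
}

#' @rdname read_genotypes
#' @param g genotype table to write as a dosage TSV.
#' @export
write_genotypes <- function(g, path) {
  tab <- data.frame(g$variants, g$dosage, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Probe filtering

#' Filter probes and split off the sex chromosomes
#'
#' Applies, in order: (1) the detection rule — a probe is kept only when its
#' detection p-value is <= `detection_p` in at least `detection_frac` of
#' samples; (2) user-supplied exclusion lists (e.g. probes with common SNPs at
#' the CpG site, multi-mapping probes); (3) routing of X/Y probes into a
#' separate matrix so autosomal and sex-chromosome scans stay apart.
#'
#' @param m [methylation_matrix()].
#' @param detection_p,detection_frac detection-rule parameters (defaults 0.01
#'   and 0.95); the rule is skipped when the matrix carries no detection
#'   p-values.
#' @param exclude character vector of probe ids, or a file of probe ids (one
#'   per line), to remove.
#' @return list with `autosomal` and `x` methylation matrices (y probes are
#'   dropped) and a `report` of per-rule removal counts.
#' @export
filter_probes <- function(m, detection_p = 0.01, detection_frac = 0.95,
                          exclude = NULL) {
  n0 <- nrow(m$beta)
  report <- list(input = n0, detection = 0L, excluded = 0L,
                 x = 0L, y = 0L)
  if (!is.null(m$detection_p)) {
    ok_frac <- rowMeans(m$detection_p <= detection_p, na.rm = TRUE)
    keep <- ok_frac >= detection_frac
    report$detection <- sum(!keep)
    m <- subset_probes(m, keep)
  }
  if (!is.null(exclude)) {
    if (length(exclude) == 1 && file.exists(exclude))
      exclude <- readLines(exclude)
    keep <- !(m$probes$probe_id %in% exclude)
    report$excluded <- sum(!keep)
    m <- subset_probes(m, keep)
  }
  is_x <- m$probes$chrom_class == "X"
  is_y <- m$probes$chrom_class == "Y"
  report$x <- sum(is_x)
  report$y <- sum(is_y)
  auto <- subset_probes(m, !is_x & !is_y)
  if (nrow(auto$beta) == 0) stop("no autosomal probes survive filtering")
  xmat <- if (any(is_x)) subset_probes(m, is_x) else NULL
  report$autosomal <- nrow(auto$beta)
  list(autosomal = auto, x = xmat, report = report)
}

# ---------------------------------------------------------------------------
# Multiple testing

#' Bonferroni per-test threshold
#'
#' @param alpha family-wise level (0 < alpha < 1).
#' @param m number of tests (>= 1).
#' @return alpha / m at full precision; reporting layers round to 2
#'   significant digits.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  alpha / m
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]); empty input returns an
#' empty vector.
#'
#' @param p p-values in \[0,1\].
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Round for display as in study tables
#'
#' Effects to 2 decimals, thresholds/p to 2 significant digits.
#' @param x value(s).
#' @param what "effect" or "threshold".
#' @export
display_round <- function(x, what = c("effect", "threshold")) {
  what <- match.arg(what)
  if (what == "effect") round(x, 2) else signif(x, 2)
}

#' Write a results table as TSV with a stable column order
#' @param records data.frame of scan results.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
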