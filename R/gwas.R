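# Genome scan plumbing: PLINK bed/bim/fam and VCF genotype input, per-variant
# association with the three analysis methods, adjusted odds ratios, and the
# genomic-inflation diagnostic.

#' Read PLINK bed/bim/fam genotypes
#'
#' Reads a binary PLINK 1 fileset (SNP-major bed, magic bytes
#' `0x6c 0x1b 0x01`) into an in-memory dosage matrix.  Dosages count the
#' minor allele: variants whose counted (A1) allele has sample frequency
#' above 0.5 are flipped (`dosage := 2 - dosage`, alleles swapped) and the
#' flip is recorded.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must exist.
#' @return an object of class `"wip_genotypes"`: list with `geno` (subjects
#'   by variants dosage matrix, `NA` for missing), `variants` (data frame
#'   with `chrom`, `id`, `pos`, `minor`, `major`, `maf`, `missing_rate`,
#'   `swapped`), and `subjects` (IIDs from the fam file).
#' @export
read_plink <- function(prefix) {
  for (ext in c(".bed", ".bim", ".fam"))
    if (!file.exists(paste0(prefix, ext)))
      stop("missing companion file: ", paste0(prefix, ext))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"))
  n <- nrow(fam); m <- nrow(bim)
  bpv <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + as.double(bpv) * m)
  if (length(raw) < 3 + bpv * m)
    stop("bed file truncated: expected ", 3 + bpv * m, " bytes")
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed file (bad magic bytes)")
  body <- raw[-(1:3)]
  # 2-bit codes per subject: 00 hom A1, 01 missing, 10 het, 11 hom A2
  lut <- c(2, NA, 1, 0)  # dosage of A1
  codes <- .bed_codes(body, n, m)
  geno <- matrix(lut[codes + 1L], n, m)
  colnames(geno) <- bim$id
  rownames(geno) <- as.character(fam$V2)
  .orient_genotypes(geno, bim, as.character(fam$V2))
}

# Unpack 2-bit genotype codes from the bed body into an n x m integer matrix.
.bed_codes <- function(body, n, m) {
  bpv <- ceiling(n / 4)
  ints <- as.integer(body)
  dim(ints) <- c(bpv, m)
  sub <- rep(seq_len(bpv), each = 4)[seq_len(n)]
  shift <- rep(c(0L, 2L, 4L, 6L), times = bpv)[seq_len(n)]
  codes <- matrix(0L, n, m)
  for (s in c(0L, 2L, 4L, 6L)) {
    rows <- which(shift == s)
    if (!length(rows)) next
    codes[rows, ] <- bitwAnd(ints[sub[rows], , drop = FALSE] %/%
                               bitwShiftL(1L, s), 3L)
  }
  codes
}

.orient_genotypes <- function(geno, bim, subjects) {
  freq <- colMeans(geno, na.rm = TRUE) / 2
  swap <- !is.na(freq) & freq > 0.5
  geno[, swap] <- 2 - geno[, swap]
  minor <- ifelse(swap, bim$a2, bim$a1)
  major <- ifelse(swap, bim$a1, bim$a2)
  maf <- ifelse(swap, 1 - freq, freq)
  variants <- data.frame(chrom = bim$chrom, id = bim$id, pos = bim$pos,
                         minor = minor, major = major, maf = maf,
                         missing_rate = colMeans(is.na(geno)),
                         swapped = swap, stringsAsFactors = FALSE)
  structure(list(geno = geno, variants = variants, subjects = subjects),
            class = "wip_genotypes")
}

#' @export
print.wip_genotypes <- function(x, ...) {
  cat("wip_genotypes:", length(x$subjects), "subjects x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' Write a PLINK bed/bim/fam fileset
#'
#' Inverse of [read_plink()]; mainly used to build test fixtures.  `geno`
#' holds dosages of the `a1` allele in `variants`.
#'
#' @param prefix output path prefix.
#' @param geno subjects-by-variants dosage matrix (0/1/2/NA).
#' @param variants data frame with `chrom`, `id`, `pos`, `a1`, `a2`.
#' @param subjects character vector of subject IIDs.
#' @export
write_plink <- function(prefix, geno, variants, subjects) {
  n <- nrow(geno); m <- ncol(geno)
  stopifnot(nrow(variants) == m, length(subjects) == n)
  fam <- data.frame(subjects, subjects, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(variants$chrom, variants$id, 0, variants$pos,
                    variants$a1, variants$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  code <- matrix(1L, n, m)           # 01 = missing
  code[!is.na(geno) & geno == 2] <- 0L
  code[!is.na(geno) & geno == 1] <- 2L
  code[!is.na(geno) & geno == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  bytes <- vapply(seq_len(m), function(j) {
    cj <- c(code[, j], rep(0L, pad))
    dim(cj) <- c(4, bpv)
    as.raw(cj[1, ] + cj[2, ] * 4L + cj[3, ] * 16L + cj[4, ] * 64L)
  }, raw(bpv))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.vector(bytes), con)
  invisible(prefix)
}

#' Read genotypes from a VCF file
#'
#' Uses the `vcfR` package.  Dosage is taken from the `DS` FORMAT field when
#' present (imputed dosages), otherwise from `GT` (missing genotypes `./.`
#' yield `NA`).  Variants are then oriented to the minor allele exactly as in
#' [read_plink()].
#'
#' @param path VCF file (plain or bgzipped).
#' @return a `"wip_genotypes"` object.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  subjects <- colnames(v@gt)[-1]
  fmt <- strsplit(v@gt[, 1], ":")
  use_ds <- vapply(fmt, function(f) "DS" %in% f, logical(1))
  if (length(use_ds) && all(use_ds)) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    geno <- t(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(g) {
      g[g %in% c("./.", ".", ".|.")] <- NA
      vapply(strsplit(g, "[/|]"), function(a)
        if (anyNA(a) || length(a) == 0L) NA_real_
        else sum(a != "0"), numeric(1))
    }
    geno <- t(apply(gt, 1, cnt))
    geno <- matrix(as.numeric(geno), nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
    geno <- t(geno)
  }
  rownames(geno) <- subjects
  colnames(geno) <- fix[, "ID"]
  bim <- data.frame(chrom = fix[, "CHROM"], id = fix[, "ID"],
                    pos = as.integer(fix[, "POS"]),
                    a1 = fix[, "ALT"], a2 = fix[, "REF"],
                    stringsAsFactors = FALSE)
  .orient_genotypes(geno, bim, subjects)
}

#' Per-variant association scan
#'
#' Runs the chosen analysis method over every variant passing the filters:
#' per variant, subjects with missing dosage are dropped, the model
#' covariates plus the dosage column are fit by [wgee_fit()] (or tested by
#' [score_test()]), and the odds ratio, p-value and genome-wide-significance
#' flag are emitted.  Variants where the fit fails or does not converge are
#' reported with `NA` and a reason code rather than aborting the scan.
#'
#' @param genotypes a `"wip_genotypes"` object.
#' @param cohort a `"wip_cohort"` whose rows align with
#'   `genotypes$subjects`.
#' @param method `"lr"`, `"ip"` or `"wip"` (see [fit_method()]).
#' @param test `"wald"` (default) or `"score"`.
#' @param min_maf,max_missing variant filters (on the analyzed subset's maf
#'   for reporting; the filter itself uses the input metadata).
#' @param adjust optional list with `d_star`, `gamma0`, `gamma1` — adds
#'   bias-adjusted odds ratios via [adjust_coefficient()]; p-values are never
#'   adjusted.
#' @param gws_threshold genome-wide significance level for the flag column.
#' @param vcov_type Wald covariance flavour, `"robust"` (default) or
#'   `"model"`.
#' @return data frame with one row per analyzed variant: `CHR`, `BP`, `SNP`,
#'   `MA`, `MAF`, `N`, `OR`, `ORADJ`, `P`, `GWS`, `NOTE`.
#' @export
run_scan <- function(genotypes, cohort, method = c("wip", "ip", "lr"),
                     test = c("wald", "score"), min_maf = 0,
                     max_missing = 1, adjust = NULL,
                     gws_threshold = 5e-8,
                     vcov_type = c("robust", "model")) {
  method <- match.arg(method)
  test <- match.arg(test)
  vcov_type <- match.arg(vcov_type)
  if (length(genotypes$subjects) != cohort$n)
    stop("genotype subjects and cohort rows do not align")
  st <- cohort$status
  sub <- if (method == "lr") which(st$label != "missing") else seq_len(cohort$n)
  w <- if (method == "wip") st$w[sub] else rep(1, length(sub))
  Z <- cohort$Z[sub, , drop = FALSE]
  y <- st$y[sub]
  B <- if (!is.null(adjust))
    bias_factor(adjust$gamma0, adjust$gamma1)

  keep <- genotypes$variants$maf >= min_maf &
    genotypes$variants$missing_rate <= max_missing
  n_filtered <- sum(!keep)
  if (n_filtered > 0L)
    message(n_filtered, " variant(s) removed by maf/missingness filters")
  vs <- which(keep)

  rows <- lapply(vs, function(j) {
    g <- genotypes$geno[sub, j]
    obs <- !is.na(g)
    v <- genotypes$variants[j, ]
    out <- data.frame(CHR = v$chrom, BP = v$pos, SNP = v$id, MA = v$minor,
                      MAF = NA_real_, N = sum(obs), OR = NA_real_,
                      ORADJ = NA_real_, P = NA_real_, GWS = FALSE,
                      NOTE = "", stringsAsFactors = FALSE)
    gg <- g[obs]
    out$MAF <- mean(gg) / 2
    if (stats::var(gg) == 0) { out$NOTE <- "monomorphic"; return(out) }
    res <- tryCatch({
      if (test == "wald") {
        f <- wgee_fit(cbind(Z[obs, , drop = FALSE], g = gg), y[obs], w[obs])
        if (!f$converged) stop("non-convergence")
        wt <- wald_test(f, "g", vcov_type = vcov_type)
        list(beta = f$coefficients[["g"]], p = wt$p.value)
      } else {
        f0 <- wgee_fit(Z[obs, , drop = FALSE], y[obs], w[obs])
        if (!f0$converged) stop("null non-convergence")
        stt <- score_test(f0, gg, vcov_type = vcov_type)
        # score test gives no beta; report OR from a Wald fit only on demand
        list(beta = NA_real_, p = stt$p.value)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) { out$NOTE <- conditionMessage(res); return(out) }
    out$OR <- exp(res$beta)
    out$P <- res$p
    out$GWS <- is.finite(res$p) && res$p < gws_threshold
    if (!is.null(adjust) && is.finite(res$beta))
      out$ORADJ <- exp(adjust_coefficient(res$beta, B, adjust$d_star))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor
#'
#' Median-based lambda: the median of the \eqn{\chi^2_1} quantiles of the
#' p-values divided by the null median 0.4549.
#'
#' @param p vector of p-values (at least 100 recommended).
#' @return scalar \eqn{\lambda_{GC}}.
#' @export
genomic_inflation <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) < 2L) stop("need p-values to compute lambda")
  stats::median(stats::qchisq(p, 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, 1)
}

#' Write a small synthetic genotype/phenotype fixture set
#'
#' Generates a toy cohort with one planted causal variant plus null variants,
#' and writes a PLINK fileset, a matching VCF, and covariate / phenotype /
#' probability tables (TSV with an `IID` column).  Purely synthetic data for
#' examples and tests.
#'
#' @param dir output directory (created if needed).
#' @param n subjects.
#' @param n_variants total variants (the first is causal).
#' @param beta log-odds effect of the causal variant.
#' @param frac_missing_status fraction of subjects whose status is masked and
#'   given an imputed probability.
#' @param seed RNG seed.
#' @return invisibly, a list with the file paths written.
#' @export
make_fixtures <- function(dir, n = 600L, n_variants = 20L, beta = 0.5,
                          frac_missing_status = 0.2, seed = 1L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iid <- sprintf("S%04d", seq_len(n))
  maf <- stats::runif(n_variants, 0.1, 0.4)
  geno <- sapply(maf, function(f) stats::rbinom(n, 2L, f))
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- round(stats::rnorm(n, 70, 6), 1)
  eta <- -0.2 + beta * geno[, 1] + 0.3 * sex
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  miss <- sample(n, round(frac_missing_status * n))
  label <- ifelse(seq_len(n) %in% miss, "missing",
                  ifelse(y == 1, "case", "control"))
  p <- rep(NA_real_, n)
  p[miss] <- stats::plogis(stats::qlogis(
    pmin(pmax(stats::plogis(eta[miss]), 0.02), 0.98)) +
      stats::rnorm(length(miss), 0, 0.5))

  variants <- data.frame(chrom = 1L, id = paste0("var", seq_len(n_variants)),
                         pos = seq_len(n_variants) * 1000L,
                         a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  prefix <- file.path(dir, "toy")
  write_plink(prefix, geno, variants, iid)

  vcf <- file.path(dir, "toy.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", iid), collapse = "\t"))
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_variants), function(j) {
    paste(c("1", variants$pos[j], variants$id[j], "G", "A", ".", "PASS",
            ".", "GT", gt_of[geno[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcf)

  covar <- file.path(dir, "covar.tsv")
  utils::write.table(data.frame(IID = iid, SEX = sex, AGE = age),
                     covar, sep = "\t", quote = FALSE, row.names = FALSE)
  pheno <- file.path(dir, "pheno.tsv")
  utils::write.table(data.frame(IID = iid, STATUS = label),
                     pheno, sep = "\t", quote = FALSE, row.names = FALSE)
  probs <- file.path(dir, "probs.tsv")
  utils::write.table(
    data.frame(IID = iid[miss], P_AFFECTED = round(p[miss], 6)),
    probs, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(plink = prefix, vcf = vcf, covar = covar, pheno = pheno,
                 probs = probs, truth = y, causal = "var1"))
}
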