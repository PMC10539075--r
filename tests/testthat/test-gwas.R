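fixture_dir <- local({
  d <- tempfile("fix")
  make_fixtures(d, n = 200, n_variants = 8, seed = 71)
  d
})

test_that("PLINK bed round-trips the dosage matrix exactly", {
  set.seed(72)
  n <- 20; m <- 5
  geno <- matrix(rbinom(n * m, 2, 0.3), n, m)
  geno[1, 2] <- NA
  variants <- data.frame(chrom = 1, id = paste0("v", 1:m),
                         pos = 1:m * 100, a1 = "A", a2 = "G")
  prefix <- tempfile()
  write_plink(prefix, geno, variants, sprintf("I%02d", 1:n))
  gp <- read_plink(prefix)
  # undo the minor-allele orientation to compare raw dosages
  raw <- gp$geno
  raw[, gp$variants$swapped] <- 2 - raw[, gp$variants$swapped]
  expect_equal(unname(raw), geno)
  expect_true(is.na(gp$geno[1, 2]))
  expect_equal(gp$variants$missing_rate[2], 1 / n)
  expect_error(read_plink(tempfile()), "companion")
})

test_that("VCF genotypes agree with PLINK and honour missing GT", {
  gp <- read_plink(file.path(fixture_dir, "toy"))
  gv <- read_vcf_genotypes(file.path(fixture_dir, "toy.vcf"))
  expect_equal(unname(gp$geno), unname(gv$geno))
  # inject a missing genotype
  lines <- readLines(file.path(fixture_dir, "toy.vcf"))
  body <- strsplit(lines[length(lines)], "\t")[[1]]
  body[10] <- "./."
  f2 <- tempfile(fileext = ".vcf")
  writeLines(c(lines[-length(lines)], paste(body, collapse = "\t")), f2)
  gv2 <- read_vcf_genotypes(f2)
  expect_true(is.na(gv2$geno[1, ncol(gv2$geno)]))
})

test_that("variants are oriented to the minor allele", {
  set.seed(73)
  n <- 100
  geno <- cbind(rbinom(n, 2, 0.7), rbinom(n, 2, 0.2))  # first is major-coded
  variants <- data.frame(chrom = 1, id = c("hi", "lo"), pos = c(1, 2),
                         a1 = "A", a2 = "G")
  prefix <- tempfile()
  write_plink(prefix, geno, variants, sprintf("I%03d", 1:n))
  gp <- read_plink(prefix)
  expect_true(gp$variants$swapped[1])
  expect_false(gp$variants$swapped[2])
  expect_equal(gp$variants$minor[1], "G")
  expect_lt(gp$variants$maf[1], 0.5)
  expect_equal(gp$geno[, 1], 2 - geno[, 1], ignore_attr = TRUE)
})

test_that("scan flags the planted causal variant and keeps nulls uniform", {
  set.seed(74)
  n <- 3000; m <- 51
  d <- tempfile()
  make_fixtures(d, n = n, n_variants = m, beta = 0.4, seed = 75)
  gp <- read_plink(file.path(d, "toy"))
  ph <- read_subject_table(file.path(d, "pheno.tsv"))
  cv <- read_subject_table(file.path(d, "covar.tsv"))
  pr <- read_subject_table(file.path(d, "probs.tsv"))
  p <- pr$P_AFFECTED[match(ph$IID, pr$IID)]
  st <- subject_status(ph$STATUS, p)
  coh <- wip_cohort(st, as.matrix(cv[, "SEX", drop = FALSE]),
                    matrix(0, n, 1))
  scan <- run_scan(gp, coh, method = "wip")
  expect_equal(scan$SNP[which.min(scan$P)], "var1")
  nullp <- scan$P[scan$SNP != "var1"]
  expect_gt(suppressWarnings(ks.test(nullp, "punif")$p.value), 0.01)
  # association output invariant under subject permutation
  perm <- sample(n)
  gp2 <- gp; gp2$geno <- gp$geno[perm, ]; gp2$subjects <- gp$subjects[perm]
  coh2 <- wip_cohort(st[perm, ],
                     as.matrix(cv[perm, "SEX", drop = FALSE]),
                     matrix(0, n, 1))
  scan2 <- run_scan(gp2, coh2, method = "wip")
  expect_equal(scan$P, scan2$P, tolerance = 1e-9)
  # allele-orientation flip inverts the OR and leaves p unchanged
  gp3 <- gp
  gp3$geno[, 1] <- 2 - gp3$geno[, 1]
  gp3$variants$maf[1] <- 1 - mean(gp3$geno[, 1]) / 2  # force no re-swap
  scan3 <- run_scan(gp3, coh, method = "wip")
  i <- which(scan$SNP == "var1")
  expect_equal(scan3$OR[i], 1 / scan$OR[i], tolerance = 1e-6)
  expect_equal(scan3$P[i], scan$P[i], tolerance = 1e-9)
})

test_that("method flags agree where they must", {
  d <- tempfile()
  make_fixtures(d, n = 400, n_variants = 6, seed = 76,
                frac_missing_status = 0)
  gp <- read_plink(file.path(d, "toy"))
  ph <- read_subject_table(file.path(d, "pheno.tsv"))
  cv <- read_subject_table(file.path(d, "covar.tsv"))
  st <- subject_status(ph$STATUS)
  coh <- wip_cohort(st, as.matrix(cv[, "SEX", drop = FALSE]),
                    matrix(0, 400, 1))
  # no imputed subjects: identical output across all method flags
  s_lr <- run_scan(gp, coh, method = "lr")
  s_ip <- run_scan(gp, coh, method = "ip")
  s_wip <- run_scan(gp, coh, method = "wip")
  expect_equal(s_lr$P, s_ip$P)
  expect_equal(s_ip$P, s_wip$P)

  # probabilities all in {0, 1}: ip and wip coincide (weights all one)
  lab <- ph$STATUS
  miss <- sample(400, 60)
  y_true <- st$y
  lab[miss] <- "missing"
  p <- rep(NA_real_, 400); p[miss] <- as.numeric(y_true[miss])
  coh2 <- wip_cohort(subject_status(lab, p),
                     as.matrix(cv[, "SEX", drop = FALSE]),
                     matrix(0, 400, 1))
  expect_equal(run_scan(gp, coh2, method = "ip")$P,
               run_scan(gp, coh2, method = "wip")$P)
})

test_that("maf filter removes variants and adjustment fills ORADJ only", {
  set.seed(77)
  n <- 300
  geno <- cbind(rbinom(n, 2, 0.03), rbinom(n, 2, 0.3))
  variants <- data.frame(chrom = 1, id = c("rare", "common"), pos = 1:2,
                         a1 = "A", a2 = "G")
  prefix <- tempfile()
  write_plink(prefix, geno, variants, sprintf("I%03d", 1:n))
  gp <- read_plink(prefix)
  st <- subject_status(ifelse(rbinom(n, 1, 0.5) == 1, "case", "control"))
  coh <- wip_cohort(st, matrix(rnorm(n), ncol = 1,
                               dimnames = list(NULL, "cv")),
                    matrix(0, n, 1))
  expect_message(scan <- run_scan(gp, coh, method = "lr", min_maf = 0.05),
                 "filter")
  expect_false("rare" %in% scan$SNP)
  adj <- list(d_star = 0.5, gamma0 = 0.05, gamma1 = 0.1)
  scan2 <- run_scan(gp, coh, method = "lr", min_maf = 0.05, adjust = adj)
  expect_true(is.finite(scan2$ORADJ[1]))
  # p-values are never touched by the adjustment
  expect_equal(scan2$P, scan$P)
  B <- bias_factor(adj$gamma0, adj$gamma1)
  expect_equal(log(scan2$ORADJ[1]),
               adjust_coefficient(log(scan2$OR[1]), B, adj$d_star))
})

test_that("genomic inflation diagnostic behaves", {
  set.seed(78)
  p <- runif(1e5)
  l <- genomic_inflation(p)
  expect_gt(l, 0.98); expect_lt(l, 1.02)
  expect_gt(genomic_inflation(p / 2), l)       # stronger signal inflates
  expect_equal(genomic_inflation(rep(0.5, 200)), 1, tolerance = 1e-12)
})

test_that("score-test scan matches the Wald scan direction", {
  d <- tempfile()
  make_fixtures(d, n = 500, n_variants = 5, beta = 0.6, seed = 79)
  gp <- read_plink(file.path(d, "toy"))
  ph <- read_subject_table(file.path(d, "pheno.tsv"))
  cv <- read_subject_table(file.path(d, "covar.tsv"))
  pr <- read_subject_table(file.path(d, "probs.tsv"))
  p <- pr$P_AFFECTED[match(ph$IID, pr$IID)]
  coh <- wip_cohort(subject_status(ph$STATUS, p),
                    as.matrix(cv[, "SEX", drop = FALSE]),
                    matrix(0, 500, 1))
  sw <- run_scan(gp, coh, method = "wip", test = "wald")
  ss <- run_scan(gp, coh, method = "wip", test = "score")
  expect_equal(which.min(sw$P), which.min(ss$P))
  expect_gt(cor(-log10(sw$P), -log10(ss$P)), 0.99)
})
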