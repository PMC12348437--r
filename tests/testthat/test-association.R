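makePheno <- function(ck, nacl, trait = "TRL", accession = "ACC001",
                      reps = 1) {
  do.call(rbind, lapply(seq_len(reps), function(r)
    data.frame(accession = accession, trait = trait,
               condition = rep(c("CK", "NaCl"), c(length(ck), length(nacl))),
               replicate = r, plant = c(seq_along(ck), seq_along(nacl)),
               value = c(ck, nacl))))
}

test_that("RSIR is the percent drop of the NaCl mean from the CK mean", {
  r <- computeRSIR(makePheno(rep(10, 5), rep(7, 5), reps = 3))
  expect_equal(r$rsir, 30)
  expect_equal(computeRSIR(makePheno(rep(4, 3), rep(4, 3)))$rsir, 0)
  # trait increasing under NaCl gives a negative, retained RSIR
  neg <- computeRSIR(makePheno(rep(10, 3), rep(12, 3)))
  expect_equal(neg$rsir, -20)
  # zero CK mean is excluded and flagged
  z <- computeRSIR(makePheno(rep(0, 3), rep(2, 3)))
  expect_equal(nrow(z), 0L)
  expect_equal(nrow(attr(z, "excluded")), 1L)
})

test_that("RSIR is invariant to plant and replicate ordering", {
  sim <- sharedStudy()
  ph <- sim$pheno[sim$pheno$trait == "RD", ]
  r1 <- computeRSIR(ph)
  withr::with_seed(2, {
    r2 <- computeRSIR(ph[sample(nrow(ph)), ])
  })
  m1 <- setNames(r1$rsir, r1$accession)
  m2 <- setNames(r2$rsir, r2$accession)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("QC thresholds are strict at both boundaries", {
  # 100 accessions, 10 hom-alt (20 alt alleles of 200): MAF exactly 0.10
  calls <- matrix("0/0", 1, 100)
  calls[1, 1:10] <- "1/1"
  expect_false(qcSnps(makeTestPanel(calls))$qc_pass)
  # 6 missing of 114 = 5.26% missing
  calls <- matrix("0/0", 1, 114)
  calls[1, 1:30] <- "1/1"
  calls[1, 31:36] <- "./."
  q <- qcSnps(makeTestPanel(calls))
  expect_gt(q$maf, 0.10)
  expect_false(q$qc_pass)
  # MAF 0.26, no missing: passes
  calls <- matrix("0/0", 1, 100)
  calls[1, 1:26] <- "1/1"
  q <- qcSnps(makeTestPanel(calls))
  expect_equal(q$maf, 0.26)
  expect_true(q$qc_pass)
  # monomorphic SNP fails with MAF 0
  q0 <- qcSnps(makeTestPanel(matrix("0/0", 1, 50)))
  expect_equal(q0$maf, 0)
  expect_false(q0$qc_pass)
})

scanOne <- function(dose, y, n_pcs = 0) {
  calls <- matrix(c("0/0", "0/1", "1/1")[dose + 1], nrow = 1)
  colnames(calls) <- names(y)
  rownames(calls) <- "s01"
  panel <- makeTestPanel(calls)
  rsir <- data.frame(accession = names(y), trait = "TRL", rsir = y)
  qc <- data.frame(snp_id = "s01", maf = 0.3, missing_rate = 0,
                   qc_pass = TRUE)
  associateRSIR(panel, rsir, "TRL", n_pcs = n_pcs, qc = qc)
}

test_that("the simple scan reproduces the correlation t closed form", {
  withr::with_seed(11, {
    for (rep in seq_len(25)) {
      n <- sample(10:60, 1)
      dose <- sample(0:2, n, TRUE)
      if (sd(dose) == 0) next
      y <- rnorm(n) + 0.3 * dose
      names(y) <- sprintf("A%03d", seq_len(n))
      res <- scanOne(dose, y)
      r <- cor(dose, y)
      p_closed <- 2 * (1 - pt(abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
      expect_equal(res$p_value, p_closed, tolerance = 1e-10)
    }
  })
})

test_that("a dosage-proportional phenotype is detected and matches a permutation oracle", {
  dose <- rep(0:2, each = 4)
  y <- setNames(as.numeric(dose), sprintf("A%02d", 1:12))
  res <- scanOne(dose, y + rnorm(12, 0, 1e-6))
  expect_lt(res$p_value, 1e-6)
  # permutation of accession labels over the regression slope
  obs <- abs(cor(dose, y))
  B <- 100000
  exceed <- withr::with_seed(4, {
    sum(replicate(B, abs(cor(dose, sample(y))) >= obs - 1e-12))
  })
  expect_lt((exceed + 1) / (B + 1), 1e-3)
})

test_that("significance requires -log10 p strictly above the threshold", {
  withr::with_seed(9, {
    n <- 40
    dose <- sample(0:2, n, TRUE)
    y <- setNames(rnorm(n) + 0.5 * dose, sprintf("A%03d", seq_len(n)))
    res <- scanOne(dose, y)
    # a threshold set exactly at the observed statistic excludes the SNP
    res2 <- associateRSIR(makeTestPanel(matrix(c("0/0", "0/1", "1/1")[dose + 1],
                                               nrow = 1,
                                               dimnames = list("s01", names(y)))),
                          data.frame(accession = names(y), trait = "TRL",
                                     rsir = unname(y)),
                          "TRL", n_pcs = 0,
                          qc = data.frame(snp_id = "s01", maf = 0.3,
                                          missing_rate = 0, qc_pass = TRUE),
                          neg_log10_threshold = res$neg_log10_p)
    expect_false(res2$significant)
  })
})

test_that("degenerate scans are refused or skipped", {
  y <- setNames(rep(5, 10), sprintf("A%02d", 1:10))
  expect_error(scanOne(rep(0:1, 5), y), "constant phenotype")
  # zero dosage variance: skipped with a log entry
  y2 <- setNames(rnorm(10), sprintf("A%02d", 1:10))
  res <- scanOne(rep(1, 10), y2)
  expect_equal(nrow(res), 0L)
  expect_identical(attr(res, "skipped"), "s01")
  expect_error(associateRSIR(makeTestPanel(matrix("0/0", 1, 2,
                                                  dimnames = list("s01", c("A1", "A2")))),
                             data.frame(accession = c("A1", "A2"),
                                        trait = "TRL", rsir = c(1, 2)),
                             "TRL"),
               "at least 3")
})

test_that("SNP context and coding effects are strand-aware", {
  # plus-strand gene: 2 exons, CDS CGA CAA GGG TAA -> protein R Q G *
  cds <- "CGACAAGGGTAA"
  genes <- data.frame(gene_id = "gp", chrom = "2D", start = 3000, end = 3111,
                      strand = "+")
  exons <- list(gp = IRanges::IRanges(start = c(3000, 3106),
                                      end = c(3005, 3111)))
  cat <- makeTestCatalog(genes, cds = c(gp = cds), exons = exons)

  # CGA -> CGG: synonymous (both Arg); third codon base at CDS pos 3
  expect_identical(annotateSnpContext(cat, "gp", 3002, alt = "G")$coding_effect,
                   "synonymous")
  # CAA -> TAA: premature stop; CDS pos 4 sits in exon 1 (position 3003)
  ann <- annotateSnpContext(cat, "gp", 3003, alt = "T")
  expect_identical(ann$coding_effect, "nonsense")
  # intron, promoter, 3'UTR, outside
  expect_identical(annotateSnpContext(cat, "gp", 3050)$context, "intron")
  expect_identical(annotateSnpContext(cat, "gp", 3000 - 1500)$context,
                   "promoter")
  expect_identical(annotateSnpContext(cat, "gp", 3111 + 200)$context, "utr3")
  expect_error(annotateSnpContext(cat, "gp", 3111 + 700), "outside")

  # minus-strand gene: promoter lies downstream in genome coordinates
  genes_m <- data.frame(gene_id = "gm", chrom = "3B", start = 5000, end = 5111,
                        strand = "-")
  cat_m <- makeTestCatalog(genes_m)
  expect_identical(annotateSnpContext(cat_m, "gm", 5111 + 1500)$context,
                   "promoter")
  expect_identical(annotateSnpContext(cat_m, "gm", 5000 - 200)$context, "utr3")
})

test_that("Manhattan tables are genome-ordered with monotone offsets", {
  snps <- GenomicRanges::GRanges(
    seqnames = c("2B", "1A", "2B"),
    ranges = IRanges::IRanges(c(500, 900, 200), width = 1),
    snp_id = c("b", "a", "c"), ref = "A", alt = "G",
    display_id = c("x", "y", "z"))
  res <- data.frame(snp_id = c("a", "b", "c"), trait = "TRL",
                    neg_log10_p = c(1, 2, 3),
                    significant = FALSE)
  tab <- manhattanTable(res, snps)
  expect_identical(tab$snp_id, c("a", "c", "b"))
  expect_true(all(diff(tab$cumulative_pos) > 0))
  expect_equal(nrow(manhattanTable(res[0, ], snps)), 0L)
  # position ties resolve by snp_id
  snps2 <- snps
  GenomicRanges::ranges(snps2) <- IRanges::IRanges(rep(500, 3), width = 1)
  tab2 <- manhattanTable(res, snps2)
  expect_identical(tab2$snp_id[2:3], c("b", "c"))
})
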