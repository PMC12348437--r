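test_that("simulated genome places members on homoeologous chromosomes", {
  cfg <- SimConfig(seed = 3, n_members = 5, tandem_fraction = 0,
                   decoy_fraction = 0.2)
  sim <- simulateGenome(cfg)
  gr <- geneRanges(sim$catalog)
  expect_length(GenomeInfoDb::seqlengths(gr), 21L)
  expect_setequal(names(GenomeInfoDb::seqlengths(gr)), wheatChromosomes())

  truth <- memberOf(sim$truth)
  fam <- names(truth)[!is.na(truth)]
  expect_lte(length(fam), 15L)                      # <= 3 copies x 5 members
  expect_equal(length(unique(truth[fam])), 5L)
  expect_setequal(scanNamDomain(proteinSequences(sim$catalog)), fam)

  # copies of one member sit on same-numbered chromosomes, distinct subgenomes
  idx <- match(fam, gr$gene_id)
  for (m in unique(truth[fam])) {
    here <- idx[truth[fam] == m]
    expect_length(unique(gr$group_number[here]), 1L)
    expect_equal(anyDuplicated(gr$subgenome[here]), 0L)
  }
})

test_that("member copies share at least 95% protein identity", {
  sim <- sharedStudy()
  truth <- memberOf(sim$truth)
  fam <- names(truth)[!is.na(truth)]
  prot <- proteinSequences(sim$catalog)
  for (m in unique(truth[fam])[1:4]) {
    copies <- fam[truth[fam] == m]
    if (length(copies) < 2L) next
    pid <- saltNAC:::proteinIdentity(prot[[copies[1]]], prot[[copies[2]]])
    expect_gte(pid, 0.95)
  }
})

test_that("forced subgenome presence yields full homoeolog triads", {
  cfg <- SimConfig(seed = 11, n_members = 4, subgenome_presence = 1,
                   tandem_fraction = 0)
  sim <- simulateGenome(cfg)
  truth <- memberOf(sim$truth)
  fam <- truth[!is.na(truth)]
  expect_true(all(table(fam) == 3L))
})

test_that("tandem cluster copies lie on one chromosome within the gap rule", {
  cfg <- SimConfig(seed = 8, n_members = 12, tandem_fraction = 1)
  sim <- simulateGenome(cfg)
  gr <- geneRanges(sim$catalog)
  cl <- clusterOf(sim$truth)
  clustered <- names(cl)[!is.na(cl)]
  expect_gt(length(clustered), 0L)
  for (cc in unique(cl[clustered])) {
    genes <- clustered[cl[clustered] == cc]
    i <- match(genes, gr$gene_id)
    expect_length(unique(as.character(GenomicRanges::seqnames(gr)[i])), 1L)
    gaps <- diff(sort(GenomicRanges::start(gr)[i]))
    expect_true(all(gaps <= 1e7))
    expect_gte(length(genes), 2L)
    expect_lte(length(genes), 9L)
  }
})

test_that("an undersized chromosome raises a sizing error", {
  expect_error(simulateGenome(SimConfig(seed = 1, chromosome_length = 5e5)),
               "too small")
})

test_that("a fixed seed reproduces every study file byte for byte", {
  cfg <- SimConfig(seed = 5, n_members = 4,
                   causal_spec = data.frame(member = 1L, trait = "TRL",
                                            variance_explained = 0.2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSimulatedStudy(cfg, d1)
  writeSimulatedStudy(cfg, d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
})

test_that("noise-free expression recovers every trajectory label", {
  cfg <- SimConfig(seed = 21, n_members = 12, replicate_cv = 0)
  g <- simulateGenome(cfg)
  e <- simulateExpression(g$catalog, cfg, g$truth)
  de <- callDifferentialExpression(e$expr)
  traj <- classifyTrajectories(de)
  truth <- trajectoryOf(e$truth)
  for (i in seq_len(nrow(traj))) {
    g_i <- traj$gene_id[i]
    if (truth[g_i] == "nonDE") {
      expect_false(traj$salt_responsive[i])
    } else {
      expect_true(traj$salt_responsive[i])
      expect_equal(paste0("Group", traj$group[i]), unname(truth[g_i]))
    }
  }
})

test_that("generated VCF round-trips through the reader without loss", {
  sim <- sharedStudy()
  path <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypesVcf(sim$panel, path)
  back <- readGenotypesVcf(path)
  expect_identical(genotypeCalls(back), genotypeCalls(sim$panel))
  expect_identical(back@snps$snp_id, sim$panel@snps$snp_id)
  expect_identical(back@snps$ref, sim$panel@snps$ref)
  expect_identical(back@snps$alt, sim$panel@snps$alt)
  expect_identical(GenomicRanges::start(snpRanges(back)),
                   GenomicRanges::start(snpRanges(sim$panel)))
  expect_identical(back@snps$display_id, sim$panel@snps$display_id)
})

test_that("planted variance explained is realized in RSIR", {
  r2 <- vapply(seq_len(30), function(s) {
    cfg <- SimConfig(seed = 500 + s, n_members = 2,
                     causal_spec = data.frame(member = 1L, trait = "TRL",
                                              variance_explained = 0.25))
    g <- simulateGenome(cfg)
    p <- simulatePopulation(g$catalog, cfg, g$truth)
    rsir <- computeRSIR(p$pheno[p$pheno$trait == "TRL", ])
    d <- dosageMatrix(p$panel)[causalSnps(p$truth)$snp_id[1], ]
    y <- setNames(rsir$rsir, rsir$accession)[names(d)]
    ok <- complete.cases(d, y)
    cor(d[ok], y[ok])^2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.25), 0.1)
})

test_that("control traits are free of the planted genetic effect", {
  sim <- sharedStudy()
  cs <- causalSnps(sim$truth)
  d <- dosageMatrix(sim$panel)[cs$snp_id[1], ]
  ck <- sim$pheno[sim$pheno$trait == cs$trait[1] &
                    sim$pheno$condition == "CK", ]
  mu <- tapply(ck$value, ck$accession, mean)
  ok <- complete.cases(d, mu[names(d)])
  r2 <- cor(d[ok], mu[names(d)][ok])^2
  expect_lt(r2, 0.05)
})

test_that("truth labels survive the JSON round trip", {
  sim <- sharedStudy()
  path <- withr::local_tempfile(fileext = ".json")
  writeTruthJson(sim$truth, path)
  back <- readTruthJson(path)
  expect_identical(memberOf(back), memberOf(sim$truth))
  expect_identical(clusterOf(back), clusterOf(sim$truth))
  expect_identical(trajectoryOf(back), trajectoryOf(sim$truth))
  expect_equal(causalSnps(back)$snp_id, causalSnps(sim$truth)$snp_id)
  expect_identical(haplotypeBlocks(back)[[1]],
                   haplotypeBlocks(sim$truth)[[1]])
})

test_that("invalid configurations are rejected", {
  expect_error(SimConfig(trajectory_mix = c(Group1 = 0.5, Group2 = 0.2,
                                            Group3 = 0.1, Group4 = 0.1,
                                            nonDE = 0.2)), "sum to 1")
  expect_error(SimConfig(n_members = 0), ">= 1")
  expect_error(SimConfig(causal_spec = data.frame(member = 1L, trait = "TRL",
                                                  variance_explained = 1.2)),
               "variance_explained")
  expect_error(SimConfig(causal_spec = data.frame(member = 99L, trait = "TRL",
                                                  variance_explained = 0.2)),
               "nonexistent")
})
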