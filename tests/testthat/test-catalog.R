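test_that("domain scan keeps motif carriers and rejects decoys", {
  motif <- namMotifConsensus()
  withr::with_seed(1, {
    pad <- function(n) paste(sample(saltNAC:::aaAlphabet(), n, TRUE),
                             collapse = "")
    carrier <- paste0(pad(40), motif, pad(60))
    decoy <- pad(150)
    kept <- scanNamDomain(c(hit = carrier, miss = decoy))
    expect_identical(kept, "hit")
  })
  expect_identical(scanNamDomain(Biostrings::AAStringSet()), character())
  # threshold tolerates mismatches up to the configured score
  mutated <- motif
  substr(mutated, 3, 3) <- if (substr(motif, 3, 3) == "A") "C" else "A"
  expect_identical(scanNamDomain(c(x = mutated)), "x")
})

test_that("homoeologs group by identity across subgenomes", {
  withr::with_seed(7, {
    base <- paste(sample(saltNAC:::aaAlphabet(), 100, TRUE), collapse = "")
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      i <- sample(length(ch), k)
      ch[i] <- vapply(ch[i], function(a)
        sample(setdiff(saltNAC:::aaAlphabet(), a), 1), character(1))
      paste(ch, collapse = "")
    }
    cat3 <- makeTestCatalog(
      data.frame(gene_id = c("gA", "gB", "gD"),
                 chrom = c("2A", "2B", "2D"),
                 start = c(100, 100, 100), end = c(400, 400, 400),
                 strand = "+"),
      proteins = c(gA = base, gB = mut(base, 4), gD = mut(base, 4)))
    out <- groupHomoeologs(cat3, identity_threshold = 0.9)
    expect_length(unique(memberTable(out)$member), 1L)

    cat2 <- makeTestCatalog(
      data.frame(gene_id = c("g1", "g2"), chrom = c("2A", "3B"),
                 start = 100, end = 400, strand = "+"),
      proteins = c(g1 = base, g2 = mut(base, 60)))
    out2 <- groupHomoeologs(cat2, identity_threshold = 0.9)
    expect_length(unique(memberTable(out2)$member), 2L)
  })
  expect_error(groupHomoeologs(sharedStudy()$catalog, identity_threshold = 0),
               "identity_threshold")
})

test_that("synthetic member partition is recovered exactly", {
  sim <- sharedStudy()
  built <- buildCatalog(sim$catalog)
  mt <- memberTable(built)
  truth <- memberOf(sim$truth)[mt$gene_id]
  # same partition: the member labelling must be a bijection
  expect_equal(length(unique(mt$member)), length(unique(truth)))
  expect_true(all(tapply(mt$member, truth, function(x) length(unique(x))) == 1))
  # decoys are screened out
  expect_false(any(is.na(truth)))
  # tandem clusters match the generator labels
  cl_truth <- clusterOf(sim$truth)[mt$gene_id]
  expect_identical(is.na(mt$cluster_id), unname(is.na(cl_truth)))
  both <- !is.na(cl_truth)
  expect_true(all(tapply(mt$cluster_id[both], cl_truth[both],
                         function(x) length(unique(x))) == 1))
})

test_that("tandem chaining equals transitive closure on random instances", {
  withr::with_seed(123, {
    for (rep in seq_len(200)) {
      n <- sample(2:20, 1)
      pos <- sort(sample(seq(1, 2e8), n))
      chain <- saltNAC:::tandemChains(pos)
      oracle <- closureOracle(pos)
      expect_true(all(tapply(chain, oracle, function(x) length(unique(x))) == 1))
      expect_equal(length(unique(chain)), length(unique(oracle)))
    }
  })
})

test_that("tandem clusters follow the consecutive-gap rule", {
  mk <- function(starts) {
    cat <- makeTestCatalog(
      data.frame(gene_id = paste0("g", seq_along(starts)), chrom = "2D",
                 start = starts, end = starts + 1000, strand = "+"))
    cat <- groupHomoeologs(cat, provided_map = setNames(
      rep(1L, length(starts)), paste0("g", seq_along(starts))))
    memberTable(detectTandemClusters(cat))$cluster_id
  }
  expect_length(unique(mk(c(1e6, 9e6))), 1L)            # 8 Mb gap: clustered
  expect_true(all(is.na(mk(c(1e6, 2.5e7)))))            # 24 Mb gap: singletons
  cl3 <- mk(c(1e6, 9e6, 1.8e7))                         # chained 1/9/18 Mb
  expect_length(unique(cl3), 1L)
  expect_false(any(is.na(cl3)))
})

test_that("member numbering follows physical position and names are unique", {
  genes <- data.frame(
    gene_id = c("x1", "x2", "y1", "z1", "z2", "z3"),
    chrom = c("2A", "2B", "1D", "2D", "2D", "2D"),
    start = c(5e6, 5.2e6, 1e6, 2e6, 4e6, 9e6),
    end = c(5e6, 5.2e6, 1e6, 2e6, 4e6, 9e6) + 1200,
    strand = "+")
  cat <- makeTestCatalog(genes)
  map <- c(x1 = 10L, x2 = 10L, y1 = 20L, z1 = 30L, z2 = 30L, z3 = 30L)
  cat <- groupHomoeologs(cat, provided_map = map)
  named <- assignMemberNames(cat)
  mt <- memberTable(named)
  nm <- setNames(mt$name, mt$gene_id)
  # chromosome group 1 before group 2
  expect_identical(nm[["y1"]], "TaNAC1-D")
  # homoeolog pair: subgenome letters, no rank needed
  expect_setequal(nm[c("x1", "x2")], c("TaNAC3-A", "TaNAC3-B"))
  # three copies on 2D: positional ranks
  expect_identical(unname(nm[c("z1", "z2", "z3")]),
                   c("TaNAC2-D1", "TaNAC2-D2", "TaNAC2-D3"))
  expect_equal(anyDuplicated(mt$name), 0L)

  # annotation-supplied sub-index produces the dotted grammar
  dotted <- assignMemberNames(cat, sub_index = c(z3 = 2L))
  expect_identical(setNames(memberTable(dotted)$name,
                            memberTable(dotted)$gene_id)[["z3"]],
                   "TaNAC2-D3.2")

  # permutation stability
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  cat_p <- makeTestCatalog(genes[perm, ])
  named_p <- assignMemberNames(groupHomoeologs(cat_p, provided_map = map))
  mt_p <- memberTable(named_p)
  expect_identical(setNames(mt_p$name, mt_p$gene_id)[names(nm)], nm)
})

test_that("reference matching demands full-length identity", {
  sim <- sharedStudy()
  prot <- proteinSequences(sim$catalog)
  target <- as.character(prot[[3]])
  off <- sub("^.", ifelse(startsWith(target, "A"), "C", "A"), target)
  ext <- Biostrings::AAStringSet(c(pub1 = target, pub2 = off, pub3 = target))
  tab <- matchReferenceSequences(sim$catalog, ext)
  expect_identical(tab$gene_id[tab$external_id == "pub1"], names(prot)[3])
  expect_identical(tab$gene_id[tab$external_id == "pub3"], names(prot)[3])
  expect_true(is.na(tab$gene_id[tab$external_id == "pub2"]))
})

test_that("expression level classes split at zero and one", {
  expect_identical(classifyExpressionLevel(c(5.2, 0.4, 0)),
                   c("normal", "low", "none"))
  expect_identical(classifyExpressionLevel(1), "normal")
  expect_identical(classifyExpressionLevel(1e-12), "none")
  expect_error(classifyExpressionLevel(-0.1), "nonnegative")
})

test_that("catalogue summary percentages round half-up to two decimals", {
  s <- catalogSummary(145, 182, 119, 118, 32)
  expect_identical(unname(s$class_pct),
                   c(32.51, 40.81, 26.68))
  expect_identical(s$tandem_member_pct, 27.12)
  expect_identical(catalogSummary(0, 5, 5, 4, 0)$class_pct[["normal"]], 0)
  expect_identical(catalogSummary(1, 1, 1, 3, 1)$class_pct[["normal"]], 33.33)
  expect_error(catalogSummary(0, 0, 0, 0, 0), "empty")
})

test_that("a full catalogue summary counts genes, members and classes", {
  sim <- sharedStudy()
  built <- classifyCatalogExpression(buildCatalog(sim$catalog), sim$expr)
  s <- summarizeCatalog(built)
  expect_equal(unname(sum(s$class_counts)), s$n_genes)
  expect_equal(sum(s$class_pct), 100, tolerance = 0.02)
  expect_equal(sum(s$per_chromosome), s$n_genes)
  truth <- memberOf(sim$truth)
  expect_equal(s$n_members, length(unique(truth[!is.na(truth)])))
})
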