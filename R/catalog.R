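#' @include io.R
NULL

#' Screen proteins for the family domain motif
#'
#' Slides the 30-residue consensus motif over each protein and retains genes
#' whose best window matches the consensus in at least \code{threshold}
#' positions (default 90\% of the consensus self-score). This is a
#' deterministic consensus scan, the package's screening stand-in for a
#' profile-HMM domain search.
#'
#' @param proteins an \code{AAStringSet} (or named character vector) of
#'   protein sequences.
#' @param motif consensus motif string.
#' @param threshold minimum number of matching positions in the best window.
#' @return Character vector of retained sequence names.
#' @examples
#' scanNamDomain(Biostrings::AAStringSet(c(g1 = namMotifConsensus())))
#' @export
scanNamDomain <- function(proteins, motif = namMotifConsensus(),
                          threshold = ceiling(0.9 * nchar(motif))) {
  if (is.character(proteins))
    proteins <- Biostrings::AAStringSet(proteins)
  if (length(proteins) == 0L) return(character())
  if (threshold > nchar(motif))
    stop("threshold cannot exceed the motif self-score")
  wide <- Biostrings::width(proteins) >= nchar(motif)
  hits <- rep(FALSE, length(proteins))
  hits[wide] <- Biostrings::vcountPattern(
    motif, proteins[wide], max.mismatch = nchar(motif) - threshold) > 0L
  names(proteins)[hits]
}

# Global protein identity (matches / alignment length) with unit
# match/mismatch scores.
proteinIdentity <- function(a, b) {
  letters <- unique(strsplit(paste0(as.character(a), as.character(b)), "")[[1]])
  mat <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 1, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Group gene copies into homoeolog members
#'
#' Without an external map, members are the connected components of the
#' graph whose edges join genes of the same homoeologous chromosome group
#' (different subgenomes, or duplicates on one chromosome) with global
#' protein identity at or above \code{identity_threshold}. Singleton members
#' are allowed. When \code{provided_map} is given (the faithful path when an
#' external homoeologue annotation exists) it is used directly.
#'
#' @param catalog a \linkS4class{NacCatalog}; only genes present in
#'   \code{proteinSequences(catalog)} are grouped.
#' @param identity_threshold fraction in (0, 1].
#' @param provided_map optional named integer/character vector gene_id ->
#'   member covering all genes.
#' @return The catalogue with the member table's \code{member} column filled
#'   (provisional component ids; [assignMemberNames()] renumbers them).
#' @export
groupHomoeologs <- function(catalog, identity_threshold = 0.9,
                            provided_map = NULL) {
  gr <- geneRanges(catalog)
  ids <- gr$gene_id
  if (!is.null(provided_map)) {
    if (!all(ids %in% names(provided_map)))
      stop("provided_map must cover all genes")
    member <- as.integer(factor(provided_map[ids]))
  } else {
    if (identity_threshold <= 0 || identity_threshold > 1)
      stop("identity_threshold must be in (0, 1]")
    prot <- proteinSequences(catalog)
    edges <- character()
    for (grp in unique(gr$group_number)) {
      here <- which(gr$group_number == grp & ids %in% names(prot))
      if (length(here) < 2L) next
      pairs <- utils::combn(here, 2L)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        pid <- proteinIdentity(prot[[ids[i]]], prot[[ids[j]]])
        if (pid >= identity_threshold)
          edges <- c(edges, ids[i], ids[j])
      }
    }
    g <- igraph::graph_from_data_frame(
      d = if (length(edges))
        data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)])
      else data.frame(from = character(), to = character()),
      directed = FALSE,
      vertices = data.frame(name = ids))
    member <- as.integer(igraph::components(g)$membership[ids])
  }
  memberTable(catalog) <- S4Vectors::DataFrame(
    gene_id = ids, member = member,
    name = rep(NA_character_, length(ids)),
    cluster_id = rep(NA_character_, length(ids)))
  catalog
}

# Single-linkage chaining of sorted start coordinates: positions whose
# consecutive gaps are <= gap belong to one chain.
tandemChains <- function(starts, gap = 1e7) {
  o <- order(starts)
  breaks <- c(0L, cumsum(diff(starts[o]) > gap))
  chain <- integer(length(starts))
  chain[o] <- breaks + 1L
  chain
}

#' Detect tandem-duplication clusters within members
#'
#' Per member and chromosome, copies are chained by single linkage on start
#' coordinates: consecutive gaps of at most \code{gap} bp (default 10 Mb)
#' join a chain, and chains of two or more genes are tandem clusters. A
#' 1/9/18 Mb chain is therefore one cluster of three even though its ends
#' are 17 Mb apart.
#'
#' @param catalog a \linkS4class{NacCatalog} with members assigned.
#' @param gap maximum consecutive start-coordinate gap in bp.
#' @return The catalogue with \code{cluster_id} filled for clustered genes.
#' @export
detectTandemClusters <- function(catalog, gap = 1e7) {
  mt <- memberTable(catalog)
  if (!nrow(mt)) stop("run groupHomoeologs() first")
  gr <- geneRanges(catalog)
  idx <- match(mt$gene_id, gr$gene_id)
  chrom <- as.character(GenomicRanges::seqnames(gr))[idx]
  start <- GenomicRanges::start(gr)[idx]
  cluster <- rep(NA_character_, nrow(mt))
  for (key in unique(paste(mt$member, chrom))) {
    here <- which(paste(mt$member, chrom) == key)
    if (length(here) < 2L) next
    chain <- tandemChains(start[here], gap)
    for (cc in unique(chain)) {
      members_cc <- here[chain == cc]
      if (length(members_cc) >= 2L)
        cluster[members_cc] <- sprintf("M%s_%s_c%d", mt$member[here[1L]],
                                       chrom[here[1L]], cc)
    }
  }
  mt$cluster_id <- cluster
  memberTable(catalog) <- mt
  catalog
}

#' Number members and name every copy
#'
#' Members are sorted by physical position -- smallest homoeologous
#' chromosome group among the copies, then smallest start coordinate on that
#' group, with subgenome order A < B < D and gene id as tie-breaks -- and
#' numbered 1..N. Each copy is named \code{prefix + number + "-" + subgenome
#' letter}; when a member has more than one copy on a chromosome the copy's
#' 1-based positional rank is appended (e.g. \code{-D3}), and an optional
#' \code{sub_index} from the input annotation adds a dotted suffix
#' (\code{-D3.2}). Naming is deterministic and invariant to input order.
#'
#' @param catalog a \linkS4class{NacCatalog} with members assigned.
#' @param prefix name prefix (default \code{"TaNAC"}).
#' @param sub_index optional named integer vector (gene_id -> sub-index) for
#'   annotations that distinguish nested duplicates.
#' @return The catalogue with \code{member} renumbered and \code{name}
#'   filled; names are unique catalogue-wide.
#' @export
assignMemberNames <- function(catalog, prefix = "TaNAC", sub_index = NULL) {
  mt <- memberTable(catalog)
  if (!nrow(mt)) stop("run groupHomoeologs() first")
  if (anyDuplicated(mt$gene_id)) stop("duplicate gene ids")
  gr <- geneRanges(catalog)
  idx <- match(mt$gene_id, gr$gene_id)
  grp <- gr$group_number[idx]
  sgn <- gr$subgenome[idx]
  start <- GenomicRanges::start(gr)[idx]

  key <- lapply(split(seq_len(nrow(mt)), mt$member), function(i) {
    gmin <- min(grp[i])
    on_g <- i[grp[i] == gmin]
    list(g = gmin, s = min(start[on_g]),
         sub = min(match(sgn[on_g], c("A", "B", "D"))),
         id = min(mt$gene_id[on_g]))
  })
  ord <- order(vapply(key, `[[`, numeric(1), "g"),
               vapply(key, `[[`, numeric(1), "s"),
               vapply(key, `[[`, numeric(1), "sub"),
               vapply(key, `[[`, character(1), "id"))
  renum <- setNames(seq_along(ord), names(key)[ord])
  number <- renum[as.character(mt$member)]

  name <- character(nrow(mt))
  for (m in unique(number)) {
    i <- which(number == m)
    chrom <- paste0(grp[i], sgn[i])
    for (ch in unique(chrom)) {
      j <- i[chrom == ch]
      j <- j[order(start[j])]
      rank <- if (length(j) > 1L) as.character(seq_along(j)) else ""
      name[j] <- paste0(prefix, m, "-", sgn[j], rank)
    }
  }
  if (!is.null(sub_index)) {
    hit <- mt$gene_id %in% names(sub_index)
    name[hit] <- paste0(name[hit], ".", sub_index[mt$gene_id[hit]])
  }
  if (anyDuplicated(name)) stop("name grammar produced duplicate names")
  mt$member <- unname(number)
  mt$name <- name
  memberTable(catalog) <- mt
  catalog
}

#' Match catalogue proteins against published sequences
#'
#' An external record corresponds to a catalogue gene when the full-length
#' sequences are exactly identical (the 100\%-identity, E = 0 rule);
#' several published names may map to one catalogue gene.
#'
#' @param catalog a \linkS4class{NacCatalog}.
#' @param external an \code{AAStringSet} of published sequences.
#' @return data.frame(external_id, gene_id); unmatched records get NA.
#' @export
matchReferenceSequences <- function(catalog, external) {
  if (is.character(external)) external <- Biostrings::AAStringSet(external)
  prot <- toupper(as.character(proteinSequences(catalog)))
  ext <- toupper(as.character(external))
  hit <- names(prot)[match(ext, prot)]
  data.frame(external_id = names(external), gene_id = hit,
             stringsAsFactors = FALSE)
}

#' Classify a gene's expression level
#'
#' \code{none} when the mean FPKM is zero (below 1e-9), \code{low} below 1,
#' \code{normal} at 1 or above.
#'
#' @param mean_fpkm nonnegative mean FPKM over replicates at the reference
#'   condition; vectorized.
#' @return Character vector of classes.
#' @export
classifyExpressionLevel <- function(mean_fpkm) {
  if (any(mean_fpkm < 0)) stop("FPKM must be nonnegative")
  ifelse(mean_fpkm <= 1e-9, "none", ifelse(mean_fpkm < 1, "low", "normal"))
}

#' Catalogue summary from raw counts
#'
#' Percentages are 100 x count / total rounded half-up to two decimals; the
#' tandem percentage is over members, the expression-class percentages over
#' genes.
#'
#' @param n_normal,n_low,n_none gene counts per expression class.
#' @param n_members,n_tandem_members member counts.
#' @return list with counts and percentages.
#' @export
catalogSummary <- function(n_normal, n_low, n_none, n_members,
                           n_tandem_members) {
  n_genes <- n_normal + n_low + n_none
  if (n_genes == 0L) stop("empty catalogue")
  list(n_genes = n_genes, n_members = n_members,
       n_tandem_members = n_tandem_members,
       class_counts = c(normal = n_normal, low = n_low, none = n_none),
       class_pct = c(normal = roundHalfUp(100 * n_normal / n_genes),
                     low = roundHalfUp(100 * n_low / n_genes),
                     none = roundHalfUp(100 * n_none / n_genes)),
       tandem_member_pct = roundHalfUp(100 * n_tandem_members / n_members))
}

#' Summarize a catalogue
#'
#' Counts genes per chromosome and expression class and members with tandem
#' clusters; delegates percentage arithmetic to [catalogSummary()].
#'
#' @param catalog a \linkS4class{NacCatalog} whose member table has
#'   \code{member}, \code{cluster_id} and \code{expression_class} filled.
#' @return list as from [catalogSummary()], plus \code{per_chromosome}.
#' @export
summarizeCatalog <- function(catalog) {
  mt <- memberTable(catalog)
  if (!nrow(mt)) stop("empty catalogue")
  if (!"expression_class" %in% names(mt))
    stop("classify expression first (classifyCatalogExpression)")
  cls <- table(factor(mt$expression_class, c("normal", "low", "none")))
  tandem <- unique(mt$member[!is.na(mt$cluster_id)])
  out <- catalogSummary(cls[["normal"]], cls[["low"]], cls[["none"]],
                        length(unique(mt$member)), length(tandem))
  gr <- geneRanges(catalog)
  idx <- match(mt$gene_id, gr$gene_id)
  out$per_chromosome <- table(factor(
    as.character(GenomicRanges::seqnames(gr))[idx], wheatChromosomes()))
  out
}

#' Attach expression classes to the catalogue
#'
#' Classifies every catalogued gene by its mean FPKM across replicates at
#' the reference time point (0 h).
#'
#' @param catalog a \linkS4class{NacCatalog} with members assigned.
#' @param expr a \linkS4class{SaltExpressionSet} covering the catalogue
#'   genes.
#' @return The catalogue with an \code{expression_class} column.
#' @export
classifyCatalogExpression <- function(catalog, expr) {
  mt <- memberTable(catalog)
  fpkm <- SummarizedExperiment::assay(expr, "fpkm")
  ref <- SummarizedExperiment::colData(expr)$time == 0
  mu <- rowMeans(fpkm[, ref, drop = FALSE])
  if (!all(mt$gene_id %in% rownames(fpkm)))
    stop("expression data missing for some catalogue genes")
  mt$expression_class <- classifyExpressionLevel(mu[mt$gene_id])
  memberTable(catalog) <- mt
  catalog
}

#' Run the whole cataloguing stage
#'
#' Domain screen, homoeolog grouping, tandem detection and naming in one
#' call; genes failing the domain screen are dropped from the catalogue.
#'
#' @param catalog a raw \linkS4class{NacCatalog} (e.g. from
#'   [readCatalogFiles()] or [simulateGenome()]).
#' @param identity_threshold,provided_map passed to [groupHomoeologs()].
#' @param prefix passed to [assignMemberNames()].
#' @return The screened, grouped, clustered and named catalogue.
#' @export
buildCatalog <- function(catalog, identity_threshold = 0.9,
                         provided_map = NULL, prefix = "TaNAC") {
  keep <- scanNamDomain(proteinSequences(catalog))
  gr <- geneRanges(catalog)
  sel <- gr$gene_id %in% keep
  catalog@genes <- gr[sel]
  catalog@proteins <- proteinSequences(catalog)[keep]
  if (length(cdsSequences(catalog)))
    catalog@cds <- cdsSequences(catalog)[intersect(names(cdsSequences(catalog)),
                                                   keep)]
  catalog <- groupHomoeologs(catalog, identity_threshold, provided_map)
  catalog <- detectTandemClusters(catalog)
  assignMemberNames(catalog, prefix = prefix)
}
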