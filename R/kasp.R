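#' @include haplotype.R
NULL

#' Estimate a primer melting temperature
#'
#' Wallace rule 4(G+C) + 2(A+T) for oligos of at most 14 bases; the
#' GC-fraction formula 64.9 + 41 x (GC - 16.4) / length above that.
#' Deterministic and case-insensitive.
#'
#' @param seq primer sequence.
#' @return Tm estimate in degrees Celsius.
#' @export
estimateTm <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  gc <- lengths(regmatches(s, gregexpr("[GC]", s)))
  ifelse(n <= 14L, 4 * gc + 2 * (n - gc), 64.9 + 41 * (gc - 16.4) / n)
}

revComp <- function(seq) {
  up <- chartr("ACGTacgt", "TGCAtgca", seq)
  vapply(strsplit(up, ""), function(x) paste(rev(x), collapse = ""),
         character(1))
}

#' Design a KASP marker for a SNP
#'
#' Builds the two tailed allele-specific forward primers and the common
#' reverse primer. The gene-specific forward part is the 18--25 base window
#' of the flank ending exactly on the SNP whose Tm estimate is closest to
#' \code{target_tm}; the two forwards share it except for the 3'-terminal
#' base (reference allele behind the FAM tail, alternative behind HEX). The
#' common reverse anneals to the plus strand downstream of the SNP, its 3'
#' end 30--120 bp away, again Tm-selected. Ties are broken toward shorter
#' primers and smaller gaps so the design is deterministic.
#'
#' @param flank plus-strand sequence around the SNP.
#' @param snp_pos 1-based index of the SNP base within \code{flank}.
#' @param ref,alt the two alleles; \code{flank[snp_pos]} must equal
#'   \code{ref}.
#' @param snp_id identifier carried into the design.
#' @param target_tm target melting temperature (default 60).
#' @param primer_length allowed gene-specific primer lengths.
#' @param reverse_gap allowed distance from the SNP to the reverse primer's
#'   3' end.
#' @return A \linkS4class{KaspDesign}.
#' @export
designKasp <- function(flank, snp_pos, ref, alt, snp_id = "snp",
                       target_tm = 60, primer_length = c(18L, 25L),
                       reverse_gap = c(30L, 120L)) {
  ref <- as.character(ref); alt <- as.character(alt)
  if (toupper(ref) == toupper(alt)) stop("ref and alt alleles must differ")
  if (toupper(substr(flank, snp_pos, snp_pos)) != toupper(ref))
    stop("flank base at snp_pos does not match the reference allele")
  lens <- seq(primer_length[1], primer_length[2])
  lens <- lens[snp_pos - lens + 1L >= 1L]
  if (!length(lens)) stop("design failure: flank too short 5' of the SNP")
  cand <- vapply(lens, function(L)
    substr(flank, snp_pos - L + 1L, snp_pos), character(1))
  best <- order(abs(estimateTm(cand) - target_tm), lens)[1L]
  fwd <- cand[best]

  # allele-specific 3' base, preserving the flank's case convention
  setLast <- function(s, base) {
    cased <- if (grepl("[a-z]", substr(s, nchar(s), nchar(s))))
      tolower(base) else toupper(base)
    paste0(substr(s, 1L, nchar(s) - 1L), cased)
  }
  fam <- paste0(kaspTails()["FAM"], setLast(fwd, ref))
  hex <- paste0(kaspTails()["HEX"], setLast(fwd, alt))

  gaps <- seq(reverse_gap[1], reverse_gap[2])
  combos <- expand.grid(gap = gaps, L = lens)
  combos <- combos[snp_pos + combos$gap + combos$L - 1L <= nchar(flank), ]
  if (!nrow(combos)) stop("design failure: flank too short 3' of the SNP")
  rseq <- vapply(seq_len(nrow(combos)), function(k) {
    s <- snp_pos + combos$gap[k]
    substr(flank, s, s + combos$L[k] - 1L)
  }, character(1))
  rb <- order(abs(estimateTm(rseq) - target_tm), combos$gap, combos$L)[1L]
  rev_primer <- revComp(rseq[rb])
  fwd_start <- snp_pos - nchar(fwd) + 1L
  product <- (snp_pos + combos$gap[rb] + combos$L[rb] - 1L) - fwd_start + 1L

  methods::new("KaspDesign",
               snp_id = snp_id, ref = toupper(ref), alt = toupper(alt),
               fam_primer = unname(fam), hex_primer = unname(hex),
               common_reverse = unname(rev_primer),
               product_length = as.integer(product),
               tm_estimates = c(FAM = unname(estimateTm(fwd)),
                                HEX = unname(estimateTm(setLast(fwd, alt))),
                                common = unname(estimateTm(rev_primer))))
}
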