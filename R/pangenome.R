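# Ortholog clustering, shared/unshared gene counts, the family frequency
# spectrum, and ortholog-based ANI with aligned-length accounting.

#' Cluster genes into families by single linkage
#'
#' Builds the graph whose edges join gene pairs with local-alignment coverage
#' strictly above `coverage_cutoff` on *both* genes and identity strictly
#' above `identity_cutoff` (matches over alignment columns), then takes
#' connected components as families (single linkage). The default cutoffs
#' follow the >75%/>75% coverage-and-identity convention. Family ids are the
#' lexicographically smallest member gene id, which makes the clustering
#' deterministic.
#'
#' @param genes named list: strain -> named character vector of gene
#'   sequences; flat gene ids are "strain:gene".
#' @param identity_cutoff identity threshold in (0, 1]; strict inequality.
#' @param coverage_cutoff coverage threshold in (0, 1]; strict inequality;
#'   coverage = aligned span / gene length, required of both genes.
#' @return a [PresenceAbsenceMatrix-class] (strains x families) carrying one
#'   representative sequence per strain and family (the strain's first member
#'   gene in id order).
#' @export
clusterGeneFamilies <- function(genes, identity_cutoff = 0.75,
                                coverage_cutoff = 0.75) {
  if (identity_cutoff <= 0 || identity_cutoff > 1 ||
      coverage_cutoff <= 0 || coverage_cutoff > 1)
    stop("cutoffs must be in (0, 1]")
  strains <- names(genes)
  ids <- unlist(lapply(strains, function(s)
    paste0(s, ":", names(genes[[s]]))))
  seqs <- setNames(unlist(unname(genes)), ids)
  if (!length(seqs))
    return(PresenceAbsenceMatrix(
      matrix(FALSE, length(strains), 0,
             dimnames = list(strains, character()))))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  n <- length(seqs)
  edges <- matrix(integer(), ncol = 2)
  if (n > 1) {
    pair <- combn(n, 2)
    hits <- logical(ncol(pair))
    for (k in seq_len(ncol(pair))) {
      i <- pair[1, k]; j <- pair[2, k]
      aln <- Biostrings::pairwiseAlignment(seqs[i], seqs[j], type = "local",
                                           substitutionMatrix = submat,
                                           gapOpening = 2, gapExtension = 0.5)
      ap <- as.character(Biostrings::alignedPattern(aln))
      as_ <- as.character(Biostrings::alignedSubject(aln))
      cov_i <- nchar(gsub("-", "", ap, fixed = TRUE)) / nchar(seqs[i])
      cov_j <- nchar(gsub("-", "", as_, fixed = TRUE)) / nchar(seqs[j])
      idn <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
      hits[k] <- cov_i > coverage_cutoff && cov_j > coverage_cutoff &&
        idn > identity_cutoff
    }
    edges <- t(pair[, hits, drop = FALSE])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  fam_of <- vapply(split(ids, comp), function(members) min(members),
                   character(1))
  fam_ids <- unname(fam_of[as.character(comp)])
  strain_of <- sub(":.*$", "", ids)
  fams <- sort(unique(fam_ids))
  pa <- matrix(FALSE, length(strains), length(fams),
               dimnames = list(strains, fams))
  sequences <- setNames(vector("list", length(strains)), strains)
  for (s in strains) sequences[[s]] <- character()
  ord <- order(ids)
  for (k in ord) {
    s <- strain_of[k]; f <- fam_ids[k]
    pa[s, f] <- TRUE
    if (!f %in% names(sequences[[s]]))
      sequences[[s]][f] <- unname(seqs[k])
  }
  PresenceAbsenceMatrix(pa, sequences = sequences)
}

#' Shared and unshared family counts for a strain pair
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param strain_i,strain_j strain ids.
#' @return named integer vector `c(shared, unshared)`: intersection size and
#'   symmetric-difference size of the two strains' family sets.
#' @export
sharedUnshared <- function(pa, strain_i, strain_j) {
  pam <- paMatrix(pa)
  if (!strain_i %in% rownames(pam)) stop("unknown strain: ", strain_i)
  if (!strain_j %in% rownames(pam)) stop("unknown strain: ", strain_j)
  a <- pam[strain_i, ]; b <- pam[strain_j, ]
  c(shared = sum(a & b), unshared = sum(xor(a, b)))
}

#' Gene-family frequency spectrum with core/rare counts
#'
#' Histogram of per-family prevalence (number of carrier strains) plus the
#' core and rare tallies: core = families present in at least
#' `core_fraction` of strains, rare = families present in fewer than
#' `rare_fraction` of strains (the 90%/10% convention by default).
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param core_fraction core prevalence cutoff in (0, 1); `>=` rule.
#' @param rare_fraction rare prevalence cutoff in (0, 1); `<` rule.
#' @return list with `spectrum` (named integer vector: carrier count ->
#'   number of families), `prevalence` (per-family carrier fraction),
#'   `n_core`, `n_rare` and `n_families`.
#' @export
familyFrequencySpectrum <- function(pa, core_fraction = 0.9,
                                    rare_fraction = 0.1) {
  if (core_fraction <= 0 || core_fraction >= 1 ||
      rare_fraction <= 0 || rare_fraction >= 1)
    stop("fractions must be in (0, 1)")
  pam <- paMatrix(pa)
  carriers <- colSums(pam)
  prev <- carriers / nrow(pam)
  spectrum <- table(factor(carriers, levels = seq_len(nrow(pam))))
  list(spectrum = setNames(as.integer(spectrum), names(spectrum)),
       prevalence = prev,
       n_core = sum(prev >= core_fraction),
       n_rare = sum(prev < rare_fraction),
       n_families = ncol(pam))
}

# Global alignment of two family representatives; returns per-family
# identity (%) and the weight (= mutually non-gapped columns), plus each
# sequence's residue count.
align_family_pair <- function(sa, sb, method) {
  if (method == "columns" || (method == "auto" && nchar(sa) == nchar(sb))) {
    a <- strsplit(toupper(sa), "", fixed = TRUE)[[1]]
    b <- strsplit(toupper(sb), "", fixed = TRUE)[[1]]
    list(identity = 100 * mean(a == b & a != "N" & b != "N"),
         weight = length(a))
  } else {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1,
                                                       baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                         substitutionMatrix = submat,
                                         gapOpening = 2, gapExtension = 0.5)
    pa_ <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sb_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    keep <- pa_ != "-" & sb_ != "-"
    list(identity = 100 * sum(pa_[keep] == sb_[keep] & pa_[keep] != "N" &
                                sb_[keep] != "N") / sum(keep),
         weight = sum(keep))
  }
}

#' Ortholog-based average nucleotide identity between two genomes
#'
#' ANI over the shared gene families: each pair of family representatives is
#' globally aligned and ANI is the length-weighted mean of per-family percent
#' identity at mutually non-gapped columns (weight = number of such columns).
#' Aligned length per genome is the summed length of its residues entering
#' those alignments; unaligned length is the remainder of both genomes,
#' `(L_a - aligned_a) + (L_b - aligned_b)`. This realises
#' "identity of pairwise aligned regions" over orthologs instead of read
#' fragments.
#'
#' @param genome_a,genome_b strain ids.
#' @param pa a [PresenceAbsenceMatrix-class] with sequences and genome
#'   lengths.
#' @param method "auto" (column comparison when representatives have equal
#'   length, else Needleman-Wunsch; default), "align" (always align), or
#'   "columns" (equal-length column comparison only).
#' @return list: `ani` (%), `aligned_length` (bp, both genomes),
#'   `unaligned_length` (bp), `n_shared_families`.
#' @export
computeAni <- function(genome_a, genome_b, pa,
                       method = c("auto", "align", "columns")) {
  method <- match.arg(method)
  seq_a <- familySequences(pa, genome_a)
  seq_b <- familySequences(pa, genome_b)
  if (is.null(seq_a) || is.null(seq_b))
    stop("both genomes must carry family sequences")
  shared <- intersect(names(seq_a), names(seq_b))
  if (!length(shared))
    stop("no shared families between ", genome_a, " and ", genome_b,
         "; ANI undefined")
  ids <- numeric(length(shared)); w <- numeric(length(shared))
  res_a <- 0; res_b <- 0
  for (k in seq_along(shared)) {
    f <- shared[k]
    r <- align_family_pair(seq_a[[f]], seq_b[[f]], method)
    ids[k] <- r$identity; w[k] <- r$weight
    res_a <- res_a + nchar(seq_a[[f]])
    res_b <- res_b + nchar(seq_b[[f]])
  }
  L <- genomeLengths(pa)
  list(ani = sum(ids * w) / sum(w),
       aligned_length = res_a + res_b,
       unaligned_length = (L[[genome_a]] - res_a) + (L[[genome_b]] - res_b),
       n_shared_families = length(shared))
}

#' Pairwise ANI table over all strain pairs
#'
#' @param pa a [PresenceAbsenceMatrix-class] with sequences.
#' @param method passed to [computeAni()].
#' @return data.frame with one row per unordered strain pair: strain_a,
#'   strain_b, ani, aligned_bp, unaligned_bp, shared, unshared.
#' @export
aniTable <- function(pa, method = "auto") {
  strains <- strainNames(pa)
  pairs <- combn(strains, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    r <- computeAni(a, b, pa, method = method)
    su <- sharedUnshared(pa, a, b)
    data.frame(strain_a = a, strain_b = b, ani = r$ani,
               aligned_bp = r$aligned_length,
               unaligned_bp = r$unaligned_length,
               shared = su[["shared"]], unshared = su[["unshared"]])
  })
  do.call(rbind, rows)
}
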