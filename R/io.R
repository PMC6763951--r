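# Plain-text IO: FASTA, newick, square-matrix and long-table TSV/CSV.

#' Write sequences to FASTA
#' @param seqs named character vector of sequences, or a character alignment
#'   matrix (rows written as records).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.matrix(seqs)) seqs <- seq_matrix_to_strings(seqs)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file to a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Write a square matrix (identity, distance, divergence) as TSV
#' @param m matrix or [IdentityMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMatrixTsv <- function(m, path) {
  if (is(m, "IdentityMatrix")) m <- matrixValues(m)
  df <- data.frame(strain = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV matrix written by [writeMatrixTsv()]
#' @param path input file.
#' @return numeric matrix with dimnames.
#' @export
readMatrixTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a presence/absence matrix as 0/1 TSV (strains as rows)
#' @param pa a [PresenceAbsenceMatrix-class] or logical matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePresenceAbsenceTsv <- function(pa, path) {
  pam <- if (is(pa, "PresenceAbsenceMatrix")) paMatrix(pa) else pa
  m <- pam * 1L
  writeMatrixTsv(m, path)
}

#' Read a 0/1 presence/absence TSV
#' @param path input file.
#' @return a [PresenceAbsenceMatrix-class] (no sequences).
#' @export
readPresenceAbsenceTsv <- function(path) {
  PresenceAbsenceMatrix(readMatrixTsv(path) > 0)
}

#' Write a tree as newick (supports as internal node labels)
#' @param tree `ape::phylo`.
#' @param path output file.
#' @param digits branch-length precision (default 6).
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path, digits = 6) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Read a newick tree
#' @param path newick file.
#' @return `ape::phylo`.
#' @export
readNewick <- function(path) ape::read.tree(path)

#' Write a feature annotation as long TSV (strain, category, feature_id, flag)
#' @param features a [FeatureAnnotation-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatureTsv <- function(features, path) {
  sets <- featureSets(features)
  rows <- do.call(rbind, lapply(names(sets), function(s) {
    f <- sets[[s]]
    if (!length(f)) return(NULL)
    data.frame(strain = s, category = featureCategory(features),
               feature_id = f,
               flag = if (length(features@flags)) features@flags[f] else NA)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
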