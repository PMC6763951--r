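# Marker-gene (rRNA) percent identity: length filtering, column identity at
# non-gapped positions, and the best-copy rule for multi-copy genomes.

#' Filter marker genes by length around a reference
#'
#' Keeps genes whose length lies within `tolerance` of the reference length
#' (closed interval), mirroring rRNA screening against reference gene
#' lengths such as 117, 1738 and 3179 bp for 5S/16S/23S. Genomes that lose
#' every copy are dropped with a warning and recorded.
#'
#' @param genes named list: genome id -> named character vector of gene
#'   sequences (DNA, A/C/G/T/N).
#' @param reference_length reference gene length in bp (> 0).
#' @param tolerance fractional half-width of the window (0 < t < 1);
#'   default 0.2 keeps lengths in `[0.8, 1.2] * reference_length`.
#' @return filtered list of the same shape; attribute `"dropped_genomes"`
#'   lists genomes whose copies were all removed.
#' @export
filterByReferenceLength <- function(genes, reference_length, tolerance = 0.2) {
  if (reference_length <= 0) stop("reference_length must be > 0")
  if (tolerance <= 0 || tolerance >= 1) stop("tolerance must be in (0, 1)")
  lo <- reference_length * (1 - tolerance)
  hi <- reference_length * (1 + tolerance)
  out <- lapply(genes, function(g) g[nchar(g) >= lo & nchar(g) <= hi])
  dropped <- names(out)[vapply(out, length, integer(1)) == 0L &
                          vapply(genes, length, integer(1)) > 0L]
  if (length(dropped)) {
    warning("genomes lost all marker copies to the length filter: ",
            paste(dropped, collapse = ", "))
    out <- out[setdiff(names(out), dropped)]
  }
  attr(out, "dropped_genomes") <- dropped
  out
}

#' Percent identity at mutually non-gapped alignment columns
#'
#' 100 x matches / columns, counting only columns where neither sequence has
#' a gap. An `N` in either sequence keeps the column (it is not a gap) but
#' can never match.
#'
#' @param aligned_a,aligned_b aligned sequences of equal length (strings).
#' @return percent identity in [0, 100].
#' @export
percentIdentityNongapped <- function(aligned_a, aligned_b) {
  a <- strsplit(toupper(aligned_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aligned_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("aligned lengths differ")
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("no mutually non-gapped column; identity undefined")
  a <- a[keep]; b <- b[keep]
  100 * sum(a == b & a != "N" & b != "N") / length(a)
}

# Column identity for rows of an alignment matrix (vectorised core of the
# string version above).
identity_from_rows <- function(a, b) {
  keep <- a != "-" & b != "-"
  if (!any(keep)) return(NA_real_)
  a <- a[keep]; b <- b[keep]
  100 * sum(a == b & a != "N" & b != "N") / length(a)
}

# Joint multiple alignment of sequences via the mafft CLI.
mafft_align <- function(seqs) {
  if (Sys.which("mafft") == "")
    stop("the 'msa' aligner needs the mafft executable on PATH; ",
         "use aligner = \"pairwise\" otherwise")
  infile <- tempfile(fileext = ".fasta")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), infile)
  out <- system2("mafft", c("--retree", "2", "--maxiterate", "0", "--quiet",
                            shQuote(infile)), stdout = TRUE)
  aln <- read_fasta_lines(out)
  toupper(aln[names(seqs)])
}

read_fasta_lines <- function(lines) {
  hdr <- grepl("^>", lines)
  ids <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1),
                 collapse = "")
  setNames(unname(seqs), ids)
}

#' Pairwise marker identity between genomes with the best-copy rule
#'
#' Computes percent identity at mutually non-gapped columns for every
#' copy-vs-copy pair between two genomes and keeps the maximum, so a genome
#' with one diverged paralog is still matched through its best copy. The
#' default backend aligns all retained copies jointly with mafft and reads
#' column identity off the single MSA; the "pairwise" backend aligns each
#' copy pair globally (Needleman-Wunsch, match 1 / mismatch -1 / gap open 2
#' / extend 0.5).
#'
#' @param genes named list genome -> named character vector of marker copies
#'   (already length-filtered; see [filterByReferenceLength()]).
#' @param aligner "msa" (joint mafft alignment, default) or "pairwise".
#' @param marker label stored on the result.
#' @return an [IdentityMatrix-class] over the genomes.
#' @export
pairwiseMarkerIdentity <- function(genes, aligner = c("msa", "pairwise"),
                                   marker = "marker") {
  aligner <- match.arg(aligner)
  genes <- genes[vapply(genes, length, integer(1)) > 0L]
  if (length(genes) < 2L)
    stop("need at least 2 genomes with surviving marker copies")
  genomes <- names(genes)
  flat <- unlist(unname(lapply(genomes, function(g) {
    s <- genes[[g]]
    setNames(unname(s), paste0(g, "\r", names(s)))
  })))
  owner <- sub("\r.*$", "", names(flat))
  m <- matrix(NA_real_, length(genomes), length(genomes),
              dimnames = list(genomes, genomes))
  diag(m) <- 100
  if (aligner == "msa") {
    if (length(unique(nchar(flat))) == 1L) {
      aln <- strings_to_seq_matrix(flat)  # already columnar (gapless input)
    } else {
      aln <- strings_to_seq_matrix(mafft_align(flat))
    }
    for (i in seq_along(genomes)[-length(genomes)]) {
      for (j in (i + 1L):length(genomes)) {
        rows_i <- which(owner == genomes[i])
        rows_j <- which(owner == genomes[j])
        best <- max(vapply(rows_i, function(ri) {
          max(vapply(rows_j, function(rj) {
            identity_from_rows(aln[ri, ], aln[rj, ])
          }, numeric(1)), na.rm = TRUE)
        }, numeric(1)), na.rm = TRUE)
        m[i, j] <- m[j, i] <- best
      }
    }
  } else {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1,
                                                       baseOnly = FALSE)
    for (i in seq_along(genomes)[-length(genomes)]) {
      for (j in (i + 1L):length(genomes)) {
        best <- -Inf
        for (sa in genes[[genomes[i]]]) {
          for (sb in genes[[genomes[j]]]) {
            aln <- Biostrings::pairwiseAlignment(
              sa, sb, type = "global", substitutionMatrix = submat,
              gapOpening = 2, gapExtension = 0.5)
            pid <- percentIdentityNongapped(
              as.character(Biostrings::alignedPattern(aln)),
              as.character(Biostrings::alignedSubject(aln)))
            if (pid > best) best <- pid
          }
        }
        m[i, j] <- m[j, i] <- best
      }
    }
  }
  IdentityMatrix(m, marker = marker)
}

#' Marker identity from a simulated pangenome
#'
#' Convenience wrapper: extracts the marker copies of a
#' [SimulatedPangenome-class] (rows named "strain:gene") into the
#' per-genome list expected by [pairwiseMarkerIdentity()].
#'
#' @param sim a [SimulatedPangenome-class].
#' @return named list genome -> named character vector of marker copies.
#' @export
markerGeneSet <- function(sim) {
  aln <- sim@markerAlignment
  ids <- rownames(aln)
  genome <- sub(":.*$", "", ids)
  gene <- sub("^.*:", "", ids)
  seqs <- seq_matrix_to_strings(aln)
  out <- lapply(split(seq_along(ids), genome), function(k) {
    setNames(unname(seqs[k]), gene[k])
  })
  out[unique(genome)]
}
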