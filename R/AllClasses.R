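#' @import methods
NULL

setOldClass("phylo")

#' Strain-by-family presence/absence matrix
#'
#' The genome-composition object: a logical matrix of strains (rows) by gene
#' or feature families (columns), optionally carrying a representative
#' nucleotide sequence per strain and family plus per-strain total genome
#' lengths so that ortholog-based average nucleotide identity (ANI) can be
#' computed with aligned/unaligned length accounting.
#'
#' @slot pa logical matrix, strains x families; no all-zero family column.
#' @slot sequences list indexed by strain; each element a named character
#'   vector mapping family id to that strain's representative sequence.
#'   May be empty when only presence/absence is known.
#' @slot genomeLength named numeric vector of per-strain total genome length
#'   in bp (zero-length when unknown).
#' @exportClass PresenceAbsenceMatrix
setClass("PresenceAbsenceMatrix",
  slots = c(pa = "matrix", sequences = "list", genomeLength = "numeric"))

setValidity("PresenceAbsenceMatrix", function(object) {
  pa <- object@pa
  if (!is.logical(pa)) return("slot 'pa' must be a logical matrix")
  if (is.null(rownames(pa)) || is.null(colnames(pa)))
    return("'pa' needs strain rownames and family colnames")
  if (anyDuplicated(rownames(pa))) return("duplicate strain ids")
  if (anyDuplicated(colnames(pa))) return("duplicate family ids")
  if (ncol(pa) > 0L && any(colSums(pa) == 0L))
    return("all-zero family columns are not allowed")
  if (length(object@sequences) &&
      !all(names(object@sequences) %in% rownames(pa)))
    return("sequence list names must be strain ids")
  if (length(object@genomeLength) &&
      !all(names(object@genomeLength) %in% rownames(pa)))
    return("genomeLength names must be strain ids")
  TRUE
})

#' Construct a PresenceAbsenceMatrix
#'
#' @param pa logical (or 0/1) matrix, strains as rows, families as columns.
#'   All-zero family columns are dropped.
#' @param sequences optional list: strain -> named character vector
#'   (family id -> representative nucleotide sequence).
#' @param genomeLength optional named numeric of per-strain genome length (bp);
#'   when omitted and sequences are given it defaults to the summed length of
#'   each strain's family representatives.
#' @return a [PresenceAbsenceMatrix-class] object.
#' @export
PresenceAbsenceMatrix <- function(pa, sequences = list(),
                                  genomeLength = numeric()) {
  storage.mode(pa) <- "logical"
  if (ncol(pa) > 0L) {
    keep <- colSums(pa) > 0L
    pa <- pa[, keep, drop = FALSE]
  }
  if (!length(genomeLength) && length(sequences)) {
    genomeLength <- vapply(sequences, function(s) sum(nchar(s)), numeric(1))
  }
  new("PresenceAbsenceMatrix", pa = pa, sequences = sequences,
      genomeLength = genomeLength)
}

#' Symmetric marker-gene percent-identity matrix
#'
#' Pairwise percent identity (0-100) between strains at a marker gene, with
#' an exact 100 diagonal.
#'
#' @slot values numeric matrix, strains x strains, symmetric, diagonal 100.
#' @slot marker single string naming the marker (e.g. "16S").
#' @exportClass IdentityMatrix
setClass("IdentityMatrix",
  slots = c(values = "matrix", marker = "character"))

setValidity("IdentityMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("'values' must be a square numeric matrix")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("row and column strain names must be present and identical")
  if (any(v < 0 | v > 100, na.rm = TRUE)) return("identities must be in [0, 100]")
  if (nrow(v) && any(diag(v) != 100)) return("diagonal must be exactly 100")
  if (any(abs(v - t(v)) > 1e-8, na.rm = TRUE)) return("matrix must be symmetric")
  TRUE
})

#' Construct an IdentityMatrix
#' @param values square numeric matrix of percent identities with strain
#'   dimnames; symmetrised and its diagonal forced to exactly 100.
#' @param marker marker gene label.
#' @return an [IdentityMatrix-class] object.
#' @export
IdentityMatrix <- function(values, marker = "marker") {
  values <- (values + t(values)) / 2
  diag(values) <- 100
  new("IdentityMatrix", values = values, marker = marker)
}

#' Strain-by-metabolite trait matrix
#'
#' Carries metabolite abundances (or scores) through the preprocessing
#' pipeline; the `stage` tag enforces stage ordering (raw -> imputed -> glog
#' -> autoscaled; normalized_score for consumed association-score matrices).
#'
#' @slot values numeric matrix, strains (or samples) x metabolites; NA =
#'   missing.
#' @slot stage one of "raw", "imputed", "glog", "autoscaled",
#'   "normalized_score".
#' @slot generator optional per-metabolite tag ("bm" or "white_noise") for
#'   simulated traits.
#' @slot metadata free-form list (generating tree id, BM rate, etc.).
#' @exportClass TraitMatrix
setClass("TraitMatrix",
  slots = c(values = "matrix", stage = "character", generator = "character",
            metadata = "list"))

.trait_stages <- c("raw", "imputed", "glog", "autoscaled", "normalized_score")

setValidity("TraitMatrix", function(object) {
  if (!is.numeric(object@values)) return("'values' must be numeric")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    return("'values' needs strain rownames and metabolite colnames")
  if (length(object@stage) != 1L || !object@stage %in% .trait_stages)
    return(sprintf("stage must be one of: %s",
                   paste(.trait_stages, collapse = ", ")))
  if (length(object@generator) &&
      length(object@generator) != ncol(object@values))
    return("generator tags must be one per metabolite")
  TRUE
})

#' Construct a TraitMatrix
#' @param values numeric matrix, strains x metabolites.
#' @param stage processing stage tag (default "raw").
#' @param generator optional per-metabolite generator tags.
#' @param metadata optional list of provenance fields.
#' @return a [TraitMatrix-class] object.
#' @export
TraitMatrix <- function(values, stage = "raw", generator = character(),
                        metadata = list()) {
  new("TraitMatrix", values = values, stage = stage, generator = generator,
      metadata = metadata)
}

#' Categorical feature annotation
#'
#' Per-strain sets of feature ids of one category (antibiotic-resistance
#' elements, biosynthetic gene cluster families, carbohydrate-active enzyme
#' families, or metabolic hallmarks), with optional per-feature flags such as
#' strict/loose confidence.
#'
#' @slot category one of "resistance", "gcf", "cazy", "hallmark".
#' @slot strains character vector of all strains in the study (including
#'   strains carrying no feature of this category).
#' @slot features named list: strain -> character vector of feature ids.
#' @slot flags optional named character vector: feature id -> flag label.
#' @exportClass FeatureAnnotation
setClass("FeatureAnnotation",
  slots = c(category = "character", strains = "character",
            features = "list", flags = "character"))

.feature_categories <- c("resistance", "gcf", "cazy", "hallmark")

setValidity("FeatureAnnotation", function(object) {
  if (length(object@category) != 1L ||
      !object@category %in% .feature_categories)
    return(sprintf("category must be one of: %s",
                   paste(.feature_categories, collapse = ", ")))
  if (!all(names(object@features) %in% object@strains))
    return("feature list names must be strain ids")
  TRUE
})

#' Construct a FeatureAnnotation
#' @param category feature category label ("resistance", "gcf", "cazy",
#'   "hallmark").
#' @param strains all strain ids in the study.
#' @param features named list mapping strain id to its feature-id set.
#' @param flags optional named character vector of per-feature flags.
#' @return a [FeatureAnnotation-class] object.
#' @export
FeatureAnnotation <- function(category, strains, features,
                              flags = character()) {
  features <- features[intersect(strains, names(features))]
  new("FeatureAnnotation", category = category, strains = strains,
      features = features, flags = flags)
}

#' Simulated pangenome bundle
#'
#' Everything the downstream comparisons consume, generated on one species
#' tree: a slowly evolving marker alignment, a faster concatenated core
#' alignment, a presence/absence matrix of gene families with per-strain
#' representative sequences, and per-strain genome lengths.
#'
#' @slot tree the generating species tree (`ape::phylo`).
#' @slot markerAlignment character matrix (strains x sites), gapless; one or
#'   more rows per strain named "strain:gene".
#' @slot coreAlignment character matrix (strains x sites), gapless.
#' @slot pa a [PresenceAbsenceMatrix-class] with sequences and genome lengths.
#' @slot params list of the simulation parameters used.
#' @exportClass SimulatedPangenome
setClass("SimulatedPangenome",
  slots = c(tree = "phylo", markerAlignment = "matrix",
            coreAlignment = "matrix", pa = "PresenceAbsenceMatrix",
            params = "list"))

# ---- accessors ----

#' Strain ids of an object
#' @param x a pansig data object.
#' @return character vector of strain ids.
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname strainNames
#' @export
setMethod("strainNames", "PresenceAbsenceMatrix",
          function(x) rownames(x@pa))

#' @rdname strainNames
#' @export
setMethod("strainNames", "IdentityMatrix", function(x) rownames(x@values))

#' @rdname strainNames
#' @export
setMethod("strainNames", "TraitMatrix", function(x) rownames(x@values))

#' @rdname strainNames
#' @export
setMethod("strainNames", "FeatureAnnotation", function(x) x@strains)

#' Presence/absence matrix accessor
#' @param x a [PresenceAbsenceMatrix-class].
#' @return the logical strains x families matrix.
#' @export
paMatrix <- function(x) x@pa

#' Family ids of a presence/absence matrix
#' @param x a [PresenceAbsenceMatrix-class].
#' @return character vector of family ids.
#' @export
familyNames <- function(x) colnames(x@pa)

#' Per-strain family representative sequences
#' @param x a [PresenceAbsenceMatrix-class].
#' @param strain optional strain id to extract one strain's sequences.
#' @return the sequence list, or one strain's named sequence vector.
#' @export
familySequences <- function(x, strain = NULL) {
  if (is.null(strain)) x@sequences else x@sequences[[strain]]
}

#' Per-strain total genome lengths (bp)
#' @param x a [PresenceAbsenceMatrix-class].
#' @return named numeric vector.
#' @export
genomeLengths <- function(x) x@genomeLength

#' Numeric values of a matrix-like pansig object
#' @param x an [IdentityMatrix-class] or [TraitMatrix-class].
#' @return the underlying numeric matrix.
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' @rdname matrixValues
#' @export
setMethod("matrixValues", "IdentityMatrix", function(x) x@values)

#' @rdname matrixValues
#' @export
setMethod("matrixValues", "TraitMatrix", function(x) x@values)

#' Processing stage of a TraitMatrix
#' @param x a [TraitMatrix-class].
#' @return stage tag string.
#' @export
traitStage <- function(x) x@stage

#' Per-strain feature sets of an annotation
#' @param x a [FeatureAnnotation-class].
#' @param flag optional flag label; only features carrying it are returned.
#' @return named list strain -> character vector of feature ids (strains with
#'   no features map to character(0)).
#' @export
featureSets <- function(x, flag = NULL) {
  out <- lapply(setNames(x@strains, x@strains), function(s) {
    f <- x@features[[s]]
    if (is.null(f)) character() else f
  })
  if (!is.null(flag)) {
    keep <- names(x@flags)[x@flags == flag]
    out <- lapply(out, intersect, y = keep)
  }
  out
}

#' Feature category of an annotation
#' @param x a [FeatureAnnotation-class].
#' @return category string.
#' @export
featureCategory <- function(x) x@category

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  pa <- object@pa
  cat(sprintf("PresenceAbsenceMatrix: %d strains x %d families\n",
              nrow(pa), ncol(pa)))
  if (ncol(pa)) {
    prev <- colMeans(pa)
    cat(sprintf("  prevalence: core (=100%%) %d | rare (<10%%) %d\n",
                sum(prev == 1), sum(prev < 0.1)))
  }
  cat(sprintf("  sequences: %s | genome lengths: %s\n",
              if (length(object@sequences)) "yes" else "no",
              if (length(object@genomeLength)) "yes" else "no"))
})

setMethod("show", "IdentityMatrix", function(object) {
  v <- object@values
  cat(sprintf("IdentityMatrix (%s): %d strains\n", object@marker, nrow(v)))
  if (nrow(v) > 1) {
    off <- v[upper.tri(v)]
    cat(sprintf("  pairwise identity: min %.2f | median %.2f | max %.2f\n",
                min(off), stats::median(off), max(off)))
  }
})

setMethod("show", "TraitMatrix", function(object) {
  cat(sprintf("TraitMatrix [%s]: %d strains x %d metabolites (%d NA)\n",
              object@stage, nrow(object@values), ncol(object@values),
              sum(is.na(object@values))))
})

setMethod("show", "FeatureAnnotation", function(object) {
  n <- vapply(featureSets(object), length, integer(1))
  cat(sprintf("FeatureAnnotation [%s]: %d strains, %d features (per strain: %s)\n",
              object@category, length(object@strains),
              length(unique(unlist(object@features))),
              paste(range(n), collapse = "-")))
})

setMethod("show", "SimulatedPangenome", function(object) {
  cat(sprintf("SimulatedPangenome: %d strains\n", length(object@tree$tip.label)))
  cat(sprintf("  marker: %d seq x %d bp | core: %d x %d bp\n",
              nrow(object@markerAlignment), ncol(object@markerAlignment),
              nrow(object@coreAlignment), ncol(object@coreAlignment)))
  cat("  "); show(object@pa)
})
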