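#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rpois rbinom sd var p.adjust aov hclust dist
#'   cophenetic as.dist complete.cases setNames
#' @importFrom utils combn write.table read.table head
#' @importFrom MASS ginv
NULL

# Evaluate `expr` with the RNG seeded by `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs a user's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derived sub-stream seeds: order-independent per-unit streams from one seed.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(counter)) %%
               2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

# Random gapless sequences as a character matrix (rows = names).
random_seq_matrix <- function(names, length) {
  m <- matrix(sample(DNA_BASES, length(names) * length, replace = TRUE),
              nrow = length(names),
              dimnames = list(names, NULL))
  m
}

seq_matrix_to_strings <- function(m) {
  apply(m, 1L, paste0, collapse = "")
}

strings_to_seq_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) == 1L)
  m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}
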