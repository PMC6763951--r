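# Small fixture builders shared across test files.

# A star tree with equal tip depths.
star_tree <- function(n = 8, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr$edge.length <- rep(depth, n)
  tr
}

# Random DNA string(s).
rand_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Mutate `k` distinct positions of a DNA string to a different base.
mutate_at <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) {
    s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  }
  paste0(s, collapse = "")
}

# Presence/absence object from a named list of family-id sets.
pa_from_sets <- function(sets) {
  fams <- sort(unique(unlist(sets)))
  m <- t(vapply(sets, function(s) fams %in% s, logical(length(fams))))
  colnames(m) <- fams
  PresenceAbsenceMatrix(m)
}

# IdentityMatrix from an upper-triangle specification.
identity_from_pairs <- function(strains, pairs) {
  m <- matrix(100, length(strains), length(strains),
              dimnames = list(strains, strains))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$a[k]; j <- pairs$b[k]
    m[i, j] <- m[j, i] <- pairs$id[k]
  }
  IdentityMatrix(m)
}

# Constant-level media-control rows for a set of metabolites (both modes).
const_ctrl <- function(mets, level = 10, reps = 2) {
  do.call(rbind, lapply(mets, function(m)
    do.call(rbind, lapply(seq_len(reps), function(r)
      rbind(lcms_row("media", r, "pos", m, level, TRUE),
            lcms_row("media", r, "neg", m, level, TRUE))))))
}

# Long LC-MS-style table row helper.
lcms_row <- function(strain, replicate, ion_mode, metabolite, abundance,
                     is_control = FALSE) {
  data.frame(strain = strain, replicate = replicate, ion_mode = ion_mode,
             metabolite = metabolite, abundance = abundance,
             is_control = is_control)
}
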