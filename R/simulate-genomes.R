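# Synthetic pangenome generator: species tree, Jukes-Cantor sequence
# evolution, gene-family gain/loss, and the bundled pangenome object.

#' Simulate a pure-birth species tree
#'
#' Draws a Yule (pure-birth) tree and rescales branch lengths so the maximum
#' root-to-tip depth equals `depth` expected substitutions per site. This is
#' the backbone every other simulator operates on.
#'
#' @param n_taxa number of tips (>= 3).
#' @param birth_rate speciation rate of the Yule process (shape only; the
#'   depth rescaling removes its absolute scale).
#' @param depth root-to-tip depth after rescaling, in expected
#'   substitutions/site.
#' @param seed integer seed; identical seeds give identical trees.
#' @param tip_prefix prefix for tip labels (`strain01`, `strain02`, ...).
#' @return an `ape::phylo` with `n_taxa` tips and positive branch lengths.
#' @export
simulateSpeciesTree <- function(n_taxa, birth_rate = 1, depth = 0.3,
                                seed = NULL, tip_prefix = "strain") {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (birth_rate <= 0 || depth <= 0) stop("birth_rate and depth must be > 0")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("%s%02d", tip_prefix, seq_len(n_taxa))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / h
  tree
}

# Number of substitutions-per-site converted to a per-site change probability
# under Jukes-Cantor.
jc_change_prob <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Evolve a gapless alignment along a tree under Jukes-Cantor
#'
#' Sites evolve independently; along an edge of length b (in expected
#' substitutions/site, multiplied by `rate_multiplier`) each site changes to
#' one of the three other bases with total probability
#' 3/4 (1 - exp(-4 b / 3)). With rate 0 every tip repeats the root sequence.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param length alignment length in sites (>= 1).
#' @param rate_multiplier factor applied to every branch length (>= 0);
#'   use a small value for a conserved marker and a larger one for the core.
#' @param seed integer seed.
#' @param root optional root sequence (character vector of bases) to reuse
#'   across calls; defaults to a uniform random sequence.
#' @return character matrix (tips x sites) with tip labels as rownames.
#' @export
evolveAlignment <- function(tree, length, rate_multiplier = 1, seed = NULL,
                            root = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (rate_multiplier < 0) stop("rate_multiplier must be >= 0")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    rootnode <- ntip + 1L
    if (is.null(root)) root <- sample(DNA_BASES, length, replace = TRUE)
    stopifnot(length(root) == length)
    seqs[[rootnode]] <- root
    # preorder: parents before children
    ord <- rev(ape::postorder(tree))
    for (e in ord) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      p <- jc_change_prob(tree$edge.length[e] * rate_multiplier)
      s <- seqs[[parent]]
      hit <- which(runif(length) < p)
      if (length(hit)) {
        # new base drawn uniformly from the three alternatives
        shift <- sample.int(3L, length(hit), replace = TRUE)
        idx <- match(s[hit], DNA_BASES)
        s[hit] <- DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
      }
      seqs[[child]] <- s
    }
    out <- do.call(rbind, seqs[seq_len(ntip)])
    rownames(out) <- tree$tip.label
    out
  })
}

#' Simulate gene-family gain and loss along a tree
#'
#' Core families are present in every strain and immune to loss. Accessory
#' families arise as gain events (Poisson with mean `gain_rate` x branch
#' length, uniform position on the branch, drawn from a finite pool) and are
#' then lost independently in each lineage at exponential rate `loss_rate`
#' per unit branch length. With both rates zero every strain carries exactly
#' the root content.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param core_size number of core families.
#' @param accessory_pool maximum number of distinct accessory families that
#'   can ever be gained.
#' @param gain_rate gains per unit branch length (>= 0).
#' @param loss_rate losses per unit branch length per family (>= 0).
#' @param seed integer seed.
#' @return a [PresenceAbsenceMatrix-class] (no sequences). Accessory families
#'   gained but extinct in all extant strains are dropped.
#' @export
evolveGeneContent <- function(tree, core_size, accessory_pool, gain_rate,
                              loss_rate, seed = NULL) {
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    core_ids <- sprintf("core%04d", seq_len(core_size))
    acc_gained <- 0L
    # per-node accessory content as integer id vectors
    content <- vector("list", nnode)
    content[[ntip + 1L]] <- integer()
    ord <- rev(ape::postorder(tree))
    for (e in ord) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      len <- tree$edge.length[e]
      fams <- content[[parent]]
      # losses of inherited families over the whole branch
      if (length(fams) && loss_rate > 0) {
        fams <- fams[runif(length(fams)) >= jc_loss_prob(loss_rate, len)]
      }
      # gains: uniform position, must survive the remainder of the branch
      n_gain <- if (gain_rate > 0) rpois(1L, gain_rate * len) else 0L
      n_gain <- min(n_gain, accessory_pool - acc_gained)
      if (n_gain > 0L) {
        pos <- runif(n_gain) * len
        surv <- runif(n_gain) >= jc_loss_prob(loss_rate, len - pos)
        new_ids <- acc_gained + seq_len(n_gain)
        acc_gained <- acc_gained + n_gain
        fams <- c(fams, new_ids[surv])
      }
      content[[child]] <- fams
    }
    acc_ids <- sprintf("acc%05d", seq_len(max(acc_gained, 0L)))
    pa <- matrix(FALSE, ntip, core_size + acc_gained,
                 dimnames = list(tree$tip.label, c(core_ids, acc_ids)))
    pa[, seq_len(core_size)] <- TRUE
    for (i in seq_len(ntip)) pa[i, core_size + content[[i]]] <- TRUE
    PresenceAbsenceMatrix(pa)
  })
}

jc_loss_prob <- function(rate, len) 1 - exp(-rate * len)

#' Simulate a full pangenome on one species tree
#'
#' Bundles the generator: a slowly evolving single-copy (optionally
#' multi-copy) marker alignment, a faster concatenated core alignment, a
#' gene-family presence/absence matrix under gain/loss, and per-family
#' representative sequences per strain (family lengths uniform on
#' `family_length_range`) so ortholog clustering and ANI operate on real
#' sequences. Genome length per strain is the summed length of its families.
#'
#' @param tree species tree, or NULL to draw one with [simulateSpeciesTree()].
#' @param n_taxa tips when `tree` is NULL.
#' @param marker_length,marker_rate marker alignment length (bp) and rate
#'   multiplier (slow: default 0.02 of the core rate).
#' @param marker_copies marker copies per strain; extra copies diverge by
#'   `marker_copy_divergence` expected substitutions/site within the genome.
#' @param marker_copy_divergence within-genome divergence of extra copies.
#' @param core_length,core_rate concatenated core alignment length and rate
#'   multiplier.
#' @param core_size,accessory_pool,gain_rate,loss_rate as in
#'   [evolveGeneContent()].
#' @param family_length_range min/max family sequence length (bp).
#' @param family_rate rate multiplier for family sequence evolution.
#' @param depth root-to-tip depth when drawing the tree.
#' @param seed integer seed driving every stage.
#' @return a [SimulatedPangenome-class].
#' @export
simulatePangenome <- function(tree = NULL, n_taxa = 16,
                              marker_length = 1500, marker_rate = 0.02,
                              marker_copies = 1, marker_copy_divergence = 0.002,
                              core_length = 30000, core_rate = 1,
                              core_size = 60, accessory_pool = 300,
                              gain_rate = 60, loss_rate = 8,
                              family_length_range = c(300, 1500),
                              family_rate = 0.5, depth = 0.3, seed = NULL) {
  if (is.null(tree))
    tree <- simulateSpeciesTree(n_taxa, depth = depth,
                                seed = derive_seed(seed %||% 0, 1))
  marker <- evolveAlignment(tree, marker_length, marker_rate,
                            seed = derive_seed(seed %||% 0, 2))
  rownames(marker) <- paste0(tree$tip.label, ":rrn1")
  if (marker_copies > 1) {
    extra <- lapply(seq_len(marker_copies - 1L), function(k) {
      m <- marker
      p <- jc_change_prob(marker_copy_divergence)
      with_seed(derive_seed(seed %||% 0, 20 + k), {
        hit <- which(matrix(runif(length(m)), nrow(m)) < p)
        if (length(hit)) {
          shift <- sample.int(3L, length(hit), replace = TRUE)
          idx <- match(m[hit], DNA_BASES)
          m[hit] <- DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
        }
        m
      })
    })
    for (k in seq_along(extra))
      rownames(extra[[k]]) <- paste0(tree$tip.label, sprintf(":rrn%d", k + 1L))
    marker <- do.call(rbind, c(list(marker), extra))
  }
  core <- evolveAlignment(tree, core_length, core_rate,
                          seed = derive_seed(seed %||% 0, 3))
  pa0 <- evolveGeneContent(tree, core_size, accessory_pool, gain_rate,
                           loss_rate, seed = derive_seed(seed %||% 0, 4))
  fams <- familyNames(pa0)
  lens <- with_seed(derive_seed(seed %||% 0, 5),
                    round(runif(length(fams), family_length_range[1],
                                family_length_range[2])))
  names(lens) <- fams
  # evolve all family sequences as one concatenated alignment, then split
  concat <- evolveAlignment(tree, sum(lens), family_rate,
                            seed = derive_seed(seed %||% 0, 6))
  stops <- cumsum(lens)
  starts <- stops - lens + 1
  pam <- paMatrix(pa0)
  sequences <- lapply(tree$tip.label, function(s) {
    present <- fams[pam[s, ]]
    out <- vapply(present, function(f) {
      paste0(concat[s, starts[[f]]:stops[[f]]], collapse = "")
    }, character(1))
    out
  })
  names(sequences) <- tree$tip.label
  pa <- PresenceAbsenceMatrix(pam, sequences = sequences)
  new("SimulatedPangenome", tree = tree, markerAlignment = marker,
      coreAlignment = core, pa = pa,
      params = list(marker_rate = marker_rate, core_rate = core_rate,
                    family_rate = family_rate, gain_rate = gain_rate,
                    loss_rate = loss_rate, core_size = core_size,
                    family_lengths = lens, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
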