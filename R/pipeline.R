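# End-to-end pipeline: simulate -> marker identity -> pangenome -> trees ->
# feature overlap -> metabolomics -> phylogenetic signal, with plain-text
# intermediates and a machine-readable JSON summary.

#' Pipeline configuration
#'
#' Collects simulation parameters and analysis thresholds with defaults
#' mirroring the analysis conventions: OTU cutoff 97% marker identity,
#' core/rare prevalence fractions 0.9/0.1, clustering cutoffs 0.75/0.75,
#' FDR alpha 0.05, signal alpha 0.01, 1000 randomizations, 100 bootstrap
#' replicates.
#'
#' @param n_taxa strains to simulate.
#' @param seed master integer seed; every stage derives its stream from it.
#' @param marker_rate,core_rate marker and core rate multipliers (marker
#'   much slower than core reproduces the conserved-marker regime).
#' @param gain_rate,loss_rate accessory turnover rates.
#' @param core_size,accessory_pool gene-family counts.
#' @param marker_length,core_length alignment lengths (bp).
#' @param depth root-to-tip tree depth (substitutions/site).
#' @param n_bm,n_noise simulated Brownian-motion / white-noise metabolites.
#' @param n_replicates,missing_rate,control_level LC-MS table parameters.
#' @param identity_thresholds marker-identity thresholds for overlap curves.
#' @param otu_cutoff OTU marker-identity cutoff (%).
#' @param core_fraction,rare_fraction prevalence cutoffs.
#' @param cluster_identity,cluster_coverage family clustering cutoffs.
#' @param fdr_alpha,signal_alpha significance levels.
#' @param n_randomizations K-test shuffles.
#' @param bootstrap_reps bootstrap replicates for tree supports.
#' @return a named list of class "pansig_config".
#' @export
pipelineConfig <- function(n_taxa = 16, seed = 1,
                           marker_rate = 0.02, core_rate = 1,
                           gain_rate = 60, loss_rate = 8,
                           core_size = 60, accessory_pool = 300,
                           marker_length = 1500, core_length = 30000,
                           depth = 0.3,
                           n_bm = 20, n_noise = 10,
                           n_replicates = 5, missing_rate = 0.1,
                           control_level = 50,
                           identity_thresholds = c(90, 95, 97, 99, 100),
                           otu_cutoff = 97,
                           core_fraction = 0.9, rare_fraction = 0.1,
                           cluster_identity = 0.75, cluster_coverage = 0.75,
                           fdr_alpha = 0.05, signal_alpha = 0.01,
                           n_randomizations = 1000, bootstrap_reps = 100) {
  cfg <- as.list(environment())
  class(cfg) <- "pansig_config"
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Simulates a pangenome and metabolite data on one species tree, then runs
#' every comparison: marker identity with best-copy rule, pairwise ANI with
#' shared/unshared counts, the family frequency spectrum, feature overlap
#' curves, marker/core/composition trees with bootstrap supports and
#' Robinson-Foulds discordances, scaled core divergence, the metabolomics
#' preprocessing chain with ANOVA/FDR, and the Blomberg's K screen against
#' the three trees. All intermediates are plain text under `outdir`; the
#' headline statistics are returned and written as JSON.
#'
#' @param config a [pipelineConfig()] list.
#' @param outdir output directory (created if missing); NULL skips writing.
#' @return invisibly, a list with all stage objects plus `summary` (the JSON
#'   content).
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL) {
  stopifnot(inherits(config, "pansig_config"))
  w <- function(f, name) if (!is.null(outdir)) f(file.path(outdir, name))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  # --- simulate ---
  sim <- simulatePangenome(
    n_taxa = config$n_taxa, marker_length = config$marker_length,
    marker_rate = config$marker_rate, core_length = config$core_length,
    core_rate = config$core_rate, core_size = config$core_size,
    accessory_pool = config$accessory_pool, gain_rate = config$gain_rate,
    loss_rate = config$loss_rate, depth = config$depth, seed = config$seed)
  traits <- simulateTraits(sim@tree, n_bm = config$n_bm,
                           n_noise = config$n_noise,
                           seed = derive_seed(config$seed, 101))
  lcms <- simulateLcms(traits, n_replicates = config$n_replicates,
                       missing_rate = config$missing_rate,
                       control_level = config$control_level,
                       seed = derive_seed(config$seed, 102))
  gcf <- assignFeatureFamilies(sim@pa, "gcf", 40,
                               seed = derive_seed(config$seed, 103))
  hallmark <- assignFeatureFamilies(
    sim@pa, "hallmark", 10,
    prevalence_distribution = c(0.9, 0.8, 0.7, 0.5, 0.3, 0.2, 0.1),
    seed = derive_seed(config$seed, 104))
  w(function(p) writeNewick(sim@tree, p), "species_tree.nwk")
  w(function(p) writeFasta(sim@markerAlignment, p), "marker.fasta")
  w(function(p) writeFasta(sim@coreAlignment, p), "core.fasta")
  w(function(p) writePresenceAbsenceTsv(sim@pa, p), "presence_absence.tsv")
  w(function(p) writeFeatureTsv(gcf, p), "features_gcf.tsv")
  w(function(p) writeFeatureTsv(hallmark, p), "features_hallmark.tsv")
  w(function(p) write.table(lcms, p, sep = ",", quote = FALSE,
                            row.names = FALSE), "lcms.csv")

  # --- marker identity ---
  identity <- pairwiseMarkerIdentity(markerGeneSet(sim), marker = "16S-like")
  w(function(p) writeMatrixTsv(identity, p), "marker_identity.tsv")

  # --- pangenome ---
  ani <- aniTable(sim@pa)
  spectrum <- familyFrequencySpectrum(sim@pa, config$core_fraction,
                                      config$rare_fraction)
  w(function(p) write.table(ani, p, sep = "\t", quote = FALSE,
                            row.names = FALSE), "ani.tsv")

  # --- trees ---
  marker_tree <- bootstrapSupport(collapse_copies(sim@markerAlignment),
                                  method = "nj", distance = "jc",
                                  n_reps = config$bootstrap_reps,
                                  seed = derive_seed(config$seed, 105))
  core_tree <- bootstrapSupport(sim@coreAlignment, method = "nj",
                                distance = "jc",
                                n_reps = config$bootstrap_reps,
                                seed = derive_seed(config$seed, 106))
  comp_tree <- bootstrapSupport(sim@pa, method = "upgma",
                                distance = "jaccard",
                                n_reps = config$bootstrap_reps,
                                seed = derive_seed(config$seed, 107))
  trees <- list(marker = marker_tree, core = core_tree,
                composition = comp_tree)
  for (nm in names(trees))
    w(function(p) writeNewick(trees[[nm]], p), paste0("tree_", nm, ".nwk"))
  divergence <- scaledPatristic(core_tree)
  w(function(p) writeMatrixTsv(divergence, p), "core_divergence.tsv")
  rf <- data.frame(
    comparison = c("marker_vs_core", "marker_vs_composition",
                   "core_vs_composition", "core_vs_generating"),
    rf = c(rfDistance(marker_tree, core_tree),
           rfDistance(marker_tree, comp_tree),
           rfDistance(core_tree, comp_tree),
           rfDistance(core_tree, sim@tree)))
  w(function(p) write.table(rf, p, sep = "\t", quote = FALSE,
                            row.names = FALSE), "rf_distances.tsv")

  # --- feature overlap ---
  curves <- list(
    gcf = overlapCurve(identity, gcf, config$identity_thresholds),
    hallmark = overlapCurve(identity, hallmark, config$identity_thresholds))
  for (nm in names(curves))
    w(function(p) write.table(curves[[nm]], p, sep = "\t", quote = FALSE,
                              row.names = FALSE),
      paste0("overlap_", nm, ".tsv"))
  spectra <- featureSpectra(gcf)

  # --- metabolomics ---
  sample_matrix <- buildTraitMatrix(lcms, collapse_replicates = FALSE)
  strain_matrix <- buildTraitMatrix(lcms, collapse_replicates = TRUE)
  sample_proc <- glogAutoscale(imputeAndFilterMissing(sample_matrix))
  strain_proc <- glogAutoscale(imputeAndFilterMissing(strain_matrix))
  anova <- anovaFdr(sample_proc, alpha = config$fdr_alpha)
  w(function(p) write.table(anova, p, sep = "\t", quote = FALSE,
                            row.names = FALSE), "anova_fdr.tsv")
  w(function(p) writeMatrixTsv(matrixValues(strain_proc), p),
    "traits_autoscaled.tsv")

  # --- phylogenetic signal ---
  screen <- signalScreen(strain_proc, trees,
                         n_randomizations = config$n_randomizations,
                         alpha = config$signal_alpha,
                         seed = derive_seed(config$seed, 108))
  w(function(p) write.table(screen, p, sep = "\t", quote = FALSE,
                            row.names = FALSE), "k_screen.tsv")

  # --- summary ---
  iv <- matrixValues(identity)
  pid <- iv[cbind(ani$strain_a, ani$strain_b)]
  cond_range <- function(cut) {
    v <- ani$ani[pid >= cut]
    if (length(v) < 2) NA_real_ else max(v) - min(v)
  }
  summary <- list(
    n_taxa = config$n_taxa, seed = config$seed,
    n_families = spectrum$n_families, n_core = spectrum$n_core,
    n_rare = spectrum$n_rare,
    mean_ani = mean(ani$ani),
    ani_range_at_otu = cond_range(config$otu_cutoff),
    ani_range_at_99 = cond_range(99),
    rf = setNames(as.list(rf$rf), rf$comparison),
    n_metabolites_tested = nrow(anova),
    n_differential = sum(anova$significant),
    n_signal_significant = sum(screen$significant),
    n_signal_incongruent = length(attr(screen, "incongruent")))
  if (!is.null(outdir))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, traits = traits, lcms = lcms,
                 identity = identity, ani = ani, spectrum = spectrum,
                 trees = trees, divergence = divergence, rf = rf,
                 features = list(gcf = gcf, hallmark = hallmark),
                 curves = curves, spectra = spectra,
                 sample_matrix = sample_matrix,
                 strain_matrix = strain_matrix,
                 processed = strain_proc, anova = anova, screen = screen,
                 summary = summary))
}

# The marker alignment may carry several copies per strain ("strain:gene"
# rownames); tree building uses the first copy per strain.
collapse_copies <- function(aln) {
  strain <- sub(":.*$", "", rownames(aln))
  keep <- !duplicated(strain)
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- strain[keep]
  out
}
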