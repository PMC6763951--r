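---
title: "Methods: quantifying marker-gene incongruence in synthetic pangenomes"
author: "pansig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying marker-gene incongruence in synthetic pangenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the package addresses

Microbial ecology routinely groups bacteria into operational taxonomic units
(OTUs) by 16S rRNA gene identity, conventionally at a 97% cutoff. Whether
strains inside one OTU actually share genome content, biosynthetic capacity
and metabolism is an empirical question: the 16S gene evolves slowly, while
accessory genes are gained and lost quickly, so two strains with identical
markers can differ by megabases of genetic material. `pansig` implements the
comparative machinery needed to quantify this incongruence — marker identity
versus whole-genome relatedness (ANI, shared orthologs), discordance among
trees built from different data (marker alignment, core genome, gene
composition), and the phylogenetic signal of metabolite traits against those
alternative topologies — together with a synthetic pangenome generator so
that every statistical property of the analysis can be tested end to end
without downloading hundreds of genomes.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the package's claims are checked.

**Species tree.** `simulateSpeciesTree()` draws a pure-birth (Yule) tree and
rescales branch lengths to a root-to-tip depth in expected
substitutions/site (default 0.3, a depth at which per-gene identities span
roughly 75–100%, the range typical of pairwise ANI within a bacterial
genus).

**Sequences.** `evolveAlignment()` evolves gapless alignments
site-independently under Jukes–Cantor. JC was chosen deliberately: it has a
closed-form identity expectation, `1/4 + 3/4 exp(-4d/3)` at distance `d`,
which the test suite uses as an exact oracle. Rate multipliers set the
regime: the marker gene uses 0.02 (a conserved rRNA-like locus: at most
~1–2% divergence across the tree), the concatenated core alignment uses 1.

**Gene content.** `evolveGeneContent()` keeps a core of families present in
every strain and immune to loss, and lets accessory families arise as
Poisson gain events along branches (uniform position, finite pool) with
exponential per-lineage loss. Defaults (60 core families, pool of 300,
gain 60 and loss 8 per unit branch length) put most accessory families at
low prevalence while leaving enough mid-frequency families for composition
trees to be informative — the rare-accessory regime reported for large
bacterial pangenomes, at desk scale. With loss 0, accessory presence is
clade-monophyletic, a brute-force-testable property.

**Family sequences.** Each family carries a sequence evolved down the tree
(lengths uniform on 300–1,500 bp, rate multiplier 0.5), so ortholog
clustering and ANI operate on real sequences. The family rate is lower than
the core-alignment rate so that per-gene identities of distant strains stay
in the 75–100% window where an "aligned-region identity" is meaningful.

**Traits and LC-MS tables.** `simulateTraits()` draws Brownian-motion
metabolites from a multivariate normal with covariance `sigma2 * V(tree)`
(`V` = shared root-to-MRCA branch length) and white-noise metabolites iid
with the same marginal scale. `simulateLcms()` converts trait values to
abundances (`baseline * 2^x`), observes five replicates in two ion modes
(signal split 60/40) under log-normal noise (sdlog 0.2), adds media-control
replicates at a low constant level, and drops sample rows completely at
random. Missingness is MCAR because no mechanism is specified for the data
the table emulates; dropout applies to sample rows only.

**What the generator does not emulate.** No indels (alignments are gapless,
so the joint-MSA step is exact on simulated data), no horizontal transfer
between lineages (gains are independent, not donor-tracked), no synteny, GC
bias or codon structure, and no intensity-dependent missingness. Passing
tests therefore demonstrate the correctness and calibration of the
statistics under a clean vertical-descent model — not robustness to
alignment error or biased dropout in real data.

# Marker identity

Percent identity is computed at mutually non-gapped alignment columns; a
gap in either sequence removes the column, an `N` keeps the column but can
never match (the choice errs toward conservatism; the convention is stated
rather than inherited). Genes are pre-filtered to within 20% of a reference
length (closed interval), and a genome with several marker copies is
compared through its best copy: the matrix entry is the maximum over
copy-pair identities, which makes deleting a lower-identity copy a no-op.
The default backend aligns all retained copies jointly (mafft) and reads
identity off the columns; equal-length input is already columnar and is
used as-is. A pairwise Needleman–Wunsch backend (match 1, mismatch −1, gap
open 2, extend 0.5) exists because the two routes bound each other: tests
require them to agree within one percentage point on small inputs.

# Pangenome similarity and ANI

Gene families are single-linkage components of the graph whose edges join
gene pairs with local-alignment coverage strictly above 0.75 on both genes
and identity strictly above 0.75 — strict inequalities, matching the
">75%" convention. Family ids are the lexicographically smallest member
gene id, which makes clustering deterministic. Single linkage is coarser
than Markov-clustering pipelines; granularity of ortholog calls is not the
quantity under study here.

ANI is defined over shared ortholog families: per family, the two
representatives are globally aligned and ANI is the length-weighted mean of
per-family identity at mutually non-gapped columns. Aligned length is the
summed residues of both genomes entering those alignments; unaligned length
is the remainder of both genomes. This realises "identity of pairwise
aligned regions" directly over orthologs instead of mapped read fragments:
the intent is identical, the computation is exactly testable (a 90%/100 bp
plus 100%/300 bp pair gives 97.5 by arithmetic), and a fragment-mapping
reimplementation would add nothing measurable at this scale. When the two
representatives have equal length the column comparison is used directly
(`method = "auto"`); for the indel-free sequences the simulator emits this
equals the optimal global alignment and removes the quadratic alignment
cost that would otherwise dominate the pipeline.

# Trees

Distance trees replace maximum-likelihood inference deliberately: NJ on JC
distances is deterministic, fast, and provably consistent on additive
inputs, which turns topology recovery into a testable property rather than
an article of faith. Numerical choices:

* JC distances saturate at `p >= 0.75`; such pairs are set to a cap of 5
  substitutions/site with a warning rather than `Inf`, keeping downstream
  agglomeration finite.
* NJ ties in the Q matrix are broken by the lowest-index pair; a negative
  estimated branch length is clamped to zero with the deficit moved to the
  sister edge, preserving the joined pair's path length.
* UPGMA breaks ties by the lowest-index pair, with the merged cluster
  taking the lower slot — so an all-ties matrix yields a caterpillar over
  the input label order, a fixed contract rather than an accident of
  implementation.
* Bootstrap supports resample columns (sites or families), rebuild the tree
  per replicate, and report the percentage of replicates containing each
  internal bipartition of the point-estimate tree; supports are stored as
  internal node labels in newick output.
* Core-genome divergence is the patristic distance matrix scaled by its
  maximum off-diagonal entry (0 = no distance, 1 = longest distance).
* Discordance is unweighted Robinson–Foulds on unrooted bipartitions. An
  option to collapse low-support edges exists but is off by default, since
  collapsing changes RF in ways that are hard to attribute.

# Metabolomics preprocessing

The chain is raw → imputed → glog → autoscaled, enforced by stage tags so a
stage cannot be applied twice. Rules, in order: a strain×metabolite value
survives only if detected in at least 3 of 5 replicates; "detected relative
to media controls" is abundance above mean(control) + 3·SD(control) for
that metabolite and ion mode (the comparison is stated by convention, the
3·SD rule is this package's choice and is configurable in spirit via the
control table); replicate abundances are then summed per ion mode and the
larger mode sum is used. Metabolites with more than 50% missing values are
removed; remaining missing entries become half of the matrix-wide minimum
positive value. The generalized log `log2((x + sqrt(x^2 + lambda))/2)` uses
`lambda = 1` (so `glog(0) = -1`); autoscaling standardises each metabolite
to mean 0, SD 1. ANOVA is one-way per metabolite with Benjamini–Hochberg
FDR (the procedure named "FDR" is taken as BH); the observation unit is the
strain:replicate sample (`collapse_replicates = FALSE`), giving each strain
five observations — testing strains as groups on the collapsed matrix would
leave one observation per group. Heatmap ordering uses Euclidean distances
with `hclust(method = "ward.D2")`, i.e. Ward's criterion applied to the
distances themselves. Consumed association-score matrices are normalised
column-wise by their maximum so the top strain scores exactly 1.

# Phylogenetic signal

Blomberg's K compares the observed ratio of mean squared deviations
(ordinary over GLS-weighted) to its Brownian-motion expectation on the
tree:

K = (MSE0 / MSE) / ((tr V − n / (1ᵀV⁻¹1)) / (n − 1)),

with `MSE0 = (x − â)ᵀ(x − â)/(n − 1)`, `MSE = (x − â)ᵀV⁻¹(x − â)/(n − 1)`
and `â` the GLS root estimate. Three exact properties anchor the tests: on
a star tree with equal depths K ≡ 1 for *any* trait (the module's strongest
oracle, held to 1e-10); K is invariant to affine trait maps — which is why
screening the autoscaled matrix is harmless per metabolite — and to global
branch-length rescaling. Significance uses tip-label shuffling with the
add-one rule `p = (1 + #{K_perm ≥ K_obs})/(n + 1)`, which is a valid
finite-sample permutation p and never returns 0. The screen runs every
metabolite against every tree (marker, core, composition) and flags
metabolites significant on some but not all topologies — the incongruence
readout. The composition tree's UPGMA heights are used as-is for V; they
are cophenetic averages, not substitutions/site, a documented caveat that
K's scale invariance partially mitigates. A singular V (tied strains at
zero distance) falls back to a Moore–Penrose pseudo-inverse with a single
warning per tree. Per-metabolite random streams are derived from one seed
by counter, so results are independent of column order.

# Pipeline and problem sizes

`runPipeline()` chains all stages on one seed and writes plain-text
intermediates (FASTA, newick, TSV/CSV) plus a JSON summary whose headline
statistics include the conditional ANI range among pairs above the OTU
cutoff — the single number that captures "identical markers, divergent
genomes". The default configuration simulates 16 strains, a 1,500 bp
marker at rate 0.02, a 30,000 bp core at rate 1, 60 core and up to 300
accessory families, 20 Brownian-motion plus 10 white-noise metabolites,
five replicates, 100 bootstrap replicates and 1,000 randomizations per
K test. These sizes keep a full run under a minute on one CPU while leaving
every regime of interest populated (pairs above 99% marker identity,
rare accessory families, significant and non-significant metabolites);
the test suite uses smaller instances of the same machinery.

# Known limitations

Marker trees built from a nearly invariant 1,500 bp gene are dominated by
ties and near-zero distances; their topology is noise-driven, which is the
phenomenon under study, but it means marker-tree bootstrap supports mostly
measure that noise. The ANI fast path assumes homologous equal-length
representatives; families with real indels take the alignment route, which
is quadratic in gene length. The clustering step is all-vs-all and intended
for tens of strains and hundreds of genes, not full genome complements.
Amino-acid-level clustering, fragment-mapping ANI, maximum-likelihood
trees, and the upstream annotation tools whose outputs the feature module
consumes are all out of scope.
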