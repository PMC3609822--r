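---
title: "Methods: mtDNA haplotype phylogeography and riverine-barrier inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA haplotype phylogeography and riverine-barrier inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Maternally inherited, non-recombining mtDNA control-region sequences are a
standard marker for asking how the genetic variation of a structured animal
population is arranged in space, and whether landscape features — here,
large rivers — act as barriers to gene flow. `mtphylogeo` implements the
full chain of analyses for such a survey: collapsing per-sample sequences
into haplotypes, inferring haplogroups (clades) from a bootstrapped
neighbor-joining tree, quantifying within-population diversity and
between-population differentiation, measuring three geographic indices
between population centroids over a river map, and asking — by correlation
and by Gaussian-GLM/AIC model selection — which geographic index best
predicts genetic distance. A synthetic landscape-genetics generator makes
every stage runnable and testable without field data.

# Sequence handling and distances

An alignment is a character matrix over `{A, C, G, T, -, N}`; the package
consumes pre-aligned sequences and never aligns. Haplotype identity is exact
string identity: gaps compare site by site and `N` matches only itself, so
two samples that differ only at an ambiguous site remain distinct
haplotypes. This is deliberately conservative — ambiguity is expected to be
resolved upstream during base calling — and it keeps collapsing
deterministic. Haplotype ids (`H001, ...`) follow order of first appearance.

Two distances are computed between haplotypes, both with *pairwise deletion*
(a site is used for a pair only when both sequences carry an unambiguous
base; per-pair comparable-site counts are attached to every matrix):

* **Difference counts** — the number of differing comparable sites. These
  are the working currency of the diversity statistics, AMOVA and Phi-ST,
  where difference counts play the role of squared Euclidean distances
  between individuals (the classical molecular-variance convention).
* **TN93 distances** — the Tamura–Nei (1993) model with separate purine and
  pyrimidine transition rates and unequal base frequencies. Base
  frequencies are estimated once from the pooled alignment (a per-pair
  option exists); this is the standard estimator and keeps the matrix a
  function of one shared parameter set. Saturated pairs (a logarithm
  argument at or below zero) are reported as missing with a warning, or as
  an error in strict mode.

Clade-level summaries report mean pairwise differences within each clade
(undefined for singletons), between each clade pair, and the corrected
(net) value `between − (within_i + within_j)/2`. The headline mean ± sd is
taken over the 15 unordered clade pairs (between) and over the clades
(within) — the granularity at which such tables are conventionally printed.
Raw difference counts are the default here; a TN93 variant is available
since the underlying quantity can be defined under either metric.

# Trees, bootstrap and haplogroups

Neighbor-joining (Saitou–Nei, via `ape`) builds the haplotype tree and
average-linkage UPGMA the population tree. NJ can produce small negative
branch lengths; they are retained internally and clamped to zero only for
display and rooting.

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and scores each internal branch of the
point-estimate tree by the percentage of replicates containing the same
bipartition. One numerical choice matters: **a replicate counts as
containing a bipartition only if the branch is positively resolved** —
internal branches of length ≤ 1e-8 in a replicate tree are collapsed before
counting. Distance ties otherwise resolve deterministically in NJ, which
would award full support to arbitrary resolutions of data with no signal
(identical sequences are the extreme case). Replicates in which some pair
has no comparable sites are skipped and logged.

Branches below the support threshold (default 70%) are contracted,
yielding a multifurcating tree with the leaf set unchanged. Haplogroups are
then the maximal supported clusters hanging off the root: rooted input
trees keep their root; unrooted trees are rooted at the *centroid* internal
node (the node whose removal leaves the smallest largest component, ties by
node number), which for a clade radiation is the central multifurcation.
Leaves attached directly to the root become singleton clades, and clades
are labelled `G1, G2, ...` by decreasing size then lexicographically
smallest member — fully deterministic. Published clade names can be
attached afterwards by the user; the package does not try to compute
nomenclature. Note the definition is *maximal*: if a grouping of two clades
is itself supported, extraction returns the merged cluster.

# Population statistics

For a population of `n` samples with haplotype frequencies `p_i`:

* haplotype (gene) diversity `h = n/(n−1) · (1 − Σ p_i²)`, with Nei's
  (1987) sampling variance;
* mean number of pairwise differences `Π` — the mean inter-haplotype
  difference count over the `n(n−1)/2` sample pairs — with the Tajima
  (1983) total variance `(n+1)Π/(3(n−1)) + 2(n²+n+3)Π²/(9n(n−1))`;
* nucleotide diversity `π = Π/L`, with the matching per-site variance
  (Nei 1987, eq. 10.7). `π·L = Π` holds exactly by construction.

Variance (sd) estimators for these quantities differ between legacy
software implementations; the closed forms above are the documented choice
here, and the point estimates are what the downstream analyses consume.

AMOVA partitions the total sum of squared distances (difference counts)
into among- and within-stratum components with method-of-moments variance
components for unequal sample sizes; percentages are variance shares and
the Phi statistic is `σ²_a / (σ²_a + σ²_w)`. Pairwise F_ST is the
two-population AMOVA Phi on inter-haplotype distances — the distance-based
Phi-ST form appropriate to haplotype data — with a permutation test that
shuffles individuals *between the two populations of the pair only* and
reports `p = (#{Phi* ≥ Phi} + 1)/(n_perm + 1)` (default `n_perm = 1023`).
Negative estimates are finite-sample outcomes of the moment estimator and
are retained, both in tables and in the downstream regressions.

Net population distance is `Π_XY − (Π_XX + Π_YY)/2` with every term the
*frequency-weighted* mean `Σ p_i q_j d_ij` (draws with replacement), so two
populations of identical composition sit at net distance exactly zero. The
UPGMA population tree is built on this net matrix by default; the Phi-ST
matrix is also emitted for users who prefer clustering on it.

# Riverscape geometry

Population centres are arithmetic means of sample coordinates (adequate at
the sub-degree extent of a sampling site). Straight distance is the
haversine on a 6371-km sphere. Rivers are polylines with a width class;
only `large` rivers count as barriers, the threshold being a map attribute
supplied by the producer of the map (field surveys express it as "at least
as wide as a reference river", which is not a computable number).

Crossing counts are transversal intersections between the straight segment
and every large-river polyline, de-duplicated within 1e-9 of the line
parameter so a tangential touch at a shared polyline vertex counts once. An
endpoint lying exactly on a large river is rejected as ill-posed.

The detoured distance formalises "go around the headwater": it is the
shortest polygonal path whose segments cross no large river, computed on a
visibility graph whose candidate nodes are the two sites plus eight compass
offsets (ε = 0.1 km) around every river vertex. Rivers are open polylines
passable only beyond the upstream terminus; the mouth end is closed by a
long ray extension (10× the scene diagonal) so paths cannot round the
downstream end, where a real river joins a larger waterway. All planar work
happens in a local equirectangular projection about the pair midpoint;
at river-basin scale (hundreds of km, low latitude) the projection error is
far below the ε offset. The offset makes the graph robust to degenerate
contact and biases the path long by at most a few ε — negligible against
detours of hundreds of km. When the straight segment is unobstructed the
function returns the haversine distance exactly.

# Barrier inference

The unit of analysis is the pairwise table: one row per population pair
with Phi-ST and the three geographic indices. These rows are not
independent observations — they share populations — and the analyses
deliberately follow the plain Pearson/GLM treatment of such tables, which
is how this class of survey is conventionally reported; a Mantel
permutation test is provided as a clearly labelled extension for users who
want a permutation-based check.

Per-site profiles correlate Phi-ST with each index over the site's pairs
(optionally excluding one population, which shrinks a 7-population design
from 6 to 5 pairs per site). Normality of the Phi-ST values is checked with
a one-sample Kolmogorov–Smirnov test against a normal with plug-in mean and
sd using the asymptotic p-value; the Lilliefors-corrected variant is
available, but the plug-in form is the default because it is what standard
one-sample KS reports. Model selection fits Gaussian identity-link GLMs
(ordinary least squares) for each single factor and for straight +
crossings, ranked by AIC under the full Gaussian log-likelihood convention
`AIC = n·log(2π·RSS/n) + n + 2(k+2)` — constants included and the variance
counted as a parameter, which is why well-fitting models on a response of
magnitude below 1 have negative AIC. Collinear predictor sets are rejected
with a condition-number diagnostic.

One statistical caveat is worth stating: when the winner is judged across
all four models, the two-factor model beats its own nested single factor by
chance whenever the AIC gain exceeds the 2-unit penalty, which under the
null has probability ≈ 0.16 (chi-square with 1 df). Exact-winner rates
should therefore be interpreted among the three single-factor fits, and
that is how the package's own recovery experiments score them.

# The synthetic generator

`sim_config()` defines the study conditions the package is tested under: a
1121-site alignment; 54 haplotypes in 6 clades; 7 populations with sample
sizes 16, 7, 35, 7, 37, 18, 16 grouped in west/central/east cohorts on a
west-to-east band about 950 km across, with two large rivers (one isolating
the easternmost population) and one small river. Coordinates are synthetic
stand-ins. Defaults for the mutation scales are `lambda_b = 15` mutations
per clade ancestor and `lambda_w = 4` private mutations per haplotype,
chosen so the expected between/within mean-pairwise-difference ratio
`(lambda_b + lambda_w)/lambda_w = 4.75` sits in the several-fold range that
motivates calling the clades deeply diverged.

Sequences follow an **infinite-sites** mutation model by default: every
substitution hits a previously unmutated site, so the haplotype genealogy
is exactly additive, expectations are analytic (within-clade expected
difference `2·lambda_w`, between-clade `2·(lambda_b + lambda_w)`), and no
homoplasy exists. `finite_sites = TRUE` restores recurrent mutation, and
`ts_bias` adds a transition preference for exercising the TN93 estimator.
Substitution is otherwise uniform — deliberately simpler than the TN93
model the estimators assume, so estimator tests are not circular.

Population structure is phenomenological rather than coalescent: each clade
is seeded at a home population and each population draws its haplotype
frequency vector from a Dirichlet whose concentration for a haplotype
decays as `alpha0 · exp(−d_eff/sigma)`, with
`d_eff = straight km + beta · crossings`. `sigma` (km) sets how fast
haplotype sharing decays with distance and `beta` (km per crossing) the
riverine penalty; `beta = 0` makes rivers genetically inert by
construction. The default `sigma = 150` produces the strong locality
clustering characteristic of these surveys (most haplotypes
locality-specific); the parameter-recovery experiments instead use
`sigma = 500`, i.e. moderate decay relative to the 950-km span, because at
`sigma = 150` differentiation saturates across distant pairs and no
distance index can be told from another. Samples are multinomial draws from
the frequency vectors; sample coordinates jitter about the population
centre (sd 0.05°).

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: homoplasy and rate heterogeneity along real
control regions (under the default model), coalescent genealogical noise
within clades, historical range shifts (refugia), sex-biased dispersal, and
uneven sampling effort within sites. The generator validates the machinery
and its qualitative signatures, not the demographic realism of any
particular inference.

# Problem sizes and known limitations

The test suite and the acceptance script run everything at the study scale:
1000 bootstrap replicates for the haplotype tree, 1023 permutations per
Phi-ST pair where p-values are reported, 100-replicate Monte-Carlo
recovery experiments, 200-test permutation-uniformity checks, and
80×80-lattice shortest-path cross-checks for the detour geometry. These
sizes were chosen so each suite completes in minutes on one CPU while
keeping Monte-Carlo error well inside the asserted margins.

Known limitations:

* Clade extraction is automated as "maximal supported clusters"; a
  published classification that subdivides a supported cluster (or merges
  unsupported ones) will not be reproduced label-for-label — names attach
  via a user mapping.
* Supports come from NJ bootstrap alone; corroboration by other inference
  methods (likelihood, parsimony) is out of scope, so supports here can
  exceed the minimum-across-methods convention some studies use.
* With the distance-based Phi-ST on deeply-diverged haplotypes at field
  sample sizes (7–37 per population), pairwise estimates are noisy; the
  exact-AIC-winner statistic over 21 pairs with strongly correlated
  geographic predictors remains variable across replicates even when the
  generating mechanism is pure isolation by distance. The package reports
  measured rates rather than overstating identifiability.
* Detour routing assumes rivers can be rounded only at the headwater and
  treats lakes or swamps only insofar as they are drawn as wide river
  polylines.
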