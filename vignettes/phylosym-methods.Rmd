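---
title: "How phylosym simulates and detects phylosymbiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How phylosym simulates and detects phylosymbiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosym)
```

## The question the simulator answers

Phylosymbiosis is the observation that closely related host species tend to
carry more similar microbial communities than distantly related hosts. The
pattern is often read as evidence for intimate host-microbe coevolution, but
a much simpler mechanism can generate it: if a host trait (gut pH, diet,
body temperature) filters which microbes establish, and that trait itself
carries phylogenetic signal, then microbiota similarity inherits the
phylogenetic structure of the trait. `phylosym` builds that null world
end-to-end so the two standard detection procedures can be calibrated
against it: how often do they fire when there is *only* neutral drift
(type-I error), and how often when there is *only* trait filtering of known
phylogenetic signal (power)?

## The generative model, step by step

**Trees.** Host and microbe phylogenies are simulated under a pure-birth
process (`sim_yule_tree()`, via `ape::rphylo` with death rate 0) and
rescaled to unit root-to-tip height so node depths live on [0, 1] and are
comparable across replicates. The birth rate is irrelevant after rescaling.
Defaults follow the study design: 25 host species and a pool of 150
microbial species (10 and 75 appear in the reduced grids).

**Traits with tunable signal.** A continuous host trait evolves by Brownian
motion, but on a tree whose node depths have first been raised to a power
`delta` (`delta_transform()`). Small `delta` pushes divergence toward the
root, producing a strongly conserved trait; large `delta` pushes it toward
the tips, erasing signal. The grid {0.01, 0.1, 1, 10, 1000} spans both
regimes. Because `delta` controls only the *expected* signal, each
replicate records its *realized* signal with Blomberg's K
(`blomberg_k()`), computed by the GLS formula on the original,
untransformed tree — the same tree all downstream phylogenetic distances
use, so K describes signal relative to the distances being tested. Results
are always summarized against realized K bins, not against `delta`.

Microbial trait preferences evolve by plain Brownian motion (`delta = 1`)
on the microbe tree and are then min-max rescaled into the realized host
trait range (`rescale_microbe_traits()`), so every host value has
plausible microbial matches. The Brownian rate defaults to `sigma2 = 1`
(the default of the standard phylogenetics toolchains). Note one subtlety:
the niche breadth below is an absolute quantity, so the ratio of host-trait
range to niche breadth does depend on `sigma2`; we keep both at their
defaults rather than treating either as free.

With more than one trait (2 or 4 are supported grid values) traits evolve
independently with the same `delta`, and a replicate's binning signal is
the mean Blomberg K across traits — the summary the multi-trait experiments
needed but no single convention defines; the replicate table keeps
per-trait values recoverable by re-running with the recorded seed.

**Assembly.** Each host community holds exactly `capacity = 150`
individuals. At each of `years = 20` time steps the whole community is
redrawn from a multinomial distribution whose cell probabilities mix three
normalized components weighted by the `beta` strengths
(`recruitment_probabilities()`):

* environment: a Gaussian niche kernel
  `exp(-(h - m)^2 / (2 * 0.5^2))` of the host-trait/preference mismatch
  (products over trait dimensions — a diagonal multivariate niche);
* abundance: the previous step's relative abundances (uniform at step 1,
  when the community is empty);
* competition: `1 -` the abundance-weighted niche overlap with residents.

The scenario presets are `filtering` (`beta_env = 1`, others 0), `neutral`
(`beta_abun = 1`, others 0) and `competition` (0.5 / 0.25 / 0.25). The
source pool is infinite and unbiased; there is no transmission between
hosts and no codiversification — deliberately, since the point is to see
phylosymbiosis emerge *without* those mechanisms.

Two design choices here were genuinely open, because the original
community-assembly engine's exact update rule is not restated in our
source material: we combine the components *additively* (a convex mixture,
which reproduces every scenario limit exactly and keeps the betas
interpretable as weights), and we use *full-replacement* dynamics (all
`capacity` individuals redrawn each step) rather than partial turnover.
Both are documented contracts of `assembly_params()`. The consequence
worth knowing: with `beta_abun = 0` full replacement makes the final
filtered community a single multinomial draw from the fitness kernel, the
least noisy dynamic consistent with the parameter description. Our
detection-power estimates at a given signal level therefore sit above the
original study's (whose engine retains more assembly noise), while type-I
error, effect sizes and every directional comparison reproduce. Treat the
power numbers as an upper envelope for this assembly rule.

**Beta diversity.** Four pairwise dissimilarities (`distance_matrix()`):
Jaccard and Bray-Curtis (via `vegan::vegdist`), and both UniFrac variants
computed per edge of the microbial tree. Unweighted UniFrac is the branch
length unique to either community divided by the branch length spanned by
their union; branches present in neither community are excluded from both
numerator and denominator. Weighted UniFrac uses the *normalized* form,
`sum(len * |A - B|) / sum(len * (A + B))` over branch-wise abundance
fractions, so that all four metrics share the [0, 1] range the UPGMA and
Mantel comparisons assume.

## The two detection procedures

**Mantel** (`mantel_test()`): Pearson correlation between host cophenetic
distances and community dissimilarities over the lower triangle, with a
one-sided permutation null (999 joint row/column permutations of the
community matrix; `p = (count + 1) / (n_perm + 1)`). Permutations tied
with the observed correlation count as exceedances, guarded by a
square-root-machine-epsilon tolerance — with few labels, exact ties are
common and floating-point noise must not break them.

**Dendrogram** (`dendrogram_test()`): UPGMA (average linkage; merge
heights are half the mean inter-cluster distance) of the community
dissimilarities, compared to the host tree by the normalized
Robinson-Foulds distance. Both trees are treated as rooted; the statistic
is the symmetric difference of non-trivial clade sets divided by
`2(n - 2)`, the rooted-binary maximum, so 1 is attainable and 0 means
identical topologies. The null shuffles host tip labels (default) or draws
fresh pure-birth topologies; the random topologies are generated by
sequential uniform pair-merging, whose tree-shape distribution coincides
with the pure-birth one while costing a handful of additions per draw.
Internally clades are encoded as exact numeric bitmasks (`sum(2^(i-1))`,
collision-free up to 52 tips), which makes a 999-draw null a few
milliseconds instead of a tree rebuild per draw.

**Trait Mantel** (`trait_mantel()`): the same Mantel machinery with
Euclidean host *trait* distances — the positive control, since the trait
is the true filter; it should always detect at least as well as the
phylogeny-based test, and does.

Numerical corner cases are errors, not silent results: constant traits
(Blomberg K and trait distances undefined), zero-variance distance
triangles, empty communities, label mismatches between tables and trees,
and delta or niche-breadth values outside their domains.

## The experiment runner

`sim_config()` bundles a parameter combination; `run_replicate()` executes
trees → traits → assembly → beta diversity → tests for one seed;
`run_set()` aggregates a batch into per-bin detection proportions and mean
statistics; `run_sweep()` writes tidy replicate- and bin-level TSVs and
resumes interrupted runs by replicate id. Seeds are counter-derived
(`master * 48271 + index * 1299721 mod 2^31`), so extending a batch or
adding a set never perturbs existing replicates.

Realized-K bins default to `[0, 0.25), [0.25, 0.5), [0.5, 1.5), [1.5, 15]`
— the last two match the moderate and very-strong ranges the study
discusses; the exact interior edges are our documented default (no
canonical set exists), and per-bin counts are always reported so the
replicate table can be re-binned.

Because bin occupancy depends on the stochastic realized K, `run_pool()`
accumulates replicates (cycling the delta grid) until a target bin holds
enough of them; the shipped analyses require at least 200 qualifying
replicates per bin, with batches of 100 and a hard cap of 1500.

## Problem sizes and what the tests show

The packaged test suite and the acceptance script run the full study
conditions (25 hosts, 150 microbes, 999 permutations) at 400-500 neutral
replicates and 200+ qualifying replicates per signal bin — enough for
Monte Carlo standard errors of 1-3 percentage points on detection
proportions, which is the scale at which the study's own numbers are
quoted. Exact properties (permutation-p enumeration, RF clade sets, GLS
arithmetic, per-edge UniFrac tables, multinomial assembly means) are
checked against independent oracles at machine precision on small cases.

What passing does *not* show: anything about real data. The generator's
world has no sequencing noise, no unobserved taxa, no intraspecific
variation, no transmission, and exactly one filtering mechanism; its
communities are far cleaner than amplicon surveys. The package calibrates
*procedures*, and its clean world makes the calibration conservative in
one specific sense — if a test has inflated power here, it is the assembly
rule, not the test, being generous.

## Known limitations

* The assembly update rule is a reconstruction (additive mixture, full
  replacement); detection power at moderate signal depends on it visibly
  (see above), effect sizes much less.
* Only Brownian/delta trait evolution; no Ornstein-Uhlenbeck variant.
* The dendrogram machinery is limited to 52 hosts by the bitmask clade
  encoding (far above the study grid's 25).
* `sigma2` and `niche_breadth` are not separately identifiable — only
  their ratio matters to filtering strength; both are fixed at the
  defaults above.
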