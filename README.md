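# phylosym

Can ecological filtering alone explain phylosymbiosis? `phylosym` is an R
package that simulates the simplest world in which the answer is yes — and
uses it to calibrate the two statistical procedures the microbiome field
actually runs.

Phylosymbiosis is the pattern in which closely related host species harbor
more similar microbiotas than distant hosts. It is routinely detected in
one of two ways:

* **Mantel approach** — Pearson's *r* between host phylogenetic distance
  and microbiota beta diversity, with significance from 999 joint
  row/column permutations of the community distance matrix;
* **Dendrogram approach** — build the UPGMA dendrogram of microbiota beta
  diversity and compare its topology to the host tree with the normalized
  Robinson–Foulds distance, nRF ∈ [0, 1] (0 = identical topologies), with
  significance from 999 shuffles of the host tip labels.

`phylosym` embeds both tests (plus a host-trait Mantel control and four
beta-diversity metrics: Jaccard, Bray–Curtis, weighted and unweighted
UniFrac) in a fully seeded simulation pipeline:

1. **Trees** — pure-birth host (*n* = 10, 25) and microbe (*m* = 75, 150)
   phylogenies, rescaled to unit height.
2. **Traits** — a continuous host trait evolved by Brownian motion on a
   delta-transformed tree (node depths raised to the power δ ∈
   {0.01, 0.1, 1, 10, 1000}), so its phylogenetic signal is tunable; the
   realized signal of every replicate is measured with Blomberg's *K* on
   the untransformed tree. Microbial trait preferences evolve neutrally
   and are rescaled into the host-trait range.
3. **Assembly** — an individual-based model: each host's community of
   *K* = 150 individuals is redrawn multinomially for 20 time steps with
   recruitment probabilities `∝ beta_env·Ê + beta_abun·Â + beta_comp·Ĉ`,
   where Ê is a Gaussian niche kernel `exp(−(h−m)²/2σ²)` (σ = 0.5) of the
   host-trait/preference match, Â the current relative abundances and Ĉ a
   niche-overlap competition penalty. Presets: *filtering*
   (beta_env = 1), *neutral* (beta_abun = 1; the negative control),
   *competition* (0.5/0.25/0.25).
4. **Detection and summary** — every replicate is tested with both
   procedures; an experiment runner bins replicates by realized *K* and
   reports detection proportions and mean effect sizes per bin.

## Worked example

One filtering-scenario data set, assembled and tested by hand:

```r
library(phylosym)

host     <- sim_yule_tree(25, seed = 11)          # host phylogeny, height 1
microbes <- sim_yule_tree(150, seed = 12)         # microbe pool phylogeny
ht       <- sim_host_traits(host, delta = 0.1, seed = 13)
ht$k_mean
#> [1] 1.71                                        # realized Blomberg K

prefs <- rescale_microbe_traits(sim_bm_traits(microbes, seed = 14), ht$traits)
tab   <- assemble_system(ht$traits, prefs, assembly_params(), seed = 15)

summary(phylosymbiosis_test(host, tab, method = "mantel",
                            metric = "wunifrac", microbe_tree = microbes,
                            seed = 16))
#> Phylosymbiosis test
#>   method: mantel (wunifrac)
#>   Pearson r = 0.3599
#>   p = 0.001  (999 permutations, matrix_permutation null, one-sided)
#>   significant at alpha = 0.05: yes
#>   null statistic quantiles: 2.5% -0.140 | median -0.002 | 97.5% 0.185

summary(phylosymbiosis_test(host, tab, method = "dendrogram",
                            metric = "wunifrac", microbe_tree = microbes,
                            seed = 17))
#> Phylosymbiosis test
#>   method: dendrogram (wunifrac)
#>   normalized RF = 0.9565
#>   p = 0.21  (999 permutations, tip_shuffle null, one-sided)
#>   significant at alpha = 0.05: no
```

The two outputs show the study's central contrast in miniature: a host
trait with strong phylogenetic signal (K ≈ 1.7) filtering the microbiota
produces a clear Mantel correlation (r = 0.36, p = 0.001), while the
dendrogram topology still matches the host tree in only one clade out of
23 (nRF = 0.96, not significant) — the Mantel approach is the more
sensitive instrument, and phylosymbiosis can arise with no coevolution at
all.

For batch experiments:

```r
cfg <- sim_config(scenario = "filtering", delta = c(0.01, 0.1, 1),
                  n_replicates = 250, seed = 1)
s <- run_set(cfg)       # per-K-bin detection proportions and effect sizes
print(s)
```

A thin command-line front end for single data sets (Newick tree + TSV
count table) and sweeps lives at `inst/cli/phylosym.R`.

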