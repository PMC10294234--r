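---
title: "Methods: clonal evolution analysis of TKI-resistant sublines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal evolution analysis of TKI-resistant sublines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkiclonal)
```

# The model

The package analyses serially sampled drug-resistance experiments: a
TKI-sensitive parental cell line, and for each replicate a low-dose and a
high-dose resistant subline (labelled `{low|high}{IM|N}-R{n}` for imatinib
and nilotinib). The unit of analysis is the *variant trajectory*: the VAF of
one variant key (`chrom:pos:ref:alt`) across the sensitive → low → high
trio. The modelling assumptions are:

* **VAF is always recomputed** as `alt_depth / depth` from the per-sample
  `AD`/`DP` FORMAT fields; an `AF` tag in the VCF is never trusted. Zero
  depth gives an undefined (`NA`) VAF, which can only fail the coverage
  gate.
* **Absence is evidence of absence**: a variant key with no record in a
  stage is treated as VAF 0 when computing deltas (`ABSENT`), because the
  caller emits a record whenever at least one alternate read exists. This is
  exactly how the generator behaves, so the convention is self-consistent.
* **Thresholds are strict** where a rule says "greater than": a delta of
  exactly 0.15 fails, a sensitive VAF of exactly 0.05 fails (the rule is
  "at or above means pre-existing"), and an intronic distance of exactly
  20 bp is kept.
* **Cascade precedence** is coverage → sensitive exclusion → deep-intronic →
  delta. A variant with high sensitive VAF *and* low coverage reports
  `FAIL_depth`: verdicts always name the earliest failing gate.

# Filter parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `min_depth` | 10 | conventional minimum for a usable VAF estimate at ~60× mean coverage |
| `sensitive_vaf_max` | 0.05 | below this a sensitive-stage signal is indistinguishable from noise; at or above it the variant pre-existed |
| `delta_vaf_min` | 0.15 | a clone must reach ~30% cell fraction (heterozygous) to clear it — selection, not drift |
| `deep_intronic_distance` | 20 bp | the conventional splice-region bound; beyond it an intronic variant is unlikely to be functional |

All are configurable (`filter_config()`) and every pipeline step writes its
effective configuration plus an md5 config hash into
`<step>_metadata.json`. The metadata deliberately carries **no timestamps**
so identical runs produce byte-identical output trees.

# The synthetic generator

Real accessions are not bundled, so the generator fabricates the entire
input side with known ground truth:

* **Reference**: one contig per gene (`n_genes = 60`, 3 kb each). The
  one-contig-per-gene convention makes gene assignment trivial and keeps
  position sampling simple; `exons_per_gene = 4` exons cover
  `exon_fraction = 0.5` of each contig so both exonic and deep-intronic
  placements are always available.
* **Planted drivers** (`default_planted_drivers()`): 18 variants whose
  trajectory shapes mirror recurrent TKI-resistance observations — late
  high-dose gains (PTPN11-, PDGFRB-, KRAS-like), early constant gains
  (NRAS-like), a two-variant gene in one subline (LRP1B-like, exercising
  MULTIHIT), a truncating variant (MCM3AP-like) and low-dose-only clones.
  Each driver drags `n_hitchhikers_per_driver = 2` passengers with the same
  trajectory jittered by ±0.05 VAF.
* **Background load**: `n_background_variants = 400` per trio, drawn from a
  category mixture (germline 0.35, acquired-high 0.25, shared 0.20,
  low-only 0.08, subthreshold 0.12). With the default depth of 60× this
  yields ~100–190 passing variants per subline — the order of magnitude a
  moderate-coverage subline screen reports. `deep_intronic_fraction = 0.05`
  of background variants are placed > 20 bp from any exon so the intronic
  rule is exercised by construction.
* **Contexts**: background trinucleotide channels are sampled from the
  configured `signature_mix` applied to a synthetic Dirichlet signature
  matrix (`make_signature_matrix()`, concentration 0.15 for COSMIC-like
  peakiness), and each variant is physically placed at a reference position
  whose pyrimidine-normalized triplet matches its channel — so the spectrum
  computed back from the sequence equals the planted one exactly.
* **Reads**: per stage, depth ~ Poisson(`depth_mean`) floored at 1, alternate
  count ~ Binomial(depth, true VAF); records with zero alternate reads are
  not written. `NA` stage VAFs mean absent, not missing.
* **Network**: a stochastic block model over the gene universe
  (`ppi_communities = 2`, within/between edge probabilities 0.2/0.01), plus
  one exact gene set per community and random decoy sets. Isolated vertices
  are tethered to a same-community partner because an edge list cannot
  carry degree-0 nodes through a round trip.

**Determinism.** All randomness flows from `sim_config(seed)`; each public
generator entry point reseeds from a value derived from the seed (and drug
index/replicate for trios), so any trio is reproducible in isolation and
`write_synthetic_inputs()` is byte-identical across runs.

**Limits.** The generator does not model mapping artefacts, strand bias,
copy-number change, indel realignment or contamination; depths are i.i.d.
per site; germline heterozygosity is a flat 0.3–0.6 VAF band. It is a test
harness for the analysis code, not a sequencing simulator.

# Numerical choices

* **Signature fitting** solves `min ‖Sx − p‖₂, x ≥ 0` with
  `pracma::lsqnonneg` on the *normalized* spectrum (`p` sums to 1), then
  renormalizes `x` to exposures summing to 1. Fitting on proportions makes
  the residual comparable across sublines with different burdens. A
  rank-deficient signature matrix warns (exposures not unique); an empty
  spectrum is a fit error rather than a silent uniform answer.
* **Propagation** iterates `F ← αW′F + (1−α)F₀` with symmetric degree
  normalization to L1 tolerance 1e−8. With `α ≤ 0.8` the spectral radius of
  `αW′` is at most 0.8, so the fixed point is unique and the iteration is a
  contraction; the test suite checks it against the direct dense solve
  `(I − αW′)⁻¹(1−α)F₀` to 1e−6. Final per-subline columns are renormalized
  to sum 1 because symmetric normalization does not conserve mass exactly
  on irregular graphs, and cross-subline comparability matters more than
  the raw diffusion scale.
* **Exon distance** is the distance to the nearer exon *boundary base*
  (a position one base past an exon end has distance 1), not the
  zero-length gap convention of range libraries — the 20 bp splice-region
  rule counts bases from the exon edge.
* **Percentage rendering** (`render_vaf_pct()`) rounds half-up
  (`floor(x·10^d + 0.5)`), so 0.2917 → "29.2%" and 0.6929 → "69%";
  banker's rounding would print "29.1%" for some inputs. Rendering is
  report-only; pipeline arithmetic never rounds.
* **Clustering** uses average-linkage hierarchical clustering on
  1 − Pearson correlation between columns; `k` is user-set or chosen by the
  largest mean silhouette width over `k ∈ 2..min(10, n−1)`. Constant
  columns are dropped with a warning since correlation is undefined for
  them.

# Recovery experiments

The test and acceptance suites validate the pipeline against the
generator's ground truth:

* **Filter oracle**: verdicts and classes must match a deliberately naive
  per-variant if/else reimplementation on 50 randomized trajectories × 20
  seeds (randomized call/depth/VAF patterns including zero depths and
  missing stages).
* **High-depth exactness**: at `depth_mean = 10000` the binomial VAF noise
  (sd ≈ 0.005) is far inside every planted margin, so each planted driver's
  class must be recovered *exactly* and reach the report.
* **Signature recovery**: a 20,000-variant trio drawn from a 0.6/0.4
  two-signature mixture must be recovered within 0.05 (and a 150-variant
  subsample within 0.15) by NNLS — through the full path of placing
  variants in sequence and reading their contexts back. NNLS is also
  checked against a 0.001-step grid search over the exposure simplex.
* **Community seeding**: a 16-gene configuration plants imatinib drivers
  exactly in PPI community 1 and nilotinib drivers in community 2 (gene
  order fixes the contiguous block assignment). Propagated subline profiles
  must then cluster by drug with adjusted Rand index 1.

Problem sizes (60 genes × 3 kb default, 100 × 20 kb for the 20k-variant
runs, graphs ≤ 200 nodes for the dense oracle) are chosen so the whole
suite runs in minutes on one CPU; they are properties of this package's
test design, not of any external dataset.
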