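---
title: "Methods: attributing ocean exocellular DNA to its sources and depths of origin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing ocean exocellular DNA to its sources and depths of origin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exodna)
```

# The problem

Over half of the DNA in the open ocean sits outside living cells. The
fraction that passes a 0.1 µm filter — *exocellular DNA* — is a mixture of
three pools: DNA inside extracellular vesicles, DNA encapsidated in virus
particles, and free (dissolved) DNA. Metagenomic sequencing of these pools,
mapped against a depth-resolved reference gene catalog, lets us ask who the
DNA came from and, less obviously, *from what depth*: if a gene's reference
coverage is concentrated at the surface and that gene shows up in a 1,000 m
free-DNA sample, the DNA it represents was probably exported downward rather
than produced in place. This package implements that chain of inference as
tested, reusable code, together with the supporting analyses an investigation
of this kind runs: composition summaries, a Martin-curve export budget,
fragment-size spectra, and ordination statistics.

# Depth-of-origin attribution

## Model

The reference catalog records, for each gene $g$ and catalog depth $d$, a
non-negative coverage $c_{gd}$. The probability that a sequence matching $g$
originated at $d$ is taken to be the coverage ratio

$$P(d \mid g) = \frac{c_{gd}}{\sum_{d'} c_{gd'}},$$

and a sample's normalised per-gene coverage $m_g$ (proportions of total
mapped counts, `normalize_counts()`) is portioned as
$\text{portion}(g,d) = P(d \mid g)\, m_g$, then accumulated into
(depth × domain) cells. The model assumes that (i) the catalog's depth
profile of a gene reflects where organisms carrying that gene live, and
(ii) a sample is a linear mixture of material produced at catalog depths.
Under those assumptions attribution is linear in the sample (verified as a
test invariant) and conserves mass exactly: portioned mass plus the
unassigned bucket equals the sample total.

## Identifiability

Attribution is only as sharp as the catalog is depth-structured. Two
boundary cases are exercised in the tests rather than hidden:

* **Depth-exclusive marker genes** (coverage at exactly one depth) make the
  mixture fully identifiable: attributing the exact mixture expectation
  returns the generating weights, and a finite multinomial sample returns
  them within binomial error.
* **A depth-uniform catalog** is completely uninformative: every sample
  attributes to the uniform distribution over depths regardless of its true
  origin. Real catalogs sit between these poles, so recovered depth masses
  are shrunk toward the catalog's average profile; the worked example in the
  README (0.60 recovered from a generating 0.67 with half the genes
  depth-exclusive) shows the typical size of that blurring.

## Choices

* **Per-depth renormalisation (default on).** The reference survey's
  sequencing effort differs by depth; without renormalising each depth
  column to unit sum, deeply sequenced depths would dominate every gene's
  ratio. The switch `renormalize_depths = FALSE` uses stored coverage as is.
* **Unassigned bucket.** Genes with zero catalog coverage at every depth,
  and sample genes absent from the catalog, carry no depth information.
  Both accumulate into an explicit `unassigned` mass (reported, never
  dropped), because silently discarding them would break conservation and
  overstate confidence.
* **Depth bins.** Summaries use contiguous half-open zones
  `[0,100) [100,200) [200,500) [500,1001) [1001,Inf)` named upper euphotic,
  DCM band, upper mesopelagic, lower mesopelagic, deep. Contiguity means
  binned masses conserve the total; the edges place the conventional
  sampling depths (75, 125, 250, 500, 1,000 m) in the zones those names
  imply, with 1,000 m counted as lower mesopelagic. Custom bins are a
  config argument.
* **Euphotic share.** `euphotic_fraction()` uses depths ≤ 200 m, so the
  200 m boundary depth counts as euphotic. It reports the share both over
  depth-assigned mass only and with the unassigned bucket in the
  denominator, since either convention is defensible.

# Export-flux model

The flux of sinking particulate DNA is modelled as a Martin curve,
$F(z) = F_{ref} \,(z/z_{ref})^{-b}$, and compared against the free-DNA
standing stock: `flux_supply_ratio()` converts the areal flux (µg DNA m⁻²
d⁻¹) arriving at depth $z$ to a volumetric daily supply by spreading it over
a remineralisation layer (default 100 m; µg m⁻³ d⁻¹ → ÷1,000 → µg L⁻¹ d⁻¹)
and reports it as a percentage of the stock (µg L⁻¹) per day.

Parameter defaults and their reasoning:

* `z_ref = 175` m — the base of the euphotic zone at a subtropical-gyre
  site, the natural reference horizon for export.
* `b = 0.86` — the canonical open-ocean flux-attenuation exponent.
* `F_ref` has **no defensible universal default** and must come from the
  user's site: export production × the DNA share of exported organic
  matter. The demo configuration uses 4,000 µg DNA m⁻² d⁻¹, an
  order-of-magnitude figure consistent with subtropical-gyre carbon export
  of tens of mg C m⁻² d⁻¹ carrying a percent-level nucleic-acid share, and
  stocks of 0.10 µg L⁻¹, the concentration scale reported for open-ocean
  free DNA. These are illustrative study conditions, not claims.
* **Deposit vs divergence.** The default conversion treats all flux arriving
  at $z$ as remineralised within the layer ($F(z)/\Delta z$, the simple,
  conservative bookkeeping); `mode = "divergence"` instead uses the flux
  actually lost across the layer, $(F(z) - F(z+\Delta z))/\Delta z$, which
  is smaller. How areal flux should be compared with a volumetric stock is
  genuinely underdetermined, so both are exposed.
* `sweep_parameters()` turns ranges of $(F_{ref}, b)$ into min/max ratio
  bounds per depth — the honest way to print a range when the inputs are
  uncertain. The model assumes steady state; there is no time stepping.

# Fragment-size spectra

Electropherogram traces arrive already sized in bp by the instrument
software (75–50,000 bp range); ladder calibration is out of scope.

* **Normalisation and band fractions** use trapezoidal integration on the
  linear bp axis over the instrument-defined grid, with linear interpolation
  at band edges so that any partition of the sizing range sums to exactly 1.
  Band boundaries default to the conventional classes: LMW < 1,000 bp,
  HMW 1,000–40,000 bp, and the < 350 bp degradation band.
* **Peak apexes are located on the log-size display curve** (signal per unit
  log size, `rfu × size`), the axis on which electropherograms are actually
  drawn. This matters: a band that is Gaussian on the log axis has its
  per-bp density mode shifted *below* its center by a factor
  $10^{-\sigma^2 \ln 10}$, so detecting apexes on the per-bp density would
  mislocate every peak; on the display curve the apex sits at the center to
  within one grid step.
* **Peak width** is measured at half prominence on the bp axis
  (full-width-at-half-maximum conventions differ between instruments, and
  half prominence is robust to overlapping bands); the distinct/broad
  classification thresholds default to 5,000 and 10,000 bp and are config.
  Per-peak mass fractions partition the trace at the minima between adjacent
  retained peaks, so they sum to at most 1.
* **Baseline** is assumed already subtracted; `subtract_baseline()` offers a
  rolling-minimum correction for traces that are not.

# Community comparisons

Composition tables (proportions of mapped counts) are square-root
transformed, turned into Bray-Curtis dissimilarities, and compared by
one-way PERMANOVA with a pseudo-F computed directly from among/within sums
of squared distances; p-values use the add-one permutation convention
$p = (1 + \#\{F_\pi \ge F_{obs}\})/(1 + n_\pi)$, whose floor is
$1/(n_\pi+1)$. Bray-Curtis, the pseudo-F and Benjamini-Hochberg are
implemented in this package because they are the statistics under test, and
each is cross-checked in the suite against an independent implementation
(vegan's `vegdist` and `adonis2`, and `p.adjust`); NMDS delegates its
numerical optimisation to `vegan::metaMDS` under a fixed seed, since an MDS
optimiser is infrastructure, not a claim. Pairwise PERMANOVA runs on every
pair of groups and BH-adjusts across all pairs — the family of tests is the
set of pairwise comparisons actually made. Which taxonomic level feeds the
comparison (family or order) is the caller's choice of composition table;
the demo uses family level.

A calibration property is enforced rather than assumed: on label-exchangeable
null data the test's type-I error at α = 0.05 must sit within Monte-Carlo
error of 0.05 (500 null datasets of 12 samples, 999 permutations each, in
the acceptance suite).

# The synthetic-data generator

The generator exists so every downstream stage has ground truth. It emulates:

* **depth-structured taxa** — taxon depth profiles are Dirichlet(α = 0.3)
  over the depth grid, giving the patchy, depth-localised distributions the
  attribution needs; α is an argument;
* **marker genes** — a configurable fraction of genes are depth-exclusive,
  guaranteeing identifiability at 1.0 and realistic blurring below it;
* **unannotated sequences** — a configurable fraction of genes carry no
  taxonomy (default 0.25, the right order for marine metagenomes);
* **fixed sequencing effort** — counts are one multinomial draw over genes
  (not per-gene Poisson), so totals are exact and attribution error is
  binomial;
* **CE traces** — mixtures of Gaussian bands in log10(bp) (CE sizing is
  approximately log-linear) plus an exponential degradation smear toward
  small fragments, with analytically normalised per-bp densities so band
  masses are known exactly.

It does **not** emulate read-level sequencing (no FASTQ, no mapping error),
chimeric or horizontally transferred genes whose catalog depth profile
misrepresents their origin, compositional coupling between taxa, or
instrument noise beyond optional additive Gaussian noise. Passing tests
therefore demonstrate that the *computations* are correct under the stated
model, not that the model captures every property of field data.

The demo configuration (`demo_config()`) mirrors the study design this
pipeline serves: 600 genes over the six conventional sampling depths
(5–1,000 m), 14 samples spanning vesicle/virus/free/cellular fractions, and
mesopelagic free-DNA samples whose mixing weights place 67% (500 m) and 46%
(1,000 m) of their mass in the euphotic zone — the regime where depth
attribution is scientifically interesting. Read depth is 2×10⁵ per sample
and PERMANOVA uses 199 permutations in the demo (999 elsewhere).

# Numerical conventions and problem sizes

* All randomness flows through a single integer seed per call; no function
  leaves global RNG state behind. Pipeline runs are byte-identical under a
  fixed config.
* Proportions are validated to sum to 1 within 1e-9 (mixture weights, peak
  masses); internal conservation checks hold to 1e-12 in tests.
* The major-taxon cutoff is a *strict* inequality (> 0.5% in at least one
  sample); ties at the cutoff are excluded, and the selected set is monotone
  non-increasing in the cutoff.
* Degenerate inputs are defined, not crashed on: zero-coverage genes flag as
  unassigned; an all-equal distance matrix yields PERMANOVA p = 1; a flat
  trace yields zero peaks; an all-zero count table is an error.
* Test problem sizes were chosen so the full suite runs in well under a
  minute of compute apart from the PERMANOVA calibration (500 × 999
  permutations, ~20 s): catalogs of 50–600 genes, read depths 10⁴–10⁷,
  traces of 1,000 points. These sizes are far past where the asymptotic
  checks stabilise.

# Known limitations

* Attribution inherits every bias of the reference catalog: genes absent
  from it are unassignable, and depths it undersamples attract too little
  mass even after per-depth renormalisation.
* Whether sample coverage entering the attribution product should be the
  per-gene proportion (default) or raw coverage under another scaling is
  not settled; raw mode is available via `use_proportions = FALSE`.
* The export model is bookkeeping on a power law, not mechanism: no particle
  disaggregation kinetics, no zooplankton transport, no water-mass
  advection. It answers "could sinking particles plausibly supply this
  much?" and nothing stronger.
* PERMANOVA is the one-way, single-factor design used for pairwise
  fraction/community comparisons; there is no multi-factor or stratified
  permutation support.
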