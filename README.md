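# exodna

Analysis of the microbial sources and depth origins of ocean **exocellular
DNA** — the DNA pool that passes a 0.1 µm filter, made up of vesicle-enclosed
DNA, virus-encapsidated DNA, and free ("dissolved") DNA. Given metagenomic
gene count tables mapped against a depth-resolved reference gene catalog
(0–4,000 m), the package answers three questions oceanographers ask of these
samples:

1. **Who is the DNA from?** Domain-, family- and ecotype/host-level
   composition of each fraction, with unannotated sequences reported
   explicitly and a ">0.5% in any sample" rule for selecting major taxa.
2. **Where in the water column did it come from?** Probabilistic depth-of-origin
   attribution: the probability that a sequence matching gene *g* originated
   at depth *d* is the ratio of that gene's catalog coverage at *d* to its
   total coverage,

   P(d | g) = cov(g, d) / Σ_d′ cov(g, d′),

   and each gene's normalised sample coverage is portioned across depths by
   these probabilities, then aggregated by domain and binned into
   water-column zones (upper euphotic, DCM band, mesopelagic, deep). Genes
   with no catalog coverage form an explicit *unassigned* bucket, so mass is
   always conserved.
3. **Could sinking particles supply it?** A Martin-curve export model,
   F(z) = F_ref · (z/z_ref)^(−b), converts the DNA flux arriving at depth
   into a daily percentage of the measured free-DNA standing stock, with
   parameter sweeps turning (F_ref, b) uncertainty into printed ranges.

Around these sit fragment-size-spectrum metrics from capillary-electrophoresis
electropherograms (LMW <1,000 bp / HMW 1,000–40,000 bp band fractions, peak
detection with distinct/broad width classes), and community comparison
statistics (square-root transform → Bray-Curtis → NMDS, pairwise PERMANOVA
with Benjamini-Hochberg correction). A seeded synthetic-data generator
produces catalogs, samples and traces with known ground truth, so the whole
pipeline is testable end to end without any external download.

## Worked example

Simulate a depth-resolved catalog, a mesopelagic free-DNA sample whose DNA is
mostly of surface origin, attribute it, and ask whether sinking particles
could supply it:

```r
library(exodna)

catalog <- make_catalog(n_genes = 400, n_taxa = 10,
                        depth_grid = c(5, 75, 125, 250, 500, 1000),
                        depth_exclusive_frac = 0.5, seed = 101)

spec <- mixture_spec("free_500m", "free", collection_depth = 500,
                     weights = c(`75` = 0.47, `125` = 0.20, `500` = 0.33),
                     read_depth = 5e5, seed = 102)
smp <- make_sample(catalog, spec)

origin <- attribute_sample(smp, origin_probabilities(catalog), catalog)
origin
#> depth_origin 'free_500m': total mass 1, unassigned 0.0000 (0.0%)
#>   top depths (m): 75=0.363 500=0.280 125=0.188 250=0.082 5=0.045

euphotic_fraction(origin)$assigned_only
#> [1] 0.596
```

Most of the sample's attributed coverage points back to the euphotic zone
(0–200 m) even though it was collected at 500 m — the half of the catalog
that is depth-exclusive identifies the mixture, while the shared-profile
genes blur some mass across depths (hence 0.60 recovered from a generating
euphotic weight of 0.67).

```r
model <- flux_model(F_ref = 4000, z_ref = 175, b = 0.86)
stocks <- stock_profile(c(500, 1000), c(0.10, 0.10), layer_m = 100)
flux_supply_ratio(500, model, stocks)
#> [1] 16.2
```

Under these parameters, the daily Martin-curve DNA flux arriving at 500 m is
16.2% of the standing free-DNA stock there — the order of magnitude at which
sinking particles alone start to fall short of the surface-derived DNA
observed at depth.

```r
trace <- normalize_trace(make_electropherogram(
  list(c(9000, 0.07, 0.7), c(450, 0.12, 0.2)), smear_fraction = 0.1))
band_fractions(trace)["lmw_under_1k"]
#> lmw_under_1k
#>        0.237
detect_peaks(trace)
#>    apex_bp  width_bp mass_fraction prominence    class
#> 1  452.106  297.3201     0.2910774  0.2840833 distinct
#> 2 8968.335 3439.4983     0.7089226  1.7336622 distinct
```

The whole pipeline runs from one config: `run_pipeline(demo_config(seed = 42),
"out/")` writes composition tables, binned attributions, flux ratios, size
spectra, Bray-Curtis/PERMANOVA/NMDS results and a JSON run manifest, byte-
identically reproducible under the same seed. A thin command-line wrapper
lives at `inst/scripts/exodna.R`.

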