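# oxifinger

Deterioration-biomarker fingerprints for storage-stability studies of
cold-pressed vegetable oils.

## What it does, and for whom

Cold-pressed oils retain the polyphenols that refining strips away, but
they are oxidatively fragile: polyunsaturated fatty acids (PUFAs) are
consumed as oxidation substrates, antioxidant polyphenols deplete while
protecting the matrix, and volatile aldehydes, furans and allylic alcohols
accumulate as markers of rancidity. Food chemists running storage studies
— concentrations of fatty acids (GC-FID, mg/g), polyphenols (LC-MS/MS,
µg/g) and volatiles (SPME-GC–MS, ppm) tracked over months across oil
types, suppliers and bottle replicates — need a reproducible way to rank
which compounds respond most reliably to storage time.

`oxifinger` provides that pipeline:

1. **Data model & IO** — long-format concentration records with
   below-LOQ censoring flags; CSV interchange; pivot to samples × compounds
   matrices.
2. **Synthetic generator** — storage datasets with the crossed design
   (oil × supplier × bottle × day), first-order substrate/antioxidant
   decay, lagged exponential volatile propagation, two-layer log-normal
   noise and LOQ censoring, for testing and power exploration.
3. **Preprocessing** — Grubbs outlier screen, forward/backward
   imputation, centered log-ratio (CLR) transform of the compositional
   fatty-acid block, z-score scaling, PCA summaries.
4. **Feature selection** — per (oil, class) block: LASSO coefficients of
   storage day on concentrations (α = 0.01, selection at 20% of the max
   |coefficient|), 100-tree random-forest importances (selection at 10% of
   the max), and Spearman ρ per compound.
5. **Composite scoring** — min–max normalization per metric within its
   block and the weighted score

   `score = 0.4 · RFR + 0.4 · |LASSO| + 0.2 · |ρ|`,

   so a compound maximal in all three metrics scores exactly 1.000;
   ranked fingerprint tables with trend arrows (↑ accumulating,
   ↓ depleting).
6. **Kinetics & statistics** — pseudo-first-order propagation fits
   `C(t) = C₀·e^{k(t−t₀)}` by log-linear least squares, percent declines,
   fold changes, one-way ANOVA + Tukey HSD compact letter displays, class
   totals.

See `vignettes/biomarker-pipeline.Rmd` for the model details and design
decisions.

## Worked example

```r
library(oxifinger)

# a full six-oil storage study: 6 oils x 3 suppliers x 3 bottles x 10 days
recs <- generate_storage_dataset(default_oil_profiles(), seed = 2026)
nrow(recs)            # 5760 records
sum(recs$below_loq)   # 398 censored below the class LOQs

# rank deterioration biomarkers for black cumin oil
res <- run_biomarker_pipeline(recs[recs$oil_type == "BC", ],
                              pipeline_config(seed = 2026))
fingerprint_report(res$scores, top_k = 5)
#>   oil_type substance_type substance       weighted_score trend
#> 1 BC       fatty_acid     linoleic acid   1.000          ↓
#> 2 BC       phenolic_acid  quinic acid     0.952          ↓
#> 3 BC       flavonoid      kaempferol      0.823          ↓
#> 4 BC       phenolic_acid  p-coumaric acid 0.713          ↓
#> 5 BC       volatile       nonanal         0.653          ↑
```

Linoleic acid — the dominant PUFA substrate of black cumin oil — tops the
fingerprint with the maximal score 1.000 and a declining trend; depleting
phenolic acids and an accumulating aldehyde follow. Volatile propagation
kinetics for linseed hexanal:

```r
fit <- fit_kinetics_records(recs, "LS", "hexanal", lag_t0 = 14, window = c(14, 42))
fit
#> <kinetic_fit> C(t) = 0.07999 * exp(0.1493 * (t - 14)), R^2 = 1.0000 (3 points, days 14-42)

percent_decline(538.2, 13.2)  # p-coumaric acid over 168 days
#> 97.5
```

The fitted amplitude (~0.08 ppm) and rate constant (~0.15 d⁻¹) recover the
generator's propagation parameters from the noisy records.

A thin command-line wrapper is installed as `exec/oxifinger`
(`oxifinger simulate|score|kinetics|report`).

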