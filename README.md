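# locusq

Quantitative analysis of the transcriptional co-regulation between an
intergenic miRNA cluster (miR-200c/141) and its upstream gene (*PTPN6*),
for molecular biologists and computational genomicists working on
read-through transcription, promoter looping, and regional co-expression
in cancer cohorts.

## What it computes

**Absolute qPCR quantification.** Each primer pair is calibrated by a
standard curve fitted to a same-plate BAC dilution series,
`Ct = b + m log10(q)`, with efficiency `E = 10^(-1/m) - 1`; unknown wells
are inverted with `q = 10^((Ct - b)/m)`. This makes picogram amounts from
different primer pairs comparable, so ratios between transcript entities
along the locus are meaningful:

- **bypass fraction** = intermediate / pri-PTPN6 (fraction of primary
  transcripts reading through the polyadenylation signal),
- **read-through yield** = pri-miR / intermediate,
- **EST ratio** = pri-miR(EST) / pri-miR,
- per-entity fold changes between conditions and cell lines,

plus 2^-ddCt relative expression, mean-centred dCt, Spearman correlation,
and qPCR copy-number genotyping.

**Transcription Correlation Score (TCS).** For position-ordered cohort
expression, `TCS(g) = sum of Spearman rho between g and its 2n genomic
neighbours` (n = 10 per side). Significance comes from a permutation
null: positions are randomized, null TCS pooled, and the empirical
`1 - p` quantile (p = 0.001) used as threshold.

**Copy-number subgrouping.** Samples are amplified / deleted / unchanged
by the +/-0.3 segment-mean rule over a 150-kb locus window, and gene-pair
correlations are compared between all / altered / unchanged subgroups.

**3C profiling.** In-silico NcoI digestion (C^CATGG) of the locus,
BAC-control normalization of junction qPCR (cancels primer bias),
relative interaction frequency over the first 3' fragment from the
anchor, restriction-efficiency QC, and local peak calling for loops.

**MeDIP / ChIP.** Spike-in-calibrated percent methylation
(`(recovery - unmeth) / (meth - unmeth)`), percent-of-input with dilution
correction, H3 normalization, and cross-region methylation correlation.

A synthetic-data generator emulates the qPCR measurement model
(log-linear Ct response, per-assay efficiency, cycle noise, censoring at
40 cycles) and the cohort/3C/enrichment structure, so the entire pipeline
is testable without any external data.

## Worked example

Simulate noisy plates for the stressed condition, quantify, and derive
the read-through ratios:

```r
library(locusq)
plates <- make_locus_plates("SKOV3_H2O2", locus_noise_model(ct_sd = 0.2),
                            seed = 42)
q <- quantify_locus(plates)
q
#> Locus quantities [SKOV3_H2O2] (pg per reaction):
#>   pri_PTPN6    0.2514 (sem 0.0063, n=6)
#>   PTPN6_dpA    0.1371 (sem 0.0053, n=6)
#>   intermediate 0.1329 (sem 0.0044, n=6)
#>   pri_miR      0.1284 (sem 0.0028, n=6)
#>   pri_miR_EST  1.689 (sem 0.057, n=6)

readthrough_summary(q)
#>            quantity  value     se
#> 1   bypass_fraction  0.529 0.0219
#> 2 readthrough_yield  0.966 0.0383
#> 3         est_ratio 13.157 0.5262
```

With 0.2 cycles of Ct noise over 3 technical x 6 biological replicates,
the recovered bypass fraction (0.53 +/- 0.02) sits at the true 0.56 of
this condition: only about half of the pri-PTPN6 molecules read through
the polyadenylation signal under stress, and essentially all of the
intermediate reaches the miRNA unit (yield ~ 1). Against the untreated
condition, `stress_fold_changes()` shows the fivefold induction of
pri-PTPN6 initiation against a ~2.8-fold induction of the intermediate:

```r
nt <- quantify_locus(make_locus_plates("SKOV3_NT",
                                       locus_noise_model(ct_sd = 0.2),
                                       seed = 41))
stress_fold_changes(nt, q)
#>         entity fold log2_fold
#> 1    pri_PTPN6 4.98      2.32
#> 2    PTPN6_dpA 2.72      1.44
#> 3 intermediate 2.82      1.50
#> 4      pri_miR 2.94      1.55
#> 5  pri_miR_EST 2.76      1.47
```

With `ct_sd = 0` every ratio is recovered exactly (bypass 1 / 0.56 / 1
for the three condition presets, yield 1, EST fold 2.4 between IGROV-1
and stressed SKOV3).

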