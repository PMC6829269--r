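# tcelsig — T cell infiltration scoring from restricted gene signatures

Bulk transcriptomes of tissues and tumors contain the mRNA of every cell in
the specimen, so the signal of genes expressed *only* by T cells reads out
the T-cell content of the sample without deconvolution software. `tcelsig`
is for computational immunologists and oncology bioinformaticians who want
that readout end to end:

* **Signature selection** — a six-round fold-change filtering procedure
  that reduces a candidate gene list to a T-cell-restricted signature using
  grouped expression of purified T cells, non-T immune subsets, healthy
  tissues and cell lines. Round 1 demands ≥ 3.32 log2 (ten-fold)
  over-expression versus every immune subset; round 2 the same versus
  tissues; round 3 keeps genes whose across-tissue range lies in 2.5–8.5
  log2; rounds 4–5 exclude genes whose tissue-wise deviation
  `nl/Tc(g,t) − M_nl/Tc(t)` exceeds 3.32 log2 (two passes, cohort profile
  recomputed between them); round 6 removes genes over-expressed by cell
  lines from ≥ 2 parenchymal sources or by immune-derived lines. The
  published 15-gene signature produced by this procedure (CD2, CD247, CD28,
  CD3D, CD3G, CD6, GPR171, GZMK, ICOS, ITK, KLRB1, PYHIN1, TIGIT, TRAT1,
  TRBC1) ships as `signature_h()`.
* **Infiltration scores** — Ts% (`100·2^mean_g[x(g,s) − t_ref(g)]`,
  purified T cells ≡ 100), Tav (mean signature log2 expression,
  platform-tagged) and Ts-l2 (mean log2 difference to matched healthy
  tissue, ±0.32 ≙ 80–125%), plus band classification, per-specimen
  `mean + 1 SD` infiltration calls, platform adaptation of signatures and
  quartile concordance between rankings.
* **Prognosis** — Tav binning (default edges 0.125, 0.5, 2 with strict
  outer bins), Kaplan–Meier curves, the log-rank Mantel–Cox test and
  hazard ratios by the log-rank method `HR = (O_A/E_A)/(O_B/E_B)`.
* **Response prediction** — the three-parameter checkpoint rule for
  anti-PD-1 response: PD-L1/PD-1 (and PD-L2/PD-1 for signature-1) strictly
  within (0.5, 10), Tav-RNAseq > 1, PD-1/Tav-RNAseq > 0.5; overall response
  rates and contingency chi-square.
* **Synthetic corpora** — generators for selection corpora (linear-scale
  T-cell/parenchyma mixtures with per-round confounder classes), survival
  cohorts with bin-dependent hazards, and checkpoint-profile cohorts, so
  the whole pipeline is testable offline.

## Worked example

```r
library(tcelsig)

co  <- generate_corpus(corpus_spec(seed = 7))      # 60 genes, 96 arrays
rep <- run_selection(co$matrix, co$annotation, rownames(co$matrix))
rep
#> Six-round T-cell-restricted gene selection
#>   candidates: 60   survivors: 10
#>   excluded per round: r1=10 r2=10 r3=10 r4=10 r5=0 r6=10
```

The ten planted T-restricted genes survive; each confounder class dies at
the round designed to catch it. Scoring tissues against the purified-T-cell
reference:

```r
gm <- group_means(co$matrix, co$annotation)
cols <- with(co$annotation, sample_id[group %in% c("brain", "colon")])[c(1:3, 7:9)]
score_infiltration(co$matrix[, cols], co$planted, gm$t_ref)
#> T-cell infiltration scores (6 samples, Tav-array)
#>  sample_id ts_percent   tav          band
#>  brain_s01     0.6918 2.851 extremely_low
#>  brain_s02     0.6421 2.744 extremely_low
#>  brain_s03     0.6632 2.790 extremely_low
#>  colon_s01     5.6963 5.893      moderate
#>  colon_s02     5.7398 5.904      moderate
#>  colon_s03     5.8411 5.929      moderate
```

Brain (simulated T-cell fraction 0.006) scores Ts% ≈ 0.7 — under 1% of the
purified-T-cell signal — while colon (fraction 0.06) scores ≈ 5.7;
bands are relative to the healthy-tissue reference Ts% of 3. Survival
stratification by Tav bin on a simulated cohort whose hazard decreases
with infiltration:

```r
d <- generate_survival_cohort(n_per_bin = c(120, 80, 80, 120),
                              hazards = c(3, 2, 1.5, 1) / 1000, seed = 7)
stratify_survival_by_tav(d)
#> Log-rank (Mantel-Cox) test: chi2 = 76.91 on 3 df, p = 1.409e-16
#> Log-rank hazard ratio (<0.125 vs >2): HR = 2.92 (95% CI 2.15-3.96)
```

Patients in the lowest-infiltration bin die at about three times the rate
of the highest bin, as designed. Checkpoint response on a synthetic
anti-PD-1 cohort:

```r
predict_response(generate_melanoma_cohort(n = 200, seed = 7))
#> Checkpoint response prediction (signature3)
#>   ORR: good 83.0% (n=100), bad 24.0% (n=100)
#>   contingency chi-square = 70, p = 6.04e-17
#>   death HR (bad vs good) = 2.38 (95% CI 1.72-3.3)
```

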