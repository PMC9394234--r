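# clonefish

Single-cell interphase-FISH clonality analysis for high-hyperdiploid
B-cell acute lymphoblastic leukemia (HHD-B-ALL).

High hyperdiploidy — a modal chromosome number above 50 with non-random
gains of chromosomes X, 4, 6, 10, 14, 17, 18 and 21 — is the most common
cytogenetic subgroup of childhood B-ALL. Most patients do well, yet a
minority relapse even after reaching MRD negativity, and conventional
karyotyping badly under-reports the clonal structure of these leukemias.
Sequential interphase FISH (seq-iFISH) counts all eight typically gained
chromosomes in the same nucleus over successive hybridization rounds,
turning each sample into hundreds of per-cell integer copy-number
profiles. `clonefish` implements the complete single-cell computational
pipeline over such data, for hematology groups running FISH panels and for
methodologists studying clonal heterogeneity as a biomarker:

* **Subclone encoding** — each informative nucleus becomes an 8-digit gain
  vector relative to the constitutional baseline (panel order X, 4, 6, 10,
  14, 17, 18, 21), e.g. `"10001002"` = +X, +14, +21, +21.
* **Karyotype parsing** — a restricted-ISCN parser turns clinical karyotype
  strings into panel gain vectors for concordance checks against the
  single-cell major clone.
* **Noise calibration** — per-chromosome false gain/loss rates from diploid
  controls; positivity cutoffs from the exact binomial tail, the minimal
  k\* with Pr[Bin(n, p̂) ≥ k\*] < α.
* **Clonal heterogeneity** — subclone tabulation, percentage of major clone
  (PMC) and Shannon entropy H = −Σ Pᵢ log₂ Pᵢ (bits); per-chromosome gain
  rates with trisomy/tetrasomy split; combined-trisomy fractions.
* **Gain hierarchy** — complete-linkage Euclidean clustering of
  chromosomes and of clone-frequency matrices (row z-scores), with an
  acquisition-order reading of the dendrogram.
* **Risk predictor** — random-forest Gini importance under leave-one-out
  CV, exhaustive fitting of two-threshold pair rules, the two-step
  chr18 → chr10 rule (unfavorable iff %+18 ≤ 40, else iff %+10 ≤ 40), and a
  uniform-noise injection stress test.
* **Survival** — Kaplan–Meier / log-rank relapse-free survival, Cox models
  (Efron ties, age per 5 years, protocol with PETHEMA reference), and
  maximally selected rank statistics for PMC dichotomization.
* **Clonal evolution** — matched diagnosis–relapse pairing and shared-clone
  vs clonal-replacement classification (top-k overlap rule).
* **Synthetic cohorts** — a generator with ordered gain acquisition,
  chromosomal-instability perturbations, Dirichlet clone frequencies,
  exact planted trisomy rates, FISH noise at control bounds, normal-cell
  admixture and a two-group exponential survival model, with a full
  ground-truth ledger for recovery tests.

## Worked example

Karyotype vs single-cell major clone, and the risk rule:

```r
library(clonefish)

# a printed discovery-cohort karyotype; the implied panel gains
parse_karyotype("55,XXY,+3,+4,+6,+10,+14,+18,+21,+21/46,XY", sex = "M")
#> KaryotypeGains: 11111012

# concordance over the 22 printed discovery cases
conc <- karyotype_concordance(discovery_cohort())
conc$n_concordant; conc$n_total
#> [1] 7
#> [1] 22          # 32%: karyotyping usually misses the single-cell major clone

# positivity cutoff at the control calibration point
binomial_cutoff(0.0037, 200, 0.05)
#> $k
#> [1] 3
#> $cutoff
#> [1] 0.015       # >= 3 of 200 nuclei (1.5%) needed to call an aberration real

# clonal heterogeneity of a toy sample
d <- tabulate_clones(rep(c("10001002", "11111111", "00000001"), c(61, 30, 9)))
d$pmc; d$entropy
#> [1] 61
#> [1] 1.268746    # bits

# the two-step risk rule
chr18_chr10_rule(c("18" = 30, "10" = 90))
#> RiskCall: unfavorable - chr18 gain % at or below threshold (step 1)
```

End-to-end on a synthetic cohort (33 favorable / 17 unfavorable patients,
500 nuclei each, planted hazard ratio 11):

```r
coh <- generate_cohort(cohort_spec(), seed = 7)
fl  <- filter_cells(coh$cells[[1]], sex = coh$clinical$sex[1])
gr  <- gain_rates(fl$blasts)
chr18_chr10_rule(gr)$label
#> [1] "favorable"
```

The numbered drivers under `analysis/` run the whole study flow and write
tables under `results/`: `01` karyotype concordance, `02` control
calibration, `03` cohort clonality statistics, `04` gain hierarchy, `05`
risk-predictor construction and stress tests, `06` survival models, `07`
diagnosis–relapse clonal evolution. Each prints a short narrative of what
it found, e.g. `analysis/05_risk_predictor.R` on the default seed reports
the chr18→chr10 rule at 98% overall accuracy with misclassification
rising from 1.0 to 13.7 patients as injected noise grows from 0 to 30%.

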