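# nicheDSS

Computational readout for **niche-like ex vivo drug sensitivity screens of
primary acute myeloid leukemia (AML)**. In this assay design, patient
mononuclear cells are co-cultured on GFP-tagged mesenchymal stromal cells
(MSCs) under hypoxia, exposed to drugs in 96-well plates (50,000 cells per
well, DMSO 0.1% vehicle controls), and read out by multiparameter flow
cytometry. The panel enumerates, per well, viable CD3/CD19+ lymphocytes and
the leukemic bulk, and partitions the bulk into a GPR56+/Diff− leukemic
stem cell (LSC)-enriched state, a CD11b/CD14/CD15+ (Diff+) differentiating
state, and the basal GPR56−/Diff− blast state. `nicheDSS` implements the
full analysis chain behind such a screen, plus a synthetic event-level data
generator with known ground truth so every stage is testable without any
instrument data.

## What it computes

* **Automated hierarchical gating** — viability → GFP+ MSC exclusion →
  lymphocyte/bulk split → GPR56 × Diff quadrants. Thresholds are estimated
  per plate from vehicle wells by a deterministic two-component Gaussian
  mixture fit per channel, cut at the equal-posterior point, with full
  manual-override support (`estimateThresholds()`, `gateWell()`).
* **Vehicle normalization** — per-well counts divided by the same-sample
  DMSO vehicle mean; within-bulk state proportions from raw counts
  (`normalizePlate()`, `summarizeReplicates()`).
* **Drug activity scoring** — the untruncated trapezoidal
  **area over the curve (AOC)** of normalized counts, with no
  dose-response model fitted. With doses mapped to log10 scale and rescaled
  to the unit interval, and v(x) the normalized count,

  AOC = ∫₀¹ (1 − v(x)) dx   (piecewise-linear, no clipping)

  so AOC ∈ [0, 1] when v stays in [0, 1], AOC = 0 for an inactive drug,
  1 for complete kill, and AOC < 0 signals outgrowth (`computeAOC()`).
  Fixed-ratio dilution series (e.g. daunorubicin–cytarabine 1:20, 5-point,
  10-fold) and PK/toxicity-bounded screening concentrations
  (min(Cmax, IC₄₀) for maximal testing; min(0.2·Cmax, IC₁₀) for low-dose
  third agents, both IC values interpolated from healthy-CD34 profiles) are
  built by `fixedRatioSeries()` and `selectScreenConcentration()`.
* **Response-pattern classification** — per-readout scaling with the
  assay's sign conventions (higher = fewer bulk cells, lower %LSC, higher
  %DIFF) and Ward/Euclidean clustering into cytotoxic, stemness-specific
  and differentiating archetypes (`scaleReadouts()`, `clusterPatterns()`).
* **Decision statistics** — lymphocyte-referenced chemosensitivity calls
  (sensitive ⇔ AOC(population) > AOC(lymphocytes)); per-patient optimal
  third-agent nomination; population-level triplet-minus-backbone benefit
  (one-sample t tests with Benjamini–Hochberg FDR); exact Fisher 2×2 and
  Mann–Whitney kernels; chemogenomic association scans
  (`sensitivityCall()`, `nominateOptimal()`, `combinationBenefit()`,
  `fisherExact2x2()`, `mannWhitney()`, `bhFDR()`, `chemogenomicScan()`).
* **Synthetic plates with ground truth** — wells seeded with stroma,
  lymphocytes and the three leukemic states; per-drug Hill survival and
  differentiation-induction models; technical replicate noise; one seed,
  fully reproducible (`GroundTruth()`, `simulatePlate()`).

## Worked example

Simulate one patient plate screened with a cytotoxic two-drug backbone at a
fixed 1:20 ratio (5-point, 10-fold dilution), gate it, normalize to
vehicle, and score activity per population:

```r
library(nicheDSS)

gt <- GroundTruth(drugs = list(
  DNR = drugModel(kill = list(basal = c(E = 0.95, ec50 = 0.05, h = 1.2),
                              DIFF  = c(E = 0.95, ec50 = 0.05, h = 1.2),
                              LSC   = c(E = 0.60, ec50 = 0.10, h = 1.2),
                              lymph = c(E = 0.30, ec50 = 0.20, h = 1.2))),
  AraC = drugModel(kill = list(basal = c(E = 0.6, ec50 = 1.0, h = 1.0),
                               DIFF  = c(E = 0.6, ec50 = 1.0, h = 1.0)))),
  acquiredFraction = 0.1)

ser <- fixedRatioSeries(base = 0.5, ratio = 20, nPoints = 5, fold = 10)
trts <- apply(ser, 1, function(r)
  formatTreatment(c("DNR", "AraC"), c(r[["conc1"]], r[["conc2"]])))

sim <- simulatePlate(plateConfig(gt, defaultPanel(), treatments = trts,
                                 nVehicle = 3L, nReplicates = 3L), seed = 1)

veh    <- sim$layout$well[sim$layout$role == "vehicle"]
th     <- estimateThresholds(sim$events[veh], sim$panel)
counts <- gatePlate(sim$events, th)
norm   <- normalizePlate(counts, sim$layout)

norm$conc <- vapply(norm$treatment, function(t)
  if (nzchar(t)) parseTreatment(t)$conc[1] else NA_real_, numeric(1))
trt <- norm[norm$role == "treated", ]
aocBulk  <- aocByGroup(transform(trt, value = bulk_ratio),
                       concCol = "conc", by = "sample")$aoc
aocLSC   <- aocByGroup(transform(trt, value = lsc_ratio),
                       concCol = "conc", by = "sample")$aoc
aocLymph <- aocByGroup(transform(trt, value = lymph_ratio),
                       concCol = "conc", by = "sample")$aoc
cat(sprintf("AOC bulk %.3f | LSC %.3f | lymphocytes %.3f\n",
            aocBulk, aocLSC, aocLymph))
sensitivityCall(aocLSC, aocLymph, patient = "S1", population = "LSC")
```

```
AOC bulk 0.261 | LSC 0.082 | lymphocytes -0.040
  patient population    aoc_pop   aoc_lymph      call
1      S1        LSC 0.08152645 -0.04015919 sensitive
```

The backbone kills the leukemic bulk far more than the LSC compartment
(AOC 0.261 vs 0.082) — the "relative sparing of LSCs" signature of a
cytotoxic pattern — while lymphocytes are essentially untouched (a small
negative AOC is sampling noise around zero). Because activity on LSCs still
exceeds activity on the patient's own lymphocytes, the LSC compartment is
called chemosensitive.

The one desk-reproducible cohort statistic — complete remission (9/9 among
patients with chemosensitive blasts vs 20/29 among chemoresistant) — is a
plain 2×2 exact test:

```r
fisherExact2x2(matrix(c(9, 0, 20, 9), 2, byrow = TRUE))
#>           test statistic         p  n
#> 1 fisher-exact         9 0.0817699 38
```

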