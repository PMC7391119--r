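# p65trans

Quantifying the speed of NF-κB activation in peripheral blood mononuclear
cells (PBMCs) and relating it to late radiation-induced skin and
subcutaneous fibrosis.

## The problem

Late fibrosis after radiotherapy varies widely between patients given the
same treatment, and no practical pre-treatment biomarker exists. One
candidate is how quickly NF-κB responds to radiation in a patient's blood
cells: on activation the p65 (RelA) subunit translocates from cytoplasm to
nucleus, so nuclear p65 accumulation after a 2-Gy ex vivo dose is a
per-patient radiosensitivity readout. This package implements the complete
quantification and analysis chain for that readout, for two assays:

* **Western-blot densitometry.** Nuclear-fraction band gray values are
  normalized per patient to the histone H3 loading control: each lane's H3
  is divided by the maximum H3 across that patient's lanes (so one lane
  gets normalized H3 = 1), and the p65 band is divided by its lane's
  normalized H3. The *activation ratio*
  `R = adjusted_p65(1 h) / adjusted_p65(0 h)` summarizes activation speed;
  the 1-h assay point is chosen by a peak finder over a sampled time
  course, and LAMP1/H3 sentinel bands provide fraction-purity QC.
* **Immunofluorescence imaging.** Two-channel fields (DAPI + p65-FITC) are
  processed per cell: nuclei segmented from DAPI (Gaussian smoothing, Otsu
  threshold, hole filling, distance-transform watershed, area gate), the
  nuclear mask eroded to avoid cytoplasmic contamination, a cytoplasmic
  ring built by dilating each nucleus and removing all nuclear pixels —
  constrained to the cell's Voronoi territory and the p65 foreground — and
  the per-cell ratio computed as
  `median nuclear intensity / median ring intensity`. A patient's value is
  the median over all retained cells.

The association stage dichotomizes RTOG/EORTC fibrosis at grade ≥ 2 and
compares the activation ratio between strata with the Wilcoxon rank-sum
test (exact when group sizes are < 50 without ties) and a linear model
adjusted for age, sex, smoking, alcohol, TNM stage, chemotherapy and
surgery, plus per-covariate χ²/Fisher tests and an unadjusted subgroup
table.

No patient data are distributed; a first-class synthetic module generates
cohorts, fields with ground-truth masks, and densitometry tables with the
calibrated statistical structure (grade frequencies 26/41.5/23.5/8.5/0.5 %,
WB ratio medians 2.04 / 2.51, image ratio medians 0.80 / 0.92, follow-up
median 3.2 y), so every stage is testable end to end.

## Worked example

```r
library(p65trans)

# choose the assay time point from a simulated densitometry time course
tc  <- simulate_timecourse(kinetics_config(grid = seq(0, 2, 0.5), seed = 1))
find_peak_time(normalize_h3(tc))$peak_time_h
#> [1] 1

# quantify a synthetic field end to end
f   <- simulate_field(field_config(seed = 3))
rec <- quantify_field(f)
patient_image_summary(rec)
#>   patient_ratio n_cells           qc_flags
#> 1     0.9208786      14 insufficient_cells

# cohort-level association
co  <- simulate_cohort(cohort_config(seed = 1))
grp <- dichotomize_fibrosis(co)
adjusted_comparison(co, grp, biomarker = "wb_ratio")
#> Group comparison of wb_ratio (late fibrosis < 2 vs >= 2)
#>  stratum   n   median      q25      q75      min      max
#>      low 140 2.169183 1.787972 2.435523 1.181785 3.554467
#>     high  60 2.563956 2.239396 2.951864 1.479907 3.437830
#> crude P (Wilcoxon) = 4.106e-07, adjusted P = 1.59e-06 (beta = 0.385, SE = 0.078)
#> adjusted for: age, sex, smoking, alcohol, stage_group, chemo, surgery; 2 record(s) excluded for missing covariates
```

The peak call says nuclear p65 is maximal 1 h after the 2-Gy dose on the
half-hour grid, which fixes the post-irradiation assay point. The field
summary is that patient's median per-cell nuclear:cytoplasmic ratio over
the retained cells; with only one field the 14 cells fall short of the
20-cell QC threshold, hence the `insufficient_cells` flag (patients pool
several fields). The comparison shows the high-fibrosis stratum's
activation ratio sitting about 0.39 above the low stratum, significant both
crudely and after covariate adjustment (this simulated cohort has the
stratum difference built in).

The numbered drivers under `analysis/` run the same stages as a narrative
workflow (`Rscript analysis/01_simulate_cohort.R 1`, ...), writing their
tables under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline from scratch at the given seed — cohort
simulation, kinetics and peak-time selection, the scaled image
quantification stage, and the association analysis — printing the headline
quantities it computes and writing the results JSON to `--out`.
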