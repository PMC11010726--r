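# fgsquant

Quantitative image analysis for comparing fluorescent contrast agents in
fluorescence-guided surgery (FGS) of brain tumors.

When a new activatable near-infrared (NIR) probe is weighed against the
clinical standard 5-ALA/protoporphyrin IX (PPIX), the figure of merit is the
**tumor-to-normal ratio**

TNR = mean fluorescence over the tumor ROI / mean fluorescence over
normal-brain tissue,

measured on coronal sections with the contralateral hemisphere as the
normal-tissue reference. `fgsquant` implements the full desk-side
measurement chain for both agent classes, plus the statistics used to
compare them, plus a synthetic phantom generator with known ground truth so
that every stage is testable without animal or patient data:

* **Phantoms** — `generate_section()` / `generate_cohort()` render
  co-registered nuclear, NIR and RGB channels of a two-hemisphere section
  with an elliptical tumor of known NIR contrast ρ;
  `generate_homogenates()` and `generate_exvivo()` emulate paired
  homogenate readings and ex-vivo fragment activation time courses
  (2/5/10/120 min with a reference-tissue group).
* **Segmentation** — `segment_tumor()` builds the tumor mask from the
  nuclear-dye channel (automatic two-class threshold, cleanup by
  morphological reconstruction, largest component); `mirror_roi()` reflects
  it across the hemispheric midline into the contralateral normal ROI;
  `transfer_mask()` moves masks between co-registered channels.
* **Quantification** — `compute_tnr()`, `normalize_to_normal()`,
  `section_cv()`, `homogenate_tnr()` (weight-normalized), `mfi_ratio()`,
  `normalize_exvivo()`, `fold_difference()`.
* **Color projection for PPIX** — `optimal_projection()` fits the unit RGB
  vector v maximizing |v·m_tumor − v·m_normal| between median region colors
  (closed form: the normalized median difference), `mean_projection()`
  averages per-sample vectors, `project_to_gray()` converts RGB images by
  scalar product, `ppix_tnr()` quantifies the result.
* **Statistics** — `mann_whitney()`, `wilcoxon_signed_rank()`, `paired_t()`
  with explicit exact/approximate switching and enumeration-exact
  small-sample p-values; `compare_agents()` pairs animals across agents.
* **Pipeline** — `run_pipeline(pipeline_config(...))` chains everything
  deterministically from one seed and writes schema-stable CSV/YAML
  outputs. A thin CLI lives in `inst/cli/fgsquant.R`.

## Worked example

```r
library(fgsquant)

spec <- phantom_spec(nir_contrast = 30)   # true tumor:normal NIR ratio 30
sec  <- generate_section(spec, seed = 1)

tumor  <- segment_tumor(sec)              # mask from the nuclear channel
normal <- mirror_roi(tumor, sec$midline_col)
compute_tnr(sec$nir, tumor, normal, section_id = "s1",
            animal_id = "m1", agent = "NIR")
#> TNR = 30.01  (tumor 30 AU over 2253 px; normal 0.9998 AU over 2253 px)  [m1 / s1 / NIR]

optimal_projection(median_color(sec$rgb, tumor),
                   median_color(sec$rgb, normal))
#> <projection_vector> (R, G, B) = (0.9396, 0.0603, -0.3369)

res <- run_pipeline(pipeline_config(n_animals = 6, sections_per_animal = 3,
                                    seed = 1))
res
#> FGS quantification pipeline result
#>   18 sections, 6 animals
#>   NIR   TNR: mean 32.9, sd 18.6 (n = 6 animals)
#>   PPIX  TNR: mean 80.2, sd 0.97 (n = 6 animals)
#>   per-animal section CV (NIR): median 0.000989, max 0.00164
#>   Wilcoxon signed-rank test: W = 0, two-sided p = 0.03125 (n = 6; exact)
```

Reading the output: the single-section TNR of 30.01 recovers the phantom's
true contrast ρ = 30 to within the noise floor; the fitted projection
vector points from the blue background toward the red-pink PPIX tumor color
(dominant red weight, negative blue weight); the cohort run reports
per-animal TNRs for both agents (the cohort draws each animal's true ρ from
a lognormal with CV 0.55, hence the spread), between-section CVs far below
the 0.15 consistency bound, and an exact paired Wilcoxon comparing the
agents across the six animals.

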