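---
title: "Methods: ensemble SDMs, shift metrics and community change in seashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SDMs, shift metrics and community change in seashift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

seashift projects where benthic species can live today and under warming
scenarios, and aggregates single-species projections into community-level
change maps. This vignette is the package's account of the science: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the package's tests and acceptance script do not themselves
compute.

## The modelling problem

Inputs are presence-only occurrence records and gridded near-bottom
environmental predictors (temperature, oxygen, chlorophyll, salinity,
current speed, sediment fraction), each summarised per cell as temporal
statistics (median, min, max, range). Because true absences are
unobservable in opportunistic archives, the pipeline models habitat
suitability $P(y = 1 \mid x)$ against pseudo-absences, projects suitability
under scenario-forced predictors, and summarises the projected ranges.

The processing chain is:

1. **Predictor preparation** — temporal aggregation of monthly series;
   optional control-run detrending of climate simulations (per cell, the
   OLS trend of the control run is subtracted from the scenario series,
   anchored at the series start); scenario anomalies as *relative* changes
   (future/present ratio) applied *multiplicatively* to the baseline
   climatology. Additive anomalies are deliberately not implemented.
2. **Predictor selection** — hierarchical clustering on the dissimilarity
   $1 - |\rho_S|$ (Spearman), tree cut at $1 - 0.7 = 0.3$; one
   representative per cluster (a caller-supplied priority list stands in
   for expert ecological judgement), then stepwise VIF pruning
   ($\mathrm{VIF}_j = 1/(1 - R_j^2)$, drop the worst until all below 10).
3. **Occurrence preparation** — thinning to one record per grid cell
   (half-open cell intervals, origin at the grid's upper-left, 0-based
   indexing convention documented in `thin_to_grid()`), then a
   minimum-prevalence filter: species occupying fewer than 120 cells are
   excluded (boundary inclusive).
4. **Pseudo-absences** — per replicate, half *target-group
   density-dependent* (sampled from a Gaussian-kernel smoothing of pooled
   target-group occurrences, truncated at the mask and normalised — this
   reproduces the survey-effort distribution and cancels coastal sampling
   bias) and half *environmentally stratified* (median temperature and
   salinity binned at their 0.3/0.6 quantiles into a 3 × 3 grid of strata,
   equal quotas per stratum). Defaults: 10,000 points per replicate, split
   half and half, three replicates. Pseudo-absences never coincide with a
   focal presence cell.
5. **Ensemble fitting** — four learners at intermediate complexity
   (logistic GLM with linear + quadratic terms; binomial GAM with smooth
   basis complexity 3; random forest with 1000 trees, terminal nodes of at
   least 40, 2 candidate predictors per split; feed-forward neural network
   with weight decay 0.1), each fitted over a spatially blocked
   5-fold × 3-repetition × 3-replicate design: 180 attempted members per
   species. Case weights equalise the weighted prevalence of presences and
   pseudo-absences. Members are scored with AUC and TSS on calibration,
   validation and spatially held-out evaluation data; the committee keeps
   members with evaluation AUC > 0.7 and averages them without weights;
   the species is dropped as unmodellable when the committee's evaluation
   AUC is not above 0.75. The continuous Boyce index (100 moving windows
   of width one tenth of the suitability range; Spearman correlation of
   P/E against window midpoint) provides a presence-only check.
6. **Projection** — committee suitability under baseline and scenario
   stacks; binarization at the threshold maximising TSS on baseline
   evaluation data, fixed per species and reused for all scenarios; a
   depth-window crop (cells outside $[0.7\,p_5,\ 1.3\,p_{95}]$ of baseline
   occurrence depths removed); MESS maps flag extrapolation diagnostically
   without zeroing projections.
7. **Species metrics** — RANGE (summed cell area), LAT (area-weighted
   latitudinal centroid), DEPTH (area-weighted mean depth), FRAG (mean
   edge-to-edge shortest sea-path distance between clumps), their changes
   ($\Delta$RANGE as a percentage, the others absolute; an empty future
   range is an extinction, $\Delta$RANGE $= -100$), ecological indicator
   values (per-species medians of baseline conditions at occurrence
   cells), and a Spearman screen of EIVs against the changes.
8. **Community metrics** — stacked continuous suitability as per-cell
   $\alpha$; temporal $\beta$ on thresholded ranges with the
   Podani-family decomposition
   $\beta_{tot} = (b + c)/(a + b + c)$,
   $\beta_{tu} = 2\min(b, c)/(a + b + c)$,
   $\beta_{ne} = |b - c|/(a + b + c)$ (so
   $\beta_{tu} + \beta_{ne} = \beta_{tot}$ exactly), and
   $\beta_{ratio} = \beta_{ne}/\beta_{tot}$.
9. **Hotspots** — self-inclusive Getis–Ord $G_i^*$ z-scores over the 24
   nearest non-missing cells, two-sided significance at $p < 0.001$ per
   tail ($z^* \approx 3.29$); $\Delta\alpha$ hotspots take precedence,
   stability spots are low-$|\Delta\alpha|$ cells among the rest, and
   turnover hotspots (high $\beta_{tu}$) form an independent overlay.
   $\beta_{ne}$ is excluded from the hotspot set because it is highly
   correlated with $|\Delta\alpha|$.

## The synthetic world and what it does (not) emulate

`generate_world()` builds a planar grid with equal-area cells: land blobs
from thresholded smoothed noise, depth increasing away from land (up to
800 m — deeper cells are excluded everywhere, matching the modelled depth
window), and spatially autocorrelated predictor fields with the
qualitative structure of a mid-latitude basin: temperature decreasing
northward and with depth, oxygen anti-correlated with temperature
(Spearman $\rho \approx -0.6$), a nearly collinear `T_min` (exercising the
correlation-clustering stage), coastal chlorophyll, a west–east salinity
gradient, and uninformative current-speed and sediment layers.

Virtual species have analytic niches — a Gaussian response to median
temperature whose product with (flat) responses on the other predictors
gives a true suitability surface — so the true occupied range, centroid
and depth under any forcing are computable exactly by thresholding at 0.5.
Sampling emulates presence-only archives: presences drawn without
replacement with probability proportional to suitability times an
exponential coastal-effort decay (e-folding 5 km).

Scenario anomalies are multiplicative temperature factors > 1, stronger in
the south (so isotherms migrate north), with mild deoxygenation; other
predictors are left unchanged. Under such forcing, cold-adapted species
(optimum below the domain median temperature) must truly shift north —
asserted on the analytic truth, independent of any model.

What this does **not** emulate: real bathymetry or basin geometry, ocean
dynamics, temporally varying sampling effort, taxonomic error,
species interactions, or dispersal limits. Passing recovery tests on this
world therefore demonstrates that the *pipeline* recovers a known signal
through realistic presence-only noise and spatial bias — not that any real
community behaves like the simulation.

### Study conditions of the bundled recovery study

The recovery study (`run_pipeline(shift_config())`) uses a 60 × 100 world
and six species: three cold-adapted (thermal optima 14.9, 16.1, 17.3 °C,
all safely below the domain median temperature of ~18.5–19.5 °C across
seeds) and three warm-adapted (20.3, 21.3, 22.3 °C, safely above it), with
niche breadth (Gaussian sd) 0.5 °C. The breadth and the ~1–1.2 °C optimum
spacing are deliberate: bands are narrow relative to the ~13.5 °C domain
range (strong-niched, recoverable species), adjacent bands barely overlap,
and the far-window warming signal (~1.5 °C at mid-domain) exceeds one band
width — so warming *constructs* a clean pattern of northern gains,
southern losses and contiguous mid-latitude replacement bands whose
existence is verifiable on the analytic truth alone. The basin narrows
northward (land is likelier at high latitude), so poleward-shifting cold
niches genuinely lose area where the construction truncates them.
Each species gets 220 occurrence cells under coastal bias; the scenario is
the RCP8.5-like far window. Because the domain holds only ~5,000 sea
cells, pseudo-absences are scaled to 1,000 per replicate (500 + 500; three
replicates): the default 10,000 cannot be drawn without replacement from
so small a grid, and prevalence-balancing case weights make the absolute
count immaterial to the fit. These conditions are fixed in
`shift_config()` and echoed into every run manifest.

Recovery of the turnover band is scored against the band's *core*
(`turnover_core()`: true-turnover cells whose 5 × 5 window is ≥ 18/25
true-turnover cells). A 24-neighbour cluster statistic cannot flag a
band's one-cell edge fringe — its neighbourhood mean is diluted by
adjacent non-turnover cells — so the core is the part of the construction
the method can, and should, recover.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `r_threshold` | 0.7 | \|Spearman ρ\| | cluster cut for predictor redundancy |
| `vif_threshold` | 10 | — | conventional multicollinearity bound |
| `n_min_cells` | 120 | cells | minimum occupied cells for a modellable species (inclusive) |
| `pa_total`, `pa_split`, `pa_reps` | 10000, 0.5, 3 | points | pseudo-absence design (package default; 1000 in the synthetic study, see above) |
| `n_folds`, `n_repeats` | 5, 3 | — | block-wise cross-validation design |
| `eval_prop` | 0.2 | share | spatial-block evaluation hold-out |
| `auc_min` | 0.7 | AUC | member retention, strict inequality |
| `auc_ensemble_min` | 0.75 | AUC | species usability, strict inequality |
| `k_neighbors` | 24 | cells | Gi* neighbourhood |
| `alpha_level` | 0.001 | per tail | hotspot significance |
| kernel bandwidth | Silverman rule | cells | effort-kernel smoothing (no principled value exists for arbitrary grids) |

## Numerical and design choices

* **Neural-network topology.** The model family's standard R implementation
  (`nnet`) supports a single hidden layer; the package uses 8 hidden units
  with decay 0.1. A multi-hidden-layer reading of "three hidden layers"
  exists but conflicts with the toolchain this model family is fitted with
  in practice; the single-layer choice is recorded here deliberately.
* **Random forest.** A regression forest on the 0/1 response (predictions
  are means of leaf means, hence in [0, 1]); identical tree complexity
  settings, substantially cheaper than probability forests.
* **Ensemble combination.** Unweighted mean of retained members — the
  simplest defensible committee; AUC-weighted averaging is not used.
* **Folds and blocks.** k-medoid (PAM) blocks on cell coordinates;
  whole blocks are allocated to the ~20% evaluation hold-out, and the
  5 CV folds are re-drawn from training blocks for each repetition, so
  evaluation cells never touch calibration or validation.
* **Tie-breaks.** Largest-VIF ties drop the lexicographically last name;
  importance ranks break ties by predictor name; AUC uses midranks;
  max-TSS picks the smallest optimal threshold. All deterministic.
* **Degenerate inputs.** Constant suitability → Boyce undefined (flagged,
  not zero); zero-variance fields → Gi* degenerate flag with no
  significant cells; single-clump or empty ranges → FRAG 0; clump pairs
  with no sea path are excluded from the FRAG mean and counted; anomaly
  ratios with a near-zero present value (|x| < 1e-6) become missing.
* **FRAG distances** are least-cost paths through sea cells (rook moves,
  land impassable), counted edge-to-edge in cell steps and scaled to km;
  straight-line distance is not used because ranges separated by land are
  biologically farther apart than geometry suggests. Clump connectivity is
  rook by default (queen available).
* **Latitude in synthetic mode** is the planar northward cell-centre
  coordinate in cell units (row 1 = northernmost); outputs carry that
  convention rather than pretending degrees.
* **Seeds.** A single master seed deterministically derives every stage
  seed (`derive_seed()`); one seed reproduces the entire run bit for bit,
  and the run manifest echoes the full configuration.
* **Problem sizes.** Permutation importance compares predictions on a
  seeded subsample of 250 presence/pseudo-absence rows (a Pearson
  correlation at that n is precise to a few hundredths, and prediction
  cost dominates the stage); the ensemble's training-stage score uses at
  most 1500 subsampled rows. Both are the package's own sizing choices and
  are configurable.

## Known limitations

* Pseudo-absence AUC is a relative, not absolute, measure of skill: some
  pseudo-absences fall in genuinely suitable habitat, bounding achievable
  AUC below 1 by design.
* Fitted committees systematically widen narrow ranges: suitability
  surfaces are smoother than a sharp true niche and the max-TSS threshold
  is calibrated against pseudo-absences, so binarized ranges of
  narrow-niche species come out substantially wider than the analytic
  truth. Range-level shift metrics are robust to this, but cellwise
  Jaccard turnover between stacked ranges is diluted wherever widened
  ranges overlap — community turnover recovered from fitted stacks
  understates a sharp constructed turnover signal.
* The regridding supports nested geometries (integer coarsening or
  refinement); arbitrary reprojection belongs to GIS tooling, not here.
* "Everything is everywhere": projections assume unlimited dispersal
  within the depth window; connectivity constraints are out of scope.
* The Gi* neighbourhood uses k-nearest cells by centroid distance; on
  ragged coastlines neighbourhoods can straddle land.
* Zonal (subbasin) averaging of community metrics is generic
  (`dplyr::group_by()` on any cell attribute); no real basin polygons are
  bundled.
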