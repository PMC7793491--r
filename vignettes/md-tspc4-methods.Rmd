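---
title: "MD-TSPC4: model, numerical choices and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MD-TSPC4: model, numerical choices and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspc4)
```

## The model

MD-TSPC4 rests on one empirical relation: the conformational flexibility of
an intramolecular i-motif, summarised from molecular-dynamics trajectories,
is linearly related to its melting temperature. Flexibility is measured as
the time-averaged best-fit RMSD of the whole molecule against the
trajectory's first frame, computed independently at several simulation
temperatures and then averaged across them:

$$\overline{\mathrm{RMSD}}(T) = \frac{1}{k}\sum_{i=1}^{k}
  \langle \mathrm{RMSD}(t;\,T_i)\rangle_t .$$

Averaging across temperatures is deliberate: single-temperature RMSD of
long-loop i-motifs correlates poorly with temperature, while the
multi-temperature mean damps run-to-run irregularity. The TR plot is the
ordinary least-squares regression of experimental CD melting temperatures
on $\overline{\mathrm{RMSD}}(T)$; predictions for new sequences read off
the fitted line. The shipped calibration is trained on three thymine-loop
model sequences (CCCT3, CCCT5, CCCT7: loops of 3, 5 and 7 thymines):

```{r}
published_calibration()
```

Assumptions worth keeping in mind: the relation is calibrated on five
short model sequences at acidic-pH folding conditions; flexibility is taken
as the single stability determinant (no pH, ionic-strength or loop-sequence
covariates); and the line is applied outside its training range at the
user's risk (predictions are flagged as extrapolations).

## Sequence architecture and pair topology

`parse_imotif()` accepts repeat notation (`d[(CCCTTT)3CCC]`) or a plain
sequence and requires exactly four equal-length cytosine tracts — maximal
runs of at least two consecutive C — that begin and end the sequence, with
three non-empty loops between them (named loop1–loop3, 5′→3′). This
matches all five model sequences and fails loudly on anything else; a
consequence is that single-cytosine "tracts" are not recognised, so the
minimal supported tract length is 2.

C:C+ pairs connect duplex partners (tract 1 with 3, tract 2 with 4), named
by tract number and a within-tract letter (`C2c:C4a` = third cytosine of
tract 2 with first of tract 4). The experimentally realised intercalation
register is structure-specific and not derivable from sequence alone, so
two conventions are exposed: `"aligned"` (i-th cytosine with i-th, the
default) and `"shifted"` (each duplex cyclically offset by one position,
which generates cross-register names such as `C2c:C4a`). Both keep the
invariant of `2 × tract length` pairs with every cytosine in at most one
pair; neither is asserted as canonical.

## Trajectory statistics

* **Superposition.** Best-fit RMSD uses the Kabsch algorithm (SVD of the
  weighted covariance matrix, determinant-corrected to a proper rotation).
  Degenerate point sets — collinear or coincident, where the rotation is
  under-determined (second singular value below $10^{-8}$ of the first) —
  fall back to a flagged translation-only fit.
* **Fit mask.** Region RMSD superposes on the same atoms being measured,
  the behaviour of per-mask trajectory tools; passing a different
  `fit_selection` measures one region's motion in another's frame. Heavy
  atoms are the default everywhere (the conventional choice when the atom
  subset is unstated); hydrogens enter only on request.
* **Averaging.** `time_average_rmsd()` defaults to burn-in 0, i.e. the full
  series, since the reference per-temperature table is described as a
  whole-simulation average; a burn-in window is available.
* **RMSF** is computed per residue about the time-mean position, optionally
  after superposition; for isotropic Gaussian displacements of
  per-coordinate sd $\sigma$ it has closed form $\sigma\sqrt{3}$, which the
  test suite recovers within 3% at $10^4$ frames.
* **RDF.** Distances are histogrammed in bins of `dR` (default 0.1 Å, to
  10 Å) and normalised by the count expected at a uniform reference density
  (default 0.03 molecules/Å³, roughly water). The default `"shell"`
  normalisation uses the exact shell volume
  $\frac{4\pi}{3}\{(R+dR)^3 - R^3\}$. A `"literal"` mode implements the
  CPPTRAJ-style expression sometimes quoted with $(dR)^3$ as the second
  term; the two differ by a term that matters most at small $r$, and the
  literal form gives the first bin zero expected volume, where an empty bin
  is reported as $g = 0$ rather than 0/0. Periodic minimum-image distances
  are applied only when a cubic box is supplied (the point-cloud fixture);
  raw MD boxes are out of scope.
* **Hydrogen-bond monitoring.** A C:C+ pair is scored by its N3–N3
  distance; "within hydrogen-bond distance" is operationalised as 3.5 Å
  (the conventional heavy-atom donor–acceptor limit) and a pair is
  *disrupted* when it exceeds the cutoff in more than 50% of frames. Both
  numbers are arguments. Loop–loop contact uses a 4.0 Å heavy-atom
  criterion, again configurable.

## CD melting curves

Tm is the temperature of steepest ellipticity change: the extremum of
$d\theta/dT$ at 285 nm. The derivative is estimated with a Savitzky–Golay
first-derivative filter (default window 11 points ≈ 2.2 K at the 0.2 K
pitch, quadratic), and the peak position is refined by fitting a parabola
to the derivative over its half-maximum region and taking the vertex. The
refinement is what makes the estimator usable at realistic noise: a bare
grid argmax of the window-11 derivative wanders by a kelvin or more under
2%-of-amplitude noise, while the vertex fit pools the whole transition
region; being symmetric, it returns the exact midpoint of a noiseless
two-state curve whether or not the midpoint lies on the temperature grid.
Magnitude (rather than sign) of the derivative makes the same code serve
heating (Tm) and annealing (Ta) directions. Curves whose derivative peak
sits at the window margin or fails to stand clear of the derivative's
median level — flat or baseline-only data — raise a "no transition
detected" error rather than returning a number. Temperatures below 200 are
taken as Celsius and converted (disable with `celsius = "no"`).

The i-motif CD signature check encodes the standard criterion: positive
band near 285 nm, negative near 265 nm, magnitude ratio at least 2.

## Synthetic data: what it does and does not emulate

The generators exist to give every analysis stage inputs with *known*
ground truth, not to mimic MD physics:

* `toy_imotif_structure()` places one bead per residue (named N3, unit
  mass) with the two duplexes' pair planes interleaved along the stacking
  axis and all pair distances at 2.8 Å; loops sit on arcs 120° apart.
* `gaussian_trajectory()` adds i.i.d. Gaussian noise per frame. Frames are
  deliberately uncorrelated in time so RMSF and RMSD expectations are
  closed-form; real trajectories are autocorrelated, anharmonic and
  diffusive, so passing these tests validates the *operators*, not any
  claim about real i-motif dynamics.
* `temperature_trajectory_set()` can solve noise amplitudes against target
  time-averaged RMSDs. The draws are held fixed while the amplitude is
  bisected (frames are `reference + σZ` with `Z` drawn once per seed), so
  the measured average is a smooth, strictly increasing, deterministic
  function of σ and the tuning is exact to tolerance 0.5% by construction.
  The Gaussian closed form `target/sqrt(3(N−2)/N)` seeds the bracket.
* `synth_melt_curve()` produces two-state sigmoids over 293–353 K at 0.2 K
  pitch; `ideal_gas_trajectory()` produces uniform periodic point clouds at
  a stated density (240 points for the default 0.03 Å⁻³ in a 20 Å box).

All generators are seed-deterministic and restore the caller's RNG state.

## Calibration conventions

The reference calibration trains on the *published one-decimal*
$\overline{\mathrm{RMSD}}(T)$ values (2.0, 3.4, 5.0 Å), which reproduces
the published coefficients exactly; `fit_tr_plot()` accepts unrounded
inputs for users with their own data. Note two rounding artefacts inherent
in working from printed tables: the CCCT3 whole-molecule mean of the
printed per-temperature values is 2.06 → 2.1 Å while the published summary
row prints 2.0 Å (the calibration honours the printed 2.0); and the fitted
line evaluated at 4.1 Å gives 316.9 → 317 K where 316 K is published,
consistent with an unrounded underlying average. Predictions are reported
at full precision and rounded to the nearest kelvin; comparisons use the
rounded value, matching the whole-kelvin convention of melting
experiments. The five-temperature protocol is a default, not a
requirement — any set of at least two temperatures is accepted.

## Validation design and problem sizes

The test suite checks each statistic against an independent route:
hand-computed geometries (cube-corner Rg, translated frames), closed-form
Gaussian expectations (RMSF at $10^4$ frames, within 3%), the ideal-gas RDF
limit (2.3 × 10⁶ distances, mean |g−1| < 0.05), Monte-Carlo melt-curve
recovery (100 seeded replicates at 2% noise, mean error < 0.5 K; 16
noiseless midpoints within one data pitch), an independent superposition
engine (bio3d, which reports RMSD to 3 decimals), and an end-to-end
pipeline run on trajectories tuned to the telomeric i-motif's reference
row (250 frames per temperature, averages within 2%, Tm within 1 K of the
analytic value). These sizes keep the full suite near ten seconds while
leaving Monte-Carlo error comfortably inside each tolerance.

## Known limitations

* The calibration derives from five short model i-motifs at one pH; loop
  compositions or lengths far outside that range are extrapolations.
* No thermodynamic fitting (van't Hoff ΔH/ΔS), no pH or ionic-strength
  modelling, no prediction of *whether* a sequence folds.
* The trajectory readers target desk-scale multi-model PDB and XYZ files;
  binary MD formats and solvent/ion handling are out of scope.
* The toy geometry is a scaffold with correct pair distances and region
  layout, not a refined i-motif structure.
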