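---
title: "Tip-link mechanics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tip-link mechanics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tiplinkmech)
```

The tip-link — the Cdh23–Pcdh15 heterodimer connecting adjacent
stereocilia of inner-ear hair cells — is the force conveyor of
mechanotransduction: sound-driven deflections load it at rates spanning
roughly 10^3^–10^6^ pN/s along the tonotopic axis. Deafness mutations at
the Ca^2+^-binding linkers of its terminal EC domains (for example
Pcdh15 D157G and Cdh23 D101G) change how the complex carries that load.
This package implements, as tested reusable code, the three analyses
through which that question is usually addressed at the single-molecule
level — smFRET conformation analysis, AFM dynamic force spectroscopy
with Bell–Evans landscape inference, and dynamic network analysis of
force propagation — together with synthetic-data generators that make
every stage verifiable at desk scale against known ground truth.

## Models

### FJC tether and force balance

Specific AFM events stretch two 5 kDa PEG spacers in series (contour
length $L_c \approx 55$ nm, Kuhn length $L_k \approx 0.7$ nm). The
freely-jointed chain gives the tether extension at force $F$:

$$L(F) = L_c\left[\coth\frac{F L_k}{k_B T} - \frac{k_B T}{F L_k}\right]$$

The cantilever (stiffness $k_c$, 20–30 pN/nm) and tether are in series,
so the piezo displacement partitions as $z = L(F) + F/k_c$, and the
instantaneous loading rate is reduced below the rigid-link value
$k_c v$ by the tether compliance:

$$\frac{1}{\dot F} = \frac{1}{k_c v}\left[1 + k_c\,\frac{L_c}{F_k}
\left(\left(\frac{F_k}{F}\right)^2 - \mathrm{csch}^2\frac{F}{F_k}\right)\right],
\qquad F_k = \frac{k_B T}{L_k}$$

The bracketed term is exactly $1 + k_c\,dL/dF$ (series compliance), and
the suite asserts this identity against numerical differentiation to
0.1%. Both loading-rate conventions are exposed — the per-event
tether-corrected rate evaluated at the rupture force (the default, used
throughout) and the nominal $k_c v$ (recovered by setting $L_c = 0$).

### Bell–Evans escape landscape

Rupture kinetics follow
$k_{\mathrm{off}}(F) = k_{\mathrm{off}}^0 \exp(F x_\beta \cos\theta / k_B T)$:
force tilts the escape barrier by $E_{\mathrm{ext}} = F x_\beta\cos\theta$,
so a complex with a larger transition distance $x_\beta$ is detached
disproportionately faster by the same force. The most probable rupture
force under a ramp is linear in log loading rate,

$$F_{mp} = \frac{k_B T}{x_\beta}\,
\ln\frac{\dot F\, x_\beta}{k_{\mathrm{off}}^0\, k_B T},$$

which the pipeline fits as an unweighted linear regression of $F_{mp}$
on $\ln \dot F$ (a $1/\sigma^2$-weighted option exists); the slope gives
$x_\beta$ and the intercept $k_{\mathrm{off}}^0$, with standard errors
propagated by the delta method. The pulling angle $\theta$ defaults to 0
in generation and analysis; it is retained as a parameter because the
tilt-energy picture needs it.

### Förster inversion

FRET efficiency maps to donor–acceptor distance through
$d = R_0\,((1-E)/E)^{1/6}$. The dye pair's Förster radius is never
measured directly here; it is calibrated from the wild-type reference
pair ($E = 0.68$ at $d = 4.62$ nm), giving $R_0 \approx 5.24$ nm, and
then applied to the mutant efficiencies (0.48, 0.40). Printed reference
distances deviate from the exact inversion by up to ~0.05 nm
(rounding of the reference values), so distance checks use a ±0.08 nm
band rather than printed precision.

### Force-propagation networks

Residues (α-carbons) are nodes; an edge joins residues whose heavy atoms
sit within 4.5 Å for ≥75% of the trajectory (α-carbon-only ensembles
fall back to an 8.5 Å Cα cutoff, always declared in the output), with
sequence neighbours excluded. Edges are weighted
$w_{ij} = -\log|c_{ij}|$ (natural log) from the dynamical
cross-correlation $c_{ij}$, so strong correlation means low
information-transfer cost. Communities come from Girvan–Newman edge
removal (betweenness with $w$ as length, modularity with $|c|$ as
strength, best level of the dendrogram); optimal paths from
Floyd–Warshall distances with deterministic reconstruction; suboptimal
paths from bounded depth-first enumeration of simple paths up to 20
edges longer than the optimum (a weight-slack alternative is exposed,
since path tools in the field use both conventions). Edge usage across
the suboptimal ensemble ranks the critical links, and the orthogonal
index decomposes each path step against the pulling axis — the
orthogonal component near the middle of the binding interface is the
force-dissipation feature that distinguishes the wild-type complex.

## Synthetic data: what it emulates, and what not

The generators define the study conditions; they are deliberately
simple:

* **Force curves** (`gen_force_curves`): retraction at the six measured
  velocities (200–5000 nm/s), $k_c = 25$ pN/nm (middle of the 20–30
  instrument range), the 55/0.7 nm tether, and exact first-passage
  sampling of the Bell hazard along the ramp — the cumulative hazard is
  integrated on a fine force grid and inverted at $-\ln u$, which is the
  continuous-time limit of per-step hazard integration. Specific events
  occur in 5% of curves; the remainder split evenly between no-event
  baselines and short-range adhesion with apparent contour lengths of
  8–30 nm, giving the classifier both negative classes seen in real
  data. Gaussian force noise (default 5 pN) is the only noise source: no
  drift, no hydrodynamic artefacts, no multiple tethers. Curves carry
  2048 samples, matching kHz-scale AFM acquisition; coarser sampling
  visibly biases rupture-force estimates.
* **FRET traces** (`gen_fret_traces`): an ideal intensity split
  $(1-E, E)$ of a 1000 counts/frame budget, 5% donor→acceptor leakage,
  channel backgrounds, 50-count Gaussian noise, and single-step acceptor
  bleaching with geometric waiting time (0.005/frame over 200 frames at
  300 ms exposure). A per-trace spread of the true efficiency (SD 0.04)
  emulates the measured histogram widths of ±0.03–0.05; without it the
  synthetic per-trace efficiencies collapse to a near-delta distribution
  no real experiment produces. No blinking, no donor bleaching, no
  direct acceptor excitation.
* **Trajectories** (`gen_trajectory`): Gaussian displacement fields
  around a reference geometry with a planted residue–residue correlation
  structure (blocks, background, and an optional high-correlation path
  with Markov-consistent geometric decay $\rho^{|k-l|}$, which keeps the
  target positive semi-definite). Targets are repaired to the nearest
  PSD correlation by eigenvalue clipping; repairs that move any entry
  by more than 0.1 are a configuration error rather than a silent
  change. Frames are sampled in a common reference frame, so generated
  ensembles are born aligned; `superpose()` (iterated Kabsch onto the
  refined mean) exists for, and is tested on, ensembles with real
  rigid-body motion. Two reference layouts are provided: a zigzag
  strand pair whose second and third sequence neighbours are in contact
  (as in real backbone geometry — a straight line would disconnect
  odd/even residues once sequence neighbours are excluded), and a
  compact two-domain grid for community closures.

Passing closures on these generators show that the estimators recover
known truth under the stated noise — not that real instrument data meet
the generators' assumptions.

## Estimator and numerical choices

* **Peak finding.** All "most-probable" quantities are Gaussian fits to
  histogram counts, with a histogram-mode fallback on fit failure.
  Rupture-force distributions are left-skewed (Gumbel-like), and a
  full-range fit at Freedman–Diaconis binning sits ~5 pN below the true
  mode — an error the Bell–Evans intercept amplifies exponentially into
  a ~1.5× off-rate bias. `most_probable_force` therefore fits locally:
  bins at 0.6× the Freedman–Diaconis width, restricted to ±0.75 SD
  around the mode bin. This choice was calibrated against the
  closed-form self-consistent mode (and cross-checked with kernel
  density modes), which leaves a residual offset of ~2 pN. Loading
  rates are fitted in log space. Efficiency histograms default to the
  Freedman–Diaconis width capped at 0.05, so both the wide measured
  peaks and narrow synthetic distributions resolve; distinct secondary
  modes (≥50% of the main peak) trigger a warning and a windowed fit of
  the dominant mode.
* **Event classification.** A specific event needs a rupture candidate
  (smoothed peak ≥30 pN returning to baseline), a converged FJC fit
  with force-equivalent RMS residual below 4× the estimated per-sample
  noise (floor 8 pN), and a contour length inside 55 ± 18 nm (±3 SD of
  the measured 55 ± 6 nm tether distribution). Residuals are mapped to
  force units through the local series-compliance slope, which makes
  the threshold noise-scale-invariant. The stretch segment ends at the
  last raw pre-drop sample; median filtering for the peak estimate is
  restricted to the segment, because a filter window straddling the
  drop biases the unbinding force low.
* **Rupture-time sampling** uses a 4000-point force grid extended until
  the cumulative hazard exceeds 50 (survival < 10^-21^), with trapezoid
  integration — discretisation error is negligible against the 5 pN
  noise floor.
* **Determinism.** Every generator takes an explicit seed and is
  bit-reproducible. Graph tie-breaks are deterministic: Girvan–Newman
  betweenness ties (common, because betweenness counts integer path
  pairs) are cut at the weakest-|c| edge first, then lexicographically;
  shortest-path reconstruction prefers the lexicographically smaller
  node name. Edges with $|c| < 10^{-4}$ are dropped as numerically
  meaningless. Terminal residues (default 3 per chain end) are trimmed
  before network construction, standing in for the flexible-end
  exclusion used on real trajectories.
* **Degenerate inputs.** Zero-displacement force is 0 without root
  finding; a rigid tether ($L_c = 0$) degenerates to the cantilever
  spring; zero-fluctuation trajectories flag correlations as undefined
  instead of fabricating them; near-isotropic domain clouds flag the
  interdomain angle as ill-defined.

## Problem sizes

The shipped closures use 300 rupture events per velocity across six
velocities per seed (10-seed medians for landscape recovery), 5625
curves for prevalence, 500 traces for efficiency peaks, and 1200–2000
frame trajectories of 20–28 residues — sizes at which every stochastic
tolerance in the test suite holds with comfortable margin on a single
CPU while keeping the whole suite in the minutes range.

## Known limitations

* Girvan–Newman returns the best partition *on its dendrogram*; on
  graphs without community structure the global modularity maximum
  often lies off the dendrogram, and no faithful implementation of the
  algorithm will find it. Oracle-equality tests therefore use
  community-structured graphs; on the synthetic strand geometry,
  maximum modularity genuinely prefers segmenting quasi-1D chains, so
  community closures use the compact-domain layout.
* The Bell–Evans intercept is an extrapolation over ~1.4 decades of
  loading rate; its standard error is honest but large (roughly
  factor-1.5 at 300 events/velocity), and off-rates should be read with
  that in mind.
* Suboptimal-path enumeration is exponential in the slack; it truncates
  at `max_paths` (default 1000) with an explicit flag, so usage
  fractions beyond the truncation are conditional on the collected set.
* The interdomain angle uses principal axes oriented away from the
  partner domain; for side-by-side parallel domains the outward
  projection vanishes and the convention is ambiguous (flagged by the
  continuity guard). Angle analyses here validate the operator on
  planted rod geometries; they do not reproduce molecular-dynamics
  angle distributions, which require the actual simulations.
* Efficiencies outside (0,1) cannot be converted to distances; the
  correction step can legitimately produce slightly negative per-frame
  efficiencies on noisy traces, and per-trace averaging handles that
  before conversion.
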