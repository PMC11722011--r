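---
title: "Mapping protein–peptide interactions from NMR observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein–peptide interactions from NMR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrmap)
```

`nmrmap` turns assigned ¹H–¹⁵N peak lists into binding-site maps, binding
constants, docking restraints and per-domain dynamics. This vignette
documents the models behind each stage, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generators do
and do not emulate, and the known limitations.

## Chemical shift perturbation

For each backbone amide observed in two conditions, the combined
perturbation is

$$\mathrm{CSP} = \sqrt{\left(\frac{\Delta\delta_{^{15}N}}{10}\right)^2 +
(\Delta\delta_{^{1}H})^2}\quad[\mathrm{ppm}],$$

the Euclidean norm of the two shift differences with ¹⁵N down-weighted by
10 to compensate for its wider dispersion. The divisor is exposed
(`n_scale`) but fixed at 10 everywhere in the package; alternative
nucleus weightings exist in the literature, and changing the divisor
changes thresholds, so it is deliberately not a routine knob.

A residue is *significant* when its CSP exceeds the mean plus `k`
standard deviations (default `k = 1`) of the CSP distribution. Two open
choices were settled as follows:

* **One global threshold.** The distribution is computed over *all*
  matched, non-overlapped residues of the construct, not per domain.
  Per-domain thresholds would let a quiet domain flag noise-level
  residues; plots of the per-residue profile conventionally draw a
  single dotted line.
* **Sample SD (n−1).** Conventional for modest-sized sets; at the
  50–300 residues of a real construct the difference from the population
  SD is immaterial (below 1% of the threshold).

Matching is strictly by assignment identity. Overlapped peaks are
excluded from all statistics (and reported), unassigned peaks are
ignored, and a residue absent from one condition is *absent*, never
imputed as zero — prolines and exchange-broadened amides simply have no
record. Peaks that disappear on ligand addition carry no CSP (there is
no bound-state position to subtract); they are surfaced separately as
broadened.

## Fast-exchange affinity fitting

In fast exchange the observed position of a peak is the
population-weighted average of its free and bound positions, so residue
$i$ at ligand concentration $L_j$ shows

$$\Delta\delta_{ij} = f_b(P, L_j, K_D)\,\Delta\delta_{\max,i},
\qquad
f_b = \frac{(P+L+K_D) - \sqrt{(P+L+K_D)^2 - 4PL}}{2P},$$

the exact two-state isotherm (no weak-binding approximation — at
millimolar $K_D$ and millimolar protein the ligand is appreciably
depleted). Numerically $f_b$ is evaluated as $2L/\big((P{+}L{+}K_D) +
\sqrt{(P{+}L{+}K_D)^2-4PL}\big)$, which is algebraically identical but
avoids the cancellation of the direct root at small $P$.

All residues share one $K_D$; each has its own $\Delta\delta_{\max,i}$.
For a trial $K_D$ the $\Delta\delta_{\max}$ values are the closed-form
linear least-squares solution, so the fit is a one-dimensional
optimization of the profiled residual sum of squares over $\log K_D$
(golden-section; search interval $10^{-8}$–$1$ M by default). The
reported $\sigma(K_D)$ is the asymptotic error from the curvature of the
profile at the optimum. Residues whose largest observed shift is below
`min_shift` (default $10^{-4}$ ppm) are excluded so that unresponsive
residues do not dilute the fit; a titration in which nothing shifts is
an error ($K_D$ unidentifiable), and an estimate pinned at the search
boundary triggers a warning rather than a silent number.

## PRE normalization and distance restraints

The paramagnetic/diamagnetic intensity ratio $I_{para}/I_{dia}$ can
exceed 1 when the diamagnetic reference relaxes more slowly than the
recycle delay assumes, so ratios are rescaled by a single per-dataset
factor $\alpha$ chosen to make the *reference set* — residues far from
the spin label — average exactly 1:
$\alpha = 1/\overline{(I_{para}/I_{dia})}_{\mathrm{ref}}$.

When no reference set is supplied it is found by iterative sigma
clipping: start from all residues, drop those below 0.8× the current
mean ratio, recompute, two passes. This recovers "the distant residues"
without needing a structure, provided a majority of residues are indeed
unaffected — true for a small ligand binding a large construct, and the
regime the auto rule is intended for. Values above 1 are preserved in
reports and clamped only for the distance mapping.

Attenuation maps linearly onto distance between 12 and 30 Å:
$d_{calc} = 12 + 18\,\min(\mathrm{PRE}, 1)$. The restraint rules are
piecewise:

| normalized PRE | restraint |
|---|---|
| 0 (peak vanished) | 1.8 – 12 Å |
| (0, 0.8) | 12 – ($d_{calc}$ + 3) Å |
| ≥ 0.8 | none |

The 1.8 Å floor is the hard-sphere contact limit; the +3 Å pad reflects
the semiquantitative character of intensity-ratio PREs. PREs in
[0.8, 1) generate *no* restraint: the rule set covers only strong
effects, and leaving weak ones unrestrained is the conservative choice
when the restraints feed docking. The restraint anchor is a pseudo-atom
at the label-bearing residue's backbone N (configurable); modelling the
nitroxide rotamer cloud is out of scope. Region-specific site-calling
cutoffs (`classify_pre_sites()`) default to 0.88 for residues 1–182 and
0.70 for 183–352 — flexible arms versus slower-tumbling core of a
two-state dimeric construct — and are strict inequalities: a residue
exactly at its cutoff is not flagged. The cutoffs are configuration,
with these values as defaults.

## ¹⁵N relaxation and per-domain correlation times

Decay series (default delay lists: 20/300/600 ms for R1, and
8.65/16.96/33.92 ms for R2) are fit to $I(t) = I_0 e^{-Rt}$ — two free
parameters, no offset term, which is the right model for three-point
pseudo-3D series. The fit is Gauss–Newton least squares started from the
log-linear regression; for three points and realistic noise it converges
in a handful of iterations, and noiseless series are recovered to
machine precision. Rate uncertainties come from the signal-to-noise
ratio by Monte-Carlo resampling: 200 synthetic datasets around the
fitted curve with Gaussian noise of the stated width, refit by the same
estimator (vectorized across replicates), $\sigma$ = SD of the refit
rates. Coverage of the true rate at 1σ is ~68%, verified by simulation
in the test suite. Constant (flat) series return rate 0 flagged
degenerate rather than an error.

The apparent rotational correlation time of a domain comes from its
R2/R1 ratio:

$$\tau_c \approx \frac{1}{4\pi\nu_N}\sqrt{6\frac{R_2}{R_1} - 7},$$

valid for $R_2/R_1 \ge 7/6$ (below that the radicand is negative and the
function errors). $\nu_N$ is derived from the ¹H field via the
gyromagnetic-ratio magnitude quotient 0.1013756 (≈91.2 MHz at 900 MHz);
the quotient is an argument for instruments calibrated differently. At a
900 MHz field this maps ratio 22 → 9.75 ns and ratio 70 → 17.7 ns.

Per-domain estimates trim once: compute mean and SD of the ratios in the
domain, retain residues within 1 SD, recompute the mean on the retained
set, convert. Trimming is a single pass, not iterated to convergence —
one pass removes exchange-broadened and locally flexible residues
without the shrinking-window pathology of iterated clipping — and can
never empty a domain (if the window would exclude everything, everything
is kept). $\sigma(\tau_c)$ is first-order propagation of the
trimmed-ratio SD through the formula,
$\partial\tau_c/\partial r = 3/(4\pi\nu_N\sqrt{6r-7})$; propagating the
ratio scatter rather than the individual fit errors makes the quoted
uncertainty reflect domain heterogeneity, which dominates at realistic
SNR.

Exchange flagging uses the *untrimmed* domain statistics (flag when
ratio > mean + 1 SD): the trimmed SD would shrink after removing the
very residues being tested. Condition comparisons use Welch's
unequal-variance t-test on the trimmed per-residue ratios at α = 0.05;
no multiple-testing correction is applied because the comparison is one
pre-specified domain at a time.

## Competition classification

With conditions free / +client / +client+competitor, CSPs are computed
for both ligand conditions against the free reference, the significance
threshold comes from the client-vs-free distribution, and each residue
receives exactly one class: `none`, `client_only`, `competitive`
(significant client CSP that increases further when the competitor
arrives — both ligands engaging the same site), or `broadened` (peak
disappears in a ligand condition). "Increases further" is a strict
inequality with an optional margin (default 0 ppm; set it to a multiple
of the shift noise for noisy data). The classifier deliberately stops at
classification: distinguishing orthosteric from allosteric competition,
or fitting ternary equilibria, needs more than chemical shifts.

## Structure comparison

`kabsch_superpose()` is the SVD form of least-squares rigid-body
superposition with the determinant correction that forbids reflections;
RMSD is reported over the fitted selection (fit set = report set by
default, a subrange fit is available). The test suite checks it against
an independently implemented quaternion-eigenvalue solver on random
instances to $10^{-9}$ Å. Because deposited ensembles rarely state which
member or residue range a printed RMSD used, `rmsd_grid()` scans
model × range combinations; comparing against the deposited free/bound
coordinate files requires fetching them from the PDB (they are not
bundled with the package).

## What the synthetic generators emulate

Each generator returns its data *and* the truth object behind it;
pipeline outputs are always validated against truth, never against
other pipeline outputs. Defaults mirror the study conditions the
package is built around: 81- and 352-residue constructs, a six-domain
map, millimolar $K_D$ at 1 mM protein with 0–4 mM ligand, the delay
lists above, SNR 50, domain correlation times {9.8, 11.0, 18} ns.

Noise models are Gaussian — additive in peak position (ppm), with the
¹⁵N noise 5× the ¹H noise to match the dispersion ratio, and
multiplicative in intensity. The generators emulate the *statistical*
structure the analysis assumes: straight-line fast-exchange peak
trajectories, exactly linear PRE–distance response with hard
disappearance below 12 Å, exactly monoexponential decays, and
domain-blocked ratios with residue-level scatter. They do not emulate
peak overlap, assignment ambiguity, slow/intermediate exchange
curvature, spin-label rotamer averaging, anisotropic tumbling, or
baseline/phase artifacts. Passing the recovery tests therefore
demonstrates the estimators are correct and well-calibrated under the
stated assumptions — not that the assumptions hold for any particular
real sample; the significance rules and trimming are the places where
real data deviate first.

## Problem sizes and numerical tolerances

The test suite and acceptance script use: 200-residue decay sets at
SNR 50 (median signed rate bias < 2%, domain τc within 5%), 50-residue
titrations with 0.002 ppm noise over 12 replicate seeds (median
relative $K_D$ error < 20%), 40 replicate PRE datasets at 2% intensity
noise (≥95% restraint coverage of true close distances), a 352-residue
zero-noise competition design (sensitivity = specificity = 1), and 100
random superposition instances (Kabsch vs quaternion to $10^{-9}$).
These sizes were chosen to make the recovery statistics stable at a
few seconds of runtime each. Hard numerical tolerances used internally:
isotherm evaluated in its cancellation-free form; Gauss–Newton
terminates at relative step $10^{-13}$ or 60 iterations with damped
steps keeping rates non-negative; the K_D profile is optimized in log
space to tolerance $10^{-12}$.

## Known limitations

* CSP cannot distinguish direct contact from propagated conformational
  change; PRE is the direct-distance evidence, and the package keeps
  the two maps separate rather than merging them into one score.
* The PRE calibration is semiquantitative by design; it produces
  docking intervals, not distances with error bars (no $r^{-6}$
  Solomon–Bloembergen fitting, no Γ₂ rates).
* The τc formula assumes isotropic tumbling dominated by dipolar/CSA
  relaxation; for strongly anisotropic or exchange-contaminated domains
  the *apparent* τc is a comparative index, not a hydrodynamic
  measurement — which is exactly how the per-domain comparison uses it.
* Follow-the-peak titration tracking is not implemented; peak lists
  must be assigned in every condition.
* The shared-K_D fit assumes one binding event; multi-site binding with
  distinct affinities needs per-site fitting on residue subsets.
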