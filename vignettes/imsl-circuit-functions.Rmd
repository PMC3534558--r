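---
title: "Modeling gene autoregulation via intronic microRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gene autoregulation via intronic microRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirloop)
```

# The circuit and its two comparators

An intronic-miRNA-mediated self-loop (iMSL) is a protein-coding host gene
that harbours a miRNA in one of its introns, on the same strand, so that the
miRNA is co-transcribed with the host mRNA and — after processing — represses
the host's own translation.  `mirloop` models this circuit and two reference
architectures under a *mathematically controlled comparison*: all shared rate
constants are equal, and the architecture-specific constant is constrained so
that all three circuits reach the same protein steady state.

* **iMSL** — transcription produces mRNA $r$ and miRNA $s$ together at rate
  $k_r(q) = k_r\,q^n/(h_r^n + q^n)$ (Michaelis–Menten for the default
  $n = 1$), and translation is repressed post-transcriptionally,
  $k_p(s) = k_p/(1 + s/h)$:
  $$\dot r = k_r(q) - g_r r,\qquad
    \dot s = k_r(q) - g_s s,\qquad
    \dot p = \frac{k_p}{1 + s/h}\,r - g_p p.$$
* **sTF** — the same transcription unit without feedback; constant
  translation rate $k_{p2}$.  Matching requires
  $k_{p2} = k_p/(1 + s_{ss}/h)$.
* **tSL** — a transcriptional self-loop.  The repression form is a modeling
  choice here (only the qualitative topology is prescribed): we use the
  minimal multiplicative form
  $k_r(q, p) = k_r\,\frac{q}{h_r + q}\,\frac{1}{1 + p/h_{fb}}$, for which
  the steady state solves a quadratic with exactly one positive root and the
  matching constant is $h_{fb} = p_{ss}^2/(p_0 - p_{ss})$ in closed form.

The upstream transcription factor (TF) is itself expressed constitutively by
a two-stage gene (mRNA $w$, protein $q$) with rates $k_w, k_q$ and
degradations $g_w, g_q$, used whenever upstream fluctuations matter.

**Half-life conventions.**  Parameter recipes quote half-lives; equations use
rates.  Both $g = \ln 2/\tau$ (the default) and $g = 1/\tau$ (mean-lifetime
reading) are supported, and every parameter set records its convention.  The
noise-setting preset (`preset("fig5")`) records `one_over_tau`: with its TF
rates that reading gives an upstream noise $CV_q \simeq 0.21$ — the ~20%
level the noise analyses are built around — whereas $\ln 2/\tau$ gives 0.17.

**The miRNA half-life of the noise preset.**  The noise setting fixes
$\tau_r = \tau_w = 30$ min and $\tau_p = \tau_q = 1.5$ h but not $\tau_s$.
We set $\tau_s = \tau_r = 30$ min — miRNA turnover comparable to the mRNA's,
the same regime ($\tau_r/\tau_s = 1$) the dynamical examples use.  This is a
modeling choice made once; a sensitivity scan over
$\tau_s \in [10\ \mathrm{min}, 1.5\ \mathrm{h}]$ moves the headline noise
ratios by only a few percent and does not change any qualitative conclusion.

# Deterministic observables

* $T_{ON}$: time for $p$ to reach half its final steady state after
  transcription switches from 0 to maximal, from the empty state;
  $T_{OFF}$: time to fall to half the initial steady state after
  transcription stops.  Both are normalised by the sTF's time $T_0$ for the
  *same direction* (for these models the sTF on- and off-times coincide, so
  the distinction is moot in practice but kept explicit).  Because the iMSL
  switch-off can transiently *boost* $p$ above its starting level (each
  degraded miRNA de-represses the surviving mRNAs), the off-crossing is the
  **last** downward crossing of the threshold.  An alternative "time to reach
  (near) zero" off-criterion is available via the `threshold` argument.
* $d$: ON-state robustness.  From the fully activated steady state the TF is
  removed for $T^*$ seconds; $d = (p_{ss} - \min_t p)/p_{ss} \in [0, 1]$.
* Adaptation indexes for a TF step $q_0 \to F q_0$ on a pre-equilibrated
  circuit:
  $$P = \left|\frac{(p_1 - p_0)/p_0}{(q_1 - q_0)/q_0}\right|^{-1},\qquad
    S = \frac{p_{max} - p_0}{p_0},$$
  with $P$ capped at $10^6$ when the steady state is input-independent to
  machine precision.  A circuit is *adaptive* when $P > 10$ and its peak is
  a recognisable signal, $S > 2\,CV_p$.
* Weber's-law error for two consecutive steps of equal fold change
  ($q_0 \to F q_0 \to F^2 q_0$), each peak measured from its own pre-step
  baseline: $E = |p_{max,2} - p_{max,1}|/p_{max,1}$; the fold-change-
  detection regime is $E < 0.1$.  $E \to 0$ requires strong repression
  ($s/h \gg 1$), nearly linear activation ($q/h_r \ll 1$) and fast mRNA
  turnover — in that limit the reduced dynamics depends on the input only
  through $\dot q/q$, so equal folds give equal peaks.

Numerical choices: piecewise `deSolve::lsoda` integration across protocol
segments (rtol = atol = 1e-8), threshold crossings located by natural-spline
interpolation on the dense output with grid doubling until the located time
is stable to 0.1%, and peaks refined by spline optimisation around the grid
maximum.  The two-step protocol waits $\max(20/g_p, 20/g_s)$ between steps
and raises a protocol error if the intermediate steady state is not
re-attained within 1%.

**The sensitivity threshold's noise level.**  The threshold $S > 2 CV_p$
assumes a 10% input noise.  The two-stage TF gene has a Poisson floor
$CV_q^2 \ge 1/\langle q \rangle$, so a 10% CV cannot be imposed by rate
tuning at a background of $q_0 = 40$ molecules (floor: 15.8%).  We therefore
treat the input noise as a quasi-static modulation and combine it with the
intrinsic fluctuations of the downstream species at clamped input:
$$CV_p^2 = CV_{p,\mathrm{int}}^2 +
  \left(\frac{d\ln p_{ss}}{d\ln q}\right)^2 CV_q^2 .$$
Where the floor permits, `tf_params_for_cv()` performs the exact closed-form
rate tuning instead.  In the adaptive regime the logarithmic gain is near
zero, so the two approaches agree where both are defined.

# Stochastic model

The master-equation model keeps the full nonlinear propensities and treats
iMSL transcription as a *single* reaction producing $r$ and $s$ together
(perfect co-transcription; `cotranscribed = FALSE` decouples them into two
independent reactions with equal rates for sensitivity analysis — the mean
field is unchanged but the $r$–$s$ correlation, and hence the buffering,
weakens).

Sampling is exact (Gillespie).  Both the first-reaction scheme and the
direct scheme are implemented in C++; they are statistically identical and
the suite tests their distributional agreement.  All randomness flows
through R's RNG, so `set.seed()` makes every path bit-reproducible.

Stationarity is declared by a deterministic criterion: the burn-in is the
time at which the mean-field trajectory from the same initial condition is
within 0.05% of its asymptote for every species.  Two sampling designs are
provided:

* **ensemble** — independent trials, one state each at the burn-in time
  (2,000 trials by default; the ensemble size is a runtime/precision
  trade-off and the standard errors reported alongside make the precision
  explicit — t1 below uses 10,000);
* **time average** — one long path after burn-in with time-weighted moments
  and batch-means standard errors (40 batches); the default for parameter
  scans, typically sampling 2,000 slowest lifetimes.

The **linear noise approximation** (LNA) solves the stationary Lyapunov
equation at the deterministic fixed point and is exact for linear systems
(birth–death, the two-stage TF gene, where it reproduces
$CV_q^2 = 1/\langle q\rangle + (1/\langle w\rangle)\,g_q/(g_q + g_w)$ to
machine precision).  For the nonlinear circuits it is an approximation used
for fast pre-scans and is validated against Gillespie in the tests (protein
CV within 15% at physiological copy numbers, converging as counts scale up).
One systematic effect worth knowing: because the Michaelis–Menten activation
is concave, the *true* stochastic mean of the downstream species sits about
$\tfrac12 |f''|\,\mathrm{var}(q) \approx 1\%$ below the mean-field fixed
point at $\langle q\rangle/h_r = 1$ — tests compare means with that
allowance.

**Noise maps.**  At each grid point $(\langle q\rangle/h_r,\ \langle
p\rangle/\langle p_0\rangle)$ the self-loop is calibrated (closed forms
$h = s_{ss}\rho/(1-\rho)$, $h_{fb} = \rho^2 p_0/(1-\rho)$) and compared with
an sTF *producing the same mean protein*: since the sTF protein mean is
linear in $k_{p2}$ and its mRNA is statistically identical to the iMSL's,
$k_{p2} = g_p \langle p\rangle_{loop}/\langle r\rangle$ matches the means
exactly; the achieved match is verified within 2% and re-calibrated once
from the measured means if violated.  Protein distributions are summarised
by moment-matched gamma densities (`gamma_overlay()`), a summary whose
adequacy is itself tested (Kolmogorov–Smirnov distance < 0.05 against the
simulated sTF distribution).

# Enrichment analysis on synthetic networks

The bioinformatic stage consumes an annotation table (miRNA genomic context:
intergenic / exonic / intronic, same or opposite strand, host gene) plus
per-algorithm target-prediction tables, and counts **iMSLs**: same-strand
intronic miRNAs predicted to target their own host by at least
`min_support` algorithms.  Over-representation is tested by permutation with
$Z = (x - \langle x\rangle_r)/\sigma_r$ under two strategies:

* `host_reshuffle` — host assignments of intronic miRNAs permuted among
  themselves, predictions untouched;
* `target_reshuffle` — the union-of-algorithms edge set rewired by permuting
  its target column (per-miRNA out-degree preserved); the permuted union is
  scored at support 1, which is exactly the support level at which $x$ is
  defined.  Permuting the union rather than each algorithm separately is a
  deliberate reading of an ambiguous procedure; the strategy enum isolates
  it so the per-algorithm variant can be added.

The Monte-Carlo host-reshuffle null has a closed-form expectation by
enumeration over the host multiset
($\sum_m \#\{\text{hosts that are union-targets of } m\}/\#\text{hosts}$),
used as an independent oracle.

**What the generator emulates — and what it does not.**  Real annotation
catalogues and eight published target predictors cannot be queried here, so
the generator draws miRNA contexts from stated fractions (defaults: 50%
intragenic, 80% of those intronic, 70% same-strand — the broad proportions
reported for the human genome), assigns hosts uniformly, and fills each
algorithm's prediction set independently with background probability
$\pi = 0.01$ per (miRNA, gene) pair.  A planted excess $\varepsilon$ raises
the own-host probability to $\min(1, \pi + \varepsilon)$ in one designated
algorithm (or several, for support-stratified analyses).  Defaults (2,000
genes, 300 miRNAs) give stable nulls with seconds-scale permutation tests.
The generator has no sequence-level realism: no seed-match structure, no
3'UTR lengths, no inter-algorithm correlation (real predictors correlate
strongly), and no degree heterogeneity beyond binomial fluctuation.  Passing
tests therefore demonstrate correct *counting, reshuffling and calibration*
of the statistic — not that any particular genome is enriched.

# Scaled-down study sizes

Stochastic summaries in the tests and the acceptance analysis use ensembles
of 10,000 trials (TF module) and time-averaged paths of $6\times10^6$–
$2\times10^7$ s (roughly 1,000–4,000 protein lifetimes) per grid point, with
standard errors reported throughout; permutation tests use 300–1,000
reshuffles.  These sizes were chosen so the whole analysis reruns in
minutes; all reported comparisons are resolved well beyond their standard
errors at these sizes.

# Known limitations

* miRNA action is modeled on translation only; a degradation-mode variant
  would change the switch-off delay (the de-repression boost can vanish),
  and is out of scope.
* No miRNA biogenesis delay, no RISC loading, no promoter (telegraph)
  states, no ceRNA/target-dilution effects.
* The tSL repression form and the $k_w, k_q$ interpretation are declared
  assumptions (see above).
* The LNA-based sensitivity threshold inherits the quasi-static treatment of
  input noise; it is a threshold choice, not a measured noise floor.
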