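# mirloop

Models of **gene autoregulation via intronic microRNAs** and a permutation
test for the over-representation of such circuits in regulatory networks.

Roughly half of human miRNA genes sit inside other genes, mostly in introns
and on the same strand, so they are co-transcribed with their host. When such
a miRNA also *targets* its host, the result is a minimal negative feedback
loop — an intronic-miRNA-mediated self-loop (iMSL) — whose repression acts
post-transcriptionally, on translation, rather than on the promoter. This
package asks, with tested code: what can this wiring do that a plain
transcription unit (sTF) or a transcriptional self-loop (tSL) cannot, and
how would one detect an excess of such loops in annotation plus
target-prediction data?

## The model

The host gene under an activating TF at level $q$, with mRNA $r$, intronic
miRNA $s$ and protein $p$:

$$\frac{dr}{dt} = k_r(q) - g_r r, \qquad
  \frac{ds}{dt} = k_r(q) - g_s s, \qquad
  \frac{dp}{dt} = \frac{k_p}{1+s/h}\, r - g_p p,$$

with Michaelis–Menten activation $k_r(q) = k_r\,q/(h_r+q)$ (Hill-$n$
optional). The identical production term for $r$ and $s$ *is* the
co-transcription. Comparisons are mathematically controlled: the sTF's
constant translation rate $k_{p2}$, or the tSL's feedback constant $h_{fb}$
in $k_r(q,p) = k_r\frac{q}{h_r+q}\frac{1}{1+p/h_{fb}}$, is solved so all
circuits share the same protein steady state. A master-equation version with
the full nonlinear propensities (plus the upstream TF gene $w \to q$) is
simulated exactly with Gillespie's algorithm (first-reaction and direct
schemes, C++), complemented by a linear noise approximation for fast scans.

Deterministic analyses cover switch-on/off response times
($T_{ON}/T_0$, $T_{OFF}/T_0$), ON-state robustness to transient input loss
(distance $d$), adaptation (precision $P$, sensitivity $S$) and Weber's law
(fold-change-detection error $E$). The stochastic analyses quantify how much
upstream TF noise the loop strips from the host protein,
$CV_p / CV_p^{sTF}$, over activation × repression grids. The bioinformatic
stage counts same-strand intronic miRNAs targeting their own host across
multiple prediction algorithms and tests enrichment with two reshuffling
nulls and $Z = (x - \langle x\rangle_r)/\sigma_r$, on synthetic networks
with a tunable planted excess of self-targeting.

## Worked example

```r
library(mirloop)

params <- preset("fig5")$params           # noise-setting rates, explicit TF gene
cv_two_stage(params$k_w, params$k_q, params$g_w, params$g_q)$cv_q
#> [1] 0.2105415

# noise buffering when miRNA repression halves the mean protein level,
# at intermediate promoter activation (<q>/h_r = 1)
set.seed(1)
noise_reduction_map(params, activations = 1, repressions = 0.5,
                    topology = "iMSL", method = "gillespie",
                    t_sample = 2e7)[c("cvp", "cvp_stf", "ratio", "se_ratio")]
#>          cvp    cvp_stf    ratio  se_ratio
#> 1 0.06013532 0.09356335 0.642723 0.0164143
```

The host protein's noise is `cvp = 0.060`, versus `cvp_stf = 0.094` for a
simple transcription unit producing the same mean — the self-loop removes
about 36% of the fluctuation (ratio 0.64) while only halving, not
silencing, its target.

```r
# a synthetic network with a planted excess of miRNA -> own-host links
set.seed(2)
net <- generate_network(network_generator_spec(epsilon = 0.3))
count_imsl(net, min_support = 1)$count
#> [1] 38
enrichment_test(net, "host_reshuffle", n_perm = 1000)
#> <enrichment_result> host_reshuffle | x = 38 | null 6.97 +/- 2.52 over 1000 permutations | Z = 12.30
```

38 self-loops where the reshuffled null expects ~7: the planted excess is
recovered at Z ≈ 12, while unplanted networks (`epsilon = 0`) give
|Z| ≲ 1.

The numbered scripts under `analysis/` run the full study — response-time
sweeps, robustness curves, the adaptation/Weber map, noise-buffering maps
and the enrichment analysis — each printing its findings and writing tidy
tables under `results/`:

```sh
Rscript analysis/01_response_times.R
Rscript analysis/04_noise_buffering.R --seed 1
Rscript analysis/05_enrichment.R --seed 1
```

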