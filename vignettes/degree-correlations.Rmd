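---
title: "Degree correlations, stability and stimulus detection in spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree correlations, stability and stimulus detection in spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

A recurrent cortical circuit has to stay quiet under a constant rain of
unrelated spikes, yet amplify a handful of stimulus-evoked spikes into a
detectable population event. `snncorr` studies one structural lever on this
trade-off: the correlation between each neuron's number of inputs
(in-degree) and outputs (out-degree). Four network families are compared at
identical marginal degree distributions:

* **ACOR** — anti-correlated: cells with many inputs have few outputs;
* **PCOR** — positively correlated: hub cells with many inputs *and* outputs;
* **UCOR** — uncorrelated (the random control);
* **XCOR** — a 50/50 mixture of the two correlated families.

## Structural generator

Joint degrees are drawn from a bivariate Gaussian with mean
`mu = n_exc * p` in both coordinates. The axis-aligned distribution with a
long axis `sigma_long = mu/3` and short axis `0.3 * sigma_long` is rotated by
45 degrees, which is implemented exactly as a covariance transform: equal
marginal variances `(sigma_long^2 + sigma_short^2)/2` and off-diagonal
`±(sigma_long^2 - sigma_short^2)/2`. Samples are rounded to integers and
redrawn while either coordinate is outside `[1, 2*mu - 1]` (a degree-0
neuron would not belong to the network; the upper bound mirrors the lower
one around the mean). `UCOR` uses the diagonal covariance with matched
marginals and a random permutation of the out-degree list.

Because the in- and out-stub totals of a sampled sequence rarely match, the
sequence is balanced before wiring: one stub is removed per neuron per pass
starting from the largest out-degrees and one added per neuron per pass
starting from the smallest in-degrees (mirrored when in-stubs exceed
out-stubs), until both sides meet at the midpoint of the two totals (a
`remove_only` mode reduces the excess side instead). The configuration
method then matches the k-th out-stub to the k-th randomly permuted
in-stub. Roughly 2.5 % of the raw connections duplicate an existing ordered
pair and 0.1–0.3 % are self connections; all copies of such collisions are
mutually permuted (their postsynaptic endpoints shuffled among themselves)
until the graph is simple, which preserves every neuron's in- and
out-degree exactly. When the offenders alone cannot be untangled — the
typical case is a twin duplicate — a small number of innocent edges joins
the permutation pool. We deliberately keep that pool at about two innocents
per offender: each re-wired edge collides again with ~10 % probability for
size-biased endpoints, so large pools regenerate offenders as fast as they
resolve them.

## Network and neuron model

The default network has 480 pyramidal cells (regular spiking), 60 PV
(fast-spiking) and 60 Sst (low-threshold spiking) interneurons. Pyramidal
cells connect to each other through the generated graph (probability `p`,
default 0.05), project to both interneuron classes with probability 0.5,
and receive dense inhibition (probability 0.6) from PV and Sst; Sst cells
receive no inhibition. Inhibitory strengths follow the measured relative
ratios of interneuron synaptic drive (PV outputs as reference, Sst to Pyr
0.54, Sst to PV 0.33).

Membrane dynamics are the two-variable quadratic integrate-and-reset model
(`dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)`, reset
`v <- c`, `u <- u + d` at `v >= 30`), integrated by forward Euler with a
0.05 ms membrane substep inside a 0.1 ms step for the slower variables.
Synapses are conductance based: each presynaptic spike increments a
conductance that decays with 2 ms (excitatory) or 10 ms (inhibitory), and
the current is `w * g * (E_rev - v)` with reversal potentials 0 and -80.

Each cell receives a private white-noise current. Its *mean* is frozen per
neuron at construction, drawn from a normal distribution with the printed
class variance (0.5; e.g. mean 3 for pyramidal cells, which places their
resting potential at -65) — the printed "±" is read as across-neuron
variability of the drive. Two numerical choices around this heterogeneity
matter and are worth stating explicitly:

* **Truncation at the stability boundary.** The quadratic model loses its
  stable rest not at the saddle-node (I = 4 for the pyramidal parameters)
  but already at the Hopf point `0.08 v* + 5 = a` (I ≈ 3.80 for Pyr, ≈ 0.69
  for Sst). An untruncated Gaussian would make ~8 % of pyramidal cells and a
  similar share of Sst cells intrinsic pacemakers, and the network then
  bursts periodically with no dependence on its input — cortical pyramidal
  neurons are not pacemakers at rest, so draws above the boundary (minus a
  small margin, `excitability_margin = 0.15`, which absorbs noise-assisted
  escape just below it) are rejected and redrawn.
* **Small per-step noise.** The per-step standard deviation of the
  white-noise current is 0.2–0.3 (default 0.3), so that intrinsic
  fluctuations contribute only a small fraction of the input variability;
  near the firing threshold the quadratic model lingers on a slow "ghost",
  where even moderate per-step noise would by itself light up the
  near-threshold tail of the population.

Background noise is a Poisson train of brief depolarizing events delivered
to pyramidal cells (rate quoted per neuron, amplitude 15). The amplitude is
read as the net depolarization of one event: a resting pyramidal cell sits
10 mV below its firing threshold, so one background event is suprathreshold
by design — these events model occasional *correlated* spiking volleys from
other areas, in contrast to the small-amplitude white noise. (A mode that
injects the 15 as a current for one 0.1 ms step exists, `bg_mode =
"current"`, but a 1.5 mV kick is dynamically inert and leaves the network
silent at any background rate.) Stimulation injects a current of 8 for
25 ms into up to six cells drawn from the ten pyramidal neurons whose
out-degree is closest to the mean, resampled for every stimulation.

All randomness inside the simulator comes from a private xoshiro256++
generator whose full state is part of the simulation snapshot, so
`simulate_network(..., state = s)` resumes a run bit-exactly — the paired
detection protocol below depends on this.

## Operating regime and calibration

Four wiring parameters are not fixed by first principles: the Pyr-to-
interneuron weight (`w_ei = 0.013`), the base inhibitory weight
(`w_inh = 0.6`), the per-step noise SD and the excitability margin. They
were calibrated jointly, once, so that the default network (a) is silent
when both noise sources are off and when background events are absent,
(b) fires near the 1.5 Hz homeostatic set point at 0.1 Hz background with
the recurrent weight at its 0.013 plasticity bound, and (c) shows the
noise-ignited transition from quiescence to sustained periodic bursting —
the "pathological" state in which noise continuously evokes bursts.

The regime that emerges has a sharper character than a gradual rate
increase: network bursts are *ignited*. A background event fires its
target; with the recurrent weight at 0.013, a single extra spike recruits
just enough of the most excitable cells that an inhibition-assisted rebound
oscillation (carried mainly by the Sst population's slow recruitment and
release) locks in, producing bursts every ~70-80 ms. Quiescence and
cycling coexist, and the background rate controls how quickly the cycling
state is entered. Consequences worth knowing when interpreting results
from this package:

* the quiescence-to-bursting transition sits at much lower background rates
  (~0.001-0.01 Hz per neuron) than the 0.075-0.11 Hz window along which the
  published study places it, and the ordering of ignition between the
  correlation families at matched rates is weak;
* stimulation of six near-mean-out-degree cells ignites a burst already at
  the bottom of the recurrent-strength sweep (0.015), so the burst
  probability saturates below the reported 0.023;
* detectability (ROC area) is degraded in the fully cycling state, where
  extra stimulation can disrupt rather than add to the ongoing burst.

The structural results (marginal-degree equality, summed-degree variance
ordering, path lengths, k-cores, collision statistics) do not depend on the
dynamical calibration at all, and the homeostatic operating point and the
plasticity-driven reorganization below are robust to it.

## Bursts and detection

Population activity is summarized by a spike-density trace: the raw sum of
unit-amplitude Gaussians (sigma = 2.5 ms) centered at the spike times of
the included neurons, evaluated on a 0.5 ms grid with the kernel truncated
at five sigma. A network burst is a maximal interval with density at or
above 10 — in these units that requires 13 near-coincident spikes within
5 ms, about 3 % of the 480 excitatory cells, which is the reading under
which the threshold, the kernel and the stated population fraction are
mutually consistent. The normalized alternative (density as a per-neuron
rate) is available by setting the kernel `amplitude`.

Detectability uses a paired state-reset protocol. Stimulation is applied
every 70 ms; at each window start the full state (including the noise
generator) is snapshotted, the window is simulated once without and once
with stimulation — identical noise by construction — and the baseline
end-state seeds the next window. The per-window statistic is the maximum of
the excitatory spike-density trace within the 60 ms detection window (5 ms
before stimulus onset and the final 5 ms are discarded against smoothing
leakage), stimulated neurons excluded. Sweeping a threshold over all
observed statistics gives the empirical ROC and its trapezoidal area. With
zero stimulated neurons the paired trajectories are bit-identical and the
AUC equals 0.5 exactly — a stringent end-to-end check of the snapshot
machinery that holds to machine precision, not approximately.

## Plasticity

The development experiment starts from a dense uncorrelated network (10 %
excitatory connectivity, initial weights at half the 0.013 bound) driven by
0.1 Hz background noise. Excitatory-to-excitatory synapses follow additive
pair-based plasticity implemented with the all-pairs trace scheme:
potentiation `A+ e^{-dt/tau}` when the presynaptic spike leads, depression
`A- e^{-dt/tau}` when it lags (`A+ = 0.005`, `A- = 1.05 A+`,
`tau = 20 ms`), with simultaneous spikes contributing nothing and weights
clipped to `[0, 0.013]` after every update. The sign convention follows
`dt = t_pre - t_post`: the pre-leads branch is the potentiating one, the
only reading under which the two exponential branches join consistently.
A weight-dependent variant scales potentiation by `(w/w_max)^mu`
(`mu = 0.4`) and makes depression proportional to `w/w_max`, which
removes the hard competition and yields a unimodal weight distribution.
Global homeostasis multiplies every plastic weight by
`1 + dt (R_tar - R)/tau_h` each step (`R_tar = 1.5 Hz`, `tau_h = 2 s`, the
sped-up developmental constants, applied to the excitatory-to-excitatory
weights only), with `R` the mean excitatory rate over the trailing 500 ms.
After the run, the weakest synapses are removed until exactly 5 %
connectivity remains (ties broken by synapse index).

Because slightly more depression than potentiation accrues per uncorrelated
spike pair, synapses between high-rate cells — and rate tracks in-degree in
this model — are weakened preferentially while homeostasis holds the mean
rate; pruning then removes them, lowering the out-degree of high-in-degree
cells. Every run of the default experiment ends with a negative
least-squares slope of out-degree on in-degree and a negative quadrant
statistic. Two honest caveats: the anti-correlation is reliable in sign but
shallower (slope around -0.2 to -0.4 after 20-50 s) than in an explicitly
constructed anti-correlated network, and the additive rule's weight
histogram is broadened rather than fully bimodal at these durations. The
weight-dependent variant is weaker still: its multiplicative form has a
rate-independent fixed point `w_max (A+/(alpha A-))^(1/(1-mu))` (0.92 of
the bound at the plain `alpha = 1`), towards which all weights relax, so
the pruned-degree correlation it leaves is small and seed-dependent;
raising `alpha` to move the fixed point down only shifts the tug-of-war
with homeostasis without stabilizing the anti-correlation. The experiment
is therefore evaluated at 20-30 s, where the additive rule's signal is
reliable.

## Statistics

Group summaries report mean ± SEM; two-group comparisons use the classical
pooled-variance two-sided t test (`aggregate_stats()`). Degree correlations
are quantified two ways: the least-squares regression slope of out-degree
on in-degree with its test against a horizontal line, and the quadrant
method — counts of neurons in the upper-right/lower-left (`P_n`) versus
upper-left/lower-right (`A_n`) quadrants around the sample means, boundary
points in neither, with statistic `P_n/A_n - 1`.

## Problem sizes used by the checks

The packaged tests run the full pipeline at reduced replication (tens of
networks for structural statistics, 2-3 seeds for the 20 s dynamical runs,
40 detection windows); the acceptance script uses 200 networks for the
collision statistics, 60 per family for path lengths, 15 networks for the
sensitivity sweep and 5 seeds for the 20-30 s plasticity and operating-rate
runs. Mean shortest paths and k-cores are computed with igraph; a
brute-force subgraph enumeration backs the k-core implementation in the
tests, and a dt = 0.001 ms reference integration backs the neuron model.

## Known limitations

* No spatial structure, transmission delays, or laminar organization.
* The dynamical regime is an ignition/rebound oscillator whose transition
  sits at lower background rates than the published figures; orderings that
  depend on the precise transition location (burst rate between correlation
  families at matched noise, detectability at high noise) are weak or
  absent here, while all structural and homeostatic quantities reproduce.
* Homeostasis uses one global set point; per-neuron homeostasis would
  change the competition between synapses.
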