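# rwddm

Simulator and analysis toolkit for the **Rescorla-Wagner Drift-Diffusion
Model (RWDDM)** of classical conditioning and interval timing.

Classical conditioning theories explain how associations between a
conditioned stimulus (CS) and an unconditioned stimulus (US) are learned,
but mostly ignore *when* within a trial the conditioned response (CR)
occurs; interval-timing theories explain response timing and its hallmark
timescale invariance, but say little about associative learning. The RWDDM
unifies the two: it is aimed at computational modellers and behavioural
scientists who want a single real-time mechanism for acquisition,
extinction, cue competition *and* response timing under the standard
conditioning protocols (fixed/variable-interval schedules, peak procedure,
blocking, conditioned inhibition, latent inhibition, mixed FI, compound
probes).

## The model

Each CS owns a noisy linear accumulator (timer) with adaptive drift:

- accumulation: `ΔΨ = A·Δt + m·√(A·Δt)·N(0,1)`; an interval is timed by Ψ
  crossing a fixed threshold θ. Threshold-crossing times have coefficient
  of variation `m/√θ` regardless of the interval — timescale invariance.
- slope adaptation at the trained time marker t\*:
  `ΔA = αt · A · (θ − Ψ(t*)) / Ψ(t*)`, whose fixed point is `A = θ/t*`;
  with θ = 1, `1/A` stores an exponential moving **harmonic** average of
  experienced intervals. Timing updates are driven by time markers, not
  the US, so the timer keeps adapting in extinction and preexposure.
- representation: a Gaussian receptive field over the accumulator,
  `x(Ψ) = exp(−(Ψ−θ)²/2σ²)`, maximal exactly at the remembered time.
- learning (Rescorla-Wagner, once per trial at the US / at CS offset with
  H = 0): `ΔVi = αV (λi − Σj Vj xj) xi` with the time-scaled asymptote
  `λi = H·Ai/Ψi(t*)` (US value spread over the estimated delay — the ISI
  effect follows, `V∞ ≈ H/t*`).
- responding: `CR(t) = V · x(Ψ)`, floored at 0 for report.
- optional Pearce-Hall learning-rate adaptation
  `αV(n+1) = αV(n) + γ(|δ| − αV(n))` for latent inhibition.

A protocol engine runs ten preset designs (`list_designs()`), handles
compounds (summing junction, faster-timer selection, temporal-averaging
fusion) and mixed-interval stimuli (credit to the maximally active
representation), and an analysis layer reduces traces to averaged response
curves, peak times, normalized-curve superimposition, acquisition
criteria and timing CVs.

## Worked example

Acquisition, extinction and reacquisition of a 5-s CS (80 + 100 + 80
trials; m = 0.15, αt = 0.1, αV = 0.1, H = 5):

```r
library(rwddm)
tr <- run_experiment("acquisition_extinction_reacquisition", seed = 1)
acq   <- subset(tr$reps, phase == "acquisition")
ext   <- subset(tr$reps, phase == "extinction")
reacq <- subset(tr$reps, phase == "reacquisition")

round(c(slope           = mean(tail(acq$A, 10)),
        remembered_s    = 1 / mean(tail(acq$A, 10)),
        V_plateau       = mean(tail(acq$V, 20)),
        slope_after_ext = mean(tail(ext$A, 10)),
        V_after_ext     = tail(ext$V, 1)), 3)
#>           slope    remembered_s       V_plateau slope_after_ext     V_after_ext
#>           0.213           4.694           1.128           0.206           0.000

c(acquisition   = trials_to_criterion(acq$V,   0.5, asymptote = 1),
  reacquisition = trials_to_criterion(reacq$V, 0.5, asymptote = 1))
#>   acquisition reacquisition
#>            15             8
```

The timer converges to the reinforced interval (`1/A ≈ 4.7 s` for the 5-s
CS; the few-percent overshoot is the accumulator-noise bias), associative
strength plateaus near the steady-state value `V∞ = H·A∞ ≈ 1`, and
extinction erases `V` while leaving the slope — the timing memory —
intact, which is why reacquisition reaches the half-asymptote criterion in
8 trials versus 15 in original acquisition.

Temporal averaging — a compound of stimuli trained at 10 s and 20 s peaks
near the harmonic mean `1/((1/10 + 1/20)/2) = 13.33 s`:

```r
ta <- run_experiment("temporal_averaging", seed = 1)
sapply(list(short = "S", long = "L", compound = "L+S"), function(s)
  round(peak_time(average_curve(ta, type = "peak", stimuli = s)), 2))
#>    short     long compound
#>     9.47    18.87    12.81
```

A thin command-line front-end is installed with the package
(`exec/rwddm`): `rwddm list-designs`, `rwddm run --design isi_effect
--seed 1 --reps 2 --out out/ --override fi=10`, `rwddm make-fixture`,
`rwddm analyze --run-dir out/rep-1`.

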