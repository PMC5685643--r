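# minimal hand-built trace for analysis-layer unit tests
make_trace <- function(curves, dt = 0.01, type = "peak") {
  n <- length(curves)
  structure(list(
    trials = data.frame(trial = seq_len(n), phase = "test", type = type,
                        stimuli = "A",
                        duration = dt * lengths(curves),
                        us_time = NA_real_, rule = "sum",
                        chosen = NA_character_, recorded = TRUE,
                        stringsAsFactors = FALSE),
    reps = data.frame(),
    curves = curves, dt = dt, seed = NULL, design = "handmade",
    params = list(dt = dt)), class = "rwddm_trace")
}

# run a noiseless timer for `t` seconds and return psi
noiseless_psi <- function(slope, t, dt = 0.01) slope * dt * round(t / dt)
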