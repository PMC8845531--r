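# Phenomenological atrial cell model (modified Mitchell-Schaeffer).
#
# Two variables: normalized potential v in [0,1] and recovery gate h.
# Transmembrane potential in mV is Vm = v_rest + v_amp * v.  APD is tuned by
# tau_close (per-vertex apd_scale multiplies it); excitability by an
# excitability_scale on the inward current 1/tau_in.  Default constants give
# an APD around 160 ms and, with calibrated conductivity, reentrant cycle
# lengths in the 180-220 ms range typical of remodeled atria.

#' Cell model parameter set
#'
#' @param model model id; only `"phenomenological_atrial"` is built in, but
#'   the list structure is the plug-in point for detailed ionic models.
#' @param tau_in,tau_out,tau_open,tau_close time constants (ms).
#' @param v_gate activation threshold on the normalized potential.
#' @param v_rest resting potential (mV); `v_amp` action-potential amplitude
#'   (mV).
#' @return object of class `cell_model_params`.
#' @export
cell_model_params <- function(model = "phenomenological_atrial",
                              tau_in = 0.3, tau_out = 6,
                              tau_open = 120, tau_close = 100,
                              v_gate = 0.13, v_rest = -81, v_amp = 110) {
  stopifnot(tau_in > 0, tau_out > 0, tau_open > 0, tau_close > 0)
  structure(list(model = model, tau_in = tau_in, tau_out = tau_out,
                 tau_open = tau_open, tau_close = tau_close,
                 v_gate = v_gate, v_rest = v_rest, v_amp = v_amp),
            class = "cell_model_params")
}

#' Activation threshold in mV for a parameter set
#' @param params a `cell_model_params`
#' @return threshold potential (mV)
#' @export
activation_threshold <- function(params) params$v_rest + params$v_amp * params$v_gate

# single-cell trajectory under pacing; returns the final paced cycle sampled
# on a regular phase grid (used to seed phase-distributed initial states)
cell_limit_cycle <- function(params, cl = 200, dt = 0.05, n_beats = 6,
                             n_phase = 256) {
  v <- 0; h <- 1
  n_steps <- round(n_beats * cl / dt)
  rec_from <- round((n_beats - 1) * cl / dt)
  rec_v <- numeric(n_steps - rec_from)
  rec_h <- numeric(n_steps - rec_from)
  stim_dur <- 2
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    tb <- t %% cl
    dv <- h * v * v * (1 - v) / params$tau_in - v / params$tau_out
    if (tb < stim_dur) dv <- dv + 0.6
    dh <- if (v < params$v_gate) (1 - h) / params$tau_open else
      -h / params$tau_close
    v <- min(1, max(0, v + dt * dv))
    h <- min(1, max(0, h + dt * dh))
    if (s > rec_from) {
      rec_v[s - rec_from] <- v
      rec_h[s - rec_from] <- h
    }
  }
  ph <- seq(0, 1, length.out = n_phase + 1)[-(n_phase + 1)]
  idx <- pmax(1, round(ph * length(rec_v)))
  list(phase = ph, v = rec_v[idx], h = rec_h[idx], cl = cl)
}
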