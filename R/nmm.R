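# Forward model: each source is a three-subpopulation neural mass (spiny
# stellate, pyramidal, inhibitory interneurons) with second-order synaptic
# kinetics and a centred sigmoid firing function, coupled by delayed
# extrinsic forward/backward/lateral connections. Forward afferents target
# the stellate population, backward target pyramidal and inhibitory
# populations, lateral target all three. The observed response per source is
# the pyramidal depolarisation times an observation gain. This
# parameterisation (He/Hi/tau/gamma and multiplicative exp(B) modulation) is
# the standard evoked-response formulation of the DCM literature; the
# specific constants below are its canonical values.

#' Default neural-mass parameters for a network model
#'
#' Canonical operating point: excitatory/inhibitory synaptic gains
#' He = 3.25 mV, Hi = 29.3 mV; time constants taue = 10 ms, taui = 16 ms;
#' intrinsic coupling gains gamma = 135 * (1, 0.8, 0.25, 0.25); firing
#' sigmoid 2*e0/(1+exp(r*(v0-v))) with its resting rate subtracted,
#' e0 = 0.0025/ms, r = 0.56/mV, threshold v0 = 6 mV (so rest is a damped
#' fixed point).
#' Extrinsic coupling strengths are base gains 32 (forward), 16 (backward),
#' 4 (lateral) on the edges the model's masks permit. Conduction delays are
#' fixed at 2 ms within and 16 ms between sources. The driving input is a
#' gamma-shaped bump (shape 2) at the auditory nodes, onset 60 ms,
#' dispersion 16 ms, amplitude 0.3 (firing units, /ms). The modulation
#' matrix \code{B} (log-gains, deviant condition) and the two temporal-node
#' intrinsic log-gains start at zero.
#'
#' @param model a \linkS4class{NetworkModel}; its masks determine where the
#'   extrinsic matrices are nonzero.
#' @return A named list of parameters understood by
#'   \code{\link{integrateModel}}.
#' @export
defaultNMMParams <- function(model) {
  n <- .N_NODES
  p <- list(
    He = rep(3.25, n), Hi = rep(29.3, n),
    taue = rep(10, n), taui = rep(16, n),
    gamma = 135 * c(1, 0.8, 0.25, 0.25),
    A_forward = 32 * (model@forwardMask * 1),
    A_backward = 16 * (model@backwardMask * 1),
    A_lateral = 4 * (model@lateralMask * 1),
    B = matrix(0, n, n, dimnames = list(nodeNames(), nodeNames())),
    intrinsic_mod = stats::setNames(rep(0, length(model@intrinsicNodes)),
                                    nodeNames()[model@intrinsicNodes]),
    delay_intra_ms = 2, delay_inter_ms = 16,
    input = list(onset_ms = 60, dispersion_ms = 16, amplitude = 0.3),
    obs_gain = rep(1, n),
    e0 = 0.0025, r = 0.56, v0 = 6)
  p
}

.check_params <- function(params, model) {
  with(params, {
    if (any(taue <= 0) || any(taui <= 0)) stop("time constants must be > 0")
    if (any(He <= 0) || any(Hi <= 0)) stop("synaptic gains must be > 0")
    if (delay_intra_ms < 0 || delay_inter_ms < 0) stop("delays must be >= 0")
  })
  if (any(params$A_forward[!model@forwardMask] != 0) ||
      any(params$A_backward[!model@backwardMask] != 0) ||
      any(params$A_lateral[!model@lateralMask] != 0))
    stop("extrinsic strengths outside the model's connectivity masks")
  if (any(params$B[!model@modulationMask] != 0))
    stop("B nonzero outside the model's modulation mask")
  invisible(TRUE)
}

#' Condition-specific effective coupling
#'
#' In the standard condition the extrinsic matrices are returned unchanged;
#' in the deviant condition every modulated entry is multiplied by
#' \code{exp(B)} and the intrinsic gain of the temporal nodes by the
#' exponential of their intrinsic log-gain.
#'
#' @param params parameters from \code{\link{defaultNMMParams}} (possibly
#'   modified).
#' @param model the governing \linkS4class{NetworkModel}.
#' @param condition "standard" or "deviant".
#' @return List with effective \code{A_forward}, \code{A_backward},
#'   \code{A_lateral} matrices and the per-source stellate-loop gain vector
#'   \code{gamma1}.
#' @export
conditionCouplings <- function(params, model, condition = c("standard", "deviant")) {
  condition <- match.arg(condition)
  .check_params(params, model)
  g1 <- rep(params$gamma[1], .N_NODES)
  AF <- params$A_forward; AB <- params$A_backward; AL <- params$A_lateral
  if (condition == "deviant") {
    gain <- exp(params$B) * model@modulationMask + !model@modulationMask
    AF <- AF * gain; AB <- AB * gain; AL <- AL * gain
    g1[model@intrinsicNodes] <- g1[model@intrinsicNodes] * exp(params$intrinsic_mod)
  }
  list(A_forward = AF, A_backward = AB, A_lateral = AL, gamma1 = g1)
}

# Gamma-shaped (shape 2) driving bump, peak `amplitude` at onset+dispersion.
.driving_input <- function(t, onset_ms, dispersion_ms, amplitude) {
  s <- (t - onset_ms) / dispersion_ms
  ifelse(s > 0, amplitude * s * exp(1 - s), 0)
}

#' Simulate per-condition source activity
#'
#' Integrates the delayed neural-mass network on a fine fixed-step grid
#' (\code{oversample} times the output sampling rate, Heun scheme) from rest
#' at t = 0 and returns the observed source waveforms, i.e. observation gain
#' times pyramidal depolarisation, sampled on \code{times}.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param params parameter list, see \code{\link{defaultNMMParams}}.
#' @param condition "standard" or "deviant".
#' @param times strictly increasing sample times in ms (>= 0); times before
#'   stimulus onset at 0 are held at rest.
#' @param sr output sampling rate in Hz (defines the integration step via
#'   \code{oversample}).
#' @param oversample integration substeps per output sample.
#' @return A \linkS4class{SourceResponse}.
#' @examples
#' m <- buildModelSpace()[[12]]
#' p <- defaultNMMParams(m)
#' r <- integrateModel(m, p, "standard", times = seq(0, 250, by = 3), sr = 333)
#' @export
integrateModel <- function(model, params, condition = "standard",
                           times = seq(0, 250, length.out = 84), sr = 333,
                           oversample = 4L) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  .check_params(params, model)
  cc <- conditionCouplings(params, model, condition)
  dt <- 1000 / sr / oversample
  t_end <- max(times)
  tfine <- seq(0, t_end + dt, by = dt)
  u <- .driving_input(tfine, params$input$onset_ms, params$input$dispersion_ms,
                      params$input$amplitude)
  C <- numeric(.N_NODES)
  C[model@inputNodes] <- 1
  y <- nmm_integrate_cpp(cc$A_forward, cc$A_backward, cc$A_lateral,
                         cc$gamma1, params$gamma[2], params$gamma[3],
                         params$gamma[4], params$He, params$Hi,
                         params$taue, params$taui, C, u, dt,
                         params$delay_intra_ms, params$delay_inter_ms,
                         params$e0, params$r, params$v0)
  if (!all(is.finite(y)))
    stop("integration diverged (non-finite state); parameter regime: ",
         sprintf("He=%.3g Hi=%.3g taue=%.3g taui=%.3g max|A|=%.3g max B=%.3g",
                 max(params$He), max(params$Hi), max(params$taue),
                 max(params$taui),
                 max(abs(cc$A_forward), abs(cc$A_backward), abs(cc$A_lateral)),
                 max(params$B)))
  # linear interpolation from the fine grid onto the requested times;
  # times <= 0 are at rest (zero)
  out <- matrix(0, .N_NODES, length(times),
                dimnames = list(nodeNames(), NULL))
  pos <- times >= 0
  for (j in seq_len(.N_NODES))
    out[j, pos] <- stats::approx(tfine, y[j, ], xout = times[pos])$y *
      params$obs_gain[j]
  new("SourceResponse", condition = condition, waveforms = out,
      time = as.numeric(times), sr = sr)
}
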