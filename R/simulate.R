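# Trial-level synthetic data: source epochs plus an EOG channel, generated
# from a known network model so every downstream stage can be scored against
# ground truth.

#' Configuration for synthetic subjects and cohorts
#'
#' Defaults emulate the study conditions: epochs of -100..400 ms at 333 Hz
#' time-locked to tone onset, a generating model with anterior modulation of
#' extrinsic gains by mean log-gain ln(1.5) plus temporal-node intrinsic
#' modulation ln(1.2) in the deviant condition, per-trial white source noise
#' with sd equal to \code{noise_rel} times the noiseless standard-response
#' RMS (0.7, i.e. single-trial SNR well below 1, so that averaging ~50-900
#' trials leaves a few-percent residual, as in evoked recordings), blink
#' artifacts on the EOG with 150 uV-rule-exceeding amplitude, and modest
#' inter-subject log-parameter jitter.
#'
#' @param model_id generating model id in \code{\link{buildModelSpace}}
#'   (default 12 = sparse family, anterior modulation).
#' @param b_mean mean modulatory log-gain on the generating model's
#'   modulated edges.
#' @param intrinsic_mod intrinsic log-gain modulation at the temporal nodes.
#' @param sr sampling rate, Hz.
#' @param window_ms epoch window (must contain 0..250 ms).
#' @param noise_rel per-trial noise sd as a fraction of the noiseless
#'   standard-response RMS; ignored when \code{noise_sd} is given.
#' @param noise_sd absolute per-trial noise sd in source units (mV), or NULL.
#' @param blink_prob per-epoch blink probability.
#' @param blink_amp_uV blink amplitude on the EOG channel (uV).
#' @param blink_leak leakage gain of the blink into every source channel
#'   (mV per uV).
#' @param eog_noise_uV sd of EOG background noise (uV).
#' @param n_subjects cohort size.
#' @param jitter_sd inter-subject sd on log dynamic/connection parameters.
#' @param jitter_sd_mod inter-subject sd on modulation parameters (B and
#'   intrinsic log-gains).
#' @param type_effects named list of c(amplitude factor, latency shift ms)
#'   per deviant type; synthetic conveniences applied by
#'   \code{\link{applyTypeEffects}} to per-type averaged responses so the
#'   waveform metrics have per-type structure to measure. The generative
#'   model itself has a single deviant response: all deviant trials share
#'   it, mirroring the network analysis which pools deviant types.
#' @param seed integer seed.
#' @return A validated config list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(model_id = 12L, b_mean = log(1.5),
                             intrinsic_mod = log(1.2), sr = 333,
                             window_ms = c(-100, 400), noise_rel = 0.7,
                             noise_sd = NULL, blink_prob = 0.1,
                             blink_amp_uV = 200, blink_leak = 0.002,
                             eog_noise_uV = 5, n_subjects = 12L,
                             jitter_sd = 0.1, jitter_sd_mod = 0.25,
                             type_effects = list(frequency = c(1, 0),
                                                 intensity = c(0.9, 5),
                                                 duration = c(1.1, 10),
                                                 side = c(0.95, 0),
                                                 gap = c(0.85, 15)),
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$sr <= 0) stop("sampling rate must be > 0")
  if (cfg$window_ms[1] > 0 || cfg$window_ms[2] < 250)
    stop("epoch window must contain 0-250 ms")
  if (cfg$blink_prob < 0 || cfg$blink_prob > 1)
    stop("blink_prob must be in [0, 1]")
  cfg$model_id <- as.integer(model_id)
  cfg$n_subjects <- as.integer(n_subjects)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "simulationConfig"
  cfg
}

# Generating parameters for one subject: population means (b_mean,
# intrinsic_mod on the model's masks) perturbed by log-normal jitter.
.subject_params <- function(model, cfg, jitter = TRUE) {
  p <- defaultNMMParams(model)
  p$B[model@modulationMask] <- cfg$b_mean
  p$intrinsic_mod[] <- cfg$intrinsic_mod
  if (jitter) {
    jit <- function(x, sd) x * exp(stats::rnorm(length(x), 0, sd))
    # dynamic constants vary as one subject-level draw each (a global
    # synaptic operating point), matching the granularity at which they
    # are estimated
    jit1 <- function(x, sd) x * exp(stats::rnorm(1, 0, sd))
    p$He <- jit1(p$He, cfg$jitter_sd); p$Hi <- jit1(p$Hi, cfg$jitter_sd)
    p$taue <- jit1(p$taue, cfg$jitter_sd); p$taui <- jit1(p$taui, cfg$jitter_sd)
    for (nm in c("A_forward", "A_backward", "A_lateral")) {
      nz <- p[[nm]] != 0
      p[[nm]][nz] <- jit(p[[nm]][nz], cfg$jitter_sd)
    }
    p$obs_gain <- jit(p$obs_gain, cfg$jitter_sd)
    p$input$amplitude <- jit(p$input$amplitude, cfg$jitter_sd)
    nz <- model@modulationMask
    p$B[nz] <- p$B[nz] + stats::rnorm(sum(nz), 0, cfg$jitter_sd_mod)
    p$intrinsic_mod <- p$intrinsic_mod +
      stats::rnorm(length(p$intrinsic_mod), 0, cfg$jitter_sd_mod)
  }
  p
}

# Raised-cosine blink transient (400 ms base width), unit peak.
.blink_wave <- function(t, centre_ms, width_ms = 400) {
  w <- 0.5 * (1 + cos(2 * pi * (t - centre_ms) / width_ms))
  w[abs(t - centre_ms) > width_ms / 2] <- 0
  w
}

#' Simulate trial epochs for one synthetic subject
#'
#' One epoch per non-lead-in event of the stimulus sequence: the
#' condition-appropriate noiseless source response (standard vs modulated
#' couplings; every deviant type shares the deviant response) plus i.i.d.
#' Gaussian source noise, and an EOG channel carrying background noise
#' plus occasional raised-cosine blink transients that also leak into the
#' sources. Deterministic given (\code{cfg$seed}, \code{subject}).
#'
#' @param seq a \linkS4class{StimulusSequence}.
#' @param cfg a \code{\link{simulationConfig}}.
#' @param subject subject index (>= 1).
#' @param space optional \linkS4class{ModelSpace} (built if missing).
#' @return A \linkS4class{TrialEpochs}; the generating parameters are
#'   attached as attribute \code{"groundTruth"}.
#' @export
simulateSubject <- function(seq, cfg, subject = 1L, space = NULL) {
  if (is.null(space)) space <- buildModelSpace()
  model <- space[[cfg$model_id]]
  ev <- toneEvents(seq)
  ev <- ev[!ev$is_lead_in, , drop = FALSE]
  if (nrow(ev) == 0) stop("sequence has no analysable events")
  times <- seq(cfg$window_ms[1], cfg$window_ms[2], by = 1000 / cfg$sr)
  nt <- length(times)
  subj_seed <- .derive_seed(cfg$seed, subject)

  .with_seed(subj_seed, {
    params <- .subject_params(model, cfg)
    std <- waveforms(integrateModel(model, params, "standard", times, cfg$sr))
    dev <- waveforms(integrateModel(model, params, "deviant", times, cfg$sr))
    sigma <- if (!is.null(cfg$noise_sd)) cfg$noise_sd else
      cfg$noise_rel * .rms(std[, times >= 0])

    # every deviant type shares the deviant response; labels are kept so
    # per-type averaging and bookkeeping still work downstream
    resp <- list(standard = std)
    for (ty in names(cfg$type_effects)) resp[[ty]] <- dev

    ntr <- nrow(ev)
    nch <- .N_NODES + 1L
    data <- array(0, dim = c(ntr, nch, nt))
    for (lab in unique(ev$label)) {
      base <- resp[[lab]]
      if (is.null(base)) stop("no response defined for condition ", lab)
      idx <- which(ev$label == lab)
      for (i in idx) data[i, 1:.N_NODES, ] <- base
    }
    data[, 1:.N_NODES, ] <- data[, 1:.N_NODES, ] +
      stats::rnorm(ntr * .N_NODES * nt, 0, sigma)
    data[, nch, ] <- stats::rnorm(ntr * nt, 0, cfg$eog_noise_uV)

    blink <- stats::runif(ntr) < cfg$blink_prob
    for (i in which(blink)) {
      centre <- stats::runif(1, cfg$window_ms[1], cfg$window_ms[2])
      bw <- .blink_wave(times, centre) * cfg$blink_amp_uV
      data[i, nch, ] <- data[i, nch, ] + bw
      for (j in 1:.N_NODES)
        data[i, j, ] <- data[i, j, ] + bw * cfg$blink_leak
    }

    out <- new("TrialEpochs", data = data,
               channels = c(nodeNames(), "EOG"),
               conditions = ev$label, time = times, sr = cfg$sr,
               subject = as.integer(subject))
    attr(out, "groundTruth") <- list(model_id = model@id, params = params,
                                     noise_sd = sigma, seed = subj_seed)
    out
  })
}

#' Differentiate deviant types on an averaged evoked response
#'
#' Applies per-type amplitude scaling and latency shifts to the averaged
#' waveforms of the non-standard conditions. This is a synthetic
#' convenience: the generative network model treats all deviants as one
#' condition, and these perturbations merely give the five deviant types
#' distinct mismatch amplitudes and latencies for the waveform-metrics
#' stage to measure.
#'
#' @param evoked an \linkS4class{EvokedResponse} with per-type conditions.
#' @param type_effects named list of c(amplitude factor, latency shift ms),
#'   as in \code{\link{simulationConfig}}.
#' @return The perturbed \linkS4class{EvokedResponse}.
#' @export
applyTypeEffects <- function(evoked, type_effects) {
  wf <- evoked@waveforms
  for (ty in intersect(names(wf), names(type_effects))) {
    fx <- type_effects[[ty]]
    w <- wf[[ty]]
    shifted <- t(apply(w, 1, function(v)
      stats::approx(evoked@time + fx[2], v, xout = evoked@time, rule = 2)$y))
    dimnames(shifted) <- dimnames(w)
    wf[[ty]] <- fx[1] * shifted
  }
  methods::initialize(evoked, waveforms = wf)
}

#' Simulate an evoked response directly (no trials)
#'
#' Convenience generator for inversion experiments: the subject's noiseless
#' standard and deviant responses plus white noise with sd equal to
#' \code{noise_rel} times the noiseless standard-response RMS — i.e. noise
#' at the evoked (averaged) level rather than the trial level. Subject
#' parameters are drawn exactly as in \code{\link{simulateSubject}}, so the
#' two generators share ground truth for a given (seed, subject).
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param subject subject index.
#' @param noise_rel evoked-level relative noise (default 0.1).
#' @param space optional \linkS4class{ModelSpace}.
#' @param window_ms,sr epoch window and sampling rate (defaults from cfg).
#' @return An \linkS4class{EvokedResponse} with conditions "standard" and
#'   "deviant"; generating parameters attached as attribute
#'   \code{"groundTruth"}.
#' @export
simulateEvoked <- function(cfg, subject = 1L, noise_rel = 0.1, space = NULL,
                           window_ms = cfg$window_ms, sr = cfg$sr) {
  if (is.null(space)) space <- buildModelSpace()
  model <- space[[cfg$model_id]]
  times <- seq(window_ms[1], window_ms[2], by = 1000 / sr)
  subj_seed <- .derive_seed(cfg$seed, subject)
  .with_seed(subj_seed, {
    params <- .subject_params(model, cfg)
    std <- waveforms(integrateModel(model, params, "standard", times, sr))
    dev <- waveforms(integrateModel(model, params, "deviant", times, sr))
    s <- noise_rel * .rms(std[, times >= 0])
    wf <- list(standard = std + stats::rnorm(length(std), 0, s),
               deviant = dev + stats::rnorm(length(dev), 0, s))
    out <- new("EvokedResponse", waveforms = wf, time = times, sr = sr,
               channels = nodeNames(),
               trialsUsed = c(standard = 1L, deviant = 1L),
               trialsRejected = c(standard = 0L, deviant = 0L),
               subject = as.integer(subject))
    attr(out, "groundTruth") <- list(model_id = model@id, params = params,
                                     noise_sd = s, seed = subj_seed)
    out
  })
}

#' Extract the packed true parameter vector for a simulated subject
#'
#' Packs a subject's generating parameters onto the same scale as
#' \code{\link{invertModel}} posteriors (log-gains relative to the
#' canonical values; B and intrinsic log-gains as-is), enabling direct
#' true-vs-estimated comparison.
#'
#' @param epochs_or_evoked an object carrying a \code{"groundTruth"}
#'   attribute from \code{\link{simulateSubject}} or
#'   \code{\link{simulateEvoked}}.
#' @param space optional \linkS4class{ModelSpace}.
#' @param priors \code{\link{priorSpec}} defining the packing.
#' @return Named numeric vector of true packed parameters.
#' @export
trueTheta <- function(epochs_or_evoked, space = NULL, priors = priorSpec()) {
  gt <- attr(epochs_or_evoked, "groundTruth")
  if (is.null(gt)) stop("object carries no groundTruth attribute")
  if (is.null(space)) space <- buildModelSpace()
  model <- space[[gt$model_id]]
  base <- defaultNMMParams(model)
  map <- .build_map(model, priors)
  prm <- gt$params
  th <- numeric(nrow(map))
  for (k in seq_len(nrow(map))) {
    ty <- map$type[k]
    th[k] <- switch(ty,
      He = log(prm$He[1] / base$He[1]),
      Hi = log(prm$Hi[1] / base$Hi[1]),
      taue = log(prm$taue[1] / base$taue[1]),
      taui = log(prm$taui[1] / base$taui[1]),
      input_amp = log(prm$input$amplitude / base$input$amplitude),
      A_forward = ,
      A_backward = ,
      A_lateral = log(prm[[ty]][map$i[k], map$j[k]] /
                      base[[ty]][map$i[k], map$j[k]]),
      B = prm$B[map$i[k], map$j[k]],
      intrinsic = unname(prm$intrinsic_mod[nodeNames()[map$i[k]]]),
      obs_gain = log(prm$obs_gain[map$i[k]] / base$obs_gain[map$i[k]]))
  }
  stats::setNames(th, map$name)
}

#' Simulate a synthetic cohort
#'
#' Per subject, generating parameters are the cohort parameters perturbed
#' by log-normal jitter (\code{\link{simulationConfig}}); the ground-truth
#' generating model and per-subject parameters are recorded for recovery
#' scoring.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param space a \linkS4class{ModelSpace} (built if missing).
#' @param seq_config a \code{\link{sequenceConfig}} for the stimulus
#'   sequence shared by all subjects (default: the full session design).
#' @return A list with elements \code{epochs} (list of
#'   \linkS4class{TrialEpochs}), \code{model_id}, \code{truth} (per-subject
#'   generating parameters) and \code{config}.
#' @export
simulateCohort <- function(cfg, space = NULL, seq_config = sequenceConfig()) {
  if (is.null(space)) space <- buildModelSpace()
  seq <- generateSequence(seq_config)
  epochs <- vector("list", cfg$n_subjects)
  truth <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    ep <- simulateSubject(seq, cfg, s, space)
    truth[[s]] <- attr(ep, "groundTruth")
    epochs[[s]] <- ep
  }
  list(epochs = epochs, model_id = cfg$model_id, truth = truth,
       config = cfg, sequence = seq)
}
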