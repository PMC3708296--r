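#' @import methods
NULL

.NODES <- data.frame(
  node = c("temporal.L", "temporal.R", "frontal.L", "frontal.R",
           "parietal.L", "parietal.R"),
  hemisphere = rep(c("L", "R"), 3),
  region = rep(c("temporal", "frontal", "parietal"), each = 2),
  x = c(-43, 43, -35, 35, -34, 34),
  y = c(-21, -21, 33, 33, -71, -71),
  z = c(-4, -4, 28, 28, 13, 13),
  stringsAsFactors = FALSE
)

.N_NODES <- 6L

#' Cortical node set
#'
#' The six modelled cortical sources: bilateral temporal (auditory), frontal
#' and parietal nodes with their MNI coordinates (mm).
#'
#' @return A data.frame with columns \code{node}, \code{hemisphere},
#'   \code{region}, \code{x}, \code{y}, \code{z}.
#' @examples
#' networkNodes()
#' @export
networkNodes <- function() .NODES

#' Node labels
#' @return Character vector of the six node labels, left/right temporal,
#'   frontal and parietal, in the canonical order used by all masks and
#'   waveform matrices in the package.
#' @export
nodeNames <- function() .NODES$node

.check_mask <- function(m, what) {
  msg <- character(0)
  if (!is.matrix(m) || !identical(dim(m), c(.N_NODES, .N_NODES)))
    msg <- c(msg, sprintf("%s must be a 6 x 6 matrix", what))
  else {
    if (!is.logical(m)) msg <- c(msg, sprintf("%s must be logical", what))
    if (any(diag(m))) msg <- c(msg, sprintf("%s must have an empty diagonal", what))
  }
  msg
}

#' NetworkModel: one hypothesised connectivity architecture
#'
#' An S4 container for one of the candidate network models: the family
#' ("full", "partial" or "sparse" extrinsic connectivity), the modulation
#' scheme ("all", "anterior", "posterior", "forward", "backward"), boolean
#' 6 x 6 masks for forward, backward and lateral extrinsic connections and
#' for the condition-specific modulation, the driving-input nodes and the
#' nodes whose intrinsic gain is modulated. Mask convention: entry [i, j]
#' is the connection from node j to node i.
#'
#' @slot id integer model id (1..15 for the built-in space).
#' @slot family character; connectivity family.
#' @slot scheme character; modulation scheme.
#' @slot forwardMask,backwardMask,lateralMask 6 x 6 logical masks.
#' @slot modulationMask 6 x 6 logical mask of modulated extrinsic edges.
#' @slot inputNodes integer indices of nodes receiving the driving input.
#' @slot intrinsicNodes integer indices of nodes with intrinsic modulation.
#' @export
setClass("NetworkModel",
  representation(id = "integer", family = "character", scheme = "character",
                 forwardMask = "matrix", backwardMask = "matrix",
                 lateralMask = "matrix", modulationMask = "matrix",
                 inputNodes = "integer", intrinsicNodes = "integer"),
  validity = function(object) {
    msg <- character(0)
    msg <- c(msg, .check_mask(object@forwardMask, "forwardMask"),
             .check_mask(object@backwardMask, "backwardMask"),
             .check_mask(object@lateralMask, "lateralMask"),
             .check_mask(object@modulationMask, "modulationMask"))
    if (!object@family %in% c("full", "partial", "sparse"))
      msg <- c(msg, "family must be full, partial or sparse")
    if (!object@scheme %in% c("all", "anterior", "posterior", "forward", "backward"))
      msg <- c(msg, "unknown modulation scheme")
    if (length(msg) == 0) {
      edges <- object@forwardMask | object@backwardMask | object@lateralMask
      if (any(object@modulationMask & !edges))
        msg <- c(msg, "modulationMask includes edges absent from the model")
      if (length(object@inputNodes) == 0 ||
          any(object@inputNodes < 1L | object@inputNodes > .N_NODES))
        msg <- c(msg, "inputNodes must be nonempty node indices")
    }
    if (length(msg)) msg else TRUE
  })

#' ModelSpace: the ordered set of candidate models
#'
#' @slot models list of \linkS4class{NetworkModel} objects.
#' @export
setClass("ModelSpace",
  representation(models = "list"),
  validity = function(object) {
    if (!all(vapply(object@models, is, logical(1), "NetworkModel")))
      return("all elements must be NetworkModel objects")
    ids <- vapply(object@models, function(m) m@id, integer(1))
    if (anyDuplicated(ids)) return("model ids must be unique")
    TRUE
  })

#' StimulusSequence: an ordered oddball tone sequence
#'
#' Events are one row per tone with columns \code{block}, \code{onset_s}
#' (seconds from block start), \code{label} ("standard" or a deviant type)
#' and \code{is_lead_in}.
#'
#' @slot events data.frame of tone events.
#' @slot config list; the generating \code{\link{sequenceConfig}}.
#' @export
setClass("StimulusSequence",
  representation(events = "data.frame", config = "list"),
  validity = function(object) {
    ev <- object@events
    need <- c("block", "onset_s", "label", "is_lead_in")
    if (!all(need %in% names(ev)))
      return(paste("events must have columns", paste(need, collapse = ", ")))
    for (b in unique(ev$block)) {
      on <- ev$onset_s[ev$block == b]
      if (any(diff(on) <= 0)) return("onsets must increase within a block")
    }
    TRUE
  })

#' SourceResponse: simulated source waveforms for one condition
#'
#' @slot condition character condition label.
#' @slot waveforms numeric matrix, sources x time (units mV of pyramidal
#'   depolarisation scaled by the observation gain).
#' @slot time numeric vector of sample times, ms relative to tone onset.
#' @slot sr sampling rate, Hz.
#' @export
setClass("SourceResponse",
  representation(condition = "character", waveforms = "matrix",
                 time = "numeric", sr = "numeric"),
  validity = function(object) {
    if (ncol(object@waveforms) != length(object@time))
      return("waveforms and time axis disagree")
    if (!all(is.finite(object@waveforms)))
      return("waveforms must be finite")
    TRUE
  })

#' TrialEpochs: trial-level source + EOG epochs for one subject
#'
#' @slot data numeric array, trials x channels x time. Channels are the six
#'   sources followed by "EOG".
#' @slot channels character channel names.
#' @slot conditions character per-trial condition label (standard or a
#'   deviant type).
#' @slot time numeric sample times, ms relative to tone onset.
#' @slot sr sampling rate, Hz.
#' @slot subject integer subject index.
#' @export
setClass("TrialEpochs",
  representation(data = "array", channels = "character",
                 conditions = "character", time = "numeric", sr = "numeric",
                 subject = "integer"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3) return("data must be trials x channels x time")
    if (d[1] != length(object@conditions))
      return("one condition label per trial required")
    if (d[2] != length(object@channels)) return("channel names disagree")
    if (d[3] != length(object@time)) return("time axis disagrees")
    TRUE
  })

#' EvokedResponse: per-condition averaged source waveforms
#'
#' @slot waveforms named list of channels x time matrices, one per condition.
#' @slot time numeric sample times (ms).
#' @slot sr sampling rate (Hz).
#' @slot channels character channel names.
#' @slot trialsUsed,trialsRejected named integer vectors per condition.
#' @slot subject integer subject index.
#' @export
setClass("EvokedResponse",
  representation(waveforms = "list", time = "numeric", sr = "numeric",
                 channels = "character", trialsUsed = "integer",
                 trialsRejected = "integer", subject = "integer"),
  validity = function(object) {
    if (is.null(names(object@waveforms)))
      return("waveforms must be a named list of condition matrices")
    ok <- vapply(object@waveforms, function(w)
      is.matrix(w) && ncol(w) == length(object@time) && all(is.finite(w)),
      logical(1))
    if (!all(ok)) return("each condition matrix must be finite, channels x time")
    TRUE
  })

#' InversionResult: variational-Laplace posterior and free energy
#'
#' @slot mean named numeric posterior mean (packed parameter vector).
#' @slot cov posterior covariance matrix.
#' @slot F free energy (nats).
#' @slot lambda estimated observation-noise precision.
#' @slot Ftrace numeric free-energy trace over iterations.
#' @slot converged logical.
#' @slot modelId integer id of the inverted model.
#' @slot map list; parameter packing map (internal layout).
#' @export
setClass("InversionResult",
  representation(mean = "numeric", cov = "matrix", F = "numeric",
                 lambda = "numeric", Ftrace = "numeric",
                 converged = "logical", modelId = "integer", map = "list"),
  validity = function(object) {
    if (nrow(object@cov) != length(object@mean))
      return("posterior covariance and mean disagree")
    if (max(abs(object@cov - t(object@cov))) > 1e-6 * (1 + max(abs(object@cov))))
      return("posterior covariance must be symmetric")
    TRUE
  })

#' EvidenceMatrix: subjects x models free energies
#'
#' @slot F numeric matrix of free energies, subjects in rows.
#' @slot modelIds integer column ids.
#' @slot subjectIds character row ids.
#' @slot diagnostics data.frame of per-fit diagnostics.
#' @export
setClass("EvidenceMatrix",
  representation(F = "matrix", modelIds = "integer", subjectIds = "character",
                 diagnostics = "data.frame"),
  validity = function(object) {
    if (ncol(object@F) != length(object@modelIds)) return("model ids disagree")
    if (nrow(object@F) != length(object@subjectIds)) return("subject ids disagree")
    if (ncol(object@F) < 2) return("need at least two models")
    if (any(is.nan(object@F) | is.infinite(object@F)))
      return("evidences must be finite (NA marks failed fits)")
    TRUE
  })

#' BMSResult: random-effects Bayesian model selection posterior
#'
#' @slot alpha named numeric Dirichlet concentration.
#' @slot r named numeric expected posterior probabilities.
#' @slot xp named numeric exceedance probabilities.
#' @slot level "model" or "family".
#' @slot nSamples integer Monte Carlo sample count used for xp.
#' @slot seed integer RNG seed used for xp sampling.
#' @slot alpha0 numeric prior concentration (per element).
#' @export
setClass("BMSResult",
  representation(alpha = "numeric", r = "numeric", xp = "numeric",
                 level = "character", nSamples = "integer", seed = "integer",
                 alpha0 = "numeric"),
  validity = function(object) {
    if (abs(sum(object@r) - 1) > 1e-9) return("expected probabilities must sum to 1")
    if (any(object@alpha <= 0)) return("alpha must be positive")
    if (length(object@alpha) != length(object@r) ||
        length(object@r) != length(object@xp))
      return("alpha, r, xp must have equal length")
    TRUE
  })
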