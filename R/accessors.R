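#' @rdname accessors
#' @name accessors
#' @title Accessors for mmnet S4 containers
#' @description Small accessor generics so user code never reaches into
#'   slots directly.
#' @param object an mmnet S4 object.
#' @param x an mmnet S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("toneEvents", function(object) standardGeneric("toneEvents"))
#' @rdname accessors
#' @export
setMethod("toneEvents", "StimulusSequence", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setMethod("modelId", "NetworkModel", function(object) object@id)
#' @rdname accessors
#' @export
setMethod("modelId", "InversionResult", function(object) object@modelId)

#' @rdname accessors
#' @export
setGeneric("modelFamily", function(object) standardGeneric("modelFamily"))
#' @rdname accessors
#' @export
setMethod("modelFamily", "NetworkModel", function(object) object@family)

#' @rdname accessors
#' @export
setGeneric("modulationScheme", function(object) standardGeneric("modulationScheme"))
#' @rdname accessors
#' @export
setMethod("modulationScheme", "NetworkModel", function(object) object@scheme)

#' @rdname accessors
#' @export
setGeneric("connectionMasks", function(object) standardGeneric("connectionMasks"))
#' @rdname accessors
#' @export
setMethod("connectionMasks", "NetworkModel", function(object)
  list(forward = object@forwardMask, backward = object@backwardMask,
       lateral = object@lateralMask, modulation = object@modulationMask))

#' @rdname accessors
#' @export
setGeneric("models", function(object) standardGeneric("models"))
#' @rdname accessors
#' @export
setMethod("models", "ModelSpace", function(object) object@models)

#' Extract one model from a model space
#' @param x a \linkS4class{ModelSpace}.
#' @param i model id (matched against \code{modelId}); if no id matches,
#'   \code{i} is used as a list position. For the built-in space ids and
#'   positions coincide.
#' @param j,drop,... unused.
#' @export
setMethod("[[", "ModelSpace", function(x, i, j, ...) {
  if (is.numeric(i)) {
    ids <- vapply(x@models, function(m) m@id, integer(1))
    k <- match(as.integer(i), ids)
    if (!is.na(k)) return(x@models[[k]])
  }
  x@models[[i]]
})

#' @rdname accessors
#' @export
setMethod("length", "ModelSpace", function(x) length(x@models))

#' @rdname accessors
#' @export
setGeneric("familyPartition", function(object) standardGeneric("familyPartition"))
#' @rdname accessors
#' @export
setMethod("familyPartition", "ModelSpace", function(object) {
  fam <- vapply(object@models, function(m) m@family, character(1))
  ids <- vapply(object@models, function(m) m@id, integer(1))
  stats::setNames(fam, ids)
})

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(object) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setMethod("timeAxis", "SourceResponse", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("timeAxis", "TrialEpochs", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("timeAxis", "EvokedResponse", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "SourceResponse", function(object) object@sr)
#' @rdname accessors
#' @export
setMethod("samplingRate", "TrialEpochs", function(object) object@sr)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EvokedResponse", function(object) object@sr)

#' @rdname accessors
#' @export
setGeneric("waveforms", function(object, ...) standardGeneric("waveforms"))
#' @rdname accessors
#' @export
setMethod("waveforms", "SourceResponse", function(object, ...) object@waveforms)
#' @rdname accessors
#' @param condition condition label for EvokedResponse waveforms; NULL
#'   returns the full named list.
#' @export
setMethod("waveforms", "EvokedResponse", function(object, condition = NULL, ...) {
  if (is.null(condition)) return(object@waveforms)
  if (!condition %in% names(object@waveforms))
    stop("no such condition: ", condition)
  object@waveforms[[condition]]
})

#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setMethod("epochData", "TrialEpochs", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("epochConditions", function(object) standardGeneric("epochConditions"))
#' @rdname accessors
#' @export
setMethod("epochConditions", "TrialEpochs", function(object) object@conditions)

#' @rdname accessors
#' @export
setGeneric("trialsUsed", function(object) standardGeneric("trialsUsed"))
#' @rdname accessors
#' @export
setMethod("trialsUsed", "EvokedResponse", function(object) object@trialsUsed)

#' @rdname accessors
#' @export
setGeneric("trialsRejected", function(object) standardGeneric("trialsRejected"))
#' @rdname accessors
#' @export
setMethod("trialsRejected", "EvokedResponse", function(object) object@trialsRejected)

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setMethod("freeEnergy", "InversionResult", function(object) object@F)

#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))
#' @rdname accessors
#' @export
setMethod("posteriorMean", "InversionResult", function(object) object@mean)

#' @rdname accessors
#' @export
setGeneric("posteriorCov", function(object) standardGeneric("posteriorCov"))
#' @rdname accessors
#' @export
setMethod("posteriorCov", "InversionResult", function(object) object@cov)

#' @rdname accessors
#' @export
setGeneric("evidence", function(object) standardGeneric("evidence"))
#' @rdname accessors
#' @export
setMethod("evidence", "EvidenceMatrix", function(object) {
  out <- object@F
  dimnames(out) <- list(object@subjectIds, object@modelIds)
  out
})

#' @rdname accessors
#' @export
setGeneric("exceedanceProb", function(object) standardGeneric("exceedanceProb"))
#' @rdname accessors
#' @export
setMethod("exceedanceProb", "BMSResult", function(object) object@xp)

#' @rdname accessors
#' @export
setGeneric("posteriorProb", function(object) standardGeneric("posteriorProb"))
#' @rdname accessors
#' @export
setMethod("posteriorProb", "BMSResult", function(object) object@r)

#' @rdname accessors
#' @export
setGeneric("dirichletAlpha", function(object) standardGeneric("dirichletAlpha"))
#' @rdname accessors
#' @export
setMethod("dirichletAlpha", "BMSResult", function(object) object@alpha)

setMethod("show", "NetworkModel", function(object) {
  ne <- sum(object@forwardMask) + sum(object@backwardMask) + sum(object@lateralMask)
  cat(sprintf("NetworkModel %d: %s family, %s modulation\n",
              object@id, object@family, object@scheme))
  cat(sprintf("  %d directed extrinsic edges, %d modulated; input at %s\n",
              ne, sum(object@modulationMask),
              paste(nodeNames()[object@inputNodes], collapse = ", ")))
})

setMethod("show", "ModelSpace", function(object) {
  fam <- table(vapply(object@models, function(m) m@family, character(1)))
  cat(sprintf("ModelSpace of %d models (%s)\n", length(object@models),
              paste(sprintf("%s: %d", names(fam), fam), collapse = ", ")))
})

setMethod("show", "StimulusSequence", function(object) {
  ev <- object@events
  cat(sprintf("StimulusSequence: %d events in %d block(s); %d analysed standards, %d deviants, %d lead-in\n",
              nrow(ev), length(unique(ev$block)),
              sum(!ev$is_lead_in & ev$label == "standard"),
              sum(!ev$is_lead_in & ev$label != "standard"),
              sum(ev$is_lead_in)))
})

setMethod("show", "SourceResponse", function(object) {
  cat(sprintf("SourceResponse [%s]: %d sources x %d samples, %.0f-%.0f ms @ %.0f Hz\n",
              object@condition, nrow(object@waveforms), ncol(object@waveforms),
              min(object@time), max(object@time), object@sr))
})

setMethod("show", "TrialEpochs", function(object) {
  cat(sprintf("TrialEpochs subject %d: %d trials x %d channels x %d samples (%s)\n",
              object@subject, dim(object@data)[1], dim(object@data)[2],
              dim(object@data)[3],
              paste(sprintf("%s: %d", names(table(object@conditions)),
                            table(object@conditions)), collapse = ", ")))
})

setMethod("show", "EvokedResponse", function(object) {
  cat(sprintf("EvokedResponse subject %d: conditions %s; %d samples @ %.0f Hz\n",
              object@subject, paste(names(object@waveforms), collapse = ", "),
              length(object@time), object@sr))
  if (length(object@trialsUsed))
    cat("  trials used:", paste(sprintf("%s=%d", names(object@trialsUsed),
                                        object@trialsUsed), collapse = " "), "\n")
})

setMethod("show", "InversionResult", function(object) {
  cat(sprintf("InversionResult model %d: F = %.2f nats, %d parameters, %s after %d iterations\n",
              object@modelId, object@F, length(object@mean),
              if (object@converged) "converged" else "NOT converged",
              length(object@Ftrace)))
})

setMethod("show", "EvidenceMatrix", function(object) {
  cat(sprintf("EvidenceMatrix: %d subjects x %d models (F in nats)\n",
              nrow(object@F), ncol(object@F)))
})

setMethod("show", "BMSResult", function(object) {
  cat(sprintf("BMSResult (%s level, alpha0 = %g, %d samples)\n",
              object@level, object@alpha0, object@nSamples))
  tab <- rbind(r = round(object@r, 3), xp = round(object@xp, 3))
  print(tab)
})
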