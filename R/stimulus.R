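#' Configuration for an Optimum-1 oddball tone sequence
#'
#' Defaults follow the multi-feature oddball design used for mismatch
#' responses: tones every 500 ms in three blocks, each block starting with
#' fifteen standard tones, after which standards strictly alternate with one
#' of five deviant types. With the default 600 alternating tones per block
#' the session yields exactly 900 analysed standards and 900 deviants.
#'
#' @param n_blocks number of blocks.
#' @param alternating_tones_per_block even count of post-lead-in tones per
#'   block (half standards, half deviants).
#' @param lead_in_standards standards opening each block, flagged
#'   \code{is_lead_in} and excluded from analysis counts.
#' @param soa_s stimulus-onset asynchrony in seconds.
#' @param deviant_types the five deviant labels.
#' @param seed integer seed controlling deviant ordering.
#' @return A validated config list of class \code{sequenceConfig}.
#' @export
sequenceConfig <- function(n_blocks = 3L, alternating_tones_per_block = 600L,
                           lead_in_standards = 15L, soa_s = 0.5,
                           deviant_types = c("frequency", "intensity",
                                             "duration", "side", "gap"),
                           seed = 1L) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              alternating_tones_per_block = as.integer(alternating_tones_per_block),
              lead_in_standards = as.integer(lead_in_standards),
              soa_s = soa_s, deviant_types = deviant_types,
              seed = as.integer(seed))
  if (cfg$n_blocks < 1L) stop("n_blocks must be >= 1")
  if (cfg$alternating_tones_per_block %% 2L != 0L)
    stop("alternating_tones_per_block must be even")
  if (cfg$lead_in_standards < 0L) stop("lead_in_standards must be >= 0")
  if (cfg$soa_s <= 0) stop("soa_s must be > 0")
  if (length(cfg$deviant_types) != 5L || anyDuplicated(cfg$deviant_types))
    stop("deviant_types must be 5 distinct labels")
  class(cfg) <- "sequenceConfig"
  cfg
}

# One block's deviant labels: a seeded uniform permutation per 5-deviant
# (10-tone) window, rejecting permutations whose first label repeats the
# previous window's last label, so the same deviant type never immediately
# repeats. A trailing partial window gets the head of a fresh permutation.
.block_deviants <- function(n_dev, types) {
  out <- character(n_dev)
  prev <- NA_character_
  pos <- 1L
  while (pos <= n_dev) {
    repeat {
      p <- sample(types)
      if (is.na(prev) || p[1] != prev) break
    }
    take <- min(5L, n_dev - pos + 1L)
    out[pos:(pos + take - 1L)] <- p[seq_len(take)]
    prev <- out[pos + take - 1L]
    pos <- pos + take
  }
  out
}

#' Generate an Optimum-1 stimulus sequence
#'
#' Each block opens with the lead-in standards, then alternates
#' deviant/standard; every aligned 10-tone window of the alternating stream
#' contains each of the five deviant types exactly once, and the same
#' deviant type is never immediately repeated (enforced across window
#' boundaries by rejection sampling). Deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{sequenceConfig}}.
#' @return A \linkS4class{StimulusSequence}.
#' @examples
#' seq <- generateSequence(sequenceConfig(seed = 7))
#' table(toneEvents(seq)$label[!toneEvents(seq)$is_lead_in] == "standard")
#' @export
generateSequence <- function(config) {
  if (!inherits(config, "sequenceConfig"))
    config <- do.call(sequenceConfig, config)
  if (length(unique(config$deviant_types)) < 2L && config$alternating_tones_per_block > 2L)
    stop("impossible constraint set: cannot avoid immediate deviant repeats with < 2 deviant types")
  n_dev <- config$alternating_tones_per_block %/% 2L
  evs <- vector("list", config$n_blocks)
  rng <- .with_seed(config$seed, {
    for (b in seq_len(config$n_blocks)) {
      dev <- if (n_dev > 0) .block_deviants(n_dev, config$deviant_types) else character(0)
      lab <- c(rep("standard", config$lead_in_standards),
               as.vector(rbind(dev, rep("standard", n_dev))))
      n <- length(lab)
      evs[[b]] <- data.frame(block = b,
                             onset_s = (seq_len(n) - 1L) * config$soa_s,
                             label = lab,
                             is_lead_in = seq_len(n) <= config$lead_in_standards,
                             stringsAsFactors = FALSE)
    }
  })
  new("StimulusSequence", events = do.call(rbind, evs),
      config = unclass(config))
}

#' Tone catalogue for the multi-feature oddball paradigm
#'
#' The standard tone is 75 ms with harmonic partials at 500, 1000 and
#' 1500 Hz, bilateral, with no gap. The five deviants differ in exactly one
#' feature: frequency band (550/1100/1650 Hz), intensity (+/- 6 dB),
#' duration (25 ms), side of sound source (unilateral), or a silent middle
#' 25 ms gap. Tone specs are stimulus metadata only; no audio is
#' synthesised.
#'
#' @return A data.frame with one row per tone type (standard + 5 deviants).
#' @export
toneCatalog <- function() {
  data.frame(
    label = c("standard", "frequency", "intensity", "duration", "side", "gap"),
    duration_ms = c(75, 75, 75, 25, 75, 75),
    partials_Hz = I(list(c(500, 1000, 1500), c(550, 1100, 1650),
                         c(500, 1000, 1500), c(500, 1000, 1500),
                         c(500, 1000, 1500), c(500, 1000, 1500))),
    intensity_offset_dB = c(0, 0, 6, 0, 0, 0),
    laterality = c("both", "both", "both", "both", "left", "both"),
    gap = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Write / read a stimulus sequence as a tab-separated table
#'
#' One event per row: block, onset_s, label, is_lead_in.
#'
#' @param seq a \linkS4class{StimulusSequence}.
#' @param path file path.
#' @export
writeSequence <- function(seq, path) {
  utils::write.table(toneEvents(seq), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeSequence
#' @export
readSequence <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ev$is_lead_in <- as.logical(ev$is_lead_in)
  new("StimulusSequence", events = ev, config = list())
}
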