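# Shared fixtures, built in code at test time.

the_space <- buildModelSpace()

small_seq_config <- function(seed = 3L)
  sequenceConfig(n_blocks = 1L, alternating_tones_per_block = 100L,
                 lead_in_standards = 5L, seed = seed)

# TrialEpochs built directly from matrices (bypasses the simulator), for
# preprocessing unit tests with exactly known content.
manual_epochs <- function(trial_list, eog_list = NULL, conditions = NULL,
                          sr = 333, t0 = -100) {
  nt <- ncol(trial_list[[1]])
  ntr <- length(trial_list)
  time <- t0 + (seq_len(nt) - 1) * 1000 / sr
  data <- array(0, dim = c(ntr, 7, nt))
  for (i in seq_len(ntr)) {
    data[i, 1:6, ] <- trial_list[[i]]
    if (!is.null(eog_list)) data[i, 7, ] <- eog_list[[i]]
  }
  if (is.null(conditions)) conditions <- rep("standard", ntr)
  new("TrialEpochs", data = data, channels = c(nodeNames(), "EOG"),
      conditions = conditions, time = time, sr = sr, subject = 1L)
}

# EvokedResponse from raw matrices.
manual_evoked <- function(wf, time, sr = 333) {
  wf <- lapply(wf, function(w) {
    if (is.null(rownames(w))) rownames(w) <- nodeNames()[seq_len(nrow(w))]
    w
  })
  n <- stats::setNames(rep(2L, length(wf)), names(wf))
  new("EvokedResponse", waveforms = wf, time = time, sr = sr,
      channels = rownames(wf[[1]]), trialsUsed = n,
      trialsRejected = 0L * n, subject = 1L)
}
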