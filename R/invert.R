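# Model inversion by variational Laplace: Gauss-Newton ascent with
# Levenberg-Marquardt damping on the free energy of a Gaussian posterior
# under Gaussian shrinkage priors and i.i.d. Gaussian observation noise
# whose single precision is updated by EM. Both conditions are fitted
# jointly: the standard condition uses the baseline couplings, the deviant
# condition the exp(B)-modulated ones.

#' Shrinkage priors for model inversion
#'
#' All dynamic and connection parameters are estimated as log-gains on
#' their canonical values with Normal(0, \code{scale_var}) priors;
#' modulatory log-gains (B, intrinsic) have Normal(0, \code{mod_var})
#' priors. Parameters outside a model's masks are fixed (not estimated).
#' Input onset and dispersion are fixed at their defaults.
#'
#' @param scale_var prior variance of log-scaling parameters (default
#'   1/16).
#' @param mod_var prior variance of modulatory log-gains (default 1/4).
#' @return List of class \code{priorSpec}.
#' @export
priorSpec <- function(scale_var = 1 / 16, mod_var = 1 / 4) {
  if (scale_var < 0 || mod_var < 0) stop("prior variances must be >= 0")
  structure(list(scale_var = scale_var, mod_var = mod_var),
            class = "priorSpec")
}

# Packed free-parameter map for a model: one row per parameter with its
# type, matrix indices where relevant, prior mean and variance.
.build_map <- function(model, priors = priorSpec()) {
  sv <- priors$scale_var; mv <- priors$mod_var
  nn <- nodeNames()
  rows <- list(
    data.frame(type = c("He", "Hi", "taue", "taui", "input_amp"),
               i = NA, j = NA, pmean = 0, pvar = sv, stringsAsFactors = FALSE))
  for (ty in c("A_forward", "A_backward", "A_lateral")) {
    mask <- switch(ty, A_forward = model@forwardMask,
                   A_backward = model@backwardMask,
                   A_lateral = model@lateralMask)
    w <- which(mask, arr.ind = TRUE)
    if (nrow(w))
      rows[[length(rows) + 1]] <- data.frame(type = ty, i = w[, 1], j = w[, 2],
                                             pmean = 0, pvar = sv,
                                             stringsAsFactors = FALSE)
  }
  w <- which(model@modulationMask, arr.ind = TRUE)
  rows[[length(rows) + 1]] <- data.frame(type = "B", i = w[, 1], j = w[, 2],
                                         pmean = 0, pvar = mv,
                                         stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(type = "intrinsic",
                                         i = model@intrinsicNodes, j = NA,
                                         pmean = 0, pvar = mv,
                                         stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(type = "obs_gain",
                                         i = seq_len(.N_NODES), j = NA,
                                         pmean = 0, pvar = sv,
                                         stringsAsFactors = FALSE)
  map <- do.call(rbind, rows)
  lab <- function(k) {
    if (map$type[k] %in% c("A_forward", "A_backward", "A_lateral", "B"))
      sprintf("%s[%s<-%s]", map$type[k], nn[map$i[k]], nn[map$j[k]])
    else if (map$type[k] %in% c("intrinsic", "obs_gain"))
      sprintf("%s[%s]", map$type[k], nn[map$i[k]])
    else map$type[k]
  }
  map$name <- vapply(seq_len(nrow(map)), lab, character(1))
  map
}

# Apply a packed parameter vector to the base parameter list.
# Log-gains multiply; B and intrinsic are additive log-gains already.
.apply_theta <- function(theta, map, base) {
  p <- base
  for (k in seq_along(theta)) {
    ty <- map$type[k]
    if (ty %in% c("He", "Hi", "taue", "taui"))
      p[[ty]] <- p[[ty]] * exp(theta[k])
    else if (ty == "input_amp")
      p$input$amplitude <- p$input$amplitude * exp(theta[k])
    else if (ty %in% c("A_forward", "A_backward", "A_lateral"))
      p[[ty]][map$i[k], map$j[k]] <- p[[ty]][map$i[k], map$j[k]] * exp(theta[k])
    else if (ty == "B")
      p$B[map$i[k], map$j[k]] <- p$B[map$i[k], map$j[k]] + theta[k]
    else if (ty == "intrinsic")
      p$intrinsic_mod[nodeNames()[map$i[k]]] <-
        p$intrinsic_mod[nodeNames()[map$i[k]]] + theta[k]
    else if (ty == "obs_gain")
      p$obs_gain[map$i[k]] <- p$obs_gain[map$i[k]] * exp(theta[k])
  }
  p
}

# Linear operator reproducing the deterministic preprocessing applied to
# the data (zero-phase Butterworth high/low pass plus baseline-window
# subtraction) on a given epoch time axis. Applying the same operator to
# model predictions keeps data and model on the same footing, so filter
# distortion cannot masquerade as network structure.
.preproc_operator <- function(time, sr, hp = filterSpec("highpass", 1, 6),
                              lp = filterSpec("lowpass", 40, 24),
                              baseline_ms = c(-100, 0)) {
  Tn <- length(time)
  nyq <- sr / 2
  bhp <- signal::butter(hp$order, hp$cutoff_Hz / nyq, type = "high")
  blp <- signal::butter(lp$order, lp$cutoff_Hz / nyq, type = "low")
  # the steady-state edge handling is linear in the input, so the whole
  # filter chain is captured exactly by its action on the identity basis
  P <- diag(Tn)
  for (j in seq_len(Tn))
    P[, j] <- .apply_filter(.apply_filter(P[, j], bhp, hp$zero_phase),
                            blp, lp$zero_phase)
  bsel <- time >= baseline_ms[1] & time <= baseline_ms[2]
  if (any(bsel)) P <- P - matrix(colMeans(P[bsel, , drop = FALSE]),
                                 Tn, Tn, byrow = TRUE)
  P
}

# Fast forward predictor factory. Precomputes the unit input bump, the
# fine-grid/data-grid alignment and linear matrix indices for every packed
# parameter, so each evaluation is a handful of vectorised operations plus
# two integrator calls. Returns g(theta) stacking both conditions' windowed
# source waveforms into one vector, plus a per-parameter flag for
# parameters that leave the standard condition untouched (saves one
# integration per Jacobian column).
.make_predictor <- function(model, base, map, times, sr, oversample = 4L,
                            P = NULL, full_times = NULL, W = NULL) {
  # with a preprocessing operator P, predictions are made on the full
  # epoch axis, passed through P, then windowed onto `times`
  use_P <- !is.null(P)
  sim_times <- if (use_P) full_times else times
  win_idx <- if (use_P) match(times, full_times) else seq_along(times)
  pos <- sim_times >= 0
  dt <- 1000 / sr / oversample
  nfine <- ceiling(max(sim_times) / dt) + 2L
  tfine <- (seq_len(nfine) - 1) * dt
  u_unit <- .driving_input(tfine, base$input$onset_ms, base$input$dispersion_ms, 1)
  ts_pos <- sim_times[pos]
  idx <- round(ts_pos / dt) + 1L
  aligned <- max(abs(ts_pos - (idx - 1) * dt)) < 1e-6
  # two-point linear interpolation weights from the fine grid
  lo <- pmin(pmax(floor(ts_pos / dt) + 1L, 1L), nfine - 1L)
  whi <- ts_pos / dt - (lo - 1L)
  C <- numeric(.N_NODES); C[model@inputNodes] <- 1
  dev_only <- map$type %in% c("B", "intrinsic")
  tP <- if (use_P) t(P) else NULL

  lin <- function(ty) {
    k <- which(map$type == ty)
    list(k = k, li = (map$j[k] - 1L) * .N_NODES + map$i[k])
  }
  pf <- lin("A_forward"); pb <- lin("A_backward"); pl <- lin("A_lateral")
  pB <- lin("B"); pint <- lin("intrinsic"); pobs <- lin("obs_gain")
  kHe <- which(map$type == "He"); kHi <- which(map$type == "Hi")
  kte <- which(map$type == "taue"); kti <- which(map$type == "taui")
  kamp <- which(map$type == "input_amp")
  g1_base <- rep(base$gamma[1], .N_NODES)

  g <- function(theta, std_cache = NULL) {
    He <- base$He * exp(theta[kHe]); Hi <- base$Hi * exp(theta[kHi])
    te <- base$taue * exp(theta[kte]); ti <- base$taui * exp(theta[kti])
    amp <- base$input$amplitude * exp(theta[kamp])
    obs <- base$obs_gain
    obs[map$i[pobs$k]] <- obs[map$i[pobs$k]] * exp(theta[pobs$k])
    AF <- base$A_forward; AF[pf$li] <- AF[pf$li] * exp(theta[pf$k])
    AB <- base$A_backward; AB[pb$li] <- AB[pb$li] * exp(theta[pb$k])
    AL <- base$A_lateral; AL[pl$li] <- AL[pl$li] * exp(theta[pl$k])
    gain <- matrix(1, .N_NODES, .N_NODES)
    gain[pB$li] <- exp(base$B[pB$li] + theta[pB$k])
    g1d <- g1_base
    g1d[map$i[pint$k]] <- g1d[map$i[pint$k]] *
      exp(base$intrinsic_mod + theta[pint$k])
    u <- amp * u_unit

    run <- function(AFc, ABc, ALc, g1c) {
      y <- nmm_integrate_cpp(AFc, ABc, ALc, g1c, base$gamma[2],
                             base$gamma[3], base$gamma[4], He, Hi, te, ti,
                             C, u, dt, base$delay_intra_ms,
                             base$delay_inter_ms, base$e0, base$r, base$v0)
      if (!all(is.finite(y))) return(NULL)
      samp <- if (aligned) y[, idx, drop = FALSE] else
        y[, lo, drop = FALSE] * rep(1 - whi, each = .N_NODES) +
        y[, lo + 1L, drop = FALSE] * rep(whi, each = .N_NODES)
      out <- matrix(0, .N_NODES, length(sim_times))
      out[, pos] <- samp
      if (use_P) out <- out %*% tP
      out <- out[, win_idx, drop = FALSE] * obs
      if (!is.null(W)) out <- out %*% W
      out
    }
    std <- if (is.null(std_cache)) run(AF, AB, AL, g1_base) else std_cache
    if (is.null(std)) return(NULL)
    dev <- run(AF * gain, AB * gain, AL * gain, g1d)
    if (is.null(dev)) return(NULL)
    list(y = c(std, dev), std = std)
  }
  list(g = g, dev_only = dev_only)
}

#' Variational-Laplace fit of a nonlinear Gaussian model
#'
#' Gauss-Newton/EM ascent on the variational free energy
#' F = accuracy - complexity for the model y = g(theta) + e with
#' theta ~ N(prior_mean, prior_cov) and e i.i.d. N(0, 1/lambda). The
#' posterior is the Laplace approximation N(m, S) with
#' S = (lambda J'J + prior precision)^-1; lambda is updated by EM unless
#' supplied. Levenberg-Marquardt damping is doubled (x4) whenever a
#' candidate step decreases F. For a linear g and fixed lambda the
#' converged F equals the exact log evidence.
#'
#' @param y observed data vector.
#' @param g forward function: numeric theta -> predicted vector (same
#'   length as y), or NULL on numerical failure.
#' @param prior_mean,prior_cov Gaussian prior (cov may be a diagonal
#'   matrix or vector of variances).
#' @param lambda fixed noise precision, or NULL to estimate by EM.
#' @param max_iter iteration cap (default 64).
#' @param tol convergence threshold on the free-energy change in nats
#'   (default 0.01).
#' @param h forward-difference step for the numerical Jacobian.
#' @param init optional starting point (default: the prior mean).
#' @param j_refresh recompute the numerical Jacobian every
#'   \code{j_refresh} iterations (default 1). With 2, alternate iterations
#'   reuse the previous Jacobian: steps are still accepted on the exact
#'   log joint, so stale curvature only affects step quality, at roughly
#'   half the forward-model cost. The final Jacobian, covariance and free
#'   energy are always computed at the accepted mean.
#' @return List: \code{mean}, \code{cov}, \code{F}, \code{lambda},
#'   \code{Ftrace}, \code{converged}, \code{iterations}.
#' @export
laplaceFit <- function(y, g, prior_mean, prior_cov, lambda = NULL,
                       max_iter = 64L, tol = 0.01, h = 1e-3, init = NULL,
                       j_refresh = 1L) {
  p <- length(prior_mean)
  if (is.vector(prior_cov) && !is.matrix(prior_cov))
    prior_cov <- diag(prior_cov, p)
  Pi0 <- solve(prior_cov)
  ldC0 <- determinant(prior_cov, logarithm = TRUE)$modulus
  N <- length(y)
  fixed_lambda <- !is.null(lambda)

  gwrap <- function(th) {
    out <- g(th)
    if (is.list(out)) out$y else out
  }
  m <- if (is.null(init)) prior_mean else init
  f <- gwrap(m)
  if (is.null(f)) stop("forward model failed at the starting point")
  e <- y - f
  if (!fixed_lambda) lambda <- N / max(sum(e^2), 1e-12)

  F_of <- function(e, J, S, m, lambda) {
    d <- m - prior_mean
    JS <- J %*% S
    acc <- -lambda / 2 * (sum(e^2) + sum(JS * J)) + N / 2 * log(lambda / (2 * pi))
    kl <- 0.5 * (sum(diag(Pi0 %*% S)) + drop(t(d) %*% Pi0 %*% d) - p +
                 ldC0 - determinant(S, logarithm = TRUE)$modulus)
    acc - as.numeric(kl)
  }

  jacobian <- function(m, f) {
    J <- matrix(0, N, p)
    for (k in seq_len(p)) {
      mk <- m; mk[k] <- mk[k] + h
      fk <- gwrap(mk)
      if (is.null(fk)) { mk[k] <- m[k] - h; fk <- gwrap(mk)
        if (is.null(fk)) stop("forward model failed in Jacobian")
        J[, k] <- (f - fk) / h
      } else J[, k] <- (fk - f) / h
    }
    J
  }

  Ftrace <- numeric(0)
  converged <- FALSE
  delta <- 1e-2      # LM damping (relative diagonal inflation)
  Fcur <- -Inf
  J <- NULL
  for (it in seq_len(max_iter)) {
    if (is.null(J) || (it - 1L) %% j_refresh == 0L) J <- jacobian(m, f)
    A <- lambda * crossprod(J) + Pi0
    S <- solve(A)
    if (!fixed_lambda) lambda <- N / max(sum(e^2) + sum((J %*% S) * J), 1e-12)
    Fcur <- F_of(e, J, S, m, lambda)
    Ftrace <- c(Ftrace, Fcur)
    grad <- lambda * drop(crossprod(J, e)) - drop(Pi0 %*% (m - prior_mean))
    # step acceptance on the exact log joint (independent of the local J)
    logjoint <- function(e, m) {
      d <- m - prior_mean
      -lambda / 2 * sum(e^2) - 0.5 * drop(t(d) %*% Pi0 %*% d)
    }
    Lcur <- logjoint(e, m)
    ok <- FALSE
    for (try in 1:14) {
      dm <- drop(solve(A + delta * diag(diag(A), p), grad))
      m_new <- m + dm
      f_new <- gwrap(m_new)
      if (!is.null(f_new)) {
        e_new <- y - f_new
        if (logjoint(e_new, m_new) > Lcur + 1e-10) {
          m <- m_new; f <- f_new; e <- e_new
          delta <- max(delta / 8, 1e-8)
          ok <- TRUE
          break
        }
      }
      delta <- delta * 8
    }
    if (!ok) { converged <- TRUE; break }   # no uphill step found: at optimum
    if (it > 1 && abs(Ftrace[it] - Ftrace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  # final curvature at the accepted mean
  J <- jacobian(m, f)
  A <- lambda * crossprod(J) + Pi0
  S <- solve(A)
  S <- (S + t(S)) / 2
  Ffin <- F_of(y - f, J, S, m, lambda)
  if (!is.finite(Ffin)) stop("inversion diverged: non-finite free energy")
  list(mean = m, cov = S, F = Ffin, lambda = lambda,
       Ftrace = c(Ftrace, Ffin), converged = converged, iterations = it)
}

#' Invert a network model on a subject's evoked responses
#'
#' Fits the model's neural-mass parameters to the standard and deviant
#' evoked source waveforms jointly over the analysis window (default
#' 0-250 ms) by \code{\link{laplaceFit}}, and returns posterior estimates
#' with the free-energy bound on the log model evidence.
#'
#' When the evoked object carries a preprocessing manifest (attribute
#' \code{"manifest"} from \code{\link{preprocessEpochs}}), the same
#' deterministic linear operations (zero-phase filters and baseline
#' subtraction) are applied to the model predictions before comparison, so
#' that filter distortion is not attributed to network structure. In
#' addition, data and predictions are whitened with the filter-implied
#' residual covariance (the filtering operator applied to white trial
#' noise gives residual covariance proportional to P P'), so the
#' independent-noise likelihood is well calibrated — without whitening,
#' smooth filtered noise masquerades as signal that richer models can
#' absorb.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param evoked an \linkS4class{EvokedResponse} containing "standard" and
#'   "deviant" conditions (source channels are used; EOG ignored).
#' @param priors a \code{\link{priorSpec}}.
#' @param window_ms analysis window.
#' @param max_iter,tol optimisation controls passed to
#'   \code{\link{laplaceFit}}.
#' @param lambda optional fixed noise precision.
#' @param n_starts maximum number of optimisation starts: the first is the
#'   prior mean, further starts are seeded draws around it; the fit with
#'   the highest free energy is returned. More starts make the ascent
#'   robust to local optima at proportional cost.
#' @param patience stop adding starts after this many consecutive starts
#'   without free-energy improvement (default Inf: run all
#'   \code{n_starts}).
#' @param seed seed for the extra starting points.
#' @param init optional named warm-start vector; entries are matched to
#'   this model's parameters by name (e.g. the posterior of a related
#'   model), unmatched parameters start at the prior mean. The warm start
#'   is tried in addition to the prior-mean start unless
#'   \code{prior_start = FALSE}.
#' @param prior_start include the prior-mean start (default TRUE).
#' @param oversample integration substeps per data sample for the forward
#'   model (default 2; the solution changes by well under 1 percent
#'   relative RMS on halving the step).
#' @return An \linkS4class{InversionResult}.
#' @export
invertModel <- function(model, evoked, priors = priorSpec(),
                        window_ms = c(0, 250), max_iter = 64L, tol = 0.01,
                        lambda = NULL, n_starts = 1L, seed = 1L,
                        init = NULL, prior_start = TRUE, oversample = 2L,
                        patience = Inf, j_refresh = 2L) {
  need <- c("standard", "deviant")
  if (!all(need %in% names(evoked@waveforms)))
    stop("evoked must contain standard and deviant conditions")
  sel_t <- evoked@time >= window_ms[1] & evoked@time <= window_ms[2]
  if (!any(sel_t)) stop("analysis window lies outside the evoked time axis")
  src <- match(nodeNames(), evoked@channels)
  if (anyNA(src)) stop("evoked must contain the six source channels")
  times <- evoked@time[sel_t]
  ystd <- evoked@waveforms[["standard"]][src, sel_t, drop = FALSE]
  ydev <- evoked@waveforms[["deviant"]][src, sel_t, drop = FALSE]
  y <- c(ystd, ydev)

  base <- defaultNMMParams(model)
  map <- .build_map(model, priors)
  W <- NULL
  P <- if (!is.null(attr(evoked, "manifest")))
    .preproc_operator(evoked@time, samplingRate(evoked)) else NULL
  if (!is.null(P)) {
    # residual covariance implied by filtering white trial noise is P P';
    # project onto its passband eigenspace and whiten there (the filter's
    # stopband carries neither signal nor noise and must not be weighted)
    Ce <- tcrossprod(P)[sel_t, sel_t]
    eg <- eigen(Ce, symmetric = TRUE)
    keep <- eg$values > 1e-4 * eg$values[1]
    W <- eg$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(eg$values[keep]), sum(keep))
    ystd <- ystd %*% W
    ydev <- ydev %*% W
    y <- c(ystd, ydev)
  }
  pred <- .make_predictor(model, base, map, times, samplingRate(evoked),
                          oversample = oversample, P = P,
                          full_times = evoked@time, W = W)

  # cache the standard-condition prediction across deviant-only Jacobian
  # columns via a closure around the packed forward model
  last_std <- NULL
  theta_ref <- NULL
  gfun <- function(th) {
    reuse <- !is.null(theta_ref) && !is.null(last_std) &&
      all(th[!pred$dev_only] == theta_ref[!pred$dev_only])
    out <- pred$g(th, std_cache = if (reuse) last_std else NULL)
    if (is.null(out)) return(NULL)
    last_std <<- out$std
    theta_ref <<- th
    out$y
  }

  starts <- if (prior_start || is.null(init)) list(NULL) else list()
  if (!is.null(init)) {
    iv <- map$pmean
    hit <- match(map$name, names(init))
    iv[!is.na(hit)] <- init[hit[!is.na(hit)]]
    starts <- c(starts, list(iv))
  }
  for (st in seq_len(max(1L, n_starts) - 1L))
    starts <- c(starts, list(
      .with_seed(.derive_seed(seed, st),
                 stats::rnorm(nrow(map), map$pmean, 0.5 * sqrt(map$pvar)))))
  fit <- NULL
  stale <- 0L
  for (st in seq_along(starts)) {
    cand <- tryCatch(
      laplaceFit(y, gfun, prior_mean = map$pmean, prior_cov = map$pvar,
                 lambda = lambda, max_iter = max_iter, tol = tol,
                 init = starts[[st]], j_refresh = j_refresh),
      error = function(e) if (st == 1L && length(starts) == 1L) stop(e) else NULL)
    if (!is.null(cand) && (is.null(fit) || cand$F > fit$F + 0.01)) {
      fit <- cand
      stale <- 0L
    } else stale <- stale + 1L
    if (stale >= patience) break
  }
  if (is.null(fit)) stop("all optimisation starts failed")
  new("InversionResult", mean = stats::setNames(fit$mean, map$name),
      cov = fit$cov, F = fit$F, lambda = fit$lambda, Ftrace = fit$Ftrace,
      converged = fit$converged, modelId = model@id,
      map = list(map = map, window_ms = window_ms))
}

#' Free-energy matrix over a cohort and model space
#'
#' Inverts every model for every subject. Fits are chained by warm starts
#' through the nested model structure: within each family the
#' all-connections-modulated model is fitted first and seeds the other
#' four schemes; across families the simpler family's fit seeds the next
#' richer one (sparse to partial to full). Every model still gets an
#' independent prior-mean start, and the better optimum is kept — the
#' chaining only helps the ascent find each model's own optimum, it never
#' transfers evidence between models.
#'
#' Failed inversions are recorded as NA with the failure reason in the
#' diagnostics; Bayesian model selection refuses incomplete matrices, so
#' callers must drop subjects or models explicitly. A partial run can be
#' resumed by passing its result as \code{resume_from}: completed
#' (subject, model) fits are reused.
#'
#' @param evoked_list list of \linkS4class{EvokedResponse} objects.
#' @param space a \linkS4class{ModelSpace}.
#' @param priors a \code{\link{priorSpec}}.
#' Because the free-energy surface is multimodal, a lagging family — one
#' whose best member falls more than \code{retry_gap} nats below the
#' global best — has its anchor re-optimised from up to
#' \code{retry_starts} extra seeded starting points (patience 2), and its
#' schemes re-fitted if the anchor improves. The retry applies to any
#' family that lags, so it spends effort where a stuck ascent is likely
#' without favouring any architecture.
#'
#' @param window_ms,max_iter,tol passed to \code{\link{invertModel}}.
#' @param resume_from optional previous \linkS4class{EvidenceMatrix}.
#' @param retry_gap free-energy lag (nats) that triggers the anchor retry.
#' @param retry_starts maximum extra starts for a retried anchor.
#' @param seed seed for retry starting points.
#' @param verbose print progress.
#' @return An \linkS4class{EvidenceMatrix}.
#' @export
computeEvidenceMatrix <- function(evoked_list, space, priors = priorSpec(),
                                  window_ms = c(0, 250), max_iter = 64L,
                                  tol = 0.01, resume_from = NULL,
                                  retry_gap = 30, retry_starts = 6L,
                                  seed = 1L, verbose = FALSE) {
  ns <- length(evoked_list)
  ids <- vapply(models(space), function(m) m@id, integer(1))
  Fm <- matrix(NA_real_, ns, length(ids))
  subj <- vapply(seq_len(ns), function(s) {
    sid <- evoked_list[[s]]@subject
    if (length(sid)) as.character(sid) else as.character(s)
  }, character(1))
  if (!is.null(resume_from)) {
    old <- evidence(resume_from)
    common_s <- intersect(rownames(old), subj)
    Fm[match(common_s, subj), ] <- old[common_s, as.character(ids)]
  }
  # warm-start chain: family anchors ("all" scheme) fitted first, families
  # ordered from fewest to most edges with upward seeding, then a downward
  # re-seeding pass, then the remaining schemes warm-started from their
  # family's anchor
  fams <- vapply(models(space), function(m) m@family, character(1))
  schemes <- vapply(models(space), function(m) m@scheme, character(1))
  n_edges <- vapply(models(space), function(m)
    sum(m@forwardMask) + sum(m@backwardMask) + sum(m@lateralMask), integer(1))
  fam_order <- names(sort(tapply(n_edges, fams, max)))
  anchors <- vapply(fam_order, function(f)
    which(fams == f & schemes == "all")[1], integer(1))

  diag_rows <- list()
  for (s in seq_len(ns)) {
    best <- vector("list", length(ids))   # best InversionResult per model
    fail <- character(length(ids))
    keep <- function(k, res) {
      if (inherits(res, "error")) {
        fail[k] <<- conditionMessage(res)
        return(invisible(NULL))
      }
      if (is.null(best[[k]]) || freeEnergy(res) > freeEnergy(best[[k]]))
        best[[k]] <<- res
      invisible(res)
    }
    fit1 <- function(k, init = NULL, prior_start = TRUE, n_starts = 1L,
                     patience = Inf) {
      res <- tryCatch(invertModel(space[[k]], evoked_list[[s]], priors,
                                  window_ms, max_iter, tol, init = init,
                                  prior_start = prior_start,
                                  n_starts = n_starts, patience = patience,
                                  seed = .derive_seed(seed, s * 100 + k)),
                      error = function(e) e)
      if (verbose)
        message(sprintf("subject %s model %d: F = %s", subj[s], ids[k],
                        if (inherits(res, "error")) "failed"
                        else sprintf("%.1f", freeEnergy(res))))
      keep(k, res)
      res
    }
    resumed <- !is.na(Fm[s, ])
    fit_schemes <- function(f) {
      aw <- best[[anchors[f]]]
      for (k in which(fams == fam_order[f] & schemes != "all")) {
        if (resumed[k]) next
        fit1(k, init = if (is.null(aw)) NULL else posteriorMean(aw),
             prior_start = is.null(aw))
      }
    }
    # upward pass over family anchors, then downward re-seeding; the first
    # anchor seeds the whole chain, so it gets a real multistart
    warm <- NULL
    for (f in seq_along(anchors)) {
      k <- anchors[f]
      if (!resumed[k])
        fit1(k, init = warm,
             n_starts = if (f == 1L) 8L else 1L,
             patience = if (f == 1L) 3L else Inf)
      if (!is.null(best[[k]])) warm <- posteriorMean(best[[k]])
    }
    for (f in rev(seq_along(anchors))[-1]) {
      k <- anchors[f]
      richer <- best[[anchors[f + 1]]]
      if (resumed[k] || is.null(richer) || is.null(best[[k]])) next
      fit1(k, init = posteriorMean(richer), prior_start = FALSE)
    }
    for (f in seq_along(fam_order)) fit_schemes(f)
    # targeted retry of lagging families
    Fnow <- function(k) if (resumed[k]) Fm[s, k] else
      if (is.null(best[[k]])) -Inf else freeEnergy(best[[k]])
    gbest <- max(vapply(seq_along(ids), Fnow, numeric(1)))
    for (f in seq_along(fam_order)) {
      kk <- which(fams == fam_order[f])
      if (max(vapply(kk, Fnow, numeric(1))) >= gbest - retry_gap) next
      k <- anchors[f]
      if (resumed[k]) next
      before <- Fnow(k)
      fit1(k, init = if (is.null(best[[k]])) NULL else
             posteriorMean(best[[k]]),
           prior_start = FALSE, n_starts = retry_starts, patience = 3L)
      if (Fnow(k) > before + 0.1) fit_schemes(f)
    }
    # bookkeeping
    for (k in seq_along(ids)) {
      if (resumed[k]) next
      if (is.null(best[[k]])) {
        diag_rows[[length(diag_rows) + 1]] <- data.frame(
          subject = subj[s], model_id = ids[k], F = NA, converged = FALSE,
          iterations = NA, reason = fail[k], stringsAsFactors = FALSE)
      } else {
        Fm[s, k] <- freeEnergy(best[[k]])
        diag_rows[[length(diag_rows) + 1]] <- data.frame(
          subject = subj[s], model_id = ids[k], F = freeEnergy(best[[k]]),
          converged = best[[k]]@converged,
          iterations = length(best[[k]]@Ftrace) - 1, reason = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  dg <- do.call(rbind, diag_rows)
  if (is.null(dg)) dg <- data.frame()
  new("EvidenceMatrix", F = Fm, modelIds = ids, subjectIds = subj,
      diagnostics = dg)
}
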