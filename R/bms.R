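# Group-level random-effects Bayesian model selection: variational Dirichlet
# posterior over model frequencies, expected posterior probabilities, and
# exceedance probabilities by Dirichlet Monte Carlo.

.check_evidence <- function(E) {
  Fm <- if (is(E, "EvidenceMatrix")) evidence(E) else as.matrix(E)
  if (any(!is.finite(Fm)))
    stop("evidence matrix contains non-finite entries; drop subjects or models explicitly")
  if (ncol(Fm) < 2) stop("need at least two models")
  Fm
}

# Variational update of the Dirichlet concentration: subject posteriors
# u_nk proportional to exp(F_nk + digamma(alpha_k) - digamma(sum alpha)),
# alpha = alpha0 + sum_n u_n. Iterated to |delta alpha| < 1e-4.
.dirichlet_vb <- function(Fm, alpha0, max_iter = 500L, tol = 1e-4) {
  K <- ncol(Fm)
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, K)
  alpha <- alpha0 + nrow(Fm) / K
  for (it in seq_len(max_iter)) {
    lg <- sweep(Fm, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    u <- exp(lg - apply(lg, 1, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      return(list(alpha = alpha, u = u, iterations = it))
    }
    alpha <- alpha_new
  }
  stop("Dirichlet update did not converge in ", max_iter, " iterations")
}

# Seeded Dirichlet draws (n x K) via independent gammas.
.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  g / rowSums(g)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model as a subject-level random variable with
#' Dirichlet-distributed frequencies r; the Dirichlet posterior is obtained
#' by variational updates from the subject-wise log evidences, and the
#' exceedance probability xp_k = P(r_k > r_j for all j != k) is estimated
#' by seeded Dirichlet sampling.
#'
#' @param E an \linkS4class{EvidenceMatrix} or a subjects x models matrix
#'   of log evidences (nats).
#' @param alpha0 prior concentration per model (default 1).
#' @param n_samples Monte Carlo draws for xp (default 1e6).
#' @param seed RNG seed for the xp sampling, recorded in the result.
#' @return A \linkS4class{BMSResult} (level "model").
#' @examples
#' Fm <- rbind(c(0, -5), c(0, -5))  # model 1 better by 5 nats in 2 subjects
#' rfxBMS(Fm, n_samples = 1e4)
#' @export
rfxBMS <- function(E, alpha0 = 1, n_samples = 1e6, seed = 1L) {
  Fm <- .check_evidence(E)
  if (n_samples < 1e4) stop("n_samples must be >= 1e4")
  ids <- colnames(Fm)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(Fm)))
  vb <- .dirichlet_vb(Fm, alpha0)
  alpha <- stats::setNames(vb$alpha, ids)
  r <- alpha / sum(alpha)
  xp <- .with_seed(seed, {
    draws <- .rdirichlet(n_samples, alpha)
    win <- max.col(draws, ties.method = "first")
    tabulate(win, ncol(Fm)) / n_samples
  })
  new("BMSResult", alpha = alpha, r = r, xp = stats::setNames(xp, ids),
      level = "model", nSamples = as.integer(n_samples),
      seed = as.integer(seed), alpha0 = alpha0)
}

#' Family-level random-effects model selection
#'
#' Families are compared with the prior re-balanced so each family carries
#' equal prior mass regardless of size: each model's prior concentration is
#' \code{alpha0_family / family size}. Family expected probabilities and
#' exceedance probabilities are obtained by summing sampled model
#' frequencies over family members within each Dirichlet draw.
#'
#' @param E evidence matrix as in \code{\link{rfxBMS}}.
#' @param partition named character vector mapping model id (column) to
#'   family label, e.g. \code{familyPartition(space)}.
#' @param alpha0_family total prior concentration per family (default 1).
#' @param n_samples,seed as in \code{\link{rfxBMS}}.
#' @return A \linkS4class{BMSResult} (level "family").
#' @export
familyBMS <- function(E, partition, alpha0_family = 1, n_samples = 1e6,
                      seed = 1L) {
  Fm <- .check_evidence(E)
  ids <- colnames(Fm)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(Fm)))
  fam <- partition[ids]
  if (anyNA(fam)) stop("partition must cover every model in the evidence matrix")
  fams <- unique(fam)
  sizes <- table(fam)
  alpha0 <- alpha0_family / as.numeric(sizes[fam])
  vb <- .dirichlet_vb(Fm, alpha0)
  alpha <- vb$alpha
  agg <- function(x) vapply(fams, function(f) sum(x[fam == f]), numeric(1))
  r_fam <- agg(alpha / sum(alpha))
  xp <- .with_seed(seed, {
    draws <- .rdirichlet(n_samples, alpha)
    fd <- vapply(fams, function(f)
      rowSums(draws[, fam == f, drop = FALSE]), numeric(n_samples))
    win <- max.col(fd, ties.method = "first")
    tabulate(win, length(fams)) / n_samples
  })
  new("BMSResult", alpha = stats::setNames(agg(alpha), fams),
      r = stats::setNames(r_fam, fams), xp = stats::setNames(xp, fams),
      level = "family", nSamples = as.integer(n_samples),
      seed = as.integer(seed), alpha0 = alpha0_family)
}

#' Model comparison within one family
#'
#' Restricts the evidence matrix to the family's member models and runs
#' \code{\link{rfxBMS}} on the restriction — the second stage of the
#' hierarchical (family then model) comparison.
#'
#' @param E evidence matrix.
#' @param partition model id to family mapping.
#' @param family family label to restrict to (must have >= 2 members).
#' @param alpha0,n_samples,seed as in \code{\link{rfxBMS}}.
#' @return A \linkS4class{BMSResult} over the family's members.
#' @export
withinFamilyBMS <- function(E, partition, family, alpha0 = 1,
                            n_samples = 1e6, seed = 1L) {
  Fm <- .check_evidence(E)
  ids <- colnames(Fm)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(Fm)))
  member <- ids[partition[ids] == family & !is.na(partition[ids])]
  if (length(member) < 2)
    stop("family ", family, " has fewer than 2 members")
  rfxBMS(Fm[, member, drop = FALSE], alpha0 = alpha0,
         n_samples = n_samples, seed = seed)
}

#' Fixed-effects group log evidence
#'
#' Column sums of the subject-wise log evidences (group Bayes factors),
#' reported alongside the random-effects results as a diagnostic; never a
#' substitute for them.
#'
#' @param E evidence matrix.
#' @return Named numeric vector of summed log evidences per model.
#' @export
ffxLogGroupEvidence <- function(E) {
  Fm <- .check_evidence(E)
  ids <- colnames(Fm)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(Fm)))
  stats::setNames(colSums(Fm), ids)
}
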