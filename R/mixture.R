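# Gaussian-mixture decomposition of effect-score distributions for variants
# of uncertain significance (VUS).
#
# Two routes are provided. The free two-component fit models the unlabeled
# score distribution as w1 N(mu1, sd1) + w2 N(mu2, sd2) via EM; the
# higher-mean (less negative) component is read as the likely-benign class.
# The fixed-class mixture instead freezes each component at the empirical
# mean/s.d. of labeled benign and pathogenic scores and maximizes the
# unlabeled likelihood over the single mixing weight.

# run code under a local RNG state, restoring the caller's state after
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Deterministic given `seed`: initialization splits the scores at their
#' median, followed by `n_restarts - 1` randomly jittered restarts whose
#' randomness is governed by `seed`; the fit with the best log-likelihood is
#' kept. Components are ordered so that `means[1] > means[2]` (benign-like
#' component first).
#'
#' @param scores Numeric vector (>= 10 finite values with nonzero spread).
#' @param seed Integer seed for the random restarts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of initializations (first is the median split).
#' @param min_sd Lower bound on component s.d. guarding degenerate
#'   collapse.
#' @return List of class `gmm_fit`: `means`, `sds`, `weights` (sum to 1),
#'   `log_likelihood`, `trajectory` (per-iteration log-likelihoods of the
#'   winning restart), `n_iterations`, `converged`.
#' @export
fit_two_component_gmm <- function(scores, seed = 1L, tol = 1e-8,
                                  max_iter = 500L, n_restarts = 5L,
                                  min_sd = 1e-3) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 10L) stop("need >= 10 finite scores", call. = FALSE)
  if (pop_sd(scores) < 1e-12) {
    stop("degenerate input: scores have (near) zero spread", call. = FALSE)
  }
  inits <- list(median_split_init(scores))
  if (n_restarts > 1L) {
    jittered <- with_seed(seed, {
      lapply(seq_len(n_restarts - 1L), function(i) jitter_init(scores))
    })
    inits <- c(inits, jittered)
  }
  best <- NULL
  for (init in inits) {
    fit <- em_two_gaussian(scores, init, tol = tol, max_iter = max_iter,
                           min_sd = min_sd)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  ord <- order(best$means, decreasing = TRUE)  # benign-like (higher mean) first
  structure(list(means = best$means[ord], sds = best$sds[ord],
                 weights = best$weights[ord],
                 log_likelihood = best$log_likelihood,
                 trajectory = best$trajectory,
                 n_iterations = best$n_iterations,
                 converged = best$converged),
            class = "gmm_fit")
}

median_split_init <- function(x) {
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0L) hi <- max(x)
  list(means = c(mean(hi), mean(lo)),
       sds = c(max(pop_sd(hi), 1e-2), max(pop_sd(lo), 1e-2)),
       weights = c(0.5, 0.5))
}

jitter_init <- function(x) {
  s <- pop_sd(x)
  m <- mean(x)
  w <- stats::runif(1, 0.2, 0.8)
  list(means = m + c(1, -1) * stats::runif(2, 0.2, 1.5) * s,
       sds = rep(max(s / 2, 1e-2), 2), weights = c(w, 1 - w))
}

em_two_gaussian <- function(x, init, tol, max_iter, min_sd) {
  mu <- init$means; sd_ <- pmax(init$sds, min_sd); w <- init$weights
  ll_old <- -Inf
  trajectory <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], sd_[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd_[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trajectory <- c(trajectory, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- d1 / tot
    n1 <- sum(r); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # one component emptied
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sd_ <- pmax(c(sqrt(sum(r * (x - mu[1])^2) / n1),
                  sqrt(sum((1 - r) * (x - mu[2])^2) / n2)), min_sd)
    w <- c(n1, n2) / length(x)
  }
  list(means = mu, sds = sd_, weights = w,
       log_likelihood = trajectory[length(trajectory)],
       trajectory = trajectory, n_iterations = it, converged = converged)
}

#' Benign/pathogenic fractions from a two-component fit
#'
#' The benign fraction is the mixing weight of the higher-mean (less
#' negative) component, the pathogenic fraction that of the lower-mean one.
#'
#' @param fit A `gmm_fit` from [fit_two_component_gmm()].
#' @return List with `benign_fraction` and `pathogenic_fraction`
#'   (summing to 1).
#' @export
estimate_class_fractions <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  list(benign_fraction = fit$weights[1],
       pathogenic_fraction = fit$weights[2])
}

#' Fixed-class mixture of labeled score distributions
#'
#' Each class component is a Gaussian frozen at the mean and population
#' s.d. of the corresponding labeled scores; the single mixing weight is
#' then chosen to maximize the likelihood of the unlabeled scores. With
#' fixed components this likelihood is concave in the weight, so the EM
#' iteration and a golden-section search agree; both are available.
#'
#' @param unlabeled_scores Scores to decompose.
#' @param benign_scores,pathogenic_scores Labeled reference scores.
#' @param method `"em"` (default) or `"golden"` (golden-section search on
#'   the log-likelihood).
#' @param tol Convergence tolerance on the weight.
#' @param max_iter Iteration cap.
#' @return List of class `fixed_mixture_fit`: `benign_fraction`,
#'   `pathogenic_fraction`, component `means`/`sds` (benign first),
#'   `log_likelihood`, `n_iterations`, `converged`.
#' @export
fit_fixed_class_mixture <- function(unlabeled_scores, benign_scores,
                                    pathogenic_scores,
                                    method = c("em", "golden"),
                                    tol = 1e-10, max_iter = 10000L) {
  method <- match.arg(method)
  x <- unlabeled_scores[is.finite(unlabeled_scores)]
  stopifnot(length(x) >= 1L, length(benign_scores) >= 2L,
            length(pathogenic_scores) >= 2L)
  mu <- c(mean(benign_scores), mean(pathogenic_scores))
  sd_ <- c(pop_sd(benign_scores), pop_sd(pathogenic_scores))
  if (any(sd_ < 1e-12)) {
    stop("labeled class with zero spread", call. = FALSE)
  }
  db <- stats::dnorm(x, mu[1], sd_[1])
  dp <- stats::dnorm(x, mu[2], sd_[2])
  loglik <- function(w) {
    mix <- w * db + (1 - w) * dp
    mix[mix == 0] <- .Machine$double.xmin
    sum(log(mix))
  }
  it <- 0L
  converged <- FALSE
  if (method == "em") {
    w <- 0.5
    while (it < max_iter) {
      it <- it + 1L
      num <- w * db
      r <- num / (num + (1 - w) * dp)
      w_new <- mean(r)
      if (abs(w_new - w) <= tol) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
  } else {
    opt <- stats::optimize(loglik, c(0, 1), maximum = TRUE, tol = tol)
    w <- opt$maximum
    converged <- TRUE
  }
  structure(list(benign_fraction = w, pathogenic_fraction = 1 - w,
                 means = mu, sds = sd_, log_likelihood = loglik(w),
                 n_iterations = it, converged = converged),
            class = "fixed_mixture_fit")
}
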