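# Constrained three-component Gaussian mixture, fit per gene by EM.
#
# Model: tumor expression x_i ~ sum_j pi_j N(mu_j, sigma^2), j = 1..3, with
# mu_1 <= mu_2 <= mu_3 and a single shared sigma; every normal sample is a
# draw from component 2, which anchors "middle" to the normal population.
# The joint log likelihood is
#   LL = sum_tumor log( sum_j pi_j f(x; mu_j, sigma) )
#      + sum_normal log f(x; mu_2, sigma).

#' Construct and validate mixture parameters
#'
#' @param pi Length-3 non-negative mixing proportions summing to 1.
#' @param mu Length-3 component means, non-decreasing.
#' @param sigma Shared standard deviation, > 0.
#' @return A list of class `mixture_params`.
#' @export
mixture_params <- function(pi, mu, sigma) {
  stopifnot(length(pi) == 3, length(mu) == 3, length(sigma) == 1)
  if (any(pi < -1e-8) || abs(sum(pi) - 1) > 1e-8) {
    stop("mixing proportions must be non-negative and sum to 1")
  }
  if (mu[1] > mu[2] + 1e-12 || mu[2] > mu[3] + 1e-12) {
    stop("component means must satisfy mu1 <= mu2 <= mu3")
  }
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(pi = as.numeric(pi), mu = as.numeric(mu),
                 sigma = as.numeric(sigma)),
            class = "mixture_params")
}

#' Joint log likelihood of tumor and normal expression under the mixture
#'
#' Tumor values contribute through the full three-component mixture; normal
#' values contribute only through the middle component's density.
#'
#' @param x_tumor,x_normal Numeric vectors of log-scale expression values.
#' @param params A [mixture_params()] object.
#' @return The log likelihood (scalar).
#' @export
tm_log_likelihood <- function(x_tumor, x_normal, params) {
  if (params$sigma <= 0) stop("sigma must be positive")
  lt <- .log_mixture_density(x_tumor, params)
  ln <- stats::dnorm(x_normal, params$mu[2], params$sigma, log = TRUE)
  sum(lt) + sum(ln)
}

# log( sum_j pi_j f(x; mu_j, sigma) ) per tumor value, in log space
.log_mixture_density <- function(x, params) {
  lf <- .log_weighted_densities(x, params$mu, params$sigma,
                                log(pmax(params$pi, .Machine$double.xmin)))
  m <- pmax(lf[, 1], lf[, 2], lf[, 3])
  m + log(exp(lf[, 1] - m) + exp(lf[, 2] - m) + exp(lf[, 3] - m))
}

# n x 3 matrix of log f(x; mu_j, sigma)
.log_densities <- function(x, mu, sigma) {
  c0 <- -log(sigma) - 0.918938533204672741780329736406  # log(sqrt(2*pi))
  cbind(c0 - 0.5 * ((x - mu[1]) / sigma)^2,
        c0 - 0.5 * ((x - mu[2]) / sigma)^2,
        c0 - 0.5 * ((x - mu[3]) / sigma)^2)
}

# n x 3 matrix of log(w_j) + log f(x; mu_j, sigma)
.log_weighted_densities <- function(x, mu, sigma, lw) {
  ld <- .log_densities(x, mu, sigma)
  ld[, 1] <- ld[, 1] + lw[1]
  ld[, 2] <- ld[, 2] + lw[2]
  ld[, 3] <- ld[, 3] + lw[3]
  ld
}

#' E-step: posterior membership weights of the tumor samples
#'
#' In `standard` weighting the responsibility of component j for sample i is
#' `pi_j f(x_i; mu_j, sigma) / sum_k pi_k f(x_i; mu_k, sigma)` (the usual
#' mixture posterior). In `paper_literal` weighting the mixing proportions
#' are omitted and the responsibilities are plain density ratios
#' `f(x_i; mu_j, sigma) / sum_k f(x_i; mu_k, sigma)`.
#'
#' Computation is done in log space; in the (extremely rare) case that all
#' three densities underflow for a sample, that sample is hard-assigned to
#' the component with the nearest mean.
#'
#' @param x_tumor Numeric vector of tumor expression values.
#' @param params A [mixture_params()] object.
#' @param weighting `"standard"` or `"paper_literal"`.
#' @return Matrix (length(x_tumor) x 3) with rows summing to 1.
#' @export
tm_e_step <- function(x_tumor, params,
                      weighting = c("standard", "paper_literal")) {
  weighting <- match.arg(weighting)
  lw <- if (weighting == "standard") {
    log(pmax(params$pi, .Machine$double.xmin))
  } else {
    c(0, 0, 0)
  }
  lf <- .log_weighted_densities(x_tumor, params$mu, params$sigma, lw)
  m <- pmax(lf[, 1], lf[, 2], lf[, 3])
  bad <- !is.finite(m)
  if (any(bad)) {
    # all densities underflown: nearest mean wins
    nearest <- apply(abs(outer(x_tumor[bad], params$mu, "-")), 1, which.min)
    lf[bad, ] <- -Inf
    lf[cbind(which(bad), nearest)] <- 0
    m[bad] <- 0
  }
  g <- exp(lf - m)
  g / rowSums(g)
}

#' M-step: constrained maximizer of the mixture parameters
#'
#' Mixing proportions are responsibility column sums over the number of
#' tumor samples. Each mean is the responsibility-weighted tumor mean, with
#' all normal values entering the middle component's numerator and
#' denominator. If the unconstrained means violate the ordering
#' `mu1 <= mu2 <= mu3`, the offending adjacent means are pooled into their
#' common weighted average (components 1-2, 2-3, or all three, depending on
#' which inequalities fail); if a pooled pair still violates the remaining
#' inequality, all three are pooled. The shared sigma pools the
#' responsibility-weighted tumor residuals with the normal residuals around
#' the middle mean, and is floored at `sigma_floor`.
#'
#' @param x_tumor,x_normal Numeric vectors of expression values.
#' @param gamma Responsibility matrix from [tm_e_step()], rows summing to 1.
#' @param prev_mu Means from the previous iteration; a component with total
#'   responsibility numerically zero keeps its previous mean.
#' @param sigma_floor Lower bound for sigma, > 0.
#' @return A [mixture_params()] object.
#' @export
tm_m_step <- function(x_tumor, x_normal, gamma, prev_mu,
                      sigma_floor = 1e-6) {
  upd <- .m_step_core(x_tumor, x_normal, gamma[, 1], gamma[, 2], gamma[, 3],
                      prev_mu, sigma_floor)
  mixture_params(upd$pi, upd$mu, upd$sigma)
}

# constrained M-step on responsibility columns; returns a plain list
.m_step_core <- function(x, x_normal, g1, g2, g3, prev_mu, sigma_floor) {
  n_t <- length(x)
  n_n <- length(x_normal)
  N <- c(sum(g1), sum(g2), sum(g3))
  num <- c(sum(g1 * x), sum(g2 * x) + sum(x_normal), sum(g3 * x))
  den <- c(N[1], N[2] + n_n, N[3])

  mu <- ifelse(den > 1e-12, num / den, prev_mu)

  pool <- function(j) sum(num[j]) / sum(den[j])
  v12 <- mu[1] > mu[2]
  v23 <- mu[2] > mu[3]
  if (v12 && v23) {
    mu[1] <- mu[2] <- mu[3] <- pool(1:3)
  } else if (v12) {
    mu[1] <- mu[2] <- pool(1:2)
    if (mu[2] > mu[3]) mu[1] <- mu[2] <- mu[3] <- pool(1:3)
  } else if (v23) {
    mu[2] <- mu[3] <- pool(2:3)
    if (mu[1] > mu[2]) mu[1] <- mu[2] <- mu[3] <- pool(1:3)
  }

  resid_t <- sum(g1 * (x - mu[1])^2) + sum(g2 * (x - mu[2])^2) +
    sum(g3 * (x - mu[3])^2)
  resid_n <- sum((x_normal - mu[2])^2)
  sigma <- max(sqrt((resid_t + resid_n) / (n_t + n_n)), sigma_floor)

  list(pi = N / n_t, mu = mu, sigma = sigma)
}

#' Decide whether a fitted mixture is trimodal
#'
#' A gene is trimodal when both mean inequalities are strict
#' (`mu2 - mu1 > tol` and `mu3 - mu2 > tol`) and every mixing proportion
#' exceeds 0.01.
#'
#' @param params A [mixture_params()] object (converged fit).
#' @param tol Strictness tolerance for the mean inequalities.
#' @return Logical flag.
#' @export
check_trimodality <- function(params, tol = 1e-8) {
  (params$mu[2] - params$mu[1] > tol) &&
    (params$mu[3] - params$mu[2] > tol) &&
    all(params$pi > 0.01)
}

#' Mode cutoffs between adjacent mixture components
#'
#' The cutoff between components j and j+1 is the expression value where the
#' pi-weighted component densities are equal:
#' `c12 = (mu1^2 - mu2^2 - 2 sigma^2 log(pi1/pi2)) / (2 (mu1 - mu2))`, and
#' analogously for `c23`. When the closed form falls outside the bracketing
#' means (possible for very unequal proportions or large sigma), the cutoff
#' falls back to the 10% (respectively 90%) empirical quantile of the tumor
#' values (type-7 quantile) and the corresponding flag is set.
#'
#' @param params A trimodal [mixture_params()] object.
#' @param x_tumor Tumor expression values (used only for the fallbacks).
#' @return List with `c12`, `c23`, `c12_fallback`, `c23_fallback`.
#' @export
compute_cutoffs <- function(params, x_tumor) {
  mu <- params$mu; pi <- params$pi; s2 <- params$sigma^2
  if (abs(mu[1] - mu[2]) < 1e-12 || abs(mu[2] - mu[3]) < 1e-12) {
    stop("cutoffs are undefined when adjacent means coincide")
  }
  c12 <- (mu[1]^2 - mu[2]^2 - 2 * s2 * log(pi[1] / pi[2])) / (2 * (mu[1] - mu[2]))
  c23 <- (mu[2]^2 - mu[3]^2 - 2 * s2 * log(pi[2] / pi[3])) / (2 * (mu[2] - mu[3]))
  c12_fallback <- c12 < mu[1] || c12 > mu[2]
  c23_fallback <- c23 < mu[2] || c23 > mu[3]
  if (c12_fallback) c12 <- stats::quantile(x_tumor, 0.10, names = FALSE, type = 7)
  if (c23_fallback) c23 <- stats::quantile(x_tumor, 0.90, names = FALSE, type = 7)
  list(c12 = c12, c23 = c23,
       c12_fallback = c12_fallback, c23_fallback = c23_fallback)
}

#' Hard-assign tumor samples to low/middle/high modes
#'
#' Values below `c12` are low, values above `c23` are high, everything else
#' (including values exactly equal to a cutoff) is middle.
#'
#' @param x_tumor Tumor expression values.
#' @param cutoffs List with `c12 < c23`, e.g. from [compute_cutoffs()].
#' @return List with `labels` (factor low/middle/high, one per sample, in
#'   input order) and `empirical_pi` (observed mode proportions).
#' @export
assign_modes <- function(x_tumor, cutoffs) {
  stopifnot(cutoffs$c12 < cutoffs$c23)
  lab <- ifelse(x_tumor < cutoffs$c12, "low",
                ifelse(x_tumor > cutoffs$c23, "high", "middle"))
  labels <- factor(lab, levels = c("low", "middle", "high"))
  list(labels = labels,
       empirical_pi = as.numeric(table(labels)) / length(x_tumor))
}

#' Fit the normal-anchored trimodal mixture to one gene by EM
#'
#' Alternates [tm_e_step()] and [tm_m_step()] from a deterministic start
#' (means at the 10th/50th/90th percentiles of the pooled tumor and normal
#' values, proportions (0.15, 0.70, 0.15), sigma at the pooled standard
#' deviation) until the log-likelihood change drops below `tol` or
#' `max_iter` is reached. Optionally runs additional random restarts and
#' keeps the best log likelihood. On convergence the fit is classified as
#' trimodal or not ([check_trimodality()]); trimodal fits also carry the
#' mode cutoffs, hard assignments and empirical mode proportions.
#'
#' @param x_tumor,x_normal Numeric vectors; at least `min_tumor` and
#'   `min_normal` finite values respectively.
#' @param weighting Responsibility weighting, see [tm_e_step()]. With
#'   `"standard"` the log likelihood is non-decreasing across iterations;
#'   `"paper_literal"` omits the mixing proportions from the E-step and
#'   carries no ascent guarantee.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param restarts Number of additional random starts (0 = deterministic
#'   start only).
#' @param seed Seed for the random restarts; ignored when `restarts = 0`.
#' @param min_tumor,min_normal Minimum sample counts required to fit.
#' @param gene_id Optional gene identifier carried into the result.
#' @return Object of class `trimodal_fit`: `params`, `loglik_trace`,
#'   `loglik`, `converged`, `n_iter`, `trimodal`, and (when trimodal)
#'   `cutoffs`, `labels`, `empirical_pi`.
#' @export
fit_trimodal_em <- function(x_tumor, x_normal,
                            weighting = c("standard", "paper_literal"),
                            tol = 1e-6, max_iter = 500,
                            restarts = 0, seed = NULL,
                            min_tumor = 10, min_normal = 2,
                            gene_id = NA_character_) {
  weighting <- match.arg(weighting)
  x_tumor <- as.numeric(x_tumor)
  x_normal <- as.numeric(x_normal)
  if (!all(is.finite(x_tumor)) || !all(is.finite(x_normal))) {
    stop("expression values must be finite; exclude genes with missing values")
  }
  if (length(x_tumor) < min_tumor || length(x_normal) < min_normal) {
    stop("too few samples to fit (need >= ", min_tumor, " tumor and >= ",
         min_normal, " normal values)")
  }
  pooled <- c(x_tumor, x_normal)
  sigma_floor <- max(1e-3 * diff(range(pooled)), .Machine$double.eps)

  starts <- list(stats::quantile(pooled, c(0.10, 0.50, 0.90), names = FALSE))
  if (restarts > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    for (r in seq_len(restarts)) {
      q <- sort(stats::runif(3))
      starts[[r + 1L]] <- sort(stats::quantile(pooled, q, names = FALSE))
    }
  }

  best <- NULL
  for (mu0 in starts) {
    run <- .em_run(x_tumor, x_normal, mu0, weighting, tol, max_iter, sigma_floor)
    if (is.null(run)) next
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best)) {
    return(structure(list(gene_id = gene_id, params = NULL,
                          loglik_trace = numeric(), loglik = NA_real_,
                          converged = FALSE, n_iter = 0L, trimodal = FALSE,
                          unfittable = TRUE,
                          cutoffs = NULL, labels = NULL, empirical_pi = NULL),
                     class = "trimodal_fit"))
  }

  trimodal <- check_trimodality(best$params)
  cutoffs <- labels <- empirical_pi <- NULL
  if (trimodal) {
    cutoffs <- compute_cutoffs(best$params, x_tumor)
    asg <- assign_modes(x_tumor, cutoffs)
    labels <- asg$labels
    empirical_pi <- asg$empirical_pi
  }
  structure(list(gene_id = gene_id, params = best$params,
                 loglik_trace = best$trace, loglik = best$loglik,
                 converged = best$converged, n_iter = best$n_iter,
                 trimodal = trimodal, unfittable = FALSE,
                 cutoffs = cutoffs, labels = labels,
                 empirical_pi = empirical_pi),
            class = "trimodal_fit")
}

# EM inner loop. Per iteration the unweighted log densities are computed
# once and shared between the log likelihood of the current parameters and
# the responsibilities, so the loop does the work of tm_e_step /
# tm_m_step / tm_log_likelihood without recomputing densities; the
# composition is asserted equivalent in the test suite. The recorded trace
# entry i is the log likelihood of the parameters after i - 1 updates, and
# the last entry always corresponds to the returned parameters.
.em_run <- function(x_tumor, x_normal, mu0, weighting, tol, max_iter,
                    sigma_floor) {
  sigma0 <- max(stats::sd(c(x_tumor, x_normal)), sigma_floor)
  params <- tryCatch(mixture_params(c(0.15, 0.70, 0.15), sort(mu0), sigma0),
                     error = function(e) NULL)
  if (is.null(params)) return(NULL)
  mu <- params$mu; pi <- params$pi; sigma <- params$sigma
  standard <- weighting == "standard"
  c_norm <- -0.918938533204672741780329736406  # -log(sqrt(2*pi))
  trace <- numeric(max_iter + 1L)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    c0 <- c_norm - log(sigma)
    d1 <- c0 - 0.5 * ((x_tumor - mu[1]) / sigma)^2
    d2 <- c0 - 0.5 * ((x_tumor - mu[2]) / sigma)^2
    d3 <- c0 - 0.5 * ((x_tumor - mu[3]) / sigma)^2
    lw <- log(pmax(pi, .Machine$double.xmin))
    l1 <- d1 + lw[1]; l2 <- d2 + lw[2]; l3 <- d3 + lw[3]
    m <- pmax(l1, l2, l3)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m) + exp(l3 - m))) +
      sum(c0 - 0.5 * ((x_normal - mu[2]) / sigma)^2)
    if (!is.finite(ll)) return(NULL)
    trace[iter + 1L] <- ll
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    iter <- iter + 1L
    if (standard) {
      g1 <- exp(l1 - m); g2 <- exp(l2 - m); g3 <- exp(l3 - m)
    } else {
      m_ <- pmax(d1, d2, d3)
      g1 <- exp(d1 - m_); g2 <- exp(d2 - m_); g3 <- exp(d3 - m_)
    }
    gs <- g1 + g2 + g3
    upd <- .m_step_core(x_tumor, x_normal, g1 / gs, g2 / gs, g3 / gs,
                        mu, sigma_floor)
    mu <- upd$mu; pi <- upd$pi; sigma <- upd$sigma
  }
  list(params = mixture_params(pi, mu, sigma),
       trace = trace[seq_len(iter + 1L)],
       loglik = trace[iter + 1L], converged = converged, n_iter = iter)
}

#' @export
print.trimodal_fit <- function(x, ...) {
  cat("Trimodal mixture fit", if (!is.na(x$gene_id)) paste0("for ", x$gene_id),
      "\n")
  if (isTRUE(x$unfittable)) {
    cat("  unfittable (non-finite likelihood)\n")
    return(invisible(x))
  }
  cat(sprintf("  mu    = (%.4f, %.4f, %.4f)\n", x$params$mu[1], x$params$mu[2],
              x$params$mu[3]))
  cat(sprintf("  pi    = (%.4f, %.4f, %.4f)\n", x$params$pi[1], x$params$pi[2],
              x$params$pi[3]))
  cat(sprintf("  sigma = %.4f\n", x$params$sigma))
  cat(sprintf("  loglik = %.4f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  cat("  trimodal:", x$trimodal, "\n")
  if (x$trimodal) {
    cat(sprintf("  cutoffs: c12 = %.4f%s, c23 = %.4f%s\n",
                x$cutoffs$c12, if (x$cutoffs$c12_fallback) " (quantile fallback)" else "",
                x$cutoffs$c23, if (x$cutoffs$c23_fallback) " (quantile fallback)" else ""))
    cat(sprintf("  empirical pi = (%.3f, %.3f, %.3f)\n", x$empirical_pi[1],
                x$empirical_pi[2], x$empirical_pi[3]))
  }
  invisible(x)
}
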