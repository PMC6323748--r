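test_that("log likelihood matches a term-by-term summation oracle", {
  set.seed(21)
  for (rep in 1:5) {
    p <- random_params()
    xt <- rnorm(30, sample(p$mu, 30, replace = TRUE, prob = p$pi), p$sigma)
    xn <- rnorm(8, p$mu[2], p$sigma)
    expect_equal(tm_log_likelihood(xt, xn, p),
                 oracle_loglik(xt, xn, p$pi, p$mu, p$sigma),
                 tolerance = 1e-12)
  }
})

test_that("log likelihood degenerate cases: single density and normal-term additivity", {
  # single tumor value at the middle mean with all weight on component 2
  p <- mixture_params(c(0, 1, 0), c(-1, 0, 1), 1)
  expect_equal(tm_log_likelihood(0, numeric(0), p), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  # appending a normal sample at mu2 adds exactly log f(mu2; mu2, sigma)
  p2 <- mixture_params(c(0.2, 0.5, 0.3), c(-2, 0.5, 3), 1.3)
  xt <- c(-2.2, 0.4, 2.9)
  base <- tm_log_likelihood(xt, numeric(0), p2)
  expect_equal(tm_log_likelihood(xt, p2$mu[2], p2),
               base - log(p2$sigma * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_error(tm_log_likelihood(0, 0, list(pi = c(0, 1, 0), mu = c(-1, 0, 1),
                                            sigma = -1)),
               "sigma")
})

test_that("responsibilities match direct density ratios in both weighting modes", {
  set.seed(22)
  p <- random_params()
  x <- rnorm(40, 0, 3)
  g_std <- tm_e_step(x, p, "standard")
  g_lit <- tm_e_step(x, p, "paper_literal")
  for (i in seq_along(x)) {
    f <- dnorm(x[i], p$mu, p$sigma)
    expect_equal(g_std[i, ], p$pi * f / sum(p$pi * f), tolerance = 1e-12)
    expect_equal(g_lit[i, ], f / sum(f), tolerance = 1e-12)
  }
  expect_equal(rowSums(g_std), rep(1, 40), tolerance = 1e-8)
})

test_that("responsibilities respect symmetry and tail dominance", {
  p <- mixture_params(c(1, 1, 1) / 3, c(-2, 0, 2), 1.4)
  g <- tm_e_step(0, p, "standard")
  expect_equal(g[1, 1], g[1, 3], tolerance = 1e-12)
  g_tail <- tm_e_step(-50, p, "standard")
  expect_equal(g_tail[1, 1], 1, tolerance = 1e-10)
})

test_that("M-step reduces to group means for hard responsibilities", {
  x <- c(-5, -4, 0.2, 0.1, -0.1, 4, 5, 6)
  gamma <- matrix(0, 8, 3)
  gamma[cbind(1:8, c(1, 1, 2, 2, 2, 3, 3, 3))] <- 1
  p <- tm_m_step(x, numeric(0), gamma, prev_mu = c(-4, 0, 5))
  expect_equal(p$mu, c(mean(x[1:2]), mean(x[3:5]), mean(x[6:8])))
  expect_equal(p$pi, c(2, 3, 3) / 8)
})

test_that("M-step floors sigma on zero-variance input", {
  gamma <- matrix(rep(c(0, 1, 0), each = 2), 2, 3)
  p <- tm_m_step(c(0, 0), 0, gamma, prev_mu = c(0, 0, 0), sigma_floor = 1e-3)
  expect_equal(p$mu, c(0, 0, 0))
  expect_equal(p$sigma, 1e-3)
})

test_that("M-step pools means exactly per the ordering-violation rules", {
  set.seed(23)
  # responsibilities engineered so component 1's weighted mean exceeds
  # component 2's (high values loaded onto component 1)
  x <- c(5, 6, 7, -1, 0, 1, 8, 9, 10, 11)
  xn <- c(-0.5, 0.5)
  gamma <- matrix(0.001, 10, 3)
  gamma[1:3, 1] <- 0.998
  gamma[4:6, 2] <- 0.998
  gamma[7:10, 3] <- 0.998
  gamma <- gamma / rowSums(gamma)
  num <- colSums(gamma * x); den <- colSums(gamma)
  num[2] <- num[2] + sum(xn); den[2] <- den[2] + length(xn)
  stopifnot(num[1] / den[1] > num[2] / den[2])  # case applies
  pooled <- sum(num[1:2]) / sum(den[1:2])       # weighted-average oracle
  p <- tm_m_step(x, xn, gamma, prev_mu = c(-1, 0, 1))
  expect_equal(p$mu[1], pooled, tolerance = 1e-12)
  expect_equal(p$mu[2], pooled, tolerance = 1e-12)
  expect_gt(p$mu[3], p$mu[2])
  expect_false(anyNA(p$mu))
})

test_that("zero-responsibility component keeps its previous mean, never NaN", {
  gamma <- cbind(0, c(1, 1, 1), 0)
  p <- tm_m_step(c(-0.1, 0, 0.1), numeric(0), gamma, prev_mu = c(-3, 0, 3))
  expect_equal(p$mu, c(-3, 0, 3))
  expect_false(anyNA(unlist(p)))
})

test_that("trimodality requires strict ordering and proportions above 1%", {
  expect_false(check_trimodality(mixture_params(c(0.3, 0.3, 0.4), c(0, 0, 1), 1)))
  expect_false(check_trimodality(
    mixture_params(c(0.005, 0.5, 0.495), c(-1, 0, 1), 1)))
  expect_true(check_trimodality(
    mixture_params(c(0.2, 0.5, 0.3), c(-4, 0, 3), 1)))
})

test_that("cutoffs sit where adjacent weighted densities cross", {
  # equal adjacent proportions: midpoint between the means
  p <- mixture_params(c(1, 1, 1) / 3, c(-2, 0, 2), 1)
  cut <- compute_cutoffs(p, seq(-3, 3, length.out = 50))
  expect_equal(cut$c12, -1, tolerance = 1e-12)
  expect_equal(cut$c23, 1, tolerance = 1e-12)
  expect_false(cut$c12_fallback || cut$c23_fallback)

  # unequal proportions: agree with a root-finding oracle on the density
  # crossing equation pi_j f_j(c) = pi_{j+1} f_{j+1}(c)
  set.seed(24)
  for (rep in 1:10) {
    p <- mixture_params(rdirichlet1(), sort(rnorm(3, sd = 3)), runif(1, 0.5, 1.5))
    if (!check_trimodality(p)) next
    cut <- compute_cutoffs(p, seq(min(p$mu), max(p$mu), length.out = 100))
    if (!cut$c12_fallback) {
      root <- uniroot(function(z) p$pi[1] * dnorm(z, p$mu[1], p$sigma) -
                        p$pi[2] * dnorm(z, p$mu[2], p$sigma),
                      lower = p$mu[1], upper = p$mu[2], tol = 1e-12)$root
      expect_equal(cut$c12, root, tolerance = 1e-8)
    }
    if (!cut$c23_fallback) {
      root <- uniroot(function(z) p$pi[2] * dnorm(z, p$mu[2], p$sigma) -
                        p$pi[3] * dnorm(z, p$mu[3], p$sigma),
                      lower = p$mu[2], upper = p$mu[3], tol = 1e-12)$root
      expect_equal(cut$c23, root, tolerance = 1e-8)
    }
  }
})

test_that("out-of-bracket cutoffs fall back to the 10%/90% tumor quantiles", {
  # large sigma pushes the closed-form c12 below mu1
  p <- mixture_params(c(0.05, 0.90, 0.05), c(-1, 0, 1), 2)
  x <- seq(-4, 4, length.out = 41)
  raw_c12 <- (p$mu[1]^2 - p$mu[2]^2 - 2 * p$sigma^2 * log(p$pi[1] / p$pi[2])) /
    (2 * (p$mu[1] - p$mu[2]))
  stopifnot(raw_c12 < p$mu[1])
  cut <- compute_cutoffs(p, x)
  expect_true(cut$c12_fallback)
  expect_equal(cut$c12, quantile(x, 0.10, names = FALSE, type = 7))
  expect_true(cut$c23_fallback)
  expect_equal(cut$c23, quantile(x, 0.90, names = FALSE, type = 7))

  expect_error(compute_cutoffs(list(pi = c(0.3, 0.3, 0.4), mu = c(0, 0, 1),
                                    sigma = 1), x),
               "coincide")
})

test_that("mode assignment is a pure cutoff comparison", {
  cut <- list(c12 = -1, c23 = 1)
  a <- assign_modes(c(-2, 0, 2), cut)
  expect_equal(as.character(a$labels), c("low", "middle", "high"))
  # boundary values go to the middle mode
  expect_equal(as.character(assign_modes(c(-1, 1), cut)$labels),
               c("middle", "middle"))
  # all below c12
  expect_equal(assign_modes(c(-5, -4, -3), cut)$empirical_pi, c(1, 0, 0))
  # counting oracle and permutation invariance
  set.seed(25)
  x <- rnorm(200)
  a <- assign_modes(x, cut)
  expect_equal(a$empirical_pi,
               c(sum(x < -1), sum(x >= -1 & x <= 1), sum(x > 1)) / 200)
  perm <- sample(200)
  expect_equal(as.character(assign_modes(x[perm], cut)$labels),
               as.character(a$labels)[perm])
})

test_that("EM fit recovers the reference three-mode simulation", {
  sim <- simulate_mixture_gene(sim_config(), seed = 42)
  fit <- fit_trimodal_em(sim$x_tumor, sim$x_normal)
  expect_true(fit$converged)
  expect_true(fit$trimodal)
  expect_true(all(abs(fit$params$mu - c(-4, 0, 3)) < 0.3))
  expect_lt(abs(fit$params$sigma - 1), 0.1)
  expect_lt(abs(fit$params$pi[1] - 0.2), 0.06)
  # cutoff equality invariant at the returned fit
  with(fit$params, {
    expect_equal(pi[1] * dnorm(fit$cutoffs$c12, mu[1], sigma),
                 pi[2] * dnorm(fit$cutoffs$c12, mu[2], sigma),
                 tolerance = 1e-8)
  })
})

test_that("the fused EM loop equals composing the public E- and M-steps", {
  set.seed(26)
  g <- random_gene(80, 12)
  pooled <- c(g$x_tumor, g$x_normal)
  sigma_floor <- max(1e-3 * diff(range(pooled)), .Machine$double.eps)
  params <- mixture_params(c(0.15, 0.70, 0.15),
                           quantile(pooled, c(0.10, 0.50, 0.90), names = FALSE),
                           max(sd(pooled), sigma_floor))
  for (i in 1:7) {
    gamma <- tm_e_step(g$x_tumor, params, "standard")
    params <- tm_m_step(g$x_tumor, g$x_normal, gamma, params$mu, sigma_floor)
  }
  fit <- fit_trimodal_em(g$x_tumor, g$x_normal, tol = 0, max_iter = 7)
  expect_equal(fit$params$mu, params$mu, tolerance = 1e-12)
  expect_equal(fit$params$pi, params$pi, tolerance = 1e-12)
  expect_equal(fit$params$sigma, params$sigma, tolerance = 1e-12)
  expect_equal(fit$n_iter, 7)
})

test_that("log likelihood never decreases under standard weighting", {
  set.seed(27)
  for (rep in 1:20) {
    g <- random_gene()
    fit <- fit_trimodal_em(g$x_tumor, g$x_normal, max_iter = 200)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("paper-literal weighting runs and returns ordered means", {
  sim <- simulate_mixture_gene(sim_config(), seed = 5)
  fit <- fit_trimodal_em(sim$x_tumor, sim$x_normal, weighting = "paper_literal")
  expect_true(!is.unsorted(fit$params$mu))
  expect_true(fit$trimodal)
  expect_true(all(abs(fit$params$mu - c(-4, 0, 3)) < 0.3))
})

test_that("fit refuses unusable gene vectors", {
  expect_error(fit_trimodal_em(c(1, NA, 3, rep(0, 10)), c(0, 0)), "finite")
  expect_error(fit_trimodal_em(rnorm(5), rnorm(5)), "too few")
})

test_that("random restarts are reproducible and never worse than the default start", {
  sim <- simulate_mixture_gene(sim_config(), seed = 9)
  f0 <- fit_trimodal_em(sim$x_tumor, sim$x_normal)
  f1 <- fit_trimodal_em(sim$x_tumor, sim$x_normal, restarts = 3, seed = 123)
  f2 <- fit_trimodal_em(sim$x_tumor, sim$x_normal, restarts = 3, seed = 123)
  expect_identical(f1$params, f2$params)
  expect_gte(f1$loglik, f0$loglik - 1e-8)
})
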