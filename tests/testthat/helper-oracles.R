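# Independent oracles used across the suite. These are deliberately naive
# (term-by-term sums, textbook formulas, exhaustive enumeration) and share
# no code with the implementation paths they check.

# brute-force joint log likelihood: literal term-by-term summation
oracle_loglik <- function(x_tumor, x_normal, pi, mu, sigma) {
  s <- 0
  for (x in x_tumor) {
    s <- s + log(sum(sapply(1:3, function(j) pi[j] * dnorm(x, mu[j], sigma))))
  }
  for (x in x_normal) s <- s + log(dnorm(x, mu[2], sigma))
  s
}

# textbook Cochran-Armitage trend z: x successes of n trials per ordered
# category with scores s; positive z = success fraction rises with score
oracle_ca_z <- function(x, n, s) {
  N <- sum(n)
  pbar <- sum(x) / N
  num <- sum(x * s) - pbar * sum(n * s)
  den <- sqrt(pbar * (1 - pbar) * (sum(n * s^2) - sum(n * s)^2 / N))
  num / den
}

# upper-tail hypergeometric P(X >= k) by direct summation of tail terms
oracle_hyper_tail <- function(k, N, K, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# random valid mixture parameters with well-separated means
random_params <- function() {
  mu <- sort(rnorm(3, sd = 3))
  pi <- as.numeric(rdirichlet1())
  mixture_params(pi, mu, runif(1, 0.5, 2))
}

rdirichlet1 <- function() {
  g <- rgamma(3, shape = 2)
  g / sum(g)
}

# small random gene vector for property tests
random_gene <- function(n_tumor = 60, n_normal = 10) {
  mu <- sort(rnorm(3, sd = 2.5))
  sizes <- as.vector(stats::rmultinom(1, n_tumor, prob = c(0.25, 0.5, 0.25)))
  list(x_tumor = rnorm(n_tumor, rep(mu, times = sizes), sd = 1),
       x_normal = rnorm(n_normal, mu[2], sd = 1))
}
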