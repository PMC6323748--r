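# Synthetic cohorts with the statistical structure the model assumes:
# per-gene tumor expression as an ordered three-component equal-variance
# Gaussian mixture with the normal population drawn from the middle
# component; exponential survival with elevated hazard in the outer modes;
# ordinal grade 1-3 from a proportional-odds model with a mode-dependent
# shift.

#' Simulation configuration
#'
#' Defaults reproduce the reference simulation used to validate the EM fit:
#' tumor samples 100/250/150 drawn from Gaussian components with means
#' (-4, 0, 3) and shared standard deviation 1, plus 50 normal samples from
#' the middle component.
#'
#' @param n_tumor Length-3 counts of tumor samples per (low, middle, high)
#'   mode.
#' @param n_normal Number of normal samples (middle component).
#' @param mu True component means, increasing.
#' @param sigma True shared standard deviation.
#' @param hazard_ratios Length-2 hazard ratios (low, high) vs the middle
#'   mode; >= 1 for risk genes.
#' @param baseline_hazard Middle-mode event rate per year.
#' @param censor_frac Target fraction of samples censored by the
#'   independent censoring process (exponential, rate calibrated against
#'   the middle-mode hazard).
#' @param grade_trend Log-odds shift toward higher grade for low/high-mode
#'   samples in the proportional-odds grade model.
#' @param grade_base Baseline grade-1/2/3 probabilities for middle-mode
#'   samples.
#' @param n_null_genes Number of unlinked unimodal genes in a screen cohort.
#' @param n_planted Number of planted trimodal risk genes.
#' @param seed Master seed; every generator is reproducible given the
#'   config.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_tumor = c(100, 250, 150), n_normal = 50,
                       mu = c(-4, 0, 3), sigma = 1,
                       hazard_ratios = c(low = 3, high = 3),
                       baseline_hazard = 0.1, censor_frac = 0.2,
                       grade_trend = 1.5, grade_base = c(0.20, 0.45, 0.35),
                       n_null_genes = 200, n_planted = 1, seed = 1L) {
  stopifnot(length(n_tumor) == 3, all(n_tumor > 0), n_normal > 0,
            length(mu) == 3, !is.unsorted(mu), sigma > 0,
            length(hazard_ratios) == 2, all(hazard_ratios >= 1),
            baseline_hazard > 0, censor_frac >= 0, censor_frac < 1,
            length(grade_base) == 3, abs(sum(grade_base) - 1) < 1e-8)
  structure(list(n_tumor = n_tumor, n_normal = n_normal, mu = mu,
                 sigma = sigma, hazard_ratios = hazard_ratios,
                 baseline_hazard = baseline_hazard, censor_frac = censor_frac,
                 grade_trend = grade_trend, grade_base = grade_base,
                 n_null_genes = n_null_genes, n_planted = n_planted,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one deterministic sub-stream per (master seed, index); kept below 2^31
.stream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

#' Simulate one gene's expression under the trimodal mixture
#'
#' Tumor values are drawn per mode from `N(mu_j, sigma^2)`, normal values
#' from the middle component `N(mu_2, sigma^2)`. The returned true labels
#' allow recovery scoring.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return List: `x_tumor`, `x_normal`, `labels_true` (factor
#'   low/middle/high, aligned with `x_tumor`).
#' @export
simulate_mixture_gene <- function(config = sim_config(), seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  labs <- rep(c("low", "middle", "high"), times = config$n_tumor)
  mus <- rep(config$mu, times = config$n_tumor)
  x_tumor <- stats::rnorm(sum(config$n_tumor), mean = mus, sd = config$sigma)
  x_normal <- stats::rnorm(config$n_normal, mean = config$mu[2],
                           sd = config$sigma)
  list(x_tumor = x_tumor, x_normal = x_normal,
       labels_true = factor(labs, levels = c("low", "middle", "high")))
}

#' Simulate clinical outcomes driven by true mode labels
#'
#' Event times are exponential with rate `baseline_hazard * HR(mode)`;
#' censoring is an independent exponential whose rate is calibrated so that
#' a middle-mode sample is censored with probability `censor_frac`, plus
#' administrative censoring at 20 years. Grade 1-3 comes from a
#' proportional-odds model: middle-mode samples follow `grade_base`, while
#' low/high-mode samples have their cumulative log-odds shifted by
#' `grade_trend` toward higher grades.
#'
#' @param labels Factor of true mode labels (low/middle/high).
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @param sample_ids Optional sample ids; defaults to `T1..Tn`.
#' @return Data.frame: `sample_id`, `time_years`, `event`, `grade`.
#' @export
simulate_clinical <- function(labels, config = sim_config(), seed = NULL,
                              sample_ids = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- length(labels)
  if (is.null(sample_ids)) sample_ids <- paste0("T", seq_len(n))
  hr <- c(low = unname(config$hazard_ratios[1]), middle = 1,
          high = unname(config$hazard_ratios[2]))[as.character(labels)]
  rate <- config$baseline_hazard * hr
  t_event <- stats::rexp(n, rate = rate)
  if (config$censor_frac > 0) {
    # P(censor first) = rc / (rc + r_event); calibrate against the middle mode
    rc <- config$baseline_hazard * config$censor_frac / (1 - config$censor_frac)
    t_cens <- stats::rexp(n, rate = rc)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens, 20)
  event <- as.integer(t_event <= t_cens & t_event <= 20)

  alpha <- stats::qlogis(cumsum(config$grade_base)[1:2])  # cumulative logits
  eta <- ifelse(as.character(labels) == "middle", 0, config$grade_trend)
  u <- stats::runif(n)
  p1 <- stats::plogis(alpha[1] - eta)
  p2 <- stats::plogis(alpha[2] - eta)
  grade <- ifelse(u <= p1, 1L, ifelse(u <= p2, 2L, 3L))

  data.frame(sample_id = sample_ids, time_years = time, event = event,
             grade = grade, stringsAsFactors = FALSE)
}

#' Simulate a full screen cohort with planted trimodal risk genes
#'
#' Generates `n_null_genes` unlinked genes whose tumor and normal expression
#' are both unimodal `N(mu_2, sigma^2)`, plus `n_planted` trimodal risk
#' genes drawn from the full mixture. One shared clinical table is driven by
#' the first planted gene's true mode labels (or is null-calibrated when no
#' gene is planted). Each gene uses its own random sub-stream derived from
#' (seed, gene index), so per-gene values do not depend on gene order.
#'
#' @param config A [sim_config()].
#' @return List: `expr` (genes x samples matrix), `sample_class` (named
#'   vector tumor/normal), `clinical` (data.frame), `truth` (character
#'   vector of planted gene ids), `labels_true` (true modes of the driving
#'   planted gene, or NULL).
#' @export
simulate_screen_cohort <- function(config = sim_config()) {
  n_t <- sum(config$n_tumor)
  n_n <- config$n_normal
  tumor_ids <- paste0("T", seq_len(n_t))
  normal_ids <- paste0("N", seq_len(n_n))
  n_genes <- config$n_null_genes + config$n_planted
  planted_idx <- seq_len(config$n_planted)
  gene_ids <- character(n_genes)
  expr <- matrix(NA_real_, n_genes, n_t + n_n,
                 dimnames = list(NULL, c(tumor_ids, normal_ids)))
  labels_first <- NULL
  for (g in seq_len(n_genes)) {
    gseed <- .stream_seed(config$seed, g)
    if (g %in% planted_idx) {
      gene_ids[g] <- sprintf("PLANTED_%03d", g)
      sim <- simulate_mixture_gene(config, seed = gseed)
      if (g == 1L) labels_first <- sim$labels_true
      expr[g, ] <- c(sim$x_tumor, sim$x_normal)
    } else {
      gene_ids[g] <- sprintf("NULL_%05d", g - config$n_planted)
      set.seed(gseed)
      expr[g, ] <- stats::rnorm(n_t + n_n, mean = config$mu[2],
                                sd = config$sigma)
    }
  }
  rownames(expr) <- gene_ids
  sample_class <- stats::setNames(c(rep("tumor", n_t), rep("normal", n_n)),
                                  c(tumor_ids, normal_ids))
  clin_labels <- if (is.null(labels_first)) {
    factor(rep("middle", n_t), levels = c("low", "middle", "high"))
  } else {
    labels_first
  }
  clinical <- simulate_clinical(clin_labels, config,
                                seed = .stream_seed(config$seed, n_genes + 1L),
                                sample_ids = tumor_ids)
  list(expr = expr, sample_class = sample_class, clinical = clinical,
       truth = gene_ids[planted_idx],
       labels_true = labels_first)
}
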