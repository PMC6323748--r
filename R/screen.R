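# Genome-wide screen: fit every gene, filter trimodal genes with all three
# modes above a minimum proportion, test both tails for survival and grade,
# and replicate candidates across cohorts.

#' Default screen configuration
#'
#' @param min_mode_prop Minimum empirical proportion required of every mode
#'   (applied to the hard-assignment counts); default 0.05.
#' @param alpha Significance threshold for the four one-tailed tests.
#' @param weighting,tol,max_iter,restarts Passed to [fit_trimodal_em()].
#' @param proportions Optional length-3 proportions for cohorts without
#'   normal samples; modes are then assigned by expression rank via
#'   [split_by_proportions()] instead of the EM fit.
#' @param censor_years Survival censoring horizon in years.
#' @param seed Base seed for any stochastic parts (random restarts).
#' @return Named list of configuration values.
#' @export
screen_config <- function(min_mode_prop = 0.05, alpha = 0.05,
                          weighting = "standard", tol = 1e-6, max_iter = 500,
                          restarts = 0, proportions = NULL,
                          censor_years = 20, seed = 1L) {
  list(min_mode_prop = min_mode_prop, alpha = alpha, weighting = weighting,
       tol = tol, max_iter = max_iter, restarts = restarts,
       proportions = proportions, censor_years = censor_years,
       seed = as.integer(seed))
}

#' Screen one cohort for tri-modal association genes
#'
#' For every gene: fit the normal-anchored mixture ([fit_trimodal_em()]);
#' if the fit is trimodal and every mode's empirical proportion is at least
#' `min_mode_prop`, run the one-tailed survival contrasts
#' ([trimodal_survival_test()]) and grade trend tests ([grade_trend_test()])
#' against the clinical table. A gene is a candidate when all four one-tailed
#' p values fall below `alpha`. Cohorts without normal samples must supply
#' `proportions` in the config; modes are then assigned by ranking tumor
#' expression. Unfittable genes (missing values, too few samples) are kept
#' in the output with a reason, never dropped silently.
#'
#' @param expr Numeric matrix, genes x samples (tumor and normal columns).
#' @param sample_class Named character vector (`tumor`/`normal`) covering
#'   every column of `expr`.
#' @param clinical Data.frame with `sample_id`, `time_years`, `event`,
#'   `grade` for (at least) the tumor samples.
#' @param config List from [screen_config()].
#' @return Data.frame with one row per gene: fit summary, empirical mode
#'   proportions, the four p values, filter flags and the candidate flag.
#' @export
screen_cohort <- function(expr, sample_class, clinical,
                          config = screen_config()) {
  miss_cls <- setdiff(colnames(expr), names(sample_class))
  if (length(miss_cls)) stop("samples without a class label: ",
                             paste(utils::head(miss_cls, 5), collapse = ", "))
  tumor_ids <- colnames(expr)[sample_class[colnames(expr)] == "tumor"]
  normal_ids <- colnames(expr)[sample_class[colnames(expr)] == "normal"]
  if (length(tumor_ids) == 0) stop("no tumor samples in the matrix")
  use_split <- length(normal_ids) == 0
  if (use_split && is.null(config$proportions)) {
    stop("cohort has no normal samples: supply config$proportions to assign ",
         "modes by expression rank (split_by_proportions)")
  }
  cl <- clinical[match(tumor_ids, clinical$sample_id), ]
  if (all(is.na(cl$sample_id))) stop("clinical table matches no tumor sample ids")

  rows <- lapply(seq_len(nrow(expr)), function(g) {
    gid <- rownames(expr)[g]
    xt <- expr[g, tumor_ids]
    xn <- if (use_split) numeric(0) else expr[g, normal_ids]
    rec <- list(gene_id = gid, n_tumor = length(xt), n_normal = length(xn),
                fitted = FALSE, reason = NA_character_, trimodal = NA,
                mu1 = NA_real_, mu2 = NA_real_, mu3 = NA_real_,
                sigma = NA_real_, c12 = NA_real_, c23 = NA_real_,
                pi1 = NA_real_, pi2 = NA_real_, pi3 = NA_real_,
                prop_filter = NA, p12_surv = NA_real_, p23_surv = NA_real_,
                p_low_grade = NA_real_, p_high_grade = NA_real_,
                candidate = FALSE)
    if (anyNA(xt) || anyNA(xn)) {
      rec$reason <- "missing expression values"
      return(rec)
    }
    if (use_split) {
      asg <- split_by_proportions(xt, config$proportions)
      rec$fitted <- TRUE
      rec$trimodal <- NA  # no mixture fit; modes imposed by rank
      labels <- asg$labels
      emp <- asg$empirical_pi
    } else {
      fit <- tryCatch(
        fit_trimodal_em(xt, xn, weighting = config$weighting,
                        tol = config$tol, max_iter = config$max_iter,
                        restarts = config$restarts,
                        seed = config$seed + g, gene_id = gid),
        error = function(e) e)
      if (inherits(fit, "error")) {
        rec$reason <- conditionMessage(fit)
        return(rec)
      }
      if (isTRUE(fit$unfittable)) {
        rec$reason <- "non-finite likelihood"
        return(rec)
      }
      rec$fitted <- TRUE
      rec$trimodal <- fit$trimodal
      rec$mu1 <- fit$params$mu[1]; rec$mu2 <- fit$params$mu[2]
      rec$mu3 <- fit$params$mu[3]; rec$sigma <- fit$params$sigma
      if (!fit$trimodal) return(rec)
      rec$c12 <- fit$cutoffs$c12; rec$c23 <- fit$cutoffs$c23
      labels <- fit$labels
      emp <- fit$empirical_pi
    }
    rec$pi1 <- emp[1]; rec$pi2 <- emp[2]; rec$pi3 <- emp[3]
    rec$prop_filter <- min(emp) >= config$min_mode_prop
    if (!rec$prop_filter) return(rec)
    st <- tryCatch(
      trimodal_survival_test(labels, cl$time_years, cl$event,
                             censor_years = config$censor_years),
      error = function(e) NULL)
    if (!is.null(st)) { rec$p12_surv <- st$p12; rec$p23_surv <- st$p23 }
    gl <- tryCatch(grade_trend_test(labels, cl$grade, "low"),
                   error = function(e) NULL)
    gh <- tryCatch(grade_trend_test(labels, cl$grade, "high"),
                   error = function(e) NULL)
    if (!is.null(gl)) rec$p_low_grade <- gl$p
    if (!is.null(gh)) rec$p_high_grade <- gh$p
    ps <- c(rec$p12_surv, rec$p23_surv, rec$p_low_grade, rec$p_high_grade)
    rec$candidate <- !anyNA(ps) && all(ps < config$alpha)
    rec
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Assign modes by ranking expression into fixed proportions
#'
#' For cohorts without normal samples: samples are ranked by expression; the
#' lowest `floor(n * p1)` become the low mode, the highest `floor(n * p3)`
#' the high mode, and every remaining sample (including all rounding
#' leftovers) the middle mode. Supplied proportions are renormalized to sum
#' to 1 (with a message when the adjustment exceeds 1e-6). Rank ties are
#' broken by stable input order.
#'
#' @param x_tumor Numeric vector of tumor expression values.
#' @param proportions Length-3 positive vector (low, middle, high).
#' @return List with `labels` (factor, input order) and `empirical_pi`.
#' @export
split_by_proportions <- function(x_tumor, proportions) {
  stopifnot(length(proportions) == 3, all(proportions >= 0))
  s <- sum(proportions)
  if (abs(s - 1) > 1e-6) {
    message(sprintf("proportions sum to %.4f; renormalizing to 1", s))
  }
  p <- proportions / s
  n <- length(x_tumor)
  n_low <- floor(n * p[1])
  n_high <- floor(n * p[3])
  if ((p[1] > 0 && n_low == 0) || (p[3] > 0 && n_high == 0)) {
    warning("too few samples for a non-empty stratum at the requested proportions")
  }
  ord <- order(x_tumor)  # stable: ties keep input order
  lab <- rep("middle", n)
  if (n_low > 0) lab[ord[seq_len(n_low)]] <- "low"
  if (n_high > 0) lab[ord[seq(n - n_high + 1, n)]] <- "high"
  labels <- factor(lab, levels = c("low", "middle", "high"))
  list(labels = labels, empirical_pi = as.numeric(table(labels)) / n)
}

#' Replicate candidate genes across cohorts
#'
#' Under the `strict` policy a gene must pass all four one-tailed tests
#' (p < `alpha`) with the mode-proportion filter in every cohort. Under the
#' `relaxed` policy it must pass strictly in the named `discovery` cohorts
#' and show at least the correct trend (all four p < 0.5) in every other
#' cohort.
#'
#' @param records Named list of [screen_cohort()] data.frames, one per
#'   cohort.
#' @param policy `"strict"` or `"relaxed"`.
#' @param alpha Significance threshold.
#' @param discovery Cohort names (for `relaxed`); must match names of
#'   `records`.
#' @return Character vector of candidate gene ids (in the gene order of the
#'   first cohort).
#' @export
cross_cohort_candidates <- function(records, policy = c("strict", "relaxed"),
                                    alpha = 0.05, discovery = NULL) {
  policy <- match.arg(policy)
  if (length(records) < 2) stop("need at least two cohorts")
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("'records' must be a named list of cohorts")
  }
  passes <- function(df, thr) {
    ok <- !is.na(df$prop_filter) & df$prop_filter &
      !is.na(df$p12_surv) & !is.na(df$p23_surv) &
      !is.na(df$p_low_grade) & !is.na(df$p_high_grade) &
      df$p12_surv < thr & df$p23_surv < thr &
      df$p_low_grade < thr & df$p_high_grade < thr
    df$gene_id[ok]
  }
  if (policy == "strict") {
    sets <- lapply(records, passes, thr = alpha)
  } else {
    if (is.null(discovery)) stop("relaxed policy needs 'discovery' cohort names")
    bad <- setdiff(discovery, names(records))
    if (length(bad)) stop("unknown cohort name(s): ", paste(bad, collapse = ", "))
    sets <- lapply(names(records), function(nm) {
      passes(records[[nm]], thr = if (nm %in% discovery) alpha else 0.5)
    })
  }
  out <- Reduce(intersect, sets)
  records[[1]]$gene_id[records[[1]]$gene_id %in% out]
}
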