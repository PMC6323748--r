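# Association of the low/middle/high modes with survival and tumor grade.
#
# Conventions: the middle mode is always the reference. One-sided p values
# are computed from the Wald z of the contrast coefficient, oriented so that
# positive z means higher hazard (survival) or enrichment at higher grades
# (trend test) than the middle mode; p = 1 - Phi(z). Covariates in the
# multivariable model keep two-sided p values. p values are floored at
# 1e-300 to avoid exact zeros from underflow.

.P_FLOOR <- 1e-300

.censor_at <- function(time, event, censor_years) {
  over <- time > censor_years
  time[over] <- censor_years
  event[over] <- 0L
  list(time = time, event = event)
}

.mode_factor <- function(labels) {
  factor(as.character(labels), levels = c("middle", "low", "high"))
}

#' One-tailed survival contrasts of the low and high modes vs middle
#'
#' Fits a Cox proportional-hazards model of survival on the mode factor
#' (middle as reference), optionally adjusted for covariates, with all
#' follow-up administratively censored at `censor_years`. `p12` is the
#' one-sided p value for the alternative that the low mode has a higher
#' hazard than the middle mode (upper tail of the low coefficient's Wald
#' statistic); `p23` is the analogue for the high mode.
#'
#' @param labels Mode labels per sample (factor or character,
#'   low/middle/high), aligned with `time`/`event`.
#' @param time Survival time in years.
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @param covariates Optional data.frame of covariate columns (same row
#'   order as `labels`).
#' @param censor_years Administrative censoring horizon; default 20.
#' @return List of class `survival_test`: `p12`, `p23`, `coef_low`,
#'   `coef_high`, `n_per_mode`, `n_events`, `flags` (character; non-empty on
#'   empty modes or a degenerate fit).
#' @export
trimodal_survival_test <- function(labels, time, event, covariates = NULL,
                                   censor_years = 20) {
  mode <- .mode_factor(labels)
  keep <- !is.na(mode) & !is.na(time) & !is.na(event)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  mode <- droplevels(mode[keep], exclude = NULL)
  cens <- .censor_at(time[keep], event[keep], censor_years)
  n_per_mode <- as.numeric(table(factor(mode, levels = c("low", "middle", "high"))))
  if (sum(cens$event) < 1) stop("no events in the data; cannot fit a Cox model")
  if (!"middle" %in% levels(mode)) stop("middle mode is empty; no reference group")

  df <- data.frame(.time = cens$time, .event = cens$event,
                   .mode = droplevels(factor(as.character(mode),
                                             levels = c("middle", "low", "high"))))
  rhs <- ".mode"
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)[keep, , drop = FALSE]
    df <- cbind(df, cv)
    rhs <- paste(c(".mode", colnames(cv)), collapse = " + ")
  }
  flags <- character(0)
  fit <- tryCatch(
    survival::coxph(stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs)),
                    data = df),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      suppressWarnings(
        survival::coxph(stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs)),
                        data = df))
    },
    error = function(e) { flags <<- c(flags, conditionMessage(e)); NULL })

  res <- list(p12 = NA_real_, p23 = NA_real_,
              coef_low = NA_real_, coef_high = NA_real_,
              n_per_mode = n_per_mode, n_events = sum(cens$event),
              flags = flags, fit = fit)
  if (!is.null(fit)) {
    sm <- summary(fit)$coefficients
    one_sided <- function(term) {
      if (!term %in% rownames(sm) || !is.finite(sm[term, "se(coef)"])) return(c(NA, NA))
      z <- sm[term, "coef"] / sm[term, "se(coef)"]
      c(sm[term, "coef"], max(stats::pnorm(z, lower.tail = FALSE), .P_FLOOR))
    }
    lo <- one_sided(".modelow"); hi <- one_sided(".modehigh")
    res$coef_low <- lo[1]; res$p12 <- lo[2]
    res$coef_high <- hi[1]; res$p23 <- hi[2]
  }
  if (n_per_mode[1] == 0) res$flags <- c(res$flags, "low mode empty")
  if (n_per_mode[3] == 0) res$flags <- c(res$flags, "high mode empty")
  class(res) <- "survival_test"
  res
}

#' Multivariable survival model with the trimodal mode contrasts
#'
#' The same proportional-hazards model as [trimodal_survival_test()] with a
#' declared covariate set. Rows with missing covariates are dropped
#' (listwise deletion, reported via message). Character/factor covariates
#' are treated as categorical; a covariate column named `pam50` or `subtype`
#' is releveled to the `Basal` reference when that level is present.
#' Collinear covariates (NA coefficients) are dropped with a warning and
#' the model refit. The mode contrasts report one-sided p values (worse
#' outcome than middle); covariates report two-sided p values.
#'
#' @inheritParams trimodal_survival_test
#' @param clinical Data.frame with columns `time_years` and `event` plus the
#'   covariate columns, aligned with `labels`.
#' @param covariate_spec Character vector of covariate column names; may be
#'   empty, in which case the model reduces to [trimodal_survival_test()].
#' @return Data.frame with one row per model term: `term`, `coef`, `se`,
#'   `z`, `p`, `sided` ("one" for the mode contrasts, "two" otherwise).
#' @export
multivariable_survival <- function(labels, clinical, covariate_spec = character(0),
                                   censor_years = 20) {
  stopifnot(all(c("time_years", "event") %in% colnames(clinical)))
  miss <- setdiff(covariate_spec, colnames(clinical))
  if (length(miss)) stop("covariate column(s) not in clinical table: ",
                         paste(miss, collapse = ", "))
  cov_df <- NULL
  if (length(covariate_spec)) {
    cov_df <- clinical[, covariate_spec, drop = FALSE]
    for (nm in covariate_spec) {
      if (is.character(cov_df[[nm]])) cov_df[[nm]] <- factor(cov_df[[nm]])
      if (is.factor(cov_df[[nm]]) && tolower(nm) %in% c("pam50", "subtype") &&
          "Basal" %in% levels(cov_df[[nm]])) {
        cov_df[[nm]] <- stats::relevel(cov_df[[nm]], ref = "Basal")
      }
    }
    n_drop <- sum(!stats::complete.cases(cov_df))
    if (n_drop > 0) message(n_drop, " sample(s) dropped for missing covariates")
  }
  st <- trimodal_survival_test(labels, clinical$time_years, clinical$event,
                               covariates = cov_df, censor_years = censor_years)
  if (is.null(st$fit)) stop("survival model did not fit: ",
                            paste(st$flags, collapse = "; "))
  fit <- st$fit
  sm <- summary(fit)$coefficients
  if (any(is.na(sm[, "coef"]))) {
    bad <- rownames(sm)[is.na(sm[, "coef"])]
    warning("dropping collinear term(s): ", paste(bad, collapse = ", "))
    keep_cov <- covariate_spec[vapply(covariate_spec, function(nm) {
      !any(startsWith(bad, nm))
    }, logical(1))]
    return(multivariable_survival(labels, clinical, keep_cov, censor_years))
  }
  term <- rownames(sm)
  term <- sub("^\\.mode", "mode_", term)
  z <- sm[, "coef"] / sm[, "se(coef)"]
  is_mode <- term %in% c("mode_low", "mode_high")
  p <- ifelse(is_mode,
              stats::pnorm(z, lower.tail = FALSE),
              2 * stats::pnorm(abs(z), lower.tail = FALSE))
  data.frame(term = term, coef = sm[, "coef"], se = sm[, "se(coef)"],
             z = z, p = pmax(p, .P_FLOOR),
             sided = ifelse(is_mode, "one", "two"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-tailed trend of mode membership across tumor grades
#'
#' Restricts to the contrast mode (low or high) plus the middle mode, forms
#' the 2 x k table of mode membership by tumor grade with integer scores,
#' and computes the Cochran-Armitage trend chi-square
#' (via [stats::prop.trend.test()]). The chi-square is converted to a signed
#' z whose sign follows the direction of the trend, and the one-tailed
#' p value is the upper-tail probability that higher grades are enriched for
#' the contrast mode; when the trend runs the other way the p value exceeds
#' 0.5 (p = 1 - upper tail). A flat trend gives exactly 0.5.
#'
#' @param labels Mode labels per sample (low/middle/high).
#' @param grades Ordinal tumor grades in 1/2/3 (NA allowed; dropped).
#' @param contrast `"low"` or `"high"`: which mode to test against middle.
#' @return List of class `grade_trend`: `p` (one-tailed), `z` (signed),
#'   `chisq`, `table` (counts contrast/middle by grade), `scores`.
#' @export
grade_trend_test <- function(labels, grades, contrast = c("low", "high")) {
  contrast <- match.arg(contrast)
  lab <- as.character(labels)
  keep <- lab %in% c(contrast, "middle") & !is.na(grades)
  lab <- lab[keep]; grades <- grades[keep]
  stopifnot(all(grades %in% 1:3))
  if (!any(lab == contrast) || !any(lab == "middle")) {
    stop("both the ", contrast, " and middle groups must be non-empty")
  }
  counts <- table(factor(lab, levels = c(contrast, "middle")),
                  factor(grades, levels = 1:3))
  n <- colSums(counts)
  present <- n > 0
  if (!all(present)) {
    warning("grade level(s) with no samples dropped: ",
            paste((1:3)[!present], collapse = ", "))
  }
  x <- counts[1, present]
  n <- n[present]
  score <- (1:3)[present]
  if (length(n) < 2) stop("need at least two grade levels with samples")
  tt <- suppressWarnings(stats::prop.trend.test(x, n, score = score))
  chisq <- unname(tt$statistic)
  # direction: positive when the contrast-mode fraction rises with grade
  pbar <- sum(x) / sum(n)
  direction <- sum(x * score) - pbar * sum(n * score)
  z <- sign(direction) * sqrt(chisq)
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(p = max(p, .P_FLOOR), z = z, chisq = chisq,
                 table = counts[, present, drop = FALSE], scores = score),
            class = "grade_trend")
}

#' Significance of the overlap between two gene lists
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap when `|listB|` genes are drawn from a universe of which `|listA|`
#' are marked.
#'
#' @param listA,listB Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all eligible gene ids.
#' @return List: `n_listA`, `n_listB`, `n_overlap`, `n_universe`, `p_hyper`.
#' @export
overlap_hypergeometric <- function(listA, listB, universe) {
  listA <- unique(listA); listB <- unique(listB); universe <- unique(universe)
  if (!all(listA %in% universe) || !all(listB %in% universe)) {
    stop("both gene lists must be subsets of the universe")
  }
  k <- length(intersect(listA, listB))
  N <- length(universe); K <- length(listA); n <- length(listB)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(n_listA = K, n_listB = n, n_overlap = k, n_universe = N,
       p_hyper = p)
}
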