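# Bayesian model-comparison summaries: within-group standardization, a
# default-prior correlation Bayes factor, and BIC-approximate Bayes factors
# for age / set-size effects on participant-by-set-size cell tables.

#' Standardize values within groups
#'
#' z-scores each value against its own group's mean and sample SD, removing
#' group-mean differences so that pooled correlations reflect within-group
#' covariation only.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return Numeric vector of z-scores, order preserved.
#' @export
standardize_within_group <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- numeric(length(values))
  for (g in unique(groups)) {
    i <- groups == g
    if (sum(i) < 2) stop("group '", g, "' has fewer than 2 observations")
    s <- stats::sd(values[i])
    if (!is.finite(s) || s == 0) stop("group '", g, "' has zero variance")
    out[i] <- (values[i] - mean(values[i])) / s
  }
  out
}

# Prior over the correlation: a symmetric beta distribution on (-1, 1)
# ("stretched beta") with shape 1/width; width 1 gives the uniform prior.
rho_prior_density <- function(rho, width) {
  stats::dbeta((rho + 1) / 2, 1 / width, 1 / width) / 2
}

#' Default-prior Bayes factor for a Pearson correlation
#'
#' Computes the sample correlation and a Bayes factor for its presence
#' (rho != 0) against the null (rho = 0) by numerical integration over rho
#' under a stretched symmetric beta prior. The marginal likelihood uses the
#' classical approximation to the sampling density of r given rho,
#' `(1 - rho^2)^((n - 1)/2) * (1 - rho * r)^((3 - 2n)/2)`, which is
#' accurate for the sample sizes this package targets (n >= 20) and depends
#' on the data only through (r, n), making the Bayes factor invariant to
#' affine rescaling of either variable.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param prior_width Width of the stretched beta prior (1 = uniform over
#'   (-1, 1)).
#' @return List: `r`, `n`, `bf10`, `bf01`, `prior_width`,
#'   `method = "jeffreys-integral"`.
#' @export
correlation_bf <- function(x, y, prior_width = 1) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    # degenerate perfect correlation: the marginal likelihood diverges, the
    # evidence for an association is unbounded
    return(list(r = r, n = n, bf10 = Inf, bf01 = 0,
                prior_width = prior_width, method = "jeffreys-integral"))
  }
  integrand <- function(rho) {
    loglik <- (n - 1) / 2 * log1p(-rho^2) +
      (3 - 2 * n) / 2 * log1p(-rho * r)
    exp(loglik) * rho_prior_density(rho, prior_width)
  }
  bf10 <- stats::integrate(integrand, -1, 1, rel.tol = 1e-8)$value
  list(r = r, n = n, bf10 = bf10, bf01 = 1 / bf10,
       prior_width = prior_width, method = "jeffreys-integral")
}

#' BIC-approximate Bayes factor for an effect on cell data
#'
#' Compares nested linear models with and without the named effect on a
#' participant-by-set-size cell table and returns
#' `exp((BIC_without - BIC_with) / 2)` as the Bayes factor for the effect's
#' presence. Participant intercepts are absorbed exactly: the set-size
#' effect and the interaction are tested within participants (fixed
#' participant intercepts in both models), while the between-participant
#' age effect is tested on participant means. This is a deliberate,
#' documented approximation to full mixed-model Bayes factors; the method
#' tag records it.
#'
#' @param table data.frame with columns `participant_id`, `age_group`,
#'   `set_size`, `value` (one row per participant x set size).
#' @param effect `"age"`, `"set_size"` or `"interaction"`.
#' @return List: `effect`, `bf10`, `bf01`, `method = "bic-approx"`.
#' @export
effect_bf <- function(table, effect = c("age", "set_size", "interaction")) {
  effect <- match.arg(effect)
  d <- table[stats::complete.cases(table[c("participant_id", "age_group",
                                           "set_size", "value")]), ]
  d$participant_id <- factor(d$participant_id)
  d$age_group <- factor(d$age_group)
  d$set_size <- factor(d$set_size)
  if (effect == "age" && nlevels(d$age_group) < 2)
    stop("age effect needs >= 2 age groups")
  if (effect != "age" && nlevels(d$set_size) < 2)
    stop("set-size effect needs >= 2 set sizes")

  if (effect == "age") {
    means <- stats::aggregate(value ~ participant_id + age_group, d, mean)
    full <- stats::lm(value ~ age_group, means)
    null <- stats::lm(value ~ 1, means)
  } else if (effect == "set_size") {
    full <- stats::lm(value ~ 0 + participant_id + set_size, d)
    null <- stats::lm(value ~ 0 + participant_id, d)
  } else {
    full <- stats::lm(value ~ 0 + participant_id + set_size +
                        set_size:age_group, d)
    null <- stats::lm(value ~ 0 + participant_id + set_size, d)
  }
  bf10 <- exp((stats::BIC(null) - stats::BIC(full)) / 2)
  list(effect = effect, bf10 = bf10, bf01 = 1 / bf10, method = "bic-approx")
}

#' Within-group standardized WM-LTM capacity correlation
#'
#' The headline individual-differences analysis: per participant, WM
#' capacity is the mean adjusted Cowan's k across set sizes and LTM
#' capacity the mean of `p(LTM) * S`; both are z-scored within age group
#' (removing the age confound) and correlated, with a default-prior Bayes
#' factor.
#'
#' @param scores Output of [score_cohort()].
#' @param prior_width Passed to [correlation_bf()].
#' @return As [correlation_bf()], plus per-participant capacity scores in
#'   `data`.
#' @export
capacity_correlation <- function(scores, prior_width = 1) {
  it <- scores$item
  wm <- it[it$phase == "WM", ]
  ltm <- it[it$phase == "LTM", ]
  ltm$capacity <- ltm$p * ltm$set_size
  kbar <- stats::aggregate(k ~ participant_id + age_group, wm, mean)
  lbar <- stats::aggregate(capacity ~ participant_id, ltm, mean)
  d <- merge(kbar, lbar, by = "participant_id")
  d$z_k <- standardize_within_group(d$k, d$age_group)
  d$z_ltm <- standardize_within_group(d$capacity, d$age_group)
  out <- correlation_bf(d$z_k, d$z_ltm, prior_width)
  out$data <- d
  out
}

#' Bayes-factor battery for a scored cohort
#'
#' Runs the BIC-approximate age, set-size and interaction comparisons for
#' each of the scored measures (p(WM), p(LTM), transfer ratio, WM and LTM
#' binding-error rates) and the standardized capacity correlation.
#'
#' @param scores Output of [score_cohort()].
#' @param prior_width Prior width for the correlation Bayes factor.
#' @return Nested list: one entry per measure with its three [effect_bf()]
#'   results, plus `correlation`.
#' @export
analyze_cohort <- function(scores, prior_width = 1) {
  cell <- function(d, value) {
    data.frame(participant_id = d$participant_id, age_group = d$age_group,
               set_size = d$set_size, value = d[[value]])
  }
  it <- scores$item
  tabs <- list(
    p_wm = cell(it[it$phase == "WM", ], "p"),
    p_ltm = cell(it[it$phase == "LTM", ], "p"),
    ratio = cell(scores$ratio, "ratio"),
    wm_binding = cell(scores$binding[scores$binding$phase == "WM", ],
                      "error_rate"),
    ltm_binding = cell(scores$binding[scores$binding$phase == "LTM" &
                                        !scores$binding$excluded, ],
                       "error_rate"))
  effects <- lapply(tabs, function(tb) {
    lapply(c(age = "age", set_size = "set_size",
             interaction = "interaction"),
           function(e) effect_bf(tb, e))
  })
  effects$correlation <- capacity_correlation(scores, prior_width)
  effects
}
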