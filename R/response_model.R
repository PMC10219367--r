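# Generative observer model: a multinomial processing tree over the three
# response options {SS, SD, DO}. Object availability follows the slots view
# of capacity, p = min(k/S, 1); when the probed object is available the
# color judgment depends on whether its binding survived; when it is not,
# the observer guesses "old" at rate g and then guesses a color. The tree
# marginalizes to the single-probe guessing model for item memory:
# hit rate h = p + (1 - p) g, false-alarm rate f = g.

#' Latent observer parameters
#'
#' Bundles the parameters of the multinomial-processing-tree observer. All
#' are probabilities except `k_true` (a capacity in items, > 0).
#'
#' @param k_true Latent WM capacity in items; availability of a probed
#'   object at set size S is `min(k_true / S, 1)`.
#' @param g_old Probability of guessing "old" when the probed object is not
#'   in memory (WM phase); equals the expected false-alarm rate.
#' @param beta_same Probability that a color guess is "same color" (the
#'   same-color response bias).
#' @param b_wm Probability the item-color binding is retained in WM given
#'   the object is available.
#' @param d_novel Probability a probe color absent from the study array is
#'   recognized as novel, given the object is available; must be at least
#'   `b_wm` (noticing a never-seen color can only be easier than recalling
#'   the exact pairing).
#' @param tau_ltm Probability a WM-held object survives into LTM.
#' @param b_ltm Probability the binding survives into LTM given the object
#'   did.
#' @param g_old_ltm Guess-"old" rate in the LTM test.
#' @return A `participant_params` list.
#' @export
participant_params <- function(k_true, g_old, beta_same, b_wm, d_novel,
                               tau_ltm, b_ltm, g_old_ltm) {
  p <- list(k_true = k_true, g_old = g_old, beta_same = beta_same,
            b_wm = b_wm, d_novel = d_novel, tau_ltm = tau_ltm,
            b_ltm = b_ltm, g_old_ltm = g_old_ltm)
  probs <- p[setdiff(names(p), "k_true")]
  if (any(vapply(probs, function(x) any(x < 0 | x > 1), logical(1))))
    stop("all rate parameters must lie in [0, 1]")
  if (any(k_true <= 0)) stop("k_true must be positive")
  if (any(d_novel < b_wm)) stop("d_novel must be >= b_wm")
  class(p) <- "participant_params"
  p
}

PARAM_FIELDS <- c("k_true", "g_old", "beta_same", "b_wm", "d_novel",
                  "tau_ltm", "b_ltm", "g_old_ltm")

# Vectorized response-probability kernel. `condition`, `set_size` and the
# parameter columns are equal-length vectors (phase: "WM" or "LTM" per
# element). Returns a 3-column matrix (SS, SD, DO).
response_prob_matrix <- function(condition, phase, set_size, par) {
  is_ltm <- phase == "LTM"
  p_obj <- pmin(par$k_true / set_size, 1)
  p_obj <- ifelse(is_ltm, p_obj * par$tau_ltm, p_obj)
  b <- ifelse(is_ltm, par$b_ltm, par$b_wm)
  g <- ifelse(is_ltm, par$g_old_ltm, par$g_old)
  beta <- par$beta_same
  d <- par$d_novel

  new_obj <- condition %in% c("NEW", "DIFF_OBJ_ARRAYCOLOR", "DIFF_OBJ_NOVELCOLOR")
  p_obj <- ifelse(new_obj, 0, p_obj)  # object never studied

  ss <- sd <- numeric(length(condition))
  guess_old_ss <- (1 - p_obj) * g * beta
  guess_old_sd <- (1 - p_obj) * g * (1 - beta)

  i <- condition == "SAME_SAME"
  ss[i] <- (p_obj * (b + (1 - b) * beta) + guess_old_ss)[i]
  sd[i] <- (p_obj * (1 - b) * (1 - beta) + guess_old_sd)[i]
  i <- condition == "SAME_DIFF_SWAP"
  ss[i] <- (p_obj * (1 - b) * beta + guess_old_ss)[i]
  sd[i] <- (p_obj * (b + (1 - b) * (1 - beta)) + guess_old_sd)[i]
  i <- condition == "SAME_DIFF_NOVEL"
  ss[i] <- (p_obj * (1 - d) * beta + guess_old_ss)[i]
  sd[i] <- (p_obj * (d + (1 - d) * (1 - beta)) + guess_old_sd)[i]
  i <- new_obj
  ss[i] <- (g * beta)[i]
  sd[i] <- (g * (1 - beta))[i]

  out <- cbind(SS = ss, SD = sd, DO = 1 - ss - sd)
  if (any(out < -1e-12) || any(out > 1 + 1e-12))
    stop("response probabilities escaped [0, 1]; corrupted parameters")
  out[out < 0] <- 0  # clear float dust at the boundaries
  out
}

#' Response probabilities for one probe
#'
#' Evaluates the observer tree for a single probe condition and returns the
#' probability of each of the three responses (`SS` = same object-same
#' color, `SD` = same object-different color, `DO` = different object). In
#' the LTM phase availability is discounted by `tau_ltm`, the binding
#' survival by `b_ltm`, and guessing uses `g_old_ltm`; novelty detection
#' (`d_novel`) is shared between phases. For old-object probes the implied
#' "old" rate is exactly `p + (1 - p) g` with `p = min(k/S, 1)` (times
#' `tau_ltm` in LTM); for new-object probes it is `g` regardless of set
#' size.
#'
#' @param condition Probe condition label (see [generate_wm_design()] /
#'   [generate_ltm_design()]).
#' @param phase `"WM"` or `"LTM"`.
#' @param set_size Set size of the originating trial (ignored for new-object
#'   probes; may be `NA` for `NEW`).
#' @param params A [participant_params()] object.
#' @return Named numeric triple `(SS, SD, DO)` summing to 1.
#' @examples
#' pp <- participant_params(k_true = 1.6, g_old = .4, beta_same = .7,
#'                          b_wm = .6, d_novel = .8, tau_ltm = .5,
#'                          b_ltm = .5, g_old_ltm = .3)
#' response_probabilities("SAME_SAME", "WM", 2, pp)  # .760 .120 .120
#' @export
response_probabilities <- function(condition, phase, set_size, params) {
  stopifnot(inherits(params, "participant_params"), length(condition) == 1)
  if (!condition %in% union(WM_CONDITIONS, LTM_CONDITIONS))
    stop("unknown condition: ", condition)
  if (!phase %in% c("WM", "LTM")) stop("phase must be 'WM' or 'LTM'")
  if (is.na(set_size))
    set_size <- 1  # irrelevant for new-object probes, keep arithmetic finite
  drop(response_prob_matrix(condition, phase, set_size, params))
}

#' Age-group simulation profile
#'
#' Describes a cohort: its size and, for every observer parameter, a mean
#' and spread. Individual participants draw each parameter from a normal
#' distribution truncated to the parameter's support (rates to \[0, 1\],
#' capacity to (0, Inf)); `d_novel` is then raised to `b_wm` where needed.
#'
#' @param name Group label.
#' @param n Number of participants (>= 1).
#' @param means,sds Named numeric vectors over the fields of
#'   [participant_params()].
#' @return An `age_group_profile` list.
#' @export
age_group_profile <- function(name, n, means, sds) {
  stopifnot(n >= 1, all(PARAM_FIELDS %in% names(means)),
            all(PARAM_FIELDS %in% names(sds)), all(sds[PARAM_FIELDS] >= 0))
  out <- list(name = name, n = as.integer(n),
              means = means[PARAM_FIELDS], sds = sds[PARAM_FIELDS])
  class(out) <- "age_group_profile"
  out
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

draw_params <- function(profile) {
  m <- profile$means; s <- profile$sds
  lo <- c(k_true = 1e-6, g_old = 0, beta_same = 0, b_wm = 0, d_novel = 0,
          tau_ltm = 0, b_ltm = 0, g_old_ltm = 0)
  hi <- c(k_true = Inf, g_old = 1, beta_same = 1, b_wm = 1, d_novel = 1,
          tau_ltm = 1, b_ltm = 1, g_old_ltm = 1)
  x <- vapply(PARAM_FIELDS,
              function(f) rtruncnorm1(1, m[[f]], s[[f]], lo[[f]], hi[[f]]),
              numeric(1))
  x["d_novel"] <- max(x["d_novel"], x["b_wm"])
  do.call(participant_params, as.list(x))
}

#' Default age-group profiles
#'
#' Three cohorts mirroring a developmental sample: 1st-2nd graders
#' (`grade1-2`, n = 43), 5th-7th graders (`grade5-7`, n = 39) and young
#' adults (`adult`, n = 42). Parameter means are calibrated so simulated
#' cohorts reproduce the canonical qualitative pattern: capacity and binding
#' retention grow with age (adult mean capacity about 3.6 items, youngest
#' about 1.8), the same-color guess bias sits near .70 in every group, LTM
#' guess-"old" rates rise with age (.13/.29/.32), and LTM binding survival
#' is equal across groups so that contingent LTM binding-error rates show no
#' systematic age gap.
#'
#' @return Named list of three [age_group_profile()] objects.
#' @export
default_profiles <- function() {
  sds <- c(k_true = 0.5, g_old = 0.08, beta_same = 0.08, b_wm = 0.10,
           d_novel = 0.08, tau_ltm = 0.12, b_ltm = 0.12, g_old_ltm = 0.10)
  list(
    "grade1-2" = age_group_profile("grade1-2", 43,
      means = c(k_true = 1.8, g_old = 0.15, beta_same = 0.70, b_wm = 0.50,
                d_novel = 0.70, tau_ltm = 0.45, b_ltm = 0.15,
                g_old_ltm = 0.13),
      sds = sds),
    "grade5-7" = age_group_profile("grade5-7", 39,
      means = c(k_true = 3.0, g_old = 0.20, beta_same = 0.70, b_wm = 0.65,
                d_novel = 0.82, tau_ltm = 0.53, b_ltm = 0.15,
                g_old_ltm = 0.29),
      sds = sds),
    "adult" = age_group_profile("adult", 42,
      means = c(k_true = 3.6, g_old = 0.20, beta_same = 0.70, b_wm = 0.75,
                d_novel = 0.90, tau_ltm = 0.53, b_ltm = 0.15,
                g_old_ltm = 0.32),
      sds = replace(sds, "k_true", 0.6))
  )
}

# Flat probe template shared by all participants of a cohort: one row per
# WM trial plus one per LTM probe.
probe_template <- function(wm, ltm) {
  wm_part <- data.frame(
    phase = "WM", probe_index = wm$trials$trial_index,
    set_size = wm$trials$set_size, condition = wm$trials$condition,
    was_wm_probe = NA, correct_response = wm$trials$correct_response,
    stringsAsFactors = FALSE)
  ltm_part <- data.frame(
    phase = "LTM", probe_index = ltm$probes$probe_index,
    set_size = ltm$probes$origin_set_size, condition = ltm$probes$condition,
    was_wm_probe = ltm$probes$was_wm_probe,
    correct_response = ltm$probes$correct_response,
    stringsAsFactors = FALSE)
  rbind(wm_part, ltm_part)
}

#' Simulate a cohort of observers on a task design
#'
#' Draws `profile$n` participants' latent parameters from the profile, gives
#' each participant a fresh presentation order (its own permutation of the
#' WM trials and of the LTM probes), and samples one response per probe from
#' the observer tree. Everything a participant produces depends only on the
#' master seed and the participant's counter index, so a cohort is
#' reproducible and earlier participants are unchanged when the cohort is
#' enlarged.
#'
#' @param wm,ltm Designs from [generate_wm_design()] /
#'   [generate_ltm_design()].
#' @param profile An [age_group_profile()].
#' @param seed Master integer seed.
#' @param participant_offset Counter offset, used when several cohorts share
#'   a master seed (participants are numbered globally).
#' @return List with `params` (one row per participant: id, group and the
#'   latent parameters) and `records` (one row per probe response:
#'   `participant_id`, `age_group`, `phase`, `probe_index`, `set_size`,
#'   `condition`, `was_wm_probe`, `presentation_order`, `response`,
#'   `object_correct`, `fully_correct`).
#' @export
simulate_cohort <- function(wm, ltm, profile, seed, participant_offset = 0L) {
  stopifnot(inherits(profile, "age_group_profile"))
  template <- probe_template(wm, ltm)
  n_wm <- sum(template$phase == "WM")
  n_ltm <- sum(template$phase == "LTM")
  n_probe <- n_wm + n_ltm
  n <- profile$n

  par_rows <- vector("list", n)
  u_all <- matrix(0, nrow = n_probe, ncol = n)
  order_all <- matrix(0L, nrow = n_probe, ncol = n)
  for (i in seq_len(n)) {
    idx <- participant_offset + i
    with_seed(substream_seed(seed, idx), {
      par_rows[[i]] <- draw_params(profile)
      order_all[, i] <- c(sample.int(n_wm), sample.int(n_ltm))
      u_all[, i] <- stats::runif(n_probe)
    })
  }

  ids <- sprintf("p%04d", participant_offset + seq_len(n))
  par_df <- do.call(rbind, lapply(par_rows, function(p)
    as.data.frame(unclass(p))))
  par_df <- cbind(participant_id = ids, age_group = profile$name, par_df,
                  stringsAsFactors = FALSE)

  rep_i <- rep(seq_len(n), each = n_probe)
  big <- template[rep.int(seq_len(n_probe), n), ]
  par_long <- lapply(par_df[PARAM_FIELDS], function(col) col[rep_i])
  probs <- response_prob_matrix(big$condition, big$phase,
                                ifelse(is.na(big$set_size), 1, big$set_size),
                                par_long)
  u <- as.vector(u_all)
  response <- ifelse(u < probs[, "SS"], "SS",
                     ifelse(u < probs[, "SS"] + probs[, "SD"], "SD", "DO"))
  old_probe <- big$correct_response != "DO"
  records <- data.frame(
    participant_id = ids[rep_i], age_group = profile$name,
    phase = big$phase, probe_index = big$probe_index,
    set_size = big$set_size, condition = big$condition,
    was_wm_probe = big$was_wm_probe,
    presentation_order = as.vector(order_all),
    response = response,
    object_correct = ifelse(old_probe, response != "DO", response == "DO"),
    fully_correct = response == big$correct_response,
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(params = par_df, records = records)
}

#' Simulate several cohorts at once
#'
#' @param wm,ltm Task designs.
#' @param profiles List of [age_group_profile()] objects.
#' @param seed Master integer seed shared by all cohorts; participants are
#'   numbered consecutively across cohorts.
#' @return As [simulate_cohort()], rows concatenated across cohorts.
#' @export
simulate_cohorts <- function(wm, ltm, profiles, seed) {
  offset <- 0L
  out <- lapply(profiles, function(pr) {
    res <- simulate_cohort(wm, ltm, pr, seed, participant_offset = offset)
    offset <<- offset + pr$n
    res
  })
  list(params = do.call(rbind, c(lapply(out, `[[`, "params"),
                                 make.row.names = FALSE)),
       records = do.call(rbind, c(lapply(out, `[[`, "records"),
                                  make.row.names = FALSE)))
}
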