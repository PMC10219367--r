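# Measurement core: guessing-corrected item memory p(WM)/p(LTM) and Cowan's
# k, implausible-value adjustment, the LTM/WM transfer ratio, contingent
# binding-error scoring with its eligibility filters, and the same-color
# guess-bias rate.

OLD_CONDITIONS <- c("SAME_SAME", "SAME_DIFF_SWAP", "SAME_DIFF_NOVEL")
NEW_CONDITIONS <- c("DIFF_OBJ_ARRAYCOLOR", "DIFF_OBJ_NOVELCOLOR", "NEW")

one_participant <- function(records) {
  if (length(unique(records$participant_id)) > 1L)
    stop("records must come from a single participant")
  invisible(records)
}

#' Tally recognition counts for one participant
#'
#' Counts old-object probes and "old" responses (either same-object option),
#' and new-object probes and false "old" responses. A `DO` response to an
#' old-object probe is a miss regardless of color; color accuracy plays no
#' role in item scoring. For the WM phase both tallies are restricted to one
#' set size (lures are allocated within set size); for the LTM phase
#' old-object probes are tallied per originating set size while the lure
#' tally always pools the new probes, which carry no set size.
#'
#' @param records Response records of one participant (see
#'   [simulate_cohort()]).
#' @param phase `"WM"` or `"LTM"`.
#' @param set_size Set-size scope for the old-object tally.
#' @param pool_wm_lures If `TRUE`, WM lures are pooled across set sizes
#'   instead of taken from the probed set size.
#' @return A one-row data.frame: `phase`, `set_size`, `n_old`,
#'   `n_old_called_old`, `n_new`, `n_new_called_old`, `h`, `f`.
#' @export
tally_recognition <- function(records, phase, set_size,
                              pool_wm_lures = FALSE) {
  one_participant(records)
  r <- records[records$phase == phase, ]
  old <- r[r$condition %in% OLD_CONDITIONS & !is.na(r$set_size) &
             r$set_size == set_size, ]
  if (phase == "WM") {
    lure <- r[r$condition %in% NEW_CONDITIONS, ]
    if (!pool_wm_lures) lure <- lure[lure$set_size == set_size, ]
  } else {
    lure <- r[r$condition == "NEW", ]
  }
  if (nrow(old) == 0L || nrow(lure) == 0L)
    stop("empty recognition scope: phase ", phase, ", set size ", set_size)
  called_old <- function(x) sum(x$response %in% c("SS", "SD"))
  data.frame(phase = phase, set_size = set_size,
             n_old = nrow(old), n_old_called_old = called_old(old),
             n_new = nrow(lure), n_new_called_old = called_old(lure),
             h = called_old(old) / nrow(old),
             f = called_old(lure) / nrow(lure))
}

#' Guessing-corrected proportion remembered
#'
#' Applies the single-probe correction `p = (h - f) / (1 - f)`, which
#' inverts `h = p + (1 - p) g` under the assumption that the false-alarm
#' rate estimates the guess-"old" rate `g`. The result can be negative when
#' `f > h` (poor memory plus unlucky guessing); see [adjust_estimates()].
#'
#' @param counts A tally from [tally_recognition()], or any object with
#'   fields `h` and `f`.
#' @return Raw (unadjusted) proportion, possibly negative.
#' @export
estimate_p <- function(counts) {
  h <- counts$h; f <- counts$f
  if (any(f >= 1)) stop("false-alarm rate is 1: degenerate respondent")
  (h - f) / (1 - f)
}

#' Adjust theoretically implausible estimates
#'
#' WM proportions implying a capacity below one item are raised to the
#' one-item floor (`p = 1/S`, i.e. k = 1); negative LTM proportions are
#' raised to 0. The default reading floors *capacity* at one item; the
#' alternative reading, flooring the WM proportion itself at 1, is
#' available via `rule = "p_floor"` for sensitivity analyses but would
#' overwrite valid intermediate data and is not the default.
#'
#' @param raw_p Raw proportion(s) from [estimate_p()].
#' @param phase `"WM"` or `"LTM"`.
#' @param set_size Set size (required for WM).
#' @param rule `"k_floor"` (default) or `"p_floor"`.
#' @return data.frame with `p` (adjusted), `raw_p` and `adjusted` flag.
#' @export
adjust_estimates <- function(raw_p, phase, set_size = NULL,
                             rule = c("k_floor", "p_floor")) {
  rule <- match.arg(rule)
  if (phase == "WM") {
    stopifnot(!is.null(set_size))
    floor_p <- if (rule == "k_floor") 1 / set_size else 1
    adj <- raw_p * set_size < 1
    if (rule == "p_floor") adj <- raw_p < 1
    p <- ifelse(adj, floor_p, raw_p)
  } else {
    adj <- raw_p < 0
    p <- ifelse(adj, 0, raw_p)
  }
  data.frame(p = p, raw_p = raw_p, adjusted = adj)
}

#' Cowan's k from a proportion remembered
#'
#' `k = p(WM) * S`: the expected number of items held, under the slots view
#' in which each of S items is available with probability k/S.
#'
#' @param p_wm Proportion(s) in \[0, 1\].
#' @param set_size Set size S.
#' @return Capacity in items.
#' @examples
#' capacity_k(0.90, 4)  # 3.6
#' @export
capacity_k <- function(p_wm, set_size) p_wm * set_size

#' LTM/WM transfer ratio
#'
#' The fraction of WM-held items that survive into LTM, `p(LTM) / p(WM)`,
#' computed per participant and set size. Group summaries must average
#' participant ratios, not take ratios of group means.
#'
#' @param p_ltm,p_wm Proportions for the same participant and set size.
#' @return data.frame with `ratio` and a `defined` flag (`FALSE` when
#'   `p_wm` is 0, which cannot occur after adjustment since adjusted
#'   `p_wm >= 1/S`).
#' @export
transfer_ratio <- function(p_ltm, p_wm) {
  defined <- p_wm > 0
  data.frame(ratio = ifelse(defined, p_ltm / p_wm, NA_real_),
             defined = defined)
}

#' Contingent binding-error cells for one participant
#'
#' Binding memory is scored only on probes that test the object-color
#' pairing and only when the object itself was called old: intact
#' (`SAME_SAME`) and re-paired (`SAME_DIFF_SWAP`) probes with a response
#' other than `DO`. Novel-color probes are excluded because noticing a
#' never-seen color does not require the binding. In the LTM phase, probes
#' whose item already served as a WM probe are dropped (re-exposure could
#' inflate hits), and cells resting on fewer than `min_trials` eligible
#' probes are flagged `excluded` unless `include_all` is set. A binding
#' error is claiming a color change on an intact probe (`SD`) or no change
#' on a re-paired probe (`SS`).
#'
#' @param records Response records of one participant.
#' @param phase `"WM"` or `"LTM"`.
#' @param include_all Disable the minimum-trial exclusion (robustness
#'   check).
#' @param min_trials Minimum eligible probes for a reliable LTM cell
#'   (default 5).
#' @return data.frame, one row per set size: `n_eligible`, `n_errors`,
#'   `error_rate` (NA when no eligible probes), `excluded`.
#' @export
binding_cells <- function(records, phase, include_all = FALSE,
                          min_trials = 5L) {
  one_participant(records)
  r <- records[records$phase == phase &
                 records$condition %in% c("SAME_SAME", "SAME_DIFF_SWAP"), ]
  if (phase == "LTM") r <- r[!(r$was_wm_probe %in% TRUE), ]
  eligible <- r[r$response != "DO", ]
  is_err <- (eligible$condition == "SAME_SAME" & eligible$response == "SD") |
    (eligible$condition == "SAME_DIFF_SWAP" & eligible$response == "SS")
  out <- do.call(rbind, lapply(sort(unique(r$set_size)), function(s) {
    el <- eligible$set_size == s
    n_el <- sum(el)
    data.frame(participant_id = records$participant_id[1], phase = phase,
               set_size = s, n_eligible = n_el, n_errors = sum(is_err[el]),
               error_rate = if (n_el > 0) sum(is_err[el]) / n_el else NA_real_,
               excluded = phase == "LTM" && !include_all && n_el < min_trials)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate binding score from response frequencies
#'
#' The contingent binding score obtained directly from mean response
#' frequencies on binding probes: for re-paired probes the correct answer is
#' "different color", so the score is `diffcol / (old + diffcol)`; for
#' intact probes it is `old / (old + diffcol)`. `old` is the count of
#' same-object-same-color responses and `diffcol` of same-object-different-
#' color responses; "different object" responses are not eligible.
#'
#' @param old,diffcol Mean response frequencies.
#' @param type `"repaired"` or `"intact"`.
#' @return Binding score in \[0, 1\]; the complement of the binding-error
#'   rate on the eligible set.
#' @export
binding_score <- function(old, diffcol, type = "repaired") {
  if (!all(type %in% c("repaired", "intact")))
    stop("type must be 'repaired' or 'intact'")
  ifelse(type == "repaired", diffcol, old) / (old + diffcol)
}

#' Same-color guess-bias rate for one participant
#'
#' Among new-object probes mistakenly called old, the proportion answered
#' "same object-same color" rather than "same object-different color".
#' Because the probed object was never studied, these responses are pure
#' color guesses and expose the observer's guess bias.
#'
#' @param records Response records of one participant.
#' @param phase `"WM"` or `"LTM"`.
#' @return One-row data.frame: `n_false_old`, `n_same_color`, `rate` (NA
#'   when the participant produced no false "old" responses).
#' @export
bias_rates <- function(records, phase) {
  one_participant(records)
  r <- records[records$phase == phase & records$condition %in% NEW_CONDITIONS, ]
  false_old <- r[r$response %in% c("SS", "SD"), ]
  n <- nrow(false_old)
  data.frame(participant_id = records$participant_id[1], phase = phase,
             n_false_old = n, n_same_color = sum(false_old$response == "SS"),
             rate = if (n > 0) mean(false_old$response == "SS") else NA_real_)
}

#' Raw object-identification rates for one participant
#'
#' The uncorrected rate at which studied objects were called old (either
#' same-object option), per phase and set size, over all old-object probe
#' conditions including novel-color probes. Unlike [estimate_p()] this
#' measure ignores performance on lures.
#'
#' @param records Response records of one participant.
#' @param phase `"WM"` or `"LTM"`.
#' @return data.frame, one row per set size: `n_old`, `n_called_old`,
#'   `rate`.
#' @export
object_id_rates <- function(records, phase) {
  one_participant(records)
  r <- records[records$phase == phase & records$condition %in% OLD_CONDITIONS, ]
  out <- do.call(rbind, lapply(sort(unique(r$set_size)), function(s) {
    x <- r[r$set_size == s, ]
    data.frame(participant_id = records$participant_id[1], phase = phase,
               set_size = s, n_old = nrow(x),
               n_called_old = sum(x$response != "DO"),
               rate = mean(x$response != "DO"))
  }))
  rownames(out) <- NULL
  out
}
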