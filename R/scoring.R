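# Cohort-level scoring: vectorized application of the per-participant
# estimators to a long-format response table, plus the two report-shaped
# summaries (capacity table and binding-frequency table).

#' Score a cohort of response records
#'
#' Applies the full measurement battery to a long-format response table:
#' guessing-corrected `p(WM)` per set size and `p(LTM)` per originating set
#' size (with the implausible-value adjustment and Cowan's k), the LTM/WM
#' transfer ratio per participant and set size, contingent binding-error
#' cells, same-color guess-bias rates, and raw object-identification rates.
#' Participants with a false-alarm rate of 1 in some scope are degenerate
#' there; the affected estimates propagate as `NA` and are counted in the
#' attached bookkeeping log.
#'
#' @param records Response records for any number of participants
#'   ([simulate_cohort()] format, or any CSV with the same columns).
#' @param pool_wm_lures Compute a single pooled WM false-alarm rate instead
#'   of per-set-size rates.
#' @param binding_include_all Disable the minimum-trial exclusion for LTM
#'   binding cells.
#' @param adjust_rule Passed to [adjust_estimates()].
#' @return List of tidy data.frames: `item` (one row per participant x
#'   phase x set size with `h`, `f`, `p_raw`, `p`, `k`, `adjusted`),
#'   `ratio`, `binding`, `bias`, `object_id`; plus a `log` attribute with
#'   filter bookkeeping counts.
#' @export
score_cohort <- function(records, pool_wm_lures = FALSE,
                         binding_include_all = FALSE,
                         adjust_rule = "k_floor") {
  stopifnot(all(c("participant_id", "phase", "set_size", "condition",
                  "response") %in% names(records)))
  if (is.null(records$age_group)) records$age_group <- "all"
  log <- list(records_in = nrow(records))

  called <- records$response %in% c("SS", "SD")
  olds <- records[records$condition %in% OLD_CONDITIONS, ]
  olds$called <- called[records$condition %in% OLD_CONDITIONS]
  h_df <- stats::aggregate(called ~ participant_id + age_group + phase + set_size,
                           olds, mean)
  names(h_df)[names(h_df) == "called"] <- "h"

  wl <- records[records$phase == "WM" & records$condition %in% NEW_CONDITIONS, ]
  wl$called <- wl$response %in% c("SS", "SD")
  if (pool_wm_lures) {
    f_wm <- stats::aggregate(called ~ participant_id, wl, mean)
  } else {
    f_wm <- stats::aggregate(called ~ participant_id + set_size, wl, mean)
  }
  names(f_wm)[names(f_wm) == "called"] <- "f"
  ll <- records[records$phase == "LTM" & records$condition == "NEW", ]
  ll$called <- ll$response %in% c("SS", "SD")
  f_ltm <- stats::aggregate(called ~ participant_id, ll, mean)
  names(f_ltm)[names(f_ltm) == "called"] <- "f"

  wm <- merge(h_df[h_df$phase == "WM", ], f_wm,
              by = intersect(names(h_df), names(f_wm)))
  ltm <- merge(h_df[h_df$phase == "LTM", ], f_ltm, by = "participant_id")

  finish <- function(d, phase) {
    d$p_raw <- ifelse(d$f < 1, (d$h - d$f) / (1 - d$f), NA_real_)
    adj <- adjust_estimates(d$p_raw, phase, d$set_size, rule = adjust_rule)
    d$p <- adj$p
    d$adjusted <- adj$adjusted
    d$k <- if (phase == "WM") capacity_k(d$p, d$set_size) else NA_real_
    d[order(d$participant_id, d$set_size), ]
  }
  wm <- finish(wm, "WM")
  ltm <- finish(ltm, "LTM")
  log$degenerate_f <- sum(is.na(wm$p_raw)) + sum(is.na(ltm$p_raw))
  item <- rbind(wm, ltm)
  rownames(item) <- NULL

  both <- merge(wm[, c("participant_id", "age_group", "set_size", "p")],
                ltm[, c("participant_id", "set_size", "p")],
                by = c("participant_id", "set_size"),
                suffixes = c("_wm", "_ltm"))
  tr <- transfer_ratio(both$p_ltm, both$p_wm)
  ratio <- cbind(both, tr)
  ratio <- ratio[order(ratio$participant_id, ratio$set_size), ]
  rownames(ratio) <- NULL

  bb <- records[records$condition %in% c("SAME_SAME", "SAME_DIFF_SWAP"), ]
  log$binding_candidates <- nrow(bb)
  drop_probed <- bb$phase == "LTM" & (bb$was_wm_probe %in% TRUE)
  log$binding_dropped_wm_probed <- sum(drop_probed)
  bb <- bb[!drop_probed, ]
  bb$eligible <- bb$response != "DO"
  bb$err <- bb$eligible &
    ((bb$condition == "SAME_SAME" & bb$response == "SD") |
     (bb$condition == "SAME_DIFF_SWAP" & bb$response == "SS"))
  binding <- stats::aggregate(cbind(n_eligible = eligible, n_errors = err) ~
                                participant_id + age_group + phase + set_size,
                              bb, sum)
  binding$error_rate <- ifelse(binding$n_eligible > 0,
                               binding$n_errors / binding$n_eligible, NA_real_)
  binding$excluded <- binding$phase == "LTM" & !binding_include_all &
    binding$n_eligible < 5
  binding <- binding[order(binding$participant_id, binding$phase,
                           binding$set_size), ]
  rownames(binding) <- NULL
  log$binding_cells <- nrow(binding)
  log$binding_cells_excluded <- sum(binding$excluded)
  log$binding_ltm_instances <- sum(binding$phase == "LTM")
  log$binding_ltm_instances_excluded <-
    sum(binding$excluded[binding$phase == "LTM"])

  nb <- records[records$condition %in% NEW_CONDITIONS, ]
  nb$false_old <- nb$response %in% c("SS", "SD")
  nb$same_col <- nb$response == "SS"
  bias <- stats::aggregate(cbind(n_false_old = false_old,
                                 n_same_color = same_col) ~
                             participant_id + age_group + phase, nb, sum)
  bias$rate <- ifelse(bias$n_false_old > 0,
                      bias$n_same_color / bias$n_false_old, NA_real_)
  rownames(bias) <- NULL

  oid <- stats::aggregate(called ~ participant_id + age_group + phase + set_size,
                          olds, mean)
  names(oid)[names(oid) == "called"] <- "rate"

  log$records_used <- log$records_in
  out <- list(item = item, ratio = ratio, binding = binding, bias = bias,
              object_id = oid)
  attr(out, "log") <- log
  out
}

#' Capacity-table summary (group means by set size)
#'
#' Summarizes scored estimates into the canonical capacity table: per age
#' group and set size, mean (SD) of `p(WM)`, `p(LTM)`, the LTM/WM ratio,
#' the WM and LTM binding-error rates (excluded LTM cells dropped), and
#' Cowan's k. Undefined participant cells are dropped listwise from the
#' specific mean they would enter.
#'
#' @param scores Output of [score_cohort()].
#' @param digits Rounding (half-up) for the summary columns; `NULL` leaves
#'   values unrounded.
#' @return data.frame, one row per age group x set size.
#' @export
table1_summary <- function(scores, digits = NULL) {
  msd <- function(d, value, keys = c("age_group", "set_size")) {
    d <- d[!is.na(d[[value]]), ]
    m <- stats::aggregate(d[[value]], d[keys], mean)
    s <- stats::aggregate(d[[value]], d[keys], stats::sd)
    names(m)[ncol(m)] <- "mean"; names(s)[ncol(s)] <- "sd"
    merge(m, s, by = keys)
  }
  wm <- scores$item[scores$item$phase == "WM", ]
  ltm <- scores$item[scores$item$phase == "LTM", ]
  bwm <- scores$binding[scores$binding$phase == "WM", ]
  bltm <- scores$binding[scores$binding$phase == "LTM" &
                           !scores$binding$excluded, ]
  parts <- list(p_wm = msd(wm, "p"), p_ltm = msd(ltm, "p"),
                ratio = msd(scores$ratio, "ratio"),
                wm_binding_err = msd(bwm, "error_rate"),
                ltm_binding_err = msd(bltm, "error_rate"),
                k = msd(wm, "k"))
  out <- NULL
  for (nm in names(parts)) {
    p <- parts[[nm]]
    names(p)[names(p) == "mean"] <- paste0(nm, "_mean")
    names(p)[names(p) == "sd"] <- paste0(nm, "_sd")
    out <- if (is.null(out)) p else
      merge(out, p, by = c("age_group", "set_size"), all = TRUE)
  }
  out <- out[order(out$age_group, out$set_size), ]
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "set_size"
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  rownames(out) <- NULL
  out
}

#' Binding-frequency summary (response counts on binding probes)
#'
#' Per age group, phase and probe type (re-paired vs intact), the mean
#' per-participant frequency of each response ("Old" = same object-same
#' color, "DiffCol" = same object-different color, "DiffObj" = different
#' object), cumulative across set sizes, plus the aggregate binding score
#' computed from the mean frequencies via [binding_score()]. LTM intact
#' probes whose item served as a WM probe are excluded, mirroring the
#' contingent binding analysis.
#'
#' @param records Response records for a cohort.
#' @return data.frame, one row per age group x phase x probe type.
#' @export
table2_summary <- function(records) {
  r <- records[records$condition %in% c("SAME_SAME", "SAME_DIFF_SWAP"), ]
  r <- r[!(r$phase == "LTM" & (r$was_wm_probe %in% TRUE)), ]
  r$type <- ifelse(r$condition == "SAME_DIFF_SWAP", "repaired", "intact")
  n_part <- tapply(records$participant_id, records$age_group,
                   function(x) length(unique(x)))
  counts <- stats::aggregate(cbind(old = r$response == "SS",
                                   diffcol = r$response == "SD",
                                   diffobj = r$response == "DO"),
                             r[c("age_group", "phase", "type")], sum)
  counts[c("old", "diffcol", "diffobj")] <-
    counts[c("old", "diffcol", "diffobj")] /
    as.vector(n_part[counts$age_group])
  counts$binding_score <- binding_score(counts$old, counts$diffcol,
                                        ifelse(counts$type == "repaired",
                                               "repaired", "intact"))
  counts[order(counts$age_group, counts$phase, counts$type), ]
}
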