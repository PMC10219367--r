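# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as naive row loops so they share no code path with
# the vectorized implementations they check.

example_params <- function(...) {
  defaults <- list(k_true = 1.6, g_old = 0.4, beta_same = 0.7, b_wm = 0.6,
                   d_novel = 0.8, tau_ltm = 0.5, b_ltm = 0.5,
                   g_old_ltm = 0.3)
  do.call(participant_params, utils::modifyList(defaults, list(...)))
}

# A profile with no heterogeneity, handy for analytic comparisons.
flat_profile <- function(name = "flat", n = 5, ...) {
  p <- unlist(unclass(example_params(...)))
  age_group_profile(name, n, means = p, sds = p * 0)
}

small_profiles <- function(n = 4) {
  lapply(default_profiles(), function(p) {
    p$n <- as.integer(n)
    p
  })
}

# Build a minimal records table by hand.
make_records <- function(phase, condition, response, set_size = 2,
                         was_wm_probe = FALSE, participant_id = "p0001") {
  n <- max(lengths(list(phase, condition, response)))
  data.frame(participant_id = participant_id, age_group = "test",
             phase = rep_len(phase, n), probe_index = seq_len(n),
             set_size = rep_len(set_size, n),
             condition = rep_len(condition, n),
             was_wm_probe = rep_len(was_wm_probe, n),
             presentation_order = seq_len(n),
             response = rep_len(response, n),
             stringsAsFactors = FALSE)
}

# Sample `n_per_cell` responses per (phase, condition, set_size) cell
# directly from the analytic response triple: a design-free generative
# oracle for estimator-consistency checks.
records_from_probs <- function(params, n_per_cell, cells) {
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    pr <- response_probabilities(cl$condition, cl$phase, cl$set_size, params)
    resp <- sample(c("SS", "SD", "DO"), n_per_cell, replace = TRUE, prob = pr)
    make_records(cl$phase, cl$condition, resp, cl$set_size)
  })
  out <- do.call(rbind, rows)
  out$probe_index <- seq_len(nrow(out))
  out
}

withr_like_tempdir <- function() {
  d <- tempfile("wmt")
  dir.create(d)
  d
}

oracle_tally <- function(records, phase, set_size) {
  n_old <- n_old_called <- n_new <- n_new_called <- 0
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$phase != phase) next
    old <- r$condition %in% c("SAME_SAME", "SAME_DIFF_SWAP", "SAME_DIFF_NOVEL")
    called <- r$response == "SS" || r$response == "SD"
    if (old && !is.na(r$set_size) && r$set_size == set_size) {
      n_old <- n_old + 1
      if (called) n_old_called <- n_old_called + 1
    }
    if (!old) {
      in_scope <- if (phase == "WM") !is.na(r$set_size) && r$set_size == set_size
                  else r$condition == "NEW"
      if (in_scope) {
        n_new <- n_new + 1
        if (called) n_new_called <- n_new_called + 1
      }
    }
  }
  list(h = n_old_called / n_old, f = n_new_called / n_new)
}

oracle_binding <- function(records, phase, set_size) {
  n_el <- n_err <- 0
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$phase != phase || is.na(r$set_size) || r$set_size != set_size) next
    if (!(r$condition %in% c("SAME_SAME", "SAME_DIFF_SWAP"))) next
    if (phase == "LTM" && isTRUE(r$was_wm_probe)) next
    if (r$response == "DO") next
    n_el <- n_el + 1
    wrong <- (r$condition == "SAME_SAME" && r$response == "SD") ||
      (r$condition == "SAME_DIFF_SWAP" && r$response == "SS")
    if (wrong) n_err <- n_err + 1
  }
  list(n_eligible = n_el, n_errors = n_err)
}
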