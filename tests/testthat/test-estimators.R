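test_that("tally_recognition scores same-object responses as hits", {
  rec <- make_records("WM",
                      c(rep("SAME_SAME", 3), "DIFF_OBJ_ARRAYCOLOR",
                        "DIFF_OBJ_NOVELCOLOR"),
                      c("SS", "SD", "DO", "SS", "DO"))
  tl <- tally_recognition(rec, "WM", 2)
  expect_equal(tl$n_old, 3)
  expect_equal(tl$n_old_called_old, 2)  # DO on an old probe is a miss
  expect_equal(tl$n_new, 2)
  expect_equal(tl$n_new_called_old, 1)
  expect_equal(tl$h, 2 / 3)
  expect_equal(tl$f, 1 / 2)
  expect_error(tally_recognition(rec, "LTM", 2), "empty")
  two <- rbind(rec, transform(rec, participant_id = "p0002"))
  expect_error(tally_recognition(two, "WM", 2), "single participant")
})

test_that("tallies match a brute-force recount on simulated data", {
  wm <- generate_wm_design(8)
  ltm <- generate_ltm_design(wm, 8)
  sim <- simulate_cohort(wm, ltm, flat_profile(n = 1), seed = 21)
  r <- sim$records
  for (s in c(2, 3, 4)) {
    for (phase in c("WM", "LTM")) {
      tl <- tally_recognition(r, phase, s)
      oc <- oracle_tally(r, phase, s)
      expect_equal(tl$h, oc$h)
      expect_equal(tl$f, oc$f)
    }
  }
})

test_that("estimate_p applies the single-probe guessing correction", {
  expect_equal(estimate_p(list(h = 0.9, f = 0.2)), 0.875)
  expect_equal(estimate_p(list(h = 0.3, f = 0.3)), 0)    # h = f
  expect_equal(estimate_p(list(h = 1, f = 0.6)), 1)      # h = 1
  expect_lt(estimate_p(list(h = 0.1, f = 0.3)), 0)       # negative raw value
  expect_error(estimate_p(list(h = 1, f = 1)), "degenerate")
  # algebraic inversion: p fed through h = p + (1 - p) g comes back exactly
  for (p in c(0, 0.25, 0.8, 1)) {
    g <- 0.2
    expect_equal(estimate_p(list(h = p + (1 - p) * g, f = g)), p)
  }
})

test_that("implausible-value adjustment floors k at 1 and p(LTM) at 0", {
  a <- adjust_estimates(0.1, "WM", 4)
  expect_equal(a$p, 0.25)  # k floored at 1 => p = 1/S
  expect_true(a$adjusted)
  b <- adjust_estimates(-0.07, "LTM")
  expect_equal(b$p, 0)
  expect_true(b$adjusted)
  c <- adjust_estimates(0.79, "WM", 2)
  expect_equal(c$p, 0.79)
  expect_false(c$adjusted)
  # idempotence and never-lowering, across a grid
  for (raw in seq(-0.5, 1, by = 0.1)) {
    for (s in c(2, 3, 4)) {
      once <- adjust_estimates(raw, "WM", s)
      twice <- adjust_estimates(once$p, "WM", s)
      expect_equal(twice$p, once$p)
      expect_gte(once$p, raw)
    }
    oncel <- adjust_estimates(raw, "LTM")
    expect_equal(adjust_estimates(oncel$p, "LTM")$p, oncel$p)
  }
  # alternative reading kept behind a flag
  alt <- adjust_estimates(0.79, "WM", 2, rule = "p_floor")
  expect_equal(alt$p, 1)
  expect_true(alt$adjusted)
})

test_that("capacity and transfer-ratio arithmetic", {
  expect_equal(capacity_k(0.90, 4), 3.6)
  expect_equal(capacity_k(0.79, 2), 1.58)
  expect_equal(capacity_k(0, 3), 0)
  expect_equal(transfer_ratio(0.52, 0.95)$ratio, 0.547, tolerance = 1e-3)
  expect_equal(transfer_ratio(0, 0.5)$ratio, 0)
  zero <- transfer_ratio(0.3, 0)
  expect_false(zero$defined)
  expect_true(is.na(zero$ratio))
})

test_that("binding cells apply eligibility filters and recount exactly", {
  # all intact probes answered SS: eligible, no errors
  rec <- make_records("WM", "SAME_SAME", "SS", set_size = 3)
  bc <- binding_cells(rec, "WM")
  expect_equal(bc$error_rate, 0)
  # novel-color probes never enter binding scoring
  recn <- make_records("WM", c("SAME_SAME", "SAME_DIFF_NOVEL"), c("SS", "SS"))
  expect_equal(binding_cells(recn, "WM")$n_eligible, 1)
  # oracle recount on simulated data
  wm <- generate_wm_design(9)
  ltm <- generate_ltm_design(wm, 9)
  sim <- simulate_cohort(wm, ltm, flat_profile(n = 1), seed = 31)
  for (phase in c("WM", "LTM")) {
    bc <- binding_cells(sim$records, phase)
    for (i in seq_len(nrow(bc))) {
      oc <- oracle_binding(sim$records, phase, bc$set_size[i])
      expect_equal(bc$n_eligible[i], oc$n_eligible)
      expect_equal(bc$n_errors[i], oc$n_errors)
    }
  }
})

test_that("LTM binding drops WM-probed items and sparse cells", {
  rec <- rbind(
    make_records("LTM", "SAME_SAME", "SS", set_size = 2, was_wm_probe = TRUE),
    make_records("LTM", rep("SAME_SAME", 3), c("SS", "SD", "DO"), set_size = 2),
    make_records("LTM", rep("SAME_DIFF_SWAP", 3), c("SD", "SS", "DO"),
                 set_size = 2))
  bc <- binding_cells(rec, "LTM")
  expect_equal(bc$n_eligible, 4)  # WM-probed and DO rows dropped
  expect_equal(bc$n_errors, 2)    # one SD on intact, one SS on re-paired
  expect_true(bc$excluded)        # fewer than 5 eligible probes
  expect_false(binding_cells(rec, "LTM", include_all = TRUE)$excluded)
})

test_that("binding scoring is invariant to a global color relabeling", {
  wm <- generate_wm_design(12)
  relabel <- setNames(c("red", "blue", "orange", "green", "brown", "indigo"),
                      wm_colors())
  wm2 <- wm
  wm2$items$color <- unname(relabel[wm2$items$color])
  wm2$trials$probe_color <- unname(relabel[wm2$trials$probe_color])
  expect_length(validate_design(wm2), 0)
  ltm <- generate_ltm_design(wm, 12)
  ltm2 <- ltm
  ltm2$probes$probe_color <- unname(relabel[ltm2$probes$probe_color])
  expect_length(validate_design(wm2, ltm2), 0)
  s1 <- simulate_cohort(wm, ltm, flat_profile(n = 2), seed = 5)
  s2 <- simulate_cohort(wm2, ltm2, flat_profile(n = 2), seed = 5)
  expect_identical(binding_cells(s1$records[s1$records$participant_id == "p0001", ], "WM"),
                   binding_cells(s2$records[s2$records$participant_id == "p0001", ], "WM"))
})

test_that("with no binding memory the balanced error rate is exactly 1/2", {
  for (beta in c(0.1, 0.5, 0.7, 0.95)) {
    for (g in c(0.1, 0.4)) {
      for (k in c(0.5, 1.5, 3)) {
        pp <- example_params(k_true = k, g_old = g, beta_same = beta,
                             b_wm = 0, d_novel = 0.5)
        ss <- response_probabilities("SAME_SAME", "WM", 2, pp)
        sw <- response_probabilities("SAME_DIFF_SWAP", "WM", 2, pp)
        errors <- ss[["SD"]] + sw[["SS"]]
        eligible <- (1 - ss[["DO"]]) + (1 - sw[["DO"]])
        expect_equal(errors / eligible, 0.5, tolerance = 1e-12)
      }
    }
  }
})

test_that("bias rates count same-color guesses on false alarms", {
  rec <- make_records("WM", rep("DIFF_OBJ_ARRAYCOLOR", 12),
                      c(rep("SS", 7), rep("SD", 3), rep("DO", 2)))
  br <- bias_rates(rec, "WM")
  expect_equal(br$n_false_old, 10)
  expect_equal(br$rate, 0.7)
  none <- make_records("WM", rep("DIFF_OBJ_ARRAYCOLOR", 4), "DO")
  expect_true(is.na(bias_rates(none, "WM")$rate))
})

test_that("object-identification rates are raw and recountable", {
  rec <- make_records("WM", c("SAME_SAME", "SAME_DIFF_NOVEL", "SAME_SAME"),
                      c("SS", "SD", "SS"), set_size = 2)
  expect_equal(object_id_rates(rec, "WM")$rate, 1)
  wm <- generate_wm_design(13)
  ltm <- generate_ltm_design(wm, 13)
  sim <- simulate_cohort(wm, ltm, flat_profile(n = 1), seed = 41)
  oir <- object_id_rates(sim$records, "WM")
  for (i in seq_len(nrow(oir))) {
    r <- sim$records
    rows <- r[r$phase == "WM" & r$set_size == oir$set_size[i] &
                r$condition %in% c("SAME_SAME", "SAME_DIFF_SWAP",
                                   "SAME_DIFF_NOVEL"), ]
    expect_equal(oir$rate[i], mean(rows$response != "DO"))
  }
})

test_that("estimators are consistent under the generative model", {
  set.seed(404)
  pp <- example_params(k_true = 2.2, g_old = 0.25, beta_same = 0.72,
                       tau_ltm = 0.5)
  cells <- rbind(
    expand.grid(phase = "WM", set_size = c(2, 3, 4),
                condition = c("SAME_SAME", "SAME_DIFF_SWAP",
                              "SAME_DIFF_NOVEL", "DIFF_OBJ_ARRAYCOLOR"),
                stringsAsFactors = FALSE),
    expand.grid(phase = "LTM", set_size = c(2, 3, 4),
                condition = c("SAME_SAME", "SAME_DIFF_SWAP",
                              "SAME_DIFF_NOVEL"),
                stringsAsFactors = FALSE),
    data.frame(phase = "LTM", set_size = 2, condition = "NEW"))
  rec <- records_from_probs(pp, 10000, cells)
  for (s in c(2, 3, 4)) {
    p_wm <- estimate_p(tally_recognition(rec, "WM", s))
    expect_lt(abs(p_wm - min(pp$k_true / s, 1)), 0.01)
    p_ltm <- estimate_p(tally_recognition(rec, "LTM", s))
    expect_lt(abs(p_ltm - min(pp$k_true / s, 1) * pp$tau_ltm), 0.02)
  }
  expect_lt(abs(bias_rates(rec, "WM")$rate - pp$beta_same), 0.01)
})

test_that("cohort-level scoring agrees with the per-participant estimators", {
  wm <- generate_wm_design(14)
  ltm <- generate_ltm_design(wm, 14)
  sim <- simulate_cohorts(wm, ltm, small_profiles(n = 3), seed = 6)
  scores <- score_cohort(sim$records)
  for (pid in unique(sim$records$participant_id)[c(1, 5, 9)]) {
    r <- sim$records[sim$records$participant_id == pid, ]
    for (s in c(2, 3, 4)) {
      row <- scores$item[scores$item$participant_id == pid &
                           scores$item$phase == "WM" &
                           scores$item$set_size == s, ]
      tl <- tally_recognition(r, "WM", s)
      expect_equal(row$h, tl$h)
      expect_equal(row$f, tl$f)
      expect_equal(row$p_raw, estimate_p(tl))
      adj <- adjust_estimates(estimate_p(tl), "WM", s)
      expect_equal(row$p, adj$p)
      expect_equal(row$k, capacity_k(adj$p, s))
    }
    bc <- binding_cells(r, "LTM")
    sc <- scores$binding[scores$binding$participant_id == pid &
                           scores$binding$phase == "LTM", ]
    expect_equal(sc$n_eligible, bc$n_eligible)
    expect_equal(sc$n_errors, bc$n_errors)
    expect_equal(sc$excluded, bc$excluded)
    expect_equal(scores$bias$rate[scores$bias$participant_id == pid &
                                    scores$bias$phase == "WM"],
                 bias_rates(r, "WM")$rate)
  }
  # mean transfer ratio equals a brute-force per-participant recomputation
  wmp <- scores$item[scores$item$phase == "WM", ]
  ltp <- scores$item[scores$item$phase == "LTM", ]
  brute <- mapply(function(pid, s) {
    ltp$p[ltp$participant_id == pid & ltp$set_size == s] /
      wmp$p[wmp$participant_id == pid & wmp$set_size == s]
  }, scores$ratio$participant_id, scores$ratio$set_size)
  expect_equal(mean(scores$ratio$ratio), mean(brute))
})

test_that("bias-rate group means recover the generating bias at scale", {
  wm <- generate_wm_design(15)
  ltm <- generate_ltm_design(wm, 15)
  prof <- flat_profile(n = 200, beta_same = 0.72, g_old = 0.3)
  sim <- simulate_cohort(wm, ltm, prof, seed = 51)
  scores <- score_cohort(sim$records)
  wm_rates <- scores$bias$rate[scores$bias$phase == "WM"]
  expect_equal(mean(wm_rates, na.rm = TRUE), 0.72, tolerance = 0.02)
})

test_that("pooled WM lures switch changes the false-alarm scope only", {
  wm <- generate_wm_design(16)
  ltm <- generate_ltm_design(wm, 16)
  sim <- simulate_cohort(wm, ltm, flat_profile(n = 3), seed = 61)
  per <- score_cohort(sim$records)
  pooled <- score_cohort(sim$records, pool_wm_lures = TRUE)
  pw <- pooled$item[pooled$item$phase == "WM", ]
  expect_true(all(tapply(pw$f, pw$participant_id, function(x)
    length(unique(x)) == 1)))
  expect_equal(per$item$h[per$item$phase == "WM"], pw$h)
})
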