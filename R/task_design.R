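# Task-design generation: WM probe-recognition trials and the delayed LTM
# recognition test.
#
# Fixed structural constants of the WM task: 120 trials (54 at set size 2,
# 36 at set size 3, 30 at set size 4), hence 54*2 + 36*3 + 30*4 = 336
# studied items. Within each set size the probe conditions split into
# thirds (same object-same color / same object-different color / different
# object), and each "different" third is halved (swap vs novel color;
# array vs novel color). All cells are even so no tie-breaking is needed.
WM_SETSIZE_TRIALS <- c(`2` = 54L, `3` = 36L, `4` = 30L)
N_STUDIED_ITEMS <- 336L
N_WM_TRIALS <- 120L
N_NOVEL_WM_PROBES <- 40L
N_LTM_PROBES <- 144L
N_LTM_NEW <- 48L
N_LTM_PER_SETSIZE <- 32L

# condition -> correct response
correct_response_for <- function(condition) {
  c(SAME_SAME = "SS", SAME_DIFF_SWAP = "SD", SAME_DIFF_NOVEL = "SD",
    DIFF_OBJ_ARRAYCOLOR = "DO", DIFF_OBJ_NOVELCOLOR = "DO",
    NEW = "DO")[condition]
}

wm_condition_counts <- function(n_trials) {
  third <- n_trials %/% 3L
  half <- third %/% 2L
  c(SAME_SAME = third,
    SAME_DIFF_SWAP = half, SAME_DIFF_NOVEL = half,
    DIFF_OBJ_ARRAYCOLOR = half, DIFF_OBJ_NOVELCOLOR = half)
}

#' Generate a working-memory task design
#'
#' Builds the 120-trial single-probe WM design: 54 trials at set size 2, 36
#' at set size 3 and 30 at set size 4, each presenting a sequence of unique
#' items in distinct colors (drawn from the six task colors) followed by one
#' probe. Probe conditions split into thirds within each set size: intact
#' probes (`SAME_SAME`), old objects in a changed color (`SAME_DIFF_SWAP`,
#' wearing another array item's color, or `SAME_DIFF_NOVEL`, wearing a color
#' absent from the array), and new objects (`DIFF_OBJ_ARRAYCOLOR` /
#' `DIFF_OBJ_NOVELCOLOR`). Trial order is a seed-dependent permutation; the
#' same seed always reproduces the identical design.
#'
#' @param seed Integer seed; the design is a deterministic function of it.
#' @return An object of class `wm_design`: a list with `trials` (one row per
#'   trial: `trial_index`, `set_size`, `probe_object`, `probe_color`,
#'   `condition`, `correct_response`), `items` (one row per studied item:
#'   `trial_index`, `set_size`, `position`, `item_id`, `color`), and
#'   `color_count`.
#' @seealso [generate_ltm_design()], [validate_design()]
#' @examples
#' wm <- generate_wm_design(seed = 1)
#' nrow(wm$trials)           # 120
#' length(unique(wm$items$item_id))  # 336
#' @export
generate_wm_design <- function(seed) {
  with_seed(seed, {
    set_sizes <- rep(as.integer(names(WM_SETSIZE_TRIALS)), WM_SETSIZE_TRIALS)
    conditions <- unlist(lapply(WM_SETSIZE_TRIALS, function(n) {
      rep(names(wm_condition_counts(n)), wm_condition_counts(n))
    }), use.names = FALSE)
    ord <- sample.int(N_WM_TRIALS)
    set_sizes <- set_sizes[ord]
    conditions <- conditions[ord]

    next_item <- 1L
    next_novel <- N_STUDIED_ITEMS + 1L
    items <- vector("list", N_WM_TRIALS)
    trials <- vector("list", N_WM_TRIALS)
    for (t in seq_len(N_WM_TRIALS)) {
      s <- set_sizes[t]
      cond <- conditions[t]
      ids <- seq.int(next_item, length.out = s)
      next_item <- next_item + s
      cols <- sample(WM_COLORS, s)
      absent <- setdiff(WM_COLORS, cols)
      if (cond == "SAME_SAME") {
        pos <- sample.int(s, 1)
        probe_object <- ids[pos]; probe_color <- cols[pos]
      } else if (cond == "SAME_DIFF_SWAP") {
        pos <- sample.int(s, 1)
        others <- setdiff(seq_len(s), pos)
        other <- others[sample.int(length(others), 1)]  # length-safe
        probe_object <- ids[pos]; probe_color <- cols[other]
      } else if (cond == "SAME_DIFF_NOVEL") {
        pos <- sample.int(s, 1)
        probe_object <- ids[pos]; probe_color <- sample(absent, 1)
      } else if (cond == "DIFF_OBJ_ARRAYCOLOR") {
        probe_object <- next_novel; next_novel <- next_novel + 1L
        probe_color <- sample(cols, 1)
      } else { # DIFF_OBJ_NOVELCOLOR
        probe_object <- next_novel; next_novel <- next_novel + 1L
        probe_color <- sample(absent, 1)
      }
      items[[t]] <- data.frame(trial_index = t, set_size = s,
                               position = seq_len(s), item_id = ids,
                               color = cols, stringsAsFactors = FALSE)
      trials[[t]] <- data.frame(trial_index = t, set_size = s,
                                probe_object = as.integer(probe_object),
                                probe_color = probe_color,
                                condition = cond,
                                correct_response = unname(correct_response_for(cond)),
                                stringsAsFactors = FALSE)
    }
    out <- list(trials = do.call(rbind, trials),
                items = do.call(rbind, items),
                color_count = length(WM_COLORS), seed = as.integer(seed))
    class(out) <- "wm_design"
    out
  })
}

# Greedy sampler: pick `n` item ids from `pool` (columns item_id,
# trial_index), preferring items from trials not yet used so that LTM probes
# spread across WM trials; reuses trials only when unavoidable.
pick_spread <- function(pool, n, used_trials) {
  picked <- integer(0)
  for (i in seq_len(n)) {
    avail <- pool[!(pool$item_id %in% picked), , drop = FALSE]
    if (nrow(avail) == 0L)
      stop("not enough eligible items in WM design for an LTM cell")
    fresh <- avail[!(avail$trial_index %in% used_trials), , drop = FALSE]
    cand <- if (nrow(fresh) > 0L) fresh else avail
    j <- cand[sample.int(nrow(cand), 1L), ]
    picked <- c(picked, j$item_id)
    used_trials <- c(used_trials, j$trial_index)
  }
  list(items = picked, used_trials = used_trials)
}

#' Generate the long-term-memory test design
#'
#' Builds the 144-probe LTM recognition test from a WM design: 48 new
#' objects (never studied, never used as WM probes) plus 32 studied items
#' per originating set size. Within each set size, 16 probes change the
#' item's color (8 `SAME_DIFF_SWAP`, re-paired with another color from the
#' item's original array; 8 `SAME_DIFF_NOVEL`, a color absent from that
#' array) and 16 show the item intact (`SAME_SAME`), half of which reuse
#' items that already served as intact WM probes (`was_wm_probe`). All other
#' studied probes are drawn from items never probed in the WM phase, spread
#' across WM trials where possible.
#'
#' @param wm A `wm_design` from [generate_wm_design()].
#' @param seed Integer seed for the (reproducible) item sampling and probe
#'   order.
#' @return An object of class `ltm_design`: a data.frame `probes` with
#'   columns `probe_index`, `origin`, `origin_set_size`, `condition`,
#'   `was_wm_probe`, `probe_object`, `probe_color`, `correct_response`.
#' @export
generate_ltm_design <- function(wm, seed) {
  stopifnot(inherits(wm, "wm_design"))
  with_seed(seed, {
    items <- wm$items
    trials <- wm$trials
    old_probe_trials <- trials[trials$condition %in%
                                 c("SAME_SAME", "SAME_DIFF_SWAP", "SAME_DIFF_NOVEL"), ]
    wm_probed_ids <- old_probe_trials$probe_object
    ss_probe_trials <- trials[trials$condition == "SAME_SAME", ]

    half <- N_LTM_PER_SETSIZE / 4L  # 8 per sub-cell
    probes <- list()
    for (s in c(2L, 3L, 4L)) {
      # intact probes of items that already served as intact WM probes
      cand_probed <- ss_probe_trials[ss_probe_trials$set_size == s,
                                     c("probe_object", "trial_index")]
      names(cand_probed)[1] <- "item_id"
      if (nrow(cand_probed) < half)
        stop("WM design has too few intact probes at set size ", s)
      sel <- cand_probed[sample.int(nrow(cand_probed), half), ]
      used <- sel$trial_index
      probed_ss <- sel$item_id

      # remaining cells use items never probed in the WM phase
      pool <- items[items$set_size == s & !(items$item_id %in% wm_probed_ids),
                    c("item_id", "trial_index")]
      got <- pick_spread(pool, 3L * half, used)
      rest <- sample(got$items)  # random split into the three cells
      unprobed_ss <- rest[seq_len(half)]
      swap_ids <- rest[half + seq_len(half)]
      novel_ids <- rest[2L * half + seq_len(half)]

      item_row <- function(id) items[items$item_id == id, ]
      array_colors <- function(id) {
        tr <- items$trial_index[items$item_id == id]
        items$color[items$trial_index == tr]
      }
      mk <- function(ids, condition, was_probe) {
        do.call(rbind, lapply(ids, function(id) {
          own <- item_row(id)$color
          col <- switch(condition,
            SAME_SAME = own,
            SAME_DIFF_SWAP = {
              opts <- setdiff(array_colors(id), own)
              opts[sample.int(length(opts), 1L)]
            },
            SAME_DIFF_NOVEL = {
              opts <- setdiff(WM_COLORS, array_colors(id))
              opts[sample.int(length(opts), 1L)]
            })
          data.frame(origin = "STUDIED", origin_set_size = s,
                     condition = condition, was_wm_probe = was_probe,
                     probe_object = id, probe_color = col,
                     correct_response = unname(correct_response_for(condition)),
                     stringsAsFactors = FALSE)
        }))
      }
      probes[[length(probes) + 1L]] <- rbind(
        mk(probed_ss, "SAME_SAME", TRUE),
        mk(unprobed_ss, "SAME_SAME", FALSE),
        mk(swap_ids, "SAME_DIFF_SWAP", FALSE),
        mk(novel_ids, "SAME_DIFF_NOVEL", FALSE))
    }

    new_start <- N_STUDIED_ITEMS + N_NOVEL_WM_PROBES + 1L
    new_probes <- data.frame(
      origin = "NEW", origin_set_size = NA_integer_, condition = "NEW",
      was_wm_probe = FALSE,
      probe_object = seq.int(new_start, length.out = N_LTM_NEW),
      probe_color = sample(WM_COLORS, N_LTM_NEW, replace = TRUE),
      correct_response = "DO", stringsAsFactors = FALSE)

    all_probes <- rbind(do.call(rbind, probes), new_probes)
    all_probes <- all_probes[sample.int(nrow(all_probes)), ]
    all_probes <- cbind(probe_index = seq_len(nrow(all_probes)), all_probes)
    rownames(all_probes) <- NULL
    out <- list(probes = all_probes, seed = as.integer(seed))
    class(out) <- "ltm_design"
    out
  })
}

#' Validate a pair of task designs against the structural constraints
#'
#' Checks every structural invariant of the WM and (optionally) LTM designs
#' and returns the violations found, without modifying its inputs. Generator
#' output always yields an empty report.
#'
#' @param wm A `wm_design`.
#' @param ltm Optionally, an `ltm_design` built from `wm`.
#' @return Character vector of human-readable violation messages (empty when
#'   the designs are valid).
#' @export
validate_design <- function(wm, ltm = NULL) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  tr <- wm$trials; it <- wm$items

  if (nrow(tr) != N_WM_TRIALS) add(sprintf("trial count: %d != 120", nrow(tr)))
  cnt <- table(factor(tr$set_size, levels = c(2, 3, 4)))
  if (!all(cnt == WM_SETSIZE_TRIALS))
    add("set-size trial counts differ from 54/36/30")
  if (length(unique(it$item_id)) != nrow(it) || nrow(it) != N_STUDIED_ITEMS)
    add(sprintf("studied items: %d unique of %d rows (expected 336)",
                length(unique(it$item_id)), nrow(it)))
  ccount <- table(factor(tr$condition, levels = WM_CONDITIONS))
  if (!all(ccount == c(40, 20, 20, 20, 20)))
    add("WM probe-condition counts differ from 40/20/20/20/20")

  studied <- it$item_id
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    arr <- it[it$trial_index == t$trial_index, ]
    lab <- sprintf("trial %d", t$trial_index)
    if (nrow(arr) != t$set_size) add(paste(lab, "item count != set size"))
    if (anyDuplicated(arr$color)) add(paste(lab, "repeated within-trial color"))
    own <- arr$color[match(t$probe_object, arr$item_id)]
    in_array_obj <- t$probe_object %in% arr$item_id
    switch(t$condition,
      SAME_SAME = {
        if (!in_array_obj || !identical(t$probe_color, own))
          add(paste(lab, "SAME_SAME probe not an intact array item"))
      },
      SAME_DIFF_SWAP = {
        if (!in_array_obj || identical(t$probe_color, own) ||
            !(t$probe_color %in% arr$color))
          add(paste(lab, "SWAP probe color must belong to a different array item"))
      },
      SAME_DIFF_NOVEL = {
        if (!in_array_obj || t$probe_color %in% arr$color)
          add(paste(lab, "NOVEL probe color must be absent from the array"))
      },
      DIFF_OBJ_ARRAYCOLOR = {
        if (t$probe_object %in% studied || !(t$probe_color %in% arr$color))
          add(paste(lab, "DIFF_OBJ_ARRAYCOLOR probe malformed"))
      },
      DIFF_OBJ_NOVELCOLOR = {
        if (t$probe_object %in% studied || t$probe_color %in% arr$color)
          add(paste(lab, "DIFF_OBJ_NOVELCOLOR probe malformed"))
      })
    if (!identical(t$correct_response, unname(correct_response_for(t$condition))))
      add(paste(lab, "correct_response inconsistent with condition"))
  }

  if (!is.null(ltm)) {
    pr <- ltm$probes
    if (nrow(pr) != N_LTM_PROBES) add(sprintf("LTM probe count: %d != 144", nrow(pr)))
    if (sum(pr$origin == "NEW") != N_LTM_NEW) add("LTM NEW count != 48")
    for (s in c(2, 3, 4)) {
      cell <- pr[!is.na(pr$origin_set_size) & pr$origin_set_size == s, ]
      if (nrow(cell) != N_LTM_PER_SETSIZE)
        add(sprintf("LTM set-size %d count != 32", s))
      if (sum(cell$condition == "SAME_DIFF_SWAP") != 8 ||
          sum(cell$condition == "SAME_DIFF_NOVEL") != 8 ||
          sum(cell$condition == "SAME_SAME" & cell$was_wm_probe) != 8 ||
          sum(cell$condition == "SAME_SAME" & !cell$was_wm_probe) != 8)
        add(sprintf("LTM set-size %d sub-cells differ from 8/8/8/8", s))
    }
    if (any(pr$was_wm_probe & pr$condition != "SAME_SAME"))
      add("was_wm_probe set outside SAME_SAME")
    ss_wm_probes <- tr$probe_object[tr$condition == "SAME_SAME"]
    bad <- pr$was_wm_probe & !(pr$probe_object %in% ss_wm_probes)
    if (any(bad)) add("was_wm_probe item was never an intact WM probe")
    all_wm_probes <- tr$probe_object
    newp <- pr[pr$origin == "NEW", ]
    if (any(newp$probe_object %in% c(studied, all_wm_probes)))
      add("NEW LTM probe object reuses a studied item or WM probe id")
    oldp <- pr[pr$origin == "STUDIED", ]
    if (any(!(oldp$probe_object %in% studied)))
      add("STUDIED LTM probe not among studied items")
    if (any(!pr$was_wm_probe & pr$origin == "STUDIED" &
            pr$probe_object %in% all_wm_probes))
      add("non-flagged studied LTM probe reuses a WM probe item")
    # color constraints for studied probes
    for (i in which(pr$origin == "STUDIED")) {
      p <- pr[i, ]
      trix <- it$trial_index[match(p$probe_object, it$item_id)]
      arr <- it[it$trial_index == trix, ]
      own <- arr$color[arr$item_id == p$probe_object]
      lab <- sprintf("LTM probe %d", p$probe_index)
      if (p$condition == "SAME_SAME" && !identical(p$probe_color, own))
        add(paste(lab, "SAME_SAME color differs from studied color"))
      if (p$condition == "SAME_DIFF_SWAP" &&
          (identical(p$probe_color, own) || !(p$probe_color %in% arr$color)))
        add(paste(lab, "SWAP color must be another color of the original array"))
      if (p$condition == "SAME_DIFF_NOVEL" && p$probe_color %in% arr$color)
        add(paste(lab, "NOVEL color must be absent from the original array"))
    }
  }
  v
}

#' @export
print.wm_design <- function(x, ...) {
  cat("WM design:", nrow(x$trials), "trials,", nrow(x$items),
      "studied items (seed", x$seed, ")\n")
  print(table(set_size = x$trials$set_size, condition = x$trials$condition))
  invisible(x)
}

#' @export
print.ltm_design <- function(x, ...) {
  cat("LTM design:", nrow(x$probes), "probes (seed", x$seed, ")\n")
  print(table(x$probes$condition))
  invisible(x)
}

#' Write task designs to CSV and JSON
#'
#' Serializes a WM design (one row per trial-item and one row per probe) and
#' an LTM design to `wm_design.csv`, `ltm_design.csv` and a combined
#' `design.json` under `dir`.
#'
#' @param wm A `wm_design`.
#' @param ltm An `ltm_design`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_design <- function(wm, ltm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  items <- wm$items
  items$row_type <- "item"
  probes <- wm$trials
  probes$row_type <- "probe"
  wm_long <- merge(items, probes,
                   by = c("trial_index", "set_size", "row_type"), all = TRUE,
                   sort = FALSE)
  wm_long <- wm_long[order(wm_long$trial_index, wm_long$row_type,
                           wm_long$position), ]
  p_wm <- file.path(dir, "wm_design.csv")
  p_ltm <- file.path(dir, "ltm_design.csv")
  p_json <- file.path(dir, "design.json")
  utils::write.csv(wm_long, p_wm, row.names = FALSE, na = "")
  utils::write.csv(ltm$probes, p_ltm, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(wm = list(trials = wm$trials, items = wm$items, seed = wm$seed),
         ltm = list(probes = ltm$probes, seed = ltm$seed)),
    p_json, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
  invisible(c(p_wm, p_ltm, p_json))
}
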