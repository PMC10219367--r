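#' @keywords internal
"_PACKAGE"

# Color vocabulary of the task. Exactly six distinct labels; set sizes never
# exceed 4, so within-trial colors can always be sampled without replacement
# and a "novel" (absent-from-array) color always exists.
WM_COLORS <- c("blue", "brown", "green", "indigo", "orange", "red")

# Probe condition labels.
WM_CONDITIONS <- c("SAME_SAME", "SAME_DIFF_SWAP", "SAME_DIFF_NOVEL",
                   "DIFF_OBJ_ARRAYCOLOR", "DIFF_OBJ_NOVELCOLOR")
LTM_CONDITIONS <- c("NEW", "SAME_SAME", "SAME_DIFF_SWAP", "SAME_DIFF_NOVEL")
RESPONSES <- c("SS", "SD", "DO")

#' Six task colors
#'
#' @return Character vector of the six color labels used throughout the task.
#' @export
wm_colors <- function() WM_COLORS

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-unit substream seeds: unit i under master seed s gets
# seed (s + 100003 * i) mod (2^31 - 1). The counter scheme makes cohorts
# stable under insertion of later participants and keeps seeds in integer
# range.
substream_seed <- function(master, index) {
  as.integer((as.numeric(master) + 100003 * as.numeric(index)) %% 2147483647)
}

# Half-up rounding for report tables (base round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
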