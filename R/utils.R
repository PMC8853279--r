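# Internal helpers shared across the pipeline.

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# ms -> number of samples (duration), and ms -> 1-based sample index.
ms_to_samples <- function(ms, sample_rate) as.integer(round(ms / 1000 * sample_rate))
ms_to_index <- function(ms, sample_rate) as.integer(round(ms / 1000 * sample_rate)) + 1L
index_to_ms <- function(idx, sample_rate) (idx - 1) / sample_rate * 1000

# Moving average via cumulative sums; O(n), unlike a convolution.
# "causal" averages the trailing window [t - width + 1, t], so smoothing
# can never advance an onset ahead of the physical signal start; "center"
# is the symmetric window.  Edges use the truncated window.
moving_average <- function(x, width, align = c("causal", "center")) {
  align <- match.arg(align)
  n <- length(x)
  width <- max(1L, as.integer(width))
  cs <- cumsum(c(0, x))
  if (align == "causal") {
    lo <- pmax(seq_len(n) - width + 1L, 1L)
    hi <- seq_len(n)
  } else {
    half <- width %/% 2L
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + (width - half - 1L), n)
  }
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Drop any low-level lead-in of a synthesized sound: cut the segment so it
# starts at the first sample reaching `frac` of peak amplitude.  Gives the
# sharpest possible physical attack, which is what the relative-threshold
# onset extractor keys on.
trim_to_attack <- function(x, frac = 0.5) {
  i <- which(abs(x) >= frac * max(abs(x)))[1]
  x[i:length(x)]
}

rms <- function(x) sqrt(mean(x^2))

quality_error <- function(msg, reason) {
  stop(errorCondition(msg, reason = reason,
                      class = c("tapsync_quality_error", "error", "condition")))
}

input_error <- function(msg) {
  stop(errorCondition(msg, class = c("tapsync_input_error", "error", "condition")))
}
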