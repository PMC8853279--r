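# Tapping-performance statistics: mean/SD of asynchrony, circular
# concentration, the linear phase-correction decomposition, and lag-1
# autocorrelations.

#' Mean and SD of asynchrony
#'
#' @param asynchronies numeric vector of tap-stimulus asynchronies, ms
#'   (negative = anticipation).
#' @return list with `mean_async` and `sd_async` (sample SD, `NA` when
#'   fewer than two values).
#' @export
asynchrony_stats <- function(asynchronies) {
  n <- length(asynchronies)
  list(mean_async = if (n >= 1) mean(asynchronies) else NA_real_,
       sd_async = if (n >= 2) stats::sd(asynchronies) else NA_real_)
}

#' Mean resultant vector length of tapping phase
#'
#' Each asynchrony is mapped to a phase angle `2*pi*A_n / IOI_n` relative
#' to its local inter-onset interval; the returned `R` is the modulus of
#' the mean unit phasor.  `R = 1` means perfectly concentrated phase,
#' `R = 0` uniform phase.
#'
#' @param asynchronies numeric, ms.
#' @param local_iois numeric, same length: the stimulus IOI local to each
#'   asynchrony, ms (a scalar is recycled).
#' @return `R` in \[0, 1\], or `NA` for empty input.
#' @export
vector_length <- function(asynchronies, local_iois) {
  if (length(asynchronies) == 0) return(NA_real_)
  if (length(local_iois) == 1) local_iois <- rep(local_iois, length(asynchronies))
  stopifnot(length(local_iois) == length(asynchronies), all(local_iois > 0))
  theta <- 2 * pi * asynchronies / local_iois
  Mod(mean(exp(1i * theta)))
}

#' Fit the linear phase-correction model by method of moments
#'
#' Under the linear phase-correction account of synchronization, centred
#' asynchronies follow
#' `A_[n+1] = (1 - alpha) A_n + T_n + M_[n+1] - M_n`,
#' with error-correction gain `alpha`, timekeeper noise `T ~ N(0, sigma_t^2)`
#' and motor noise `M ~ N(0, sigma_m^2)`.  The stationary autocovariances
#' `g(0), g(1), g(2)` identify all three components in closed form:
#' `beta = g(2)/g(1)`, `alpha = 1 - beta`,
#' `sigma_m^2 = beta*g(0) - g(1)`,
#' `sigma_t^2 = (1 - beta^2)*g(0) - 2*(1 - beta)*sigma_m^2`.
#' Negative variance estimates are clipped to zero and flagged.
#'
#' @param asynchronies numeric vector; a stationary series of at least ~30
#'   values is recommended.
#' @return list with `vw_alpha`, `vw_sigma_t`, `vw_sigma_m` (SDs in ms),
#'   `valid` (FALSE when estimation is degenerate or the series is shorter
#'   than 30 taps, where moment estimates are too noisy to interpret),
#'   `clipped` (TRUE when a variance was clipped at zero).
#' @export
fit_vorberg_wing <- function(asynchronies) {
  n <- length(asynchronies)
  bad <- list(vw_alpha = NA_real_, vw_sigma_t = NA_real_, vw_sigma_m = NA_real_,
              valid = FALSE, clipped = FALSE)
  if (n < 4 || stats::sd(asynchronies) == 0) return(bad)
  g <- as.numeric(stats::acf(asynchronies, lag.max = 2, type = "covariance",
                             plot = FALSE, demean = TRUE)$acf)
  g0 <- g[1]; g1 <- g[2]; g2 <- g[3]
  if (abs(g1) < 1e-12 * g0) return(bad)
  beta <- g2 / g1
  alpha <- 1 - beta
  var_m <- beta * g0 - g1
  clipped <- FALSE
  if (var_m < 0) { var_m <- 0; clipped <- TRUE }
  var_t <- (1 - beta^2) * g0 - 2 * (1 - beta) * var_m
  if (var_t < 0) { var_t <- 0; clipped <- TRUE }
  list(vw_alpha = alpha, vw_sigma_t = sqrt(var_t), vw_sigma_m = sqrt(var_m),
       valid = n >= 30, clipped = clipped)
}

#' Lag-1 autocorrelation
#'
#' Sample autocorrelation at lag 1, used on the asynchrony series and on
#' the inter-tap intervals as alternative measures of error correction.
#'
#' @param series numeric vector, length >= 3.
#' @return autocorrelation in \[-1, 1\], `NA` for constant or too-short
#'   series.
#' @export
lag1_autocorrelation <- function(series) {
  if (length(series) < 3 || stats::sd(series) == 0) return(NA_real_)
  as.numeric(stats::acf(series, lag.max = 1, plot = FALSE, demean = TRUE)$acf[2])
}

#' Full tapping-performance summary for an aligned trial
#'
#' @param aligned result of [realign()] after matching (must carry
#'   `matches` and `asynchronies`); local IOIs are taken as successive
#'   differences of the realigned stimulus onsets (the last onset reuses
#'   the previous IOI), which also covers stimuli with variable IOIs such
#'   as music.
#' @return object of class `sms_metrics`.
#' @export
sms_metrics <- function(aligned) {
  a <- aligned$asynchronies
  stim <- aligned$realigned_stim_onsets
  iois <- if (length(stim) >= 2) {
    d <- diff(stim)
    c(d, d[length(d)])
  } else rep(NA_real_, length(stim))
  stats_ <- asynchrony_stats(a)
  vl <- if (length(a) > 0 && length(stim) >= 2) {
    vector_length(a, iois[aligned$matches$stim_index])
  } else NA_real_
  vw <- fit_vorberg_wing(a)
  itis <- diff(aligned$matches$tap_onset)
  structure(list(
    n_matched = length(a),
    mean_async = stats_$mean_async,
    sd_async = stats_$sd_async,
    vector_length = vl,
    vw_alpha = vw$vw_alpha,
    vw_sigma_t = vw$vw_sigma_t,
    vw_sigma_m = vw$vw_sigma_m,
    vw_valid = vw$valid,
    lag1_async = lag1_autocorrelation(a),
    lag1_iti = lag1_autocorrelation(itis)
  ), class = "sms_metrics")
}

#' @export
print.sms_metrics <- function(x, ...) {
  cat(sprintf("tapping metrics over %d matched taps\n", x$n_matched))
  cat(sprintf("  asynchrony: mean %.2f ms, SD %.2f ms, vector length %.3f\n",
              x$mean_async, x$sd_async, x$vector_length))
  if (isTRUE(x$vw_valid)) {
    cat(sprintf("  phase correction: alpha %.2f, sigma_t %.1f ms, sigma_m %.1f ms\n",
                x$vw_alpha, x$vw_sigma_t, x$vw_sigma_m))
  }
  cat(sprintf("  lag-1 autocorrelation: asynchrony %.2f, ITI %.2f\n",
              x$lag1_async, x$lag1_iti))
  invisible(x)
}

#' Aggregate trial metrics into a participant summary
#'
#' Per-trial metrics are averaged (mean of per-trial values, failed trials
#' excluded), matching the convention of scoring a participant by the mean
#' of their per-trial tapping performance.
#'
#' @param analyses list of `trial_analysis` objects.
#' @return one-row data frame with the averaged metrics and trial counts.
#' @export
summarize_trials <- function(analyses) {
  ok <- vapply(analyses, function(a) isTRUE(a$diagnostics$passed), logical(1))
  usable <- analyses[ok]
  pick <- function(f) vapply(usable, function(a) {
    v <- a$metrics[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  mean_or_na <- function(v) if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
  data.frame(
    n_trials = length(analyses),
    n_passed = sum(ok),
    mean_async = mean_or_na(pick("mean_async")),
    sd_async = mean_or_na(pick("sd_async")),
    vector_length = mean_or_na(pick("vector_length")),
    vw_alpha = mean_or_na(pick("vw_alpha")),
    vw_sigma_t = mean_or_na(pick("vw_sigma_t")),
    vw_sigma_m = mean_or_na(pick("vw_sigma_m")),
    lag1_async = mean_or_na(pick("lag1_async")),
    lag1_iti = mean_or_na(pick("lag1_iti"))
  )
}
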