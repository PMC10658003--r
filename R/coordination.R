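# Time-course synchrony via windowed cross-lagged correlations (WCLC),
# turn-based adaptation, and their surrogate (pseudosynchrony /
# pseudoadaptation) nulls with a paired Jeffreys-Zellner-Siow Bayes factor.

#' WCLC configuration
#'
#' Window, step and lag defaults follow the conversational-synchrony
#' convention of 16 s windows advanced in 8 s steps with lags up to 2 s.
#'
#' @param window_s Window length in seconds.
#' @param step_s Step between window starts in seconds.
#' @param max_lag_s Maximum lag in seconds (lags run from `-max_lag_s` to
#'   `+max_lag_s` in whole frames, lag 0 included).
#' @param min_valid_fraction Minimum fraction of pairwise-present frame pairs
#'   (at the best lag) a window must have to be used.
#' @param peak_rule `"max_signed"` (largest positive correlation across lags;
#'   synchrony as in-phase similarity) or `"max_abs"` (largest absolute
#'   correlation, reported as its absolute value).
#' @return A `wclc_config` object.
#' @export
wclc_config <- function(window_s = 16, step_s = 8, max_lag_s = 2,
                        min_valid_fraction = 0.5,
                        peak_rule = c("max_signed", "max_abs")) {
  peak_rule <- match.arg(peak_rule)
  stopifnot(window_s > 0, step_s > 0, max_lag_s >= 0,
            min_valid_fraction >= 0, min_valid_fraction <= 1)
  if (window_s <= 2 * max_lag_s)
    stop("window_s must exceed twice max_lag_s", call. = FALSE)
  if (step_s > window_s)
    stop("step_s must not exceed window_s", call. = FALSE)
  structure(list(window_s = window_s, step_s = step_s, max_lag_s = max_lag_s,
                 min_valid_fraction = min_valid_fraction,
                 peak_rule = peak_rule), class = "wclc_config")
}

# Cross-correlation sums of two (zero-filled) matrices of windowed series via
# FFT; returns, for each requested lag and window, sum_t u[t] * v[t + lag].
fft_ccf <- function(U_fft, V_fft, m, lags) {
  cc <- Re(stats::mvfft(Conj(U_fft) * V_fft, inverse = TRUE)) / m
  idx <- ifelse(lags >= 0, lags + 1L, m + lags + 1L)
  cc[idx, , drop = FALSE]
}

#' Windowed cross-lagged correlation synchrony
#'
#' Slides a window of `cfg$window_s` seconds across two equally sampled
#' series; in each window computes, for every whole-frame lag in
#' `[-max_lag_s, +max_lag_s]`, the Pearson correlation between `x` frames and
#' lag-shifted `y` frames over the pairwise-present frames of that window
#' (both members of a pair inside the window). The per-window peak across lags
#' (per `cfg$peak_rule`) summarises momentary synchrony; the summary value is
#' the mean of the per-window peaks. Windows whose best-lag fraction of valid
#' pairs is below `cfg$min_valid_fraction`, or in which no lag has enough
#' variance, are skipped.
#'
#' @param x,y Numeric vectors on the same frame grid (`NA` = missing).
#' @param frame_step_s Frame step of both series in seconds.
#' @param cfg A [wclc_config()].
#' @return List with `summary` (mean per-window peak), `per_window` (data
#'   frame: `window_start_s`, `peak_r`, `peak_lag_s`, `valid_fraction`,
#'   `used`) and `n_windows_used`.
#' @export
wclc_synchrony <- function(x, y, frame_step_s = 0.01, cfg = wclc_config()) {
  if (length(x) != length(y))
    stop("series must share one frame grid", call. = FALSE)
  n <- length(x)
  wlen <- round(cfg$window_s / frame_step_s)
  stepf <- max(1L, round(cfg$step_s / frame_step_s))
  maxlag <- round(cfg$max_lag_s / frame_step_s)
  if (n < wlen)
    stop("undefined synchrony: series shorter than one window", call. = FALSE)
  starts <- seq.int(1L, n - wlen + 1L, by = stepf)
  lags <- seq.int(-maxlag, maxlag)
  W <- length(starts)
  # centre by global means: correlations are shift-invariant and this avoids
  # cancellation in the raw-moment formula
  xc <- x - mean(x, na.rm = TRUE)
  yc <- y - mean(y, na.rm = TRUE)
  mx <- !is.na(xc); my <- !is.na(yc)
  x0 <- xc; x0[!mx] <- 0
  y0 <- yc; y0[!my] <- 0
  widx <- outer(0:(wlen - 1L), starts, "+")
  win <- function(v) matrix(v[widx], wlen, W)
  m <- stats::nextn(wlen + maxlag)
  pad <- function(M) {
    P <- matrix(0, m, W)
    P[seq_len(wlen), ] <- M
    P
  }
  Xw <- win(x0); Yw <- win(y0)
  dense <- all(mx) && all(my)
  if (dense) {
    # masks are all-ones: moment sums over the lag overlap come from prefix
    # sums; only the cross term needs the FFT
    Fx <- stats::mvfft(pad(Xw)); Fy <- stats::mvfft(pad(Yw))
    Sxy <- fft_ccf(Fx, Fy, m, lags)
    # moment sums over the per-lag overlap come from zero-padded cumulative
    # sums, indexed for all lags at once
    pad0 <- function(M) rbind(0, apply(M, 2, cumsum))
    csx <- pad0(Xw); csy <- pad0(Yw)
    csx2 <- pad0(Xw^2); csy2 <- pad0(Yw^2)
    ax <- pmax(1L, 1L - lags); bx <- pmin(wlen, wlen - lags)
    ay <- ax + lags; by <- bx + lags
    Np <- matrix(bx - ax + 1L, length(lags), W)
    Sx <- csx[bx + 1L, , drop = FALSE] - csx[ax, , drop = FALSE]
    Sxx <- csx2[bx + 1L, , drop = FALSE] - csx2[ax, , drop = FALSE]
    Sy <- csy[by + 1L, , drop = FALSE] - csy[ay, , drop = FALSE]
    Syy <- csy2[by + 1L, , drop = FALSE] - csy2[ay, , drop = FALSE]
  } else {
    Mxw <- win(as.numeric(mx)); Myw <- win(as.numeric(my))
    Fx <- stats::mvfft(pad(Xw));    Fy <- stats::mvfft(pad(Yw))
    Fx2 <- stats::mvfft(pad(Xw^2)); Fy2 <- stats::mvfft(pad(Yw^2))
    Fmx <- stats::mvfft(pad(Mxw));  Fmy <- stats::mvfft(pad(Myw))
    Np <- fft_ccf(Fmx, Fmy, m, lags)
    Sxy <- fft_ccf(Fx, Fy, m, lags)
    Sx <- fft_ccf(Fx, Fmy, m, lags);  Sxx <- fft_ccf(Fx2, Fmy, m, lags)
    Sy <- fft_ccf(Fmx, Fy, m, lags);  Syy <- fft_ccf(Fmx, Fy2, m, lags)
    Np <- round(Np)
  }
  denx <- Np * Sxx - Sx^2
  deny <- Np * Syy - Sy^2
  num <- Np * Sxy - Sx * Sy
  tol <- 1e-9 * (1 + abs(Np * Sxx)) # guard zero-variance lags
  r <- num / sqrt(pmax(denx, 0) * pmax(deny, 0))
  r[!(Np >= 3 & denx > tol & deny > tol)] <- NA_real_
  possible <- wlen - abs(lags)
  frac <- apply(Np / possible, 2, max)
  peak_r <- peak_lag <- rep(NA_real_, W)
  for (w in seq_len(W)) {
    rw <- r[, w]
    if (all(is.na(rw))) next
    k <- if (cfg$peak_rule == "max_signed") which.max(rw)
         else which.max(abs(rw))
    peak_r[w] <- if (cfg$peak_rule == "max_abs") abs(rw[k]) else rw[k]
    peak_lag[w] <- lags[k] * frame_step_s
  }
  used <- frac >= cfg$min_valid_fraction & !is.na(peak_r)
  per_window <- data.frame(
    window_start_s = (starts - 1L) * frame_step_s,
    peak_r = peak_r, peak_lag_s = peak_lag,
    valid_fraction = frac, used = used)
  if (!any(used))
    stop("undefined synchrony: no usable windows", call. = FALSE)
  list(summary = mean(peak_r[used]), per_window = per_window,
       n_windows_used = sum(used))
}

#' Turn-based adaptation
#'
#' For one speaker, correlates across their turns each turn-level feature
#' (mean pitch, mean intensity, articulation rate) with the same feature of
#' the partner's immediately preceding turn. Pairs with a missing value are
#' dropped; fewer than three valid pairs, or zero variance on either side,
#' leaves the adaptation undefined (an error).
#'
#' @param tp Per-turn prosody data frame from [turn_prosody()].
#' @param speaker Speaker id whose adaptation is measured.
#' @param min_pairs Minimum number of valid turn pairs (default 3).
#' @return Named list `adapt_pitch`, `adapt_intensity`, `adapt_articulation`.
#' @export
turn_adaptation <- function(tp, speaker, min_pairs = 3L) {
  own_idx <- which(tp$speaker == speaker)
  own_idx <- own_idx[own_idx > 1L]
  if (length(own_idx) < min_pairs)
    stop("undefined adaptation: fewer than ", min_pairs,
         " own turns with a preceding partner turn", call. = FALSE)
  prev_idx <- own_idx - 1L
  feats <- c(adapt_pitch = "mean_pitch_hz",
             adapt_intensity = "mean_intensity_db",
             adapt_articulation = "articulation_rate_sps")
  out <- lapply(feats, function(col) {
    a <- tp[[col]][own_idx]; b <- tp[[col]][prev_idx]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_pairs)
      stop("undefined adaptation: fewer than ", min_pairs,
           " valid pairs for ", col, call. = FALSE)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      stop("undefined adaptation: zero variance in ", col, call. = FALSE)
    stats::cor(a[ok], b[ok])
  })
  names(out) <- names(feats)
  out
}

#' Shuffle a series in fixed-length segments
#'
#' Splits the series into consecutive segments of `seg_len` frames, permutes
#' the complete segments and leaves a trailing partial segment in place —
#' destroying cross-partner timing while preserving local structure.
#'
#' @param v Numeric vector.
#' @param seg_len Segment length in frames.
#' @return The segment-shuffled vector.
#' @export
shuffle_segments <- function(v, seg_len) {
  n <- length(v)
  k <- n %/% seg_len
  if (k < 2L) return(v)
  perm <- sample.int(k)
  idx <- unlist(lapply(perm, function(j) ((j - 1L) * seg_len + 1L):(j * seg_len)))
  c(v[idx], v[seq_len(n - k * seg_len) + k * seg_len])
}

#' Surrogate null for a coordination statistic
#'
#' Recomputes a statistic on `n_surrogates` shuffled versions of the data and
#' collects observed value, surrogate values and their mean. Deterministic
#' given `seed`.
#'
#' @param observed The observed statistic.
#' @param surrogate_fn Function of the surrogate index returning one surrogate
#'   statistic; it may use the RNG and may error (an undefined surrogate
#'   becomes `NA`).
#' @param n_surrogates Number of surrogates (default 100).
#' @param seed Integer seed.
#' @return A `surrogate_result`: list with `observed`, `surrogates`,
#'   `surrogate_mean`.
#' @export
surrogate_null <- function(observed, surrogate_fn, n_surrogates = 100,
                           seed = 1L) {
  if (n_surrogates < 1L) stop("n_surrogates must be >= 1", call. = FALSE)
  set.seed(seed)
  sur <- vapply(seq_len(n_surrogates), function(i)
    tryCatch(as.numeric(surrogate_fn(i)), error = function(e) NA_real_),
    numeric(1))
  if (mean(is.na(sur)) > 0.5)
    stop("null-construction error: statistic undefined on more than half ",
         "of the surrogates", call. = FALSE)
  structure(list(observed = observed, surrogates = sur,
                 surrogate_mean = mean(sur, na.rm = TRUE)),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> observed %.4f, pseudo mean %.4f (n = %d)\n",
              x$observed, x$surrogate_mean, length(x$surrogates)))
  invisible(x)
}

#' Pseudosynchrony null for WCLC
#'
#' Shuffles one partner's series in window-length segments (trailing partial
#' segment kept in place) and recomputes the WCLC summary for each surrogate.
#'
#' @param x,y Series as in [wclc_synchrony()] (`y` is shuffled).
#' @param frame_step_s Frame step in seconds.
#' @param cfg A [wclc_config()].
#' @inheritParams surrogate_null
#' @return A `surrogate_result`.
#' @export
pseudo_synchrony <- function(x, y, frame_step_s = 0.01, cfg = wclc_config(),
                             n_surrogates = 100, seed = 1L) {
  obs <- wclc_synchrony(x, y, frame_step_s, cfg)$summary
  seg_len <- round(cfg$window_s / frame_step_s)
  surrogate_null(obs, function(i) {
    ys <- shuffle_segments(y, seg_len)
    wclc_synchrony(x, ys, frame_step_s, cfg)$summary
  }, n_surrogates = n_surrogates, seed = seed)
}

#' Pseudoadaptation null for turn-based adaptation
#'
#' Permutes the partner's turn-feature sequence (all three features jointly)
#' and recomputes the adaptation correlations.
#'
#' @inheritParams turn_adaptation
#' @inheritParams surrogate_null
#' @return Named list of three `surrogate_result`s (`adapt_pitch`,
#'   `adapt_intensity`, `adapt_articulation`).
#' @export
pseudo_adaptation <- function(tp, speaker, n_surrogates = 100, seed = 1L) {
  obs <- turn_adaptation(tp, speaker)
  partner_rows <- which(tp$speaker != speaker)
  cols <- c("mean_pitch_hz", "mean_intensity_db", "articulation_rate_sps")
  set.seed(seed)
  sur <- matrix(NA_real_, n_surrogates, 3,
                dimnames = list(NULL, names(obs)))
  for (i in seq_len(n_surrogates)) {
    tps <- tp
    perm <- sample(partner_rows)
    tps[partner_rows, cols] <- tp[perm, cols]
    val <- tryCatch(turn_adaptation(tps, speaker), error = function(e) NULL)
    if (!is.null(val)) sur[i, ] <- unlist(val)
  }
  if (mean(is.na(sur)) > 0.5)
    stop("null-construction error: statistic undefined on more than half ",
         "of the surrogates", call. = FALSE)
  out <- lapply(names(obs), function(nm)
    structure(list(observed = obs[[nm]], surrogates = sur[, nm],
                   surrogate_mean = mean(sur[, nm], na.rm = TRUE)),
              class = "surrogate_result"))
  names(out) <- names(obs)
  out
}

#' Paired Bayes factor of observed versus pseudo values
#'
#' One-sided (observed greater) paired Jeffreys-Zellner-Siow Bayes factor on
#' the differences `observed - pseudo`, with a Cauchy prior of scale
#' `r = sqrt(2)/2` on the standardised effect, computed by numerical
#' integration. Returned on the natural-log scale.
#'
#' @param observed_values Numeric vector of per-dyad or per-person observed
#'   coordination values.
#' @param pseudo_means Matched vector of surrogate means.
#' @param r Cauchy prior scale.
#' @param one_sided Restrict the prior to positive effects (default `TRUE`).
#' @return Natural-log BF10.
#' @export
compare_to_pseudo <- function(observed_values, pseudo_means,
                              r = sqrt(2) / 2, one_sided = TRUE) {
  if (length(observed_values) != length(pseudo_means) ||
      length(observed_values) < 2L)
    stop("need matched vectors of length >= 2", call. = FALSE)
  d <- observed_values - pseudo_means
  n <- length(d)
  s <- stats::sd(d)
  t <- if (s == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * 50
  } else mean(d) / (s / sqrt(n))
  jzs_logbf_t(t, n_eff = n, df = n - 1, r = r, one_sided = one_sided)
}

#' JZS Bayes factor from a t statistic
#'
#' Natural-log Jeffreys-Zellner-Siow BF10 for a t statistic with effective
#' sample size `n_eff` and `df` degrees of freedom, Cauchy prior scale `r` on
#' the standardised effect; `one_sided` uses the positive half-Cauchy. The
#' marginal likelihood is integrated over the effect size with the
#' non-central-t likelihood.
#'
#' @param t Observed t statistic.
#' @param n_eff Effective sample size (one-sample: n; two-sample:
#'   `n1 * n2 / (n1 + n2)`).
#' @param df Degrees of freedom.
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @param one_sided Logical.
#' @return Natural-log BF10.
#' @export
jzs_logbf_t <- function(t, n_eff, df, r = sqrt(2) / 2, one_sided = FALSE) {
  if (!is.finite(t)) stop("non-finite t statistic", call. = FALSE)
  t <- max(min(t, 50), -50)  # likelihood ratios overflow beyond this anyway
  l0 <- stats::dt(t, df, log = TRUE)
  # dt(ncp =) warns about pnt precision at extreme noncentralities; the
  # residual error there is far below the integration tolerance
  ratio <- function(delta)
    exp(suppressWarnings(
      stats::dt(t, df, ncp = delta * sqrt(n_eff), log = TRUE)) - l0)
  if (one_sided) {
    v <- stats::integrate(function(d) ratio(d) * 2 * stats::dcauchy(d, 0, r),
                          0, Inf, rel.tol = 1e-9, stop.on.error = FALSE)
  } else {
    v <- stats::integrate(function(d) ratio(d) * stats::dcauchy(d, 0, r),
                          -Inf, Inf, rel.tol = 1e-9, stop.on.error = FALSE)
  }
  log(v$value)
}
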