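# Independent reference implementations and small fixture builders used
# across the test files. The oracles deliberately use different algorithms
# from the package code paths they check.

# Naive WCLC reference: explicit loops over windows and lags, correlations
# via cor() on pairwise-complete subsets.
naive_wclc <- function(x, y, frame_step_s, cfg) {
  wlen <- round(cfg$window_s / frame_step_s)
  stepf <- round(cfg$step_s / frame_step_s)
  L <- round(cfg$max_lag_s / frame_step_s)
  starts <- seq(1, length(x) - wlen + 1, stepf)
  peaks <- numeric(0)
  peak_lags <- numeric(0)
  for (s in starts) {
    rs <- rep(NA_real_, 2 * L + 1)
    fr <- rep(0, 2 * L + 1)
    for (k in seq(-L, L)) {
      tt <- max(1, 1 - k):min(wlen, wlen - k)
      a <- x[s + tt - 1]
      b <- y[s + tt + k - 1]
      ok <- !is.na(a) & !is.na(b)
      fr[k + L + 1] <- sum(ok) / length(tt)
      if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
        rs[k + L + 1] <- stats::cor(a[ok], b[ok])
    }
    if (max(fr) >= cfg$min_valid_fraction && any(!is.na(rs))) {
      if (cfg$peak_rule == "max_signed") {
        j <- which.max(rs)
        peaks <- c(peaks, rs[j])
      } else {
        j <- which.max(abs(rs))
        peaks <- c(peaks, abs(rs[j]))
      }
      peak_lags <- c(peak_lags, (j - L - 1) * frame_step_s)
    }
  }
  list(summary = mean(peaks), peaks = peaks, peak_lags = peak_lags)
}

# Fixed-grid trapezoid quadrature for the JZS Bayes factor, integrating over
# the effect size with the substitution delta = r * tan(u).
trapz_jzs_logbf <- function(t, n_eff, df, r = sqrt(2) / 2, one_sided = TRUE) {
  if (one_sided) {
    u <- seq(1e-7, pi / 2 - 1e-7, length.out = 40001)
  } else {
    u <- seq(-pi / 2 + 1e-7, pi / 2 - 1e-7, length.out = 80001)
  }
  delta <- r * tan(u)
  jac <- r / cos(u)^2
  lik <- suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n_eff)))
  prior <- stats::dcauchy(delta, 0, r) * if (one_sided) 2 else 1
  f <- lik * prior * jac
  integral <- sum((f[-1] + f[-length(f)]) / 2 * diff(u))
  log(integral) - stats::dt(t, df, log = TRUE)
}

# Enumeration oracle for turn segmentation: over all partitions of the
# onset-ordered segments into consecutive blocks, exactly one satisfies the
# turn definition (single-speaker blocks, alternating speakers, maximal runs).
enum_turn_oracle <- function(seg) {
  seg <- seg[order(seg$start), ]
  n <- nrow(seg)
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    blocks <- lapply(seq_len(length(bounds) - 1), function(i)
      seg[(bounds[i] + 1):bounds[i + 1], , drop = FALSE])
    spk <- vapply(blocks, function(b) {
      u <- unique(b$speaker)
      if (length(u) == 1) u else NA_character_
    }, character(1))
    if (anyNA(spk)) next
    if (length(spk) > 1 && any(spk[-1] == spk[-length(spk)])) next
    if (!is.null(best)) stop("oracle: non-unique valid partition")
    best <- data.frame(
      speaker = spk,
      start_s = vapply(blocks, function(b) min(b$start), numeric(1)),
      end_s = vapply(blocks, function(b) max(b$end), numeric(1)))
  }
  best
}

# random two-speaker annotation with non-overlapping within-speaker segments
# and no onset ties
random_annotation <- function(n_segs = 6, duration = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    sp <- sample(c("A", "B"), n_segs, replace = TRUE)
    if (length(unique(sp)) == 2) break
  }
  starts <- sort(stats::runif(n_segs, 0, duration - 5))
  lens <- stats::runif(n_segs, 0.3, 3)
  seg <- data.frame(speaker = sp, start = starts,
                    end = pmin(starts + lens, duration))
  # enforce within-speaker non-overlap
  for (s in c("A", "B")) {
    rows <- which(seg$speaker == s)
    if (length(rows) > 1) {
      for (i in 2:length(rows)) {
        lo <- seg$end[rows[i - 1]]
        if (seg$start[rows[i]] < lo) seg$start[rows[i]] <- lo + 0.01
        if (seg$end[rows[i]] <= seg$start[rows[i]])
          seg$end[rows[i]] <- seg$start[rows[i]] + 0.2
      }
    }
  }
  seg <- seg[seg$end <= duration, ]
  ann <- annotation_set("rand", "hobbies",
                        list(A = seg[seg$speaker == "A", c("start", "end")],
                             B = seg[seg$speaker == "B", c("start", "end")]),
                        duration)
  ann
}

# constructed prosody track: flat base intensity with raised-cosine bumps
bump_track <- function(duration = 10, base_db = 60, bump_db = 4,
                       bump_at = c(2, 5, 8), width = 0.2, voiced = TRUE,
                       step = 0.01) {
  n <- round(duration / step)
  tt <- (seq_len(n) - 1) * step
  intensity <- rep(base_db, n)
  for (b in bump_at) {
    sel <- abs(tt - b) <= width / 2
    intensity[sel] <- intensity[sel] +
      bump_db * 0.5 * (1 + cos(pi * (tt[sel] - b) / (width / 2)))
  }
  pitch <- if (voiced) rep(120, n) else rep(NA_real_, n)
  prosody_track(pitch, intensity, step)
}

# gaussian feature matrix with dyad structure (both members share the dyad
# effect), for classifier tests that do not need the full generator
gaussian_fm <- function(n_mixed = 7, n_non = 7, shift = 0, p = 4,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_mixed + n_non
  lab <- rep(c("mixed", "non_autistic"), c(n_mixed, n_non))
  dy <- sprintf("D%02d", seq_len(n))
  mu <- rep(ifelse(lab == "mixed", shift, 0), each = 2)
  X <- matrix(stats::rnorm(2 * n * p, mu), 2 * n, p)
  rownames(X) <- paste0(rep(dy, each = 2), c("A", "B"))
  structure(list(X = X,
                 y = factor(rep(lab, each = 2),
                            levels = c("non_autistic", "mixed")),
                 dyad_id = rep(dy, each = 2),
                 participant_id = rownames(X)),
            class = "feature_matrix")
}

# lazily built study-sized default corpus feature table (shared by tests
# that need realistic features; records themselves are not kept)
.ds_cache <- new.env(parent = emptyenv())
study_features <- function() {
  if (is.null(.ds_cache$ft)) {
    cfg <- generator_config(seed = 20260929)
    corp <- generate_corpus(cfg)
    .ds_cache$ft <- compute_feature_table(corp$records)
    .ds_cache$truth <- corp$truth
  }
  list(ft = .ds_cache$ft, truth = .ds_cache$truth)
}
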