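# Individual speech features and per-turn prosody summaries. Syllable nuclei
# follow the intensity-peak approach of speech-rate detectors: peaks above the
# median intensity of voiced frames, separated by a dip of at least 2 dB, and
# coinciding with voiced speech.

#' Detect syllable nuclei from an intensity contour
#'
#' Candidate nuclei are local intensity maxima inside the speaker's speaking
#' segments that exceed `median(intensity over voiced frames) + threshold_db`.
#' A candidate is kept only if the intensity dips at least `dip_db` below it
#' before the previous kept nucleus (segment onsets count as dips) and the
#' peak frame is voiced (pitch present).
#'
#' @param track A [prosody_track()].
#' @param segments Data frame of the speaker's speaking segments
#'   (`start`/`end`, seconds).
#' @param dip_db Minimum dip between consecutive nuclei in dB (default 2).
#' @param threshold_db Offset above the voiced-frame median intensity that a
#'   peak must reach (default 0).
#' @return Sorted numeric vector of nucleus times in seconds (empty if the
#'   intensity is entirely missing inside the segments).
#' @export
detect_syllable_nuclei <- function(track, segments, dip_db = 2,
                                   threshold_db = 0) {
  n <- track$n_frames
  inseg <- segment_mask(segments, n, track$frame_step_s)
  int <- track$intensity_db
  voiced <- !is.na(track$pitch_hz)
  usable <- inseg & !is.na(int)
  if (!any(usable)) return(numeric(0))
  med <- stats::median(int[usable & voiced])
  if (is.na(med)) med <- stats::median(int[usable])
  thr <- med + threshold_db
  x <- int
  x[!usable] <- -Inf
  # strict local maxima over the usable contour, plateau-aware: compress
  # runs of equal values and require a strict rise before and fall after,
  # so flat stretches and segment-boundary frames are not peaks
  fidx <- which(is.finite(x))
  if (length(fidx) == 0L) return(numeric(0))
  rr <- rle(x[fidx])
  k <- length(rr$values)
  is_max <- rr$values > c(Inf, rr$values[-k]) &
    rr$values > c(rr$values[-1L], Inf)
  run_start <- cumsum(c(1L, rr$lengths[-k]))
  cand <- fidx[run_start[is_max]]
  cand <- cand[x[cand] >= thr & voiced[cand]]
  if (length(cand) == 0L) return(numeric(0))
  kept <- integer(0)
  last <- NA_integer_
  for (i in cand) {
    if (is.na(last)) {
      # first candidate in the track: require a dip before it within the data
      before <- x[seq_len(i - 1L)]
      before <- before[is.finite(before)]
      dipped <- length(before) == 0L || min(before) <= x[i] - dip_db
      if (dipped) { kept <- c(kept, i); last <- i }
    } else {
      between <- x[(last + 1L):(i - 1L)]
      fin <- between[is.finite(between)]
      # missing intensity between peaks (silence) counts as a full dip
      dip_ok <- length(fin) < length(between) ||
        (length(fin) > 0L && min(fin) <= x[i] - dip_db)
      if (dip_ok) { kept <- c(kept, i); last <- i }
      else if (x[i] > x[last]) kept[length(kept)] <- last <- i
    }
  }
  (kept - 1L) * track$frame_step_s
}

#' Individual speech features for one participant and task
#'
#' Phonation time is the summed duration of the speaker's own speaking
#' segments; pauses are silent stretches of at least `min_pause_s` between
#' consecutive own segments inside one own turn; the articulation rate is
#' syllables per second of phonation; pitch and intensity variances are taken
#' over the speaker's own voiced / speaking frames across the whole task.
#' Turn-based adaptation fields are filled by the coordination layer.
#'
#' @param annotations An [annotation_set()].
#' @param track The speaker's [prosody_track()].
#' @param turns A `turn_sequence` from [segment_turns()].
#' @param speaker Speaker id (must be one of the annotation set's speakers).
#' @param min_pause_s Minimum silent stretch counted as a pause (default 0.3).
#' @return Named list with `articulation_rate_sps`, `n_pauses`,
#'   `n_syllables`, `phonation_time_s`, `var_intensity_db2`, `var_pitch_hz2`,
#'   and the nucleus times in `nuclei`.
#' @export
individual_features <- function(annotations, track, turns, speaker,
                                min_pause_s = 0.3) {
  if (!speaker %in% annotations$speakers)
    stop("unknown speaker: ", speaker, call. = FALSE)
  seg <- annotations$segments[[speaker]]
  phonation <- if (nrow(seg)) sum(seg$end - seg$start) else 0
  if (phonation <= 0)
    stop("articulation rate undefined: zero phonation time for speaker ",
         speaker, call. = FALSE)
  nuc <- detect_syllable_nuclei(track, seg)
  n_syll <- length(nuc)
  # pauses: silences >= min_pause_s between consecutive own segments that fall
  # inside the same own turn
  segdf <- turns$segments
  own <- segdf[segdf$speaker == speaker, , drop = FALSE]
  n_pauses <- 0L
  if (nrow(own) > 1L) {
    for (k in unique(own$turn_id)) {
      s <- own[own$turn_id == k, , drop = FALSE]
      if (nrow(s) > 1L) {
        s <- s[order(s$start), ]
        gaps <- s$start[-1L] - s$end[-nrow(s)]
        n_pauses <- n_pauses + sum(gaps >= min_pause_s - 1e-9)
      }
    }
  }
  inseg <- segment_mask(seg, track$n_frames, track$frame_step_s)
  pit <- track$pitch_hz[inseg]
  int <- track$intensity_db[inseg]
  list(articulation_rate_sps = n_syll / phonation,
       n_pauses = n_pauses,
       n_syllables = n_syll,
       phonation_time_s = phonation,
       var_intensity_db2 = if (sum(!is.na(int)) > 1L)
         stats::var(int, na.rm = TRUE) else NA_real_,
       var_pitch_hz2 = if (sum(!is.na(pit)) > 1L)
         stats::var(pit, na.rm = TRUE) else NA_real_,
       nuclei = nuc)
}

#' Per-turn prosody summaries
#'
#' For every turn: mean pitch and mean intensity over the frames inside the
#' turn's own speaking segments, the syllable-nucleus count, and the per-turn
#' articulation rate (nuclei per second of within-turn phonation). Turns with
#' no voiced frame get a missing mean pitch.
#'
#' @param turns A `turn_sequence` from [segment_turns()].
#' @param tracks Named list of [prosody_track()]s, one per speaker.
#' @param nuclei Optional named list of nucleus times per speaker (computed
#'   with [detect_syllable_nuclei()] if omitted).
#' @return Data frame with one row per turn: `turn_id`, `speaker`,
#'   `gap_before_s`, `mean_pitch_hz`, `mean_intensity_db`, `n_syllables`,
#'   `articulation_rate_sps`.
#' @export
turn_prosody <- function(turns, tracks, nuclei = NULL) {
  tt <- turns$turns
  segdf <- turns$segments
  if (is.null(nuclei)) {
    nuclei <- lapply(stats::setNames(nm = names(tracks)), function(sp) {
      seg <- segdf[segdf$speaker == sp, c("start", "end"), drop = FALSE]
      detect_syllable_nuclei(tracks[[sp]], seg)
    })
  }
  out <- tt[, c("turn_id", "speaker", "gap_before_s")]
  out$mean_pitch_hz <- out$mean_intensity_db <- NA_real_
  out$n_syllables <- 0L
  out$articulation_rate_sps <- NA_real_
  for (sp in unique(tt$speaker)) {
    tr <- tracks[[sp]]
    srows <- segdf[segdf$speaker == sp, , drop = FALSE]
    srows <- srows[order(srows$start), , drop = FALSE]
    if (nrow(srows) == 0L) next
    t0 <- (seq_len(tr$n_frames) - 1) * tr$frame_step_s
    bounds <- as.vector(rbind(srows$start, srows$end)) - 1e-9
    pos <- findInterval(t0, bounds)
    sel <- which(pos %% 2L == 1L)
    idx_by_turn <- split(sel, srows$turn_id[(pos[sel] + 1L) %/% 2L])
    npos <- findInterval(nuclei[[sp]] + 1e-12, bounds)
    nin <- npos %% 2L == 1L
    nuc_turn <- srows$turn_id[(npos[nin] + 1L) %/% 2L]
    for (i in which(tt$speaker == sp)) {
      k <- tt$turn_id[i]
      idx <- idx_by_turn[[as.character(k)]]
      if (length(idx)) {
        pit <- tr$pitch_hz[idx]; int <- tr$intensity_db[idx]
        if (any(!is.na(pit))) out$mean_pitch_hz[i] <- mean(pit, na.rm = TRUE)
        if (any(!is.na(int)))
          out$mean_intensity_db[i] <- mean(int, na.rm = TRUE)
      }
      cnt <- sum(nuc_turn == k)
      out$n_syllables[i] <- cnt
      seg_k <- srows[srows$turn_id == k, , drop = FALSE]
      phon <- sum(seg_k$end - seg_k$start)
      if (phon > 0) out$articulation_rate_sps[i] <- cnt / phon
    }
  }
  out[, c("turn_id", "speaker", "gap_before_s", "mean_pitch_hz",
          "mean_intensity_db", "n_syllables", "articulation_rate_sps")]
}
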