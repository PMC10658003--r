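# End-to-end feature pipeline: from conversation records (annotations +
# prosody tracks) to the per-individual-per-task feature table, and the
# observed-versus-pseudo coordination report.

#' Default WCLC validity floor for pitch
#'
#' Pitch is only defined during a speaker's own voiced speech, so in an
#' alternating conversation the fraction of pairwise-present frames between
#' the two speakers' pitch series is structurally small; the pitch WCLC
#' therefore uses a lower validity floor than the dense intensity channel.
#'
#' @keywords internal
PITCH_MIN_VALID <- 0.05

analyze_record <- function(rec, wclc_cfg = wclc_config(),
                           pitch_min_valid = PITCH_MIN_VALID) {
  ann <- rec$annotations
  ts <- segment_turns(ann)
  sp <- ann$speakers
  tracks <- rec$tracks
  step <- tracks[[1L]]$frame_step_s
  indiv <- lapply(sp, function(s)
    tryCatch(individual_features(ann, tracks[[s]], ts, s),
             error = function(e) NULL))
  names(indiv) <- sp
  nuclei <- lapply(indiv, function(x) if (is.null(x)) numeric(0) else x$nuclei)
  tp <- turn_prosody(ts, tracks, nuclei)
  adapt <- lapply(sp, function(s)
    tryCatch(turn_adaptation(tp, s), error = function(e)
      list(adapt_pitch = NA_real_, adapt_intensity = NA_real_,
           adapt_articulation = NA_real_)))
  names(adapt) <- sp
  syll_total <- sum(vapply(indiv, function(x)
    if (is.null(x)) 0L else x$n_syllables, integer(1)))
  dyf <- dyadic_turn_features(ts, syll_total)
  sync_int <- tryCatch(
    wclc_synchrony(tracks[[sp[1]]]$intensity_db, tracks[[sp[2]]]$intensity_db,
                   step, wclc_cfg)$summary,
    error = function(e) NA_real_)
  pcfg <- wclc_cfg
  pcfg$min_valid_fraction <- pitch_min_valid
  sync_pit <- tryCatch(
    wclc_synchrony(tracks[[sp[1]]]$pitch_hz, tracks[[sp[2]]]$pitch_hz,
                   step, pcfg)$summary,
    error = function(e) NA_real_)
  list(turns = ts, turn_prosody = tp, individual = indiv, adaptation = adapt,
       dyadic = dyf, sync_intensity = sync_int, sync_pitch = sync_pit)
}

#' Compute the feature table for a corpus
#'
#' Runs the full extraction for every conversation record: turn segmentation,
#' syllable nuclei, individual speech features, turn-based adaptation, dyadic
#' turn-taking features and WCLC synchrony of intensity and pitch. Returns one
#' row per participant and task (dyadic values repeated for both members).
#'
#' @param records List of `conversation_record`s (from [generate_corpus()] or
#'   assembled from [read_annotations()] + [read_track()] with `dyad_id`,
#'   `participants`, `groups`, `dyad_type` fields).
#' @param wclc_cfg WCLC configuration for the synchrony features.
#' @param pitch_min_valid Validity floor for the sparse pitch WCLC.
#' @return Feature table data frame with columns [feature_table_columns()].
#' @export
compute_feature_table <- function(records, wclc_cfg = wclc_config(),
                                  pitch_min_valid = PITCH_MIN_VALID) {
  rows <- list()
  for (rec in records) {
    an <- analyze_record(rec, wclc_cfg, pitch_min_valid)
    for (s in rec$annotations$speakers) {
      iv <- an$individual[[s]]
      ad <- an$adaptation[[s]]
      grp <- if (!is.null(rec$groups)) unname(rec$groups[s]) else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = s,
        dyad_id = if (!is.null(rec$dyad_id)) rec$dyad_id else
          rec$annotations$conversation_id,
        task = rec$annotations$task,
        group = grp,
        dyad_type = if (!is.null(rec$dyad_type)) rec$dyad_type else
          NA_character_,
        articulation_rate_sps = if (is.null(iv)) NA_real_ else
          iv$articulation_rate_sps,
        n_pauses = if (is.null(iv)) NA_integer_ else iv$n_pauses,
        n_syllables = if (is.null(iv)) NA_integer_ else iv$n_syllables,
        phonation_time_s = if (is.null(iv)) NA_real_ else iv$phonation_time_s,
        adapt_articulation = ad$adapt_articulation,
        adapt_intensity = ad$adapt_intensity,
        adapt_pitch = ad$adapt_pitch,
        var_intensity_db2 = if (is.null(iv)) NA_real_ else iv$var_intensity_db2,
        var_pitch_hz2 = if (is.null(iv)) NA_real_ else iv$var_pitch_hz2,
        n_turns = an$dyadic$n_turns,
        mean_gap_s = an$dyadic$mean_gap_s,
        silence_to_turn_ratio = an$dyadic$silence_to_turn_ratio,
        speech_rate_sps = an$dyadic$speech_rate_sps,
        sync_intensity = an$sync_intensity,
        sync_pitch = an$sync_pitch,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed versus pseudo coordination report
#'
#' For every conversation record computes the observed WCLC synchrony of
#' intensity and pitch (per dyad) and the turn-based adaptation of pitch,
#' intensity and articulation rate (per participant), together with the mean
#' of `n_surrogates` segment-shuffled pseudo values. Each measure is then
#' compared against its pseudo values with a one-sided paired JZS Bayes
#' factor, mirroring the usual observed-versus-chance coordination table.
#'
#' @param records List of `conversation_record`s.
#' @param n_surrogates Surrogates per value (default 100).
#' @param seed Integer seed (drives all shuffles deterministically).
#' @param wclc_cfg WCLC configuration.
#' @param pitch_min_valid Validity floor for the pitch WCLC.
#' @return List with `values` (long data frame: `measure`, `unit_id`, `task`,
#'   `observed`, `pseudo_mean`) and `table` (per measure: mean/SD of observed
#'   and pseudo values plus `log_bf10`).
#' @export
coordination_report <- function(records, n_surrogates = 100, seed = 1L,
                                wclc_cfg = wclc_config(),
                                pitch_min_valid = PITCH_MIN_VALID) {
  set.seed(seed)
  rec_seeds <- sample.int(.Machine$integer.max %/% 2L, length(records) * 2L)
  vals <- list()
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    ann <- rec$annotations
    sp <- ann$speakers
    step <- rec$tracks[[1L]]$frame_step_s
    unit <- if (!is.null(rec$dyad_id)) rec$dyad_id else ann$conversation_id
    sync_i <- tryCatch(
      pseudo_synchrony(rec$tracks[[sp[1]]]$intensity_db,
                       rec$tracks[[sp[2]]]$intensity_db, step, wclc_cfg,
                       n_surrogates, seed = rec_seeds[2L * ri - 1L]),
      error = function(e) NULL)
    if (!is.null(sync_i))
      vals[[length(vals) + 1L]] <- data.frame(
        measure = "sync_intensity", unit_id = unit, task = ann$task,
        observed = sync_i$observed, pseudo_mean = sync_i$surrogate_mean)
    pcfg <- wclc_cfg
    pcfg$min_valid_fraction <- pitch_min_valid
    sync_p <- tryCatch(
      pseudo_synchrony(rec$tracks[[sp[1]]]$pitch_hz,
                       rec$tracks[[sp[2]]]$pitch_hz, step, pcfg,
                       n_surrogates, seed = rec_seeds[2L * ri - 1L] + 1L),
      error = function(e) NULL)
    if (!is.null(sync_p))
      vals[[length(vals) + 1L]] <- data.frame(
        measure = "sync_pitch", unit_id = unit, task = ann$task,
        observed = sync_p$observed, pseudo_mean = sync_p$surrogate_mean)
    ts <- segment_turns(ann)
    tp <- turn_prosody(ts, rec$tracks)
    for (k in 1:2) {
      ad <- tryCatch(
        pseudo_adaptation(tp, sp[k], n_surrogates,
                          seed = rec_seeds[2L * ri] + k),
        error = function(e) NULL)
      if (is.null(ad)) next
      for (nm in names(ad))
        vals[[length(vals) + 1L]] <- data.frame(
          measure = nm, unit_id = sp[k], task = ann$task,
          observed = ad[[nm]]$observed, pseudo_mean = ad[[nm]]$surrogate_mean)
    }
  }
  values <- do.call(rbind, vals)
  measures <- unique(values$measure)
  table <- do.call(rbind, lapply(measures, function(m) {
    v <- values[values$measure == m & !is.na(values$observed) &
                !is.na(values$pseudo_mean), ]
    data.frame(measure = m, n = nrow(v),
               mean_observed = mean(v$observed),
               sd_observed = stats::sd(v$observed),
               mean_pseudo = mean(v$pseudo_mean),
               sd_pseudo = stats::sd(v$pseudo_mean),
               log_bf10 = if (nrow(v) >= 2L)
                 compare_to_pseudo(v$observed, v$pseudo_mean) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(values = values, table = table)
}
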