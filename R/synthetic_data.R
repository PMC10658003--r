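# Synthetic dyadic-conversation generator with known ground truth. Emulates
# alternating turns (log-normal turn and gap lengths), within-turn pauses,
# per-speaker pitch/intensity baselines with AR(1) contours, syllable-scale
# intensity bumps, turn-based adaptation and lagged cross-partner intensity
# coupling. Group and dyad-type contrasts are planted through effect
# multipliers; setting every multiplier to 1 yields the null world.

#' Generator configuration
#'
#' Defaults encode the study conditions the generator emulates: two 10-minute
#' conversations per dyad (tasks hobbies and meal planning), a log-normal turn
#' distribution with median 1.8 s and gaps with median 0.2 s, 26 mixed and 14
#' non-autistic dyads. Planted effect directions follow the reported group
#' differences: autistic speakers with lower pitch variance, lower intensity
#' variance and slower articulation; mixed dyads with longer gaps, more
#' within-turn pausing and stronger lagged intensity coupling. All effect
#' sizes are configuration, not claims; `effect_multipliers` of 1 remove every
#' planted contrast.
#'
#' @param n_mixed_dyads,n_nonautistic_dyads Dyad counts per type.
#' @param duration_s Conversation duration in seconds (default 600).
#' @param tasks Character vector of tasks to generate per dyad.
#' @param frame_step_s Prosody frame step in seconds.
#' @param turn_median_s,turn_log_sd Log-normal turn-length parameters
#'   (median + log-sd).
#' @param gap_median_s,gap_log_sd Log-normal between-turn gap parameters.
#' @param within_turn_pause_rate Expected within-turn pauses per second of
#'   turn span.
#' @param pause_median_s,pause_log_sd Log-normal within-turn pause lengths.
#' @param pitch_base_hz Two modes of the bimodal per-speaker pitch baseline
#'   draw (Hz).
#' @param pitch_base_jitter_hz SD of the per-speaker baseline jitter.
#' @param pitch_sd_hz Stationary SD of the within-speaker pitch contour (Hz).
#' @param intensity_base_db Speech intensity baseline (dB).
#' @param intensity_sd_db Stationary SD of the slow within-turn intensity
#'   wander (dB); intensity contours are smooth, so most loudness
#'   variability lives at the turn level (`turn_level_sd`).
#' @param noise_floor_db Channel intensity during silence (dB).
#' @param articulation_rate_sps Syllable rate per second of phonation.
#' @param syllable_bump_db,syllable_bump_width_s Height and width of the
#'   syllable-scale intensity peaks.
#' @param ar_coef AR(1) coefficient of the frame-level pitch contour (at
#'   10 ms).
#' @param intensity_ar_coef AR(1) coefficient of the intensity contour;
#'   higher than pitch because measured intensity is low-passed by its
#'   analysis window.
#' @param turn_level_sd Named vector: SDs of the per-turn offsets for
#'   `pitch_hz`, `intensity_db`, `articulation_sps`. The pitch and intensity
#'   entries are scaled by the same group multipliers as the frame-level SDs
#'   (the multiplier acts on the speaker's overall prosodic variability).
#' @param adapt_gain Named vector: turn-based adaptation gains for `pitch`,
#'   `intensity`, `articulation` (own turn offset regressed on the partner's
#'   previous turn offset).
#' @param intensity_coupling_gain Gain of the lagged cross-partner intensity
#'   coupling (applied to the receiver's non-speech frames, as microphone
#'   cross-talk would be).
#' @param intensity_coupling_lag_s Coupling lag in seconds (must stay below
#'   the WCLC lag bound to be detectable).
#' @param effect_multipliers Named list of planted-effect ratios:
#'   `pitch_sd_autistic`, `intensity_sd_autistic`, `articulation_autistic`
#'   (autistic / non-autistic parameter ratios), `gap_mixed`, `silence_mixed`,
#'   `coupling_mixed` (mixed / non-autistic dyad ratios). All 1 = null world.
#' @param task_effects Named list of task modifiers: `articulation_meal`
#'   (articulation ratio in meal planning), `coupling_hobbies` (coupling ratio
#'   in hobbies), `gap_meal_mixed` (extra gap ratio for mixed dyads in meal
#'   planning).
#' @param seed Integer seed; fully determines the corpus.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_mixed_dyads = 26, n_nonautistic_dyads = 14,
                             duration_s = 600, tasks = TASKS,
                             frame_step_s = 0.01,
                             turn_median_s = 1.8, turn_log_sd = 0.9,
                             gap_median_s = 0.2, gap_log_sd = 0.7,
                             within_turn_pause_rate = 0.10,
                             pause_median_s = 0.5, pause_log_sd = 0.5,
                             pitch_base_hz = c(120, 220),
                             pitch_base_jitter_hz = 12,
                             pitch_sd_hz = 25,
                             intensity_base_db = 62, intensity_sd_db = 1.2,
                             noise_floor_db = 40,
                             articulation_rate_sps = 4.2,
                             syllable_bump_db = 6,
                             syllable_bump_width_s = 0.12,
                             ar_coef = 0.95,
                             intensity_ar_coef = 0.995,
                             turn_level_sd = c(pitch_hz = 8,
                                               intensity_db = 2.5,
                                               articulation_sps = 0.35),
                             adapt_gain = c(pitch = 0.35, intensity = 0.35,
                                            articulation = 0.35),
                             intensity_coupling_gain = 0.6,
                             intensity_coupling_lag_s = 1,
                             effect_multipliers = list(
                               pitch_sd_autistic = 0.6,
                               intensity_sd_autistic = 0.75,
                               articulation_autistic = 0.85,
                               gap_mixed = 1.6,
                               silence_mixed = 1.5,
                               coupling_mixed = 1.5),
                             task_effects = list(articulation_meal = 1.05,
                                                 coupling_hobbies = 1.2,
                                                 gap_meal_mixed = 1.15),
                             seed = 1L) {
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  cfg <- list(n_mixed_dyads = n_mixed_dyads,
              n_nonautistic_dyads = n_nonautistic_dyads,
              duration_s = duration_s, tasks = tasks,
              frame_step_s = frame_step_s,
              turn_median_s = turn_median_s, turn_log_sd = turn_log_sd,
              gap_median_s = gap_median_s, gap_log_sd = gap_log_sd,
              within_turn_pause_rate = within_turn_pause_rate,
              pause_median_s = pause_median_s, pause_log_sd = pause_log_sd,
              pitch_base_hz = pitch_base_hz,
              pitch_base_jitter_hz = pitch_base_jitter_hz,
              pitch_sd_hz = pitch_sd_hz,
              intensity_base_db = intensity_base_db,
              intensity_sd_db = intensity_sd_db,
              noise_floor_db = noise_floor_db,
              articulation_rate_sps = articulation_rate_sps,
              syllable_bump_db = syllable_bump_db,
              syllable_bump_width_s = syllable_bump_width_s,
              ar_coef = ar_coef, intensity_ar_coef = intensity_ar_coef,
              turn_level_sd = turn_level_sd,
              adapt_gain = adapt_gain,
              intensity_coupling_gain = intensity_coupling_gain,
              intensity_coupling_lag_s = intensity_coupling_lag_s,
              effect_multipliers = effect_multipliers,
              task_effects = task_effects, seed = as.integer(seed))
  pos <- c("duration_s", "frame_step_s", "turn_median_s", "turn_log_sd",
           "gap_median_s", "gap_log_sd", "pause_median_s", "pause_log_sd",
           "pitch_sd_hz", "intensity_sd_db", "articulation_rate_sps",
           "syllable_bump_db", "syllable_bump_width_s")
  for (p in pos) if (!is.finite(cfg[[p]]) || cfg[[p]] <= 0)
    stop("config error: ", p, " must be positive", call. = FALSE)
  if (cfg$within_turn_pause_rate < 0)
    stop("config error: within_turn_pause_rate must be >= 0", call. = FALSE)
  if (cfg$intensity_coupling_lag_s < 0)
    stop("config error: intensity_coupling_lag_s must be >= 0", call. = FALSE)
  if (any(unlist(cfg$effect_multipliers) <= 0))
    stop("config error: effect multipliers must be positive", call. = FALSE)
  if (cfg$n_mixed_dyads < 0 || cfg$n_nonautistic_dyads < 0 ||
      cfg$n_mixed_dyads + cfg$n_nonautistic_dyads < 1)
    stop("config error: need at least one dyad", call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Null-world version of a configuration
#'
#' Sets every planted-effect multiplier to 1, removing all group and
#' dyad-type contrasts while keeping the shared conversational structure.
#'
#' @param cfg A [generator_config()].
#' @return The modified configuration.
#' @export
null_world <- function(cfg) {
  cfg$effect_multipliers[] <- lapply(cfg$effect_multipliers, function(x) 1)
  cfg
}

# stationary AR(1) noise with given marginal sd
ar1_noise <- function(n, phi, sd) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - phi^2)),
                           phi, method = "recursive"))
}

# turn skeleton + within-turn pauses for one conversation; returns a data
# frame of speaking segments with speaker and turn index
simulate_skeleton <- function(cfg, speakers, gap_mult, pause_mult) {
  turns <- list()
  t <- stats::rlnorm(1, log(cfg$gap_median_s * gap_mult), cfg$gap_log_sd)
  cur <- sample(speakers, 1)
  while (t < cfg$duration_s - 0.5) {
    # redraw rather than drop sub-300-ms turns so that strict alternation
    # holds and every between-turn gap is exactly one gap draw
    repeat {
      len <- stats::rlnorm(1, log(cfg$turn_median_s), cfg$turn_log_sd)
      if (len >= 0.3) break
    }
    end <- min(t + len, cfg$duration_s)
    if (end - t >= 0.3)
      turns[[length(turns) + 1L]] <- list(speaker = cur, start = t, end = end)
    gap <- stats::rlnorm(1, log(cfg$gap_median_s * gap_mult), cfg$gap_log_sd)
    t <- end + gap
    cur <- setdiff(speakers, cur)
  }
  if (length(turns) == 0L)
    stop("config error: no turns generated; duration too short", call. = FALSE)
  segs <- list()
  for (k in seq_along(turns)) {
    tn <- turns[[k]]
    span <- tn$end - tn$start
    pauses <- NULL
    if (span > 0.8 && cfg$within_turn_pause_rate > 0) {
      n_p <- stats::rpois(1, cfg$within_turn_pause_rate * pause_mult * span)
      if (n_p > 0) {
        ps <- sort(stats::runif(n_p, tn$start + 0.25, tn$end - 0.25))
        pl <- stats::rlnorm(n_p, log(cfg$pause_median_s), cfg$pause_log_sd)
        pe <- pmin(ps + pl, tn$end - 0.15)
        keep <- pe > ps
        pauses <- data.frame(start = ps[keep], end = pe[keep])
        if (nrow(pauses) > 1L) {  # merge overlapping pauses
          pauses <- merge_close_segments(pauses, 0)
        }
      }
    }
    if (is.null(pauses) || nrow(pauses) == 0L) {
      sp <- data.frame(start = tn$start, end = tn$end)
    } else {
      b <- c(tn$start, t(as.matrix(pauses)), tn$end)
      sp <- data.frame(start = b[seq(1, length(b) - 1, by = 2)],
                       end = b[seq(2, length(b), by = 2)])
      sp <- sp[sp$end - sp$start >= 0.12, , drop = FALSE]
      if (nrow(sp) == 0L) sp <- data.frame(start = tn$start, end = tn$end)
    }
    sp$speaker <- tn$speaker
    sp$turn <- k
    segs[[k]] <- sp
  }
  do.call(rbind, segs)
}

simulate_conversation <- function(cfg, dyad, task) {
  em <- cfg$effect_multipliers
  te <- cfg$task_effects
  gap_mult <- dyad$gap_style * (if (dyad$dyad_type == "mixed")
    em$gap_mixed * (if (task == "meal_planning") te$gap_meal_mixed else 1)
  else 1)
  pause_mult <- dyad$pause_style *
    (if (dyad$dyad_type == "mixed") em$silence_mixed else 1)
  segs <- simulate_skeleton(cfg, dyad$speakers, gap_mult, pause_mult)

  # per-turn offsets with cross-partner adaptation on the offset sequence
  n_turn <- max(segs$turn)
  turn_speaker <- vapply(seq_len(n_turn), function(k)
    segs$speaker[segs$turn == k][1L], character(1))
  tls <- cfg$turn_level_sd
  g <- cfg$adapt_gain
  off <- matrix(0, n_turn, 3, dimnames = list(NULL, c("pitch", "intensity",
                                                      "articulation")))
  gains <- c(g[["pitch"]], g[["intensity"]], g[["articulation"]])
  for (k in seq_len(n_turn)) {
    par_k <- dyad$params[[turn_speaker[k]]]
    sds <- c(tls[["pitch_hz"]] * par_k$var_mult,
             tls[["intensity_db"]] * par_k$int_var_mult,
             tls[["articulation_sps"]])
    prev <- if (k > 1L) off[k - 1L, ] else c(0, 0, 0)
    off[k, ] <- gains * prev +
      stats::rnorm(3, 0, sds * sqrt(pmax(1 - gains^2, 0.05)))
  }

  nfr <- round(cfg$duration_s / cfg$frame_step_s)
  step <- cfg$frame_step_s
  tracks <- list()
  seg_by_sp <- split(segs, segs$speaker)
  for (sp in dyad$speakers) {
    par <- dyad$params[[sp]]
    pitch <- rep(NA_real_, nfr)
    intensity <- cfg$noise_floor_db +
      ar1_noise(nfr, cfg$intensity_ar_coef, 1.0)
    ep <- ar1_noise(nfr, cfg$ar_coef, par$pitch_sd)
    ei <- ar1_noise(nfr, cfg$intensity_ar_coef, par$intensity_sd)
    own <- seg_by_sp[[sp]]
    artic_task <- par$articulation *
      (if (task == "meal_planning") te$articulation_meal else 1)
    for (i in seq_len(nrow(own))) {
      # frame i covers time (i-1)*step; fill exactly the frames that
      # segment_mask() assigns to the half-open segment [start, end)
      i0 <- ceiling((own$start[i] - 1e-9) / step) + 1L
      i1 <- min(nfr, ceiling((own$end[i] - 1e-9) / step))
      if (i1 < i0) next
      idx <- i0:i1
      k <- own$turn[i]
      pitch[idx] <- pmax(50, par$pitch_base + off[k, "pitch"] + ep[idx])
      intensity[idx] <- par$intensity_base + off[k, "intensity"] + ei[idx]
      # syllable-scale intensity bumps at the turn's articulation rate
      rate <- max(1.5, artic_task + off[k, "articulation"])
      dur <- own$end[i] - own$start[i]
      n_syl <- max(1L, round(rate * dur))
      centres <- own$start[i] + (seq_len(n_syl) - 0.5) / n_syl * dur +
        stats::rnorm(n_syl, 0, 0.15 / rate)
      centres <- sort(centres[centres > own$start[i] + 0.02 &
                              centres < own$end[i] - 0.02])
      # syllables do not overlap: keep peaks separated by >= bump width
      if (length(centres) > 1L) {
        min_sep <- cfg$syllable_bump_width_s + 0.01
        for (q in 2:length(centres))
          centres[q] <- max(centres[q], centres[q - 1L] + min_sep)
        centres <- centres[centres < own$end[i] - 0.02]
      }
      hw <- cfg$syllable_bump_width_s / 2
      for (ct in centres) {
        j0 <- max(i0, floor((ct - hw) / step) + 1L)
        j1 <- min(i1, ceiling((ct + hw) / step))
        if (j1 < j0) next
        jj <- j0:j1
        amp <- cfg$syllable_bump_db + stats::rnorm(1, 0, 0.6)
        tt <- (jj - 1) * step
        intensity[jj] <- intensity[jj] +
          amp * 0.5 * (1 + cos(pi * (tt - ct) / hw)) *
          (abs(tt - ct) <= hw)
      }
    }
    tracks[[sp]] <- list(pitch = pitch, intensity = intensity)
  }

  # lagged cross-partner intensity coupling on non-speech frames (cross-talk)
  lagf <- round(cfg$intensity_coupling_lag_s / step)
  gain <- dyad$coupling_gain *
    (if (task == "hobbies") te$coupling_hobbies else 1)
  if (gain > 0) {
    pre <- lapply(tracks, function(tr) tr$intensity)
    for (i in 1:2) {
      recv <- dyad$speakers[i]; send <- dyad$speakers[3 - i]
      dev <- pre[[send]] - mean(pre[[send]])
      lagged <- if (lagf > 0) c(rep(0, lagf), dev[seq_len(nfr - lagf)]) else dev
      own_mask <- segment_mask(seg_by_sp[[recv]], nfr, step)
      tracks[[recv]]$intensity[!own_mask] <-
        tracks[[recv]]$intensity[!own_mask] + gain * lagged[!own_mask]
    }
  }

  ann <- annotation_set(
    conversation_id = paste(dyad$dyad_id, task, sep = "_"), task = task,
    segments = lapply(seg_by_sp[dyad$speakers], function(s)
      s[, c("start", "end")]),
    duration_s = cfg$duration_s)
  pts <- lapply(dyad$speakers, function(sp)
    prosody_track(tracks[[sp]]$pitch, tracks[[sp]]$intensity, step))
  names(pts) <- dyad$speakers
  structure(list(annotations = ann, tracks = pts, dyad_id = dyad$dyad_id,
                 task = task, participants = dyad$speakers,
                 groups = dyad$groups, dyad_type = dyad$dyad_type),
            class = "conversation_record")
}

#' Generate a synthetic corpus of dyadic conversations
#'
#' For each dyad one conversation record per task. The turn skeleton
#' alternates speakers with log-normal turn and gap lengths (gap medians
#' inflated for mixed dyads), within-turn pauses split turns into speaking
#' segments, and prosody tracks carry AR(1) pitch/intensity contours,
#' syllable-scale intensity bumps at the speaker's articulation rate,
#' turn-based adaptation and lagged cross-partner intensity coupling. The
#' output is deterministic given `cfg$seed`; generation uses R's default
#' Mersenne-Twister generator.
#'
#' @param cfg A [generator_config()].
#' @return List with `records` (list of `conversation_record`s: annotations +
#'   tracks + metadata) and `truth` (ground truth: `participants` and `dyads`
#'   data frames with realized parameter values).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  em <- cfg$effect_multipliers
  n_dyads <- cfg$n_mixed_dyads + cfg$n_nonautistic_dyads
  dyad_types <- c(rep("mixed", cfg$n_mixed_dyads),
                  rep("non_autistic", cfg$n_nonautistic_dyads))
  records <- list()
  part_rows <- list(); dyad_rows <- list()
  for (d in seq_len(n_dyads)) {
    dyad_id <- sprintf("D%02d", d)
    speakers <- paste0(dyad_id, c("A", "B"))
    dtype <- dyad_types[d]
    groups <- if (dtype == "mixed") {
      aut <- sample(1:2, 1)
      ifelse(seq_len(2) == aut, "autistic", "non_autistic")
    } else c("non_autistic", "non_autistic")
    names(groups) <- speakers
    params <- lapply(speakers, function(sp) {
      autistic <- groups[[sp]] == "autistic"
      # between-speaker heterogeneity: the group multiplier shifts a
      # log-normal spread of individual prosodic variability
      var_mult <- (if (autistic) em$pitch_sd_autistic else 1) *
        exp(stats::rnorm(1, 0, 0.25))
      int_var_mult <- (if (autistic) em$intensity_sd_autistic else 1) *
        exp(stats::rnorm(1, 0, 0.25))
      list(pitch_base = sample(cfg$pitch_base_hz, 1) +
             stats::rnorm(1, 0, cfg$pitch_base_jitter_hz),
           pitch_sd = cfg$pitch_sd_hz * var_mult,
           var_mult = var_mult,
           intensity_base = cfg$intensity_base_db + stats::rnorm(1, 0, 1.5),
           intensity_sd = cfg$intensity_sd_db * int_var_mult,
           int_var_mult = int_var_mult,
           articulation = cfg$articulation_rate_sps *
             (if (autistic) em$articulation_autistic else 1) *
             exp(stats::rnorm(1, 0, 0.07)))
    })
    names(params) <- speakers
    coupling_gain <- cfg$intensity_coupling_gain *
      (if (dtype == "mixed") em$coupling_mixed else 1) *
      exp(stats::rnorm(1, 0, 0.15))
    # dyad-level conversational style: gap and pausing habits vary between
    # pairs, so planted dyad contrasts sit on top of real heterogeneity
    dyad <- list(dyad_id = dyad_id, speakers = speakers, groups = groups,
                 dyad_type = dtype, params = params,
                 coupling_gain = coupling_gain,
                 gap_style = exp(stats::rnorm(1, 0, 0.3)),
                 pause_style = exp(stats::rnorm(1, 0, 0.3)))
    for (task in cfg$tasks)
      records[[length(records) + 1L]] <- simulate_conversation(cfg, dyad, task)
    for (sp in speakers)
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        participant_id = sp, dyad_id = dyad_id, group = groups[[sp]],
        dyad_type = dtype, pitch_base_hz = params[[sp]]$pitch_base,
        pitch_sd_hz = params[[sp]]$pitch_sd,
        intensity_sd_db = params[[sp]]$intensity_sd,
        articulation_rate_sps = params[[sp]]$articulation,
        stringsAsFactors = FALSE)
    dyad_rows[[length(dyad_rows) + 1L]] <- data.frame(
      dyad_id = dyad_id, dyad_type = dtype, coupling_gain = coupling_gain,
      stringsAsFactors = FALSE)
  }
  list(records = records,
       truth = list(participants = do.call(rbind, part_rows),
                    dyads = do.call(rbind, dyad_rows)))
}

#' Planted-effect recovery report
#'
#' Joins the generator's ground truth with a computed feature table and
#' reports, per planted effect, the empirical standardised group difference
#' (Cohen's d) and its sign. Individual effects contrast autistic minus
#' non-autistic participants; dyadic effects contrast mixed minus
#' non-autistic dyads.
#'
#' @param truth Ground truth from [generate_corpus()].
#' @param feature_table Feature table computed from the same corpus.
#' @return Data frame with `effect`, `level`, `feature`, `d` (standardised
#'   difference) and `sign`.
#' @export
planted_effect_report <- function(truth, feature_table) {
  ft <- feature_table
  if (!all(ft$participant_id %in% truth$participants$participant_id))
    stop("join error: feature table has participants missing from the ",
         "ground truth", call. = FALSE)
  cohen_d <- function(v, grp, pos) {
    a <- v[grp == pos & !is.na(v)]
    b <- v[grp != pos & !is.na(v)]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
    if (sp == 0) return(NA_real_)
    (mean(a) - mean(b)) / sp
  }
  ind <- data.frame(effect = c("articulation_autistic", "pitch_sd_autistic",
                               "intensity_sd_autistic"),
                    feature = c("articulation_rate_sps", "var_pitch_hz2",
                                "var_intensity_db2"),
                    stringsAsFactors = FALSE)
  ind$level <- "individual"
  ind$d <- vapply(ind$feature, function(f)
    cohen_d(ft[[f]], ft$group, "autistic"), numeric(1))
  dy_ft <- ft[!duplicated(paste(ft$dyad_id, ft$task)), , drop = FALSE]
  dy <- data.frame(effect = c("gap_mixed", "silence_mixed", "coupling_mixed"),
                   feature = c("mean_gap_s", "silence_to_turn_ratio",
                               "sync_intensity"),
                   stringsAsFactors = FALSE)
  dy$level <- "dyadic"
  dy$d <- vapply(dy$feature, function(f)
    cohen_d(dy_ft[[f]], dy_ft$dyad_type, "mixed"), numeric(1))
  out <- rbind(ind, dy)
  out$sign <- sign(out$d)
  out[, c("effect", "level", "feature", "d", "sign")]
}
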