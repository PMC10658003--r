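# Containers and readers/writers for speaking-instance annotations, prosody
# tracks, feature tables and run configuration. Times are seconds from
# conversation start; intervals are half-open [start, end).

TASKS <- c("hobbies", "meal_planning")

#' Construct an annotation set for one conversation
#'
#' An annotation set holds, for one dyad and one task, the speaking instances
#' (intervals in seconds) of exactly two speakers plus the total conversation
#' duration.
#'
#' @param conversation_id Identifier of the conversation.
#' @param task Conversation task, `"hobbies"` or `"meal_planning"`.
#' @param segments Named list with one element per speaker (exactly two), each
#'   a data frame with columns `start` and `end` in seconds.
#' @param duration_s Total conversation duration in seconds.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(conversation_id, task, segments, duration_s) {
  task <- match.arg(task, TASKS)
  if (!is.list(segments) || is.null(names(segments)) || any(names(segments) == ""))
    stop("`segments` must be a named list, one element per speaker", call. = FALSE)
  segments <- lapply(segments, function(s) {
    s <- as.data.frame(s)
    if (!all(c("start", "end") %in% names(s)))
      stop("speaker segments need `start` and `end` columns", call. = FALSE)
    s <- s[order(s$start), c("start", "end"), drop = FALSE]
    rownames(s) <- NULL
    s
  })
  x <- structure(
    list(conversation_id = as.character(conversation_id), task = task,
         speakers = names(segments), segments = segments,
         duration_s = as.numeric(duration_s)),
    class = "annotation_set")
  validate_annotation_set(x)
}

#' Validate an annotation set
#'
#' Checks the dyad constraint (exactly two speakers) and, per speaker, that
#' intervals are sorted, non-overlapping and inside `[0, duration_s]`.
#'
#' @param x An `annotation_set`.
#' @return `x`, invisibly-valid (errors otherwise).
#' @export
validate_annotation_set <- function(x) {
  if (length(x$speakers) != 2L)
    stop("an annotation set needs exactly two speakers, got ",
         length(x$speakers), call. = FALSE)
  if (!is.finite(x$duration_s) || x$duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  for (sp in x$speakers) {
    s <- x$segments[[sp]]
    if (nrow(s) == 0L) next
    if (any(!is.finite(s$start)) || any(!is.finite(s$end)))
      stop("non-finite segment bounds for speaker ", sp, call. = FALSE)
    if (any(s$start >= s$end))
      stop("empty or inverted segment for speaker ", sp, call. = FALSE)
    if (any(s$start < 0) || any(s$end > x$duration_s + 1e-9))
      stop("segment outside [0, duration_s] for speaker ", sp, call. = FALSE)
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)] - 1e-9))
      stop("overlapping segments within speaker ", sp, call. = FALSE)
  }
  x
}

# Merge adjacent same-speaker intervals separated by less than `gap_tol`
# seconds (annotation tools often split on frame boundaries).
merge_close_segments <- function(seg, gap_tol) {
  if (nrow(seg) < 2L) return(seg)
  seg <- seg[order(seg$start), , drop = FALSE]
  out_s <- seg$start[1L]; out_e <- seg$end[1L]
  for (i in 2L:nrow(seg)) {
    if (seg$start[i] - out_e[length(out_e)] < gap_tol) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], seg$end[i])
    } else {
      out_s <- c(out_s, seg$start[i]); out_e <- c(out_e, seg$end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Construct a prosody track
#'
#' Frame-level pitch and intensity sampled on a uniform grid; frame `i` covers
#' time `(i - 1) * frame_step_s`. Pitch is missing (`NA`) wherever the speaker
#' is not producing voiced speech. Intensity follows the recording channel: it
#' may be defined at every frame (a per-speaker microphone picks up the room
#' noise floor during silence) or missing where nothing was recorded.
#'
#' @param pitch_hz Numeric vector of per-frame pitch values in Hz (`NA` =
#'   unvoiced/silent).
#' @param intensity_db Numeric vector of per-frame intensity values in dB
#'   (`NA` = not recorded).
#' @param frame_step_s Frame step in seconds (default 0.01).
#' @return An object of class `prosody_track`.
#' @export
prosody_track <- function(pitch_hz, intensity_db, frame_step_s = 0.01) {
  if (length(pitch_hz) != length(intensity_db))
    stop("pitch and intensity tracks must have the same number of frames",
         call. = FALSE)
  if (!is.finite(frame_step_s) || frame_step_s <= 0)
    stop("frame_step_s must be positive", call. = FALSE)
  if (any(!is.na(pitch_hz) & pitch_hz <= 0))
    stop("pitch_hz must be > 0 wherever present", call. = FALSE)
  structure(list(frame_step_s = frame_step_s,
                 pitch_hz = as.numeric(pitch_hz),
                 intensity_db = as.numeric(intensity_db),
                 n_frames = length(pitch_hz)),
            class = "prosody_track")
}

#' Frame start times of a prosody track
#' @param track A `prosody_track`.
#' @return Numeric vector of frame start times in seconds.
#' @export
frame_times <- function(track) {
  (seq_len(track$n_frames) - 1) * track$frame_step_s
}

#' Logical frame mask for a set of segments
#'
#' @param segments Data frame with `start`/`end` columns (seconds).
#' @param n_frames Number of frames.
#' @param frame_step_s Frame step in seconds.
#' @return Logical vector, `TRUE` for frames whose start time falls inside any
#'   half-open segment `[start, end)`.
#' @export
segment_mask <- function(segments, n_frames, frame_step_s) {
  if (NROW(segments) == 0L) return(logical(n_frames))
  t0 <- (seq_len(n_frames) - 1) * frame_step_s
  o <- order(segments$start)
  bounds <- as.vector(rbind(segments$start[o], segments$end[o])) - 1e-9
  findInterval(t0, bounds) %% 2L == 1L
}

## ---- TextGrid ----------------------------------------------------------

# Reduce a TextGrid (long or short text dialect) to one token per line, with
# source line numbers kept for error messages.
tg_tokens <- function(lines) {
  keep_tok <- character(0); keep_line <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (grepl("<exists>", ln, fixed = TRUE)) next
    if (grepl("^(item|intervals|points)\\s*\\[", ln) && !grepl("=", ln, fixed = TRUE)) next
    if (grepl("^item\\s*\\[\\]", ln)) next
    if (grepl("=", ln, fixed = TRUE)) ln <- trimws(sub("^[^=]*=", "", ln))
    if (ln == "") next
    keep_tok <- c(keep_tok, ln); keep_line <- c(keep_line, i)
  }
  data.frame(token = keep_tok, line = keep_line, stringsAsFactors = FALSE)
}

tg_is_string <- function(tok) startsWith(tok, "\"")
tg_string <- function(tok) gsub("\"\"", "\"", sub("\"$", "", sub("^\"", "", tok)))

read_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 2L || !grepl("ooTextFile", lines[1L]))
    stop("TextGrid parse error at line 1: missing ooTextFile header in ", path,
         call. = FALSE)
  if (!grepl("TextGrid", lines[2L]))
    stop("TextGrid parse error at line 2: object class is not TextGrid in ",
         path, call. = FALSE)
  tk <- tg_tokens(lines[-(1:2)])
  pos <- 0L
  take <- function() {
    pos <<- pos + 1L
    if (pos > nrow(tk))
      stop("TextGrid parse error: file truncated after line ",
           if (nrow(tk)) tk$line[nrow(tk)] + 2L else 2L, call. = FALSE)
    tk[pos, ]
  }
  num <- function() {
    t <- take()
    v <- suppressWarnings(as.numeric(t$token))
    if (is.na(v))
      stop("TextGrid parse error at line ", t$line + 2L,
           ": expected a number, got '", t$token, "'", call. = FALSE)
    v
  }
  str <- function() {
    t <- take()
    if (!tg_is_string(t$token))
      stop("TextGrid parse error at line ", t$line + 2L,
           ": expected a quoted string, got '", t$token, "'", call. = FALSE)
    tg_string(t$token)
  }
  xmin <- num(); xmax <- num(); ntier <- num()
  tiers <- vector("list", ntier); tier_names <- character(ntier)
  for (k in seq_len(ntier)) {
    cls <- str()
    if (!identical(cls, "IntervalTier"))
      stop("TextGrid parse error at line ", tk$line[pos] + 2L,
           ": unsupported tier class '", cls, "' (only IntervalTier)",
           call. = FALSE)
    tier_names[k] <- str()
    num(); num()                      # tier xmin / xmax
    nint <- num()
    s <- e <- numeric(nint); lab <- character(nint)
    for (j in seq_len(nint)) {
      s[j] <- num(); e[j] <- num(); lab[j] <- str()
    }
    tiers[[k]] <- data.frame(start = s, end = e, label = lab,
                             stringsAsFactors = FALSE)
  }
  list(xmin = xmin, xmax = xmax, tiers = tiers, tier_names = tier_names)
}

## ---- RTTM --------------------------------------------------------------

read_rttm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(;;|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("RTTM parse error: no records in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) < 8L)
  if (length(bad))
    stop("RTTM parse error at line ", bad[1L], ": fewer than 8 fields",
         call. = FALSE)
  typ <- vapply(fields, `[[`, "", 1L)
  keep <- typ == "SPEAKER"
  fields <- fields[keep]
  if (length(fields) == 0L)
    stop("RTTM parse error: no SPEAKER records in ", path, call. = FALSE)
  tbeg <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  tdur <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (anyNA(tbeg) || anyNA(tdur)) {
    bad <- which(keep)[which(is.na(tbeg) | is.na(tdur))[1L]]
    stop("RTTM parse error at line ", bad, ": non-numeric onset/duration",
         call. = FALSE)
  }
  data.frame(file = vapply(fields, `[[`, "", 2L),
             speaker = vapply(fields, `[[`, "", 8L),
             start = tbeg, end = tbeg + tdur, stringsAsFactors = FALSE)
}

#' Read speaking-instance annotations
#'
#' Reads a Praat TextGrid (long or short text dialect; one interval tier per
#' speaker, non-empty labels marking speech) or an RTTM diarization file
#' (`SPEAKER` records; onset + duration convention) into an
#' [annotation_set()]. Tier names / RTTM speaker names become speaker ids
#' verbatim. Adjacent same-speaker intervals closer than one frame are merged.
#'
#' @param path Path to the annotation file.
#' @param dialect `"textgrid"` or `"rttm"`.
#' @param task Conversation task to record in the annotation set.
#' @param conversation_id Conversation id; defaults to the file name (RTTM:
#'   the file field of the first record).
#' @param duration_s Conversation duration; defaults to the TextGrid `xmax`
#'   (RTTM: the last segment end).
#' @param frame_step_s Frame step used as the merge tolerance for adjacent
#'   intervals.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, dialect = c("textgrid", "rttm"),
                             task = "hobbies", conversation_id = NULL,
                             duration_s = NULL, frame_step_s = 0.01) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "textgrid") {
    tg <- read_textgrid(path)
    if (length(tg$tiers) != 2L)
      stop("annotation validation error: expected exactly 2 speaker tiers, ",
           "got ", length(tg$tiers), call. = FALSE)
    segs <- lapply(tg$tiers, function(tier) {
      sp <- tier[nzchar(trimws(tier$label)), c("start", "end"), drop = FALSE]
      merge_close_segments(sp, frame_step_s)
    })
    names(segs) <- tg$tier_names
    if (is.null(duration_s)) duration_s <- tg$xmax
    if (is.null(conversation_id))
      conversation_id <- sub("\\.[^.]*$", "", basename(path))
  } else {
    rt <- read_rttm(path)
    spk <- unique(rt$speaker)
    if (length(spk) != 2L)
      stop("annotation validation error: expected exactly 2 speakers, got ",
           length(spk), call. = FALSE)
    segs <- lapply(spk, function(s) {
      merge_close_segments(rt[rt$speaker == s, c("start", "end")], frame_step_s)
    })
    names(segs) <- spk
    if (is.null(duration_s)) duration_s <- max(rt$end)
    if (is.null(conversation_id)) conversation_id <- rt$file[1L]
  }
  annotation_set(conversation_id, task, segs, duration_s)
}

#' Write an annotation set as a long-format TextGrid
#'
#' One interval tier per speaker; speech intervals carry the label
#' `"speech"`, silences an empty label.
#'
#' @param x An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(x, path) {
  fmt <- function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("File type = \"ooTextFile\"")
  w("Object class = \"TextGrid\"")
  w("")
  w("xmin = 0")
  w("xmax = ", fmt(x$duration_s))
  w("tiers? <exists>")
  w("size = 2")
  w("item []:")
  for (k in 1:2) {
    sp <- x$speakers[k]
    seg <- x$segments[[sp]]
    # full tier: alternate empty / speech intervals covering [0, duration]
    b <- sort(unique(c(0, seg$start, seg$end, x$duration_s)))
    b <- b[b <= x$duration_s + 1e-12]
    ints <- data.frame(start = b[-length(b)], end = b[-1L])
    mid <- (ints$start + ints$end) / 2
    lab <- ifelse(vapply(mid, function(m)
      any(m >= seg$start & m < seg$end), logical(1)), "speech", "")
    w("    item [", k, "]:")
    w("        class = \"IntervalTier\"")
    w("        name = \"", sp, "\"")
    w("        xmin = 0")
    w("        xmax = ", fmt(x$duration_s))
    w("        intervals: size = ", nrow(ints))
    for (j in seq_len(nrow(ints))) {
      w("        intervals [", j, "]:")
      w("            xmin = ", fmt(ints$start[j]))
      w("            xmax = ", fmt(ints$end[j]))
      w("            text = \"", lab[j], "\"")
    }
  }
  invisible(path)
}

## ---- prosody track files -----------------------------------------------

#' Write / read a prosody track as a delimited frame table
#'
#' Columns `time_s`, `pitch_hz`, `intensity_db`; empty fields are missing.
#'
#' @param track A [prosody_track()].
#' @param path File path.
#' @return `write_track()`: `path`, invisibly. `read_track()`: a
#'   [prosody_track()].
#' @export
write_track <- function(track, path) {
  df <- data.frame(time_s = frame_times(track), pitch_hz = track$pitch_hz,
                   intensity_db = track$intensity_db)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"))
  need <- c("time_s", "pitch_hz", "intensity_db")
  if (!all(need %in% names(df)))
    stop("track schema error: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  step <- if (nrow(df) > 1L) stats::median(diff(df$time_s)) else 0.01
  prosody_track(df$pitch_hz, df$intensity_db, frame_step_s = step)
}

## ---- feature tables ----------------------------------------------------

#' Feature-table column schema
#'
#' Fixed column order of the per-individual-per-task feature table: ids and
#' labels, nine individual speech features, six dyadic interactional features
#' (repeated for both dyad members).
#'
#' @return Character vector of column names.
#' @export
feature_table_columns <- function() {
  c("participant_id", "dyad_id", "task", "group", "dyad_type",
    "articulation_rate_sps", "n_pauses", "n_syllables", "phonation_time_s",
    "adapt_articulation", "adapt_intensity", "adapt_pitch",
    "var_intensity_db2", "var_pitch_hz2",
    "n_turns", "mean_gap_s", "silence_to_turn_ratio", "speech_rate_sps",
    "sync_intensity", "sync_pitch")
}

#' Write / read a feature table
#'
#' Comma-separated, UTF-8, one row per individual x task; columns are matched
#' by name on read so column order in the file is irrelevant. The round trip
#' is lossless to full double precision.
#'
#' @param features Data frame conforming to [feature_table_columns()].
#' @param path File path.
#' @return `write_feature_table()`: `path`, invisibly. `read_feature_table()`:
#'   the feature table with columns in canonical order.
#' @export
write_feature_table <- function(features, path) {
  cols <- feature_table_columns()
  unknown <- setdiff(names(features), cols)
  if (length(unknown))
    stop("feature table schema error: unknown column(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(cols, names(features))
  if (length(missing))
    stop("feature table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  readr::write_csv(features[, cols], path, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- as.data.frame(readr::read_csv(path, show_col_types = FALSE,
                                      progress = FALSE))
  cols <- feature_table_columns()
  unknown <- setdiff(names(df), cols)
  if (length(unknown))
    stop("feature table schema error: unknown column(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("feature table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, cols]
  for (ch in c("participant_id", "dyad_id", "task", "group", "dyad_type"))
    df[[ch]] <- as.character(df[[ch]])
  df
}

#' Read a generator configuration from a YAML file
#'
#' Top-level keys are passed as arguments to [generator_config()].
#'
#' @param path Path to a YAML file.
#' @return A `generator_config` object.
#' @export
read_generator_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(generator_config, vals)
}

## ---- logging -----------------------------------------------------------

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Line-oriented logging with levels
#'
#' Writes `[timestamp] LEVEL message` lines to `stderr` (or the file set in
#' option `dyadsync.log_file`). Messages below the threshold in option
#' `dyadsync.log_level` (default `"info"`) are suppressed.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... Message parts, pasted together.
#' @return The formatted line, invisibly (or `NULL` if suppressed).
#' @export
ds_log <- function(level = c("info", "warn", "error", "debug"), ...) {
  level <- match.arg(level)
  thr <- getOption("dyadsync.log_level", "info")
  if (.log_levels[[level]] < .log_levels[[thr]]) return(invisible(NULL))
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(..., collapse = ""))
  dest <- getOption("dyadsync.log_file", NULL)
  if (is.null(dest)) cat(line, "\n", sep = "", file = stderr())
  else cat(line, "\n", sep = "", file = dest, append = TRUE)
  invisible(line)
}
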