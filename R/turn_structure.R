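# Turn segmentation for two-party conversations and the dyadic turn-taking
# features derived from it. A turn is all speaking instances of one
# interactant up to the end of the speaking instance that precedes the other
# interactant's next speaking instance; speakers therefore alternate strictly.

#' Segment a conversation into turns
#'
#' Walks the two speakers' speaking instances in onset order and coalesces
#' consecutive same-speaker instances into turns. A turn starts at the onset
#' of its first instance and ends at the end of its last instance; the gap
#' before a turn is its onset minus the previous turn's offset and is negative
#' when the new speaker starts while the previous one is still talking.
#'
#' When both speakers have an instance with an identical onset, the speaker
#' holding the floor loses it: the other speaker's turn starts there. At the
#' very start of a conversation such a tie goes to the speaker listed first in
#' the annotation set.
#'
#' @param annotations An [annotation_set()].
#' @return An object of class `turn_sequence`: a list with `turns` (data frame
#'   with `turn_id`, `speaker`, `start_s`, `end_s`, `gap_before_s`),
#'   `segments` (all speaking instances with their assigned `turn_id`) and
#'   `duration_s`. Zero speaking instances give an empty sequence.
#' @export
segment_turns <- function(annotations) {
  validate_annotation_set(annotations)
  seg <- do.call(rbind, lapply(annotations$speakers, function(sp) {
    s <- annotations$segments[[sp]]
    if (nrow(s) == 0L) return(NULL)
    data.frame(speaker = sp, start = s$start, end = s$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(seg) || nrow(seg) == 0L) {
    return(structure(list(
      turns = data.frame(turn_id = integer(0), speaker = character(0),
                         start_s = numeric(0), end_s = numeric(0),
                         gap_before_s = numeric(0)),
      segments = data.frame(speaker = character(0), start = numeric(0),
                            end = numeric(0), turn_id = integer(0)),
      duration_s = annotations$duration_s), class = "turn_sequence"))
  }
  seg <- seg[order(seg$start, seg$end), , drop = FALSE]
  n <- nrow(seg)
  turn_of <- integer(n)
  cur_speaker <- NA_character_
  turn_id <- 0L
  i <- 1L
  while (i <= n) {
    # identical onsets for both speakers: the continuing speaker loses the
    # floor, so pick the other speaker's segment first
    pick <- i
    tie <- which(seg$start == seg$start[i] & seq_len(n) >= i & turn_of == 0L)
    if (length(tie) > 1L && length(unique(seg$speaker[tie])) > 1L) {
      prefer <- if (is.na(cur_speaker)) annotations$speakers[1L] else
        setdiff(annotations$speakers, cur_speaker)
      cand <- tie[seg$speaker[tie] == prefer]
      if (length(cand)) pick <- cand[1L]
    }
    if (pick != i) {          # move picked row up to position i
      idx <- c(seq_len(i - 1L), pick, setdiff(i:n, pick))
      seg <- seg[idx, , drop = FALSE]
    }
    if (!identical(seg$speaker[i], cur_speaker)) {
      turn_id <- turn_id + 1L
      cur_speaker <- seg$speaker[i]
    }
    turn_of[i] <- turn_id
    i <- i + 1L
  }
  seg$turn_id <- turn_of
  turns <- do.call(rbind, lapply(seq_len(turn_id), function(k) {
    rows <- seg[seg$turn_id == k, , drop = FALSE]
    data.frame(turn_id = k, speaker = rows$speaker[1L],
               start_s = min(rows$start), end_s = max(rows$end),
               stringsAsFactors = FALSE)
  }))
  turns$gap_before_s <- c(NA_real_, turns$start_s[-1L] - turns$end_s[-nrow(turns)])
  rownames(turns) <- NULL
  structure(list(turns = turns, segments = seg,
                 duration_s = annotations$duration_s),
            class = "turn_sequence")
}

#' @export
print.turn_sequence <- function(x, ...) {
  cat("<turn_sequence> ", nrow(x$turns), " turns over ", x$duration_s,
      " s\n", sep = "")
  invisible(x)
}

# Total length of the union of a set of intervals.
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1L]; ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] > ce) { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
    else ce <- max(ce, end[i])
  }
  tot + (ce - cs)
}

#' Dyadic turn-taking features
#'
#' Computes the conversation-level interactional features: number of turns,
#' mean signed turn-taking gap, silence-to-turn ratio (total non-speech time
#' of the conversation over the summed turn spans — leading and trailing
#' silence included) and speech rate (syllables per second of total time).
#'
#' @param turns A `turn_sequence` from [segment_turns()].
#' @param syllables_total Total syllable count of both speakers over the
#'   conversation (for the speech-rate feature).
#' @return Named list with `n_turns`, `mean_gap_s`, `silence_to_turn_ratio`,
#'   `speech_rate_sps`, `talk_s`, `silence_s`.
#' @export
dyadic_turn_features <- function(turns, syllables_total) {
  stopifnot(inherits(turns, "turn_sequence"))
  tt <- turns$turns
  n_turns <- nrow(tt)
  talk <- interval_union_length(turns$segments$start, turns$segments$end)
  silence <- turns$duration_s - talk
  span_sum <- sum(tt$end_s - tt$start_s)
  if (n_turns == 0L || span_sum <= 0)
    stop("silence-to-turn ratio undefined: zero total turn duration",
         call. = FALSE)
  gaps <- tt$gap_before_s[-1L]
  list(n_turns = n_turns,
       mean_gap_s = if (length(gaps)) mean(gaps) else NA_real_,
       silence_to_turn_ratio = silence / span_sum,
       speech_rate_sps = syllables_total / turns$duration_s,
       talk_s = talk, silence_s = silence)
}
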