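test_that("syllable nuclei are intensity peaks with a sufficient dip", {
  seg <- data.frame(start = 0, end = 10)
  tr <- bump_track(bump_db = 4)
  nuc <- detect_syllable_nuclei(tr, seg)
  expect_length(nuc, 3L)
  expect_equal(nuc, c(2, 5, 8), tolerance = 0.02)
  # 1 dB bumps fail the 2 dB dip criterion
  expect_length(detect_syllable_nuclei(bump_track(bump_db = 1), seg), 0L)
  # unvoiced peaks are not nuclei
  expect_length(detect_syllable_nuclei(bump_track(voiced = FALSE), seg), 0L)
  # entirely missing intensity yields an empty list
  tr2 <- prosody_track(rep(120, 100), rep(NA_real_, 100))
  expect_length(detect_syllable_nuclei(tr2, data.frame(start = 0, end = 1)),
                0L)
})

test_that("individual features follow their definitions on a toy case", {
  ann <- annotation_set("c", "hobbies",
                        list(A = data.frame(start = c(0, 3), end = c(2, 4)),
                             B = data.frame(start = 6, end = 7)), 10)
  ts <- segment_turns(ann)
  # 12 nuclei inside A's 3 s of phonation -> articulation rate 4
  tr <- bump_track(duration = 10, bump_db = 5,
                   bump_at = c(seq(0.1, 1.9, length.out = 8),
                               seq(3.1, 3.9, length.out = 4)), width = 0.12)
  iv <- individual_features(ann, tr, ts, "A")
  expect_equal(iv$phonation_time_s, 3)
  expect_equal(iv$n_syllables, 12L)
  expect_equal(iv$articulation_rate_sps, 4)
  # the 1 s silence inside A's turn is one pause
  expect_equal(iv$n_pauses, 1L)
  # constant pitch has zero variance
  expect_equal(iv$var_pitch_hz2, 0)
  expect_error(individual_features(ann, tr, ts, "Z"), "unknown speaker")
})

test_that("zero phonation time is an articulation-rate error", {
  ann <- annotation_set("c", "hobbies",
                        list(A = data.frame(start = numeric(0),
                                            end = numeric(0)),
                             B = data.frame(start = 0, end = 1)), 2)
  ts <- segment_turns(ann)
  tr <- bump_track(duration = 2, bump_at = 0.5)
  expect_error(individual_features(ann, tr, ts, "A"), "zero phonation")
})

test_that("turn prosody means are segment-restricted frame means", {
  ann <- annotation_set("c", "hobbies",
                        list(A = data.frame(start = 0, end = 2),
                             B = data.frame(start = 3, end = 5)), 6)
  ts <- segment_turns(ann)
  n <- 600
  trA <- prosody_track(rep(c(110, NA), c(200, 400)),
                       rep(70, n))
  # B fully unvoiced
  trB <- prosody_track(rep(NA_real_, n),
                       c(rep(50, 300), rep(64, 200), rep(50, 100)))
  tp <- turn_prosody(ts, list(A = trA, B = trB),
                     nuclei = list(A = numeric(0), B = numeric(0)))
  expect_equal(tp$mean_intensity_db, c(70, 64))
  expect_equal(tp$mean_pitch_hz[1], 110)
  expect_true(is.na(tp$mean_pitch_hz[2]))
})

test_that("merging two turns gives the duration-weighted mean of their means", {
  set.seed(31)
  n <- 1000
  intens <- 60 + stats::rnorm(n)
  tr <- prosody_track(rep(120, n), intens, 0.01)
  two <- annotation_set("c", "hobbies",
                        list(A = data.frame(start = c(0, 4), end = c(2, 7)),
                             B = data.frame(start = c(2.5, 7.5),
                                            end = c(3.5, 8))), 10)
  ts2 <- segment_turns(two)
  tp2 <- turn_prosody(ts2, list(A = tr, B = tr),
                      nuclei = list(A = numeric(0), B = numeric(0)))
  a_rows <- tp2[tp2$speaker == "A", ]
  w <- c(2, 3) * 100                       # frames per A turn
  pooled <- sum(a_rows$mean_intensity_db * w) / sum(w)
  # single spanning turn over the same frames
  one <- annotation_set("c", "hobbies",
                        list(A = data.frame(start = c(0, 4), end = c(2, 7)),
                             B = data.frame(start = 8.5, end = 9)), 10)
  ts1 <- segment_turns(one)
  tp1 <- turn_prosody(ts1, list(A = tr, B = tr),
                      nuclei = list(A = numeric(0), B = numeric(0)))
  expect_equal(tp1$mean_intensity_db[1], pooled, tolerance = 1e-10)
})

test_that("per-turn nucleus counts sum to the participant total", {
  cfg <- generator_config(n_mixed_dyads = 1, n_nonautistic_dyads = 0,
                          duration_s = 120, tasks = "hobbies", seed = 14)
  rec <- generate_corpus(cfg)$records[[1]]
  ts <- segment_turns(rec$annotations)
  for (sp in rec$annotations$speakers) {
    iv <- individual_features(rec$annotations, rec$tracks[[sp]], ts, sp)
    tp <- turn_prosody(ts, rec$tracks)
    expect_equal(sum(tp$n_syllables[tp$speaker == sp]), iv$n_syllables)
  }
})

test_that("features are invariant to uniform time translation", {
  cfg <- generator_config(n_mixed_dyads = 0, n_nonautistic_dyads = 1,
                          duration_s = 60, tasks = "hobbies", seed = 8)
  rec <- generate_corpus(cfg)$records[[1]]
  ann <- rec$annotations
  ts <- segment_turns(ann)
  shift <- 5
  pad <- round(shift / 0.01)
  ann2 <- annotation_set(ann$conversation_id, ann$task,
                         lapply(ann$segments, function(s)
                           data.frame(start = s$start + shift,
                                      end = s$end + shift)),
                         ann$duration_s + shift)
  ts2 <- segment_turns(ann2)
  for (sp in ann$speakers) {
    tr <- rec$tracks[[sp]]
    tr2 <- prosody_track(c(rep(NA_real_, pad), tr$pitch_hz),
                         c(rep(40, pad), tr$intensity_db), 0.01)
    iv <- individual_features(ann, tr, ts, sp)
    iv2 <- individual_features(ann2, tr2, ts2, sp)
    for (f in c("articulation_rate_sps", "n_pauses", "n_syllables",
                "phonation_time_s", "var_pitch_hz2"))
      expect_equal(iv2[[f]], iv[[f]], info = f)
  }
})

test_that("pitch variance is order-free over frames", {
  set.seed(4)
  ann <- annotation_set("c", "hobbies",
                        list(A = data.frame(start = 0, end = 5),
                             B = data.frame(start = 6, end = 7)), 8)
  ts <- segment_turns(ann)
  pit <- c(100 + stats::rnorm(500), rep(NA, 300))
  tr <- prosody_track(pit, rep(60, 800), 0.01)
  perm <- c(sample(500), 501:800)
  tr_p <- prosody_track(pit[perm], rep(60, 800), 0.01)
  iv <- individual_features(ann, tr, ts, "A")
  iv_p <- individual_features(ann, tr_p, ts, "A")
  expect_equal(iv$var_pitch_hz2, iv_p$var_pitch_hz2)
})

test_that("the generator's articulation rate is recovered within 10%", {
  cfg <- generator_config(n_mixed_dyads = 0, n_nonautistic_dyads = 1,
                          duration_s = 300, tasks = "hobbies",
                          articulation_rate_sps = 4.0, seed = 51)
  corp <- generate_corpus(cfg)
  rec <- corp$records[[1]]
  ts <- segment_turns(rec$annotations)
  for (sp in rec$annotations$speakers) {
    iv <- individual_features(rec$annotations, rec$tracks[[sp]], ts, sp)
    planted <- corp$truth$participants$articulation_rate_sps[
      corp$truth$participants$participant_id == sp]
    expect_lt(abs(iv$articulation_rate_sps / planted - 1), 0.10)
  }
})
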