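test_that("the same seed reproduces the corpus exactly", {
  cfg <- generator_config(n_mixed_dyads = 1, n_nonautistic_dyads = 1,
                          duration_s = 120, seed = 7)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$truth, c2$truth)
  for (i in seq_along(c1$records)) {
    expect_identical(c1$records[[i]]$annotations, c2$records[[i]]$annotations)
    expect_identical(c1$records[[i]]$tracks, c2$records[[i]]$tracks)
  }
  c3 <- generate_corpus(generator_config(n_mixed_dyads = 1,
                                         n_nonautistic_dyads = 1,
                                         duration_s = 120, seed = 8))
  expect_false(identical(c1$records[[1]]$tracks, c3$records[[1]]$tracks))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(duration_s = -5), "duration_s")
  expect_error(generator_config(gap_median_s = 0), "gap_median_s")
  expect_error(generator_config(n_mixed_dyads = 0, n_nonautistic_dyads = 0),
               "at least one dyad")
  expect_error(generator_config(effect_multipliers = list(
    pitch_sd_autistic = -1, intensity_sd_autistic = 1,
    articulation_autistic = 1, gap_mixed = 1, silence_mixed = 1,
    coupling_mixed = 1)), "multipliers")
})

test_that("generated records validate as annotation + prosody pairs", {
  cfg <- generator_config(n_mixed_dyads = 1, n_nonautistic_dyads = 1,
                          duration_s = 180, seed = 33)
  corp <- generate_corpus(cfg)
  expect_length(corp$records, 4L)   # 2 dyads x 2 tasks
  for (rec in corp$records) {
    expect_silent(validate_annotation_set(rec$annotations))
    for (sp in rec$annotations$speakers) {
      tr <- rec$tracks[[sp]]
      expect_true(all(tr$pitch_hz > 0, na.rm = TRUE))
      # pitch exists only inside own speaking segments
      m <- segment_mask(rec$annotations$segments[[sp]], tr$n_frames,
                        tr$frame_step_s)
      expect_true(all(is.na(tr$pitch_hz[!m])))
      # channel intensity is defined at every frame
      expect_false(anyNA(tr$intensity_db))
    }
    # speakers never overlap: the union of segments equals the sum of
    # segment lengths
    allseg <- do.call(rbind, rec$annotations$segments)
    expect_equal(dyadsync:::interval_union_length(allseg$start, allseg$end),
                 sum(allseg$end - allseg$start), tolerance = 1e-9)
  }
  # mixed dyads hold exactly one autistic member, non-autistic dyads none
  tp <- corp$truth$participants
  n_aut <- tapply(tp$group == "autistic", tp$dyad_id, sum)
  ty <- corp$truth$dyads$dyad_type[match(names(n_aut),
                                         corp$truth$dyads$dyad_id)]
  expect_true(all(n_aut[ty == "mixed"] == 1))
  expect_true(all(n_aut[ty == "non_autistic"] == 0))
})

test_that("generated between-turn gaps have the configured median", {
  # accumulate >= 10^4 extracted gaps from null-world conversations
  gaps <- numeric(0)
  seed <- 60
  while (length(gaps) < 1e4) {
    cfg <- null_world(generator_config(n_mixed_dyads = 5,
                                       n_nonautistic_dyads = 5,
                                       tasks = "hobbies", seed = seed))
    for (r in generate_corpus(cfg)$records) {
      g <- segment_turns(r$annotations)$turns$gap_before_s
      gaps <- c(gaps, g[!is.na(g)])
    }
    seed <- seed + 1
  }
  expect_lt(abs(stats::median(gaps) / 0.2 - 1), 0.05)
})

test_that("generated turn lengths have the configured median", {
  cfg <- null_world(generator_config(n_mixed_dyads = 5,
                                     n_nonautistic_dyads = 5,
                                     tasks = "hobbies", seed = 71))
  lens <- unlist(lapply(generate_corpus(cfg)$records, function(r) {
    tt <- segment_turns(r$annotations)$turns
    tt$end_s - tt$start_s
  }))
  expect_lt(abs(stats::median(lens) / 1.8 - 1), 0.10)
})

test_that("planted effects are recovered with the planted signs", {
  sf <- study_features()
  rep <- planted_effect_report(sf$truth, sf$ft)
  expect_equal(rep$sign[rep$effect == "articulation_autistic"], -1)
  expect_equal(rep$sign[rep$effect == "pitch_sd_autistic"], -1)
  expect_equal(rep$sign[rep$effect == "intensity_sd_autistic"], -1)
  expect_equal(rep$sign[rep$effect == "gap_mixed"], 1)
  expect_equal(rep$sign[rep$effect == "silence_mixed"], 1)
  expect_equal(rep$sign[rep$effect == "coupling_mixed"], 1)
  expect_error(planted_effect_report(sf$truth, transform(
    sf$ft, participant_id = paste0("X", participant_id))), "join error")
})

test_that("the null world centres every group contrast on zero", {
  # Monte-Carlo over 200 small corpora; per-corpus standardised differences
  # should average to zero within 3 standard errors
  n_rep <- 200
  ds <- matrix(NA_real_, n_rep, 6)
  for (i in seq_len(n_rep)) {
    cfg <- null_world(generator_config(n_mixed_dyads = 2,
                                       n_nonautistic_dyads = 2,
                                       duration_s = 300, tasks = "hobbies",
                                       seed = 1000 + i))
    corp <- generate_corpus(cfg)
    ft <- compute_feature_table(corp$records)
    rep <- planted_effect_report(corp$truth, ft)
    ds[i, ] <- rep$d
    if (i == 1) colnames(ds) <- rep$effect
  }
  for (j in seq_len(ncol(ds))) {
    v <- ds[, j][is.finite(ds[, j])]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v)), 3 * se + 1e-12)
  }
})
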