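# Affect attachment, high-affect thresholds, streak compression,
# compounding, timing features.

test_that("attach_affect windows both events per player and flags emptiness", {
  tr <- hand_trials(c("A", "B", "A"), c(4, 6, 2))
  ef_a <- flat_emotions(t_end = 80, negative = 0.5, positive = 1)
  ef_b <- flat_emotions(t_end = 80, negative = 0.2, positive = 2)
  # player B's video drops out around the third selection (t = 51)
  ef_b <- ef_b[ef_b$timestamp < 49, ]
  aff <- attach_affect(tr, list(C001P1 = ef_a, C001P2 = ef_b))
  expect_equal(nrow(aff), 6) # 3 trials x 2 players
  a1 <- aff[aff$player_id == "C001P1", ]
  expect_equal(a1$neg_T2, rep(0.5, 3)) # constant stream -> exact
  b3 <- aff[aff$player_id == "C001P2" & aff$round == 3, ]
  expect_identical(b3$neg_T2, NA_real_) # missing marker, not zero
  expect_equal(b3$frames_T2, 0L)

  # clock mismatch: every window empty is a hard error
  late <- flat_emotions(t_end = 10, negative = 0.5)
  late$timestamp <- late$timestamp + 10000
  expect_error(attach_affect(tr, list(C001P1 = late, C001P2 = late)),
               "clocks")
  expect_error(attach_affect(tr, list(C001P1 = ef_a)), "C001P2")
})

test_that("T1 and T2 windows may overlap and are computed independently", {
  tr <- hand_trials("A", 4) # immediate: selection 1 s after announcement
  ts <- seq(8, 13, by = 0.1)
  ef <- structure(data.frame(timestamp = ts, happiness = 0, anger = 0,
                             disgust = 0, positive = 0, negative = ts),
                  class = c("emotion_frames", "data.frame"))
  aff <- attach_affect(tr, list(C001P1 = ef, C001P2 = ef))
  w <- aff[aff$role == "winner", ]
  # centres 10 (T1) and 11 (T2); linear signal -> window means = centres
  expect_equal(w$neg_T1, 10, tolerance = 1e-9)
  expect_equal(w$neg_T2, 11, tolerance = 1e-9)
})

test_that("classify_high_affect uses a strict mean + 1 SD rule", {
  v <- c(0, 0, 0, 0, 1)
  r <- classify_high_affect(v)
  expect_equal(r$threshold, 0.2 + sd(v), tolerance = 1e-12) # ~0.647
  expect_equal(which(r$flags), 5L)
  # constant series: SD = 0, nothing flagged
  expect_true(!any(classify_high_affect(rep(2, 10))$flags))
  # missing values excluded from estimation, NA flags propagate
  r2 <- classify_high_affect(c(v, NA))
  expect_equal(r2$threshold, r$threshold)
  expect_identical(r2$flags[6], NA)
  expect_error(classify_high_affect(c(NA_real_, NA_real_)), "missing")
  # order invariance
  perm <- sample(5)
  expect_equal(classify_high_affect(v[perm])$flags, r$flags[perm])
  # per-group scope yields one threshold per group
  g <- rep(c("s1", "s2"), each = 5)
  vals <- c(v, 10 * v)
  rg <- classify_high_affect(vals, scope = "by_group", groups = g)
  expect_equal(unname(rg$threshold["s2"]), 10 * r$threshold)
  expect_equal(which(rg$flags), c(5L, 10L))
})

test_that("compress_win_streaks collapses maximal runs and conserves rounds", {
  tr <- hand_trials(c("A", "A"), c(4, 6))
  cp <- compress_win_streaks(tr)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$blast_mean, 5)
  expect_equal(cp$n_rounds_in_streak, 2L)

  tr2 <- hand_trials(c("A", "A", "B", "A"), c(2, 4, 7, 5),
                     neg_winner = c(0.2, 0.4, 0.6, 0.8),
                     neg_loser = c(0.1, 0.1, 0.3, 0.5))
  cp2 <- compress_win_streaks(tr2)
  expect_equal(cp2$blast_mean, c(3, 7, 5))
  expect_equal(cp2$winner_id, c("C001P1", "C001P2", "C001P1"))
  expect_equal(cp2$neg_t2_winner_mean, c(0.3, 0.6, 0.8))
  expect_equal(sum(cp2$n_rounds_in_streak), 4L)
  # grand mean conserved under streak weighting
  expect_equal(sum(cp2$blast_mean * cp2$n_rounds_in_streak) /
                 sum(cp2$n_rounds_in_streak), mean(tr2$blast))

  # no-streak identity: alternating winners pass through unchanged
  alt <- hand_trials(rep(c("A", "B"), 15), rep(c(3, 5), 15))
  cpa <- compress_win_streaks(alt)
  expect_equal(nrow(cpa), 30)
  expect_equal(cpa$blast_mean, alt$blast)
  # winners always alternate in the output
  st <- small_study(n_couples = 5, n_rounds = 25, seed = 13)
  cps <- compress_win_streaks(st$trials)
  for (cc in split(cps, cps$couple_id))
    expect_true(all(cc$winner_id[-1] != cc$winner_id[-nrow(cc)]))
})

test_that("compound_category partitions trials exhaustively", {
  expect_equal(as.character(compound_category(TRUE, FALSE)), "winner_only")
  expect_equal(as.character(compound_category(TRUE, TRUE)), "both")
  w <- c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  l <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  cats <- compound_category(w, l)
  expect_equal(unname(table(cats)), array(c(3L, 2L, 2L, 1L)))
  expect_equal(sum(prop.table(table(cats))), 1)
  expect_message(compound_category(c(TRUE, NA), c(FALSE, TRUE)), "excluded")
})

test_that("timing features derive elective extra and latency", {
  tr <- data.frame(t_winner_announced = c(100, 50, 20),
                   t_blast_selected = c(114.2, 51.8, 30),
                   forced_break_s = c(10, 0, 10))
  ft <- timing_features(tr)
  expect_equal(ft$elective_extra_s, c(4.2, 1.8, 0))
  expect_equal(ft$selection_latency_s, c(14.2, 1.8, 10))
  tr$t_blast_selected[1] <- 105 # selected before the break ended
  expect_error(timing_features(tr), "integrity")
})

test_that("noiseless synthetic affect round-trips through the classifier", {
  cfg <- sim_config(n_couples = 4, n_rounds = 12, condition = "immediate",
                    elective_extra_rate = 0, emit_au = FALSE)
  st <- simulate_study(cfg, seed = 19)
  tr <- st$trials
  vals <- c(tr$neg_t2_winner, tr$neg_t2_loser)
  r <- classify_high_affect(vals)
  # flags recompute exactly from the known generating intensities
  expect_equal(r$flags, vals > mean(vals) + sd(vals))
})
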