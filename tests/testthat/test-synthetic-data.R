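# Generative simulator: rigging, decay, session dynamics, AU emission.

test_that("rig_winner is deterministic outside the window, fair inside", {
  expect_equal(rig_winner(500, 700, 100), "a")
  expect_equal(rig_winner(700, 500, 100), "b")
  expect_equal(rig_winner(500, 601, 0), "a") # zero window = pure speed
  set.seed(1)
  draws <- rig_winner(rep(500, 10000), rep(500, 10000), 100)
  expect_lt(abs(mean(draws == "a") - 0.5), 0.02)
  expect_error(rig_winner(-1, 500, 100), "positive")
  expect_error(rig_winner(500, 500, -5), "rig_window")
})

test_that("decay_negativity is exponential with the calibrated default", {
  expect_equal(decay_negativity(0.48, 0, 0.5), 0.48) # identity at zero delay
  expect_equal(decay_negativity(0, 10, 0.1164), 0)   # zero fixed point
  expect_equal(decay_negativity(0.48, 10, 0.1164), 0.15, tolerance = 2e-3)
  # default rate solves 0.48 -> 0.15 over 10 s exactly
  expect_equal(decay_negativity(0.48, 10), 0.15, tolerance = 1e-12)
  # monotone non-increasing in elapsed
  tt <- seq(0, 30, by = 0.5)
  expect_true(all(diff(decay_negativity(1.7, tt, 0.2)) < 0))
  expect_error(decay_negativity(0.3, -1, 0.1), "elapsed")
  expect_error(decay_negativity(7, 1, 0.1), "\\[0, 5\\]")
})

test_that("simulate_study honours degenerate configurations", {
  # zero noise, zero carry-over: negativity pinned at the baseline
  cfg <- sim_config(n_couples = 2, n_rounds = 8, condition = "immediate",
                    actor_effect = 0, partner_effect = 0,
                    neg_noise_sd = 0, couple_re_sd = 0, pos_noise_sd = 0,
                    elective_extra_rate = 0, emit_au = FALSE)
  st <- simulate_study(cfg, seed = 3)
  expect_true(all(abs(st$trials$neg_t1_winner - cfg$neg_baseline) < 1e-12))
  expect_true(all(abs(st$trials$neg_t2_loser - cfg$neg_baseline) < 1e-12))

  # pure imitation: every blast equals the partner's previous blast
  cfg2 <- sim_config(n_couples = 3, n_rounds = 12, condition = "immediate",
                     match_weight = 1, blast_baseline = 0,
                     own_neg_weight = 0, partner_neg_weight = 0,
                     asymmetry_sd = 0, blast_noise_sd = 0, emit_au = FALSE)
  st2 <- simulate_study(cfg2, seed = 4)
  for (cc in split(st2$trials, st2$trials$couple_id)) {
    last <- c(NA, NA)
    for (i in seq_len(nrow(cc))) {
      w <- ifelse(grepl("P1$", cc$winner_id[i]), 1, 2)
      if (i > 1 && !is.na(last[3 - w]))
        expect_equal(cc$blast[i], last[3 - w])
      last[w] <- cc$blast[i]
    }
  }
})

test_that("simulated studies satisfy the structural invariants", {
  st <- small_study(n_couples = 8, n_rounds = 20, seed = 9)
  tr <- st$trials
  # one winner and one loser per trial, from the same couple
  expect_true(all(tr$winner_id != tr$loser_id))
  expect_true(all(substr(tr$winner_id, 1, 4) == tr$couple_id))
  # blasts on the grid, intensities in range
  expect_true(all(tr$blast %in% 1:8))
  neg_cols <- c("neg_t1_winner", "neg_t2_winner", "neg_t1_loser", "neg_t2_loser")
  expect_true(all(unlist(tr[neg_cols]) >= 0 & unlist(tr[neg_cols]) <= 5))
  # strictly increasing timestamps within a session
  for (cc in split(tr, tr$couple_id)) {
    expect_true(all(diff(cc$t_go) > 0))
    expect_true(all(cc$t_blast_selected >
                      cc$t_winner_announced + cc$forced_break_s - 1e-9))
  }
  # truth travels with the data
  expect_s3_class(st$truth, "sim_config")
  expect_equal(st$truth$actor_effect, 0.3)
})

test_that("seed determinism: identical configs and seeds reproduce studies", {
  a <- small_study(n_couples = 3, n_rounds = 10, seed = 77)
  b <- small_study(n_couples = 3, n_rounds = 10, seed = 77)
  expect_identical(a$trials, b$trials)
  c1 <- simulate_study(sim_config(n_couples = 2, n_rounds = 6, fps = 10,
                                  condition = "break5"), seed = 5)
  c2 <- simulate_study(sim_config(n_couples = 2, n_rounds = 6, fps = 10,
                                  condition = "break5"), seed = 5)
  expect_identical(c1$au_streams, c2$au_streams)
})

test_that("longer breaks decrease expected negativity at selection", {
  negs <- sapply(c("immediate", "break5", "break10", "break15"), function(cond) {
    st <- simulate_study(sim_config(n_couples = 12, n_rounds = 15,
                                    condition = cond, emit_au = FALSE,
                                    elective_extra_rate = 0), seed = 21)
    mean(st$trials$neg_t2_winner)
  })
  expect_true(all(diff(negs) < 0))
})

test_that("AU emission carries the trajectory and round-trips the scorer", {
  cfg <- sim_config(n_couples = 1, au_noise_sd = 0)
  # noiseless emission: signal AUs equal the intensities on epoch frames
  traj <- data.frame(t_center = 5, half_width = 1, positive = 2, negative = 0)
  fr <- emit_au_frames(traj, cfg, session_end = 10)
  ep <- fr$timestamp >= 4 & fr$timestamp <= 6
  expect_equal(sum(ep), 61L) # 2 s epoch at 30 fps, inclusive endpoints
  expect_true(all(fr$AU06_r[ep] == 2 & fr$AU12_r[ep] == 2))
  expect_true(all(fr$AU04_r[ep] == 0 & fr$AU09_r[ep] == 0 & fr$AU23_r[ep] == 0))
  expect_true(all(fr$AU06_r[!ep] == 0))
  expect_error(emit_au_frames(traj[0, ], cfg), "empty")

  # noisy round-trip: score_emotions + window_intensity recover the intensity
  cfgn <- sim_config(n_couples = 1, au_noise_sd = 0.1)
  set.seed(31)
  rec <- replicate(100, {
    traj <- data.frame(t_center = 3, half_width = 1, positive = 0.4,
                       negative = 1.5)
    fr <- emit_au_frames(traj, cfgn, session_end = 6)
    window_intensity(score_emotions(fr), 3, 1)$negative
  })
  expect_lt(abs(mean(rec) - 1.5), 0.05)
})

test_that("trial logs and configs round-trip through files", {
  st <- small_study(n_couples = 2, n_rounds = 6, seed = 55)
  p <- tempfile(fileext = ".csv")
  write_trial_log(st$trials, p)
  back <- read_trial_log(p)
  expect_equal(nrow(back), nrow(st$trials))
  expect_false("neg_t1_winner" %in% names(back)) # truth columns dropped
  expect_equal(back$blast, st$trials$blast)

  cfgp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_couples = 4, n_rounds = 10, decay_rate = 0.2,
                            condition = "break10"),
                       cfgp, auto_unbox = TRUE)
  cfg <- read_sim_config(cfgp)
  expect_equal(cfg$n_couples, 4L)
  expect_equal(cfg$decay_rate, 0.2)
  jsonlite::write_json(list(not_a_key = 1), cfgp, auto_unbox = TRUE)
  expect_error(read_sim_config(cfgp), "unknown config keys")
  expect_error(sim_config(condition = "break20"), "invalid condition")
  expect_error(simulate_study(sim_config(n_rounds = 2)), NA)
})
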