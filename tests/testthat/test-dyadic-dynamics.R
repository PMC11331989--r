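# Escalation records, summaries, asymmetry, matching statistics.

compressed_from <- function(blasts, couple = "C001") {
  data.frame(couple_id = couple, interval_index = seq_along(blasts),
             winner_id = paste0(couple, c("P1", "P2"))[
               (seq_along(blasts) + 1) %% 2 + 1],
             loser_id = paste0(couple, c("P2", "P1"))[
               (seq_along(blasts) + 1) %% 2 + 1],
             blast_mean = blasts,
             neg_t1_winner_mean = NA_real_, neg_t2_winner_mean = NA_real_,
             neg_t1_loser_mean = NA_real_, neg_t2_loser_mean = NA_real_,
             n_rounds_in_streak = 1L)
}

test_that("escalation coefficients difference the alternating series", {
  rec <- escalation_records(compressed_from(c(1, 8)))
  expect_equal(rec$coefficient, 7)
  expect_equal(rec$class, "escalate")
  rec2 <- escalation_records(compressed_from(c(5, 5)))
  expect_equal(rec2$class, "match")
  rec3 <- escalation_records(compressed_from(rep(c(3, 4), 5)))
  expect_equal(rec3$coefficient, rep(c(1, -1), length.out = 9))
  # first interval skipped: k intervals -> k-1 records
  expect_equal(nrow(rec3), 9)
  expect_error(escalation_records(compressed_from(5)), "shorter than 2")
  # match tolerance flag treats sub-half-blast differences as matches
  rt <- escalation_records(compressed_from(c(4, 4.4, 5.5)), match_tol = 0.5)
  expect_equal(rt$class, c("match", "escalate"))
})

test_that("escalation summaries partition to one and count correctly", {
  rec <- escalation_records(compressed_from(c(5, 5, 5)))
  s <- escalation_summary(rec)
  expect_equal(s$prop_match, 1)
  expect_equal(s$mean_coefficient, 0)
  rec2 <- escalation_records(compressed_from(c(4, 5, 4)))
  s2 <- escalation_summary(rec2)
  expect_equal(c(s2$prop_match, s2$prop_escalate, s2$prop_de_escalate),
               c(0, 0.5, 0.5))
  expect_equal(s2$mean_coefficient, 0)

  # counting oracle on a constructed 20-record set
  blasts <- c(3, 3, 5, 5, 2, 2, 2, 6, 6, 1, 4, 4, 4, 7, 7, 3, 3, 8, 8, 8, 8)
  rec3 <- escalation_records(compressed_from(blasts))
  s3 <- escalation_summary(rec3)
  d <- diff(blasts)
  expect_equal(s3$n, 20)
  expect_equal(s3$prop_match, sum(d == 0) / 20)
  expect_equal(s3$prop_escalate, sum(d > 0) / 20)
  expect_equal(s3$prop_de_escalate, sum(d < 0) / 20)
  expect_equal(s3$prop_match + s3$prop_escalate + s3$prop_de_escalate, 1,
               tolerance = 1e-12)
  # per-player grouping
  sp <- escalation_summary(rec3, by = "player_id")
  expect_equal(sum(sp$n), 20)
})

test_that("couple_asymmetry orders partners and excludes singletons", {
  rec <- escalation_records(compressed_from(c(3, 4, 3, 4, 3)))
  # P2 always +1, P1 always -1
  asym <- couple_asymmetry(rec)
  expect_equal(asym$higher, 1)
  expect_equal(asym$lower, -1)
  # tie: both partners mean 0
  rec0 <- escalation_records(compressed_from(c(4, 4, 4)))
  a0 <- couple_asymmetry(rec0)
  expect_equal(c(a0$higher, a0$lower), c(0, 0))
  # partner without records excluded with a message
  one <- escalation_records(compressed_from(c(2, 6)))
  expect_message(ax <- couple_asymmetry(one), "excluded")
  expect_equal(attr(ax, "excluded"), 1L)

  # simulated asymmetry: higher and lower series negatively correlated
  st <- small_study(n_couples = 30, n_rounds = 25, seed = 23,
                    asymmetry_sd = 1)
  recs <- escalation_records(compress_win_streaks(st$trials))
  ac <- couple_asymmetry(recs, quiet = TRUE)
  expect_lt(cor(ac$higher, ac$lower), 0)
})

test_that("matching statistics: grand-mean, lagged, and time trend", {
  # partners' means equal pairwise with cross-couple spread -> r = 1
  comp <- rbind(compressed_from(c(2, 2, 2, 2), "C001"),
                compressed_from(c(5, 5, 5, 5), "C002"),
                compressed_from(c(7, 7, 7, 7), "C003"))
  ms <- matching_statistics(comp)
  expect_equal(ms$grand_mean$r, 1)
  expect_equal(nrow(ms$grand_mean$points), 6) # both partners contribute
  # the same construction is the imitation limit: every blast repeats the
  # partner's previous one, so the pooled lagged correlation is 1
  expect_equal(ms$lagged$r, 1)

  # pure imitation simulator converges to lock-step blasts; downstream the
  # correlation over its constant pooled pairs is flagged degenerate
  cfg <- sim_config(n_couples = 4, n_rounds = 15, condition = "immediate",
                    match_weight = 1, blast_baseline = 0, own_neg_weight = 0,
                    partner_neg_weight = 0, asymmetry_sd = 0,
                    blast_noise_sd = 0, emit_au = FALSE)
  st <- simulate_study(cfg, seed = 29)
  msi <- matching_statistics(compress_win_streaks(st$trials))
  expect_true(is.na(msi$lagged$r))
  expect_true(msi$degenerate$lagged)

  # brute-force lagged pair construction on a small series
  blasts <- c(3, 5, 4, 6, 2)
  m1 <- matching_statistics(rbind(compressed_from(blasts, "C001"),
                                  compressed_from(rev(blasts), "C002"),
                                  compressed_from(blasts + 1, "C003")))
  hand <- rbind(cbind(blasts[-5], blasts[-1]),
                cbind(rev(blasts)[-5], rev(blasts)[-1]),
                cbind((blasts + 1)[-5], (blasts + 1)[-1]))
  expect_equal(m1$lagged$r, cor(hand[, 1], hand[, 2]))

  # zero-trend calibration: slope within 2 SE in most seeded runs
  hits <- 0
  for (s in 1:30) {
    sim <- small_study(n_couples = 8, n_rounds = 20, seed = 400 + s)
    tr <- matching_statistics(compress_win_streaks(sim$trials))$trend
    if (abs(tr$slope) < 2 * tr$se) hits <- hits + 1
  }
  expect_gte(hits, 27)
  expect_error(matching_statistics(compressed_from(c(1, 2))), "3 couples")
})
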