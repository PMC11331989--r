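# Shared fixtures built in code.

# Small default-world study, no AU emission (fast).
small_study <- function(n_couples = 6, n_rounds = 15, seed = 101, ...) {
  simulate_study(sim_config(n_couples = n_couples, n_rounds = n_rounds,
                            emit_au = FALSE, ...), seed = seed)
}

# Hand-built trial table: one couple, explicit winners/blasts/timestamps.
hand_trials <- function(winners, blasts,
                        condition = "immediate", forced = 0,
                        neg_winner = NULL, neg_loser = NULL) {
  n <- length(winners)
  t_ann <- seq(10, by = 20, length.out = n)
  df <- data.frame(
    couple_id = "C001", study = "test", condition = condition,
    round = seq_len(n),
    winner_id = ifelse(winners == "A", "C001P1", "C001P2"),
    loser_id = ifelse(winners == "A", "C001P2", "C001P1"),
    rt_winner_ms = 300, rt_loser_ms = 450, blast = blasts,
    t_go = t_ann - 0.5, t_winner_announced = t_ann,
    t_blast_selected = t_ann + forced + 1, forced_break_s = forced)
  if (!is.null(neg_winner)) {
    df$neg_t1_winner <- neg_winner; df$neg_t2_winner <- neg_winner
    df$neg_t1_loser <- neg_loser; df$neg_t2_loser <- neg_loser
    df$pos_winner <- 0.5; df$pos_loser <- 0.5
  }
  df
}

# Emotion frames with constant intensities on a regular grid.
flat_emotions <- function(t_end = 100, negative = 0.5, positive = 1,
                          fps = 30) {
  ts <- seq(0, t_end, by = 1 / fps)
  structure(data.frame(timestamp = ts, happiness = positive, anger = negative,
                       disgust = negative, positive = positive,
                       negative = negative),
            class = c("emotion_frames", "data.frame"))
}
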