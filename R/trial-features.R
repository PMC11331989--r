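# Join trial logs with windowed affect, classify high/low affect trials,
# compress win streaks into the alternating-winner series, and derive timing
# features (elective extra waiting, selection latency).

#' Attach windowed affect to trials
#'
#' For every trial and both players, computes the windowed emotion
#' intensities at the winner-announcement time (T1) and the blast-selection
#' time (T2), each over a closed +/- `half_width` second window
#' ([window_intensity()]). Trials whose window contains no frames carry an
#' explicit `NA` (never a silent zero) and are excluded downstream from
#' threshold estimation. If every window of every trial is empty the trial
#' and video clocks almost certainly disagree, and that is a hard error.
#'
#' @param trials Trial data frame (trial-log schema).
#' @param emotions Named list of `emotion_frames`, one per player id
#'   appearing in `trials`.
#' @param half_width Window half width in seconds.
#' @return Data frame of class `trial_affect`, one row per trial x player:
#'   `couple_id`, `round`, `player_id`, `role`, `neg_T1`, `neg_T2`, `pos_T2`,
#'   `frames_T1`, `frames_T2`.
#' @export
attach_affect <- function(trials, emotions, half_width = 1) {
  players <- unique(c(trials$winner_id, trials$loser_id))
  missing_players <- setdiff(players, names(emotions))
  if (length(missing_players))
    stop("no emotion frames for player(s): ",
         paste(missing_players, collapse = ", "), call. = FALSE)
  out <- vector("list", 2L * nrow(trials))
  k <- 0L
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    for (role in c("winner", "loser")) {
      pid <- if (role == "winner") tr$winner_id else tr$loser_id
      ef <- emotions[[pid]]
      w1 <- window_intensity(ef, tr$t_winner_announced, half_width)
      w2 <- window_intensity(ef, tr$t_blast_selected, half_width)
      k <- k + 1L
      out[[k]] <- data.frame(
        couple_id = tr$couple_id, round = tr$round, player_id = pid,
        role = role,
        neg_T1 = w1$negative, neg_T2 = w2$negative, pos_T2 = w2$positive,
        frames_T1 = w1$n_frames, frames_T2 = w2$n_frames)
    }
  }
  res <- do.call(rbind, out)
  if (all(res$frames_T1 == 0L & res$frames_T2 == 0L))
    stop("every affect window is empty: trial and video clocks do not match",
         call. = FALSE)
  structure(res, class = c("trial_affect", "data.frame"))
}

#' Classify high-affect observations against a mean + 1 SD threshold
#'
#' An observation is flagged high iff its value is strictly greater than the
#' mean plus one sample standard deviation of the values in its pooling
#' scope. Missing values are excluded from threshold estimation and receive
#' an `NA` flag; a zero-SD scope flags nothing.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param scope `"pooled"` (one threshold over all values, the default) or
#'   `"by_group"` (a threshold per level of `groups`).
#' @param groups Grouping vector, required for `"by_group"`.
#' @return List with `flags` (logical, `NA` where the value is missing) and
#'   `threshold` (named per group under `"by_group"`).
#' @export
classify_high_affect <- function(values, scope = c("pooled", "by_group"),
                                 groups = NULL) {
  scope <- match.arg(scope)
  if (all(is.na(values))) stop("all values are missing", call. = FALSE)
  one <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2L)
      stop("need >= 2 non-missing values to estimate a threshold", call. = FALSE)
    thr <- mean(v[ok]) + stats::sd(v[ok])
    flags <- v > thr # strict; NA propagates
    if (stats::sd(v[ok]) == 0) flags[ok] <- FALSE
    list(flags = flags, threshold = thr)
  }
  if (scope == "pooled") return(one(values))
  if (is.null(groups) || length(groups) != length(values))
    stop("by_group scope needs a groups vector matching values", call. = FALSE)
  flags <- rep(NA, length(values))
  thr <- c()
  for (g in unique(groups)) {
    sel <- groups == g
    r <- one(values[sel])
    flags[sel] <- r$flags
    thr[as.character(g)] <- r$threshold
  }
  list(flags = flags, threshold = thr)
}

#' Merge attached affect back into the trial table
#'
#' Spreads a `trial_affect` table (long, per player) into per-role columns of
#' the trial table (`neg_t1_winner`, `neg_t2_winner`, `neg_t1_loser`,
#' `neg_t2_loser`, `pos_winner`, `pos_loser`), the layout the compression and
#' modelling stages consume. Overwrites any same-named columns (e.g.
#' simulator truth).
#'
#' @param trials Trial data frame.
#' @param affect A `trial_affect` data frame from [attach_affect()].
#' @return The augmented trial data frame.
#' @export
merge_affect_into_trials <- function(trials, affect) {
  key <- function(c_id, r) paste(c_id, r, sep = "\r")
  for (role in c("winner", "loser")) {
    a <- affect[affect$role == role, ]
    idx <- match(key(trials$couple_id, trials$round), key(a$couple_id, a$round))
    trials[[paste0("neg_t1_", role)]] <- a$neg_T1[idx]
    trials[[paste0("neg_t2_", role)]] <- a$neg_T2[idx]
    trials[[paste0("pos_", role)]] <- a$pos_T2[idx]
  }
  trials
}

#' Compress win streaks into the alternating-winner series
#'
#' Maximal runs of consecutive same-winner rounds collapse into one interval
#' whose blast is the mean blast of the streak and whose winner/loser
#' negativity is the mean negativity expressed across the streak. Winners
#' alternate in the output and the total round count is conserved via
#' `n_rounds_in_streak`.
#'
#' @param trials Trial data frame ordered (or orderable) by round, carrying
#'   `blast` and optionally the per-role negativity columns of
#'   [merge_affect_into_trials()].
#' @return Data frame of class `compressed_rounds`: `couple_id`,
#'   `interval_index`, `winner_id`, `loser_id`, `blast_mean`,
#'   `neg_t1_winner_mean`, `neg_t2_winner_mean`, `neg_t1_loser_mean`,
#'   `neg_t2_loser_mean`, `n_rounds_in_streak`.
#' @export
compress_win_streaks <- function(trials) {
  trials <- trials[order(trials$couple_id, trials$round), , drop = FALSE]
  has_neg <- all(c("neg_t1_winner", "neg_t2_winner",
                   "neg_t1_loser", "neg_t2_loser") %in% names(trials))
  res <- lapply(split(trials, trials$couple_id), function(tt) {
    runs <- rle(tt$winner_id)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    mean_of <- function(col, i) {
      if (!has_neg) return(NA_real_)
      mean(tt[[col]][starts[i]:ends[i]])
    }
    data.frame(
      couple_id = tt$couple_id[1],
      interval_index = seq_along(runs$values),
      winner_id = runs$values,
      loser_id = vapply(seq_along(runs$values), function(i)
        tt$loser_id[starts[i]], character(1)),
      blast_mean = vapply(seq_along(runs$values), function(i)
        mean(tt$blast[starts[i]:ends[i]]), numeric(1)),
      neg_t1_winner_mean = vapply(seq_along(runs$values), function(i)
        mean_of("neg_t1_winner", i), numeric(1)),
      neg_t2_winner_mean = vapply(seq_along(runs$values), function(i)
        mean_of("neg_t2_winner", i), numeric(1)),
      neg_t1_loser_mean = vapply(seq_along(runs$values), function(i)
        mean_of("neg_t1_loser", i), numeric(1)),
      neg_t2_loser_mean = vapply(seq_along(runs$values), function(i)
        mean_of("neg_t2_loser", i), numeric(1)),
      n_rounds_in_streak = runs$lengths)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("compressed_rounds", "data.frame"))
}

#' Compound affect category of a trial
#'
#' Classifies each trial by whether neither, only the loser, only the winner,
#' or both members of the couple exhibited high negative affect. The
#' partition is exhaustive and exclusive; trials with a missing flag are
#' labelled `NA` and counted.
#'
#' @param winner_high,loser_high Logical high-negativity flags per trial.
#' @param quiet Suppress the excluded-trial message.
#' @return Factor with levels `neither`, `loser_only`, `winner_only`, `both`.
#' @export
compound_category <- function(winner_high, loser_high, quiet = FALSE) {
  if (length(winner_high) != length(loser_high))
    stop("flag vectors must have equal length", call. = FALSE)
  lab <- ifelse(is.na(winner_high) | is.na(loser_high), NA_character_,
         ifelse(winner_high & loser_high, "both",
         ifelse(winner_high, "winner_only",
         ifelse(loser_high, "loser_only", "neither"))))
  n_excl <- sum(is.na(lab))
  if (n_excl > 0 && !quiet)
    message("compound_category: ", n_excl, " trial(s) excluded (missing flag)")
  factor(lab, levels = c("neither", "loser_only", "winner_only", "both"))
}

#' Timing features of each trial
#'
#' `elective_extra_s` is the time the winner voluntarily waited beyond the
#' forced break (`t_blast_selected - t_winner_announced - forced_break_s`);
#' `selection_latency_s` is the full announcement-to-selection latency. A
#' negative elective extra indicates corrupt timestamps and is an error.
#'
#' @param trials Trial data frame.
#' @return `trials` with the two feature columns appended.
#' @export
timing_features <- function(trials) {
  extra <- trials$t_blast_selected - trials$t_winner_announced -
    trials$forced_break_s
  if (any(extra < -1e-9))
    stop("data integrity: blast selected before the forced break ended",
         call. = FALSE)
  trials$elective_extra_s <- pmax(0, extra)
  trials$selection_latency_s <- trials$t_blast_selected - trials$t_winner_announced
  trials
}
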