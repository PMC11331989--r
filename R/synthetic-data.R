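# Generative simulator of dyadic competitive reaction time sessions.
#
# Each couple plays n_rounds rounds: both players press on "GO!!", the faster
# player wins unless the reaction times fall within the rig window (then the
# winner is drawn at random, keeping win rates near 0.5), and the winner
# selects a sound-blast volume on the 1-8 grid after a condition-dependent
# forced break plus an elective extra wait. Facial negativity carries over
# from interval to interval of the alternating-winner series with actor and
# partner effects, decays exponentially across breaks, and is emitted as AU
# intensity frames consistent with the scoring rules, so the entire analysis
# pipeline can be exercised end to end with known ground truth.

.CONDITIONS <- c(immediate = 0, break5 = 5, break10 = 10, break15 = 15)

#' Calibrated negativity decay rate
#'
#' Solves \eqn{\exp(-\lambda\,t) = n_2 / n_1} for \eqn{\lambda}. The package
#' default is calibrated so that mean negativity falls from the
#' winner-revealed level to the blast-selection level over a 10 s forced
#' break (0.48 to 0.15), giving \eqn{\lambda \approx 0.1163} per second.
#'
#' @param neg_start,neg_end Intensities (0-5], start and end of the break.
#' @param elapsed Break length in seconds (> 0).
#' @return Decay rate per second.
#' @export
calibrate_decay_rate <- function(neg_start = 0.48, neg_end = 0.15, elapsed = 10) {
  if (neg_start <= 0 || neg_end <= 0 || neg_end > neg_start)
    stop("need 0 < neg_end <= neg_start", call. = FALSE)
  if (elapsed <= 0) stop("elapsed must be > 0", call. = FALSE)
  log(neg_start / neg_end) / elapsed
}

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_study()]. Defaults state
#' the conditions the analysis assumes: 30 rounds per session; condition
#' weights proportional to the primary study's allocation (immediate 23,
#' 5 s 32, 10 s 23, 15 s 26 couples); a 100 ms rig window; negativity
#' carry-over with actor effect 0.3 and partner effect 0.15 on the
#' alternating-winner interval series; exponential decay of negativity across
#' forced and elective breaks calibrated from the winner-revealed (0.48) to
#' blast-selection (0.15) means over 10 s; predominantly positive affect
#' (positive baseline 0.83); and a blast-choice rule combining retaliation
#' (matching the partner's previous blast), both players' negativity, and a
#' per-player escalation asymmetry.
#'
#' @param n_couples Number of couples (>= 1).
#' @param n_rounds Rounds per session (>= 2).
#' @param condition Either a single condition label (`"immediate"`,
#'   `"break5"`, `"break10"`, `"break15"`), a vector of labels of length
#'   `n_couples`, or a named numeric vector of sampling weights over the four
#'   labels.
#' @param rt_location,rt_scale Log-scale reaction-time parameters (ms):
#'   reaction times are lognormal with these meanlog/sdlog.
#' @param rig_window Rigging window in ms (>= 0).
#' @param actor_effect,partner_effect Unitless negativity carry-over
#'   coefficients on the previous interval's own / partner negativity.
#' @param neg_baseline Negativity intercept, intensity units in [0,5].
#' @param neg_noise_sd Interval-level negativity innovation SD.
#' @param couple_re_sd SD of the couple-level random intercept in negativity.
#' @param pos_baseline,pos_noise_sd Positive-affect baseline and round-level
#'   noise SD.
#' @param decay_rate Negativity decay per second across breaks (>= 0).
#' @param blast_baseline Intercept of the blast-choice rule (blast units).
#' @param match_weight Blast units per unit of the partner's previous blast.
#' @param own_neg_weight,partner_neg_weight Blast units per intensity unit of
#'   own / partner negativity at selection time.
#' @param asymmetry_sd Between-player SD of the escalation tendency offset.
#' @param blast_noise_sd Round-level blast-choice noise SD.
#' @param elective_extra_rate Mean of the exponential elective extra wait, in
#'   seconds (0 disables elective waiting).
#' @param fps Frames per second of AU emission (>= 1).
#' @param au_noise_sd Emission noise SD on the AU channels.
#' @param emit_au Emit per-player AU frame streams (can be expensive for
#'   large simulations; the trial table always carries the true intensities).
#' @param seed Optional RNG seed stored with the config.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_couples = 20L,
                       n_rounds = 30L,
                       condition = c(immediate = 23, break5 = 32,
                                     break10 = 23, break15 = 26),
                       rt_location = log(300), rt_scale = 0.25,
                       rig_window = 100,
                       actor_effect = 0.3, partner_effect = 0.15,
                       neg_baseline = 0.26, neg_noise_sd = 0.2,
                       couple_re_sd = 0.05,
                       pos_baseline = 0.83, pos_noise_sd = 0.7,
                       decay_rate = calibrate_decay_rate(),
                       blast_baseline = 1.4,
                       match_weight = 0.45,
                       own_neg_weight = 1.26, partner_neg_weight = 1.0,
                       asymmetry_sd = 0.75,
                       blast_noise_sd = 1.8,
                       elective_extra_rate = 2,
                       fps = 30L,
                       au_noise_sd = 0.1,
                       emit_au = TRUE,
                       seed = NULL) {
  stopifnot(n_couples >= 1, n_rounds >= 2, rig_window >= 0, decay_rate >= 0,
            fps >= 1, rt_scale >= 0, neg_noise_sd >= 0, couple_re_sd >= 0,
            pos_noise_sd >= 0, asymmetry_sd >= 0, blast_noise_sd >= 0,
            elective_extra_rate >= 0, au_noise_sd >= 0)
  if (neg_baseline < 0 || neg_baseline > 5 || pos_baseline < 0 || pos_baseline > 5)
    stop("affect baselines must lie in [0, 5]", call. = FALSE)
  cond <- .resolve_conditions(condition, n_couples)
  structure(list(
    n_couples = as.integer(n_couples), n_rounds = as.integer(n_rounds),
    condition = condition, condition_resolved = cond,
    rt_location = rt_location, rt_scale = rt_scale, rig_window = rig_window,
    actor_effect = actor_effect, partner_effect = partner_effect,
    neg_baseline = neg_baseline, neg_noise_sd = neg_noise_sd,
    couple_re_sd = couple_re_sd,
    pos_baseline = pos_baseline, pos_noise_sd = pos_noise_sd,
    decay_rate = decay_rate,
    blast_baseline = blast_baseline, match_weight = match_weight,
    own_neg_weight = own_neg_weight, partner_neg_weight = partner_neg_weight,
    asymmetry_sd = asymmetry_sd, blast_noise_sd = blast_noise_sd,
    elective_extra_rate = elective_extra_rate,
    fps = as.integer(fps), au_noise_sd = au_noise_sd,
    emit_au = isTRUE(emit_au), seed = seed), class = "sim_config")
}

# Resolve the condition argument to one of three forms: "sample" with
# weights, or a fixed per-couple label vector.
.resolve_conditions <- function(condition, n_couples) {
  labels <- names(.CONDITIONS)
  if (is.numeric(condition)) {
    if (is.null(names(condition)) || !all(names(condition) %in% labels) ||
        any(condition < 0) || sum(condition) <= 0)
      stop("condition weights must be a named non-negative vector over ",
           paste(labels, collapse = ", "), call. = FALSE)
    return(list(mode = "sample", weights = condition))
  }
  condition <- as.character(condition)
  if (!all(condition %in% labels))
    stop("invalid condition label(s): ",
         paste(setdiff(condition, labels), collapse = ", "), call. = FALSE)
  if (length(condition) == 1L) condition <- rep(condition, n_couples)
  if (length(condition) != n_couples)
    stop("condition labels must have length 1 or n_couples", call. = FALSE)
  list(mode = "fixed", labels = condition)
}

#' Read a simulation config from a JSON file
#'
#' Keys mirror the arguments of [sim_config()]; omitted keys take defaults.
#'
#' @param path Path to a JSON file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(sim_config)), "...")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(sim_config, cfg)
}

#' Decide the winner of a round under partial rigging
#'
#' When the two reaction times differ by more than `rig_window` ms the faster
#' player wins deterministically; within the window the winner is drawn
#' uniformly at random, keeping per-player win rates near 0.5 without
#' arousing suspicion. Vectorized over rounds.
#'
#' @param rt_a,rt_b Reaction times in ms (> 0).
#' @param rig_window Window in ms (>= 0); 0 degenerates to pure speed.
#' @return Character vector of `"a"` / `"b"`.
#' @export
rig_winner <- function(rt_a, rt_b, rig_window = 100) {
  if (any(rt_a <= 0) || any(rt_b <= 0))
    stop("reaction times must be positive", call. = FALSE)
  if (rig_window < 0) stop("rig_window must be >= 0", call. = FALSE)
  n <- max(length(rt_a), length(rt_b))
  rt_a <- rep_len(rt_a, n); rt_b <- rep_len(rt_b, n)
  close_call <- abs(rt_a - rt_b) <= rig_window
  out <- ifelse(rt_a < rt_b, "a", "b")
  if (any(close_call))
    out[close_call] <- ifelse(stats::runif(sum(close_call)) < 0.5, "a", "b")
  out
}

#' Exponential decay of negativity across a break
#'
#' Returns \eqn{n \cdot \exp(-\lambda\, t)}: monotone non-increasing in the
#' elapsed time, the identity at `elapsed = 0`, with 0 a fixed point.
#'
#' @param neg Negativity intensity in [0, 5]; vectorized.
#' @param elapsed Elapsed break time in seconds (>= 0); vectorized.
#' @param decay_rate Decay rate per second (>= 0).
#' @return Decayed intensity.
#' @export
decay_negativity <- function(neg, elapsed, decay_rate = calibrate_decay_rate()) {
  if (any(neg < 0 | neg > 5)) stop("negativity must lie in [0, 5]", call. = FALSE)
  if (any(elapsed < 0)) stop("elapsed must be >= 0", call. = FALSE)
  if (decay_rate < 0) stop("decay_rate must be >= 0", call. = FALSE)
  neg * exp(-decay_rate * elapsed)
}

.clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Simulate a full study of dyadic sessions
#'
#' Runs the generative loop for every couple: reaction times are lognormal,
#' winners follow [rig_winner()], negativity evolves on the
#' alternating-winner interval series as
#' \eqn{N_i = \beta_0 + u_c + a\,N_{i-1}^{own} + p\,N_{i-1}^{partner} + \epsilon}
#' (clipped to [0,5]), decays across the forced break plus elective extra
#' wait, and the winner's blast is
#' `clip(round(gamma0 + match * partner_prev_blast + w1 * own_neg + w2 *
#' partner_neg + asymmetry + noise), 1, 8)`. A player with no previous blast
#' from the partner is matched against the grid midpoint 4.5. Identical seeds
#' reproduce identical studies.
#'
#' @param config A `sim_config`.
#' @param seed Overrides `config$seed` when given.
#' @return An object of class `simulated_study`: list with `trials` (trial
#'   log plus the true affect intensities per round), `au_streams` (named
#'   list of `au_frames` per player, when `emit_au`), and `truth` (the
#'   generating config).
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  if (config$n_rounds < 2L)
    stop("n_rounds must be >= 2 (no lagged structure possible)", call. = FALSE)

  cond_of <- function(i) {
    rc <- config$condition_resolved
    if (rc$mode == "fixed") rc$labels[i]
    else sample(names(rc$weights), 1L, prob = rc$weights)
  }

  trial_list <- vector("list", config$n_couples)
  au_streams <- list()
  for (ci in seq_len(config$n_couples)) {
    couple_id <- sprintf("C%03d", ci)
    players <- paste0(couple_id, c("P1", "P2"))
    condition <- cond_of(ci)
    forced <- unname(.CONDITIONS[condition])
    asym <- stats::rnorm(2, 0, config$asymmetry_sd)
    u_c <- stats::rnorm(1, 0, config$couple_re_sd)
    ap_sum <- config$actor_effect + config$partner_effect
    # start each player's interval negativity at the stationary mean of the
    # carry-over recursion (= baseline when both effects are zero)
    init <- if (abs(1 - ap_sum) < 1e-8) config$neg_baseline
            else (config$neg_baseline + u_c) / (1 - ap_sum)
    neg_now <- .clip(init + stats::rnorm(2, 0, config$neg_noise_sd), 0, 5)
    last_blast <- c(NA_real_, NA_real_) # last blast chosen by each player
    prev_winner_idx <- 0L
    t_clock <- 0
    nr <- config$n_rounds
    v <- list(w = integer(nr), rt1 = numeric(nr), rt2 = numeric(nr),
              blast = numeric(nr), t_go = numeric(nr), t_ann = numeric(nr),
              t_sel = numeric(nr),
              neg_t1_1 = numeric(nr), neg_t1_2 = numeric(nr),
              neg_t2_1 = numeric(nr), neg_t2_2 = numeric(nr),
              pos_1 = numeric(nr), pos_2 = numeric(nr))
    for (r in seq_len(nr)) {
      t_go <- t_clock + 1 + stats::runif(1, 0, 8)
      rt <- stats::rlnorm(2, config$rt_location, config$rt_scale)
      win_lab <- rig_winner(rt[1], rt[2], config$rig_window)
      w <- if (win_lab == "a") 1L else 2L
      l <- 3L - w
      if (w != prev_winner_idx) {
        # new interval of the alternating-winner series: advance carry-over
        eps <- stats::rnorm(2, 0, config$neg_noise_sd)
        neg_new <- config$neg_baseline + u_c +
          config$actor_effect * neg_now +
          config$partner_effect * rev(neg_now) + eps
        neg_now <- .clip(neg_new, 0, 5)
        prev_winner_idx <- w
      }
      t_ann <- t_go + max(rt) / 1000
      extra <- if (config$elective_extra_rate > 0)
        stats::rexp(1, 1 / config$elective_extra_rate) else 0
      t_sel <- t_ann + forced + extra
      neg_t1 <- neg_now
      neg_t2 <- decay_negativity(neg_now, forced + extra, config$decay_rate)
      pos <- .clip(config$pos_baseline + stats::rnorm(2, 0, config$pos_noise_sd), 0, 5)
      partner_prev <- if (is.na(last_blast[l])) 4.5 else last_blast[l]
      blast <- .clip(round(
        config$blast_baseline + config$match_weight * partner_prev +
          config$own_neg_weight * neg_t2[w] +
          config$partner_neg_weight * neg_t2[l] +
          asym[w] + stats::rnorm(1, 0, config$blast_noise_sd)), 1, 8)
      last_blast[w] <- blast
      v$w[r] <- w; v$rt1[r] <- rt[1]; v$rt2[r] <- rt[2]
      v$blast[r] <- blast
      v$t_go[r] <- t_go; v$t_ann[r] <- t_ann; v$t_sel[r] <- t_sel
      v$neg_t1_1[r] <- neg_t1[1]; v$neg_t1_2[r] <- neg_t1[2]
      v$neg_t2_1[r] <- neg_t2[1]; v$neg_t2_2[r] <- neg_t2[2]
      v$pos_1[r] <- pos[1]; v$pos_2[r] <- pos[2]
      t_clock <- t_sel + 2 # 2 s blast playback, next round begins
    }
    w <- v$w; l <- 3L - w
    pick <- function(a, b, idx) ifelse(idx == 1L, a, b)
    trial_list[[ci]] <- data.frame(
      couple_id = couple_id, study = "sim", condition = condition,
      round = seq_len(nr), winner_id = players[w], loser_id = players[l],
      rt_winner_ms = pick(v$rt1, v$rt2, w), rt_loser_ms = pick(v$rt1, v$rt2, l),
      blast = v$blast, t_go = v$t_go, t_winner_announced = v$t_ann,
      t_blast_selected = v$t_sel, forced_break_s = forced,
      neg_t1_winner = pick(v$neg_t1_1, v$neg_t1_2, w),
      neg_t2_winner = pick(v$neg_t2_1, v$neg_t2_2, w),
      neg_t1_loser = pick(v$neg_t1_1, v$neg_t1_2, l),
      neg_t2_loser = pick(v$neg_t2_1, v$neg_t2_2, l),
      pos_winner = pick(v$pos_1, v$pos_2, w),
      pos_loser = pick(v$pos_1, v$pos_2, l))
    if (config$emit_au) {
      for (p in 1:2) {
        traj <- data.frame(
          t_center = c(rbind(v$t_ann, v$t_sel)), half_width = 1,
          positive = rep(if (p == 1L) v$pos_1 else v$pos_2, each = 2),
          negative = c(rbind(if (p == 1L) v$neg_t1_1 else v$neg_t1_2,
                             if (p == 1L) v$neg_t2_1 else v$neg_t2_2)))
        au_streams[[players[p]]] <-
          emit_au_frames(traj, config, session_end = t_clock + 1)
      }
    }
  }
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 au_streams = if (config$emit_au) au_streams else NULL,
                 truth = config),
            class = "simulated_study")
}

#' Emit AU intensity frames for an emotion trajectory
#'
#' Produces frames at `fps` on a regular grid covering the session. Within an
#' expression epoch (a closed window around a game event) the positive-channel
#' AUs (6, 12) carry the epoch's positive intensity plus channel noise and the
#' negative-channel AUs (4, 9, 23) carry the negative intensity plus channel
#' noise; noise is drawn once per channel per frame, mimicking whole-display
#' jitter (the AUs of a display move together). All other AU columns of the
#' dialect carry pure half-normal noise, as do out-of-epoch frames. All
#' intensities are clipped to [0, 5]. When epochs overlap (e.g. immediate
#' responses where selection follows announcement within a second), the epoch
#' whose centre is nearest the frame wins.
#'
#' @param trajectory Data frame with columns `t_center`, `half_width`,
#'   `positive`, `negative` (intensities in [0, 5]), one row per epoch.
#' @param config A `sim_config` (supplies `fps` and `au_noise_sd`).
#' @param session_end Session length in seconds; defaults to the last epoch
#'   end.
#' @return An `au_frames` data frame.
#' @export
emit_au_frames <- function(trajectory, config = sim_config(),
                           session_end = NULL) {
  if (is.null(trajectory) || nrow(trajectory) == 0L)
    stop("empty emotion trajectory", call. = FALSE)
  if (any(trajectory$positive < 0 | trajectory$positive > 5 |
          trajectory$negative < 0 | trajectory$negative > 5))
    stop("trajectory intensities must lie in [0, 5]", call. = FALSE)
  fps <- config$fps
  noise_sd <- config$au_noise_sd
  session_end <- session_end %||% max(trajectory$t_center + trajectory$half_width)
  ts <- seq(0, session_end, by = 1 / fps)
  n <- length(ts)
  # nearest-centre epoch assignment, NA outside every epoch
  epoch_idx <- rep(NA_integer_, n)
  best_dist <- rep(Inf, n)
  for (k in seq_len(nrow(trajectory))) {
    d <- abs(ts - trajectory$t_center[k])
    inside <- d <= trajectory$half_width[k] + 1e-12
    better <- inside & d < best_dist
    epoch_idx[better] <- k
    best_dist[better] <- d[better]
  }
  pos_sig <- ifelse(is.na(epoch_idx), 0, trajectory$positive[epoch_idx])
  neg_sig <- ifelse(is.na(epoch_idx), 0, trajectory$negative[epoch_idx])
  in_epoch <- !is.na(epoch_idx)
  pos_chan <- .clip(ifelse(in_epoch, pos_sig + stats::rnorm(n, 0, noise_sd),
                           abs(stats::rnorm(n, 0, noise_sd))), 0, 5)
  neg_chan <- .clip(ifelse(in_epoch, neg_sig + stats::rnorm(n, 0, noise_sd),
                           abs(stats::rnorm(n, 0, noise_sd))), 0, 5)
  out <- data.frame(timestamp = ts, confidence = 0.98, success = 1L)
  for (code in .AU_DIALECT_CODES) {
    col <- .au_col(code)
    out[[col]] <- if (code %in% c(6L, 12L)) pos_chan
      else if (code %in% c(4L, 9L, 23L)) neg_chan
      else .clip(abs(stats::rnorm(n, 0, noise_sd)), 0, 5)
  }
  structure(out, dropped = 0L, class = c("au_frames", "data.frame"))
}

#' Sample uniform BPAQ-SF item responses
#'
#' Convenience generator of questionnaire items (12 per respondent, uniform
#' on 1..5); no trait structure is modelled.
#'
#' @param n Number of respondents.
#' @return An `n x 12` integer matrix.
#' @export
simulate_bpaq_items <- function(n) {
  matrix(sample.int(5L, n * 12L, replace = TRUE), nrow = n, ncol = 12L)
}

#' Write the trial-log CSV for a simulated (or real) trial table
#'
#' Writes the canonical schema `couple_id, study, condition, round,
#' winner_id, loser_id, rt_winner_ms, rt_loser_ms, blast, t_go,
#' t_winner_announced, t_blast_selected, forced_break_s`; any extra columns
#' (e.g. simulator truth intensities) are dropped unless `keep_truth`.
#'
#' @param trials Trial data frame.
#' @param path Output CSV path.
#' @param keep_truth Keep non-schema columns.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path, keep_truth = FALSE) {
  schema <- c("couple_id", "study", "condition", "round", "winner_id",
              "loser_id", "rt_winner_ms", "rt_loser_ms", "blast", "t_go",
              "t_winner_announced", "t_blast_selected", "forced_break_s")
  missing_cols <- setdiff(schema, names(trials))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cols <- if (keep_truth) union(schema, names(trials)) else schema
  utils::write.csv(trials[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a trial-log CSV
#'
#' @param path CSV path in the trial-log schema.
#' @return Trial data frame, sorted by couple and round.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("trial log is empty: ", path, call. = FALSE)
  needed <- c("couple_id", "round", "winner_id", "loser_id", "blast",
              "condition", "t_winner_announced", "t_blast_selected",
              "forced_break_s")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("trial log lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(df$blast < 1 | df$blast > 8))
    stop("blast levels outside the 1-8 grid", call. = FALSE)
  df[order(df$couple_id, df$round), , drop = FALSE]
}
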