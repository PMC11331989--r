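# Pipeline orchestration: run every stage on a trial log (plus optional AU
# streams), persist intermediates, and produce the headline study summary.

#' Percent change between two category means
#'
#' `100 * (m_to - m_from) / m_from`, the contrast used for the compounding
#' headline (both-partners-negative vs neither). Undefined when the baseline
#' mean is zero or missing.
#'
#' @param m_to,m_from Category means.
#' @return Percent change (e.g. `85.7`), or `NA` when undefined.
#' @export
percent_change <- function(m_to, m_from) {
  if (is.na(m_to) || is.na(m_from) || m_from == 0) return(NA_real_)
  100 * (m_to - m_from) / m_from
}

#' Run the full analysis pipeline
#'
#' Orchestrates: timing features; AU reading + scoring + affect attachment
#' (skipped with a warning when no AU streams are available and no affect
#' columns are present); high-affect classification; compounding categories
#' (immediate-response condition); win-streak compression; escalation,
#' asymmetry and matching statistics; the actor-partner model; and the
#' forced-break mediation model. Deterministic given inputs and `seed`;
#' every stage's output is persisted as tidy CSV when `out_dir` is given,
#' together with a run log recording the package version, seed, thresholds
#' and dropped-row counts.
#'
#' @param trials Trial data frame or path to a trial-log CSV.
#' @param au Optional: named list of `au_frames` / `emotion_frames` per
#'   player, or a directory containing `<player_id>.csv` AU tables.
#' @param rules `au_rules` for scoring.
#' @param threshold_scope Pooling scope for the high-affect threshold.
#' @param boot Bootstrap replicates for the mediation stage.
#' @param seed Seed for the bootstrap stage.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return Object of class `study_pipeline`: list of all intermediates
#'   (`trials`, `affect`, `compressed`, `escalation`, `asymmetry`,
#'   `matching`, `apim`, `mediation`, `log`) plus `summary`.
#' @export
run_pipeline <- function(trials, au = NULL, rules = au_rules(),
                         threshold_scope = "pooled",
                         boot = 1000L, seed = NULL, out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(trials)) trials <- read_trial_log(trials)
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("empty trial input", call. = FALSE)
  say <- function(...) if (!quiet) message("run_pipeline: ", ...)
  log_lines <- c(sprintf("dyadarc %s", as.character(utils::packageVersion("dyadarc"))),
                 sprintf("seed: %s", if (is.null(seed)) "none" else seed),
                 sprintf("n_trials: %d  n_couples: %d",
                         nrow(trials), length(unique(trials$couple_id))))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  trials <- stage("timing_features", timing_features(trials))

  # --- affect ---------------------------------------------------------------
  affect <- NULL
  affect_source <- "none"
  if (!is.null(au)) {
    emotions <- stage("emotion_scoring", {
      streams <- if (is.character(au)) {
        files <- list.files(au, pattern = "\\.csv$", full.names = TRUE)
        stats::setNames(lapply(files, read_au_table, rules = rules, quiet = quiet),
                        sub("\\.csv$", "", basename(files)))
      } else au
      lapply(streams, function(s)
        if (inherits(s, "emotion_frames")) s else score_emotions(s, rules))
    })
    players <- unique(c(trials$winner_id, trials$loser_id))
    if (all(players %in% names(emotions))) {
      affect <- stage("attach_affect", attach_affect(trials, emotions))
      trials <- merge_affect_into_trials(trials, affect)
      affect_source <- "au_streams"
    } else {
      warning("AU streams do not cover every player; affect stages skipped",
              call. = FALSE)
    }
  } else if (all(c("neg_t2_winner", "neg_t2_loser") %in% names(trials))) {
    affect_source <- "trial_columns"
    say("using affect columns already present on the trial table")
  } else {
    warning("no AU streams supplied and no affect columns present; ",
            "affect stages skipped, dynamics stages still run", call. = FALSE)
  }
  log_lines <- c(log_lines, sprintf("affect_source: %s", affect_source))

  # --- high-affect classification & compounding -----------------------------
  flags <- NULL
  compound <- NULL
  if (affect_source != "none") {
    flags <- stage("classify_high_affect", {
      neg_vals <- c(trials$neg_t2_winner, trials$neg_t2_loser)
      pos_vals <- c(trials$pos_winner %||% rep(NA_real_, nrow(trials)),
                    trials$pos_loser %||% rep(NA_real_, nrow(trials)))
      neg_cls <- classify_high_affect(neg_vals, scope = threshold_scope)
      n <- nrow(trials)
      out <- list(
        threshold_neg = neg_cls$threshold,
        high_neg_winner = neg_cls$flags[seq_len(n)],
        high_neg_loser = neg_cls$flags[n + seq_len(n)])
      if (!all(is.na(pos_vals))) {
        pos_cls <- classify_high_affect(pos_vals, scope = threshold_scope)
        out$threshold_pos <- pos_cls$threshold
        out$high_pos_winner <- pos_cls$flags[seq_len(n)] &
          !out$high_neg_winner
        out$high_pos_loser <- pos_cls$flags[n + seq_len(n)] &
          !out$high_neg_loser
      }
      out
    })
    trials$high_neg_winner <- flags$high_neg_winner
    trials$high_neg_loser <- flags$high_neg_loser
    log_lines <- c(log_lines,
                   sprintf("high_negativity_threshold: %.6g",
                           flags$threshold_neg[1]),
                   sprintf("prop_high_neg: %.4f",
                           mean(c(flags$high_neg_winner, flags$high_neg_loser),
                                na.rm = TRUE)))
    imm <- trials[trials$condition == "immediate", , drop = FALSE]
    if (nrow(imm) > 0) {
      compound <- stage("compound_category",
        data.frame(couple_id = imm$couple_id, round = imm$round,
                   blast = imm$blast,
                   category = compound_category(imm$high_neg_winner,
                                                imm$high_neg_loser,
                                                quiet = quiet)))
    }
  }

  # --- dynamics -------------------------------------------------------------
  compressed <- stage("compress_win_streaks", compress_win_streaks(trials))
  records <- stage("escalation_records", escalation_records(compressed))
  escalation <- stage("escalation_summary", escalation_summary(records))
  asymmetry <- stage("couple_asymmetry", couple_asymmetry(records, quiet = quiet))
  matching <- stage("matching_statistics", matching_statistics(compressed))

  # --- models ---------------------------------------------------------------
  apim <- NULL
  mediation <- NULL
  if (affect_source != "none") {
    apim <- tryCatch(
      fit_apim(build_apim_table(compressed)),
      error = function(e) { say("APIM skipped: ", conditionMessage(e)); NULL })
    mediation <- tryCatch(
      fit_mediation(mediation_data_from_trials(trials), B = boot, seed = seed),
      error = function(e) { say("mediation skipped: ", conditionMessage(e)); NULL })
  }

  out <- list(trials = trials, affect = affect, flags = flags,
              compound = compound, compressed = compressed,
              escalation_records = records, escalation = escalation,
              asymmetry = asymmetry, matching = matching,
              apim = apim, mediation = mediation, log = log_lines)
  out$summary <- summarize_study(out)
  out <- structure(out, class = "study_pipeline")
  if (!is.null(out_dir)) .persist_pipeline(out, out_dir)
  out
}

.persist_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, name),
                                       row.names = FALSE)
  wr(x$trials, "trials_features.csv")
  wr(x$affect, "trial_affect.csv")
  wr(x$compound, "compound_categories.csv")
  wr(x$compressed, "compressed_rounds.csv")
  wr(x$escalation_records, "escalation_records.csv")
  wr(x$escalation, "escalation_summary.csv")
  wr(x$asymmetry, "couple_asymmetry.csv")
  if (!is.null(x$apim)) wr(x$apim$effects, "apim_effects.csv")
  jsonlite::write_json(unclass(x$summary), file.path(out_dir, "study_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(x$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Summarize a pipeline run into the headline study table
#'
#' Mean/SD of blast per condition class (immediate vs all forced breaks
#' pooled — the headline contrast — plus each break length), mean/SD of
#' positive and negative affect, T1/T2 negativity means by condition class,
#' the proportion of high-negative trials, escalation proportions, matching
#' correlations, per-compound-category blast means, and the percent change
#' in mean blast from the neither category to the both category. Cells whose
#' inputs are unavailable are explicitly `NA`; a compounding contrast with an
#' empty category is flagged undefined.
#'
#' @param x A `study_pipeline` list (or compatible list of intermediates).
#' @return A named list (class `study_summary`).
#' @export
summarize_study <- function(x) {
  trials <- x$trials
  msd <- function(v) if (length(v) == 0 || all(is.na(v)))
    c(mean = NA_real_, sd = NA_real_)
    else c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  is_break <- trials$condition != "immediate"
  blast_by_cond <- list(
    immediate = msd(trials$blast[!is_break]),
    forced_break = msd(trials$blast[is_break]))
  for (cond in setdiff(unique(trials$condition), "immediate"))
    blast_by_cond[[cond]] <- msd(trials$blast[trials$condition == cond])

  has_affect <- all(c("neg_t2_winner", "neg_t2_loser") %in% names(trials))
  aff <- if (has_affect) {
    list(negative = msd(c(trials$neg_t2_winner, trials$neg_t2_loser)),
         positive = msd(c(trials$pos_winner %||% NA_real_,
                          trials$pos_loser %||% NA_real_)),
         neg_T1_immediate = msd(trials$neg_t1_winner[!is_break]),
         neg_T2_immediate = msd(trials$neg_t2_winner[!is_break]),
         neg_T1_forced_break = msd(trials$neg_t1_winner[is_break]),
         neg_T2_forced_break = msd(trials$neg_t2_winner[is_break]))
  } else NULL
  prop_high_neg <- if (!is.null(x$flags))
    mean(c(x$flags$high_neg_winner, x$flags$high_neg_loser), na.rm = TRUE)
    else NA_real_

  compound <- NULL
  if (!is.null(x$compound)) {
    cats <- levels(x$compound$category)
    cmeans <- vapply(cats, function(cc)
      msd(x$compound$blast[x$compound$category == cc])[["mean"]], numeric(1))
    csd <- vapply(cats, function(cc)
      msd(x$compound$blast[x$compound$category == cc])[["sd"]], numeric(1))
    n_cat <- vapply(cats, function(cc)
      sum(x$compound$category == cc, na.rm = TRUE), numeric(1))
    pc <- percent_change(cmeans[["both"]], cmeans[["neither"]])
    compound <- list(mean = as.list(cmeans), sd = as.list(csd),
                     n = as.list(n_cat),
                     percent_change_both_vs_neither = round(pc, 1),
                     percent_change_headline = round(pc),
                     contrast_defined = all(n_cat[c("neither", "both")] > 0))
  }

  esc <- if (!is.null(x$escalation)) {
    e <- x$escalation[x$escalation$group == "all", ]
    list(prop_match = e$prop_match, prop_escalate = e$prop_escalate,
         prop_de_escalate = e$prop_de_escalate,
         mean_coefficient = e$mean_coefficient)
  } else NULL
  match_stats <- if (!is.null(x$matching))
    list(grand_mean_r = x$matching$grand_mean$r,
         lagged_r = x$matching$lagged$r,
         trend_slope = x$matching$trend$slope) else NULL

  structure(list(blast = blast_by_cond, affect = aff,
                 prop_high_negative = prop_high_neg,
                 compound = compound, escalation = esc,
                 matching = match_stats),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Study summary\n")
  cat(sprintf("  blast (immediate):    mean %.2f sd %.2f\n",
              x$blast$immediate[["mean"]], x$blast$immediate[["sd"]]))
  cat(sprintf("  blast (forced break): mean %.2f sd %.2f\n",
              x$blast$forced_break[["mean"]], x$blast$forced_break[["sd"]]))
  if (!is.null(x$affect)) {
    cat(sprintf("  affect: positive %.2f, negative %.2f; high-negative trials %.1f%%\n",
                x$affect$positive[["mean"]], x$affect$negative[["mean"]],
                100 * x$prop_high_negative))
    cat(sprintf("  winner negativity T1 -> T2 (forced break): %.2f -> %.2f\n",
                x$affect$neg_T1_forced_break[["mean"]],
                x$affect$neg_T2_forced_break[["mean"]]))
  }
  if (!is.null(x$compound))
    cat(sprintf("  compounding: neither %.2f, both %.2f (+%.0f%%)\n",
                x$compound$mean$neither, x$compound$mean$both,
                x$compound$percent_change_headline))
  if (!is.null(x$escalation))
    cat(sprintf("  escalation: match %.0f%%, escalate %.0f%%, de-escalate %.0f%%\n",
                100 * x$escalation$prop_match, 100 * x$escalation$prop_escalate,
                100 * x$escalation$prop_de_escalate))
  if (!is.null(x$matching))
    cat(sprintf("  matching: grand-mean r %.2f, lagged r %.2f, trend slope %.3g\n",
                x$matching$grand_mean_r, x$matching$lagged_r,
                x$matching$trend_slope))
  invisible(x)
}
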