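# Escalation and retaliation structure on the alternating-winner series:
# per-transition escalation coefficients (own blast minus the partner's
# previous blast, a possible -7..+7), match/escalate/de-escalate
# classification, within-couple asymmetry, and blast-matching correlations.

#' Escalation records from the compressed series
#'
#' For every interval from the second onward, the acting player's escalation
#' coefficient is their mean blast minus their partner's previous mean blast
#' (the partner acted in the previous interval because winners alternate).
#' Coefficients lie in [-7, 7]; the class is `match` when the coefficient is
#' within `match_tol` of zero (exactly zero by default), `escalate` above,
#' `de_escalate` below.
#'
#' @param compressed A `compressed_rounds` data frame.
#' @param match_tol Absolute tolerance for calling a match; the default 0
#'   requires exact equality of the streak means, `0.5` treats
#'   sub-half-blast differences as matches.
#' @return Data frame of class `escalation_records`: `couple_id`,
#'   `interval_index`, `player_id`, `coefficient`, `class`.
#' @export
escalation_records <- function(compressed, match_tol = 0) {
  if (match_tol < 0) stop("match_tol must be >= 0", call. = FALSE)
  res <- lapply(split(compressed, compressed$couple_id), function(cc) {
    cc <- cc[order(cc$interval_index), , drop = FALSE]
    if (nrow(cc) < 2L)
      stop("couple ", cc$couple_id[1],
           ": compressed series shorter than 2 intervals", call. = FALSE)
    if (any(cc$winner_id[-1] == cc$winner_id[-nrow(cc)]))
      stop("compressed series winners do not alternate", call. = FALSE)
    i <- 2:nrow(cc)
    coefficient <- cc$blast_mean[i] - cc$blast_mean[i - 1]
    data.frame(couple_id = cc$couple_id[1],
               interval_index = cc$interval_index[i],
               player_id = cc$winner_id[i],
               coefficient = coefficient)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$class <- ifelse(abs(out$coefficient) <= match_tol, "match",
               ifelse(out$coefficient > 0, "escalate", "de_escalate"))
  structure(out, class = c("escalation_records", "data.frame"))
}

#' Summarize escalation behaviour
#'
#' Proportions of match / escalate / de-escalate records (always summing to
#' one) and the mean coefficient, overall or per group.
#'
#' @param records An `escalation_records` data frame.
#' @param by Optional grouping column name (`"player_id"`, `"couple_id"`) or
#'   a grouping vector of the same length as `records`.
#' @return Data frame with `group`, `n`, `prop_match`, `prop_escalate`,
#'   `prop_de_escalate`, `mean_coefficient`.
#' @export
escalation_summary <- function(records, by = NULL) {
  if (nrow(records) == 0L) stop("no escalation records", call. = FALSE)
  g <- if (is.null(by)) rep("all", nrow(records))
       else if (is.character(by) && length(by) == 1L) records[[by]]
       else by
  res <- lapply(split(records, g), function(rr) {
    data.frame(n = nrow(rr),
               prop_match = mean(rr$class == "match"),
               prop_escalate = mean(rr$class == "escalate"),
               prop_de_escalate = mean(rr$class == "de_escalate"),
               mean_coefficient = mean(rr$coefficient))
  })
  out <- do.call(rbind, res)
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Within-couple escalation asymmetry
#'
#' Orders each couple's two per-player mean escalation coefficients into a
#' (higher, lower) pair; ties are broken by player id order. Couples where a
#' partner has no records are excluded and counted. The two cross-couple
#' series are what the asymmetry correlation is computed on.
#'
#' @param records An `escalation_records` data frame.
#' @param quiet Suppress the exclusion message.
#' @return Data frame `couple_id`, `higher`, `lower`, with the excluded
#'   couple count as attribute `excluded`.
#' @export
couple_asymmetry <- function(records, quiet = FALSE) {
  res <- lapply(split(records, records$couple_id), function(rr) {
    means <- tapply(rr$coefficient, rr$player_id, mean)
    if (length(means) < 2L) return(NULL)
    means <- means[order(names(means))] # tie-break by id order
    hi <- which.max(means)
    data.frame(couple_id = rr$couple_id[1],
               higher = unname(means[hi]), lower = unname(means[3L - hi]))
  })
  excluded <- sum(vapply(res, is.null, logical(1)))
  if (excluded > 0 && !quiet)
    message("couple_asymmetry: ", excluded,
            " couple(s) excluded (a partner lacks records)")
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(couple_id = character(0), higher = numeric(0),
                      lower = numeric(0))
  rownames(out) <- NULL
  structure(out, excluded = excluded)
}

#' Blast-matching and escalation-over-time statistics
#'
#' Three statistics of the retaliation structure:
#' \describe{
#'   \item{grand-mean matching}{per couple, each partner's grand mean blast
#'     (over the intervals they won); every participant contributes a point
#'     (own mean, partner mean) and the Pearson correlation is computed
#'     across those points (requires >= 3 couples).}
#'   \item{lagged matching}{pairs (partner's previous mean blast, own mean
#'     blast) pooled over compressed intervals; Pearson correlation —
#'     trial-level retaliation.}
#'   \item{escalation over time}{least-squares slope of mean blast on
#'     interval index, pooled; a near-zero slope means no escalation across
#'     the session.}
#' }
#' Degenerate (zero-variance) inputs yield `NA` correlations with a flag.
#'
#' @param compressed A `compressed_rounds` data frame.
#' @return List with `grand_mean` (points + `r`), `lagged` (pairs + `r`),
#'   `trend` (`slope`, `se`, `p`), and `degenerate` flags.
#' @export
matching_statistics <- function(compressed) {
  by_couple <- split(compressed, compressed$couple_id)
  if (length(by_couple) < 3L)
    stop("grand-mean matching needs >= 3 couples", call. = FALSE)
  pts <- do.call(rbind, lapply(by_couple, function(cc) {
    means <- tapply(cc$blast_mean, cc$winner_id, mean)
    if (length(means) < 2L) return(NULL)
    data.frame(couple_id = cc$couple_id[1],
               own = c(means[1], means[2]),
               partner = c(means[2], means[1]),
               player_id = names(means))
  }))
  rownames(pts) <- NULL
  degenerate <- list(grand_mean = FALSE, lagged = FALSE)
  r_grand <- if (stats::sd(pts$own) == 0 || stats::sd(pts$partner) == 0) {
    degenerate$grand_mean <- TRUE; NA_real_
  } else stats::cor(pts$own, pts$partner)

  lagged <- do.call(rbind, lapply(by_couple, function(cc) {
    cc <- cc[order(cc$interval_index), , drop = FALSE]
    if (nrow(cc) < 2L) return(NULL)
    i <- 2:nrow(cc)
    data.frame(couple_id = cc$couple_id[1],
               partner_prev = cc$blast_mean[i - 1], own = cc$blast_mean[i])
  }))
  rownames(lagged) <- NULL
  r_lag <- if (stats::sd(lagged$own) == 0 || stats::sd(lagged$partner_prev) == 0) {
    degenerate$lagged <- TRUE; NA_real_
  } else stats::cor(lagged$partner_prev, lagged$own)

  fit <- stats::lm(blast_mean ~ interval_index, data = compressed)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(grand_mean = list(points = pts, r = r_grand),
       lagged = list(pairs = lagged, r = r_lag),
       trend = list(slope = sm["interval_index", "Estimate"],
                    se = sm["interval_index", "Std. Error"],
                    p = sm["interval_index", "Pr(>|t|)"]),
       degenerate = degenerate)
}
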