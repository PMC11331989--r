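# Longitudinal actor-partner interdependence modelling of negativity on the
# alternating-winner series, and the forced-break mediation model of blast
# level through winner negativity.

#' Build the lagged actor-partner table
#'
#' From the compressed alternating-winner series, builds one winner-role and
#' one loser-role row per interval from the second onward: the outcome is the
#' role's negativity at interval \eqn{R_i}; the actor regressor is the same
#' player's negativity at \eqn{R_{i-1}} (where they held the opposite role,
#' because winners alternate); the partner regressor is the other player's
#' negativity at \eqn{R_{i-1}}. A session of k intervals yields 2(k-1) rows.
#' Input order does not matter (internal sort).
#'
#' @param compressed A `compressed_rounds` data frame with per-role
#'   negativity means.
#' @param negativity Which windowed negativity to model: `"t2"`
#'   (blast-selection window, default) or `"t1"` (winner-announcement
#'   window).
#' @return Data frame of class `apim_table`: `couple_id`, `interval_index`,
#'   `role`, `player_id`, `outcome`, `actor`, `partner`.
#' @export
build_apim_table <- function(compressed, negativity = c("t2", "t1")) {
  negativity <- match.arg(negativity)
  wcol <- paste0("neg_", negativity, "_winner_mean")
  lcol <- paste0("neg_", negativity, "_loser_mean")
  if (!all(c(wcol, lcol) %in% names(compressed)) ||
      all(is.na(compressed[[wcol]])))
    stop("compressed series carries no per-role negativity", call. = FALSE)
  res <- lapply(split(compressed, compressed$couple_id), function(cc) {
    cc <- cc[order(cc$interval_index), , drop = FALSE]
    k <- nrow(cc)
    if (k < 2L) stop("couple ", cc$couple_id[1], ": fewer than 2 intervals",
                     call. = FALSE)
    if (any(cc$winner_id[-1] == cc$winner_id[-k]))
      stop("winners do not alternate in the compressed series", call. = FALSE)
    i <- 2:k
    rbind(
      data.frame(couple_id = cc$couple_id[1], interval_index = cc$interval_index[i],
                 role = "winner", player_id = cc$winner_id[i],
                 outcome = cc[[wcol]][i],
                 actor = cc[[lcol]][i - 1],    # current winner lost R_{i-1}
                 partner = cc[[wcol]][i - 1]), # partner won R_{i-1}
      data.frame(couple_id = cc$couple_id[1], interval_index = cc$interval_index[i],
                 role = "loser", player_id = cc$loser_id[i],
                 outcome = cc[[lcol]][i],
                 actor = cc[[wcol]][i - 1],
                 partner = cc[[lcol]][i - 1]))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$couple_id, out$interval_index, out$role), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("apim_table", "data.frame"))
}

#' Fit the two-intercept actor-partner interdependence model
#'
#' Linear mixed model with role-specific intercepts, actor slopes and
#' partner slopes, plus a couple-level random intercept, estimated by
#' maximum likelihood with `lme4::lmer`:
#' `outcome ~ 0 + role + role:actor + role:partner + (1 | couple_id)`.
#' When the mixed fit is degenerate (e.g. a zero-variance outcome, where no
#' variance decomposition exists) the fixed-effect structure is estimated by
#' ordinary least squares with a zero couple variance, and the fallback is
#' recorded in the diagnostics.
#'
#' @param table An `apim_table`.
#' @param conf_level Wald confidence level.
#' @return Object of class `apim_result`: `effects` (data frame of role,
#'   term, estimate, se, ci_lo, ci_hi, df, stat), `couple_var`,
#'   `residual_var`, `diagnostics`.
#' @export
fit_apim <- function(table, conf_level = 0.95) {
  if (length(unique(table$couple_id)) < 2L)
    stop("need >= 2 couples", call. = FALSE)
  if (nrow(table) < 10L) stop("need >= 10 rows", call. = FALSE)
  if (anyNA(table$outcome) || anyNA(table$actor) || anyNA(table$partner))
    stop("missing values in the APIM table; drop incomplete intervals first",
         call. = FALSE)
  table$role <- factor(table$role, levels = c("winner", "loser"))
  diagnostics <- list(estimator = "lmer-ML", singular = FALSE, messages = character())
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(outcome ~ 0 + role + role:actor + role:partner +
                   (1 | couple_id), data = table, REML = FALSE),
      warning = function(w) {
        diagnostics$messages <<- c(diagnostics$messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        diagnostics$messages <<- c(diagnostics$messages, conditionMessage(m))
        invokeRestart("muffleMessage")
      }),
    error = function(e) e)
  if (inherits(fit, "error") || stats::sigma(fit) < 1e-10) {
    # degenerate data: fall back to OLS on the identical fixed structure
    diagnostics$estimator <- "ols-fallback"
    if (inherits(fit, "error"))
      diagnostics$messages <- c(diagnostics$messages, conditionMessage(fit))
    ols <- stats::lm(outcome ~ 0 + role + role:actor + role:partner, data = table)
    est <- stats::coef(ols)
    co <- suppressWarnings(summary(ols))$coefficients
    se <- stats::setNames(rep(NA_real_, length(est)), names(est))
    se[rownames(co)] <- co[, "Std. Error"]
    # aliased (unidentifiable) terms in degenerate data: report 0, no SE
    est[is.na(est)] <- 0
    couple_var <- 0; resid_var <- stats::sigma(ols)^2
    df <- stats::df.residual(ols)
  } else {
    diagnostics$singular <- lme4::isSingular(fit)
    co <- summary(fit)$coefficients
    est <- co[, "Estimate"]; se <- co[, "Std. Error"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    couple_var <- vc$vcov[vc$grp == "couple_id"]
    resid_var <- stats::sigma(fit)^2
    df <- nrow(table) - length(est)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  term_of <- function(nm) {
    if (grepl(":actor$", nm)) "actor"
    else if (grepl(":partner$", nm)) "partner"
    else "intercept"
  }
  role_of <- function(nm) if (grepl("rolewinner", nm)) "winner" else "loser"
  effects <- data.frame(
    role = vapply(names(est), role_of, character(1)),
    term = vapply(names(est), term_of, character(1)),
    estimate = unname(est), se = unname(se),
    ci_lo = unname(est - z * se), ci_hi = unname(est + z * se),
    df = df, stat = unname(est / ifelse(se > 0, se, NA)))
  rownames(effects) <- NULL
  structure(list(effects = effects, couple_var = couple_var,
                 residual_var = resid_var, diagnostics = diagnostics),
            class = "apim_result")
}

#' @export
print.apim_result <- function(x, ...) {
  cat("Actor-partner interdependence model (", x$diagnostics$estimator, ")\n",
      sep = "")
  print(x$effects, digits = 4)
  cat(sprintf("couple-level variance %.4g, residual variance %.4g\n",
              x$couple_var, x$residual_var))
  invisible(x)
}

#' Extract an APIM effect estimate
#'
#' @param result An `apim_result`.
#' @param role `"winner"` or `"loser"`.
#' @param term `"intercept"`, `"actor"` or `"partner"`.
#' @return The one-row effects data frame.
#' @export
apim_effect <- function(result, role, term) {
  e <- result$effects
  e[e$role == role & e$term == term, , drop = FALSE]
}

#' Simple mediation of the forced-break effect on blast through negativity
#'
#' OLS path model on trial-level data: total effect `c` of the forced-break
#' indicator on blast; `a` of the indicator on the mediator (winner
#' negativity at selection); `b` (mediator, adjusted) and direct effect `c'`
#' from the joint outcome model. The indirect effect is `a * b`, with a
#' nonparametric percentile bootstrap that resamples whole couples
#' (preserving within-couple dependence). On the same sample the OLS
#' decomposition `c = c' + a * b` holds exactly.
#'
#' @param data Data frame with columns `couple_id`, `forced_break` (logical
#'   or 0/1), `neg` (mediator), `blast` (outcome).
#' @param B Bootstrap replicates (>= 100; default 5000).
#' @param seed Optional RNG seed for the bootstrap.
#' @param conf_level Percentile-interval level.
#' @return Object of class `mediation_result` with paths `c`, `a`, `b`,
#'   `c_prime`, `indirect`, their SEs and Wald p-values, and bootstrap
#'   percentile CIs for the indirect and direct effects.
#' @export
fit_mediation <- function(data, B = 5000L, seed = NULL, conf_level = 0.95) {
  need <- c("couple_id", "forced_break", "neg", "blast")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("mediation data lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (B < 100L) stop("B must be >= 100", call. = FALSE)
  data <- data[!is.na(data$neg) & !is.na(data$blast), , drop = FALSE]
  data$forced_break <- as.numeric(data$forced_break)
  if (length(unique(data$forced_break)) < 2L)
    stop("both exposure levels (immediate and forced break) must be present",
         call. = FALSE)
  paths <- function(d) {
    fc <- stats::lm(blast ~ forced_break, data = d)
    fa <- stats::lm(neg ~ forced_break, data = d)
    fb <- stats::lm(blast ~ forced_break + neg, data = d)
    list(c = stats::coef(fc)[["forced_break"]],
         a = stats::coef(fa)[["forced_break"]],
         b = stats::coef(fb)[["neg"]],
         c_prime = stats::coef(fb)[["forced_break"]],
         fits = list(fc = fc, fa = fa, fb = fb))
  }
  pt <- paths(data)
  wald <- function(fit, term) {
    co <- summary(fit)$coefficients
    c(se = co[term, "Std. Error"], p = co[term, "Pr(>|t|)"],
      stat = co[term, "t value"], df = stats::df.residual(fit))
  }
  if (!is.null(seed)) set.seed(seed)
  couples <- unique(data$couple_id)
  by_couple <- split(seq_len(nrow(data)), data$couple_id)
  boot <- matrix(NA_real_, nrow = B, ncol = 2,
                 dimnames = list(NULL, c("indirect", "direct")))
  for (bidx in seq_len(B)) {
    draw <- sample(couples, length(couples), replace = TRUE)
    rows <- unlist(by_couple[draw], use.names = FALSE)
    d <- data[rows, , drop = FALSE]
    if (length(unique(d$forced_break)) < 2L) next # degenerate resample
    p <- paths(d)
    boot[bidx, ] <- c(p$a * p$b, p$c_prime)
  }
  ok <- stats::complete.cases(boot)
  alpha <- (1 - conf_level) / 2
  qs <- apply(boot[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(alpha, 1 - alpha))
  structure(
    list(c = pt$c, a = pt$a, b = pt$b, c_prime = pt$c_prime,
         indirect = pt$a * pt$b,
         ci_indirect = unname(qs[, "indirect"]),
         ci_direct = unname(qs[, "direct"]),
         wald = list(c = wald(pt$fits$fc, "forced_break"),
                     a = wald(pt$fits$fa, "forced_break"),
                     b = wald(pt$fits$fb, "neg"),
                     c_prime = wald(pt$fits$fb, "forced_break")),
         B = B, boot_used = sum(ok), conf_level = conf_level),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Forced-break mediation through winner negativity\n")
  cat(sprintf("  total  c      = %8.4f (p = %.3g)\n", x$c, x$wald$c[["p"]]))
  cat(sprintf("  a (break->neg)= %8.4f (p = %.3g)\n", x$a, x$wald$a[["p"]]))
  cat(sprintf("  b (neg->blast)= %8.4f (p = %.3g)\n", x$b, x$wald$b[["p"]]))
  cat(sprintf("  direct c'     = %8.4f [%.4f, %.4f]\n",
              x$c_prime, x$ci_direct[1], x$ci_direct[2]))
  cat(sprintf("  indirect a*b  = %8.4f [%.4f, %.4f] (%d bootstrap resamples)\n",
              x$indirect, x$ci_indirect[1], x$ci_indirect[2], x$boot_used))
  invisible(x)
}

#' Assemble mediation input from a trial table
#'
#' Exposure is the forced-break indicator (any non-immediate condition),
#' the mediator the winner's negativity at blast selection, the outcome the
#' blast level.
#'
#' @param trials Trial table carrying `neg_t2_winner`.
#' @return Data frame for [fit_mediation()].
#' @export
mediation_data_from_trials <- function(trials) {
  if (!"neg_t2_winner" %in% names(trials))
    stop("trials lack winner negativity (neg_t2_winner)", call. = FALSE)
  data.frame(couple_id = trials$couple_id,
             forced_break = trials$condition != "immediate",
             neg = trials$neg_t2_winner,
             blast = trials$blast)
}
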