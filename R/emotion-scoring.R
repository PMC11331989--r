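# From per-frame facial action-unit (AU) intensities to prototypic emotion
# intensities. AUs are scored 0-5 by automated FACS tools; prototypic displays
# are fixed AU combinations: positive affect = happiness, negative affect =
# anger or disgust (the "moral emotions").

# AU intensity columns of the automated-FACS CSV dialect, "AUxx_r" naming.
.AU_DIALECT_CODES <- c(1L, 2L, 4L, 5L, 6L, 7L, 9L, 10L, 12L, 14L, 15L, 17L,
                       20L, 23L, 25L, 26L, 45L)

.au_col <- function(codes) sprintf("AU%02d_r", as.integer(codes))

#' Prototypic-emotion combination rules
#'
#' Defines which AUs constitute each prototypic display and how anger and
#' disgust combine into the negative channel. Defaults follow the displays
#' used in this pipeline: happiness = {AU6 cheek raiser, AU12 lip corner
#' puller}; anger = {AU4 brow lowerer, AU23 lip tightener}; disgust =
#' {AU9 nose wrinkle}. Within an emotion the intensity is the mean of its
#' required AUs (which keeps the 0-5 scale); the negative channel is by
#' default the max of anger and disgust, so either moral emotion alone marks
#' the display as negative. Full EMFACS variants can be supplied instead.
#'
#' @param happiness,anger,disgust Integer AU codes required for each display.
#' @param negative How anger and disgust combine: `"max"` (default) or
#'   `"mean"`.
#' @return An object of class `au_rules`.
#' @export
au_rules <- function(happiness = c(6L, 12L), anger = c(4L, 23L),
                     disgust = 9L, negative = c("max", "mean")) {
  negative <- match.arg(negative)
  for (s in list(happiness, anger, disgust)) {
    if (length(s) < 1L || any(s != round(s)) || any(s < 1))
      stop("each required AU set must be a non-empty set of integer AU codes",
           call. = FALSE)
  }
  structure(list(happiness = as.integer(happiness),
                 anger = as.integer(anger),
                 disgust = as.integer(disgust),
                 negative = negative),
            class = "au_rules")
}

#' Read rules from a JSON config file
#'
#' Expected keys: `happiness`, `anger`, `disgust` (integer AU code arrays) and
#' optionally `negative` ("max" or "mean"); omitted keys take the defaults.
#'
#' @param path Path to a JSON file.
#' @return An `au_rules` object.
#' @export
read_au_rules <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- au_rules()
  au_rules(happiness = cfg$happiness %||% d$happiness,
           anger = cfg$anger %||% d$anger,
           disgust = cfg$disgust %||% d$disgust,
           negative = cfg$negative %||% d$negative)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.rules_codes <- function(rules) {
  sort(unique(c(rules$happiness, rules$anger, rules$disgust)))
}

#' Read a per-frame AU intensity table
#'
#' Reads the automated-FACS CSV dialect (`frame, timestamp, confidence,
#' success, AU01_r ... AU45_r`; intensity channels on the 0-5 scale). Rows
#' whose tracking `success` flag is 0 are dropped and counted; binary AU
#' presence columns, if present, are ignored. Column order does not matter.
#'
#' @param source Path to the CSV file, or a data frame already in the dialect.
#' @param rules Active `au_rules`; the file must contain the intensity column
#'   of every AU the rules require.
#' @param quiet Suppress the dropped-row message.
#' @return A data frame of class `au_frames` with columns `timestamp`,
#'   `confidence`, `success`, and the AU intensity columns, one row per
#'   retained frame; the number of dropped rows is attached as attribute
#'   `dropped`.
#' @export
read_au_table <- function(source, rules = au_rules(), quiet = FALSE) {
  df <- if (is.data.frame(source)) source else {
    if (!file.exists(source)) stop("AU table not found: ", source, call. = FALSE)
    utils::read.csv(source, check.names = FALSE)
  }
  names(df) <- trimws(names(df))
  if (nrow(df) == 0L) stop("AU table is empty", call. = FALSE)
  needed <- .au_col(.rules_codes(rules))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("AU table lacks required intensity columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"timestamp" %in% names(df))
    stop("AU table lacks a 'timestamp' column", call. = FALSE)
  if (!"success" %in% names(df)) df$success <- 1L
  if (!"confidence" %in% names(df)) df$confidence <- 1
  keep <- df$success != 0
  dropped <- sum(!keep)
  if (dropped > 0 && !quiet)
    message("read_au_table: dropped ", dropped, " frame(s) with success = 0")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("AU table has no successfully tracked frames", call. = FALSE)
  if (any(df$timestamp < 0)) stop("negative timestamps in AU table", call. = FALSE)
  au_cols <- grep("^AU[0-9]{2}_r$", names(df), value = TRUE)
  out <- df[, c("timestamp", "confidence", "success", au_cols), drop = FALSE]
  rownames(out) <- NULL
  structure(out, dropped = dropped, class = c("au_frames", "data.frame"))
}

#' Score prototypic emotions per frame
#'
#' Pointwise conversion of AU intensities to emotion intensities: each
#' emotion's intensity is the mean of its required AUs; `positive` equals
#' happiness; `negative` combines anger and disgust per the rules. Output
#' length equals input length and permuting frames permutes outputs
#' identically.
#'
#' @param frames An `au_frames` data frame (or any data frame carrying the
#'   required `AUxx_r` columns and `timestamp`).
#' @param rules `au_rules`.
#' @return A data frame of class `emotion_frames` with columns `timestamp`,
#'   `happiness`, `anger`, `disgust`, `positive`, `negative`.
#' @export
score_emotions <- function(frames, rules = au_rules()) {
  needed <- .au_col(.rules_codes(rules))
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols))
    stop("frames lack required AU columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  emo_mean <- function(codes) {
    m <- as.matrix(frames[, .au_col(codes), drop = FALSE])
    rowMeans(m)
  }
  happiness <- emo_mean(rules$happiness)
  anger <- emo_mean(rules$anger)
  disgust <- emo_mean(rules$disgust)
  negative <- if (rules$negative == "max") pmax(anger, disgust)
              else (anger + disgust) / 2
  structure(
    data.frame(timestamp = frames$timestamp,
               happiness = happiness, anger = anger, disgust = disgust,
               positive = happiness, negative = negative),
    class = c("emotion_frames", "data.frame"))
}

#' Windowed emotion intensity around an event
#'
#' Mean positive and negative intensity over frames falling in the closed
#' interval `[t_center - half_width, t_center + half_width]` (the event
#' window, e.g. blast initiation +/- 1 s). An empty window is signalled
#' explicitly rather than silently returned as zero.
#'
#' @param frames An `emotion_frames` data frame.
#' @param t_center Window centre, seconds on the session clock.
#' @param half_width Half width in seconds (> 0), default 1.
#' @return List with `positive`, `negative` (window means, `NA` when empty),
#'   `n_frames`, and `empty`.
#' @export
window_intensity <- function(frames, t_center, half_width = 1) {
  if (half_width <= 0) stop("half_width must be > 0", call. = FALSE)
  sel <- frames$timestamp >= t_center - half_width &
         frames$timestamp <= t_center + half_width
  n <- sum(sel)
  if (n == 0L)
    return(list(positive = NA_real_, negative = NA_real_,
                n_frames = 0L, empty = TRUE))
  list(positive = mean(frames$positive[sel]),
       negative = mean(frames$negative[sel]),
       n_frames = as.integer(n), empty = FALSE)
}

#' Write an AU intensity table in the CSV dialect
#'
#' @param frames An `au_frames` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_au_table <- function(frames, path) {
  df <- as.data.frame(frames)
  df <- cbind(frame = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
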