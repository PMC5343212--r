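#' MVPA minutes from a minute-level accelerometer count stream
#'
#' Scores per-minute activity counts into bout-qualified MVPA minutes: a
#' minute counts toward MVPA when it is worn, its count meets the intensity
#' threshold, and it lies inside a bout of at least `min_bout` such minutes.
#' By default bouts are strict maximal runs of consecutive qualifying minutes
#' (no interruptions tolerated); `max_interruption` allows runs separated by
#' at most that many sub-threshold minutes to be merged into one bout
#' (interruption minutes themselves never count).
#'
#' @param counts Integer-valued per-minute activity counts (>= 0), in
#'   chronological order at one-minute resolution.
#' @param worn Optional logical (or 0/1) wear flags per minute; unworn
#'   minutes never qualify and break bouts. Default: all worn.
#' @param threshold Minimum count for an MVPA minute (default 1952
#'   counts/min, the conventional vertical-axis moderate-intensity cut point).
#' @param min_bout Minimum qualifying minutes per bout (default 10).
#' @param max_interruption Sub-threshold minutes tolerated inside a bout
#'   (default 0).
#' @return Total MVPA minutes (integer-valued).
#' @examples
#' mvpa_minutes(c(rep(2500, 15), rep(0, 45))) # 15
#' mvpa_minutes(c(rep(2500, 9), rep(0, 51)))  # 0 (bout too short)
#' @export
mvpa_minutes <- function(counts, worn = NULL, threshold = 1952,
                         min_bout = 10, max_interruption = 0) {
  if (length(counts) == 0) return(0)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be nonnegative numbers", call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  if (min_bout < 1) stop("`min_bout` must be >= 1", call. = FALSE)
  if (max_interruption < 0) {
    stop("`max_interruption` must be >= 0", call. = FALSE)
  }
  if (is.null(worn)) worn <- rep(TRUE, length(counts))
  if (length(worn) != length(counts)) {
    stop("`worn` must match `counts` in length", call. = FALSE)
  }
  worn <- as.logical(worn)
  active <- worn & counts >= threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  if (length(idx) == 0) return(0)
  # Merge active runs separated by short worn sub-threshold gaps.
  bout_active <- integer(0)
  cur <- r$lengths[idx[1]]
  cur_end <- ends[idx[1]]
  if (length(idx) > 1) {
    for (k in idx[-1]) {
      gap <- starts[k] - cur_end - 1
      gap_worn <- all(worn[(cur_end + 1):(starts[k] - 1)])
      if (gap <= max_interruption && gap_worn) {
        cur <- cur + r$lengths[k]
      } else {
        bout_active <- c(bout_active, cur)
        cur <- r$lengths[k]
      }
      cur_end <- ends[k]
    }
  }
  bout_active <- c(bout_active, cur)
  sum(bout_active[bout_active >= min_bout])
}

#' Wear-time validity of an accelerometer week
#'
#' A participant-week is valid when it has at least 10 hours (600 minutes) of
#' wear on at least 5 days, or at least 3000 total minutes of wear spread
#' over at least 4 days with any wear.
#'
#' @param day_wear_minutes Per-day wear minutes (1-7 days, each in
#'   `[0, 1440]`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' wear_valid(rep(600, 5))  # TRUE
#' wear_valid(rep(750, 4))  # TRUE (3000 minutes over 4 days)
#' wear_valid(rep(1440, 3)) # FALSE
#' @export
wear_valid <- function(day_wear_minutes) {
  if (length(day_wear_minutes) < 1 || length(day_wear_minutes) > 7) {
    stop("supply 1-7 days of wear minutes", call. = FALSE)
  }
  if (any(!is.finite(day_wear_minutes)) || any(day_wear_minutes < 0) ||
      any(day_wear_minutes > 1440)) {
    stop("per-day wear minutes must lie in [0, 1440]", call. = FALSE)
  }
  sum(day_wear_minutes >= 600) >= 5 ||
    (sum(day_wear_minutes) >= 3000 && sum(day_wear_minutes > 0) >= 4)
}

#' Flag non-wear from long runs of zero counts
#'
#' Optional heuristic for streams without wear flags: any run of at least
#' `window` consecutive zero counts is flagged as non-wear.
#'
#' @param counts Per-minute counts.
#' @param window Minimum zero-run length flagged as non-wear (default 60).
#' @return Logical vector of wear flags (`TRUE` = worn).
#' @export
detect_nonwear <- function(counts, window = 60) {
  if (length(counts) == 0) return(logical(0))
  r <- rle(counts == 0)
  flags <- rep(!(r$values & r$lengths >= window), r$lengths)
  flags
}

#' Score a minute-level count-stream table into weekly MVPA minutes
#'
#' Reads the long-format stream (one row per worn-or-not minute per
#' participant), checks one-minute spacing, assigns each minute to a study
#' week (7-day blocks from each participant's first timestamp), and scores
#' MVPA minutes and wear validity per participant-week.
#'
#' @param stream `data.frame` with columns `participant_id`, `timestamp`
#'   (POSIXct or ISO-8601 text at minute resolution), `counts`, and
#'   optionally `worn` (0/1).
#' @inheritParams mvpa_minutes
#' @return `data.frame(participant_id, week, mvpa_minutes, valid)`.
#' @export
score_accelerometry <- function(stream, threshold = 1952, min_bout = 10,
                                max_interruption = 0) {
  required <- c("participant_id", "timestamp", "counts")
  missing_cols <- setdiff(required, names(stream))
  if (length(missing_cols) > 0) {
    stop("stream is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- stream$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in stream", call. = FALSE)
  if (!"worn" %in% names(stream)) stream$worn <- 1L
  out <- lapply(split(seq_len(nrow(stream)), stream$participant_id),
                function(ix) {
    ix <- ix[order(ts[ix])]
    t_i <- ts[ix]
    if (length(ix) > 1) {
      gaps <- as.numeric(diff(t_i), units = "mins")
      same_day <- diff(as.integer(as.Date(t_i, tz = "UTC"))) == 0
      if (any(same_day & abs(gaps - 1) > 1e-6)) {
        stop("stream for participant ", stream$participant_id[ix[1]],
             " is not at one-minute resolution", call. = FALSE)
      }
    }
    day <- floor(as.numeric(t_i - t_i[1], units = "days"))
    week <- day %/% 7L
    res <- lapply(split(seq_along(ix), week), function(jx) {
      wk_worn <- as.logical(stream$worn[ix[jx]])
      wear_by_day <- tapply(wk_worn, day[jx], sum)
      data.frame(
        participant_id = stream$participant_id[ix[1]],
        week = week[jx[1]],
        mvpa_minutes = mvpa_minutes(stream$counts[ix[jx]], wk_worn,
                                    threshold, min_bout, max_interruption),
        valid = wear_valid(pmin(as.numeric(wear_by_day), 1440))
      )
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read a minute-level count stream from CSV
#'
#' @param path CSV with columns `participant_id`, `timestamp` (ISO-8601,
#'   minute resolution), `counts`, and optionally `worn` (0/1).
#' @return `data.frame` with parsed timestamps.
#' @export
read_count_stream <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "timestamp", "counts")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("count-stream file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$timestamp <- as.POSIXct(raw$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                             "%Y-%m-%d %H:%M:%S",
                                             "%Y-%m-%dT%H:%M",
                                             "%Y-%m-%d %H:%M"))
  if (anyNA(raw$timestamp)) {
    stop("unparseable timestamps in ", path, call. = FALSE)
  }
  raw
}
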