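#' @title Roster, sleep-log and rating file handling
#' @description Readers, writers and validators for the three delimited-text
#'   schemas used throughout the package. All internal times are decimal
#'   hours on the home-base clock, measured from the log's first midnight;
#'   ISO-8601 timestamps are converted on ingest. Episodes are half-open
#'   intervals `[start, end)`.
#' @name roster_io
NULL

# decimal hours from the first midnight; accepts numeric strings or ISO-8601
.parse_times <- function(x, origin = NULL) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(list(hours = num, origin = origin))
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) stop("times must be decimal hours or ISO-8601 timestamps")
  if (is.null(origin)) origin <- trunc(min(ts), units = "days")
  list(hours = as.numeric(difftime(ts, origin, units = "hours")),
       origin = origin)
}

#' Read and validate a duty file
#'
#' Schema: `start,end,dep_tz,arr_tz,label` with times as decimal hours or
#' ISO-8601. Duties must have `start < end`, must not overlap, and
#' time-zone offsets must lie in `(-12, 12]`.
#'
#' @param path CSV file path.
#' @return Validated duty data frame.
#' @export
read_duties <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "dep_tz", "arr_tz")
  if (!all(need %in% names(d))) {
    stop("duty file must have columns: ", paste(need, collapse = ", "))
  }
  org <- NULL
  st <- .parse_times(d$start); org <- st$origin
  en <- .parse_times(d$end, org)
  d$start <- st$hours; d$end <- en$hours
  if (!"label" %in% names(d)) d$label <- "duty"
  validate_duties(d)
}

#' @rdname read_duties
#' @param duties Duty data frame to validate.
#' @export
validate_duties <- function(duties) {
  bad <- which(duties$end <= duties$start)
  if (length(bad)) {
    stop("duty start must precede end at row(s): ", paste(bad, collapse = ", "))
  }
  bad_tz <- which(duties$dep_tz <= -12 | duties$dep_tz > 12 |
                    duties$arr_tz <= -12 | duties$arr_tz > 12)
  if (length(bad_tz)) {
    stop("time-zone offsets outside (-12, 12] at row(s): ",
         paste(bad_tz, collapse = ", "))
  }
  ord <- order(duties$start)
  ds <- duties[ord, , drop = FALSE]
  if (nrow(ds) > 1) {
    ov <- which(ds$start[-1] < ds$end[-nrow(ds)])
    if (length(ov)) {
      stop("overlapping duties at row(s): ",
           paste(ord[ov + 1], collapse = ", "))
    }
    # consistent transitions: next departure zone matches previous arrival
    if (all(c("dep_tz", "arr_tz") %in% names(ds))) {
      mism <- which(ds$dep_tz[-1] != ds$arr_tz[-nrow(ds)])
      if (length(mism)) {
        warning("departure time zone differs from previous arrival at row(s): ",
                paste(ord[mism + 1], collapse = ", "))
      }
    }
  }
  duties
}

#' Read and validate a sleep log
#'
#' Schema: `start,end[,provenance]`. Episodes must have `start < end` and
#' must not overlap.
#'
#' @param path CSV file path.
#' @return Validated sleep data frame (`start`, `end`, `provenance`).
#' @export
read_sleep_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start", "end") %in% names(d))) {
    stop("sleep log must have columns: start, end")
  }
  st <- .parse_times(d$start)
  en <- .parse_times(d$end, st$origin)
  d$start <- st$hours; d$end <- en$hours
  if (!"provenance" %in% names(d)) d$provenance <- "observed"
  validate_sleep(d)
}

#' @rdname read_sleep_log
#' @param sleep Sleep data frame to validate.
#' @export
validate_sleep <- function(sleep) {
  bad <- which(sleep$end <= sleep$start)
  if (length(bad)) {
    stop("sleep end before start at row(s): ", paste(bad, collapse = ", "))
  }
  ord <- order(sleep$start)
  ss <- sleep[ord, , drop = FALSE]
  if (nrow(ss) > 1) {
    ov <- which(ss$start[-1] < ss$end[-nrow(ss)])
    if (length(ov)) {
      stop("overlapping sleep episodes at row(s): ",
           paste(ord[ov + 1], collapse = ", "))
    }
  }
  sleep
}

#' Read and validate KSS rating records
#'
#' Schema: `time,kss,subject_id[,circadian_type]`; KSS must be an integer
#' 1-9.
#'
#' @param path CSV file path.
#' @return Validated ratings data frame.
#' @export
read_ratings <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "kss", "subject_id")
  if (!all(need %in% names(d))) {
    stop("ratings file must have columns: ", paste(need, collapse = ", "))
  }
  d$time <- .parse_times(d$time)$hours
  bad <- which(!(d$kss %in% 1:9))
  if (length(bad)) {
    stop("KSS outside 1..9 at row(s): ", paste(bad, collapse = ", "))
  }
  d
}

#' Read a full roster (duties + sleep log + ratings)
#'
#' @param duties,sleep,ratings CSV file paths (any may be `NULL`).
#' @return A list of class `tpm_roster` with the validated components.
#' @export
read_roster <- function(duties = NULL, sleep = NULL, ratings = NULL) {
  out <- list(
    duties = if (!is.null(duties)) read_duties(duties),
    sleep = if (!is.null(sleep)) read_sleep_log(sleep),
    ratings = if (!is.null(ratings)) read_ratings(ratings)
  )
  class(out) <- "tpm_roster"
  out
}

#' Write roster components as CSV
#'
#' Inverse of the readers; `read_*` after `write_*` reproduces the parsed
#' representation.
#'
#' @param x Data frame (duties, sleep or ratings).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_roster_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Apply the analysis selection rules to ratings
#'
#' Two rules give the model a reliable starting state and bound
#' extrapolation: ratings are analyzed only when the sleep history holds at
#' least two completed sleeps (ratings before the end of the second sleep
#' are excluded as warm-up) and only up to 16 hours after the end of the
#' last logged sleep.
#'
#' @param ratings Ratings data frame (`time`, ...).
#' @param sleep Sleep episode data frame (`start`, `end`).
#' @return List: `ratings` (the included subset) and `exclusions` (data
#'   frame of excluded row numbers and reasons).
#' @export
apply_selection_rules <- function(ratings, sleep) {
  if (is.null(ratings) || nrow(ratings) == 0) {
    return(list(ratings = ratings, exclusions = data.frame(
      row = integer(0), reason = character(0))))
  }
  sleep <- sleep[order(sleep$start), , drop = FALSE]
  warmup_end <- if (nrow(sleep) >= 2) sleep$end[2] else Inf
  last_end <- if (nrow(sleep)) max(sleep$end) else -Inf
  reason <- rep(NA_character_, nrow(ratings))
  reason[ratings$time < warmup_end] <- "before end of second sleep"
  late <- ratings$time > last_end + 16
  reason[late & is.na(reason)] <- "more than 16 h after last sleep"
  keep <- is.na(reason)
  list(
    ratings = ratings[keep, , drop = FALSE],
    exclusions = data.frame(row = which(!keep),
                            reason = reason[!keep])
  )
}

#' Expand a log to a per-segment state grid
#'
#' Splits a window into half-open segments of `step` hours and assigns each
#' segment the state of the episode covering its start: `sleep`,
#' `duty-wake` (awake during a duty) or `wake`. A boundary instant belongs
#' to the following episode.
#'
#' @param sleep Sleep episode data frame, or `NULL`.
#' @param duties Duty data frame, or `NULL`.
#' @param from,to Window (defaults to the span of the episodes).
#' @param step Segment length in hours (default 5 minutes).
#' @return Data frame: `time` (segment start) and `state`.
#' @export
to_grid <- function(sleep = NULL, duties = NULL, from = NULL, to = NULL,
                    step = 1 / 12) {
  lo <- c(if (!is.null(sleep) && nrow(sleep)) sleep$start,
          if (!is.null(duties) && nrow(duties)) duties$start)
  hi <- c(if (!is.null(sleep) && nrow(sleep)) sleep$end,
          if (!is.null(duties) && nrow(duties)) duties$end)
  if (is.null(from)) from <- min(lo)
  if (is.null(to)) to <- max(hi)
  times <- from + seq(0, to - from - step / 2, by = step)
  state <- rep("wake", length(times))
  if (!is.null(duties)) {
    for (k in seq_len(nrow(duties))) {
      state[times >= duties$start[k] & times < duties$end[k]] <- "duty-wake"
    }
  }
  if (!is.null(sleep)) {
    for (k in seq_len(nrow(sleep))) {
      state[times >= sleep$start[k] & times < sleep$end[k]] <- "sleep"
    }
  }
  data.frame(time = times, state = state)
}
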