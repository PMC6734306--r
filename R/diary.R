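#' Construct a headache diary
#'
#' A diary is one subject's ordered record of consecutive days, each flagged
#' for migraine and for menstrual bleeding. Day indices are 1-based and
#' strictly consecutive; all windowing, trimming and testing in this package
#' operate on this object.
#'
#' @param subject_id character scalar identifying the subject.
#' @param migraine logical (or 0/1) vector, one element per day: migraine
#'   present on that day.
#' @param bleeding logical (or 0/1) vector of the same length: menstrual
#'   bleeding on that day.
#' @param age optional subject age in years, kept as metadata.
#' @return An object of class \code{mm_diary}: a list with elements
#'   \code{subject_id}, \code{days} (a data frame with columns
#'   \code{day_index}, \code{migraine}, \code{bleeding}) and \code{meta}.
#' @examples
#' d <- mm_diary("s1", migraine = c(0, 1, 1, 1, 0, 0, 0, 1, 1),
#'               bleeding = c(0, 0, 0, 1, 1, 1, 0, 0, 0))
#' detect_windows(d)
#' @export
mm_diary <- function(subject_id, migraine, bleeding, age = NULL) {
  if (length(subject_id) != 1L || is.na(subject_id))
    stop("'subject_id' must be a single non-missing value")
  migraine <- as_flag(migraine, "migraine")
  bleeding <- as_flag(bleeding, "bleeding")
  if (length(migraine) != length(bleeding))
    stop("'migraine' and 'bleeding' must have the same length")
  if (length(migraine) == 0L)
    stop("a diary must contain at least one day")
  d <- list(
    subject_id = as.character(subject_id),
    days = data.frame(
      day_index = seq_along(migraine),
      migraine = migraine,
      bleeding = bleeding
    ),
    meta = list(age = if (is.null(age)) NA_real_ else as.numeric(age))
  )
  class(d) <- "mm_diary"
  d
}

# coerce a 0/1 or logical flag column, rejecting anything else
as_flag <- function(x, what) {
  if (is.logical(x)) {
    if (anyNA(x)) stop("missing values in '", what, "' flags")
    return(x)
  }
  x <- suppressWarnings(as.numeric(x))
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop("'", what, "' flags must be 0/1 or logical")
  x == 1
}

#' @export
print.mm_diary <- function(x, ...) {
  nd <- nrow(x$days)
  cat(sprintf(
    "<mm_diary> subject %s: %d days, %d migraine days, %d bleeding days\n",
    x$subject_id, nd, sum(x$days$migraine), sum(x$days$bleeding)
  ))
  invisible(x)
}

#' @export
length.mm_diary <- function(x) nrow(x$days)

# internal: subset a diary to a day interval [from, to] and re-anchor at 1
subset_diary <- function(diary, from, to) {
  keep <- diary$days$day_index >= from & diary$days$day_index <= to
  d <- diary
  d$days <- diary$days[keep, , drop = FALSE]
  d$days$day_index <- seq_len(nrow(d$days))
  rownames(d$days) <- NULL
  d
}

#' Read headache diaries from a CSV file
#'
#' The expected format has a header
#' \code{subject_id,day_index,migraine,bleeding[,age]} with flags encoded
#' 0/1, one row per subject-day, rows for a subject contiguous and sorted by
#' \code{day_index}. Day indices must be consecutive integers starting at 1;
#' a subject violating this is rejected (dropped with a message) rather than
#' silently repaired, since a gap means the diary has missing days.
#'
#' @param source path to a CSV file (or a connection).
#' @return A list of \code{mm_diary} objects, named by subject id. Rejected
#'   subjects are recorded in the \code{"rejected"} attribute, a data frame
#'   with columns \code{subject_id} and \code{reason}.
#' @seealso [write_diaries()] for the inverse operation.
#' @export
read_diaries <- function(source) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("subject_id", "day_index", "migraine", "bleeding")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop("diary file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- list()
    attr(out, "rejected") <- data.frame(subject_id = character(),
                                        reason = character())
    return(out)
  }
  day_index <- suppressWarnings(as.integer(raw$day_index))
  bad <- which(is.na(day_index) | is.na(raw$subject_id) | raw$subject_id == "")
  if (length(bad) > 0L)
    stop("malformed diary row at line ", bad[1L] + 1L,
         " (counting the header as line 1)")
  bad_flag <- which(!(raw$migraine %in% c("0", "1", "TRUE", "FALSE")) |
                    !(raw$bleeding %in% c("0", "1", "TRUE", "FALSE")))
  if (length(bad_flag) > 0L)
    stop("non-boolean migraine/bleeding flag at line ", bad_flag[1L] + 1L,
         " (counting the header as line 1)")
  has_age <- "age" %in% names(raw)

  ids <- unique(raw$subject_id)
  out <- list()
  rejected <- data.frame(subject_id = character(), reason = character())
  for (id in ids) {
    rows <- raw[raw$subject_id == id, , drop = FALSE]
    di <- as.integer(rows$day_index)
    if (!identical(di, seq_len(nrow(rows)))) {
      reason <- "day_index not consecutive from 1"
      message("read_diaries: rejecting subject '", id, "': ", reason)
      rejected <- rbind(rejected,
                        data.frame(subject_id = id, reason = reason))
      next
    }
    age <- if (has_age) suppressWarnings(as.numeric(rows$age[1L])) else NULL
    out[[id]] <- mm_diary(id,
                          migraine = rows$migraine %in% c("1", "TRUE"),
                          bleeding = rows$bleeding %in% c("1", "TRUE"),
                          age = age)
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write headache diaries to a CSV file
#'
#' Inverse of [read_diaries()]: \code{read_diaries(write_diaries(x, f))}
#' reproduces \code{x}. An \code{age} column is emitted when any diary
#' carries a non-missing age.
#'
#' @param diaries a list of \code{mm_diary} objects.
#' @param sink path to the output CSV file (or a connection).
#' @return Invisibly, the path/connection written to.
#' @export
write_diaries <- function(diaries, sink) {
  ages <- vapply(diaries, function(d) d$meta$age, numeric(1))
  with_age <- any(!is.na(ages))
  rows <- lapply(diaries, function(d) {
    df <- data.frame(subject_id = d$subject_id,
                     day_index = d$days$day_index,
                     migraine = as.integer(d$days$migraine),
                     bleeding = as.integer(d$days$bleeding))
    if (with_age) df$age <- d$meta$age
    df
  })
  tab <- if (length(rows) == 0L) {
    df <- data.frame(subject_id = character(), day_index = integer(),
                     migraine = integer(), bleeding = integer())
    if (with_age) df$age <- numeric()
    df
  } else {
    do.call(rbind, rows)
  }
  utils::write.csv(tab, sink, row.names = FALSE, quote = FALSE)
  invisible(sink)
}

#' Locate 5-day menstrual windows in a diary
#'
#' A menstruation onset is a bleeding day whose immediately preceding diary
#' day is not a bleeding day (the first diary day counts as an onset when it
#' is a bleeding day, but the window is then flagged partial since the true
#' onset may be unobserved). Each onset anchors the 5-day menstrual window
#' spanning two days before through two days after the onset (bleeding day
#' 1 +/- 2), clipped to the diary extent. Consecutive bleeding days belong
#' to a single bleed and contribute one window regardless of bleed length.
#'
#' @param diary an \code{mm_diary}.
#' @return A data frame with one row per onset, columns \code{onset_day},
#'   \code{start}, \code{end} (closed day-index interval) and \code{partial}
#'   (\code{TRUE} when the window was clipped at a diary boundary).
#' @examples
#' d <- mm_diary("s1", migraine = rep(0, 9),
#'               bleeding = c(0, 0, 0, 1, 1, 1, 0, 0, 0))
#' detect_windows(d)  # onset day 4, window days 2..6
#' @export
detect_windows <- function(diary) {
  b <- diary$days$bleeding
  nd <- length(b)
  onset <- which(b & !c(FALSE, b[-nd]))
  if (length(onset) == 0L)
    return(data.frame(onset_day = integer(), start = integer(),
                      end = integer(), partial = logical()))
  start <- pmax(1L, onset - 2L)
  end <- pmin(nd, onset + 2L)
  data.frame(
    onset_day = onset,
    start = start,
    end = end,
    partial = (onset - 2L < 1L) | (onset + 2L > nd)
  )
}

#' Days covered by a set of menstrual windows
#'
#' Returns the union of the window day-indices. Overlapping windows (onsets
#' fewer than five days apart) are merged by set union for day
#' classification, while each onset still counts as one window for the
#' two-out-of-three criterion denominator.
#'
#' @param windows a data frame as returned by [detect_windows()].
#' @param n_days diary length, used only to validate bounds.
#' @return Sorted integer vector of day indices lying in any window.
#' @export
window_days <- function(windows, n_days) {
  if (nrow(windows) == 0L) return(integer())
  days <- unlist(mapply(seq.int, windows$start, windows$end,
                        SIMPLIFY = FALSE))
  days <- sort(unique(days))
  days[days >= 1L & days <= n_days]
}

# internal: logical mask over diary days for window membership
window_mask <- function(windows, n_days) {
  m <- logical(n_days)
  m[window_days(windows, n_days)] <- TRUE
  m
}
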