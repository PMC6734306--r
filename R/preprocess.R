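#' Menstrual cycle lengths of a diary
#'
#' A cycle runs from one menstruation onset to the next; its length in days
#' is the difference of the two onset day-indices. Diaries with fewer than
#' two onsets have no measurable cycle.
#'
#' @param diary an \code{mm_diary}.
#' @return Data frame with columns \code{start_onset}, \code{end_onset},
#'   \code{length_days}, one row per consecutive onset pair, in diary order.
#' @export
cycle_lengths <- function(diary) {
  onsets <- detect_windows(diary)$onset_day
  if (length(onsets) < 2L)
    return(data.frame(start_onset = integer(), end_onset = integer(),
                      length_days = integer()))
  data.frame(
    start_onset = onsets[-length(onsets)],
    end_onset = onsets[-1L],
    length_days = diff(onsets)
  )
}

new_report <- function(subject_id, excluded, reason, range = c(NA, NA),
                       imputed = 0L, n_cycles = 0L) {
  r <- list(subject_id = subject_id, excluded = excluded,
            exclusion_reason = reason,
            retained_day_range = as.integer(range),
            imputed_locked_days = as.integer(imputed),
            n_cycles = as.integer(n_cycles))
  class(r) <- "mm_preprocess_report"
  r
}

#' @export
print.mm_preprocess_report <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<preprocess> subject %s: EXCLUDED (%s)\n",
                x$subject_id, x$exclusion_reason))
  } else {
    cat(sprintf(
      "<preprocess> subject %s: retained days %d..%d (%d cycles), %d locked day(s) imputed\n",
      x$subject_id, x$retained_day_range[1], x$retained_day_range[2],
      x$n_cycles, x$imputed_locked_days))
  }
  invisible(x)
}

#' Remove atypically long menstrual cycles
#'
#' Cycles longer than twice the subject's individual mean cycle length are
#' taken to represent missing diary data. The individual mean is computed
#' once over all of the subject's cycles (candidates for removal included).
#' After flagging, the longest remaining run of at least three consecutive
#' typical cycles is retained (ties broken toward the earliest run) and the
#' diary is cut to that run, with a 15-day margin on each side so that the
#' later truncation step keeps its usual context. When no such run exists
#' the diary is excluded.
#'
#' @param diary an \code{mm_diary}.
#' @param cycles cycles of \code{diary}, as from [cycle_lengths()].
#' @return A list with elements \code{diary} (the retained, re-anchored
#'   \code{mm_diary}, or \code{NULL} when excluded) and \code{report} (an
#'   \code{mm_preprocess_report}).
#' @export
drop_atypical_cycles <- function(diary, cycles = cycle_lengths(diary)) {
  id <- diary$subject_id
  if (nrow(cycles) < 3L) {
    return(list(diary = NULL,
                report = new_report(id, TRUE, "too_few_cycles",
                                    n_cycles = nrow(cycles))))
  }
  atypical <- cycles$length_days > 2 * mean(cycles$length_days)
  if (!any(atypical)) {
    return(list(diary = diary,
                report = new_report(id, FALSE, "none",
                                    range = range(diary$days$day_index),
                                    n_cycles = nrow(cycles))))
  }
  runs <- rle(!atypical)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  valid <- runs$values & runs$lengths >= 3L
  if (!any(valid)) {
    return(list(diary = NULL,
                report = new_report(id, TRUE, "atypical_unsalvageable",
                                    n_cycles = nrow(cycles))))
  }
  best <- which(valid)[which.max(runs$lengths[valid])]
  first_cycle <- starts[best]
  last_cycle <- ends[best]
  nd <- nrow(diary$days)
  from <- max(1L, cycles$start_onset[first_cycle] - 15L)
  to <- min(nd, cycles$end_onset[last_cycle] + 15L)
  kept <- subset_diary(diary, from, to)
  list(diary = kept,
       report = new_report(id, FALSE, "none", range = c(from, to),
                           n_cycles = last_cycle - first_cycle + 1L))
}

#' Truncate a diary around its observed bleeding span
#'
#' Removes days more than 15 days before the first, or more than 15 days
#' after the last, registered bleeding day, so that no migraine can be
#' mis-attributed relative to an unobserved menstruation. Day indices are
#' re-anchored at 1.
#'
#' @param diary an \code{mm_diary} with at least one bleeding day.
#' @return The truncated \code{mm_diary}; the original day interval kept is
#'   stored in the \code{"retained_range"} attribute.
#' @export
truncate_diary <- function(diary) {
  b <- which(diary$days$bleeding)
  if (length(b) == 0L)
    stop("diary has no bleeding days and cannot be truncated or analysed")
  nd <- nrow(diary$days)
  from <- max(1L, min(b) - 15L)
  to <- min(nd, max(b) + 15L)
  out <- subset_diary(diary, from, to)
  attr(out, "retained_range") <- c(from, to)
  out
}

#' Impute migraine-locked days
#'
#' A migraine-locked day is a non-migraine day whose immediate predecessor
#' and successor are both migraine days; under the 48-hour relapse rule such
#' a day belongs to a single ongoing attack and is imputed as a migraine
#' day. Imputation is applied iteratively to a fixed point, so alternating
#' patterns like M.M.M fill completely.
#'
#' @param diary an \code{mm_diary}.
#' @return List with elements \code{diary} (imputed) and \code{n_imputed}.
#' @export
impute_locked_days <- function(diary) {
  m <- diary$days$migraine
  nd <- length(m)
  n_imputed <- 0L
  repeat {
    locked <- !m & c(FALSE, m[-nd]) & c(m[-1L], FALSE)
    if (!any(locked)) break
    m[locked] <- TRUE
    n_imputed <- n_imputed + sum(locked)
  }
  diary$days$migraine <- m
  list(diary = diary, n_imputed = n_imputed)
}

#' Eligibility of a diary for analysis
#'
#' A diary is eligible when, after atypical-cycle handling, it still
#' contains at least three consecutive typical menstrual cycles.
#'
#' @param diary an \code{mm_diary}.
#' @return An \code{mm_preprocess_report} (the diary itself is unchanged).
#' @export
eligibility <- function(diary) {
  drop_atypical_cycles(diary)$report
}

#' Full preprocessing pipeline for one diary
#'
#' Applies, in order: cycle extraction, atypical-cycle removal with the
#' three-consecutive-cycles eligibility rule, truncation to 15 days around
#' the observed bleeding span, and migraine-locked-day imputation. The
#' pipeline is idempotent: running it on its own output changes nothing.
#'
#' @param diary an \code{mm_diary}.
#' @return A list with elements \code{diary} (preprocessed \code{mm_diary},
#'   or \code{NULL} when the subject is excluded) and \code{report}.
#' @export
preprocess_diary <- function(diary) {
  step1 <- drop_atypical_cycles(diary)
  if (step1$report$excluded) return(step1)
  d <- truncate_diary(step1$diary)
  imp <- impute_locked_days(d)
  rep <- step1$report
  # compose retained range back to original day indices
  tr <- attr(d, "retained_range")
  rep$retained_day_range <-
    as.integer(rep$retained_day_range[1L] + tr - 1L)
  rep$imputed_locked_days <- imp$n_imputed
  list(diary = imp$diary, report = rep)
}

#' Summarise preprocessing reports across subjects
#'
#' @param reports list of \code{mm_preprocess_report} objects.
#' @return Data frame with one row per subject (id, excluded, reason,
#'   retained range, imputed count, cycle count).
#' @export
preprocess_summary <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(subject_id = r$subject_id,
               excluded = r$excluded,
               exclusion_reason = r$exclusion_reason,
               retained_from = r$retained_day_range[1L],
               retained_to = r$retained_day_range[2L],
               imputed_locked_days = r$imputed_locked_days,
               n_cycles = r$n_cycles)
  }))
}
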