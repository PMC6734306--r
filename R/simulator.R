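#' Layout of a simulated diary
#'
#' Each cycle consists of \code{cycle_length_days - 5} non-window days
#' followed by the 5-day menstrual window (for the default 28-day cycle:
#' 23 + 5 days), with \code{tail_days} extra windowless days after the last
#' full cycle. Bleeding onset falls on the window's middle day so that the
#' window is exactly onset +/- 2 and [detect_windows()] recovers the layout
#' from the written bleeding flags.
#'
#' @param n_cycles number of full cycles (= number of menstrual windows).
#' @param cycle_length_days days per cycle, at least 15; default 28.
#' @param tail_days windowless days appended after the last cycle;
#'   default 10.
#' @return Object of class \code{mm_layout} with the arguments plus
#'   \code{n_days}, \code{onset_days}, \code{window} (logical day mask) and
#'   \code{bleeding} (logical day mask, onset day plus two bleeding days).
#' @export
diary_layout <- function(n_cycles, cycle_length_days = 28L, tail_days = 10L) {
  n_cycles <- as.integer(n_cycles)
  cycle_length_days <- as.integer(cycle_length_days)
  tail_days <- as.integer(tail_days)
  if (n_cycles < 1L) stop("'n_cycles' must be at least 1")
  if (cycle_length_days < 15L) stop("'cycle_length_days' must be >= 15")
  if (tail_days < 0L) stop("'tail_days' must be non-negative")
  n_days <- n_cycles * cycle_length_days + tail_days
  window_start <- (seq_len(n_cycles) - 1L) * cycle_length_days +
    cycle_length_days - 4L
  onset_days <- window_start + 2L
  window <- logical(n_days)
  for (s in window_start) window[s:(s + 4L)] <- TRUE
  bleeding <- logical(n_days)
  for (o in onset_days) bleeding[o:(o + 2L)] <- TRUE
  structure(list(n_cycles = n_cycles,
                 cycle_length_days = cycle_length_days,
                 tail_days = tail_days,
                 n_days = n_days,
                 onset_days = onset_days,
                 window = window,
                 bleeding = bleeding),
            class = "mm_layout")
}

#' Simulate one diary from the Markov attack model
#'
#' Day-by-day chain: from the susceptible state an attack starts with
#' probability \code{mu_m} on window days and \code{mu_nm} elsewhere (equal
#' for a null subject); an ongoing attack continues with probability
#' \code{delta}, independent of menstrual state, and the day after it ends
#' the subject is susceptible again. The simulator writes only the
#' migraine and bleeding flags; day classification is entirely the job of
#' the downstream trimming code.
#'
#' Uses the current R random number stream; seed with [set.seed()] or use
#' [sample_population()] for reproducible cohorts.
#'
#' @param params a \code{markov_params}.
#' @param layout an \code{mm_layout}.
#' @param subject_id id for the simulated diary.
#' @return An \code{mm_diary}.
#' @examples
#' set.seed(1)
#' d <- simulate_diary(markov_params(mu = 0.083, delta = 0.444),
#'                     diary_layout(n_cycles = 4))
#' diagnose_diary(d)
#' @export
simulate_diary <- function(params, layout, subject_id = "sim") {
  stopifnot(inherits(layout, "mm_layout"))
  nd <- layout$n_days
  onset_p <- ifelse(layout$window, params$mu_m, params$mu_nm)
  u <- stats::runif(nd)
  m <- logical(nd)
  prev <- FALSE
  for (d in seq_len(nd)) {
    m[d] <- if (prev) u[d] < params$delta else u[d] < onset_p[d]
    prev <- m[d]
  }
  mm_diary(subject_id, migraine = m, bleeding = layout$bleeding)
}

#' Specification of a simulated two-arm population
#'
#' Describes a cohort of diaries with a true menstrual association
#' (positives, distinct \code{mu_nm} and \code{mu_m}) and without one
#' (negatives, flat \code{mu}). Defaults are the empirical subgroup means
#' of a clinical diary cohort: positives drawn at the means of the women
#' fulfilling both diagnostic criteria (\code{mu_nm} = 0.045,
#' \code{mu_m} = 0.244 per day) and negatives at the mean of women
#' fulfilling neither (\code{mu} = 0.083), with per-day continuation
#' \code{delta} = 0.444 (mean attack duration 1.8 days). Parameters are
#' point masses by default; \code{sd_log > 0} adds a log-normal
#' between-subject spread (values clipped to [0, 1]).
#'
#' @param n_diaries diaries per arm.
#' @param positive \code{markov_params} for the association arm.
#' @param negative \code{markov_params} for the null arm.
#' @param seed integer seed fixing the whole output stream.
#' @param sd_log standard deviation of log-normal parameter spread
#'   (0 = point masses).
#' @return Object of class \code{mm_popspec}.
#' @export
population_spec <- function(n_diaries,
                            positive = markov_params(mu_nm = 0.045,
                                                     mu_m = 0.244,
                                                     delta = 0.444),
                            negative = markov_params(mu = 0.083,
                                                     delta = 0.444),
                            seed = 1L,
                            sd_log = 0) {
  structure(list(n_diaries = as.integer(n_diaries),
                 positive = positive, negative = negative,
                 seed = as.integer(seed), sd_log = sd_log),
            class = "mm_popspec")
}

# one log-normal multiplicative draw per parameter, clipped into [0, 1]
jitter_params <- function(params, sd_log) {
  if (sd_log <= 0) return(params)
  jit <- function(x) min(1, max(0, x * exp(stats::rnorm(1L, 0, sd_log))))
  markov_params(mu_nm = jit(params$mu_nm), mu_m = jit(params$mu_m),
                delta = jit(params$delta))
}

#' Simulate a labelled two-arm diary population
#'
#' Generates \code{n_diaries} true-positive and \code{n_diaries}
#' true-negative diaries under the given layout. Each diary gets its own
#' RNG substream derived from the spec seed and the diary index, so the
#' output is reproducible and independent of evaluation order.
#'
#' @param spec an \code{mm_popspec}.
#' @param layout an \code{mm_layout}.
#' @return List with \code{diaries} (list of \code{mm_diary}) and
#'   \code{labels} (logical vector, \code{TRUE} for the association arm).
#' @export
sample_population <- function(spec, layout) {
  n <- spec$n_diaries
  total <- 2L * n
  set.seed(spec$seed)
  sub_seeds <- sample.int(2147483646L, total)
  diaries <- vector("list", total)
  labels <- rep(c(TRUE, FALSE), each = n)
  for (i in seq_len(total)) {
    set.seed(sub_seeds[i])
    base <- if (labels[i]) spec$positive else spec$negative
    par_i <- jitter_params(base, spec$sd_log)
    id <- sprintf("%s_%04d", if (labels[i]) "tp" else "tn",
                  if (labels[i]) i else i - n)
    diaries[[i]] <- simulate_diary(par_i, layout, subject_id = id)
  }
  list(diaries = diaries, labels = labels)
}
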