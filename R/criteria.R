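#' Statistical menstrual migraine diagnosis, sMM(alpha)
#'
#' Applies the one-sided mid-p exact test to the trimmed (onset-based)
#' contingency counts of a diary and declares the subject sMM-positive when
#' the p-value falls below \code{alpha}. Any \code{alpha < 0.5} defines a
#' member of the sMM family; the test's specificity on subjects without a
#' true menstruation-migraine association is \code{1 - alpha} by
#' construction.
#'
#' @param diary a preprocessed \code{mm_diary}.
#' @param alpha significance cut-off in (0, 0.5); default 0.1.
#' @return List with \code{subject_id}, \code{counts}, \code{p},
#'   \code{p_plain}, \code{evaluable}, \code{alpha}, \code{smm_positive}.
#'   A non-evaluable diary is never positive.
#' @export
smm_diagnose <- function(diary, alpha = 0.1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must lie strictly between 0 and 0.5")
  counts <- trimmed_counts(diary)
  mid <- midp_value(counts)
  list(subject_id = diary$subject_id,
       counts = counts,
       p = mid$p,
       p_plain = mid$p_plain,
       evaluable = mid$evaluable,
       alpha = alpha,
       smm_positive = isTRUE(mid$evaluable && mid$p < alpha))
}

#' Two-out-of-three window criterion (2/3MRM)
#'
#' The ICHD-style rule: positive when a migraine attack started within at
#' least two thirds of the recorded menstrual windows. "Started within"
#' means an ATTACK_START day lies inside the window; mere overlap of an
#' ongoing attack does not count. Every onset contributes one window to the
#' denominator even when neighbouring windows overlap. At least three
#' windows are required for the criterion to be assessable.
#'
#' @param diary a preprocessed \code{mm_diary}.
#' @param threshold fraction of windows that must contain an onset;
#'   default 2/3 (the canonical rule).
#' @return List with \code{subject_id}, \code{windows_total},
#'   \code{windows_with_onset}, \code{fraction}, \code{assessable} and
#'   \code{two_thirds_positive} (\code{NA} when fewer than 3 windows).
#' @export
two_thirds_diagnose <- function(diary, threshold = 2 / 3) {
  windows <- detect_windows(diary)
  states <- classify_days(diary)
  onset_days <- which(states == "ATTACK_START")
  hit <- vapply(seq_len(nrow(windows)), function(i) {
    any(onset_days >= windows$start[i] & onset_days <= windows$end[i])
  }, logical(1))
  total <- nrow(windows)
  assessable <- total >= 3L
  frac <- if (total > 0L) sum(hit) / total else 0
  list(subject_id = diary$subject_id,
       windows_total = total,
       windows_with_onset = sum(hit),
       fraction = frac,
       assessable = assessable,
       two_thirds_positive = if (assessable) frac >= threshold else NA)
}

#' Construct Markov attack-model parameters
#'
#' The two-state model: on a susceptible day an attack starts with per-day
#' probability \code{mu} (or \code{mu_m} on window days and \code{mu_nm}
#' elsewhere, when the subject has a menstrual association); on an attack
#' day the attack continues with probability \code{delta}, so attack
#' durations are geometric with mean \code{1 / (1 - delta)} days.
#'
#' @param mu flat per-day onset probability (no menstrual modulation).
#'   When given alone, \code{mu_nm} and \code{mu_m} default to it.
#' @param mu_nm onset probability outside menstrual windows.
#' @param mu_m onset probability inside menstrual windows.
#' @param delta per-day continuation probability of an ongoing attack.
#' @return Object of class \code{markov_params} with fields \code{mu},
#'   \code{mu_nm}, \code{mu_m}, \code{delta}, \code{delta_mu}.
#' @examples
#' markov_params(mu = 0.083, delta = 0.444)               # null subject
#' markov_params(mu_nm = 0.045, mu_m = 0.244, delta = 0.444)
#' @export
markov_params <- function(mu = NULL, mu_nm = NULL, mu_m = NULL, delta) {
  if (is.null(mu_nm) != is.null(mu_m))
    stop("supply both of 'mu_nm' and 'mu_m', or neither")
  if (is.null(mu) && is.null(mu_nm))
    stop("supply 'mu', or 'mu_nm' and 'mu_m'")
  if (is.null(mu_nm)) {
    mu_nm <- mu
    mu_m <- mu
  }
  if (is.null(mu)) mu <- NA_real_
  vals <- c(mu = mu, mu_nm = mu_nm, mu_m = mu_m, delta = delta)
  if (any(!is.na(vals) & (vals < 0 | vals > 1)))
    stop("all Markov parameters must lie in [0, 1]")
  structure(list(mu = mu, mu_nm = mu_nm, mu_m = mu_m, delta = delta,
                 delta_mu = mu_m - mu_nm),
            class = "markov_params")
}

#' @export
print.markov_params <- function(x, ...) {
  cat(sprintf(
    "<markov_params> mu=%s mu_nm=%s mu_m=%s (delta_mu=%s), delta=%s\n",
    format(x$mu, digits = 4), format(x$mu_nm, digits = 4),
    format(x$mu_m, digits = 4), format(x$delta_mu, digits = 4),
    format(x$delta, digits = 4)))
  invisible(x)
}

#' Estimate the Markov attack-model parameters from a diary
#'
#' Moment estimates from the trimmed classification: \code{mu = n/N},
#' \code{mu_m = k/K}, \code{mu_nm = (n-k)/(N-K)} from the onset-based
#' counts, and \code{delta} as the fraction of migraine days in attacks
#' with an identifiable start that are continuation (non-first) days —
#' the empirical per-day continuation probability implied by geometric
#' attack durations.
#'
#' @param diary a preprocessed \code{mm_diary}.
#' @return A \code{markov_params}; fields with an empty denominator
#'   (e.g. \code{mu_m} when no classifiable window day exists) are
#'   \code{NA}.
#' @export
estimate_params <- function(diary) {
  windows <- detect_windows(diary)
  states <- classify_days(diary)
  counts <- trimmed_counts(diary, windows, states)
  mu <- counts$n / counts$N
  mu_m <- if (counts$K > 0L) counts$k / counts$K else NA_real_
  mu_nm <- if (counts$N - counts$K > 0L)
    (counts$n - counts$k) / (counts$N - counts$K) else NA_real_
  # delta from maximal migraine runs with an identifiable start: the
  # fraction of their days that are continuation (non-first) days
  runs <- segment_attacks(diary)
  runs <- runs[runs$identifiable_start, , drop = FALSE]
  attack_days <- sum(runs$end_day - runs$start_day + 1L)
  delta <- if (attack_days > 0L)
    (attack_days - nrow(runs)) / attack_days else NA_real_
  structure(list(mu = mu, mu_nm = mu_nm, mu_m = mu_m, delta = delta,
                 delta_mu = mu_m - mu_nm),
            class = "markov_params")
}

#' Diagnose one diary with both criteria
#'
#' Runs imputation (idempotent on already-imputed diaries), the trimmed
#' mid-p test at level \code{alpha}, the two-out-of-three window criterion,
#' and parameter estimation, returning everything as a one-row data frame
#' suitable for row-binding across subjects.
#'
#' @param diary an \code{mm_diary} (preprocess raw data first with
#'   [preprocess_diary()]).
#' @param alpha sMM significance cut-off in (0, 0.5).
#' @param also_untrimmed also report the day-based (untrimmed) mid-p value
#'   in a \code{p_untrimmed} column, for comparison with the older
#'   probability criterion.
#' @return One-row data frame: subject_id, N, K, n, k, p, smm_positive,
#'   windows_total, windows_with_onset, two_thirds_positive, mu, mu_nm,
#'   mu_m, delta.
#' @export
diagnose_diary <- function(diary, alpha = 0.1, also_untrimmed = FALSE) {
  diary <- impute_locked_days(diary)$diary
  smm <- smm_diagnose(diary, alpha)
  tt <- two_thirds_diagnose(diary)
  est <- estimate_params(diary)
  out <- data.frame(
    subject_id = diary$subject_id,
    N = smm$counts$N, K = smm$counts$K, n = smm$counts$n, k = smm$counts$k,
    p = smm$p,
    smm_positive = smm$smm_positive,
    windows_total = tt$windows_total,
    windows_with_onset = tt$windows_with_onset,
    two_thirds_positive = tt$two_thirds_positive,
    mu = est$mu, mu_nm = est$mu_nm, mu_m = est$mu_m, delta = est$delta
  )
  if (also_untrimmed)
    out$p_untrimmed <- midp_value(untrimmed_counts(diary))$p
  out
}
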