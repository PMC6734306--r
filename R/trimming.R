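#' Segment a diary into migraine attacks
#'
#' An attack is a maximal run of consecutive migraine days (the diary should
#' already be free of migraine-locked days, see [impute_locked_days()]). A
#' run that begins on the diary's first retained day has no identifiable
#' start: its onset day may lie before observation began.
#'
#' @param diary an \code{mm_diary}.
#' @return Data frame with columns \code{start_day}, \code{end_day},
#'   \code{identifiable_start}, one row per attack in diary order.
#' @examples
#' d <- mm_diary("s1", migraine = c(0, 1, 1, 1, 0, 0, 0, 1, 1),
#'               bleeding = c(0, 0, 0, 1, 1, 1, 0, 0, 0))
#' segment_attacks(d)  # attacks on days 2-4 and 8-9
#' @export
segment_attacks <- function(diary) {
  m <- diary$days$migraine
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start_day = starts[keep],
    end_day = ends[keep],
    identifiable_start = starts[keep] > 1L
  )
}

#' Day-state levels of the Markov classification
#' @export
day_states <- c("SUSCEPTIBLE", "ATTACK_START", "ONGOING", "REFRACTORY",
                "EXCLUDED")

#' Classify each diary day by its role in the attack process
#'
#' Maps every day onto the state it occupies in the two-state attack model:
#' \describe{
#'   \item{ATTACK_START}{first day of an attack whose start is observed;}
#'   \item{ONGOING}{later migraine days of that attack;}
#'   \item{REFRACTORY}{the two days immediately after an attack ends, on
#'     which a recorded migraine would count as a relapse of the same attack
#'     rather than a new one;}
#'   \item{EXCLUDED}{days of an attack without an identifiable start (a run
#'     touching the diary's first day);}
#'   \item{SUSCEPTIBLE}{all remaining days, on which a new attack could
#'     start.}
#' }
#' A migraine run beginning on one of the two refractory days after a
#' previous attack is merged into that attack (48-hour relapse rule): its
#' migraine days become ONGOING (or EXCLUDED when the merged attack has no
#' identifiable start), the non-migraine gap days stay REFRACTORY, and the
#' two-day refractory period restarts after the merged run.
#'
#' Only SUSCEPTIBLE and ATTACK_START days carry information about the
#' per-day onset probability; trimming a diary means restricting attention
#' to those days.
#'
#' @param diary an \code{mm_diary} (already imputed).
#' @param attacks attacks of \code{diary}, as from [segment_attacks()].
#' @return Factor vector, one element per diary day, levels [day_states].
#' @export
classify_days <- function(diary, attacks = segment_attacks(diary)) {
  nd <- nrow(diary$days)
  state <- rep("SUSCEPTIBLE", nd)
  nr <- nrow(attacks)
  i <- 1L
  while (i <= nr) {
    s0 <- attacks$start_day[i]
    e <- attacks$end_day[i]
    identifiable <- attacks$identifiable_start[i]
    # absorb runs relapsing within the two-day refractory period
    j <- i + 1L
    while (j <= nr && attacks$start_day[j] <= e + 2L) {
      e <- attacks$end_day[j]
      j <- j + 1L
    }
    span <- s0:e
    mig <- diary$days$migraine[span]
    state[span][!mig] <- "REFRACTORY"          # gap days inside a merged attack
    if (identifiable) {
      state[span][mig] <- "ONGOING"
      state[s0] <- "ATTACK_START"
    } else {
      state[span][mig] <- "EXCLUDED"
    }
    if (e < nd)
      state[(e + 1L):min(e + 2L, nd)] <- "REFRACTORY"
    i <- j
  }
  factor(state, levels = day_states)
}

new_counts <- function(N, K, n, k, variant) {
  N <- as.integer(N); K <- as.integer(K)
  n <- as.integer(n); k <- as.integer(k)
  if (any(c(N, K, n, k) < 0L) || k > min(n, K) || n > N || K > N)
    stop("invalid contingency counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  structure(list(N = N, K = K, n = n, k = k, variant = variant),
            class = "mm_counts")
}

#' @export
print.mm_counts <- function(x, ...) {
  cat(sprintf("<mm_counts %s> N=%d K=%d n=%d k=%d\n",
              x$variant, x$N, x$K, x$n, x$k))
  invisible(x)
}

#' Day-based (untrimmed) contingency counts
#'
#' Cross-classifies every diary day as inside/outside the menstrual windows
#' and migraine/non-migraine. These counts drive the older day-based
#' probability criterion, whose validity rests on a non-clustering
#' assumption that real attacks violate; they are provided for comparison.
#'
#' @param diary an \code{mm_diary}.
#' @param windows windows of \code{diary}, as from [detect_windows()].
#' @return An \code{mm_counts} with \code{N} all days, \code{K} window
#'   days, \code{n} migraine days, \code{k} migraine days inside windows.
#' @export
untrimmed_counts <- function(diary, windows = detect_windows(diary)) {
  nd <- nrow(diary$days)
  w <- window_mask(windows, nd)
  m <- diary$days$migraine
  new_counts(N = nd, K = sum(w), n = sum(m), k = sum(m & w),
             variant = "untrimmed_days")
}

#' Onset-based (trimmed) contingency counts
#'
#' Restricts the cross-classification to days on which a new attack could
#' start: SUSCEPTIBLE and ATTACK_START days of [classify_days()]. Ongoing
#' attack days, the two refractory days after each attack, and attacks
#' without an identifiable start are discarded, removing the dependence on
#' day-to-day clustering of migraine.
#'
#' @param diary an \code{mm_diary} (already imputed).
#' @param windows windows of \code{diary}, as from [detect_windows()].
#' @param states optional precomputed [classify_days()] result.
#' @return An \code{mm_counts} with \code{N} classifiable days, \code{K}
#'   classifiable window days, \code{n} attack-onset days, \code{k} onsets
#'   inside windows. Window membership is evaluated on the original day
#'   index: trimming removes days from the count, it does not renumber.
#' @export
trimmed_counts <- function(diary, windows = detect_windows(diary),
                           states = classify_days(diary)) {
  nd <- nrow(diary$days)
  w <- window_mask(windows, nd)
  classifiable <- states %in% c("SUSCEPTIBLE", "ATTACK_START")
  onset <- states == "ATTACK_START"
  if (!any(classifiable))
    stop("no classifiable days remain after trimming; diary non-evaluable")
  new_counts(N = sum(classifiable), K = sum(classifiable & w),
             n = sum(onset), k = sum(onset & w),
             variant = "trimmed_onsets")
}
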