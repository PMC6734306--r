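# Independent brute-force oracles, deliberately written in a different
# style from the package code paths they check.

# Exhaustive-enumeration mid-p value: place the n event days in every one
# of the choose(N, n) equally likely positions among N days of which the
# first K are window days, and read the upper tail off the realised
# in-window counts.
oracle_in_window_counts <- function(K, n, N) {
  if (n == 0L) return(0L)
  apply(utils::combn(N, n), 2L, function(s) sum(s <= K))
}

oracle_midp <- function(k, K, n, N) {
  kk <- oracle_in_window_counts(K, n, N)
  mean(kk >= k) - 0.5 * mean(kk == k)
}

oracle_pmf <- function(k, K, n, N) {
  kk <- oracle_in_window_counts(K, n, N)
  mean(kk == k)
}

# Day-by-day scan classifying each day of a migraine flag vector, applying
# the trimming rules directly: walk each attack, absorb relapses within
# two days of its end, mark the two post-attack days refractory, and leave
# attacks touching day 1 unidentifiable.
oracle_classify <- function(m) {
  D <- length(m)
  st <- rep("SUSCEPTIBLE", D)
  d <- 1L
  while (d <= D) {
    if (!m[d]) {
      d <- d + 1L
      next
    }
    identifiable <- d > 1L
    e <- d
    repeat {
      while (e < D && m[e + 1L]) e <- e + 1L
      relapse <- 0L
      for (g in 1:2) {
        if (e + g <= D && m[e + g]) {
          relapse <- e + g
          break
        }
      }
      if (relapse == 0L) break
      e <- relapse
    }
    for (x in d:e) {
      st[x] <- if (!m[x]) "REFRACTORY"
      else if (!identifiable) "EXCLUDED"
      else if (x == d) "ATTACK_START"
      else "ONGOING"
    }
    for (g in 1:2) if (e + g <= D) st[e + g] <- "REFRACTORY"
    d <- e + 3L
  }
  st
}

# Trimmed contingency counts recomputed from the oracle classification.
oracle_trimmed_counts <- function(m, window_mask) {
  st <- oracle_classify(m)
  cls <- st %in% c("SUSCEPTIBLE", "ATTACK_START")
  ons <- st == "ATTACK_START"
  list(N = sum(cls), K = sum(cls & window_mask),
       n = sum(ons), k = sum(ons & window_mask))
}
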