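# Shared fixtures: diaries are always built in code.

# The worked 9-day diary excerpt: migraine on days 2,3,4,8,9; first
# bleeding day on day 4 (bleeding days 4-6), so the menstrual window is
# days 2-6.
fig2_diary <- function() {
  mm_diary("fig2",
           migraine = c(0, 1, 1, 1, 0, 0, 0, 1, 1),
           bleeding = c(0, 0, 0, 1, 1, 1, 0, 0, 0))
}

# Build a diary realising a given sequence of cycle lengths: onsets at
# cumulative positions, three bleeding days per onset, optional migraine
# days, lead-in/lead-out padding.
diary_from_cycles <- function(lengths, lead = 5L, trail = 20L,
                              migraine_days = integer(), id = "cyc") {
  onsets <- lead + cumsum(c(0L, lengths))
  n_days <- max(onsets) + trail
  bleeding <- logical(n_days)
  for (o in onsets) bleeding[o:min(o + 2L, n_days)] <- TRUE
  migraine <- logical(n_days)
  migraine[migraine_days] <- TRUE
  mm_diary(id, migraine = migraine, bleeding = bleeding)
}

# Random diary with bernoulli migraine flags and a few bleeding episodes.
random_diary <- function(n_days = 60L, p_mig = 0.2, n_bleeds = 2L,
                         id = "rand") {
  migraine <- stats::runif(n_days) < p_mig
  bleeding <- logical(n_days)
  if (n_bleeds > 0L) {
    onsets <- sort(sample.int(n_days, n_bleeds))
    for (o in onsets) bleeding[o:min(o + 2L, n_days)] <- TRUE
  }
  mm_diary(id, migraine = migraine, bleeding = bleeding)
}
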