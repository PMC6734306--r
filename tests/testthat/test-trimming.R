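test_that("attacks are maximal migraine runs with identifiable starts", {
  a <- segment_attacks(fig2_diary())
  expect_equal(a$start_day, c(2L, 8L))
  expect_equal(a$end_day, c(4L, 9L))
  expect_true(all(a$identifiable_start))

  # a run touching the first day has no identifiable start
  d <- mm_diary("head", migraine = c(1, 1, 0, 0, 0), bleeding = rep(0, 5))
  a2 <- segment_attacks(d)
  expect_equal(nrow(a2), 1L)
  expect_false(a2$identifiable_start)

  # no migraine days at all
  d0 <- mm_diary("quiet", migraine = rep(0, 6), bleeding = rep(0, 6))
  expect_equal(nrow(segment_attacks(d0)), 0L)
})

test_that("the worked diary classifies exactly as printed", {
  d <- fig2_diary()
  st <- as.character(classify_days(d))
  expect_equal(st, c("SUSCEPTIBLE", "ATTACK_START", "ONGOING", "ONGOING",
                     "REFRACTORY", "REFRACTORY", "SUSCEPTIBLE",
                     "ATTACK_START", "ONGOING"))
  # removed (non-classifiable) days are exactly 3,4,5,6,9
  removed <- which(!(st %in% c("SUSCEPTIBLE", "ATTACK_START")))
  expect_equal(removed, c(3L, 4L, 5L, 6L, 9L))
})

test_that("an isolated one-day attack leaves two refractory days", {
  m <- logical(10); m[5] <- TRUE
  d <- mm_diary("iso", migraine = m, bleeding = rep(0, 10))
  st <- as.character(classify_days(d))
  expect_equal(st[5], "ATTACK_START")
  expect_equal(st[6:7], rep("REFRACTORY", 2))
  expect_equal(st[c(1:4, 8:10)], rep("SUSCEPTIBLE", 7))
})

test_that("a migraine run on a refractory day merges into the attack", {
  # attack days 3-4, relapse on day 6 (inside the 2-day refractory window)
  m <- c(0, 0, 1, 1, 0, 1, 1, 0, 0, 0, 0, 0)
  d <- mm_diary("merge", migraine = m, bleeding = rep(0, 12))
  st <- as.character(classify_days(d))
  expect_equal(st[3], "ATTACK_START")
  expect_equal(st[4], "ONGOING")
  expect_equal(st[5], "REFRACTORY")      # gap day inside the merged attack
  expect_equal(st[6:7], rep("ONGOING", 2))  # relapse, not a new onset
  expect_equal(st[8:9], rep("REFRACTORY", 2))  # refractory restarts
  expect_equal(st[10:12], rep("SUSCEPTIBLE", 3))
  # exactly one onset counted
  expect_equal(sum(st == "ATTACK_START"), 1L)
})

test_that("attacks without identifiable start are excluded but still
           generate refractory days", {
  m <- c(1, 1, 0, 0, 0, 1, 0, 0, 0, 0)
  d <- mm_diary("head2", migraine = m, bleeding = rep(0, 10))
  st <- as.character(classify_days(d))
  expect_equal(st[1:2], rep("EXCLUDED", 2))
  expect_equal(st[3:4], rep("REFRACTORY", 2))
  expect_equal(st[6], "ATTACK_START")
})

test_that("an attack truncated by the diary end still counts as an onset", {
  m <- c(0, 0, 0, 1, 1)
  d <- mm_diary("tail", migraine = m, bleeding = rep(0, 5))
  st <- as.character(classify_days(d))
  expect_equal(st[4], "ATTACK_START")
  expect_equal(st[5], "ONGOING")
  ct <- trimmed_counts(d, detect_windows(d))
  expect_equal(ct$n, 1L)
})

test_that("untrimmed counts reproduce the worked diary table", {
  ct <- untrimmed_counts(fig2_diary())
  expect_equal(ct$N, 9L)
  expect_equal(ct$n, 5L)
  expect_equal(ct$K, 5L)
  expect_equal(ct$k, 3L)

  # no migraine: n = k = 0
  d0 <- mm_diary("q", migraine = rep(0, 9), bleeding = fig2_diary()$days$bleeding)
  ct0 <- untrimmed_counts(d0)
  expect_equal(c(ct0$n, ct0$k), c(0L, 0L))

  # windows covering the whole diary: K = N and k = n
  b <- logical(5); b[3] <- TRUE
  d1 <- mm_diary("full", migraine = c(1, 0, 0, 0, 1), bleeding = b)
  ct1 <- untrimmed_counts(d1)
  expect_equal(ct1$K, ct1$N)
  expect_equal(ct1$k, ct1$n)
})

test_that("trimmed counts reproduce the worked diary table", {
  ct <- trimmed_counts(fig2_diary())
  expect_equal(ct$N, 4L)
  expect_equal(ct$n, 2L)
  expect_equal(ct$K, 1L)
  expect_equal(ct$k, 1L)
  expect_equal(ct$variant, "trimmed_onsets")

  # no attacks: n = k = 0 and every day classifiable
  d0 <- mm_diary("q", migraine = rep(0, 9),
                 bleeding = fig2_diary()$days$bleeding)
  ct0 <- trimmed_counts(d0)
  expect_equal(ct0$N, 9L)
  expect_equal(c(ct0$n, ct0$k), c(0L, 0L))

  # an all-migraine diary has no classifiable day
  dall <- mm_diary("all", migraine = rep(1, 6),
                   bleeding = c(0, 0, 1, 1, 0, 0))
  expect_error(trimmed_counts(dall), "non-evaluable")
})

test_that("classification agrees with the brute-force oracle on simulated
           diaries", {
  set.seed(31)
  layout <- diary_layout(7)  # ~206-day diaries
  params <- markov_params(mu_nm = 0.05, mu_m = 0.25, delta = 0.45)
  for (i in 1:25) {
    d <- impute_locked_days(simulate_diary(params, layout))$diary
    expect_equal(as.character(classify_days(d)),
                 oracle_classify(d$days$migraine))
    w <- window_mask(detect_windows(d), nrow(d$days))
    got <- trimmed_counts(d)
    want <- oracle_trimmed_counts(d$days$migraine, w)
    expect_equal(got[c("N", "K", "n", "k")], want,
                 ignore_attr = TRUE, tolerance = 0)
  }
})

test_that("day states partition the diary and respect trimming bounds", {
  set.seed(90)
  for (i in 1:30) {
    d <- random_diary(n_days = 80L, p_mig = stats::runif(1, 0.05, 0.5))
    d <- impute_locked_days(d)$diary
    st <- classify_days(d)
    expect_equal(length(st), nrow(d$days))
    expect_false(anyNA(st))
    tu <- untrimmed_counts(d)
    # trimmed N never exceeds untrimmed N; equality iff no migraine days
    if (any(st %in% c("SUSCEPTIBLE", "ATTACK_START"))) {
      tt <- trimmed_counts(d)
      expect_lte(tt$N, tu$N)
      if (tu$n == 0L) expect_equal(tt$N, tu$N)
      # onset count equals identifiable merged attacks
      expect_equal(tt$n, sum(st == "ATTACK_START"))
    }
    # ATTACK_START days are migraine days preceded by a non-migraine day
    for (day in which(st == "ATTACK_START")) {
      expect_true(d$days$migraine[day])
      expect_true(day > 1 && !d$days$migraine[day - 1])
    }
  }
})

test_that("length-1 attacks separated by >2 clear days trim to the same n", {
  m <- logical(20); m[c(4, 9, 16)] <- TRUE
  d <- mm_diary("sparse", migraine = m, bleeding = rep(0, 20))
  expect_equal(trimmed_counts(d)$n, untrimmed_counts(d)$n)
})
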