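test_that("cycle lengths are onset-to-onset differences", {
  d <- diary_from_cycles(c(28L, 28L), lead = 10L)
  cl <- cycle_lengths(d)
  expect_equal(cl$length_days, c(28L, 28L))
  expect_equal(cl$start_onset, c(10L, 38L))
  expect_equal(cl$end_onset, c(38L, 66L))

  # spanning the observed clinical range of cycle lengths
  d2 <- diary_from_cycles(c(15L, 84L), lead = 5L)
  expect_equal(cycle_lengths(d2)$length_days, c(15L, 84L))

  # fewer than two onsets: no cycles
  one <- mm_diary("one", migraine = rep(0, 30),
                  bleeding = c(rep(0, 9), 1, 1, 1, rep(0, 18)))
  expect_equal(nrow(cycle_lengths(one)), 0L)
})

test_that("cycles longer than twice the individual mean are dropped, keeping
           the longest run of three consecutive typical cycles", {
  d <- diary_from_cycles(c(28L, 28L, 80L, 28L, 28L, 28L))
  res <- drop_atypical_cycles(d)
  expect_false(res$report$excluded)
  expect_equal(res$report$n_cycles, 3L)
  # the retained diary contains exactly the last four onsets
  expect_equal(nrow(cycle_lengths(res$diary)), 3L)
  expect_equal(cycle_lengths(res$diary)$length_days, rep(28L, 3))
})

test_that("a diary without three consecutive typical cycles is excluded", {
  d <- diary_from_cycles(c(28L, 28L, 80L, 28L, 28L))
  res <- drop_atypical_cycles(d)
  expect_true(res$report$excluded)
  expect_equal(res$report$exclusion_reason, "atypical_unsalvageable")
  expect_null(res$diary)
})

test_that("diaries with only typical cycles pass through unchanged", {
  d <- diary_from_cycles(c(28L, 28L, 28L))
  res <- drop_atypical_cycles(d)
  expect_false(res$report$excluded)
  expect_equal(res$diary, d)
})

test_that("eligibility needs at least three consecutive cycles", {
  expect_true(eligibility(diary_from_cycles(c(28L, 28L)))$excluded)
  expect_equal(eligibility(diary_from_cycles(c(28L, 28L)))$exclusion_reason,
               "too_few_cycles")
  expect_false(eligibility(diary_from_cycles(c(28L, 28L, 28L)))$excluded)
  expect_false(eligibility(diary_from_cycles(rep(28L, 15)))$excluded)
})

test_that("truncation keeps 15 days around the bleeding span and re-anchors", {
  b <- logical(100)
  b[30] <- TRUE  # single-day bleeds at 30 and 70
  b[70] <- TRUE
  d <- mm_diary("t", migraine = rep(FALSE, 100), bleeding = b)
  out <- truncate_diary(d)
  expect_equal(nrow(out$days), 71L)  # days 15..85
  expect_equal(attr(out, "retained_range"), c(15L, 85L))
  expect_equal(out$days$day_index, 1:71)
  expect_true(out$days$bleeding[16])  # old day 30

  # first bleed on day 1: no left truncation
  b2 <- logical(40); b2[1] <- TRUE
  d2 <- mm_diary("t2", migraine = rep(FALSE, 40), bleeding = b2)
  expect_equal(nrow(truncate_diary(d2)$days), 16L)

  # diary already inside the margins: only re-anchoring happens
  b3 <- logical(20); b3[10] <- TRUE
  d3 <- mm_diary("t3", migraine = rep(FALSE, 20), bleeding = b3)
  expect_equal(truncate_diary(d3)$days, d3$days)

  expect_error(truncate_diary(
    mm_diary("nb", migraine = rep(0, 5), bleeding = rep(0, 5))),
    "no bleeding")
})

test_that("migraine-locked days are imputed to a fixed point", {
  mk <- function(m) mm_diary("i", migraine = m, bleeding = rep(0, length(m)))
  # single locked day
  r <- impute_locked_days(mk(c(0, 1, 0, 1, 0)))
  expect_equal(r$diary$days$migraine, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$n_imputed, 1L)
  # alternating M.M.M fills fully
  r2 <- impute_locked_days(mk(c(1, 0, 1, 0, 1)))
  expect_true(all(r2$diary$days$migraine))
  expect_equal(r2$n_imputed, 2L)
  # a two-day gap is not locked
  r3 <- impute_locked_days(mk(c(1, 0, 0, 1)))
  expect_equal(r3$diary$days$migraine, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(r3$n_imputed, 0L)
  # all-migraine diary unchanged
  r4 <- impute_locked_days(mk(rep(1, 4)))
  expect_equal(r4$n_imputed, 0L)
})

test_that("imputation never removes migraine days; truncation never adds", {
  set.seed(2024)
  for (i in 1:20) {
    d <- random_diary(n_days = 50L, p_mig = 0.3)
    before <- sum(d$days$migraine)
    expect_gte(sum(impute_locked_days(d)$diary$days$migraine), before)
    tr <- truncate_diary(d)
    expect_lte(sum(tr$days$migraine), before)
  }
})

test_that("the preprocessing pipeline is idempotent", {
  set.seed(77)
  layout <- diary_layout(5)
  for (i in 1:10) {
    d <- simulate_diary(markov_params(mu = 0.1, delta = 0.4), layout)
    once <- preprocess_diary(d)
    expect_false(once$report$excluded)
    twice <- preprocess_diary(once$diary)
    expect_equal(twice$diary$days, once$diary$days)
    expect_equal(twice$report$imputed_locked_days, 0L)
  }
})

test_that("pipeline report composes retained range in original indices", {
  # 100-day diary, bleeds at 30 and 70 only: retained 15..85
  b <- logical(100); b[c(30, 50, 70, 90)] <- TRUE
  d <- mm_diary("rng", migraine = rep(FALSE, 100), bleeding = b)
  res <- preprocess_diary(d)
  expect_equal(res$report$retained_day_range, c(15L, 100L))
  expect_equal(nrow(res$diary$days), 86L)
})
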