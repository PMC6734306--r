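#' Trapezoidal area under an ROC curve
#'
#' Input points are de-duplicated and sorted into sweep order (by
#' false-positive rate, then true-positive rate), the corner points (0,0)
#' and (1,1) are appended when absent, and the trapezoid rule is applied
#' along the resulting polyline. Tied false-positive rates form vertical
#' segments of the staircase and contribute no area of their own.
#'
#' @param fpr false-positive rates (1 - specificity).
#' @param tpr true-positive rates (sensitivity).
#' @return Area under the curve, in [0, 1].
#' @examples
#' auc(c(0, 0, 1), c(0, 1, 1))   # perfect separation: 1
#' auc(c(0, 0.5, 1), c(0, 0.5, 1))  # chance: 0.5
#' @export
auc <- function(fpr, tpr) {
  stopifnot(length(fpr) == length(tpr))
  keep <- !is.na(fpr) & !is.na(tpr)
  pts <- unique(rbind(data.frame(fpr = fpr[keep], tpr = tpr[keep]),
                      data.frame(fpr = c(0, 1), tpr = c(0, 1))))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  sum(diff(pts$fpr) *
        (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# scores for one diary: the trimmed mid-p value (lower = more positive;
# non-evaluable diaries score 1, i.e. never positive) and the fraction of
# windows containing an attack onset (higher = more positive)
diary_scores <- function(diary) {
  diary <- impute_locked_days(diary)$diary
  windows <- detect_windows(diary)
  states <- classify_days(diary)
  counts <- trimmed_counts(diary, windows, states)
  mid <- midp_value(counts)
  onset_days <- which(states == "ATTACK_START")
  hit <- vapply(seq_len(nrow(windows)), function(i) {
    any(onset_days >= windows$start[i] & onset_days <= windows$end[i])
  }, logical(1))
  c(p = if (mid$evaluable) mid$p else 1,
    frac = if (nrow(windows) > 0L) mean(hit) else 0)
}

# sweep one score into ROC points; `direction` is "lt" for scores where
# smaller means positive (p-values) and "ge" for larger-means-positive
roc_sweep <- function(score_pos, score_neg, thresholds, direction) {
  pts <- lapply(thresholds, function(t) {
    if (direction == "lt") {
      c(threshold = t, tpr = mean(score_pos < t), fpr = mean(score_neg < t))
    } else {
      c(threshold = t, tpr = mean(score_pos >= t), fpr = mean(score_neg >= t))
    }
  })
  as.data.frame(do.call(rbind, pts))
}

#' ROC/AUC study comparing the sMM and 2/3 criteria
#'
#' For each cycle count, simulates a labelled two-arm population (see
#' [sample_population()]), diagnoses every diary with both criteria, and
#' traces ROC curves: the sMM curve by sweeping the significance level
#' alpha over (0, 0.5), the two-out-of-three curve by sweeping the
#' window-fraction threshold over [0, 1]. The canonical operating points
#' (alpha itself, and the 2/3 fraction) are reported with Monte-Carlo
#' standard errors.
#'
#' @param spec an \code{mm_popspec}; its seed fixes all arms and cycle
#'   counts (each cycle count gets a derived substream).
#' @param cycles integer vector of cycle counts to study; default 3:9.
#' @param alpha canonical sMM operating level; default 0.1.
#' @param cycle_length_days,tail_days layout knobs, see [diary_layout()].
#' @return Object of class \code{mm_roc_study}: list with
#'   \code{summary} (one row per criterion x cycle count: auc, canonical
#'   threshold, sensitivity, specificity and their standard errors) and
#'   \code{points} (the swept ROC points).
#' @export
roc_study <- function(spec, cycles = 3:9, alpha = 0.1,
                      cycle_length_days = 28L, tail_days = 10L) {
  set.seed(spec$seed)
  cycle_seeds <- sample.int(2147483646L, length(cycles))
  summary_rows <- list()
  point_rows <- list()
  for (ci in seq_along(cycles)) {
    nc <- cycles[ci]
    layout <- diary_layout(nc, cycle_length_days, tail_days)
    spec_c <- spec
    spec_c$seed <- cycle_seeds[ci]
    pop <- sample_population(spec_c, layout)
    scores <- vapply(pop$diaries, diary_scores, numeric(2))
    p_pos <- scores["p", pop$labels]
    p_neg <- scores["p", !pop$labels]
    f_pos <- scores["frac", pop$labels]
    f_neg <- scores["frac", !pop$labels]
    n <- spec$n_diaries

    a_thr <- sort(unique(c(p_pos[p_pos < 0.5], p_neg[p_neg < 0.5], alpha, 0.5)))
    smm_pts <- roc_sweep(p_pos, p_neg, a_thr, "lt")
    f_thr <- sort(unique(c(f_pos, f_neg, 2 / 3, 0, 1)))
    tt_pts <- roc_sweep(f_pos, f_neg, f_thr, "ge")

    sens_smm <- mean(p_pos < alpha)
    spec_smm <- mean(p_neg >= alpha)
    sens_tt <- mean(f_pos >= 2 / 3)
    spec_tt <- mean(f_neg < 2 / 3)
    se <- function(p) sqrt(p * (1 - p) / n)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      criterion = c("smm", "two_thirds"),
      n_cycles = nc,
      threshold = c(alpha, 2 / 3),
      auc = c(auc(smm_pts$fpr, smm_pts$tpr), auc(tt_pts$fpr, tt_pts$tpr)),
      sensitivity = c(sens_smm, sens_tt),
      specificity = c(spec_smm, spec_tt),
      se_sensitivity = c(se(sens_smm), se(sens_tt)),
      se_specificity = c(se(spec_smm), se(spec_tt))
    )
    smm_pts$criterion <- "smm"
    tt_pts$criterion <- "two_thirds"
    pts <- rbind(smm_pts, tt_pts)
    pts$n_cycles <- nc
    point_rows[[length(point_rows) + 1L]] <- pts
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 points = do.call(rbind, point_rows),
                 alpha = alpha,
                 n_per_arm = spec$n_diaries),
            class = "mm_roc_study")
}

#' @export
print.mm_roc_study <- function(x, ...) {
  cat(sprintf(
    "<mm_roc_study> %d diaries per arm; canonical sMM level alpha = %g\n",
    x$n_per_arm, x$alpha))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.mm_roc_study <- function(x, ...) {
  pts <- x$points
  cyc <- sort(unique(pts$n_cycles))
  shades <- grDevices::gray(seq(0.75, 0, length.out = length(cyc)))
  graphics::par(mfrow = c(1, 2))
  for (crit in c("smm", "two_thirds")) {
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "red",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = crit, ...)
    for (i in seq_along(cyc)) {
      p <- pts[pts$criterion == crit & pts$n_cycles == cyc[i], ]
      o <- order(p$fpr, p$tpr)
      graphics::lines(c(0, p$fpr[o], 1), c(0, p$tpr[o], 1),
                      col = shades[i])
    }
  }
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
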