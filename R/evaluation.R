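# Alarm classification, sensitivity, FPR/h, surrogate chance-level
# analysis, and the statistics used to compare approaches.

#' Classify alarms as true or false under SOP/SPH semantics
#'
#' An alarm at time `t` is a true alarm iff some test onset lies in
#' `[t + sph_s, t + sph_s + sop_s)` — the seizure occurs inside the
#' occurrence period that opens once the prediction horizon has elapsed. At
#' most one alarm counts as true per seizure (the earliest qualifying one);
#' every other alarm is false.
#'
#' @param alarm_times alarm times in seconds (an `alarm_record` also works).
#' @param onsets test seizure onsets in seconds.
#' @param sop_s seizure occurrence period (s).
#' @param sph_s seizure prediction horizon (s).
#' @return List with `n_true`, `n_false`, `true_alarm_times`, and
#'   `seizure_hit` (logical per onset).
#' @export
classify_alarms <- function(alarm_times, onsets, sop_s = 1800, sph_s = 600) {
  if (inherits(alarm_times, "alarm_record")) alarm_times <- alarm_times$alarm_times
  is_true <- logical(length(alarm_times))
  hit <- logical(length(onsets))
  for (i in seq_along(onsets)) {
    o <- onsets[i]
    qual <- which(!is_true & alarm_times + sph_s <= o &
                    o < alarm_times + sph_s + sop_s)
    if (length(qual)) {
      is_true[qual[1]] <- TRUE
      hit[i] <- TRUE
    }
  }
  list(n_true = sum(is_true), n_false = sum(!is_true),
       true_alarm_times = alarm_times[is_true], seizure_hit = hit)
}

#' Seizure sensitivity
#'
#' Ratio of true alarms to test seizures.
#'
#' @param n_true number of true alarms.
#' @param n_test_seizures number of test seizures (at least 1).
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(n_true, n_test_seizures) {
  if (n_test_seizures < 1) stopf("at least one test seizure required")
  n_true / n_test_seizures
}

#' False prediction rate per hour
#'
#' False alarms divided by the interictal duration minus the refractory time
#' consumed by those false alarms (during which no new alarm could fire).
#'
#' @param n_false number of false alarms.
#' @param interictal_h interictal duration in hours.
#' @param refractory_h refractory period in hours (40 min = 2/3 h).
#' @return False alarms per hour.
#' @export
fpr_per_hour <- function(n_false, interictal_h, refractory_h = 2 / 3) {
  den <- interictal_h - n_false * refractory_h
  if (den <= 0) {
    stopf("non-positive effective interictal time (%g h interictal, %d false alarms)",
          interictal_h, n_false)
  }
  n_false / den
}

#' Surrogate chance-level analysis
#'
#' Monte-Carlo test of whether the model's sensitivity beats chance: the
#' real alarms are held fixed while each test seizure's onset is relocated
#' uniformly at random within its own test segment (leaving room for
#' SPH + SOP before it, unless the segment is too short, in which case the
#' full segment is used with a warning), and sensitivity is re-scored per
#' surrogate repetition. The default p-value is the Monte-Carlo rank of the
#' real sensitivity in the surrogate distribution with randomised
#' tie-breaking, `p = (#{S > R} + U (1 + #{S = R})) / (n + 1)` with
#' `U ~ Uniform(0, 1)` — exactly uniform under an exchangeable null, so the
#' above-chance declaration is calibrated at its nominal level even though
#' sensitivity is discrete. A one-sample t-type alternative is available via
#' `method = "t"`. A model is above chance when its real sensitivity exceeds
#' the surrogate mean and the p-value is below `alpha`.
#'
#' @param alarm_times real alarm times in seconds (fixed model output).
#' @param test_segments data.frame with columns `start`, `end`: one test
#'   segment per test seizure.
#' @param onsets real test onsets (one per segment, in order).
#' @param n_surrogates surrogate repetitions (at least 20).
#' @param seed integer seed.
#' @param sop_s,sph_s alarm semantics, as in [classify_alarms()].
#' @param method `"rank"` (default) or `"t"`.
#' @param alpha significance level.
#' @return List with `real_sensitivity`, `surrogate_sensitivities`,
#'   `p_value`, `above_chance`.
#' @export
surrogate_analysis <- function(alarm_times, test_segments, onsets,
                               n_surrogates = 30, seed = 1,
                               sop_s = 1800, sph_s = 600,
                               method = c("rank", "t"), alpha = 0.05) {
  method <- match.arg(method)
  if (inherits(alarm_times, "alarm_record")) alarm_times <- alarm_times$alarm_times
  if (n_surrogates < 20) stopf("at least 20 surrogate repetitions required")
  n_seg <- nrow(test_segments)
  stopifnot(length(onsets) == n_seg)
  real <- sensitivity(classify_alarms(alarm_times, onsets, sop_s, sph_s)$n_true,
                      n_seg)
  lo <- test_segments$start + sop_s + sph_s
  hi <- test_segments$end
  short <- lo >= hi
  if (any(short)) {
    warning(sprintf("%d test segment(s) shorter than SPH+SOP; using the full segment", sum(short)))
    lo[short] <- test_segments$start[short]
  }
  local_seed(derive_seed(seed, 41), {
    surr <- vapply(seq_len(n_surrogates), function(r) {
      s_on <- stats::runif(n_seg, lo, hi)
      sensitivity(classify_alarms(alarm_times, sort(s_on), sop_s, sph_s)$n_true,
                  n_seg)
    }, 0)
    p <- if (method == "rank") {
      u <- stats::runif(1)
      (sum(surr > real) + u * (1 + sum(surr == real))) / (n_surrogates + 1)
    } else {
      if (stats::sd(surr) == 0) {
        if (mean(surr) < real) 0 else 1
      } else {
        stats::t.test(surr, mu = real, alternative = "less")$p.value
      }
    }
    list(real_sensitivity = real, surrogate_sensitivities = surr,
         p_value = p, above_chance = (real > mean(surr)) && (p < alpha))
  })
}

#' One-tailed Mann-Whitney U test
#'
#' Rank-sum test with midranks under ties (exact p-value for small untied
#' samples, normal approximation otherwise, as provided by
#' `stats::wilcox.test`). When every value in both groups is identical the
#' test is undefined; 0.5 is returned by convention with a message.
#'
#' @param group_a,group_b numeric samples.
#' @param direction `"b_greater"` tests whether `group_b` tends larger than
#'   `group_a`; `"b_less"` the reverse.
#' @return One-tailed p-value.
#' @export
mann_whitney_one_tailed <- function(group_a, group_b,
                                    direction = c("b_greater", "b_less")) {
  direction <- match.arg(direction)
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  if (length(unique(c(group_a, group_b))) == 1) {
    message("all values identical across both groups; p = 0.5 by convention")
    return(0.5)
  }
  alt <- if (direction == "b_greater") "greater" else "less"
  suppressWarnings(
    stats::wilcox.test(group_b, group_a, alternative = alt)$p.value)
}

#' Geometric mean of sensitivity and specificity
#'
#' The grid-search scoring metric: `sqrt(sensitivity * specificity)`.
#'
#' @param sens,spec values in `[0, 1]`.
#' @return The geometric mean.
#' @export
geometric_mean_sens_spec <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  sqrt(sens * spec)
}

#' Assemble an evaluation report for one patient and approach
#'
#' @param n_test_seizures,n_true_alarms,n_false_alarms alarm counts.
#' @param interictal_h interictal duration in hours.
#' @param surrogate result of [surrogate_analysis()], or `NULL`.
#' @param meta optional named list of run metadata.
#' @return An `eval_report` list.
#' @export
eval_report <- function(n_test_seizures, n_true_alarms, n_false_alarms,
                        interictal_h, surrogate = NULL, meta = list()) {
  rep <- list(
    n_test_seizures = n_test_seizures,
    n_true_alarms = n_true_alarms,
    n_false_alarms = n_false_alarms,
    interictal_duration_h = interictal_h,
    sensitivity = sensitivity(n_true_alarms, n_test_seizures),
    # a model alarming at the refractory limit can exhaust the effective
    # interictal time; report that as an infinite rate rather than failing
    fpr_per_h = tryCatch(fpr_per_hour(n_false_alarms, interictal_h),
                         error = function(e) Inf),
    surrogate_sensitivities = surrogate$surrogate_sensitivities,
    p_value = surrogate$p_value,
    above_chance = surrogate$above_chance %||% FALSE,
    meta = meta)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d test seizure(s): sensitivity %.2f, FPR/h %.3f, above chance: %s\n",
              x$n_test_seizures, x$sensitivity, x$fpr_per_h,
              if (isTRUE(x$above_chance)) "yes" else "no"))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
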