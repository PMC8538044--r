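# Stage-reporter fluorescence: normalization, peak calling, threshold
# calibration, developmental-toxicity calls, cell-type proportioning and the
# qualitative/quantitative agreement tally.

#' Normalize a reporter fluorescence course
#'
#' Each replicate's raw fluorescence is divided by that replicate's total
#' signal over the time course, so normalized values sum to 1 per replicate
#' and their mean over the `T` time points is exactly `1/T`.  Normalization is
#' idempotent and invariant to rescaling the raw signal.
#'
#' @param course Long data frame with columns `replicate_id`, `time_h` and
#'   `fluorescence` (plus optionally `reporter`).  All raw values must be
#'   >= 0; at least 2 time points per replicate.
#'
#' @return The input with an added `normalized` column.  A replicate whose
#'   total signal is zero cannot be normalized: its normalized values are NA
#'   and it is flagged in the `dead` column.
#' @examples
#' rc <- gen_reporter_course("slug", seed = 1)
#' head(normalize_course(rc))
#' @export
normalize_course <- function(course) {
  stopifnot(is.data.frame(course),
            all(c("replicate_id", "time_h", "fluorescence") %in% names(course)))
  if (any(course$fluorescence < 0))
    stop("raw fluorescence must be >= 0", call. = FALSE)
  out <- lapply(split(course, course$replicate_id), function(df) {
    if (nrow(df) < 2) stop("need >= 2 time points", call. = FALSE)
    if (is.unsorted(df$time_h, strictly = TRUE))
      df <- df[order(df$time_h), , drop = FALSE]
    tot <- sum(df$fluorescence)
    df$normalized <- if (tot > 0) df$fluorescence / tot else NA_real_
    df$dead <- tot <= 0
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.course_matrix <- function(norm_course) {
  # replicates x time matrix of normalized values, common time grid required
  sp <- split(norm_course, norm_course$replicate_id)
  times <- sort(unique(norm_course$time_h))
  m <- t(vapply(sp, function(df) {
    df <- df[order(df$time_h), ]
    if (!isTRUE(all.equal(df$time_h, times)))
      stop("replicates must share the time grid", call. = FALSE)
    df$normalized
  }, numeric(length(times))))
  colnames(m) <- times
  m
}

#' Detect a developmental expression profile in a normalized course
#'
#' A reporter is considered to have a developmental profile when the
#' across-replicate mean normalized value at any time point is at least
#' `threshold` times the mean of the total signal over the course.  Because
#' normalized replicates sum to 1 over `T` points, that reference mean is
#' `1/T`, so the test is `max_t mean_course(t) >= threshold / T`.  The peak
#' time is the argmax of the mean course among qualifying points.  Detection
#' is monotone in the threshold.
#'
#' @param norm_course Output of [normalize_course()] (dead replicates are
#'   excluded; if all replicates are dead there is no profile).
#' @param threshold Fold threshold in `[1.1, 1.6]`.
#'
#' @return A list of class `peak_call` with `has_profile`, `threshold_used`,
#'   `peak_time_h`, `peak_value` (the latter two NA when no profile).
#' @examples
#' rc <- normalize_course(gen_reporter_course("slug", seed = 1))
#' detect_profile(rc, threshold = 1.3)
#' @export
detect_profile <- function(norm_course, threshold) {
  if (threshold < 1.1 || threshold > 1.6)
    stop("threshold must lie in [1.1, 1.6]", call. = FALSE)
  if ("dead" %in% names(norm_course))
    norm_course <- norm_course[!norm_course$dead, , drop = FALSE]
  if (nrow(norm_course) == 0L || all(is.na(norm_course$normalized)))
    return(structure(list(has_profile = FALSE, threshold_used = threshold,
                          peak_time_h = NA_real_, peak_value = NA_real_),
                     class = "peak_call"))
  m <- .course_matrix(norm_course)
  mean_course <- colMeans(m)
  tt <- as.numeric(colnames(m))
  ref <- threshold / ncol(m)
  qual <- mean_course >= ref
  if (!any(qual))
    return(structure(list(has_profile = FALSE, threshold_used = threshold,
                          peak_time_h = NA_real_, peak_value = NA_real_),
                     class = "peak_call"))
  k <- which(qual)[which.max(mean_course[qual])]
  structure(list(has_profile = TRUE, threshold_used = threshold,
                 peak_time_h = tt[k], peak_value = unname(mean_course[k])),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak_call> profile=%s threshold=%.1f peak_time=%s peak=%s\n",
              x$has_profile, x$threshold_used, format(x$peak_time_h),
              format(signif(x$peak_value, 4))))
  invisible(x)
}

#' Calibrate the per-reporter peak-detection threshold on controls
#'
#' Returns the highest threshold on the grid at which a peak is detected in
#' every control development for the reporter.  If even the lowest grid value
#' fails on some control, calibration fails with a diagnostic naming the
#' offending control.
#'
#' @param control_courses A list of normalized control courses (each an
#'   output of [normalize_course()]), one per control experiment.
#' @param grid Candidate thresholds (default 1.1 to 1.6 in steps of 0.1).
#' @return The calibrated threshold (scalar).
#' @examples
#' ctrl <- lapply(1:3, function(s)
#'   normalize_course(gen_reporter_course("slug", seed = s)))
#' calibrate_threshold(ctrl)
#' @export
calibrate_threshold <- function(control_courses, grid = seq(1.1, 1.6, by = 0.1)) {
  if (length(control_courses) == 0L)
    stop("empty control set", call. = FALSE)
  for (th in sort(grid, decreasing = TRUE)) {
    ok <- vapply(control_courses,
                 function(cc) detect_profile(cc, th)$has_profile, logical(1))
    if (all(ok)) return(th)
  }
  bad <- which(!vapply(control_courses,
                       function(cc) detect_profile(cc, min(grid))$has_profile,
                       logical(1)))
  stop("threshold calibration failed: control(s) ",
       paste(bad, collapse = ", "), " show no peak even at ",
       format(min(grid)), call. = FALSE)
}

# Per-replicate peak statistics (time of max, value of max) of a normalized
# course; used for the timing/strength t-tests.
.replicate_peaks <- function(norm_course) {
  if ("dead" %in% names(norm_course))
    norm_course <- norm_course[!norm_course$dead, , drop = FALSE]
  m <- .course_matrix(norm_course)
  tt <- as.numeric(colnames(m))
  data.frame(replicate_id = rownames(m),
             peak_time_h = tt[apply(m, 1, which.max)],
             peak_value = apply(m, 1, max), row.names = NULL)
}

#' Compare treated and control reporter courses
#'
#' Calls the developmental-toxicity phenotype of one stage reporter.  If the
#' control shows a profile but the treated course does not, the call is
#' `absent`.  Otherwise per-replicate peak times and peak values are compared
#' by Welch two-sided t-tests: a significant timing difference gives
#' `delayed`/`advanced`, a significant strength difference gives
#' `attenuated`/`elevated`, and `normal` otherwise.  When both tests are
#' significant the timing call takes precedence (both p-values are returned).
#'
#' @param control,treated Normalized courses ([normalize_course()]) with at
#'   least 2 replicates each (the assay design uses 3).
#' @param threshold Peak threshold (from [calibrate_threshold()]).
#' @param alpha Significance level (default 0.05).
#' @param reporter Reporter label stored in the call.
#'
#' @return A list of class `devtox_call` with `reporter`, `call`, `timing_p`,
#'   `strength_p` and the two [detect_profile()] results.
#' @details A control without a profile invalidates the assay (error), the
#'   in-silico analogue of failing the manual control inspection.
#' @export
compare_development <- function(control, treated, threshold, alpha = 0.05,
                                reporter = NA_character_) {
  pc_ctrl <- detect_profile(control, threshold)
  if (!pc_ctrl$has_profile)
    stop("control development shows no reporter profile: assay invalid",
         call. = FALSE)
  pc_trt <- detect_profile(treated, threshold)
  if (!pc_trt$has_profile) {
    return(structure(list(reporter = reporter, call = "absent",
                          timing_p = NA_real_, strength_p = NA_real_,
                          control_peak = pc_ctrl, treated_peak = pc_trt),
                     class = "devtox_call"))
  }
  pk_c <- .replicate_peaks(control)
  pk_t <- .replicate_peaks(treated)
  if (nrow(pk_c) < 2 || nrow(pk_t) < 2)
    stop("need >= 2 replicates per condition", call. = FALSE)
  timing_p <- .welch_p(pk_t$peak_time_h, pk_c$peak_time_h)
  strength_p <- .welch_p(pk_t$peak_value, pk_c$peak_value)
  call <- "normal"
  if (!is.na(timing_p) && timing_p < alpha) {
    call <- if (mean(pk_t$peak_time_h) > mean(pk_c$peak_time_h))
      "delayed" else "advanced"
  } else if (!is.na(strength_p) && strength_p < alpha) {
    call <- if (mean(pk_t$peak_value) < mean(pk_c$peak_value))
      "attenuated" else "elevated"
  }
  structure(list(reporter = reporter, call = call, timing_p = timing_p,
                 strength_p = strength_p, control_peak = pc_ctrl,
                 treated_peak = pc_trt),
            class = "devtox_call")
}

#' @export
print.devtox_call <- function(x, ...) {
  cat(sprintf("<devtox_call> %s: %s (timing p=%s, strength p=%s)\n",
              x$reporter, x$call, format(signif(x$timing_p, 3)),
              format(signif(x$strength_p, 3))))
  invisible(x)
}

#' Score prespore/prestalk cell-type proportioning
#'
#' Compares prespore and prestalk marker expression at the 24 h point between
#' a treated condition and the wild type.  The score is only valid when the
#' fruiting-body reporter call for the treatment is `normal` (development
#' completed); otherwise no ratio is emitted.
#'
#' @param prespore_treated,prestalk_treated,prespore_wt,prestalk_wt
#'   Normalized courses ([normalize_course()]).
#' @param fruiting_body_call A `devtox_call` for the fruiting-body reporter
#'   under the same treatment, or a call string.
#' @param at_time_h Time point used (default 24).
#'
#' @return List of class `proportioning_result` with `valid`,
#'   `prespore_signal`, `prestalk_signal` (treated means at `at_time_h`),
#'   `ratio_vs_wildtype` and a Welch `p_value` across replicate-level ratios.
#' @export
proportioning_score <- function(prespore_treated, prestalk_treated,
                                prespore_wt, prestalk_wt,
                                fruiting_body_call, at_time_h = 24) {
  fb <- if (inherits(fruiting_body_call, "devtox_call"))
    fruiting_body_call$call else as.character(fruiting_body_call)
  if (!identical(fb, "normal")) {
    return(structure(list(valid = FALSE, prespore_signal = NA_real_,
                          prestalk_signal = NA_real_,
                          ratio_vs_wildtype = NA_real_, p_value = NA_real_),
                     class = "proportioning_result"))
  }
  at_point <- function(nc) {
    nc <- nc[nc$time_h == at_time_h & !nc$dead, , drop = FALSE]
    stats::setNames(nc$normalized, nc$replicate_id)
  }
  sp_t <- at_point(prespore_treated); st_t <- at_point(prestalk_treated)
  sp_w <- at_point(prespore_wt);      st_w <- at_point(prestalk_wt)
  if (any(st_t == 0) || any(st_w == 0) || mean(st_t) == 0 || mean(st_w) == 0)
    stop("zero prestalk signal: proportioning ratio undefined", call. = FALSE)
  ratio_t <- mean(sp_t) / mean(st_t)
  ratio_w <- mean(sp_w) / mean(st_w)
  # replicate-level ratios for the significance test (replicates paired by order)
  n <- min(length(sp_t), length(st_t), length(sp_w), length(st_w))
  rt <- sp_t[seq_len(n)] / st_t[seq_len(n)]
  rw <- sp_w[seq_len(n)] / st_w[seq_len(n)]
  structure(list(valid = TRUE, prespore_signal = mean(sp_t),
                 prestalk_signal = mean(st_t),
                 ratio_vs_wildtype = ratio_t / ratio_w,
                 p_value = .welch_p(rt, rw)),
            class = "proportioning_result")
}

#' Tally agreement between qualitative and quantitative call matrices
#'
#' Counts identical observations between two phenotype call tables keyed by
#' `(compound, reporter)` under three pooling rules: `strict` (calls must be
#' identical), `timing_pooled` (timing defects -- `delayed`/`advanced` -- and
#' `absent` count as one class), and `plus_strength` (additionally pools the
#' strength defects `attenuated`/`elevated` into the same defect class, i.e.
#' any defect matches any defect).
#'
#' @param qualitative,quantitative Data frames with columns `compound`,
#'   `reporter`, `call`.  The two tables must share exactly the same
#'   `(compound, reporter)` keys.
#'
#' @return Data frame with columns `rule`, `n_identical`, `n_total`,
#'   `percent`.
#' @export
agreement_tally <- function(qualitative, quantitative) {
  req <- c("compound", "reporter", "call")
  stopifnot(all(req %in% names(qualitative)), all(req %in% names(quantitative)))
  key <- function(df) paste(df$compound, df$reporter, sep = "\r")
  qk <- key(qualitative); nk <- key(quantitative)
  if (length(qk) != length(nk) || !setequal(qk, nk) || anyDuplicated(qk))
    stop("call matrices must share the same (compound, reporter) keys",
         call. = FALSE)
  q <- qualitative$call[order(qk)]
  v <- quantitative$call[order(nk)]
  pool_timing <- function(x)
    ifelse(x %in% c("delayed", "advanced", "absent"), "timing_or_absent", x)
  pool_all <- function(x) ifelse(x == "normal", "normal", "defect")
  n <- length(q)
  data.frame(
    rule = c("strict", "timing_pooled", "plus_strength"),
    n_identical = c(sum(q == v),
                    sum(pool_timing(q) == pool_timing(v)),
                    sum(pool_all(q) == pool_all(v))),
    n_total = n,
    percent = 100 * c(sum(q == v), sum(pool_timing(q) == pool_timing(v)),
                      sum(pool_all(q) == pool_all(v))) / n)
}
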