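# Growth toxicity: doubling times, anchor doses, dose ladders, NOAEL/LOAEL.

#' Fit exponential-phase doubling times from per-frame cell counts
#'
#' Log-linear least squares of `ln(count)` against time inside the
#' exponential-phase window.  The fit window is selected automatically by
#' sliding over all contiguous sub-windows of at least `min_span_h` hours
#' inside `window` and keeping the one that maximizes r-squared (ties: more
#' points, then earlier start).  The doubling time is `ln(2) / slope`.
#'
#' @param counts Data frame with columns `time_h`, `count` and optionally
#'   `well_id` (one fit per well).
#' @param window Two-element vector giving the hours inside which the
#'   exponential phase is sought (default `c(8, 48)`).
#' @param min_span_h Minimum sub-window span in hours (default 8).
#' @param min_points Preferred minimum number of points per sub-window
#'   (default 5; relaxed to the available number when fewer usable points
#'   exist, but never below 4).
#' @param r2_tol Sub-window selection tolerance: among windows whose
#'   r-squared is within `r2_tol` of the maximum, the longest (then
#'   earliest) is kept.  A pure argmax would favour short windows that fit
#'   the count noise rather than the growth trend.
#'
#' @return A data frame of class `growth_fit`, one row per well, with columns
#'   `well_id`, `doubling_time_h` (NA when no growth), `window_start_h`,
#'   `window_end_h`, `r_squared`, `n_points`, `no_growth`.
#' @details Counts must be positive to enter the fit; wells with fewer than 4
#'   usable points inside the window are an error.  A non-positive best-fit
#'   slope (including constant counts) yields `no_growth = TRUE` with an
#'   undefined doubling time.  The estimate is invariant to rescaling all
#'   counts by a constant.
#' @examples
#' cfg <- sim_config(seed = 1, count_noise_cv = 0)
#' fit_doubling_time(gen_growth_counts(cfg))
#' @export
fit_doubling_time <- function(counts, window = c(8, 48), min_span_h = 8,
                              min_points = 5L, r2_tol = 0.15) {
  stopifnot(is.data.frame(counts), all(c("time_h", "count") %in% names(counts)))
  if (!"well_id" %in% names(counts)) counts$well_id <- "well1"
  res <- lapply(split(counts, counts$well_id), function(df) {
    .fit_one_well(df$time_h, df$count, unique(df$well_id),
                  window, min_span_h, min_points, r2_tol)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("growth_fit", "data.frame")
  out
}

.fit_one_well <- function(time_h, count, well_id, window, min_span_h,
                          min_points, r2_tol) {
  keep <- time_h >= window[1] & time_h <= window[2] & count > 0
  t <- time_h[keep]; y <- log(count[keep])
  o <- order(t); t <- t[o]; y <- y[o]
  n <- length(t)
  if (n < 4)
    stop("well ", well_id, ": fewer than 4 usable points in the fit window",
         call. = FALSE)
  npt <- max(4L, min(min_points, n))
  # all contiguous index windows with span >= min_span_h and >= npt points
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$j - idx$i + 1L >= npt & t[idx$j] - t[idx$i] >= min_span_h, ,
             drop = FALSE]
  if (nrow(idx) == 0L) idx <- data.frame(i = 1L, j = n)
  st <- cumsum(t); st2 <- cumsum(t^2); sy <- cumsum(y); sy2 <- cumsum(y^2)
  sty <- cumsum(t * y)
  csum <- function(cs, i, j) cs[j] - c(0, cs)[i]
  m <- idx$j - idx$i + 1L
  Sx <- csum(st, idx$i, idx$j);  Sx2 <- csum(st2, idx$i, idx$j)
  Sy <- csum(sy, idx$i, idx$j);  Sy2 <- csum(sy2, idx$i, idx$j)
  Sxy <- csum(sty, idx$i, idx$j)
  ssxx <- Sx2 - Sx^2 / m
  ssyy <- Sy2 - Sy^2 / m
  ssxy <- Sxy - Sx * Sy / m
  slope <- ssxy / ssxx
  r2 <- ifelse(ssyy > 0, ssxy^2 / (ssxx * ssyy), NA_real_)
  if (all(is.na(r2))) {                      # flat counts: no growth signal
    return(data.frame(well_id = well_id, doubling_time_h = NA_real_,
                      window_start_h = t[1], window_end_h = t[n],
                      r_squared = NA_real_, n_points = n, no_growth = TRUE,
                      stringsAsFactors = FALSE))
  }
  # prefer the longest window whose fit is near the best r2: a pure
  # argmax-r2 rule favours short windows that overfit count noise, inflating
  # the doubling-time variance across replicate wells.  The tolerance scales
  # with the best fit's residual variance (and vanishes for noiseless data),
  # capped at r2_tol, so phase transitions -- which depress r2 far more than
  # counting noise does -- still force a sub-window.
  r2max <- max(r2, na.rm = TRUE)
  tol <- min(r2_tol, max(0, 3 * (1 - r2max)))
  near <- which(r2 >= r2max - tol)
  best <- near[order(-m[near], idx$i[near])[1L]]
  sl <- slope[best]
  no_growth <- !is.finite(sl) || sl <= 0
  data.frame(well_id = well_id,
             doubling_time_h = if (no_growth) NA_real_ else log(2) / sl,
             window_start_h = t[idx$i[best]], window_end_h = t[idx$j[best]],
             r_squared = r2[best], n_points = m[best], no_growth = no_growth,
             stringsAsFactors = FALSE)
}

#' Convert a rat LD50 (mg/kg) to an anchor molar concentration
#'
#' Assumes 1 kg of mammalian body weight is equivalent to 1 litre, so
#' mg/kg divided by g/mol gives mmol/L: the returned anchor is
#' `(ld50_mg_per_kg / mw_g_per_mol) / 1000` mol/L.
#'
#' @param ld50_mg_per_kg Rat LD50 in mg/kg (> 0).
#' @param mw_g_per_mol Molecular weight in g/mol (> 0).
#' @return Anchor dose in mol/L.
#' @examples
#' anchor_dose_from_ld50(100, 100)  # 1 mmol/L
#' @export
anchor_dose_from_ld50 <- function(ld50_mg_per_kg, mw_g_per_mol) {
  if (any(is.na(ld50_mg_per_kg)))
    stop("LD50 missing: supply a manual anchor dose", call. = FALSE)
  if (any(ld50_mg_per_kg <= 0) || any(mw_g_per_mol <= 0))
    stop("LD50 and molecular weight must be > 0", call. = FALSE)
  (ld50_mg_per_kg / mw_g_per_mol) / 1000
}

#' Build a dose ladder around an anchor dose
#'
#' Two ladder modes are used.  `"development"` reproduces the qualitative
#' assay design: three doses 5-, 25- and 125-fold below the anchor and two
#' doses 5- and 25-fold above it (six doses including the anchor).
#' `"growth_initial"` builds a geometric ladder of `n_doses` doses spanning
#' `span_log10` decades centred on the anchor, for first-pass growth range
#' finding.
#'
#' @param anchor_molar Anchor dose in mol/L (> 0).
#' @param mode `"development"` or `"growth_initial"`.
#' @param span_log10 Total span of the growth ladder in log10 units
#'   (default 2, i.e. 100-fold).
#' @param n_doses Number of doses in the growth ladder (default 6).
#' @return Numeric vector of doses in mol/L, strictly increasing.
#' @examples
#' build_dose_ladder(125e-6, "development") * 1e6  # 1 5 25 125 625 3125 uM
#' @export
build_dose_ladder <- function(anchor_molar,
                              mode = c("development", "growth_initial"),
                              span_log10 = 2, n_doses = 6L) {
  mode <- match.arg(mode)
  if (anchor_molar <= 0) stop("anchor dose must be > 0", call. = FALSE)
  if (mode == "development") {
    anchor_molar * c(1 / 125, 1 / 25, 1 / 5, 1, 5, 25)
  } else {
    10 ^ seq(log10(anchor_molar) - span_log10 / 2,
             log10(anchor_molar) + span_log10 / 2, length.out = n_doses)
  }
}

#' Construct a dose-response result
#'
#' Container for a per-compound, per-assay NOAEL/LOAEL call with censoring.
#'
#' @param compound Compound label.
#' @param assay `"growth"` or `"development"`.
#' @param noael_molar NOAEL in mol/L or NA.
#' @param loael_molar LOAEL in mol/L or NA.
#' @param censored One of `"none"`, `"noael_only_max_dose"`, `"precipitated"`.
#' @param doses_tested Doses tested, mol/L.
#' @param adverse_table Optional per-dose diagnostics data frame.
#' @return A list of class `dose_response_result`.
#' @export
dose_response_result <- function(compound = NA_character_,
                                 assay = c("growth", "development"),
                                 noael_molar = NA_real_, loael_molar = NA_real_,
                                 censored = c("none", "noael_only_max_dose",
                                              "precipitated"),
                                 doses_tested = numeric(),
                                 adverse_table = NULL) {
  assay <- match.arg(assay)
  censored <- match.arg(censored)
  if (!is.na(noael_molar) && !is.na(loael_molar) && noael_molar >= loael_molar)
    stop("NOAEL must be < LOAEL when both are defined", call. = FALSE)
  if (censored == "noael_only_max_dose" && !is.na(loael_molar))
    stop("a NOAEL-only censored result cannot carry a LOAEL", call. = FALSE)
  structure(list(compound = compound, assay = assay,
                 noael_molar = noael_molar, loael_molar = loael_molar,
                 censored = censored, doses_tested = doses_tested,
                 adverse_table = adverse_table),
            class = "dose_response_result")
}

#' @export
print.dose_response_result <- function(x, ...) {
  cat(sprintf("<dose_response_result> %s [%s]\n", x$compound, x$assay))
  cat(sprintf("  NOAEL: %s mol/L  LOAEL: %s mol/L  censored: %s\n",
              format(x$noael_molar), format(x$loael_molar), x$censored))
  invisible(x)
}

#' Call growth NOAEL and LOAEL from per-dose replicate endpoints
#'
#' The LOAEL is the lowest dose whose endpoint differs adversely from the
#' vehicle control (Welch two-sample t-test at `alpha`, adverse direction
#' only: an *increase* in doubling time).  The NOAEL is the highest tested
#' dose below the LOAEL.  If no dose is adverse the NOAEL is the maximum
#' tested dose and the result is censored (`"noael_only_max_dose"`).
#'
#' @param endpoints Data frame with columns `dose` (mol/L) and `value`
#'   (endpoint per replicate well, e.g. doubling time in hours); at least two
#'   replicates per dose; doses must be unique when sorted.
#' @param control Numeric vector of control replicate endpoints (>= 2 values).
#' @param alpha Significance level (default 0.05).
#' @param min_effect Minimum fractional increase of the mean endpoint over the
#'   control mean additionally required to call a dose adverse (default 0:
#'   significance alone decides).  See the methods vignette for when a
#'   non-zero floor is advisable.
#' @param compound,assay Labels stored in the result.
#'
#' @return A [dose_response_result()] whose `adverse_table` holds per-dose
#'   means, p-values and adverse flags.
#' @details A non-monotone response (an adverse dose above a non-adverse one)
#'   keeps the lowest adverse dose as LOAEL and emits a warning.  Replicate
#'   endpoint vectors with zero variance in both groups are compared by their
#'   means alone (identical means: not adverse).
#' @examples
#' ep <- data.frame(dose = rep(c(5e-3, 1e-2, 2e-2), each = 3),
#'                  value = c(10, 10.2, 9.9, 15, 15.5, 14.8, 21, 20, 20.6))
#' call_noael_loael(ep, control = c(10, 10.1, 9.95), compound = "LiCl")
#' @export
call_noael_loael <- function(endpoints, control, alpha = 0.05,
                             min_effect = 0, compound = NA_character_,
                             assay = "growth") {
  stopifnot(is.data.frame(endpoints),
            all(c("dose", "value") %in% names(endpoints)))
  if (length(control) < 2) stop("need >= 2 control replicates", call. = FALSE)
  doses <- sort(unique(endpoints$dose))
  if (any(duplicated(doses)) || is.unsorted(doses, strictly = TRUE))
    stop("doses must be unique", call. = FALSE)
  ctrl_mean <- mean(control)
  per_dose <- lapply(doses, function(d) {
    v <- endpoints$value[endpoints$dose == d]
    if (length(v) < 2)
      stop("need >= 2 replicates per dose (dose ", format(d), ")",
           call. = FALSE)
    p <- .welch_p(v, control)
    adverse <- !is.na(p) && p < alpha && mean(v) > ctrl_mean &&
      (mean(v) - ctrl_mean) / ctrl_mean >= min_effect
    data.frame(dose = d, mean_value = mean(v), n = length(v), p_value = p,
               adverse = adverse)
  })
  tab <- do.call(rbind, per_dose)
  .noael_loael_from_flags(doses, tab$adverse, tab, compound, assay)
}

# Welch t-test p-value robust to zero-variance groups.
.welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y)$p.value
}

.noael_loael_from_flags <- function(doses, adverse, tab, compound, assay) {
  if (!any(adverse)) {
    return(dose_response_result(compound, assay,
                                noael_molar = max(doses),
                                censored = "noael_only_max_dose",
                                doses_tested = doses, adverse_table = tab))
  }
  loael <- min(doses[adverse])
  above <- doses > loael
  if (any(above & !adverse))
    warning("non-monotone dose-response for ", compound,
            ": dose(s) above the LOAEL not called adverse", call. = FALSE)
  below <- doses[doses < loael]
  noael <- if (length(below)) max(below) else NA_real_
  dose_response_result(compound, assay, noael_molar = noael,
                       loael_molar = loael, doses_tested = doses,
                       adverse_table = tab)
}

#' Call NOAEL/LOAEL from per-dose binary adverse flags
#'
#' Variant of [call_noael_loael()] for assays whose per-dose readout is
#' already a discrete adverse/normal call (e.g. qualitative developmental
#' scoring, or reporter-profile loss).
#'
#' @param doses Tested doses in mol/L, ascending.
#' @param adverse Logical vector, one flag per dose.
#' @param compound,assay Labels stored in the result.
#' @return A [dose_response_result()].
#' @export
call_noael_loael_binary <- function(doses, adverse,
                                    compound = NA_character_,
                                    assay = "development") {
  stopifnot(length(doses) == length(adverse))
  o <- order(doses)
  doses <- doses[o]; adverse <- as.logical(adverse[o])
  if (any(duplicated(doses))) stop("doses must be unique", call. = FALSE)
  tab <- data.frame(dose = doses, adverse = adverse)
  .noael_loael_from_flags(doses, adverse, tab, compound, assay)
}
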