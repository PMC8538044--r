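# Teratogen classification: ratio classifier, predictivity metrics,
# cross-model dose conversion/correlation, phenotype-vs-dose tests.

#' Classify a compound by its growth-LOAEL / development-NOAEL ratio
#'
#' The teratogenic-potential ratio is the growth toxicity LOAEL divided by
#' the developmental toxicity NOAEL (both mol/L).  A ratio >= `ratio_cutoff`
#' (default 10, boundary inclusive) classifies the compound as a teratogen.
#' Where no growth LOAEL could be defined (growth toxicity not reached at the
#' highest soluble dose) the growth NOAEL is used in its place and recorded.
#'
#' @param growth,development [dose_response_result()] objects for the two
#'   assays.  The development NOAEL is required; the growth result must carry
#'   a LOAEL or a NOAEL.
#' @param ratio_cutoff Classification threshold (default 10).
#'
#' @return List of class `teratogen_call` with `compound`, `ratio`,
#'   `growth_value_used` (`"LOAEL"` or `"NOAEL"`) and `call`
#'   (`"teratogen"`/`"nonteratogen"`).
#' @examples
#' g <- dose_response_result("X", "growth", noael_molar = 5e-3,
#'                           loael_molar = 1e-2)
#' d <- dose_response_result("X", "development", noael_molar = 1e-3)
#' classify_compound(g, d)
#' @export
classify_compound <- function(growth, development, ratio_cutoff = 10) {
  stopifnot(inherits(growth, "dose_response_result"),
            inherits(development, "dose_response_result"))
  if (is.na(development$noael_molar))
    stop("development NOAEL missing: compound unclassifiable", call. = FALSE)
  if (!is.na(growth$loael_molar)) {
    gv <- growth$loael_molar; used <- "LOAEL"
  } else if (!is.na(growth$noael_molar)) {
    gv <- growth$noael_molar; used <- "NOAEL"
  } else {
    stop("growth result carries neither LOAEL nor NOAEL", call. = FALSE)
  }
  ratio <- gv / development$noael_molar
  structure(list(compound = growth$compound, ratio = ratio,
                 growth_value_used = used,
                 call = if (ratio >= ratio_cutoff) "teratogen"
                        else "nonteratogen"),
            class = "teratogen_call")
}

#' Predictivity metrics from classifier calls and truth labels
#'
#' Builds the confusion matrix of model calls against mammalian in vivo truth
#' labels (teratogen = positive class) and derives the standard performance
#' endpoints, as percentages:
#' sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`,
#' PPV `100*TP/(TP+FP)`, NPV `100*TN/(TN+FN)`,
#' overall predictive value `(PPV+NPV)/2`, and
#' concordance `100*(TP+TN)/N`.  Metrics whose denominator is an empty class
#' are reported as `NA` (undefined), never as 0.
#'
#' @param calls Character vector of model calls
#'   (`"teratogen"`/`"nonteratogen"`), or a list of `teratogen_call` objects.
#' @param truth Character vector of truth labels, same length and order.
#'
#' @return List of class `predictivity_metrics` with the counts (`tp`, `fp`,
#'   `tn`, `fn`), full-precision metrics, and a `rounded` vector to the
#'   nearest integer (the convention used when reporting such tables).
#' @examples
#' m <- predictivity_metrics_from_counts(tp = 18, fn = 9, tn = 8, fp = 2)
#' m$rounded
#' @export
predictivity_metrics <- function(calls, truth) {
  if (is.list(calls) && all(vapply(calls, inherits, logical(1),
                                   "teratogen_call")))
    calls <- vapply(calls, `[[`, character(1), "call")
  stopifnot(length(calls) == length(truth))
  ok <- c("teratogen", "nonteratogen")
  if (!all(calls %in% ok) || !all(truth %in% ok))
    stop("calls and truth must be 'teratogen' or 'nonteratogen'",
         call. = FALSE)
  predictivity_metrics_from_counts(
    tp = sum(calls == "teratogen" & truth == "teratogen"),
    fp = sum(calls == "teratogen" & truth == "nonteratogen"),
    tn = sum(calls == "nonteratogen" & truth == "nonteratogen"),
    fn = sum(calls == "nonteratogen" & truth == "teratogen"))
}

#' @rdname predictivity_metrics
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @export
predictivity_metrics_from_counts <- function(tp, fp, tn, fn) {
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- pct(tp, tp + fn)
  spec <- pct(tn, tn + fp)
  ppv <- pct(tp, tp + fp)
  npv <- pct(tn, tn + fn)
  opv <- if (is.na(ppv) || is.na(npv)) NA_real_ else (ppv + npv) / 2
  conc <- pct(tp + tn, tp + fp + tn + fn)
  full <- c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
            overall_predictive_value = opv, concordance = conc)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 overall_predictive_value = opv, concordance = conc,
                 rounded = round(full)),
            class = "predictivity_metrics")
}

#' @export
print.predictivity_metrics <- function(x, ...) {
  cat(sprintf("<predictivity_metrics> TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  print(x$rounded)
  invisible(x)
}

#' Convert an mg/kg dose table to molar concentrations
#'
#' Applies the body-weight assumption that 1 kg is equivalent to 1 litre, so
#' `mol/L = (mg/kg) / MW(g/mol) / 1000`.  When duplicate entries for the same
#' `(endpoint, compound)` disagree (multiple literature sources), the lowest
#' dose is used.  Compounds without a molecular weight are dropped with a
#' warning.
#'
#' @param doses Data frame with columns `endpoint`, `compound`,
#'   `dose_mg_per_kg`.
#' @param compounds Data frame with columns `name`, `mw_g_per_mol`.
#' @return Long data frame `endpoint, compound, dose_molar`.
#' @examples
#' convert_dose_table(
#'   data.frame(endpoint = "acute", compound = "urea", dose_mg_per_kg = 90),
#'   data.frame(name = "urea", mw_g_per_mol = 90))
#' @export
convert_dose_table <- function(doses, compounds) {
  stopifnot(all(c("endpoint", "compound", "dose_mg_per_kg") %in% names(doses)),
            all(c("name", "mw_g_per_mol") %in% names(compounds)))
  agg <- stats::aggregate(dose_mg_per_kg ~ endpoint + compound, data = doses,
                          FUN = min)
  mw <- stats::setNames(compounds$mw_g_per_mol, compounds$name)
  missing <- setdiff(unique(agg$compound), names(mw))
  if (length(missing)) {
    warning("dropping compound(s) without molecular weight: ",
            paste(missing, collapse = ", "), call. = FALSE)
    agg <- agg[!agg$compound %in% missing, , drop = FALSE]
  }
  if (any(mw[agg$compound] <= 0)) stop("molecular weights must be > 0",
                                       call. = FALSE)
  data.frame(endpoint = agg$endpoint, compound = agg$compound,
             dose_molar = agg$dose_mg_per_kg / mw[agg$compound] / 1000,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlations between toxicity dose datasets
#'
#' For every pair of endpoints, compounds present in both are intersected
#' (pairwise-complete) and Pearson correlation is computed on log10 molar
#' doses (doses span several orders of magnitude; a linear-scale analysis is
#' available via `log_scale = FALSE`).  Pairs whose overlap does not exceed
#' `min_n` compounds are reported but flagged as not tested.
#'
#' @param dose_table Long data frame `endpoint, compound, dose_molar`
#'   (all doses > 0).
#' @param min_n Minimum overlap, exclusive: a pair is tested only when
#'   `n > min_n` (default 3).
#' @param log_scale Correlate log10 doses (default TRUE).
#'
#' @return Data frame `endpoint_a, endpoint_b, n, r, r_squared, p_value,
#'   tested` covering all unordered endpoint pairs (including self-pairs,
#'   which have r = 1).
#' @export
correlation_matrix <- function(dose_table, min_n = 3L, log_scale = TRUE) {
  stopifnot(all(c("endpoint", "compound", "dose_molar") %in% names(dose_table)))
  if (any(dose_table$dose_molar <= 0))
    stop("doses must be positive", call. = FALSE)
  eps <- unique(dose_table$endpoint)
  rows <- list()
  for (i in seq_along(eps)) for (j in i:length(eps)) {
    a <- dose_table[dose_table$endpoint == eps[i], ]
    b <- dose_table[dose_table$endpoint == eps[j], ]
    m <- merge(a, b, by = "compound")
    x <- m$dose_molar.x; y <- m$dose_molar.y
    if (log_scale) { x <- log10(x); y <- log10(y) }
    n <- length(x)
    tested <- n > min_n && stats::sd(x) > 0 && stats::sd(y) > 0
    if (tested) {
      ct <- stats::cor.test(x, y, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    } else {
      r <- NA_real_; p <- NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      endpoint_a = eps[i], endpoint_b = eps[j], n = n, r = r,
      r_squared = r^2, p_value = p, tested = tested,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Test whether developmental phenotype classes differ in NOAEL dose
#'
#' One-way ANOVA of log10 NOAEL doses across phenotype groups (e.g. first
#' developmental stage affected), or a Welch t-test when exactly two groups
#' are compared (e.g. presence/absence of a cell-type proportioning defect).
#'
#' @param dose_molar Numeric NOAEL doses in mol/L (> 0 when `log_scale`).
#' @param group Factor/character grouping of the same length.
#' @param method `"auto"` (ANOVA for > 2 groups, Welch t for 2), `"anova"`,
#'   or `"t"`.
#' @param log_scale Analyze log10 doses (default TRUE).
#' @return List with `method`, `p_value`, `statistic`, `df`.
#' @export
phenotype_dose_test <- function(dose_molar, group,
                                method = c("auto", "anova", "t"),
                                log_scale = TRUE) {
  method <- match.arg(method)
  group <- factor(group)
  tab <- table(group)
  if (nlevels(group) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  y <- if (log_scale) log10(dose_molar) else dose_molar
  if (method == "auto") method <- if (nlevels(group) == 2) "t" else "anova"
  if (method == "t") {
    if (nlevels(group) != 2)
      stop("t-test variant requires exactly 2 groups", call. = FALSE)
    tt <- stats::t.test(y ~ group)
    list(method = "welch_t", p_value = tt$p.value,
         statistic = unname(tt$statistic), df = unname(tt$parameter))
  } else {
    fit <- stats::aov(y ~ group)
    s <- summary(fit)[[1]]
    list(method = "anova", p_value = s[["Pr(>F)"]][1],
         statistic = s[["F value"]][1], df = s[["Df"]])
  }
}
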