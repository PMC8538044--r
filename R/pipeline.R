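# End-to-end pipeline: synthetic cohort -> growth fits -> developmental
# reporter calls -> NOAEL/LOAEL -> teratogen classification, with a
# reproducibility manifest.

# Sub-seeds derived from a master seed, kept below 2^31.
.sub_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate a test-compound cohort with planted toxicity thresholds
#'
#' Builds a cohort of synthetic compounds with known (planted) growth-LOAEL
#' and development-NOAEL positions on a shared 5-fold dose ladder, then
#' generates the raw data both assays would produce: per-well growth count
#' films for every dose plus a vehicle control (a toxic dose doubles the
#' doubling time), and stage-reporter fluorescence courses for every dose
#' (a developmentally toxic dose blocks development at the streaming stage,
#' silencing all later reporters).  The planted teratogenic-potential ratio
#' of compound `i` is `5^(growth_idx - dev_idx)`, so the classifier's
#' expected call is known exactly.
#'
#' @param seed Master seed; all sub-draws derive from it.
#' @param design Optional data frame overriding the default 12-compound
#'   design; columns `name`, `truth`, `anchor_molar`, `dev_noael_idx`
#'   (1-5), `growth_loael_idx` (1-6 or NA for no growth toxicity at any
#'   tested dose).
#' @param growth_cv,reporter_cv Count/fluorescence noise CVs.
#' @param ratio_cutoff Classification cutoff used to derive the planted call.
#'
#' @return List of class `synthetic_cohort` with `compounds` (design plus
#'   planted ratio and call), `growth_data` and `dev_data` (long data
#'   frames; `dose_molar = 0` rows are the vehicle controls).
#' @export
simulate_cohort <- function(seed = 1L, design = NULL, growth_cv = 0.05,
                            reporter_cv = 0.05, ratio_cutoff = 10) {
  if (is.null(design)) design <- default_cohort_design()
  stopifnot(all(c("name", "truth", "anchor_molar", "dev_noael_idx",
                  "growth_loael_idx") %in% names(design)))
  n <- nrow(design)
  ladders <- lapply(design$anchor_molar, build_dose_ladder, mode = "development")
  gval <- vapply(seq_len(n), function(i) {
    gi <- design$growth_loael_idx[i]
    if (is.na(gi)) ladders[[i]][6] else ladders[[i]][gi]
  }, numeric(1))
  design$planted_ratio <- gval /
    vapply(seq_len(n), function(i) ladders[[i]][design$dev_noael_idx[i]],
           numeric(1))
  design$planted_call <- ifelse(design$planted_ratio >= ratio_cutoff,
                                "teratogen", "nonteratogen")
  seeds <- .sub_seeds(seed, n * (7 + 7 * length(STAGE_ORDER)))
  k <- 0L
  nxt <- function() { k <<- k + 1L; seeds[k] }
  growth <- list(); dev <- list()
  for (i in seq_len(n)) {
    ladder <- ladders[[i]]
    gi <- design$growth_loael_idx[i]
    di <- design$dev_noael_idx[i]
    for (d in c(0, ladder)) {                       # 0 = vehicle control
      effect <- if (!is.na(gi) && d > 0 && d >= ladder[gi]) 2 else 1
      cfg <- sim_config(seed = nxt(), count_noise_cv = growth_cv)
      gc <- gen_growth_counts(cfg, dose_effect = effect,
                              well_prefix = sprintf("c%02dd%g_", i, d))
      gc$compound <- design$name[i]; gc$dose_molar <- d
      growth[[length(growth) + 1L]] <- gc
      blocked <- d > 0 && d > ladder[di]
      for (st in STAGE_ORDER) {
        rc <- gen_reporter_course(
          st, seed = nxt(), noise_cv = reporter_cv,
          block_at_stage = if (blocked) "streaming" else NULL)
        rc$compound <- design$name[i]; rc$dose_molar <- d
        dev[[length(dev) + 1L]] <- rc
      }
    }
  }
  structure(list(compounds = design,
                 growth_data = do.call(rbind, growth),
                 dev_data = do.call(rbind, dev)),
            class = "synthetic_cohort")
}

#' @rdname simulate_cohort
#' @export
default_cohort_design <- function() {
  data.frame(
    name = sprintf("cmpd%02d", 1:12),
    truth = c(rep("teratogen", 7), rep("nonteratogen", 5)),
    anchor_molar = 1e-3 * (1 + (0:11) / 10),
    dev_noael_idx    = c(1, 1, 2, 1, 2, 3, 4,  3, 4, 4, 5, 2),
    growth_loael_idx = c(3, 4, 4, NA, 5, 4, 4, 3, 5, 4, 6, 4),
    stringsAsFactors = FALSE)
}

#' Growth dose-response analysis of a cohort
#'
#' Fits per-well doubling times ([fit_doubling_time()]) and calls the growth
#' NOAEL/LOAEL per compound against the vehicle-control wells
#' ([call_noael_loael()]).
#'
#' @param growth_data Long data frame `compound, dose_molar, well_id, time_h,
#'   count` with `dose_molar = 0` control rows per compound.
#' @param alpha Significance level for the per-dose Welch test.
#' @param min_effect Minimum fractional doubling-time increase additionally
#'   required for an adverse call (default 0.2; see the methods vignette).
#' @return Named list of [dose_response_result()] objects, one per compound.
#' @export
analyze_growth <- function(growth_data, alpha = 0.05, min_effect = 0.2) {
  res <- lapply(split(growth_data, growth_data$compound), function(df) {
    fits <- fit_doubling_time(df[, c("well_id", "time_h", "count")])
    well_dose <- unique(df[, c("well_id", "dose_molar")])
    fits$dose_molar <- well_dose$dose_molar[match(fits$well_id,
                                                  well_dose$well_id)]
    if (any(fits$no_growth))
      warning("no-growth wells in compound ", df$compound[1], call. = FALSE)
    ctrl <- fits$doubling_time_h[fits$dose_molar == 0 & !fits$no_growth]
    trt <- fits[fits$dose_molar > 0 & !fits$no_growth, ]
    call_noael_loael(data.frame(dose = trt$dose_molar,
                                value = trt$doubling_time_h),
                     control = ctrl, alpha = alpha, min_effect = min_effect,
                     compound = df$compound[1], assay = "growth")
  })
  res
}

#' Developmental reporter analysis of a cohort
#'
#' For each compound, per-reporter peak thresholds are calibrated on the
#' compound's own vehicle-control developments ([calibrate_threshold()]),
#' every dosed development is compared with the control
#' ([compare_development()]), and the development NOAEL/LOAEL is called from
#' the per-dose adverse flags, where a dose is adverse when any reporter's
#' call falls in `adverse_classes` (default: loss of the expression profile).
#'
#' @param dev_data Long data frame `compound, dose_molar, reporter,
#'   replicate_id, time_h, fluorescence` with control rows at
#'   `dose_molar = 0`.
#' @param alpha Significance level for the timing/strength t-tests.
#' @param adverse_classes Calls that make a dose adverse (default
#'   `"absent"`; widen to include `"delayed"`, `"attenuated"`, etc. to let
#'   timing/strength defects drive the NOAEL).
#' @return List per compound with `result` (a [dose_response_result()]),
#'   `thresholds` (per reporter) and `calls` (data frame of per-dose,
#'   per-reporter calls).
#' @export
analyze_devtox <- function(dev_data, alpha = 0.05,
                           adverse_classes = "absent") {
  lapply(split(dev_data, dev_data$compound), function(df) {
    compound <- df$compound[1]
    doses <- sort(unique(df$dose_molar[df$dose_molar > 0]))
    thresholds <- numeric(0)
    ctrl_norm <- list()
    for (st in unique(df$reporter)) {
      cc <- normalize_course(df[df$reporter == st & df$dose_molar == 0, ])
      ctrl_norm[[st]] <- cc
      thresholds[st] <- calibrate_threshold(list(cc))
    }
    calls <- list()
    for (d in doses) for (st in unique(df$reporter)) {
      tc <- normalize_course(df[df$reporter == st & df$dose_molar == d, ])
      dc <- compare_development(ctrl_norm[[st]], tc, thresholds[st],
                                alpha = alpha, reporter = st)
      calls[[length(calls) + 1L]] <- data.frame(
        compound = compound, dose_molar = d, reporter = st, call = dc$call,
        timing_p = dc$timing_p, strength_p = dc$strength_p,
        stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, calls)
    adverse <- vapply(doses, function(d)
      any(calls$call[calls$dose_molar == d] %in% adverse_classes), logical(1))
    list(result = call_noael_loael_binary(doses, adverse, compound,
                                          "development"),
         thresholds = thresholds, calls = calls)
  })
}

#' Classify a cohort and score predictivity
#'
#' @param growth_results,dev_results Outputs of [analyze_growth()] and
#'   [analyze_devtox()] (named by compound).
#' @param truth Named character vector of truth labels per compound.
#' @param ratio_cutoff Ratio classification cutoff (default 10).
#' @return List with `calls` (data frame per compound) and `metrics`
#'   (a [predictivity_metrics()] object).
#' @export
classify_cohort <- function(growth_results, dev_results, truth,
                            ratio_cutoff = 10) {
  compounds <- names(growth_results)
  rows <- lapply(compounds, function(cm) {
    tc <- classify_compound(growth_results[[cm]], dev_results[[cm]]$result,
                            ratio_cutoff = ratio_cutoff)
    data.frame(compound = cm, ratio = tc$ratio,
               growth_value_used = tc$growth_value_used, call = tc$call,
               truth = unname(truth[cm]), stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  list(calls = calls,
       metrics = predictivity_metrics(calls$call, calls$truth))
}

#' Run the full simulate-to-classify pipeline
#'
#' Executes the end-to-end round trip -- synthetic cohort, growth fits,
#' developmental reporter calls, NOAEL/LOAEL, ratio classification,
#' predictivity metrics -- and, if an output directory is given, writes the
#' stage outputs as TSV plus a JSON manifest (configuration, seed, package
#' and R versions, output checksums) sufficient to reproduce the run
#' byte-identically.
#'
#' @param seed Master seed.
#' @param output_dir Optional directory for stage outputs and the manifest.
#' @param design Cohort design (see [simulate_cohort()]).
#' @param alpha,min_effect,ratio_cutoff,adverse_classes Analysis settings,
#'   passed through to the stages.
#' @return List with the cohort, per-stage results, `calls`, `metrics`,
#'   `confusion` (recovered vs planted-call confusion counts) and
#'   `planted_recovered` (TRUE when every recovered call equals its planted
#'   call).
#' @export
run_pipeline <- function(seed = 1L, output_dir = NULL, design = NULL,
                         alpha = 0.05, min_effect = 0.2, ratio_cutoff = 10,
                         adverse_classes = "absent") {
  cohort <- simulate_cohort(seed = seed, design = design,
                            ratio_cutoff = ratio_cutoff)
  growth_res <- analyze_growth(cohort$growth_data, alpha = alpha,
                               min_effect = min_effect)
  dev_res <- analyze_devtox(cohort$dev_data, alpha = alpha,
                            adverse_classes = adverse_classes)
  truth <- stats::setNames(cohort$compounds$truth, cohort$compounds$name)
  cls <- classify_cohort(growth_res, dev_res, truth,
                         ratio_cutoff = ratio_cutoff)
  planted <- stats::setNames(cohort$compounds$planted_call,
                             cohort$compounds$name)
  recovered <- stats::setNames(cls$calls$call, cls$calls$compound)
  out <- list(cohort = cohort, growth_results = growth_res,
              dev_results = dev_res, calls = cls$calls,
              metrics = cls$metrics,
              planted_recovered = all(recovered == planted[names(recovered)]))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_file(cohort$compounds, file.path(output_dir, "compounds.tsv"))
    write_tsv_file(cls$calls, file.path(output_dir, "teratogen_calls.tsv"))
    dr <- do.call(rbind, lapply(names(growth_res), function(cm) {
      g <- growth_res[[cm]]; d <- dev_res[[cm]]$result
      data.frame(compound = cm, growth_noael = g$noael_molar,
                 growth_loael = g$loael_molar, growth_censored = g$censored,
                 dev_noael = d$noael_molar, dev_loael = d$loael_molar,
                 dev_censored = d$censored, stringsAsFactors = FALSE)
    }))
    write_tsv_file(dr, file.path(output_dir, "dose_response.tsv"))
    files <- file.path(output_dir, c("compounds.tsv", "teratogen_calls.tsv",
                                     "dose_response.tsv"))
    manifest <- list(
      seed = seed,
      settings = list(alpha = alpha, min_effect = min_effect,
                      ratio_cutoff = ratio_cutoff,
                      adverse_classes = adverse_classes),
      package_version = as.character(utils::packageVersion("dictytox")),
      r_version = R.version.string,
      outputs = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$manifest = manifest
  }
  out
}
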