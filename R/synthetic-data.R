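# Developmental stage order of the 24 h D. discoideum cycle.  Used by the
# reporter simulator and by block-at-stage logic.
STAGE_ORDER <- c("initiation", "streaming", "mound", "slug",
                 "culminant", "fruiting_body")

# Canonical reporter course shapes.  Centers/widths (hours) follow the
# qualitative timings of each stage reporter: streaming signal detectable from
# ~6 h, mound from ~12 h, a sharp slug rise between 12 and 16 h, culminant
# after ~20 h and fruiting body only after 22-24 h.  All reporters are
# modelled as a Gaussian bump on a constant baseline so that a planted delay
# moves the argmax of the course (see the methods vignette for why the two
# broad "rising" reporters are bumps rather than saturating sigmoids).
.stage_params <- function(stage) {
  p <- switch(stage,
    initiation    = list(center = 0,  width = 5,   amplitude = 1000, baseline = 100),
    streaming     = list(center = 10, width = 5,   amplitude = 1000, baseline = 100),
    mound         = list(center = 14, width = 5,   amplitude = 1000, baseline = 100),
    slug          = list(center = 14, width = 2,   amplitude = 1200, baseline = 200),
    culminant     = list(center = 21, width = 2,   amplitude = 1000, baseline = 100),
    fruiting_body = list(center = 23, width = 1.5, amplitude = 1000, baseline = 50),
    stop("unknown stage name: ", stage, call. = FALSE))
  p
}

#' Simulation configuration for well growth time courses
#'
#' Parameters of the time-lapse growth assay emulator: wells are filmed at a
#' fixed framerate and per-frame cell counts follow a lag phase, exponential
#' growth at a fixed doubling time, and a carrying-capacity plateau, with
#' overdispersed (Poisson-lognormal) count noise.
#'
#' @param seed Integer seed; fixes every random draw so identical seeds give
#'   identical tables.
#' @param n_wells Number of replicate wells.
#' @param true_doubling_h True exponential-phase doubling time in hours
#'   (must be > 0).
#' @param lag_h Lag-phase duration in hours before exponential growth starts.
#' @param carrying_capacity Plateau cell count per frame.
#' @param count_noise_cv Coefficient of variation of the multiplicative
#'   lognormal component of the count noise (>= 0).  With `count_noise_cv = 0`
#'   the generator returns the exact deterministic expectation (no Poisson
#'   sampling either), which is what the closed-form test oracles rely on.
#' @param time_step_h Frame interval in hours (default 1).
#' @param horizon_h Total filming duration in hours (default 48).
#' @param n0_cells Initial cells per frame.
#'
#' @return A list of class `sim_config`.
#' @seealso [gen_growth_counts()]
#' @export
sim_config <- function(seed = 1L, n_wells = 3L, true_doubling_h = 10,
                       lag_h = 4, carrying_capacity = 2000,
                       count_noise_cv = 0.05, time_step_h = 1,
                       horizon_h = 48, n0_cells = 50) {
  if (!is.numeric(true_doubling_h) || true_doubling_h <= 0)
    stop("true_doubling_h must be > 0", call. = FALSE)
  if (count_noise_cv < 0) stop("count_noise_cv must be >= 0", call. = FALSE)
  if (time_step_h <= 0 || horizon_h <= 0)
    stop("time_step_h and horizon_h must be > 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_wells = as.integer(n_wells),
                 true_doubling_h = true_doubling_h, lag_h = lag_h,
                 carrying_capacity = carrying_capacity,
                 count_noise_cv = count_noise_cv, time_step_h = time_step_h,
                 horizon_h = horizon_h, n0_cells = n0_cells),
            class = "sim_config")
}

#' Generate per-well cell-count growth time series
#'
#' Emulates the time-lapse microscopy growth assay: per-frame cell counts with
#' a lag phase, exponential growth, and a carrying-capacity cap.  A dose
#' effect acts as a multiplier on the doubling time (a toxic dose slows
#' growth, i.e. `dose_effect > 1`).
#'
#' @param cfg A [sim_config()].
#' @param dose_effect Multiplier applied to the true doubling time
#'   (must leave the effective doubling time positive).
#' @param well_prefix Prefix for well identifiers.
#'
#' @return A long-format data frame with columns `well_id`, `time_h`, `count`.
#' @examples
#' cfg <- sim_config(seed = 1, count_noise_cv = 0)
#' head(gen_growth_counts(cfg))
#' @export
gen_growth_counts <- function(cfg, dose_effect = 1, well_prefix = "W") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(dose_effect) || dose_effect <= 0 ||
      cfg$true_doubling_h * dose_effect <= 0)
    stop("effective doubling time must be > 0", call. = FALSE)
  td <- cfg$true_doubling_h * dose_effect
  times <- seq(0, cfg$horizon_h, by = cfg$time_step_h)
  mu <- cfg$n0_cells * 2 ^ (pmax(times - cfg$lag_h, 0) / td)
  mu <- pmin(mu, cfg$carrying_capacity)
  set.seed(cfg$seed)
  out <- vector("list", cfg$n_wells)
  for (w in seq_len(cfg$n_wells)) {
    if (cfg$count_noise_cv == 0) {
      counts <- mu
    } else {
      s <- sqrt(log1p(cfg$count_noise_cv^2))
      lam <- mu * stats::rlnorm(length(mu), meanlog = -s^2 / 2, sdlog = s)
      counts <- stats::rpois(length(mu), lam)
    }
    out[[w]] <- data.frame(well_id = sprintf("%s%02d", well_prefix, w),
                           time_h = times, count = counts,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a stage-reporter fluorescence time course
#'
#' Emulates one developmental stage reporter read on a fluorescence plate
#' reader every 2 h over the 24 h developmental cycle (13 time points,
#' t = 0 included).  Untreated courses carry a detectable peak in the stage's
#' canonical window.  Treatments mimic developmental toxicity: a block at an
#' upstream stage abolishes all later-stage signal, a delay shifts the peak,
#' and attenuation scales it down.
#'
#' @param stage One of `"initiation"`, `"streaming"`, `"mound"`, `"slug"`,
#'   `"culminant"`, `"fruiting_body"`.
#' @param n_reps Number of replicate developments (the assay design uses 3).
#' @param seed Integer seed.
#' @param block_at_stage Optional stage name at which development arrests:
#'   reporters of stages strictly downstream of the block lose their bump and
#'   read baseline only.
#' @param delay_h Hours by which the reporter peak is shifted (developmental
#'   delay).
#' @param attenuate_frac Multiplier in (0, 1] applied to the peak amplitude
#'   (1 = untreated strength).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise; 0 gives the deterministic expectation.
#' @param times Time grid in hours.
#'
#' @return Long data frame with columns `reporter`, `replicate_id`, `time_h`,
#'   `fluorescence`.
#' @examples
#' gen_reporter_course("fruiting_body", seed = 1, noise_cv = 0)
#' @export
gen_reporter_course <- function(stage, n_reps = 3L, seed = 1L,
                                block_at_stage = NULL, delay_h = 0,
                                attenuate_frac = 1, noise_cv = 0.05,
                                times = seq(0, 24, by = 2)) {
  stage <- match.arg(stage, STAGE_ORDER)
  if (!is.null(block_at_stage))
    block_at_stage <- match.arg(block_at_stage, STAGE_ORDER)
  if (attenuate_frac <= 0 || attenuate_frac > 1)
    stop("attenuate_frac must be in (0, 1]", call. = FALSE)
  p <- .stage_params(stage)
  amplitude <- p$amplitude * attenuate_frac
  if (!is.null(block_at_stage) &&
      match(stage, STAGE_ORDER) > match(block_at_stage, STAGE_ORDER))
    amplitude <- 0
  center <- p$center + delay_h
  mu <- p$baseline + amplitude * exp(-(times - center)^2 / (2 * p$width^2))
  set.seed(seed)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    if (noise_cv == 0) {
      y <- mu
    } else {
      s <- sqrt(log1p(noise_cv^2))
      y <- mu * stats::rlnorm(length(mu), meanlog = -s^2 / 2, sdlog = s)
    }
    out[[r]] <- data.frame(reporter = stage,
                           replicate_id = sprintf("rep%d", r),
                           time_h = times, fluorescence = y,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Configuration for a pooled insertional-mutagenesis selection screen
#'
#' Parameters of the multi-round pooled screen emulator.  Each round grows the
#' pool for a fixed number of generations; a mutant with selection coefficient
#' `s` changes in frequency as `(1 + s)^g` per round.  Sequencing reads are
#' drawn multinomially at a fixed depth per sample.  The vehicle (control)
#' screen always has all selection coefficients 0.
#'
#' @param seed Integer seed.
#' @param n_mutants Number of insertion mutants in the pool.
#' @param n_rounds Number of selection rounds (default 5).
#' @param generations_per_round Generations of growth per round (default 3.5,
#'   growth to confluency).
#' @param read_depth Sequencing reads per sample (> 0).
#' @param n_replicates Biological replicate populations per screen (default 2).
#' @param selection_coefficients Per-mutant selection coefficient in the drug
#'   screen; recycled scalar 0 allowed.  Every `s` must be > -1.
#' @param abundance_dispersion Log-normal sigma of the initial mutant
#'   abundances.
#' @param sample_rounds Rounds at which samples are sequenced (default 2 and 5).
#'
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(seed = 1L, n_mutants = 2000L, n_rounds = 5L,
                              generations_per_round = 3.5, read_depth = 5e6,
                              n_replicates = 2L, selection_coefficients = 0,
                              abundance_dispersion = 1,
                              sample_rounds = c(2L, 5L)) {
  if (read_depth <= 0) stop("read_depth must be > 0", call. = FALSE)
  s <- rep_len(selection_coefficients, n_mutants)
  if (any(s <= -1)) stop("selection coefficients must be > -1", call. = FALSE)
  if (any(sample_rounds > n_rounds))
    stop("sample_rounds must be <= n_rounds", call. = FALSE)
  structure(list(seed = as.integer(seed), n_mutants = as.integer(n_mutants),
                 n_rounds = as.integer(n_rounds),
                 generations_per_round = generations_per_round,
                 read_depth = read_depth,
                 n_replicates = as.integer(n_replicates),
                 selection_coefficients = s,
                 abundance_dispersion = abundance_dispersion,
                 sample_rounds = as.integer(sample_rounds)),
            class = "screen_sim_config")
}

#' Generate raw screen count matrices for drug and vehicle selections
#'
#' Simulates the pooled-screen design: one starting pool (log-normal mutant
#' abundances) split into a drug screen with the configured per-mutant
#' selection coefficients and a vehicle screen where every coefficient is 0.
#' Frequencies update deterministically per round as `f * (1 + s)^g` and reads
#' are drawn multinomially at the configured depth, independently per
#' biological replicate and sampled round.
#'
#' @param cfg A [screen_sim_config()].
#' @param screens Named list mapping screen name to its per-mutant selection
#'   coefficients; by default `drug` uses `cfg$selection_coefficients` and
#'   `vehicle` uses all-zero.
#'
#' @return A list of class `screen_sim` with elements `counts` (long data
#'   frame `insertion_id, screen, replicate, round, count`) and `config`.
#' @examples
#' cfg <- screen_sim_config(seed = 1, n_mutants = 50, read_depth = 1e4)
#' sim <- gen_screen_counts(cfg)
#' head(sim$counts)
#' @export
gen_screen_counts <- function(cfg, screens = NULL) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  if (is.null(screens))
    screens <- list(drug = cfg$selection_coefficients,
                    vehicle = rep(0, cfg$n_mutants))
  set.seed(cfg$seed)
  a0 <- stats::rlnorm(cfg$n_mutants, meanlog = 0,
                      sdlog = cfg$abundance_dispersion)
  ids <- sprintf("mut%05d", seq_len(cfg$n_mutants))
  g <- cfg$generations_per_round
  rows <- list()
  for (sc in names(screens)) {
    s <- rep_len(screens[[sc]], cfg$n_mutants)
    if (any(s <= -1)) stop("selection coefficients must be > -1", call. = FALSE)
    for (rd in cfg$sample_rounds) {
      w <- a0 * (1 + s) ^ (g * rd)
      p <- w / sum(w)
      for (rep_i in seq_len(cfg$n_replicates)) {
        counts <- as.vector(stats::rmultinom(1, size = cfg$read_depth, prob = p))
        rows[[length(rows) + 1L]] <- data.frame(
          insertion_id = ids, screen = sc, replicate = rep_i, round = rd,
          count = counts, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(counts = do.call(rbind, rows), config = cfg,
                 truth = data.frame(insertion_id = ids,
                                    s = rep_len(screens[[1L]], cfg$n_mutants),
                                    stringsAsFactors = FALSE)),
            class = "screen_sim")
}

#' Generate a two-strain growth-competition trajectory
#'
#' Emulates a competition between a test mutant and a labelled wild type mixed
#' 50:50 at the start.  The mutant's odds are multiplied by
#' `fitness_ratio^generations_per_round` each round; measured fractions can
#' carry beta-distributed noise.
#'
#' @param fitness_ratio Per-generation fitness of the mutant relative to the
#'   reference strain (> 0; 1 = neutral).
#' @param n_rounds Number of competition rounds (default 6).
#' @param start_frac Mutant fraction at round 0 (in (0, 1)).
#' @param generations_per_round Generations per round (default 3.5).
#' @param noise_precision Beta precision of the measured fraction
#'   (`Inf` = exact measurement; smaller = noisier).
#' @param seed Integer seed.
#'
#' @return Data frame with columns `round`, `fraction` (mutant fraction).
#' @examples
#' gen_competition(2, n_rounds = 3, generations_per_round = 1)
#' @export
gen_competition <- function(fitness_ratio, n_rounds = 6L, start_frac = 0.5,
                            generations_per_round = 3.5,
                            noise_precision = Inf, seed = 1L) {
  if (fitness_ratio <= 0) stop("fitness_ratio must be > 0", call. = FALSE)
  if (start_frac <= 0 || start_frac >= 1)
    stop("start_frac must be in (0, 1)", call. = FALSE)
  mult <- fitness_ratio ^ generations_per_round
  odds0 <- start_frac / (1 - start_frac)
  odds <- odds0 * mult ^ (0:n_rounds)
  frac <- odds / (1 + odds)
  if (is.finite(noise_precision)) {
    set.seed(seed)
    frac <- stats::rbeta(length(frac), noise_precision * frac,
                         noise_precision * (1 - frac))
  }
  data.frame(round = 0:n_rounds, fraction = frac)
}
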