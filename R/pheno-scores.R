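# Individual-mutant validation assays: competition fitness and fluid uptake.

#' Normalize a competition trajectory to a 50:50 start
#'
#' The observed mixes never start at exactly 50:50, so each round's mutant
#' odds are rescaled by the factor that moves the round-0 odds to 1 (fraction
#' 0.5).  This odds-based renormalization preserves the 0-1 range of the
#' mutant-to-labelled-wild-type ratio; output fractions are clipped to
#' `[0, 1]`.
#'
#' @param series Data frame with columns `round` and `fraction` (mutant
#'   fraction of the mixed population); round 0 must be present with a
#'   fraction strictly inside (0, 1).
#' @return The input with an added `normalized` column (round-0 value exactly
#'   0.5).
#' @examples
#' normalize_competition(data.frame(round = 0:2,
#'                                  fraction = c(0.6, 0.6, 0.6)))
#' @export
normalize_competition <- function(series) {
  stopifnot(is.data.frame(series), all(c("round", "fraction") %in% names(series)))
  if (!0 %in% series$round) stop("round 0 must be present", call. = FALSE)
  f0 <- series$fraction[series$round == 0][1]
  if (f0 <= 0 || f0 >= 1)
    stop("round-0 fraction must be in (0, 1): normalization undefined",
         call. = FALSE)
  scale <- (1 - f0) / f0                      # moves round-0 odds to 1
  odds <- series$fraction / (1 - series$fraction) * scale
  norm <- ifelse(series$fraction >= 1, 1, odds / (1 + odds))
  series$normalized <- pmin(pmax(norm, 0), 1)
  series
}

#' Competition fitness score of a mutant under drug selection
#'
#' The score is the mean over rounds 3 and the final round (6, or the round
#' at which one strain fixed) of the log2 ratio of the mutant's normalized
#' fraction in the drug competition to its normalized fraction in the vehicle
#' competition.  A positive score means the mutant performs better under the
#' drug than its vehicle behaviour predicts (resistant); the score is 0 when
#' the two trajectories coincide and is antisymmetric in the two series.
#' Fixation values are floored at `eps` before the log to keep the score
#' finite.
#'
#' @param drug,vehicle Normalized competition series
#'   ([normalize_competition()] output).
#' @param final_round Final round used (default: the largest round present
#'   in both series).
#' @param cells_measured Cells scored per flow-cytometry measurement; the
#'   fixation floor is `1 / (2 * cells_measured)`.
#' @return List of class `fitness_score` with `score`, `rounds_used` and the
#'   per-round log2 ratios.
#' @examples
#' d <- data.frame(round = c(0, 3, 6), normalized = c(0.5, 0.8, 0.8))
#' v <- data.frame(round = c(0, 3, 6), normalized = c(0.5, 0.4, 0.4))
#' competition_fitness(d, v)$score  # log2(2) = 1
#' @export
competition_fitness <- function(drug, vehicle, final_round = NULL,
                                cells_measured = 1e5) {
  stopifnot("normalized" %in% names(drug), "normalized" %in% names(vehicle))
  common <- intersect(drug$round, vehicle$round)
  if (is.null(final_round)) final_round <- max(common)
  rounds_used <- unique(c(3, final_round))
  if (!all(rounds_used %in% common))
    stop("rounds ", paste(setdiff(rounds_used, common), collapse = ", "),
         " missing from the competition series", call. = FALSE)
  eps <- 1 / (2 * cells_measured)
  val <- function(s, r) max(s$normalized[match(r, s$round)], eps)
  lr <- vapply(rounds_used,
               function(r) log2(val(drug, r) / val(vehicle, r)), numeric(1))
  structure(list(score = mean(lr), rounds_used = rounds_used,
                 log2_ratios = stats::setNames(lr, paste0("round", rounds_used))),
            class = "fitness_score")
}

#' @export
print.fitness_score <- function(x, ...) {
  cat(sprintf("<fitness_score> %.3f (rounds %s)\n", x$score,
              paste(x$rounds_used, collapse = ", ")))
  invisible(x)
}

#' Fluid-uptake score of a mutant relative to a control mutant
#'
#' Macropinocytic fluid uptake is read as the median fluorescence intensity
#' (MFI) of ingested labelled dextran.  For each strain the fold-change
#' reduction under treatment is `MFI_untreated / MFI_treated`; the score is
#' the log2 ratio of the test mutant's fold reduction to the control
#' mutant's.  A score of 0 means the mutant responds exactly like the
#' control; a negative score means its uptake is less reduced by the drug
#' (resistant uptake machinery).  The score is invariant to rescaling all
#' MFIs by a constant.
#'
#' @param mutant_untreated,mutant_treated,control_untreated,control_treated
#'   MFIs (> 0).
#' @param mutant,drug Labels stored in the result.
#' @return List of class `uptake_score` with the two fold reductions and
#'   `score`.
#' @examples
#' fluid_uptake_score(100, 100, 100, 50)$score  # -1
#' @export
fluid_uptake_score <- function(mutant_untreated, mutant_treated,
                               control_untreated, control_treated,
                               mutant = NA_character_, drug = NA_character_) {
  v <- c(mutant_untreated, mutant_treated, control_untreated, control_treated)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all MFIs must be positive", call. = FALSE)
  fr_m <- mutant_untreated / mutant_treated
  fr_c <- control_untreated / control_treated
  structure(list(mutant = mutant, drug = drug,
                 fold_reduction_mutant = fr_m,
                 fold_reduction_control = fr_c,
                 score = log2(fr_m / fr_c)),
            class = "uptake_score")
}

#' @export
print.uptake_score <- function(x, ...) {
  cat(sprintf("<uptake_score> %s [%s]: %.3f (mutant %.2fx, control %.2fx)\n",
              x$mutant, x$drug, x$score, x$fold_reduction_mutant,
              x$fold_reduction_control))
  invisible(x)
}
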