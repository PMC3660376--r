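#' Simulation parameters
#'
#' Constructs and validates the population-level parameter set of the
#' macronuclear-evolution simulator. The defaults describe a founding
#' population with a near-diploid macronucleus (low ploidy, few chromosome
#' types, no DNA elimination), the presumed ancestral state from which
#' fragmented, polyploid macronuclei evolve.
#'
#' @param X0 Initial copy number (copies per chromosome type). Default 10.
#' @param N0 Initial chromosome number (distinct chromosome types). Default 50.
#' @param Sd_copy Standard deviation of the copy-number mutation applied at
#'   conjugation (copies). Default 5.
#' @param Sd_elim Standard deviation of the elimination-coefficient mutation
#'   applied at conjugation (fraction). Default 0.01.
#' @param I Minimum iteration age before a cell may divide (iterations).
#'   Default 2: conjugation takes roughly twice as long as an asexual cycle.
#' @param M Minimum generation number before a cell may conjugate
#'   (asexual divisions). Default 15.
#' @param K Exponent weighting the DNA-content fitness cost. Default 0.2.
#' @param P Weight of the chromosome-imbalance fitness cost (multiplies the
#'   chromosome-number exponent). Default 1.
#' @param S Per-iteration conjugation probability for mature cells.
#'   Default 0.02.
#' @param pop_size Number of cells kept after each iteration's cull.
#'   Default 1000.
#' @param n_iter Number of iterations to simulate. Default 100000.
#' @param seed Integer RNG seed for the run.
#'
#' @return An object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params(n_iter = 1000)
#' p$X0
#' @export
sim_params <- function(X0 = 10, N0 = 50, Sd_copy = 5, Sd_elim = 0.01,
                       I = 2, M = 15, K = 0.2, P = 1, S = 0.02,
                       pop_size = 1000, n_iter = 100000, seed = 1L) {
  p <- list(X0 = as.numeric(X0), N0 = as.numeric(N0),
            Sd_copy = as.numeric(Sd_copy), Sd_elim = as.numeric(Sd_elim),
            I = as.numeric(I), M = as.numeric(M), K = as.numeric(K),
            P = as.numeric(P), S = as.numeric(S),
            pop_size = as.integer(pop_size), n_iter = as.integer(n_iter),
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  for (f in c("X0", "N0", "K", "P")) {
    stop_if(!is.finite(p[[f]]) || p[[f]] <= 0,
            sprintf("parameter '%s' must be strictly positive", f))
  }
  for (f in c("Sd_copy", "Sd_elim")) {  # zero = mutation disabled
    stop_if(!is.finite(p[[f]]) || p[[f]] < 0,
            sprintf("parameter '%s' must be >= 0", f))
  }
  stop_if(!is.finite(p$S) || p$S <= 0 || p$S > 1,
          "parameter 'S' must satisfy 0 < S <= 1")
  stop_if(p$I < 0, "parameter 'I' must be >= 0")
  stop_if(p$M < 0, "parameter 'M' must be >= 0")
  stop_if(is.na(p$pop_size) || p$pop_size < 1,
          "parameter 'pop_size' must be >= 1")
  stop_if(is.na(p$n_iter) || p$n_iter < 0,
          "parameter 'n_iter' must be >= 0")
  stop_if(is.na(p$seed), "parameter 'seed' must be an integer")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Macronuclear-evolution simulation parameters\n")
  flds <- c("X0", "N0", "Sd_copy", "Sd_elim", "I", "M", "K", "P", "S",
            "pop_size", "n_iter", "seed")
  for (f in flds) cat(sprintf("  %-8s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Table of heritable/age fields a single cell carries; used by the per-cell
# helpers and by initialize_population().
cell_fields <- c("G", "A", "N", "X", "E")
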