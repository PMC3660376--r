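# Explicit per-chromosome assortment simulator. This is the "brute force"
# view of amitosis -- tracking every chromosome type's copy number through
# successive divisions -- which is far too slow to sit inside the
# evolutionary loop but is exactly what the closed-form imbalance penalty
# (1 - q_G^X)^N summarises. It therefore serves as an independent
# Monte-Carlo oracle for that formula.

#' Simulate chromosome retention under explicit amitotic assortment
#'
#' Follows one daughter lineage of a cell whose macronucleus holds
#' `n_types` chromosome types at `copies` copies each. At every division
#' each copy is duplicated and each of the two resulting copies is
#' inherited by the followed daughter independently with probability 1/2,
#' so a type with `c` copies passes `Binomial(2c, 1/2)` copies on. After
#' `generations` divisions a replicate counts as "retained" if no type has
#' hit zero copies at any point.
#'
#' @param n_types Number of distinct chromosome types (N).
#' @param copies Initial copies per type (X), a positive integer.
#' @param generations Number of amitotic divisions to simulate (G).
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Optional RNG seed; if `NULL`, the current RNG state is used.
#' @return A list with `retained` (fraction of replicates with all types
#'   surviving), `se` (binomial standard error), and the configuration.
#' @examples
#' simulate_lineage_retention(1, 1, 1, reps = 1000, seed = 1)$retained # ~0.75
#' @export
simulate_lineage_retention <- function(n_types, copies, generations, reps,
                                       seed = NULL) {
  if (any(c(n_types, copies) < 1) || generations < 0)
    stop("n_types and copies must be >= 1, generations >= 0", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  alive <- rep(TRUE, reps)
  counts <- matrix(as.integer(copies), nrow = reps, ncol = n_types)
  g <- 0L
  while (g < generations && any(alive)) {
    idx <- which(alive)
    cc <- counts[idx, , drop = FALSE]
    cc[] <- stats::rbinom(length(cc), size = 2L * as.vector(cc), prob = 0.5)
    counts[idx, ] <- cc
    # a type at zero copies is permanently lost; drop those replicates
    alive[idx[rowSums(cc == 0L) > 0L]] <- FALSE
    g <- g + 1L
  }
  p <- mean(alive)
  list(retained = p, se = sqrt(p * (1 - p) / reps),
       n_types = n_types, copies = copies, generations = generations,
       reps = reps)
}

#' Compare the Monte-Carlo assortment oracle with the closed-form retention
#'
#' Runs [simulate_lineage_retention()] and compares the estimated retention
#' probability with the branching-process formula `(1 - q_G^X)^N`, reporting
#' the discrepancy in standard-error units.
#'
#' @inheritParams simulate_lineage_retention
#' @param se_limit Discrepancies beyond this many standard errors are
#'   flagged (default 3).
#' @return A one-row data frame with the estimate, its standard error, the
#'   formula value, the z-discrepancy and an `agree` flag.
#' @examples
#' compare_to_formula(1, 1, 1, reps = 2000, seed = 1)
#' @export
compare_to_formula <- function(n_types, copies, generations, reps,
                               seed = NULL, se_limit = 3) {
  mc <- simulate_lineage_retention(n_types, copies, generations, reps, seed)
  expected <- (1 - extinction_probability(generations)^copies)^n_types
  # guard against zero SE when the estimate saturates at 0 or 1
  se <- max(mc$se, sqrt(0.25 / reps) / 10)
  z <- (mc$retained - expected) / se
  data.frame(n_types = n_types, copies = copies, generations = generations,
             reps = reps, estimate = mc$retained, se = mc$se,
             formula = expected, z = z, agree = abs(z) <= se_limit)
}
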