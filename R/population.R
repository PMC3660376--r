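# The iteration loop. A population is stored column-wise (one numeric
# vector per cell property) so that conjugation, division and culling are
# single vectorised operations; at 1,000 cells this keeps a 100,000-
# iteration run in the minutes range without compiled code.
#
# Per iteration, each cell takes exactly one action:
#   1. a mature cell (G >= M) conjugates with probability S: X and E are
#      mutated (clamped normal), A and G reset to 0, N recomputed from E;
#   2. otherwise, a cell of age A >= I divides with probability equal to
#      its fitness F, adding an identical daughter to the pool (both with
#      G and A incremented); non-dividers just age by one iteration;
#   3. the pool (survivors + daughters) is culled uniformly at random,
#      independent of fitness, back to pop_size cells.

#' Initialize a founding population
#'
#' Every founding cell has the ancestral near-diploid state: copy number
#' `X0`, chromosome number `N0`, no DNA elimination (`E = 0`) and both age
#' counters at zero, hence fitness 1.
#'
#' @param params A [sim_params()] object.
#' @return A `mac_population`: a list of per-cell vectors `X`, `E`, `N`,
#'   `G`, `A` plus the current `iteration`.
#' @examples
#' pop <- initialize_population(sim_params(pop_size = 10))
#' @export
initialize_population <- function(params) {
  n <- params$pop_size
  structure(list(X = rep(params$X0, n),
                 E = numeric(n),
                 N = rep(params$N0, n),
                 G = numeric(n),
                 A = numeric(n),
                 iteration = 0L),
            class = "mac_population")
}

#' @export
print.mac_population <- function(x, ...) {
  cat(sprintf("Population of %d cells at iteration %d\n",
              length(x$X), x$iteration))
  cat(sprintf("  mean X %.3g, mean E %.4f, mean N %.4g, mean G %.2f\n",
              mean(x$X), mean(x$E), mean(x$N), mean(x$G)))
  invisible(x)
}

#' @export
as.data.frame.mac_population <- function(x, ...) {
  data.frame(X = x$X, E = x$E, N = x$N, G = x$G, A = x$A)
}

#' Clamped normal mutation
#'
#' Draws from a normal distribution centred on the parent value and
#' reassigns any draw outside `[lo, hi]` to the violated bound (no
#' resampling). This is the mutation kernel applied to the heritable copy
#' number (`lo = 0`) and elimination coefficient (`lo = 0`, `hi = 0.98`,
#' above which elimination is lethal) at conjugation.
#'
#' @param value Parent value(s).
#' @param sd Mutation standard deviation (>= 0).
#' @param lo,hi Bounds; draws outside are clamped.
#' @return Mutated value(s), in `[lo, hi]`.
#' @export
mutate_clamped <- function(value, sd, lo = -Inf, hi = Inf) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (lo > hi) stop("lo must be <= hi", call. = FALSE)
  pmin(hi, pmax(lo, stats::rnorm(length(value), mean = value, sd = sd)))
}

#' Attempt sexual conjugation for one cell
#'
#' A cell may conjugate only once its generation number has reached the
#' maturity threshold `M`; it then does so with probability `S` in any
#' given iteration. Conjugation here is self-conjugation (no partner, no
#' exchange): the heritable copy number and elimination coefficient are
#' mutated, both age counters reset to zero, and the chromosome number is
#' recomputed from the new elimination coefficient.
#'
#' @param cell Named list with fields `X`, `E`, `N`, `G`, `A`.
#' @param params A [sim_params()] object.
#' @return List with the (possibly updated) `cell` and a `conjugated` flag.
#' @export
attempt_conjugation <- function(cell, params) {
  if (cell$G >= params$M && stats::runif(1) < params$S) {
    cell$X <- mutate_clamped(cell$X, params$Sd_copy, lo = 0)
    cell$E <- mutate_clamped(cell$E, params$Sd_elim, lo = 0, hi = 0.98)
    cell$N <- chromosome_number_from_elimination(cell$E, params$N0)
    cell$G <- 0
    cell$A <- 0
    list(cell = cell, conjugated = TRUE)
  } else {
    list(cell = cell, conjugated = FALSE)
  }
}

#' Attempt asexual division for one cell
#'
#' A cell that did not conjugate this iteration and has iteration age
#' `A >= I` divides with probability equal to its fitness. Division
#' increments `G` and `A` and adds an identical daughter; the heritable
#' `X`, `E`, `N` are fixed between conjugations. A cell that neither
#' conjugates nor divides ages by one iteration (`A` only).
#'
#' @param cell Named list with fields `X`, `E`, `N`, `G`, `A`.
#' @param params A [sim_params()] object.
#' @return List with the updated `cell` and `daughter` (`NULL` if no
#'   division occurred).
#' @export
attempt_division <- function(cell, params) {
  divided <- cell$A >= params$I &&
    stats::runif(1) < total_fitness(cell, params)
  if (divided) cell$G <- cell$G + 1
  cell$A <- cell$A + 1
  list(cell = cell, daughter = if (divided) cell else NULL)
}

#' Cull a population to the target size
#'
#' Selects `pop_size` survivors uniformly at random without replacement
#' from the pooled parents and daughters, independent of fitness. Pools at
#' or below the target survive intact.
#'
#' @param pop A `mac_population`.
#' @param params A [sim_params()] object.
#' @return The culled `mac_population`.
#' @export
cull <- function(pop, params) {
  n <- length(pop$X)
  if (n == 0L) stop("population is extinct", call. = FALSE)
  if (n <= params$pop_size) return(pop)
  keep <- sample.int(n, params$pop_size)
  for (f in cell_fields) pop[[f]] <- pop[[f]][keep]
  pop
}

# one vectorised iteration; returns the culled population
step_population <- function(pop, params) {
  n <- length(pop$X)
  # -- conjugation pass -----------------------------------------------
  conj <- pop$G >= params$M & stats::runif(n) < params$S
  nc <- sum(conj)
  if (nc > 0L) {
    pop$X[conj] <- mutate_clamped(pop$X[conj], params$Sd_copy, lo = 0)
    pop$E[conj] <- mutate_clamped(pop$E[conj], params$Sd_elim,
                                  lo = 0, hi = 0.98)
    pop$N[conj] <- chromosome_number_from_elimination(pop$E[conj], params$N0)
    pop$G[conj] <- 0
    pop$A[conj] <- 0
  }
  # -- division pass --------------------------------------------------
  fit <- dna_fitness(pop$X, pop$E, params$X0, params$K) *
    imbalance_fitness(pop$X, pop$N, pop$G, params$P)
  div <- !conj & pop$A >= params$I & stats::runif(n) < fit
  pop$G[div] <- pop$G[div] + 1
  pop$A[!conj] <- pop$A[!conj] + 1
  d <- which(div)
  if (length(d) > 0L) {
    for (f in cell_fields) pop[[f]] <- c(pop[[f]], pop[[f]][d])
  }
  pop$iteration <- pop$iteration + 1L
  cull(pop, params)
}

summary_columns <- c("iteration",
                     "mean_X", "median_X", "sd_X",
                     "mean_E", "median_E", "sd_E",
                     "mean_N", "median_N", "sd_N",
                     "mean_Fdna", "mean_Fimb", "mean_F", "frac_mature")

summarize_population <- function(pop, params) {
  fdna <- dna_fitness(pop$X, pop$E, params$X0, params$K)
  fimb <- imbalance_fitness(pop$X, pop$N, pop$G, params$P)
  c(pop$iteration,
    mean(pop$X), stats::median(pop$X), stats::sd(pop$X),
    mean(pop$E), stats::median(pop$E), stats::sd(pop$E),
    mean(pop$N), stats::median(pop$N), stats::sd(pop$N),
    mean(fdna), mean(fimb), mean(fdna * fimb),
    mean(pop$G >= params$M))
}

#' Run the evolutionary simulation
#'
#' Iterates conjugation, division and uniform culling for `params$n_iter`
#' iterations, recording population summaries at a fixed cadence. The run
#' is fully reproducible from `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param record_every Record a summary every this many iterations
#'   (iteration 0 and the final iteration are always recorded).
#' @return A `mac_sim` object: list with `summary` (data frame of
#'   [PopulationSummary][run_simulation] rows: iteration, mean/median/sd of
#'   X, E, N, mean fitness components, fraction of conjugation-mature
#'   cells), `final` (data frame of end-state cells), `params`, and
#'   `collapsed` (`TRUE` when the final mean fitness is below 1e-3,
#'   i.e. the population has effectively stopped dividing).
#' @examples
#' sim <- run_simulation(sim_params(pop_size = 50, n_iter = 200, seed = 1))
#' tail(sim$summary)
#' @export
run_simulation <- function(params, record_every = 100L) {
  stopifnot(inherits(params, "sim_params"))
  record_every <- max(1L, as.integer(record_every))
  set.seed(params$seed)
  pop <- initialize_population(params)
  n_rec <- params$n_iter %/% record_every + 2L
  recs <- matrix(NA_real_, nrow = n_rec, ncol = length(summary_columns))
  recs[1L, ] <- summarize_population(pop, params)
  k <- 1L
  if (params$n_iter > 0) {
    for (it in seq_len(params$n_iter)) {
      pop <- step_population(pop, params)
      if (it %% record_every == 0L || it == params$n_iter) {
        k <- k + 1L
        recs[k, ] <- summarize_population(pop, params)
      }
    }
  }
  summary <- as.data.frame(recs[seq_len(k), , drop = FALSE])
  names(summary) <- summary_columns
  summary <- summary[!duplicated(summary$iteration), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 final = as.data.frame(pop),
                 params = params,
                 collapsed = summary$mean_F[nrow(summary)] < 1e-3),
            class = "mac_sim")
}

#' @export
print.mac_sim <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("Macronuclear-evolution run: %d cells, %d iterations (seed %d)\n",
              x$params$pop_size, x$params$n_iter, x$params$seed))
  cat(sprintf("  end state: mean X %.1f, mean E %.4f, mean N %.0f, mean F %.3f%s\n",
              last$mean_X, last$mean_E, last$mean_N, last$mean_F,
              if (x$collapsed) " [collapsed]" else ""))
  invisible(x)
}
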