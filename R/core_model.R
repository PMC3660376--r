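# Closed-form components of the fitness model: the elimination-to-
# fragmentation map, the amitotic chromosome-loss probability from a
# critical Galton-Watson branching process, and the two fitness penalties
# (DNA content, chromosome imbalance) whose product is a cell's division
# probability.

# cache of extinction probabilities q_g, grown on demand
.q_env <- new.env(parent = emptyenv())
.q_env$q <- 0  # q_0 = 0

#' Chromosome number implied by an elimination coefficient
#'
#' Maps the fraction `E` of germline (micronuclear) DNA eliminated during
#' macronuclear development to the number of distinct macronuclear
#' chromosomes, assuming fragmentation grows exponentially with elimination.
#' The map is pinned by two fixed points: with no elimination the
#' macronucleus keeps the `N0` germline chromosomes, and at the maximum
#' elimination observed in spirotrichs (98% of the micronuclear genome) the
#' chromosome number reaches 20,000, approximately one chromosome per gene:
#'
#' \deqn{N(E) = N_0 \, (20000/N_0)^{E/0.98}}
#'
#' @param E Elimination coefficient(s), in \[0, 0.98\].
#' @param N0 Initial (germline) chromosome number, > 0.
#' @return Chromosome number(s), same length as `E`.
#' @examples
#' chromosome_number_from_elimination(0, 50)     # 50
#' chromosome_number_from_elimination(0.98, 50)  # 20000
#' @export
chromosome_number_from_elimination <- function(E, N0) {
  if (length(N0) != 1L || !is.finite(N0) || N0 <= 0)
    stop("N0 must be a single positive number", call. = FALSE)
  if (any(!is.finite(E)) || any(E < 0) || any(E > 0.98))
    stop("E must lie in [0, 0.98]", call. = FALSE)
  N0 * (20000 / N0)^(E / 0.98)
}

#' Extinction probability of a single chromosome copy's lineage
#'
#' Under amitosis each chromosome copy is duplicated and each of the two
#' resulting copies lands in a given daughter independently with probability
#' 1/2, so a copy's lineage within one daughter line is a critical
#' Galton-Watson process with Binomial(2, 1/2) offspring. `extinction_probability`
#' returns the probability `q_G` that the lineage founded by one copy is
#' extinct after `G` divisions, from the exact generating-function recursion
#'
#' \deqn{q_0 = 0, \qquad q_{g+1} = \left(\frac{1 + q_g}{2}\right)^2}
#'
#' The process is critical (mean offspring 1), so \eqn{q_G \to 1} with the
#' classical asymptotics \eqn{G (1 - q_G) \to 4}. Values are memoised: the
#' recursion is evaluated once up to the largest `G` ever requested.
#'
#' @param G Non-negative integer number of amitotic divisions (vectorised).
#' @return `q_G`, in \[0, 1).
#' @examples
#' extinction_probability(0:2)  # 0, 0.25, 0.390625
#' @export
extinction_probability <- function(G) {
  if (any(!is.finite(G)) || any(G < 0) || any(G != floor(G)))
    stop("G must be a non-negative integer", call. = FALSE)
  gmax <- max(G, 0)
  q <- .q_env$q
  if (length(q) <= gmax) {
    old <- length(q)
    q <- c(q, numeric(gmax + 1 - old))
    for (g in old:(gmax)) q[g + 1L] <- ((1 + q[g]) / 2)^2
    .q_env$q <- q
  }
  .q_env$q[G + 1L]
}

#' DNA-content fitness penalty
#'
#' Relative fitness cost of replicating the macronuclear genome, measured as
#' the retained DNA content of the founding population over that of the
#' cell, raised to the exponent `K` and capped at 1 (a cell cannot do better
#' than the founding fitness by shedding DNA):
#'
#' \deqn{F_{DNA} = \min\left(1, \left(\frac{X_0}{X (1 - E)}\right)^K\right)}
#'
#' A cell's total macronuclear DNA is proportional to its ploidy `X` times
#' the fraction `1 - E` of the germline genome it retains. Cells with no
#' macronuclear DNA (`X <= 0`) get fitness 0 rather than an error.
#'
#' @param X Copy number(s) (real-valued ploidy).
#' @param E Elimination coefficient(s), in \[0, 1).
#' @param X0 Founding copy number, > 0.
#' @param K Cost exponent, > 0.
#' @return Fitness in \[0, 1\], vectorised over `X` and `E`.
#' @examples
#' dna_fitness(10, 0, 10, 0.2)    # founding cell: 1
#' dna_fitness(20, 0, 10, 0.2)    # 0.5^0.2
#' dna_fitness(500, 0.98, 10, 0.2)  # retained DNA back at X0: 1
#' @export
dna_fitness <- function(X, E, X0, K) {
  if (any(!is.finite(E)) || any(E < 0) || any(E >= 1))
    stop("E must lie in [0, 1)", call. = FALSE)
  if (length(X0) != 1L || X0 <= 0) stop("X0 must be positive", call. = FALSE)
  if (length(K) != 1L || K <= 0) stop("K must be positive", call. = FALSE)
  len <- max(length(X), length(E))
  X <- rep_len(X, len); E <- rep_len(E, len)
  out <- numeric(len)
  ok <- X > 0
  out[ok] <- pmin(1, (X0 / (X[ok] * (1 - E[ok])))^K)
  out
}

#' Chromosome-imbalance fitness penalty
#'
#' Probability that a cell has not completely lost any chromosome type after
#' `G` amitotic divisions, used as a proxy for the fitness cost of the
#' copy-number imbalances amitosis generates. A type with `X` starting
#' copies is lost when all `X` copy lineages go extinct
#' (probability `q_G^X`, see [extinction_probability()]); with `N`
#' independent, exchangeable types and an imbalance weight `P`,
#'
#' \deqn{F_{imb} = (1 - q_G^X)^{N P}}
#'
#' At `P = 1` this is the plain retention probability for `N` types. A
#' freshly conjugated cell (`G = 0`) has a balanced macronucleus and
#' `F_imb = 1`; a cell with no DNA (`X = 0`) that has divided at least once
#' has `F_imb = 0`.
#'
#' @param X Copy number(s), >= 0 (real-valued).
#' @param N Chromosome number(s), > 0.
#' @param G Generation number(s) (divisions since conjugation), >= 0.
#' @param P Imbalance weight, > 0.
#' @return Fitness in \[0, 1\], vectorised over `X`, `N`, `G`.
#' @examples
#' imbalance_fitness(10, 50, 0, 1)  # balanced: 1
#' imbalance_fitness(1, 1, 1, 1)    # 1 - 1/4
#' @export
imbalance_fitness <- function(X, N, G, P) {
  if (any(X < 0)) stop("X must be >= 0", call. = FALSE)
  if (any(N <= 0)) stop("N must be > 0", call. = FALSE)
  if (length(P) != 1L || P <= 0) stop("P must be positive", call. = FALSE)
  q <- extinction_probability(G)
  len <- max(length(X), length(N), length(G))
  X <- rep_len(X, len); N <- rep_len(N, len); q <- rep_len(q, len)
  out <- (1 - q^X)^(N * P)
  # q_0 = 0 and 0^0 = 1 would wrongly zero a balanced cell with X = 0
  out[rep_len(G, len) == 0] <- 1
  out
}

#' Total fitness of a cell
#'
#' Product of the DNA-content and chromosome-imbalance penalties; used as
#' the per-iteration division probability.
#'
#' @param cell A cell (named list or data frame with fields `X`, `E`, `N`,
#'   `G`); vectorised when the fields are vectors.
#' @param params A [sim_params()] object.
#' @return Fitness in \[0, 1\].
#' @examples
#' p <- sim_params()
#' total_fitness(list(X = 10, E = 0, N = 50, G = 0), p)  # 1
#' @export
total_fitness <- function(cell, params) {
  dna_fitness(cell$X, cell$E, params$X0, params$K) *
    imbalance_fitness(cell$X, cell$N, cell$G, params$P)
}
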