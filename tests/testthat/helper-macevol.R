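# small-population parameter sets used across tests
tiny_params <- function(...) {
  args <- list(pop_size = 40, n_iter = 200, seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

# brute-force retention probability by full enumeration for one chromosome
# type: exact P(lineage not extinct after g divisions) starting from x
# copies, via the generating-function recursion evaluated independently of
# extinction_probability(). Used as an oracle for the q-recursion itself.
enum_retention_one_type <- function(x, g) {
  # distribution over copy counts, truncated at a generous maximum
  maxc <- max(4 * x, 64)
  pr <- numeric(maxc + 1)
  pr[x + 1] <- 1
  for (i in seq_len(g)) {
    nxt <- numeric(maxc + 1)
    for (c in 0:maxc) {
      if (pr[c + 1] == 0) next
      if (c == 0) { nxt[1] <- nxt[1] + pr[1]; next }
      ks <- 0:min(2 * c, maxc)
      nxt[ks + 1] <- nxt[ks + 1] + pr[c + 1] * stats::dbinom(ks, 2 * c, 0.5)
    }
    pr <- nxt
  }
  1 - pr[1]
}
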