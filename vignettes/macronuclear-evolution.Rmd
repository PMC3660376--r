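---
title: "Modelling the evolution of fragmented, polyploid macronuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of fragmented, polyploid macronuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macevol)
```

## The biological question

Ciliates carry two nuclei: a diploid, mitotically dividing germline
micronucleus (MIC) and a polyploid somatic macronucleus (MAC) that divides
by *amitosis* — duplicated chromosomes are distributed to daughter nuclei
at random, without a spindle. In several lineages (spirotrichs most
famously) the MAC is extraordinarily derived: ~20,000 distinct, often
single-gene "nanochromosomes", each at hundreds to thousands of copies,
produced by eliminating up to 98% of the germline genome during MAC
development. `macevol` implements a population model in which this
architecture emerges from the competition of just two costs:

* **Chromosome imbalance.** Random assortment means a chromosome type can
  be lost outright after enough divisions; the fewer copies each type has,
  the sooner. Loss (and the aneuploid imbalance preceding it) is costly.
* **DNA content.** Raising ploidy to buffer assortment noise multiplies
  the total DNA to replicate, which slows division. Eliminating germline
  DNA offsets that cost — but elimination fragments the genome into more
  chromosome types, each of which can now be lost independently, renewing
  the pressure for ploidy.

The feedback loop (more ploidy → more DNA → more elimination → more
fragmentation → more ploidy) pushes populations toward the observed
extreme: elimination near its viable maximum, ~20,000 chromosome types,
and a large ploidy increase.

## State, parameters and the three structural equations

Each cell carries five properties: copy number $X$ (copies per chromosome
type, real-valued), elimination coefficient $E \in [0, 0.98]$, chromosome
number $N$, generation number $G$ (divisions since the last conjugation)
and iteration age $A$ (iterations since the last conjugation). $X$ and $E$
are heritable and mutate only at conjugation; $N$ is a deterministic
function of $E$.

**Fragmentation map.** $N(E) = N_0\,(20000/N_0)^{E/0.98}$, exponential in
$E$ and pinned by two fixed points: no elimination keeps the $N_0$
germline chromosomes, and maximal elimination (98%, the spirotrich
extreme) yields 20,000 chromosomes — roughly one per gene, the natural
ceiling on fragmentation.

**Chromosome loss.** Under amitosis a copy is duplicated and each of the
two products goes to a given daughter independently with probability 1/2,
so the lineage of one copy within a daughter line is a *critical
Galton–Watson process* with Binomial(2, 1/2) offspring. Its extinction
probability after $G$ divisions obeys the exact recursion
$q_0 = 0$, $q_{g+1} = ((1+q_g)/2)^2$, with the classical critical
asymptotics $G(1-q_G) \to 4$. We evaluate the recursion exactly (memoised)
rather than using the asymptotic form, so small $G$ — where most cells
live — is handled correctly.

**Fitness.** Division probability is the product of two penalties:

$$F_{\mathrm{DNA}} = \min\!\left(1, \left(\frac{X_0}{X\,(1-E)}\right)^{K}\right),
\qquad
F_{\mathrm{imb}} = \left(1 - q_G^{\,X}\right)^{N P},
\qquad F = F_{\mathrm{DNA}} \cdot F_{\mathrm{imb}}.$$

$F_{\mathrm{DNA}}$ compares a cell's retained DNA content $X(1-E)$ with
the founding content $X_0$ and is capped at 1 (shedding DNA below the
founding content confers no advantage). $F_{\mathrm{imb}}$ is the
probability that none of the $N$ types has been completely lost after $G$
divisions, used as a proxy for imbalance costs generally; the exponents
$K$ and $P$ weight the two penalties. On the surface $X(1-E) = X_0$ the
DNA penalty vanishes exactly; with $E$ pinned at its 0.98 bound and
$X_0 = 10$ that surface passes through $X = 500$, which is why end-state
ploidy hovers near a 50-fold increase.

The printed functional forms of these penalties exist in the source
literature only as figure images; the forms above are reconstructions
pinned by the accompanying verbal descriptions, and each lives behind a
single function (`dna_fitness()`, `imbalance_fitness()`) so alternates
can be swapped. Two points were genuinely open and were decided here:
$P$ enters as a multiplier on the chromosome-number exponent (so at
$P = 1$ the imbalance penalty reduces to the plain retention
probability), and $X$ is kept real-valued, with $q_G^X$ evaluated for
real $X$ — mutations are normal draws and nothing in the model requires
integer ploidy.

## The population loop

A population of `pop_size` (default 1,000) cells is iterated; per
iteration each cell takes exactly one action:

1. **Conjugation.** A cell with $G \ge M$ conjugates with probability
   $S$. Conjugation is *self*-conjugation — no partner, no exchange —
   which sidesteps mate choice and trait averaging. $X$ and $E$ are
   mutated by clamped normal draws (s.d. `Sd_copy`, `Sd_elim`; draws
   outside bounds are reassigned to the bound, with $E > 0.98$ lethal
   hence clamped at 0.98 and both bounded below by 0), $N$ is recomputed
   from the new $E$, and $G = A = 0$: the rebuilt MAC is balanced.
2. **Division.** Otherwise, a cell with $A \ge I$ divides with
   probability $F$, adding an identical daughter (both with $G$, $A$
   incremented); non-dividers age by one iteration. The age gate $I$
   models the extra time conjugation takes relative to an asexual cycle.
3. **Culling.** The pool of survivors plus daughters is culled uniformly
   at random — *independent of fitness* — back to `pop_size`. Selection
   acts only through differential division.

Daughters join the pool but are not processed further within the
iteration. Cells are updated as columns of vectors; because cells do not
interact within an iteration (the only coupling is the final uniform
cull), the update is order-free and no explicit shuffling is needed.
Founding cells start at $X = X_0$, $E = 0$, $N = N_0$, $G = A = 0$, hence
fitness exactly 1, and must wait $I$ iterations before first dividing,
consistent with the post-conjugation recovery rule. A single RNG stream
is seeded from `seed`; identical parameters and seed reproduce a
trajectory bit-for-bit.

Default parameter values (and the ranges the sweep machinery explores):
$X_0 = 10$ [10–50], $N_0 = 50$ [35–75] (a "nearly diploid" karyorelict-like
founding MAC), `Sd_copy` $= 5$ [5–50] copies, `Sd_elim` $= 0.01$
[0.01–0.05], $I = 2$ [0–4] iterations, $M = 15$ [5–20] generations,
$K = 0.2$ [0.1–1.0], $P = 1$ [0.5–2], $S = 0.02$ [0.01–0.1] per iteration.

Under this model a population can never literally die out — parents
always survive to the cull — so "extinction" is operationalised as
*collapse*: a final mean fitness below $10^{-3}$, i.e. division has
effectively ceased. Starting ploidy near 1 produces exactly this: a
single amitotic division strands most lineages, fitness crashes before
any cell reaches the conjugation threshold, and the population freezes.

## The assortment oracle

`simulate_lineage_retention()` implements the "brute force" view the
closed form summarises: it tracks every type's copy count through
explicit Binomial$(2c, 1/2)$ assortment draws, following one daughter
lineage per replicate (by symmetry this suffices for retention
probabilities and keeps cost linear in $G$). Types assort independently —
no constraint forces daughters to receive exactly half the total DNA,
matching the per-chromosome 50% mechanism; a total-DNA-conserving
(hypergeometric) variant would be a different model and is deliberately
not implemented. `compare_to_formula()` reports the z-discrepancy between
the Monte-Carlo estimate and $(1 - q_G^X)^N$; the test suite holds them
to within 3 standard errors over a grid of $(X, N, G)$, and to exact
small-case values ($3/4$ for one copy of one type surviving one division,
$9/16$ for two types).

This equivalence is also why the evolutionary loop never needs
per-chromosome bookkeeping: with thousands of types such tracking is
prohibitively slow, and the closed form is exact for the question the
fitness function asks.

## Convergence, replicates and sweeps

`detect_convergence()` declares a recorded series stable at the first
iteration from which its windowed mean (window 2,000 iterations, relative
tolerance 5% by default) stays within tolerance of its final windowed
mean, provided that stretch spans at least one full window — a series
still ramping at the end is reported as not converged. The choice of
windowed-mean stability is this package's operationalisation; nothing in
the underlying model prescribes one.

`run_replicates()` spaces replicate seeds `seed_stride` apart;
`run_sweep()` varies one parameter at a time around the defaults (a full
factorial would add little at desk scale and was not part of the original
study design) and guarantees seed uniqueness across (setting, replicate)
pairs. Sweep output is a plain data frame — re-aggregating the per-run
rows reproduces the table.

## Problem sizes and what the checks show

A default run at the historical scale (1,000 cells × 100,000 iterations)
takes on the order of a minute here. The package's own acceptance runs
use 60,000 iterations with three seeds: the elimination coefficient
stabilises near 0.98 by roughly iteration 20,000 and the copy number near
450–470 by roughly 45,000, so a final window of 1,000 iterations sits
well inside the stationary regime while keeping the whole computation in
the minutes range.

The budget matters because the *onset* of the feedback loop is a
stochastic waiting time: a population can linger near the founding state
for tens of thousands of iterations before elimination and ploidy take
off together, and then converge quickly. Parameters that strengthen the
penalties ($K$, $P$), delay division ($I$) or raise the founding DNA
content ($X_0$) stretch that waiting time considerably — at 20,000
iterations a run with $K = 1$ has typically not ignited at all, while by
40,000–60,000 every endpoint of every admissible range reaches the same
fragmented, polyploid end state. The bundled reduced sweep therefore
exercises the endpoints of the three population-wide force parameters
($K$, $P$, $S$) at 60,000 iterations × 3 replicates; the full
nine-parameter range sweep is a `run_sweep()` call away but takes a
couple of CPU-hours.

These simulations are *synthetic by construction*: they demonstrate that
the two-cost model is sufficient to generate extreme fragmentation and
polyploidy, with the end state robust across the parameter ranges. They
do not — and cannot — show that real spirotrich ploidy levels (thousands
of copies) are quantitatively reproduced: the model caps the DNA-cost-free
ploidy at $X_0/(1-E_{\max}) = 500$ for the default founding state, an
order of magnitude below nature, and it omits copy-number regulation,
true sexual exchange, dosage-dependent (partial-imbalance) fitness and
any mechanism of how fragmentation evolves mechanistically.

## Numerical notes

* $q_G$ values are memoised once per session; the recursion is $O(G)$ and
  exact to machine precision.
* $F_{\mathrm{imb}}$ special-cases $G = 0$ to 1, since `0^0` would
  otherwise zero a balanced cell with $X = 0$; a cell with $X = 0$ that
  has divided is inviable ($F = 0$) but persists until culled.
* Mutation s.d. of zero is allowed and simply disables mutation — useful
  for invariance testing, though outside the studied ranges.
* Trajectory CSVs are written at 17 significant digits so round-trips are
  bit-exact; manifests are schema-versioned JSON carrying everything
  needed to reproduce a run (parameters + seed).
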