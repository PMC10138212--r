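---
title: "Methods: rare-event sampling of the genetic code fitness landscape"
author: "codonscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-event sampling of the genetic code fitness landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(codonscape)
```

## The question and the model

The standard genetic code (SGC) maps 64 codons to 20 amino acids plus three
stop codons, and does so in a conspicuously non-random, block-wise fashion.
The error-minimisation hypothesis holds that this structure was selected to
damp the phenotypic consequences of translational misreading: when codon
$c$ is misread as a single-base neighbour $c'$, the damage is smaller if the
two encoded amino acids are physicochemically similar. `codonscape`
implements a complete, tested pipeline for quantifying how rare codes as
robust as the SGC are in a *fully random* code ensemble, reconstructing the
low-cost landscape, and measuring how strongly a simple evolutionary
algorithm's outcome distribution deviates from the unbiased one.

The cost of a code $a$ is the weight-normalised mean substitution penalty
over ordered single-error codon pairs,

$$\mathrm{cost}(a) \;=\; \sum_{c}\sum_{c'} P(c'\mid c)\,
  d\!\big(a(c),\,a(c')\big),$$

with misreading weights that depend only on the changed base position and
on whether the change is a transition (within purines or within
pyrimidines) or a transversion: any third-base change has weight 1, a
first-base transition 1, a first-base transversion 0.5, a second-base
transition 0.5, a second-base transversion 0.1; double and triple changes
carry weight 0, so every codon has exactly nine weighted neighbours (raw
weight sum 5.7). $P(c'\mid c)$ is these weights normalised by the total
over all ordered sense–sense pairs. The penalty
$d(x,y) = (\mathrm{PR}(x) - \mathrm{PR}(y))^2$ is the squared difference on
Woese's polar-requirement scale, on which Asp (13.0) and Glu (12.5) are the
two extreme values. Misreadings into or out of stop codons are assigned
constant costs $c_0 = c_1 = 0$; they shift only the baseline, never the
difference between two codes, and with zeros the stop pairs drop out of
both numerator and denominator. Under these conventions the SGC scores
**2.628**, printed as 2.6 at display precision — this is also the indirect
validation of the transcribed polar-requirement fixture.

```{r}
codeCost(sgcCode())   # 2.628345
```

## The constrained random ensemble

Random codes keep the biology minimal but non-degenerate: (1) each sense
codon may encode any of the 20 amino acids; (2) stops stay exactly at the
SGC's three positions; (3) all 20 amino acids must be present; (4) Asp and
Glu each appear at least twice (their multiplicity in the SGC). Condition
(4) exists because the two extreme polar-requirement values dominate the
cost; without it, almost all low-cost codes carry a single Asp and a single
Glu, a structurally different regime (the relaxed ensemble with floors of 1
is available via `ensembleConstraints(minAsp = 1, minGlu = 1)`).

`countEnsemble()` counts this ensemble exactly: multiplicities of the
floor-2 amino acids are convolved explicitly and the remaining surjectivity
is handled by inclusion–exclusion, all in exact integer arithmetic (a small
internal big-number module; the environment the package targets has no
arbitrary-precision integer package). The count is $6.1 \times 10^{78}$
codes, i.e. on the order of $10^{79}$ — about $10^{61}$ times larger than
the $20! \approx 10^{18}$ block-permutation ensemble of the earlier
literature (`blockSample()`), which permutes amino acids over the SGC's
blocks and therefore never alters the block structure itself.

## Rare-event estimation of the density of states

Naive uniform sampling (`naiveSample()`, rejection on the constraints,
acceptance rate $\approx 0.27$) cannot reach SGC-level costs: the mean
random-code cost is about 12.7 and the density of codes below 2.63 turns
out to be of order $10^{-20}$. The package therefore treats the cost axis
as an energy and estimates the density of states $\Omega(\mathrm{cost})$
multicanonically:

1. **Weight training** (`wangLandau()`): the flat-histogram Wang–Landau
   iteration builds $w(\mathrm{cost}) \propto 1/\Omega(\mathrm{cost})$ on a
   binned cost axis. Defaults: initial log modification factor 1.0, halved
   each time every visited bin holds at least 80% of the mean count,
   stopping below $10^{-6}$. These schedule constants are standard
   Wang–Landau practice; they are exposed in `wlSchedule()`.
2. **Production** (`mucaSample()`): a fixed-weight Markov chain with
   single-codon flip proposals and acceptance
   $\min\{1, w(\mathrm{cost}')/w(\mathrm{cost})\}$, which performs an
   unbiased random walk along the cost axis. Candidates violating the
   ensemble constraints are rejected in place (the current bin is
   re-counted), which preserves the stationary distribution on the
   constrained set.
3. **Estimation** (`estimateDOS()`): $\Omega \propto H/w$ from the
   production histogram $H$; fraction mode normalises to unit mass,
   absolute mode anchors the integral to the exact `countEnsemble()` size —
   a stronger anchor than matching the naive-sampling histogram, which is
   instead kept as a cross-check in the high-cost overlap region.
   `tailFraction()` then integrates the DOS below a threshold.

Numerical choices: the default grid spans costs 2 to 21 with 0.01-wide
half-open bins (the bulk of the naive distribution ends near 20; 0.01
resolves the $2.6 \pm 0.1$ slice; out-of-range costs clamp to the edge
bins, so the top bin also absorbs the negligible mass beyond the grid).
The chain's running cost is refreshed by a full recomputation every
$10^6$ steps to cancel floating-point drift of the incremental updates.
All randomness flows through R's generator, so a seed makes chains
bit-reproducible; single-flip cost updates touch only the nine neighbours
of the flipped codon, which is what makes $10^8$-step chains affordable
(the compiled kernel runs roughly $10^7$ steps per second per core).

At the package's study scale — $1.3\times10^8$ training steps followed by
$6\times10^8$ production steps — the estimated fraction of random codes
more robust than the SGC is $10^{-20.4}$, which with the exact ensemble
size corresponds to $\sim 10^{58}$ such codes: vanishingly rare and yet
astronomically numerous.

## Landscape reconstruction

Codes retained below cost 2.7 are vectorised (`vectorizeCodes()`): entry
$c$ holds the polar requirement of the amino acid at codon $c$; the three
stop positions are ensemble-invariant and carry zero variance. The
principal components are fitted on this low-cost subset, mean-centred and
unscaled (all 64 coordinates share polar-requirement units, and rescaling
would distort exactly the geometry being interpreted). Signs are fixed
deterministically (the SGC's first coordinate nonnegative; later
components' largest loading positive).

Cluster count selection (`elbowK()`) runs seeded k-means (50 restarts) for
$k = 1..8$ and takes the knee of the within-cluster sum-of-squares curve.
The knee rule: a drop is *dominant* when it exceeds the following drop by
at least a factor 4 while still being a nontrivial share (1%) of the total
variance, and the knee is the largest such $k$ — the point where a rapid
decline turns slow. If no drop dominates, the curve is declared elbow-free
and $k = 1$ is returned. The rule recovers planted isotropic blobs at
separations of five within-cluster standard deviations and above (taking
the largest dominant drop, not the single strongest one, matters when the
planted clusters are unevenly spaced and merge at unequal SSE scales).

**Clustering operates on the first three principal components.** This was
a genuinely open design point: the landscape is displayed on PC1–PC2, but
the third component still carries ~11% of the variance, and empirically the
split between the two clusters that both concentrate high polar-requirement
amino acids in the codon table's A column rides on PC3. In two dimensions
the SSE elbow is ambiguous between 3 and 4; in three dimensions it is
unambiguous (the $k=4$ drop dominates its successor by an order of
magnitude), and the resulting four clusters are the interpretable classes:
three broad peaks distinguished by where the high polar-requirement
amino acids sit (A column; G column; both, as in the SGC's half of the
table) and one narrow, well-separated peak with the high values in the two
*left* columns — negative right–left asymmetry
$\Delta_{PR} = \langle PR\rangle_R - \langle PR\rangle_L$
(`deltaPR()`; right = second base A or G).

Cluster naming is deterministic (`clusterCodes()`): the
negative-asymmetry cluster is *blue*; the cluster containing the SGC is
*green*; the remaining clusters are *red*, *orange*, … by decreasing
occupancy of the $2.6 \pm 0.1$ slice. Occupancy (`clusterOccupancy()`)
counts raw multicanonical samples inside a slice: within a narrow cost
slice the multicanonical chain is ensemble-weighted, so raw counts estimate
phase-volume shares; comparisons *across* cost levels go through the DOS
instead. At the study scale the slice occupancies come out near 44%, 30%,
23% and 3% (blue), with PC1/PC2 explained-variance ratios near 27% and 15%.

## The genetic algorithm and path dependence

`gaRun()` evolves populations of $N = 100$ constraint-satisfying codes for
500 generations: each generation the cheapest 50% survive, the population
is refilled by copying each survivor exactly once (drawn without
replacement), and every element of each copy mutates independently with
probability $\mu = 0.1$; a mutant that loses an amino acid or an Asp/Glu
floor has its mutation redrawn from the survivor. There is no crossover.
Two readings of the refill step are possible; the default keeps survivors
unmutated (which makes the best cost monotone — elitism), and
`mutateSurvivors = TRUE` switches to the alternative. Ties in ranking break
by stable population order, for determinism.

Most runs reach the SGC cost slice within 500 generations. Placing each
run's first slice-entering code on the multicanonical projection shows the
headline bias: the narrow blue peak, holding only ~3% of the unbiased
phase volume, captures ~25–30% of GA outcomes — an order-of-magnitude
over-concentration. The trajectory diagnostics (`trajectoryStats()`)
explain it: the rate of $\Delta_{PR}$ sign changes collapses to nearly
zero below cost 4–5 (0.1-wide cost bins, the slice convention), so whether
a run ends blue is decided early, while costs are still high — the basin
of attraction, not the peak volume, sets the outcome frequency. The
fraction of negative-asymmetry codes along GA trajectories accordingly
plateaus below cost 4–5, whereas the unbiased multicanonical fraction
(`mucaNegFraction()`) declines monotonically as cost decreases.

## Synthetic oracles

Every stochastic stage is validated against exact ground truth on
enumerable toy codon systems (`makeToy()`): a reduced base alphabet and
codon length, a seeded property scale whose two designated top symbols
mirror Asp/Glu (with the same multiplicity floors), and misreading weights
that reuse the position/transition class structure of the full model, so
toy validation exercises the same kernel code paths. `exactDOS()`
enumerates all assignments (incremental-cost odometer, up to $2\times10^7$
states); the Wang-Landau/multicanonical estimates match it bin by bin
within 0.2 in $\log_{10}$ at $10^7$ production steps, and the chain's
bin-to-bin flows are symmetric (detailed balance). `plantedBlobs()`
provides ground truth for the elbow/k-means stage.

What the toys do *not* emulate: stop-codon placement beyond fixed excluded
positions, 64-codon scale, and the real polar-requirement geometry — so
passing toy checks demonstrates correctness of the machinery, not of any
biological claim; the full-scale claims rest on the production runs above.

## Problem sizes, limitations

The shipped configuration (`defaultPipelineConfig()`) uses $6\times10^8$
production steps (thinning 150, retaining ~$1.5\times10^5$ codes below
cost 2.7), $10^7$ block permutations and $10^3$ GA runs. These reproduce
the qualitative structure and the tail estimate to well within an order of
magnitude; fully converged DOS tails and occupancies would use
$10^{10}$–$10^{11}$ steps and $10^5$ GA runs. Known limitations: the
landscape is conditional on stops staying at their SGC positions (the
asymmetric peak shapes partly reflect that); the frequency-weighted and
substitution-score (BLOSUM62) cost variants are supported as extension
points (`costConfig(freq = ...)`, `scorePenalty()`) with a transform
chosen by this package, and are validated only qualitatively; codon usage,
frameshift robustness and code/metabolism coevolution are out of scope.
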