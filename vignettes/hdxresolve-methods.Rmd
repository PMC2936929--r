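---
title: "Resolving residue-level exchange classes from overlapping fragments: models and methods"
author: "hdxresolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving residue-level exchange classes from overlapping fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Solution-phase hydrogen/deuterium exchange (sHDX) probes protein structure
through the exchange rates of backbone amide hydrogens. Mass analysis of a
proteolytic digest yields, for every peptic fragment, how many of its amides
exchange slowly, at medium rate, or fast — but not *which* residues do.
When fragments overlap, their counts jointly constrain single residues.
`hdxresolve` turns the per-fragment class counts into residue-level class
assignments, and — because the data rarely pin down a unique answer —
enumerates *all* minimum-error assignments in a compact equivalence-class
representation, plus consensus summaries over them.

## Model

Number the residues $1..n$. A fragment is an integer interval $(i,j)$; the
set of fragments is $\mathcal{F}$. There are $K$ rate classes ("colors",
$K = 3$ for slow/medium/fast). The measured data are requirement counts
$b_f^k \ge 0$: the number of residues of fragment $f$ in class $k$. An
assignment $\pi$ maps each covered residue to a color; its error is

$$\sum_{k} \sum_{f \in \mathcal{F}}
  \bigl|\, b_f^k - \#\{ l \in f : \pi(l) = k \} \,\bigr|,$$

and the goal is to find every assignment minimizing this total. Noise makes
exactly feasible data the exception, so rows whose counts do not sum to the
fragment length are accepted (with a validator warning); the objective
absorbs the discrepancy.

**Parts and equivalence classes.** Residues covered by exactly the same set
of fragments form a *part*; no fragment starts or ends inside a part, so
permuting colors within a part changes no fragment's count. Solutions are
therefore stored per part as count matrices $y$ with $y_p^k$ = number of
residues of part $p$ in class $k$, $\sum_k y_p^k = |p|$. One count matrix
stands for $\prod_p |p|!/\prod_k y_p^k!$ residue-level assignments
(`count_expansions()`). We restrict parts to *contiguous* runs: the
set-theoretic definition would allow two separate runs with coincidentally
identical fragment sets to merge, but contiguity is what gives the
fragment-to-part incidence matrix its consecutive-ones property (used by
the flow construction below) and it never changes the residue-level
solution set. Uncovered residues get no prediction.

**Independent subproblems.** Fragments that never overlap (transitively)
form components that are solved separately; the optima add. The run
summary reports per-subproblem $n$, $|P|$, $n/|P|$, $|\mathcal{F}|$,
$\epsilon$ and solution counts.

## Exact solving and enumeration (integer programs)

The *basic* formulation uses binaries $x_l^k$ per covered residue and
color, with error variables linearizing the absolute deviations. The
*improved* formulation aggregates each part into integer counts $y_p^k \in
[0, |p|]$ — same optimum, far fewer equivalent solutions. Both run through
one branch-and-bound engine (the basic formulation is the improved one on
singleton parts). LP relaxations are solved with the `boot` simplex;
branching follows the fractional variable closest to one half (ties: lowest
part, then color); when a relaxation comes back integral the engine splits
the domain of the lowest-index unfixed variable at $\le v$ / $\ge v{+}1$,
which guarantees progress and lets enumeration visit *every* integral
solution within the error bound, not just one per relaxation. Boxes are
propagated through $\sum_k y_p^k = |p|$ before any LP is solved, and a
cheap interval bound (per fragment, the gap between $b_f^k$ and the
reachable count range) prunes most nodes without an LP. Solutions are
deduplicated by canonical row-major serialization and reported in
lexicographic order; `error_bound = "auto"` first computes the optimum and
then enumerates exactly the minimum-error set.

## The two-color case: minimum-cost circulation

For $K = 2$, $y_p^2 = |p| - y_p^1$ eliminates one color. With fragment
sizes $F$, upper target $b = \max(b^1, F - b^2)$ and lower target
$\bar b = \min(b^1, F - b^2)$ (componentwise), each fragment pays a fixed
cost $b_f - \bar b_f$ inside the corridor $[\bar b_f, b_f]$ and 2 per unit
outside, so

$$\text{total error} = \sum_f (b_f - \bar b_f) + 2 \cdot \text{(corridor LP optimum)}.$$

The corridor LP has an interval (consecutive-ones) constraint matrix and
is solved through its dual, a minimum-cost circulation on the *fragment
graph*: nodes $1..|P|{+}1$; per part the arc pair $(i, i{+}1)$ (cost 0) and
$(i{+}1, i)$ (cost $|p|$) encoding $0 \le y_p \le |p|$; per fragment
spanning part positions $i..j$ the arcs $(j{+}1, i)$ (cost $b_f$, capacity
1) and $(i, j{+}1)$ (cost $-\bar b_f$, capacity 1). Total unimodularity
makes the LP value integral and equal to the integer optimum. The solver
is a successive-shortest-path minimum-cost-flow routine (negative arcs
pre-saturated, SPFA shortest paths); optimal node potentials are recovered
by Bellman-Ford from a virtual source on the optimal residual network, and
$y_p$ is the difference of the potentials flanking part $p$. Among multiple
optima the lexicographically smallest $y$ (by part position) is returned,
located by a per-part binary search that exploits convexity of the LP value
in each bound; this makes every downstream consumer deterministic.
`build_fragment_graph()` exposes the construction (with a DOT export) for
inspection; the solver builds the same network internally.

## Heuristic for $K \ge 3$

Colors are fixed one at a time: for the current color $k$ the two-color
problem "$k$ versus the pooled remaining colors" — right-hand sides
$(b^k, \sum_{k' \ne k} b^{k'})$ over the *remaining* colors — is solved
exactly by the circulation solver on the current part capacities; the
counts assigned $k$ are frozen, capacities shrink accordingly, and the
procedure recurses on $K-1$ colors (the two-color base case is solved
exactly for both colors at once). All $K!$ orders are tried by default
($K \le 4$; beyond that a fixed order by descending total requirement) and
the best result kept. The spec question of how fragment requirements
evolve after deletion is resolved by *recomputing* each stage's merged
right-hand side from the original per-color columns while only the
capacities shrink: on consistent data this equals a running decrement, and
on noisy data it avoids clamped bookkeeping drift — each stage always sees
the experiment's own counts. The reported error is always the exact
objective of the final counts, never a sum of stage objectives. The
heuristic is sound (never below the optimum) but carries no approximation
guarantee; empirically it attains the optimum on the large majority of
noisy synthetic instances (the acceptance script reports the rate).

## Lagrangian relaxation and branch-and-bound

Dualizing the linking constraints $\sum_k y^k = P$ with multipliers
$\lambda$ splits the improved formulation into one interval problem per
color — minimize $\sum_f |a_f^\top y - b_f^k| + \lambda^\top y$ over the
box — each solved as a minimum-cost flow on the same fragment network with
node supplies given by the differenced multipliers
($\bar\lambda_1 = \lambda_1$, $\bar\lambda_i = \lambda_i - \lambda_{i-1}$,
$\bar\lambda_{|P|+1} = -\lambda_{|P|}$). Costs stay integral, so the
potential-recovered per-color solutions are integral even though supplies
are real. The dual function $z(\lambda) = \sum_k v_k(\lambda) -
\lambda^\top P$ lower-bounds the optimum for every $\lambda$ and its
maximum equals the LP-relaxation value (the subproblems have no
integrality gap of their own).

Held–Karp subgradient ascent maximizes $z$: $\lambda^0 = P$ (which speeds
convergence markedly), step $\mu_\ell = \theta_\ell (UB - z)/\lVert g
\rVert^2$ along the subgradient $g = \sum_k y^k - P$, $\theta_0 = 2$.
Constants the formulation leaves open were fixed once: $\theta$ halves
after 30 iterations without bound improvement, ascent stops at $\theta <
10^{-4}$ or at the iteration cap — 1000 at the root, $\max(100, 1000 -
100\,d)$ at depth $d$. The upper bound comes from the heuristic over all
orders. A vanishing subgradient certifies a feasible, provably optimal
solution.

The surrounding branch-and-bound enumerates all optima independently of
any LP backend: bounds are rounded up before pruning (the objective is
integral), children inherit the parent's best multipliers, and branching
picks the unfixed variable whose *average* value over the last $h = 10$
subproblem solutions has fractional part closest to one half (ties: lowest
part, then color), splitting its domain at $\le \lfloor \bar y \rfloor$ /
$\ge \lfloor \bar y \rfloor + 1$ — integral variables are branched the
same way, so every surviving box shrinks to a single count matrix, which
is evaluated exactly. The resulting solution set is identical, element by
element, to the ILP enumeration (tested on the full tiny benchmark tier).

## Consensus and agreement scoring

With many optimal solutions, three condensations are offered per part:
*single* (first solution in canonical order — which solution a "single"
report should use is genuinely open; canonical-first is this package's
convention), *majority vote* (apportion the $|p|$ residue slots by largest
remainder on summed counts, remainder ties to the lower color index) and
*arithmetic mean* (lay each solution's colors out in ascending order over
the slots, average the color ordinals per slot — optionally weighted by
class expansions — round half-to-even, re-tabulate). Neither vote nor mean
is operationally defined in the source material; these constructions are
this package's concrete choices and are tagged in the output. One vote per
equivalence class is the default weighting; expansion weighting is a flag.

Agreement with a per-residue reference (e.g. NMR-derived rates discretized
at slow $\le 0.1\,h^{-1}$ and fast $\ge 8\,h^{-1}$, boundaries inclusive
toward the extreme classes) is scored per part as the maximum multiset
overlap $\sum_k \min(\text{pred}_k, \text{ref}_k)$ — i.e. under the
optimal within-part ordering, since within-part order is unidentifiable by
construction. Residues with missing reference leave both numerator and
denominator; the score is $100 \cdot \sum_p \text{matched}_p / \sum_p
\text{compared}_p$.

## Synthetic data

`generate_instance()` emulates the *shape* of combined-digest inputs: each
of `multiplicity` protease generations tiles the protein with contiguous
fragments (a random composition with mean length `mean_length`, minimum
`min_length`), so overlaps arise between generations, as when pepsin and
protease XIII digests are merged. A planted coloring (default class
frequencies 0.4/0.3/0.3 for slow/medium/fast — fixed arbitrarily for
reproducibility; no empirical distribution is claimed) yields exact counts,
so the noise-free optimum is 0 and the planted coloring is among the
optima. Noise is `noise_moves` unit count swaps — a fragment loses one
count in one class and gains it in another (clamped to $[0, |f|]$) —
because the inputs are integer class counts and a unit swap is the smallest
physically meaningful corruption; each swap changes two entries by one, so
the optimum is at most `2 * noise_moves`. What the generator does *not*
emulate: uptake-curve deconvolution errors (which correlate across
fragments sharing residues), back-exchange, missing fragments in one
charge state, or proline/N-terminal amide bookkeeping (trimming options
exist at I/O, off by default, since real inputs arrive already reduced).
Passing tests therefore demonstrate correctness of the combinatorics on
realistically shaped instances, not robustness to every experimental
artifact.

`benchmark_suite()` fixes two tiers from one seed: a *tiny* tier (n 6–12,
K = 3, at most 6 fragments; 200 instances by default) where exhaustive
$3^n$ search provides ground truth, and a *scale* tier (n 74–152, 18–49
fragments, K = 3, noise 0–8 moves) matching the size range of published
combined-digest experiments. The test suite and the acceptance script use
exactly these tiers (200 tiny / 10 scale); a scale-tier instance solves to
optimality in well under a second.

## Numerical choices and degenerate inputs

* All solvers are deterministic: fixed tie-breaks (lowest part, then
  color), lexicographic two-color solutions, canonical ordering of
  solution sets, seeded generators.
* Flow arithmetic uses real capacities/supplies with tolerance $10^{-9}$;
  arc costs are always integral, so potentials and recovered counts are
  exact integers. Sub-tolerance residual imbalances (rounding dust from
  real multiplier supplies) are treated as zero.
* Bounds are compared after `ceiling(. - 1e-6)`; the objective is integral.
* Empty instances (no fragments), uncovered residues, fragments with
  inconsistent count rows, and enumeration bounds below the optimum are
  all legal and covered by tests (the last returns an empty set).
* `boot::simplex` serves every LP relaxation; rows with negative
  right-hand sides are negated to meet its sign convention.

## On the infinite integrality gap

For $K \ge 3$ total unimodularity fails and fractional LP vertices exist.
The stronger statement — an instance with LP value 0 but positive integer
optimum — is verified *not* to occur in the natural small search family:
on the reference 4-fragment layout over 7 unit parts,
`find_gap_witness()` enumerates all consistent right-hand sides completely
and finds exactly 12 that are per-color achievable yet admit no integral
coloring, every one with LP value $\ge 2$. There is a structural reason
small interval layouts cannot witness the gap: a half-integral (or
uniformly third-integral) fractional solution intersects every fragment in
a contiguous run of patterned residues, and periodic alternation along
that run rounds it to an integral solution. Gap witnesses do exist —
feasibility of interval-constrained 3-coloring is NP-complete, so the LP
cannot characterize it — but they arise from hardness-gadget
constructions far larger than this search family. The search, its
complete negative result, and the bound it does find are reported as-is
by the acceptance machinery.

## Known limitations

* Enumeration is output-sensitive; instances with millions of equivalence
  classes are enumerable in principle but the solution list itself becomes
  the bottleneck. Solve-only mode scales much further.
* The heuristic's stage order matters; "all orders" is exhaustive only for
  $K \le 4$.
* Agreement scoring compares discretized classes; information in the raw
  rates beyond the class boundaries is not used.
* Published per-dataset error tables and NMR agreement percentages cannot
  be reproduced here because the underlying experimental fragment tables
  and reference rates were never deposited; all empirical statements in
  this package are about its own synthetic battery.
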