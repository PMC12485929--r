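---
title: "Predicting multi-step enzyme mechanisms from reaction stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting multi-step enzyme mechanisms from reaction stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Biochemical databases catalogue tens of thousands of balanced enzymatic
reactions, but only a few hundred entries carry a complete, step-by-step
mechanistic annotation — every bond-breaking and bond-forming event from
substrates to products. `mechstep` addresses this gap: given only the
overall reaction stoichiometry (substrates and products as SMILES), it
proposes ranked, elementally and charge-balanced multi-step mechanisms by
selecting and ordering *elementary rules* drawn from a database of curated
mechanistic steps, and then re-ranks the candidates by their similarity to
known mechanisms. No protein structure and no user-supplied active-site
residues are needed, which is what makes whole-database annotation
feasible.

## The moiety abstraction

All chemistry in the package is projected onto *moieties*: every
non-hydrogen atom is classified by its first bonding shell — the central
element, its formal charge, its attached hydrogen count, and the sorted
multiset of (bond order, neighbour element, neighbour charge) over its
heavy neighbours. The canonical serialization is a structured text key,
e.g. the hydroxyl oxygen of ethanol is `O+0H1(-C+0)` and an aromatic CH
carbon of benzene is `C+0H1(:C+0,:C+0)`.

Design choices behind the key, and why:

* **Hydrogen counts are part of the key.** Protonation and deprotonation
  steps are first-class elementary rules; without the H count they would
  be invisible to the encoding.
* **Neighbour formal charges are part of the key.** Otherwise a
  protonated and a deprotonated carboxylate would collide through the
  eyes of their carbon neighbour.
* **Aromatic bonds keep their own `:` bond symbol** instead of a Kekulé
  single/double assignment, so resonance-equivalent SMILES writings of
  the same heteroaromatic ring produce identical keys.
* **Stereochemistry is stripped at parse time.** Molecules are handled as
  constitutional isomers; this mirrors the scope of available curated
  mechanism data (stereo-specific rules are a known, deliberate
  limitation). A useful side effect: epimerisations and racemisations
  surface as zero-delta reactions and are reported as `no_net_change`
  rather than needing an annotation-based filter.
* The key is *structured text*, not a fragment SMILES: a one-shell
  fragment containing aromatic bonds is not a valid standalone SMILES
  (kekulisation fails outside a ring), so a fragment-SMILES serialization
  could not be made canonical for aromatic environments.

A molecule becomes a sparse vector of non-negative moiety counts whose
total equals its heavy-atom count; a reaction becomes the *net change
vector* T° (products minus substrates, stoichiometry-weighted); an
elementary step becomes a signed *rule delta* (a column of the rule
matrix T). Moieties contributed by catalytic residues and cofactors are
*labeled* (`His*…`), forming the set M*.

SMILES parsing, canonicalisation, aromaticity perception and hydrogen
accounting are delegated to RDKit through a small bundled Python helper
(one batched interpreter call, memoised per SMILES string); the moiety
classification itself is done in R on the returned molecular graph.

## The optimization model

A valid mechanism is a sequence of elementary rules whose deltas sum to
T° and which never consumes a moiety before it is available. With
integer variables $y_r \ge 0$ (how many times rule $r$ fires) and binary
step-assignment variables $z_{k,r}$ (rule $r$ fires at step $k$), the
monolithic problem is

$$\min \sum_r y_r$$

subject to

* **balance** $\sum_r T_{m,r}\, y_r = T^\circ_m$ for every moiety $m$;
* **prefix feasibility** $C^\circ_m + \sum_{k' \le k} \sum_r T_{m,r}
  z_{k',r} \ge 0$ for every step $k$ and every moiety $m \notin M^*$,
  where $C^\circ$ are the substrate moiety counts;
* one rule per step, contiguity of used steps, and the linking constraint
  $\sum_k z_{k,r} = y_r$.

Minimising the step count enforces the principle of *parsimony*. The
exemption of M* from prefix feasibility is essential: catalytic machinery
is reusable, so a protonated histidine may be consumed in one step and
regenerated in another without the running count constraint firing.

Because the monolithic problem couples selection and ordering, the
package (like the practice it models) also provides a decomposed path:
`solve_min_rules()` finds the minimal multiset satisfying balance with
$\sum_r y_r \le W$ (default $W = 20$), and `solve_order_rules()` then
searches for any feasible ordering of that multiset — a pure feasibility
problem. `enumerate_mechanisms()` iterates the two, appending an *integer
cut* after each selection so that a ranked list of optima emerges;
selections that admit no feasible ordering are cut and skipped without
producing a candidate. Ranks are 1-based in order of discovery, and step
counts never decrease with rank because every cut only shrinks the
feasible region.

### Integer-cut semantics

Two cut styles are offered via `solver_config(cut_style = …)`:

* `"as_printed"` (default): $\sum_{r \in S} y_r \le |S| - 1$ for a found
  support $S$. This forbids $S$ itself, but as a side effect also forbids
  any selection that uses rules of $S$ with total multiplicity $\ge |S|$
  — e.g. after cutting $S = \{A, B\}$, the selection $\{A{:}2\}$ is also
  excluded.
* `"support_exact"`: excludes exactly the selections whose support equals
  $S$, and nothing else.

The default reproduces the classical printed form first; the exact form
is available behind the flag and the divergence is pinned down by a test.

### The search engine

The formulations are solved by an exact combinatorial engine written for
the purpose: iterative deepening on the step count with per-moiety
reachability bounds (a moiety needing $d$ more units can never be
finished in fewer than $\lceil d / \max_r T_{m,r} \rceil$ steps), and
memoisation of dead states in the ordering search (the running state is a
pure function of the remaining multiset, so failed sub-multisets are
cached). The search is deterministic — rules are always explored in
stable id order — so results are reproducible without reference to any
solver seed, and every optimum it reports is certified by construction.
This engine is designed for the rule-set sizes exercised here (tens of
rules, mechanisms up to ~20 steps); scaling to databases of thousands of
rules would call for an LP-relaxation-based branch-and-bound and is a
known limitation.

All solves share a per-reaction wall-clock budget (`time_limit`, default
1200 s); a single ordering attempt is additionally capped at
`per_order_time_limit` (default `time_limit/10`) so one pathological
ordering cannot starve the enumeration. Timeouts are reported as a
distinct outcome, never silently.

## Similarity-based re-ranking

Parsimony alone cannot distinguish equally short, chemically plausible
alternatives. Each candidate is therefore scored against a database of
known mechanisms using the *unordered* similarity over step multisets:
by default the multiset Jaccard index
$\sum_s \min(a_s, b_s) / \sum_s \max(a_s, b_s)$, which is 1 exactly for
identical step multisets and 0 exactly for disjoint ones (set-based
Jaccard and Dice are available as options). A candidate's score is its
*maximum* over the database — the similarity to its closest known analog
— and candidates are re-sorted stably in descending score, so ties keep
the parsimony order and re-ranking can never do worse than the parsimony
baseline on a tied field. Step identity is the rule id within one rule
set, or the canonical delta signature when comparing across rule sets
(`identity = "delta"`).

## Pipeline and outcome taxonomy

`predict_mechanism()` applies, in order: the elemental/charge balance
check (`unbalanced`), the zero-delta screen (`no_net_change`), the
compatibility screen (`incompatible`, listing every target moiety absent
from the rule set — by construction no rule combination can balance such
a reaction), then enumeration and re-ranking (`predicted`), with
`timeout` and `infeasible` for searches that exhaust their budget or
provably have no solution within $W$ steps. `unbalanced` and
`no_net_change` fold dataset pre-filters into the tool itself so it is
self-contained; `infeasible` is kept distinct from `predicted` so that
the invariant *predicted ⇔ candidates non-empty* holds exactly.
`batch_predict()` maps this over a reaction table, never aborts on a
single bad row, and tabulates counts and percentages per status.

`build_step_network()` compiles the top candidates into a network of
competing catalytic strategies: nodes are distinct cumulative moiety
states along candidate prefixes, edges are elementary steps. States can
be projected by a configured list of *generic exchange* moieties (the
same default list as the protonation carriers: water/oxonium,
water/hydroxide, ammonium/amine, carboxyl/carboxylate), which merges
steps differing only in which generic acid/base carries the proton onto
a single edge bearing all their rule ids.

## The synthetic-instance generator

`generate_instance()` draws a random sparse rule universe over abstract
moieties, plants a random rule sequence, and *constructs* feasibility
rather than sampling it: the target is the planted sequence's summed
delta and the initial counts are exactly the running prefix deficits of
each unlabeled moiety. A recovery failure therefore always indicts the
solver, never the instance. Generation is a pure function of its
parameters and seed (the session RNG stream is saved and restored).

Default study conditions used throughout the tests and the acceptance
script, chosen to keep the brute-force oracle exhaustive yet fast:
solver-equivalence instances use 5 moieties, 6 rules, planted lengths
1–4 (200 instances; brute force enumerates all sequences up to length
4); recovery instances use 6 moieties, 7 rules, planted lengths 2–4 with
25% labeled moieties (100 instances); similarity properties are checked
over 1000 random step-multiset pairs; encoding invariance over 100
randomized SMILES writings of a 25-molecule panel.

What the generator emulates: sparse integer rule deltas, catalytic
exemptions, repeated rule use, infeasible orderings. What it does not
emulate: the size (thousands of rules) and redundancy structure of a
curated rule database, realistic moiety co-occurrence, or the EC-class
composition of real reaction sets — so passing these tests certifies the
algorithms, not chemical coverage on real databases.

The bundled `toy_esterase()` bridges the abstract and chemical layers: a
miniature ester hydrolysis with two planted strategies (direct water
attack through a tetrahedral intermediate, 2 steps; a covalent route
through a labeled serine, 3 steps). Enumeration must find both supports,
re-ranking against a database containing the covalent route must promote
it from parsimony rank 2 to similarity rank 1, and the compiled network
must branch at the substrate state with every source→sink path summing
to the overall target.

```{r}
library(mechstep)
toy <- toy_esterase()
enum <- enumerate_mechanisms(toy$problem, solver_config(top_n = 10))
rr <- rerank_mechanisms(enum$mechanisms, toy$mechanism_db)
attr(rr, "ranking")
```

## Numerical and degenerate-input conventions

* All arithmetic is integer; balance and prefix feasibility are checked
  exactly, with no tolerances. Rule deduplication is exact-vector
  equality.
* A zero-delta elementary step is rejected at rule-building time; a
  zero-target *problem* is legal to the solver (the empty mechanism is
  the unique optimum) but is screened upstream by the pipeline as
  `no_net_change`.
* Stoichiometric coefficients must be positive integers; moiety counts
  are integral by construction, so fractional coefficients are rejected.
* Ties among equally parsimonious mechanisms are broken by the stable
  rule ordering of the search; ties in similarity by parsimony rank.
* `time_limit = 0` returns an empty timeout outcome immediately, so
  budget handling is testable.

## Limitations

* The search engine is exact but enumerative; it is not intended for
  curated rule databases with thousands of rules (see above).
* The one-shell environment key is a committed choice: wider shells
  would discriminate more environments at the cost of rule-set sparsity.
* Protonation carriers and generic-exchange moieties are a configurable
  default list, not a chemically exhaustive enumeration.
* No stereochemistry, tautomer enumeration, pKa prediction or 3D
  geometry: inputs are treated as constitutional isomers.
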