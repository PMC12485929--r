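# mechstep

Parsimony-based prediction of multi-step enzyme mechanisms from overall
reaction stoichiometry alone.

Fewer than a thousand enzymatic reactions in the open literature carry a
complete mechanistic annotation, while reaction databases catalogue tens
of thousands of balanced transformations with no mechanistic detail.
`mechstep` is for computational enzymologists and enzyme engineers who
want ranked, elementally and charge-balanced mechanistic hypotheses for
such reactions — without a protein structure and without guessing
active-site residues — as a starting point for transition-state modeling
and de novo active-site design.

## How it works

Every non-hydrogen atom is classified by its first bonding shell
(element, formal charge, hydrogen count, and the multiset of
bond/neighbour-element/neighbour-charge triples) — a *moiety*. A
reaction collapses to its net moiety-change vector **T°**, and each
curated elementary step to a signed rule delta, a column of the rule
matrix **T**. A mechanism is a sequence of rules that reproduces **T°**
while never consuming a moiety before it exists. With integer rule
counts `y_r` and step assignments `z_{k,r}`, the package solves

```
min  Σ_r y_r                                   (parsimony)
s.t. Σ_r T[m,r] y_r = T°[m]        ∀ m         (balance)
     C°[m] + Σ_{k'≤k} Σ_r T[m,r] z_{k',r} ≥ 0  ∀ k, ∀ m ∉ M*
     one rule per step, Σ_k z_{k,r} = y_r, Σ_r y_r ≤ W
```

where `C°` are the substrate moiety counts and `M*` the labeled
moieties from catalytic residues/cofactors, exempt from the running
non-negativity constraint because the enzyme's machinery is reusable.
Both the monolithic formulation and the faster decomposed pair
(minimal rule selection, then ordering feasibility) are provided;
integer cuts appended after each solve enumerate a ranked list of
optima. Candidates are finally re-ranked by their maximal *unordered*
similarity (multiset Jaccard over elementary steps) to a database of
known mechanisms. See the methods vignette
(`vignettes/mechanism-prediction.Rmd`) for the full model and design
rationale.

## Worked example

The bundled toy esterase (ester + water → acid + alcohol) carries two
classic catalytic strategies. Enumeration finds both, shortest first:

```r
library(mechstep)
toy <- toy_esterase()
enum <- enumerate_mechanisms(toy$problem, solver_config(top_n = 10))
for (m in enum$mechanisms) print(m)
#> <ordered_mechanism: 2 steps, rank 1 | 1 -> 2>
#> <ordered_mechanism: 3 steps, rank 2 | 3 -> 4 -> 5>
```

Rank 1 is the direct water attack (2 steps); rank 2 the covalent serine
route (3 steps). Re-ranking against a mechanism database that contains
the covalent strategy promotes it to the top:

```r
rr <- rerank_mechanisms(enum$mechanisms, toy$mechanism_db)
attr(rr, "ranking")
#>   similarity_rank parsimony_rank total_steps score        best_match
#> 1               1              2           3     1 covalent_esterase
#> 2               2              1           2     0 covalent_esterase
```

The score of 1 means the candidate's step multiset is identical to the
database record's; the parsimony runner-up becomes the top prediction —
exactly the behaviour that motivates similarity re-ranking.

Real chemistry goes through the same interface. Build rules from two
balanced elementary steps of methyl-formate hydrolysis, then predict the
overall reaction:

```r
steps <- list(
  list(substrates = c("COC=O", "O"), products = "COC(O)O"),
  list(substrates = "COC(O)O", products = c("OC=O", "CO")))
rules <- build_rule_matrix(steps, reversible = TRUE)
out <- predict_mechanism("COC=O.O>>OC=O.CO", rules)
print(out)
#> <reaction_outcome 'reaction': predicted, 1 candidates>
print(out$candidates[[1]])
#> <ordered_mechanism: 2 steps, rank 1 | 1 -> 3>
```

Unbalanced inputs, zero-net-change reactions (e.g. epimerisations after
stereo stripping) and reactions touching moieties unknown to the rule
set are reported as `unbalanced`, `no_net_change` and `incompatible`
respectively; `batch_predict()` tabulates the taxonomy over a reaction
file. A thin CLI wraps the same functions:

```sh
inst/cli/mechstep encode  --smiles "CC(=O)OC"
inst/cli/mechstep predict --reaction "COC=O.O>>OC=O.CO" --rules rules.json
inst/cli/mechstep batch   --input reactions.tsv --rules rules.json --summary summary.tsv
```

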