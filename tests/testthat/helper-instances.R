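# Shared toy instances and fixture data used across test files.

# Worked instance: rules A {m1:-1,m2:+1}, B {m2:-1,m3:+1}, C {m1:-1,m3:+1};
# target {m1:-1,m3:+1}; one unit of m1 available.
abc_instance <- function(with_c = TRUE) {
  rules <- list(
    elementary_rule(1L, c(m1 = -1, m2 = 1)),
    elementary_rule(2L, c(m2 = -1, m3 = 1))
  )
  if (with_c) rules[[3L]] <- elementary_rule(3L, c(m1 = -1, m3 = 1))
  rm_ <- rule_matrix(rules)
  reaction_problem(moiety_vector(c(m1 = -1, m3 = 1)),
                   moiety_vector(c(m1 = 1)), rm_)
}

# Instance orderable only because labeled moieties are exempt from prefix
# non-negativity: r1 consumes the catalytic moiety before r2 restores it.
exemption_instance <- function(exempt = TRUE) {
  h <- label_moiety("h_plus", "cat")
  rules <- list(
    elementary_rule(1L, stats::setNames(c(-1, -1, 1), c(h, "a", "b"))),
    elementary_rule(2L, stats::setNames(c(1, -1, 1), c(h, "b", "cc")))
  )
  rm_ <- rule_matrix(rules)
  reaction_problem(
    moiety_vector(c(a = -1, cc = 1)), moiety_vector(c(a = 1)), rm_,
    labeled_set = if (exempt) h else character()
  )
}

fast_config <- function(...) {
  solver_config(time_limit = 30, ...)
}

# A hand-curated 3-step hydroxide-assisted ester hydrolysis; every step is
# elementally and charge balanced and the step deltas sum to the overall
# reaction delta (methyl formate + water -> formic acid + methanol).
ester_steps <- function() {
  list(
    list(substrates = c("COC=O", "[OH-]"), products = "COC([O-])O",
         provenance = "hydroxide attack on the carbonyl"),
    list(substrates = "COC([O-])O", products = c("[O-]C=O", "CO"),
         provenance = "tetrahedral collapse expelling methanol"),
    list(substrates = c("[O-]C=O", "O"), products = c("OC=O", "[OH-]"),
         provenance = "proton transfer regenerating hydroxide")
  )
}

ester_overall <- "COC=O.O>>OC=O.CO"

# neutral-water route for the same hydrolysis: orderable from the bare
# substrates (no hydroxide needed up front)
neutral_ester_steps <- function() {
  list(
    list(substrates = c("COC=O", "O"), products = "COC(O)O",
         provenance = "direct water addition"),
    list(substrates = "COC(O)O", products = c("OC=O", "CO"),
         provenance = "neutral tetrahedral collapse")
  )
}

# small SMILES panel covering charges, aromatics, heteroatoms and rings
fixture_smiles <- function() {
  c("C", "O", "CCO", "CC=O", "c1ccccc1", "c1ccncc1", "CC(=O)OC",
    "CC(=O)[O-]", "C(=O)(O)O", "OC(=O)CN", "C[NH3+]", "[OH-]", "N#C[O-]",
    "CSC", "CC(C)O", "O=C=O", "c1cc[nH]c1", "OCC(O)CO", "CC#N", "OO",
    "C1CCOC1", "NC(=O)N", "CCOC(=O)C", "Oc1ccccc1", "NCC(=O)[O-]")
}
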