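test_that("atom environments follow the documented key construction", {
  # single-heavy-atom molecules: element, charge, hydrogens, no neighbours
  expect_identical(atom_environment("C", 1), "C+0H4()")
  expect_identical(atom_environment("O", 1), "O+0H2()")
  expect_identical(atom_environment("[NH4+]", 1), "N+1H4()")
  # hand-enumerated first shell of ethanol's central carbon
  eth <- parse_molecule("CCO")
  expect_identical(atom_environment(eth, 2), "C+0H2(-C+0,-O+0)")
  expect_identical(atom_environment(eth, 1), "C+0H3(-C+0)")
  expect_identical(atom_environment(eth, 3), "O+0H1(-C+0)")
  # aromatic neighbours keep the ':' bond symbol
  expect_identical(atom_environment("c1ccccc1", 1), "C+0H1(:C+0,:C+0)")
})

test_that("atom_environment rejects bad indices and hydrogen atoms", {
  mol <- parse_molecule("CCO")
  expect_error(atom_environment(mol, 0))
  expect_error(atom_environment(mol, 4))
  expect_error(atom_environment("[H][H]", 1), "hydrogen")
})

test_that("moiety counts conserve heavy atoms and group identical shells", {
  expect_identical(moiety_counts("C"),
                   moiety_vector(c("C+0H4()" = 1)))
  eth <- moiety_counts("CCO")
  expect_length(eth, 3L)
  expect_true(all(as.integer(eth) == 1L))
  # benzene: all six aromatic CH environments identical
  benz <- moiety_counts("c1ccccc1")
  expect_length(benz, 1L)
  expect_identical(as.integer(benz), 6L)
  # conservation across the fixture panel
  for (smi in fixture_smiles()) {
    mol <- parse_molecule(smi)
    expect_identical(sum(moiety_counts(mol)), nrow(mol$atoms))
  }
})

test_that("labelled counts carry the tag on every key", {
  labelled <- moiety_counts("CCO", label_tag = "Ser")
  expect_true(all(moiety_is_labeled(names(labelled))))
  expect_true(all(moiety_label_tag(names(labelled)) == "Ser"))
  expect_error(moiety_counts("CCO", label_tag = "bad tag"))
})

test_that("encoding is invariant to atom order and stereochemistry", {
  for (smi in c("CCO", "CC(=O)OC", "c1ccncc1", "OC(=O)CN")) {
    ref <- moiety_counts(smi)
    for (variant in randomize_smiles(smi, n = 4, seed = 7)) {
      expect_true(mv_equal(moiety_counts(variant), ref), info = variant)
    }
  }
  expect_true(mv_equal(moiety_counts("C[C@H](O)F"),
                       moiety_counts("C[C@@H](O)F")))
  expect_true(mv_equal(moiety_counts("C/C=C/C"), moiety_counts("CC=CC")))
})

test_that("reaction_delta matches the hand-computed oxidation delta", {
  # ethanol -> acetaldehyde: CH2 and OH lost, CHO carbon and =O gained,
  # the methyl carbon key keeps its single-bonded C neighbour so cancels
  delta <- reaction_delta("CCO", "CC=O")
  expected <- moiety_vector(c(
    "C+0H2(-C+0,-O+0)" = -1, "O+0H1(-C+0)" = -1,
    "C+0H1(-C+0,=O+0)" = 1, "O+0H0(=C+0)" = 1
  ))
  expect_true(mv_equal(delta, expected))
})

test_that("reaction_delta cancels identical sides and respects coefficients", {
  expect_true(mv_is_zero(reaction_delta("CCO", "CCO")))
  # products a permutation of substrates
  expect_true(mv_is_zero(reaction_delta(c("CCO", "O", "C"), c("C", "CCO", "O"))))
  # 2 H2O -> H2O2 + (H2 lost): coefficient weighting on the substrate side
  d <- reaction_delta("O", "OO", sub_coeffs = 2L)
  expect_identical(as.integer(d[["O+0H2()"]]), -2L)
  expect_error(reaction_delta("O", "OO", sub_coeffs = 1.5))
})

test_that("balance reports catch elemental and charge deficits", {
  rep1 <- check_balance("O", "OO", sub_coeffs = 2L)
  expect_false(rep1$elemental)
  expect_identical(rep1$element_deficit[["H"]], -2L)
  rep2 <- check_balance("CCO", "CC=O")
  expect_false(rep2$elemental)
  expect_identical(rep2$element_deficit[["H"]], -2L)
  rep3 <- check_balance("CCO", "CCO")
  expect_true(rep3$elemental && rep3$charge)
  rep4 <- check_balance("[NH4+]", "N")
  expect_false(rep4$charge)
  expect_identical(rep4$charge_deficit, -1L)
})

test_that("moiety vectors are canonical sparse integer maps", {
  v <- moiety_vector(c(b = 2, a = 1, c = 0))
  expect_identical(names(v), c("a", "b")) # zero dropped, sorted
  expect_true(mv_is_zero(mv_add(v, mv_neg(v))))
  expect_true(mv_equal(mv_add(v, moiety_vector()), v))
  expect_error(moiety_vector(c(a = 1.5)))
  expect_error(moiety_vector(stats::setNames(1L, "")))
  # merging of repeated keys
  expect_identical(as.integer(moiety_vector(c(a = 1, a = 2))), 3L)
})

test_that("signatures and file serialization round-trip", {
  v <- moiety_vector(c("C+0H1(:C+0,:C+0)" = 6, "O-1H0(-C+0)" = -2))
  expect_true(mv_equal(mv_from_signature(mv_signature(v)), v))
  expect_identical(mv_signature(moiety_vector()), "0")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_moiety_vector(v, path)
  expect_true(mv_equal(read_moiety_vector(path), v))
})

test_that("molecule parsing is canonical and strips stereo", {
  m1 <- parse_molecule("OCC")
  m2 <- parse_molecule("CCO")
  expect_identical(m1$canonical, m2$canonical)
  expect_identical(parse_molecule("C[C@H](O)F")$canonical,
                   parse_molecule("CC(O)F")$canonical)
  expect_identical(m1$element_counts[["H"]], 6L)
  expect_identical(parse_molecule("[NH4+]")$net_charge, 1L)
  expect_error(parse_molecule("not_a_smiles("))
})

test_that("protonation pair syntax is checked through key parsing", {
  k <- parse_moiety_key("Ser*O-1H0(-C+0)")
  expect_identical(k$element, "O")
  expect_identical(k$charge, -1L)
  expect_identical(k$n_h, 0L)
  expect_true(k$labeled)
  expect_identical(k$tag, "Ser")
  expect_error(parse_moiety_key("m01"), "structured")
})
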