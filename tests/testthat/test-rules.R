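test_that("a proton-transfer step encodes labelled and unlabelled changes", {
  # methylammonium + ethoxide -> methylamine + ethanol, amine labelled as
  # a stand-in catalytic residue; the full first-shell key construction
  # makes six environments change: the N in both protonation states, the
  # O in both, and the carbons adjacent to each (their neighbour charge
  # enters the key)
  r <- rule_from_step(
    c("C[NH3+]", "CC[O-]"), c("CN", "CCO"),
    labels = c("C[NH3+]" = "Lys", "CN" = "Lys"),
    rule_id = 7L, provenance = "proton transfer"
  )
  expect_s3_class(r, "elementary_rule")
  d <- r$delta
  expect_identical(as.integer(d[["Lys*N+1H3(-C+0)"]]), -1L)
  expect_identical(as.integer(d[["Lys*N+0H2(-C+0)"]]), 1L)
  expect_identical(as.integer(d[["O-1H0(-C+0)"]]), -1L)
  expect_identical(as.integer(d[["O+0H1(-C+0)"]]), 1L)
  expect_identical(as.integer(d[["Lys*C+0H3(-N+1)"]]), -1L)
  expect_identical(as.integer(d[["Lys*C+0H3(-N+0)"]]), 1L)
  # labelled moieties from the catalytic species appear in the delta
  expect_true(any(moiety_is_labeled(names(d))))
  expect_identical(r$provenance, "proton transfer")
})

test_that("degenerate steps are rejected with a reason", {
  expect_error(rule_from_step("CCO", "CCO"), "zero")
  expect_error(rule_from_step("CCO", "CC=O"), "not balanced")
  expect_error(elementary_rule(1L, moiety_vector()), "non-zero")
})

test_that("reversal is an involution that negates the delta", {
  r <- elementary_rule(1L, c(m1 = -1, m2 = 1))
  rev <- reverse_rule(r)
  expect_true(mv_equal(rev$delta, moiety_vector(c(m1 = 1, m2 = -1))))
  expect_identical(rev$direction, "backward")
  expect_true(mv_equal(reverse_rule(rev)$delta, r$delta))
})

test_that("rule matrices deduplicate deltas and close under negation", {
  steps <- ester_steps()
  rm_ <- build_rule_matrix(c(steps, steps[1]), reversible = TRUE)
  # the duplicated first step contributes nothing new
  expect_identical(length(rm_$rules), 6L)
  sigs <- vapply(rule_deltas(rm_), mv_signature, character(1))
  expect_false(anyDuplicated(sigs) > 0)
  # reversibility closure: every delta's negation is present
  for (d in rule_deltas(rm_)) {
    expect_true(mv_signature(mv_neg(d)) %in% sigs)
  }
  # bound |rules| <= 2 * |steps|
  expect_lte(length(rm_$rules), 2L * length(steps))
  # labelled-set consistency
  expect_true(all(moiety_is_labeled(rm_$labeled_set)))
  expect_true(all(rm_$labeled_set %in% rm_$moiety_index))
})

test_that("unbalanced steps are logged, not fatal, during a build", {
  steps <- c(ester_steps(),
             list(list(substrates = "CCO", products = "CC=O")))
  rm_ <- build_rule_matrix(steps, reversible = FALSE)
  expect_identical(length(rm_$rules), 3L)
  rej <- attr(rm_, "rejections")
  expect_identical(nrow(rej), 1L)
  expect_identical(rej$step, 4L)
})

test_that("empty step list gives an empty matrix", {
  rm_ <- build_rule_matrix(list())
  expect_identical(length(rm_$rules), 0L)
  expect_identical(rm_$moiety_index, character())
})

test_that("protonation rules come in mutually inverse pairs", {
  pair <- list(c(protonated = "O+0H1(-C+0)", deprotonated = "O-1H0(-C+0)"))
  carriers <- default_proton_carriers()["oxonium_water"]
  rules <- protonation_rules(pair, carriers)
  expect_length(rules, 2L)
  expect_true(all(vapply(rules, `[[`, logical(1), "is_protonation")))
  expect_true(mv_is_zero(mv_add(rules[[1]]$delta, rules[[2]]$delta)))
  # applying one then the other returns any vector unchanged
  v <- moiety_vector(c("O+0H1(-C+0)" = 2, "O+0H2()" = 1))
  expect_true(mv_equal(mv_add(v, rules[[1]]$delta, rules[[2]]$delta), v))
  # a pair that does not differ by one H and one charge unit is rejected
  expect_error(protonation_rules(
    list(c(protonated = "O+0H2()", deprotonated = "O-1H0(-C+0)"))),
    "protonation pair")
  expect_length(protonation_rules(list()), 0L)
})

test_that("duplicate ids or duplicate deltas are constructor errors", {
  expect_error(rule_matrix(list(
    elementary_rule(1L, c(m1 = 1)), elementary_rule(1L, c(m2 = 1))
  )), "duplicate rule_id")
  expect_error(rule_matrix(list(
    elementary_rule(1L, c(m1 = 1)), elementary_rule(2L, c(m1 = 1))
  )), "duplicate rule delta")
})

test_that("rule files round-trip in both dialects and agree", {
  rm_ <- build_rule_matrix(ester_steps(), reversible = TRUE,
                           protonation_pairs = list(
                             c(protonated = "O+0H1(-C+0)",
                               deprotonated = "O-1H0(-C+0)")),
                           carriers = default_proton_carriers()["oxonium_water"])
  json_path <- withr::local_tempfile(fileext = ".json")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_rules(rm_, json_path)
  write_rules(rm_, csv_path)
  from_json <- read_rules(json_path)
  from_csv <- read_rules(csv_path)
  for (loaded in list(from_json, from_csv)) {
    expect_identical(rule_ids(loaded), rule_ids(rm_))
    expect_identical(loaded$labeled_set, rm_$labeled_set)
    expect_identical(loaded$moiety_index, rm_$moiety_index)
    for (i in seq_along(rm_$rules)) {
      expect_true(mv_equal(loaded$rules[[i]]$delta, rm_$rules[[i]]$delta))
      expect_identical(loaded$rules[[i]]$direction, rm_$rules[[i]]$direction)
      expect_identical(loaded$rules[[i]]$is_protonation,
                       rm_$rules[[i]]$is_protonation)
    }
  }
})

test_that("malformed rule files fail with informative errors", {
  rm_ <- rule_matrix(list(elementary_rule(1L, c(m1 = 1, m2 = -1))))
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_rules(rm_, csv_path)
  # duplicate rule_id
  meta <- utils::read.csv(csv_path)
  utils::write.csv(rbind(meta, meta), csv_path, row.names = FALSE)
  expect_error(read_rules(csv_path), "duplicate rule_id")
  # unknown chemical key syntax in the triplet file
  rm2 <- rule_matrix(list(elementary_rule(1L, c("C+0Hx()" = 1, m2 = -1))))
  csv2 <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_rules(rm2, csv2) |> read_rules(),
               "moiety key")
})

test_that("labeled moiety lists read one key per line", {
  path <- withr::local_tempfile()
  writeLines(c("His*N+1H1(:C+0,:C+0)", "", "cat*m01"), path)
  keys <- read_labeled_moieties(path)
  expect_length(keys, 2L)
  expect_true(all(moiety_is_labeled(keys)))
})
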