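test_that("minimum rule selection matches the exhaustive optimum", {
  prob <- abc_instance(with_c = FALSE)
  res <- solve_min_rules(prob, fast_config())
  expect_identical(res$status, "optimal")
  expect_identical(res$selection$counts, c("1" = 1L, "2" = 1L))
  expect_identical(res$selection$total_steps, 2L)
})

test_that("zero target admits the trivial empty optimum", {
  rm_ <- rule_matrix(list(elementary_rule(1L, c(m1 = 1))))
  prob <- reaction_problem(moiety_vector(), moiety_vector(c(m1 = 1)), rm_)
  res <- solve_min_rules(prob, fast_config())
  expect_identical(res$status, "optimal")
  expect_identical(res$selection$total_steps, 0L)
  mono <- solve_min_order_rules(prob, fast_config())
  expect_identical(mono$mechanism$total_steps, 0L)
})

test_that("integer cuts walk the parsimony ranking", {
  prob <- abc_instance()
  cfg <- fast_config()
  first <- solve_min_rules(prob, cfg)
  expect_identical(first$selection$counts, c("3" = 1L))
  second <- solve_min_rules(prob, cfg, prior_solutions = list(first$selection))
  expect_identical(second$selection$counts, c("1" = 1L, "2" = 1L))
  # cutting every feasible support proves infeasibility
  third <- solve_min_rules(prob, cfg,
                           prior_solutions = list(first$selection,
                                                  second$selection))
  expect_identical(third$status, "infeasible")
})

test_that("both cut styles exclude the found support", {
  prob <- abc_instance()
  for (style in c("as_printed", "support_exact")) {
    cfg <- fast_config(cut_style = style)
    first <- solve_min_rules(prob, cfg)
    nxt <- solve_min_rules(prob, cfg, prior_solutions = list(first$selection))
    expect_identical(nxt$selection$counts, c("1" = 1L, "2" = 1L),
                     info = style)
  }
})

test_that("the printed cut over-excludes multiplicity, support_exact does not", {
  # target {m1:-2, m2:+2} is reachable as {A:2}; after cutting the support
  # {A, B}, the printed form sum(y_A + y_B) <= 1 also kills {A:2}
  rm_ <- rule_matrix(list(
    elementary_rule(1L, c(m1 = -1, m2 = 1)),
    elementary_rule(2L, c(m1 = -1, m2 = 1, m3 = 1))
  ))
  prob <- reaction_problem(moiety_vector(c(m1 = -2, m2 = 2)),
                           moiety_vector(c(m1 = 2)), rm_)
  cut_sel <- rule_selection(c("1" = 1L, "2" = 1L))
  printed <- solve_min_rules(prob, fast_config(cut_style = "as_printed"),
                             prior_solutions = list(cut_sel))
  exact <- solve_min_rules(prob, fast_config(cut_style = "support_exact"),
                           prior_solutions = list(cut_sel))
  expect_identical(printed$status, "infeasible")
  expect_identical(exact$status, "optimal")
  expect_identical(exact$selection$counts, c("1" = 2L))
})

test_that("ordering respects prefix feasibility of unlabeled moieties", {
  prob <- abc_instance(with_c = FALSE)
  sel <- rule_selection(c("1" = 1L, "2" = 1L))
  ord <- solve_order_rules(prob, sel, fast_config())
  expect_identical(ord$status, "feasible")
  # B first would drive m2 to -1, so the only ordering is [A, B]
  expect_identical(ord$mechanism$sequence, c("1", "2"))
  expect_true(validate_sequence(prob, ord$mechanism$sequence))
  # single-rule selection
  one <- solve_order_rules(prob, rule_selection(c("1" = 1L)), fast_config())
  expect_identical(one$mechanism$sequence, "1")
})

test_that("labeled moieties are exempt from prefix non-negativity", {
  sel <- rule_selection(c("1" = 1L, "2" = 1L))
  with_exemption <- solve_order_rules(exemption_instance(TRUE), sel,
                                      fast_config())
  without <- solve_order_rules(exemption_instance(FALSE), sel, fast_config())
  expect_identical(with_exemption$status, "feasible")
  expect_identical(with_exemption$mechanism$sequence, c("1", "2"))
  expect_identical(without$status, "infeasible")
  # the independent validator agrees on both readings
  expect_true(validate_sequence(exemption_instance(TRUE), c("1", "2")))
  expect_false(validate_sequence(exemption_instance(TRUE), c("1", "2"),
                                 exempt_labeled = FALSE))
})

test_that("the monolithic search agrees with the decomposed path", {
  prob <- abc_instance(with_c = FALSE)
  mono <- solve_min_order_rules(prob, fast_config())
  expect_identical(mono$status, "optimal")
  expect_identical(mono$mechanism$sequence, c("1", "2"))
  # infeasible when the target lies outside the integer span
  rm_ <- rule_matrix(list(elementary_rule(1L, c(m1 = 2))))
  bad <- reaction_problem(moiety_vector(c(m1 = 1)), moiety_vector(), rm_)
  expect_identical(solve_min_order_rules(bad, fast_config())$status,
                   "infeasible")
  expect_identical(solve_min_rules(bad, fast_config())$status, "infeasible")
})

test_that("enumeration ranks mechanisms by non-decreasing length", {
  enum <- enumerate_mechanisms(abc_instance(), fast_config(top_n = 2))
  expect_identical(enum$status, "complete")
  expect_length(enum$mechanisms, 2L)
  expect_identical(enum$mechanisms[[1]]$sequence, "3")
  expect_identical(enum$mechanisms[[2]]$selection$support, c("1", "2"))
  expect_identical(vapply(enum$mechanisms, `[[`, integer(1), "total_steps"),
                   c(1L, 2L))
  expect_identical(vapply(enum$mechanisms, `[[`, integer(1),
                          "parsimony_rank"), c(1L, 2L))
})

test_that("enumeration stops cleanly when supports are exhausted", {
  enum <- enumerate_mechanisms(abc_instance(), fast_config(top_n = 10))
  expect_identical(enum$status, "complete")
  expect_length(enum$mechanisms, 2L) # only two feasible supports exist
  supports <- lapply(enum$mechanisms, function(m) m$selection$support)
  expect_false(any(duplicated(supports)))
})

test_that("a zero time limit yields an empty timeout outcome", {
  enum <- enumerate_mechanisms(abc_instance(),
                               solver_config(time_limit = 0))
  expect_identical(enum$status, "timeout")
  expect_length(enum$mechanisms, 0L)
})

test_that("ordering-infeasible selections are skipped, not returned", {
  # without the exemption the only balancing selection cannot be ordered
  enum <- enumerate_mechanisms(exemption_instance(FALSE), fast_config())
  expect_identical(enum$status, "infeasible")
  expect_length(enum$mechanisms, 0L)
  # with the exemption the same selection orders fine
  enum2 <- enumerate_mechanisms(exemption_instance(TRUE), fast_config())
  expect_identical(enum2$status, "complete")
  expect_identical(enum2$mechanisms[[1]]$sequence, c("1", "2"))
})

test_that("solver results agree with brute force on random instances", {
  agree <- 0L
  n_cases <- 40L
  for (seed in seq_len(n_cases)) {
    inst <- generate_instance(n_moieties = 5L, n_rules = 6L,
                              planted_length = 1L + (seed %% 4L),
                              labeled_fraction = 0.2, seed = seed)
    bf <- brute_force_min_mechanism(inst$problem, max_len = 4L)
    mono <- solve_min_order_rules(inst$problem, fast_config())
    enum <- enumerate_mechanisms(inst$problem, fast_config(top_n = 1))
    expect_identical(bf$status, "optimal", info = seed)
    lengths <- c(bf$length, mono$mechanism$total_steps,
                 enum$mechanisms[[1]]$total_steps)
    if (length(unique(lengths)) == 1L) agree <- agree + 1L
    # every returned mechanism is exactly balanced and prefix-feasible
    expect_true(validate_sequence(inst$problem, mono$mechanism$sequence))
    expect_true(validate_sequence(inst$problem,
                                  enum$mechanisms[[1]]$sequence))
  }
  expect_identical(agree, n_cases)
})

test_that("enumeration soundness: cutting all returned supports exhausts them", {
  inst <- generate_instance(n_moieties = 5L, n_rules = 6L,
                            planted_length = 3L, seed = 11L)
  cfg <- fast_config(top_n = 5)
  enum <- enumerate_mechanisms(inst$problem, cfg)
  expect_gt(length(enum$mechanisms), 0L)
  sels <- lapply(enum$mechanisms, `[[`, "selection")
  supports <- lapply(sels, `[[`, "support")
  expect_false(any(duplicated(supports)))
  res <- solve_min_rules(inst$problem, cfg, prior_solutions = sels)
  if (res$status == "optimal") {
    expect_gte(res$selection$total_steps,
               max(vapply(sels, `[[`, integer(1), "total_steps")))
  } else {
    expect_identical(res$status, "infeasible")
  }
})

test_that("selections referencing unknown rules are rejected", {
  prob <- abc_instance()
  expect_error(solve_order_rules(prob, rule_selection(c("99" = 1L)),
                                 fast_config()), "unknown rule id")
  expect_error(solve_min_rules(prob, fast_config(),
                               prior_solutions = list(rule_selection(integer()))),
               "non-empty")
})
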