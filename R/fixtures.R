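# Synthetic instances and brute-force oracles. Abstract (opaque) moiety
# ids decouple solver validation from the chemistry encoding; the toy
# esterase bridges the two layers.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random solver instance with a planted mechanism
#'
#' Draws a universe of random sparse rule deltas over abstract moieties,
#' samples a random rule sequence of the requested length, and constructs
#' the problem so that the planted sequence is feasible by construction:
#' the target is the sequence's summed delta and the initial counts cover
#' every prefix deficit of each unlabeled moiety (exactly the running
#' minimum, so feasibility is guaranteed, not merely sampled — a recovery
#' failure always indicts the solver). A fraction of moieties is marked
#' as labeled (catalytic, exempt from prefix non-negativity).
#'
#' @param n_moieties number of abstract moieties.
#' @param n_rules number of distinct rules.
#' @param planted_length length of the planted sequence (rules may
#'   repeat).
#' @param labeled_fraction fraction of moieties marked as labeled (M*).
#' @param seed integer seed; generation is a pure function of the
#'   arguments and the seed.
#' @param max_retries resampling budget for degenerate draws (zero
#'   target).
#' @return a `synthetic_instance`: list with `rule_matrix`, `problem`,
#'   `planted_sequence` (character rule ids), `planted_length`,
#'   `generator_seed`.
#' @export
generate_instance <- function(n_moieties = 5L, n_rules = 6L,
                              planted_length = 3L, labeled_fraction = 0,
                              seed = 1L, max_retries = 100L) {
  stopifnot(n_moieties >= 2L, n_rules >= 1L, planted_length >= 1L,
            labeled_fraction >= 0, labeled_fraction <= 1)
  .with_seed(seed, {
    n_lab <- floor(labeled_fraction * n_moieties)
    keys <- sprintf("m%02d", seq_len(n_moieties))
    if (n_lab > 0L) {
      lab_idx <- sample(n_moieties, n_lab)
      keys[lab_idx] <- label_moiety(keys[lab_idx], "cat")
    }
    draw_delta <- function() {
      k <- sample(2:min(3L, n_moieties), 1L)
      on_keys <- sample(keys, k)
      vals <- sample(c(-2L, -1L, 1L, 2L), k, replace = TRUE)
      moiety_vector(stats::setNames(vals, on_keys))
    }
    rules <- list()
    seen <- character()
    tries <- 0L
    while (length(rules) < n_rules) {
      tries <- tries + 1L
      if (tries > max_retries * n_rules) {
        stop("could not draw ", n_rules, " distinct non-zero rule deltas")
      }
      d <- draw_delta()
      sig <- mv_signature(d)
      if (mv_is_zero(d) || sig %in% seen) next
      seen <- c(seen, sig)
      rules[[length(rules) + 1L]] <- elementary_rule(
        length(rules) + 1L, d, provenance = sprintf("synthetic seed %d", seed))
    }
    rm_ <- rule_matrix(rules)
    deltas <- rule_deltas(rm_)
    for (attempt in seq_len(max_retries)) {
      seq_ids <- as.character(sample(n_rules, planted_length, replace = TRUE))
      target <- do.call(mv_add, unname(deltas[seq_ids]))
      if (!mv_is_zero(target)) break
      if (attempt == max_retries) {
        stop("planted sequence kept collapsing to a zero target")
      }
    }
    # prefix deficits per unlabeled moiety -> exact initial counts
    unlabeled <- keys[!moiety_is_labeled(keys)]
    running <- stats::setNames(integer(length(unlabeled)), unlabeled)
    c0 <- running
    for (id in seq_ids) {
      d <- deltas[[id]]
      hit <- intersect(names(d), unlabeled)
      running[hit] <- running[hit] + as.integer(d[hit])
      c0 <- pmin(c0, running)
    }
    c0 <- stats::setNames(pmax(0L, -c0), unlabeled)
    problem <- reaction_problem(
      target, moiety_vector(c0[c0 > 0L]), rm_,
      labeled_set = keys[moiety_is_labeled(keys)]
    )
    structure(
      list(rule_matrix = rm_, problem = problem,
           planted_sequence = seq_ids,
           planted_length = as.integer(planted_length),
           generator_seed = as.integer(seed)),
      class = "synthetic_instance"
    )
  })
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat("<synthetic_instance: ", length(x$rule_matrix$rules), " rules, ",
      "planted length ", x$planted_length, ", seed ", x$generator_seed,
      ">\n", sep = "")
  invisible(x)
}

#' Independent feasibility check of an ordered rule sequence
#'
#' Recomputes, with plain moiety-vector arithmetic, whether a sequence
#' (i) sums exactly to the problem target and (ii) keeps every unlabeled
#' moiety's running count non-negative after every prefix. Used as the
#' validator for planted instances and for solver outputs.
#'
#' @param problem a `reaction_problem`.
#' @param sequence character vector of rule ids.
#' @param exempt_labeled exempt labeled moieties from prefix
#'   non-negativity (the standard semantics); set `FALSE` to check the
#'   constraint without the catalytic exemption.
#' @return TRUE/FALSE.
#' @export
validate_sequence <- function(problem, sequence, exempt_labeled = TRUE) {
  deltas <- rule_deltas(problem$rule_matrix)
  state <- problem$initial_counts
  for (id in as.character(sequence)) {
    state <- mv_add(state, deltas[[id]])
    checked <- if (exempt_labeled) {
      state[!(names(state) %in% problem$labeled_set)]
    } else {
      state
    }
    if (length(checked) && any(as.integer(checked) < 0L)) return(FALSE)
  }
  total <- if (length(sequence)) {
    do.call(mv_add, unname(deltas[as.character(sequence)]))
  } else {
    moiety_vector()
  }
  mv_equal(total, problem$target)
}

#' Brute-force shortest feasible mechanism
#'
#' Exhaustively enumerates every rule sequence up to `max_len` (shortest
#' first) and returns the first that is feasible under
#' [validate_sequence()]'s semantics. Completely independent of the
#' optimizing search — this is the ground-truth oracle for solver
#' equivalence tests. Refuses instances where the enumeration would
#' exceed `guard` sequences.
#'
#' @param problem a `reaction_problem`.
#' @param max_len maximum sequence length to enumerate.
#' @param guard upper bound on the number of sequences to visit.
#' @return list with `status` (`"optimal"`/`"infeasible"`) and, when
#'   optimal, `sequence` and `length`.
#' @export
brute_force_min_mechanism <- function(problem, max_len, guard = 1e6) {
  n <- length(problem$rule_matrix$rules)
  total_seqs <- sum(n ^ (0:max_len))
  if (total_seqs > guard) {
    stop("brute force would enumerate ", format(total_seqs, big.mark = ","),
         " sequences (guard: ", format(guard, big.mark = ","), ")")
  }
  ids <- as.character(rule_ids(problem$rule_matrix))
  deltas <- rule_deltas(problem$rule_matrix)
  unlabeled_ok <- function(state) {
    checked <- state[!(names(state) %in% problem$labeled_set)]
    length(checked) == 0L || all(as.integer(checked) >= 0L)
  }
  if (mv_is_zero(problem$target)) {
    return(list(status = "optimal", sequence = character(), length = 0L))
  }
  recurse <- function(len_left, state, acc, seq_so_far) {
    if (mv_equal(acc, problem$target)) {
      return(seq_so_far)
    }
    if (len_left == 0L) return(NULL)
    for (id in ids) {
      state2 <- mv_add(state, deltas[[id]])
      if (!unlabeled_ok(state2)) next
      hit <- recurse(len_left - 1L, state2, mv_add(acc, deltas[[id]]),
                     c(seq_so_far, id))
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  for (L in seq_len(max_len)) {
    hit <- recurse(L, problem$initial_counts, moiety_vector(), character())
    if (!is.null(hit)) {
      return(list(status = "optimal", sequence = hit, length = length(hit)))
    }
  }
  list(status = "infeasible")
}

#' Miniature esterase chemistry with two planted catalytic strategies
#'
#' A hand-built abstraction of ester hydrolysis (ester + water -> acid +
#' alcohol) carrying two classic strategies: direct nucleophilic attack
#' by water through a tetrahedral intermediate (2 steps), and a covalent
#' serine route (acylation of a labeled serine hydroxyl, then hydrolysis
#' of the acyl-enzyme, 3 steps). Both strategies sum to the same overall
#' target, so enumeration must discover two distinct supports and the
#' compiled step network contains a branch point at the substrate state.
#'
#' @return list with `rule_matrix`, `problem`, `strategies` (named list
#'   of the two planted rule-id sequences) and `mechanism_db` (records of
#'   both strategies, usable for re-ranking demos).
#' @export
toy_esterase <- function() {
  ser <- label_moiety("ser_hydroxyl", "Ser")
  rules <- list(
    elementary_rule(1L, moiety_vector(c(
      ester_carbonyl = -1L, water = -1L, tetrahedral_w = 1L)),
      provenance = "direct attack of water on the ester carbonyl"),
    elementary_rule(2L, moiety_vector(c(
      tetrahedral_w = -1L, acid = 1L, alcohol = 1L)),
      provenance = "collapse of the water tetrahedral intermediate"),
    elementary_rule(3L, stats::setNames(
      c(-1L, -1L, 1L, 1L),
      c("ester_carbonyl", ser, "acyl_enzyme", "alcohol")),
      provenance = "serine acylation releasing the alcohol"),
    elementary_rule(4L, moiety_vector(c(
      acyl_enzyme = -1L, water = -1L, tetrahedral_s = 1L)),
      provenance = "water attack on the acyl-enzyme"),
    elementary_rule(5L, stats::setNames(
      c(-1L, 1L, 1L),
      c("tetrahedral_s", "acid", ser)),
      provenance = "collapse regenerating the serine")
  )
  rm_ <- rule_matrix(rules)
  target <- moiety_vector(c(ester_carbonyl = -1L, water = -1L,
                            acid = 1L, alcohol = 1L))
  c0 <- moiety_vector(stats::setNames(c(1L, 1L, 1L),
                                      c("ester_carbonyl", "water", ser)))
  problem <- reaction_problem(target, c0, rm_)
  strategies <- list(direct = c("1", "2"), covalent = c("3", "4", "5"))
  db <- list(
    mechanism_record("covalent_esterase", strategies$covalent,
                     metadata = list(note = "serine hydrolase strategy")),
    mechanism_record("unrelated", c("90", "91", "92"))
  )
  list(rule_matrix = rm_, problem = problem, strategies = strategies,
       mechanism_db = db)
}

#' Write a synthetic instance to files
#'
#' Emits `<base>_rules.json` (the rule set), `<base>_problem.json` (the
#' target, initial counts and labeled set) and `<base>_planted.json` (the
#' planted sequence), all plain text.
#'
#' @param instance a `synthetic_instance`.
#' @param base path prefix.
#' @return the three paths, invisibly.
#' @export
write_instance <- function(instance, base) {
  paths <- c(rules = paste0(base, "_rules.json"),
             problem = paste0(base, "_problem.json"),
             planted = paste0(base, "_planted.json"))
  write_rules(instance$rule_matrix, paths[["rules"]])
  p <- instance$problem
  jsonlite::write_json(
    list(
      target = as.list(stats::setNames(as.integer(p$target), names(p$target))),
      initial_counts = as.list(stats::setNames(as.integer(p$initial_counts),
                                               names(p$initial_counts))),
      labeled_set = as.list(p$labeled_set)
    ),
    paths[["problem"]], auto_unbox = TRUE, pretty = TRUE
  )
  jsonlite::write_json(
    list(planted_sequence = as.list(instance$planted_sequence),
         planted_length = instance$planted_length,
         generator_seed = instance$generator_seed),
    paths[["planted"]], auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}

#' @rdname write_instance
#' @param rules_path,problem_path paths written by `write_instance()`.
#' @return `read_problem()` returns a `reaction_problem`.
#' @export
read_problem <- function(rules_path, problem_path) {
  rm_ <- read_rules(rules_path)
  doc <- jsonlite::fromJSON(problem_path, simplifyVector = FALSE)
  to_mv <- function(x) {
    if (length(x) == 0L) return(moiety_vector())
    moiety_vector(stats::setNames(vapply(x, as.integer, integer(1)), names(x)))
  }
  reaction_problem(to_mv(doc$target), to_mv(doc$initial_counts), rm_,
                   labeled_set = unlist(doc$labeled_set) %||% character())
}
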