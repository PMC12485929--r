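#' Solver configuration
#'
#' Tunable limits for mechanism search. `max_rules` is the cap W on the
#' total number of elementary steps in a mechanism (default 20);
#' `max_steps` is the step horizon K of the monolithic formulation and
#' defaults to W (a longer horizon is useless under the W cap). `top_n`
#' is how many ordered mechanisms enumeration returns (default 10).
#' `time_limit` is the per-reaction wall-clock budget in seconds shared by
#' all solves for that reaction; `per_order_time_limit` (default
#' `time_limit/10`) bounds any single ordering attempt so one hard
#' ordering cannot starve the enumeration. `cut_style` selects the
#' integer-cut semantics (see [add_integer_cut()]).
#'
#' @param max_rules integer W >= 1.
#' @param max_steps integer K >= W.
#' @param top_n integer >= 1.
#' @param time_limit seconds.
#' @param per_order_time_limit seconds.
#' @param cut_style `"as_printed"` or `"support_exact"`.
#' @param solver_seed integer, recorded for reproducibility (the exact
#'   search is deterministic; the seed is carried into outcome digests).
#' @return a `solver_config` list.
#' @export
solver_config <- function(max_rules = 20L, max_steps = max_rules,
                          top_n = 10L, time_limit = 1200,
                          per_order_time_limit = time_limit / 10,
                          cut_style = c("as_printed", "support_exact"),
                          solver_seed = 1L) {
  cut_style <- match.arg(cut_style)
  stopifnot(max_rules >= 1L, max_steps >= max_rules, top_n >= 1L,
            time_limit >= 0, per_order_time_limit >= 0)
  structure(
    list(max_rules = as.integer(max_rules), max_steps = as.integer(max_steps),
         top_n = as.integer(top_n), time_limit = as.numeric(time_limit),
         per_order_time_limit = as.numeric(per_order_time_limit),
         cut_style = cut_style, solver_seed = as.integer(solver_seed)),
    class = "solver_config"
  )
}

#' Reaction problem: the input to mechanism search
#'
#' Bundles the overall reaction target (the net moiety-change vector), the
#' initial substrate moiety counts, the rule matrix and the labeled set
#' M*. Labeled moieties — those originating from catalytic residues and
#' cofactors — are exempt from the running non-negativity constraint
#' because the enzyme's machinery is reusable: a protonated histidine may
#' be consumed in one step and regenerated in another.
#'
#' @param target `moiety_vector` of net changes.
#' @param initial_counts `moiety_vector` of substrate moiety counts
#'   (non-negative).
#' @param rule_matrix a `rule_matrix`.
#' @param labeled_set character vector of labeled moiety keys (defaults to
#'   the rule matrix's labeled set).
#' @return a `reaction_problem`.
#' @export
reaction_problem <- function(target, initial_counts = moiety_vector(),
                             rule_matrix, labeled_set = rule_matrix$labeled_set) {
  if (!inherits(target, "moiety_vector")) target <- moiety_vector(target)
  if (!inherits(initial_counts, "moiety_vector")) {
    initial_counts <- moiety_vector(initial_counts)
  }
  if (any(as.integer(initial_counts) < 0L)) {
    stop("initial_counts must be non-negative")
  }
  structure(
    list(target = target, initial_counts = initial_counts,
         rule_matrix = rule_matrix,
         labeled_set = unique(c(labeled_set,
                                names(target)[moiety_is_labeled(names(target))]))),
    class = "reaction_problem"
  )
}

#' Rule selection (an unordered solution of the parsimony problem)
#'
#' @param counts named positive integer vector, names are rule ids: the
#'   number of times each rule is used.
#' @return a `rule_selection` with `counts`, `support` and `total_steps`.
#' @export
rule_selection <- function(counts) {
  counts <- counts[counts > 0L]
  ids <- names(counts)
  o <- order(as.integer(ids))
  counts <- stats::setNames(as.integer(counts[o]), ids[o])
  structure(
    list(counts = counts, support = names(counts),
         total_steps = sum(counts)),
    class = "rule_selection"
  )
}

#' @export
print.rule_selection <- function(x, ...) {
  cat("<rule_selection: ", x$total_steps, " steps | ",
      paste(sprintf("%sx%d", x$support, x$counts), collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}

## ---- internal search engine ------------------------------------------------

# Align problem data onto a shared row space. Rows cover the rule matrix's
# moiety index plus the support of the target and the initial counts, so
# an unsupported target moiety shows up as an all-zero row (=> infeasible).
.solver_prep <- function(problem) {
  rm <- problem$rule_matrix
  rows <- sort(unique(c(rm$moiety_index, names(problem$target),
                        names(problem$initial_counts))), method = "radix")
  Tm <- rule_delta_matrix(rm, extra_moieties = rows)
  Tm <- Tm[rows, , drop = FALSE]
  expand <- function(v) {
    out <- stats::setNames(integer(length(rows)), rows)
    out[names(v)] <- as.integer(v)
    out
  }
  list(
    rows = rows,
    Tm = Tm,
    target = expand(problem$target),
    c0 = expand(problem$initial_counts),
    unlabeled = !(rows %in% problem$labeled_set),
    ids = colnames(Tm)
  )
}

.deadline <- function(seconds) {
  if (is.null(seconds) || !is.finite(seconds)) return(Inf)
  proc.time()[["elapsed"]] + seconds
}

.expired <- function(deadline) {
  is.finite(deadline) && proc.time()[["elapsed"]] > deadline
}

# Preprocess cuts against the column order of Tm.
.prep_cuts <- function(cuts, ids) {
  lapply(cuts, function(cut) {
    support <- as.character(cut$support)
    idx <- match(support, ids)
    if (anyNA(idx)) stop("cut support refers to unknown rule id")
    list(style = cut$style, idx = idx, support = sort(support),
         limit = length(support) - 1L)
  })
}

# Exact search for the minimum-cardinality rule multiset y with
# T y = target, sum(y) <= W, subject to integer cuts. Iterative deepening
# on the step count with a per-moiety reachability bound.
.search_min_rules <- function(prep, W, cuts, deadline) {
  Tm <- prep$Tm
  n <- ncol(Tm)
  target <- prep$target
  if (n == 0L) {
    if (all(target == 0L)) {
      return(list(status = "optimal", counts = integer()))
    }
    return(list(status = "infeasible"))
  }
  untouched <- rowSums(Tm != 0L) == 0L
  if (any(target != 0L & untouched)) return(list(status = "infeasible"))

  # suffix bounds: largest gain / loss available from rule j onwards
  maxpos <- matrix(0L, nrow(Tm), n + 1L)
  maxneg <- matrix(0L, nrow(Tm), n + 1L)
  for (j in n:1) {
    maxpos[, j] <- pmax(maxpos[, j + 1L], Tm[, j])
    maxneg[, j] <- pmin(maxneg[, j + 1L], Tm[, j])
  }

  cuts <- .prep_cuts(cuts, prep$ids)
  printed <- Filter(function(c) c$style == "as_printed", cuts)
  exact <- Filter(function(c) c$style == "support_exact", cuts)

  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  env$timeout <- FALSE

  accept <- function(counts) {
    support <- sort(prep$ids[counts > 0L])
    for (cut in exact) {
      if (identical(support, cut$support)) return(FALSE)
    }
    TRUE
  }

  dfs <- function(j, remaining, residual, counts, printed_sums) {
    env$nodes <- env$nodes + 1L
    if (env$nodes %% 2048L == 0L && .expired(deadline)) {
      env$timeout <- TRUE
      return(NULL)
    }
    if (all(residual == 0L) && accept(counts)) return(counts)
    if (j > n) return(NULL)
    # lower bound on steps still needed
    pos <- residual > 0L
    neg <- residual < 0L
    if (any(pos & maxpos[, j] <= 0L) || any(neg & maxneg[, j] >= 0L)) {
      return(NULL)
    }
    need <- 0L
    if (any(pos)) {
      need <- max(need, max(ceiling(residual[pos] / maxpos[pos, j])))
    }
    if (any(neg)) {
      need <- max(need, max(ceiling(residual[neg] / maxneg[neg, j])))
    }
    if (need > remaining) return(NULL)
    cap <- remaining
    for (ci in seq_along(printed)) {
      if (j %in% printed[[ci]]$idx) {
        cap <- min(cap, printed[[ci]]$limit - printed_sums[ci])
      }
    }
    if (cap < 0L) return(NULL)
    col <- Tm[, j]
    for (c in 0L:cap) {
      ps <- printed_sums
      if (c > 0L) {
        for (ci in seq_along(printed)) {
          if (j %in% printed[[ci]]$idx) ps[ci] <- ps[ci] + c
        }
      }
      counts[j] <- c
      hit <- dfs(j + 1L, remaining - c, residual - c * col, counts, ps)
      if (!is.null(hit) || env$timeout) return(hit)
    }
    NULL
  }

  for (L in 0L:W) {
    hit <- dfs(1L, L, target, integer(n), integer(length(printed)))
    if (env$timeout) return(list(status = "timeout"))
    if (!is.null(hit)) {
      return(list(status = "optimal",
                  counts = stats::setNames(hit[hit > 0L],
                                           prep$ids[hit > 0L])))
    }
  }
  list(status = "infeasible")
}

# Feasible ordering of a fixed rule multiset: depth-first over the next
# rule to fire, with prefix non-negativity on unlabeled moieties and
# memoisation of dead remaining-multisets (the running state is a pure
# function of the remaining multiset).
.search_order <- function(prep, counts, deadline) {
  ids <- names(counts)
  idx <- match(ids, prep$ids)
  if (anyNA(idx)) stop("selection refers to unknown rule id")
  cols <- prep$Tm[prep$unlabeled, idx, drop = FALSE]
  state0 <- prep$c0[prep$unlabeled]
  K <- sum(counts)
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  env$timeout <- FALSE
  dead <- new.env(parent = emptyenv())

  dfs <- function(remaining, state, seq_so_far) {
    env$nodes <- env$nodes + 1L
    if (env$nodes %% 2048L == 0L && .expired(deadline)) {
      env$timeout <- TRUE
      return(NULL)
    }
    if (sum(remaining) == 0L) return(seq_so_far)
    key <- paste(remaining, collapse = ",")
    if (exists(key, envir = dead, inherits = FALSE)) return(NULL)
    for (i in seq_along(remaining)) {
      if (remaining[i] == 0L) next
      state2 <- state + cols[, i]
      if (any(state2 < 0L)) next
      remaining[i] <- remaining[i] - 1L
      hit <- dfs(remaining, state2, c(seq_so_far, ids[i]))
      if (!is.null(hit) || env$timeout) return(hit)
      remaining[i] <- remaining[i] + 1L
    }
    assign(key, TRUE, envir = dead)
    NULL
  }

  hit <- dfs(as.integer(counts), state0, character())
  if (env$timeout) return(list(status = "timeout"))
  if (is.null(hit)) return(list(status = "infeasible"))
  list(status = "feasible", sequence = hit)
}

# Exact search for a shortest feasible *ordered* mechanism (the monolithic
# formulation): iterative deepening over sequence length with prefix
# non-negativity, a per-moiety reachability bound and memoisation keyed by
# (residual, remaining budget) - the running state is determined by the
# residual.
.search_min_order <- function(prep, K, deadline) {
  Tm <- prep$Tm
  n <- ncol(Tm)
  target <- prep$target
  if (all(target == 0L)) {
    return(list(status = "optimal", sequence = character()))
  }
  if (n == 0L) return(list(status = "infeasible"))
  untouched <- rowSums(Tm != 0L) == 0L
  if (any(target != 0L & untouched)) return(list(status = "infeasible"))
  maxpos <- apply(Tm, 1, max)
  maxneg <- apply(Tm, 1, min)
  unl <- prep$unlabeled
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  env$timeout <- FALSE

  bound <- function(residual) {
    pos <- residual > 0L
    neg <- residual < 0L
    if (any(pos & maxpos <= 0L) || any(neg & maxneg >= 0L)) return(Inf)
    need <- 0L
    if (any(pos)) need <- max(need, max(ceiling(residual[pos] / maxpos[pos])))
    if (any(neg)) need <- max(need, max(ceiling(residual[neg] / maxneg[neg])))
    need
  }

  for (L in seq_len(K)) {
    dead <- new.env(parent = emptyenv())
    dfs <- function(remaining, state, residual, seq_so_far) {
      env$nodes <- env$nodes + 1L
      if (env$nodes %% 2048L == 0L && .expired(deadline)) {
        env$timeout <- TRUE
        return(NULL)
      }
      if (all(residual == 0L)) return(seq_so_far)
      if (remaining == 0L) return(NULL)
      if (bound(residual) > remaining) return(NULL)
      key <- paste(remaining, paste(residual, collapse = ","), sep = "|")
      if (exists(key, envir = dead, inherits = FALSE)) return(NULL)
      for (j in seq_len(n)) {
        state2 <- state + Tm[unl, j]
        if (any(state2 < 0L)) next
        hit <- dfs(remaining - 1L, state2, residual - Tm[, j],
                   c(seq_so_far, prep$ids[j]))
        if (!is.null(hit) || env$timeout) return(hit)
      }
      assign(key, TRUE, envir = dead)
      NULL
    }
    hit <- dfs(L, prep$c0[unl], target, character())
    if (env$timeout) return(list(status = "timeout"))
    if (!is.null(hit)) return(list(status = "optimal", sequence = hit))
  }
  list(status = "infeasible")
}

## ---- public solver operations ----------------------------------------------

#' Minimal rule selection satisfying the overall moiety balance
#'
#' Solves the first stage of the decomposed search: find the smallest
#' multiset of elementary rules whose summed deltas equal the reaction
#' target, with the total number of steps capped at W, excluding any prior
#' solutions through integer cuts. The search is exact (iterative
#' deepening with reachability bounds), so the returned selection is a
#' certified optimum under the cuts.
#'
#' @param problem a `reaction_problem`.
#' @param config a `solver_config`.
#' @param prior_solutions list of `rule_selection`s to exclude (each is
#'   turned into an integer cut of the configured style).
#' @param cuts optional list of explicit cuts (as built by
#'   [add_integer_cut()]); appended to those from `prior_solutions`.
#' @param time_limit optional override of `config$time_limit`, seconds.
#' @return a list with `status` (`"optimal"`, `"infeasible"` or
#'   `"timeout"`) and, when optimal, `selection` (a `rule_selection`).
#' @export
solve_min_rules <- function(problem, config = solver_config(),
                            prior_solutions = list(), cuts = list(),
                            time_limit = config$time_limit) {
  prep <- .solver_prep(problem)
  all_cuts <- c(
    lapply(prior_solutions, function(s) {
      if (length(s$support) == 0L) stop("prior solution must be non-empty")
      list(support = s$support, style = config$cut_style)
    }),
    cuts
  )
  res <- .search_min_rules(prep, config$max_rules, all_cuts,
                           .deadline(time_limit))
  if (res$status != "optimal") return(res)
  list(status = "optimal", selection = rule_selection(res$counts))
}

#' Feasible ordering of a rule selection
#'
#' Solves the second stage: given a rule multiset from
#' [solve_min_rules()], find any ordering in which no unlabeled moiety's
#' running count ever drops below zero (labeled moieties in M* are
#' exempt: catalytic machinery is reusable). Pure feasibility — there is
#' no objective.
#'
#' @inheritParams solve_min_rules
#' @param selection a `rule_selection` satisfying the moiety balance.
#' @return list with `status` (`"feasible"`, `"infeasible"`, `"timeout"`)
#'   and, when feasible, `mechanism` (an `ordered_mechanism`).
#' @export
solve_order_rules <- function(problem, selection, config = solver_config(),
                              time_limit = config$per_order_time_limit) {
  prep <- .solver_prep(problem)
  res <- .search_order(prep, selection$counts, .deadline(time_limit))
  if (res$status != "feasible") return(res)
  list(status = "feasible",
       mechanism = .assemble_mechanism(problem, res$sequence, selection))
}

#' One-shot search for a shortest ordered mechanism
#'
#' The monolithic formulation: simultaneously selects and orders rules,
#' minimising the number of steps subject to overall balance and prefix
#' non-negativity of unlabeled moieties. Exact but slower than the
#' decomposed path; it serves as the reference for the decomposed solver
#' on small instances.
#'
#' @inheritParams solve_min_rules
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"timeout"`)
#'   and, when optimal, `mechanism` (an `ordered_mechanism`; the empty
#'   mechanism for a zero target).
#' @export
solve_min_order_rules <- function(problem, config = solver_config(),
                                  time_limit = config$time_limit) {
  prep <- .solver_prep(problem)
  res <- .search_min_order(prep, min(config$max_steps, config$max_rules),
                           .deadline(time_limit))
  if (res$status != "optimal") return(res)
  counts <- table(res$sequence)
  sel <- if (length(res$sequence)) {
    rule_selection(stats::setNames(as.integer(counts), names(counts)))
  } else {
    rule_selection(integer())
  }
  list(status = "optimal",
       mechanism = .assemble_mechanism(problem, res$sequence, sel))
}

#' Append an integer cut excluding a found rule selection
#'
#' Two semantics are available. `"as_printed"` adds
#' `sum(y[r in S]) <= |S| - 1`: it forbids the found support S but, as a
#' side effect, also forbids any solution that uses rules of S with total
#' multiplicity |S| or more (e.g. after cutting S = \{A, B\}, the selection
#' \{A: 2\} is also excluded). `"support_exact"` excludes exactly the
#' selections whose support equals S and nothing else. The default
#' follows `config$cut_style`.
#'
#' @param model a solver model state from [solver_model()].
#' @param support character vector of rule ids (non-empty).
#' @param cut_style cut semantics for this cut.
#' @return the model state with the cut appended.
#' @export
add_integer_cut <- function(model, support,
                            cut_style = model$config$cut_style) {
  support <- as.character(support)
  if (length(support) == 0L) stop("cut support must be non-empty")
  cut_style <- match.arg(cut_style, c("as_printed", "support_exact"))
  model$cuts <- c(model$cuts, list(list(support = support, style = cut_style)))
  model
}

#' @rdname add_integer_cut
#' @param problem a `reaction_problem`.
#' @param config a `solver_config`.
#' @export
solver_model <- function(problem, config = solver_config()) {
  structure(list(problem = problem, config = config, cuts = list()),
            class = "solver_model")
}

.assemble_mechanism <- function(problem, sequence, selection,
                                parsimony_rank = NA_integer_) {
  # cumulative states over all moieties, labeled included, for reporting
  deltas <- rule_deltas(problem$rule_matrix)
  state <- problem$initial_counts
  states <- vector("list", length(sequence) + 1L)
  states[[1L]] <- state
  for (k in seq_along(sequence)) {
    state <- mv_add(state, deltas[[as.character(sequence[k])]])
    states[[k + 1L]] <- state
  }
  structure(
    list(sequence = as.character(sequence), selection = selection,
         total_steps = selection$total_steps,
         parsimony_rank = parsimony_rank, states = states),
    class = "ordered_mechanism"
  )
}

#' @export
print.ordered_mechanism <- function(x, ...) {
  cat("<ordered_mechanism: ", x$total_steps, " steps",
      if (!is.na(x$parsimony_rank)) paste0(", rank ", x$parsimony_rank),
      " | ", paste(x$sequence, collapse = " -> "), ">\n", sep = "")
  invisible(x)
}

#' Enumerate the most parsimonious ordered mechanisms
#'
#' Iterates the decomposed search: [solve_min_rules()] proposes a minimal
#' rule selection, [solve_order_rules()] tries to order it; selections
#' with no feasible ordering are cut and skipped (they consume budget but
#' produce no candidate). Each accepted mechanism's support is cut before
#' re-solving, so ranks are 1-based in order of discovery and step counts
#' never decrease with rank. Enumeration stops at `top_n` mechanisms,
#' proven infeasibility, or the time limit.
#'
#' @inheritParams solve_min_rules
#' @return list with `mechanisms` (list of `ordered_mechanism`) and
#'   `status`: `"complete"` (top_n reached or possibilities exhausted
#'   after at least the full enumeration), `"timeout"`, or `"infeasible"`
#'   (proven infeasible with no mechanism found).
#' @export
enumerate_mechanisms <- function(problem, config = solver_config()) {
  t0 <- proc.time()[["elapsed"]]
  deadline <- if (is.finite(config$time_limit)) t0 + config$time_limit else Inf
  remaining <- function() deadline - proc.time()[["elapsed"]]
  mechanisms <- list()
  model <- solver_model(problem, config)
  if (.expired(deadline) || config$time_limit == 0) {
    return(list(mechanisms = mechanisms, status = "timeout"))
  }
  repeat {
    sel_res <- solve_min_rules(problem, config, cuts = model$cuts,
                               time_limit = remaining())
    if (sel_res$status == "timeout") {
      return(list(mechanisms = mechanisms, status = "timeout"))
    }
    if (sel_res$status == "infeasible") {
      status <- if (length(mechanisms)) "complete" else "infeasible"
      return(list(mechanisms = mechanisms, status = status))
    }
    sel <- sel_res$selection
    if (sel$total_steps == 0L) {
      # zero target: the empty mechanism is the unique optimum
      mech <- .assemble_mechanism(problem, character(), sel, 1L)
      return(list(mechanisms = list(mech), status = "complete"))
    }
    ord_budget <- min(config$per_order_time_limit, remaining())
    ord_res <- solve_order_rules(problem, sel, config,
                                 time_limit = ord_budget)
    if (ord_res$status == "timeout" && .expired(deadline)) {
      return(list(mechanisms = mechanisms, status = "timeout"))
    }
    if (ord_res$status == "feasible") {
      mech <- ord_res$mechanism
      mech$parsimony_rank <- length(mechanisms) + 1L
      mechanisms[[length(mechanisms) + 1L]] <- mech
      if (length(mechanisms) >= config$top_n) {
        return(list(mechanisms = mechanisms, status = "complete"))
      }
    }
    # cut this support whether ordered, unorderable, or order-timed-out
    model <- add_integer_cut(model, sel$support)
  }
}
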