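#' Moieties of a reaction that the rule set cannot touch
#'
#' A reaction is only solvable if every moiety it gains or loses appears
#' in the rule matrix's moiety index; otherwise no combination of rules
#' can balance it and the reaction is reported as incompatible (the
#' outcome class driven by gaps in the curated rule set, e.g. cyanate or
#' isothiocyanate chemistry).
#'
#' @param problem a `reaction_problem`.
#' @param strict also require the initial substrate moieties to be known.
#' @return character vector of unknown moiety keys (empty = compatible).
#' @export
compatibility_check <- function(problem, strict = FALSE) {
  need <- names(problem$target) %||% character()
  if (strict) need <- union(need, names(problem$initial_counts))
  as.character(setdiff(need, problem$rule_matrix$moiety_index))
}

.problem_from_reaction <- function(rxn_smiles, rule_matrix) {
  rxn <- parse_reaction(rxn_smiles)
  delta <- reaction_delta(rxn$substrates, rxn$products)
  c0 <- do.call(mv_add, lapply(rxn$substrates, moiety_counts))
  list(reaction = rxn,
       problem = reaction_problem(delta, c0, rule_matrix))
}

#' Predict ranked mechanisms for one reaction
#'
#' The end-to-end pipeline for a single reaction: check elemental/charge
#' balance, screen for a zero net moiety change and for moieties the rule
#' set does not know, enumerate the most parsimonious ordered mechanisms,
#' and (when a mechanism database is given) re-rank them by similarity to
#' known mechanisms. Deterministic for a fixed configuration.
#'
#' @param reaction a reaction SMILES string
#'   (`"sub1.sub2>>prod1.prod2"`) or a prebuilt `reaction_problem` (the
#'   balance check is skipped for prebuilt problems, whose inputs are
#'   abstract moiety vectors).
#' @param rule_matrix a `rule_matrix`.
#' @param mechanism_db optional list of `mechanism_record`s for
#'   re-ranking.
#' @param config a `solver_config`.
#' @param reaction_id identifier carried into the outcome.
#' @param identity step-identity mode for re-ranking (see
#'   [as_mechanism_record()]).
#' @return a `reaction_outcome`: list with `reaction_id`, `status` (one of
#'   `"predicted"`, `"timeout"`, `"infeasible"`, `"incompatible"`,
#'   `"unbalanced"`, `"no_net_change"`), `candidates` (re-ranked list,
#'   non-empty iff status is `"predicted"`), `incompatible_moieties`
#'   (non-empty iff status is `"incompatible"`), `balance` (report, for
#'   SMILES input) and `enumeration_status`.
#' @export
predict_mechanism <- function(reaction, rule_matrix, mechanism_db = NULL,
                              config = solver_config(),
                              reaction_id = "reaction",
                              identity = c("rule_id", "delta")) {
  identity <- match.arg(identity)
  outcome <- function(status, candidates = list(),
                      incompatible = character(), balance = NULL,
                      enum_status = NA_character_) {
    structure(
      list(reaction_id = reaction_id, status = status,
           candidates = candidates, incompatible_moieties = incompatible,
           balance = balance, enumeration_status = enum_status,
           config = config),
      class = "reaction_outcome"
    )
  }
  balance <- NULL
  if (is.character(reaction)) {
    built <- .problem_from_reaction(reaction, rule_matrix)
    balance <- check_balance(built$reaction$substrates,
                             built$reaction$products)
    if (!balance$elemental || !balance$charge) {
      return(outcome("unbalanced", balance = balance))
    }
    problem <- built$problem
  } else if (inherits(reaction, "reaction_problem")) {
    problem <- reaction
  } else {
    stop("reaction must be a reaction SMILES or a reaction_problem")
  }
  if (mv_is_zero(problem$target)) {
    return(outcome("no_net_change", balance = balance))
  }
  unknown <- compatibility_check(problem)
  if (length(unknown)) {
    return(outcome("incompatible", incompatible = unknown,
                   balance = balance))
  }
  enum <- enumerate_mechanisms(problem, config)
  if (length(enum$mechanisms) == 0L) {
    status <- if (enum$status == "infeasible") "infeasible" else "timeout"
    return(outcome(status, balance = balance, enum_status = enum$status))
  }
  candidates <- enum$mechanisms
  if (!is.null(mechanism_db) && length(mechanism_db)) {
    candidates <- rerank_mechanisms(candidates, mechanism_db,
                                    rule_matrix = rule_matrix,
                                    identity = identity)
  }
  outcome("predicted", candidates = candidates, balance = balance,
          enum_status = enum$status)
}

#' @export
print.reaction_outcome <- function(x, ...) {
  cat("<reaction_outcome '", x$reaction_id, "': ", x$status,
      if (length(x$candidates)) paste0(", ", length(x$candidates),
                                       " candidates"),
      ">\n", sep = "")
  invisible(x)
}

.outcome_statuses <- c("predicted", "timeout", "infeasible", "incompatible",
                       "unbalanced", "no_net_change", "error")

.outcome_to_list <- function(x) {
  list(
    reaction_id = x$reaction_id,
    status = x$status,
    incompatible_moieties = as.list(x$incompatible_moieties),
    candidates = lapply(x$candidates, function(m) {
      list(
        parsimony_rank = m$parsimony_rank,
        similarity_rank = m$similarity_rank %||% NULL,
        similarity_score = m$similarity_score %||% NULL,
        similarity_best_match = m$similarity_best_match %||% NULL,
        total_steps = m$total_steps,
        sequence = as.list(m$sequence),
        states = lapply(m$states, function(s) {
          as.list(stats::setNames(as.integer(s), names(s)))
        })
      )
    }),
    config = list(max_rules = x$config$max_rules, top_n = x$config$top_n,
                  time_limit = x$config$time_limit,
                  cut_style = x$config$cut_style,
                  solver_seed = x$config$solver_seed)
  )
}

#' Batch mechanism prediction over a reaction file
#'
#' Reads a two-column delimited file (`id<TAB>reaction-SMILES`, header
#' optional), predicts each reaction in turn, and tabulates the outcome
#' taxonomy: predicted / timeout / infeasible / incompatible / unbalanced /
#' no_net_change (+ error for rows that fail to parse). A failing row
#' never aborts the batch. Output is deterministic for a fixed
#' configuration, so re-runs produce byte-identical files.
#'
#' @param reaction_file path to the reaction table (or a data.frame with
#'   columns id, reaction).
#' @param rule_matrix a `rule_matrix` or path to a rule-set file.
#' @param mechanism_db optional list of `mechanism_record`s or path to a
#'   mechanism-database JSON.
#' @param config a `solver_config`.
#' @param out_file optional path: per-reaction outcomes as JSON.
#' @param summary_file optional path: summary table as TSV.
#' @return list with `outcomes` (list of `reaction_outcome`) and `summary`
#'   (data.frame of counts and percentages per status).
#' @export
batch_predict <- function(reaction_file, rule_matrix, mechanism_db = NULL,
                          config = solver_config(), out_file = NULL,
                          summary_file = NULL) {
  if (is.character(rule_matrix)) rule_matrix <- read_rules(rule_matrix)
  if (is.character(mechanism_db)) mechanism_db <- read_mechanism_db(mechanism_db)
  if (is.data.frame(reaction_file)) {
    tab <- reaction_file
    names(tab)[1:2] <- c("id", "reaction")
  } else {
    raw <- readLines(reaction_file)
    raw <- raw[nzchar(raw)]
    if (length(raw) == 0L) {
      tab <- data.frame(id = character(), reaction = character(),
                        stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(raw, "\t", fixed = TRUE)
      bad <- which(vapply(parts, length, integer(1)) < 2L)
      if (length(bad)) stop("malformed reaction row at line ", bad[1])
      tab <- data.frame(id = vapply(parts, `[[`, character(1), 1L),
                        reaction = vapply(parts, `[[`, character(1), 2L),
                        stringsAsFactors = FALSE)
      if (nrow(tab) && tolower(tab$id[1]) == "id") tab <- tab[-1L, ]
    }
  }
  outcomes <- lapply(seq_len(nrow(tab)), function(i) {
    tryCatch(
      predict_mechanism(tab$reaction[i], rule_matrix, mechanism_db,
                        config, reaction_id = tab$id[i]),
      error = function(e) {
        structure(
          list(reaction_id = tab$id[i], status = "error",
               candidates = list(), incompatible_moieties = character(),
               balance = NULL, enumeration_status = NA_character_,
               config = config, message = conditionMessage(e)),
          class = "reaction_outcome"
        )
      }
    )
  })
  statuses <- vapply(outcomes, `[[`, character(1), "status")
  counts <- vapply(.outcome_statuses, function(s) sum(statuses == s),
                   integer(1))
  total <- length(statuses)
  summary <- data.frame(
    outcome = c("reactions_tested", .outcome_statuses),
    count = c(total, counts),
    percent = round(100 * c(total, counts) / max(total, 1L), 1),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_file)) {
    jsonlite::write_json(lapply(outcomes, .outcome_to_list), out_file,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (!is.null(summary_file)) {
    utils::write.table(summary, summary_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  list(outcomes = outcomes, summary = summary)
}

## ---- mechanistic-diversity network -----------------------------------------

.project_state <- function(v, generic) {
  if (length(generic) == 0L) return(v)
  keep <- !(names(v) %in% generic)
  moiety_vector(stats::setNames(as.integer(v)[keep], names(v)[keep]))
}

#' Compile candidate mechanisms into a network of catalytic strategies
#'
#' Nodes are the distinct cumulative moiety states reached along the
#' candidates' step prefixes (the substrate state is the source, the
#' product state the sink); directed edges are elementary steps. States
#' are projected by zeroing the configured generic-exchange moieties
#' (general acids/bases such as water/oxonium), so steps that differ only
#' in which generic base abstracts a proton collapse onto one edge
#' carrying all their rule ids.
#'
#' @param candidates non-empty list of `ordered_mechanism`s sharing one
#'   problem.
#' @param problem the `reaction_problem` they solve.
#' @param generic_moieties character vector of moiety keys treated as
#'   generic acid/base carriers (default: none).
#' @return an `igraph` directed graph; vertices carry a `state` signature
#'   attribute plus `source`/`sink` flags, edges carry `rules` (comma-
#'   joined rule ids) and `delta` (projected delta signature).
#' @export
build_step_network <- function(candidates, problem,
                               generic_moieties = character()) {
  if (length(candidates) == 0L) stop("no candidate mechanisms supplied")
  node_key <- function(state) mv_signature(.project_state(state, generic_moieties))
  edges <- list()
  for (mech in candidates) {
    states <- mech$states
    for (k in seq_along(mech$sequence)) {
      from <- node_key(states[[k]])
      to <- node_key(states[[k + 1L]])
      key <- paste(from, to, sep = " => ")
      prev <- edges[[key]] %||% list(from = from, to = to,
                                     rules = character())
      prev$rules <- sort(unique(c(prev$rules, mech$sequence[k])),
                         method = "radix")
      edges[[key]] <- prev
    }
  }
  edf <- data.frame(
    from = vapply(edges, `[[`, character(1), "from"),
    to = vapply(edges, `[[`, character(1), "to"),
    rules = vapply(edges, function(e) paste(e$rules, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE
  )
  edf$delta <- vapply(seq_len(nrow(edf)), function(i) {
    mv_signature(mv_add(mv_from_signature(edf$to[i]),
                        mv_neg(mv_from_signature(edf$from[i]))))
  }, character(1))
  g <- igraph::graph_from_data_frame(edf, directed = TRUE)
  src <- node_key(problem$initial_counts)
  snk <- node_key(mv_add(problem$initial_counts, problem$target))
  igraph::V(g)$state <- igraph::V(g)$name
  igraph::V(g)$source <- igraph::V(g)$name == src
  igraph::V(g)$sink <- igraph::V(g)$name == snk
  g
}

#' @rdname build_step_network
#' @param network an igraph network from `build_step_network()`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
write_step_network <- function(network, path,
                               format = c("graphml", "dot")) {
  format <- match.arg(format)
  if (format == "dot") {
    # the DOT writer has no boolean attribute type
    igraph::V(network)$source <- as.integer(igraph::V(network)$source)
    igraph::V(network)$sink <- as.integer(igraph::V(network)$sink)
  }
  igraph::write_graph(network, path, format = format)
  invisible(path)
}
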