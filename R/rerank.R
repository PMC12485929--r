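#' Record of a known (curated) mechanism
#'
#' A mechanism is compared purely through the multiset of its elementary
#' steps. Steps may be rule ids (within one rule set) or canonical delta
#' signatures from [mv_signature()] (for comparisons across rule sets).
#'
#' @param mechanism_id text identifier.
#' @param steps non-empty character vector (multiset) of step identities.
#' @param metadata optional list (source entry, organism, ...).
#' @return a `mechanism_record`.
#' @export
mechanism_record <- function(mechanism_id, steps, metadata = list()) {
  steps <- as.character(steps)
  if (length(steps) == 0L) stop("a mechanism must have at least one step")
  structure(
    list(mechanism_id = as.character(mechanism_id), steps = steps,
         metadata = metadata),
    class = "mechanism_record"
  )
}

#' Convert an ordered mechanism into a comparable record
#'
#' @param mechanism an `ordered_mechanism`.
#' @param rule_matrix the rule matrix it was built from; when supplied
#'   with `identity = "delta"`, steps become canonical delta signatures so
#'   candidates can be compared against records from another rule set.
#' @param identity `"rule_id"` or `"delta"`.
#' @param mechanism_id id for the record.
#' @return a `mechanism_record`.
#' @export
as_mechanism_record <- function(mechanism, rule_matrix = NULL,
                                identity = c("rule_id", "delta"),
                                mechanism_id = "candidate") {
  identity <- match.arg(identity)
  steps <- mechanism$sequence
  if (identity == "delta") {
    if (is.null(rule_matrix)) stop("identity='delta' needs the rule matrix")
    deltas <- rule_deltas(rule_matrix)
    steps <- vapply(steps, function(id) mv_signature(deltas[[id]]),
                    character(1), USE.NAMES = FALSE)
  }
  mechanism_record(mechanism_id, steps)
}

#' Unordered similarity between two mechanisms
#'
#' Similarity over the step multisets, ignoring order: 1 means identical
#' multisets of steps, 0 means no step in common. The default is the
#' multiset Jaccard index (intersection/union by minimum/maximum
#' multiplicities); `"jaccard"` collapses multiplicities to sets first,
#' `"dice"` is the set-based Dice coefficient.
#'
#' @param a,b `mechanism_record`s (or bare character step multisets).
#' @param method similarity formula.
#' @return a number in `[0, 1]`.
#' @export
unordered_similarity <- function(a, b, method = c("multiset_jaccard",
                                                  "jaccard", "dice")) {
  method <- match.arg(method)
  steps_of <- function(x) {
    if (inherits(x, "mechanism_record")) x$steps else as.character(x)
  }
  sa <- steps_of(a)
  sb <- steps_of(b)
  if (length(sa) == 0L || length(sb) == 0L) {
    stop("cannot score an empty mechanism")
  }
  if (method == "multiset_jaccard") {
    keys <- union(sa, sb)
    ca <- vapply(keys, function(k) sum(sa == k), integer(1))
    cb <- vapply(keys, function(k) sum(sb == k), integer(1))
    return(sum(pmin(ca, cb)) / sum(pmax(ca, cb)))
  }
  ua <- unique(sa)
  ub <- unique(sb)
  inter <- length(intersect(ua, ub))
  if (method == "jaccard") {
    inter / length(union(ua, ub))
  } else {
    2 * inter / (length(ua) + length(ub))
  }
}

#' Maximal similarity of a candidate to a mechanism database
#'
#' Scores the candidate against every record and keeps the maximum — its
#' similarity to its closest known analog. Ties go to the earliest record
#' in database order.
#'
#' @param candidate a `mechanism_record`.
#' @param db non-empty list of `mechanism_record`s.
#' @inheritParams unordered_similarity
#' @return a `similarity_score`: list with `value` in `[0,1]` and
#'   `best_match` (a mechanism_id).
#' @export
max_similarity <- function(candidate, db, method = "multiset_jaccard") {
  if (length(db) == 0L) stop("mechanism database is empty")
  values <- vapply(db, function(rec) {
    unordered_similarity(candidate, rec, method = method)
  }, numeric(1))
  best <- which.max(values) # first index on ties
  structure(
    list(value = values[best], best_match = db[[best]]$mechanism_id),
    class = "similarity_score"
  )
}

#' Re-rank parsimonious candidates by similarity to known mechanisms
#'
#' Assigns each candidate its maximal unordered similarity to the
#' database, then stably sorts in descending score; ties keep the
#' original parsimony order, so a run where all scores tie never does
#' worse than the parsimony baseline. Both ranks are retained.
#'
#' @param candidates non-empty list of `ordered_mechanism`s (ranked by
#'   parsimony, as returned by [enumerate_mechanisms()]).
#' @param db non-empty list of `mechanism_record`s.
#' @param rule_matrix rule matrix for the candidates; needed when
#'   `identity = "delta"`.
#' @param identity step-identity mode, see [as_mechanism_record()].
#' @inheritParams unordered_similarity
#' @return the permuted candidate list; each element gains
#'   `similarity_score`, `similarity_best_match` and `similarity_rank`.
#'   A summary table is attached as attribute `"ranking"`.
#' @export
rerank_mechanisms <- function(candidates, db, rule_matrix = NULL,
                              identity = c("rule_id", "delta"),
                              method = "multiset_jaccard") {
  if (length(candidates) == 0L) stop("no candidates to re-rank")
  identity <- match.arg(identity)
  scored <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    rec <- as_mechanism_record(cand, rule_matrix, identity,
                               mechanism_id = sprintf("rank%d", i))
    sc <- max_similarity(rec, db, method = method)
    cand$similarity_score <- sc$value
    cand$similarity_best_match <- sc$best_match
    cand
  })
  scores <- vapply(scored, `[[`, numeric(1), "similarity_score")
  parsimony <- vapply(scored, `[[`, integer(1), "parsimony_rank")
  ord <- order(-scores, parsimony) # stable: ties keep parsimony order
  out <- scored[ord]
  for (i in seq_along(out)) out[[i]]$similarity_rank <- i
  attr(out, "ranking") <- data.frame(
    similarity_rank = seq_along(out),
    parsimony_rank = vapply(out, `[[`, integer(1), "parsimony_rank"),
    total_steps = vapply(out, `[[`, integer(1), "total_steps"),
    score = vapply(out, `[[`, numeric(1), "similarity_score"),
    best_match = vapply(out, `[[`, character(1), "similarity_best_match"),
    stringsAsFactors = FALSE
  )
  out
}

#' Read and write mechanism-database files
#'
#' JSON list of `{mechanism_id, steps, metadata}` objects.
#'
#' @param db list of `mechanism_record`s.
#' @param path file path.
#' @return `read_mechanism_db()` returns a list of `mechanism_record`s.
#' @export
write_mechanism_db <- function(db, path) {
  doc <- lapply(db, function(rec) {
    list(mechanism_id = rec$mechanism_id, steps = as.list(rec$steps),
         metadata = rec$metadata)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mechanism_db
#' @export
read_mechanism_db <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc, function(rec) {
    mechanism_record(rec$mechanism_id,
                     vapply(rec$steps, as.character, character(1)),
                     metadata = rec$metadata %||% list())
  })
}
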