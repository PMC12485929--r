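#' Elementary mechanistic rule
#'
#' An elementary rule abstracts one mechanistic step as a signed
#' moiety-change vector (a column of the rule matrix T): positive entries
#' are moieties gained, negative entries moieties lost. Rules with an
#' empty delta are rejected — a step that changes nothing is not a step.
#'
#' @param rule_id stable integer identifier.
#' @param delta a non-zero `moiety_vector`.
#' @param direction `"forward"` or `"backward"`.
#' @param provenance free-text source annotation (mechanism entry, step
#'   index, organism); carried through to reports, never used in solving.
#' @param is_protonation flag for generated protonation/deprotonation rules.
#' @return an `elementary_rule` object.
#' @export
elementary_rule <- function(rule_id, delta, direction = "forward",
                            provenance = "", is_protonation = FALSE) {
  if (!inherits(delta, "moiety_vector")) delta <- moiety_vector(delta)
  if (mv_is_zero(delta)) stop("elementary rule delta must be non-zero")
  direction <- match.arg(direction, c("forward", "backward"))
  structure(
    list(rule_id = as.integer(rule_id), delta = delta, direction = direction,
         provenance = as.character(provenance),
         is_protonation = isTRUE(is_protonation)),
    class = "elementary_rule"
  )
}

#' @export
print.elementary_rule <- function(x, ...) {
  cat(sprintf("<rule %d (%s%s)> %s\n", x$rule_id, x$direction,
              if (x$is_protonation) ", protonation" else "",
              mv_signature(x$delta)))
  invisible(x)
}

#' Build a rule from a balanced elementary step
#'
#' Encodes one elementary step (given as substrate and product molecules)
#' as a rule delta. The step must be elementally and charge balanced
#' across all participating species — including catalytic ones — or it is
#' rejected with the balance report. Catalytic species (enzyme residues,
#' cofactors) are marked through `labels`, so their moieties enter the
#' delta as labeled members of M*.
#'
#' @inheritParams reaction_delta
#' @param labels optional named character vector mapping an input SMILES
#'   string to its label tag (e.g. `c("c1cc[nH+]cn1" = "His")`); applies to
#'   whichever side the molecule appears on.
#' @param rule_id integer id for the new rule.
#' @param provenance free-text provenance.
#' @return an `elementary_rule`.
#' @export
rule_from_step <- function(substrates, products, labels = NULL,
                           sub_coeffs = 1L, prod_coeffs = 1L,
                           rule_id = 1L, provenance = "") {
  report <- check_balance(substrates, products, sub_coeffs, prod_coeffs)
  if (!report$elemental || !report$charge) {
    msg <- utils::capture.output(print(report))
    stop("elementary step is not balanced; rejected:\n",
         paste(msg, collapse = "\n"))
  }
  lookup <- function(side) {
    if (is.null(labels) || !is.character(side)) {
      return(rep(NA_character_, length(.side_to_molecules(side))))
    }
    ifelse(side %in% names(labels), labels[side], NA_character_)
  }
  delta <- reaction_delta(substrates, products, sub_coeffs, prod_coeffs,
                          sub_labels = lookup(substrates),
                          prod_labels = lookup(products))
  if (mv_is_zero(delta)) {
    stop("elementary step has a zero moiety delta; rejected")
  }
  elementary_rule(rule_id, delta, provenance = provenance)
}

#' Reverse an elementary rule
#'
#' Every curated mechanistic step is treated as reversible; the reverse
#' rule negates the delta and flips the direction.
#'
#' @param rule an `elementary_rule`.
#' @param rule_id id for the reversed rule (defaults to `-rule_id` of the
#'   input; [build_rule_matrix()] reassigns sequential ids).
#' @return an `elementary_rule`.
#' @export
reverse_rule <- function(rule, rule_id = -rule$rule_id) {
  elementary_rule(
    rule_id, mv_neg(rule$delta),
    direction = if (rule$direction == "forward") "backward" else "forward",
    provenance = rule$provenance,
    is_protonation = rule$is_protonation
  )
}

#' Default proton-carrier moieties
#'
#' Protonation/deprotonation steps move a proton between a substrate
#' moiety and a generic carrier. The shipped default covers the carriers a
#' curated mechanism typically invokes: water/oxonium, hydroxide/water, a
#' primary-amine pair (lysine-like) and a carboxylate pair
#' (aspartate/glutamate-like). Each entry is a pair of moiety keys, the
#' acid (protonated) and base (deprotonated) form.
#'
#' @return a named list of `c(acid=, base=)` key pairs.
#' @export
default_proton_carriers <- function() {
  list(
    oxonium_water = c(acid = "O+1H3()", base = "O+0H2()"),
    water_hydroxide = c(acid = "O+0H2()", base = "O-1H1()"),
    ammonium_amine = c(acid = "N+1H3(-C+0)", base = "N+0H2(-C+0)"),
    carboxyl_carboxylate = c(acid = "O+0H1(-C+0)", base = "O-1H0(-C+0)")
  )
}

#' @rdname default_proton_carriers
#' @export
default_generic_moieties <- function() {
  unique(unlist(default_proton_carriers(), use.names = FALSE))
}

.check_protonation_pair <- function(protonated, deprotonated) {
  p <- parse_moiety_key(protonated)
  d <- parse_moiety_key(deprotonated)
  ok <- identical(p$element, d$element) &&
    identical(sort(p$neighbors), sort(d$neighbors)) &&
    p$n_h == d$n_h + 1L && p$charge == d$charge + 1L
  if (!ok) {
    stop("not a protonation pair (must differ by exactly one H and one ",
         "charge unit): ", protonated, " / ", deprotonated)
  }
  invisible(TRUE)
}

#' Generate protonation/deprotonation rules
#'
#' For each (protonated, deprotonated) moiety pair, emits two mutually
#' inverse rules per configured proton carrier: deprotonation transfers
#' the proton from the substrate moiety to the carrier base (producing the
#' carrier acid), protonation is the exact negation. Pairs must differ by
#' exactly one hydrogen and one unit of formal charge.
#'
#' @param moiety_pairs list of `c(protonated=, deprotonated=)` key pairs.
#' @param carriers list of carrier pairs, as [default_proton_carriers()].
#' @param id_start first rule id to assign.
#' @return a list of `elementary_rule` objects with `is_protonation=TRUE`.
#' @export
protonation_rules <- function(moiety_pairs,
                              carriers = default_proton_carriers(),
                              id_start = 1L) {
  rules <- list()
  next_id <- as.integer(id_start)
  for (pair in moiety_pairs) {
    protonated <- pair[["protonated"]]
    deprotonated <- pair[["deprotonated"]]
    .check_protonation_pair(protonated, deprotonated)
    for (cn in names(carriers)) {
      carrier <- carriers[[cn]]
      delta <- moiety_vector(stats::setNames(
        c(-1L, 1L, -1L, 1L),
        c(protonated, deprotonated, carrier[["base"]], carrier[["acid"]])
      ))
      if (mv_is_zero(delta)) next # carrier coincides with the pair itself
      prov <- sprintf("deprotonation of %s via %s", protonated, cn)
      rules[[length(rules) + 1L]] <- elementary_rule(
        next_id, delta, direction = "forward", provenance = prov,
        is_protonation = TRUE
      )
      rules[[length(rules) + 1L]] <- elementary_rule(
        next_id + 1L, mv_neg(delta), direction = "backward",
        provenance = sub("^deprotonation", "protonation", prov),
        is_protonation = TRUE
      )
      next_id <- next_id + 2L
    }
  }
  rules
}

#' Rule matrix: the deduplicated elementary-rule database
#'
#' Collects elementary rules into the matrix T whose columns are rule
#' deltas and whose rows are the moiety index M; the labeled subset M*
#' gathers every labeled moiety seen in any delta. Rule ids must be unique
#' and no two rules may share an identical delta.
#'
#' @param rules list of `elementary_rule` objects.
#' @return a `rule_matrix` with fields `rules`, `moiety_index`,
#'   `labeled_set`.
#' @export
rule_matrix <- function(rules = list()) {
  ids <- vapply(rules, function(r) r$rule_id, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicate rule_id: ", ids[duplicated(ids)][1])
  }
  sigs <- vapply(rules, function(r) mv_signature(r$delta), character(1))
  if (anyDuplicated(sigs)) {
    stop("duplicate rule delta (rules must be unique): ",
         sigs[duplicated(sigs)][1])
  }
  idx <- unique(unlist(lapply(rules, function(r) names(r$delta))))
  idx <- if (is.null(idx)) character() else sort(idx, method = "radix")
  structure(
    list(
      rules = rules,
      moiety_index = idx,
      labeled_set = idx[moiety_is_labeled(idx)]
    ),
    class = "rule_matrix"
  )
}

#' @export
print.rule_matrix <- function(x, ...) {
  cat("<rule_matrix: ", length(x$rules), " rules over ",
      length(x$moiety_index), " moieties (", length(x$labeled_set),
      " labeled)>\n", sep = "")
  invisible(x)
}

#' @rdname rule_matrix
#' @param x a `rule_matrix`.
#' @export
rule_ids <- function(x) vapply(x$rules, function(r) r$rule_id, integer(1))

#' @rdname rule_matrix
#' @export
rule_deltas <- function(x) {
  stats::setNames(lapply(x$rules, function(r) r$delta),
                  as.character(rule_ids(x)))
}

#' @rdname rule_matrix
#' @param id a rule id.
#' @export
get_rule <- function(x, id) {
  for (r in x$rules) if (r$rule_id == id) return(r)
  stop("no rule with id ", id)
}

#' Dense T matrix (moieties x rules) of a rule matrix
#'
#' @param x a `rule_matrix`.
#' @param extra_moieties additional row keys to include (e.g. the support
#'   of a reaction target).
#' @return an integer matrix, rownames = moiety keys, colnames = rule ids.
#' @export
rule_delta_matrix <- function(x, extra_moieties = character()) {
  rows <- sort(unique(c(x$moiety_index, extra_moieties)), method = "radix")
  m <- matrix(0L, nrow = length(rows), ncol = length(x$rules),
              dimnames = list(rows, as.character(rule_ids(x))))
  for (j in seq_along(x$rules)) {
    d <- x$rules[[j]]$delta
    m[names(d), j] <- as.integer(d)
  }
  m
}

#' Assemble a deduplicated rule matrix from elementary steps
#'
#' Runs each step through [rule_from_step()], optionally adds the reverse
#' of every rule and the configured protonation rules, and deduplicates by
#' exact delta equality (integer counts, no tolerance). Steps that fail
#' balance or have zero delta are logged, not fatal; the rejection log is
#' attached as the `"rejections"` attribute.
#'
#' @param steps list of steps; each step is a list with `substrates`,
#'   `products`, optional `sub_coeffs`, `prod_coeffs`, `labels`,
#'   `provenance`.
#' @param reversible add the negated version of every step rule.
#' @param protonation_pairs optional list of pairs for
#'   [protonation_rules()].
#' @param carriers proton carriers for the protonation rules.
#' @return a `rule_matrix`; ids are sequential in insertion order.
#' @export
build_rule_matrix <- function(steps, reversible = TRUE,
                              protonation_pairs = NULL,
                              carriers = default_proton_carriers()) {
  candidates <- list()
  rejections <- data.frame(step = integer(), reason = character(),
                           stringsAsFactors = FALSE)
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    prov <- if (!is.null(st$provenance)) st$provenance else sprintf("step %d", i)
    r <- tryCatch(
      rule_from_step(st$substrates, st$products, labels = st$labels,
                     sub_coeffs = st$sub_coeffs %||% 1L,
                     prod_coeffs = st$prod_coeffs %||% 1L,
                     rule_id = i, provenance = prov),
      error = function(e) conditionMessage(e)
    )
    if (is.character(r)) {
      rejections <- rbind(rejections, data.frame(
        step = i, reason = r, stringsAsFactors = FALSE))
    } else {
      candidates[[length(candidates) + 1L]] <- r
      if (reversible) {
        candidates[[length(candidates) + 1L]] <- reverse_rule(r)
      }
    }
  }
  if (!is.null(protonation_pairs) && length(protonation_pairs)) {
    candidates <- c(candidates,
                    protonation_rules(protonation_pairs, carriers))
  }
  # deduplicate by exact delta, keep first occurrence, renumber
  kept <- list()
  seen <- character()
  for (r in candidates) {
    sig <- mv_signature(r$delta)
    if (sig %in% seen) next
    seen <- c(seen, sig)
    r$rule_id <- length(kept) + 1L
    kept[[length(kept) + 1L]] <- r
  }
  out <- rule_matrix(kept)
  attr(out, "rejections") <- rejections
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- persistence -----------------------------------------------------------

#' Read and write rule-set files
#'
#' Two dialects are supported. JSON (`*.json`): a single document with
#' `rules` (each with `rule_id`, `direction`, `is_protonation`,
#' `provenance` and a dense `delta` map) and `labeled_set`. CSV: a
#' metadata table `path` with columns (rule_id, direction, is_protonation,
#' provenance), a sparse-triplet sidecar `<base>_deltas.csv` with columns
#' (rule_id, moiety_key, count), and a labeled-moiety list
#' `<base>_labeled.txt` with one key per line. `write_rules()` followed by
#' `read_rules()` is the identity on a `rule_matrix`.
#'
#' @param x a `rule_matrix`.
#' @param path file path; dialect chosen by extension (`.json` vs `.csv`).
#' @return `read_rules()` returns a `rule_matrix`; `write_rules()` returns
#'   `path` invisibly.
#' @export
write_rules <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- list(
      rules = lapply(x$rules, function(r) {
        list(rule_id = r$rule_id, direction = r$direction,
             is_protonation = r$is_protonation, provenance = r$provenance,
             delta = as.list(stats::setNames(as.integer(r$delta),
                                             names(r$delta))))
      }),
      labeled_set = as.list(x$labeled_set)
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  base <- tools::file_path_sans_ext(path)
  meta <- data.frame(
    rule_id = rule_ids(x),
    direction = vapply(x$rules, function(r) r$direction, character(1)),
    is_protonation = vapply(x$rules, function(r) r$is_protonation, logical(1)),
    provenance = vapply(x$rules, function(r) r$provenance, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(meta, path, row.names = FALSE)
  trip <- do.call(rbind, lapply(x$rules, function(r) {
    data.frame(rule_id = r$rule_id, moiety_key = names(r$delta),
               count = as.integer(r$delta), stringsAsFactors = FALSE)
  }))
  if (is.null(trip)) {
    trip <- data.frame(rule_id = integer(), moiety_key = character(),
                       count = integer())
  }
  utils::write.csv(trip, paste0(base, "_deltas.csv"), row.names = FALSE)
  writeLines(x$labeled_set, paste0(base, "_labeled.txt"))
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rules <- lapply(doc$rules, function(r) {
      keys <- names(r$delta)
      for (k in keys) validate_moiety_key(k)
      elementary_rule(
        r$rule_id,
        moiety_vector(stats::setNames(vapply(r$delta, as.integer, integer(1)),
                                      keys)),
        direction = r$direction, provenance = r$provenance %||% "",
        is_protonation = isTRUE(r$is_protonation)
      )
    })
    return(rule_matrix(rules))
  }
  base <- tools::file_path_sans_ext(path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("rule_id", "direction", "is_protonation", "provenance")
  if (!all(required %in% names(meta))) {
    stop("rule metadata file must have columns: ",
         paste(required, collapse = ", "))
  }
  meta$provenance <- ifelse(is.na(meta$provenance), "",
                            as.character(meta$provenance))
  if (anyDuplicated(meta$rule_id)) {
    stop("duplicate rule_id in ", path, ": ",
         meta$rule_id[duplicated(meta$rule_id)][1])
  }
  trip <- utils::read.csv(paste0(base, "_deltas.csv"), stringsAsFactors = FALSE)
  if (!all(c("rule_id", "moiety_key", "count") %in% names(trip))) {
    stop("delta triplet file must have columns rule_id, moiety_key, count")
  }
  bad <- which(is.na(suppressWarnings(as.integer(trip$count))) |
                 trip$count != round(trip$count))
  if (length(bad)) {
    stop("non-integer count in delta triplet file at data line ", bad[1])
  }
  for (k in unique(trip$moiety_key)) validate_moiety_key(k)
  rules <- lapply(seq_len(nrow(meta)), function(i) {
    rows <- trip[trip$rule_id == meta$rule_id[i], , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("rule ", meta$rule_id[i], " has no delta entries")
    }
    elementary_rule(
      meta$rule_id[i],
      moiety_vector(stats::setNames(as.integer(rows$count), rows$moiety_key)),
      direction = meta$direction[i], provenance = meta$provenance[i],
      is_protonation = as.logical(meta$is_protonation[i])
    )
  })
  out <- rule_matrix(rules)
  labeled_path <- paste0(base, "_labeled.txt")
  if (file.exists(labeled_path)) {
    extra <- intersect(read_labeled_moieties(labeled_path), out$moiety_index)
    out$labeled_set <- sort(unique(c(out$labeled_set, extra)), method = "radix")
  }
  out
}

#' @rdname write_rules
#' @export
read_labeled_moieties <- function(path) {
  keys <- readLines(path)
  keys <- keys[nzchar(keys)]
  for (k in keys) validate_moiety_key(k)
  keys
}
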