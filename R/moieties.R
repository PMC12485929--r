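#' Classify one heavy atom by its first bonding shell
#'
#' Builds the canonical moiety key of a single non-hydrogen atom: the
#' central element, its formal charge, its attached hydrogen count, and
#' the sorted multiset of (bond order, neighbour element, neighbour formal
#' charge) over its heavy neighbours. The key is deterministic and
#' independent of atom numbering or SMILES writing order; aromatic bonds
#' keep a distinct `:` bond symbol so resonance-equivalent inputs agree.
#'
#' @param molecule a `molecule` from [parse_molecule()] (or a SMILES string).
#' @param atom_index 1-based index into the molecule's heavy atoms.
#' @return a moiety key string (see [moiety_key()]).
#' @examples
#' \dontrun{
#' atom_environment("CCO", 2) # the CH2 carbon: "C+0H2(-C+0,-O+0)"
#' }
#' @export
atom_environment <- function(molecule, atom_index) {
  molecule <- .as_molecule(molecule)
  n <- nrow(molecule$atoms)
  if (!is.numeric(atom_index) || length(atom_index) != 1L ||
      atom_index < 1L || atom_index > n) {
    stop("atom_index must be in 1..", n)
  }
  atom_index <- as.integer(atom_index)
  atom <- molecule$atoms[atom_index, ]
  if (atom$element == "H") {
    stop("atom ", atom_index, " is a hydrogen; moieties classify heavy atoms only")
  }
  bonds <- molecule$bonds
  hit <- bonds$a == atom_index | bonds$b == atom_index
  neighbors <- character()
  if (any(hit)) {
    nb <- bonds[hit, ]
    other <- ifelse(nb$a == atom_index, nb$b, nb$a)
    neighbors <- vapply(seq_along(other), function(i) {
      o <- molecule$atoms[other[i], ]
      moiety_neighbor(nb$order[i], o$element, o$charge)
    }, character(1))
  }
  moiety_key(atom$element, atom$charge, atom$n_h, neighbors)
}

#' Moiety-count vector of a molecule
#'
#' Classifies every heavy atom with [atom_environment()] and tallies the
#' resulting keys: the entry total always equals the molecule's heavy-atom
#' count. If `label_tag` is given every key is marked as a labeled moiety
#' (a member of the catalytic set M*), namespaced by the tag — used for
#' catalytic residues and cofactors, e.g. `label_tag = "His"`.
#'
#' @inheritParams atom_environment
#' @param label_tag optional label-tag string.
#' @return a `moiety_vector` with positive counts.
#' @export
moiety_counts <- function(molecule, label_tag = NULL) {
  molecule <- .as_molecule(molecule)
  n <- nrow(molecule$atoms)
  if (n == 0L) return(moiety_vector())
  keys <- vapply(seq_len(n), function(i) atom_environment(molecule, i),
                 character(1))
  if (!is.null(label_tag)) keys <- label_moiety(keys, label_tag)
  moiety_vector(stats::setNames(rep(1L, n), keys))
}

.side_to_molecules <- function(side) {
  if (inherits(side, "molecule")) return(list(side))
  if (is.character(side)) {
    mols <- parse_molecule(side)
    return(if (length(side) == 1L) list(mols) else mols)
  }
  if (is.list(side)) return(lapply(side, .as_molecule))
  stop("expected molecules or SMILES strings")
}

.check_coeffs <- function(coeffs, n) {
  if (length(coeffs) == 1L) coeffs <- rep(coeffs, n)
  if (length(coeffs) != n) stop("one stoichiometric coefficient per molecule required")
  if (any(coeffs != round(coeffs)) || any(coeffs <= 0)) {
    stop("stoichiometric coefficients must be positive integers")
  }
  as.integer(coeffs)
}

#' Net moiety change of a reaction
#'
#' Encodes a reaction as the sum of the products' moiety counts minus the
#' sum of the substrates' (each weighted by its stoichiometric
#' coefficient): the overall reaction target vector that any valid
#' mechanism's elementary steps must reproduce. Moieties untouched by the
#' transformation cancel exactly.
#'
#' @param substrates,products lists of `molecule` objects (or character
#'   vectors of SMILES).
#' @param sub_coeffs,prod_coeffs positive integer stoichiometric
#'   coefficients (recycled if scalar).
#' @param sub_labels,prod_labels optional character vectors of label tags
#'   (NA for unlabeled molecules), marking catalytic species.
#' @return a `moiety_vector` (the reaction delta).
#' @export
reaction_delta <- function(substrates, products,
                           sub_coeffs = 1L, prod_coeffs = 1L,
                           sub_labels = NULL, prod_labels = NULL) {
  subs <- .side_to_molecules(substrates)
  prods <- .side_to_molecules(products)
  sc <- .check_coeffs(sub_coeffs, length(subs))
  pc <- .check_coeffs(prod_coeffs, length(prods))
  side_sum <- function(mols, coeffs, labels, sign) {
    parts <- lapply(seq_along(mols), function(i) {
      tag <- if (!is.null(labels) && !is.na(labels[i])) labels[i] else NULL
      mv_scale(moiety_counts(mols[[i]], tag), sign * coeffs[i])
    })
    do.call(mv_add, parts)
  }
  mv_add(side_sum(prods, pc, prod_labels, 1L),
         side_sum(subs, sc, sub_labels, -1L))
}

#' Elemental and charge balance of a reaction
#'
#' Compares element counts (hydrogen included) and net charges of the two
#' sides. Unbalanced reactions are excluded from mechanism prediction, and
#' unbalanced elementary steps are rejected at rule-building time.
#'
#' @inheritParams reaction_delta
#' @return a `balance_report`: list with `elemental` and `charge` logical
#'   flags, `element_deficit` (products minus substrates, only non-zero
#'   elements) and `charge_deficit`.
#' @examples
#' \dontrun{
#' check_balance("CCO", "CC=O") # H deficit -2
#' }
#' @export
check_balance <- function(substrates, products,
                          sub_coeffs = 1L, prod_coeffs = 1L) {
  subs <- .side_to_molecules(substrates)
  prods <- .side_to_molecules(products)
  sc <- .check_coeffs(sub_coeffs, length(subs))
  pc <- .check_coeffs(prod_coeffs, length(prods))
  tally <- function(mols, coeffs) {
    counts <- integer()
    charge <- 0L
    for (i in seq_along(mols)) {
      ec <- mols[[i]]$element_counts * coeffs[i]
      for (el in names(ec)) {
        counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + ec[[el]]
      }
      charge <- charge + mols[[i]]$net_charge * coeffs[i]
    }
    list(counts = counts, charge = charge)
  }
  s <- tally(subs, sc)
  p <- tally(prods, pc)
  els <- union(names(s$counts), names(p$counts))
  deficit <- vapply(els, function(el) {
    pe <- if (el %in% names(p$counts)) p$counts[[el]] else 0L
    se <- if (el %in% names(s$counts)) s$counts[[el]] else 0L
    pe - se
  }, integer(1))
  deficit <- deficit[deficit != 0L]
  structure(
    list(
      elemental = length(deficit) == 0L,
      charge = p$charge == s$charge,
      element_deficit = deficit,
      charge_deficit = p$charge - s$charge
    ),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report: ",
      if (x$elemental) "elementally balanced" else "elementally UNBALANCED",
      ", ", if (x$charge) "charge balanced" else "charge UNBALANCED",
      ">\n", sep = "")
  if (length(x$element_deficit)) {
    for (el in names(x$element_deficit)) {
      cat(sprintf("  %s deficit %+d\n", el, x$element_deficit[[el]]))
    }
  }
  if (x$charge_deficit != 0L) {
    cat(sprintf("  charge deficit %+d\n", x$charge_deficit))
  }
  invisible(x)
}

#' Read and write moiety vectors as delimited text
#'
#' Serialization is two tab-separated columns: moiety key, signed count.
#'
#' @param x a `moiety_vector`.
#' @param path file path.
#' @return `read_moiety_vector` returns a `moiety_vector`;
#'   `write_moiety_vector` returns `path` invisibly.
#' @export
write_moiety_vector <- function(x, path) {
  lines <- sprintf("%s\t%d", names(x), as.integer(x))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_moiety_vector
#' @export
read_moiety_vector <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(moiety_vector())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) stop("malformed moiety-vector row at line ", bad[1])
  keys <- vapply(parts, `[[`, character(1), 1L)
  for (k in keys) validate_moiety_key(k)
  counts <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(counts)) stop("non-integer count at line ", which(is.na(counts))[1])
  moiety_vector(stats::setNames(counts, keys))
}
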