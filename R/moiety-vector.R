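#' Sparse signed moiety-count vector
#'
#' A `moiety_vector` is the package's fundamental algebraic object: a sparse
#' mapping from moiety keys (see [moiety_key()]) to signed integer counts.
#' It represents molecules (all counts positive), elementary-rule deltas
#' (mixed signs) and overall reaction targets. Zero entries are never
#' stored and keys are kept in a canonical (radix-sorted) order, so two
#' vectors are equal iff they are `identical()`.
#'
#' @param counts named numeric/integer vector; names are moiety keys.
#' @return An integer vector of class `moiety_vector` with sorted names and
#'   no zero entries.
#' @examples
#' a <- moiety_vector(c("m1" = 1, "m2" = -2))
#' b <- moiety_vector(c("m2" = 2))
#' mv_add(a, b)
#' @export
moiety_vector <- function(counts = integer()) {
  if (length(counts) == 0L) {
    x <- integer()
    class(x) <- "moiety_vector"
    return(x)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("moiety_vector entries must be named by moiety keys")
  }
  if (any(counts != round(counts))) {
    stop("moiety counts must be integers")
  }
  counts <- vapply(split(as.integer(counts), names(counts)), sum, integer(1))
  counts <- counts[counts != 0L]
  counts <- counts[sort(names(counts), method = "radix")]
  x <- as.integer(counts)
  names(x) <- names(counts)
  class(x) <- "moiety_vector"
  x
}

#' @export
print.moiety_vector <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<moiety_vector: zero>\n")
  } else {
    cat("<moiety_vector:", length(x), "entries>\n")
    for (i in seq_along(x)) {
      cat(sprintf("  %+d  %s\n", unclass(x)[i], names(x)[i]))
    }
  }
  invisible(x)
}

#' Moiety-vector arithmetic
#'
#' Component-wise addition, negation and integer scaling. The zero vector
#' (`moiety_vector()`) is the additive identity.
#'
#' @param ... `moiety_vector` objects (or named integer vectors) to sum.
#' @return A `moiety_vector`.
#' @export
mv_add <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, length, integer(1)) > 0L]
  if (length(parts) == 0L) return(moiety_vector())
  all_counts <- unlist(lapply(parts, function(p) {
    stats::setNames(as.integer(p), names(p))
  }))
  moiety_vector(all_counts)
}

#' @rdname mv_add
#' @param x a `moiety_vector`.
#' @export
mv_neg <- function(x) {
  moiety_vector(stats::setNames(-as.integer(x), names(x)))
}

#' @rdname mv_add
#' @param k integer scale factor.
#' @export
mv_scale <- function(x, k) {
  if (k != round(k)) stop("scale factor must be an integer")
  moiety_vector(stats::setNames(as.integer(x) * as.integer(k), names(x)))
}

#' @rdname mv_add
#' @param a,b `moiety_vector` objects.
#' @export
mv_equal <- function(a, b) {
  identical(moiety_vector(stats::setNames(as.integer(a), names(a))),
            moiety_vector(stats::setNames(as.integer(b), names(b))))
}

#' @rdname mv_add
#' @export
mv_is_zero <- function(x) length(x) == 0L

#' @rdname mv_add
#' @export
mv_support <- function(x) names(x)

#' Canonical text signature of a moiety vector
#'
#' Used for exact-delta deduplication of rules and cross-database step
#' identity in similarity scoring.
#'
#' @param x a `moiety_vector`.
#' @return a single string; equal vectors yield equal signatures.
#' @export
mv_signature <- function(x) {
  if (length(x) == 0L) return("0")
  paste(sprintf("%s:%d", names(x), as.integer(x)), collapse = ";")
}

#' @rdname mv_signature
#' @param sig a signature string produced by `mv_signature()`.
#' @export
mv_from_signature <- function(sig) {
  if (identical(sig, "0")) return(moiety_vector())
  parts <- strsplit(strsplit(sig, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  moiety_vector(stats::setNames(
    vapply(parts, function(p) as.integer(p[length(p)]), integer(1)),
    vapply(parts, function(p) paste(p[-length(p)], collapse = ":"), character(1))
  ))
}

## ---- moiety identifiers ----------------------------------------------------

.bond_symbols <- c("-", "=", "#", ":")

#' Build and inspect canonical moiety keys
#'
#' A moiety classifies one non-hydrogen atom by its first bonding shell:
#' the central element, its formal charge, its attached hydrogen count and
#' the sorted multiset of (bond order, neighbour element, neighbour formal
#' charge) over heavy neighbours. The canonical serialization is
#' `El{+-}chgH{n}(bondElchg,...)`, e.g. the hydroxyl oxygen of ethanol is
#' `O+0H1(-C+0)` and an aromatic CH carbon of benzene is
#' `C+0H1(:C+0,:C+0)`. Aromatic bonds keep their own bond symbol `:` so the
#' key is independent of any Kekule assignment. Labeled moieties (catalytic
#' residues/cofactors, the set M*) carry a `tag*` prefix, e.g.
#' `His*N+1H1(:C+0,:C+0)`.
#'
#' @param element central-atom element symbol.
#' @param charge central-atom formal charge.
#' @param n_h attached hydrogen count.
#' @param neighbors character vector of neighbour descriptors built with
#'   [moiety_neighbor()]; order does not matter.
#' @return a single canonical key string.
#' @seealso [atom_environment()]
#' @export
moiety_key <- function(element, charge, n_h, neighbors = character()) {
  sprintf("%s%+dH%d(%s)", element, as.integer(charge), as.integer(n_h),
          paste(sort(neighbors, method = "radix"), collapse = ","))
}

#' @rdname moiety_key
#' @param order bond symbol: `"-"`, `"="`, `"#"` or `":"` (aromatic).
#' @export
moiety_neighbor <- function(order, element, charge) {
  if (!order %in% .bond_symbols) stop("unknown bond symbol: ", order)
  sprintf("%s%s%+d", order, element, as.integer(charge))
}

#' @rdname moiety_key
#' @param key a moiety key string.
#' @param tag label-tag naming the catalytic residue/cofactor namespace.
#' @export
label_moiety <- function(key, tag) {
  if (any(!nzchar(tag))) stop("label tag must be non-empty")
  if (any(grepl("[*[:space:]]", tag))) {
    stop("label tag must not contain '*' or whitespace")
  }
  paste0(tag, "*", key)
}

#' @rdname moiety_key
#' @export
moiety_is_labeled <- function(key) grepl("\\*", key)

#' @rdname moiety_key
#' @export
moiety_label_tag <- function(key) {
  ifelse(moiety_is_labeled(key), sub("\\*.*$", "", key), NA_character_)
}

#' @rdname moiety_key
#' @export
moiety_base_key <- function(key) sub("^[^*]*\\*", "", key)

#' Parse the structured fields out of a chemical moiety key
#'
#' Inverse of [moiety_key()]. Only works for chemically structured keys;
#' abstract opaque identifiers (as used by the synthetic-instance
#' generator) do not parse.
#'
#' @param key a moiety key string.
#' @return a list with `element`, `charge`, `n_h`, `neighbors`, `labeled`,
#'   `tag`.
#' @export
parse_moiety_key <- function(key) {
  stopifnot(length(key) == 1L)
  labeled <- moiety_is_labeled(key)
  tag <- if (labeled) moiety_label_tag(key) else NA_character_
  base <- moiety_base_key(key)
  pat <- "^([A-Z][a-z]?)([+-][0-9]+)H([0-9]+)\\(([^)]*)\\)$"
  if (!grepl(pat, base)) stop("not a structured chemical moiety key: ", key)
  element <- sub(pat, "\\1", base)
  charge <- as.integer(sub(pat, "\\2", base))
  n_h <- as.integer(sub(pat, "\\3", base))
  nb <- sub(pat, "\\4", base)
  neighbors <- if (nzchar(nb)) strsplit(nb, ",", fixed = TRUE)[[1]] else character()
  list(element = element, charge = charge, n_h = n_h,
       neighbors = neighbors, labeled = labeled, tag = tag)
}

# loose syntactic validation used by the file readers: chemical keys must
# parse; abstract keys are any '*'-free token without whitespace/comma/tab
validate_moiety_key <- function(key) {
  base <- moiety_base_key(key)
  if (!nzchar(base) || grepl("[[:space:]]", key)) {
    stop("malformed moiety key: '", key, "'")
  }
  if (grepl("^[A-Z][a-z]?[+-]", base)) {
    parse_moiety_key(key) # throws if the chemical syntax is broken
  }
  invisible(TRUE)
}
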