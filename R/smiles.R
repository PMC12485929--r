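# Bridge to the bundled RDKit helper (inst/python/smiles_env.py).
# Parsing is batched (one interpreter start per batch) and memoised in a
# package-level cache keyed by the input SMILES string.

.mechstep_env <- new.env(parent = emptyenv())

.python_binary <- function() {
  py <- Sys.getenv("MECHSTEP_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no 'python' interpreter found on the PATH")
  py
}

.smiles_helper <- function() {
  system.file("python", "smiles_env.py", package = "mechstep", mustWork = TRUE)
}

.call_smiles_helper <- function(request) {
  out <- suppressWarnings(system2(
    .python_binary(), shQuote(.smiles_helper()),
    input = jsonlite::toJSON(request, auto_unbox = TRUE),
    stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("SMILES helper failed (exit ", status, ")")
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

.smiles_cache <- function() {
  if (is.null(.mechstep_env$smiles_cache)) {
    .mechstep_env$smiles_cache <- new.env(parent = emptyenv())
  }
  .mechstep_env$smiles_cache
}

.molecule_from_record <- function(smiles, rec) {
  if (!is.null(rec$error)) {
    stop("cannot parse SMILES '", smiles, "': ", rec$error)
  }
  atoms <- data.frame(
    element = vapply(rec$atoms, `[[`, character(1), "element"),
    charge = vapply(rec$atoms, `[[`, integer(1), "charge"),
    n_h = vapply(rec$atoms, `[[`, integer(1), "n_h"),
    aromatic = vapply(rec$atoms, `[[`, logical(1), "aromatic"),
    stringsAsFactors = FALSE
  )
  bonds <- if (length(rec$bonds)) {
    data.frame(
      a = vapply(rec$bonds, `[[`, integer(1), "a"),
      b = vapply(rec$bonds, `[[`, integer(1), "b"),
      order = vapply(rec$bonds, `[[`, character(1), "order"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(a = integer(), b = integer(), order = character(),
               stringsAsFactors = FALSE)
  }
  structure(
    list(
      smiles = smiles,
      canonical = rec$canonical,
      net_charge = as.integer(rec$net_charge),
      element_counts = vapply(rec$element_counts, as.integer, integer(1)),
      atoms = atoms,
      bonds = bonds
    ),
    class = "molecule"
  )
}

#' Parse SMILES strings into molecular graphs
#'
#' Parses one or more SMILES strings with RDKit (through the bundled
#' helper), dropping all stereochemical annotations so that molecules are
#' handled as constitutional isomers, and folding explicit hydrogens into
#' per-atom hydrogen counts. Results are cached, so repeated parsing of
#' the same string costs nothing.
#'
#' @param smiles character vector of SMILES strings.
#' @return For a single string, a `molecule` object (list with `canonical`
#'   SMILES, `net_charge`, `element_counts` including hydrogen, an `atoms`
#'   table of heavy atoms and a `bonds` table); for several strings, a
#'   list of `molecule` objects.
#' @examples
#' \dontrun{
#' mol <- parse_molecule("CCO")
#' mol$element_counts
#' }
#' @export
parse_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  cache <- .smiles_cache()
  missing <- unique(smiles[!vapply(smiles, exists, logical(1), envir = cache)])
  if (length(missing)) {
    recs <- .call_smiles_helper(list(op = "parse", smiles = as.list(missing)))
    for (i in seq_along(missing)) {
      assign(missing[i], .molecule_from_record(missing[i], recs[[i]]),
             envir = cache)
    }
  }
  out <- lapply(smiles, get, envir = cache)
  if (length(out) == 1L) out[[1]] else out
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule ", x$canonical, ": ", nrow(x$atoms), " heavy atoms, charge ",
      sprintf("%+d", x$net_charge), ">\n", sep = "")
  invisible(x)
}

.as_molecule <- function(x) {
  if (inherits(x, "molecule")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_molecule(x))
  stop("expected a molecule or a single SMILES string")
}

#' Random-order SMILES variants of a molecule
#'
#' Returns alternative, randomly ordered SMILES writings of the same
#' molecule (used to exercise permutation invariance of the encoding).
#' Deterministic for a fixed seed.
#'
#' @param smiles a single SMILES string.
#' @param n number of variants.
#' @param seed integer seed for the SMILES writer.
#' @return character vector of `n` SMILES strings.
#' @export
randomize_smiles <- function(smiles, n = 5L, seed = 1L) {
  recs <- .call_smiles_helper(list(op = "randomize", smiles = as.list(smiles),
                                   n = n, seed = seed))
  rec <- recs[[1]]
  if (!is.null(rec$error)) stop("cannot parse SMILES '", smiles, "'")
  vapply(rec$variants, identity, character(1))
}

#' Parse a reaction SMILES into substrate and product molecules
#'
#' Accepts the `"sub1.sub2>>prod1.prod2"` dialect; repeated molecules
#' express stoichiometric coefficients (coefficients are always integral).
#'
#' @param rxn_smiles a single reaction SMILES string.
#' @return a list with `substrates` and `products`, each a list of
#'   `molecule` objects (one entry per stoichiometric unit).
#' @export
parse_reaction <- function(rxn_smiles) {
  stopifnot(is.character(rxn_smiles), length(rxn_smiles) == 1L)
  sides <- strsplit(rxn_smiles, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("reaction SMILES must contain exactly one '>>': ", rxn_smiles)
  }
  split_side <- function(s) {
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) stop("empty reaction side in: ", rxn_smiles)
    mols <- parse_molecule(parts)
    if (length(parts) == 1L) list(mols) else mols
  }
  list(substrates = split_side(sides[1]), products = split_side(sides[2]))
}
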