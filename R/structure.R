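#' Atomic structures as tibbles
#'
#' A `fil_structure` is a tibble with one row per atom and columns
#' `chain` (single-character chain id), `residue_index` (1-based, contiguous
#' per chain), `residue_name` (e.g. `"DA"`), `atom` (atom label: `P`, `C1'`,
#' `N9`/`N1`, `CEN`, `O3'`), `element`, `x`, `y`, `z` (Angstrom) and `role`
#' (one of `"initiating"`, `"complementary"`, `"outgoing"`, `"scaffold"`).
#' Free-form provenance and junction tags live in the `fil_meta` attribute.
#' Nucleic chains are ordered 5' to 3'. The filament helix axis is +z and the
#' right-handed filament has positive twist.
#'
#' @param atoms A data frame with the columns above (role optional; defaults
#'   to `"scaffold"`).
#' @param metadata A named list of provenance tags (may include `junctions`).
#' @return A `fil_structure` tibble.
#' @export
#' @examples
#' s <- fil_structure(tibble::tibble(
#'   chain = "A", residue_index = 1L, residue_name = "DA",
#'   atom = "P", element = "P", x = 0, y = 0, z = 0))
#' roles(s)
fil_structure <- function(atoms, metadata = list()) {
  atoms <- as_tibble(atoms)
  req <- c("chain", "residue_index", "residue_name", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"role" %in% names(atoms)) atoms$role <- "scaffold"
  atoms$residue_index <- as.integer(atoms$residue_index)
  s <- new_tibble(atoms, class = "fil_structure")
  attr(s, "fil_meta") <- metadata
  validate_structure(s)
  s
}

#' @export
#' @rdname fil_structure
#' @param x An object to coerce or test.
as_fil_structure <- function(x) {
  if (is_fil_structure(x)) return(x)
  fil_structure(x, metadata = attr(x, "fil_meta") %||% list())
}

#' @export
#' @rdname fil_structure
is_fil_structure <- function(x) inherits(x, "fil_structure")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @rdname fil_structure
#' @param s A `fil_structure`.
fil_meta <- function(s) attr(s, "fil_meta") %||% list()

set_fil_meta <- function(s, meta) {
  attr(s, "fil_meta") <- meta
  s
}

#' @export
#' @rdname fil_structure
roles <- function(s) {
  r <- dplyr::distinct(as_tibble(s)[, c("chain", "role")])
  setNames(r$role, r$chain)
}

# internal sanity checks on the atom table
validate_structure <- function(s) {
  if (!all(is.finite(c(s$x, s$y, s$z)))) abort("non-finite coordinates")
  if (any(s$residue_index < 1L)) abort("residue_index must be >= 1")
  if (any(!nzchar(s$atom))) abort("atom names must be non-empty")
  key <- paste(s$chain, s$residue_index, s$atom)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate atom: ", key[duplicated(key)][1]))
  }
  ok_roles <- c("initiating", "complementary", "outgoing", "scaffold")
  if (!all(s$role %in% ok_roles)) abort("invalid role label")
  invisible(s)
}

#' Annotate strand roles on a structure
#'
#' Assigns each chain its role in the synaptic assembly: the filament-bound
#' `initiating` strand, the duplex `complementary` strand that can pair with
#' it, the displaced `outgoing` strand, or protein `scaffold`. Coordinates are
#' never modified.
#'
#' @param structure A [fil_structure()].
#' @param assignment Named character vector, `chain id -> role`.
#' @param strict If `TRUE`, refuse duplicate nucleic roles across chains.
#' @return The structure with its `role` column updated.
#' @export
#' @examples
#' s <- build_bdna("ACGT")
#' s <- annotate_roles(s, c(A = "complementary", B = "outgoing"))
annotate_roles <- function(structure, assignment, strict = FALSE) {
  structure <- as_fil_structure(structure)
  unknown <- setdiff(names(assignment), unique(structure$chain))
  if (length(unknown)) {
    abort(paste0("unknown chain id(s): ", paste(unknown, collapse = ", ")))
  }
  ok <- c("initiating", "complementary", "outgoing", "scaffold")
  if (!all(assignment %in% ok)) abort("invalid role label")
  new_roles <- roles(structure)
  new_roles[names(assignment)] <- assignment
  if (strict) {
    nuc <- new_roles[new_roles != "scaffold"]
    if (anyDuplicated(nuc)) abort("duplicate nucleic role across chains")
  }
  structure$role <- unname(new_roles[structure$chain])
  validate_structure(structure)
  structure
}

#' @export
#' @rdname fil_structure
#' @param role_name Role to select atoms for.
chain_for_role <- function(s, role_name) {
  ch <- unique(s$chain[s$role == role_name])
  if (length(ch) == 0) abort(paste0("no chain annotated as ", role_name))
  ch
}

# atoms of one chain, ordered as stored (5'->3' for nucleic chains)
chain_atoms <- function(s, chain_id) {
  as_tibble(s)[s$chain == chain_id, , drop = FALSE]
}

# phosphate positions of one chain as a matrix, in residue order
p_positions <- function(s, chain_id) {
  a <- s[s$chain == chain_id & s$atom == "P", , drop = FALSE]
  a <- a[order(a$residue_index), , drop = FALSE]
  list(residue_index = a$residue_index, xyz = coords_mat(a))
}

#' Apply a rigid motion to a structure
#'
#' @param structure A [fil_structure()].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector.
#' @return The transformed structure (metadata preserved).
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  structure <- as_fil_structure(structure)
  m <- coords_mat(structure)
  m2 <- sweep(m %*% t(R), 2, -t)
  out <- set_coords(structure, m2)
  meta <- fil_meta(out)
  if (!is.null(meta$axis)) {
    meta$axis <- fil_axis(as.vector(R %*% meta$axis$point) + t,
                          as.vector(R %*% meta$axis$direction))
    out <- set_fil_meta(out, meta)
  }
  out
}
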