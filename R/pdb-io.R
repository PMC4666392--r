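#' Read a PDB file into a structure tibble
#'
#' Parses fixed-width ATOM/HETATM records (via bio3d) preserving record order,
#' chain ids and residue numbering. Roles default to `"scaffold"` until
#' annotated with [annotate_roles()].
#'
#' @param path Path to a PDB file.
#' @return A [fil_structure()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(build_bdna("ACG"), f)
#' s <- read_pdb(f)
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) abort(paste0("malformed PDB record in ", path, ": ",
                                     conditionMessage(e)))
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) abort(paste0("no ATOM/HETATM records in ", path))
  elem <- a$elesy
  elem[is.na(elem) | !nzchar(trimws(elem))] <-
    substr(trimws(a$elety[is.na(elem) | !nzchar(trimws(elem))]), 1, 1)
  chain <- a$chain
  chain[is.na(chain)] <- "A"
  fil_structure(
    tibble(
      chain = chain,
      residue_index = as.integer(a$resno),
      residue_name = trimws(a$resid),
      atom = trimws(a$elety),
      element = trimws(elem),
      x = a$x, y = a$y, z = a$z
    ),
    metadata = list(source = path)
  )
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-width v3.3 ATOM records, one TER per chain and a
#' final END. Coordinates are written to 3 decimals, so
#' `read_pdb(write_pdb(s))` reproduces coordinates to 1e-3 A.
#'
#' @param structure A non-empty [fil_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  structure <- as_fil_structure(structure)
  if (nrow(structure) == 0) abort("cannot write an empty structure")
  s <- as_tibble(structure)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(s$chain)) {
    a <- s[s$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom[i]
      # atom-name column alignment: names < 4 chars start in column 14
      nm_f <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_f, substr(a$residue_name[i], 1, 3), ch,
        a$residue_index[i] %% 10000L, a$x[i], a$y[i], a$z[i], 1, 0,
        substr(a$element[i], 1, 2)))
    }
    serial <- serial + 1L
    last <- a[nrow(a), ]
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                              serial %% 100000L, substr(last$residue_name, 1, 3),
                              ch, last$residue_index %% 10000L))
  }
  lines <- c(lines, "END")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("cannot write PDB file: ", path))
  invisible(path)
}
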