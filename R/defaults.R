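#' Package defaults for filament and DNA geometry
#'
#' Returns the full set of geometric and energetic constants used by the
#' builders, anchor generators, relaxation and metrics. All lengths are in
#' Angstrom, all angles in degrees, spring constants in kcal mol^-1 A^-2
#' (energy convention E = k * dr^2, so printed restraint constants are usable
#' verbatim).
#'
#' Key values:
#' * B-form DNA: rise 3.38 A, twist 36 deg per step, phosphate radius 9.4 A.
#' * Filament-bound DNA: mean rise 5.1 A and mean twist 20 deg per base-pair
#'   step, realised as a triplet pattern (intra-triplet rise 3.6 A / twist
#'   25 deg; inter-triplet rise 8.1 A / twist 10 deg) so that the extension
#'   and untwisting concentrate in the rises between triplets.
#' * Strand radii: initiating strand 9 A (site I), outgoing strand 15 A
#'   (site II); the complementary strand sits between them at 12 A.
#' * Filament symmetry: six monomers per turn (60 deg per monomer) and three
#'   nucleotides per monomer, hence 15.3 A axial translation per monomer.
#' * Junction bend between B-form tails and filament DNA: 90 deg.
#' * Default restraint spring constant 0.5 kcal mol^-1 A^-2.
#'
#' @param ... named overrides of individual defaults.
#' @return A named list of constants.
#' @export
#' @examples
#' cfg <- fil_defaults(bend_angle = 45)
#' cfg$mean_rise
fil_defaults <- function(...) {
  cfg <- list(
    # canonical B-form
    b_rise = 3.38,
    b_twist = 36,
    b_p_radius = 9.4,
    # reduced-atom residue geometry
    c1_radial_offset = 1.7,   # C1' sits this far inside the P radius
    p_c1_bond = 4.0,          # ideal P-C1' virtual-bond length
    glyco_len = 1.5,          # C1' -> N9/N1
    cen_len = 3.5,            # C1' -> base centroid pseudo-atom
    pair_span = 10.4,         # Watson-Crick C1'-C1' span of the builder
    o3p_len = 1.6,            # O3'-P backbone bond
    # filament-bound DNA (triplet-patterned)
    intra_rise = 3.6,
    inter_rise = 8.1,
    intra_twist = 25,
    inter_twist = 10,
    mean_rise = 5.1,
    mean_twist = 20,
    # strand radii in the synaptic model
    r_initiating = 9.0,
    r_complementary = 12.0,
    r_outgoing = 15.0,
    # strand azimuthal phases (geometric defaults; the complementary phase
    # puts pre-flip bases beyond the paired D1 threshold, the outgoing phase
    # closes the site-II duplex at the builder's own pair span)
    phase_initiating = 0,
    phase_complementary = 90,
    # filament helical symmetry
    nt_per_monomer = 3,
    monomer_twist = 60,       # 360 / 6 monomers per turn
    monomer_rise = 15.3,      # 3 * 5.1
    # junction
    bend_angle = 90,
    # anchors
    siteII_anchor_radius = 16.5,
    ctd_anchor_radius = 22,
    salt_bridge_cutoff = 5.0,
    # relaxation
    k_anchor = 0.5,
    k_bond = 0.5,
    k_rep = 0.5,
    r_min = 2.5,
    minim_tol = 1e-4,
    minim_max_iter = 50000,
    # flip-state classification
    d1_tol = 1.5,
    theta1_tol = 25,
    flip_fraction = 0.3,
    # registration windows
    reg_axial_halfwidth = 2.55,  # half a mean rise
    reg_az_halfwidth = 10        # 20-degree sector
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) abort(paste0("unknown default(s): ", paste(bad, collapse = ", ")))
    cfg[names(over)] <- over
  }
  cfg
}

#' Read a plain-text key=value configuration file
#'
#' Lines are `key = value`; blank lines and lines starting with `#` are
#' ignored. Values are parsed as numbers where possible. Keys must be valid
#' [fil_defaults()] names.
#'
#' @param path file path.
#' @return A defaults list as from [fil_defaults()] with the file's overrides.
#' @export
read_fil_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 1L) != 2L]
  if (length(bad)) abort(paste0("malformed config line: ", bad[[1]]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  num <- suppressWarnings(as.numeric(vals))
  parsed <- ifelse(is.na(num), vals, num)
  over <- as.list(ifelse(is.na(num), as.list(vals), as.list(num)))
  over <- map2(as.list(num), as.list(vals), function(n, v) if (is.na(n)) v else n)
  names(over) <- keys
  do.call(fil_defaults, over)
}
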