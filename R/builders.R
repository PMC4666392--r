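#' Per-strand helical building parameters
#'
#' Filament-bound DNA is triplet-patterned: three near-B-form nucleotides per
#' RecA monomer with the extension and untwisting concentrated in the rises
#' between triplets. `intra_*` apply to the two steps inside a triplet,
#' `inter_*` to the step at the triplet boundary; the configured means are
#' `(2*intra + inter)/3`.
#'
#' @param intra_rise,inter_rise Axial rise per step, Angstrom.
#' @param intra_twist,inter_twist Twist per step, degrees.
#' @param radius Phosphate distance from the helix axis, Angstrom (> 0).
#' @param phase Azimuthal offset of the first phosphate, degrees.
#' @return A `helical_params` object with `mean_rise`/`mean_twist` fields.
#' @export
#' @examples
#' p <- filament_params()
#' p$mean_rise   # 5.1
helical_params <- function(intra_rise, inter_rise, intra_twist, inter_twist,
                           radius, phase = 0) {
  if (radius <= 0) abort("radius must be > 0")
  structure(list(
    intra_rise = intra_rise, inter_rise = inter_rise,
    intra_twist = intra_twist, inter_twist = inter_twist,
    radius = radius, phase = phase,
    mean_rise = (2 * intra_rise + inter_rise) / 3,
    mean_twist = (2 * intra_twist + inter_twist) / 3
  ), class = "helical_params")
}

#' @rdname helical_params
#' @param cfg Defaults from [fil_defaults()].
#' @export
filament_params <- function(cfg = fil_defaults(), radius = cfg$r_initiating,
                            phase = 0) {
  helical_params(cfg$intra_rise, cfg$inter_rise, cfg$intra_twist,
                 cfg$inter_twist, radius, phase)
}

#' @rdname helical_params
#' @param rise,twist Uniform per-step values for an unpatterned helix.
#' @export
uniform_params <- function(rise, twist, radius, phase = 0) {
  helical_params(rise, rise, twist, twist, radius, phase)
}

#' Triplet pattern of a synaptic assembly
#'
#' @param n_triplets_siteII Number of site-II-bound triplets (1-5 in the
#'   scenarios studied; 0 allowed only with tails).
#' @param tail_bp_5p,tail_bp_3p B-form tail lengths in base pairs (5' and 3'
#'   of the complementary strand).
#' @param bend_angle Kink angle at the B-form/filament junction, degrees in
#'   [0, 180).
#' @return A `triplet_pattern` object.
#' @export
triplet_pattern <- function(n_triplets_siteII = 2, tail_bp_5p = 6,
                            tail_bp_3p = 6, bend_angle = 90) {
  if (n_triplets_siteII < 0) abort("n_triplets_siteII must be >= 0")
  if (tail_bp_5p < 0 || tail_bp_3p < 0) abort("tail lengths must be >= 0")
  if (bend_angle < 0 || bend_angle >= 180) abort("bend_angle must be in [0, 180)")
  structure(list(n_triplets_siteII = as.integer(n_triplets_siteII),
                 tail_bp_5p = as.integer(tail_bp_5p),
                 tail_bp_3p = as.integer(tail_bp_3p),
                 bend_angle = bend_angle),
            class = "triplet_pattern")
}

# ---- sequence helpers --------------------------------------------------

check_sequence <- function(sequence) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 1 || !all(bases %in% c("A", "C", "G", "T"))) {
    abort("sequence must be non-empty over the alphabet {A, C, G, T}")
  }
  bases
}

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

n_atom_name <- function(b) ifelse(b %in% c("A", "G"), "N9", "N1")

# ---- strand placement --------------------------------------------------

# per-step type: steps (pos + offset) divisible by 3 are inter-triplet
step_types <- function(n_steps, pattern_offset = 0) {
  ifelse(((seq_len(n_steps) + pattern_offset) %% 3) == 0, "inter", "intra")
}

# azimuthal P -> C1' offset (deg) at a given P radius: the angle that closes
# the P-C1' virtual bond at its ideal length for the fixed radial offset
c1_az_offset_at <- function(r_p, cfg) {
  r_c1 <- r_p - cfg$c1_radial_offset
  cosv <- (r_p^2 + r_c1^2 - cfg$p_c1_bond^2) / (2 * r_p * r_c1)
  if (abs(cosv) > 1) abort("radius incompatible with the P-C1' virtual bond")
  rad2deg(acos(cosv))
}

# cumulative (azimuth, z) frame of a strand's phosphates, residue order
strand_frame <- function(n, params, sense = 1, z0 = 0, phase = NULL,
                         pattern_offset = 0) {
  phase <- phase %||% params$phase
  types <- step_types(max(n - 1, 0), pattern_offset)
  rises <- ifelse(types == "inter", params$inter_rise, params$intra_rise)
  twists <- ifelse(types == "inter", params$inter_twist, params$intra_twist)
  tibble(
    i = seq_len(n),
    phi = phase + sense * c(0, cumsum(twists)),
    z = z0 + sense * c(0, cumsum(rises)),
    step_after = c(types, NA)
  )
}

# Place one strand's reduced atoms. base_targets: n x 3 matrix of points the
# glycosidic direction should aim at; NULL uses the virtual-pair default
# (a partner C1' mirrored across the pair chord at the same radius).
place_strand <- function(bases, params, sense = 1, z0 = 0, phase = NULL,
                         chain = "A", pattern_offset = 0, base_targets = NULL,
                         cfg = fil_defaults()) {
  n <- length(bases)
  fr <- strand_frame(n, params, sense, z0, phase, pattern_offset)
  r_p <- params$radius
  r_c1 <- r_p - cfg$c1_radial_offset
  if (r_c1 <= 0) abort("radius too small for the reduced-atom geometry")
  P <- t(vapply(seq_len(n), function(i) cyl2cart(r_p, fr$phi[i], fr$z[i]), numeric(3)))
  phi_c1 <- fr$phi - sense * c1_az_offset_at(r_p, cfg)
  C1 <- t(vapply(seq_len(n), function(i) cyl2cart(r_c1, phi_c1[i], fr$z[i]), numeric(3)))
  if (is.null(base_targets)) {
    if (2 * r_c1 <= cfg$pair_span) abort("radius too small to host a paired partner")
    dc <- rad2deg(asin(cfg$pair_span / (2 * r_c1)))
    base_targets <- t(vapply(seq_len(n), function(i)
      cyl2cart(r_c1, phi_c1[i] + sense * 2 * dc, fr$z[i]), numeric(3)))
  }
  bdir <- base_targets - C1
  bdir <- bdir / sqrt(rowSums(bdir^2))
  Nats <- C1 + cfg$glyco_len * bdir
  CEN <- C1 + cfg$cen_len * bdir
  # O3' points at the next phosphate; the last residue extrapolates along the
  # pattern so that screw-replicated fragments are exactly continuous
  nxtP <- rbind(P[-1, , drop = FALSE], NA)
  last_type <- if (((n + pattern_offset) %% 3) == 0) "inter" else "intra"
  lr <- if (last_type == "inter") params$inter_rise else params$intra_rise
  lt <- if (last_type == "inter") params$inter_twist else params$intra_twist
  nxtP[n, ] <- cyl2cart(r_p, fr$phi[n] + sense * lt, fr$z[n] + sense * lr)
  O3 <- t(vapply(seq_len(n), function(i) {
    d <- unitize(C1[i, ] - nxtP[i, ])
    nxtP[i, ] + cfg$o3p_len * d
  }, numeric(3)))
  rows <- map(seq_len(n), function(i) {
    nm <- c("P", "C1'", n_atom_name(bases[i]), "CEN", "O3'")
    el <- c("P", "C", "N", "C", "O")
    xyz <- rbind(P[i, ], C1[i, ], Nats[i, ], CEN[i, ], O3[i, ])
    tibble(chain = chain, residue_index = i, residue_name = paste0("D", bases[i]),
           atom = nm, element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  out <- bind_rows(rows)
  attr(out, "frame") <- fr
  attr(out, "c1_phi") <- phi_c1
  attr(out, "r_c1") <- r_c1
  out
}

#' Build an ideal B-form DNA duplex
#'
#' Canonical reference state: uniform rise 3.38 A and twist 36 degrees per
#' step, phosphate radius 9.4 A, Watson-Crick paired reduced-atom geometry
#' (P, C1', N9/N1, base-centroid pseudo-atom, O3' per nucleotide). By
#' definition its extension factor is 1.0.
#'
#' @param sequence Strand-A sequence, 5' to 3', over {A, C, G, T}.
#' @param cfg Defaults from [fil_defaults()].
#' @param chains Chain ids for the two strands.
#' @return A [fil_structure()] with two antiparallel chains.
#' @export
#' @examples
#' d <- build_bdna("ACGTACGTA")
#' extension_factor(d, chain = "A")
build_bdna <- function(sequence, cfg = fil_defaults(), chains = c("A", "B")) {
  bases_a <- check_sequence(sequence)
  n <- length(bases_a)
  r_c1 <- cfg$b_p_radius - cfg$c1_radial_offset
  dc <- rad2deg(asin(cfg$pair_span / (2 * r_c1)))
  off_b <- c1_az_offset_at(cfg$b_p_radius, cfg)
  par_a <- uniform_params(cfg$b_rise, cfg$b_twist, cfg$b_p_radius,
                          phase = -dc + off_b)
  # pair-frame azimuth of bp i is (i-1)*36; strand A C1' sits at -dc, strand
  # B C1' at +dc of that frame, so their span equals the configured pair span
  a <- place_strand(bases_a, par_a, sense = 1, chain = chains[1], cfg = cfg)
  fr_a <- attr(a, "frame")
  pair_phi <- fr_a$phi - (-dc + off_b)   # (i-1)*36
  bases_b <- unname(complement_base(rev(bases_a)))
  # strand B residue j pairs bp n+1-j; as a helix in its own 5'->3' order it
  # descends z with sense -1
  par_b <- uniform_params(cfg$b_rise, cfg$b_twist, cfg$b_p_radius)
  phase_b <- pair_phi[n] + dc - off_b
  b <- place_strand(bases_b, par_b, sense = -1, z0 = fr_a$z[n],
                    phase = phase_b, chain = chains[2], cfg = cfg)
  s <- fil_structure(bind_rows(a, b),
                     metadata = list(kind = "bdna", period = 1L,
                                     axis = fil_axis(), sequence = sequence))
  # aim bases at the actual partner C1'
  repoint_bases(s, chains[1], chains[2], pairing = "antiparallel", cfg = cfg)
}

# redirect N/CEN of both chains toward the actual partner C1'
repoint_bases <- function(s, chain1, chain2, pairing = "antiparallel",
                          cfg = fil_defaults()) {
  a1 <- chain_atoms(s, chain1); a2 <- chain_atoms(s, chain2)
  n <- max(a1$residue_index)
  c1_1 <- coords_mat(a1[a1$atom == "C1'", ][order(a1$residue_index[a1$atom == "C1'"]), ])
  c1_2 <- coords_mat(a2[a2$atom == "C1'", ][order(a2$residue_index[a2$atom == "C1'"]), ])
  partner_of_1 <- if (pairing == "antiparallel") c1_2[n:1, , drop = FALSE] else c1_2
  partner_of_2 <- if (pairing == "antiparallel") c1_1[n:1, , drop = FALSE] else c1_1
  s <- aim_bases_at(s, chain1, partner_of_1, cfg)
  aim_bases_at(s, chain2, partner_of_2, cfg)
}

# set N/CEN of `chain` to point from C1' toward targets (n x 3, residue order)
aim_bases_at <- function(s, chain, targets, cfg = fil_defaults()) {
  tb <- as_tibble(s)
  idx <- which(tb$chain == chain)
  a <- tb[idx, ]
  resids <- sort(unique(a$residue_index))
  for (k in seq_along(resids)) {
    ri <- resids[k]
    c1 <- as.numeric(a[a$residue_index == ri & a$atom == "C1'", c("x", "y", "z")])
    d <- unitize(targets[k, ] - c1)
    for (nm in c("N9", "N1", "CEN")) {
      j <- idx[a$residue_index == ri & a$atom == nm]
      if (length(j)) {
        len <- if (nm == "CEN") cfg$cen_len else cfg$glyco_len
        tb[j, c("x", "y", "z")] <- as.list(c1 + len * d)
      }
    }
  }
  out <- new_tibble(tb, class = "fil_structure")
  attr(out, "fil_meta") <- fil_meta(s)
  out
}

#' Build a single filament-bound DNA strand
#'
#' Threads a strand on the filament screw at the given radius with the
#' triplet-patterned rise/twist of filament-bound DNA (defaults: mean rise
#' 5.1 A, mean twist 20 degrees per step). The mean axial rise and twist over
#' any whole number of triplets equal the configured means exactly.
#'
#' @param sequence 5' to 3' sequence; a multiple of 3 is recommended (a
#'   warning is raised otherwise).
#' @param params A [helical_params()]; default [filament_params()].
#' @param chain Chain id.
#' @param sense +1 to run 5'->3' toward +z, -1 toward -z.
#' @param z0,phase Position of the first residue.
#' @param cfg Defaults from [fil_defaults()].
#' @return A [fil_structure()] with one chain.
#' @export
#' @examples
#' s <- build_filament_strand(strrep("T", 18))
#' dplyr::n_distinct(s$residue_index)
build_filament_strand <- function(sequence, params = filament_params(cfg),
                                  chain = "A", sense = 1, z0 = 0, phase = NULL,
                                  cfg = fil_defaults()) {
  bases <- check_sequence(sequence)
  if (length(bases) %% 3 != 0) {
    warn("sequence length is not a multiple of 3; partial triplet at the end")
  }
  a <- place_strand(bases, params, sense = sense, z0 = z0, phase = phase,
                    chain = chain, cfg = cfg)
  period <- if (isTRUE(all.equal(params$intra_rise, params$inter_rise)) &&
                isTRUE(all.equal(params$intra_twist, params$inter_twist))) 1L else 3L
  fil_structure(a, metadata = list(kind = "filament_strand", period = period,
                                   axis = fil_axis(), params = params,
                                   sequence = sequence))
}
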