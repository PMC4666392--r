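# Three-strand synaptic assemblies: site-I initiating strand, site-II-bound
# complementary/outgoing duplex, B-form tails through kinked junctions.

# minimal rotation taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- unitize(a); b <- unitize(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- vnorm(v); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 about any perpendicular
    perp <- if (abs(a[1]) < 0.9) unitize(c(0, -a[3], a[2])) else unitize(c(-a[3], 0, a[1]))
    return(rotation_about(perp, 180))
  }
  rotation_about(v / s, rad2deg(atan2(s, c_)))
}

# radial unit vector at azimuth (deg) about +z
radial_unit <- function(az_deg) {
  a <- deg2rad(az_deg)
  c(cos(a), sin(a), 0)
}

atom_pos <- function(s, chain, resid, atom) {
  r <- s[s$chain == chain & s$residue_index == resid & s$atom == atom, ]
  if (nrow(r) != 1) abort(paste0("atom not found: ", chain, "/", resid, "/", atom))
  as.numeric(r[1, c("x", "y", "z")])
}

# pair-span half-angle (deg) at a given C1' radius
pair_half_angle <- function(r_c1, cfg) {
  if (2 * r_c1 <= cfg$pair_span) abort("radius too small to host a paired partner")
  rad2deg(asin(cfg$pair_span / (2 * r_c1)))
}

# Place a tail duplex at a junction. The junction constrains the tail's
# axis direction and one backbone attachment point, leaving the spin about
# its own axis free; the spin is chosen on a 30-degree grid to maximise the
# clearance between the tail and the already-placed atoms (the attaching
# residue itself is ignored: it is covalently tied to the junction).
place_tail <- function(tail, R0, axis_dir, anchor_local, attach_point,
                       placed_xyz, skip_chain, skip_res) {
  tm <- coords_mat(tail)
  eval_rows <- !(tail$chain == skip_chain & tail$residue_index == skip_res)
  best_R <- NULL; best_tr <- NULL; best_min <- -Inf
  for (spin in seq(0, 330, by = 30)) {
    R <- rotation_about(axis_dir, spin) %*% R0
    tr <- attach_point - as.vector(R %*% anchor_local)
    xyz <- sweep(tm %*% t(R), 2, -tr)
    xe <- xyz[eval_rows, , drop = FALSE]
    d2 <- outer(rowSums(xe^2), rep(1, nrow(placed_xyz))) +
      outer(rep(1, nrow(xe)), rowSums(placed_xyz^2)) - 2 * xe %*% t(placed_xyz)
    dmin <- sqrt(max(min(d2), 0))
    if (dmin > best_min + 1e-9) {
      best_min <- dmin; best_R <- R; best_tr <- tr
    }
  }
  transform_structure(tail, best_R, best_tr)
}

#' Build a full synaptic starting model
#'
#' Constructs the three-strand assembly of a RecA filament testing a duplex:
#' the initiating strand in site I (phosphate radius ~9 A), the
#' complementary/outgoing duplex threaded into site II (complementary at
#' 12 A, outgoing at 15 A) with bases of the three strands in triplet
#' registration, and B-form tails attached through kinked junctions at
#' `pattern$bend_angle`. The default pattern (2 site-II triplets, 6-bp tails)
#' is the principal starting structure in which 8 bp are positioned to
#' rapidly undergo strand exchange.
#'
#' Chains: `I` = initiating, `C` = complementary, `O` = outgoing (roles
#' annotated). The complementary strand runs 5'->3' toward -z; the other two
#' run toward +z.
#'
#' @param sequence Complementary-strand sequence, 5' to 3', covering
#'   `tail_bp_5p + 3*n_triplets_siteII + tail_bp_3p` bases (a longer sequence
#'   is truncated). Default: poly-dA, giving a (dT.dA) assembly.
#' @param pattern A [triplet_pattern()].
#' @param cfg Defaults from [fil_defaults()].
#' @return A [fil_structure()] with site-II bookkeeping and junction tags in
#'   its metadata.
#' @export
#' @examples
#' m <- build_synaptic_model()
#' roles(m)
build_synaptic_model <- function(sequence = NULL, pattern = triplet_pattern(),
                                 cfg = fil_defaults()) {
  n_trip <- pattern$n_triplets_siteII
  t5 <- pattern$tail_bp_5p; t3 <- pattern$tail_bp_3p
  if (n_trip == 0) {
    if (t5 == 0 && t3 == 0) abort("degenerate model: no site-II triplets and no tails")
    abort("a synaptic model needs at least one site-II triplet")
  }
  if (n_trip > 5) warn("more than five site-II triplets is outside the studied range")
  L <- 3L * n_trip
  need <- t5 + L + t3
  if (is.null(sequence)) sequence <- strrep("A", need)
  comp_bases <- check_sequence(sequence)
  if (length(comp_bases) < need) {
    abort(sprintf("sequence too short: need %d bases, got %d", need, length(comp_bases)))
  }
  comp_bases <- comp_bases[seq_len(need)]

  # --- site-II / site-I core -------------------------------------------
  # initiating strand: site I, sense +1, levels 1..L bottom-up
  init_bases <- unname(complement_base(comp_bases[t5 + (L:1)]))
  par_i <- filament_params(cfg, radius = cfg$r_initiating,
                           phase = cfg$phase_initiating)
  init <- place_strand(init_bases, par_i, sense = 1, chain = "I", cfg = cfg)
  fr <- attr(init, "frame")           # levels: phi, z
  phi_c1_i <- attr(init, "c1_phi")
  dc9 <- pair_half_angle(cfg$r_initiating - cfg$c1_radial_offset, cfg)

  # complementary strand site-II core: sense -1 from the top level
  comp_core_bases <- comp_bases[t5 + seq_len(L)]
  par_c <- filament_params(cfg, radius = cfg$r_complementary)
  comp <- place_strand(comp_core_bases, par_c, sense = -1, z0 = fr$z[L],
                       phase = cfg$phase_complementary + (fr$phi[L] - fr$phi[1]),
                       chain = "C", cfg = cfg)
  phi_c1_c <- attr(comp, "c1_phi")    # comp residue order (top level first)

  # outgoing strand site-II core: azimuth chosen so the site-II duplex closes
  # at the builder's own pair span
  r_c1_c <- cfg$r_complementary - cfg$c1_radial_offset
  r_c1_o <- cfg$r_outgoing - cfg$c1_radial_offset
  cosd <- (r_c1_c^2 + r_c1_o^2 - cfg$pair_span^2) / (2 * r_c1_c * r_c1_o)
  if (abs(cosd) > 1) abort("strand radii incompatible with the pair span")
  dphi_co <- rad2deg(acos(cosd))
  out_bases <- unname(complement_base(rev(comp_bases)))
  # comp C1' azimuth at level 1 is the last entry of phi_c1_c
  phase_o <- (phi_c1_c[L] + dphi_co) + c1_az_offset_at(cfg$r_outgoing, cfg)
  par_o <- filament_params(cfg, radius = cfg$r_outgoing, phase = phase_o)
  outg_core_bases <- out_bases[t3 + seq_len(L)]
  outg <- place_strand(outg_core_bases, par_o, sense = 1, chain = "O", cfg = cfg)

  # global residue numbering
  comp$residue_index <- comp$residue_index + t5
  outg$residue_index <- outg$residue_index + t3

  core <- fil_structure(bind_rows(init, comp, outg))
  # aim bases: comp <-> outgoing (site-II duplex); initiating at its virtual
  # postsynaptic partner (already the default placement, but recompute against
  # actual frame for exactness)
  c1_o <- coords_mat(outg[outg$atom == "C1'", ][order(outg$residue_index[outg$atom == "C1'"]), ])
  c1_c <- coords_mat(comp[comp$atom == "C1'", ][order(comp$residue_index[comp$atom == "C1'"]), ])
  # comp residue j (level L+1-j) pairs outgoing residue at the same level
  core <- aim_bases_at(core, "C", c1_o[L:1, , drop = FALSE], cfg)
  core <- aim_bases_at(core, "O", c1_c[L:1, , drop = FALSE], cfg)

  site_II <- list(
    levels = L,
    init_res = seq_len(L),                         # level i -> init residue
    comp_res = t5 + (L:1),                         # level i -> comp residue
    outgoing_res = t3 + seq_len(L),                # level i -> outgoing residue
    level_z = fr$z, level_phi = fr$phi,
    n_triplets = n_trip
  )
  meta <- list(kind = "synaptic", axis = fil_axis(), period = 3L,
               site_II = site_II, pattern = pattern, sequence = paste(comp_bases, collapse = ""),
               junctions = list())
  core <- set_fil_meta(core, meta)

  # --- B-form tails through kinked junctions ---------------------------
  beta <- pattern$bend_angle
  parts <- list(as_tibble(core))
  junctions <- list()
  if (t3 > 0) {
    # 3' tail of the complementary strand, attached below level 1
    seq_a <- paste(comp_bases[t5 + L + seq_len(t3)], collapse = "")
    tail <- build_bdna(seq_a, cfg = cfg, chains = c("C", "O"))
    phi_att <- fr$phi[1]
    d_out <- unitize(-cos(deg2rad(beta)) * c(0, 0, 1) + sin(deg2rad(beta)) * radial_unit(phi_att))
    R0 <- rotation_between(c(0, 0, 1), d_out)
    o3_end <- atom_pos(core, "C", t5 + L, "O3'")
    p_local <- atom_pos(tail, "C", 1L, "P")
    tail <- place_tail(tail, R0, d_out, p_local,
                       o3_end + cfg$o3p_len * d_out,
                       coords_mat(bind_rows(parts)), "C", 1L)
    tt <- as_tibble(tail)
    tt$residue_index[tt$chain == "C"] <- tt$residue_index[tt$chain == "C"] + t5 + L
    # outgoing tail partner (strand B) keeps its own 1..t3 numbering: it is
    # the outgoing strand's 5' tail
    parts[[length(parts) + 1]] <- tt
    junctions[[length(junctions) + 1]] <- list(
      id = length(junctions) + 1L, end = "3p",
      tail = list(chain = "C", res = t5 + L + seq_len(t3), period = 1L),
      fil = list(chain = "C", res = t5 + seq_len(L), period = 3L))
  }
  if (t5 > 0) {
    # 5' tail of the complementary strand, attached above level L
    seq_a <- paste(comp_bases[seq_len(t5)], collapse = "")
    tail <- build_bdna(seq_a, cfg = cfg, chains = c("C", "O"))
    phi_att <- fr$phi[L]
    e_out <- unitize(cos(deg2rad(beta)) * c(0, 0, 1) + sin(deg2rad(beta)) * radial_unit(phi_att))
    R0 <- rotation_between(c(0, 0, 1), -e_out)
    p_top <- atom_pos(core, "C", t5 + 1L, "P")
    o3_local <- atom_pos(tail, "C", t5, "O3'")
    tail <- place_tail(tail, R0, -e_out, o3_local,
                       p_top + cfg$o3p_len * e_out,
                       coords_mat(bind_rows(parts)), "C", t5)
    tt <- as_tibble(tail)
    tt$residue_index[tt$chain == "O"] <- tt$residue_index[tt$chain == "O"] + t3 + L
    parts[[length(parts) + 1]] <- tt
    junctions[[length(junctions) + 1]] <- list(
      id = length(junctions) + 1L, end = "5p",
      tail = list(chain = "C", res = seq_len(t5), period = 1L),
      fil = list(chain = "C", res = t5 + seq_len(L), period = 3L))
  }
  allatoms <- bind_rows(parts)
  allatoms <- allatoms[order(match(allatoms$chain, c("I", "C", "O")),
                             allatoms$residue_index), ]
  meta$junctions <- junctions
  s <- fil_structure(allatoms, metadata = meta)
  annotate_roles(s, c(I = "initiating", C = "complementary", O = "outgoing"),
                 strict = TRUE)
}

#' Join a B-form segment to a filament segment through a kink
#'
#' Rigidly places `b_segment` so that the angle between its helix axis and
#' the filament segment's axis equals `bend_angle`, with the junction
#' backbone gap (filament-end O3' to B-segment 5' phosphate) set to the
#' backbone bond length. The kink is assigned to a single step; stacking is
#' interrupted exactly there.
#'
#' @param b_segment,fil_segment [fil_structure()]s with free termini and
#'   disjoint chain ids.
#' @param bend_angle Kink angle in degrees.
#' @param cfg Defaults from [fil_defaults()].
#' @return The merged structure with a junction tag in its metadata.
#' @export
#' @examples
#' fil <- build_filament_strand(strrep("T", 9), chain = "F")
#' j <- build_junction(build_bdna("ACGTAC"), fil, 45)
#' junction_angle(j)
build_junction <- function(b_segment, fil_segment, bend_angle,
                           cfg = fil_defaults()) {
  b_segment <- as_fil_structure(b_segment)
  fil_segment <- as_fil_structure(fil_segment)
  shared <- intersect(unique(b_segment$chain), unique(fil_segment$chain))
  if (length(shared)) {
    abort(paste0("segments share chain id(s): ", paste(shared, collapse = ", ")))
  }
  fil_chain <- unique(fil_segment$chain)[1]
  fil_res <- sort(unique(fil_segment$residue_index[fil_segment$chain == fil_chain]))
  fil_period <- fil_meta(fil_segment)$period %||% 3L
  ax <- tryCatch(infer_axis(fil_segment, period = fil_period, chain = fil_chain),
                 error = function(e) fil_meta(fil_segment)$axis %||% fil_axis())
  u <- ax$direction
  # attach at the 3' end of the filament chain
  o3_end <- atom_pos(fil_segment, fil_chain, max(fil_res), "O3'")
  # bend about a direction perpendicular to the filament axis at the end
  radial <- o3_end - ax$point
  radial <- radial - sum(radial * u) * u
  rhat <- if (vnorm(radial) < 1e-9) {
    if (abs(u[1]) < 0.9) unitize(c(0, -u[3], u[2])) else unitize(c(-u[3], 0, u[1]))
  } else unitize(radial)
  d <- unitize(cos(deg2rad(bend_angle)) * u + sin(deg2rad(bend_angle)) * rhat)
  b_chain <- unique(b_segment$chain)[1]
  b_res <- sort(unique(b_segment$residue_index[b_segment$chain == b_chain]))
  b_axis <- tryCatch(infer_axis(b_segment, period = fil_meta(b_segment)$period %||% 1L,
                                chain = b_chain),
                     error = function(e) fil_axis())
  R <- rotation_between(b_axis$direction, d)
  p_first <- atom_pos(b_segment, b_chain, min(b_res), "P")
  tr <- (o3_end + cfg$o3p_len * d) - as.vector(R %*% p_first)
  b_placed <- transform_structure(b_segment, R, tr)
  merged <- fil_structure(
    bind_rows(as_tibble(fil_segment), as_tibble(b_placed)),
    metadata = list(
      kind = "junction", axis = ax,
      junctions = list(list(
        id = 1L, end = "3p",
        tail = list(chain = b_chain, res = b_res,
                    period = fil_meta(b_segment)$period %||% 1L),
        fil = list(chain = fil_chain, res = fil_res, period = fil_period)))))
  merged
}
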