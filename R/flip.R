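# Duplet base flipping: moving complementary bases from the site-II duplex
# into pairing range of the initiating strand in site I.

# orthonormal frame attached to an axis, for cylindrical bookkeeping
axis_frame <- function(ax) {
  u <- unitize(ax$direction)
  e1 <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0)
  e1 <- unitize(e1 - sum(e1 * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(point = ax$point, u = u, e1 = e1, e2 = e2)
}

frame_cyl <- function(fr, p) {
  rel <- p - fr$point
  zc <- sum(rel * fr$u)
  radial <- rel - zc * fr$u
  c(r = vnorm(radial),
    az = rad2deg(atan2(sum(radial * fr$e2), sum(radial * fr$e1))),
    z = zc)
}

frame_cart <- function(fr, r, az, z) {
  fr$point + z * fr$u +
    r * (cos(deg2rad(az)) * fr$e1 + sin(deg2rad(az)) * fr$e2)
}

#' Flip a complementary duplet toward the initiating strand
#'
#' Moves the two 5'-most complementary bases of one bound triplet (a duplet)
#' out of the site-II duplex and into Watson-Crick pairing range of the
#' initiating strand in site I; the triplet's 3' base stays in site II,
#' sterically blocked by the L2 loop. The initiating and outgoing strands are
#' not moved: exactly two complementary residues change coordinates. After
#' the flip the duplet's pairs classify as `paired` (D1 at the pair span,
#' theta1 at the paired-template value).
#'
#' @param structure A synaptic model (from [build_synaptic_model()]).
#' @param triplet_index Which bound triplet to flip (1 = bottom of site II).
#' @param which Only `"5p-duplet"` is modelled.
#' @param cfg Defaults from [fil_defaults()].
#' @return The structure with the duplet repositioned and the flip recorded
#'   in its metadata (`flipped`).
#' @export
#' @examples
#' m <- build_synaptic_model()
#' m2 <- flip_duplet(m, 2)
#' basepair_metrics(m2)
flip_duplet <- function(structure, triplet_index, which = "5p-duplet",
                        cfg = fil_defaults()) {
  structure <- as_fil_structure(structure)
  if (!identical(which, "5p-duplet")) {
    abort("only the 5'-duplet flip is modelled; the 3' base is blocked by the L2 loop")
  }
  m <- pair_maps(structure)
  n_trip <- m$n_triplets
  if (length(triplet_index) != 1 || !(triplet_index %in% seq_len(n_trip))) {
    abort(paste0("triplet_index must be a single value in 1..", n_trip))
  }
  lv_dup <- c(3L * triplet_index, 3L * triplet_index - 1L)
  bp <- basepair_metrics(structure, pair_index = lv_dup, cfg = cfg)
  if (all(bp$state == "paired")) {
    abort(paste0("duplet of triplet ", triplet_index, " is already paired"))
  }
  chain_i <- chain_for_role(structure, "initiating")
  chain_c <- chain_for_role(structure, "complementary")
  fr <- axis_frame(resolve_axis(structure))
  dc9 <- pair_half_angle(cfg$r_initiating - cfg$c1_radial_offset, cfg)
  tb <- as_tibble(structure)

  # postsynaptic placement per level, top (comp-5'-most) level first so the
  # intra-duplet O3' can chain onto the updated phosphate
  new_p <- list(); new_c1 <- list()
  for (lv in lv_dup) {
    ci <- atom_pos(structure, chain_i, m$init_res[lv], "C1'")
    cyl <- frame_cyl(fr, ci)
    az_c1 <- unname(cyl["az"]) + 2 * dc9
    rc <- m$comp_res[lv]
    new_c1[[as.character(rc)]] <-
      frame_cart(fr, cfg$r_initiating - cfg$c1_radial_offset, az_c1,
                 unname(cyl["z"]))
    # complementary strand runs 5'->3' toward -z (sense -1): its P sits on
    # the minus-azimuth side of the C1' at the virtual-bond offset
    new_p[[as.character(rc)]] <-
      frame_cart(fr, cfg$r_initiating,
                 az_c1 - c1_az_offset_at(cfg$r_initiating, cfg),
                 unname(cyl["z"]))
  }

  upd <- function(res_id, atom_names, p) {
    j <- which(tb$chain == chain_c & tb$residue_index == res_id &
                 tb$atom %in% atom_names)
    tb[j, c("x", "y", "z")] <<- as.list(p)
    invisible(NULL)
  }
  for (lv in lv_dup) {
    rc <- m$comp_res[lv]
    key <- as.character(rc)
    c1 <- new_c1[[key]]
    upd(rc, "P", new_p[[key]])
    upd(rc, "C1'", c1)
    ci <- atom_pos(structure, chain_i, m$init_res[lv], "C1'")
    d <- unitize(ci - c1)
    upd(rc, c("N9", "N1"), c1 + cfg$glyco_len * d)
    upd(rc, "CEN", c1 + cfg$cen_len * d)
    # O3' points at the next phosphate along the chain (updated if that
    # residue is the duplet partner)
    nxt_key <- as.character(rc + 1L)
    nxt_p <- new_p[[nxt_key]] %||% atom_pos(structure, chain_c, rc + 1L, "P")
    upd(rc, "O3'", nxt_p + cfg$o3p_len * unitize(c1 - nxt_p))
  }

  meta <- fil_meta(structure)
  meta$flipped <- sort(unique(c(meta$flipped, triplet_index)))
  out <- fil_structure(tb, metadata = meta)
  out
}
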