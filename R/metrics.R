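# Structural observables of filament-bound DNA models.

# resolve the working axis for a structure: explicit > metadata > inferred
resolve_axis <- function(structure, axis = NULL, chain = NULL) {
  if (!is.null(axis)) return(axis)
  meta_ax <- fil_meta(structure)$axis
  if (!is.null(meta_ax)) return(meta_ax)
  infer_axis(structure, period = fil_meta(structure)$period %||% 1L,
             chain = chain)
}

# orient an axis so the strand's net phosphate displacement projects >= 0
orient_axis_along <- function(ax, pmat) {
  disp <- pmat[nrow(pmat), ] - pmat[1, ]
  if (sum(disp * ax$direction) < 0) fil_axis(ax$point, -ax$direction) else ax
}

#' Per-step helical parameters of a strand
#'
#' For each consecutive phosphate pair reports the axially projected rise
#' (projection of the P->P displacement onto the helix axis), the signed
#' twist (angle between the radial components about the axis; positive =
#' right-handed), and the Euclidean P-P distance. The axis is oriented along
#' the strand so rises are positive for ideal helices. Site-II-bound DNA at
#' package defaults yields mean rise 5.1 A and mean twist 20 degrees per
#' step over whole triplets.
#'
#' @param structure A [fil_structure()].
#' @param chain Chain to analyse (default: the only chain present).
#' @param axis A [fil_axis()]; defaults to the build axis or an inferred one.
#' @param residues Optional residue subset (e.g. the site-II region).
#' @return A `fil_steps` tibble: step_index, axial_rise, twist, pp_distance.
#' @export
#' @examples
#' s <- build_filament_strand(strrep("T", 18))
#' step_summary(step_parameters(s))
step_parameters <- function(structure, chain = NULL, axis = NULL,
                            residues = NULL) {
  structure <- as_fil_structure(structure)
  chain <- chain %||% unique(structure$chain)
  if (length(chain) != 1) abort("specify a single chain")
  pp <- p_positions(structure, chain)
  keep <- if (is.null(residues)) seq_along(pp$residue_index) else
    which(pp$residue_index %in% residues)
  missing_p <- setdiff(residues %||% integer(0), pp$residue_index)
  if (length(missing_p)) {
    abort(paste0("missing P atom in residue ", missing_p[1], " of chain ", chain))
  }
  if (length(keep) < 2) {
    abort(paste0("chain ", chain,
                 " has fewer than 2 phosphates in the requested range"))
  }
  m <- pp$xyz[keep, , drop = FALSE]
  ax <- resolve_axis(structure, axis, chain)
  ax <- orient_axis_along(ax, m)
  u <- ax$direction
  rel <- sweep(m, 2, ax$point)
  radial <- rel - outer(as.vector(rel %*% u), u)
  n <- nrow(m)
  steps <- map(seq_len(n - 1), function(i) {
    dv <- m[i + 1, ] - m[i, ]
    tibble(
      step_index = i,
      axial_rise = sum(dv * u),
      twist = signed_angle_about(radial[i, ], radial[i + 1, ], u),
      pp_distance = vnorm(dv)
    )
  })
  out <- bind_rows(steps)
  out <- new_tibble(out, class = "fil_steps")
  attr(out, "chain") <- chain
  attr(out, "axis") <- ax
  out
}

#' @rdname step_parameters
#' @param steps A `fil_steps` tibble.
#' @return `step_summary()`: a one-row tibble of means over whole triplets
#'   (the first `3 * floor(n/3)` steps; all steps if fewer than 3).
#' @export
step_summary <- function(steps) {
  n <- nrow(steps)
  n_use <- if (n >= 3) 3L * (n %/% 3L) else n
  use <- steps[seq_len(n_use), ]
  tibble(mean_rise = mean(use$axial_rise), mean_twist = mean(use$twist),
         mean_pp = mean(use$pp_distance), n_steps = n_use)
}

#' Radial distance of a strand's phosphates from the helix axis
#'
#' In the default synaptic model the outgoing strand backbone is displaced
#' ~15 A from the filament axis and the initiating strand only ~9 A.
#'
#' @inheritParams step_parameters
#' @return A tibble (chain, residue_index, radius).
#' @export
#' @examples
#' m <- build_synaptic_model()
#' r <- strand_radius(m, chain = "I")
#' mean(r$radius)
strand_radius <- function(structure, chain = NULL, axis = NULL, residues = NULL) {
  structure <- as_fil_structure(structure)
  chain <- chain %||% unique(structure$chain)
  if (length(chain) != 1) abort("specify a single chain")
  pp <- p_positions(structure, chain)
  keep <- if (is.null(residues)) seq_along(pp$residue_index) else
    which(pp$residue_index %in% residues)
  if (!length(keep)) abort("no phosphates in the requested range")
  ax <- resolve_axis(structure, axis, chain)
  u <- ax$direction
  if (abs(vnorm(u) - 1) > 1e-6) abort("degenerate axis")
  rel <- sweep(pp$xyz[keep, , drop = FALSE], 2, ax$point)
  radial <- rel - outer(as.vector(rel %*% u), u)
  tibble(chain = chain, residue_index = pp$residue_index[keep],
         radius = sqrt(rowSums(radial^2)))
}

#' Extension factor relative to B-form DNA
#'
#' Mean axial rise per step (over whole triplets) divided by the canonical
#' B-form rise of 3.38 A. B-DNA returns 1.0; filament-bound DNA about 1.5.
#'
#' @inheritParams step_parameters
#' @param cfg Defaults from [fil_defaults()].
#' @return A single number.
#' @export
extension_factor <- function(structure, chain = NULL, axis = NULL,
                             residues = NULL, cfg = fil_defaults()) {
  st <- step_parameters(structure, chain = chain, axis = axis, residues = residues)
  step_summary(st)$mean_rise / cfg$b_rise
}

# ---- base-pairing metrics ---------------------------------------------

# level -> residue maps for structures carrying site-II bookkeeping
pair_maps <- function(structure) {
  m <- fil_meta(structure)$site_II
  if (is.null(m)) abort("structure carries no pairing bookkeeping (site_II metadata)")
  m
}

# thresholds calibrated against the package's own templates: the paired
# reference is the postsynaptic duplex in site I, the unflipped reference the
# untouched site-II model
flip_thresholds <- function(cfg = fil_defaults()) {
  key <- hash(cfg[c("r_initiating", "r_complementary", "r_outgoing", "pair_span",
                    "c1_radial_offset", "p_c1_bond", "phase_complementary",
                    "intra_rise", "inter_rise", "intra_twist", "inter_twist")])
  cached <- the$thresholds[[key]]
  if (!is.null(cached)) return(cached)
  post <- make_postsynaptic_reference(3, cfg = cfg)
  bp_post <- basepair_metrics_raw(post, cfg)
  pre <- build_synaptic_model(pattern = triplet_pattern(1, 0, 0), cfg = cfg)
  bp_pre <- basepair_metrics_raw(pre, cfg)
  th <- list(d1_paired = mean(bp_post$D1), theta1_paired = mean(bp_post$theta1),
             d1_unflipped = mean(bp_pre$D1))
  if (is.null(the$thresholds)) the$thresholds <- list()
  the$thresholds[[key]] <- th
  th
}

# D1/theta1 without state classification (used during calibration)
basepair_metrics_raw <- function(structure, cfg = fil_defaults()) {
  structure <- as_fil_structure(structure)
  rl <- roles(structure)
  if (!all(c("initiating", "complementary") %in% rl)) {
    abort("initiating and complementary roles must be annotated")
  }
  chain_i <- chain_for_role(structure, "initiating")
  chain_c <- chain_for_role(structure, "complementary")
  m <- pair_maps(structure)
  ci <- structure[structure$chain == chain_i & structure$atom == "C1'", ]
  cc <- structure[structure$chain == chain_c & structure$atom == "C1'", ]
  cc_all <- chain_atoms(structure, chain_c)
  rows <- map(seq_len(m$levels), function(lv) {
    ri <- m$init_res[lv]; rc <- m$comp_res[lv]
    c1i <- as.numeric(ci[ci$residue_index == ri, c("x", "y", "z")])
    c1c <- as.numeric(cc[cc$residue_index == rc, c("x", "y", "z")])
    nrow_ <- cc_all[cc_all$residue_index == rc & cc_all$atom %in% c("N9", "N1"), ]
    nn <- as.numeric(nrow_[1, c("x", "y", "z")])
    # local complementary-strand tangent defines the base-flipping plane
    res_c <- sort(unique(cc$residue_index))
    pos_in <- match(rc, res_c)
    prev <- res_c[max(pos_in - 1, 1)]
    nxt <- res_c[min(pos_in + 1, length(res_c))]
    tangent <- as.numeric(cc[cc$residue_index == nxt, c("x", "y", "z")]) -
      as.numeric(cc[cc$residue_index == prev, c("x", "y", "z")])
    tangent <- unitize(tangent)
    v_init <- c1i - c1c
    v_base <- nn - c1c
    p1 <- v_init - sum(v_init * tangent) * tangent
    p2 <- v_base - sum(v_base * tangent) * tangent
    th <- if (vnorm(p1) < 1e-9 || vnorm(p2) < 1e-9) NA_real_ else
      rad2deg(acos(max(-1, min(1, sum(unitize(p1) * unitize(p2))))))
    tibble(pair_index = lv, D1 = vnorm(c1i - c1c), theta1 = th)
  })
  bind_rows(rows)
}

#' Classify a base pair's flip state from D1 and theta1
#'
#' `paired` requires D1 within `d1_tol` of the paired template and theta1
#' within `theta1_tol` of it; `flipping` requires D1 to have moved at least
#' `flip_fraction` of the way from the unflipped template toward the paired
#' one; otherwise `unflipped`.
#'
#' @param D1,theta1 Metric values (Angstrom / degrees).
#' @param cfg Defaults from [fil_defaults()].
#' @return Character vector of states.
#' @export
classify_flip <- function(D1, theta1, cfg = fil_defaults()) {
  th <- flip_thresholds(cfg)
  paired <- abs(D1 - th$d1_paired) <= cfg$d1_tol &
    abs(theta1 - th$theta1_paired) <= cfg$theta1_tol
  frac <- (th$d1_unflipped - D1) / (th$d1_unflipped - th$d1_paired)
  flipping <- !paired & frac >= cfg$flip_fraction
  ifelse(paired, "paired", ifelse(flipping, "flipping", "unflipped"))
}

#' Base-pairing metrics D1 and theta1
#'
#' D1 is the C1'-C1' distance between the complementary and initiating
#' strands of a pair; theta1 is the C1'-C1'-N9 (or N1) angle at the
#' complementary C1', projected onto the base-flipping plane (the plane
#' normal to the local complementary-strand tangent). The flip state is a
#' deterministic function of (D1, theta1) and thresholds calibrated against
#' the package's own postsynaptic template.
#'
#' @param structure A [fil_structure()] with initiating/complementary roles
#'   and pairing bookkeeping (synaptic models and postsynaptic references).
#' @param pair_index Pair (level) selection; `NULL` = all.
#' @param cfg Defaults from [fil_defaults()].
#' @return A `fil_bp` tibble: pair_index, D1, theta1, state.
#' @export
#' @examples
#' post <- make_postsynaptic_reference(9)
#' basepair_metrics(post)
basepair_metrics <- function(structure, pair_index = NULL, cfg = fil_defaults()) {
  out <- basepair_metrics_raw(structure, cfg)
  if (!is.null(pair_index)) out <- out[out$pair_index %in% pair_index, ]
  out$state <- classify_flip(out$D1, out$theta1, cfg)
  new_tibble(out, class = "fil_bp")
}

#' Junction angle between a B-form tail and the filament DNA
#'
#' Returns the angle between the helix axes of the two tagged segments, each
#' inferred independently (screw fits over the segment's own period) and
#' oriented along its chain's residue order. The default synaptic model
#' reproduces the sharp ~90-degree change of direction seen where DNA enters
#' the filament.
#'
#' @param structure A structure with junction tags (from
#'   [build_synaptic_model()] or [build_junction()]).
#' @param junction Which junction (index into the metadata tags).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
junction_angle <- function(structure, junction = 1) {
  structure <- as_fil_structure(structure)
  js <- fil_meta(structure)$junctions
  if (is.null(js) || length(js) < junction) abort("no junction tag found")
  j <- js[[junction]]
  d_tail <- segment_direction(structure, j$tail)
  d_fil <- segment_direction(structure, j$fil)
  rad2deg(acos(max(-1, min(1, sum(d_tail * d_fil)))))
}

# oriented axis direction of a tagged segment
segment_direction <- function(structure, seg) {
  sub <- structure[structure$chain == seg$chain &
                     structure$residue_index %in% seg$res, ]
  nres <- length(unique(sub$residue_index))
  ax <- if (nres >= 2 * seg$period) {
    infer_axis(fil_structure(as_tibble(sub)), period = seg$period,
               chain = seg$chain)
  } else {
    fil_meta(structure)$axis %||% abort("segment too short and no stored axis")
  }
  c1 <- sub[sub$atom == "C1'", ]
  c1 <- c1[order(c1$residue_index), ]
  disp <- as.numeric(c1[nrow(c1), c("x", "y", "z")]) -
    as.numeric(c1[1, c("x", "y", "z")])
  u <- ax$direction
  if (sum(disp * u) < 0) -u else u
}

#' Triplet registration of the three strands
#'
#' Checks that corresponding bases of the initiating (site I), complementary
#' and outgoing strands (site II) remain in registration: at each level the
#' three C1' atoms must fall in the same axial window (one mean rise tall)
#' and the same azimuthal sector (20 degrees), after removing each strand's
#' constant axial/azimuthal binding offset (the strands sit at different
#' fixed azimuths in the groove).
#'
#' @param structure A synaptic model with all three nucleic roles annotated.
#' @param cfg Defaults from [fil_defaults()].
#' @return A tibble (triplet, pass, max_dz, max_daz); overall pass as the
#'   `all_pass` attribute.
#' @export
registration_check <- function(structure, cfg = fil_defaults()) {
  structure <- as_fil_structure(structure)
  rl <- roles(structure)
  need <- c("initiating", "complementary", "outgoing")
  if (!all(need %in% rl)) abort("all three nucleic roles must be annotated")
  m <- pair_maps(structure)
  ax <- resolve_axis(structure)
  u <- ax$direction
  chain_i <- chain_for_role(structure, "initiating")
  chain_c <- chain_for_role(structure, "complementary")
  chain_o <- chain_for_role(structure, "outgoing")
  # orthonormal frame perpendicular to the axis, for azimuth bookkeeping
  e1 <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0)
  e1 <- unitize(e1 - sum(e1 * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cylpos <- function(p) {
    rel <- p - ax$point
    zc <- sum(rel * u)
    radial <- rel - zc * u
    c(z = zc, az = rad2deg(atan2(sum(radial * e2), sum(radial * e1))))
  }
  lv_dat <- map(seq_len(m$levels), function(lv) {
    pi_ <- cylpos(atom_pos(structure, chain_i, m$init_res[lv], "C1'"))
    pc <- cylpos(atom_pos(structure, chain_c, m$comp_res[lv], "C1'"))
    po <- cylpos(atom_pos(structure, chain_o, m$outgoing_res[lv], "C1'"))
    tibble(level = lv,
           dz_c = unname(pc["z"] - pi_["z"]),
           daz_c = wrap_deg(pc["az"] - pi_["az"]),
           dz_o = unname(po["z"] - pi_["z"]),
           daz_o = wrap_deg(po["az"] - pi_["az"]))
  })
  d <- bind_rows(lv_dat)
  resid_of <- function(x) x - median(x)
  resid_az <- function(x) {
    w <- wrap_deg(x - x[1])
    w - median(w)
  }
  d$rz_c <- resid_of(d$dz_c); d$rz_o <- resid_of(d$dz_o)
  d$raz_c <- resid_az(d$daz_c); d$raz_o <- resid_az(d$daz_o)
  d$ok <- abs(d$rz_c) <= cfg$reg_axial_halfwidth &
    abs(d$rz_o) <= cfg$reg_axial_halfwidth &
    abs(d$raz_c) <= cfg$reg_az_halfwidth &
    abs(d$raz_o) <= cfg$reg_az_halfwidth
  d$triplet <- (d$level + 2L) %/% 3L
  out <- d %>%
    group_by(.data$triplet) %>%
    summarise(pass = all(.data$ok),
              max_dz = max(abs(c(.data$rz_c, .data$rz_o))),
              max_daz = max(abs(c(.data$raz_c, .data$raz_o))),
              .groups = "drop")
  attr(out, "all_pass") <- all(out$pass)
  out
}
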