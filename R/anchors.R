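#' Screw-replicated protein anchor sets
#'
#' The protein is represented by pseudo-atom anchor points replicated along
#' the filament screw: per-monomer site-II basic clusters (R226, R227, R243,
#' K245) that bind two consecutive outgoing-strand phosphates of each bound
#' triplet, C-terminal-domain lysine patches (K280, K282, K286, K302) at the
#' groove entrance that first tether incoming B-form duplex, and L2-loop
#' steric markers (residues 198-206 centroid, F203, M202) at the
#' inter-triplet rises.
#'
#' An `anchor_set` is a tibble with columns `label`, `monomer`, `kind`
#' (`siteII`, `ctd` or `L2`), `x`, `y`, `z`, carrying the replication screw
#' as an attribute. Anchors of equal label on consecutive monomers are
#' related by exactly one screw step.
#'
#' @param anchors Tibble with the columns above.
#' @param screw The [screw_transform()] used for replication.
#' @return An `anchor_set` tibble.
#' @export
anchor_set <- function(anchors, screw) {
  anchors <- as_tibble(anchors)
  req <- c("label", "monomer", "kind", "x", "y", "z")
  if (!all(req %in% names(anchors))) abort("anchor table missing required columns")
  out <- new_tibble(anchors, class = "anchor_set")
  attr(out, "screw") <- screw
  out
}

#' @rdname anchor_set
#' @param x An object.
#' @export
is_anchor_set <- function(x) inherits(x, "anchor_set")

anchor_screw <- function(a) attr(a, "screw")

replicate_template <- function(template, screw, n_monomers, kind) {
  if (n_monomers < 1) abort("n_monomers must be >= 1")
  pos <- do.call(rbind, template)
  base <- tibble(label = names(template), kind = kind,
                 x = pos[, 1], y = pos[, 2], z = pos[, 3])
  copies <- map(seq_len(n_monomers), function(m) {
    xyz <- apply_screw(screw, as.matrix(base[, c("x", "y", "z")]), m - 1L)
    tibble(label = base$label, monomer = m, kind = kind,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  bind_rows(copies)
}

# default site-II cluster template, monomer-1 frame, derived from where the
# builder puts the first triplet's outgoing duplet phosphates
siteII_template <- function(cfg = fil_defaults()) {
  stub <- build_synaptic_model(pattern = triplet_pattern(1, 0, 0), cfg = cfg)
  m <- fil_meta(stub)$site_II
  # duplet phosphates of triplet 1: levels 2 and 3 (the complementary
  # strand's 5'-most pair of the triplet)
  p2 <- atom_pos(stub, "O", m$outgoing_res[2], "P")
  p3 <- atom_pos(stub, "O", m$outgoing_res[3], "P")
  mid <- (p2 + p3) / 2
  az <- rad2deg(atan2(mid[2], mid[1]))
  rad <- cfg$siteII_anchor_radius
  # comp duplet 5' phosphate (level 3) hosts the K245 contact
  pc <- atom_pos(stub, "C", m$comp_res[3], "P")
  azc <- rad2deg(atan2(pc[2], pc[1]))
  list(
    R226 = cyl2cart(rad, az - 2, mid[3] - 0.5),
    R227 = cyl2cart(rad, az + 2, mid[3] + 0.5),
    R243 = cyl2cart(rad, az, mid[3] + 1.2),
    K245 = cyl2cart(cfg$r_complementary + 3, azc, pc[3])
  )
}

# default CTD lysine-patch template: placed at the groove entrance where the
# default 3' B-form tail passes (~22 A radius); K286/K302 are expressed in
# the monomer-1 frame so that their monomer-2 copies sit at the tail
ctd_template <- function(cfg = fil_defaults()) {
  model <- build_synaptic_model(pattern = triplet_pattern(2, 6, 6, cfg$bend_angle),
                                cfg = cfg)
  t5 <- 6L; L <- 6L; t3 <- 6L
  pc2 <- atom_pos(model, "C", t5 + L + 2L, "P")
  pc3 <- atom_pos(model, "C", t5 + L + 3L, "P")
  po2 <- atom_pos(model, "O", 2L, "P")
  po3 <- atom_pos(model, "O", 3L, "P")
  off <- function(p) p + 1.5 * unitize(c(p[1], p[2], 0))
  screw <- filament_screw(cfg)
  back1 <- function(p) as.numeric(apply_screw(screw, matrix(p, 1, 3), -1L))
  list(
    K280 = off(pc2), K282 = off(pc3),
    K286 = back1(off(po2)), K302 = back1(off(po3))
  )
}

# L2-loop steric markers at the inter-triplet rise of monomer 1
l2_template <- function(cfg = fil_defaults()) {
  z_gap <- 2 * cfg$intra_rise + cfg$inter_rise / 2
  az <- cfg$phase_complementary / 2
  list(
    `L2:198-206` = cyl2cart(10.5, az, z_gap),
    F203 = cyl2cart(10.0, az + 8, z_gap),
    M202 = cyl2cart(10.0, az - 8, z_gap)
  )
}

#' Generate helically replicated anchor sets
#'
#' `generate_siteII_anchors()` places one basic-residue cluster per monomer
#' at a radius compatible with binding the 15 A outgoing backbone;
#' `generate_ctd_anchors()` places the CTD lysine patch at the
#' filament-groove entrance; `generate_l2_anchors()` places L2-loop steric
#' markers at the inter-triplet rises. Template positions are given in the
#' monomer-1 frame and replicated by the screw.
#'
#' @param screw A [screw_transform()]; default the filament screw.
#' @param n_monomers Number of monomers (>= 1).
#' @param template_positions Named list label -> 3-vector (monomer-1 frame);
#'   defaults are derived from the builder's own frame.
#' @param cfg Defaults from [fil_defaults()].
#' @return An [anchor_set()].
#' @export
#' @examples
#' a <- generate_siteII_anchors(n_monomers = 6)
#' nrow(a)
generate_siteII_anchors <- function(screw = filament_screw(cfg), n_monomers = 1,
                                    template_positions = NULL,
                                    cfg = fil_defaults()) {
  template_positions <- template_positions %||% siteII_template(cfg)
  need <- c("R226", "R227", "R243", "K245")
  if (!all(need %in% names(template_positions))) {
    abort(paste0("site-II template missing label(s): ",
                 paste(setdiff(need, names(template_positions)), collapse = ", ")))
  }
  anchor_set(replicate_template(template_positions, screw, n_monomers, "siteII"),
             screw)
}

#' @rdname generate_siteII_anchors
#' @export
generate_ctd_anchors <- function(screw = filament_screw(cfg), n_monomers = 1,
                                 template_positions = NULL,
                                 cfg = fil_defaults()) {
  template_positions <- template_positions %||% ctd_template(cfg)
  need <- c("K280", "K282", "K286", "K302")
  if (!all(need %in% names(template_positions))) {
    abort(paste0("CTD template missing label(s): ",
                 paste(setdiff(need, names(template_positions)), collapse = ", ")))
  }
  anchor_set(replicate_template(template_positions, screw, n_monomers, "ctd"),
             screw)
}

#' @rdname generate_siteII_anchors
#' @export
generate_l2_anchors <- function(screw = filament_screw(cfg), n_monomers = 1,
                                template_positions = NULL,
                                cfg = fil_defaults()) {
  template_positions <- template_positions %||% l2_template(cfg)
  anchor_set(replicate_template(template_positions, screw, n_monomers, "L2"),
             screw)
}

#' @rdname anchor_set
#' @param ... Anchor sets to combine (sharing one screw).
#' @export
bind_anchor_sets <- function(...) {
  sets <- list(...)
  if (!length(sets)) abort("no anchor sets given")
  anchor_set(bind_rows(map(sets, as_tibble)), anchor_screw(sets[[1]]))
}

#' Map salt bridges between DNA phosphates and anchors
#'
#' Lists every phosphate-anchor pair within `cutoff` (centroid-to-P
#' distance), sorted by distance; ties break deterministically on chain,
#' residue and label. In the default synaptic model each bound triplet
#' contributes exactly its two consecutive outgoing duplet phosphates to the
#' site-II clusters.
#'
#' @param structure A [fil_structure()].
#' @param anchors An [anchor_set()].
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return A tibble (chain, residue_index, role, label, monomer, kind,
#'   distance).
#' @export
salt_bridge_map <- function(structure, anchors, cutoff = fil_defaults()$salt_bridge_cutoff) {
  structure <- as_fil_structure(structure)
  if (!nrow(anchors)) abort("empty anchor set")
  if (cutoff <= 0) abort("cutoff must be > 0")
  p <- as_tibble(structure)[structure$atom == "P", ]
  if (!nrow(p)) {
    return(tibble(chain = character(), residue_index = integer(),
                  role = character(), label = character(), monomer = integer(),
                  kind = character(), distance = numeric()))
  }
  pm <- as.matrix(p[, c("x", "y", "z")])
  am <- as.matrix(anchors[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rep(1, nrow(am))) +
    outer(rep(1, nrow(pm)), rowSums(am^2)) - 2 * pm %*% t(am)
  d2[d2 < 0] <- 0
  hits <- which(sqrt(d2) <= cutoff, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(tibble(chain = character(), residue_index = integer(),
                  role = character(), label = character(), monomer = integer(),
                  kind = character(), distance = numeric()))
  }
  out <- tibble(
    chain = p$chain[hits[, 1]],
    residue_index = p$residue_index[hits[, 1]],
    role = p$role[hits[, 1]],
    label = anchors$label[hits[, 2]],
    monomer = as.integer(anchors$monomer[hits[, 2]]),
    kind = anchors$kind[hits[, 2]],
    distance = sqrt(d2[hits])
  )
  out[order(out$distance, out$chain, out$residue_index, out$label), ]
}
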