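#' Spring networks for restrained relaxation
#'
#' The internal flexibility of the DNA (and any anchored protein stand-ins)
#' is represented by an augmented spring network: harmonic bonds along the
#' backbone, harmonic positional anchors on restrained phosphates, and soft
#' excluded-volume repulsions. The energy convention is `E = k * (r - r0)^2`
#' (no 1/2 factor), so printed restraint constants such as
#' 0.5 kcal mol^-1 A^-2 are usable verbatim.
#'
#' `build_network()` creates bonds between consecutive backbone atoms within
#' each chain (P-C1' 4.0 A virtual bond, C1'-O3' at its built length,
#' O3'-P 1.6 A), attaches an anchor to every phosphate within the
#' salt-bridge cutoff of an anchor point (target = its current position, the
#' restrained-in-place protocol), and adds repulsions between non-bonded
#' atom pairs closer than `r_min`. Consecutive residues whose O3'-P gap
#' exceeds `break_gap` are treated as a deliberate strand break (the
#' displaced outgoing strand is discontinuous at the tail junctions) and get
#' no bond.
#'
#' @param structure A [fil_structure()].
#' @param anchors An [anchor_set()], a tibble with columns
#'   `node`,`k`,`tx`,`ty`,`tz`, or `NULL`.
#' @param k_anchor,k_bond,k_rep Spring constants, kcal mol^-1 A^-2.
#' @param r_min Repulsion onset distance, Angstrom.
#' @param break_gap O3'-P gap beyond which consecutive residues are treated
#'   as a strand break, Angstrom (same budget as closable junctions).
#' @param cfg Defaults from [fil_defaults()].
#' @return A `spring_network` object (nodes, bonds, anchors, repulsions).
#' @export
#' @examples
#' s <- build_filament_strand("TTTTTT")
#' net <- build_network(s)
#' network_energy(net, coords_of(s))   # built structures are at rest
build_network <- function(structure, anchors = NULL,
                          k_anchor = fil_defaults()$k_anchor,
                          k_bond = fil_defaults()$k_bond,
                          k_rep = fil_defaults()$k_rep,
                          r_min = fil_defaults()$r_min,
                          break_gap = 5,
                          cfg = fil_defaults()) {
  structure <- as_fil_structure(structure)
  s <- as_tibble(structure)
  s$node <- seq_len(nrow(s))
  bonds <- list()
  add_bond <- function(i, j, r0) {
    bonds[[length(bonds) + 1]] <<- c(i = i, j = j, r0 = r0)
  }
  xyz <- coords_mat(s)
  cur_len <- function(i, j) vnorm(xyz[i, ] - xyz[j, ])
  for (ch in unique(s$chain)) {
    a <- s[s$chain == ch, ]
    resids <- sort(unique(a$residue_index))
    node_of <- function(ri, nm) {
      v <- a$node[a$residue_index == ri & a$atom == nm]
      if (length(v)) v[1] else NA_integer_
    }
    for (k in seq_along(resids)) {
      ri <- resids[k]
      p <- node_of(ri, "P"); c1 <- node_of(ri, "C1'"); o3 <- node_of(ri, "O3'")
      nb <- node_of(ri, "N9"); if (is.na(nb)) nb <- node_of(ri, "N1")
      ce <- node_of(ri, "CEN")
      if (!is.na(p) && !is.na(c1)) add_bond(p, c1, cfg$p_c1_bond)
      if (!is.na(c1) && !is.na(o3)) add_bond(c1, o3, cur_len(c1, o3))
      if (!is.na(c1) && !is.na(nb)) add_bond(c1, nb, cfg$glyco_len)
      if (!is.na(nb) && !is.na(ce)) add_bond(nb, ce, cfg$cen_len - cfg$glyco_len)
      if (k < length(resids)) {
        pn <- node_of(resids[k + 1], "P")
        if (!is.na(o3) && !is.na(pn) && cur_len(o3, pn) <= break_gap) {
          add_bond(o3, pn, cfg$o3p_len)
        }
      }
    }
  }
  bonds <- if (length(bonds)) {
    b <- as_tibble(do.call(rbind, bonds))
    b$k <- k_bond
    b
  } else tibble(i = integer(), j = integer(), r0 = numeric(), k = numeric())

  anch <- tibble(node = integer(), k = numeric(), tx = numeric(),
                 ty = numeric(), tz = numeric())
  if (!is.null(anchors)) {
    if (is_anchor_set(anchors)) {
      sb <- salt_bridge_map(structure, anchors, cutoff = cfg$salt_bridge_cutoff)
      if (nrow(sb)) {
        key <- paste(sb$chain, sb$residue_index)
        key <- unique(key)
        idx <- map_dbl(key, function(k2) {
          parts <- strsplit(k2, " ")[[1]]
          s$node[s$chain == parts[1] & s$residue_index == as.integer(parts[2]) &
                   s$atom == "P"][1]
        })
        anch <- tibble(node = as.integer(idx), k = k_anchor,
                       tx = xyz[idx, 1], ty = xyz[idx, 2], tz = xyz[idx, 3])
      }
    } else {
      anchors <- as_tibble(anchors)
      if (!all(c("node", "k", "tx", "ty", "tz") %in% names(anchors))) {
        abort("explicit anchors need columns node, k, tx, ty, tz")
      }
      bad <- setdiff(anchors$node, s$node)
      if (length(bad)) abort("anchor maps to a missing atom")
      anch <- anchors
    }
  }

  # candidate repulsion pairs: non-bonded atoms currently within r_min + 1
  bonded_key <- character(0)
  if (nrow(bonds)) bonded_key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  rep_pairs <- tibble(i = integer(), j = integer())
  if (nrow(s) >= 2) {
    d <- as.matrix(stats::dist(xyz))
    cand <- which(d < r_min + 1 & upper.tri(d), arr.ind = TRUE)
    if (nrow(cand)) {
      # exclude the covalently connected neighborhood: atoms of the same or
      # of consecutive residues within one chain
      near_res <- s$chain[cand[, 1]] == s$chain[cand[, 2]] &
        abs(s$residue_index[cand[, 1]] - s$residue_index[cand[, 2]]) <= 1L
      keyed <- paste(pmin(cand[, 1], cand[, 2]), pmax(cand[, 1], cand[, 2]))
      keep <- !near_res & !(keyed %in% bonded_key)
      rep_pairs <- tibble(i = cand[keep, 1], j = cand[keep, 2])
    }
  }
  rep_pairs$k <- if (nrow(rep_pairs)) k_rep else numeric(0)
  rep_pairs$r_min <- if (nrow(rep_pairs)) r_min else numeric(0)

  structure(list(atoms = s, bonds = bonds, anchors = anch,
                 repulsions = rep_pairs, meta = fil_meta(structure)),
            class = "spring_network")
}

#' @rdname build_network
#' @param net A `spring_network`.
#' @param xyz Coordinate matrix (defaults to the network's own).
#' @export
network_energy <- function(net, xyz = NULL) {
  xyz <- xyz %||% coords_mat(net$atoms)
  e <- 0
  b <- net$bonds
  if (nrow(b)) {
    d <- sqrt(rowSums((xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE])^2))
    e <- e + sum(b$k * (d - b$r0)^2)
  }
  a <- net$anchors
  if (nrow(a)) {
    dv <- xyz[a$node, , drop = FALSE] - cbind(a$tx, a$ty, a$tz)
    e <- e + sum(a$k * rowSums(dv^2))
  }
  r <- net$repulsions
  if (nrow(r)) {
    d <- sqrt(rowSums((xyz[r$i, , drop = FALSE] - xyz[r$j, , drop = FALSE])^2))
    pen <- pmax(r$r_min - d, 0)
    e <- e + sum(r$k * pen^2)
  }
  e
}

# add per-pair force contributions into the gradient matrix
accumulate_pairs <- function(g, i, j, f) {
  ai <- rowsum(f, i)
  g[as.integer(rownames(ai)), ] <- g[as.integer(rownames(ai)), , drop = FALSE] + ai
  aj <- rowsum(-f, j)
  g[as.integer(rownames(aj)), ] <- g[as.integer(rownames(aj)), , drop = FALSE] + aj
  g
}

#' @rdname build_network
#' @export
network_gradient <- function(net, xyz = NULL) {
  xyz <- xyz %||% coords_mat(net$atoms)
  g <- matrix(0, nrow(xyz), 3)
  b <- net$bonds
  if (nrow(b)) {
    dv <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    d[d < 1e-12] <- 1e-12
    g <- accumulate_pairs(g, b$i, b$j, dv * (2 * b$k * (d - b$r0) / d))
  }
  a <- net$anchors
  if (nrow(a)) {
    dv <- xyz[a$node, , drop = FALSE] - cbind(a$tx, a$ty, a$tz)
    ag <- rowsum(dv * (2 * a$k), a$node)
    g[as.integer(rownames(ag)), ] <- g[as.integer(rownames(ag)), , drop = FALSE] + ag
  }
  r <- net$repulsions
  if (nrow(r)) {
    dv <- xyz[r$i, , drop = FALSE] - xyz[r$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    d[d < 1e-12] <- 1e-12
    active <- d < r$r_min
    if (any(active)) {
      coef <- numeric(length(d))
      coef[active] <- -2 * r$k[active] * (r$r_min[active] - d[active]) / d[active]
      g <- accumulate_pairs(g, r$i, r$j, dv * coef)
    }
  }
  g
}

#' Minimize a spring network
#'
#' Deterministic first-order descent (spectral/Barzilai-Borwein step with a
#' monotone backtracking safeguard): the energy is non-increasing along the
#' trace, and identical inputs reproduce the trajectory exactly. The default
#' iteration cap of 50,000 mirrors conjugate-gradient practice for such
#' restrained minimizations.
#'
#' @param net A `spring_network` from [build_network()].
#' @param tol Convergence threshold on the gradient max-norm (> 0).
#' @param max_iter Iteration cap.
#' @param snapshot_every Record intermediate coordinates every this many
#'   iterations (0 = none) for trace auditing.
#' @return A `fil_minim` list: `structure` (relaxed), `trace` tibble
#'   (iteration, energy, gradient norm), `snapshots`, `converged`,
#'   `iterations`, `energy`.
#' @export
#' @examples
#' s <- build_filament_strand("TTT")
#' net <- build_network(s)
#' res <- minimize(net)
#' res$converged
minimize <- function(net, tol = fil_defaults()$minim_tol,
                     max_iter = fil_defaults()$minim_max_iter,
                     snapshot_every = 0) {
  if (tol <= 0) abort("tol must be > 0")
  x <- coords_mat(net$atoms)
  e <- network_energy(net, x)
  if (!is.finite(e)) abort("non-finite energy at start")
  g <- network_gradient(net, x)
  gmax <- max(abs(g))
  trace <- list(tibble(iteration = 0L, energy = e, gnorm = gmax))
  snapshots <- list()
  if (snapshot_every > 0) snapshots[["0"]] <- x
  alpha <- 1 / max(1, gmax)
  it <- 0L
  x_prev <- NULL; g_prev <- NULL
  while (gmax > tol && it < max_iter) {
    it <- it + 1L
    if (!is.null(x_prev)) {
      sx <- x - x_prev; sg <- g - g_prev
      denom <- sum(sx * sg)
      if (denom > 1e-30) alpha <- sum(sx * sx) / denom
      alpha <- min(max(alpha, 1e-8), 10)
    }
    # monotone safeguard: backtrack until the energy decreases
    repeat {
      x_new <- x - alpha * g
      e_new <- network_energy(net, x_new)
      if (e_new <= e || alpha < 1e-12) break
      alpha <- alpha / 2
    }
    x_prev <- x; g_prev <- g
    x <- x_new; e <- e_new
    g <- network_gradient(net, x)
    gmax <- max(abs(g))
    trace[[length(trace) + 1]] <- tibble(iteration = it, energy = e, gnorm = gmax)
    if (snapshot_every > 0 && it %% snapshot_every == 0) {
      snapshots[[as.character(it)]] <- x
    }
  }
  out_s <- set_coords(net$atoms, x)
  out_s$node <- NULL
  structure(list(
    structure = fil_structure(out_s, metadata = net$meta %||% list()),
    trace = bind_rows(trace),
    snapshots = snapshots,
    converged = gmax <= tol,
    iterations = it,
    energy = e
  ), class = "fil_minim")
}

#' Close the backbone of screw-replicated fragments
#'
#' Links screw-periodic fragment copies into continuous strands: the
#' fragments are concatenated (sequential renumbering per chain), inter-
#' fragment O3'-P bonds are added at the backbone bond length, all
#' phosphates are anchored at their pre-closure positions (the interacting
#' phosphates must keep their protein contacts), and the network is
#' minimized.
#'
#' @param fragments List of [fil_structure()] fragments (screw-periodic
#'   copies), or a single already-concatenated structure.
#' @param screw The [screw_transform()] relating consecutive fragments (used
#'   for bookkeeping/validation).
#' @param max_gap Largest closable O3'-P junction gap, Angstrom.
#' @param cfg Defaults from [fil_defaults()].
#' @return A `fil_minim` result whose `structure` is the closed strand; the
#'   junction residue indices are reported in `junction_res`.
#' @export
close_backbone <- function(fragments, screw = filament_screw(cfg), max_gap = 5,
                           cfg = fil_defaults()) {
  if (is_fil_structure(fragments)) fragments <- list(fragments)
  nfrag <- length(fragments)
  res_off <- setNames(rep(0L, length(unique(fragments[[1]]$chain))),
                      unique(fragments[[1]]$chain))
  parts <- list(); junction_res <- integer(0)
  for (k in seq_len(nfrag)) {
    f <- as_tibble(fragments[[k]])
    if (k > 1) {
      for (ch in names(res_off)) {
        sel <- f$chain == ch
        if (k <= nfrag) junction_res <- c(junction_res, res_off[ch])
        f$residue_index[sel] <- f$residue_index[sel] + res_off[ch]
      }
    }
    for (ch in unique(f$chain)) {
      res_off[ch] <- max(f$residue_index[f$chain == ch])
    }
    parts[[k]] <- f
  }
  joined <- bind_rows(parts)
  joined <- joined[order(match(joined$chain, unique(joined$chain)),
                         joined$residue_index), ]
  s <- fil_structure(joined, metadata = fil_meta(fragments[[1]]))
  # validate junction gaps before attempting closure
  for (ch in unique(s$chain)) {
    a <- chain_atoms(s, ch)
    resids <- sort(unique(a$residue_index))
    for (ri in setdiff(unique(junction_res), 0L)) {
      if (!(ri %in% resids) || !((ri + 1L) %in% resids)) next
      o3 <- atom_pos(s, ch, ri, "O3'")
      p <- atom_pos(s, ch, ri + 1L, "P")
      gap <- vnorm(o3 - p)
      if (gap > max_gap) {
        abort(sprintf("junction gap %.2f A after residue %d of chain %s exceeds the movement budget",
                      gap, ri, ch))
      }
    }
  }
  # anchor every phosphate in place; the O3'-P bonds (r0 = bond length,
  # including the inter-fragment ones created by consecutive numbering) pull
  # the junctions closed
  net <- build_network(s, cfg = cfg)
  pnodes <- net$atoms$node[net$atoms$atom == "P"]
  xyz <- coords_mat(net$atoms)
  net$anchors <- tibble(node = pnodes, k = cfg$k_anchor,
                        tx = xyz[pnodes, 1], ty = xyz[pnodes, 2],
                        tz = xyz[pnodes, 3])
  res <- minimize(net, tol = 1e-5)
  res$junction_res <- sort(unique(junction_res))
  res$structure <- set_fil_meta(res$structure, fil_meta(s))
  res
}

#' Radially pull selected phosphates to a target radius
#'
#' Applies harmonic restraints pulling the phosphates of the selected
#' residues to the target radius (targets keep each atom's azimuth and
#' height, so the pull is purely radial), with weak positional anchors on
#' the remaining residues, then minimizes. Because the restraints act
#' radially and the selection is triplet-periodic, the helical symmetry of
#' the input (its global stretching and winding) is conserved.
#'
#' @param structure A [fil_structure()] with known helical symmetry.
#' @param selection Residue indices whose phosphates are pulled.
#' @param target_radius Target phosphate radius, Angstrom (> 0).
#' @param k Pull spring constant, kcal mol^-1 A^-2.
#' @param chain Chain to operate on (default: the only chain).
#' @param cfg Defaults from [fil_defaults()].
#' @return A `fil_minim` result whose `structure` is the pulled strand.
#' @export
#' @examples
#' s <- build_filament_strand(strrep("T", 9),
#'   params = filament_params(radius = 12))
#' res <- radial_pull(s, c(1, 2, 4, 5, 7, 8), 15)
radial_pull <- function(structure, selection, target_radius, k = 5,
                        chain = NULL, cfg = fil_defaults()) {
  if (target_radius <= 0) abort("target_radius must be > 0")
  structure <- as_fil_structure(structure)
  chain <- chain %||% unique(structure$chain)
  if (length(chain) != 1) abort("specify a single chain")
  net <- build_network(structure, cfg = cfg)
  at <- net$atoms
  xyz <- coords_mat(at)
  sel_rows <- which(at$chain == chain & at$residue_index %in% selection)
  if (!length(sel_rows)) abort("selection matches no residues")
  # per selected residue: rigid radial displacement taking its P to the
  # target radius
  anchors <- list()
  for (ri in intersect(selection, unique(at$residue_index[at$chain == chain]))) {
    rows <- which(at$chain == chain & at$residue_index == ri)
    prow <- rows[at$atom[rows] == "P"]
    pr <- sqrt(sum(xyz[prow, 1:2]^2))
    rhat <- c(xyz[prow, 1:2] / pr, 0)
    shift <- (target_radius - pr) * rhat
    tgt <- sweep(xyz[rows, , drop = FALSE], 2, -shift)
    anchors[[length(anchors) + 1]] <- tibble(node = rows, k = k,
                                             tx = tgt[, 1], ty = tgt[, 2],
                                             tz = tgt[, 3])
  }
  other <- which(at$chain == chain & !(at$residue_index %in% selection))
  if (length(other)) {
    anchors[[length(anchors) + 1]] <- tibble(node = other, k = k / 20,
                                             tx = xyz[other, 1],
                                             ty = xyz[other, 2],
                                             tz = xyz[other, 3])
  }
  net$anchors <- bind_rows(anchors)
  res <- minimize(net, tol = 1e-5)
  res$structure <- set_fil_meta(res$structure, fil_meta(structure))
  res
}
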