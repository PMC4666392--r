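#' Screw transforms: the generators of filament helical symmetry
#'
#' A screw transform is a rigid motion combining a right-handed rotation of
#' `angle_per_step` degrees about an axis with a translation of
#' `translation_per_step` Angstrom along it. The default filament screw is
#' 60 degrees and 15.3 A per RecA monomer (six subunits per turn, three
#' nucleotides per subunit at 5.1 A mean rise).
#'
#' @param axis_point A point on the axis (length-3, Angstrom).
#' @param axis_dir Axis direction (normalised internally).
#' @param angle_per_step Rotation per step, degrees, in (-180, 180].
#' @param translation_per_step Translation per step, Angstrom.
#' @return A `screw_transform` object.
#' @export
#' @examples
#' t <- filament_screw()
#' t$angle_per_step
screw_transform <- function(axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                            angle_per_step = 0, translation_per_step = 0) {
  structure(
    list(
      axis_point = as.numeric(axis_point),
      axis_dir = unitize(as.numeric(axis_dir)),
      angle_per_step = wrap_deg(angle_per_step),
      translation_per_step = as.numeric(translation_per_step)
    ),
    class = "screw_transform"
  )
}

#' @rdname screw_transform
#' @param cfg Defaults list from [fil_defaults()].
#' @export
filament_screw <- function(cfg = fil_defaults()) {
  screw_transform(c(0, 0, 0), c(0, 0, 1), cfg$monomer_twist, cfg$monomer_rise)
}

#' @export
print.screw_transform <- function(x, ...) {
  cat(sprintf(
    "<screw_transform> %.4f deg / %.4f A per step about axis (%.3f, %.3f, %.3f) through (%.2f, %.2f, %.2f)\n",
    x$angle_per_step, x$translation_per_step,
    x$axis_dir[1], x$axis_dir[2], x$axis_dir[3],
    x$axis_point[1], x$axis_point[2], x$axis_point[3]))
  invisible(x)
}

#' Helix axis
#'
#' @param point A point on the axis.
#' @param direction Axis direction (normalised internally).
#' @return A `fil_axis` object.
#' @export
fil_axis <- function(point = c(0, 0, 0), direction = c(0, 0, 1)) {
  structure(list(point = as.numeric(point), direction = unitize(direction)),
            class = "fil_axis")
}

# rotation matrix + translation vector realising n steps of a screw
screw_rt <- function(t, n = 1) {
  R <- rotation_about(t$axis_dir, t$angle_per_step * n)
  p <- t$axis_point
  tr <- p - as.vector(R %*% p) + t$translation_per_step * n * t$axis_dir
  list(R = R, t = tr)
}

#' Fit the screw motion relating two point sets
#'
#' Finds the rigid motion superposing `coords_a` onto `coords_b`
#' (least-squares, Kabsch) and decomposes it into a rotation about a unique
#' axis plus a translation along it. For consecutive equivalent regions of
#' the filament this recovers the helical symmetry (60 degrees per monomer,
#' i.e. six subunits per turn).
#'
#' @param coords_a,coords_b Paired point sets: n x 3 matrices, data frames
#'   with `x`,`y`,`z` columns, or [fil_structure()]s with identical atom
#'   ordering. At least 3 non-collinear points.
#' @return A [screw_transform()] with an `rmsd` attribute (fit residual). The
#'   translation is reported along `axis_dir`; for a pure translation the
#'   angle is 0 and the axis is the translation direction.
#' @export
#' @examples
#' a <- coords_of(build_bdna("ACGTAA"))
#' b <- a %*% t(rotation_about(c(0, 0, 1), 60)); b[, 3] <- b[, 3] + 15.3
#' fit_screw(a, b)
fit_screw <- function(coords_a, coords_b) {
  a <- as_coords(coords_a)
  b <- as_coords(coords_b)
  if (nrow(a) != nrow(b)) abort("point sets must be paired (equal size)")
  if (nrow(a) < 3) abort("need at least 3 points to fit a screw")
  sv <- svd(sweep(a, 2, colMeans(a)))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) abort("points are collinear")
  fit <- kabsch(a, b)
  aa <- rotation_axis_angle(fit$R)
  resid <- rmsd(sweep(a %*% t(fit$R), 2, -fit$t), b)
  # acos() noise on an identity rotation can read as up to ~1e-5 deg; treat
  # anything below 1e-4 deg as a pure translation
  if (!is.finite(aa$angle) || abs(aa$angle) < 1e-4) {
    # pure translation (or identity)
    tr <- vnorm(fit$t)
    dir <- if (tr < 1e-12) c(0, 0, 1) else fit$t / tr
    out <- screw_transform(colMeans(a), dir, 0, tr)
    attr(out, "rmsd") <- resid
    return(out)
  }
  u <- aa$axis
  # orient the axis so the parallel translation is non-negative
  d_par <- sum(fit$t * u)
  if (d_par < 0) {
    u <- -u
    aa$angle <- -aa$angle
    d_par <- -d_par
  }
  t_perp <- fit$t - d_par * u
  # axis point p solves (I - R) p = t_perp in the plane perpendicular to u
  M <- diag(3) - fit$R
  p <- tryCatch(as.vector(qr.solve(M + u %*% t(u), t_perp)),
                error = function(e) abort("degenerate screw decomposition"))
  p <- p - sum(p * u) * u
  out <- screw_transform(p, u, wrap_deg(aa$angle), d_par)
  attr(out, "rmsd") <- resid
  out
}

# accept matrix / data frame / structure
as_coords <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) abort("coordinate matrix must have 3 columns")
    return(x)
  }
  if (is.data.frame(x)) return(coords_mat(x))
  abort("cannot interpret coordinates")
}

#' @rdname fit_screw
#' @param structure A [fil_structure()].
#' @export
coords_of <- function(structure) coords_mat(as_fil_structure(structure))

#' Apply n steps of a screw transform to a structure
#'
#' A rigid motion: all intra-structure distances are preserved. Negative `n`
#' applies the inverse.
#'
#' @param t A [screw_transform()].
#' @param structure A [fil_structure()] (or coordinate matrix).
#' @param n Integer step count.
#' @return The transformed structure (or matrix).
#' @export
apply_screw <- function(t, structure, n = 1) {
  rt <- screw_rt(t, n)
  if (is.matrix(structure)) {
    return(sweep(structure %*% t(rt$R), 2, -rt$t))
  }
  transform_structure(structure, rt$R, rt$t)
}

#' Replicate a fragment along a screw
#'
#' Places `count` copies of the fragment, copy k transformed by k-1 screw
#' steps, and concatenates them with sequential residue renumbering per
#' chain. This is how trinucleotide fragments are replicated at each
#' equivalent region along the filament, following its helical symmetry.
#'
#' @param fragment A [fil_structure()].
#' @param t A [screw_transform()].
#' @param count Number of copies (>= 1).
#' @return A single [fil_structure()].
#' @export
#' @examples
#' frag <- build_filament_strand("TTT")
#' strand <- replicate_along_screw(frag, filament_screw(), 6)
#' max(strand$residue_index)
replicate_along_screw <- function(fragment, t, count) {
  fragment <- as_fil_structure(fragment)
  if (count < 1) abort("count must be >= 1")
  res_per_chain <- vapply(split(fragment$residue_index, fragment$chain),
                          function(r) length(unique(r)), 1L)
  copies <- map(seq_len(count) - 1L, function(k) {
    cp <- apply_screw(t, fragment, k)
    cp$residue_index <- cp$residue_index + k * res_per_chain[cp$chain]
    as_tibble(cp)
  })
  out <- bind_rows(copies)
  out <- out[order(match(out$chain, unique(fragment$chain)), out$residue_index), ]
  fil_structure(out, metadata = c(fil_meta(fragment), list(replicated = count)))
}

#' Infer the helix axis of a periodic structure
#'
#' Fits the screw motion mapping residues `i..i+period-1` onto
#' `i+period..i+2*period-1` for every available window and averages the axis
#' directions (equal weight) and axis points.
#'
#' @param structure A single-chain [fil_structure()] (or pass `chain`).
#' @param period Helical repeat in residues (1 for a uniform helix, 3 for one
#'   triplet of filament DNA).
#' @param chain Chain to use; defaults to the only chain present.
#' @return A [fil_axis()]; direction oriented along increasing residue order.
#' @export
infer_axis <- function(structure, period = 1, chain = NULL) {
  structure <- as_fil_structure(structure)
  chain <- chain %||% unique(structure$chain)
  if (length(chain) != 1) abort("specify a single chain")
  a <- chain_atoms(structure, chain)
  resids <- sort(unique(a$residue_index))
  nres <- length(resids)
  if (nres < 2 * period) abort("need at least two periods of the stated repeat")
  dirs <- list(); pts <- list()
  for (i in seq_len(nres - 2 * period + 1)) {
    w1 <- a[a$residue_index %in% resids[i:(i + period - 1)], ]
    w2 <- a[a$residue_index %in% resids[(i + period):(i + 2 * period - 1)], ]
    # pair atoms by (relative residue, atom name)
    w1 <- w1[order(w1$residue_index, w1$atom), ]
    w2 <- w2[order(w2$residue_index, w2$atom), ]
    if (nrow(w1) != nrow(w2)) next
    sc <- fit_screw(coords_mat(w1), coords_mat(w2))
    dirs[[length(dirs) + 1]] <- sc$axis_dir
    pts[[length(pts) + 1]] <- sc$axis_point
  }
  if (!length(dirs)) abort("no usable windows for axis inference")
  ref <- dirs[[1]]
  dmat <- do.call(rbind, map(dirs, function(d) if (sum(d * ref) < 0) -d else d))
  fil_axis(colMeans(do.call(rbind, pts)), unitize(colMeans(dmat)))
}
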