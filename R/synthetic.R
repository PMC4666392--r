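# Deterministic synthetic scenarios: reference structures, decoys and noise.

#' Ideal postsynaptic reference duplex
#'
#' The product-state template: the initiating strand in site I paired with
#' the complementary strand, both threaded on the filament screw with the
#' triplet-patterned rise/twist, C1'-C1' spans at the Watson-Crick pair span
#' and both phosphate backbones at the site-I radius. It calibrates the
#' `paired` thresholds of [basepair_metrics()].
#'
#' @param length_bp Number of base pairs (multiples of 3 recommended).
#' @param sequence Complementary-strand sequence, 5' to 3' (default poly-dA).
#' @param cfg Defaults from [fil_defaults()].
#' @return A [fil_structure()] with chains `I` (initiating) and `C`
#'   (complementary) and pairing bookkeeping in its metadata.
#' @export
#' @examples
#' post <- make_postsynaptic_reference(6)
#' basepair_metrics(post)$state
make_postsynaptic_reference <- function(length_bp = 9, sequence = NULL,
                                        cfg = fil_defaults()) {
  if (length_bp < 1) abort("length_bp must be >= 1")
  if (is.null(sequence)) sequence <- strrep("A", length_bp)
  comp_bases <- check_sequence(sequence)
  if (length(comp_bases) < length_bp) {
    abort(sprintf("sequence too short: need %d bases, got %d",
                  length_bp, length(comp_bases)))
  }
  comp_bases <- comp_bases[seq_len(length_bp)]
  L <- as.integer(length_bp)

  init_bases <- unname(complement_base(comp_bases[L:1]))
  par_i <- filament_params(cfg, radius = cfg$r_initiating,
                           phase = cfg$phase_initiating)
  init <- place_strand(init_bases, par_i, sense = 1, chain = "I", cfg = cfg)
  fr <- attr(init, "frame")
  dc9 <- pair_half_angle(cfg$r_initiating - cfg$c1_radial_offset, cfg)

  # complementary strand paired in site I: its C1' sits across the pair
  # chord from the initiating C1' at the same radius and level
  par_c <- filament_params(cfg, radius = cfg$r_initiating)
  phase_c <- fr$phi[L] - 2 * c1_az_offset_at(cfg$r_initiating, cfg) + 2 * dc9
  comp <- place_strand(comp_bases, par_c, sense = -1, z0 = fr$z[L],
                       phase = phase_c, chain = "C", cfg = cfg)

  site_II <- list(
    levels = L,
    init_res = seq_len(L),
    comp_res = L:1,
    level_z = fr$z, level_phi = fr$phi,
    n_triplets = L %/% 3L
  )
  s <- fil_structure(bind_rows(init, comp),
                     metadata = list(kind = "postsynaptic", period = 3L,
                                     axis = fil_axis(), site_II = site_II,
                                     sequence = paste(comp_bases, collapse = "")))
  annotate_roles(s, c(I = "initiating", C = "complementary"), strict = TRUE)
}

#' Add isotropic Gaussian coordinate noise
#'
#' @param structure A [fil_structure()].
#' @param sigma Standard deviation per coordinate, Angstrom (>= 0).
#' @param seed Optional integer seed; when given the perturbation is
#'   reproducible and the caller's RNG state is left untouched.
#' @return The perturbed structure (metadata preserved).
#' @export
perturb_structure <- function(structure, sigma, seed = NULL) {
  structure <- as_fil_structure(structure)
  if (sigma < 0) abort("sigma must be >= 0")
  if (sigma == 0) return(structure)
  n <- nrow(structure)
  noise <- if (is.null(seed)) {
    matrix(rnorm(3 * n, sd = sigma), n, 3)
  } else {
    with_seed_local(seed, matrix(rnorm(3 * n, sd = sigma), n, 3))
  }
  set_coords(structure, coords_mat(structure) + noise)
}

#' Specify a synthetic scenario
#'
#' A scenario is a deterministic recipe for a starting structure: assembly
#' size, tail lengths, junction bend, coordinate noise, and an optional
#' decoy mode producing a structure that violates exactly one structural
#' expectation:
#' * `wrong_twist`: all strands built at a uniform 30 degrees per step
#'   (helical twist off; rises, radii, registration and junctions intact).
#' * `misregistered`: the complementary strand's triplet phasing is offset
#'   by one residue, breaking three-strand registration only.
#' * `unkinked`: tails attached straight (bend 0) so only the junction
#'   angle deviates.
#'
#' @param n_triplets Site-II-bound triplets (1-5).
#' @param tail_bp_5p,tail_bp_3p B-form tail lengths in base pairs.
#' @param bend_angle Junction bend, degrees (ignored for `unkinked`).
#' @param noise_sigma Gaussian coordinate noise, Angstrom.
#' @param seed Integer seed in [1, 2^31) controlling the noise.
#' @param decoy_mode One of `"none"`, `"wrong_twist"`, `"misregistered"`,
#'   `"unkinked"`.
#' @param sequence Optional complementary-strand sequence.
#' @return A `scenario_spec` object.
#' @export
#' @examples
#' sp <- scenario_spec(n_triplets = 2, noise_sigma = 0.3, seed = 7)
#' m <- make_scenario(sp)
scenario_spec <- function(n_triplets = 2, tail_bp_5p = 6, tail_bp_3p = 6,
                          bend_angle = 90, noise_sigma = 0, seed = 1L,
                          decoy_mode = c("none", "wrong_twist",
                                         "misregistered", "unkinked"),
                          sequence = NULL) {
  decoy_mode <- match.arg(decoy_mode)
  if (n_triplets < 1 || n_triplets > 5) abort("n_triplets must be in 1..5")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed != trunc(seed) || seed < 1 || seed >= 2^31) {
    abort("seed must be an integer in [1, 2^31)")
  }
  seed <- as.integer(seed)
  structure(list(n_triplets = as.integer(n_triplets),
                 tail_bp_5p = as.integer(tail_bp_5p),
                 tail_bp_3p = as.integer(tail_bp_3p),
                 bend_angle = bend_angle,
                 noise_sigma = noise_sigma,
                 seed = seed,
                 decoy_mode = decoy_mode,
                 sequence = sequence),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @param spec A `scenario_spec`.
#' @param cfg Defaults from [fil_defaults()].
#' @return `make_scenario()`: the scenario's [fil_structure()], bitwise
#'   reproducible for equal spec and cfg.
#' @export
make_scenario <- function(spec, cfg = fil_defaults()) {
  if (!inherits(spec, "scenario_spec")) abort("spec must be a scenario_spec")
  cfg_used <- cfg
  bend <- spec$bend_angle
  if (spec$decoy_mode == "wrong_twist") {
    cfg_used$intra_twist <- 30
    cfg_used$inter_twist <- 30
  }
  if (spec$decoy_mode == "unkinked") bend <- 0
  pattern <- triplet_pattern(spec$n_triplets, spec$tail_bp_5p,
                             spec$tail_bp_3p, bend)
  model <- build_synaptic_model(spec$sequence, pattern, cfg_used)
  if (spec$decoy_mode == "misregistered") {
    model <- offset_comp_phasing(model, cfg_used)
  }
  model <- perturb_structure(model, spec$noise_sigma, seed = spec$seed)
  meta <- fil_meta(model)
  meta$scenario <- spec
  set_fil_meta(model, meta)
}

# rebuild the complementary site-II core with its triplet phasing offset by
# one residue (decoy: breaks registration, leaves per-triplet means intact)
offset_comp_phasing <- function(model, cfg) {
  m <- fil_meta(model)$site_II
  L <- m$levels
  t5 <- fil_meta(model)$pattern$tail_bp_5p
  comp_bases <- strsplit(fil_meta(model)$sequence, "")[[1]][t5 + seq_len(L)]
  par_c <- filament_params(cfg, radius = cfg$r_complementary)
  phase_c <- cfg$phase_complementary + (m$level_phi[L] - m$level_phi[1])
  comp2 <- place_strand(comp_bases, par_c, sense = -1, z0 = m$level_z[L],
                        phase = phase_c, chain = "C", pattern_offset = 1L,
                        cfg = cfg)
  comp2$residue_index <- comp2$residue_index + t5
  # aim the rebuilt bases at their site-II partners (unchanged outgoing C1')
  chain_o <- chain_for_role(model, "outgoing")
  c1_o <- t(vapply(seq_len(L), function(lv)
    atom_pos(model, chain_o, m$outgoing_res[lv], "C1'"), numeric(3)))
  c2s <- fil_structure(comp2)
  c2s <- aim_bases_at(c2s, "C", c1_o[L:1, , drop = FALSE], cfg)
  tb <- as_tibble(model)
  keep <- !(tb$chain == "C" & tb$residue_index %in% (t5 + seq_len(L)))
  tb2 <- bind_rows(tb[keep, ], as_tibble(c2s))
  tb2 <- tb2[order(match(tb2$chain, c("I", "C", "O")), tb2$residue_index), ]
  s <- fil_structure(tb2, metadata = fil_meta(model))
  annotate_roles(s, c(I = "initiating", C = "complementary", O = "outgoing"),
                 strict = TRUE)
}
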