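# End-to-end runs: scenario -> anchors -> relaxation -> metrics -> report.

#' Run a scenario end to end
#'
#' Builds the scenario structure, generates the protein anchor sets
#' (site-II clusters and CTD lysine patches, replicated along the filament
#' screw), relaxes the DNA in the spring network restrained by those
#' anchors, recomputes all structural observables from the relaxed
#' coordinates, and returns a report. Identical spec and config reproduce
#' the report bitwise; the provenance records the configuration hash and
#' seed.
#'
#' @param spec A [scenario_spec()].
#' @param config Defaults from [fil_defaults()] (or [read_fil_config()]).
#' @param outdir Optional output directory; when given, writes `model.pdb`
#'   (relaxed coordinates), `report.json`, `steps.tsv` and `contacts.tsv`.
#' @param relax Set `FALSE` to analyse the built structure unrelaxed.
#' @return A `fil_run_report`: `spec`, `provenance` (config hash, seed),
#'   `strands` (per-strand means over the site-II region), `junction_angles`,
#'   `registration`, `flip_states` (per-pair metrics), `contacts` (salt
#'   bridges), `minim` (relaxation outcome or `NULL`), `steps` (per-strand
#'   step tables) and `structure` (the analysed coordinates).
#' @export
#' @examples
#' rep <- run_scenario(scenario_spec(n_triplets = 1, tail_bp_5p = 0,
#'                                   tail_bp_3p = 0), relax = FALSE)
#' rep$strands
run_scenario <- function(spec = scenario_spec(), config = fil_defaults(),
                         outdir = NULL, relax = TRUE) {
  model <- make_scenario(spec, config)
  screw <- filament_screw(config)
  anch <- bind_anchor_sets(
    generate_siteII_anchors(screw, n_monomers = spec$n_triplets, cfg = config),
    generate_ctd_anchors(screw, n_monomers = max(2L, spec$n_triplets),
                         cfg = config))

  minim <- NULL
  analysed <- model
  if (relax) {
    net <- build_network(model, anchors = anch, k_anchor = config$k_anchor,
                         k_bond = config$k_bond, k_rep = config$k_rep,
                         r_min = config$r_min, cfg = config)
    minim <- minimize(net, tol = config$minim_tol,
                      max_iter = config$minim_max_iter)
    analysed <- minim$structure
  }

  m <- pair_maps(analysed)
  strand_res <- list(
    initiating = list(chain = chain_for_role(analysed, "initiating"),
                      res = sort(m$init_res)),
    complementary = list(chain = chain_for_role(analysed, "complementary"),
                         res = sort(m$comp_res)),
    outgoing = list(chain = chain_for_role(analysed, "outgoing"),
                    res = sort(m$outgoing_res)))
  steps <- map(strand_res, function(sr)
    step_parameters(analysed, chain = sr$chain, residues = sr$res))
  strands <- imap(strand_res, function(sr, nm) {
    sm <- step_summary(steps[[nm]])
    rad <- strand_radius(analysed, chain = sr$chain, residues = sr$res)
    tibble(strand = nm, chain = sr$chain,
           mean_rise = sm$mean_rise, mean_twist = sm$mean_twist,
           mean_pp = sm$mean_pp, mean_radius = mean(rad$radius),
           extension = sm$mean_rise / config$b_rise)
  }) %>% list_rbind()

  junctions <- fil_meta(analysed)$junctions %||% list()
  junction_angles <- map_dbl(seq_along(junctions),
                             function(j) junction_angle(analysed, j))
  registration <- registration_check(analysed, config)
  flip_states <- basepair_metrics(analysed, cfg = config)
  contacts <- salt_bridge_map(analysed, anch, config$salt_bridge_cutoff)

  report <- structure(list(
    spec = spec,
    provenance = list(config_hash = hash(config), seed = spec$seed),
    strands = strands,
    junction_angles = junction_angles,
    registration = registration,
    flip_states = flip_states,
    contacts = contacts,
    minim = if (is.null(minim)) NULL else
      list(converged = minim$converged, iterations = minim$iterations,
           energy = minim$energy),
    steps = steps,
    structure = analysed
  ), class = "fil_run_report")

  if (!is.null(outdir)) write_run_outputs(report, outdir)
  report
}

# write the on-disk artefacts of a run
write_run_outputs <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_pdb(report$structure, file.path(outdir, "model.pdb"))
  steps_tab <- imap(report$steps, function(st, nm) {
    out <- as_tibble(st)
    out$strand <- nm
    out[, c("strand", "step_index", "axial_rise", "twist", "pp_distance")]
  }) %>% list_rbind()
  utils::write.table(steps_tab, file.path(outdir, "steps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as_tibble(report$contacts),
                     file.path(outdir, "contacts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  js <- list(
    spec = unclass(report$spec),
    provenance = report$provenance,
    strands = as_tibble(report$strands),
    junction_angles = report$junction_angles,
    registration_pass = isTRUE(attr(report$registration, "all_pass")),
    flip_states = table_states(report$flip_states$state),
    n_contacts = nrow(report$contacts),
    minim = report$minim
  )
  jsonlite::write_json(js, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

table_states <- function(states) {
  lv <- c("paired", "flipping", "unflipped")
  as.list(setNames(vapply(lv, function(s) sum(states == s), 1L), lv))
}

#' @export
print.fil_run_report <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("<fil_run_report> %d triplet(s), tails %d/%d bp, noise %.2f, seed %d%s\n",
              sp$n_triplets, sp$tail_bp_5p, sp$tail_bp_3p, sp$noise_sigma,
              sp$seed,
              if (sp$decoy_mode == "none") "" else paste0(", decoy ", sp$decoy_mode)))
  print(x$strands)
  if (length(x$junction_angles)) {
    cat(sprintf("junction angles: %s deg\n",
                paste(sprintf("%.1f", x$junction_angles), collapse = ", ")))
  }
  cat(sprintf("registration: %s; contacts: %d; flip states: %s\n",
              if (isTRUE(attr(x$registration, "all_pass"))) "in register" else "OUT OF REGISTER",
              nrow(x$contacts),
              paste(names(table_states(x$flip_states$state)),
                    unlist(table_states(x$flip_states$state)),
                    sep = "=", collapse = " ")))
  invisible(x)
}
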