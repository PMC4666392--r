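# Tidier methods for run reports and minimization results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a run report
#'
#' One row per strand with the per-strand means over the site-II region.
#'
#' @param x A `fil_run_report` from [run_scenario()].
#' @param ... Unused.
#' @return A tibble (strand, chain, mean_rise, mean_twist, mean_pp,
#'   mean_radius, extension).
#' @export
tidy.fil_run_report <- function(x, ...) {
  as_tibble(x$strands)
}

#' Glance at a run report
#'
#' @param x A `fil_run_report`.
#' @param ... Unused.
#' @return A one-row tibble of headline observables: initiating-strand mean
#'   rise/twist, outgoing and initiating mean radii, extension factor, first
#'   junction angle, registration flag, contact and flip-state counts, and
#'   provenance.
#' @export
glance.fil_run_report <- function(x, ...) {
  st <- x$strands
  pick <- function(strand, col) st[[col]][st$strand == strand]
  states <- table_states(x$flip_states$state)
  tibble(
    mean_rise = pick("initiating", "mean_rise"),
    mean_twist = pick("initiating", "mean_twist"),
    radius_initiating = pick("initiating", "mean_radius"),
    radius_outgoing = pick("outgoing", "mean_radius"),
    extension = pick("initiating", "extension"),
    junction_angle = if (length(x$junction_angles)) x$junction_angles[1] else NA_real_,
    in_register = isTRUE(attr(x$registration, "all_pass")),
    n_contacts = nrow(x$contacts),
    n_paired = states$paired,
    n_unflipped = states$unflipped,
    converged = if (is.null(x$minim)) NA else x$minim$converged,
    seed = x$spec$seed,
    config_hash = x$provenance$config_hash
  )
}

#' Tidy a minimization result
#'
#' @param x A `fil_minim` from [minimize()].
#' @param ... Unused.
#' @return The iteration trace tibble (iteration, energy, gnorm).
#' @export
tidy.fil_minim <- function(x, ...) {
  as_tibble(x$trace)
}

#' Glance at a minimization result
#'
#' @param x A `fil_minim`.
#' @param ... Unused.
#' @return A one-row tibble (converged, iterations, energy, final gradient
#'   max-norm).
#' @export
glance.fil_minim <- function(x, ...) {
  tibble(converged = x$converged, iterations = x$iterations,
         energy = x$energy, gnorm = x$trace$gnorm[nrow(x$trace)])
}
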