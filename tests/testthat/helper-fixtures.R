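# Shared fixtures and small test utilities. Expensive models are built once
# and reused read-only across files.

.fixtures <- new.env()

default_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- build_synaptic_model()
  .fixtures$model
}

default_report <- function() {
  if (is.null(.fixtures$report)) .fixtures$report <- run_scenario(scenario_spec())
  .fixtures$report
}

# position of one atom
apos <- function(s, chain, resid, atom) {
  r <- s[s$chain == chain & s$residue_index == resid & s$atom == atom, ]
  as.numeric(r[1, c("x", "y", "z")])
}

vlen <- function(v) sqrt(sum(v^2))

# random rigid motion (rotation matrix + translation), seeded by the caller
random_motion <- function() {
  ax <- rnorm(3)
  ax <- ax / vlen(ax)
  list(R = filamentforge:::rotation_about(ax, runif(1, -180, 180)),
       t = rnorm(3, sd = 20))
}

# mean consecutive P-P distance of one chain over given residues
mean_pp_dist <- function(s, chain, residues = NULL) {
  a <- s[s$chain == chain & s$atom == "P", ]
  if (!is.null(residues)) a <- a[a$residue_index %in% residues, ]
  a <- a[order(a$residue_index), ]
  m <- as.matrix(a[, c("x", "y", "z")])
  mean(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}
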