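# Shared fixtures: small models and panels built in code.

# reversible 3-state birth-death spec over two generic processes
bd_spec <- function(link = "inverse", processes = c("p1", "p2"), ...) {
  cmsm_spec(n_states = 3, processes = processes, link = link, ...)
}

# the published two-process kidney model (shared inverse frailty estimates)
kidney_model <- function(link = "inverse", theta = 0.549) {
  spec <- cmsm_spec(processes = c("eGFR", "PU"), link = link)
  cmsm_model(spec,
    intensities = list(eGFR = c(0.053, 0.496, 0.073, 0.453),
                       PU = c(0.468, 0.653, 0.127, 2.111)),
    theta = if (link == "none") NULL else theta)
}

# the published no-random-effect (marginal) estimates
kidney_marginal_model <- function() {
  spec <- cmsm_spec(processes = c("eGFR", "PU"), link = "none")
  cmsm_model(spec,
    intensities = list(eGFR = c(0.051, 0.461, 0.112, 0.346),
                       PU = c(0.272, 0.565, 0.158, 1.224)))
}

# tiny complete two-process panel (two informative subjects)
tiny_panel <- function() {
  tibble::tibble(
    id = rep(c("a", "b"), c(3, 4)),
    time = c(0, 1.1, 2.3, 0, 1, 2.2, 3.1),
    p1 = c(1L, 2L, 1L, 1L, 2L, 2L, 1L),
    p2 = c(2L, 3L, 2L, 1L, 1L, 2L, 2L)
  )
}

# simulated annual-visit cohort from a known truth
sim_cohort <- function(n, visits = 0:7, link = "inverse", theta = 0.5,
                       seed = 1, p1 = c(0.05, 0.5, 0.1, 0.4),
                       p2 = c(0.3, 0.6, 0.15, 1.2)) {
  spec <- bd_spec(link)
  nth <- switch(link, none = NULL, separate = c(theta, theta), theta)
  truth <- cmsm_model(spec, intensities = list(p1 = p1, p2 = p2), theta = nth)
  cfg <- cmsm_sim_config(
    n_subjects = n, model = truth, visit_times = visits,
    initial_probs = list(p1 = c(0.5, 0.35, 0.15), p2 = c(0.5, 0.35, 0.15)),
    seed = seed
  )
  panel <- cmsm_simulate(cfg)
  attr(panel, "truth") <- truth
  panel
}
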