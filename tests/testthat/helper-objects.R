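# shared fixtures, built in code

aav8 <- vp_stoichiometry()

default_cfg <- instrument_config()
noiseless_mz_cfg <- instrument_config(rel_sigma_mz = 0,
                                      multiple_ion_rate = 0,
                                      short_trap_rate = 0)
default_cm <- charge_model()

table1 <- data.frame(
  name = c("CMV-CRE", "CMV-GFP", "CMV-mCherry", "CAG-GFP", "CAG-mCherry",
           "EF1a-GFP", "CBA-GFP", "CMV-SaCas9"),
  n_bases = c(2219, 2544, 2784, 2876, 2895, 3458, 4354, 4844),
  expected_mda = c(0.683, 0.783, 0.857, 0.886, 0.892, 1.065, 1.341, 1.492))

# construct a bare ion_events object with given masses (for binning /
# classification tests that need exact masses)
make_events <- function(mass, z = 150, multiple_ion = FALSE,
                        short_trap = FALSE, component = "x") {
  out <- data.frame(mz = mass / z, z = rep_len(z, length(mass)),
                    mass = mass,
                    component = rep_len(component, length(mass)),
                    multiple_ion = rep_len(multiple_ion, length(mass)),
                    short_trap = rep_len(short_trap, length(mass)))
  class(out) <- c("ion_events", "data.frame")
  out
}

empty_full_mixture <- function(goi_mass, w_full = 0.5,
                               stoich = aav8) {
  list(
    mixture_component("empty", packaging_state("empty"), 1 - w_full,
                      stoich = stoich),
    mixture_component("full", packaging_state("full_GOI",
                                              goi_mass = goi_mass),
                      w_full, stoich = stoich))
}

# independent exact-enumeration oracle for the capsid mass distribution,
# deliberately using a different code path (expand.grid + dmultinom)
enumerate_capsid_oracle <- function(p, masses, n) {
  grid <- expand.grid(n1 = 0:n, n2 = 0:n)
  grid <- grid[grid$n1 + grid$n2 <= n, ]
  grid$n3 <- n - grid$n1 - grid$n2
  pr <- apply(grid, 1L, function(r) stats::dmultinom(r, prob = p))
  m <- as.matrix(grid) %*% masses
  mu <- sum(pr * m)
  list(mean = mu, sd = sqrt(sum(pr * m^2) - mu^2), prob = pr, mass = m)
}

scenario_path <- function(name)
  system.file("extdata", "scenarios", name, package = "cdmsaav")
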