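#' CDMS instrument configuration
#'
#' Measurement-resolution parameters of a single-ion electrostatic linear
#' ion trap experiment. The charge uncertainty scales with
#' (trapping time)^-1/2 and is ~1 e RMSD at the reference 100 ms trap time;
#' the relative m/z error is kept subdominant by default.
#'
#' @param trap_time Trapping time in ms (> 0). Default 100.
#' @param sigma_z_ref Charge RMSD in elementary charges at the 100 ms
#'   reference trap time. Default 1.
#' @param rel_sigma_mz Relative m/z RMSD (dimensionless). Default 0.001.
#' @param bin_width Mass histogram bin width in Da. Default 20,000.
#' @param multiple_ion_rate Probability that an event traps more than one
#'   ion (flagged and discarded downstream). Default 0.05.
#' @param short_trap_rate Probability that an ion is not trapped for the
#'   full trapping period (flagged and discarded downstream). Default 0.02.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(trap_time = 100, sigma_z_ref = 1,
                              rel_sigma_mz = 0.001, bin_width = 20000,
                              multiple_ion_rate = 0.05,
                              short_trap_rate = 0.02) {
  assert_scalar_number(trap_time, "trap_time", lower = 0, strict = TRUE)
  assert_scalar_number(sigma_z_ref, "sigma_z_ref", lower = 0)
  assert_scalar_number(rel_sigma_mz, "rel_sigma_mz", lower = 0)
  assert_scalar_number(bin_width, "bin_width", lower = 0, strict = TRUE)
  assert_scalar_number(multiple_ion_rate, "multiple_ion_rate", lower = 0)
  assert_scalar_number(short_trap_rate, "short_trap_rate", lower = 0)
  if (multiple_ion_rate >= 1 || short_trap_rate >= 1)
    stop("event-flag rates must be < 1", call. = FALSE)
  structure(list(trap_time = trap_time, sigma_z_ref = sigma_z_ref,
                 rel_sigma_mz = rel_sigma_mz, bin_width = bin_width,
                 multiple_ion_rate = multiple_ion_rate,
                 short_trap_rate = short_trap_rate),
            class = "instrument_config")
}

#' Charge-versus-mass model
#'
#' Under the charge residue mechanism the charge picked up by a large ion
#' tracks its size. We model the mean charge as a power law,
#' \eqn{z(m) = s\, z_{ref} (m/m_{ref})^{2/3}}, anchored at 150 e for the
#' 3.7 MDa empty capsid; the 2/3 exponent is surface-area (Rayleigh-like)
#' scaling. The per-species `shape_factor` \eqn{s \ge 1} absorbs extended
#' geometries that pick up more charge than a compact sphere of equal mass.
#'
#' @param z_ref Charge in e at the reference mass. Default 150.
#' @param m_ref Reference mass in Da. Default 3.7e6.
#' @param exponent Power-law exponent. Default 2/3.
#' @param shape_factor Default per-species multiplier (>= 1).
#' @return An object of class `charge_model`.
#' @export
charge_model <- function(z_ref = 150, m_ref = 3.7e6, exponent = 2 / 3,
                         shape_factor = 1) {
  assert_scalar_number(z_ref, "z_ref", lower = 0, strict = TRUE)
  assert_scalar_number(m_ref, "m_ref", lower = 0, strict = TRUE)
  assert_scalar_number(exponent, "exponent", lower = 0)
  assert_scalar_number(shape_factor, "shape_factor", lower = 1)
  structure(list(z_ref = z_ref, m_ref = m_ref, exponent = exponent,
                 shape_factor = shape_factor),
            class = "charge_model")
}

#' Charge measurement uncertainty
#'
#' RMSD of the single-ion charge measurement:
#' `sigma_z_ref * (trap_time / 100 ms)^(-1/2)`. To first order independent
#' of the charge itself.
#'
#' @param cfg An [instrument_config()].
#' @return Charge RMSD in e.
#' @examples
#' charge_sigma(instrument_config(trap_time = 400))  # 0.5 e
#' @export
charge_sigma <- function(cfg) {
  stopifnot(inherits(cfg, "instrument_config"))
  cfg$sigma_z_ref * (cfg$trap_time / 100)^(-0.5)
}

#' Single-ion mass uncertainty
#'
#' Propagates the charge and m/z errors to mass (m = m/z x z): quadrature
#' sum of `(m/z) * sigma_z` and `m * rel_sigma_mz`.
#'
#' @param mass Ion mass in Da.
#' @param charge Ion charge in e.
#' @param cfg An [instrument_config()].
#' @return Mass RMSD in Da.
#' @export
mass_sigma <- function(mass, charge, cfg) {
  stopifnot(inherits(cfg, "instrument_config"))
  assert_numeric_vec(mass, "mass", lower = 0, strict = TRUE)
  assert_numeric_vec(charge, "charge", lower = 0, strict = TRUE)
  sqrt(((mass / charge) * charge_sigma(cfg))^2 + (mass * cfg$rel_sigma_mz)^2)
}

#' Mean charge at a given mass
#'
#' @param mass Mass in Da (vectorized).
#' @param cm A [charge_model()].
#' @param shape_factor Per-species multiplier; defaults to the model's.
#' @return Mean charge in e.
#' @examples
#' mean_charge(3.7e6, charge_model())   # 150
#' mean_charge(7.4e6, charge_model())   # ~238
#' @export
mean_charge <- function(mass, cm, shape_factor = cm$shape_factor) {
  stopifnot(inherits(cm, "charge_model"))
  assert_numeric_vec(mass, "mass", lower = 0, strict = TRUE)
  shape_factor * cm$z_ref * (mass / cm$m_ref)^cm$exponent
}

#' Expected peak shape for a heterogeneous particle
#'
#' Convolves the exact capsid mass distribution (shifted by any packaged DNA
#' mass) with the instrument resolution: each support point becomes a
#' Gaussian whose width is [mass_sigma()] evaluated at that point's mass and
#' model charge. The result is the peak shape expected in a measured mass
#' distribution when capsid heterogeneity and resolution are both included.
#'
#' @param pmf A [capsid_mass_pmf()].
#' @param dna_mass Packaged DNA mass added to every composition, Da.
#' @param cfg An [instrument_config()].
#' @param cm A [charge_model()].
#' @param grid Optional mass grid (Da). Must cover the shifted support plus
#'   5 total standard deviations on each side, else an error is raised.
#' @param n_grid Grid size when `grid` is NULL. Default 2001.
#' @return An object of class `peak_shape`: list with `mass` (grid),
#'   `density` (normalized to unit integral), and grid-computed `mean` and
#'   `sd`.
#' @export
expected_peak_shape <- function(pmf, dna_mass = 0, cfg = instrument_config(),
                                cm = charge_model(), grid = NULL,
                                n_grid = 2001L) {
  stopifnot(inherits(pmf, "capsid_mass_pmf"),
            inherits(cfg, "instrument_config"),
            inherits(cm, "charge_model"))
  assert_scalar_number(dna_mass, "dna_mass", lower = 0)

  m <- pmf$support$mass + dna_mass
  p <- pmf$support$prob
  z <- mean_charge(m, cm)
  s <- mass_sigma(m, z, cfg)
  s <- pmax(s, .Machine$double.eps)

  # total sd of the mixture: heterogeneity variance + mean instrument variance
  mu_m <- sum(p * m)
  sd_tot <- sqrt(sum(p * m^2) - mu_m^2 + sum(p * s^2))
  lo_req <- min(m) - 5 * sd_tot
  hi_req <- max(m) + 5 * sd_tot
  if (is.null(grid)) {
    grid <- seq(lo_req, hi_req, length.out = n_grid)
  } else {
    assert_numeric_vec(grid, "grid")
    if (min(grid) > lo_req || max(grid) < hi_req)
      stop("grid too narrow: must cover the support +/- 5 total sd",
           call. = FALSE)
  }

  dens <- rowSums(vapply(seq_along(m), function(k)
    p[k] * stats::dnorm(grid, m[k], s[k]), numeric(length(grid))))
  # trapezoid normalization and moments
  w <- diff(grid)
  trap <- function(f) sum(w * (f[-1] + f[-length(f)]) / 2)
  area <- trap(dens)
  dens <- dens / area
  mu <- trap(dens * grid)
  va <- trap(dens * (grid - mu)^2)
  structure(list(mass = grid, density = dens, mean = mu, sd = sqrt(va)),
            class = "peak_shape")
}

#' @export
print.peak_shape <- function(x, ...) {
  cat(sprintf("Peak shape on %d-point grid: mean %.4f MDa, sd %.1f kDa\n",
              length(x$mass), x$mean / 1e6, x$sd / 1e3))
  invisible(x)
}
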