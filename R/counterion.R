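#' Counterion mass-balance parameters
#'
#' The mass-balance model for the systematic excess of measured genome
#' masses over sequence masses. The capsid interior carries `i` basic sites;
#' in the empty particle each is neutralized by an anion of mean mass
#' `m_minus`. A packaged genome of `j` nucleotides (mean ionized nucleotide
#' mass `m_N`) displaces those anions, and every phosphate charge not
#' neutralized by a basic site carries a cation of mean mass `m_plus`
#' (contributing `m_plus / valence` per nucleotide charge for multivalent
#' cations).
#'
#' @param M Bare capsid mass in Da (without counterions).
#' @param i Number of internal basic sites.
#' @param j Number of genome nucleotides.
#' @param m_N Mean ionized nucleotide mass, Da. Default
#'   [mean_ionized_nucleotide_mass()].
#' @param m_plus Mean cation mass, Da.
#' @param m_minus Mean anion mass, Da. Default acetate (59.04).
#' @param valence Cation valence, 1 or 2.
#' @return An object of class `counterion_params`.
#' @export
counterion_params <- function(M, i, j, m_N = mean_ionized_nucleotide_mass(),
                              m_plus, m_minus = ACETATE_MASS, valence = 1) {
  assert_scalar_number(M, "M", lower = 0)
  assert_scalar_number(i, "i", lower = 0)
  assert_scalar_number(j, "j", lower = 0)
  assert_scalar_number(m_N, "m_N", lower = 0, strict = TRUE)
  assert_scalar_number(m_plus, "m_plus", lower = 0)
  assert_scalar_number(m_minus, "m_minus", lower = 0)
  if (!valence %in% c(1, 2))
    stop("`valence` must be 1 or 2", call. = FALSE)
  structure(list(M = M, i = i, j = j, m_N = m_N, m_plus = m_plus,
                 m_minus = m_minus, valence = valence),
            class = "counterion_params")
}

#' Empty-particle mass under the mass-balance model
#'
#' `M_E = M + i * m_minus`: the bare capsid plus one anion per internal
#' basic site.
#'
#' @param p A [counterion_params()].
#' @return Mass in Da.
#' @export
empty_particle_mass <- function(p) {
  stopifnot(inherits(p, "counterion_params"))
  p$M + p$i * p$m_minus
}

#' Full-particle mass under the mass-balance model
#'
#' `M_F = M + j * m_N + (j - i) * m_plus_eff` where
#' `m_plus_eff = m_plus / valence` is the cation mass per neutralized
#' nucleotide charge.
#'
#' @inheritParams empty_particle_mass
#' @return Mass in Da.
#' @export
full_particle_mass <- function(p) {
  stopifnot(inherits(p, "counterion_params"))
  m_eff <- p$m_plus / p$valence
  p$M + p$j * p$m_N + (p$j - p$i) * m_eff
}

#' Predicted full-minus-empty mass difference
#'
#' The difference form of the mass balance:
#' \deqn{M_F - M_E = (1 + m^+_{eff}/m_N)(j\, m_N) - i\,(m^+_{eff} + m^-)}
#' which is algebraically identical to [full_particle_mass()] minus
#' [empty_particle_mass()]. Plotted against the genome sequence mass
#' \eqn{j\, m_N}, the model is a line with slope \eqn{1 + m^+_{eff}/m_N} and
#' intercept \eqn{-i\,(m^+_{eff} + m^-)}.
#'
#' @inheritParams empty_particle_mass
#' @return Mass difference in Da.
#' @export
predicted_mass_difference <- function(p) {
  stopifnot(inherits(p, "counterion_params"))
  m_eff <- p$m_plus / p$valence
  (1 + m_eff / p$m_N) * (p$j * p$m_N) - p$i * (m_eff + p$m_minus)
}

#' Expected slope of measured vs sequence genome mass
#'
#' `1 + (m_plus / valence) / m_N`: e.g. 1.075 if every phosphate carries
#' Na+, 1.059 for ammonium, 1.039 for Mg2+ (one cation per two charges),
#' and 1.003 for H+ (unionized).
#'
#' @param m_plus Cation mass in Da.
#' @param valence Cation valence (1 or 2).
#' @param m_N Mean ionized nucleotide mass in Da.
#' @return Dimensionless slope.
#' @examples
#' expected_slope(22.99)              # Na+,  1.075
#' expected_slope(24.305, valence = 2)  # Mg2+, 1.039
#' @export
expected_slope <- function(m_plus, valence = 1,
                           m_N = mean_ionized_nucleotide_mass()) {
  assert_scalar_number(m_plus, "m_plus", lower = 0)
  assert_scalar_number(m_N, "m_N", lower = 0, strict = TRUE)
  if (!valence %in% c(1, 2))
    stop("`valence` must be 1 or 2", call. = FALSE)
  1 + (m_plus / valence) / m_N
}

#' Least-squares fit of measured genome mass vs sequence mass
#'
#' Ordinary least squares of the measured full-minus-empty mass differences
#' on the genome sequence masses. Under the mass-balance model the slope
#' reflects the cation mass per nucleotide and the (negative) intercept the
#' number of internal basic sites.
#'
#' @param points A data frame with columns `sequence_mass` and
#'   `measured_difference` (Da), or the two vectors given separately.
#' @param measured_difference Optional vector when `points` is a vector of
#'   sequence masses.
#' @return An object of class `counterion_fit`: list with `slope`,
#'   `intercept` (Da), `r_squared`, `n`, and the input `points`.
#' @export
fit_counterion_model <- function(points, measured_difference = NULL) {
  if (!is.null(measured_difference))
    points <- data.frame(sequence_mass = points,
                         measured_difference = measured_difference)
  if (!is.data.frame(points) ||
      !all(c("sequence_mass", "measured_difference") %in% names(points)))
    stop("`points` needs columns sequence_mass and measured_difference",
         call. = FALSE)
  points <- points[stats::complete.cases(
    points[c("sequence_mass", "measured_difference")]), , drop = FALSE]
  if (nrow(points) < 2L)
    stop("at least 2 points are required", call. = FALSE)
  if (length(unique(points$sequence_mass)) < 2L)
    stop("sequence masses are all identical; slope is not identifiable",
         call. = FALSE)
  fit <- stats::lm(measured_difference ~ sequence_mass, data = points)
  # R^2 computed directly (summary.lm warns on noise-free data)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((points$measured_difference -
                mean(points$measured_difference))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (tss == 0) 1 else 1 - rss / tss,
                 n = nrow(points),
                 points = points),
            class = "counterion_fit")
}

#' @export
print.counterion_fit <- function(x, ...) {
  cat(sprintf(
    "Counterion fit (n = %d): slope %.4f, intercept %.4f MDa, R^2 %.4f\n",
    x$n, x$slope, x$intercept / 1e6, x$r_squared))
  invisible(x)
}

#' Physical interpretation of a counterion fit
#'
#' Converts the fitted line back to model quantities: the effective cation
#' mass per nucleotide `m_plus_eff = (slope - 1) * m_N`, and, for an assumed
#' cation/anion pair, the implied number of internal basic sites
#' `i_total = -intercept / (m_plus_assumed + m_minus_assumed)` and its
#' per-protein value. A positive intercept gives a (flagged) negative site
#' count rather than an error.
#'
#' @param fit A [fit_counterion_model()] result, or any list with `slope`
#'   and `intercept` fields.
#' @param m_N Mean ionized nucleotide mass, Da.
#' @param m_plus_assumed Assumed cation mass, Da. Default ammonium
#'   (electrospray buffer).
#' @param m_minus_assumed Assumed anion mass, Da. Default acetate.
#' @param n_proteins Number of capsid proteins. Default 60.
#' @return A list with `m_plus_eff` (Da), `i_total`, `i_per_protein`, and a
#'   logical `negative_sites` warning flag.
#' @examples
#' interpret_fit(list(slope = 1.041, intercept = -0.016e6))
#' @export
interpret_fit <- function(fit, m_N = mean_ionized_nucleotide_mass(),
                          m_plus_assumed = CATION_MASS[["NH4"]],
                          m_minus_assumed = ACETATE_MASS,
                          n_proteins = 60) {
  stopifnot(is.list(fit), !is.null(fit$slope), !is.null(fit$intercept))
  if (m_plus_assumed + m_minus_assumed <= 0)
    stop("m_plus_assumed + m_minus_assumed must be > 0", call. = FALSE)
  m_plus_eff <- (fit$slope - 1) * m_N
  i_total <- -fit$intercept / (m_plus_assumed + m_minus_assumed)
  neg <- i_total < 0
  if (neg)
    warning("positive intercept implies a negative basic-site count",
            call. = FALSE)
  list(m_plus_eff = m_plus_eff, i_total = i_total,
       i_per_protein = i_total / n_proteins, negative_sites = neg)
}
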