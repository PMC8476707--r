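#' VP1/VP2/VP3 capsid stoichiometry
#'
#' An AAV capsid is built from `n_subunits` copies of three capsid proteins
#' drawn (per capsid) from a fixed incorporation ratio, so the per-capsid
#' copy numbers follow a multinomial distribution and the capsid mass is
#' heterogeneous even for a chemically pure sample.
#'
#' @param vp_masses Average sequence masses of VP1, VP2, VP3 in Da.
#'   Defaults to the AAV8 values (81,667 / 66,692 / 59,805 Da).
#' @param ratio Nonnegative incorporation weights for VP1:VP2:VP3; they are
#'   normalized internally to probabilities. Default `c(1, 1, 10)`.
#' @param n_subunits Number of capsid proteins per particle (default 60).
#' @return An object of class `vp_stoichiometry` with fields `vp_masses`,
#'   `ratio`, `p` (normalized probabilities) and `n_subunits`.
#' @examples
#' stoich <- vp_stoichiometry()
#' mean_capsid_mass(stoich) / 1e6  # ~3.732 MDa
#' @export
vp_stoichiometry <- function(vp_masses = AAV8_VP_MASSES,
                             ratio = AAV8_VP_RATIO,
                             n_subunits = AAV8_N_SUBUNITS) {
  assert_numeric_vec(vp_masses, "vp_masses", len = 3L, lower = 0, strict = TRUE)
  assert_numeric_vec(ratio, "ratio", len = 3L, lower = 0)
  if (sum(ratio) <= 0)
    stop("`ratio` must have positive sum", call. = FALSE)
  n_subunits <- assert_count(n_subunits, "n_subunits", lower = 1L)
  structure(
    list(vp_masses = unname(as.numeric(vp_masses)),
         ratio = unname(as.numeric(ratio)),
         p = unname(ratio / sum(ratio)),
         n_subunits = n_subunits),
    class = "vp_stoichiometry")
}

#' @export
print.vp_stoichiometry <- function(x, ...) {
  cat(sprintf("VP stoichiometry: %d subunits, ratio %s\n", x$n_subunits,
              paste(format(x$ratio), collapse = ":")))
  cat(sprintf("  VP masses (Da): %s\n",
              paste(format(x$vp_masses, big.mark = ","), collapse = " / ")))
  cat(sprintf("  mean capsid mass: %.0f Da (%.3f MDa), sd %.1f kDa\n",
              mean_capsid_mass(x), mean_capsid_mass(x) / 1e6,
              capsid_mass_moments(x)$sd / 1e3))
  invisible(x)
}

#' Expected capsid mass
#'
#' Mean of the multinomial capsid mass distribution:
#' \eqn{n \sum_i p_i m_i}.
#'
#' @param stoich A [vp_stoichiometry()] object.
#' @return Mass in Da.
#' @examples
#' mean_capsid_mass(vp_stoichiometry())  # 3,732,045 Da
#' @export
mean_capsid_mass <- function(stoich) {
  stopifnot(inherits(stoich, "vp_stoichiometry"))
  stoich$n_subunits * sum(stoich$p * stoich$vp_masses)
}

#' Closed-form moments of the capsid mass distribution
#'
#' For a multinomial draw of `n` subunits with probabilities \eqn{p_i} and
#' subunit masses \eqn{m_i}, the capsid mass is a sum of `n` iid subunit
#' masses, so mean \eqn{= n\sum p_i m_i} and variance
#' \eqn{= n(\sum p_i m_i^2 - (\sum p_i m_i)^2)}.
#'
#' @inheritParams mean_capsid_mass
#' @return A list with `mean` and `sd`, both in Da.
#' @export
capsid_mass_moments <- function(stoich) {
  stopifnot(inherits(stoich, "vp_stoichiometry"))
  mu1 <- sum(stoich$p * stoich$vp_masses)
  v1 <- sum(stoich$p * stoich$vp_masses^2) - mu1^2
  list(mean = stoich$n_subunits * mu1,
       sd = sqrt(stoich$n_subunits * max(v1, 0)))
}

#' Exact capsid mass distribution
#'
#' Enumerates every composition \eqn{(n_1, n_2, n_3)} with
#' \eqn{n_1+n_2+n_3 = n} together with its multinomial probability and mass
#' \eqn{\sum_i n_i m_i}. At the default 60 subunits there are
#' \eqn{\binom{62}{2} = 1891} compositions, so exact enumeration is cheap and
#' is the default. Compositions that happen to share a mass are kept as
#' distinct support points (mass collisions are accidental); merging happens
#' only when a spectrum is histogrammed.
#'
#' @inheritParams mean_capsid_mass
#' @param max_states Guard on the enumeration size (default `1e4`
#'   compositions). Exceeding it raises an error suggesting
#'   [capsid_mass_moments()] or `method = "normal"`.
#' @param method `"exact"` (default) enumerates the multinomial support;
#'   `"normal"` returns a discretized normal approximation with the
#'   closed-form moments, for subunit counts too large to enumerate.
#' @param n_grid Number of grid points for `method = "normal"`.
#' @return An object of class `capsid_mass_pmf`: a list with `support` (a
#'   data frame with columns `n1, n2, n3, mass, prob`), `mean`, `sd`, and the
#'   generating `stoich`.
#' @examples
#' pmf <- capsid_mass_pmf(vp_stoichiometry())
#' nrow(pmf$support)   # 1891
#' sum(pmf$support$prob)
#' @export
capsid_mass_pmf <- function(stoich, max_states = 1e4,
                            method = c("exact", "normal"), n_grid = 512L) {
  stopifnot(inherits(stoich, "vp_stoichiometry"))
  method <- match.arg(method)
  n <- stoich$n_subunits
  mom <- capsid_mass_moments(stoich)

  if (method == "normal") {
    lo <- mom$mean - 6 * mom$sd
    hi <- mom$mean + 6 * mom$sd
    if (mom$sd == 0) { lo <- mom$mean - 1; hi <- mom$mean + 1 }
    grid <- seq(lo, hi, length.out = n_grid)
    pr <- stats::dnorm(grid, mom$mean, max(mom$sd, .Machine$double.eps))
    pr <- pr / sum(pr)
    support <- data.frame(n1 = NA_real_, n2 = NA_real_, n3 = NA_real_,
                          mass = grid, prob = pr)
  } else {
    n_states <- choose(n + 2, 2)
    if (n_states > max_states)
      stop(sprintf(paste0(
        "exact enumeration would need %d compositions (> max_states = %g); ",
        "use capsid_mass_moments() or method = \"normal\""),
        n_states, max_states), call. = FALSE)
    n1 <- rep(0:n, times = (n + 1):1)
    n2 <- sequence((n + 1):1) - 1L
    n3 <- n - n1 - n2
    # multinomial log-probabilities; 0*log(0) handled as 0
    lp <- lgamma(n + 1) - lgamma(n1 + 1) - lgamma(n2 + 1) - lgamma(n3 + 1)
    for (i in 1:3) {
      ni <- list(n1, n2, n3)[[i]]
      term <- ifelse(ni == 0, 0, ni * log(stoich$p[i]))
      lp <- lp + term
    }
    pr <- exp(lp)
    mass <- n1 * stoich$vp_masses[1] + n2 * stoich$vp_masses[2] +
      n3 * stoich$vp_masses[3]
    support <- data.frame(n1 = n1, n2 = n2, n3 = n3, mass = mass, prob = pr)
  }

  structure(list(support = support, mean = mom$mean, sd = mom$sd,
                 stoich = stoich, method = method),
            class = "capsid_mass_pmf")
}

#' @export
print.capsid_mass_pmf <- function(x, ...) {
  cat(sprintf("Capsid mass pmf (%s): %d support points\n", x$method,
              nrow(x$support)))
  cat(sprintf("  mean %.0f Da, sd %.1f kDa\n", x$mean, x$sd / 1e3))
  invisible(x)
}

# Sample per-capsid masses under the multinomial model. Internal: the
# simulator's capsid draw.
sample_capsid_mass <- function(n, stoich) {
  if (n == 0L) return(numeric(0))
  counts <- stats::rmultinom(n, size = stoich$n_subunits, prob = stoich$p)
  as.numeric(colSums(counts * stoich$vp_masses))
}
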