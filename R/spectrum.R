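accepted_events <- function(events) {
  stopifnot(inherits(events, "ion_events"))
  events[!(events$multiple_ion | events$short_trap), , drop = FALSE]
}

#' Bin single-ion events into a mass spectrum
#'
#' Flagged events (multi-ion traps, short traps) are discarded and counted
#' in `n_discarded`; the remaining masses are histogrammed on uniform
#' half-open bins `[left, right)` whose left edges are anchored at 0 Da.
#'
#' @param events An `ion_events` data frame.
#' @param cfg An [instrument_config()] supplying `bin_width`, or a numeric
#'   bin width in Da.
#' @return An object of class `mass_spectrum`: list with `bin_edges`,
#'   `bin_mid`, `counts`, `bin_width`, `n_accepted`, `n_discarded`.
#' @export
bin_events <- function(events, cfg = instrument_config()) {
  bw <- if (inherits(cfg, "instrument_config")) cfg$bin_width else cfg
  assert_scalar_number(bw, "bin_width", lower = 0, strict = TRUE)
  acc <- accepted_events(events)
  n_acc <- nrow(acc)
  n_disc <- nrow(events) - n_acc
  if (n_acc == 0L) {
    edges <- c(0, bw)
    counts <- 0L
  } else {
    m <- pmax(acc$mass, 0)
    hi <- (floor(max(m) / bw) + 1) * bw
    edges <- seq(0, hi, by = bw)
    # findInterval with default settings implements [left, right)
    counts <- tabulate(findInterval(m, edges), nbins = length(edges) - 1L)
  }
  structure(list(bin_edges = edges,
                 bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, bin_width = bw,
                 n_accepted = n_acc, n_discarded = n_disc),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf(
    "Mass spectrum: %d bins of %.0f kDa, %d accepted / %d discarded ions\n",
    length(x$counts), x$bin_width / 1e3, x$n_accepted, x$n_discarded))
  if (x$n_accepted > 0)
    cat(sprintf("  mode bin at %.3f MDa\n",
                x$bin_mid[which.max(x$counts)] / 1e6))
  invisible(x)
}

#' Write a spectrum as delimited text
#'
#' @param spectrum A [bin_events()] result.
#' @param path Output path; columns `bin_mid_Da`, `count`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  utils::write.table(
    data.frame(bin_mid_Da = spectrum$bin_mid, count = spectrum$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gaussian mixture fit of the ion mass distribution
#'
#' Fits a `k`-component Gaussian mixture to the accepted ion masses by
#' expectation-maximization, initialized at caller-supplied means (peak
#' positions are always approximately known here: expected empty / full /
#' capacity masses). Each component's mean observed charge is reported
#' alongside its mass parameters, so charge-versus-mass cluster structure
#' can be quantified from the same fit.
#'
#' @param events An `ion_events` data frame.
#' @param k Number of components (>= 1).
#' @param init_means Initial component means in Da (length `k`). Optionally
#'   named; names become component labels.
#' @param max_iter Maximum EM iterations. Default 500.
#' @param tol Termination tolerance on the mean per-ion log-likelihood
#'   change. Default 1e-8.
#' @return A `component_table` data frame with columns `label`, `mean`,
#'   `sd`, `fraction`, `mean_charge`, ordered by mean; attributes `loglik`,
#'   `n_iter`, `converged`.
#' @export
fit_components <- function(events, k, init_means, max_iter = 500L,
                           tol = 1e-8) {
  k <- assert_count(k, "k", lower = 1L)
  assert_numeric_vec(init_means, "init_means", len = k, lower = 0,
                     strict = TRUE)
  acc <- accepted_events(events)
  x <- acc$mass
  n <- length(x)
  if (n < 10L * k)
    stop(sprintf("need at least %d accepted events for k = %d (got %d)",
                 10L * k, k, n), call. = FALSE)

  labels <- names(init_means)
  if (is.null(labels)) labels <- paste0("comp", seq_len(k))
  mu <- as.numeric(init_means)
  # initialize by nearest-mean hard assignment
  assign0 <- apply(abs(outer(x, mu, "-")), 1L, which.min)
  sig <- vapply(seq_len(k), function(j) {
    xs <- x[assign0 == j]
    s <- if (length(xs) > 1L) stats::sd(xs) else NA_real_
    if (!is.finite(s) || s <= 0) diff(range(x)) / (6 * k) else s
  }, 0)
  sig <- pmax(sig, 1)
  w <- tabulate(assign0, nbins = k) / n
  w <- pmax(w, 1e-6); w <- w / sum(w)

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  resp <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sig[j], log = TRUE),
      numeric(n))
    m_row <- apply(logd, 1L, max)
    lse <- m_row + log(rowSums(exp(logd - m_row)))
    ll <- mean(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sig <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    sig <- pmax(sig, 1)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  mean_z <- colSums(resp * acc$z) / colSums(resp)
  ord <- order(mu)
  tab <- data.frame(label = labels[ord], mean = mu[ord], sd = sig[ord],
                    fraction = w[ord], mean_charge = mean_z[ord],
                    stringsAsFactors = FALSE)
  class(tab) <- c("component_table", "data.frame")
  attr(tab, "loglik") <- ll
  attr(tab, "n_iter") <- iter
  attr(tab, "converged") <- converged
  if (!converged)
    stop(errorCondition(
      sprintf("EM did not converge in %d iterations", max_iter),
      class = c("cdmsaav_em_not_converged", "error", "condition"),
      last_iterate = tab))
  tab
}

#' Classify ions into packaging states by mass windows
#'
#' Window-based assignment of every accepted ion to one of `empty`,
#' `partial`, `full_GOI`, `overfull` (headful / extra DNA), or `multimer`.
#' The empty and full windows are `n_sd * window_sd` around their centers;
#' masses between the windows are partial; masses above the full window up
#' to `multimer_min` are overfull; anything beyond is multimer. Masses
#' below the empty window are counted as empty. Ties at window boundaries
#' go to the lower-mass state.
#'
#' @param events An `ion_events` data frame.
#' @param empty_mass Expected empty-particle mass, Da.
#' @param goi_mass Genome (GOI) mass, Da; the full-particle center is
#'   `empty_mass + goi_mass`.
#' @param capacity_mass Packaging-capacity guide, Da. Default 5.33e6.
#' @param window_sd One standard deviation of a peak, Da (capsid
#'   heterogeneity plus instrument resolution).
#' @param n_sd Half-width of the empty/full windows in units of
#'   `window_sd`. Default 3.
#' @param multimer_min Lower mass bound for multimers, Da. Default midway
#'   between the capacity and twice the empty mass (dimer position).
#' @return A list with `fractions` (named, summing to 1), `counts`,
#'   `n_accepted`, and the window `bounds`.
#' @export
classify_packaging <- function(events, empty_mass, goi_mass,
                               capacity_mass = AAV8_CAPACITY_DA,
                               window_sd, n_sd = 3,
                               multimer_min = (capacity_mass +
                                                 2 * empty_mass) / 2) {
  assert_scalar_number(empty_mass, "empty_mass", lower = 0, strict = TRUE)
  assert_scalar_number(goi_mass, "goi_mass", lower = 0, strict = TRUE)
  assert_scalar_number(window_sd, "window_sd", lower = 0, strict = TRUE)
  assert_scalar_number(n_sd, "n_sd", lower = 0, strict = TRUE)
  full_mass <- empty_mass + goi_mass
  e_hi <- empty_mass + n_sd * window_sd
  f_lo <- full_mass - n_sd * window_sd
  f_hi <- full_mass + n_sd * window_sd
  if (e_hi >= f_lo)
    stop(paste0("empty and full windows overlap; reduce window_sd or n_sd ",
                "(empty upper edge exceeds full lower edge)"), call. = FALSE)
  if (f_hi >= multimer_min)
    stop("full window reaches multimer_min; thresholds inconsistent",
         call. = FALSE)
  acc <- accepted_events(events)
  states <- c("empty", "partial", "full_GOI", "overfull", "multimer")
  # right-closed breaks put boundary masses in the lower state
  lab <- cut(acc$mass, breaks = c(-Inf, e_hi, f_lo, f_hi, multimer_min, Inf),
             labels = states, right = TRUE)
  counts <- table(factor(lab, levels = states))
  n_acc <- nrow(acc)
  fractions <- if (n_acc > 0) as.numeric(counts) / n_acc
    else rep(0, length(states))
  names(fractions) <- states
  list(fractions = fractions,
       counts = stats::setNames(as.integer(counts), states),
       n_accepted = n_acc,
       bounds = c(empty_hi = e_hi, full_lo = f_lo, full_hi = f_hi,
                  multimer_min = multimer_min))
}

#' Genome mass from the full-minus-empty mass difference
#'
#' @param full_mean Measured mean mass of the full particle, Da.
#' @param empty_mean Measured mean mass of the empty particle, Da.
#' @return The difference in Da, with attribute `negative = TRUE` (and a
#'   warning) when the difference is negative.
#' @export
genome_mass_difference <- function(full_mean, empty_mean) {
  assert_scalar_number(full_mean, "full_mean", lower = 0)
  assert_scalar_number(empty_mean, "empty_mean", lower = 0)
  d <- full_mean - empty_mean
  if (d < 0) {
    warning("full mean is below empty mean; negative genome mass",
            call. = FALSE)
    attr(d, "negative") <- TRUE
  }
  d
}
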