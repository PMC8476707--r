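#' Packaging state of a particle species
#'
#' Describes the DNA content of one particle species in a simulated mixture:
#' \describe{
#'   \item{empty}{no genome-derived DNA (heterogeneous fragments may still be
#'     attached via the component's `extra_dna` settings).}
#'   \item{partial}{a random fraction of one genome copy, uniform on (0,1)
#'     by default or truncated-normal.}
#'   \item{full_GOI}{`genome_copies` complete copies of the genome of
#'     interest.}
#'   \item{headful}{DNA packaged to the capsid capacity: the total particle
#'     mass is drawn around `capacity` and the DNA mass is whatever fills
#'     the capsid.}
#'   \item{multimer}{DNA-free species whose order is set by the component's
#'     `multimer_order` (dimers/trimers of empty capsids).}
#' }
#'
#' @param kind One of `"empty"`, `"partial"`, `"full_GOI"`, `"headful"`,
#'   `"multimer"`.
#' @param goi_mass Sequence mass of the genome of interest, Da.
#' @param genome_copies Copies packaged for `full_GOI` (default 1).
#' @param capacity Headful total-particle mass center, Da. Default 5.33e6.
#' @param capacity_sd SD of the headful total mass, Da. Default 50 kDa.
#' @param partial_dist Distribution of the packaged fraction for `partial`:
#'   `"uniform"` (default) or `"truncnorm"`.
#' @param partial_mean,partial_sd Mean and SD of the packaged fraction for
#'   `partial_dist = "truncnorm"` (truncated to (0, 1)).
#' @return An object of class `packaging_state`.
#' @export
packaging_state <- function(kind = c("empty", "partial", "full_GOI",
                                     "headful", "multimer"),
                            goi_mass = 0, genome_copies = 1,
                            capacity = AAV8_CAPACITY_DA, capacity_sd = 5e4,
                            partial_dist = c("uniform", "truncnorm"),
                            partial_mean = 0.5, partial_sd = 0.25) {
  kind <- match.arg(kind)
  partial_dist <- match.arg(partial_dist)
  assert_scalar_number(goi_mass, "goi_mass", lower = 0)
  assert_numeric_vec(genome_copies, "genome_copies", len = 1L, lower = 0)
  assert_scalar_number(capacity, "capacity", lower = 0, strict = TRUE)
  assert_scalar_number(capacity_sd, "capacity_sd", lower = 0)
  if (kind %in% c("partial", "full_GOI") && goi_mass <= 0)
    stop(sprintf("kind '%s' requires a positive goi_mass", kind),
         call. = FALSE)
  structure(list(kind = kind, goi_mass = goi_mass,
                 genome_copies = genome_copies, capacity = capacity,
                 capacity_sd = capacity_sd, partial_dist = partial_dist,
                 partial_mean = partial_mean, partial_sd = partial_sd),
            class = "packaging_state")
}

#' One component of a simulated particle mixture
#'
#' @param label Component label carried through to simulated events.
#' @param state A [packaging_state()].
#' @param weight Mixture fraction; weights across a mixture must sum to 1.
#' @param stoich Capsid [vp_stoichiometry()] (default AAV8 1:1:10, 60-mer).
#' @param charge_shape_factor Per-species charge multiplier (>= 1); extended
#'   structures pick up more charge than a compact particle of equal mass.
#' @param extra_dna_mean,extra_dna_sd Mean and SD (Da) of co-packaged
#'   heterogeneous DNA-fragment mass, Gaussian truncated at 0.
#' @param multimer_order Integer >= 1; particle mass is this multiple of one
#'   capsid draw.
#' @return An object of class `mixture_component`.
#' @export
mixture_component <- function(label, state, weight = 1,
                              stoich = vp_stoichiometry(),
                              charge_shape_factor = 1,
                              extra_dna_mean = 0, extra_dna_sd = 0,
                              multimer_order = 1L) {
  stopifnot(inherits(state, "packaging_state"),
            inherits(stoich, "vp_stoichiometry"))
  assert_scalar_number(weight, "weight", lower = 0)
  assert_scalar_number(charge_shape_factor, "charge_shape_factor", lower = 1)
  assert_scalar_number(extra_dna_mean, "extra_dna_mean", lower = 0)
  assert_scalar_number(extra_dna_sd, "extra_dna_sd", lower = 0)
  multimer_order <- assert_count(multimer_order, "multimer_order", lower = 1L)
  structure(list(label = as.character(label), state = state, weight = weight,
                 stoich = stoich, charge_shape_factor = charge_shape_factor,
                 extra_dna_mean = extra_dna_mean, extra_dna_sd = extra_dna_sd,
                 multimer_order = multimer_order),
            class = "mixture_component")
}

check_mixture <- function(mixture) {
  if (inherits(mixture, "mixture_component")) mixture <- list(mixture)
  stopifnot(length(mixture) >= 1L,
            all(vapply(mixture, inherits, TRUE, "mixture_component")))
  w <- vapply(mixture, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-6)
    stop(sprintf("mixture weights must sum to 1 (got %.6f)", sum(w)),
         call. = FALSE)
  mixture
}

# per-ion sequence-derived DNA mass for one component (vectorized over n)
draw_dna_mass <- function(st, n, capsid_mass, dna_inflation, dna_offset) {
  if (n == 0L) return(numeric(0))
  seq_dna <- switch(st$kind,
    empty = ,
    multimer = rep(0, n),
    full_GOI = rep(st$genome_copies * st$goi_mass, n),
    partial = {
      frac <- if (st$partial_dist == "uniform") stats::runif(n)
        else pmin(pmax(stats::rnorm(n, st$partial_mean, st$partial_sd),
                       .Machine$double.eps), 1)
      frac * st$goi_mass
    },
    headful = NULL)
  if (st$kind == "headful") {
    # total particle mass pinned near capacity; DNA fills the capsid
    target <- stats::rnorm(n, st$capacity, st$capacity_sd)
    return(pmax(target - capsid_mass, 0))
  }
  # counterion inflation + basic-site offset apply to genome-derived DNA
  ifelse(seq_dna > 0, pmax(dna_inflation * seq_dna + dna_offset, 0), 0)
}

#' Simulate single-ion CDMS events
#'
#' Forward model for a trapped-ion experiment on a particle mixture. For
#' each ion: a component is drawn by weight; the capsid mass is a
#' multinomial composition draw (times `multimer_order`); genome-derived DNA
#' mass is added per the component's [packaging_state()], with counterion
#' uptake modeled by `dna_inflation` and `dna_offset`; a truncated-Gaussian
#' heterogeneous DNA fragment is added; the true charge follows
#' [mean_charge()] with the component's shape factor; the observed charge
#' gets Gaussian noise of RMSD [charge_sigma()] and the observed m/z gets
#' relative Gaussian noise `rel_sigma_mz`. Events are flagged as multi-ion
#' or short-trap with the configured probabilities (flagged events are
#' discarded by the analysis functions). Fully reproducible from `seed`.
#'
#' @param mixture A list of [mixture_component()]s (weights summing to 1).
#' @param cfg An [instrument_config()].
#' @param cm A [charge_model()].
#' @param n_ions Number of single-ion events to simulate.
#' @param seed Integer RNG seed (recorded as an attribute and in files
#'   written by [write_ion_events()]).
#' @param dna_inflation Multiplier on genome-derived DNA mass emulating
#'   counterions bound to the packaged genome. Default 1.041.
#' @param dna_offset Additive offset (Da) on genome-derived DNA mass
#'   emulating displacement of internal basic-site anions. Default -16,000.
#' @return An `ion_events` data frame with columns `mz` (Th), `z` (e,
#'   real-valued), `mass` (Da, = mz * z), `component`, and logical flags
#'   `multiple_ion`, `short_trap`.
#' @examples
#' mix <- list(mixture_component("empty", packaging_state("empty"), 1))
#' ev <- simulate_ion_events(mix, n_ions = 100, seed = 1)
#' mean(ev$mass) / 1e6
#' @export
simulate_ion_events <- function(mixture, cfg = instrument_config(),
                                cm = charge_model(), n_ions, seed,
                                dna_inflation = 1.041, dna_offset = -16000) {
  mixture <- check_mixture(mixture)
  stopifnot(inherits(cfg, "instrument_config"), inherits(cm, "charge_model"))
  n_ions <- assert_count(n_ions, "n_ions", lower = 0L)
  seed <- assert_count(seed, "seed")
  assert_scalar_number(dna_inflation, "dna_inflation", lower = 0)
  assert_scalar_number(dna_offset, "dna_offset", finite = TRUE)

  out <- data.frame(mz = numeric(n_ions), z = numeric(n_ions),
                    mass = numeric(n_ions),
                    component = character(n_ions),
                    multiple_ion = logical(n_ions),
                    short_trap = logical(n_ions))
  if (n_ions > 0L) {
    set.seed(seed)
    w <- vapply(mixture, `[[`, 0, "weight")
    idx <- sample.int(length(mixture), n_ions, replace = TRUE, prob = w)
    sz <- charge_sigma(cfg)
    for (ci in seq_along(mixture)) {
      comp <- mixture[[ci]]
      rows <- which(idx == ci)
      n_c <- length(rows)
      if (n_c == 0L) next
      capsid <- comp$multimer_order * sample_capsid_mass(n_c, comp$stoich)
      dna <- draw_dna_mass(comp$state, n_c, capsid, dna_inflation, dna_offset)
      extra <- if (comp$extra_dna_mean > 0 || comp$extra_dna_sd > 0)
        pmax(stats::rnorm(n_c, comp$extra_dna_mean, comp$extra_dna_sd), 0)
        else rep(0, n_c)
      true_mass <- capsid + dna + extra
      true_z <- mean_charge(true_mass, cm,
                            shape_factor = comp$charge_shape_factor)
      obs_z <- true_z + stats::rnorm(n_c, 0, sz)
      obs_mz <- (true_mass / true_z) *
        (1 + stats::rnorm(n_c, 0, cfg$rel_sigma_mz))
      out$mz[rows] <- obs_mz
      out$z[rows] <- obs_z
      out$mass[rows] <- obs_mz * obs_z
      out$component[rows] <- comp$label
      out$multiple_ion[rows] <-
        stats::runif(n_c) < cfg$multiple_ion_rate
      out$short_trap[rows] <- stats::runif(n_c) < cfg$short_trap_rate
    }
  }
  attr(out, "seed") <- seed
  class(out) <- c("ion_events", "data.frame")
  out
}

#' Rescale co-packaged DNA fragments after incubation
#'
#' Emulates temperature cycling, which removes part of the loosely bound
#' heterogeneous DNA: every component's `extra_dna` mean and SD are scaled
#' by `1 - removal_fraction`; all other fields are unchanged.
#'
#' @param mixture A list of [mixture_component()]s.
#' @param removal_fraction Fraction of extra DNA removed, in \[0, 1\].
#' @return The rescaled mixture.
#' @export
apply_incubation <- function(mixture, removal_fraction) {
  single <- inherits(mixture, "mixture_component")
  mixture <- check_mixture(mixture)
  assert_scalar_number(removal_fraction, "removal_fraction", lower = 0)
  if (removal_fraction > 1)
    stop("`removal_fraction` must be in [0, 1]", call. = FALSE)
  out <- lapply(mixture, function(comp) {
    comp$extra_dna_mean <- comp$extra_dna_mean * (1 - removal_fraction)
    comp$extra_dna_sd <- comp$extra_dna_sd * (1 - removal_fraction)
    comp
  })
  if (single) out[[1]] else out
}

#' Write / read single-ion event tables
#'
#' Events are stored as tab-separated text with a `#`-prefixed header
#' recording the seed, so a run can be reproduced from its output alone.
#'
#' @param events An `ion_events` data frame.
#' @param path Output file path.
#' @return `write_ion_events` returns `path` invisibly; `read_ion_events`
#'   returns an `ion_events` data frame with the seed attribute restored
#'   (NA if absent).
#' @export
write_ion_events <- function(events, path) {
  stopifnot(inherits(events, "ion_events"))
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(events, "seed")
  writeLines(c(sprintf("# cdmsaav ion events v1"),
               sprintf("# seed: %s", if (is.null(seed)) "NA" else seed)),
             con)
  df <- as.data.frame(events)
  names(df) <- c("mz_Th", "z_e", "mass_Da", "component", "multiple_ion",
                 "short_trap")
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ion_events
#' @export
read_ion_events <- function(path) {
  head_lines <- readLines(path, n = 5L)
  seed_line <- grep("^# seed:", head_lines, value = TRUE)
  seed <- if (length(seed_line))
    suppressWarnings(as.integer(sub("^# seed:\\s*", "", seed_line[1])))
    else NA_integer_
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("mz_Th", "z_e", "mass_Da") %in% names(df)))
  out <- data.frame(mz = df$mz_Th, z = df$z_e, mass = df$mass_Da,
                    component = if ("component" %in% names(df))
                      df$component else NA_character_,
                    multiple_ion = if ("multiple_ion" %in% names(df))
                      as.logical(df$multiple_ion) else FALSE,
                    short_trap = if ("short_trap" %in% names(df))
                      as.logical(df$short_trap) else FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("ion_events", "data.frame")
  out
}
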