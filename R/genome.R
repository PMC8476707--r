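#' ssDNA genome mass from base count
#'
#' AAV packages single-stranded DNA with plus and minus strands packaged at
#' equal frequency, so the relevant genome mass is the strand average for an
#' ionized (deprotonated phosphate) backbone. In length mode the mass is
#' simply `n_bases * per_base_mass`.
#'
#' The default per-base constant (307.97 Da) is back-computed from the
#' printed expected masses of the eight reference constructs; the
#' residue-table value at 50% GC is [mean_ionized_nucleotide_mass()]
#' (307.94 Da). The two differ by < 0.03 Da/base.
#'
#' @param n_bases Genome length in nucleotides, including the ITRs.
#' @param per_base_mass Mass per ionized nucleotide in Da.
#' @return Mass in Da.
#' @examples
#' genome_mass_from_length(2219) / 1e6  # 0.683 MDa
#' genome_mass_from_length(4844) / 1e6  # 1.492 MDa
#' @export
genome_mass_from_length <- function(n_bases,
                                    per_base_mass = DEFAULT_PER_BASE_MASS) {
  assert_numeric_vec(n_bases, "n_bases", lower = 0)
  assert_scalar_number(per_base_mass, "per_base_mass", lower = 0,
                       strict = TRUE)
  n_bases * per_base_mass
}

#' ssDNA genome mass from sequence
#'
#' Computes the average masses of the ionized sense strand and its reverse
#' complement from per-residue average masses, with one proton removed per
#' nucleotide (ionized phosphate) and one terminal water per strand, and
#' returns both strand masses and their mean. `N` bases contribute the
#' four-base mean residue mass.
#'
#' @param seq A nucleotide string (sense strand, alphabet `A C G T N`,
#'   case-insensitive) or a [Biostrings::DNAString].
#' @return A list with `plus`, `minus` and `average` masses in Da.
#' @examples
#' genome_mass_from_sequence("ACGTACGTAC")$average
#' @export
genome_mass_from_sequence <- function(seq) {
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single nucleotide string", call. = FALSE)
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("invalid nucleotide '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  if (length(chars) == 0L)
    return(list(plus = 0, minus = 0, average = 0))

  res <- c(DNA_RESIDUE_MASS, N = mean(DNA_RESIDUE_MASS))
  strand_mass <- function(v)
    sum(res[v]) - length(v) * PROTON_MASS + WATER_MASS
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  minus_chars <- rev(unname(comp[chars]))
  plus <- strand_mass(chars)
  minus <- strand_mass(minus_chars)
  list(plus = plus, minus = minus, average = (plus + minus) / 2)
}

#' Expected mass of a vector particle
#'
#' Empty-capsid mass plus `copies` packaged genomes, e.g. 3.732 MDa + 0.683
#' MDa = 4.415 MDa for a single 2,219-base genome.
#'
#' @param empty_mass Empty capsid mass in Da.
#' @param genome_mass Genome mass in Da.
#' @param copies Number of packaged genome copies (may be fractional for
#'   partially filled particles).
#' @return Mass in Da.
#' @export
expected_vector_mass <- function(empty_mass, genome_mass, copies = 1) {
  assert_scalar_number(empty_mass, "empty_mass", lower = 0)
  assert_scalar_number(genome_mass, "genome_mass", lower = 0)
  assert_numeric_vec(copies, "copies", lower = 0)
  empty_mass + copies * genome_mass
}

#' Named genome construct
#'
#' A genome of interest (GOI) defined by its base count (including ITRs)
#' and/or its sense-strand sequence. When both are given they must agree;
#' when only the sequence is given the length is derived from it.
#'
#' @param name Construct label (e.g. `"CMV-GFP"`).
#' @param n_bases Number of nucleotides including the ITRs.
#' @param sequence Optional sense-strand nucleotide string.
#' @param per_base_mass Per-base mass used in length mode, Da.
#' @return An object of class `genome_construct` with a `mass` field:
#'   the strand-averaged sequence mass when a sequence is supplied,
#'   otherwise `n_bases * per_base_mass`.
#' @export
genome_construct <- function(name, n_bases = NULL, sequence = NULL,
                             per_base_mass = DEFAULT_PER_BASE_MASS) {
  if (is.null(n_bases) && is.null(sequence))
    stop("supply `n_bases` and/or `sequence`", call. = FALSE)
  if (!is.null(sequence)) {
    if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
    if (is.null(n_bases)) n_bases <- nchar(sequence)
    if (nchar(sequence) != n_bases)
      stop(sprintf("sequence length (%d) does not match n_bases (%d)",
                   nchar(sequence), n_bases), call. = FALSE)
  }
  n_bases <- assert_count(n_bases, "n_bases", lower = 0L)
  mass <- if (!is.null(sequence)) genome_mass_from_sequence(sequence)$average
          else genome_mass_from_length(n_bases, per_base_mass)
  structure(list(name = as.character(name), n_bases = n_bases,
                 sequence = sequence, per_base_mass = per_base_mass,
                 mass = mass),
            class = "genome_construct")
}

#' @export
print.genome_construct <- function(x, ...) {
  cat(sprintf("Genome construct '%s': %s bases, %.3f MDa (%s mode)\n",
              x$name, format(x$n_bases, big.mark = ","), x$mass / 1e6,
              if (is.null(x$sequence)) "length" else "sequence"))
  invisible(x)
}

#' Read genome constructs from a FASTA file
#'
#' Each record becomes a [genome_construct()] in sequence mode, named by its
#' FASTA header.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A named list of `genome_construct` objects.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i)
    genome_construct(names(seqs)[i], sequence = as.character(seqs[[i]])))
  names(out) <- names(seqs)
  out
}

#' Reference AAV8 construct table
#'
#' The eight vector genomes (promoter-transgene constructs, lengths
#' including ITRs) studied with the AAV8 capsid, plus the empty capsid row,
#' with their expected strand-averaged masses in MDa.
#'
#' @param path Optional path to an alternative tab-separated table with
#'   columns `name`, `n_bases`, `expected_mass_MDa`.
#' @return A data frame with columns `name`, `n_bases`, `expected_mass_MDa`
#'   and `mass_da` (the package-computed mass from `n_bases`).
#' @examples
#' head(aav8_constructs())
#' @export
aav8_constructs <- function(path = system.file("extdata",
                                               "aav8_constructs.tsv",
                                               package = "cdmsaav")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "n_bases", "expected_mass_MDa") %in% names(tab)))
  tab$mass_da <- genome_mass_from_length(tab$n_bases)
  tab
}
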