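Package: cdmsaav
Title: Charge Detection Mass Spectrometry Models for AAV Genome Packaging
Version: 0.1.0
Authors@R: person("Packaging", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models and simulation tools for characterizing recombinant
    adeno-associated virus (rAAV) vectors by charge detection mass
    spectrometry (CDMS). Provides the multinomial VP1/VP2/VP3 capsid mass
    distribution, single-stranded DNA genome masses averaged over ionized
    plus and minus strands, an instrument resolution model for single-ion
    trapping, a forward simulator of single-ion events from mixtures of
    empty, partially filled, full, headful and multimeric particles,
    spectrum binning and Gaussian mixture quantitation of packaging-state
    fractions, and a counterion mass-balance model that relates measured
    full-minus-empty mass differences to genome sequence mass, counterion
    masses and internal basic sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
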