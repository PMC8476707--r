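---
title: "Models and methods: CDMS characterization of AAV genome packaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CDMS characterization of AAV genome packaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmsaav)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, every tunable parameter that matters, what
the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or the acceptance script does not itself
compute.

# The measurement

In charge detection mass spectrometry a single electrosprayed ion
oscillates in an electrostatic linear ion trap; the oscillation frequency
gives m/z and the induced signal gives the charge z, so each trapped ion
yields a mass m = (m/z) × z. Thousands of such per-ion masses, binned,
give a mass distribution for samples too heterogeneous for charge-state
resolved native MS — exactly the situation for rAAV lots, which mix empty,
partially filled, full, overfull and multimeric particles. This package
starts downstream of the trap electronics: its unit of data is the
(m/z, z) pair, and everything upstream (trajectory simulation, FFT signal
processing, ion optics) is out of scope.

# Capsid mass model

The capsid is a 60-mer of VP1, VP2 and VP3 sharing a common C-terminal
sequence. Subunit identities are drawn independently at assembly, so the
per-capsid copy numbers (n1, n2, n3) are multinomial with probabilities
from the bulk incorporation ratio (1:1:10 for the default, HEK293-style
stoichiometry). The capsid mass is then a sum of 60 iid subunit masses:

- mean `n Σ p_i m_i` = 3,732,045 Da for AAV8;
- sd `sqrt(n (Σ p_i m_i² − (Σ p_i m_i)²))` ≈ 47.8 kDa.

`capsid_mass_pmf()` enumerates the full support — choose(62, 2) = 1,891
compositions at n = 60 — exactly; exactness is cheap at this size, so
enumeration is the default and a discretized-normal approximation sits
behind an explicit `method = "normal"` flag, with a guard (default 10⁴
states) that points there when enumeration would blow up. Compositions
that happen to share a mass are kept as distinct support points: collisions
are accidental, and merging is a histogramming concern, not a model one.

Assumptions worth stating: subunit draws are independent (no cooperative
assembly), the ratio is the same for empty and full particles, and
post-translational modifications or VP truncations are representable only
by supplying alternative subunit masses — there is no PTM model. Insect
cell-derived capsids likely deviate from 1:1:10, but no alternative ratio
is established, so 1:1:10 is the only built-in default.

# Genome mass model

AAV packages plus and minus ssDNA strands with equal frequency, so the
relevant genome mass is the two-strand average for an ionized
(deprotonated-phosphate) backbone. Two routes:

- **Length mode** (canonical for construct tables): `n_bases ×
  per_base_mass`.
- **Sequence mode**: per-residue average-mass sums for the sense strand
  and its reverse complement, minus one proton per nucleotide, plus one
  terminal water per strand; `N` contributes the four-base mean. The
  strand average is invariant under reverse complement, and base
  composition moves the average by well under 0.5 Da/base, which is why a
  single per-base constant suffices at MDa reporting precision. Terminal
  water (≤ 18 Da/strand) is ignored in length mode — far below reporting
  precision.

**The per-base constant.** Two defensible constants exist and the package
uses both, each where it belongs:

- `mean_ionized_nucleotide_mass()` = mean of the four deoxynucleotide
  chain-residue masses − one proton = **307.943 Da**. This is the m_N of
  the counterion model: a chemical constant at 50% GC, independent of any
  particular construct set.
- `DEFAULT_PER_BASE_MASS` = **307.97 Da** for length-mode genome masses.
  The reference construct table's printed expected masses (3-decimal MDa)
  are only all reproduced by constants in [307.945, 307.980) — the
  residue-table value misses one row (2,895 bases: 0.8915 MDa needed,
  0.8915 × 10⁶/2,895 = 307.945) by ~14 Da — and least-squares
  back-computation from the printed rows gives 307.974. The gap is real
  chemistry, not rounding: the constructs' promoters and transgenes are
  slightly GC-rich, and GC base pairs average ~0.5 Da more per base than
  AT. The table was evidently computed from actual sequences; lacking
  those sequences, 307.97 is the faithful effective constant.

Both constants give identical counterion slopes at the 3-decimal precision
they are quoted at, so nothing downstream hinges on the distinction; it is
configurable everywhere it appears.

# Instrument model

Three parameters govern resolution:

| parameter | default | units | basis |
|---|---|---|---|
| `trap_time` | 100 | ms | reference trapping time |
| `sigma_z_ref` | 1 | e | charge RMSD at 100 ms; scales as (trap time)^−½, first-order independent of z |
| `rel_sigma_mz` | 0.001 | — | m/z error; never quantified for this instrument, chosen subdominant to the charge term and configurable |
| `bin_width` | 20,000 | Da | histogram convention |
| `multiple_ion_rate` | 0.05 | — | fraction of multi-ion trap events (flagged, discarded) |
| `short_trap_rate` | 0.02 | — | fraction of incompletely trapped ions (flagged, discarded) |

Mass error per ion is the quadrature sum of `(m/z)·σ_z` and
`m·rel_sigma_mz`; at 3.7 MDa and 150 e with the defaults the charge term
is ≈ 24.7 kDa and dominates.

**Charge model.** The mean charge is `z(m) = s · z_ref (m/m_ref)^γ` with
`z_ref = 150 e` at `m_ref = 3.7 MDa`, γ = 2/3, and a per-species shape
factor s ≥ 1. No functional form is established for this instrument, so
the exponent is this module's central modeling choice: 2/3 is
surface-area (Rayleigh-like) scaling under the charge residue mechanism,
anchored to the observed 150 e cluster for the empty capsid. The model
then predicts ≈ 238 e for a compact dimer at 7.4 MDa; observed compact
dimers sit slightly below (≈ 225 e), a ~5% model error we accept rather
than allow s < 1, while the extended dimer population (≈ 300 e) is
represented by s ≈ 1.26. Charge noise is Gaussian with no heavy tails —
adequate for peak-shape and fraction work, not for outlier studies.

`expected_peak_shape()` convolves the enumerated capsid distribution
(shifted by any packaged DNA mass) with a per-support-point Gaussian of
width `mass_sigma` at that point's mass and model charge, on a grid
covering the support ± 5 total SD (too-narrow user grids are an error,
not a silent truncation). Its grid moments satisfy mean = pmf mean + DNA
mass and variance = heterogeneity variance + mean instrument variance;
the empty-capsid prediction at 100 ms, sqrt(47.8² + 24.7²) ≈ 53.8 kDa, is
verified by the test suite against the trapezoid-integrated density.

# Counterion mass balance

With i internal basic sites (each carrying an anion of mean mass m⁻ in
the empty particle), a genome of j nucleotides of mean ionized mass m_N,
and a cation of mean mass m⁺ on every phosphate not neutralized by a
basic site:

```
M_E = M + i m⁻
M_F = M + j m_N + (j − i) m⁺_eff ,  m⁺_eff = m⁺ / valence
M_F − M_E = (1 + m⁺_eff/m_N)(j m_N) − i (m⁺_eff + m⁻)
```

The difference form and the two-state difference are implemented
separately and tested for exact agreement. Divalent cations contribute
m⁺/2 per nucleotide charge — required to reproduce the quoted Mg²⁺ slope
of 1.039. Fitting is ordinary (unweighted) least squares on
(sequence mass, measured difference) points: nothing justifies weights,
all constructs being measured the same way. `interpret_fit()` inverts the
line under an assumed cation/anion pair; ammonium/acetate is the
documented default because that is the electrospray buffer, with the
explicit caveat that the counterion identity is not identifiable from a
single slope — only the effective mass per nucleotide, (slope − 1)·m_N,
is. Jointly fitting i and m⁺ by nonlinear optimization is deliberately
out of scope (unidentifiable from one line); a positive intercept returns
a flagged negative site count rather than an error.

# The synthetic-data generator

No raw single-ion data for this instrument are public, so the simulator
is the package's stated world — first-class, tested code, not a fixture.
Per ion: component by weight; capsid mass by multinomial draw (times the
multimer order); genome-derived DNA per the packaging state; a
truncated-Gaussian "extra DNA" fragment; power-law mean charge times the
species shape factor; Gaussian charge and m/z noise; Bernoulli multi-ion
and short-trap flags. Everything is reproducible from one integer seed,
and event files carry the seed in their header.

Generator defaults are the stated experimental world, chosen once:

- spectra of 10,000 ions (the figure-caption figure; the methods text
  says ~5,000 — scenario files default to the former and this discrepancy
  is recorded in the decisions ledger);
- counterion uptake as `dna_inflation = 1.041` and
  `dna_offset = −16,000 Da` applied to genome-derived DNA, i.e. the
  generating line of the measured-vs-sequence panel;
- headful particles pinned at a total mass of 5.33 MDa (SD 50 kDa, a
  design default matching observed "consistent mass" second peaks), DNA
  filling whatever the drawn capsid leaves — uninflated, since the
  capacity guide is an observed total mass;
- partial genomes as a uniform fraction of one genome by default (the
  observed featureless tail between empty and full), configurable to
  truncated-normal for populations known to be interior peaks;
- incubation/temperature-cycling modeled purely as removal of a fraction
  of the extra-DNA load (`apply_incubation()`), which reproduces the
  ~32 kDa downshift and renarrowing of the empty-capsid peak as a
  calibration scenario — no kinetic or mechanistic claim.

What the generator does **not** emulate: charge-state quantization,
non-Gaussian tails, ion-optics transmission bias, the unassigned ~6.4 MDa
cluster (representable only as a generic extra component), detector
waveforms, and any correlation between capsid composition and packaging
state. A green test therefore establishes that the analysis recovers the
stated world's parameters at the stated noise — not that real instrument
data obey this forward model.

# Spectrum quantitation

- **Binning**: half-open [left, right) bins anchored at 0 Da (no
  convention is published for the reference spectra; anchoring at zero
  makes bin membership seed- and data-independent). Flagged events are
  discarded and counted.
- **Mixture fitting**: 1-D Gaussian EM, initialized at caller-supplied
  means — peak positions are always approximately known here (expected
  empty/full/capacity masses) — terminated on a 1e−8 mean-log-likelihood
  change, max 500 iterations, non-convergence raising a condition that
  carries the last iterate. SDs are floored at 1 Da against collapse.
  Component mean charges are responsibility-weighted, so charge-vs-mass
  cluster statements are assertable from the same fit. A dedicated
  mixture package would add model-selection machinery not needed here;
  the ~50-line EM is tested against simulation oracles.
- **Window classification** is the primary, transparent quantitation:
  empty and full windows of ±3 peak-SD (configurable), partial between
  them, overfull from the full window up to a multimer threshold
  (default: midway between the 5.33 MDa capacity and the dimer mass),
  multimer beyond. Ties at boundaries go to the lower-mass state;
  below-empty masses count as empty. The reference percentages this
  reproduces (14% sub-full; 3.8% + 0.8% multimers) were published without
  window definitions, so the windows are package choices and the tests
  check recovery of *generating* fractions, not agreement with published
  windows.

# Workflow layer

Scenarios are JSON: capsid, instrument, charge-model, DNA-chemistry
sections, a construct table, a mixture template, seed and analysis
switches. Every omitted field is filled from package defaults and logged
with its provenance (reference value vs design default) into the run log.
Outputs are delimited text and JSON only; run logs carry no timestamps,
so identical config + seed gives byte-identical bundles (tested at the
file level). Per-construct seeds are derived as `seed × 1000 + index`,
keeping them far below 2³¹.

# Known limitations

- The per-base constant and terminal/ionization conventions behind the
  printed construct masses are reverse-engineered; exact sequences would
  supersede them.
- The charge model's exponent is a modeling choice anchored at one point;
  shape factors absorb, rather than explain, geometry.
- The counterion fit published for the real construct panel cannot be
  reproduced from print (the per-construct measured masses were never
  tabulated); it is recoverable only on synthetic data, which is exactly
  what the end-to-end acceptance criterion does.
- Self-complementary (scAAV) genomes, ITR secondary structure, serotype
  sequence databases and PTM mass shifts are out of scope.
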