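---
title: "Structural profiling of circulating nuclear and mitochondrial DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural profiling of circulating nuclear and mitochondrial DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirDNAstructure)
```

# The problem

Cell-free DNA circulating in plasma (cirDNA) is a mixture of two very
different molecules. DNA of nuclear origin (cir-nDNA) circulates mostly as
nucleosome-protected fragments around 166 bp; DNA of mitochondrial origin
(cir-mtDNA) has no histones, is present in tens of thousands-fold more
genome copies, and travels inside larger carriers — extracellular
mitochondria, extracellular vesicles (EVs), nucleoprotein complexes. Three
complementary read-outs expose this structure:

1. **Fragment-size profiles** from low-pass whole-genome sequencing, built
   separately from double-strand (DSP) and single-strand (SSP) library
   preparations. DSP reads intact duplexes (sizes in bp); SSP denatures
   first and reads every single strand, splitting at internal nicks (sizes
   in nt). Their disagreement is informative: short, nicked or
   single-stranded material is visible to SSP only.
2. **qPCR quantification** with a short and a long amplicon per genome
   (KRAS 67/320 bp; MT-CO3 67/310 bp) against a standard curve; the
   long/short concentration ratio is the DNA Integrity Index (DII), ~1 for
   intact DNA.
3. **Differential centrifugation / filtration series**: measuring the
   supernatant DNA after successively harsher physical steps (16,000 g,
   40,000 g, 200,000 g spins; 0.22 µm filtration; freeze–thaw) partitions
   the DNA across structure classes by their pelleting behaviour.

The package implements all three read-outs plus a synthetic-data generator
calibrated to published healthy-individual values, so the full pipeline is
testable without any sequencing download (no raw data are publicly
deposited for this assay design).

# Size profiles and their statistics

A profile is a raw 1-bp histogram over the inclusive window 30–1,000 bp
(nt) — the practical detection limits of the sequencing read-out — with
frequencies normalised by the in-window total. No smoothing is applied at
any point; every statistic operates on the raw histogram:

* `bandFraction(p, lo, hi)` — mass in an inclusive size band;
* `modalSize(p)` — argmax frequency, ties broken to the smallest size so
  results are deterministic;
* `shortLongRatio(p)` — frequency below 90 over frequency above 200, both
  strict inequalities (the boundary sizes 90 and 200 count for neither
  side; the convention is documented rather than resolved by the assay
  itself). A zero denominator yields `NA`, flagged rather than thrown;
* `periodicityScore(p)` — mean excess of the frequency at the canonical
  10-bp comb positions (102, 112, …, 152 bp) over their ±5 bp neighbours;
  exactly zero on locally linear profiles, positive when nucleosomal
  combing is present;
* `compareLibraries(dsp, ssp, offsetBp)` — SSP/DSP fold of the below-90
  fraction, DSP/SSP fold of the above-200 fraction and the ratio of
  short/long ratios. `offsetBp` shifts the SSP profile before comparison
  (overlay convention SSP = DSP − 3, reflecting the ~3 bp end-repair
  extension of DSP sizes); it defaults to 0, which is correct for the
  synthetic generator where both chemistries see the same molecules.

`meanProfile()` averages per-sample frequencies with equal subject weights
(then renormalises) rather than pooling counts: a deeply sequenced subject
must not dominate a cohort mean. Band percentages quoted for cohorts are
computed on that mean profile.

`readInsertSizes()` obtains fragment lengths from aligned paired-end
SAM/BAM via the template-length field, counting each properly paired,
primary alignment pair once (the mate with positive TLEN) and classifying
pairs as mitochondrial by contig name (`chrM`, `MT`, `chrMT`,
case-insensitive, configurable). No mapping-quality or duplicate filter is
applied by default; both are exposed as options since the assay definition
specifies none.

# The empirical fragment simulator

`defaultMixtureConfig()` encodes each published mean profile as a small
banded mixture: band edges and weights are the published band fractions
(with the ≤0.4% unreported residual folded into the long band, so band
fractions are exact in expectation), and within-band shapes are discrete
asymmetric-Laplace peaks — exponential decay with separate left/right
scales — whose sharp modes make the sampled modal size statistically
stable at the study's draw sizes. The nuclear configurations add a comb of
point masses every 10 bp (102–152 bp for DSP; 53–143 nt for SSP, mass
0.003/0.002 per tooth) carved out of the band's own weight; the
mitochondrial configurations have no comb, matching the observation that
periodic sub-peaks are detectable only for nuclear DNA.

Scale choices for the peaks (e.g. 12/55 bp around the 120 bp mitochondrial
DSP mode, 22/18 bp around the 166 bp nuclear mode) were set once to
reproduce the qualitative "sharp rise, slow decay" (or the reverse)
descriptions of the published profiles; they are not fitted to data, and
the statistics the package reports on these defaults are exact only where
the band arithmetic makes them so (band fractions, and modes up to
sampling noise).

What the generator deliberately does **not** emulate: base-level sequence
content, GC bias, mappability, nuclear copies of mitochondrial sequence
(NUMTs), duplicate reads and sequencing error. Tests passing on this
generator therefore validate the measurement arithmetic and the
calibration, not robustness to those real-data artefacts.

# The mechanistic jagged-end / nick simulator

The second generator explains the DSP/SSP contrast instead of imitating
it. A molecule is a duplex of some span whose strands may be recessed at
either end (jagged ends) and carry Poisson-distributed internal nicks
(`nickRate` per bp, positions uniform on the strand interior). The two
observation operators are the simplest ones consistent with the library
chemistries:

* `dspObserve()` — end repair fills recessed ends and the duplex holds
  together across nicks, so the read-out is the maximal extent covered by
  either strand; internal nicks are invisible.
* `sspObserve()` — heat denaturation separates the strands, each of which
  falls apart at its nicks; every maximal nick-free single-strand segment
  inside the 30–1,000 nt window is observed.

Three consequences are tested as invariants: with no nicks and no jags the
two operators agree exactly (each span observed once by DSP, twice by
SSP); increasing the nick rate strictly shortens mean SSP output while
leaving DSP output untouched; and SSP segment lengths are conserved —
kept plus dropped segments sum to the strand length, exactly, because nick
positions are kept continuous rather than rounded.

# qPCR quantification

Standard-curve quantification is ordinary least squares of Cq on
log10(quantity) (`fitStandardCurve()`), inverted at the mean Cq of the
replicate wells (`quantifyCq()`): replicates are summarised on the Cq
scale, not by averaging back-transformed quantities. Efficiency is
`10^(-1/slope) − 1` (slope −3.3219 ⇔ 100%). `toPlasmaConcentration()`
carries a per-reaction amount back through the extraction volumes
(defaults: 80 µL eluate from 200 µL plasma; the 25 µL reaction's template
volume is a required user input, since no universal default exists).
`copiesPerMl()` converts mass to genome copies at 660 g/mol/bp with
configurable genome lengths (16,569 bp mitochondrial; 3.2×10⁹ bp haploid
nuclear).

The DII is defined here as the long-amplicon over short-amplicon
concentration ratio — the definition that makes an unfragmented target
score 1 and matches how the index is used for platelet/blood-cell
contamination checks. The bridge to fragment populations is a threshold
detection model (`ampliconDetectableFraction()`): a fragment amplifies iff
it is at least as long as the amplicon. Under this model the DII of a
simulated population is monotone non-increasing in the nick rate, which
the test suite verifies.

# Plasma-preparation simulation and partition inference

`defaultStructuralClasses()` distributes supernatant DNA (relative to the
16,000 g supernatant) as: mid-structures pelleting at 40,000 g (75.7%
mitochondrial / 36.3% nuclear), small-structures pelleting at 200,000 g
(20.1% / 53.1%) and a never-pelleting soluble class (4.2% / 10.6%) — so
24.3% / 63.7% remain after 40,000 g and 4.2% / 10.6% after 200,000 g by
construction. These weights are anchored on the published
remaining-fraction statements, which are internally consistent, rather
than on the published summary table whose percentages cannot be reproduced
from its own printed copy numbers (9.0/26.9/49.1/15.0 from
1,100→1,001→705→165 versus the tabled 8.6/27.7/53.1/10.6; presumed
rounding of per-subject values — flagged, not resolved, and reproducing
that table's normalisation is a non-goal).

Freezing is modelled only for mitochondrial DNA: plasma freeze–thaw lyses
platelets, whose interior mtDNA then appears in the supernatant, while
nuclear DNA concentrations are unchanged. The assay literature quantifies
the *effect* (a 12-fold rise of post-16,000 g supernatant mtDNA) rather
than the platelet compartment itself, so the model parameterises the
release by that fold factor: a freeze step adds `(fold − 1) ×` the current
supernatant total to the release target class (the soluble class) and
empties the platelet compartment. With the default classes this reproduces
the 12-fold post-spin increase exactly and keeps the no-freeze arithmetic
untouched.

Measurement noise is multiplicative log-normal, mean-unbiased, with
coefficient of variation `noiseCv` — 0.20 as a realistic default for
qPCR-on-plasma series, 0.02 in the calibration tests where the quantity of
interest is the arithmetic, not the robustness. No noise model is given
with the assay; log-normal is the standard choice for strictly positive
concentration measurements.

Inference inverts the simulation: `supernatantFractions()` divides each
step's measurement by the reference step's (per replicate, then averaged),
clipping fractions above 1 to 1 with a warning — biological replicate
series do occasionally read a later supernatant above an earlier one —
and `inferPartition()` takes consecutive differences of the remaining
fractions as class fractions, with the final remainder as residual. The
class map must list the post-reference steps in protocol order; a
mismatch is an error rather than a warning because inference on reordered
steps silently answers a different question. For monotone series,
fractions plus residual sum to 1 exactly; when noise breaks monotonicity
the negative differences are clipped to zero and the vector renormalised,
again with a warning. The reference step defaults to the series' first
(lowest-g) supernatant but is configurable, because published analyses
normalise sometimes to the low-speed and sometimes to the 16,000 g
supernatant.

# Numerical and design choices

* Windows and thresholds are inclusive `[30, 1000]`, strict `<90` / `>200`.
* Mode ties break to the smallest size.
* All randomness flows from one explicit `seed` argument per call through
  a local RNG scope; the caller's random stream is never advanced.
* Profile normalisation is checked to 1e-9; partition conservation to
  1e-9 after clipping.
* Degenerate inputs fail loudly: profiles with no in-window fragment,
  zero reference measurements, non-positive qPCR quantities, all-equal
  dilution quantities and inverted band bounds are errors; undefined
  ratios (zero denominators in profile statistics) are `NA` flags.

Problem sizes in the shipped tests were chosen so each stochastic check
has comfortable power at three standard errors: 500,000 draws for the
calibrated band fractions and modes (binomial SE ≈ 0.06 pp), 10,000–
100,000 molecules for Poisson and monotonicity properties, 20 replicates
× 50 seeds for partition recovery (mean absolute error < 2 pp at 2%
noise).

# Known limitations

* The mixture defaults describe healthy-individual *mean* profiles;
  subject-to-subject variability is not modelled (every draw is one
  homogeneous sample).
* The threshold qPCR detection model ignores partial amplification of
  nicked templates spanning the amplicon.
* The mechanistic simulator treats nicks as independent of position;
  real nicking is sequence- and nucleosome-context dependent.
* The partition calculus attributes each inter-step drop entirely to one
  structure class; co-pelleting mixtures are not deconvolved.
* SAM/BAM reading assumes a well-formed header and proper-pair flags set
  by the aligner; CRAM and duplicate marking are out of scope.
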