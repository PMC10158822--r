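# cirDNAstructure

Structural profiling of circulating cell-free nuclear (cir-nDNA) and
mitochondrial (cir-mtDNA) DNA from plasma.

Plasma cirDNA is heterogeneous: nuclear DNA circulates mostly as
nucleosome-protected ~166 bp fragments, while mitochondrial DNA — histone-free
but ~50,000-fold more abundant in genome copies — travels largely intact
inside bigger carriers (extracellular mitochondria, extracellular vesicles,
nucleoprotein complexes). This package implements the three measurements that
together resolve that structure, plus a calibrated synthetic-data generator so
the whole pipeline runs and is tested without any sequencing download:

* **Fragment-size profiles** (`readInsertSizes`, `buildProfile`,
  `meanProfile`): raw 1-bp histograms of paired-end insert sizes over the
  30–1,000 bp (nt) window, built separately for double-strand (DSP, bp) and
  single-strand (SSP, nt) library preparations, with summary statistics —
  `bandFraction`, `modalSize`, the strict `shortLongRatio`
  (freq < 90)/(freq > 200), the 10-bp nucleosomal `periodicityScore`, and
  DSP-vs-SSP `compareLibraries` folds with a configurable ±3 bp overlay
  offset.
* **qPCR quantification** (`fitStandardCurve`, `quantifyCq`,
  `toPlasmaConcentration`, `copiesPerMl`, `dnaIntegrityIndex`): standard-curve
  quantification of the KRAS 67/320 bp and MT-CO3 67/310 bp amplicon pairs,
  with the DNA Integrity Index DII = C_long / C_short (≈1 for intact DNA).
* **Partition inference** (`simulatePlasmaPrep`, `supernatantFractions`,
  `inferPartition`, `stepEffect`): converts supernatant measurements along a
  differential centrifugation/filtration protocol (16,000 g → 40,000 g →
  200,000 g spins, 0.22 µm filtration, freeze–thaw) into the fraction of DNA
  carried by each structural class, as consecutive differences of remaining
  supernatant fractions relative to a reference spin.
* **Generators** (`sampleFragmentLengths` from banded mixtures;
  `simulateMolecules` + `dspObserve`/`sspObserve` for the mechanistic
  jagged-end/nick model of the DSP–SSP contrast; `generateQpcrCq`).

See the vignette (`vignettes/cirdna-structural-profiling.Rmd`) for the models,
calibration and design decisions.

## Worked example

```r
library(cirDNAstructure)

## calibrated mitochondrial DSP mixture, 100,000 fragments
cfg  <- defaultMixtureConfig("mitochondrial", "DSP")
prof <- buildProfile(sampleFragmentLengths(cfg, 100000, seed = 7))
prof
#> SizeProfile: synthetic [mitochondrial, DSP]
#>   window 30..1000 bp, 1e+05 in-window reads
#>   modal size 121 bp (frequency 0.0127)

s <- profileSummary(prof, bands = data.frame(lo = c(90, 261), hi = c(260, 425)))
s$bandFractions
#>    lo  hi fraction
#> 1  90 260  0.77902
#> 2 261 425  0.21198
round(s$shortLongRatio, 3)
#> [1] 0.028

## DSP vs SSP: single-strand chemistry sees far more short material
ssp <- buildProfile(sampleFragmentLengths(
    defaultMixtureConfig("mitochondrial", "SSP"), 100000, seed = 8))
compareLibraries(prof, ssp)
#> Library comparison (SSP overlaid with offset +0)
#>   fold below 90 (SSP/DSP): 41.10778
#>   fold above 200 (DSP/SSP): 1.740441
#>   short/long ratio-of-ratios (SSP/DSP): 71.54568

## three-spin series at 2% measurement noise, then invert it
series <- simulatePlasmaPrep(defaultStructuralClasses(),
    totals   = c(mitochondrial = 3.7e6, nuclear = 1100),
    protocol = prepProtocol(centrifugeStep(16000, "HS16000"),
                            centrifugeStep(40000, "UC40000"),
                            centrifugeStep(200000, "UC200000")),
    noiseCv = 0.02, replicates = 20, seed = 9)
inferPartition(series$mitochondrial,
               c(UC40000 = "mid-structures", UC200000 = "small-structures"))
#> PartitionEstimate (fraction of reference supernatant DNA)
#>   mid-structures         75.6%
#>   small-structures       20.2%
#>   residual supernatant    4.2%
```

Reading: 77.9% of mitochondrial DSP fragments fall in the 90–260 bp band with
a mode near 120 bp, and almost none below 90 bp (short/long ratio 0.03) —
whereas the SSP profile of the same compartment is ~41-fold richer below
90 nt, the signature of nicked/jagged molecules invisible to double-strand
chemistry. The inverted centrifugation series recovers the configured
structural repartition (75.7 / 20.1 / 4.2%) to within the 2% measurement
noise.

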