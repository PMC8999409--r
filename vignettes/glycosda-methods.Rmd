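---
title: "GlycoSda: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GlycoSda: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GlycoSda)
```

## The analytical problem

The Sda (Sd^a^/Cad) histo-blood-group epitope is the trisaccharide
GalNAcβ1-4(NeuAcα2-3)Galβ-R, synthesized by the B4GALNT2-encoded
β4GalNAc-T2. At the level of glycan *composition* — which is all that a mass
spectrometer measures directly — the epitope is one extra HexNAc on a
sialylated galactose: the disialo biantennary N-glycan NeuAc₂Hex₅HexNAc₄
becomes NeuAc₂Hex₅HexNAc₅ (one antenna) or NeuAc₂Hex₅HexNAc₆ (both), and
the disialo core 1 O-glycan NeuAc₂Hex₁HexNAc₁ becomes NeuAc₂Hex₁HexNAc₂.

GlycoSda implements the LC-MS/MS side of characterizing this epitope on
glycopeptides:

1. **Mass arithmetic** for peptides, modifications, glycan compositions,
   glycopeptide precursors and oxonium ions.
2. **In-silico digestion** (trypsin, chymotrypsin, pronase) with reversed
   decoys.
3. **HCD fragment prediction** at stepped collision energies: at NCE 20%
   the glycan fragments glycosidically while the peptide stays intact
   (Y-ion ladder, oxonium B-ions); at NCE 30/40% the backbone fragments
   into b/y ions that identify the peptide.
4. **Spectrum matching** of NCE 20/30/40 triplets with verification rules
   and target-decoy FDR.
5. **Diagnostic-ion screening**: a run-wide MS² chromatogram of the Sda
   oxonium ion (NeuAc₁Hex₁HexNAc₂)⁺ at m/z 860.3143.
6. **Relative quantification**: MS¹ XIC/AUC comparison of an Sda glycoform
   against its −1 HexNAc precursor glycoform on the shared peptide.
7. A **ground-truth simulator** so that every stage is testable without any
   raw-data download.

## Mass model

All masses are monoisotopic and flow from one constant table
(`massConstants()`): residue masses derived from elemental formulas, water
18.01056469, proton 1.00727646688, Hex 162.052823, HexNAc 203.079373,
NeuAc 291.095417, dHex 146.057909. Ile and Leu are distinct codes with
identical mass; no disambiguation is attempted. Glycan identity is
composition only — linkage and topology are not modelled, which is exactly
why the package carries an explicit per-library-entry `sda` annotation (see
below).

Key reproduced values:

```{r anchors}
tm9s3 <- function(hexnac) Glycopeptide(
  "IVDVNLTSEGK", GlycanComposition(hex = 5, hexnac = hexnac, neuac = 2),
  glycoClass = "N", glycosite = 5, sda = hexnac > 4)
c(biantennary_z3 = round(precursorMz(tm9s3(4), 3), 2),
  sda_both_antennae_z3 = round(precursorMz(tm9s3(6), 3), 2),
  sda_oxonium = round(oxoniumMz(GlycanComposition(hex = 1, hexnac = 2,
                                                  neuac = 1)), 4),
  neuac_oxonium = round(oxoniumMz(GlycanComposition(neuac = 1)), 2))
```

## Defaults and the parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| MS¹ tolerance | 10 | ppm | precursor search accuracy of the workflow |
| MS² tolerance | 20 | ppm | fragment/diagnostic-ion accuracy; ±0.017 at m/z 860 also covers the ion when measured as 860.32 |
| static modification | methylthio on Cys, +45.9877 | Da | the workflow's Cys derivatization |
| variable modification | Met oxidation, +15.9949, ≤2 per peptide | Da | standard sample-handling artifact |
| missed cleavages | 2 | — | trypsin/chymotrypsin search setting |
| proline rule | off | — | plain C-terminal K/R cleavage; available as a toggle |
| pronase length bounds | 4–20 | residues | bounds the nonspecific search space; the documented pronase hit is 9 residues |
| precursor charges | 2–7 | — | data-dependent selection range |
| score cutoff | 8 | package score | calibrated once on simulated null runs (below) |
| quant charges | 2–3 | — | charges summed before AUC ratioing |

## Scoring and FDR

Byonic-style proprietary scores are not portable, so the package defines its
own: for each spectrum of the NCE triplet, every matched theoretical ion
contributes `classWeight × log10(1 + 100·I/basepeak)`, with class weights
1 (glycosidic), 0.5 (oxonium, because oxonium ions are shared between all
glycoforms of the same composition family) and 1 (backbone); the triplet's
contributions are summed. The published cutoff of 300 on the Byonic scale
therefore does **not** transfer; `searchConfig(scoreCutoff=)` exposes the
package-scale cutoff. The default of 8 was calibrated once during
development: on simulated runs, planted identities score above 300 on this
scale, while decoy-only databases and pure-noise runs produce *no* PSM at
all (no decoy candidate ever falls within 10 ppm and matches ions), so any
small positive cutoff separates them; 8 was chosen conservatively and not
revisited.

Verification rules are computed from the spectra, never asserted:
N-glycopeptides must show the peptide+HexNAc Y ion, O-glycopeptides the
bare peptide ion, and any NeuAc-containing assignment must show both the
NeuAc oxonium (292.10) and its water loss (274.09). FDR is estimated as
(verified decoys ≥ cutoff) / (verified targets ≥ cutoff); with zero targets
the estimate is undefined and reported `NA`. Below-cutoff verified PSMs are
rescued only when their peptide is already in the accepted set
(alternative-glycoform rescue).

One PSM is retained per precursor triplet; ties break deterministically
(verified first, then score, matched-ion count, peptide, glycan name). How
to combine the NCE 20/30/40 triplet is not prescribed anywhere; summing the
matched-ion score across the three tiers was chosen because each tier
carries complementary ions, and is flagged here as a package decision.

## The Sda/bisecting ambiguity

A bisecting GlcNAc produces the same composition as an Sda-extended
antenna (e.g. NeuAc₂Hex₅HexNAc₅dHex₁) but does not fragment into the
860.3143 oxonium ion. The glycan library therefore annotates each entry
with an `sda` flag; `oxoniumIons()` predicts 860.31 only for Sda-positive
entries that contain the NeuAc₁Hex₁HexNAc₂ sub-composition. This lets the
simulator plant isomeric negatives, and it propagates to quantification:
`relativePeakIntensity()` marks a pair `ambiguous` unless MS² diagnostic
evidence (a screen candidate within the isolation window of the Sda
glycoform's precursor, or an accepted PSM with the 860.31 flag) is
supplied. The ambiguity is surfaced, not solved — co-eluting isomers
contribute to the MS¹ precursor and only the diagnostic ion
distinguishes them.

## Quantification model

The relative peak intensity of an Sda glycoform A versus its precursor
glycoform B (glycan(A) = glycan(B) + HexNAc) is
`100 · AUC_A / (AUC_A + AUC_B)`, with trapezoidal AUCs of monoisotopic-peak
XICs (±10 ppm) summed over the configured charge states before ratioing.
The two-glycoform denominator mirrors comparing "the two glycopeptide MS¹
precursor ions"; ratioing against all detected glycoforms of a peptide
would be a straightforward extension. Whether to sum charge states is
likewise unstated in the source methodology; summing is the default and a
single charge can be configured. Extraction is monoisotopic-only by
design — the simulator's isotope envelopes exist precisely to verify that
the +1/+2/+3 isotopes do not leak into the XIC window.

## The simulator: what it emulates, and what it does not

`simulateRun()` emulates: a 90-minute gradient sampled by MS¹ survey scans
every 0.05 min (the ~3 s duty cycle of the emulated instrument) over m/z
600–2000; Gaussian elution peaks (default FWHM 0.2 min, σ = 0.085 min);
4-isotope envelopes with a simple averagine-style Poisson intensity model
(λ = 4.7·10⁻⁴ per Da); charge states 2–7 with per-species weights;
per-peak mass error (Gaussian, 2 ppm SD); data-dependent NCE 20/30/40 MS²
triplets (from `theoreticalSpectrum()`, flat intensities within an ion
class with per-tier class weights: glycosidic 1.0/backbone 0.05 at NCE 20,
0.3/1.0 at NCE 30/40) for every species above a selection threshold;
log-normal noise peaks on both MS levels; and occasional noise-precursor
triplets. Everything stochastic derives from the mandatory manifest seed,
so identical manifests give identical runs.

It deliberately does **not** emulate: retention-time prediction, profile
mode peaks, ion mobility, dynamic exclusion, co-isolation chimeras, or —
most importantly — glycoform-specific ionization/detection efficiency.
Efficiencies default to equal, so recovered fractions equal planted
fractions *by construction*; passing the recovery tests demonstrates that
the XIC/AUC machinery is unbiased, not that real-world relative peak
intensities are unbiased abundance estimates (they are reproducible
relative indications only, as the source methodology itself stresses).

Presets encode the study conditions: `mock`/`hek_rs7224888` plant only
precursor glycoforms, `hek_wt`/`hek_rs148441237`/`hek_rs61743617` plant
the Sda glycoforms, `cad_a` plants the GLPA DTYAATPR O-glycoform pair at a
12% Sda fraction and the B3AT N-glycoform pair at 18%, `cad_b` plants GLPA
at 0.1%, and `control_bisecting` plants the isomeric
NeuAc₂Hex₅HexNAc₅dHex composition with no 860.31 fragment. Planted
abundances use a 10⁶ apex against a noise floor of ~100 (log-normal,
σ = 1 log), which keeps the 0.1% glycoform detectable in MS¹ while leaving
it below the MS² selection threshold — matching its real counterpart,
which required a separate digest to identify.

The carrier "proteins" shipped in `extdata/synthetic_proteins.fasta` are
synthetic: short invented flanks around the documented glycopeptide
sequences, sufficient for digestion/decoy/search mechanics. They are not
UniProt sequences, and coordinates reported against them are internal.

## Numerical choices and degenerate inputs

* ppm errors are computed against theoretical m/z.
* Peak matching takes the nearest centroid within tolerance
  (`findInterval` on the sorted peak list); scores depend only on matched
  ions, so peak order and off-tolerance noise cannot change them.
* AUC integration is trapezoidal (`pracma::trapz`); traces need ≥ 2 points.
* Empty compositions have mass 0 but no oxonium ion; empty peptides,
  empty RT windows, runs without the required MS level, and unknown
  residues/elements/proteases/presets raise errors rather than guessing.
* Y-ladders enumerate all sub-compositions; N-ladders keep ≥ 1 HexNAc
  (core GlcNAc) and only O-ladders include the bare peptide ion. The
  doubly-Sda TM9S3 glycoform needs no special casing — both singly and
  doubly extended sub-compositions are ladder members automatically.
* Decoys are full sequence reversals (an involution), prefixed `decoy_`.

## Problem sizes used in the shipped tests

The test suite and the pipeline-closure checks run the simulator at the
defaults above (≈1 800 MS¹ scans, tens of MS² triplets per preset, ~1 200
candidates from the 10 synthetic carriers plus decoys); quantification
recovery uses 20 seeded replicates of `cad_a` and 3 of `cad_b`. These sizes
were chosen as the smallest at which every stage (isotope interference,
noise floors, decoy competition) is genuinely exercised.

## Known limitations

* Composition-level identity: NeuAc α2,3 vs α2,6 linkage, antenna
  placement and other topology are invisible; only the `sda` annotation +
  diagnostic ion separate isomers.
* Site localization is sequon/Ser-Thr enumeration; ambiguous O-sites are
  reported as ranges, not scored.
* The score scale is package-specific; cross-engine score comparisons are
  meaningless by design.
* The simulator's flat within-class fragment intensities are a convenience,
  not a fragmentation-physics model.
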