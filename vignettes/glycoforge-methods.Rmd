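---
title: "Glycoform enumeration and binding analytics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycoform enumeration and binding analytics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoforge)
```

## The problem

MUC1 is a transmembrane mucin whose extracellular domain is a variable-number
tandem repeat (VNTR) of a 20-amino-acid unit, each copy carrying five
potential O-glycosylation sites (two Thr-Ser/Ser-Thr pairs and one isolated
Thr). In carcinomas, O-glycan elongation is frequently blocked (e.g. by loss
of the COSMC chaperone required by core-1 β1,3-galactosyltransferase), so the
repeats display truncated glycans: the Tn antigen (a single α-GalNAc on
Ser/Thr) and sialyl-Tn (NeuAcα2-6GalNAc). A monoclonal antibody raised
against such a tumour glycoform recognises a *glycopeptide* epitope — both
the sugar and a short stretch of peptide backbone — so designing reagents
requires knowing which glycoforms can exist at all.

glycoforge answers the combinatorial half of that question exhaustively and
provides the downstream analytics used to verify candidate epitopes:
theoretical glycopeptide masses for ESI-MS characterisation, dissociation
constants from SPR rate constants, and 4PL ELISA fits with EC50 estimation.

## Enumeration model

Each site takes one state from an ordered *glycan alphabet* whose state 0 is
always UNOCCUPIED; a glycoform is therefore a base-k digit vector over the n
sites, and the set of modified glycoforms has exactly k^n − 1 members (the
all-zero vector is the naked peptide and is excluded by default, though
`include_unmodified = TRUE` reports it for assay controls). For the 5-site
MUC1 unit this gives 31 binary (Tn-only) and 242 ternary (Tn/sialyl-Tn)
glycoforms:

```{r counts}
sites <- identify_glycosites(muc1_unit())
sites
length(enumerate_glycoforms(sites, alphabet_tn()))
length(enumerate_glycoforms(sites, alphabet_tn_stn()))
```

Composite glycans are single states: sialyl-Tn is one attached disaccharide,
not two independent decorations, which is what makes the ternary digit
encoding exact. Positional isomers at occupancy m number
choose(n, m)·(k−1)^m — 5/10/10/5/1 across the binary MUC1 strata.

**Ordering.** The digit-counting construction does not pin down a display
order, so it is a named option. The default, `"occupancy"`, sorts by number
of glycans then lexicographically (site 1 most significant), because isomer
strata are the scientifically meaningful grouping; `"counter"` is plain
base-k integer order, the literal sequential construction. Counts and set
membership are order-invariant, which the tests assert against a brute-force
digit oracle.

**Size guard.** k^n grows fast; `enumerate_glycoforms()` refuses jobs above
`max_bits = 20` total bits (n·log2 k, about 10⁶ glycoforms) or `max_states
= 5` states per site. Both are configuration, raisable deliberately.

## Epitope grammar and windows

Annotated glycopeptides are written with `(StateName)` immediately
*following* the modified residue — `RPAPGS(GalNAc)TAPPAHG` is the 13-mer
with GalNAc on Ser6. The grammar is deliberately minimal (no whitespace, no
nesting) and `parse_epitope()`/`render_epitope()` are exact inverses, a
property tested on 10⁴ random epitopes. Note that for adjacent Ser-Thr
pairs this inline notation is ambiguous in parts of the literature (the
annotation is sometimes read as belonging to the *following* residue); this
package applies the follows-the-residue rule uniformly, so every string has
one parse.

Candidate epitopes are fixed-length windows cut around occupied sites after
applying a glycoform periodically to every repeat copy. Centered mode places
the modified residue at window position ⌈w/2⌉ and *shifts* (rather than
truncates) windows that would overhang a terminus, so short flanks still
yield full-length candidates; tiled mode returns every window containing at
least one occupied site. Window length is a free parameter: reported
epitopes in this system are 13-mers and 10-mers with no stated rationale, so
the default of 13 is a convenience choice only. Deduplication is by rendered
string, keeping first occurrence; tandem periodicity then makes the interior
window set independent of copy number (asserted for 3 vs 5 copies). Biotin
or PEG-linker tags used for plate immobilisation are never part of the
epitope string; they enter only as an optional fixed `tag_mass` in the mass
module, since no linker mass is part of the epitope chemistry proper.

## Mass arithmetic

All masses derive from one versioned atomic-mass table (monoisotopic:
IUPAC/CODATA; average: standard atomic weights) through elemental
compositions — residue masses are computed, never hard-coded decimals.
GalNAc adds the HexNAc residue C8H13NO5 (203.0794 Da mono), sialyl-Tn adds
C8H13NO5 + C11H17NO8, and Ac3GalNAc (the protected synthetic precursor kept
for binding fixtures, not in design alphabets) adds three C2H2O acetyls.
m/z uses the protonation-only adduct model, (M + z·1.00728)/z; no isotope
envelopes. Fragment ions cover b/y backbone series — in glycan-retained and
glycan-lost variants wherever a fragment spans an annotated site, since
O-glycans fragment readily under CID — and the standard oxonium diagnostics
(HexNAc⁺ 204.087 with its water/ketene-loss secondaries; NeuAc⁺ 292.103
when sialylated). An independently coded residue-mass oracle in the test
suite pins everything to 1e-4 Da.

## Binding analytics

**SPR.** KD = kd/ka, reported in nM (internal unit molar). The sensorgram
model is the 1:1 Langmuir interaction: association
R(t) = Req·(1 − e^{−(ka·C + kd)t}) with Req = Rmax·C/(C + KD), then pure
exponential dissociation at rate kd. `fit_langmuir()` fits (ka, kd, Rmax)
globally across curves by Levenberg–Marquardt on the log scale (positivity
by construction), with a deterministic start policy: kd from a log-linear
regression on the dissociation tail of the highest-response curve, Rmax =
1.5× the peak response, ka = kd/median(C) (i.e. KD assumed near the middle
of the dilution series). Standard errors come off the log-scale covariance
by the delta method, including the correlation term for KD. Fewer than
three distinct concentrations triggers an identifiability warning;
non-convergence is a hard error with diagnostics, never a silent fallback.
Mass-transport limitation, drift, and bivalent-analyte (avidity) terms are
deliberately excluded: ELISA/SPR affinity discrepancies for IgG binding
plate-bound glycopeptides are an avidity phenomenon and out of scope here.

**ELISA.** The 4PL model y = bottom + (top − bottom)/(1 + (EC50/x)^hill),
parameterised so hill > 0 is an increasing signal and y(EC50) is exactly
half-maximal. Starts: extrema for bottom/top, the concentration nearest
half-maximal response for EC50, hill = 1. Fits with bottom > top are
normalised by the exact symmetry (swap bottom/top, negate hill). Flat data
and fits with R² < 0.5 raise a fit-quality error reporting R².

## Synthetic data: what it emulates and what it does not

`generate_fixture()` produces a mucin-like tandem-repeat protein (random
unit with exactly n non-adjacent Ser/Thr sites; default 20 residues, 5
sites, 3 copies), a simulated ELISA dilution series, and Langmuir
sensorgrams, all with ground truth written alongside. The default study
conditions mirror the experimental regime this package serves: 120 s
association / 200 s dissociation at 1 Hz; ka = 5.6e4 1/(M·s), kd = 0.028
1/s (KD = 500 nM, the magnitude typical of anti-glycopeptide monoclonals by
SPR); Rmax = 100 RU; analyte at KD×{0.1, 0.3, 1, 3, 10}; Gaussian noise of
2 RU (2% of Rmax). ELISA: bottom 0.05, top 2.0 OD, EC50 9.278 ng/ml, hill
1, 2-fold serial dilutions from 1000 ng/ml, noise 5% of span. Every
simulation takes an explicit seed and restores the caller's RNG state.

Passing recovery tests on these fixtures shows the estimators are correct
*for the stated model*: ideal 1:1 kinetics with white noise, no baseline
drift, no mass transport, no avidity, no plate-edge or dilution errors, and
glycoforms drawn uniformly rather than by glycosyltransferase kinetics.
Real sensorgrams and plates violate several of these; the fits here
characterise the arithmetic, not instrument reality.

## Pre-registered tolerances and problem sizes

The statistical acceptance checks were fixed before running: median
relative KD error < 10% over 50 seeded replicates at 2% noise with 3
concentrations; mean EC50 bias < 5% over 100 seeded replicates at 5% noise;
noiseless fits recover generating parameters to 1e-6 relative error;
enumeration matches the brute-force oracle for all n ≤ 6, k ≤ 4, and the
isomer-sum identity Σ C(n,m)(k−1)^m = k^n − 1 holds exhaustively for n ≤ 8,
k ≤ 4. These sizes keep the whole suite within a few minutes on one CPU
while exercising every code path at the scale the science needs (the real
design problem is n = 5).

## Known limitations

* No biosynthetic weighting: all glycoforms are enumerated as combinatorially
  possible, not biologically probable.
* The annotation grammar supports one state per residue; branched site
  chemistry must be modelled as a composite single state.
* KD from two printed rate constants inherits their rounding; reported
  4-significant-digit ka values limit agreement to about ±0.2 nM.
* The Langmuir fitter assumes a shared Rmax across curves (same surface,
  same analyte), which is the standard global-fit design but wrong for
  mixed surfaces.
* Immunogenicity, MHC/B-cell scoring, and antibody sequence analysis are out
  of scope; the library designs *antigens*, not antibodies.
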