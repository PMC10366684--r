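---
title: "Designing and quantifying short germline promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying short germline promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promforge)
```

## The problem

Germline promoters are a workhorse of *C. elegans* transgenesis: heritable
genome editing, germline-restricted expression of toxic or dosage-sensitive
proteins, and reporter assays all need promoters whose strength and tissue
specificity are known. promforge implements the computational half of a
promoter characterization loop: pick candidate genes from tissue-resolved
expression data, define a compact promoter for each, make the sequence
synthesizable and clonable, simulate the cloning itself, and reduce the
downstream cytometry to per-strain expression summaries.

The package also ships, as a plain-text fixture, a characterized panel of
twenty such promoters (two controls and eighteen candidates, 254–880 bp of
endogenous sequence each) that the scanning and census code is validated
against.

## Candidate selection

Expression input is a gene-by-tissue TPM table over a fixed five-tissue set
(germline, neurons, intestine, hypodermis, muscle). Specificity is the
*relative germline fraction*

$$f_g = \frac{\mathrm{TPM}_{germline}}{\sum_{t \in \mathrm{tissues}} \mathrm{TPM}_t},$$

computed over exactly those five tissues. A gene silent in all five has no
defined fraction and is an error, never a silent zero.

A candidate's promoter is the intergenic interval from the nearest upstream
protein-coding neighbor's proximal coding boundary (stop codon for a tandem
neighbor, start codon for a head-to-head one) to, and excluding, the
candidate's own start codon. Non-coding genes are skipped during the
neighbor search. Coordinates are 0-based half-open internally; GFF3 is
converted at the boundary.

Decisions that were genuinely open:

* **Thresholds.** "High absolute and relative germline expression" has no
  canonical numeric values, so both are exposed as configuration with
  defaults TPM ≥ 100 and fraction ≥ 0.4.
* **Length cut-off.** The length filter is inclusive (≤ 1000 bp), and
  configurable.
* **Ranking.** Fraction descending, then germline TPM descending, ties
  broken lexicographically by gene id, making selection deterministic and
  row-order independent.
* **The candidate's ATG** is excluded from the promoter region; in the final
  construct the reporter ATG follows the linker instead.

## Domestication

Two rules make a sequence synthesis- and Golden-Gate-ready: no homopolymer
run of 10 bp or more, and no BsaI recognition site (GGTCTC) on either
strand. `domesticate()` enforces both with the minimum number of single-base
substitutions:

* a run of length $L$ needs exactly $\lfloor L/10 \rfloor$ substitutions,
  placed every 10th base so each residual sub-run is at most 9 bp;
* an isolated recognition site needs one substitution, placed at the third
  base of the hexamer.

Where the choice was not forced, the defaults are deterministic: replacement
bases are tried transition-first (A↔G, C↔T), the first base that creates no
*new* violation covering the edited position wins, and a ±1 position
fallback exists for the rare case where no base is safe at the default
position. Because the policy has no random component the `seed` argument is
accepted but unused. Case is preserved (the panel marks the reporter ATG in
uppercase); all comparisons are case-insensitive. Minimality is tested
against an exhaustive substitution-search oracle on short sequences, and
soundness/idempotence over ten thousand fuzz sequences.

The fixed 15 bp cloning linker `aaaagcaggctaaaa` (a partial attB1 site plus
the `aaaa` consensus start) sits between every promoter and the reporter
ATG; `append_cloning_linker()` adds it. All twenty panel entries end with
linker + ATG, which the acceptance suite asserts as their longest common
suffix.

## Assembly simulation

BsaI geometry (cut one nucleotide downstream of GGTCTC on the top strand,
five on the bottom, leaving 4 nt 5′ overhangs) is encoded in a
`type_iis_enzyme` value, not hard-coded. `digest()` reports fragments on the
top strand with their overhangs; `assemble()` digests parts and destination,
keeps recognition-free fragments, and walks the overhang-complementarity
graph. Exactly one circular product must exist — zero or several (for
example two parts sharing an overhang pair) raise errors rather than pick
arbitrarily, because silent mis-assembly is the worst failure mode. Circular
products compare equal under rotation and strand flip via a canonical
rotation key.

The real destination vector is unpublished, so `synthetic_destination()`
builds a labelled synthetic stand-in with the documented feature order
(acceptor sites around a stuffer, `aaaa` + ATG, gfp with two NLS, a 3′ UTR
segment, backbone stub). Its overhangs — `ggag` upstream of the promoter and
`aaaa` at the linker junction, the package's own choice since the published
design does not print its overhangs — make the linker's last four bases
double as the ligation overhang, so an assembled reporter reads
`promoter + aaaagcaggctaaaa + ATG` with no scar.

## Cytometry quantification

COPAS events carry time of flight (size proxy), peak-height extinction
(density proxy) and green fluorescence. Adults are gated from mixed-stage
populations with TOF in \[1500, 1800\] and extinction below 35,000. The
written gate is ambiguous about boundaries; the package reads the TOF bounds
as inclusive and the extinction bound as strict, keeps both configurable,
and stamps the convention into the gated output's metadata. Summaries are
per-strain mean and SEM (n−1 standard deviation — unstated in the source
material, so the conventional estimator). Both normalizations against the
non-transgenic control are computed — baseline subtraction (control becomes
0, differences preserved) and ratio (control becomes 1) — with the mode
recorded, never silently mixed; reported relative levels in the recovery
tests use the ratio. Visual scores (0–4, three plates per strain) aggregate
the same way after decoding the blinding map.

## What the synthetic data states, and what a green test establishes

Each generator is a pure function of (parameters, seed) and writes its
planted truth:

* `synth_genome_annotation()` — tandem/head-to-head genes on one
  chromosome; ten of fifty inter-gene gaps short (200–900 bp) by default,
  the rest 1500–4000 bp, so "designable" is unambiguous. The truth records
  the strand-aware upstream gaps.
* `synth_expression()` — baseline 100 TPM everywhere, enriched genes at
  10× in the germline, lognormal noise at CV 0.1 by default. Columns are
  renormalized to $10^6$ per tissue (TPM semantics); the analytic fraction
  $\mathrm{fold}/(\mathrm{fold}+4)$ is exact only without renormalization,
  which the noiseless test uses, and approximate when enriched genes are a
  small minority, which the recovery tests respect.
* `plant_violations()` — rejection-sampled clean background with runs and
  sites planted at recorded positions.
* `synth_copas()` — adult/larval TOF mixture (normal components at
  1650 ± 50 and 600 ± 150, adult fraction 0.3 as in a mixed-stage plate
  wash), uniform clean extinction band, exponential debris tail above
  35,000 at 2%, lognormal adult green scaled by the planted fold (σ = 0.5,
  heavy-tailed as peak-height fluorescence is), fold-independent larval
  background. Ratio of gated means recovers the planted fold exactly in
  expectation.

The generators do not emulate real genome content, operons, enhancers,
position effects or germline silencing, so a green recovery test
establishes that the *pipeline arithmetic* is faithful — not that selected
promoters will express. Indeed the characterized panel itself contains
three candidates with high germline RNA signal and no reporter expression;
their classification ships as data, and nothing in the package pretends to
predict it.

## Numerical and degenerate-input choices

* All-zero expression → classed error, never NaN.
* Candidates without an upstream coding neighbor, or overlapping it, are
  undesignable and dropped from selection (classed errors when asked for
  directly).
* Digestion of a linear molecule whose cut would run off the end is a
  truncation error; a circular molecule with zero sites is returned whole.
* Domestication that cannot converge (pathological configurations) fails
  with a diagnostic after a bounded number of passes rather than looping.
* Overhangs must be 4 nt and pairwise distinct; a junction that itself
  spells a recognition site is rejected at `add_flanks()` time.

## Known limitations

* Single-base substitutions are the only domestication edit type; no
  GC-window or vendor complexity scoring beyond the two stated rules.
* Ligation is modeled as exact overhang complementarity — no fidelity or
  kinetics.
* The destination stand-in shares only the architecture, not the sequence,
  of the real vector, so junction-level checks are exact but full-plasmid
  coordinates are synthetic.
* Visual scores are treated as plate-level replicates, not per-animal data.
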