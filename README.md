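# promforge

Design and quantification of short germline-specific promoters for
single-copy reporter transgenes in *Caenorhabditis elegans*.

Synthetic biology in the worm needs compact, well-characterized germline
promoters: for heritable genome editing, for dosage-tuned expression of
toxic transgenes, and for cheap gene synthesis. promforge implements the
computational workflow around characterizing such promoters:

1. **Selection** — rank genes by relative germline expression
   *f* = TPM<sub>germline</sub> / Σ<sub>t∈{germline, neurons, intestine,
   hypodermis, muscle}</sub> TPM<sub>t</sub> from a tissue-resolved TPM
   table, and extract each candidate's promoter as the intergenic interval
   from the upstream protein-coding neighbor's proximal coding boundary to
   the candidate's start codon (≤ 1 kb by default).
2. **Domestication** — make sequences synthesis- and Golden-Gate-ready by
   removing homopolymer runs ≥ 10 bp and BsaI sites (GGTCTC, both strands)
   with a provably minimal number of single-base substitutions
   (⌊L/10⌋ per run, one per site), then append the fixed 15 bp cloning
   linker `aaaagcaggctaaaa` and BsaI donor flanks with 4 nt overhangs.
3. **Assembly** — simulate BsaI Golden Gate digestion/ligation: fragment
   bookkeeping with sticky-end overhangs, a ligation graph whose unique
   circular, recognition-free product is the final reporter construct, plus
   construct verification and the injection-mix recipe helper.
4. **Quantification** — gate adults from mixed-stage COPAS large-particle
   cytometry runs (TOF 1500–1800, extinction < 35,000), summarize green
   fluorescence per strain (mean ± SEM), normalize to a non-transgenic
   control by difference or ratio, aggregate blinded 0–4 visual scores, and
   census expression-pattern classifications.
5. **Synthetic data** — generators for every input (genome + GFF3
   annotation, TPM tables, violation-planted sequences, COPAS event
   tables), each a pure function of (parameters, seed) with its planted
   ground truth serialized alongside.

The package ships a characterized panel of twenty promoter sequences (two
controls + eighteen candidates, 254–880 bp endogenous length) under
`inst/extdata/`, together with their expression-pattern classification
(6 somatic+germline / 3 silent / 9 germline-specific) and per-strain gated
event counts; the panel is the fixture the domestication scans and census
code are validated against.

## Worked example

```r
library(promforge)

## simulate a genome + annotation and a TPM table with planted enrichment
g    <- synth_genome_annotation(seed = 1)
se   <- synth_expression(g$annotation$gene_id, n_enriched = 8,
                         enrichment_fold = 10, seed = 1)
cand <- select_candidates(se$table, g$annotation,
                          min_germline_tpm = 100, min_fraction = 0.4)
head(cand[c("gene_id", "length_bp", "germline_tpm",
            "relative_germline_fraction", "adjacent_boundary")], 3)
#>   gene_id length_bp germline_tpm relative_germline_fraction adjacent_boundary
#> 1 gene039       441        85005                     0.5148        stop_codon
#> 2 gene023       248        69441                     0.4614        stop_codon
```

Only enriched genes with a designable (≤ 1 kb) upstream interval survive;
candidates are ranked by fraction, then TPM.

```r
## scrub a sequence with one planted 13 bp run and one BsaI site
pv <- plant_violations(seq_len = 120, n_runs = 1, run_lengths = 13,
                       n_sites = 1, seed = 2)
d  <- domesticate(pv$sequence)
d$edits
#>   position ref alt      reason
#> 1       35   T   C homopolymer
#> 2       79   T   C    type_iis

## linker + flanks, then in silico Golden Gate into the synthetic destination
part    <- paste0(d$edited, "aaaagcaggct")          # linker minus its last aaaa
frag    <- add_flanks(part, "ggag", "aaaa")         # aaaa doubles as overhang
product <- assemble(c(promoter = frag), synthetic_destination())
product
#> <construct> circular, 649 bp, 2 feature(s)
#>       name start end strand
#> 1 promoter     0 135      +
#> 2 backbone   135 649      +
```

The assembled circle contains no residual BsaI site and reads
`...promoter-aaaagcaggctaaaa-ATG-gfp...` across the junction — exactly two
edits fixed the two planted violations, and the linker's last four bases
served as the ligation overhang.

```r
## synthetic cytometry with planted fold-changes, published event counts
sc <- synth_copas(c(NegCtrl = 1, mex5 = 8, klp19 = 20),
                  n_events = c(64, 179, 134), seed = 1)
s  <- relative_to_control(summarize_strains(gate_adults(sc$events)),
                          "NegCtrl", "ratio")
s
#>    strain n_gated mean_green sem_green relative_to_control
#> 1   klp19      35       1954     151.7               14.20
#> 2    mex5      59        822      47.6                5.97
#> 3 NegCtrl      15        138      21.0                1.00
```

Gating keeps roughly the planted 30% adults; the recovered ratios preserve
the planted ranking (1 < 8 < 20) with the sampling noise you would expect
from a few dozen gated animals per strain.

## Command line

```sh
inst/cli/promforge select --expression tpm.tsv --gff genes.gff3 --out candidates.tsv
inst/cli/promforge domesticate --in parts.fa --linker --overhangs ggag,aaaa \
    --out parts.ready.fa --edits edits.tsv
inst/cli/promforge quantify --events events.csv --control N2 --relative ratio \
    --out summary.tsv
inst/cli/promforge simulate --what copas --seed 1 --out simdir   # writes truth.json
```

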