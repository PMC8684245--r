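---
title: "The FineMAV statistic: model, implementation choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FineMAV statistic: model, implementation choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemav)
```

## The model

Selection scans based on population differentiation flag genomic regions,
not variants: every neutral allele linked to a selected one rides the same
sweep, so the region's top F_ST outlier is usually not the causal site.
FineMAV addresses this by scoring each biallelic SNP on the conjunction of
three signals a positively selected functional allele should show.

For a panel of $n$ populations, let $d_i$ be the derived allele frequency
(DAF) of the site in population $i$, obtained by polarising the observed
alternate-allele frequency against the inferred ancestral allele. With

$$d_N = \sum_{i=1}^n d_i, \qquad f_i = \frac{d_i}{d_N}, \qquad
\mathrm{DAP} = \sum_{i=1}^n f_i^{\,x},$$

the per-population score is

$$\mathrm{FineMAV}_i = \mathrm{DAP} \times d_i \times \mathrm{CADD\_PHRED}.$$

DAP (derived allele purity) measures how confined the derived allele is:
it is exactly 1 when one population carries all of it and falls to its
minimum $n^{1-x}$ under equal sharing. The penalty exponent $x > 1$
controls how harshly sharing is punished. The DAF factor rewards high
frequency, and the phred-scaled CADD score rewards predicted functional
impact, separating plausible targets of selection from hitchhikers that
reached the same frequency neutrally.

Two modelling commitments are worth making explicit:

* **Frequencies, not counts.** The purity shares $f_i$ are computed from
  frequencies, so panels with unequal sample sizes need no correction.
  A raw-count mode is deliberately not offered.
* **SNPs only.** Ancestral states can be assigned with reasonable
  confidence only for single-nucleotide substitutions, so the row
  validator enforces single-base REF/ALT in {A, C, G, T}; indels and
  multi-allelic rows are rejected with a counted reason.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `penalty` ($x$) | per-$n$ table | sharing penalty exponent (unitless); recommended minimal values are 4.96, 3.50, 2.98, 2.71, 2.53, 2.41 for $n$ = 2..7 |
| `chunk_size` | 200,000 lines | rows streamed per chunk; bounds memory, does not affect output |
| `strict_ancestral` | `FALSE` | reject lowercase (low-confidence) ancestral calls |
| `has_aa`, `has_cadd`, `header` | `TRUE, TRUE, FALSE` | declared column layout of the extract |
| `max_annotation_entries` | 5×10⁶ | budget for the in-memory annotation lookup |

The per-$n$ penalty defaults were established empirically in the method's
original formulation and are exposed through `default_penalty()`; they are
*minimal* recommendations, so a user-supplied larger $x$ is accepted, and
any panel larger than 7 requires an explicit $x$ (there is no principled
default to silently extrapolate).

Lowercase ancestral calls encode low-confidence inference in the Ensembl
ancestral-genome FASTA convention. They are accepted by default because
discarding them removes a large fraction of otherwise usable sites;
`strict_ancestral = TRUE` is available when the analysis demands
high-confidence polarisation throughout.

## Filter policy

Sites are excluded — with a per-reason counter surfaced in the run log —
rather than imputed, in exactly these cases:

* `AA_MISSING`: ancestral allele absent, `.`, `-`, or `N` after the
  annotation merge;
* `AA_LOW_CONFIDENCE`: lowercase call under strict mode;
* `AA_MISMATCH`: ancestral allele matches neither REF nor ALT (the site
  cannot be polarised; often a triallelic history);
* `CADD_MISSING`: no CADD score anywhere. Scoring these 0 instead would
  silently conflate "not annotated" with "benign" and distort the
  browser tracks, so exclusion is deliberate;
* row-level validation failures (`MALFORMED_ROW`, `BAD_LOCATION`,
  `BAD_ALLELE`, `AF_OUT_OF_RANGE`, `CADD_INVALID`).

When both the variant table and the annotation file carry a value for the
same field, the variant table wins and the annotation never overwrites it;
the merge is therefore idempotent. Duplicate annotation keys keep the
first occurrence and count a warning — deterministic and order-stable on
concatenated VEP outputs.

## Numerical and format choices

* **$d_N = 0$** (derived allele absent everywhere): DAP is defined as 0.
  Every score at such a site is 0 anyway ($d_i = 0$ for all $i$), and 0
  keeps the output total; the alternative (dropping or NaN-ing the site)
  would leave holes in the track.
* **Sites monomorphic-derived everywhere** ($d_i = 1$ for all $i$) are
  retained and score with DAP $= n^{1-x}$; they carry information about
  shared fixation and excluding them would be an extra filtering rule
  the statistic itself does not require.
* **Score TSV** renders reals with 6 significant digits (relative
  rounding ≤ 5×10⁻⁶) and is the precision-bearing artifact.
* **bigWig** stores float32 (relative error ≤ ~10⁻⁷). Each SNP becomes
  the 0-based half-open single-base interval $[pos-1, pos)$ — the only
  lossless representation of per-SNP values in this format. Duplicate
  `chrom:pos` among scored sites is fatal at write time: overlapping
  per-base values are ill-defined in bigWig, and under the biallelic-SNP
  contract a duplicate signals an upstream filtering bug, not data to be
  merged.
* **Order**: input row order is preserved end-to-end in the TSV; only the
  bigWig writer sorts its own interval buffer, as the format requires.

## The streaming engine

The variant table is read in chunks of `chunk_size` lines; each chunk is
parsed, supplemented from the annotation lookup, polarised, scored, and
appended to the output table. The annotation table is *not* chunked: it
must be randomly accessible from every chunk, so it is loaded once and
held in memory behind an entry budget (exceeding the budget aborts with
advice to pre-join the inputs). Score rows stream directly to the final
TSV rather than through per-chunk temporary files — with one writer this
is equivalent to writing chunk files and concatenating them, avoids
thousands of temporary files at small chunk sizes, and makes
byte-identical-across-chunk-sizes a structural property. Per-population
score buffers (chromosome, position, score) accumulate across chunks and
are written to bigWig once at the end. On any failure the pipeline aborts
and removes partial outputs; there is no resume mode.

The memory contract is therefore: peak usage scales with
`chunk_size` + the annotation lookup + the slim bigWig buffers, not with
the variant-table size. The test suite checks the structural half of this
contract (no block ever exceeds `chunk_size` lines; outputs are invariant
to `chunk_size`) rather than asserting absolute RSS numbers, which are
hardware- and allocator-specific.

## The synthetic generator and what passing tests mean

`generate_fixture()` produces schema-conformant inputs with known ground
truth: a configurable mix of population-specific sites (truth DAP = 1),
shared polymorphisms (DAF uniform on [0, 1] per population), and one
defect class per rejection reason, with CADD_PHRED uniform on [0, 40] and
a fraction of sites whose AA/CADD arrive only via the annotation file, so
the join is exercised end-to-end. Truth scores are computed by
`oracle_score()`, a deliberately unvectorised per-site loop that shares
no code with the production path — the independence is what makes the
equivalence tests meaningful.

The generator emulates the *schema and the statistic's input space*, not
population genetics: sites are independent (no linkage disequilibrium),
frequencies are uniform rather than drawn from any demographic model, and
no selection is simulated. Passing tests therefore demonstrate that the
pipeline computes the statistic correctly and deterministically on
conforming inputs of every class — they say nothing about the statistic's
power to detect selection in real data, which is a property of the method,
not of this implementation.

Default problem sizes in the test suite were chosen to exercise every
code path while keeping the suite fast: 5,000-site fixtures for
chunk-invariance (chunk sizes 1, 7, 64 and 200,000), 10,000 random sites
for oracle equivalence (agreement within 10⁻¹²), and a 1,000-site
fixture for the bigWig round-trip.

## Known limitations

* Single-threaded; no parallel chunk execution or cluster dispatch.
* No haploid/X-chromosome frequency adjustment: male X hemizygosity is
  the caller's concern when computing the input frequencies.
* The VCF itself is never parsed; the package consumes the `bcftools
  query` extract. This keeps the input contract explicit and the
  dependency surface small, at the cost of one extra preprocessing step.
* Per-site significance is not assessed; the statistic is a ranking
  tool, and the conventional display threshold (99th percentile,
  `score_percentiles()`) is descriptive, not inferential.
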