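---
title: "Designing explorative degenerate probes for functional gene microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing explorative degenerate probes for functional gene microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(exoprobe)
library(dplyr)
```

## The problem

Functional DNA microarrays monitor the genes behind a metabolic capability
— say, the dioxygenases that open polycyclic aromatic hydrocarbon (PAH)
rings in a contaminated soil. Probes designed against known sequences only
detect known genes; in an environmental sample most gene variants have
never been sequenced. *Explorative* probes solve this by targeting the
protein, not the gene: a conserved protein region is backtranslated
through the full redundancy of the genetic code into a degenerate
oligonucleotide that hybridizes with every DNA sequence that could encode
that region, including variants nobody has deposited yet.

This vignette walks through the model behind each stage of the package
and records the design decisions that were genuinely open.

## From alignment to degenerate consensus

Given a protein multiple alignment anchored on a reference sequence,
every column where the reference has a residue is backtranslated: the
codons of all amino acids observed in the column are pooled and collapsed
position-wise into IUPAC ambiguity codes
(`backtranslate_column()`). Two conventions matter:

* **Fully degenerate positions become inosine.** Wherever the pooled
  base set is `{A,C,G,T}` (IUPAC `N`) we write `I`. Inosine is a
  universal-pairing base: it is a *single* synthesized residue, so it
  contributes a factor 1 to the design degeneracy, but it stands for all
  four bases, so it contributes a factor 4 to the *total degeneracy* that
  determines how many fully specified probes an in-situ synthesis
  platform must print. Keeping these two counts separate is the heart of
  the method's accounting.
* **Lossy merging is accepted.** An IUPAC codon can encode more amino
  acids than the column contained (merging `GAY` ∪ `GAR` into `GAI`
  also admits `GAC/GAT/GAA/GAG` side products); this is inherent to
  column-wise backtranslation and errs on the explorative side.

Columns gapped in the reference are skipped, so the consensus coordinate
system is the ungapped reference CDS — 3 nt per reference residue, which
is how probe positions are reported. Gaps and `X` in other rows simply do
not contribute to the column set; a column left empty after exclusions is
an error rather than a silent skip. Stop codons never enter a codon
union, and the ambiguity symbols `B`/`Z` expand to `{D,N}`/`{E,Q}`. We
always emit `I` at fully degenerate positions and apply the inosine
threshold afterwards, rather than switching mid-window to `N`.

```{r}
aln <- tibble::tibble(id = c("ref", "m1", "m2"),
                      seq = c("HGWDE", "HGWEE", "HGWDE"))
cons <- build_consensus(aln, "ref")
cons
tidy(cons)
```

## Probe enumeration and the two design strategies

`enumerate_probes()` slides a window of `probe_length` (default 24 nt)
along the consensus at step 1 — probes need not be codon-aligned — and
keeps windows passing two **inclusive** thresholds: design degeneracy
`<= degeneracy_max` and inosine content `<= inosine_max_fraction` of the
probe length. Inclusive comparison is the only reading consistent with
the published bound arithmetic below. Two parameter sets are the
reference strategies:

| strategy | degeneracy max | inosine max | max total degeneracy |
|---|---|---|---|
| permissive | 129 | 25% | `129 * 4^6 = 528384` |
| stringent | 258 | 9% | `258 * 4^2 = 4128` |

```{r}
max_total_degeneracy(design_params(24, 129, 0.25))
max_total_degeneracy(design_params(24, 258, 0.09))
```

The bound is `degeneracy_max * 4^floor(L * inosine_max_fraction)`: each
allowed inosine multiplies the expanded probe count by 4. With 9% of a
24-mer, `floor(2.16) = 2` inosines are allowed.

The final base of an enumerated probe is usually a degenerate base or an
inosine (it tends to fall on a third codon position), so
`trim_probes()` removes it, halving or quartering the synthesized set at
negligible coverage cost; the published probes are 23-mers for exactly
this reason. `expand_probe()` turns a degenerate probe into its fully
specified set — `"expand"` mode (inosine to all four bases) for in-situ
synthesis, `"keep"` mode (literal `I`) for ex-situ synthesis with
inosine — with lexicographically sorted, duplicate-free output so reruns
are byte-identical.

Ranking (`rank_probes()`) follows three sequential criteria: fewest
cross-hybridization clusters, then lowest total degeneracy, then — when
selecting a fixed number of probes per gene — a greedy spacing rule that
fixes the top candidate and repeatedly picks the candidate maximizing
the minimum start-coordinate distance to those already picked. The
spacing rule is our codification of "target two different regions"; the
greedy maximin choice is deterministic and reproduces the intuitive
pick-the-ends behaviour on collinear candidates.

## Specificity screening

Cross-hybridization risk follows Kane's empirical criteria for long
oligos: a probe is at risk from a non-target sequence sharing more than
75% identity over the probe, or an identical stretch of at least 15
contiguous bases. "Longer than 15" is ambiguous for integer lengths; we
adopt the stricter `>= 15` reading, configurable in
`screen_params()`. A probe is flagged when **either** criterion is
violated.

The background is a CDS database: each coding sequence extended by 100 nt
of putative UTR flank on each side (`build_crosshyb_db()`), truncated at
contig ends and reverse-complemented for minus-strand genes. Screening
(`screen_probes()`) scans every probe variant against every record at
every offset on both strands (`kane_check()`, implemented in C++ with a
pure-R brute-force oracle in the test suite). Probe inosine matches any
base and counts as a match for both statistics. Because inosine behaves
as a universal base during hybridization, variants are enumerated in
`"keep"` mode for screening: expanding inosine would only replicate
identical scan outcomes four-fold per inosine. The scan keeps, per
variant and record, the best-identity placement (plus-strand first on
ties) and the longest stretch found anywhere on either strand.

A flagged hit is not necessarily spurious: it may be another member of
the targeted gene family, which the probe is *supposed* to detect. Each
flagged record is therefore translated in all six frames and locally
aligned against the reference protein (`family_membership()`); records
reaching a bit-score threshold are classified `target_family` and do not
count against the probe. The default threshold of 50 bits approximates
an E-value cutoff of 1e-10 at typical search-space sizes under the
Karlin–Altschul transform used throughout (`lambda = 0.267`,
`K = 0.041`, the standard gapped BLOSUM62 constants). These E-values are
estimates on a fixed scale — consistent and comparable across runs, but
not NCBI BLAST E-values.

Flagged hits are clustered by single linkage over their target regions
(the aligned window extended by one probe length each side), linking
regions with at least 90% ungapped identity (a default; no published
value exists). A candidate's `crosshyb_count` is the number of distinct
`cross_hybridization` clusters — counting loci, not raw variant hits, so
a single repeated decoy region does not dominate the ranking.

The original implementation pre-screened with a translated-database
search and verified with a nucleotide search; exhaustive scanning
dominates that cascade in sensitivity at the scale this package targets
and removes the external binary dependency. `translate_in_frame()` is
retained as the utility that enumerates the peptide combinations of a
degenerate window.

## Homolog mining

`score_homologs()` ranks a local protein database against the reference
query by best local alignment score (Smith–Waterman, affine gaps, gap of
length *g* costing `11 + g`), with `select_by_threshold()` applying the
per-gene E-value cutoffs on the estimated scale and
`filter_by_size_divergence()` excluding sequences whose length deviates
from the reference by more than a tolerance (default 20%, inclusive) —
the prefilter that keeps indel-rich rows out of the alignment. Ties in
ranking break by subject id, ascending.

## Array analysis: spatially segmented SNR'

Hybridized arrays carry thousands of random-sequence control probes that
measure technical background. Because spatial artifacts dominate
within-slide variation, the surface is segmented into a 4 × 4 grid of 16
sub-squares on the spot coordinates (half-open intervals, boundary spots
joining the higher-index square). Within each square, the random probes
give a background position (median) and dispersion, and each spot is
reduced-centralized as

SNR' = (intensity − B<sub>position</sub>) / B<sub>dispersion</sub>

Per-probe SNR' is the median over replicates (three on the reference
layout), and a probe is positive when that median **strictly** exceeds 3
— a spot sitting exactly 3 dispersions above background is not called.
The dispersion estimator is 1.4826 × MAD by default: the reference
description of the dispersion component is not given in closed form in
the main text, so a robust scale estimator consistent with the normal
standard deviation is used as a documented stand-in, with `"iqr"`
(IQR/1.349) and `"sd"` available through `background_stats()`. The
dispersion is floored at a small epsilon (default 1e-6 intensity units)
so constant backgrounds do not divide by zero; squares with fewer than
10 random probes fall back to whole-array background with a warning.
Channels of two-colour hybridizations are analyzed independently; no
ratio normalization is applied, since calls are made per channel.

```{r}
arr <- simulate_array(seed = 2, n_targets = 200, n_spiked = 10,
                      spike_k = 10, n_random = 2000, noise_sd = 5)
res <- array_snr(arr$features)
glance(res)
tidy(res) |> filter(positive) |> head()
```

## What the simulators emulate — and what they do not

The package is testable offline because every stage has a deterministic
generator (`simulate_protein_family()`, `simulate_background_db()`,
`simulate_array()`), each a pure function of its configuration and seed,
each emitting ground-truth labels.

* **Families**: a reference protein with members at a per-site
  substitution rate (default 10%, i.e. ~90% identity, typical of the
  protein families the method targets) and optional indels; coding DNA
  drawn per codon from a configurable codon-usage distribution (uniform
  by default). Defaults of 4–10 members at 150–500 residues mirror the
  published per-gene input sizes (2–9 sequences).
* **Backgrounds**: random records of 0.5–3 kb (CDS-scale) plus decoys
  engineered to violate exactly one Kane criterion: an exact probe copy,
  an evenly spaced-mismatch construct exceeding 75% identity while
  keeping every identical run short, or a construct sharing exactly a
  15-base block with every other position substituted.
* **Arrays**: spots placed uniformly at random (mirroring randomized
  layouts), a smooth spatial background gradient, Gaussian spot noise,
  three replicates per target probe, and spikes at a chosen multiple of
  the noise standard deviation.

The generators do **not** model hybridization thermodynamics, sequence-
dependent probe sensitivity, scanner saturation, or correlated spatial
noise. Passing tests therefore demonstrate that the *computational*
pipeline recovers what it is defined to recover (planted decoys, spiked
signals, exact expansion counts) — not that a physical array will behave
ideally; the reference study's wet-lab validation is out of scope here.

## Numerical choices and degenerate inputs

* Threshold comparisons (degeneracy, inosine fraction, E-value,
  identity ≥ at clustering) are inclusive; the Kane identity criterion
  is strict (`> 75%`) and the stretch criterion inclusive (`>= 15`), and
  the positive call is strict (`> 3`).
* Inosine-fraction comparisons add a square-root-of-machine-epsilon
  guard so `floor` and `<=` are immune to binary-fraction artifacts
  (e.g. `24 * 0.09`).
* Expansion refuses above a configurable cap (default 1e6 variants)
  rather than exhausting memory; the error reports the offending count.
* Degeneracy is returned as a double: products over long consensus
  sequences overflow 32-bit integers by design.
* Alignment duplicate rows are dropped before consensus (they carry no
  information); windows shorter than the probe yield an empty candidate
  table with a warning, not an error.
* All randomized tests and examples fix seeds; sizes are chosen so the
  whole suite runs in a few minutes on a single core (family fixtures of
  30–60 residues, backgrounds of 3–10 records, one 8,000-probe array
  with 8,000 random controls for the false-positive check).

## Known limitations

* E-values are Karlin–Altschul estimates over a local database; per-gene
  published E-value thresholds are honored on this estimated scale, which
  tracks but does not equal NCBI BLAST's.
* The exhaustive scanner is quadratic in (variants × background size);
  it is meant for curated backgrounds up to the few-megabase scale, not
  whole metagenomes.
* One published probe (`bphB_MD_B`) prints an expansion count
  inconsistent with its printed sequence under any reading of the
  expansion rule validated by the other fifteen probes; the package
  implements the validated rule.
* Melting-temperature/thermodynamic scoring and external
  multiple-aligner integration are deliberately out of scope; alignments
  are inputs.
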