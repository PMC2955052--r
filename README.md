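# exoprobe

Design and in-silico evaluation of **explorative degenerate probes** for
functional gene microarrays.

Classical functional arrays carry probes matched to known gene sequences,
so they only ever detect genes that are already in a database. In an
environmental sample — a PAH-contaminated soil, an anaerobic digester —
most variants of a catabolic gene have never been sequenced. Explorative
probes target the *protein* instead: a conserved region of a protein
family is backtranslated through the full redundancy of the genetic code
into a degenerate oligonucleotide (IUPAC ambiguity codes plus inosine)
that hybridizes with every coding sequence the region could have,
including unknown variants.

`exoprobe` implements the complete design pipeline as a tidyverse-style R
package:

1. **Homolog mining** — rank a local protein database against a
   reference query by Smith–Waterman score with Karlin–Altschul E-value
   estimates (`score_homologs()`, `select_by_threshold()`), and
   prefilter by size divergence before alignment
   (`filter_by_size_divergence()`).
2. **Degenerate consensus** — backtranslate each column of a protein
   multiple alignment into a degenerate codon, writing inosine (`I`) at
   fully degenerate positions (`build_consensus()`,
   `backtranslate_column()`). Inosine counts 1 toward the design
   *degeneracy* `D(s) = prod(|base set|), I = 1` but 4 toward the *total
   degeneracy* `D_tot(s) = prod(|base set|), I = 4`, the number of fully
   specified probes synthesized in situ.
3. **Probe enumeration** — slide a 24-mer window at step 1 and keep
   windows with `D <= degeneracy_max` and inosine fraction
   `<= inosine_max` (`enumerate_probes()`); trim the (usually
   degenerate) last base (`trim_probes()`); expand to the specific probe
   set (`expand_probes()`). The two reference strategies bound the total
   degeneracy at `129 * 4^6 = 528,384` and `258 * 4^2 = 4,128`
   (`max_total_degeneracy()`).
4. **Specificity screening** — scan every variant against a CDS + 100 nt
   flank background database (`build_crosshyb_db()`) at every offset on
   both strands and flag matches by Kane's criteria for long oligos:
   identity > 75% **or** an identical stretch of >= 15 contiguous bases
   (`kane_check()`, `screen_probes()`). Flagged records that align to
   the reference protein in six-frame translation are rescued as
   `target_family` (`family_membership()`); the rest are clustered into
   cross-hybridization loci (`cluster_hits()`) and counted against the
   probe (`add_crosshyb_counts()`, `rank_probes()`).
5. **Array analysis** — normalize spotted-array intensities into
   `SNR' = (intensity - Bposition) / Bdispersion`, with background
   position/dispersion measured from random control probes within each
   of 16 spatial sub-squares, median over 3 replicates, positive call at
   `SNR' > 3` strictly (`array_snr()` and friends).
6. **Simulators** — deterministic generators for homologous families
   with true coding DNA, backgrounds with decoys violating exactly one
   Kane criterion, and arrays with spatial gradients and spiked probes
   (`simulate_protein_family()`, `simulate_background_db()`,
   `simulate_array()`), each emitting ground-truth labels.

Results are tibbles throughout; fitted objects support `tidy()`,
`glance()` and `autoplot()`. A thin command-line wrapper with
`design`, `screen`, `build-db`, `array-snr` and `simulate` subcommands
lives at `system.file("cli", "exoprobe.R", package = "exoprobe")`.

## Worked example

```r
library(exoprobe)
library(dplyr)

# a simulated family: reference + 6 members at ~92% identity
fam <- simulate_protein_family(seed = 42, reference_length = 120,
                               n_members = 6, substitution_rate = 0.08,
                               indel_rate = 0)

# stringent design strategy: degeneracy <= 258, inosine <= 9% of 24
d <- design_probes(fam$proteins, "REF",
                   design_params(24, 258, 0.09), gene = "phn")

# background: the source gene, 5 random CDS-like records, one decoy
# sharing a 16-base stretch with the first candidate
db <- simulate_background_db(
  seed = 43, n_records = 5, length_range = c(300, 600),
  planted = tibble::tibble(probe = d$candidates$seq[1],
                           type = "stretch", value = 16))
full_db <- bind_rows(
  tibble::tibble(id = "source_gene",
                 seq = fam$cds$seq[fam$cds$id == "REF"]),
  db$db)

res <- screen_and_rank(d$candidates, full_db,
                       fam$proteins$seq[fam$proteins$id == "REF"])
res$candidates |> select(probe_id, seq, start_nt, total_degeneracy,
                         crosshyb_count)
#> # A tibble: 3 × 5
#>   probe_id   seq                     start_nt total_degeneracy crosshyb_count
#> 1 phn_MD_002 THGARGARGTICCITTYGARTGY       89             1536              1
#> 2 phn_MD_003 HGARGARGTICCITTYGARTGYG       90             1536              1
#> 3 phn_MD_001 ATHGARGARGTICCITTYGARTG       88              768              2
```

Three 23-mer candidates survive the thresholds. Every hit on
`source_gene` is classified `target_family` (the probe is *supposed* to
bind its own gene family), so it costs nothing; the planted decoy is
flagged and counted, and probes are ranked by cross-hybridization
cluster count before total degeneracy — which is why `phn_MD_002`
(1 cluster, 1,536 variants) outranks `phn_MD_001` (2 clusters, 768
variants).

```r
arr <- simulate_array(seed = 7, n_targets = 500, n_spiked = 12,
                      spike_k = 10, n_random = 4000, noise_sd = 5)
snr <- array_snr(arr$features)
glance(snr)
#> # A tibble: 1 × 5
#>   n_probes n_positive n_squares median_background threshold
#> 1      500         12        16              235.         3
```

All 12 probes spiked at 10 sigma above the local background — and no
others — are called positive at the strict `SNR' > 3` threshold.

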