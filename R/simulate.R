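# Deterministic simulators: homologous protein families with their true
# coding DNA, background databases with decoys engineered to violate
# exactly one Kane criterion, and array feature tables with a spatial
# background gradient plus random control probes. Every generator is a
# pure function of its configuration and seed and emits ground-truth
# labels, so screening and calling accuracy can be measured.

.sample_protein <- function(n) {
  paste(sample(.standard_aas, n, replace = TRUE), collapse = "")
}

#' Simulate a homologous protein family with coding DNA
#'
#' A reference protein is drawn uniformly over the 20 standard residues;
#' each member is derived from it by independent per-site substitution
#' (to a different residue) and indel events (insertion or deletion,
#' equal odds). True coding DNA is drawn per residue from the synonymous
#' codons under `codon_usage`.
#'
#' @param seed Integer seed; the output is a pure function of the
#'   configuration and seed.
#' @param reference_length Reference length in residues.
#' @param n_members Number of derived family members.
#' @param substitution_rate,indel_rate Per-site event probabilities.
#' @param codon_usage Optional named numeric vector of codon weights
#'   (names = codons); default uniform over synonymous codons.
#' @param code Genetic code from [genetic_code()].
#' @return List: `reference_id`, `proteins` (tibble `id`, `seq`;
#'   reference first), `cds` (tibble `id`, `seq`: true coding DNA,
#'   including the reference's).
#' @export
simulate_protein_family <- function(seed = 1, reference_length = 300,
                                    n_members = 6,
                                    substitution_rate = 0.1,
                                    indel_rate = 0.01,
                                    codon_usage = NULL,
                                    code = genetic_code()) {
  stopifnot(reference_length >= 1, n_members >= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  withr::local_seed(seed)
  reference <- .sample_protein(reference_length)
  mutate_protein <- function(ref) {
    res <- strsplit(ref, "")[[1]]
    out <- character(0)
    for (a in res) {
      r <- stats::runif(1)
      if (r < substitution_rate) {
        a <- sample(setdiff(.standard_aas, a), 1L)
      }
      ri <- stats::runif(1)
      if (ri < indel_rate / 2) {
        next  # deletion
      } else if (ri < indel_rate) {
        out <- c(out, a, sample(.standard_aas, 1L))  # insertion after
        next
      }
      out <- c(out, a)
    }
    if (length(out) == 0L) out <- sample(.standard_aas, 1L)
    paste(out, collapse = "")
  }
  members <- vapply(seq_len(n_members), function(i) mutate_protein(reference),
                    character(1))
  ids <- c("REF", sprintf("member_%02d", seq_len(n_members)))
  proteins <- tibble(id = ids, seq = c(reference, members))
  codons_of <- lapply(.standard_aas, function(a) names(code)[code == a])
  names(codons_of) <- .standard_aas
  encode <- function(prot) {
    paste(vapply(strsplit(prot, "")[[1]], function(a) {
      cands <- codons_of[[a]]
      w <- if (is.null(codon_usage)) NULL else codon_usage[cands]
      sample(cands, 1L, prob = w)
    }, character(1)), collapse = "")
  }
  cds <- tibble(id = ids, seq = vapply(proteins$seq, encode, character(1)))
  list(reference_id = "REF", proteins = proteins, cds = cds)
}

.sample_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# plant `insert` into `host` at a random interior position
.plant <- function(host, insert) {
  n <- nchar(host)
  L <- nchar(insert)
  stopifnot(L <= n)
  pos <- sample.int(n - L + 1L, 1L)
  list(seq = paste0(substr(host, 1L, pos - 1L), insert,
                    substr(host, pos + L, n)),
       position = pos)
}

#' Simulate a background database with Kane-criterion decoys
#'
#' Generates random CDS-like nucleotide records and, for each row of
#' `planted`, embeds a decoy engineered from one fully specified variant
#' of the given probe:
#' * `"copy"` — the exact variant (identity 100, stretch = probe length);
#' * `"identity"` — the variant with mismatches placed at even spacing so
#'   the identity is close to (and not below) `value` percent while every
#'   identical stretch stays shorter than 15 bases;
#' * `"stretch"` — a full-length construct sharing exactly a
#'   `value`-base block (default 15) with the variant, every other
#'   position substituted, so only the stretch criterion is violated.
#'
#' @param seed Integer seed.
#' @param n_records Number of random background records.
#' @param length_range Record length range in nucleotides.
#' @param planted Optional tibble with columns `probe` (degenerate
#'   sequence), `type` (`"copy"`, `"identity"`, `"stretch"`) and `value`
#'   (identity percent or stretch length; ignored for `"copy"`).
#' @param gc GC content of the random records.
#' @return List: `db` (tibble `id`, `seq`), `truth` (tibble `id`,
#'   `probe`, `type`, `value`, `position`, `planted_seq`; one row per
#'   decoy).
#' @export
simulate_background_db <- function(seed = 1, n_records = 100,
                                   length_range = c(500, 3000),
                                   planted = NULL, gc = 0.5) {
  stopifnot(n_records >= 1, length_range[1] >= 30)
  withr::local_seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_records, replace = TRUE)
  db <- tibble(
    id = sprintf("bg_%04d", seq_len(n_records)),
    seq = vapply(lens, .sample_dna, character(1), gc = gc)
  )
  truth <- tibble(id = character(), probe = character(), type = character(),
                  value = numeric(), position = integer(),
                  planted_seq = character())
  if (!is.null(planted) && nrow(planted) > 0L) {
    stopifnot(all(c("probe", "type") %in% names(planted)))
    if (!"value" %in% names(planted)) planted$value <- NA_real_
    for (i in seq_len(nrow(planted))) {
      probe <- planted$probe[[i]]
      type <- planted$type[[i]]
      value <- planted$value[[i]]
      variant <- expand_probe(probe, "expand")[[1]]
      L <- nchar(variant)
      insert <- switch(
        type,
        copy = variant,
        identity = {
          if (is.na(value)) value <- 90
          if (value > 100) abort("planted identity above 100%")
          n_mm <- ceiling(L * (1 - value / 100))
          if (n_mm >= 1) {
            # even spacing keeps every identical run under 15 bases
            pos <- round(seq(1, L, length.out = n_mm + 2L))[2:(n_mm + 1L)]
            ch <- strsplit(variant, "")[[1]]
            for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                   ch[p]), 1L)
            paste(ch, collapse = "")
          } else variant
        },
        stretch = {
          if (is.na(value)) value <- 15
          if (value > L) abort("planted stretch longer than the probe")
          # full-length construct sharing exactly a value-base block:
          # every position outside the block is a deliberate mismatch, so
          # only the stretch criterion is violated (identity ~ value/L)
          start <- sample.int(L - value + 1L, 1L)
          ch <- strsplit(variant, "")[[1]]
          outside <- setdiff(seq_len(L), start:(start + value - 1L))
          for (p in outside) {
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          }
          paste(ch, collapse = "")
        },
        abort(sprintf("unknown plant type '%s'", type))
      )
      host_id <- sprintf("decoy_%04d", i)
      host <- .sample_dna(max(length_range[1], 3L * L), gc = gc)
      pl <- .plant(host, insert)
      db <- dplyr::bind_rows(db, tibble(id = host_id, seq = pl$seq))
      truth <- dplyr::bind_rows(truth, tibble(
        id = host_id, probe = probe, type = type, value = value,
        position = pl$position, planted_seq = insert))
    }
  }
  list(db = db, truth = truth)
}

#' Simulate a spotted-array feature table
#'
#' Spots are placed uniformly at random over `extent`; each target probe
#' gets `replicates` randomly placed spots (mirroring random replicate
#' distribution across real arrays), random control probes one spot
#' each. Intensities are `gradient(x, y) + noise + spike`, where spiked
#' target probes sit `spike_k` noise standard deviations above the local
#' background and random probes carry no spike. Intensities are clipped
#' at 0.
#'
#' @param seed Integer seed.
#' @param n_targets Number of target probes.
#' @param n_spiked Number of target probes receiving the spike (the
#'   first `n_spiked` ids).
#' @param spike_k Spike height in units of `noise_sd`.
#' @param replicates Replicate spots per target probe (default 3).
#' @param n_random Number of random control probes.
#' @param noise_sd Gaussian noise standard deviation.
#' @param gradient Function of `(x, y)` giving the spatial background
#'   surface; default a tilted plane `200 + 0.05 x + 0.02 y`.
#' @param extent Array surface size `c(width, height)`.
#' @return List: `features` (tibble `probe_id`, `x`, `y`, `intensity`,
#'   `probe_class`, `replicate`), `truth` (tibble `probe_id`, `spiked`).
#' @export
simulate_array <- function(seed = 1, n_targets = 100, n_spiked = 10,
                           spike_k = 10, replicates = 3, n_random = 2000,
                           noise_sd = 5,
                           gradient = NULL, extent = c(1000, 1000)) {
  stopifnot(n_targets >= 0, n_spiked <= n_targets, n_random >= 1,
            replicates >= 1, noise_sd >= 0)
  withr::local_seed(seed)
  gradient <- gradient %||% function(x, y) 200 + 0.05 * x + 0.02 * y
  target_ids <- sprintf("probe_%04d", seq_len(n_targets))
  spiked_ids <- target_ids[seq_len(n_spiked)]
  feats <- dplyr::bind_rows(
    tidyr::expand_grid(probe_id = target_ids,
                       replicate = seq_len(replicates)) |>
      dplyr::mutate(probe_class = "target"),
    tibble(probe_id = sprintf("random_%05d", seq_len(n_random)),
           replicate = 1L, probe_class = "random")
  )
  n <- nrow(feats)
  feats$x <- stats::runif(n, 0, extent[1])
  feats$y <- stats::runif(n, 0, extent[2])
  spike <- ifelse(feats$probe_id %in% spiked_ids, spike_k * noise_sd, 0)
  feats$intensity <- pmax(
    0, gradient(feats$x, feats$y) + stats::rnorm(n, 0, noise_sd) + spike)
  list(
    features = dplyr::select(feats, "probe_id", "x", "y", "intensity",
                             "probe_class", "replicate"),
    truth = tibble(probe_id = target_ids,
                   spiked = target_ids %in% spiked_ids)
  )
}
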