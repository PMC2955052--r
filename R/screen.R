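# Cross-hybridization screening: CDS+flank background database, Kane's
# specificity criteria (75% identity / 15-base identical stretch),
# target-family rescue by six-frame comparison with the reference
# protein, and single-linkage clustering of flagged hits.

#' Screening parameters
#'
#' @param identity_max Identity percentage above which a background match
#'   is a cross-hybridization risk (strictly greater; default 75, Kane's
#'   first criterion for long oligos).
#' @param stretch_min Length in bases of a contiguous identical stretch
#'   that flags a match (at least; default 15, Kane's second criterion in
#'   its stricter reading).
#' @param family_min_bitscore Minimum estimated bit score of the best
#'   six-frame local alignment of the target against the reference
#'   protein for the target to count as a member of the probed gene
#'   family (default 50, approximating an E-value cutoff of 1e-10 at
#'   typical search-space sizes).
#' @param cluster_min_identity Minimum ungapped identity (percent) linking
#'   two hit regions into one cross-hybridization cluster (default 90).
#' @param expansion_cap Refuse probe expansions above this variant count.
#' @return A `screen_params` list.
#' @export
screen_params <- function(identity_max = 75, stretch_min = 15,
                          family_min_bitscore = 50,
                          cluster_min_identity = 90,
                          expansion_cap = 1e6) {
  stopifnot(identity_max >= 0, identity_max <= 100, stretch_min >= 1,
            cluster_min_identity >= 0, cluster_min_identity <= 100)
  structure(
    list(identity_max = identity_max, stretch_min = stretch_min,
         family_min_bitscore = family_min_bitscore,
         cluster_min_identity = cluster_min_identity,
         expansion_cap = expansion_cap),
    class = "screen_params"
  )
}

#' Build the cross-hybridization background database
#'
#' Extracts one record per CDS feature: the CDS extended by up to `flank`
#' nucleotides of putative 5' and 3' UTR on each side (truncated at the
#' parent sequence ends), reverse-complemented for minus-strand features
#' so every record reads 5' to 3' of the coding strand.
#'
#' @param genome A named character vector / tibble (`id`, `seq`) of
#'   parent sequences, a `Biostrings::DNAStringSet`, or a FASTA path.
#' @param annotations CDS features: a GFF3 path, a
#'   `GenomicRanges::GRanges`, or a tibble with columns `seqid`, `start`,
#'   `end`, `strand` (1-based inclusive) and optionally `id`.
#' @param flank Flank length in nucleotides (default 100).
#' @return Tibble of background records: `id`, `seq`, `parent`, `strand`,
#'   `cds_start`, `cds_end`, `flank5`, `flank3`.
#' @export
build_crosshyb_db <- function(genome, annotations, flank = 100) {
  seqs <- .as_dna_named(genome)
  feats <- .as_cds_table(annotations)
  missing <- setdiff(feats$seqid, names(seqs))
  if (length(missing) > 0L) {
    abort(sprintf("CDS parent sequence not in genome: '%s'", missing[[1]]))
  }
  purrr::pmap_dfr(feats, function(seqid, start, end, strand, id) {
    parent <- seqs[[seqid]]
    plen <- nchar(parent)
    if (start < 1L || end > plen || start > end) {
      abort(sprintf("CDS %d..%d outside parent '%s' (1..%d)",
                    start, end, seqid, plen))
    }
    f5 <- min(flank, start - 1L)
    f3 <- min(flank, plen - end)
    rec <- substr(parent, start - f5, end + f3)
    if (strand == "-") {
      rec <- .revcomp(rec)
      tmp <- f5; f5 <- f3; f3 <- tmp  # flanks follow the coding strand
    }
    tibble(id = id, seq = rec, parent = seqid, strand = strand,
           cds_start = start, cds_end = end, flank5 = f5, flank3 = f3)
  })
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.as_dna_named <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.data.frame(genome)) {
    return(stats::setNames(genome$seq, genome$id))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  abort("genome must be a FASTA path, DNAStringSet, tibble or named vector")
}

.as_cds_table <- function(annotations) {
  if (is.character(annotations) && length(annotations) == 1L &&
      file.exists(annotations)) {
    annotations <- rtracklayer::import(annotations)
  }
  if (methods::is(annotations, "GRanges")) {
    gr <- annotations
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[tolower(as.character(gr$type)) == "cds"]
    }
    ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
           else sprintf("cds_%04d", seq_along(gr))
    return(tibble(
      seqid = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                      "-", "+"),
      id = ids
    ))
  }
  if (is.data.frame(annotations)) {
    stopifnot(all(c("seqid", "start", "end", "strand") %in%
                    names(annotations)))
    out <- as_tibble(annotations)
    if (!"id" %in% names(out)) {
      out$id <- sprintf("cds_%04d", seq_len(nrow(out)))
    }
    return(dplyr::select(out, "seqid", "start", "end", "strand", "id"))
  }
  abort("annotations must be a GFF3 path, GRanges or tibble")
}

#' Kane specificity scan of a probe against one background record
#'
#' Evaluates the best ungapped alignment of the probe at every offset of
#' the target and its reverse complement. Identity is the match count at
#' the best offset over the probe length; the longest stretch is the
#' longest run of consecutive matches anywhere on either strand (it may
#' come from a different offset than the best identity). Probe inosine
#' matches any base and counts as a match for both statistics.
#'
#' @param probe Probe sequence (fully specified or inosine-containing).
#' @param target Background nucleotide sequence (`A C G T N`).
#' @return One-row tibble: `identity_pct`, `longest_stretch`, `position`
#'   (1-based start of the best-identity alignment on the scanned
#'   strand), `strand`.
#' @export
kane_check <- function(probe, target) {
  stopifnot(length(probe) == 1L, length(target) == 1L)
  as_tibble(.kane_scan_cpp(toupper(probe), toupper(target)))
}

#' Does a background record belong to the targeted gene family?
#'
#' A flagged background match may simply be another member of the probed
#' gene family rather than a spurious cross-hybridization. The record is
#' translated in all six frames (stops retained, fuzzy codons as `X`)
#' and locally aligned against the reference protein with the same
#' scoring as [score_homologs()]; membership holds iff the best bit
#' score reaches `min_bitscore`.
#'
#' @param target Background nucleotide sequence.
#' @param reference_protein Reference protein sequence.
#' @param min_bitscore Minimum estimated bit score (default 50).
#' @return Logical.
#' @export
family_membership <- function(target, reference_protein, min_bitscore = 50) {
  stopifnot(nchar(target) > 0L)
  peps <- .six_frame_peptides(target)
  peps <- peps[nchar(peps) > 0L]
  if (length(peps) == 0L) return(FALSE)
  raw <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(peps),
    subject = Biostrings::AAString(reference_protein),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
  )
  bit <- (.ka_lambda * max(raw, 0) - log(.ka_K)) / log(2)
  bit >= min_bitscore
}

.six_frame_peptides <- function(dna) {
  dna <- toupper(dna)
  strands <- c(dna, .revcomp(dna))
  unlist(lapply(strands, function(s) {
    vapply(1:3, function(f) {
      n <- (nchar(s) - f + 1L) %/% 3L
      if (n < 1L) return("")
      sub <- substr(s, f, f + 3L * n - 1L)
      as.character(Biostrings::translate(
        Biostrings::DNAString(sub),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
    }, character(1))
  }))
}

#' Screen candidate probes against a background database
#'
#' Every probe variant (IUPAC codes expanded, inosine retained as the
#' universal base it is during hybridization) is scanned against every
#' background record on both strands with [kane_check()]. A match is
#' flagged when it violates either Kane criterion (identity above
#' `identity_max` percent, or an identical stretch of at least
#' `stretch_min` bases). Flagged matches on records belonging to the
#' targeted gene family ([family_membership()]) are classified
#' `target_family`; the rest are `cross_hybridization`. Each record
#' contributes at most one hit per variant per strand (the scan already
#' keeps the best offset). Hits are clustered with [cluster_hits()].
#'
#' @param candidates Candidate tibble from [enumerate_probes()] (or any
#'   tibble with `probe_id`, `seq`).
#' @param db Background tibble from [build_crosshyb_db()] (or `id`,
#'   `seq`).
#' @param reference_protein Reference protein for family rescue.
#' @param params A [screen_params()] object.
#' @return Tibble of flagged hits: `probe_id`, `variant_seq`, `target_id`,
#'   `strand`, `target_start`, `identity_pct`, `longest_stretch`,
#'   `classification`, `cluster_id`.
#' @export
screen_probes <- function(candidates, db, reference_protein,
                          params = screen_params()) {
  stopifnot(is.data.frame(candidates),
            all(c("probe_id", "seq") %in% names(candidates)),
            is.data.frame(db), all(c("id", "seq") %in% names(db)))
  if (nrow(db) == 0L) abort("empty background database")
  family_cache <- new.env(parent = emptyenv())
  is_family <- function(rec_id, rec_seq) {
    if (is.null(family_cache[[rec_id]])) {
      family_cache[[rec_id]] <- family_membership(
        rec_seq, reference_protein, params$family_min_bitscore)
    }
    family_cache[[rec_id]]
  }
  hits <- purrr::map2_dfr(candidates$probe_id, candidates$seq,
                          function(pid, pseq) {
    variants <- expand_probe(pseq, "keep", params$expansion_cap)
    per_rec <- purrr::map_dfr(seq_len(nrow(db)), function(r) {
      res <- as_tibble(.kane_scan_cpp(variants, toupper(db$seq[[r]])))
      res$variant_seq <- variants
      res$target_id <- db$id[[r]]
      flagged <- res$identity_pct > params$identity_max |
        res$longest_stretch >= params$stretch_min
      res <- res[flagged, , drop = FALSE]
      if (nrow(res) == 0L) return(res)
      res$classification <- if (is_family(db$id[[r]], db$seq[[r]]))
        "target_family" else "cross_hybridization"
      res
    })
    if (nrow(per_rec) == 0L) return(per_rec)
    per_rec$probe_id <- pid
    per_rec
  })
  if (nrow(hits) == 0L) {
    return(tibble(probe_id = character(), variant_seq = character(),
                  target_id = character(), strand = character(),
                  target_start = integer(), identity_pct = numeric(),
                  longest_stretch = integer(),
                  classification = character(), cluster_id = integer()))
  }
  hits <- dplyr::transmute(
    hits,
    probe_id = .data$probe_id, variant_seq = .data$variant_seq,
    target_id = .data$target_id, strand = .data$strand,
    target_start = .data$position,
    identity_pct = .data$identity_pct,
    longest_stretch = .data$longest_stretch,
    classification = .data$classification
  ) |>
    dplyr::arrange(.data$probe_id, .data$target_id, .data$variant_seq,
                   .data$strand)
  cluster_hits(hits, db, params$cluster_min_identity)
}

#' Cluster flagged hits by target-region similarity
#'
#' Single-linkage clustering of hit regions: the region around each hit
#' (the aligned window extended by one probe length on each side) is
#' extracted from its target record, and two hits are linked when their
#' regions share ungapped identity of at least `min_identity` percent on
#' either strand. Cluster ids are assigned by increasing smallest member
#' index within each probe.
#'
#' @param hits Hit tibble (see [screen_probes()]).
#' @param db Background tibble the hits refer to.
#' @param min_identity Linking identity threshold in percent (default 90).
#' @return `hits` with a `cluster_id` column.
#' @export
cluster_hits <- function(hits, db, min_identity = 90) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    hits$cluster_id <- integer(0)
    return(hits)
  }
  rec <- stats::setNames(toupper(db$seq), db$id)
  L <- nchar(hits$variant_seq)
  regions <- vapply(seq_len(nrow(hits)), function(i) {
    t <- rec[[hits$target_id[[i]]]]
    Tn <- nchar(t)
    pos <- hits$target_start[[i]]
    len <- L[[i]]
    if (hits$strand[[i]] == "-") {  # convert to plus-strand coordinates
      pos <- Tn - (pos + len - 1L) + 1L
    }
    substr(t, max(1L, pos - len), min(Tn, pos + 2L * len - 1L))
  }, character(1))
  # hits at the same locus share a region string; cluster unique regions
  hits$cluster_id <- NA_integer_
  for (pid in unique(hits$probe_id)) {
    sel <- which(hits$probe_id == pid)
    reg <- regions[sel]
    ureg <- unique(reg)
    n <- length(ureg)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        a <- ureg[[i]]; b <- ureg[[j]]
        if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
        ident <- .kane_scan_cpp(a, b)$identity_pct[[1]]
        if (ident >= min_identity) parent[find(j)] <- find(i)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    # cluster ids by increasing smallest member index within the probe
    hit_root <- roots[match(reg, ureg)]
    hits$cluster_id[sel] <- as.integer(match(hit_root, unique(hit_root)))
  }
  hits
}

#' Fill per-candidate cross-hybridization counts from screened hits
#'
#' The cross-hybridization count of a candidate is the number of distinct
#' hit clusters classified `cross_hybridization` (target-family hits do
#' not count against a probe).
#'
#' @param candidates Candidate tibble.
#' @param hits Hit tibble from [screen_probes()].
#' @return `candidates` with `crosshyb_count` populated (0 where no
#'   cross-hybridizing cluster was found).
#' @export
add_crosshyb_counts <- function(candidates, hits) {
  counts <- hits |>
    dplyr::filter(.data$classification == "cross_hybridization") |>
    dplyr::distinct(.data$probe_id, .data$cluster_id) |>
    dplyr::count(.data$probe_id, name = "crosshyb_count")
  candidates |>
    dplyr::select(-dplyr::any_of("crosshyb_count")) |>
    dplyr::left_join(counts, by = "probe_id") |>
    dplyr::mutate(crosshyb_count =
                    dplyr::coalesce(.data$crosshyb_count, 0L))
}
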