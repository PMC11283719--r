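## Per-bead vSAG construction: virality filtering, tetranucleotide +
## abundance binning, poly-N concatenation, completeness estimation and
## highest-completeness bin selection with exclusion bookkeeping.

## Canonical 4-mer classes: each of the 256 4-mers pooled with its reverse
## complement -> 136 classes, named by the lexicographically smaller member.
canonical_tetramers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, stringsAsFactors = FALSE)
  kmers <- paste0(g[[4]], g[[3]], g[[2]], g[[1]])
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  stats::setNames(pmin(kmers, rc), kmers)
}

#' Canonical tetranucleotide frequency vector
#'
#' Counts all forward-strand 4-mers, pools each with its reverse complement
#' into 136 canonical classes and normalises to sum 1, so
#' `compute_tnf(x) == compute_tnf(revcomp(x))`. Windows containing non-ACGT
#' symbols (e.g. N linkers) are skipped.
#'
#' @param sequence DNA string of length >= 1000.
#' @return Named numeric vector of length 136 summing to 1.
#' @export
compute_tnf <- function(sequence) {
  stopifnot(nchar(sequence) >= 1000)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sequence), 4)
  canon <- canonical_tetramers()
  agg <- tapply(counts[names(canon)], canon, sum)
  out <- as.numeric(agg) / sum(agg)
  names(out) <- names(agg)
  out
}

#' Surrogate virality filter
#'
#' Scores each contig by the fraction of its length covered by ground-truth
#' viral genes of its source genome (simulation mode); a custom
#' `scorer(contig)` can be plugged in for real data. Contigs scoring below
#' `score_threshold` are dropped -- background/host contigs carry no viral
#' genes and score ~0.
#'
#' @param contigs List of `Contig`s.
#' @param community The `Community` providing ground-truth gene annotations.
#' @param score_threshold Keep contigs with score >= threshold.
#' @param scorer Optional function `(contig) -> score` overriding the
#'   ground-truth scorer.
#' @return List: `kept` (contigs), `scores` (data.frame `contig_id`, `score`,
#'   `kept`).
#' @export
virality_filter <- function(contigs, community = NULL, score_threshold = 0.3,
                            scorer = NULL) {
  if (is.null(scorer)) {
    stopifnot(!is.null(community))
    scorer <- function(ct) {
      g <- community$genomes[[ct$source_genome_id]]
      if (is.null(g) || !nrow(g$genes)) return(0)
      iv <- ct$source_interval
      ov <- pmin(g$genes$end, iv[2]) - pmax(g$genes$start, iv[1])
      sum(pmax(ov, 0)) / (iv[2] - iv[1])
    }
  }
  scores <- vapply(contigs, scorer, numeric(1))
  keep <- scores >= score_threshold
  list(kept = contigs[keep],
       scores = data.frame(
         contig_id = vapply(contigs, `[[`, character(1), "contig_id"),
         score = scores, kept = keep, stringsAsFactors = FALSE))
}

#' Contig features for binning
#'
#' Computes the canonical TNF vector and a pooled-read abundance per contig.
#' In simulation mode the abundance surrogate is the expected metagenomic
#' depth of the contig's source genome, `relative abundance / genome length`
#' (scaled by 1e6); in real mode supply `abundance` (named by contig_id)
#' from an external read-mapping table.
#'
#' @param contigs List of `Contig`s (length >= 1 kb each).
#' @param community `Community` for the simulation-mode abundance surrogate.
#' @param abundance Optional named numeric vector of per-contig abundances.
#' @return List of `ContigFeatures`: `contig_id`, `tnf`, `abundance`,
#'   `length`, `contig`.
#' @export
contig_features <- function(contigs, community = NULL, abundance = NULL) {
  lapply(contigs, function(ct) {
    ab <- if (!is.null(abundance)) unname(abundance[ct$contig_id]) else {
      src <- ct$source_genome_id
      if (!is.null(community$genomes[[src]])) {
        1e6 * community$abundances[[src]] / nchar(community$genomes[[src]]$sequence)
      } else if (!is.null(community$background_genome) &&
                 src == community$background_genome$genome_id) {
        1e6 * community$background_genome$abundance /
          nchar(community$background_genome$sequence)
      } else 0
    }
    list(contig_id = ct$contig_id, tnf = compute_tnf(ct$sequence),
         abundance = ab, length = nchar(ct$sequence), contig = ct)
  })
}

#' Bin one bead's contigs on TNF and abundance
#'
#' Pairwise distance is `tnf_weight * ||tnf_i - tnf_j||_2 +
#' abund_weight * |log(a_i / a_j)|`; contigs are clustered by single linkage
#' and cut at `cutoff`; clusters whose total length falls below
#' `min_bin_size` are discarded.
#'
#' @param features List from [contig_features()].
#' @param bead_id Bead identifier for bin naming.
#' @param min_bin_size Minimum bin total length (default 10 kb).
#' @param tnf_weight,abund_weight Distance weights.
#' @param cutoff Single-linkage cut height.
#' @return List of `Bin`s: `bin_id`, `bead_id`, `contig_ids`, `contigs`,
#'   `total_length`, `completeness` (NA), `quality_tier` (NA).
#' @export
bin_bead <- function(features, bead_id, min_bin_size = 10000,
                     tnf_weight = 1.0, abund_weight = 0.5, cutoff = 0.3) {
  stopifnot(length(features) >= 1)
  n <- length(features)
  if (n == 1) {
    cl <- 1L
  } else {
    tnf <- do.call(rbind, lapply(features, `[[`, "tnf"))
    la <- log(pmax(vapply(features, `[[`, numeric(1), "abundance"), 1e-12))
    d <- tnf_weight * stats::dist(tnf) + abund_weight * stats::dist(la)
    cl <- stats::cutree(stats::hclust(d, method = "single"), h = cutoff)
  }
  bins <- list()
  for (k in sort(unique(cl))) {
    members <- features[cl == k]
    tot <- sum(vapply(members, `[[`, numeric(1), "length"))
    if (tot < min_bin_size) next
    i <- length(bins) + 1
    bins[[i]] <- structure(list(
      bin_id = sprintf("%s_bin%02d", bead_id, i), bead_id = bead_id,
      contig_ids = vapply(members, `[[`, character(1), "contig_id"),
      contigs = lapply(members, `[[`, "contig"),
      total_length = tot, completeness = NA_real_,
      quality_tier = NA_character_), class = "Bin")
  }
  bins
}

#' Concatenate a bin's contigs with poly-N linkers
#'
#' Contigs are joined in descending length order, separated by runs of `N`
#' of `linker_len`; a single contig is returned unchanged. The result is
#' decodable back to the contig list by [split_polyN()].
#'
#' @param bin A `Bin` (or list of contigs).
#' @param linker_len Linker length in bp.
#' @return The concatenated sequence (character string).
#' @export
concatenate_with_polyN <- function(bin, linker_len = 100) {
  contigs <- if (inherits(bin, "Bin")) bin$contigs else bin
  stopifnot(length(contigs) >= 1)
  seqs <- vapply(contigs, `[[`, character(1), "sequence")
  seqs <- seqs[order(nchar(seqs), decreasing = TRUE)]
  paste(seqs, collapse = strrep("N", linker_len))
}

#' Split a poly-N concatenated sequence back into contigs
#'
#' Any maximal run of >= `min_run` Ns is treated as a linker.
#'
#' @param sequence Concatenated sequence.
#' @param min_run Minimum N-run length recognised as a linker.
#' @return Character vector of contig sequences.
#' @export
split_polyN <- function(sequence, min_run = 10) {
  parts <- strsplit(sequence, sprintf("N{%d,}", min_run))[[1]]
  parts[nchar(parts) > 0]
}

#' Estimate bin completeness from an expected-length model
#'
#' `completeness = 100 * min(1, ungapped_length / expected_length)`. In
#' simulation mode the expected length is the true length of the bin's
#' (length-weighted) majority source genome, looked up in
#' `reference_lengths`; otherwise the best-matching length class is used:
#' the smallest expected length >= the bin's ungapped length, or the
#' largest class if none. Quality tiers follow the high >= 90%,
#' medium >= 50%, low < 50% convention.
#'
#' @param bin A `Bin`.
#' @param reference_lengths Named numeric vector of expected genome lengths
#'   (simulation: named by genome_id; real mode: user-supplied classes).
#' @return The bin with `completeness`, `quality_tier` (and
#'   `completeness_flag` when no length model was available) set.
#' @export
estimate_completeness <- function(bin, reference_lengths = NULL) {
  stopifnot(inherits(bin, "Bin"), length(bin$contigs) >= 1)
  ungapped <- sum(vapply(bin$contigs, function(ct) nchar(ct$sequence), numeric(1)))
  if (is.null(reference_lengths) || !length(reference_lengths)) {
    bin$completeness <- NA_real_
    bin$quality_tier <- "low"
    bin$completeness_flag <- "no_length_model"
    return(bin)
  }
  src <- majority_source(bin)
  expected <- if (!is.na(src) && src %in% names(reference_lengths)) {
    reference_lengths[[src]]
  } else {
    bigger <- reference_lengths[reference_lengths >= ungapped]
    if (length(bigger)) min(bigger) else max(reference_lengths)
  }
  bin$completeness <- 100 * min(1, ungapped / expected)
  bin$quality_tier <- if (bin$completeness >= 90) "high"
                      else if (bin$completeness >= 50) "medium" else "low"
  bin
}

## Length-weighted majority source genome of a bin (NA without provenance).
majority_source <- function(bin) {
  src <- vapply(bin$contigs, function(ct)
    if (is.null(ct$source_genome_id)) NA_character_ else ct$source_genome_id,
    character(1))
  len <- vapply(bin$contigs, function(ct) nchar(ct$sequence), numeric(1))
  if (all(is.na(src))) return(NA_character_)
  w <- tapply(len[!is.na(src)], src[!is.na(src)], sum)
  names(w)[which.max(w)]
}

#' Length-weighted provenance purity of a bin
#'
#' @param bin A `Bin` with ground-truth contig provenance.
#' @return Fraction of the bin's length from its majority source genome.
#' @export
bin_purity <- function(bin) {
  src <- vapply(bin$contigs, `[[`, character(1), "source_genome_id")
  len <- vapply(bin$contigs, function(ct) nchar(ct$sequence), numeric(1))
  max(tapply(len, src, sum)) / sum(len)
}

#' Select the vSAG from one bead's bins
#'
#' The bin with the highest completeness (> 0, strictly) becomes the vSAG;
#' ties break toward larger total length, then lexicographic bin id. All
#' other bins are recorded as excluded. Returns `NULL` when no bin
#' qualifies (the bead counts as carrying no viral sequence).
#'
#' @param bins List of `Bin`s from a single bead, with completeness set.
#' @param linker_len Poly-N linker length for the concatenated sequence.
#' @return A `VSAG` (list: `vsag_id`, `bead_id`, `bin`, `excluded_bins`,
#'   `n_contigs`, `is_single_contig`, `sequence`) or `NULL`.
#' @export
select_vsag <- function(bins, linker_len = 100) {
  if (!length(bins)) return(NULL)
  stopifnot(length(unique(vapply(bins, `[[`, character(1), "bead_id"))) == 1)
  comp <- vapply(bins, function(b) ifelse(is.na(b$completeness), 0, b$completeness),
                 numeric(1))
  eligible <- comp > 0
  if (!any(eligible)) return(NULL)
  len <- vapply(bins, `[[`, numeric(1), "total_length")
  id <- vapply(bins, `[[`, character(1), "bin_id")
  ord <- order(-comp, -len, id)
  best <- ord[eligible[ord]][1]
  sel <- bins[[best]]
  structure(list(
    vsag_id = sprintf("vSAG_%s", sel$bead_id), bead_id = sel$bead_id,
    bin = sel, excluded_bins = bins[-best],
    n_contigs = length(sel$contigs),
    is_single_contig = length(sel$contigs) == 1,
    sequence = concatenate_with_polyN(sel, linker_len)), class = "VSAG")
}

#' Build vSAGs for a whole bead run
#'
#' Applies the virality filter, TNF+abundance binning, completeness
#' estimation and highest-completeness selection to every sorted bead, and
#' classifies beads as `vsag`, `no_viral`, or `small_data` (fewer than
#' `small_data_pairs` read pairs, when reads were simulated).
#'
#' @param beads Amplified beads with contigs (and optionally reads).
#' @param community The `Community` (ground truth for the virality filter,
#'   abundances and reference lengths).
#' @param min_bin_size,tnf_weight,abund_weight,cutoff See [bin_bead()].
#' @param score_threshold See [virality_filter()].
#' @param linker_len Poly-N linker length.
#' @param small_data_pairs Read-pair threshold below which a sorted bead is
#'   reported as small-data (applied only when reads exist).
#' @return List: `vsags` (list of `VSAG`), `status` (data.frame `bead_id`,
#'   `status`), `bins` (data.frame of all emitted bins with completeness,
#'   tier, purity and selection flag).
#' @export
build_vsags <- function(beads, community, min_bin_size = 10000,
                        tnf_weight = 1.0, abund_weight = 0.5, cutoff = 0.3,
                        score_threshold = 0.3, linker_len = 100,
                        small_data_pairs = 5000) {
  ref_lens <- vapply(community$genomes, function(g) nchar(g$sequence), numeric(1))
  vsags <- list()
  status <- list()
  bin_rows <- list()
  for (b in beads) {
    if (!b$positive) next
    has_reads <- !is.null(b$reads)
    if (has_reads && nrow(b$reads) < small_data_pairs) {
      status[[b$bead_id]] <- "small_data"
      next
    }
    kept <- if (length(b$contigs))
      virality_filter(b$contigs, community, score_threshold)$kept else list()
    if (!length(kept)) { status[[b$bead_id]] <- "no_viral"; next }
    feats <- contig_features(kept, community)
    bins <- bin_bead(feats, b$bead_id, min_bin_size, tnf_weight,
                     abund_weight, cutoff)
    bins <- lapply(bins, estimate_completeness, reference_lengths = ref_lens)
    vs <- select_vsag(bins, linker_len)
    if (is.null(vs)) { status[[b$bead_id]] <- "no_viral"; next }
    status[[b$bead_id]] <- "vsag"
    vsags[[vs$vsag_id]] <- vs
    for (bn in bins) {
      bin_rows[[bn$bin_id]] <- data.frame(
        bin_id = bn$bin_id, bead_id = bn$bead_id,
        n_contigs = length(bn$contigs), total_length = bn$total_length,
        completeness = bn$completeness, quality_tier = bn$quality_tier,
        purity = bin_purity(bn), selected = bn$bin_id == vs$bin$bin_id,
        stringsAsFactors = FALSE)
    }
  }
  status_df <- data.frame(bead_id = names(status),
                          status = unlist(status, use.names = FALSE),
                          stringsAsFactors = FALSE)
  bins_df <- if (length(bin_rows)) do.call(rbind, bin_rows) else
    data.frame(bin_id = character(), bead_id = character(),
               n_contigs = integer(), total_length = numeric(),
               completeness = numeric(), quality_tier = character(),
               purity = numeric(), selected = logical())
  rownames(bins_df) <- NULL
  list(vsags = vsags, status = status_df, bins = bins_df)
}
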