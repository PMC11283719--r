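## Gel-bead encapsulation, whole-genome-amplification bias, read generation
## and the assembly surrogate that turns per-bead coverage into contigs.

#' Encapsulate a community into gel beads
#'
#' Per-bead particle counts are Poisson(`mean_loading`); each particle's
#' genome identity is drawn from the community's relative abundances. A bead
#' is provisionally positive when it holds at least one particle; the
#' detection model proper is applied by [amplify()], which may reset the flag
#' if the amplified yield stays below the detection threshold.
#'
#' @param community A `Community`.
#' @param n_beads Number of beads to generate.
#' @param mean_loading Poisson mean particles per bead (> 0).
#' @param seed Integer seed.
#' @param loading_counts Optional integer vector overriding the Poisson draw
#'   (e.g. to force a co-encapsulation rate in experiments).
#' @return List of `Bead` objects: `bead_id`, `loaded_genomes` (character,
#'   possibly with repeats), `positive`, plus empty `coverage_profiles`,
#'   `reads`, `contigs` slots.
#' @export
encapsulate <- function(community, n_beads, mean_loading, seed = 1,
                        loading_counts = NULL) {
  stopifnot(mean_loading > 0 || !is.null(loading_counts), n_beads >= 1)
  with_seed(seed, {
    k <- if (is.null(loading_counts)) stats::rpois(n_beads, mean_loading)
         else rep_len(as.integer(loading_counts), n_beads)
    ids <- names(community$abundances)
    draws <- sample(ids, sum(k), replace = TRUE, prob = community$abundances)
    at <- c(0L, cumsum(k))
    lapply(seq_len(n_beads), function(i) {
      loaded <- if (k[i] > 0) draws[(at[i] + 1):at[i + 1]] else character()
      structure(list(bead_id = sprintf("bead%05d", i), loaded_genomes = loaded,
                     positive = k[i] > 0, coverage_profiles = list(),
                     reads = NULL, contigs = list()),
                class = "Bead")
    })
  })
}

## Smoothed lognormal random field over L positions: lognormal values at
## knots spaced `corr_bp` apart, linearly interpolated between knots.
lognormal_field <- function(L, sigma, corr_bp = 2000) {
  n_knots <- max(2, ceiling(L / corr_bp) + 1)
  knots_x <- seq(1, L, length.out = n_knots)
  knots_y <- stats::rlnorm(n_knots, meanlog = 0, sdlog = sigma)
  stats::approx(knots_x, knots_y, xout = seq_len(L))$y
}

#' Amplify a bead's loaded genomes with MDA-style bias
#'
#' Per-base depth for each loaded genome is a smoothed lognormal random
#' field (correlation length ~2 kb) scaled by `base_depth`; windows of
#' `dropout_window` bp are zeroed independently with probability `dropout`.
#' ssDNA genomes are scaled by `ssdna_multiplier`. The bead is positive iff
#' total amplified yield exceeds `yield_threshold`.
#'
#' @param bead A `Bead`.
#' @param community The `Community` the bead was drawn from.
#' @param sigma Lognormal log-sd of the amplification field (0 = uniform).
#' @param dropout Per-window dropout probability.
#' @param seed Integer seed.
#' @param base_depth Mean depth scale.
#' @param ssdna_multiplier Yield multiplier for ssDNA genomes.
#' @param dropout_window Dropout window size in bp.
#' @param yield_threshold Total-yield detection threshold (default 0: any
#'   amplified base makes the bead positive).
#' @return The bead with `coverage_profiles` filled (one numeric vector per
#'   distinct loaded genome; duplicate loads sum) and `positive` set.
#' @export
amplify <- function(bead, community, sigma = 1.2, dropout = 0.05, seed = 1,
                    base_depth = 30, ssdna_multiplier = 1,
                    dropout_window = 1000, yield_threshold = 0) {
  with_seed(seed, {
    profs <- list()
    for (gid in unique(bead$loaded_genomes)) {
      g <- community$genomes[[gid]]
      L <- nchar(g$sequence)
      n_copies <- sum(bead$loaded_genomes == gid)
      depth <- numeric(L)
      for (cp in seq_len(n_copies)) {
        f <- if (sigma > 0) lognormal_field(L, sigma) else rep(1, L)
        if (dropout > 0) {
          nw <- ceiling(L / dropout_window)
          drop <- stats::runif(nw) < dropout
          if (any(drop)) {
            for (w in which(drop)) {
              a <- (w - 1) * dropout_window + 1
              f[a:min(L, w * dropout_window)] <- 0
            }
          }
        }
        mult <- if (g$nucleic_type == "ssDNA") ssdna_multiplier else 1
        depth <- depth + base_depth * mult * f
      }
      profs[[gid]] <- depth
    }
    bead$coverage_profiles <- profs
    bead$positive <- sum(vapply(profs, sum, numeric(1))) > yield_threshold
    bead
  })
}

apply_read_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) mutate_sequence(s, error_rate), character(1),
         USE.NAMES = FALSE)
}

#' Generate paired reads from an amplified bead
#'
#' Fragment midpoint positions are sampled proportionally to the local
#' amplification depth; a `background_fraction` of pairs is drawn uniformly
#' from the community's background genome (packaging-extract carry-over).
#'
#' @param bead An amplified `Bead`.
#' @param community The `Community`.
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (>= 50).
#' @param insert Numeric `c(mean, sd)` insert size in bp.
#' @param error_rate Per-base substitution error rate.
#' @param background_fraction Fraction of pairs from the background genome.
#' @param seed Integer seed.
#' @return The bead with `reads`: data.frame `pair_id`, `source_id`,
#'   `start` (0-based fragment start), `frag_len`, `seq1`, `seq2` (read 2 is
#'   the reverse complement of the fragment end).
#' @export
generate_reads <- function(bead, community, n_pairs = 1000, read_len = 150,
                           insert = c(350, 30), error_rate = 0.001,
                           background_fraction = 0, seed = 1) {
  stopifnot(read_len >= 50, background_fraction >= 0, background_fraction <= 1)
  with_seed(seed, {
    tot <- vapply(bead$coverage_profiles, sum, numeric(1))
    n_bg <- stats::rbinom(1, n_pairs, background_fraction)
    if (is.null(community$background_genome)) n_bg <- 0
    n_viral <- n_pairs - n_bg
    if (sum(tot) <= 0 && n_bg == 0) {
      warning("bead has zero amplified depth and no background; empty read set")
      bead$reads <- data.frame(pair_id = character(), source_id = character(),
                               start = integer(), frag_len = integer(),
                               seq1 = character(), seq2 = character(),
                               stringsAsFactors = FALSE)
      return(bead)
    }
    alloc <- if (sum(tot) > 0 && n_viral > 0)
      stats::rmultinom(1, n_viral, tot / sum(tot))[, 1] else
      stats::setNames(integer(length(tot)), names(tot))
    recs <- list()
    emit <- function(src_seq, src_id, n) {
      L <- nchar(src_seq)
      prob <- if (src_id %in% names(bead$coverage_profiles))
        bead$coverage_profiles[[src_id]] else rep(1, L)
      flen <- pmax(2 * read_len,
                   round(stats::rnorm(n, insert[1], insert[2])))
      flen <- pmin(flen, L)
      mid <- sample.int(L, n, replace = TRUE, prob = prob)
      st <- pmin(pmax(1, mid - flen %/% 2), L - flen + 1)
      s1 <- substring(src_seq, st, st + read_len - 1)
      tail_start <- st + flen - read_len
      s2raw <- substring(src_seq, tail_start, tail_start + read_len - 1)
      s2 <- vapply(s2raw, revcomp, character(1), USE.NAMES = FALSE)
      data.frame(source_id = src_id, start = as.integer(st - 1L),
                 frag_len = as.integer(flen),
                 seq1 = apply_read_errors(s1, error_rate),
                 seq2 = apply_read_errors(s2, error_rate),
                 stringsAsFactors = FALSE)
    }
    for (gid in names(alloc)) {
      if (alloc[[gid]] > 0 && sum(bead$coverage_profiles[[gid]]) > 0)
        recs[[gid]] <- emit(community$genomes[[gid]]$sequence, gid, alloc[[gid]])
    }
    if (n_bg > 0)
      recs[["bg"]] <- emit(community$background_genome$sequence,
                           community$background_genome$genome_id, n_bg)
    rd <- do.call(rbind, recs)
    if (is.null(rd)) rd <- data.frame(source_id = character(), start = integer(),
                                      frag_len = integer(), seq1 = character(),
                                      seq2 = character(), stringsAsFactors = FALSE)
    rd <- cbind(pair_id = sprintf("%s_r%06d", bead$bead_id, seq_len(nrow(rd))),
                rd, stringsAsFactors = FALSE)
    rownames(rd) <- NULL
    bead$reads <- rd
    bead
  })
}

#' Fragment amplified coverage into contigs (assembly surrogate)
#'
#' Contigs are the maximal intervals of each loaded genome whose depth
#' exceeds `depth_floor`; intervals shorter than `min_contig` are not
#' emitted, so dropout windows become contig breakpoints. Ground-truth
#' provenance (source genome and interval) is recorded on every contig but
#' is hidden from the analysis modules.
#'
#' @param bead An amplified `Bead`.
#' @param community The `Community`.
#' @param min_contig Minimum contig length (default 1000 bp).
#' @param depth_floor Depth above which a base is considered assembled.
#' @param seed Integer seed (reserved for error simulation).
#' @param error_rate Per-base substitution rate applied to contig sequences.
#' @return The bead with `contigs`: list of `Contig` lists (`contig_id`,
#'   `bead_id`, `sequence`, `source_genome_id`, `source_interval` 0-based
#'   half-open).
#' @export
fragment_to_contigs <- function(bead, community, min_contig = 1000,
                                depth_floor = 0, seed = 1, error_rate = 0) {
  with_seed(seed, {
    contigs <- list()
    ci <- 0
    for (gid in names(bead$coverage_profiles)) {
      depth <- bead$coverage_profiles[[gid]]
      above <- depth > depth_floor
      if (!any(above)) next
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in which(r$values)) {
        len <- ends[j] - starts[j] + 1
        if (len < min_contig) next
        ci <- ci + 1
        sq <- substr(community$genomes[[gid]]$sequence, starts[j], ends[j])
        if (error_rate > 0) sq <- mutate_sequence(sq, error_rate)
        contigs[[ci]] <- structure(list(
          contig_id = sprintf("%s_c%03d", bead$bead_id, ci),
          bead_id = bead$bead_id, sequence = sq, source_genome_id = gid,
          source_interval = c(starts[j] - 1L, ends[j])), class = "Contig")
      }
    }
    bead$contigs <- contigs
    bead
  })
}

#' Simulate a full bead run (encapsulate, amplify, contigs, manifest)
#'
#' @param community A `Community`.
#' @param n_beads Number of beads.
#' @param mean_loading Poisson mean particles per bead.
#' @param seed Integer seed.
#' @param sigma,dropout,base_depth Amplification parameters (see [amplify()]).
#' @param n_pairs Read pairs per positive bead (0 skips read generation).
#' @param background_fraction Background read fraction.
#' @param method_label Free label recorded in the manifest (e.g. "I").
#' @param loading_counts Optional loading override (see [encapsulate()]).
#' @param min_contig Minimum contig length.
#' @return List with `beads` (amplified, with contigs) and `manifest` (see
#'   [run_manifest()]).
#' @export
simulate_bead_run <- function(community, n_beads, mean_loading = 0.223,
                              seed = 1, sigma = 1.2, dropout = 0.05,
                              base_depth = 30, n_pairs = 0,
                              background_fraction = 0.02, method_label = "I",
                              loading_counts = NULL, min_contig = 1000) {
  beads <- encapsulate(community, n_beads, mean_loading, seed = seed,
                       loading_counts = loading_counts)
  for (i in seq_along(beads)) {
    if (length(beads[[i]]$loaded_genomes) == 0) next
    beads[[i]] <- amplify(beads[[i]], community, sigma = sigma,
                          dropout = dropout, base_depth = base_depth,
                          seed = child_seed(seed, 2L * i))
    beads[[i]] <- fragment_to_contigs(beads[[i]], community,
                                      min_contig = min_contig)
    if (n_pairs > 0 && beads[[i]]$positive)
      beads[[i]] <- generate_reads(beads[[i]], community, n_pairs = n_pairs,
                                   background_fraction = background_fraction,
                                   seed = child_seed(seed, 2L * i + 1L))
  }
  list(beads = beads, manifest = run_manifest(beads, seed, method_label))
}

#' Build the run manifest from a list of beads
#'
#' @param beads List of `Bead`s (positive beads are the sorted set).
#' @param seed Seed used for the run.
#' @param method_label Free method label.
#' @return A `RunManifest`: list with counts (`n_beads_generated`,
#'   `n_beads_positive`, `n_beads_sorted`), a per-bead data.frame `records`
#'   (`bead_id`, `n_loaded`, `yield`, `n_read_pairs`, `n_contigs`, `positive`,
#'   `sorted`), `seed`, `method_label`.
#' @export
run_manifest <- function(beads, seed = NA, method_label = "I") {
  rec <- do.call(rbind, lapply(beads, function(b) {
    data.frame(bead_id = b$bead_id, n_loaded = length(b$loaded_genomes),
               yield = sum(vapply(b$coverage_profiles, sum, numeric(1))),
               n_read_pairs = if (is.null(b$reads)) 0L else nrow(b$reads),
               n_contigs = length(b$contigs),
               positive = b$positive, sorted = b$positive,
               stringsAsFactors = FALSE)
  }))
  m <- structure(list(n_beads_generated = length(beads),
                      n_beads_positive = sum(rec$positive),
                      n_beads_sorted = sum(rec$sorted),
                      records = rec, seed = seed, method_label = method_label),
                 class = "RunManifest")
  stopifnot(m$n_beads_sorted <= m$n_beads_positive,
            m$n_beads_positive <= m$n_beads_generated)
  m
}

#' @export
print.RunManifest <- function(x, ...) {
  cat(sprintf("<RunManifest [%s]: %d beads, %d positive, %d sorted>\n",
              x$method_label, x$n_beads_generated, x$n_beads_positive,
              x$n_beads_sorted))
  invisible(x)
}
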