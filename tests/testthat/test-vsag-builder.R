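test_that("canonical TNF is strand-symmetric and well normalised", {
  tn <- compute_tnf(strrep("A", 2000))
  expect_length(tn, 136)
  expect_equal(sum(tn), 1, tolerance = 1e-12)
  expect_equal(unname(tn[["AAAA"]]), 1)

  comm <- small_community()
  s <- comm$genomes[[1]]$sequence
  expect_equal(compute_tnf(s), compute_tnf(revcomp(s)), tolerance = 1e-12)

  ## two halves of one genome are similar; viral vs GC-offset host is not
  L <- nchar(s)
  h1 <- compute_tnf(substr(s, 1, L %/% 2))
  h2 <- compute_tnf(substr(s, L %/% 2 + 1, L))
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gte(cos(h1, h2), 0.95)
  expect_lt(cos(compute_tnf(s), compute_tnf(comm$background_genome$sequence)),
            0.9)

  ## N linker windows are skipped, not counted
  with_n <- compute_tnf(paste0(strrep("A", 1000), strrep("N", 100),
                               strrep("A", 1000)))
  expect_equal(unname(with_n[["AAAA"]]), 1)
})

test_that("virality filter keeps viral contigs and drops host contigs", {
  comm <- small_community()
  g <- comm$genomes[[1]]
  viral_ct <- structure(list(contig_id = "c1", bead_id = "b", sequence =
                               substr(g$sequence, 1, 15000),
                             source_genome_id = g$genome_id,
                             source_interval = c(0L, 15000L)), class = "Contig")
  host_ct <- structure(list(contig_id = "c2", bead_id = "b", sequence =
                              substr(comm$background_genome$sequence, 1, 15000),
                            source_genome_id = "host_bg",
                            source_interval = c(0L, 15000L)), class = "Contig")
  res <- virality_filter(list(viral_ct, host_ct), comm)
  expect_gte(res$scores$score[1], 0.6)
  expect_true(res$scores$kept[1])
  expect_lt(res$scores$score[2], 0.05)
  expect_false(res$scores$kept[2])
  res0 <- virality_filter(list(viral_ct, host_ct), comm, score_threshold = 0)
  expect_length(res0$kept, 2)
})

test_that("binning separates co-encapsulated genomes and keeps fragments together", {
  comm <- small_community()
  ab <- sort(comm$abundances, decreasing = TRUE)
  pair <- c(names(ab)[1], names(ab)[length(ab)])
  expect_gte(ab[[pair[1]]] / ab[[pair[2]]], 5)

  seps <- vapply(1:5, function(s) {
    bb <- encapsulate(comm, 1, 1, seed = s, loading_counts = 2)[[1]]
    bb$loaded_genomes <- pair
    bb <- amplify(bb, comm, sigma = 1.0, dropout = 0.05, seed = s + 20)
    bb <- fragment_to_contigs(bb, comm)
    kept <- virality_filter(bb$contigs, comm)$kept
    bins <- bin_bead(contig_features(kept, comm), bb$bead_id)
    if (length(bins) != 2) return(FALSE)
    all(vapply(bins, bin_purity, numeric(1)) >= 0.9)
  }, logical(1))
  expect_gte(mean(seps), 0.8)

  ## a fragmented single genome stays in one bin
  together <- vapply(1:10, function(s) {
    b <- single_bead(sigma = 1.2, dropout = 0.25, seed = 300 + s)
    b <- fragment_to_contigs(b, comm)
    if (length(b$contigs) < 2) return(NA)
    bins <- bin_bead(contig_features(b$contigs, comm), b$bead_id,
                     min_bin_size = 2000)
    sizes <- vapply(bins, function(x) length(x$contigs), numeric(1))
    max(sizes) / length(b$contigs) >= 0.8
  }, logical(1))
  expect_gte(mean(together, na.rm = TRUE), 0.8)

  ## one contig -> one bin
  b1 <- single_bead()
  b1 <- fragment_to_contigs(b1, comm)
  bins1 <- bin_bead(contig_features(b1$contigs, comm), b1$bead_id)
  expect_length(bins1, 1)
  expect_length(bins1[[1]]$contigs, 1)
})

test_that("poly-N concatenation is length-exact and invertible", {
  ct <- function(id, seq) structure(list(contig_id = id, bead_id = "b",
                                         sequence = seq,
                                         source_genome_id = "g",
                                         source_interval = c(0L, nchar(seq))),
                                    class = "Contig")
  set.seed(5)
  c1 <- ct("a", random_dna(10000))
  c2 <- ct("b", random_dna(5000))
  joined <- concatenate_with_polyN(list(c1, c2), linker_len = 100)
  expect_equal(nchar(joined), 15100)
  expect_identical(split_polyN(joined), c(c1$sequence, c2$sequence))
  ## single contig unchanged
  expect_identical(concatenate_with_polyN(list(c2)), c2$sequence)
  ## descending length order regardless of input order
  expect_identical(concatenate_with_polyN(list(c2, c1)), joined)
})

test_that("completeness is the recovered fraction of the expected length", {
  comm <- small_community()
  g <- comm$genomes[[1]]
  L <- nchar(g$sequence)
  mkbin <- function(frac) {
    ct <- structure(list(contig_id = "c", bead_id = "b",
                         sequence = substr(g$sequence, 1, round(frac * L)),
                         source_genome_id = g$genome_id,
                         source_interval = c(0L, round(frac * L))),
                    class = "Contig")
    structure(list(bin_id = "b_bin01", bead_id = "b", contig_ids = "c",
                   contigs = list(ct), total_length = round(frac * L),
                   completeness = NA_real_, quality_tier = NA_character_),
              class = "Bin")
  }
  lens <- stats::setNames(vapply(comm$genomes, function(x)
    nchar(x$sequence), numeric(1)), names(comm$genomes))
  full <- estimate_completeness(mkbin(1), lens)
  expect_equal(full$completeness, 100)
  expect_equal(full$quality_tier, "high")
  half <- estimate_completeness(mkbin(0.5), lens)
  expect_equal(half$completeness, 50, tolerance = 0.01)
  expect_equal(half$quality_tier, "medium")  # boundary inclusive
  low <- estimate_completeness(mkbin(0.2), lens)
  expect_equal(low$quality_tier, "low")
  ## no length model -> flagged, kept low
  noref <- estimate_completeness(mkbin(0.5), NULL)
  expect_true(is.na(noref$completeness))
  expect_equal(noref$quality_tier, "low")
  expect_equal(noref$completeness_flag, "no_length_model")
  expect_error(estimate_completeness(structure(list(contigs = list()),
                                               class = "Bin"), lens))
})

test_that("vSAG selection takes the highest positive completeness with tie rules", {
  mk <- function(id, comp, len, n_ct = 2) {
    cts <- lapply(seq_len(n_ct), function(i)
      structure(list(contig_id = paste0(id, "_c", i), bead_id = "bead1",
                     sequence = strrep("A", len / n_ct),
                     source_genome_id = "g", source_interval = c(0L, 10L)),
                class = "Contig"))
    structure(list(bin_id = id, bead_id = "bead1",
                   contig_ids = paste0(id, "_c", seq_len(n_ct)),
                   contigs = cts, total_length = len, completeness = comp,
                   quality_tier = "low"), class = "Bin")
  }
  v <- select_vsag(list(mk("bead1_bin01", 80, 30000),
                        mk("bead1_bin02", 30, 20000)))
  expect_equal(v$bin$bin_id, "bead1_bin01")
  expect_length(v$excluded_bins, 1)
  expect_false(v$is_single_contig)
  expect_gte(v$bin$completeness, max(vapply(v$excluded_bins, `[[`,
                                            numeric(1), "completeness")))

  expect_null(select_vsag(list(mk("bead1_bin01", 0, 30000))))

  tie <- select_vsag(list(mk("bead1_bin01", 60, 20000),
                          mk("bead1_bin02", 60, 30000)))
  expect_equal(tie$bin$bin_id, "bead1_bin02")  # longer wins

  single <- select_vsag(list(mk("bead1_bin01", 50, 12000, n_ct = 1)))
  expect_true(single$is_single_contig)
  expect_false(grepl("N", single$sequence))
})

test_that("vSAG build pipeline reports bead status and multi-bin accounting", {
  comm <- small_community()
  run <- simulate_bead_run(comm, 80, 0.3, seed = 12)
  built <- build_vsags(run$beads, comm)
  expect_true(all(built$status$status %in% c("vsag", "no_viral", "small_data")))
  expect_equal(sum(built$status$status == "vsag"), length(built$vsags))
  ## multi-bin accounting equals the count from bin records
  per_bead <- table(built$bins$bead_id)
  expect_equal(sum(per_bead > 1),
               sum(vapply(built$vsags, function(v)
                 length(v$excluded_bins) > 0, logical(1))))
  for (v in built$vsags) {
    expect_gt(v$bin$completeness, 0)
    expect_equal(v$is_single_contig, length(v$bin$contigs) == 1)
  }
})
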