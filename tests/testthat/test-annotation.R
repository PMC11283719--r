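ranks <- c("realm", "order", "family", "genus")

lineage_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- ranks[seq_len(ncol(m))]
  m
}

test_that("taxonomy voting gates on hit fraction and majority per rank", {
  ## 2 of 10 proteins hit: 0.2 <= 0.3, no call
  hits <- lineage_matrix(c("R", "O", "F", "G"), c("R", "O", "F", "G"))
  expect_equal(vote_taxonomy(10, hits)$method, "none")

  ## 6 of 10 hit; 4/6 say family X (0.667 > 0.5); genus split 2/2/2 stops
  hits6 <- lineage_matrix(c("R", "O1", "FX", "G1"), c("R", "O1", "FX", "G1"),
                          c("R", "O1", "FX", "G2"), c("R", "O1", "FX", "G2"),
                          c("R", "O1", "FY", "G3"), c("R", "O1", "FZ", "G3"))
  call <- vote_taxonomy(10, hits6)
  expect_equal(call$method, "vote")
  expect_equal(unname(call$lineage[["family"]]), "FX")
  expect_false("genus" %in% names(call$lineage))
  expect_equal(unname(call$support[["family"]]), 4 / 6, tolerance = 1e-12)

  ## unanimous hits give the full lineage with support 1
  full <- vote_taxonomy(4, lineage_matrix(c("R", "O", "F", "G"),
                                          c("R", "O", "F", "G")))
  expect_equal(length(full$lineage), 4)
  expect_true(all(full$support == 1))

  ## monotonicity: adding a hit agreeing with the majority never truncates
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    base <- lineage_matrix(c("R", "O", "F", "G"))[rep(1, n), , drop = FALSE]
    flip <- sample(n, sample(0:(n %/% 2 - 1), 1))
    base[flip, "genus"] <- "Gx"
    before <- vote_taxonomy(n, base)
    after <- vote_taxonomy(n + 1, rbind(base, c("R", "O", "F", "G")))
    expect_gte(length(after$lineage), length(before$lineage))
  }
})

test_that("marker taxonomy truncates to the agreeing prefix and filters hits", {
  mh <- data.frame(score = c(60, 55), evalue = c(1e-10, 1e-8),
                   realm = "R", order = "O", family = c("F1", "F2"),
                   stringsAsFactors = FALSE)
  call <- marker_taxonomy(mh, c("realm", "order", "family"))
  expect_equal(names(call$lineage), c("realm", "order"))

  single <- marker_taxonomy(mh[1, ], c("realm", "order", "family"))
  expect_equal(length(single$lineage), 3)

  ## score 39 excluded (minimum 40 inclusive); bad E-value excluded
  mh2 <- data.frame(score = c(39, 40), evalue = c(1e-10, 1e-10),
                    realm = "R", order = "O", family = c("F1", "F2"),
                    stringsAsFactors = FALSE)
  call2 <- marker_taxonomy(mh2, c("realm", "order", "family"))
  expect_equal(unname(call2$lineage[["family"]]), "F2")
  none <- marker_taxonomy(data.frame(score = 39, evalue = 1, realm = "R",
                                     stringsAsFactors = FALSE), "realm")
  expect_equal(none$method, "none")
})

test_that("AMG identification respects the auxiliary-score gate", {
  comm <- small_community()
  amgs <- identify_amgs(comm$genomes)
  truth <- do.call(rbind, lapply(comm$genomes, function(g)
    g$genes[g$genes$role == "AMG", ]))
  expect_equal(nrow(amgs), sum(truth$aux_score %in% 1:3))
  expect_true(all(amgs$aux_score %in% 1:3))
  ## genes with aux score 4-5 exist in the pool and are excluded
  expect_gt(sum(truth$aux_score %in% 4:5), 0)
  expect_false(any(paste(amgs$genome_id, amgs$gene_id) %in%
                     paste(truth$genome_id[truth$aux_score > 3],
                           truth$gene_id[truth$aux_score > 3])))
  expect_equal(amg_category_priority(NA, "CAZY1", "PF1"), "CAZY1")
  expect_equal(amg_category_priority("K001", "CAZY1", "PF1"), "K001")
  expect_true(is.na(amg_category_priority()))
})

test_that("Fisher's exact test matches enumeration and the reference implementation", {
  r <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(r$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r$p, 0.00794, tolerance = 1e-3)

  set.seed(11)
  for (i in 1:100) {
    tab <- matrix(stats::rpois(4, sample(1:8, 1)), 2, 2)
    r <- fisher_exact_2x2(tab)
    if (r$degenerate) {
      expect_equal(r$p, 1.0)
      next
    }
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(r$p, ref, tolerance = 1e-9)
    ## invariance under transposition; p in (0, 1]
    expect_equal(fisher_exact_2x2(t(tab))$p, r$p, tolerance = 1e-12)
    expect_gt(r$p, 0)
    expect_lte(r$p, 1)
  }

  expect_equal(fisher_exact_2x2(matrix(c(0, 10, 0, 10), 2, 2))$p, 1.0)

  pc_table <- data.frame(n_vcs_touched = c(2, 2, 1, 1, 1),
                         multi_vc = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                         is_amg_pc = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  res <- amg_sharing_test(pc_table)
  expect_equal(unname(res$table["multi_vc", "amg"]), 1)
  expect_equal(sum(res$table), 5)
  expect_gt(res$p, 0)
})

test_that("reads-per-base abundance is linear", {
  expect_equal(reads_per_base(0, 1000), 0)
  expect_equal(reads_per_base(1000, 30000), 0.03333, tolerance = 1e-3)
  expect_equal(reads_per_base(2000, 30000), 2 * reads_per_base(1000, 30000))
  expect_equal(reads_per_base(1000, 10000, log10_transform = TRUE), -1)
})

test_that("recruitment curves respect strict filters and concentrate mass", {
  aln <- data.frame(identity = rep(100, 50), qcov = 95, evalue = 1e-10)
  cv <- recruitment_curve(aln)
  expect_equal(cv$n_recruited, 50)
  expect_equal(cv$identity[which.max(cv$percent)], 100)
  ## curve integrates to 100
  tr <- sum((cv$percent[-1] + cv$percent[-length(cv$percent)]) / 2 *
              diff(cv$identity))
  expect_equal(tr, 100, tolerance = 1e-6)

  ## qcov exactly 80 excluded ("over 80%" strict)
  aln2 <- data.frame(identity = c(99, 98), qcov = c(80, 81), evalue = 1e-10)
  expect_equal(recruitment_curve(aln2)$n_recruited, 1)

  ## recruited count non-increasing in every threshold
  set.seed(9)
  big <- data.frame(identity = stats::runif(200, 40, 100),
                    qcov = stats::runif(200, 60, 100),
                    evalue = 10^stats::runif(200, -20, -2))
  n0 <- recruitment_curve(big)$n_recruited
  expect_lte(recruitment_curve(big, id_min = 70)$n_recruited, n0)
  expect_lte(recruitment_curve(big, qcov_min = 90)$n_recruited, n0)
  expect_lte(recruitment_curve(big, evalue_max = 1e-10)$n_recruited, n0)

  expect_equal(recruitment_curve(big[0, ])$n_recruited, 0)
})

test_that("OG matrix splits core and flexible genes correctly", {
  st <- strain_set()
  mg <- stats::setNames(lapply(st$strains, `[[`, "genes"),
                        vapply(st$strains, `[[`, character(1), "genome_id"))
  om <- build_og_matrix(mg)
  cas_labels <- vapply(st$cassettes, `[[`, character(1), "og_label")
  planted_cas <- intersect(cas_labels, rownames(om$matrix))
  expect_true(all(om$og_class[planted_cas] == "flexible"))
  backbone <- st$parent$genes$og_label
  expect_true(all(om$og_class[backbone] == "core"))
  ## partition: core + flexible covers all OGs, disjoint by construction
  expect_setequal(names(om$og_class), rownames(om$matrix))

  ## identical members -> everything core
  om2 <- build_og_matrix(list(a = st$parent$genes, b = st$parent$genes))
  expect_true(all(om2$og_class == "core"))

  ## removing a member can move OGs flexible -> core, never the reverse
  om_small <- build_og_matrix(mg[-1])
  was_core <- names(om$og_class)[om$og_class == "core"]
  still <- intersect(was_core, names(om_small$og_class))
  expect_true(all(om_small$og_class[still] == "core"))
})

test_that("insertion detection recovers planted cassettes with core flanks", {
  st <- strain_set()
  mg <- stats::setNames(lapply(st$strains, `[[`, "genes"),
                        vapply(st$strains, `[[`, character(1), "genome_id"))
  om <- build_og_matrix(mg)
  ev <- detect_insertions(mg, om)
  expect_gt(nrow(ev), 0)
  ## a strain with no cassettes yields no events
  bare <- spawn_strains(st$parent, 2, snv_rate = 0.001,
                        flexible_cassettes = list(), seed = 77)
  mg2 <- stats::setNames(lapply(bare, `[[`, "genes"),
                         paste0("bare_", seq_along(bare)))
  om2 <- build_og_matrix(c(mg, mg2))
  ev2 <- detect_insertions(mg2, om2)
  expect_equal(nrow(ev2), 0)

  ## flanks: each event's flanks are the true neighbouring core genes
  for (i in seq_len(nrow(ev))) {
    t <- mg[[ev$genome_id[i]]]
    t <- t[order(t$start), ]
    run_ogs <- strsplit(ev$ogs[i], ";")[[1]]
    idx <- which(t$og_label == run_ogs[1])
    if (ev$partial[i]) next
    expect_equal(t$og_label[idx - 1], ev$left_flank[i])
    idx2 <- which(t$og_label == run_ogs[length(run_ogs)])
    expect_equal(t$og_label[idx2 + 1], ev$right_flank[i])
  }
})
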