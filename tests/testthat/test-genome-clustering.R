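test_that("ANI/AF has the right fixed points and symmetry", {
  set.seed(8)
  s <- random_dna(20000, 0.45)
  r <- compute_ani_af(s, s)
  expect_equal(r$ani, 100)
  expect_equal(r$af, 100)

  ## unrelated random sequences share essentially nothing
  u <- compute_ani_af(random_dna(15000), random_dna(15000))
  expect_lt(u$af, 10)

  ## reverse-complemented subject is still found
  rc <- compute_ani_af(s, revcomp(s))
  expect_equal(rc$ani, 100)
  expect_equal(rc$af, 100)

  ## N linkers are stripped before comparison
  withn <- compute_ani_af(paste0(substr(s, 1, 10000), strrep("N", 100),
                                 substr(s, 10001, 20000)), s)
  expect_equal(withn$ani, 100, tolerance = 0.2)

  ## near-symmetry on a strain pair
  st <- strain_set()
  a <- st$strains[[1]]$sequence; b <- st$strains[[2]]$sequence
  expect_lt(abs(compute_ani_af(a, b)$ani - compute_ani_af(b, a)$ani), 1)
})

test_that("vOTU clustering is sound, deterministic, and splits distinct species", {
  st <- strain_set()
  seqs <- c(stats::setNames(vapply(st$strains, `[[`, character(1), "sequence"),
                            vapply(st$strains, `[[`, character(1), "genome_id")),
            trunc = st$trunc$sequence)
  comp <- stats::setNames(c(rep(95, 6), 50), names(seqs))
  res <- cluster_votus_greedy(seqs, comp)
  expect_length(res$votus, 1)
  expect_length(res$votus[[1]]$members, 7)

  ## soundness: member-centroid pairs satisfy the thresholds
  v <- res$votus[[1]]
  for (m in setdiff(v$members, v$centroid_id)) {
    r <- compute_ani_af(seqs[[m]], seqs[[v$centroid_id]])
    expect_gte(r$ani, 95)
    expect_gte(r$af, 85)
  }

  ## all-distinct genomes become singletons; shuffling does not matter
  comm <- small_community()
  gseqs <- vapply(comm$genomes, `[[`, character(1), "sequence")
  gdf <- data.frame(genome_id = names(gseqs), completeness = 90,
                    length = nchar(gseqs), stringsAsFactors = FALSE)
  ani <- ani_table(gseqs)
  v1 <- cluster_votus(gdf, ani)
  expect_length(v1, length(gseqs))
  v2 <- cluster_votus(gdf[sample(nrow(gdf)), ], ani)
  expect_identical(lapply(v1, `[[`, "members"), lapply(v2, `[[`, "members"))
})

test_that("ORF calling finds planted genes on both strands", {
  ## one planted 300-nt gene flanked by stops, in an all-A context that
  ## cannot harbour spurious ORFs (AAA = Lys, no stops, but no ATG either)
  set.seed(21)
  gene <- paste(c("ATG", sample(c("GCT", "GAA", "TGC", "CTG"), 98,
                                replace = TRUE), "TAA"), collapse = "")
  seqn <- paste0(strrep("T", 901), "TAATAA", gene, "TAATAA", strrep("T", 900))
  orfs <- find_orfs(seqn, min_aa = 60)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$end - orfs$start, 300)
  expect_equal(orfs$strand, "+")
  expect_identical(substr(seqn, orfs$start + 1, orfs$end), gene)

  ## reverse complement flips strands but keeps the set
  o2 <- find_orfs(revcomp(seqn), min_aa = 60)
  expect_equal(nrow(o2), 1)
  expect_equal(o2$strand, "-")
  L <- nchar(seqn)
  expect_equal(unname(L - o2$end), unname(orfs$start))

  ## recovery of planted genes across simulated genomes
  comm <- small_community()
  hits <- 0; total <- 0
  for (g in comm$genomes[1:4]) {
    orfs <- find_orfs(g$sequence)
    for (i in seq_len(nrow(g$genes))) {
      total <- total + 1
      ov <- pmin(orfs$end, g$genes$end[i]) - pmax(orfs$start, g$genes$start[i])
      if (any(ov >= 0.9 * (g$genes$end[i] - g$genes$start[i]) &
                orfs$strand == g$genes$strand[i])) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("Markov clustering matches hand-run expectations on toy graphs", {
  ## two triangles joined by one weak edge split into two clusters
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1
  }
  A[3, 4] <- A[4, 3] <- 0.3
  m <- mcl_cluster(A)
  expect_length(unique(m), 2)
  expect_equal(length(unique(m[1:3])), 1)
  expect_equal(length(unique(m[4:6])), 1)
  expect_false(m[1] == m[4])

  ## high inflation collapses a 5-node path toward its strongest edges:
  ## strong pairs (1,2) and (4,5) survive, the weakly attached 3 cannot
  ## bridge them into one cluster
  P <- matrix(0, 5, 5)
  P[1, 2] <- P[2, 1] <- 1
  P[4, 5] <- P[5, 4] <- 1
  P[2, 3] <- P[3, 2] <- 0.1
  P[3, 4] <- P[4, 3] <- 0.1
  mh <- mcl_cluster(P, inflation = 6)
  expect_false(mh[1] == mh[5])
  expect_equal(mh[1], mh[2])
  expect_equal(mh[4], mh[5])

  ## a connected clique converges to a single cluster
  K <- matrix(1, 4, 4); diag(K) <- 0
  expect_length(unique(mcl_cluster(K)), 1)
})

test_that("protein clustering recovers planted OG families", {
  expect_length(cluster_proteins(c(a = "MKLVWAAEE", b = "MKLVWAAEE"), k = 2), 1)

  ps <- protein_set()
  pcs <- cluster_proteins(ps$proteins)
  memb <- stats::setNames(
    rep(seq_along(pcs), vapply(pcs, function(p) length(p$members), numeric(1))),
    unlist(lapply(pcs, `[[`, "members")))
  ok <- !is.na(ps$labels)
  score <- ari(memb[names(ps$labels)[ok]], ps$labels[ok])
  expect_gte(score, 0.9)

  ## purity and completeness per family
  for (lab in unique(ps$labels[ok])) {
    members <- names(ps$labels)[which(ps$labels == lab)]
    expect_length(unique(memb[members]), 1)  # family completeness
  }
})

test_that("VC network uses hypergeometric edge weights and MCL", {
  gp <- list(g1 = paste0("PC", 1:10), g2 = paste0("PC", 1:10),
             g3 = paste0("PC", 91:95), g4 = "PC1")
  comp <- c(g1 = 90, g2 = 80, g3 = 70, g4 = 60)
  lens <- c(g1 = 4e4, g2 = 3e4, g3 = 2e4, g4 = 1e4)
  net <- build_vc_network(gp, comp, lens, n_pc_universe = 100)
  ## sharing all 10 PCs out of a universe of 100 is overwhelming evidence
  expect_equal(nrow(net$edges), 1)
  expect_gt(net$edges$weight, 10)
  ## oracle: -log10 upper hypergeometric tail
  expect_equal(net$edges$weight,
               -log10(stats::phyper(9, 10, 90, 10, lower.tail = FALSE)),
               tolerance = 1e-9)
  expect_length(net$vcs, 1)
  expect_setequal(net$vcs[[1]]$members, c("g1", "g2"))
  expect_equal(net$vcs[[1]]$representative_id, "g1")  # max completeness
  ## g3 shares nothing, g4 has < 2 PCs: both outliers
  expect_setequal(net$outliers, c("g3", "g4"))
  expect_error(build_vc_network(list(g1 = character()), comp, lens),
               "empty PC universe")
})
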