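## Species-level vOTU clustering (ANI/AF), ORF calling, protein clustering
## into PCs by Markov clustering, and the shared-protein viral-cluster (VC)
## network with hypergeometric edge weights.

strip_linkers <- function(x) gsub("N+", "", x)

kmer_strings <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1), k:n))
}

## Rolling 2-bit codes of all k-mers of `s` (numeric vector, length
## n - k + 1); positions covering a non-ACGT symbol are NA.
encode_kmers <- function(s, k) {
  x <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1
  n <- length(x)
  if (n < k) return(numeric())
  code <- numeric(n - k + 1)
  for (j in seq_len(k)) code <- code * 4 + x[j:(n - k + j)]
  code
}

#' Pairwise ANI and aligned fraction (fragment-based)
#'
#' Sequence `a` is cut into non-overlapping fragments; each fragment is
#' located on `b` (either strand) by exact shared-k-mer seeding, then
#' aligned globally against the seeded window. ANI is the length-weighted
#' mean identity of aligned fragments; AF is the aligned length over the
#' shorter sequence. Poly-N linkers are stripped before comparison.
#'
#' @param a,b DNA strings (>= 1 kb after linker stripping).
#' @param fragment Fragment size in bp.
#' @param kmer_seed Seed k-mer length.
#' @param min_identity Percent identity below which a fragment alignment is
#'   discarded as spurious.
#' @return List (`ANIRecord`): `ani` (percent; `NA` when nothing aligns),
#'   `af` (percent of the shorter sequence), `n_fragments`,
#'   `n_aligned`.
#' @export
compute_ani_af <- function(a, b, fragment = 1000, kmer_seed = 15,
                           min_identity = 50) {
  a <- strip_linkers(a); b <- strip_linkers(b)
  stopifnot(nchar(a) >= 1000, nchar(b) >= 1000)
  la <- nchar(a)
  starts <- seq(1, la, by = fragment)
  ends <- pmin(starts + fragment - 1, la)
  keep <- (ends - starts + 1) >= fragment / 2
  starts <- starts[keep]; ends <- ends[keep]
  b_fwd <- b
  b_rev <- revcomp(b)
  ## numeric rolling 2-bit codes of all k-mers (integer-compare seeding);
  ## 4^15 < 2^53 so doubles represent every code exactly, N gives NA
  bk <- list(encode_kmers(b_fwd, kmer_seed), encode_kmers(b_rev, kmer_seed))
  acode <- encode_kmers(a, kmer_seed)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  pad <- 150
  hamming_pid <- function(x, y) {
    100 * sum(charToRaw(x) == charToRaw(y)) / nchar(x)
  }
  idents <- rep(NA_real_, length(starts))
  weights <- rep(0, length(starts))
  for (i in seq_along(starts)) {
    frag <- substr(a, starts[i], ends[i])
    flen <- nchar(frag)
    offs <- unique(pmax(0, round(c(0, 0.25, 0.5, 0.75) * (flen - kmer_seed))))
    for (sidx in 1:2) {
      bchr <- if (sidx == 1) b_fwd else b_rev
      ## candidate placements implied by each seed hit; repeated gene copies
      ## can seed several places, so placements are ranked by vote count
      cand <- integer()
      for (off in offs) {
        seed_code <- acode[starts[i] + off]
        if (is.na(seed_code)) next
        hits <- which(bk[[sidx]] == seed_code)
        if (length(hits)) cand <- c(cand, utils::head(hits, 4) - off)
      }
      if (!length(cand)) next
      ## seeds from the same (indel-free) placement imply the same position
      ranked <- as.integer(names(sort(table(cand), decreasing = TRUE)))
      ranked <- utils::head(ranked, 3)
      best_id <- NA_real_; best_w <- 0; best_pos <- ranked[1]
      ## direct positional comparison of every candidate first
      ## (substitution-only divergence; also rejects paralogous placements)
      for (pos in ranked) {
        if (pos >= 1 && pos + flen - 1 <= nchar(bchr)) {
          idt <- hamming_pid(frag, substr(bchr, pos, pos + flen - 1))
          if (is.na(best_id) || idt > best_id) {
            best_id <- idt; best_w <- flen; best_pos <- pos
          }
        }
      }
      if (is.na(best_id) || best_id < 98) {
        ## local alignment around the best candidate: handles indels,
        ## partial fragment overlap, and fragments dominated by a shared
        ## gene cassette sitting at a different genomic position
        pos <- best_pos
        ws <- max(1, pos - pad)
        we <- min(nchar(bchr), pos + flen + pad)
        if (we - ws >= kmer_seed) {
          aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(frag),
            Biostrings::DNAString(substr(bchr, ws, we)), type = "local",
            substitutionMatrix = submat, gapOpening = 10, gapExtension = 1)
          cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
          idt <- Biostrings::pid(aln, type = "PID1")
          if (!is.na(idt) && cols >= 0.2 * flen &&
              (is.na(best_id) || idt > best_id)) {
            best_id <- idt; best_w <- cols
          }
        }
      }
      if (!is.na(best_id) && best_id >= min_identity) {
        idents[i] <- best_id; weights[i] <- best_w; break
      }
    }
  }
  aligned <- !is.na(idents)
  if (!any(aligned)) {
    return(list(ani = NA_real_, af = 0, n_fragments = length(starts),
                n_aligned = 0L))
  }
  list(ani = stats::weighted.mean(idents[aligned], weights[aligned]),
       af = min(100, 100 * sum(weights[aligned]) / min(nchar(a), nchar(b))),
       n_fragments = length(starts), n_aligned = sum(aligned))
}

#' All-vs-all ANI/AF table with a k-mer prefilter
#'
#' Pairs sharing almost no 13-mers are skipped (their AF is ~0 by
#' construction); remaining pairs go through [compute_ani_af()].
#'
#' @param seqs Named character vector of sequences.
#' @param prefilter_jaccard Minimum 13-mer Jaccard to attempt alignment.
#' @param ... Passed to [compute_ani_af()].
#' @return data.frame `query_id`, `target_id`, `ani`, `af`.
#' @export
ani_table <- function(seqs, prefilter_jaccard = 0.005, ...) {
  ids <- names(seqs)
  stopifnot(!is.null(ids))
  sets <- lapply(seqs, function(s)
    unique(stats::na.omit(encode_kmers(strip_linkers(s), 13))))
  rows <- list()
  if (length(ids) >= 2) {
    for (i in 1:(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        inter <- sum(sets[[i]] %in% sets[[j]])
        jac <- inter / (length(sets[[i]]) + length(sets[[j]]) - inter)
        if (is.na(jac) || jac < prefilter_jaccard) next
        r <- compute_ani_af(seqs[[i]], seqs[[j]], ...)
        rows[[length(rows) + 1]] <- data.frame(
          query_id = ids[i], target_id = ids[j], ani = r$ani, af = r$af,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(query_id = character(),
                                      target_id = character(),
                                      ani = numeric(), af = numeric())
  out
}

#' Greedy centroid clustering into species-level vOTUs
#'
#' Genomes are sorted by completeness, then length, descending (ties by id
#' for determinism); each genome joins the first centroid it matches at
#' ANI >= `ani_min` and AF >= `af_min`, else founds a new vOTU.
#'
#' @param genomes data.frame `genome_id`, `completeness`, `length`.
#' @param ani_records data.frame `query_id`, `target_id`, `ani`, `af`
#'   (symmetric lookup; missing pairs count as no match).
#' @param ani_min,af_min MiUViG species thresholds (ANI >= 95, AF >= 85).
#' @return List of `VOTU`s: `votu_id`, `members`, `centroid_id`.
#' @export
cluster_votus <- function(genomes, ani_records, ani_min = 95, af_min = 85) {
  stopifnot(all(c("genome_id", "completeness", "length") %in% names(genomes)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- list()
  if (nrow(ani_records)) {
    lut <- stats::setNames(
      split(ani_records[, c("ani", "af")],
            seq_len(nrow(ani_records))),
      key(ani_records$query_id, ani_records$target_id))
  }
  ord <- order(-genomes$completeness, -genomes$length, genomes$genome_id)
  g <- genomes[ord, ]
  centroids <- character()
  assign <- stats::setNames(character(nrow(g)), g$genome_id)
  for (id in g$genome_id) {
    hit <- NA_character_
    for (c_id in centroids) {
      r <- lut[[key(id, c_id)]]
      if (!is.null(r) && !is.na(r$ani) && r$ani >= ani_min && r$af >= af_min) {
        hit <- c_id; break
      }
    }
    if (is.na(hit)) { centroids <- c(centroids, id); hit <- id }
    assign[id] <- hit
  }
  lapply(seq_along(centroids), function(k) {
    structure(list(votu_id = sprintf("vOTU%03d", k),
                   members = names(assign)[assign == centroids[k]],
                   centroid_id = centroids[k]), class = "VOTU")
  })
}

#' Greedy vOTU clustering with lazy ANI computation
#'
#' Same greedy centroid procedure as [cluster_votus()], but ANI/AF is
#' computed on demand against current centroids only (after a 13-mer
#' Jaccard prefilter), which scales far better than an all-vs-all table.
#'
#' @param seqs Named character vector of genome sequences.
#' @param completeness Named numeric completeness per genome.
#' @param ani_min,af_min MiUViG species thresholds.
#' @param prefilter_jaccard Minimum shared 13-mer Jaccard to attempt ANI.
#' @return List: `votus` (list of `VOTU`), `ani_records` (the pairs
#'   actually computed).
#' @export
cluster_votus_greedy <- function(seqs, completeness, ani_min = 95,
                                 af_min = 85, prefilter_jaccard = 0.005) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), all(ids %in% names(completeness)))
  lens <- nchar(gsub("N", "", seqs))
  ord <- order(-completeness[ids], -lens, ids)
  ids <- ids[ord]
  sets <- lapply(seqs, function(s)
    unique(stats::na.omit(encode_kmers(strip_linkers(s), 13))))
  centroids <- character()
  assign <- stats::setNames(character(length(ids)), ids)
  recs <- list()
  for (id in ids) {
    hit <- NA_character_
    for (c_id in centroids) {
      inter <- sum(sets[[id]] %in% sets[[c_id]])
      jac <- inter / (length(sets[[id]]) + length(sets[[c_id]]) - inter)
      if (is.na(jac) || jac < prefilter_jaccard) next
      r <- compute_ani_af(seqs[[id]], seqs[[c_id]])
      recs[[length(recs) + 1]] <- data.frame(
        query_id = id, target_id = c_id, ani = r$ani, af = r$af,
        stringsAsFactors = FALSE)
      if (!is.na(r$ani) && r$ani >= ani_min && r$af >= af_min) {
        hit <- c_id; break
      }
    }
    if (is.na(hit)) { centroids <- c(centroids, id); hit <- id }
    assign[id] <- hit
  }
  votus <- lapply(seq_along(centroids), function(k) {
    structure(list(votu_id = sprintf("vOTU%03d", k),
                   members = names(assign)[assign == centroids[k]],
                   centroid_id = centroids[k]), class = "VOTU")
  })
  recs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(query_id = character(), target_id = character(),
               ani = numeric(), af = numeric())
  list(votus = votus, ani_records = recs)
}

## ORF candidates in the three forward frames of one oriented sequence.
scan_orfs_oriented <- function(s, min_aa) {
  L <- nchar(s)
  out <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3
    if (n_cod < min_aa + 2) next
    cpos <- f + 3 * (seq_len(n_cod) - 1) + 1
    codons <- substring(s, cpos, cpos + 2)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% START_CODONS
    prev <- 0
    for (si in which(is_stop)) {
      if (si - prev >= min_aa + 1) {
        seg <- (prev + 1):(si - 1)
        st <- seg[is_start[seg]]
        st <- st[si - st >= min_aa]
        if (length(st)) {
          a <- st[1]
          out[[length(out) + 1]] <- c(start = cpos[a], end = cpos[si] + 2)
        }
      }
      prev <- si
    }
  }
  out
}

#' Find open reading frames (surrogate gene caller)
#'
#' Maximal start(ATG/GTG/TTG)-to-stop frames of at least `min_aa` codons on
#' both strands, made (near-)non-overlapping by longest-first greedy
#' selection; overlaps up to `max_overlap` bp are tolerated, as gene starts
#' commonly overlap neighbouring genes by a few codons. Coordinates are
#' 0-based half-open on the forward strand.
#'
#' @param sequence DNA string.
#' @param min_aa Minimum protein length (aa, excluding the stop).
#' @param max_overlap Maximum tolerated overlap (bp) between selected ORFs.
#' @return data.frame `orf_id`, `start`, `end`, `strand`, `aa` (translation,
#'   first residue forced to M, stop excluded).
#' @export
find_orfs <- function(sequence, min_aa = 60, max_overlap = 45) {
  L <- nchar(sequence)
  cands <- list()
  for (o in scan_orfs_oriented(sequence, min_aa)) {
    cands[[length(cands) + 1]] <- list(start = o[["start"]] - 1L,
                                       end = o[["end"]], strand = "+")
  }
  rc <- revcomp(sequence)
  for (o in scan_orfs_oriented(rc, min_aa)) {
    cands[[length(cands) + 1]] <- list(start = L - o[["end"]],
                                       end = L - (o[["start"]] - 1L),
                                       strand = "-")
  }
  if (!length(cands)) {
    return(data.frame(orf_id = character(), start = integer(), end = integer(),
                      strand = character(), aa = character(),
                      stringsAsFactors = FALSE))
  }
  lens <- vapply(cands, function(o) o$end - o$start, numeric(1))
  ## longest-first greedy, ties broken by position then strand (determinism)
  ord <- order(-lens,
               vapply(cands, `[[`, numeric(1), "start"),
               vapply(cands, `[[`, character(1), "strand"))
  taken_s <- integer(); taken_e <- integer()
  sel <- list()
  for (i in ord) {
    o <- cands[[i]]
    ov <- pmin(o$end, taken_e) - pmax(o$start, taken_s)
    if (length(ov) && any(ov > max_overlap)) next
    taken_s <- c(taken_s, o$start); taken_e <- c(taken_e, o$end)
    sel[[length(sel) + 1]] <- o
  }
  sel <- sel[order(vapply(sel, `[[`, numeric(1), "start"))]
  aa <- vapply(sel, function(o) {
    nt <- substr(sequence, o$start + 1, o$end)
    if (o$strand == "-") nt <- revcomp(nt)
    nt <- substr(nt, 1, nchar(nt) - 3)  # drop stop codon
    p <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    paste0("M", substr(p, 2, nchar(p)))
  }, character(1))
  data.frame(orf_id = sprintf("orf%04d", seq_along(sel)),
             start = vapply(sel, function(o) as.integer(o$start), integer(1)),
             end = vapply(sel, function(o) as.integer(o$end), integer(1)),
             strand = vapply(sel, `[[`, character(1), "strand"),
             aa = aa, stringsAsFactors = FALSE)
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Column-stochastic expansion/inflation iterations with pruning; clusters
#' are read off the converged matrix as the connected components of its
#' non-negligible entries.
#'
#' @param adj Symmetric non-negative weight matrix.
#' @param inflation Inflation exponent.
#' @param expansion Expansion power.
#' @param pruning Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap (a warning is issued when reached).
#' @param add_self_loops Add self-loops (scaled to each node's strongest
#'   incident edge) before normalisation, as weighted MCL requires.
#' @return Integer cluster membership vector (named when `adj` has dimnames).
#' @export
mcl_cluster <- function(adj, inflation = 2.0, expansion = 2, pruning = 1e-5,
                        max_iter = 100, add_self_loops = TRUE) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  n <- nrow(adj)
  M <- adj
  if (add_self_loops) {
    ## loop weight on the scale of the node's strongest edge: a unit loop
    ## on a strongly-weighted pair would collapse it to singletons
    diag(M) <- pmax(diag(M), apply(M, 2, max), 1)
  }
  norm_cols <- function(m) sweep(m, 2, pmax(colSums(m), .Machine$double.eps), "/")
  M <- norm_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M_prev <- M
    for (e in seq_len(expansion - 1)) M <- M %*% M
    M <- norm_cols(M^inflation)
    M[M < pruning] <- 0
    M <- norm_cols(M)
    if (max(abs(M - M_prev)) < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge; emitting current clustering")
  adj_bin <- (M > 1e-4) | t(M > 1e-4)
  g <- igraph::graph_from_adjacency_matrix(adj_bin, mode = "undirected")
  memb <- igraph::components(g)$membership
  if (!is.null(rownames(adj))) names(memb) <- rownames(adj)
  memb
}

#' Cluster proteins into protein clusters (PCs)
#'
#' Builds a similarity graph (amino-acid 4-mer Jaccard >= `threshold` by
#' default; a custom `similarity(a, b)` function may be plugged in) and runs
#' Markov clustering on each connected component. Singletons form their own
#' PCs.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param threshold Similarity threshold for an edge.
#' @param inflation MCL inflation.
#' @param k K-mer length for the Jaccard similarity.
#' @param similarity Optional function `(a, b) -> [0, 1]` replacing the
#'   k-mer Jaccard.
#' @return List of `ProteinCluster`s: `pc_id`, `members` (protein names).
#' @export
cluster_proteins <- function(proteins, threshold = 0.3, inflation = 2.0,
                             k = 4, similarity = NULL) {
  stopifnot(length(proteins) >= 1, !is.null(names(proteins)))
  n <- length(proteins)
  ids <- names(proteins)
  if (is.null(similarity)) {
    sets <- lapply(proteins, kmer_strings, k = k)
    dict <- unique(unlist(sets, use.names = FALSE))
    ii <- rep(seq_len(n), lengths(sets))
    jj <- match(unlist(sets, use.names = FALSE), dict)
    X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(n, length(dict)))
    inter <- Matrix::tcrossprod(X)
    sizes <- lengths(sets)
    sim <- as.matrix(inter)
    uni <- outer(sizes, sizes, "+") - sim
    sim <- sim / pmax(uni, 1)
  } else {
    sim <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      sim[i, j] <- similarity(proteins[[i]], proteins[[j]])
  }
  dimnames(sim) <- list(ids, ids)
  adj <- sim
  adj[adj < threshold] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max", weighted = TRUE)
  comp <- igraph::components(g)$membership
  memb <- integer(n); names(memb) <- ids
  next_id <- 0
  for (cmp in sort(unique(comp))) {
    members <- which(comp == cmp)
    if (length(members) == 1) {
      next_id <- next_id + 1
      memb[members] <- next_id
    } else {
      sub <- adj[members, members, drop = FALSE]
      cl <- mcl_cluster(sub, inflation = inflation)
      memb[members] <- next_id + cl
      next_id <- next_id + max(cl)
    }
  }
  lapply(sort(unique(memb)), function(cid) {
    structure(list(pc_id = sprintf("PC%05d", cid),
                   members = ids[memb == cid]), class = "ProteinCluster")
  })
}

#' Build the shared-PC viral-cluster (VC) network
#'
#' Edge weight between two genomes is `-log10` of the hypergeometric
#' upper-tail probability of sharing at least the observed number of PCs
#' given each genome's PC repertoire and the PC universe; edges below
#' `sig_threshold` are dropped, and only genomes sharing at least one PC
#' (and holding >= 2 PCs) enter the network. The weighted graph is
#' clustered by MCL; each VC's representative is the member with the
#' highest completeness (ties toward the longer genome).
#'
#' @param genome_pcs Named list: genome_id -> character vector of PC ids.
#' @param completeness Named numeric completeness per genome.
#' @param genome_lengths Named numeric genome lengths.
#' @param n_pc_universe Size of the PC universe (default: number of distinct
#'   PCs observed).
#' @param sig_threshold Minimum `-log10 p` edge weight.
#' @param inflation MCL inflation.
#' @return List: `vcs` (list of `ViralCluster`: `vc_id`, `members`,
#'   `representative_id`), `edges` (data.frame `source`, `target`,
#'   `shared_pcs`, `weight`), `outliers` (genomes excluded or unclustered).
#' @export
build_vc_network <- function(genome_pcs, completeness, genome_lengths,
                             n_pc_universe = NULL, sig_threshold = 1,
                             inflation = 2.0) {
  all_pcs <- unique(unlist(genome_pcs, use.names = FALSE))
  if (!length(all_pcs)) stop("empty PC universe")
  if (is.null(n_pc_universe)) n_pc_universe <- length(all_pcs)
  eligible <- names(genome_pcs)[lengths(genome_pcs) >= 2]
  outliers <- setdiff(names(genome_pcs), eligible)
  edges <- list()
  if (length(eligible) >= 2) {
    for (i in 1:(length(eligible) - 1)) {
      for (j in (i + 1):length(eligible)) {
        a <- genome_pcs[[eligible[i]]]; b <- genome_pcs[[eligible[j]]]
        kshare <- length(intersect(a, b))
        if (kshare == 0) next
        p <- stats::phyper(kshare - 1, length(a), n_pc_universe - length(a),
                           length(b), lower.tail = FALSE)
        w <- -log10(max(p, 1e-300))
        if (w < sig_threshold) next
        edges[[length(edges) + 1]] <- data.frame(
          source = eligible[i], target = eligible[j],
          shared_pcs = kshare, weight = w, stringsAsFactors = FALSE)
      }
    }
  }
  edges_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               shared_pcs = integer(), weight = numeric())
  in_net <- unique(c(edges_df$source, edges_df$target))
  outliers <- union(outliers, setdiff(eligible, in_net))
  vcs <- list()
  if (length(in_net)) {
    adj <- matrix(0, length(in_net), length(in_net),
                  dimnames = list(in_net, in_net))
    for (r in seq_len(nrow(edges_df))) {
      adj[edges_df$source[r], edges_df$target[r]] <- edges_df$weight[r]
      adj[edges_df$target[r], edges_df$source[r]] <- edges_df$weight[r]
    }
    memb <- mcl_cluster(adj, inflation = inflation)
    for (cid in sort(unique(memb))) {
      members <- names(memb)[memb == cid]
      if (length(members) < 2) { outliers <- union(outliers, members); next }
      comp <- completeness[members]
      len <- genome_lengths[members]
      rep_id <- members[order(-comp, -len, members)][1]
      vcs[[length(vcs) + 1]] <- structure(
        list(vc_id = sprintf("VC%03d", length(vcs) + 1), members = members,
             representative_id = rep_id), class = "ViralCluster")
    }
  }
  list(vcs = vcs, edges = edges_df, outliers = sort(outliers))
}

#' PC-by-VC incidence with AMG flags
#'
#' @param pcs List of `ProteinCluster`s whose member names are
#'   `genome_id|gene_id`.
#' @param vc_of Named character: genome_id -> vc_id (unclustered genomes
#'   absent).
#' @param amg_gene_ids Character vector of `genome_id|gene_id` keys that are
#'   AMGs.
#' @return data.frame `pc_id`, `n_members`, `n_vcs_touched`, `is_amg_pc`,
#'   `multi_vc`.
#' @export
pc_vc_incidence <- function(pcs, vc_of, amg_gene_ids = character()) {
  rows <- lapply(pcs, function(pc) {
    genomes <- sub("\\|.*$", "", pc$members)
    vcs <- unique(stats::na.omit(vc_of[genomes]))
    data.frame(pc_id = pc$pc_id, n_members = length(pc$members),
               n_vcs_touched = length(vcs),
               is_amg_pc = any(pc$members %in% amg_gene_ids),
               multi_vc = length(vcs) > 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
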