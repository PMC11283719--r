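## Taxonomy voting and marker-gene conflict resolution, AMG identification
## and VC-sharing statistics, abundance and recruitment-curve metrics, and
## strain-level core/flexible comparative genomics.

#' Consensus taxonomy by protein-hit voting
#'
#' No call is made unless strictly more than `min_hit_fraction` of the
#' genome's proteins have a reference hit. Ranks are then assigned from the
#' top of the lineage downward: a rank value is accepted when strictly more
#' than `majority` of the hit proteins agree; voting stops at the first rank
#' without a majority, truncating the lineage there.
#'
#' @param n_proteins Total predicted proteins of the genome (> 0).
#' @param hit_lineages Character matrix, one row per protein hit, ordered
#'   rank columns (e.g. realm, order, family, genus); `NA` cells allowed.
#' @param min_hit_fraction Hit-fraction gate (strict >).
#' @param majority Vote fraction required per rank (strict >).
#' @return A `TaxonomyCall`: list `lineage` (named character, possibly
#'   truncated), `method` ("vote" or "none"), `support` (vote fraction per
#'   assigned rank), `hit_fraction`.
#' @export
vote_taxonomy <- function(n_proteins, hit_lineages,
                          min_hit_fraction = 0.30, majority = 0.50) {
  stopifnot(n_proteins > 0)
  if (is.null(hit_lineages))
    hit_lineages <- matrix(character(), nrow = 0, ncol = 0)
  if (is.null(dim(hit_lineages)))
    hit_lineages <- matrix(hit_lineages, nrow = 1,
                           dimnames = list(NULL, names(hit_lineages)))
  n_hits <- nrow(hit_lineages)
  hit_fraction <- n_hits / n_proteins
  if (hit_fraction <= min_hit_fraction) {
    return(structure(list(lineage = character(), method = "none",
                          support = numeric(), hit_fraction = hit_fraction),
                     class = "TaxonomyCall"))
  }
  lineage <- character()
  support <- numeric()
  for (rk in colnames(hit_lineages)) {
    vals <- hit_lineages[, rk]
    tab <- sort(table(vals[!is.na(vals)]), decreasing = TRUE)
    if (!length(tab) || tab[1] / n_hits <= majority) break
    lineage[rk] <- names(tab)[1]
    support[rk] <- as.numeric(tab[1]) / n_hits
  }
  structure(list(lineage = lineage,
                 method = if (length(lineage)) "vote" else "none",
                 support = support, hit_fraction = hit_fraction),
            class = "TaxonomyCall")
}

#' Taxonomy from marker-gene hits with conflict resolution
#'
#' Hits with score below `score_min` (inclusive minimum) or E-value above
#' `evalue_max` are dropped; the call is the longest common prefix of the
#' surviving marker lineages, so conflicting markers truncate the annotation
#' to the deepest rank at which they agree.
#'
#' @param marker_hits data.frame with `score`, `evalue` and ordered rank
#'   columns (any other columns are ignored).
#' @param rank_cols Names of the lineage rank columns, outermost first.
#' @param score_min Minimum score (keep >= `score_min`).
#' @param evalue_max Maximum E-value (keep <= `evalue_max`).
#' @return A `TaxonomyCall` with method "marker" (or "none" when no marker
#'   survives).
#' @export
marker_taxonomy <- function(marker_hits, rank_cols,
                            score_min = 40, evalue_max = 1e-5) {
  keep <- marker_hits$score >= score_min & marker_hits$evalue <= evalue_max
  hits <- marker_hits[keep, , drop = FALSE]
  if (!nrow(hits)) {
    return(structure(list(lineage = character(), method = "none",
                          support = numeric(), hit_fraction = NA_real_),
                     class = "TaxonomyCall"))
  }
  lineage <- character()
  for (rk in rank_cols) {
    vals <- unique(hits[[rk]])
    if (length(vals) != 1 || is.na(vals)) break
    lineage[rk] <- vals
  }
  structure(list(lineage = lineage, method = "marker",
                 support = stats::setNames(rep(1, length(lineage)),
                                           names(lineage)),
                 hit_fraction = NA_real_), class = "TaxonomyCall")
}

#' Identify auxiliary metabolic genes (AMGs)
#'
#' Simulation mode reads ground-truth gene annotations; genes with role
#' "AMG" and auxiliary score inside `aux_score_range` yield records. Real
#' mode consumes an external annotation table with the same columns; when
#' several category sources are present the KEGG > CAZY > Pfam priority is
#' applied via [amg_category_priority()].
#'
#' @param genomes List of `ViralGenome`s (or any list with a `genes` table).
#' @param aux_score_range Accepted auxiliary scores.
#' @param pc_of Optional named map `genome_id|gene_id` -> pc_id.
#' @return data.frame (`AMGRecord`s): `genome_id`, `gene_id`,
#'   `amg_category`, `aux_score`, `pc_id`.
#' @export
identify_amgs <- function(genomes, aux_score_range = 1:3, pc_of = NULL) {
  rows <- lapply(genomes, function(g) {
    gn <- g$genes
    gn <- gn[gn$role == "AMG" & gn$aux_score %in% aux_score_range, ,
             drop = FALSE]
    if (!nrow(gn)) return(NULL)
    key <- paste(g$genome_id, gn$gene_id, sep = "|")
    data.frame(genome_id = g$genome_id, gene_id = gn$gene_id,
               amg_category = gn$amg_category, aux_score = gn$aux_score,
               pc_id = if (is.null(pc_of)) NA_character_ else
                 unname(pc_of[key]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(genome_id = character(),
                                      gene_id = character(),
                                      amg_category = character(),
                                      aux_score = integer(),
                                      pc_id = character())
  rownames(out) <- NULL
  out
}

#' Pick an AMG description with KEGG > CAZY > Pfam priority
#'
#' @param kegg,cazy,pfam Candidate annotations (`NA` when absent).
#' @return The first non-missing annotation in priority order, else `NA`.
#' @export
amg_category_priority <- function(kegg = NA, cazy = NA, pfam = NA) {
  for (x in list(kegg, cazy, pfam)) if (!is.na(x) && nzchar(x)) return(x)
  NA_character_
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration over the table's support: the two-sided
#' p-value sums the probabilities of all tables with the same margins that
#' are no more probable than the observed one. The odds ratio uses the
#' Haldane correction (+0.5 per cell) when any cell is zero. Degenerate
#' margins (an all-zero row or column) return p = 1 with a flag.
#'
#' @param tab 2x2 integer matrix.
#' @return List: `p`, `odds_ratio`, `table`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1.0, odds_ratio = NA_real_, table = tab,
                degenerate = TRUE))
  }
  m <- a + b       # row 1 total
  n2 <- c_ + d     # row 2 total
  kk <- a + c_     # column 1 total
  support <- max(0, kk - n2):min(kk, m)
  probs <- stats::dhyper(support, m, n2, kk)
  p_obs <- stats::dhyper(a, m, n2, kk)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  list(p = min(1, p), odds_ratio = or, table = tab, degenerate = FALSE)
}

#' Test whether AMG-containing PCs are shared across VCs more often
#'
#' Builds the 2x2 table {PC in multiple VCs, PC in a single VC} x
#' {AMG-containing, not} from a PC incidence table and applies
#' [fisher_exact_2x2()].
#'
#' @param pc_table data.frame with logical `multi_vc` and `is_amg_pc`
#'   columns and `n_vcs_touched >= 1` (see [pc_vc_incidence()]).
#' @return List: `table`, `p`, `odds_ratio`, `degenerate`.
#' @export
amg_sharing_test <- function(pc_table) {
  stopifnot(all(pc_table$n_vcs_touched >= 1))
  tab <- matrix(c(sum(pc_table$multi_vc & pc_table$is_amg_pc),
                  sum(pc_table$multi_vc & !pc_table$is_amg_pc),
                  sum(!pc_table$multi_vc & pc_table$is_amg_pc),
                  sum(!pc_table$multi_vc & !pc_table$is_amg_pc)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("multi_vc", "single_vc"),
                                c("amg", "not_amg")))
  res <- fisher_exact_2x2(tab)
  list(table = tab, p = res$p, odds_ratio = res$odds_ratio,
       degenerate = res$degenerate)
}

#' Reads-per-base abundance
#'
#' @param mapped_read_count Reads mapped to the reference.
#' @param reference_length Reference length in bp (> 0).
#' @param log10_transform Return `log10(rpb)` instead (for plotting scales).
#' @return `mapped_read_count / reference_length` (or its log10).
#' @export
reads_per_base <- function(mapped_read_count, reference_length,
                           log10_transform = FALSE) {
  stopifnot(reference_length > 0, mapped_read_count >= 0)
  rpb <- mapped_read_count / reference_length
  if (log10_transform) log10(rpb) else rpb
}

#' Read-recruitment (diversity) curve for a VC representative
#'
#' Alignments are filtered by identity >= `id_min`, query coverage strictly
#' over `qcov_min`, and E-value <= `evalue_max`; the recruited identities
#' are smoothed with a Gaussian kernel (bandwidth = `smooth_bandwidth` x
#' their SD) and reported as percentage of recruited reads per identity
#' value, so the curve integrates to 100%.
#'
#' @param alignments data.frame `identity` (percent), `qcov` (percent),
#'   `evalue`.
#' @param id_min,qcov_min,evalue_max Recruitment filters.
#' @param smooth_bandwidth Bandwidth factor relative to the identity SD.
#' @param grid Identity grid on which the curve is evaluated.
#' @return A `RecruitmentCurve`: list `identity` (grid), `percent` (curve),
#'   `recruited` (filtered identities), `n_recruited`. Zero recruited reads
#'   give an empty curve.
#' @export
recruitment_curve <- function(alignments, id_min = 50, qcov_min = 80,
                              evalue_max = 1e-5, smooth_bandwidth = 0.5,
                              grid = seq(50, 100, by = 0.25)) {
  keep <- alignments$identity >= id_min & alignments$qcov > qcov_min &
    alignments$evalue <= evalue_max
  ids <- alignments$identity[keep]
  if (!length(ids)) {
    return(structure(list(identity = grid, percent = rep(0, length(grid)),
                          recruited = numeric(), n_recruited = 0L),
                     class = "RecruitmentCurve"))
  }
  s <- stats::sd(ids)
  bw <- if (is.na(s) || s == 0) 0.1 else max(smooth_bandwidth * s, 1e-3)
  dens <- vapply(grid, function(x)
    mean(stats::dnorm(x, mean = ids, sd = bw)), numeric(1))
  step <- diff(grid)
  total <- sum((dens[-1] + dens[-length(dens)]) / 2 * step)
  pct <- if (total > 0) 100 * dens / total else dens
  structure(list(identity = grid, percent = pct, recruited = ids,
                 n_recruited = length(ids)), class = "RecruitmentCurve")
}

#' Interquartile range of recruited identities
#'
#' @param curve A `RecruitmentCurve`.
#' @return IQR of the recruited read identities (percentage points).
#' @export
recruitment_iqr <- function(curve) {
  stopifnot(inherits(curve, "RecruitmentCurve"))
  if (!length(curve$recruited)) return(NA_real_)
  unname(diff(stats::quantile(curve$recruited, c(0.25, 0.75))))
}

#' Orthologous-group presence matrix for one vOTU
#'
#' Rows are OGs, columns the member genomes, cells the per-genome gene
#' counts. An OG present in every member is core; all others are flexible.
#' Rows are ordered core-first.
#'
#' @param member_genes Named list: genome_id -> gene table with `og_label`
#'   (a `ViralGenome$genes` table works directly).
#' @return An `OGMatrix`: list `matrix` (counts), `og_class` (named
#'   "core"/"flexible"), `members`, `flagged` (members with zero genes).
#' @export
build_og_matrix <- function(member_genes) {
  stopifnot(length(member_genes) >= 2, !is.null(names(member_genes)),
            !anyDuplicated(names(member_genes)))
  members <- names(member_genes)
  flagged <- members[vapply(member_genes, function(t)
    is.null(t) || nrow(t) == 0, logical(1))]
  ogs <- sort(unique(unlist(lapply(member_genes, function(t)
    if (is.null(t)) character() else t$og_label))))
  M <- matrix(0L, length(ogs), length(members),
              dimnames = list(ogs, members))
  for (m in members) {
    t <- member_genes[[m]]
    if (is.null(t) || !nrow(t)) next
    cnt <- table(t$og_label)
    M[names(cnt), m] <- as.integer(cnt)
  }
  core <- rowSums(M > 0) == length(members)
  og_class <- stats::setNames(ifelse(core, "core", "flexible"), ogs)
  ord <- order(!core, ogs)
  M <- M[ord, , drop = FALSE]
  og_class <- og_class[ord]
  structure(list(matrix = M, og_class = og_class, members = members,
                 flagged = flagged), class = "OGMatrix")
}

#' Detect flexible-gene insertions between core flanks
#'
#' For each vOTU member, maximal runs of genes whose OG is flexible, bounded
#' by flank-eligible OGs (present in at least half the members), are
#' reported as insertion events with their flanking OGs; a missing flank is
#' reported as partial.
#'
#' @param member_genes Named list: genome_id -> gene table with `og_label`
#'   and `start` (gene order).
#' @param og_matrix An `OGMatrix` from [build_og_matrix()].
#' @return data.frame `genome_id`, `ogs` (";"-joined run), `left_flank`,
#'   `right_flank` (`NA` when absent), `partial`.
#' @export
detect_insertions <- function(member_genes, og_matrix) {
  stopifnot(inherits(og_matrix, "OGMatrix"))
  n_members <- length(og_matrix$members)
  presence <- rowSums(og_matrix$matrix > 0)
  flank_ok <- names(presence)[presence >= n_members / 2 &
                                og_matrix$og_class == "core"]
  flexible <- names(og_matrix$og_class)[og_matrix$og_class == "flexible"]
  rows <- list()
  for (m in names(member_genes)) {
    t <- member_genes[[m]]
    if (is.null(t) || !nrow(t)) next
    t <- t[order(t$start), ]
    is_flex <- t$og_label %in% flexible
    r <- rle(is_flex)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      left <- if (starts[j] > 1) t$og_label[starts[j] - 1] else NA_character_
      right <- if (ends[j] < nrow(t)) t$og_label[ends[j] + 1] else NA_character_
      if (!is.na(left) && !(left %in% flank_ok)) left <- NA_character_
      if (!is.na(right) && !(right %in% flank_ok)) right <- NA_character_
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = m,
        ogs = paste(t$og_label[starts[j]:ends[j]], collapse = ";"),
        left_flank = left, right_flank = right,
        partial = is.na(left) || is.na(right), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(genome_id = character(),
                                      ogs = character(),
                                      left_flank = character(),
                                      right_flank = character(),
                                      partial = logical())
  rownames(out) <- NULL
  out
}
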