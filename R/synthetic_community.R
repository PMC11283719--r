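## Synthetic viral community generator: ground-truth genomes, genes,
## taxonomy, strain groups and abundances with the statistical structure the
## downstream single-virus analysis assumes.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

## A random open reading frame: ATG + non-stop codons + one stop codon.
## Codons are weighted by the target base composition so planted genes do
## not wash out the genome-wide GC signature.
random_orf <- function(n_codons, gc = 0.5) {
  stopifnot(n_codons >= 3)
  cods <- sense_codons()
  pbase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(cods, function(cd)
    prod(pbase[strsplit(cd, "")[[1]]]), numeric(1))
  body <- sample(cods, n_codons - 2, replace = TRUE, prob = w)
  paste(c("ATG", body, sample(STOP_CODONS, 1)), collapse = "")
}

## Synonymous codon table from the standard genetic code.
syn_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), gc)
    }
    tab
  }
})

## Replace codons with a random synonymous alternative at rate `rate`:
## the protein is untouched while nucleotide identity decays, the way
## gene families diverge between species.
synonymous_shuffle <- function(orf, rate) {
  if (rate <= 0) return(orf)
  n <- nchar(orf) / 3
  codons <- substring(orf, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
  tab <- syn_table()
  gc <- Biostrings::GENETIC_CODE
  hit <- which(stats::runif(n) < rate)
  hit <- hit[hit > 1 & hit < n]
  for (i in hit) {
    alts <- tab[[gc[[codons[i]]]]]
    if (length(alts) > 1) codons[i] <- sample(alts, 1)
  }
  paste(codons, collapse = "")
}

## Replace internal codons with random sense codons at rate `rate`; the
## start and stop codons are preserved so the copy remains a clean ORF.
mutate_orf <- function(orf, rate) {
  if (rate <= 0) return(orf)
  n <- nchar(orf) / 3
  codons <- substring(orf, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
  hit <- which(stats::runif(n) < rate)
  hit <- hit[hit > 1 & hit < n]
  if (length(hit)) codons[hit] <- sample(sense_codons(), length(hit), replace = TRUE)
  paste(codons, collapse = "")
}

#' Build a shared pool of orthologous groups (OGs)
#'
#' Every OG owns a canonical ORF sequence; genomes planting the same OG carry
#' mutated copies of it, so distinct genomes can share protein families. A
#' fraction of OGs are auxiliary metabolic genes (AMGs) carrying an auxiliary
#' score; scores 1-3 denote confident AMGs, 4-5 are low-confidence decoys.
#'
#' @param n_ogs Number of orthologous groups in the pool.
#' @param amg_fraction Fraction of pool OGs that are AMGs.
#' @param len_codons Integer range (min, max) of ORF length in codons.
#' @param gc Codon base composition of the canonical ORFs.
#' @param seed Integer seed.
#' @return A data.frame with columns `og_label`, `role`, `amg_category`,
#'   `aux_score`, `sequence`.
#' @export
make_og_pool <- function(n_ogs = 120, amg_fraction = 0.1,
                         len_codons = c(200, 400), gc = 0.45, seed = 1) {
  with_seed(seed, {
    lens <- sample(seq(len_codons[1], len_codons[2]), n_ogs, replace = TRUE)
    roles <- sample(c("structural", "replication", "other"), n_ogs,
                    replace = TRUE, prob = c(0.4, 0.3, 0.3))
    n_amg <- round(amg_fraction * n_ogs)
    if (n_amg > 0) {
      amg_idx <- sample(n_ogs, n_amg)
      roles[amg_idx] <- "AMG"
    }
    aux <- ifelse(roles == "AMG",
                  sample(1:5, n_ogs, replace = TRUE,
                         prob = c(0.3, 0.3, 0.25, 0.1, 0.05)), NA_integer_)
    cat_pool <- c("carbon", "nitrogen", "sulfur", "phosphorus", "methylation")
    data.frame(
      og_label = sprintf("OG%04d", seq_len(n_ogs)),
      role = roles,
      amg_category = ifelse(roles == "AMG",
                            sample(cat_pool, n_ogs, replace = TRUE),
                            NA_character_),
      aux_score = as.integer(aux),
      sequence = vapply(lens, random_orf, character(1), gc = gc),
      stringsAsFactors = FALSE
    )
  })
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), og_label = character(), role = character(),
             amg_category = character(), aux_score = integer(),
             og_class = character(), stringsAsFactors = FALSE)
}

#' Construct a ViralGenome object
#'
#' @param genome_id Identifier.
#' @param sequence Nucleotide string over `{A,C,G,T}`.
#' @param topology `"linear"` or `"circular"`.
#' @param nucleic_type `"dsDNA"` or `"ssDNA"`.
#' @param taxonomy Ordered lineage (realm down to genus), named character.
#' @param strain_group_id Optional strain-group identifier.
#' @param genes Gene table (see [plant_genes()]); 0-based half-open coords.
#' @return An object of class `ViralGenome`.
#' @export
viral_genome <- function(genome_id, sequence, topology = "linear",
                         nucleic_type = "dsDNA", taxonomy = character(),
                         strain_group_id = NA_character_,
                         genes = empty_gene_table()) {
  stopifnot(nchar(sequence) >= 1000,
            topology %in% c("linear", "circular"),
            nucleic_type %in% c("dsDNA", "ssDNA"))
  g <- structure(list(genome_id = genome_id, sequence = sequence,
                      topology = topology, nucleic_type = nucleic_type,
                      taxonomy = taxonomy, strain_group_id = strain_group_id,
                      genes = genes),
                 class = "ViralGenome")
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  L <- nchar(g$sequence)
  if (grepl("[^ACGT]", g$sequence)) stop("genome sequence must be over ACGT")
  gn <- g$genes
  if (nrow(gn)) {
    stopifnot(all(gn$end > gn$start), all(gn$start >= 0), all(gn$end <= L),
              all((gn$end - gn$start) %% 3 == 0),
              all(gn$strand %in% c("+", "-")))
    for (s in c("+", "-")) {
      gs <- gn[gn$strand == s, , drop = FALSE]
      if (nrow(gs) > 1) {
        gs <- gs[order(gs$start), ]
        if (any(gs$start[-1] < gs$end[-nrow(gs)]))
          stop("genes overlap on strand ", s)
      }
    }
    has_aux <- !is.na(gn$aux_score)
    if (!all(has_aux == (gn$role == "AMG")))
      stop("aux_score must be present iff role == 'AMG'")
  }
  invisible(TRUE)
}

#' @export
print.ViralGenome <- function(x, ...) {
  cat(sprintf("<ViralGenome %s: %d bp, %s, %s, %d genes>\n", x$genome_id,
              nchar(x$sequence), x$topology, x$nucleic_type, nrow(x$genes)))
  invisible(x)
}

#' Plant genes on a genome from a shared OG pool
#'
#' Genes are placed sequentially on alternating random strands with
#' exponential inter-gene gaps sized so that the expected gene density is
#' `gene_density` per kb. Each gene is a mutated copy of its OG's canonical
#' ORF (minus strand genes are inserted as the reverse complement, so the
#' forward-strand annotation translates from the reverse complement).
#'
#' @param genome A `ViralGenome`.
#' @param gene_density Expected genes per kb.
#' @param amg_fraction Probability a planted gene is drawn from the pool's
#'   AMG subset.
#' @param seed Integer seed.
#' @param og_pool OG pool from [make_og_pool()]; one is derived from `seed`
#'   when omitted.
#' @param copy_divergence Per-codon (non-synonymous) substitution rate
#'   applied to each planted copy relative to the canonical OG sequence.
#' @param synonymous_rate Per-codon synonymous replacement rate applied to
#'   each copy: it decouples nucleotide identity between genomes sharing an
#'   OG (distinct species do not share near-identical nucleotide genes)
#'   while leaving the protein family recognisable.
#' @return The genome with `genes` filled in and gene regions rewritten.
#' @export
plant_genes <- function(genome, gene_density = 1, amg_fraction = 0.1,
                        seed = 1, og_pool = NULL, copy_divergence = 0.05,
                        synonymous_rate = 0.6) {
  stopifnot(amg_fraction >= 0, amg_fraction <= 1, gene_density > 0)
  if (is.null(og_pool)) og_pool <- make_og_pool(seed = child_seed(seed, 999))
  with_seed(seed, {
    L <- nchar(genome$sequence)
    amg_pool <- og_pool[og_pool$role == "AMG", , drop = FALSE]
    non_pool <- og_pool[og_pool$role != "AMG", , drop = FALSE]
    mean_len <- mean(nchar(og_pool$sequence))
    gap_mean <- max(20, 1000 / gene_density - mean_len)
    min_len <- min(nchar(og_pool$sequence))
    if (L < min_len + 6) {
      warning("genome too short for a single gene; empty gene list")
      genome$genes <- empty_gene_table()
      return(genome)
    }
    chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
    genes <- list()
    pos <- 1 + round(stats::rexp(1, 1 / gap_mean))  # 1-based cursor
    i <- 0
    ## OGs are drawn without replacement so a genome carries no
    ## near-identical paralogs (the pool is recycled only if exhausted)
    avail_amg <- seq_len(nrow(amg_pool))
    avail_non <- seq_len(nrow(non_pool))
    while (TRUE) {
      take_amg <- nrow(amg_pool) > 0 && stats::runif(1) < amg_fraction
      if (!length(avail_amg)) avail_amg <- seq_len(nrow(amg_pool))
      if (!length(avail_non)) avail_non <- seq_len(nrow(non_pool))
      if (take_amg || nrow(non_pool) == 0) {
        pick <- avail_amg[sample.int(length(avail_amg), 1)]
        avail_amg <- setdiff(avail_amg, pick)
        og <- amg_pool[pick, ]
      } else {
        pick <- avail_non[sample.int(length(avail_non), 1)]
        avail_non <- setdiff(avail_non, pick)
        og <- non_pool[pick, ]
      }
      gseq <- mutate_orf(synonymous_shuffle(og$sequence, synonymous_rate),
                         copy_divergence)
      glen <- nchar(gseq)
      if (pos + glen - 1 > L) break
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") gseq else revcomp(gseq)
      chars[pos:(pos + glen - 1)] <- strsplit(ins, "", fixed = TRUE)[[1]]
      i <- i + 1
      genes[[i]] <- data.frame(
        gene_id = sprintf("%s_g%03d", genome$genome_id, i),
        start = pos - 1L, end = as.integer(pos - 1L + glen),
        strand = strand, og_label = og$og_label, role = og$role,
        amg_category = og$amg_category, aux_score = og$aux_score,
        og_class = "core", stringsAsFactors = FALSE)
      pos <- pos + glen + round(stats::rexp(1, 1 / gap_mean)) + 1
    }
    genome$sequence <- paste(chars, collapse = "")
    genome$genes <- if (length(genes)) do.call(rbind, genes) else empty_gene_table()
    validate_genome(genome)
    genome
  })
}

#' Generate a ground-truth viral community
#'
#' Genome lengths are lognormal (median `length_distribution$median_bp`,
#' log-sd `length_distribution$sdlog`), truncated to 1-300 kb. Relative
#' abundances follow a discrete power law over abundance rank,
#' `p_i` proportional to `i^(-abundance_exponent)`, then normalised to 1.
#' A fraction of genomes are ssDNA; an optional background host genome with
#' a GC content offset (so its tetranucleotide signature is separable)
#' models carried-over non-viral DNA.
#'
#' @param n_genomes Number of viral genomes (>= 1).
#' @param length_distribution List with `median_bp` and `sdlog`.
#' @param abundance_exponent Power-law slope over abundance rank.
#' @param seed Integer seed.
#' @param gc Mean viral GC content.
#' @param ssdna_fraction Fraction of ssDNA genomes.
#' @param gene_density,amg_fraction Passed to [plant_genes()] per genome;
#'   `gene_density = 0` skips gene planting.
#' @param og_pool Shared OG pool; derived from `seed` when omitted.
#' @param background Logical; add a 1 Mb host background genome whose GC is
#'   offset by `background_gc_offset` from the viral mean.
#' @param background_abundance Relative abundance assigned to the background
#'   genome (viral abundances still sum to 1 among themselves).
#' @param background_length Background genome length in bp.
#' @param background_gc_offset GC offset (fraction) of the background genome
#'   (>= 0.10 keeps the host tetranucleotide signature separable).
#' @return A `Community` object: list with `genomes` (named list of
#'   `ViralGenome`), `abundances` (named, sums to 1), `background_genome`
#'   (or `NULL`), `og_pool`.
#' @export
generate_community <- function(n_genomes,
                               length_distribution = list(median_bp = 40000, sdlog = 0.6),
                               abundance_exponent = 1.5, seed = 1,
                               gc = 0.45, ssdna_fraction = 0.1,
                               gene_density = 1, amg_fraction = 0.1,
                               og_pool = NULL, background = TRUE,
                               background_abundance = 0.05,
                               background_length = 100000,
                               background_gc_offset = 0.15) {
  stopifnot(n_genomes >= 1)
  if (!is.list(length_distribution) ||
      is.null(length_distribution$median_bp) || is.null(length_distribution$sdlog) ||
      length_distribution$median_bp <= 0 || length_distribution$sdlog < 0)
    stop("invalid length_distribution parameters")
  if (is.null(og_pool)) og_pool <- make_og_pool(gc = gc, seed = child_seed(seed, 999))
  with_seed(seed, {
    lens <- stats::rlnorm(n_genomes, meanlog = log(length_distribution$median_bp),
                          sdlog = length_distribution$sdlog)
    lens <- as.integer(pmin(pmax(round(lens), 1000), 300000))
    types <- ifelse(stats::runif(n_genomes) < ssdna_fraction, "ssDNA", "dsDNA")
    topo <- sample(c("linear", "circular"), n_genomes, replace = TRUE,
                   prob = c(0.8, 0.2))
    n_fam <- max(1, ceiling(n_genomes / 4))
    fam <- sample(n_fam, n_genomes, replace = TRUE)
    genomes <- vector("list", n_genomes)
    for (i in seq_len(n_genomes)) {
      gid <- sprintf("vg%03d", i)
      tax <- c(realm = ifelse(types[i] == "dsDNA", "Duplodnaviria", "Monodnaviria"),
               order = sprintf("Order_%02d", (fam[i] - 1) %/% 3 + 1),
               family = sprintf("Family_%02d", fam[i]),
               genus = sprintf("Genus_%03d", i))
      g <- viral_genome(gid, random_dna(lens[i], gc), topo[i], types[i], tax)
      if (gene_density > 0)
        g <- plant_genes(g, gene_density, amg_fraction,
                         seed = child_seed(seed, i), og_pool = og_pool)
      genomes[[i]] <- g
    }
    names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
    ab <- seq_len(n_genomes)^(-abundance_exponent)
    ab <- ab[sample(n_genomes)]  # ranks shuffled across genome ids
    ab <- ab / sum(ab)
    names(ab) <- names(genomes)
    bg <- NULL
    if (background) {
      bg <- list(genome_id = "host_bg",
                 sequence = random_dna(background_length,
                                       min(0.95, gc + background_gc_offset)),
                 abundance = background_abundance)
    }
    structure(list(genomes = genomes, abundances = ab,
                   background_genome = bg, og_pool = og_pool),
              class = "Community")
  })
}

#' @export
print.Community <- function(x, ...) {
  cat(sprintf("<Community: %d genomes, median length %d bp%s>\n",
              length(x$genomes),
              as.integer(stats::median(vapply(x$genomes, function(g)
                nchar(g$sequence), numeric(1)))),
              if (!is.null(x$background_genome)) ", host background" else ""))
  invisible(x)
}

#' Make MTase-style flexible gene cassettes
#'
#' Each cassette is a single methyltransferase-subtype gene suitable for
#' [spawn_strains()] flexible insertion.
#'
#' @param n Number of distinct subtypes.
#' @param len_codons Range of cassette ORF lengths in codons.
#' @param gc Codon base composition.
#' @param seed Integer seed.
#' @return List of cassettes, each `list(og_label, role, sequence)`.
#' @export
make_mtase_cassettes <- function(n, len_codons = c(150, 250), gc = 0.45,
                                 seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(og_label = sprintf("MTase_%s", LETTERS[i]), role = "MTase",
           sequence = random_orf(sample(seq(len_codons[1], len_codons[2]), 1),
                                 gc = gc))
    })
  })
}

#' Spawn near-identical strains of a genome
#'
#' Each strain is the parent plus (i) point substitutions at sites outside
#' core genes, so conserved marker genes stay identical, and (ii) insertion
#' of a strain-specific subset of flexible gene cassettes at inter-gene
#' positions flanked by core genes, mirroring the core/flexible architecture
#' seen in within-species viral comparative genomics.
#'
#' @param genome Parent `ViralGenome` (its genes are the core set).
#' @param n_strains Number of strains to derive.
#' @param snv_rate Per-site substitution rate (<= 0.02 keeps strains within
#'   one species under the ANI >= 95 criterion).
#' @param flexible_cassettes List of cassettes from [make_mtase_cassettes()]
#'   (may be empty).
#' @param seed Integer seed.
#' @param cassette_prob Inclusion probability per cassette per strain (each
#'   strain receives at least one when cassettes are supplied).
#' @return List of `ViralGenome` strains sharing `strain_group_id`.
#' @export
spawn_strains <- function(genome, n_strains, snv_rate = 0.005,
                          flexible_cassettes = list(), seed = 1,
                          cassette_prob = 0.5) {
  stopifnot(n_strains >= 1, snv_rate >= 0, snv_rate <= 0.02)
  group <- genome$genome_id
  with_seed(seed, {
    lapply(seq_len(n_strains), function(k) {
      s <- genome
      s$genome_id <- sprintf("%s_s%d", group, k)
      s$strain_group_id <- group
      if (nrow(s$genes)) {
        s$genes$gene_id <- sub(group, s$genome_id, s$genes$gene_id, fixed = TRUE)
      }
      ## substitutions only outside core genes
      if (snv_rate > 0) {
        covered <- rep(FALSE, nchar(s$sequence))
        if (nrow(s$genes)) {
          for (j in seq_len(nrow(s$genes)))
            covered[(s$genes$start[j] + 1):s$genes$end[j]] <- TRUE
        }
        s$sequence <- mutate_sequence(s$sequence, snv_rate, which(!covered))
      }
      ## strain-specific flexible cassette insertions
      if (length(flexible_cassettes)) {
        pick <- which(stats::runif(length(flexible_cassettes)) < cassette_prob)
        if (!length(pick)) pick <- sample(length(flexible_cassettes), 1)
        for (ci in pick) s <- insert_cassette(s, flexible_cassettes[[ci]])
      }
      validate_genome(s)
      s
    })
  })
}

## Insert one cassette gene at a random inter-gene position flanked by core
## genes; downstream gene coordinates shift by the cassette length.
insert_cassette <- function(genome, cassette) {
  gn <- genome$genes[order(genome$genes$start), ]
  core <- gn[gn$og_class == "core", , drop = FALSE]
  if (nrow(core) < 2) stop("cassette placement error: need two core genes to flank")
  ## candidate gaps between consecutive core genes with no gene in between
  gaps <- list()
  for (j in seq_len(nrow(core) - 1)) {
    lo <- core$end[j]; hi <- core$start[j + 1]
    if (hi - lo >= 2 && !any(gn$start >= lo & gn$end <= hi))
      gaps[[length(gaps) + 1]] <- c(lo, hi)
  }
  if (!length(gaps)) stop("cassette placement error: no inter-gene gap available")
  gap <- gaps[[sample(length(gaps), 1)]]
  at <- gap[1] + sample.int(gap[2] - gap[1] - 1, 1)  # 0-based insertion point
  cas_len <- nchar(cassette$sequence)
  strand <- sample(c("+", "-"), 1)
  ins <- if (strand == "+") cassette$sequence else revcomp(cassette$sequence)
  genome$sequence <- paste0(substr(genome$sequence, 1, at), ins,
                            substr(genome$sequence, at + 1, nchar(genome$sequence)))
  shift <- genome$genes$start >= at
  genome$genes$start[shift] <- genome$genes$start[shift] + cas_len
  genome$genes$end[genome$genes$end > at] <-
    genome$genes$end[genome$genes$end > at] + cas_len
  new_gene <- data.frame(
    gene_id = sprintf("%s_%s", genome$genome_id, cassette$og_label),
    start = at, end = as.integer(at + cas_len), strand = strand,
    og_label = cassette$og_label,
    role = if (is.null(cassette$role)) "MTase" else cassette$role,
    amg_category = NA_character_, aux_score = NA_integer_,
    og_class = "flexible", stringsAsFactors = FALSE)
  genome$genes <- rbind(genome$genes, new_gene)
  genome$genes <- genome$genes[order(genome$genes$start), ]
  rownames(genome$genes) <- NULL
  genome
}

#' Ground-truth OG table of a community
#'
#' One row per OG label planted in at least one genome, with its class.
#' @param community A `Community`.
#' @return data.frame `og_label`, `role`, `og_class`, `n_genomes`.
#' @export
og_truth_table <- function(community) {
  tabs <- lapply(community$genomes, function(g) g$genes)
  all <- do.call(rbind, tabs)
  if (is.null(all) || !nrow(all))
    return(data.frame(og_label = character(), role = character(),
                      og_class = character(), n_genomes = integer()))
  agg <- unique(all[, c("og_label", "role", "og_class")])
  agg <- agg[!duplicated(agg$og_label), ]
  cnt <- vapply(agg$og_label, function(l)
    sum(vapply(tabs, function(t) any(t$og_label == l), logical(1))), integer(1))
  agg$n_genomes <- as.integer(cnt)
  rownames(agg) <- NULL
  agg[order(agg$og_label), ]
}
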