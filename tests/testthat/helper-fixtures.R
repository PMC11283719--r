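## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

## Six-genome community with host background (genes planted).
small_community <- function() fx("comm6", generate_community(6, seed = 3))

## Parent genome + six strains with MTase cassettes, plus a truncated copy.
strain_set <- function() fx("strains", {
  comm <- generate_community(4, seed = 3, background = FALSE)
  parent <- comm$genomes[[2]]
  cassettes <- make_mtase_cassettes(6, seed = 4)
  strains <- spawn_strains(parent, 6, snv_rate = 0.005,
                           flexible_cassettes = cassettes, seed = 9)
  trunc <- viral_genome("trunc",
                        substr(parent$sequence, 1,
                               floor(nchar(parent$sequence) * 0.5)),
                        taxonomy = parent$taxonomy)
  list(comm = comm, parent = parent, cassettes = cassettes,
       strains = strains, trunc = trunc)
})

## ORFs and ground-truth OG labels for the proteins of a few genomes.
protein_set <- function() fx("proteins", {
  comm <- small_community()
  prots <- character(); labs <- character()
  for (g in comm$genomes[1:4]) {
    o <- find_orfs(g$sequence)
    for (i in seq_len(nrow(o))) {
      ov <- pmin(o$end[i], g$genes$end) - pmax(o$start[i], g$genes$start)
      j <- which(ov >= 0.9 * (g$genes$end - g$genes$start) &
                   o$strand[i] == g$genes$strand)
      key <- paste(g$genome_id, o$orf_id[i], sep = "|")
      prots[key] <- o$aa[i]
      labs[key] <- if (length(j) == 1) g$genes$og_label[j] else NA
    }
  }
  list(proteins = prots, labels = labs)
})

## One single-loaded amplified bead from the small community.
single_bead <- function(sigma = 0, dropout = 0, seed = 2) {
  comm <- small_community()
  beads <- encapsulate(comm, 200, 0.3, seed = 5)
  b <- beads[[which(vapply(beads, function(x)
    length(x$loaded_genomes) == 1, logical(1)))[1]]]
  amplify(b, comm, sigma = sigma, dropout = dropout, seed = seed)
}

## Adjusted Rand index (contingency-table closed form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
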