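## Platform QC: Poisson loading inversion, concentration estimation,
## dilution decision, bead classification by reference mapping,
## cross-contamination flagging, genome breadth and Lorenz/Gini metrics.

#' Estimate mean bead loading from the positive rate
#'
#' Inverts the Poisson zero-class: with loading ~ Poisson(lambda), the
#' probability a bead holds at least one particle is `1 - exp(-lambda)`, so
#' `lambda = -log(1 - p)`.
#'
#' @param p_positive Observed fraction of positive beads, in `[0, 1)`.
#' @return The estimated Poisson mean `lambda`.
#' @export
estimate_mean_loading <- function(p_positive) {
  if (!is.numeric(p_positive) || p_positive < 0) stop("p_positive must be >= 0")
  if (p_positive >= 1) stop("p_positive = 1 leaves lambda undefined")
  -log(1 - p_positive)
}

#' Probability a positive bead holds multiple particles
#'
#' `P(k >= 2 | k >= 1) = 1 - lambda * exp(-lambda) / (1 - exp(-lambda))`.
#'
#' @param lambda Poisson mean loading.
#' @return Conditional multi-loading probability.
#' @export
p_multi_given_positive <- function(lambda) {
  stopifnot(lambda >= 0)
  if (lambda == 0) return(0)
  1 - lambda * exp(-lambda) / (1 - exp(-lambda))
}

#' Particle concentration from mean loading
#'
#' `concentration = lambda / V_bead * dilution_factor`, with the bead volume
#' `V_bead = (pi/6) d^3` converted to mL. The default dilution factor 2
#' accounts for the 1:1 mix of suspension with molten agarose.
#'
#' @param lambda Mean particles per bead (>= 0).
#' @param bead_diameter Bead diameter in micrometres.
#' @param dilution_factor Fold-dilution of the suspension before
#'   encapsulation.
#' @return Particles per mL of original suspension.
#' @export
concentration_from_loading <- function(lambda, bead_diameter = 30,
                                       dilution_factor = 2) {
  stopifnot(lambda >= 0, bead_diameter > 0, dilution_factor > 0)
  v_ml <- pi / 6 * (bead_diameter * 1e-4)^3  # um -> cm; cm^3 == mL
  lambda / v_ml * dilution_factor
}

#' Decide whether the suspension must be diluted
#'
#' The platform dilutes and re-encapsulates whenever the fluorescence-positive
#' rate exceeds 20% (strictly), to limit co-encapsulation of multiple
#' particles.
#'
#' @param p_positive Positive rate in `[0, 1]`.
#' @param threshold Dilution threshold (default 0.20).
#' @return List: `decision` ("proceed" or "dilute"), `lambda`,
#'   `p_multi_given_positive`.
#' @export
dilution_decision <- function(p_positive, threshold = 0.20) {
  stopifnot(p_positive >= 0, p_positive <= 1)
  lam <- if (p_positive < 1) estimate_mean_loading(p_positive) else Inf
  list(decision = if (p_positive > threshold) "dilute" else "proceed",
       lambda = lam,
       p_multi_given_positive = if (is.finite(lam)) p_multi_given_positive(lam) else 1)
}

#' Classify one bead from its per-reference read counts
#'
#' The bead is labelled with the viral reference attracting the most reads;
#' it is flagged contaminated when reads mapping to other viral references
#' exceed `minor_threshold` of the viral reads, and background-dominated when
#' background reads outnumber viral reads.
#'
#' @param counts Named numeric vector of read counts per reference.
#' @param background_ids Names in `counts` that are background references.
#' @param minor_threshold Minor-viral fraction above which (strictly) the
#'   bead is contaminated.
#' @return List: `majority_ref`, `minor_viral_fraction`, `contaminated`,
#'   `background_fraction`, `background_dominated`. `majority_ref` is `NA`
#'   (unclassified) when no viral read maps.
#' @export
classify_bead <- function(counts, background_ids = character(),
                          minor_threshold = 0.01) {
  stopifnot(sum(counts) > 0, all(counts >= 0))
  viral <- counts[setdiff(names(counts), background_ids)]
  bg <- sum(counts[intersect(names(counts), background_ids)])
  total <- sum(counts)
  if (length(viral) == 0 || sum(viral) == 0) {
    return(list(majority_ref = NA_character_, minor_viral_fraction = NA_real_,
                contaminated = FALSE, background_fraction = bg / total,
                background_dominated = bg > 0))
  }
  maj <- names(viral)[which.max(viral)]
  minor <- (sum(viral) - max(viral)) / sum(viral)
  list(majority_ref = maj, minor_viral_fraction = minor,
       contaminated = minor > minor_threshold,
       background_fraction = bg / total,
       background_dominated = bg > sum(viral))
}

#' Per-reference mapping table for a set of beads
#'
#' Simulation mode: read assignment uses exact ground-truth provenance of
#' simulated reads. Real-data mode consumes an external mapper's counts via
#' [read_mapping_table()] instead.
#'
#' @param beads List of beads with `reads` populated.
#' @return data.frame `bead_id`, `reference_id`, `read_count`.
#' @export
mapping_table <- function(beads) {
  rows <- lapply(beads, function(b) {
    if (is.null(b$reads) || !nrow(b$reads)) return(NULL)
    t <- table(b$reads$source_id)
    data.frame(bead_id = b$bead_id, reference_id = names(t),
               read_count = as.integer(t), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(bead_id = character(),
                                      reference_id = character(),
                                      read_count = integer())
  rownames(out) <- NULL
  out
}

#' Fraction of reference positions covered by at least one read
#'
#' @param depth Non-negative integer/numeric per-base depth vector.
#' @return Breadth in `[0, 1]`.
#' @export
genome_breadth <- function(depth) {
  stopifnot(length(depth) > 0, all(depth >= 0))
  mean(depth > 0)
}

#' Gini coefficient of per-base depth (amplification bias)
#'
#' `G = 1 - 2 * area` under the trapezoidal Lorenz curve of the sorted
#' per-base depths, zero-depth positions included. `G = 0` means perfectly
#' uniform amplification; values near 1 indicate extreme bias.
#'
#' @param depth Non-negative per-base depth vector with positive total.
#' @return List: `gini`, and `lorenz` (data.frame `p` cumulative fraction of
#'   positions, `L` cumulative fraction of depth, including the origin).
#' @export
gini_coefficient <- function(depth) {
  stopifnot(length(depth) > 0, all(depth >= 0))
  if (sum(depth) <= 0) stop("total depth is zero; Gini undefined")
  x <- sort(as.numeric(depth))
  n <- length(x)
  cum <- cumsum(x) / sum(x)
  p <- seq_len(n) / n
  lorenz <- data.frame(p = c(0, p), L = c(0, cum))
  area <- sum((lorenz$L[-1] + lorenz$L[-(n + 1)]) / 2 * diff(lorenz$p))
  list(gini = 1 - 2 * area, lorenz = lorenz)
}

#' Run-level QC report
#'
#' @param manifest A `RunManifest`.
#' @param map Mapping table from [mapping_table()].
#' @param background_ids Background reference names.
#' @param bead_diameter,dilution_factor Passed to
#'   [concentration_from_loading()].
#' @param minor_threshold Passed to [classify_bead()].
#' @param beads Optional bead list to compute per-bead breadth and Gini from
#'   coverage profiles.
#' @return A `QCReport`: list with `p_positive`, `lambda`, `concentration`,
#'   `dilution`, and data.frame `per_bead` (majority reference, minor viral
#'   fraction, contamination and background flags, breadth, Gini).
#' @export
qc_report <- function(manifest, map, background_ids = "host_bg",
                      bead_diameter = 30, dilution_factor = 2,
                      minor_threshold = 0.01, beads = NULL) {
  p <- manifest$n_beads_positive / manifest$n_beads_generated
  lam <- estimate_mean_loading(min(p, 1 - 1e-12))
  per <- NULL
  if (nrow(map)) {
    per <- do.call(rbind, lapply(split(map, map$bead_id), function(d) {
      cls <- classify_bead(stats::setNames(d$read_count, d$reference_id),
                           background_ids, minor_threshold)
      data.frame(bead_id = d$bead_id[1], majority_ref = cls$majority_ref,
                 minor_viral_fraction = cls$minor_viral_fraction,
                 contaminated = cls$contaminated,
                 background_fraction = cls$background_fraction,
                 background_dominated = cls$background_dominated,
                 stringsAsFactors = FALSE)
    }))
    rownames(per) <- NULL
  }
  if (!is.null(beads) && !is.null(per)) {
    bg <- vapply(beads, function(b) {
      if (!length(b$coverage_profiles)) return(c(NA_real_, NA_real_))
      d <- b$coverage_profiles[[which.max(vapply(b$coverage_profiles, sum,
                                                 numeric(1)))]]
      c(genome_breadth(d), if (sum(d) > 0) gini_coefficient(d)$gini else NA_real_)
    }, numeric(2))
    idx <- match(per$bead_id, vapply(beads, `[[`, character(1), "bead_id"))
    per$breadth <- bg[1, idx]
    per$gini <- bg[2, idx]
  }
  structure(list(p_positive = p, lambda = lam,
                 concentration = concentration_from_loading(lam, bead_diameter,
                                                            dilution_factor),
                 dilution = dilution_decision(p), per_bead = per),
            class = "QCReport")
}

#' Read an external per-reference mapping table (real-data mode)
#'
#' @param path TSV with columns `bead_id`, `reference_id`, `read_count`.
#' @return data.frame in [mapping_table()] layout.
#' @export
read_mapping_table <- function(path) {
  d <- read_tsv_file(path)
  stopifnot(all(c("bead_id", "reference_id", "read_count") %in% names(d)),
            all(d$read_count >= 0))
  d
}
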