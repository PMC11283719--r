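## Shared internal helpers: seeded evaluation, sequence utilities, rounding.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded operations do not
#' perturb the global random stream. A `NULL` seed evaluates the code with
#' the current stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## Derive a distinct child seed from a parent seed; keeps values < 2^31.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7907 * as.double(i)) %% 2147483647)
}

#' Generate a random DNA sequence
#'
#' @param n Sequence length in bp.
#' @param gc Target GC content in `[0, 1]`.
#' @return A single character string over `{A,C,G,T}`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x Character string over `{A,C,G,T,N}`.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Apply random point substitutions to a DNA string
#'
#' Each eligible position is substituted independently with probability
#' `rate`; substitutions always change the base.
#'
#' @param x DNA string.
#' @param rate Per-site substitution probability.
#' @param positions Optional 1-based positions eligible for substitution
#'   (default: all).
#' @return The mutated string.
#' @export
mutate_sequence <- function(x, rate, positions = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(x)
  n <- nchar(x)
  if (is.null(positions)) positions <- seq_len(n)
  hit <- positions[stats::runif(length(positions)) < rate]
  if (length(hit) == 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Round half-up to one decimal, as percentages are reported
#'
#' @param num Numerator.
#' @param den Denominator (> 0).
#' @return `100 * num / den` rounded half-up to 1 decimal.
#' @export
pct1 <- function(num, den) {
  stopifnot(den > 0)
  floor(100 * num / den * 10 + 0.5) / 10
}

## Cosine similarity between two numeric vectors.
cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

## Write a data.frame as a headered TSV with '\n' newlines (deterministic).
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}
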