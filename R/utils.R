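#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed and labels
#'
#' Stable across sessions and platforms: labels are hashed by character
#' codes, mixed with the master seed, and reduced modulo 2^31 - 1 so the
#' result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed
#' @param ... character or numeric labels naming the substream
#'   (e.g. strain, tissue, stage)
#' @return an integer seed
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  labels <- paste(vapply(list(...), function(x) paste(as.character(x),
    collapse = "\r"), character(1)), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(labels)) h <- (h * 131 + v) %% 2147483587
  as.integer((abs(seed) * 2654435761 + h) %% 2147483587 + 1)
}

#' @noRd
assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(min), format(max)), call. = FALSE)
  invisible(x)
}

#' @noRd
random_dna <- function(n, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse-complement DNA sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N)
#' @return character vector of the same length
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' @noRd
write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
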