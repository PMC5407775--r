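#' Per-TE genomic abundance from DNA-seq alignments
#'
#' DNA reads are mapped with the same contract as small RNAs (up to 3
#' mismatches on canonical TEs, fractional multi-family weights).
#' `dna_rpm = weight / depth * 1e6`; a per-position coverage vector over
#' each canonical sequence is accumulated alongside.
#'
#' @param alignments [map_to_canonical()] output for the DNA-seq reads
#' @param te_panel panel with `id` and `length`
#' @param depth library depth (> 0); defaults to the alignments' attribute
#' @return data.frame `te_id`, `weight`, `dna_rpm`, `length`, with a
#'   `coverage` attribute (named list of per-position depth vectors)
#' @export
te_genomic_abundance <- function(alignments, te_panel, depth = NULL) {
  depth <- depth %||% attr(alignments, "depth")
  if (is.null(depth) || depth <= 0) stop("depth must be > 0")
  w <- setNames(numeric(nrow(te_panel)), te_panel$id)
  if (nrow(alignments)) {
    s <- tapply(alignments$weight, alignments$te_id, sum)
    w[names(s)] <- s
  }
  coverage <- lapply(setNames(seq_len(nrow(te_panel)), te_panel$id),
                     function(j) {
    cov <- numeric(te_panel$length[j])
    aln <- alignments[alignments$te_id == te_panel$id[j], , drop = FALSE]
    for (i in seq_len(nrow(aln))) {
      span <- (aln$start[i] + 1L):(aln$start[i] + aln$read_length[i])
      cov[span] <- cov[span] + aln$weight[i]
    }
    cov
  })
  structure(data.frame(te_id = te_panel$id, weight = as.numeric(w),
                       dna_rpm = as.numeric(w) / depth * 1e6,
                       length = te_panel$length, stringsAsFactors = FALSE),
            coverage = coverage, depth = depth)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration of all `choose(n+m, n)` group assignments when
#' `n + m <= max_exact` (ties included); otherwise the normal approximation
#' with continuity and tie correction. Two-sided exact p doubles the
#' smaller tail (capped at 1).
#'
#' @param x,y numeric samples
#' @param max_exact size threshold for exact enumeration (default 20)
#' @return list `statistic` (Mann-Whitney U for `x`), `p_value`, `method`
#' @export
wilcoxon_ranksum <- function(x, y, max_exact = 20L) {
  n <- length(x); m <- length(y)
  if (!n || !m) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1])
    return(list(statistic = U, p_value = 1, method = "degenerate"))
  if (n + m <= max_exact) {
    combos <- combn(n + m, n)
    u_all <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    lo <- mean(u_all <= U)
    hi <- mean(u_all >= U)
    p <- min(1, 2 * min(lo, hi))
    list(statistic = U, p_value = p, method = "exact")
  } else {
    N <- n + m
    ties <- table(r)
    mu <- n * m / 2
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0)
      return(list(statistic = U, p_value = 1, method = "normal-approx"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    list(statistic = U, p_value = min(1, 2 * pnorm(-abs(z))),
         method = "normal-approx")
  }
}

#' Compare TE genomic occupancy between two strains
#'
#' Per-position coverage over the same canonical sequence is
#' depth-normalized to RPM and compared with a two-sided Wilcoxon rank-sum
#' test. Optional binning (`bin` positions per window, mean coverage per
#' window) reduces positional autocorrelation.
#'
#' @param coverage_a,coverage_b equal-length per-position depth vectors
#' @param depth_a,depth_b library depths used for RPM normalization
#'   (default 1e6 each, i.e. coverage already normalized)
#' @param bin optional window size in positions (e.g. 500)
#' @return list `te_length`, `statistic`, `p_value`, `method`, `binned`
#' @export
compare_occupancy <- function(coverage_a, coverage_b,
                              depth_a = 1e6, depth_b = 1e6, bin = NULL) {
  if (length(coverage_a) != length(coverage_b))
    stop("coverage vectors must have equal length (same canonical TE)")
  a <- coverage_a / depth_a * 1e6
  b <- coverage_b / depth_b * 1e6
  if (!is.null(bin)) {
    g <- (seq_along(a) - 1L) %/% bin
    a <- tapply(a, g, mean)
    b <- tapply(b, g, mean)
  }
  wt <- wilcoxon_ranksum(as.numeric(a), as.numeric(b))
  list(te_length = length(coverage_a), statistic = wt$statistic,
       p_value = wt$p_value, method = wt$method, binned = !is.null(bin))
}
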