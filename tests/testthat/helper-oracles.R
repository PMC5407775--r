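# Independent oracles used across tests. These deliberately use the dumbest
# possible algorithms (full scans, exhaustive enumeration) so they stay
# independent of the implementation paths they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc <- function(x) chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
  paste(rev(s), collapse = ""), character(1)))

# all-positions Hamming scan of one query against named subjects,
# both strands; returns all placements with mm <= max_mm
naive_scan <- function(query, subjects, max_mm) {
  out <- list()
  for (ori in c("+", "-")) {
    q <- if (ori == "+") query else rc(query)
    qs <- strsplit(q, "")[[1]]
    for (sj in seq_along(subjects)) {
      s <- strsplit(subjects[[sj]], "")[[1]]
      L <- length(qs)
      if (length(s) < L) next
      for (st in 0:(length(s) - L)) {
        mm <- sum(qs != s[(st + 1):(st + L)])
        if (mm <= max_mm)
          out[[length(out) + 1L]] <- data.frame(
            subject = sj, start = st, strand = ori, mismatches = mm)
      }
    }
  }
  if (!length(out)) return(data.frame(subject = integer(0), start = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0)))
  do.call(rbind, out)
}

# brute-force 5'-overlap pair counts: double loop over all read pairs
naive_overlap_counts <- function(aln, offsets = 1:30,
                                 length_range = c(24L, 29L)) {
  aln <- aln[aln$read_length >= length_range[1] &
             aln$read_length <= length_range[2], , drop = FALSE]
  five <- ifelse(aln$strand == "+", aln$start,
                 aln$start + aln$read_length - 1L)
  w <- if ("weight" %in% names(aln)) aln$weight else rep(1, nrow(aln))
  counts <- setNames(numeric(length(offsets)), offsets)
  si <- which(aln$strand == "+")
  ai <- which(aln$strand == "-")
  for (i in si) for (j in ai) {
    o <- five[j] - five[i] + 1L
    k <- match(o, offsets)
    if (!is.na(k)) counts[k] <- counts[k] + w[i] * w[j]
  }
  as.numeric(counts)
}

# exhaustive permutation distribution of Spearman rho
naive_spearman_p <- function(x, y) {
  n <- length(x)
  perm_all <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm_all(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  rhos <- vapply(perm_all(seq_len(n)), function(p) cor(rx, ry[p]),
                 numeric(1))
  mean(abs(rhos) >= abs(rho) - 1e-12)
}

# exhaustive two-sided Wilcoxon rank-sum p via all C(n+m, n) assignments
naive_wilcoxon_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(n + m, n)
  u_all <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
  min(1, 2 * min(mean(u_all <= U), mean(u_all >= U)))
}

# random alignment table in canonical TE coordinates
random_alignments <- function(n, te_len = 300L, te_id = "TEx",
                              weights = FALSE) {
  len <- sample(24:29, n, TRUE)
  start <- sample.int(te_len - 30L, n, TRUE) - 1L
  data.frame(read_id = paste0("r", seq_len(n)), te_id = te_id,
             start = start, strand = sample(c("+", "-"), n, TRUE),
             mismatches = 0L, read_length = len,
             weight = if (weights) runif(n, 0.25, 1) else rep(1, n),
             stringsAsFactors = FALSE)
}

tiny_panel <- function(seed = 42L, n = 3L, len = 400L) {
  withr::with_seed(seed, data.frame(
    id = paste0("TE", seq_len(n)), length = len,
    class = "germline", active = FALSE,
    sequence = vapply(rep(len, n), rand_dna, character(1)),
    stringsAsFactors = FALSE))
}
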