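#' 5'-overlap profile of sense/antisense piRNA pairs on one TE
#'
#' For each offset `o` in `offsets`, the profile counts weighted pairs of a
#' sense read with 5' end at reference position `p` and an antisense read
#' whose biological 5' end (the rightmost reference base of its span) sits
#' at `p + o - 1`. Offset 10 is the ping-pong signature. Pair weight is the
#' product of the two read weights; `species_mode = TRUE` collapses
#' duplicate 5'-position species to weight 1 first.
#'
#' @param alignments TE alignments ([map_to_canonical()] output) for one TE;
#'   if several TEs are present, supply `te` or get a list back
#' @param te optional TE id to subset on
#' @param length_range read lengths considered (default 24--29)
#' @param offsets overlap offsets scored (default 1:30)
#' @param species_mode collapse duplicate read species (default FALSE)
#' @return an `overlap_profile`: list with `te_id`, `offsets`, `counts`,
#'   `z` (NA until sd > 0), `z10`
#' @export
overlap_profile <- function(alignments, te = NULL,
                            length_range = c(24L, 29L), offsets = 1:30,
                            species_mode = FALSE) {
  aln <- alignments
  if (!is.null(te)) aln <- aln[aln$te_id == te, , drop = FALSE]
  if (length(unique(aln$te_id)) > 1L) {
    tes <- sort(unique(aln$te_id))
    return(lapply(setNames(tes, tes), function(t)
      overlap_profile(aln, te = t, length_range = length_range,
                      offsets = offsets, species_mode = species_mode)))
  }
  aln <- aln[aln$read_length >= length_range[1] &
             aln$read_length <= length_range[2], , drop = FALSE]
  five <- ifelse(aln$strand == "+", aln$start,
                 aln$start + aln$read_length - 1L)
  w <- aln$weight %||% rep(1, nrow(aln))
  if (species_mode) {
    key <- paste(aln$strand, five)
    first <- !duplicated(key)
    aln <- aln[first, , drop = FALSE]
    five <- five[first]
    w <- rep(1, nrow(aln))
  }
  sense <- aln$strand == "+"
  # S(p), A(q): summed weights of 5' ends per reference position
  S <- tapply(w[sense], five[sense], sum)
  A <- tapply(w[!sense], five[!sense], sum)
  counts <- setNames(numeric(length(offsets)), offsets)
  if (length(S) && length(A)) {
    pS <- as.integer(names(S))
    pA <- as.integer(names(A))
    for (k in seq_along(offsets)) {
      idx <- match(pS + offsets[k] - 1L, pA)
      hit <- !is.na(idx)
      counts[k] <- sum(S[hit] * A[idx[hit]])
    }
  }
  prof <- structure(list(te_id = if (nrow(aln)) aln$te_id[1] else NA_character_,
                         offsets = offsets, counts = as.numeric(counts),
                         z = rep(NA_real_, length(offsets)),
                         z10 = NA_real_),
                    class = "overlap_profile")
  znormalize(prof)
}

#' z-normalize an overlap profile
#'
#' Standardizes the per-offset counts to mean 0, sample (n-1) SD 1, and
#' extracts the offset-10 z-score (the ping-pong signature). When the SD is
#' zero (e.g. a constant or empty profile) the z-scores are reported
#' missing.
#'
#' @param profile an `overlap_profile` (or bare numeric vector of counts)
#' @return the profile with `z` and `z10` populated
#' @export
znormalize <- function(profile) {
  if (is.numeric(profile))
    profile <- structure(list(te_id = NA_character_,
                              offsets = seq_along(profile),
                              counts = as.numeric(profile),
                              z = rep(NA_real_, length(profile)),
                              z10 = NA_real_),
                         class = "overlap_profile")
  x <- profile$counts
  if (length(x) >= 2L && is.finite(sd(x)) && sd(x) > 0) {
    profile$z <- (x - mean(x)) / sd(x)
    i10 <- match(10L, profile$offsets)
    profile$z10 <- if (is.na(i10)) NA_real_ else profile$z[i10]
  } else {
    profile$z <- rep(NA_real_, length(x))
    profile$z10 <- NA_real_
  }
  profile
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat(sprintf("<overlap_profile> te=%s pairs=%.1f z10=%s\n",
              x$te_id, sum(x$counts),
              ifelse(is.na(x$z10), "NA", sprintf("%.2f", x$z10))))
  invisible(x)
}

#' Spearman correlation of two z-normalized ping-pong profiles
#'
#' @param zA,zB numeric z-profiles on the same offsets, or
#'   `overlap_profile` objects
#' @return list with `rho` (average-rank Spearman), `n` offsets used;
#'   `rho` is `NA` when fewer than 3 finite shared offsets remain
#' @export
profile_correlation <- function(zA, zB) {
  if (inherits(zA, "overlap_profile")) zA <- zA$z
  if (inherits(zB, "overlap_profile")) zB <- zB$z
  stopifnot(length(zA) == length(zB))
  ok <- is.finite(zA) & is.finite(zB)
  n <- sum(ok)
  if (n < 3L) return(list(rho = NA_real_, n = n))
  list(rho = cor(rank(zA[ok]), rank(zB[ok])), n = n)
}
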