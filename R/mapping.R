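#' Map small-RNA (or DNA-seq) reads onto canonical TE sequences
#'
#' All best-stratum placements (minimal mismatch count up to
#' `max_mismatches`) are reported on both strands of every TE. A read whose
#' best stratum hits `k` distinct TE families receives weight `1/k` per
#' family; within one family the read contributes weight once, split evenly
#' across its equally-good positions, so the summed weight of a mapped read
#' is always 1 (`multimap = "fractional"`, the default). With
#' `multimap = "all"` each family receives the full weight 1.
#'
#' @param reads a [smallrna_library()], a data.frame with `id`/`sequence`,
#'   or a character vector of sequences
#' @param te_panel data.frame with `id` and `sequence` columns (one row per
#'   canonical TE)
#' @param max_mismatches maximum Hamming mismatches, 0--3 (default 3)
#' @param multimap `"fractional"` or `"all"` (see Details)
#' @return data.frame of alignments: `read_id`, `te_id`, `start` (0-based),
#'   `strand`, `mismatches`, `read_length`, `weight`; the library depth is
#'   carried in the `depth` attribute
#' @export
map_to_canonical <- function(reads, te_panel, max_mismatches = 3L,
                             multimap = c("fractional", "all")) {
  multimap <- match.arg(multimap)
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0L || max_mismatches > 3L)
    stop("max_mismatches must be between 0 and 3")
  if (!nrow(te_panel)) stop("te_panel is empty")
  reads <- as_read_table(reads)
  depth <- library_depth(reads)

  empty <- data.frame(read_id = character(0), te_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), read_length = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(reads)) return(structure(empty, depth = depth))

  uniq <- unique(reads$sequence)
  hits <- .cpp_hamming_map(uniq, te_panel$sequence, max_mismatches, 6L)
  if (!nrow(hits)) return(structure(empty, depth = depth))

  ht <- data.table::as.data.table(hits)
  # best stratum per unique sequence, then fractional family weights
  ht[, best := min(mismatches), by = query]
  ht <- ht[ht$mismatches == ht$best]
  ht[, npos := .N, by = c("query", "subject")]
  ht[, nfam := data.table::uniqueN(subject), by = query]
  ht[, weight := if (multimap == "fractional") 1 / (nfam * npos)
                 else 1 / npos]
  rd <- data.table::data.table(query = match(reads$sequence, uniq),
                               read_id = reads$id,
                               read_length = nchar(reads$sequence))
  m <- ht[rd, on = "query", allow.cartesian = TRUE, nomatch = NULL]
  out <- data.frame(
    read_id = m$read_id,
    te_id = te_panel$id[m$subject],
    start = m$start,
    strand = ifelse(m$minus, "-", "+"),
    mismatches = m$mismatches,
    read_length = m$read_length,
    weight = m$weight,
    stringsAsFactors = FALSE)
  structure(out, depth = depth)
}

#' @noRd
as_read_table <- function(reads) {
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("read", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  reads
}

#' Map reads to the genome with exact matching
#'
#' Finds all exact (0-mismatch by default) placements on both strands of
#' every chromosome and records the genomic multiplicity of each read
#' (number of equally-best loci). Output is deterministically ordered by
#' (chrom, start, strand).
#'
#' @param reads reads as in [map_to_canonical()]
#' @param genome named character vector of chromosome sequences
#' @param max_mismatches default 0 (the genome-mapping rule)
#' @return data.frame: `read_id`, `chrom`, `start` (0-based), `strand`,
#'   `multiplicity`, `read_length`; `depth` attribute carried over
#' @export
map_to_genome <- function(reads, genome, max_mismatches = 0L) {
  reads <- as_read_table(reads)
  depth <- library_depth(reads)
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), strand = character(0),
                      multiplicity = integer(0), read_length = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(reads)) return(structure(empty, depth = depth))
  uniq <- unique(reads$sequence)
  hits <- .cpp_hamming_map(uniq, unname(genome), as.integer(max_mismatches), 6L)
  if (!nrow(hits)) return(structure(empty, depth = depth))
  ht <- data.table::as.data.table(hits)
  ht[, multiplicity := .N, by = query]
  rd <- data.table::data.table(query = match(reads$sequence, uniq),
                               read_id = reads$id,
                               read_length = nchar(reads$sequence))
  m <- ht[rd, on = "query", allow.cartesian = TRUE, nomatch = NULL]
  out <- data.frame(
    read_id = m$read_id,
    chrom = names(genome)[m$subject],
    start = m$start,
    strand = ifelse(m$minus, "-", "+"),
    multiplicity = m$multiplicity,
    read_length = m$read_length,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand, out$read_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, depth = depth)
}

#' Keep only single-mapped genome alignments
#'
#' @param alignments output of [map_to_genome()] (must carry `multiplicity`)
#' @return the multiplicity-1 subset
#' @export
select_single_mappers <- function(alignments) {
  stopifnot("multiplicity" %in% names(alignments))
  structure(alignments[alignments$multiplicity == 1L, , drop = FALSE],
            depth = attr(alignments, "depth"))
}

#' Assign single-mapped reads to piRNA clusters (or TE fragments)
#'
#' A read is assigned to a region when its alignment interval overlaps the
#' region by at least `min_overlap_frac` of the read length (default 50%).
#' Counts are reported per region, strand and size class (21 nt siRNA-like;
#' 24--29 nt piRNA-sized; other). With `restrict_to_fragments = TRUE` the
#' targets are the annotated TE fragments nested in the clusters.
#'
#' @param single_mappers output of [select_single_mappers()]
#' @param clusters data.frame with `id`, `chrom`, `start`, `end` (0-based
#'   half-open), `type`
#' @param restrict_to_fragments count against TE fragments instead of whole
#'   clusters
#' @param fragments data.frame of fragments (`cluster_id`, `te_id`, `chrom`,
#'   `start`, `end`); required when `restrict_to_fragments = TRUE`
#' @param min_overlap_frac minimum overlap as a fraction of read length
#' @return data.frame of counts: `region_id`, `cluster_id`, `te_id` (NA for
#'   whole clusters), `strand`, `size_class`, `count`; per-read assignments
#'   in the `assignments` attribute
#' @export
assign_to_clusters <- function(single_mappers, clusters,
                               restrict_to_fragments = FALSE,
                               fragments = NULL, min_overlap_frac = 0.5) {
  if (restrict_to_fragments) {
    if (is.null(fragments)) stop("fragments required when restricting")
    targets <- data.frame(
      region_id = sprintf("%s:%s:%d", fragments$cluster_id, fragments$te_id,
                          seq_len(nrow(fragments))),
      cluster_id = fragments$cluster_id, te_id = fragments$te_id,
      chrom = fragments$chrom, start = fragments$start, end = fragments$end,
      stringsAsFactors = FALSE)
  } else {
    targets <- data.frame(region_id = clusters$id, cluster_id = clusters$id,
                          te_id = rep(NA_character_, nrow(clusters)),
                          chrom = clusters$chrom,
                          start = clusters$start, end = clusters$end,
                          stringsAsFactors = FALSE)
  }
  aln <- single_mappers
  empty <- data.frame(region_id = character(0), cluster_id = character(0),
                      te_id = character(0), strand = character(0),
                      size_class = character(0), count = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(aln) || !nrow(targets))
    return(structure(empty, assignments = empty))

  gr_reads <- GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start + 1L, aln$start + aln$read_length))
  gr_targets <- GenomicRanges::GRanges(
    targets$chrom, IRanges::IRanges(targets$start + 1L, targets$end))
  ov <- GenomicRanges::findOverlaps(gr_reads, gr_targets)
  if (!length(ov)) return(structure(empty, assignments = empty))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  ow <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_reads)[qh], IRanges::ranges(gr_targets)[sh]))
  keep <- ow >= min_overlap_frac * aln$read_length[qh]
  qh <- qh[keep]; sh <- sh[keep]
  if (anyDuplicated(qh))
    message(sum(duplicated(qh)),
            " read(s) overlap multiple regions; counted in each")
  size_class <- ifelse(aln$read_length[qh] == 21L, "21",
                ifelse(aln$read_length[qh] >= 24L &
                       aln$read_length[qh] <= 29L, "24_29", "other"))
  asg <- data.frame(read_id = aln$read_id[qh],
                    region_id = targets$region_id[sh],
                    cluster_id = targets$cluster_id[sh],
                    te_id = ifelse(is.na(targets$te_id[sh]), ".",
                                   targets$te_id[sh]),
                    strand = aln$strand[qh],
                    size_class = size_class,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1, nrow(asg))),
                          asg[c("region_id", "cluster_id", "te_id",
                                "strand", "size_class")],
                          FUN = sum, drop = TRUE)
  structure(agg, assignments = asg, depth = attr(single_mappers, "depth"))
}
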