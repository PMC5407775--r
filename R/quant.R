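#' Per-length, per-strand size distribution of aligned reads
#'
#' @param alignments alignments with `read_length` and `strand`
#' @param length_range inclusive range tallied (default 18--30)
#' @return data.frame `length`, `strand`, `count`, `fraction` (fractions
#'   sum to 1 per strand over the range, NA when a strand is empty)
#' @export
size_distribution <- function(alignments, length_range = c(18L, 30L)) {
  lens <- seq(length_range[1], length_range[2])
  out <- expand.grid(length = lens, strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(l, s)
    sum(alignments$read_length == l & alignments$strand == s),
    out$length, out$strand)
  for (s in c("+", "-")) {
    tot <- sum(out$count[out$strand == s])
    out$fraction[out$strand == s] <-
      if (tot > 0) out$count[out$strand == s] / tot else NA_real_
  }
  out
}

#' 1U bias of piRNA-sized reads
#'
#' Per strand, the fraction of reads in `min_len`--`max_len` whose first
#' sequenced base (in read orientation) is U (stored as T). Requires read
#' sequences, joined to the alignments by `read_id`.
#'
#' @param alignments TE or genome alignments with `read_id`, `strand`,
#'   `read_length`
#' @param reads read table with `id`, `sequence`
#' @param min_len,max_len size window (default 24--29)
#' @return data.frame `strand`, `n_reads`, `fraction_1U` (NA when a strand
#'   has no in-range reads)
#' @export
u1_bias <- function(alignments, reads, min_len = 24L, max_len = 29L) {
  aln <- alignments[alignments$read_length >= min_len &
                    alignments$read_length <= max_len, , drop = FALSE]
  # one vote per read and strand
  aln <- aln[!duplicated(paste(aln$read_id, aln$strand)), , drop = FALSE]
  first <- substr(reads$sequence[match(aln$read_id, reads$id)], 1L, 1L)
  out <- data.frame(strand = c("+", "-"), n_reads = NA_integer_,
                    fraction_1U = NA_real_, stringsAsFactors = FALSE)
  for (i in 1:2) {
    sel <- aln$strand == out$strand[i] & !is.na(first)
    out$n_reads[i] <- sum(sel)
    out$fraction_1U[i] <- if (sum(sel) > 0)
      mean(first[sel] == "T") else NA_real_
  }
  out
}

#' RPM / RPKM / TPM normalization of feature counts
#'
#' `rpm = count / depth * 1e6`; `rpkm = rpm / (length/1000)`;
#' `tpm = (count/length_kb) / sum(count/length_kb) * 1e6`.
#'
#' @param counts named numeric vector (feature -> weighted count)
#' @param depth library depth (> 0)
#' @param lengths named numeric vector of feature lengths in nt
#' @return data.frame `feature`, `count`, `length`, `rpm`, `rpkm`, `tpm`
#' @export
normalize_counts <- function(counts, depth, lengths) {
  if (is.null(depth) || !is.finite(depth) || depth <= 0)
    stop("depth must be > 0")
  feats <- names(counts)
  if (is.null(feats)) stop("counts must be named by feature")
  len <- lengths[feats]
  if (anyNA(len)) stop("missing lengths for: ",
                       paste(feats[is.na(len)], collapse = ", "))
  rpm <- counts / depth * 1e6
  rpkm <- rpm / (len / 1000)
  rate <- counts / (len / 1000)
  tpm <- if (sum(rate) > 0) rate / sum(rate) * 1e6 else rate * 0
  data.frame(feature = feats, count = as.numeric(counts),
             length = as.numeric(len), rpm = as.numeric(rpm),
             rpkm = as.numeric(rpkm), tpm = as.numeric(tpm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-TE expression from canonical alignments
#'
#' Sums fractional alignment weights per TE family (within the given size
#' window) and normalizes by library depth.
#'
#' @param alignments [map_to_canonical()] output (carries `depth`)
#' @param te_panel panel with `id` and `length`
#' @param depth library depth; defaults to the alignments' `depth` attribute
#' @param length_range size window, default 24--29 nt; `NULL` keeps all
#' @return [normalize_counts()] data.frame over all panel TEs
#' @export
te_expression <- function(alignments, te_panel, depth = NULL,
                          length_range = c(24L, 29L)) {
  depth <- depth %||% attr(alignments, "depth")
  aln <- alignments
  if (!is.null(length_range))
    aln <- aln[aln$read_length >= length_range[1] &
               aln$read_length <= length_range[2], , drop = FALSE]
  counts <- setNames(numeric(nrow(te_panel)), te_panel$id)
  if (nrow(aln)) {
    s <- tapply(aln$weight, aln$te_id, sum)
    counts[names(s)] <- s
  }
  normalize_counts(counts, depth, setNames(te_panel$length, te_panel$id))
}

#' Copy-number normalization of piRNA expression
#'
#' Default (`log-ratio`) dialect:
#' `value = log2(pirna_rpm + pc) - log2(dna_rpm + pc)`. The literal
#' `divide-by-log2` dialect computes
#' `log2(pirna_rpm + pc) / log2(dna_rpm + pc)`. Features with zero DNA RPM
#' are flagged (`dna_zero`), not dropped.
#'
#' @param pirna data.frame with `feature` and `rpm` (piRNA expression)
#' @param dna data.frame with `te_id`/`feature` and `dna_rpm`/`rpm`
#' @param pseudocount pseudocount in RPM units (default 1)
#' @param dialect `"log-ratio"` (default) or `"divide-by-log2"`
#' @return data.frame `feature`, `log2_pirna_rpm`, `log2_dna_rpm`, `value`,
#'   `dna_zero`, with `dialect` and `pseudocount` attributes
#' @export
copy_number_normalize <- function(pirna, dna, pseudocount = 1,
                                  dialect = c("log-ratio", "divide-by-log2")) {
  dialect <- match.arg(dialect)
  pfeat <- pirna$feature %||% pirna$te_id
  dfeat <- dna$feature %||% dna$te_id
  prpm <- pirna$rpm
  drpm <- dna$dna_rpm %||% dna$rpm
  if (any(prpm < 0, na.rm = TRUE) || any(drpm < 0, na.rm = TRUE))
    stop("RPM values must be non-negative")
  idx <- match(pfeat, dfeat)
  if (anyNA(idx)) stop("DNA abundance missing for: ",
                       paste(pfeat[is.na(idx)], collapse = ", "))
  drpm <- drpm[idx]
  lp <- log2(prpm + pseudocount)
  ld <- log2(drpm + pseudocount)
  value <- if (dialect == "log-ratio") lp - ld else lp / ld
  structure(data.frame(feature = pfeat, log2_pirna_rpm = lp,
                       log2_dna_rpm = ld, value = value,
                       dna_zero = drpm == 0, stringsAsFactors = FALSE),
            dialect = dialect, pseudocount = pseudocount)
}

#' Genic 3'UTR piRNA-cluster RPKM matrix relative to a reference strain
#'
#' For each strain library, 24--29 nt single-mapped genome alignments are
#' assigned to the genic clusters and converted to RPKM; the returned
#' matrix holds `log2(RPKM_strain / RPKM_reference)` with rows (clusters)
#' sorted by decreasing value in `sort_strain`. Strains are additionally
#' clustered by average-linkage on Euclidean distances of the log2 ratios
#' (columns ordered by label first, so ties break deterministically).
#'
#' @param libraries named list of [smallrna_library()] objects
#' @param genome named character vector of chromosomes
#' @param genic_clusters cluster table (rows with `type == "genic_3utr"`
#'   are used if a `type` column is present)
#' @param reference_strain name (in `names(libraries)`) of the reference
#' @param sort_strain strain whose column orders the rows (default: first
#'   non-reference library)
#' @return list: `matrix` (clusters x strains, reference column dropped),
#'   `rpkm` (raw RPKM matrix), `hclust` (strain dendrogram or NULL),
#'   `row_order`
#' @export
genic_cluster_matrix <- function(libraries, genome, genic_clusters,
                                 reference_strain, sort_strain = NULL) {
  if (!reference_strain %in% names(libraries))
    stop("reference strain '", reference_strain, "' not among libraries")
  if ("type" %in% names(genic_clusters))
    genic_clusters <- genic_clusters[genic_clusters$type == "genic_3utr", ,
                                     drop = FALSE]
  if (!nrow(genic_clusters)) stop("no genic clusters supplied")
  rpkm <- sapply(names(libraries), function(nm) {
    lib <- libraries[[nm]]
    gal <- map_to_genome(lib, genome)
    sm <- select_single_mappers(gal)
    cc <- assign_to_clusters(sm, genic_clusters)
    cc <- cc[cc$size_class == "24_29", , drop = FALSE]
    cnt <- setNames(numeric(nrow(genic_clusters)), genic_clusters$id)
    if (nrow(cc)) {
      s <- tapply(cc$count, cc$cluster_id, sum)
      cnt[names(s)] <- s
    }
    lens <- (genic_clusters$end - genic_clusters$start) / 1000
    cnt / lens / library_depth(lib) * 1e6
  })
  rownames(rpkm) <- genic_clusters$id
  ref <- rpkm[, reference_strain]
  others <- setdiff(colnames(rpkm), reference_strain)
  ratio <- log2(sweep(rpkm[, others, drop = FALSE], 1, ref, "/"))
  ratio[, ] <- ifelse(is.finite(as.matrix(ratio)), as.matrix(ratio), NA)
  sort_strain <- sort_strain %||% others[1]
  row_order <- order(ratio[, sort_strain], decreasing = TRUE, rownames(ratio))
  ratio <- ratio[row_order, , drop = FALSE]
  hc <- NULL
  if (ncol(ratio) >= 2L && !anyNA(ratio)) {
    m <- t(ratio[, sort(colnames(ratio)), drop = FALSE])
    hc <- hclust(dist(m, method = "euclidean"), method = "average")
  }
  list(matrix = ratio, rpkm = rpkm, hclust = hc,
       row_order = rownames(ratio))
}
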