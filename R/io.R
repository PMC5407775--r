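#' Small-RNA library container
#'
#' A plain `data.frame` of reads (columns `id`, `sequence`, `length`, plus
#' optional provenance columns) with `strain`, `tissue` and `depth`
#' attributes. `depth` is the normalization denominator; by default it is
#' the number of reads surviving clipping and filtering (a genome-mapped
#' denominator can be supplied instead; see the methods vignette).
#'
#' @param reads data.frame with at least `id` and `sequence` columns
#' @param strain strain name
#' @param tissue `"ovary"` or `"embryo_0_2h"`
#' @param depth normalization denominator; defaults to `nrow(reads)`
#' @return a `smallrna_library` (data.frame subclass)
#' @export
smallrna_library <- function(reads, strain = "unknown",
                             tissue = c("ovary", "embryo_0_2h"),
                             depth = NULL) {
  tissue <- match.arg(tissue)
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  reads$sequence <- chartr("U", "T", toupper(reads$sequence))
  bad <- grepl("[^ACGTN]", reads$sequence)
  if (any(bad)) stop("sequences contain characters outside {A,C,G,T,N,U}")
  reads$length <- nchar(reads$sequence)
  depth <- depth %||% nrow(reads)
  if (depth < 0) stop("depth must be non-negative")
  structure(reads, class = c("smallrna_library", "data.frame"),
            strain = strain, tissue = tissue, depth = depth)
}

#' @export
print.smallrna_library <- function(x, ...) {
  cat(sprintf("<smallrna_library> strain=%s tissue=%s reads=%d depth=%d\n",
              attr(x, "strain"), attr(x, "tissue"), nrow(x),
              as.integer(attr(x, "depth"))))
  invisible(x)
}

#' Library depth (normalization denominator)
#' @param x a `smallrna_library` or data.frame of reads
#' @return integer depth
#' @export
library_depth <- function(x) {
  d <- attr(x, "depth")
  if (is.null(d)) nrow(x) else d
}

#' Clip the 3' sequencing adapter from small-RNA reads
#'
#' Removes, for each read, everything from the 3'-most exact match of an
#' adapter prefix of length at least `min_overlap` to the read end. Reads
#' in which no adapter prefix is detected are discarded (conservative:
#' their insert boundary is unknown).
#'
#' @param reads data.frame with `id` and `sequence` columns
#' @param adapter adapter sequence (non-empty)
#' @param min_overlap minimum adapter prefix length to accept (default 6)
#' @return the clipped reads; attributes `n_clipped` and `n_discarded`
#'   carry the clip statistics
#' @export
clip_adapter <- function(reads, adapter, min_overlap = 6L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L || nchar(adapter) < min_overlap)
    stop("need adapter length >= min_overlap >= 1")
  seqs <- reads$sequence
  alen <- nchar(adapter)
  clip_at <- rep(NA_integer_, length(seqs))
  lens <- nchar(seqs)
  # scan candidate start positions from the 3' end; first match wins
  for (p in seq(max(lens) - min_overlap + 1L, 1L)) {
    todo <- which(is.na(clip_at) & lens - p + 1L >= min_overlap)
    if (!length(todo)) next
    w <- pmin(lens[todo] - p + 1L, alen)
    hit <- substr(seqs[todo], p, p + w - 1L) == substring(adapter, 1L, w)
    clip_at[todo[hit]] <- p
  }
  keep <- !is.na(clip_at)
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substr(out$sequence, 1L, clip_at[keep] - 1L)
  out$length <- nchar(out$sequence)
  structure(out, n_clipped = sum(keep), n_discarded = sum(!keep))
}

#' Length/quality filter for small-RNA reads
#'
#' Retains reads of length at least `min_len` (default 19, i.e. the
#' strict ">18 nt" rule) whose sequences contain no disallowed characters
#' (any `N` discards the read when `max_n_fraction = 0`).
#'
#' @param reads data.frame with `sequence` column
#' @param min_len minimum retained length (default 19)
#' @param max_n_fraction maximum tolerated fraction of N bases (default 0)
#' @return filtered reads
#' @export
filter_reads <- function(reads, min_len = 19L, max_n_fraction = 0) {
  stopifnot(min_len >= 1L)
  lens <- nchar(reads$sequence)
  n_count <- lens - nchar(gsub("N", "", reads$sequence, fixed = TRUE))
  keep <- lens >= min_len & (n_count <= max_n_fraction * lens)
  out <- reads[keep, , drop = FALSE]
  out$length <- nchar(out$sequence)
  if (!nrow(out)) warning("no reads survived filtering")
  out
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (uncompressed or gzipped)
#' @return data.frame with `id`, `sequence`, `length`
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e) stop("malformed FASTQ '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  data.frame(id = names(x) %||% paste0("read", seq_along(x)),
             sequence = as.character(x),
             length = Biostrings::width(x),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (fixed quality 'I')
#'
#' @param reads data.frame with `id` and `sequence`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param seqs named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED file (0-based half-open intervals, BED6)
#'
#' @param path BED file with at least 3 columns
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive),
#'   `name`, `score`, `strand`
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) stop("malformed BED '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 3L) stop("BED needs at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$name <- if (ncol(df) >= 4L) df[[4L]] else "."
  df$score <- if (ncol(df) >= 5L) df[[5L]] else 0
  df$strand <- if (ncol(df) >= 6L) df[[6L]] else "*"
  bad <- which(df$start >= df$end)
  if (length(bad)) stop("BED line ", bad[1], ": start >= end")
  df[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Write intervals as BED6
#' @param df data.frame with chrom/start/end/name/score/strand
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$chrom, df$start, df$end,
                    df$name %||% ".", df$score %||% 0, df$strand %||% "*")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GFF3 file with conversion to BED interval semantics
#'
#' GFF3 1-based closed intervals are converted to the package's 0-based
#' half-open convention on load.
#'
#' @param path GFF3 file
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive),
#'   `name` (the feature type), `score`, `strand`, `attributes`
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 9L) stop("GFF3 needs 9 columns: ", path)
  bad <- which(df[[4]] > df[[5]])
  if (length(bad)) stop("GFF3 line ", bad[1], ": start > end")
  data.frame(chrom = df[[1]], start = df[[4]] - 1L, end = df[[5]],
             name = df[[3]], score = df[[6]], strand = df[[7]],
             attributes = df[[9]], stringsAsFactors = FALSE)
}

#' Write a per-position coverage vector as bedGraph
#'
#' Consecutive equal-coverage positions are collapsed into intervals
#' (0-based half-open, as bedGraph requires).
#'
#' @param coverage numeric vector of per-position depth
#' @param chrom sequence name the track refers to
#' @param path output path
#' @param track_name optional bedGraph track line name
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(coverage, chrom, path, track_name = NULL) {
  r <- rle(as.numeric(coverage))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%g", chrom, starts[keep], ends[keep],
                   r$values[keep])
  if (!is.null(track_name))
    lines <- c(sprintf("track type=bedGraph name=\"%s\"", track_name),
               lines)
  writeLines(lines, path)
  invisible(path)
}

#' Ingest alignments from a SAM file
#'
#' Minimal read-only ingestion so published external alignments can replace
#' the built-in mapper. FLAG bit 16 maps to strand `-`; the 1-based POS is
#' converted to a 0-based start. Unmapped records (bit 4) are dropped.
#'
#' @param path SAM file
#' @param reference_lengths optional named vector used to detect coordinate
#'   overflow beyond the reference
#' @return data.frame with `read_id`, `chrom`, `start` (0-based), `strand`,
#'   `read_length`
#' @export
read_sam <- function(path, reference_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  if (!length(body))
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), strand = character(0),
                      read_length = integer(0)))
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop("malformed SAM record at line ", body[which(nf < 11L)[1]])
  flag <- as.integer(vapply(parts, `[[`, "", 2L))
  pos <- as.integer(vapply(parts, `[[`, "", 4L))
  if (anyNA(flag) || anyNA(pos))
    stop("malformed SAM record at line ",
         body[which(is.na(flag) | is.na(pos))[1]])
  keep <- bitwAnd(flag, 4L) == 0L
  seq_ <- vapply(parts, `[[`, "", 10L)
  out <- data.frame(
    read_id = vapply(parts, `[[`, "", 1L)[keep],
    chrom = vapply(parts, `[[`, "", 3L)[keep],
    start = pos[keep] - 1L,
    strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+"),
    read_length = nchar(seq_)[keep],
    stringsAsFactors = FALSE)
  if (!is.null(reference_lengths)) {
    lim <- reference_lengths[out$chrom]
    over <- which(!is.na(lim) & out$start + out$read_length > lim)
    if (length(over))
      stop("SAM record for read '", out$read_id[over[1]],
           "' extends beyond reference '", out$chrom[over[1]], "'")
  }
  out
}
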