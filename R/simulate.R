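#' Default canonical TE panel for simulations
#'
#' Six TE families: an ancestral, transpositionally inactive family whose
#' remnants sit in dual-strand germline clusters (the I-element analogue),
#' one active germline family subject to ping-pong amplification, two
#' further germline families, one family with intermediate maternal
#' deposition, and one somatic (flamenco-type) family.
#'
#' @return data.frame with `id`, `length`, `class`
#'   (germline/intermediate/somatic), `active`
#' @export
default_te_panel <- function() {
  data.frame(
    id = c("I_like", "jockey_like", "copia_like", "mdg1_like",
           "roo_like", "gypsy_like"),
    length = c(2000L, 2500L, 2200L, 2000L, 2400L, 2600L),
    class = c("germline", "germline", "germline", "intermediate",
              "germline", "somatic"),
    active = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Default piRNA-cluster composition
#'
#' One dual-strand germline cluster carrying a single ancestral-TE fragment
#' (30% of the canonical length) among larger fragments of other germline
#' TEs; one uni-strand germline cluster; one uni-strand somatic cluster
#' containing all somatic-TE fragments; two genic 3'UTR clusters.
#'
#' @return a list understood by [simulate_genome()]
#' @export
default_cluster_spec <- function() {
  list(dual = 1L, uni_germline = 1L, uni_somatic = 1L, genic_3utr = 2L,
       ancestral_te = "I_like", ancestral_frac = 0.3,
       dual_members = c(jockey_like = 2L, copia_like = 2L, roo_like = 2L),
       dual_frag_len = 1000L,
       uni_germline_members = c(mdg1_like = 2L, roo_like = 1L),
       uni_germline_frag_len = 900L,
       uni_somatic_members = c(gypsy_like = 3L),
       uni_somatic_frag_len = 1000L,
       genic_len = 2000L,
       spacer = c(200L, 400L),
       background_len = 30000L)
}

#' Simulate a genome skeleton with TE panel and cluster annotations
#'
#' Builds one synthetic chromosome containing piRNA clusters assembled from
#' exact fragments of canonical TE sequences, genic 3'UTR cluster loci, one
#' full-length genomic copy of every active TE (so that fragment-derived
#' reads can be multi-mappers), and random intergenic background.
#'
#' @param panel_spec a TE panel data.frame as from [default_te_panel()], or
#'   a list with `n_te`, `length_range`, `gc` for a generic panel
#' @param cluster_spec list as from [default_cluster_spec()]; the four
#'   cluster-count entries may be zero
#' @param seed integer seed (required; reproducibility is mandatory)
#' @param gc background GC content (default 0.42)
#' @param outdir optional directory; writes `genome.fa`, `te_panel.fa`,
#'   `clusters.bed`, `fragments.bed`
#' @return a `sim_dataset` list: `genome` (named character), `te_panel`
#'   (with `sequence` column), `clusters`, `fragments`, `cluster_spec`
#' @export
simulate_genome <- function(panel_spec = default_te_panel(),
                            cluster_spec = default_cluster_spec(),
                            seed, gc = 0.42, outdir = NULL) {
  if (missing(seed)) stop("seed is required")
  if (is.list(panel_spec) && !is.data.frame(panel_spec)) {
    n_te <- panel_spec$n_te %||% 5L
    lr <- panel_spec$length_range %||% c(1500L, 3000L)
    gc <- panel_spec$gc %||% gc
    panel_spec <- data.frame(
      id = paste0("TE", seq_len(n_te)),
      length = as.integer(round(seq(lr[1], lr[2], length.out = max(n_te, 1)))),
      class = "germline", active = FALSE, stringsAsFactors = FALSE)
  }
  if (!nrow(panel_spec)) stop("TE panel must not be empty")
  if (any(panel_spec$length < 100L)) stop("TE lengths must be >= 100 nt")
  cs <- utils::modifyList(default_cluster_spec(), cluster_spec)
  counts <- c(cs$dual, cs$uni_germline, cs$uni_somatic, cs$genic_3utr)
  if (any(counts < 0)) stop("cluster counts must be >= 0")

  withr::with_seed(seed, {
    panel <- panel_spec
    panel$sequence <- vapply(panel$length, random_dna, character(1), gc = gc)
    te_seq <- setNames(panel$sequence, panel$id)

    # adapt cluster membership to the panel at hand (generic panels get a
    # generic composition: first TE ancestral, one fragment of each other)
    if (!cs$ancestral_te %in% panel$id) cs$ancestral_te <- panel$id[1]
    others <- setdiff(panel$id, cs$ancestral_te)
    fix_members <- function(m, fallback) {
      m <- m[names(m) %in% panel$id]
      if (!length(m)) fallback else m
    }
    none <- setNames(integer(0), character(0))
    cs$dual_members <- fix_members(cs$dual_members,
      if (length(others)) setNames(rep(1L, length(others)), others) else none)
    cs$uni_germline_members <- fix_members(cs$uni_germline_members,
      if (length(others)) setNames(1L, others[length(others)]) else none)
    cs$uni_somatic_members <- fix_members(cs$uni_somatic_members,
      if (length(others)) setNames(1L, others[1]) else none)

    chrom <- "chr_sim"
    segs <- character(0)     # sequence segments in order
    cursor <- 0L
    clusters <- list()
    fragments <- list()
    spacer <- function() random_dna(sample(cs$spacer[1]:cs$spacer[2], 1L))
    push <- function(s) {
      segs[[length(segs) + 1L]] <<- s
      start <- cursor
      cursor <<- cursor + nchar(s)
      c(start, cursor)
    }

    make_fragment <- function(cluster_id, te_id, frag_len) {
      L <- nchar(te_seq[[te_id]])
      frag_len <- min(frag_len, L)
      te_start <- sample.int(L - frag_len + 1L, 1L) - 1L
      ori <- sample(c("+", "-"), 1L)
      s <- substr(te_seq[[te_id]], te_start + 1L, te_start + frag_len)
      if (ori == "-") s <- revcomp(s)
      span <- push(s)
      fragments[[length(fragments) + 1L]] <<- data.frame(
        cluster_id = cluster_id, te_id = te_id, chrom = chrom,
        start = span[1], end = span[2], strand = ori,
        te_start = te_start, frag_len = frag_len, stringsAsFactors = FALSE)
    }

    make_cluster <- function(id, type, members, frag_len, ancestral = FALSE) {
      push(spacer())
      start <- cursor
      push(spacer())
      if (ancestral && cs$ancestral_te %in% panel$id) {
        alen <- as.integer(round(
          cs$ancestral_frac * nchar(te_seq[[cs$ancestral_te]])))
        make_fragment(id, cs$ancestral_te, alen)
        push(spacer())
      }
      for (te in names(members)) {
        if (!te %in% panel$id) stop("cluster member '", te, "' not in panel")
        for (i in seq_len(members[[te]])) {
          make_fragment(id, te, frag_len)
          push(spacer())
        }
      }
      strand <- if (type == "dual") "*" else sample(c("+", "-"), 1L)
      clusters[[length(clusters) + 1L]] <<- data.frame(
        id = id, chrom = chrom, start = start, end = cursor,
        type = type, strand = strand, stringsAsFactors = FALSE)
    }

    push(random_dna(2000L, gc))
    for (i in seq_len(cs$dual))
      make_cluster(paste0("cluster_dual_", i), "dual", cs$dual_members,
                   cs$dual_frag_len, ancestral = TRUE)
    for (i in seq_len(cs$uni_germline))
      make_cluster(paste0("cluster_uniG_", i), "uni_germline",
                   cs$uni_germline_members, cs$uni_germline_frag_len)
    for (i in seq_len(cs$uni_somatic))
      make_cluster(paste0("cluster_uniS_", i), "uni_somatic",
                   cs$uni_somatic_members, cs$uni_somatic_frag_len)
    for (i in seq_len(cs$genic_3utr)) {
      push(spacer())
      start <- cursor
      push(random_dna(cs$genic_len, gc))
      clusters[[length(clusters) + 1L]] <- data.frame(
        id = paste0("cluster_genic_", i), chrom = chrom,
        start = start, end = cursor, type = "genic_3utr",
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
    # full-length genomic copies of active TEs (multi-mapper realism)
    te_copies <- list()
    for (te in panel$id[panel$active]) {
      push(spacer())
      span <- push(te_seq[[te]])
      te_copies[[length(te_copies) + 1L]] <- data.frame(
        te_id = te, chrom = chrom, start = span[1], end = span[2],
        stringsAsFactors = FALSE)
    }
    if (cursor < cs$background_len)
      push(random_dna(cs$background_len - cursor, gc))

    genome <- setNames(paste(segs, collapse = ""), chrom)
    clusters <- if (length(clusters)) do.call(rbind, clusters) else
      data.frame(id = character(0), chrom = character(0), start = integer(0),
                 end = integer(0), type = character(0), strand = character(0),
                 stringsAsFactors = FALSE)
    fragments <- if (length(fragments)) do.call(rbind, fragments) else
      data.frame(cluster_id = character(0), te_id = character(0),
                 chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), te_start = integer(0),
                 frag_len = integer(0), stringsAsFactors = FALSE)

    te_copies <- if (length(te_copies)) do.call(rbind, te_copies) else
      data.frame(te_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0),
                 stringsAsFactors = FALSE)

    ds <- structure(list(genome = genome, te_panel = panel,
                         clusters = clusters, fragments = fragments,
                         te_copies = te_copies,
                         cluster_spec = cs, seed = seed),
                    class = "sim_dataset")
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(ds$genome, file.path(outdir, "genome.fa"))
      write_fasta(te_seq, file.path(outdir, "te_panel.fa"))
      write_bed(data.frame(chrom = clusters$chrom, start = clusters$start,
                           end = clusters$end,
                           name = paste0(clusters$id, "|", clusters$type),
                           score = 0, strand = clusters$strand),
                file.path(outdir, "clusters.bed"))
      write_bed(data.frame(chrom = fragments$chrom, start = fragments$start,
                           end = fragments$end,
                           name = paste0(fragments$cluster_id, "|",
                                         fragments$te_id),
                           score = 0, strand = fragments$strand),
                file.path(outdir, "fragments.bed"))
    }
    ds
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> genome %d nt, %d TEs, %d clusters, %d fragments\n",
              sum(nchar(x$genome)), nrow(x$te_panel), nrow(x$clusters),
              nrow(x$fragments)))
  invisible(x)
}

# deposition multiplier by TE class (genic/somatic sources barely deposited)
.deposition_factor <- c(germline = 1, intermediate = 0.4, somatic = 0.02)

#' @noRd
.library_sources <- function(dataset, strain, tissue, background_fraction) {
  frags <- dataset$fragments
  clusters <- dataset$clusters
  panel <- dataset$te_panel
  anc <- dataset$cluster_spec$ancestral_te
  src <- list()
  add <- function(...) src[[length(src) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  if (nrow(frags)) {
    ctype <- clusters$type[match(frags$cluster_id, clusters$id)]
    cstrand <- clusters$strand[match(frags$cluster_id, clusters$id)]
    for (i in seq_len(nrow(frags))) {
      w <- frags$frag_len[i] *
        if (frags$te_id[i] == anc) strain$primary_efficiency else 1
      klass <- panel$class[match(frags$te_id[i], panel$id)]
      if (ctype[i] == "dual") {
        add(kind = "fragment", frag = i, te_id = frags$te_id[i],
            strand_te = "+", weight = w / 2, class = klass)
        add(kind = "fragment", frag = i, te_id = frags$te_id[i],
            strand_te = "-", weight = w / 2, class = klass)
      } else {
        st <- if (cstrand[i] == frags$strand[i]) "+" else "-"
        klass2 <- if (ctype[i] == "uni_somatic") "somatic" else klass
        add(kind = "fragment", frag = i, te_id = frags$te_id[i],
            strand_te = st, weight = w, class = klass2)
      }
    }
  }
  genic <- clusters[clusters$type == "genic_3utr", , drop = FALSE]
  for (i in seq_len(nrow(genic)))
    add(kind = "genic", frag = NA_integer_, te_id = genic$id[i],
        strand_te = genic$strand[i],
        weight = genic$end[i] - genic$start[i], class = "somatic")
  src <- if (length(src)) do.call(rbind, src) else
    data.frame(kind = character(0), frag = integer(0), te_id = character(0),
               strand_te = character(0), weight = numeric(0),
               class = character(0), stringsAsFactors = FALSE)
  w_ov <- sum(src$weight)
  bg_ov <- background_fraction / (1 - background_fraction) * max(w_ov, 1)
  if (tissue == "embryo_0_2h") {
    dep <- strain$maternal_transmission *
      .deposition_factor[src$class]
    src$weight <- src$weight * as.numeric(dep)
    bg <- (w_ov + bg_ov) - sum(src$weight)   # background tops up the library
  } else {
    bg <- bg_ov
  }
  rbind(src,
        data.frame(kind = "background_sirna", frag = NA_integer_,
                   te_id = NA_character_, strand_te = "*",
                   weight = bg / 2, class = "background",
                   stringsAsFactors = FALSE),
        data.frame(kind = "background_junk", frag = NA_integer_,
                   te_id = NA_character_, strand_te = "*",
                   weight = bg / 2, class = "background",
                   stringsAsFactors = FALSE))
}

#' @noRd
.background_intervals <- function(dataset) {
  # complement of cluster spans and embedded full-length TE copies, so that
  # background reads are genuinely non-piRNA, non-TE sequence
  len <- nchar(dataset$genome[[1]])
  spans <- dataset$clusters[, c("start", "end"), drop = FALSE]
  if (!is.null(dataset$te_copies) && nrow(dataset$te_copies))
    spans <- rbind(spans, dataset$te_copies[, c("start", "end")])
  if (!nrow(spans)) return(data.frame(start = 0L, end = len))
  ord <- spans[order(spans$start), , drop = FALSE]
  starts <- c(0L, ord$end)
  ends <- c(ord$start, len)
  keep <- ends - starts > 100L
  data.frame(start = starts[keep], end = ends[keep])
}

#' Simulate a strain/tissue small-RNA library
#'
#' Primary piRNA reads are drawn from cluster transcripts with sampling
#' weight proportional to fragment length, boosted by the strain's
#' `primary_efficiency` for ancestral-TE fragments; lengths are uniform on
#' 24--29 nt and the 5' base is uridine with probability `p1U` (enforced by
#' resampling the first base). For active TEs, secondary reads are appended
#' on the opposite strand with 5' ends offset by exactly 10 nt at rate
#' `pingpong_gain` per primary read. Embryo libraries scale every maternal
#' source by `maternal_transmission` times a deposition-class factor, with
#' non-piRNA background topping the library up, so per-TE read fractions in
#' the embryo equal `m` times the ovary fractions. Background reads (10% of
#' an ovary library by default) are drawn from non-cluster genome: half
#' exactly 21 nt (endo-siRNA-like), half 18--23 nt.
#'
#' @param dataset a `sim_dataset` from [simulate_genome()]
#' @param strain a [strain_model()]
#' @param tissue `"ovary"` or `"embryo_0_2h"`
#' @param n_reads target number of primary + background reads (> 0);
#'   ping-pong secondaries are appended on top
#' @param p1U probability of a 5' U on primary reads (default 0.9)
#' @param seed integer seed (required)
#' @param background_fraction background share of an ovary library
#' @param error_rate per-base sequencing error rate (default 0.001)
#' @return a [smallrna_library()] with provenance columns (`source`,
#'   `te_id`, `kind`) and a `truth` attribute holding expected per-TE RPM
#' @export
simulate_small_rna_library <- function(dataset, strain,
                                       tissue = c("ovary", "embryo_0_2h"),
                                       n_reads = 20000L, p1U = 0.9, seed,
                                       background_fraction = 0.1,
                                       error_rate = 0.001) {
  tissue <- match.arg(tissue)
  if (missing(seed)) stop("seed is required")
  stopifnot(n_reads > 0)
  withr::with_seed(seed, {
    src <- .library_sources(dataset, strain, tissue, background_fraction)
    if (!nrow(src) || sum(src$weight) <= 0)
      stop("dataset has no read sources (no clusters?)")
    counts <- as.integer(rmultinom(1L, n_reads, src$weight))
    te_seq <- setNames(dataset$te_panel$sequence, dataset$te_panel$id)
    active <- setNames(dataset$te_panel$active, dataset$te_panel$id)
    genome <- dataset$genome[[1]]
    bg_iv <- .background_intervals(dataset)
    out <- list()
    emit <- function(df) out[[length(out) + 1L]] <<- df

    for (i in seq_len(nrow(src))) {
      n <- counts[i]
      if (n == 0L) next
      kind <- src$kind[i]
      if (kind == "fragment") {
        fr <- dataset$fragments[src$frag[i], ]
        ts <- te_seq[[fr$te_id]]
        L <- sample(24:29, n, replace = TRUE)
        maxs <- fr$frag_len - L
        ok <- maxs >= 0L
        L <- L[ok]; n <- sum(ok)
        if (!n) next
        start_local <- floor(runif(n) * (maxs[ok] + 1L))
        a <- fr$te_start + start_local
        if (src$strand_te[i] == "+") {
          seqs <- substr(rep(ts, n), a + 1L, a + L)
          five <- a
        } else {
          seqs <- revcomp(substr(rep(ts, n), a + 1L, a + L))
          five <- a + L - 1L
        }
        u <- runif(n) < p1U
        substr(seqs[u], 1L, 1L) <- "T"
        emit(data.frame(sequence = seqs, te_id = fr$te_id,
                        source = fr$cluster_id, kind = "primary",
                        stringsAsFactors = FALSE))
        # ping-pong partners for active TEs
        if (isTRUE(active[[fr$te_id]]) && strain$pingpong_gain > 0) {
          k <- rpois(n, strain$pingpong_gain)
          idx <- rep.int(seq_len(n), k)
          if (length(idx)) {
            L2 <- sample(24:29, length(idx), replace = TRUE)
            lo <- fr$te_start
            hi <- fr$te_start + fr$frag_len - 1L
            if (src$strand_te[i] == "+") {
              f2 <- five[idx] + 9L
              s_start <- f2 - L2 + 1L
              ok2 <- f2 <= hi & s_start >= lo
              sseq <- revcomp(substr(rep(ts, sum(ok2)),
                                     s_start[ok2] + 1L, f2[ok2] + 1L))
            } else {
              f2 <- five[idx] - 9L
              s_end <- f2 + L2 - 1L
              ok2 <- f2 >= lo & s_end <= hi
              sseq <- substr(rep(ts, sum(ok2)), f2[ok2] + 1L,
                             s_end[ok2] + 1L)
            }
            if (any(ok2))
              emit(data.frame(sequence = sseq, te_id = fr$te_id,
                              source = fr$cluster_id, kind = "secondary",
                              stringsAsFactors = FALSE))
          }
        }
      } else if (kind == "genic") {
        cl <- dataset$clusters[dataset$clusters$id == src$te_id[i], ]
        L <- sample(24:29, n, replace = TRUE)
        start <- cl$start + floor(runif(n) * (cl$end - cl$start - L + 1L))
        seqs <- substr(rep(genome, n), start + 1L, start + L)
        if (src$strand_te[i] == "-") seqs <- revcomp(seqs)
        u <- runif(n) < p1U
        substr(seqs[u], 1L, 1L) <- "T"
        emit(data.frame(sequence = seqs, te_id = NA_character_,
                        source = cl$id, kind = "genic",
                        stringsAsFactors = FALSE))
      } else {
        L <- if (kind == "background_sirna") rep(21L, n) else
          sample(18:23, n, replace = TRUE)
        iv <- bg_iv[sample.int(nrow(bg_iv), n, replace = TRUE,
                               prob = bg_iv$end - bg_iv$start), ]
        start <- iv$start + floor(runif(n) * (iv$end - iv$start - L + 1L))
        seqs <- substr(rep(genome, n), start + 1L, start + L)
        neg <- runif(n) < 0.5
        seqs[neg] <- revcomp(seqs[neg])
        emit(data.frame(sequence = seqs, te_id = NA_character_,
                        source = "background",
                        kind = if (kind == "background_sirna") "sirna"
                               else "background", stringsAsFactors = FALSE))
      }
    }
    reads <- do.call(rbind, out)
    reads$sequence <- inject_errors(reads$sequence, error_rate)
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]  # shuffle
    reads$id <- sprintf("%s_%s_r%07d", strain$name, tissue,
                        seq_len(nrow(reads)))
    rownames(reads) <- NULL
    lib <- smallrna_library(reads[, c("id", "sequence", "te_id", "source",
                                      "kind")],
                            strain = strain$name, tissue = tissue)
    attr(lib, "truth") <- .expected_te_rpm(dataset, strain, src)
    lib
  })
}

#' @noRd
.expected_te_rpm <- function(dataset, strain, src) {
  active <- setNames(dataset$te_panel$active, dataset$te_panel$id)
  gain <- ifelse(dataset$te_panel$active, strain$pingpong_gain, 0)
  names(gain) <- dataset$te_panel$id
  is_te <- src$kind == "fragment"
  w <- src$weight / sum(src$weight)
  amp <- ifelse(is_te, 1 + gain[src$te_id], 1)
  amp[is.na(amp)] <- 1
  w_amp <- w * amp
  te_rate <- tapply(w_amp[is_te], src$te_id[is_te], sum) / sum(w_amp)
  data.frame(te_id = names(te_rate),
             expected_rpm = as.numeric(te_rate) * 1e6,
             stringsAsFactors = FALSE)
}

#' Simulate a DNA-seq library reflecting strain TE copy numbers
#'
#' Reads are sampled uniformly from a virtual strain genome consisting of
#' the non-cluster background plus `copy_number` full copies of every
#' canonical TE, so expected per-TE DNA RPM is proportional to
#' `copy_number * TE length / genome length`.
#'
#' @param dataset a `sim_dataset`
#' @param strain a [strain_model()]; its `te_copy_numbers` must name TEs
#'   present in the panel
#' @param n_reads number of reads
#' @param read_len read length (>= 30)
#' @param seed integer seed (required)
#' @param error_rate per-base error rate
#' @return data.frame of reads (`id`, `sequence`) with a `truth` attribute
#'   of expected per-TE DNA RPM; `depth` attribute = `n_reads`
#' @export
simulate_dnaseq <- function(dataset, strain, n_reads = 50000L,
                            read_len = 100L, seed, error_rate = 0.001) {
  if (missing(seed)) stop("seed is required")
  if (read_len < 30L) stop("read_len must be >= 30")
  cn <- strain$te_copy_numbers
  unknown <- setdiff(names(cn), dataset$te_panel$id)
  if (length(unknown))
    stop("copy number given for TE absent from panel: ",
         paste(unknown, collapse = ", "))
  withr::with_seed(seed, {
    panel <- dataset$te_panel
    te_seq <- setNames(panel$sequence, panel$id)
    bg_iv <- .background_intervals(dataset)
    bg_len <- sum(bg_iv$end - bg_iv$start)
    w_te <- vapply(panel$id, function(t)
      (cn[t] %||% 0) * panel$length[match(t, panel$id)], numeric(1))
    w_te[is.na(w_te)] <- 0
    weights <- c(background = bg_len, w_te)
    counts <- as.integer(rmultinom(1L, n_reads, weights))
    genome <- dataset$genome[[1]]
    out <- list()
    # background
    n <- counts[1]
    if (n > 0L) {
      iv <- bg_iv[sample.int(nrow(bg_iv), n, replace = TRUE,
                             prob = bg_iv$end - bg_iv$start), ]
      width <- pmin(read_len, iv$end - iv$start)
      start <- iv$start + floor(runif(n) * (iv$end - iv$start - width + 1L))
      seqs <- substr(rep(genome, n), start + 1L, start + width)
      neg <- runif(n) < 0.5
      seqs[neg] <- revcomp(seqs[neg])
      out[[1]] <- data.frame(sequence = seqs, origin = "background",
                             stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(panel))) {
      n <- counts[j + 1L]
      if (n == 0L) next
      ts <- te_seq[[panel$id[j]]]
      width <- min(read_len, nchar(ts))
      start <- floor(runif(n) * (nchar(ts) - width + 1L))
      seqs <- substr(rep(ts, n), start + 1L, start + width)
      neg <- runif(n) < 0.5
      seqs[neg] <- revcomp(seqs[neg])
      out[[length(out) + 1L]] <- data.frame(sequence = seqs,
                                            origin = panel$id[j],
                                            stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    reads$sequence <- inject_errors(reads$sequence, error_rate)
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    reads$id <- sprintf("%s_dna_r%07d", strain$name, seq_len(nrow(reads)))
    rownames(reads) <- NULL
    truth <- data.frame(te_id = panel$id,
                        expected_rpm = as.numeric(w_te / sum(weights)) * 1e6,
                        stringsAsFactors = FALSE)
    structure(reads[, c("id", "sequence", "origin")],
              truth = truth, depth = nrow(reads))
  })
}

#' Simulate a reactivity assay for one strain
#'
#' Reactivity (percent non-hatching embryos in a dysgenic cross) follows a
#' negative exponential link in the strain's ancestral-TE piRNA abundance:
#' `clamp(100 * exp(-lambda * rpm) + Normal(0, sd), 0, 100)`, drawn for
#' three replicates.
#'
#' @param strain a [strain_model()] (supplies `reactivity_slope` lambda and
#'   `reactivity_noise_sd`)
#' @param i_pirna_rpm ancestral-TE piRNA abundance in RPM (>= 0)
#' @param seed integer seed (required)
#' @param n_replicates number of replicate egg lays (default 3)
#' @param embryos_per_replicate embryos scored per replicate (default 100)
#' @return a `reactivity_measure` list: `strain`, `replicates` (percent),
#'   `counts` (non-hatched/total), `mean`, `sd`, `n`
#' @export
simulate_reactivity <- function(strain, i_pirna_rpm, seed,
                                n_replicates = 3L,
                                embryos_per_replicate = 100L) {
  if (missing(seed)) stop("seed is required")
  if (i_pirna_rpm < 0) stop("i_pirna_rpm must be >= 0")
  if (strain$reactivity_slope < 0) stop("reactivity_slope must be >= 0")
  withr::with_seed(seed, {
    base <- 100 * exp(-strain$reactivity_slope * i_pirna_rpm)
    reps <- pmin(pmax(base + rnorm(n_replicates, 0,
                                   strain$reactivity_noise_sd), 0), 100)
    non_hatched <- round(reps / 100 * embryos_per_replicate)
    structure(list(strain = strain$name, replicates = reps,
                   counts = data.frame(non_hatched = non_hatched,
                                       total = embryos_per_replicate),
                   mean = mean(reps),
                   sd = if (n_replicates >= 2L) sd(reps) else NA_real_,
                   n = n_replicates * embryos_per_replicate),
              class = "reactivity_measure")
  })
}

#' Simulate a complete multi-strain dataset
#'
#' Convenience wrapper: genome plus ovary (and optionally embryo) libraries,
#' DNA-seq and reactivity for a panel of strains, with ground truth
#' recorded for recovery tests.
#'
#' @param strains named list of [strain_model()]s (default
#'   [default_strains()])
#' @param seed integer seed (required)
#' @param n_reads small-RNA reads per library
#' @param n_dna_reads DNA-seq reads per strain
#' @param embryo_strains strain names for which embryo libraries are made
#' @param ... passed to [simulate_genome()]
#' @return a `sim_dataset` with `libraries` (named `strain.tissue`),
#'   `dnaseq`, `reactivity` and `strains` elements added
#' @export
simulate_dataset <- function(strains = default_strains(), seed,
                             n_reads = 20000L, n_dna_reads = 20000L,
                             embryo_strains = character(0), ...) {
  if (missing(seed)) stop("seed is required")
  ds <- simulate_genome(seed = substream_seed(seed, "genome"), ...)
  ds$strains <- strains
  ds$libraries <- list()
  ds$dnaseq <- list()
  for (nm in names(strains)) {
    st <- strains[[nm]]
    ds$libraries[[paste0(nm, ".ovary")]] <- simulate_small_rna_library(
      ds, st, "ovary", n_reads = n_reads,
      seed = substream_seed(seed, nm, "ovary", "smallrna"))
    if (nm %in% embryo_strains)
      ds$libraries[[paste0(nm, ".embryo_0_2h")]] <- simulate_small_rna_library(
        ds, st, "embryo_0_2h", n_reads = n_reads,
        seed = substream_seed(seed, nm, "embryo_0_2h", "smallrna"))
    ds$dnaseq[[nm]] <- simulate_dnaseq(
      ds, st, n_reads = n_dna_reads,
      seed = substream_seed(seed, nm, "dna", "dnaseq"))
  }
  ds
}
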