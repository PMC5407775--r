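#' Default pipeline configuration
#'
#' @return nested list of defaults; see [run_pipeline()]
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    simulate = list(enabled = TRUE, n_reads = 8000L, n_dna_reads = 10000L,
                    embryo_strains = list("weak1", "strong1")),
    inputs = list(genome = NULL, te_panel = NULL, clusters = NULL,
                  libraries = NULL, dnaseq = NULL, reactivity = NULL),
    params = list(mm_te = 3L, mm_genome = 0L,
                  depth_mode = "filtered", cn_dialect = "log-ratio",
                  pseudocount = 1, min_len = 19L, adapter = NULL,
                  pirna_range = list(24L, 29L)),
    stages = list("map", "quant", "pingpong", "abundance", "de",
                  "correlate", "deposition"))
}

#' @noRd
.validate_config <- function(config) {
  def <- default_config()
  check <- function(x, ref, path) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown))
      stop("unknown config key: ",
           paste0(path, unknown, collapse = ", "), call. = FALSE)
    for (k in names(x))
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]]))
        check(x[[k]], ref[[k]], paste0(path, k, "."))
  }
  check(config, def, "")
  merge2 <- function(ref, x) {
    # like modifyList, but unnamed lists (e.g. stages) replace wholesale
    for (k in names(x)) {
      ref[[k]] <- if (is.list(ref[[k]]) && is.list(x[[k]]) &&
                      !is.null(names(ref[[k]])) && !is.null(names(x[[k]])))
        merge2(ref[[k]], x[[k]]) else x[[k]]
    }
    ref
  }
  cfg <- merge2(def, config)
  if (is.null(cfg$seed)) stop("config$seed is required")
  cfg
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages execute in dependency order (simulate/load -> map -> quant /
#' ping-pong / abundance -> phenotype statistics). With
#' `simulate$enabled = TRUE` (the default) all inputs are generated by the
#' synthetic module under `seed`; otherwise `inputs` paths (FASTA genome
#' and TE panel, BED clusters, FASTQ libraries named `strain.tissue`) are
#' loaded. Re-running an unchanged configuration reproduces byte-identical
#' outputs.
#'
#' @param config nested list or path to a JSON file; unknown keys are
#'   rejected by name. See [default_config()] for the schema.
#' @return a run report: list with `config_hash`, per-stage record counts,
#'   headline tables (`te_expression`, `pingpong_z10`, `de`, `correlation`,
#'   `deposition`), warnings, and written `files` with checksums
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  cfg <- .validate_config(config)
  stages <- unlist(cfg$stages)
  report <- list(config_hash = substr(.config_hash(cfg), 1, 12),
                 counts = list(), tables = list(), warnings = character(0),
                 files = NULL)
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    ds <- simulate_dataset(seed = cfg$seed,
                           n_reads = cfg$simulate$n_reads,
                           n_dna_reads = cfg$simulate$n_dna_reads,
                           embryo_strains = unlist(cfg$simulate$embryo_strains))
  } else {
    inp <- cfg$inputs
    need <- c("genome", "te_panel", "clusters", "libraries")
    miss <- need[vapply(inp[need], is.null, logical(1))]
    if (length(miss))
      stop("missing input(s): ", paste(miss, collapse = ", "))
    for (p in c(inp$genome, inp$te_panel, inp$clusters,
                unlist(inp$libraries), unlist(inp$dnaseq)))
      if (!file.exists(p)) stop("missing input file: ", p)
    te_seq <- read_fasta(inp$te_panel)
    bed <- read_bed(inp$clusters)
    nm <- strsplit(bed$name, "|", fixed = TRUE)
    ds <- structure(list(
      genome = read_fasta(inp$genome),
      te_panel = data.frame(id = names(te_seq), length = nchar(te_seq),
                            class = "germline", active = FALSE,
                            sequence = unname(te_seq),
                            stringsAsFactors = FALSE),
      clusters = data.frame(id = vapply(nm, `[`, "", 1L), chrom = bed$chrom,
                            start = bed$start, end = bed$end,
                            type = vapply(nm, function(x)
                              x[length(x)], ""), strand = bed$strand,
                            stringsAsFactors = FALSE),
      fragments = data.frame(), cluster_spec = default_cluster_spec(),
      strains = NULL, dnaseq = list()), class = "sim_dataset")
    ds$libraries <- lapply(inp$libraries, function(p) {
      reads <- read_fastq(p)
      if (!is.null(cfg$params$adapter))
        reads <- clip_adapter(reads, cfg$params$adapter)
      smallrna_library(filter_reads(reads, cfg$params$min_len))
    })
  }
  report$counts$libraries <- vapply(ds$libraries, nrow, integer(1))

  # --- mapping ------------------------------------------------------------
  te_aln <- list(); genome_aln <- list()
  if ("map" %in% stages) {
    te_aln <- lapply(ds$libraries, map_to_canonical, te_panel = ds$te_panel,
                     max_mismatches = cfg$params$mm_te)
    genome_aln <- lapply(ds$libraries, map_to_genome, genome = ds$genome,
                         max_mismatches = cfg$params$mm_genome)
    report$counts$te_alignments <- vapply(te_aln, nrow, integer(1))
    report$counts$genome_alignments <- vapply(genome_aln, nrow, integer(1))
  }

  # --- quantification -----------------------------------------------------
  expr <- list()
  if ("quant" %in% stages && length(te_aln)) {
    pr <- unlist(cfg$params$pirna_range)
    expr <- lapply(te_aln, te_expression, te_panel = ds$te_panel,
                   length_range = pr)
    tab <- do.call(rbind, lapply(names(expr), function(nm)
      cbind(library = nm, expr[[nm]])))
    report$tables$te_expression <- tab
  }

  # --- ping-pong ----------------------------------------------------------
  if ("pingpong" %in% stages && length(te_aln)) {
    z10 <- do.call(rbind, lapply(names(te_aln), function(nm) {
      profs <- overlap_profile(te_aln[[nm]])
      if (inherits(profs, "overlap_profile")) profs <- list(profs)
      data.frame(library = nm,
                 te_id = vapply(profs, `[[`, "", "te_id"),
                 z10 = vapply(profs, `[[`, numeric(1), "z10"),
                 stringsAsFactors = FALSE)
    }))
    report$tables$pingpong_z10 <- z10
  }

  # --- genomic abundance --------------------------------------------------
  dna_ab <- list()
  if ("abundance" %in% stages && length(ds$dnaseq)) {
    dna_ab <- lapply(ds$dnaseq, function(dr) {
      aln <- map_to_canonical(dr, ds$te_panel,
                              max_mismatches = cfg$params$mm_te)
      te_genomic_abundance(aln, ds$te_panel, depth = nrow(dr))
    })
    report$counts$dnaseq <- vapply(ds$dnaseq, nrow, integer(1))
  }

  # --- differential abundance (weak vs strong pseudo-replicates) ----------
  anc <- ds$cluster_spec$ancestral_te
  if ("de" %in% stages && length(expr) >= 4L && !is.null(ds$strains)) {
    eff <- vapply(ds$strains, `[[`, numeric(1), "primary_efficiency")
    ord <- order(eff, decreasing = TRUE)
    ov <- grep("\\.ovary$", names(expr), value = TRUE)
    if (length(ov) >= 4L) {
      st <- sub("\\.ovary$", "", ov)
      grp <- ifelse(eff[st] >= stats::median(eff), "weak", "strong")
      if (min(table(grp)) >= 2L) {
        cnt <- sapply(ov, function(nm) setNames(expr[[nm]]$count,
                                                expr[[nm]]$feature))
        de <- differential_abundance(
          cnt, grp, numerator = "weak",
          lib_sizes = vapply(ds$libraries[ov], library_depth, numeric(1)))
        report$tables$de <- de
      }
    }
  }

  # --- reactivity correlation ---------------------------------------------
  if ("correlate" %in% stages && length(expr) >= 4L && !is.null(ds$strains)) {
    ov <- grep("\\.ovary$", names(expr), value = TRUE)
    strains <- sub("\\.ovary$", "", ov)
    rpm <- vapply(ov, function(nm)
      expr[[nm]]$rpm[expr[[nm]]$feature == anc], numeric(1))
    react <- vapply(seq_along(strains), function(i)
      simulate_reactivity(ds$strains[[strains[i]]], rpm[i],
                          seed = substream_seed(cfg$seed, strains[i],
                                                "reactivity"))$mean,
      numeric(1))
    tab <- data.frame(strain = strains, pirna = rpm, reactivity = react)
    if (nrow(tab) >= 4L) {
      report$tables$correlation_input <- tab
      cr <- correlate_reactivity(tab)
      report$tables$correlation <- data.frame(
        rho = cr$spearman$rho, p_two_sided = cr$spearman$p_two_sided,
        slope = cr$slope, adj_r_squared = cr$adj_r_squared)
    }
  }

  # --- maternal deposition ------------------------------------------------
  if ("deposition" %in% stages && length(expr)) {
    for (nm in grep("\\.embryo_0_2h$", names(expr), value = TRUE)) {
      st <- sub("\\.embryo_0_2h$", "", nm)
      ovnm <- paste0(st, ".ovary")
      if (!ovnm %in% names(expr)) next
      dep <- maternal_deposition(
        expr[[ovnm]], expr[[nm]],
        dna = if (length(dna_ab)) dna_ab[[st]] else NULL,
        classes = setNames(ds$te_panel$class, ds$te_panel$id),
        dialect = cfg$params$cn_dialect,
        pseudocount = cfg$params$pseudocount)
      report$tables[[paste0("deposition.", st)]] <- dep
    }
  }

  # --- write outputs ------------------------------------------------------
  if (!is.null(outdir)) {
    for (nm in names(report$tables))
      write_tsv_file(report$tables[[nm]],
                     file.path(outdir, paste0(gsub("\\.", "_", nm), ".tsv")))
    files <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
    report$files <- data.frame(path = basename(files),
                               md5 = unname(tools::md5sum(files)),
                               stringsAsFactors = FALSE)
    jsonlite::write_json(
      list(config_hash = report$config_hash, counts = report$counts,
           files = report$files),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @noRd
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
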