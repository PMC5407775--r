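test_that("size distribution tallies per length and strand", {
  aln <- data.frame(read_id = paste0("r", 1:4), te_id = "TEx", start = 0L,
                    strand = c("+", "+", "+", "-"), mismatches = 0L,
                    read_length = c(25L, 25L, 25L, 26L), weight = 1)
  sd_ <- size_distribution(aln)
  expect_equal(sd_$count[sd_$length == 25 & sd_$strand == "+"], 3)
  expect_equal(sd_$count[sd_$length == 26 & sd_$strand == "-"], 1)
  expect_equal(sum(sd_$fraction[sd_$strand == "+"]), 1)
  empty <- size_distribution(aln[0, ])
  expect_true(all(empty$count == 0))
  expect_true(all(is.na(empty$fraction)))
})

test_that("1U bias is computed on the read's own 5' base", {
  reads <- data.frame(
    id = paste0("r", 1:6),
    sequence = c("TAAAAAAAAAAAAAAAAAAAAAAAA",  # + 25nt, 1U
                 "TCCCCCCCCCCCCCCCCCCCCCCCC",  # + 25nt, 1U
                 "GCCCCCCCCCCCCCCCCCCCCCCCC",  # + 25nt, not U
                 "TGGGGGGGGGGGGGGGGGGGGGGGG",  # + 25nt, 1U
                 "TTTTTTTTTTTTTTTTTTTTTTTTT",  # - strand read, 1U
                 "TAAAAAAAAAAAAAAAAAAAA"),     # 21nt, out of range
    stringsAsFactors = FALSE)
  aln <- data.frame(read_id = reads$id, te_id = "TEx", start = 0L,
                    strand = c("+", "+", "+", "+", "-", "+"),
                    mismatches = 0L,
                    read_length = c(25L, 25L, 25L, 25L, 25L, 21L),
                    weight = 1, stringsAsFactors = FALSE)
  ub <- u1_bias(aln, reads)
  expect_equal(ub$fraction_1U[ub$strand == "+"], 0.75)
  expect_equal(ub$fraction_1U[ub$strand == "-"], 1)
  # nothing in range -> missing
  ub2 <- u1_bias(aln[aln$read_length == 21, ], reads)
  expect_true(all(is.na(ub2$fraction_1U)))
  # forcing all first bases to U gives exactly 1
  reads$sequence <- paste0("T", substr(reads$sequence, 2, 99))
  ub3 <- u1_bias(aln, reads)
  expect_equal(ub3$fraction_1U, c(1, 1))
})

test_that("RPM/RPKM/TPM normalization matches hand arithmetic", {
  out <- normalize_counts(c(feat = 50), depth = 2e6, c(feat = 5000))
  expect_equal(out$rpm, 25)
  expect_equal(out$rpkm, 5)
  expect_equal(out$tpm, 1e6)                 # single nonzero feature
  multi <- normalize_counts(c(a = 10, b = 0, c = 30), 1e6,
                            c(a = 1000, b = 2000, c = 3000))
  expect_equal(sum(multi$tpm), 1e6)
  expect_equal(multi$tpm[2], 0)
  expect_error(normalize_counts(c(a = 1), 0, c(a = 100)), "depth")
  # RPM linear in counts
  expect_equal(normalize_counts(c(a = 100), 1e6, c(a = 1000))$rpm,
               10 * normalize_counts(c(a = 10), 1e6, c(a = 1000))$rpm)
})

test_that("copy-number normalization honors both dialects", {
  pirna <- data.frame(feature = "te", rpm = 100)
  dna <- data.frame(te_id = "te", dna_rpm = 100)
  expect_equal(copy_number_normalize(pirna, dna, pseudocount = 0)$value, 0)
  dna2 <- data.frame(te_id = "te", dna_rpm = 200)
  expect_equal(copy_number_normalize(pirna, dna2, pseudocount = 0)$value, -1)
  p32 <- data.frame(feature = "te", rpm = 32)
  d2 <- data.frame(te_id = "te", dna_rpm = 2)
  expect_equal(copy_number_normalize(p32, d2, pseudocount = 0,
                                     dialect = "divide-by-log2")$value, 5)
  # scale invariance of the log-ratio dialect
  withr::with_seed(3, {
    p <- data.frame(feature = letters[1:5], rpm = runif(5, 10, 1000))
    d <- data.frame(te_id = letters[1:5], dna_rpm = runif(5, 10, 1000))
    v1 <- copy_number_normalize(p, d, pseudocount = 0)$value
    p$rpm <- p$rpm * 7; d$dna_rpm <- d$dna_rpm * 7
    expect_equal(copy_number_normalize(p, d, pseudocount = 0)$value, v1,
                 tolerance = 1e-12)
  })
  # zero DNA flagged, not dropped
  dz <- data.frame(te_id = "te", dna_rpm = 0)
  res <- copy_number_normalize(pirna, dz)
  expect_true(res$dna_zero)
  expect_error(copy_number_normalize(data.frame(feature = "te", rpm = -1),
                                     dna), "non-negative")
})

test_that("genic cluster matrix computes log2 ratios and sibling strains", {
  ds <- simulate_genome(seed = 71)
  st <- strain_model("s", te_copy_numbers = default_copy_numbers())
  mk <- function(seed) simulate_small_rna_library(ds, st, "ovary",
                                                  n_reads = 4000, seed = seed)
  libs <- list(ref = mk(1), s1 = mk(2), s2 = mk(2), s3 = mk(3))
  res <- genic_cluster_matrix(libs, ds$genome, ds$clusters,
                              reference_strain = "ref")
  expect_equal(sort(colnames(res$matrix)), c("s1", "s2", "s3"))
  expect_equal(nrow(res$matrix), sum(ds$clusters$type == "genic_3utr"))
  # identical libraries: all-zero column difference and dendrogram siblings
  expect_equal(unname(res$matrix[, "s1"]), unname(res$matrix[, "s2"]))
  if (!is.null(res$hclust)) {
    merged <- res$hclust$merge[1, ]
    expect_setequal(res$hclust$labels[-merged], c("s1", "s2"))
  }
  # rows sorted by decreasing value in the sort strain
  expect_false(is.unsorted(rev(res$matrix[, "s1"])))
})
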