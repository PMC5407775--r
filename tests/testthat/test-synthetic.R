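test_that("genome simulation is deterministic and bookkeeps counts", {
  ds1 <- simulate_genome(panel_spec = list(n_te = 5), seed = 7)
  ds2 <- simulate_genome(panel_spec = list(n_te = 5), seed = 7)
  expect_identical(ds1$genome, ds2$genome)
  expect_identical(ds1$fragments, ds2$fragments)
  expect_equal(nrow(ds1$te_panel), 5L)
  ds3 <- simulate_genome(panel_spec = list(n_te = 5),
                         cluster_spec = list(dual = 1, uni_germline = 0,
                                             uni_somatic = 0, genic_3utr = 0,
                                             ancestral_te = "TE1",
                                             dual_members = c(TE2 = 2)),
                         seed = 7)
  expect_equal(sum(ds3$clusters$type == "dual"), 1L)
  expect_error(simulate_genome(seed = 7,
                               panel_spec = default_te_panel()[0, ]),
               "empty")
  expect_error(simulate_genome(), "seed")
  # file outputs round-trip
  out <- file.path(tempdir(), "simout")
  ds4 <- simulate_genome(seed = 7, outdir = out)
  expect_equal(read_fasta(file.path(out, "genome.fa")), ds4$genome)
  bed <- read_bed(file.path(out, "clusters.bed"))
  expect_equal(nrow(bed), nrow(ds4$clusters))
  expect_equal(bed$start, ds4$clusters$start)
})

test_that("an all-zero cluster spec yields no clusters and no mappers", {
  ds <- simulate_genome(cluster_spec = list(dual = 0, uni_germline = 0,
                                            uni_somatic = 0, genic_3utr = 0),
                        seed = 9)
  expect_equal(nrow(ds$clusters), 0L)
  st <- strain_model("s", te_copy_numbers = default_copy_numbers())
  lib <- simulate_small_rna_library(ds, st, "ovary", n_reads = 500, seed = 9)
  expect_true(all(lib$kind %in% c("background", "sirna")))
  aln <- map_to_genome(lib, ds$genome)
  cc <- assign_to_clusters(select_single_mappers(aln), ds$clusters)
  expect_equal(nrow(cc), 0L)
})

test_that("library simulation is deterministic and writes valid reads", {
  ds <- simulate_genome(seed = 11)
  st <- strain_model("s", te_copy_numbers = default_copy_numbers())
  l1 <- simulate_small_rna_library(ds, st, "ovary", n_reads = 2000, seed = 3)
  l2 <- simulate_small_rna_library(ds, st, "ovary", n_reads = 2000, seed = 3)
  expect_identical(l1$sequence, l2$sequence)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(l1, f1); write_fastq(l2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  expect_true(all(nchar(l1$sequence) >= 18 & nchar(l1$sequence) <= 29))
  expect_error(simulate_small_rna_library(ds, st, "ovary", 100), "seed")
  expect_error(simulate_small_rna_library(ds, st, "pupa", 100, seed = 1))
})

test_that("per-TE read rates are recovered within 3 SE at 1e5 reads", {
  ds <- simulate_genome(seed = 13)
  st <- strain_model("s", primary_efficiency = 2, pingpong_gain = 0,
                     te_copy_numbers = default_copy_numbers())
  lib <- simulate_small_rna_library(ds, st, "ovary", n_reads = 1e5,
                                    seed = 17)
  aln <- map_to_canonical(lib, ds$te_panel)
  ex <- te_expression(aln, ds$te_panel, length_range = NULL)
  truth <- attr(lib, "truth")
  for (te in truth$te_id) {
    p <- truth$expected_rpm[truth$te_id == te] / 1e6
    se <- sqrt(p * (1 - p) / nrow(lib)) * 1e6
    obs <- ex$rpm[ex$feature == te]
    expect_lt(abs(obs - p * 1e6), 3 * se + 1e-9,
              label = paste(te, "RPM deviation"))
  }
})

test_that("maternal transmission scales embryo libraries correctly", {
  ds <- simulate_genome(seed = 19)
  st0 <- strain_model("m0", maternal_transmission = 0,
                      te_copy_numbers = default_copy_numbers())
  emb0 <- simulate_small_rna_library(ds, st0, "embryo_0_2h",
                                     n_reads = 3000, seed = 21)
  expect_true(all(emb0$kind %in% c("background", "sirna")))

  st25 <- strain_model("m25", maternal_transmission = 0.25,
                       pingpong_gain = 0,
                       te_copy_numbers = default_copy_numbers())
  ov <- simulate_small_rna_library(ds, st25, "ovary", n_reads = 8e4,
                                   seed = 23)
  em <- simulate_small_rna_library(ds, st25, "embryo_0_2h", n_reads = 8e4,
                                   seed = 24)
  ov_ex <- te_expression(map_to_canonical(ov, ds$te_panel), ds$te_panel)
  em_ex <- te_expression(map_to_canonical(em, ds$te_panel), ds$te_panel)
  dep <- maternal_deposition(ov_ex, em_ex,
                             classes = setNames(ds$te_panel$class,
                                                ds$te_panel$id))
  germ <- dep[dep$deposition_class == "germline", ]
  expect_equal(mean(germ$log2_ratio), 2, tolerance = 0.15)
})

test_that("DNA-seq respects copy numbers and determinism", {
  ds <- simulate_genome(seed = 25)
  cn <- default_copy_numbers()
  cn["roo_like"] <- 0L
  st <- strain_model("s", te_copy_numbers = cn)
  d1 <- simulate_dnaseq(ds, st, n_reads = 5000, seed = 27)
  d2 <- simulate_dnaseq(ds, st, n_reads = 5000, seed = 27)
  expect_identical(d1$sequence, d2$sequence)
  # zero-copy TE receives no exact DNA hits
  aln0 <- map_to_canonical(d1, ds$te_panel, max_mismatches = 0)
  expect_equal(sum(aln0$te_id == "roo_like"), 0L)
  expect_error(simulate_dnaseq(ds, st, 100, read_len = 20, seed = 1),
               "read_len")
  bad <- strain_model("bad", te_copy_numbers = c(nosuch = 3L))
  expect_error(simulate_dnaseq(ds, bad, 100, seed = 1), "absent")
})

test_that("reactivity link hits its analytic anchors", {
  st0 <- strain_model("s", reactivity_slope = 0.01, reactivity_noise_sd = 0,
                      te_copy_numbers = default_copy_numbers())
  r0 <- simulate_reactivity(st0, 0, seed = 1)
  expect_equal(r0$mean, 100)
  stBig <- strain_model("s", reactivity_slope = 100,
                        reactivity_noise_sd = 0,
                        te_copy_numbers = default_copy_numbers())
  expect_equal(simulate_reactivity(stBig, 10, seed = 1)$mean, 0,
               tolerance = 1e-6)
  # monotone construction gives Spearman rho = -1 downstream
  st <- strain_model("s", reactivity_slope = 1e-3, reactivity_noise_sd = 0,
                     te_copy_numbers = default_copy_numbers())
  rpm <- c(10, 200, 800, 2000, 5000)
  react <- vapply(rpm, function(x)
    simulate_reactivity(st, x, seed = 5)$mean, numeric(1))
  expect_equal(spearman_test(rpm, react)$rho, -1)
  expect_error(simulate_reactivity(st, -1, seed = 1), "i_pirna_rpm")
})

test_that("primary-efficiency contrast shows up in ancestral-TE RPM", {
  ds <- simulate_genome(seed = 33)
  mk <- function(eps, seed) {
    st <- strain_model("s", primary_efficiency = eps, pingpong_gain = 0,
                       te_copy_numbers = default_copy_numbers())
    lib <- simulate_small_rna_library(ds, st, "ovary", n_reads = 2e5,
                                      seed = seed)
    ex <- te_expression(map_to_canonical(lib, ds$te_panel), ds$te_panel)
    ex$rpm[ex$feature == "I_like"]
  }
  ratio <- mk(5, 35) / mk(1, 36)
  expect_equal(log2(ratio), 2.32, tolerance = 0.3)
})
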