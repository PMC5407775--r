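test_that("reactivity summarizes hatching replicates", {
  r <- reactivity(data.frame(non_hatched = c(90, 80, 85), total = 100))
  expect_equal(r$mean, 85)
  expect_equal(r$sd, 5)
  expect_equal(r$n, 300)
  expect_true(is.na(reactivity(data.frame(non_hatched = 5, total = 10))$sd))
  expect_equal(reactivity(data.frame(non_hatched = c(0, 0, 0),
                                     total = 50))$mean, 0)
  expect_error(reactivity(data.frame(non_hatched = 11, total = 10)),
               "exceed")
})

test_that("exact Spearman permutation p matches full enumeration", {
  s <- spearman_test(1:5, 5:1)
  expect_equal(s$rho, -1)
  expect_equal(s$p_two_sided, 2 / 120)
  withr::with_seed(47, {
    for (trial in 1:6) {
      n <- sample(4:6, 1)
      x <- sample(1:6, n, TRUE)                 # ties allowed
      y <- rnorm(n)
      if (length(unique(x)) < 2) next
      got <- spearman_test(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p_two_sided, naive_spearman_p(x, y),
                   info = paste("trial", trial))
    }
  })
  expect_true(is.na(spearman_test(rep(1, 5), rnorm(5))$rho))
})

test_that("reactivity correlation reports rho, regression and band", {
  tab <- data.frame(pirna = c(10, 50, 200, 600, 1500),
                    reactivity = c(95, 70, 40, 15, 3))
  res <- correlate_reactivity(tab)
  expect_equal(res$spearman$rho, -1)
  expect_equal(res$spearman$p_two_sided, 2 / 120)
  expect_lt(res$slope, 0)
  expect_equal(names(res$band), c("pirna", "fit", "lwr", "upr"))
  expect_true(all(res$band$lwr <= res$band$upr))
  expect_error(correlate_reactivity(tab[1:3, ]), "4 strains")
})

test_that("differential abundance recovers trivial contrasts", {
  cnt <- matrix(c(40, 40, 10, 10), nrow = 1,
                dimnames = list("I", paste0("lib", 1:4)))
  grp <- c("weak", "weak", "strong", "strong")
  de <- differential_abundance(cnt, grp, numerator = "weak",
                               lib_sizes = rep(1e6, 4))
  expect_equal(de$log2fc, 2)
  same <- differential_abundance(
    matrix(c(25, 25, 25, 25), 1, dimnames = list("I", NULL)), grp,
    lib_sizes = rep(1e6, 4))
  expect_equal(same$log2fc, 0)
  expect_gte(same$p_value, 0.5)
  # all-zero group flagged via pseudocount path
  zer <- differential_abundance(
    matrix(c(0, 0, 12, 8), 1, dimnames = list("I", NULL)), grp,
    lib_sizes = rep(1e6, 4))
  expect_lt(zer$log2fc, 0)
  expect_error(differential_abundance(cnt, c("a", "b", "c", "d")),
               "two groups")
})

test_that("NB exact test keeps type-I error near nominal under the null", {
  withr::with_seed(53, {
    n_te <- 1000
    mu <- runif(n_te, 20, 200)
    cnt <- t(vapply(mu, function(m)
      rnbinom(4, mu = m, size = 1 / 0.05), numeric(4)))
    rownames(cnt) <- paste0("TE", seq_len(n_te))
    de <- differential_abundance(cnt, c("weak", "weak", "strong", "strong"),
                                 lib_sizes = rep(sum(mu), 4))
    rate <- mean(de$p_value < 0.05, na.rm = TRUE)
    expect_lt(rate, 1.5 * 0.05)
  })
})

test_that("maternal deposition ratios and flags", {
  ov <- data.frame(feature = c("a", "b"), rpkm = c(100, 10),
                   tpm = c(100, 10))
  em <- data.frame(feature = c("a", "b"), rpkm = c(50, 0), tpm = c(50, 0))
  dep <- maternal_deposition(ov, em)
  expect_equal(dep$ratio[1], 2)
  expect_equal(dep$log2_ratio[1], 1)
  expect_true(dep$embryo_zero[2])
  expect_true(is.na(dep$ratio[2]))
  dna <- data.frame(te_id = c("a", "b"), dna_rpm = c(1, 1))
  dep2 <- maternal_deposition(ov, em, dna = dna, pseudocount = 1)
  expect_equal(dep2$cn_value[1], 1 - 1)            # log2(2) - log2(2)
})

test_that("ChIP percent input follows the 2^(dCt) formula", {
  expect_equal(chip_percent_input(20, 20, 1), 100)
  expect_equal(chip_percent_input(20, 25, 1), 3.125)
  expect_equal(chip_percent_input(18, 24, 10), 15.625)
  # strictly decreasing in Ct_IP, linear in F_d
  ct <- seq(20, 30, by = 0.5)
  vals <- chip_percent_input(20, ct, 1)
  expect_true(all(diff(vals) < 0))
  expect_equal(chip_percent_input(20, 25, 7), 7 * 3.125)
  expect_error(chip_percent_input(Inf, 20, 1), "finite")
  expect_error(chip_percent_input(20, 20, 0), "dilution")
})

test_that("2^-ddCt calculator and t-test stars", {
  expect_equal(qpcr_relative(22, 20, 2)$relative_expression, 1)
  expect_equal(qpcr_relative(21, 20, 2)$relative_expression, 2)
  multi <- qpcr_relative(c(22, 22, 22), c(20, 20, 20), 2)
  expect_equal(multi$mean, 1)
  expect_equal(multi$sem, 0)
  same <- qpcr_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(1e-4), "***")
})
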