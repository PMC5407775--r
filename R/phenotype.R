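#' Reactivity summary from hatching replicates
#'
#' Reactivity is the percentage of non-hatching embryos laid by the progeny
#' of a dysgenic cross.
#'
#' @param replicates data.frame (or list of pairs) with `non_hatched` and
#'   `total` per replicate
#' @return list `percent` (per replicate), `mean`, `sd` (sample SD when
#'   two or more replicates are given, else NA), `n` (total embryos)
#' @export
reactivity <- function(replicates) {
  if (!is.data.frame(replicates))
    replicates <- do.call(rbind, lapply(replicates, function(p)
      data.frame(non_hatched = p[1], total = p[2])))
  if (any(replicates$total <= 0)) stop("totals must be > 0")
  if (any(replicates$non_hatched > replicates$total))
    stop("non_hatched cannot exceed total")
  pct <- replicates$non_hatched / replicates$total * 100
  list(percent = pct, mean = mean(pct),
       sd = if (length(pct) >= 2L) sd(pct) else NA_real_,
       n = sum(replicates$total))
}

#' @noRd
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Exact permutation Spearman correlation test
#'
#' Average-rank Spearman rho; for `n <= max_exact` (default 8) the p-value
#' enumerates all `n!` permutations of one variable, so exact p-values are
#' multiples of `1/n!`. Larger samples use the t approximation.
#'
#' @param x,y numeric vectors
#' @param max_exact enumeration threshold
#' @return list `rho`, `p_two_sided`, `p_one_sided` (in the direction of
#'   the observed rho), `method`
#' @export
spearman_test <- function(x, y, max_exact = 8L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p_two_sided = NA_real_,
                p_one_sided = NA_real_, method = "degenerate"))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  if (n <= max_exact) {
    perms <- .permutations(n)
    rho_all <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    eps <- 1e-12
    p2 <- mean(abs(rho_all) >= abs(rho) - eps)
    p1 <- if (rho >= 0) mean(rho_all >= rho - eps)
          else mean(rho_all <= rho + eps)
    list(rho = rho, p_two_sided = p2, p_one_sided = p1, method = "exact")
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p2 <- 2 * pt(-abs(tstat), n - 2)
    list(rho = rho, p_two_sided = min(1, p2), p_one_sided = p2 / 2,
         method = "t-approx")
  }
}

#' Reactivity--piRNA correlation and regression
#'
#' Spearman correlation (exact permutation p for small strain panels) plus
#' ordinary least squares of reactivity on piRNA abundance with adjusted
#' R-squared and a pointwise confidence band (default 90%).
#'
#' @param table data.frame with `reactivity` and `pirna` columns (one row
#'   per strain)
#' @param conf_level confidence-band level (default 0.90)
#' @return list `n`, `spearman` (see [spearman_test()]), `slope`,
#'   `intercept`, `adj_r_squared`, `lm_p_value`, `band` (data.frame
#'   `pirna`, `fit`, `lwr`, `upr`)
#' @export
correlate_reactivity <- function(table, conf_level = 0.90) {
  stopifnot(all(c("reactivity", "pirna") %in% names(table)))
  if (nrow(table) < 4L) stop("need at least 4 strains")
  sp <- spearman_test(table$pirna, table$reactivity)
  fit <- lm(reactivity ~ pirna, data = table)
  sm <- summary(fit)
  grid <- data.frame(pirna = seq(min(table$pirna), max(table$pirna),
                                 length.out = 50L))
  ci <- predict(fit, grid, interval = "confidence", level = conf_level)
  list(n = nrow(table), spearman = sp,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       adj_r_squared = sm$adj.r.squared,
       lm_p_value = unname(sm$coefficients[2, 4]),
       band = cbind(grid, as.data.frame(ci)))
}

#' @noRd
.tmm_factor <- function(obs, ref, logratio_trim = 0.3, abs_trim = 0.05) {
  ok <- obs > 0 & ref > 0
  if (sum(ok) < 2L) return(1)
  no <- sum(obs); nr <- sum(ref)
  M <- log2((obs[ok] / no) / (ref[ok] / nr))
  A <- (log2(obs[ok] / no) + log2(ref[ok] / nr)) / 2
  keepM <- M >= quantile(M, logratio_trim) & M <= quantile(M, 1 - logratio_trim)
  keepA <- A >= quantile(A, abs_trim) & A <= quantile(A, 1 - abs_trim)
  keep <- keepM & keepA
  if (!any(keep)) keep <- rep(TRUE, length(M))
  2^mean(M[keep])
}

#' Differential piRNA abundance with pseudo-replicates
#'
#' Libraries are normalized by trimmed-mean-of-M-values (TMM) size factors;
#' per-TE `log2FC = log2(mean normalized count, numerator group / mean,
#' denominator group)` with a 0.5 pseudocount only when a group mean is
#' zero. P-values come from a negative-binomial exact test conditioned on
#' the two group totals, using one common dispersion estimated across all
#' TEs by method of moments on within-group variability;
#' Benjamini-Hochberg FDR is reported alongside.
#'
#' @param counts numeric matrix, TEs x libraries (weighted counts)
#' @param groups factor/character of length `ncol(counts)` with two levels
#' @param numerator group name forming the log2FC numerator (default the
#'   first level, e.g. "weak")
#' @param lib_sizes optional library depths; defaults to `colSums(counts)`
#'   (use the true depths when the matrix covers only part of a library)
#' @return data.frame `te_id`, `log2fc`, `p_value`, `fdr`, `mean_num`,
#'   `mean_den`, `dispersion`, `method`; normalization factors in the
#'   `norm_factors` attribute
#' @export
differential_abundance <- function(counts, groups, numerator = NULL,
                                   lib_sizes = NULL) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required")
  if (min(table(groups)) < 2L) stop("need >= 2 libraries per group")
  numerator <- numerator %||% lv[1]
  denominator <- setdiff(lv, numerator)
  if (!numerator %in% lv) stop("unknown numerator group: ", numerator)

  libsize <- lib_sizes %||% colSums(counts)
  ref <- which.min(abs(libsize - stats::median(libsize)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    .tmm_factor(counts[, j], counts[, ref]), numeric(1))
  f <- f / exp(mean(log(f)))                       # geometric mean 1
  eff <- libsize * f
  norm <- sweep(counts, 2, mean(eff) / eff, "*")   # common-scale counts

  i_num <- which(groups == numerator)
  i_den <- which(groups == denominator)
  mu_n <- rowMeans(norm[, i_num, drop = FALSE])
  mu_d <- rowMeans(norm[, i_den, drop = FALSE])

  # common dispersion, method of moments: Var = mu + phi mu^2 within groups
  v_n <- apply(norm[, i_num, drop = FALSE], 1, var)
  v_d <- apply(norm[, i_den, drop = FALSE], 1, var)
  num <- sum(pmax(v_n - mu_n, 0), na.rm = TRUE) +
         sum(pmax(v_d - mu_d, 0), na.rm = TRUE)
  den <- sum(mu_n^2, na.rm = TRUE) + sum(mu_d^2, na.rm = TRUE)
  phi <- max(num / max(den, 1e-12), 1e-8)

  pc <- ifelse(mu_n > 0 & mu_d > 0, 0, 0.5)
  log2fc <- log2((mu_n + pc) / (mu_d + pc))
  log2fc[mu_n == 0 & mu_d == 0] <- 0
  both_zero <- mu_n == 0 & mu_d == 0

  nn <- length(i_num); nd <- length(i_den)
  p <- vapply(seq_len(nrow(norm)), function(i) {
    if (both_zero[i]) return(NA_real_)
    ya <- round(sum(norm[i, i_num]))
    yb <- round(sum(norm[i, i_den]))
    .nb_exact_p(ya, yb, nn, nd, phi)
  }, numeric(1))

  out <- data.frame(te_id = rownames(counts) %||%
                      paste0("TE", seq_len(nrow(counts))),
                    log2fc = log2fc, p_value = p,
                    fdr = p.adjust(p, "BH"),
                    mean_num = mu_n, mean_den = mu_d,
                    dispersion = phi,
                    method = "tmm+nb-exact-common-dispersion",
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, norm_factors = f, numerator = numerator,
            denominator = denominator)
}

# Exact conditional NB test: given group totals ya + yb = t with group
# sizes nn, nd and common per-library mean mu0 under the null, p is the
# summed probability of splits at most as likely as the observed one.
#' @noRd
.nb_exact_p <- function(ya, yb, nn, nd, phi) {
  t <- ya + yb
  if (t == 0) return(NA_real_)
  mu0 <- t / (nn + nd)
  size_a <- nn / max(phi, 1e-8)
  size_b <- nd / max(phi, 1e-8)
  a <- 0:t
  la <- stats::dnbinom(a, mu = nn * mu0, size = size_a, log = TRUE)
  lb <- stats::dnbinom(t - a, mu = nd * mu0, size = size_b, log = TRUE)
  lp <- la + lb
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- pr[ya + 1L]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Maternal-deposition ratios (ovary vs 0--2 h embryo)
#'
#' Ratio of per-kilobase depth-normalized piRNA expression (RPKM by
#' default; see the vignette for why TPM-within-panel would cancel a
#' uniform transmission rate) in ovaries to embryos, with an additional
#' copy-number-normalized variant per the active dialect.
#'
#' @param ovary,embryo [normalize_counts()]-style data.frames for matched
#'   TE panels
#' @param dna optional [te_genomic_abundance()] output for the
#'   copy-number-normalized variant
#' @param classes optional named vector TE -> deposition class
#' @param value_col which expression column feeds the ratio (default
#'   `"rpkm"`; `"tpm"` gives the within-panel relative variant)
#' @param pseudocount RPM pseudocount for the copy-number variant
#' @param dialect copy-number dialect, as in [copy_number_normalize()]
#' @return data.frame `te_id`, `ovary`, `embryo`, `ratio`, `log2_ratio`,
#'   `cn_value`, `deposition_class`, `embryo_zero`
#' @export
maternal_deposition <- function(ovary, embryo, dna = NULL, classes = NULL,
                                value_col = c("rpkm", "tpm"),
                                pseudocount = 1,
                                dialect = c("log-ratio", "divide-by-log2")) {
  value_col <- match.arg(value_col)
  dialect <- match.arg(dialect)
  idx <- match(ovary$feature, embryo$feature)
  if (anyNA(idx)) stop("embryo expression missing for: ",
                       paste(ovary$feature[is.na(idx)], collapse = ", "))
  ov <- ovary[[value_col]]
  em <- embryo[[value_col]][idx]
  ratio <- ifelse(em > 0, ov / em, NA_real_)
  out <- data.frame(te_id = ovary$feature, ovary = ov, embryo = em,
                    ratio = ratio, log2_ratio = log2(ratio),
                    cn_value = NA_real_,
                    deposition_class = if (is.null(classes)) NA_character_
                      else unname(classes[ovary$feature]),
                    embryo_zero = em == 0, stringsAsFactors = FALSE)
  if (!is.null(dna)) {
    drpm <- (dna$dna_rpm %||% dna$rpm)[match(out$te_id,
                                             dna$te_id %||% dna$feature)]
    ld <- log2(drpm + pseudocount)
    out$cn_value <- if (dialect == "log-ratio")
      out$log2_ratio - ld else out$log2_ratio / ld
  }
  out
}

#' ChIP percent-input calculator
#'
#' `% input = 2^(Ct_input - Ct_IP) * F_d * 100`.
#'
#' @param ct_input,ct_ip threshold cycles for input and IP samples
#' @param f_d dilution factor (> 0)
#' @return percent input (vectorized)
#' @export
chip_percent_input <- function(ct_input, ct_ip, f_d = 1) {
  if (any(!is.finite(ct_input)) || any(!is.finite(ct_ip)))
    stop("Ct values must be finite")
  if (any(f_d <= 0)) stop("dilution factor must be > 0")
  2^(ct_input - ct_ip) * f_d * 100
}

#' Relative expression by the 2^-ddCt method
#'
#' Target Ct is normalized to the reference gene (rp49) and to a calibrator
#' delta-Ct: `2^-((ct_target - ct_reference) - calibrator_delta_ct)`.
#'
#' @param ct_target,ct_reference threshold cycles (vectorized over samples)
#' @param calibrator_delta_ct calibrator delta-Ct (default 0)
#' @return list `relative_expression` (per sample), `mean`, `sem` (sample
#'   SEM when two or more samples are given, else NA)
#' @export
qpcr_relative <- function(ct_target, ct_reference, calibrator_delta_ct = 0) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  rel <- 2^-((ct_target - ct_reference) - calibrator_delta_ct)
  list(relative_expression = rel, mean = mean(rel),
       sem = if (length(rel) >= 2L) sd(rel) / sqrt(length(rel)) else NA_real_)
}

#' Two-sample t-test with figure-legend star annotation
#'
#' Stars follow the convention: `*` 0.05--0.01, `**` 0.01--0.001, `***`
#' < 0.001.
#'
#' @param a,b numeric samples
#' @return list `p_value`, `stars`
#' @export
qpcr_ttest <- function(a, b) {
  p <- if (sd(c(a, b)) == 0) 1 else t.test(a, b)$p.value
  list(p_value = p, stars = significance_stars(p))
}

#' Star annotation for a p-value
#' @param p p-value
#' @return `""`, `"*"`, `"**"` or `"***"`
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
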