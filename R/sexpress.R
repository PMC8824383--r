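#' Build an expressed allele-ratio matrix at sex-linked SNPs
#'
#' Converts per-sample expressed allele counts at sex-linked SNP positions
#' into alternate-allele read fractions. Cells with fewer than `min_reads`
#' total reads are missing (not zero), so coverage dropouts cannot masquerade
#' as monoallelic expression. SNPs for which one of the two alleles is never
#' observed in any sample are dropped, as are SNPs absent from the count
#' matrices.
#'
#' @param ref_counts,alt_counts integer matrices (SNPs x samples) of expressed
#'   reference (X) and alternate (Y) allele reads, rownames `"chrom:pos"`.
#' @param snps optional character vector of SNP ids to restrict to (e.g. from
#'   [extract_sexlinked()]).
#' @param min_reads minimum reads for a cell to be non-missing.
#' @return numeric matrix of alt-allele fractions with `NA` for missing cells.
#' @export
build_allele_ratio_matrix <- function(ref_counts, alt_counts, snps = NULL,
                                      min_reads = 1) {
  stopifnot(identical(dim(ref_counts), dim(alt_counts)))
  if (!is.null(snps)) {
    missing_snps <- setdiff(snps, rownames(ref_counts))
    if (length(missing_snps) > 0) {
      warning(length(missing_snps), " SNP(s) absent from the count matrices")
    }
    keep <- intersect(snps, rownames(ref_counts))
    ref_counts <- ref_counts[keep, , drop = FALSE]
    alt_counts <- alt_counts[keep, , drop = FALSE]
  }
  tot <- ref_counts + alt_counts
  ratio <- ifelse(tot >= min_reads & tot > 0, alt_counts / tot, NA_real_)
  dimnames(ratio) <- dimnames(ref_counts)
  both_seen <- rowSums(alt_counts > 0, na.rm = TRUE) > 0 &
    rowSums(ref_counts > 0, na.rm = TRUE) > 0
  ratio[both_seen, , drop = FALSE]
}

#' Assign genetic sex by hierarchical clustering of allele ratios
#'
#' Clusters samples by average-linkage hierarchical clustering on Euclidean
#' distances over expressed allele ratios (missing cells ignored pairwise),
#' cuts the tree into two groups and labels as XY the group with the higher
#' mean Y-allele ratio. The result is invariant to row and column order.
#'
#' @param ratio_matrix output of [build_allele_ratio_matrix()].
#' @return list with `sexes` (named vector, `"XX"`/`"XY"`), `tree` (an
#'   [stats::hclust] object), and `confidence` (between-group separation of
#'   mean Y-allele ratios).
#' @export
assign_genetic_sex <- function(ratio_matrix) {
  if (ncol(ratio_matrix) < 2 || nrow(ratio_matrix) < 1) {
    stop("need at least two samples and one retained SNP")
  }
  x <- t(ratio_matrix)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diff2 <- (x[i, ] - x[j, ])^2
      ok <- !is.na(diff2)
      # scale pairwise-complete distances to the full SNP dimension
      d[i, j] <- d[j, i] <- if (any(ok)) {
        sqrt(mean(diff2[ok]) * ncol(x))
      } else {
        NA_real_
      }
    }
  }
  if (any(is.na(d))) stop("some sample pairs share no covered SNP")
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(tree, k = 2)
  mean_ratio <- vapply(1:2, function(g) {
    mean(ratio_matrix[, names(grp)[grp == g], drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  if (!all(is.finite(mean_ratio)) || diff(range(mean_ratio)) == 0) {
    stop("clusters are indistinguishable: identical allele ratios in both ",
         "groups; cannot orient XX vs XY")
  }
  xy_group <- which.max(mean_ratio)
  sexes <- ifelse(grp == xy_group, "XY", "XX")
  list(sexes = sexes[colnames(ratio_matrix)], tree = tree,
       confidence = abs(diff(mean_ratio)))
}

#' Two-group differential expression screen between genetic sexes
#'
#' Normalises counts to counts-per-million per sample, tests each gene's
#' log2(CPM + 1) values between XY and XX samples with a two-sided t-test
#' (Student's by default, Welch via `var_equal = FALSE`) and reports the
#' male/female log2 expression ratio. Genes with identical values in every
#' sample get ratio 0 and p = 1. A Benjamini-Hochberg adjusted column is
#' included; ordering and significance calls use the raw p-values.
#'
#' @param expr count matrix (genes x samples).
#' @param labels named vector of `"XX"`/`"XY"` per sample.
#' @param var_equal use the pooled-variance t statistic (default `TRUE`).
#' @param normalize `"cpm"` (default) or `"none"` to test the input as is.
#' @return tibble: `gene`, `mean_xy`, `mean_xx`, `log2_ratio`, `t`, `p`,
#'   `p_adj`, sorted by `p`.
#' @export
de_scan <- function(expr, labels, var_equal = TRUE, normalize = c("cpm", "none")) {
  normalize <- match.arg(normalize)
  labels <- labels[colnames(expr)]
  if (any(is.na(labels))) stop("every sample needs an XX/XY label")
  xy <- which(labels == "XY")
  xx <- which(labels == "XX")
  if (length(xy) < 2 || length(xx) < 2) {
    stop("need at least two samples per group")
  }
  m <- if (normalize == "cpm") {
    sweep(expr, 2, colSums(expr), "/") * 1e6
  } else {
    expr
  }
  lm2 <- log2(m + 1)
  n1 <- length(xy); n2 <- length(xx)
  mu1 <- rowMeans(lm2[, xy, drop = FALSE])
  mu2 <- rowMeans(lm2[, xx, drop = FALSE])
  v1 <- apply(lm2[, xy, drop = FALSE], 1, stats::var)
  v2 <- apply(lm2[, xx, drop = FALSE], 1, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (mu1 - mu2) / se
  p <- 2 * pt(-abs(tstat), df)
  zero_var <- se == 0 | !is.finite(se)
  tstat[zero_var & mu1 == mu2] <- 0
  p[zero_var & mu1 == mu2] <- 1
  p[zero_var & mu1 != mu2] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  out <- tibble(
    gene = rownames(expr), mean_xy = unname(mu1), mean_xx = unname(mu2),
    log2_ratio = unname(mu1 - mu2), t = unname(tstat), p = unname(p),
    p_adj = unname(p.adjust(p, method = "BH"))
  )
  out[order(out$p), ]
}

#' Call consistent allelic imbalance at expressed sex-linked SNPs
#'
#' A SNP is informative in an XY sample when both alleles are observed with at
#' least one read. SNPs informative in at least `min_informative` XY samples
#' are retained; a retained SNP is flagged imbalanced when every informative
#' XY sample has the same higher-count allele (a tie in any sample breaks
#' consistency), and the shared direction (X-higher or Y-higher) is recorded.
#'
#' @param ref_counts,alt_counts expressed allele count matrices
#'   (SNPs x samples); alt is the Y allele.
#' @param xy_samples character vector of XY sample names.
#' @param min_informative minimum informative XY samples; default
#'   `ceiling(6/7 * length(xy_samples))`.
#' @return tibble: `snp`, `n_informative`, `imbalanced`, `direction`
#'   (`NA` where not flagged).
#' @export
call_allelic_imbalance <- function(ref_counts, alt_counts, xy_samples,
                                   min_informative = NULL) {
  if (length(xy_samples) == 0) stop("xy_samples must be nonempty")
  min_informative <- min_informative %||% ceiling(6 * length(xy_samples) / 7)
  r <- ref_counts[, xy_samples, drop = FALSE]
  a <- alt_counts[, xy_samples, drop = FALSE]
  informative <- r >= 1 & a >= 1
  n_inf <- rowSums(informative)
  keep <- n_inf >= min_informative
  sgn <- sign(a - r)
  sgn[!informative] <- NA
  all_y <- rowSums(sgn == 1, na.rm = TRUE) == n_inf
  all_x <- rowSums(sgn == -1, na.rm = TRUE) == n_inf
  out <- tibble(
    snp = rownames(r), n_informative = as.integer(unname(n_inf)),
    imbalanced = unname(keep & (all_y | all_x) & n_inf > 0),
    direction = unname(ifelse(keep & all_y, "Y-higher",
                              ifelse(keep & all_x, "X-higher",
                                     NA_character_)))
  )
  out$direction[!out$imbalanced] <- NA_character_
  out[keep, ]
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' E = -1 + 10^(-1/slope); a slope of about -3.32 corresponds to perfect
#' doubling (E = 1, i.e. 100 percent).
#'
#' @param slope standard-curve slope (Ct versus log10 template amount).
#' @return efficiency E.
#' @export
qpcr_efficiency <- function(slope) {
  if (any(slope == 0)) stop("slope must be nonzero")
  -1 + 10^(-1 / slope)
}

#' Relative expression by the comparative Ct (2^-ddCt) method
#'
#' Computes dCt = Ct(target) - Ct(reference) per sample, calibrates to the
#' sample with the lowest dCt (or a supplied calibrator) and returns
#' 2^-(dCt - dCt_calibrator). Samples missing a reference Ct are excluded.
#'
#' @param ct_target,ct_reference named numeric vectors of Ct values.
#' @param calibrator optional sample name; default is the sample with the
#'   lowest dCt.
#' @return named vector of relative expression levels (calibrator = 1).
#' @export
ddct_relative_expression <- function(ct_target, ct_reference,
                                     calibrator = NULL) {
  common <- intersect(names(ct_target), names(ct_reference))
  dropped <- setdiff(names(ct_target), common)
  ct_target <- ct_target[common]
  ct_reference <- ct_reference[common]
  ok <- is.finite(ct_target) & is.finite(ct_reference)
  if (length(dropped) > 0 || any(!ok)) {
    warning(length(dropped) + sum(!ok),
            " sample(s) without usable reference Ct excluded")
  }
  dct <- (ct_target - ct_reference)[ok]
  if (length(dct) == 0) stop("no samples with both Ct values")
  calibrator <- calibrator %||% names(dct)[which.min(dct)]
  if (!calibrator %in% names(dct)) stop("calibrator sample not found")
  2^(-(dct - dct[[calibrator]]))
}
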