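#' Compute per-SNP delta allele frequency between sex pools
#'
#' For each biallelic SNP the alternate-allele frequency is computed in the
#' male and the female pool from allelic depths, and the delta allele
#' frequency dAF = |maleAF - femaleAF| is derived. Records whose total depth
#' falls below `min_depth` in either pool are retained but marked excluded
#' (`pass = FALSE`); multiallelic records (comma in ALT) are excluded and
#' counted in a warning.
#'
#' @param variants a `pool_variants` tibble: `chrom`, `pos`, `ref`, `alt`,
#'   `m_ref`, `m_alt`, `f_ref`, `f_alt`.
#' @param min_depth minimum per-pool read depth for a SNP to enter the scan.
#' @return the input with `male_af`, `female_af`, `daf` and `pass` columns.
#'   Frequencies are `NA` where the pool has zero depth.
#' @export
compute_daf <- function(variants, min_depth = 10) {
  stopifnot(all(c("m_ref", "m_alt", "f_ref", "f_alt") %in% names(variants)))
  multi <- if ("alt" %in% names(variants)) grepl(",", variants$alt)
    else rep(FALSE, nrow(variants))
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) excluded from the scan")
  }
  dm <- variants$m_ref + variants$m_alt
  df <- variants$f_ref + variants$f_alt
  if (any(c(variants$m_ref, variants$m_alt,
            variants$f_ref, variants$f_alt) < 0)) {
    stop("allele depths must be non-negative")
  }
  variants$male_af <- ifelse(dm > 0, variants$m_alt / dm, NA_real_)
  variants$female_af <- ifelse(df > 0, variants$f_alt / df, NA_real_)
  variants$daf <- abs(variants$male_af - variants$female_af)
  variants$pass <- dm >= min_depth & df >= min_depth & !multi
  variants
}

#' Windowed delta-allele-frequency genome scan
#'
#' Averages dAF over non-overlapping windows along each chromosome, computes
#' the genome mean and standard deviation over all windows holding at least
#' one passing SNP, flags windows whose Z-score reaches `z_threshold`, and
#' ranks chromosomes by their maximum window mean. The terminal partial window
#' of each chromosome is retained. Window means are unweighted across SNPs
#' unless `depth_weighted` is set, in which case each SNP is weighted by its
#' summed pool depth.
#'
#' @param variants output of [compute_daf()].
#' @param window_bp window width in bp.
#' @param z_threshold flagging threshold in genome standard deviations.
#' @param chrom_lengths optional named lengths; when omitted windows run to
#'   the last observed SNP of each chromosome.
#' @param depth_weighted weight SNPs by total depth within windows.
#' @return list with `windows` (tibble: `chrom`, `start`, `end`, `n_snps`,
#'   `mean_daf`, `z`, `flagged`), `genome_mean`, `genome_sd`, and `ranking`
#'   (chromosomes ordered by max window mean).
#' @export
window_scan <- function(variants, window_bp = 5e5, z_threshold = 3,
                        chrom_lengths = NULL, depth_weighted = FALSE) {
  if (!"daf" %in% names(variants)) stop("run compute_daf() first")
  v <- variants[variants$pass & !is.na(variants$daf), ]
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(v$pos, v$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  wnd <- tile_windows(chrom_lengths, window_bp)
  key <- paste0(v$chrom, ":", window_index(v$pos, window_bp))
  wkey <- paste0(wnd$chrom, ":", wnd$start / window_bp)
  w <- if (depth_weighted) {
    v$m_ref + v$m_alt + v$f_ref + v$f_alt
  } else {
    rep(1, nrow(v))
  }
  sums <- tapply(v$daf * w, key, sum)
  wsum <- tapply(w, key, sum)
  nsnp <- tapply(v$daf, key, length)
  wnd$n_snps <- as.integer(ifelse(is.na(nsnp[wkey]), 0L, nsnp[wkey]))
  wnd$mean_daf <- as.numeric(sums[wkey] / wsum[wkey])

  used <- !is.na(wnd$mean_daf)
  gm <- mean(wnd$mean_daf[used])
  gs <- sd(wnd$mean_daf[used])
  if (!is.finite(gs)) gs <- 0
  wnd$z <- if (gs > 0) (wnd$mean_daf - gm) / gs else
    ifelse(used, 0, NA_real_)
  wnd$flagged <- !is.na(wnd$z) & wnd$z >= z_threshold

  mx <- tapply(wnd$mean_daf[used], wnd$chrom[used], max)
  ranking <- tibble(chrom = names(mx), max_window_daf = as.numeric(mx))
  ranking <- ranking[order(-ranking$max_window_daf), ]
  list(windows = wnd, genome_mean = gm, genome_sd = gs, ranking = ranking)
}

#' Extract sex-linked SNPs
#'
#' Returns the passing-depth SNPs whose delta allele frequency exceeds
#' `daf_min` while the female pool is fixed for one allele. "Fixed" means an
#' observed female frequency of exactly 0 or 1 unless a tolerance is supplied.
#'
#' @param variants output of [compute_daf()].
#' @param daf_min minimum delta allele frequency (exclusive).
#' @param fixed_tol tolerance around 0/1 for the female-fixation rule
#'   (default 0: literal fixation of the observed pool).
#' @return tibble of sex-linked SNPs with an `id` (`"chrom:pos"`) column; the
#'   attribute `"chrom_counts"` holds per-chromosome counts.
#' @export
extract_sexlinked <- function(variants, daf_min = 0.40, fixed_tol = 0) {
  if (!"daf" %in% names(variants)) stop("run compute_daf() first")
  keep <- variants$pass & !is.na(variants$daf) &
    variants$daf > daf_min &
    (variants$female_af <= fixed_tol | variants$female_af >= 1 - fixed_tol)
  out <- variants[keep & !is.na(keep), ]
  out$id <- paste0(out$chrom, ":", out$pos)
  counts <- table(out$chrom)
  attr(out, "chrom_counts") <- setNames(as.integer(counts), names(counts))
  out
}
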