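#' Unbiased per-site heterozygosity from read counts
#'
#' He = 2 * c1 * c2 / (d * (d - 1)) for a biallelic site with allele read
#' counts c1, c2 and depth d = c1 + c2 — the read-based analogue of the
#' unbiased sample heterozygosity (expectation 2p(1-p) under binomial
#' sampling at true frequency p).
#'
#' @param c_major,c_minor read counts of the two alleles.
#' @return numeric vector of He values.
#' @export
site_heterozygosity <- function(c_major, c_minor) {
  d <- c_major + c_minor
  if (any(d < 2)) stop("site heterozygosity is undefined for depth < 2")
  2 * c_major * c_minor / (d * (d - 1))
}

#' Windowed nucleotide diversity from a pileup-like site table
#'
#' Applies the site filters (mapping quality at least `min_mq`, depth between
#' `min_depth` and `max_depth`), computes per-site heterozygosity and averages
#' it in fixed windows. By default the window estimate divides by the number
#' of passing sites (a per-covered-site diversity, robust to depth dropouts);
#' `per_bp = TRUE` divides by window length instead. Sites with more than two
#' observed alleles should be reduced to their two most frequent counts
#' upstream; the table here is already biallelic.
#'
#' @param pileup tibble: `chrom`, `pos` (1-based, sorted within chromosome),
#'   `depth`, `count_major`, `count_minor`, `mq`.
#' @param min_depth,max_depth inclusive depth bounds (use `Inf` to disable
#'   the upper bound).
#' @param min_mq minimum mapping quality.
#' @param window_bp window width in bp.
#' @param per_bp divide by window length rather than passing sites.
#' @param chrom_lengths optional named lengths for window tiling.
#' @return `pi_windows` tibble: `chrom`, `start`, `end`, `n_sites`, `pi`
#'   (`NA` where no site passes), with a `"filter_loss"` attribute counting
#'   sites lost to each filter.
#' @export
window_pi <- function(pileup, min_depth = 10, max_depth = 50, min_mq = 20,
                      window_bp = 5e5, per_bp = FALSE, chrom_lengths = NULL) {
  req <- c("chrom", "pos", "depth", "count_major", "count_minor", "mq")
  stopifnot(all(req %in% names(pileup)))
  unsorted <- tapply(pileup$pos, pileup$chrom, is.unsorted)
  if (any(unsorted)) stop("pileup must be position-sorted within chromosomes")
  fail_mq <- pileup$mq < min_mq
  fail_depth <- pileup$depth < min_depth | pileup$depth > max_depth
  pass <- !fail_mq & !fail_depth & pileup$depth >= 2
  loss <- c(total = nrow(pileup), fail_mq = sum(fail_mq),
            fail_depth = sum(fail_depth), passing = sum(pass))
  v <- pileup[pass, ]
  if (is.null(chrom_lengths)) {
    mx <- tapply(pileup$pos, pileup$chrom, max)
    chrom_lengths <- setNames(as.numeric(mx), names(mx))
  }
  wnd <- tile_windows(chrom_lengths, window_bp)
  if (nrow(v) == 0) {
    wnd$n_sites <- 0L
    wnd$pi <- NA_real_
    attr(wnd, "filter_loss") <- loss
    class(wnd) <- c("pi_windows", class(wnd))
    return(wnd)
  }
  he <- site_heterozygosity(v$count_major, v$count_minor)
  key <- paste0(v$chrom, ":", window_index(v$pos, window_bp))
  wkey <- paste0(wnd$chrom, ":", wnd$start / window_bp)
  s <- tapply(he, key, sum)
  n <- tapply(he, key, length)
  wnd$n_sites <- as.integer(ifelse(is.na(n[wkey]), 0L, n[wkey]))
  wnd$pi <- if (per_bp) {
    as.numeric(ifelse(is.na(s[wkey]), NA, s[wkey])) / (wnd$end - wnd$start)
  } else {
    as.numeric(s[wkey] / n[wkey])
  }
  attr(wnd, "filter_loss") <- loss
  class(wnd) <- c("pi_windows", class(wnd))
  wnd
}

join_window_class <- function(windows, classification) {
  cls <- rep(NA_character_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    ci <- classification[classification$chrom == ch, ]
    if (nrow(ci) == 0) next
    mid <- (windows$start[wi] + windows$end[wi]) / 2
    j <- findInterval(mid, ci$start)
    ok <- j >= 1 & j <= nrow(ci) & mid < ci$end[pmax(j, 1)]
    cls[wi[ok]] <- ci$class[j[ok]]
  }
  cls
}

#' Contrast windowed diversity between region classes
#'
#' Joins each diversity window to the region class covering its midpoint and
#' summarises the per-class distributions, the per-chromosome log2 M-value
#' (mean MRR diversity over mean FRR diversity) and the genome-level fold.
#'
#' @param pi_windows output of [window_pi()], or any window table with a
#'   `pi` column; windows may already carry a `class` column, in which case
#'   `classification` is optional.
#' @param classification a `region_classification`.
#' @return list with `summary` (per-class n, mean, median, quartiles),
#'   `by_chrom` (per-chromosome `m_value`), and `fold`
#'   (mean MRR pi / mean FRR pi).
#' @export
contrast_regions <- function(pi_windows, classification = NULL) {
  w <- pi_windows
  if (!"class" %in% names(w)) {
    if (is.null(classification)) stop("supply a classification")
    w$class <- join_window_class(w, classification)
  }
  w <- w[!is.na(w$class) & !is.na(w$pi), ]
  sm <- lapply(split(w$pi, w$class), function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(n = length(x), mean = mean(x), q25 = q[1], median = q[2], q75 = q[3])
  })
  summary <- do.call(rbind, sm)
  summary <- cbind(tibble(class = names(sm)), summary)
  by_chrom <- lapply(split(w, w$chrom), function(d) {
    mm <- mean(d$pi[d$class == "MRR"])
    mf <- mean(d$pi[d$class == "FRR"])
    tibble(chrom = d$chrom[1],
           mean_mrr = mm, mean_frr = mf,
           m_value = if (is.finite(mm) && is.finite(mf) && mf > 0)
             log2(mm / mf) else NA_real_)
  })
  by_chrom <- do.call(rbind, by_chrom)
  rownames(by_chrom) <- NULL
  fold <- mean(w$pi[w$class == "MRR"]) / mean(w$pi[w$class == "FRR"])
  list(summary = tibble::as_tibble(summary), by_chrom = by_chrom, fold = fold)
}

#' Contrast another species' diversity windows in reference region classes
#'
#' Lifts each query-species window onto the reference genome through a
#' paired-interval map (query interval matched to reference interval,
#' coordinates mapped linearly within pairs), assigns the reference region
#' class covering the majority of the mapped footprint (ties or no overlap
#' leave the window unclassified and excluded) and applies
#' [contrast_regions()].
#'
#' @param pi_windows windowed diversity of the query species, in query
#'   coordinates.
#' @param interval_map tibble: `q_chrom`, `q_start`, `q_end`, `r_chrom`,
#'   `r_start`, `r_end` (half-open; a negative-stride reference pair, with
#'   `r_start > r_end`, maps the query interval in reverse orientation).
#' @param classification reference `region_classification`.
#' @return as [contrast_regions()], plus `windows` with the inherited class.
#' @export
liftover_contrast <- function(pi_windows, interval_map, classification) {
  w <- pi_windows
  cls_bp <- matrix(0, nrow(w), 0)
  classes <- sort(unique(classification$class))
  acc <- matrix(0, nrow(w), length(classes),
                dimnames = list(NULL, classes))
  for (k in seq_len(nrow(interval_map))) {
    m <- interval_map[k, ]
    rev <- m$r_start > m$r_end
    r0 <- min(m$r_start, m$r_end); r1 <- max(m$r_start, m$r_end)
    wi <- which(w$chrom == m$q_chrom & w$end > m$q_start & w$start < m$q_end)
    if (length(wi) == 0) next
    scale <- (r1 - r0) / (m$q_end - m$q_start)
    for (i in wi) {
      q0 <- max(w$start[i], m$q_start); q1 <- min(w$end[i], m$q_end)
      if (!rev) {
        s0 <- r0 + (q0 - m$q_start) * scale
        s1 <- r0 + (q1 - m$q_start) * scale
      } else {
        s0 <- r1 - (q1 - m$q_start) * scale
        s1 <- r1 - (q0 - m$q_start) * scale
      }
      ci <- classification[classification$chrom == m$r_chrom, ]
      if (nrow(ci) == 0) next
      ol <- pmin(ci$end, s1) - pmax(ci$start, s0)
      for (j in which(ol > 0)) {
        acc[i, ci$class[j]] <- acc[i, ci$class[j]] + ol[j]
      }
    }
  }
  best <- apply(acc, 1, function(x) {
    if (all(x == 0)) return(NA_character_)
    top <- which(x == max(x))
    if (length(top) > 1) return(NA_character_) # tie: unclassified
    colnames(acc)[top]
  })
  w$class <- best
  res <- contrast_regions(w)
  res$windows <- w
  res
}
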