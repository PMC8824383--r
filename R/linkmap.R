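#' Detect crossovers in phased pedigree genotypes
#'
#' Scans each meiosis along each chromosome (markers in fixed assembly order)
#' for switches of grandparental phase. A crossover is recorded between the
#' last informative marker of the old phase and the first marker of the new
#' phase, but only when the new phase is supported by at least `min_support`
#' consecutive informative markers; shorter runs are treated as genotyping
#' errors and skipped, as are missing phase calls. The initial phase is taken
#' from the first sufficiently supported run.
#'
#' @param pedigree a `phased_pedigree` (see [simulate_pedigree()]).
#' @param min_support minimum consecutive informative markers confirming the
#'   new phase.
#' @return tibble of events: `meiosis_id`, `parent_sex`, `chrom`, `left_pos`,
#'   `right_pos` (flanking informative markers, bp) and `pos` (interval
#'   midpoint).
#' @export
detect_crossovers <- function(pedigree, min_support = 2) {
  stopifnot(inherits(pedigree, "phased_pedigree"), min_support >= 1)
  sex_of <- setNames(pedigree$meioses$parent_sex, pedigree$meioses$meiosis_id)
  out <- list()
  for (ch in names(pedigree$phases)) {
    mat <- pedigree$phases[[ch]]
    mpos <- pedigree$markers$pos[pedigree$markers$chrom == ch]
    for (mid in colnames(mat)) {
      ph <- mat[, mid]
      idx <- which(!is.na(ph))
      if (length(idx) < 2) {
        warning("chromosome ", ch, ", meiosis ", mid,
                ": fewer than 2 informative markers, no events called")
        next
      }
      r <- rle(ph[idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      first_ok <- which(r$lengths >= min_support)
      k0 <- if (length(first_ok) > 0) first_ok[1] else 1L
      cur <- r$values[k0]
      last_cur <- idx[ends[k0]]
      k <- k0 + 1L
      while (k <= length(r$values)) {
        if (r$values[k] == cur) {
          last_cur <- idx[ends[k]]
        } else if (r$lengths[k] >= min_support) {
          lp <- mpos[last_cur]
          rp <- mpos[idx[starts[k]]]
          out[[length(out) + 1L]] <- tibble(
            meiosis_id = mid, parent_sex = unname(sex_of[mid]), chrom = ch,
            left_pos = lp, right_pos = rp, pos = (lp + rp) / 2
          )
          cur <- r$values[k]
          last_cur <- idx[ends[k]]
        }
        k <- k + 1L
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(meiosis_id = character(), parent_sex = character(),
                  chrom = character(), left_pos = numeric(),
                  right_pos = numeric(), pos = numeric()))
  }
  do.call(rbind, out)
}

#' Build male and female genetic maps from detected crossovers
#'
#' For every adjacent-marker interval and parental sex, the centimorgan
#' increment is `100 * events / informative meioses`; cumulative positions are
#' the running sums along each chromosome. No mapping function is applied:
#' with dense markers in fixed physical order, recombinant fractions per short
#' interval are summed directly.
#'
#' @param events output of [detect_crossovers()].
#' @param pedigree the `phased_pedigree` the events came from (supplies marker
#'   positions and meiosis counts per sex).
#' @return object of class `genetic_maps`: `maps` (tibble `chrom`, `pos`,
#'   `male_cm`, `female_cm`), `events`, `n_meioses` (named by sex),
#'   `chrom_lengths`.
#' @export
build_sex_maps <- function(events, pedigree) {
  stopifnot(inherits(pedigree, "phased_pedigree"))
  n_meio <- table(pedigree$meioses$parent_sex)
  n_meio <- setNames(as.integer(n_meio), names(n_meio))
  maps <- list()
  for (ch in names(pedigree$phases)) {
    mpos <- pedigree$markers$pos[pedigree$markers$chrom == ch]
    ev <- events[events$chrom == ch, ]
    inc <- function(sex) {
      e <- ev$pos[ev$parent_sex == sex]
      n <- n_meio[[sex]] %||% 0L
      cnt <- tabulate(findInterval(e, mpos), nbins = length(mpos) - 1)
      if (n > 0) 100 * cnt / n else rep(0, length(mpos) - 1)
    }
    maps[[ch]] <- tibble(
      chrom = ch, pos = mpos,
      male_cm = c(0, cumsum(inc("male"))),
      female_cm = c(0, cumsum(inc("female")))
    )
  }
  structure(list(
    maps = do.call(rbind, maps), events = events, n_meioses = n_meio,
    chrom_lengths = pedigree$chrom_lengths
  ), class = "genetic_maps")
}

#' Cumulative recombination proportion along each chromosome
#'
#' Per sex and chromosome, the cumulative map position divided by the total
#' map length, a monotone 0-to-1 curve against bp. Chromosomes with a zero
#' total for a sex get `NA` for that sex and are listed in the
#' `"undefined"` attribute.
#'
#' @param maps a `genetic_maps`.
#' @return tibble `chrom`, `pos`, `male_prop`, `female_prop`.
#' @export
cumulative_curves <- function(maps) {
  stopifnot(inherits(maps, "genetic_maps"))
  m <- maps$maps
  undef <- character()
  out <- lapply(split(m, factor(m$chrom, levels = unique(m$chrom))), function(d) {
    tm <- max(d$male_cm); tf <- max(d$female_cm)
    if (tm == 0) undef <<- c(undef, paste0(d$chrom[1], ":male"))
    if (tf == 0) undef <<- c(undef, paste0(d$chrom[1], ":female"))
    tibble(chrom = d$chrom, pos = d$pos,
           male_prop = if (tm > 0) d$male_cm / tm else NA_real_,
           female_prop = if (tf > 0) d$female_cm / tf else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "undefined") <- undef
  out
}

window_rates <- function(maps, window_bp, chrom_lengths) {
  ev <- maps$events
  res <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    nw <- ceiling(L / window_bp)
    starts <- (seq_len(nw) - 1) * window_bp
    width <- pmin(starts + window_bp, L) - starts
    cnt <- function(sex) {
      e <- ev$pos[ev$chrom == ch & ev$parent_sex == sex]
      tabulate(pmin(window_index(e, window_bp) + 1L, nw), nbins = nw)
    }
    fcm <- 100 * cnt("female") / maps$n_meioses[["female"]]
    mcm <- 100 * cnt("male") / maps$n_meioses[["male"]]
    res[[ch]] <- tibble(
      chrom = ch, start = starts, end = starts + width,
      female_cm = fcm, male_cm = mcm,
      female_rate = fcm / (width / 1e6), male_rate = mcm / (width / 1e6)
    )
  }
  do.call(rbind, res)
}

classify_window <- function(frate, mrate, eps, frac) {
  tot <- frate + mrate
  ifelse(frate < eps & mrate < eps, "NR",
         ifelse(frate / tot >= frac, "FRR",
                ifelse(mrate / tot >= frac, "MRR", "BR")))
}

# rate-weighted boundary placement inside the event gap at an FRR|MRR
# junction: unbiased when waiting distances on either side are exponential
refine_junction <- function(left_run, right_run, ev, window_bp) {
  f_first <- left_run$class == "FRR"
  lsex <- if (f_first) "female" else "male"
  rsex <- if (f_first) "male" else "female"
  le <- ev$pos[ev$parent_sex == lsex &
                 ev$pos >= left_run$start & ev$pos < right_run$end]
  re <- ev$pos[ev$parent_sex == rsex &
                 ev$pos >= left_run$start & ev$pos < right_run$end]
  if (length(le) == 0 || length(re) == 0) return(NULL)
  a <- max(le); b <- min(re)
  if (b <= a) return(NULL)
  lam_l <- length(le) / ((left_run$end - left_run$start) / 1e6)
  lam_r <- length(re) / ((right_run$end - right_run$start) / 1e6)
  x <- a + (b - a) * lam_r / (lam_l + lam_r)
  x <- round(x / window_bp) * window_bp
  max(left_run$start + window_bp, min(x, right_run$end - window_bp))
}

#' Classify the genome into MRR, FRR, NR and BR regions
#'
#' Computes female and male recombination rates (cM/Mb) per window from the
#' sex-specific maps, classifies each window (NR when both rates fall below
#' `eps_cm_per_mb`; FRR/MRR when one sex holds at least `one_sex_frac` of the
#' summed rate; BR otherwise), merges adjacent same-class windows, absorbs
#' short no-event (NR) gaps into a surrounding or adjoining class (with the
#' per-window event expectation at realistic pedigree sizes, ~20 percent of
#' windows inside a one-sex region show zero events by chance), and places
#' each FRR|MRR junction by a rate-weighted split of the gap between the two
#' regions' nearest events, snapped to the window grid.
#'
#' @param maps a `genetic_maps`.
#' @param window_bp classification window width (bp).
#' @param eps_cm_per_mb rate below which a sex is considered non-recombining
#'   in a window.
#' @param one_sex_frac minimum share of the summed rate for a one-sex call.
#' @param max_nr_gap maximum NR run length (windows) absorbed into a
#'   neighbouring class.
#' @param refine place FRR|MRR boundaries by the rate-weighted event-gap
#'   split (default) instead of the raw window edge.
#' @param prune_terminal drop cM from terminal windows whose rate exceeds
#'   this multiple of the chromosome median window rate (guards against
#'   map-end inflation); `Inf` disables.
#' @return `region_classification` tibble: `chrom`, `start`, `end`, `class`,
#'   `female_cm`, `male_cm`, `length_mb`, `female_rate`, `male_rate`.
#' @export
classify_regions <- function(maps, window_bp = 5e5, eps_cm_per_mb = 0.5,
                             one_sex_frac = 0.9, max_nr_gap = 4,
                             refine = TRUE, prune_terminal = 10) {
  stopifnot(inherits(maps, "genetic_maps"))
  lens <- maps$chrom_lengths
  wr <- window_rates(maps, window_bp, lens)
  out <- list()
  for (ch in names(lens)) {
    d <- wr[wr$chrom == ch, ]
    ev <- maps$events[maps$events$chrom == ch, ]
    if (is.finite(prune_terminal) && nrow(d) > 2) {
      rates <- d$female_rate + d$male_rate
      med <- median(rates[rates > 0])
      if (is.finite(med) && med > 0) {
        for (i in c(1L, nrow(d))) {
          if (rates[i] > prune_terminal * med) {
            d$female_cm[i] <- d$male_cm[i] <- 0
            d$female_rate[i] <- d$male_rate[i] <- 0
            ev <- ev[!(ev$pos >= d$start[i] & ev$pos < d$end[i]), ]
          }
        }
      }
    }
    cls <- classify_window(d$female_rate, d$male_rate,
                           eps_cm_per_mb, one_sex_frac)
    r <- rle(cls)
    runs <- tibble(
      class = r$values,
      from = cumsum(r$lengths) - r$lengths + 1,
      to = cumsum(r$lengths)
    )
    # absorb short NR gaps: same flanking class on both sides wins; at
    # chromosome ends the single neighbour wins
    changed <- TRUE
    while (changed && nrow(runs) > 1) {
      changed <- FALSE
      for (i in seq_len(nrow(runs))) {
        if (runs$class[i] != "NR") next
        if (runs$to[i] - runs$from[i] + 1 > max_nr_gap) next
        left <- if (i > 1) runs$class[i - 1] else NA
        right <- if (i < nrow(runs)) runs$class[i + 1] else NA
        new <- if (!is.na(left) && !is.na(right) && left == right) left
          else if (is.na(left) && !is.na(right)) right
          else if (is.na(right) && !is.na(left)) left
          else NA
        if (!is.na(new)) {
          runs$class[i] <- new
          r2 <- rle(runs$class)
          keep <- cumsum(r2$lengths)
          runs <- tibble(
            class = r2$values,
            from = runs$from[c(1, head(keep, -1) + 1)],
            to = runs$to[keep]
          )
          changed <- TRUE
          break
        }
      }
    }
    iv <- tibble(
      chrom = ch, class = runs$class,
      start = d$start[runs$from], end = d$end[runs$to]
    )
    if (refine && nrow(iv) > 1) {
      # split NR gaps sandwiched between the two one-sex classes
      i <- 1L
      while (i <= nrow(iv) - 2) {
        gap_w <- (iv$end[i + 1] - iv$start[i + 1]) / window_bp
        if (iv$class[i + 1] == "NR" && gap_w <= max_nr_gap &&
            identical(sort(c(iv$class[i], iv$class[i + 2])),
                      c("FRR", "MRR"))) {
          x <- refine_junction(iv[i, ], iv[i + 2, ], ev, window_bp)
          x <- x %||% ((iv$start[i + 1] + iv$end[i + 1]) / 2)
          x <- round(x / window_bp) * window_bp
          iv$end[i] <- x
          iv$start[i + 2] <- x
          iv <- iv[-(i + 1), ]
        }
        i <- i + 1L
      }
      for (i in seq_len(nrow(iv) - 1)) {
        pair <- sort(c(iv$class[i], iv$class[i + 1]))
        if (identical(pair, c("FRR", "MRR"))) {
          x <- refine_junction(iv[i, ], iv[i + 1, ], ev, window_bp)
          if (!is.null(x)) {
            iv$end[i] <- x
            iv$start[i + 1] <- x
          }
        }
      }
    }
    nf <- maps$n_meioses[["female"]]; nm <- maps$n_meioses[["male"]]
    iv$female_cm <- vapply(seq_len(nrow(iv)), function(i) {
      100 * sum(ev$parent_sex == "female" &
                  ev$pos >= iv$start[i] & ev$pos < iv$end[i]) / nf
    }, numeric(1))
    iv$male_cm <- vapply(seq_len(nrow(iv)), function(i) {
      100 * sum(ev$parent_sex == "male" &
                  ev$pos >= iv$start[i] & ev$pos < iv$end[i]) / nm
    }, numeric(1))
    iv$length_mb <- (iv$end - iv$start) / 1e6
    iv$female_rate <- iv$female_cm / iv$length_mb
    iv$male_rate <- iv$male_cm / iv$length_mb
    out[[ch]] <- iv
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("chrom", "start", "end", "class", "female_cm", "male_cm",
                 "length_mb", "female_rate", "male_rate")]
  attr(res, "window_bp") <- window_bp
  class(res) <- c("region_classification", class(res))
  res
}

#' Per-chromosome and genome-wide region statistics
#'
#' Summarises a region classification: per chromosome the FRR/MRR extents,
#' the MRR fraction, each region's own-sex recombination rate and the
#' MRR/FRR rate ratio (male rate in MRRs over female rate in FRRs; `NA`
#' where a chromosome lacks one class), plus whether the centromere falls in
#' the FRR. Genome totals report Mb and percentages per class.
#'
#' @param classification a `region_classification`.
#' @param centromeres optional tibble `chrom`, `pos`.
#' @param genome_length optional total genome length (bp) for the
#'   percentage denominator; default is the summed classified length.
#' @return list with `per_chrom` and `genome` tibbles.
#' @export
region_rate_stats <- function(classification, centromeres = NULL,
                              genome_length = NULL) {
  cl <- classification
  chroms <- unique(cl$chrom)
  per <- lapply(chroms, function(ch) {
    d <- cl[cl$chrom == ch, ]
    frr <- d[d$class == "FRR", ]; mrr <- d[d$class == "MRR", ]
    frr_mb <- sum(frr$length_mb); mrr_mb <- sum(mrr$length_mb)
    tot_mb <- sum(d$length_mb)
    frate <- if (frr_mb > 0) sum(frr$female_cm) / frr_mb else NA_real_
    mrate <- if (mrr_mb > 0) sum(mrr$male_cm) / mrr_mb else NA_real_
    cen <- NA
    if (!is.null(centromeres) && ch %in% centromeres$chrom) {
      cp <- centromeres$pos[centromeres$chrom == ch][1]
      cen <- any(frr$start <= cp & cp < frr$end)
    }
    tibble(
      chrom = ch, frr_mb = frr_mb, mrr_mb = mrr_mb,
      other_mb = tot_mb - frr_mb - mrr_mb,
      mrr_fraction = mrr_mb / tot_mb,
      frr_female_rate = frate, mrr_male_rate = mrate,
      rate_ratio = mrate / frate,
      centromere_in_frr = cen
    )
  })
  per <- do.call(rbind, per)
  denom <- (genome_length %||% (sum(cl$length_mb) * 1e6)) / 1e6
  genome <- tibble(
    class = c("FRR", "MRR", "other"),
    mb = c(sum(per$frr_mb), sum(per$mrr_mb), sum(per$other_mb)),
    pct = 100 * c(sum(per$frr_mb), sum(per$mrr_mb), sum(per$other_mb)) / denom
  )
  list(per_chrom = per, genome = genome)
}
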