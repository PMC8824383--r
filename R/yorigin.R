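#' Count Y-specific divergent sites against X and an outgroup
#'
#' A site is Y-specific when the Y haplotype allele differs from the X allele
#' while the X allele is shared with the outgroup (so the change is on the Y
#' lineage; sites where X differs from the outgroup reflect X-lineage change
#' and are not counted). Putatively neutral sites are the Y-specific total
#' minus those labelled nonsynonymous. Sites with a missing or non-ACGT
#' allele are skipped and counted.
#'
#' @param table tibble: `chrom`, `pos`, `y`, `x`, `outgroup` (single-base
#'   alleles) and `label` (`"nonsynonymous"`, `"synonymous"` or `"other"`).
#' @return list: `total` Y-specific sites, `nonsynonymous`, `neutral`
#'   (= total - nonsynonymous), `skipped`.
#' @export
count_y_specific <- function(table) {
  stopifnot(all(c("y", "x", "outgroup") %in% names(table)))
  bases <- c("A", "C", "G", "T")
  ok <- table$y %in% bases & table$x %in% bases & table$outgroup %in% bases
  skipped <- sum(!ok)
  t2 <- table[ok, ]
  yspec <- t2$y != t2$x & t2$x == t2$outgroup
  label <- t2$label %||% rep("other", nrow(t2))
  nonsyn <- sum(yspec & label == "nonsynonymous")
  total <- sum(yspec)
  list(total = total, nonsynonymous = nonsyn,
       neutral = total - nonsyn, skipped = skipped)
}

#' Molecular age of a Y stratum from neutral Y-specific divergence
#'
#' T = (S / L) / mu * g years, where S neutral Y-specific sites accumulated
#' over a stratum of L bp at per-site per-generation mutation rate mu with
#' generation time g years. No factor-of-two correction is applied: the
#' counted sites are Y-lineage-specific derived alleles (the X allele matches
#' the outgroup), so divergence accrues on one lineage only. Because standing
#' variation at the time of recombination arrest inflates S, the estimate is
#' an upper bound on the stratum age.
#'
#' @param S neutral Y-specific site count.
#' @param L stratum length in bp.
#' @param mu per-site per-generation mutation rate.
#' @param g generation time in years.
#' @return object of class `y_age`: `years`, `my` (million years) and
#'   `my_rendered` (1-decimal character rendering).
#' @export
estimate_y_age <- function(S, L, mu, g) {
  if (L <= 0 || mu <= 0 || g <= 0) stop("L, mu and g must be positive")
  if (S < 0) stop("S must be non-negative")
  years <- (S / L) / mu * g
  structure(list(years = years, my = years / 1e6,
                 my_rendered = sprintf("%.1f", years / 1e6)),
            class = "y_age")
}

#' @exportS3Method base::print
print.y_age <- function(x, ...) {
  cat(sprintf("Y-stratum age: %.3g years (%s MY)\n", x$years, x$my_rendered))
  invisible(x)
}

#' Per-haplotype, per-region agreement with Y-marker alleles
#'
#' Counts, for each assembly pseudo-haplotype and each region, how many
#' sex-linked markers carry the Y allele on that haplotype, and identifies
#' the Y-bearing haplotype per region as the one with the highest count
#' (margin reported; undetermined when no marker intersects).
#'
#' @param y_markers tibble: `chrom`, `pos`, `y_allele`.
#' @param haplotype_alleles tibble with `chrom`, `pos` and one column per
#'   haplotype holding that haplotype's allele.
#' @param regions tibble: `chrom`, `start`, `end` (half-open), `name`.
#' @return list with `counts` (region x haplotype tibble) and `winners`
#'   (per region: Y haplotype, margin; `NA` when undetermined).
#' @export
haplotype_y_agreement <- function(y_markers, haplotype_alleles, regions) {
  haps <- setdiff(names(haplotype_alleles), c("chrom", "pos"))
  if (length(haps) == 0) stop("no haplotype columns supplied")
  key_m <- paste0(y_markers$chrom, ":", y_markers$pos)
  key_h <- paste0(haplotype_alleles$chrom, ":", haplotype_alleles$pos)
  j <- match(key_m, key_h)
  counts <- list()
  winners <- list()
  for (ri in seq_len(nrow(regions))) {
    rg <- regions[ri, ]
    inside <- y_markers$chrom == rg$chrom &
      y_markers$pos >= rg$start & y_markers$pos < rg$end & !is.na(j)
    cnt <- vapply(haps, function(h) {
      sum(haplotype_alleles[[h]][j[inside]] ==
            y_markers$y_allele[inside], na.rm = TRUE)
    }, numeric(1))
    counts[[ri]] <- tibble(region = rg$name, haplotype = haps,
                           n_y_allele = as.integer(cnt),
                           n_markers = sum(inside))
    winners[[ri]] <- if (sum(inside) == 0) {
      tibble(region = rg$name, y_haplotype = NA_character_,
             margin = NA_integer_)
    } else {
      o <- order(-cnt)
      tibble(region = rg$name, y_haplotype = haps[o[1]],
             margin = as.integer(cnt[o[1]] -
                                   (if (length(cnt) > 1) cnt[o[2]] else 0)))
    }
  }
  list(counts = do.call(rbind, counts), winners = do.call(rbind, winners))
}

#' Check an insertion for LTR-hallmark TG..CA boundaries
#'
#' Tests whether the inserted sequence starts with `TG` and ends with `CA`
#' (the canonical LTR boundary dinucleotides); on failure the reverse
#' complement is tested, reporting a minus-strand insertion. Note that the
#' motif is orientation-symmetric — the reverse complement of `TG..CA` is
#' again `TG..CA` — so an intact element passes on its plus strand whichever
#' orientation it inserted in; the minus report can only arise for inputs
#' whose boundaries are asymmetric.
#'
#' @param locus an `insertion_locus`, or a character insertion sequence.
#' @return `"plus"`, `"minus"`, or `"none"`.
#' @export
check_ltr_boundaries <- function(locus) {
  ins <- if (inherits(locus, "insertion_locus")) {
    substr(locus$with_insertion, locus$insertion_start, locus$insertion_end)
  } else {
    locus
  }
  if (nchar(ins) < 4) stop("insertion shorter than 4 bp")
  tgca <- function(s) {
    substr(s, 1, 2) == "TG" && substr(s, nchar(s) - 1, nchar(s)) == "CA"
  }
  if (tgca(ins)) return("plus")
  if (tgca(reverse_complement(ins))) return("minus")
  "none"
}

#' Find a target-site duplication flanking an insertion
#'
#' Compares, for k from the top of `k_range` downward, the k bp immediately
#' upstream of the insertion with the k bp immediately downstream; the
#' longest exact match is returned as the TSD motif. Optionally verifies that
#' the empty-site allele carries a single copy of the motif at the excision
#' point.
#'
#' @param locus an `insertion_locus`.
#' @param k_range candidate TSD lengths (default 4:6).
#' @param check_empty verify single-copy motif on the empty-site allele by
#'   re-excising the insertion plus one motif copy.
#' @return the TSD motif, or `NULL` when none is found.
#' @export
find_tsd <- function(locus, k_range = 4:6, check_empty = FALSE) {
  stopifnot(inherits(locus, "insertion_locus"))
  s <- locus$with_insertion
  i0 <- locus$insertion_start
  i1 <- locus$insertion_end
  kmax <- max(k_range)
  if (i0 - 1 < kmax || nchar(s) - i1 < kmax) {
    stop("insufficient flanking sequence for TSD search")
  }
  for (k in sort(k_range, decreasing = TRUE)) {
    up <- substr(s, i0 - k, i0 - 1)
    down <- substr(s, i1 + 1, i1 + k)
    if (up == down) {
      if (check_empty) {
        reconstructed <- paste0(substr(s, 1, i0 - 1),
                                substr(s, i1 + k + 1, nchar(s)))
        if (!identical(reconstructed, locus$empty)) next
      }
      return(up)
    }
  }
  NULL
}
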