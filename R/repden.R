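#' Parse a RepeatMasker `.out` annotation table
#'
#' Reads the standard whitespace-aligned `.out` dialect (header lines are
#' detected and skipped), extracting the query sequence, match coordinates
#' (converted to 0-based half-open), strand and the repeat class — the text
#' before the first `/` of the class/family column. Malformed lines are
#' skipped and counted in a warning; an empty file yields an empty table.
#'
#' @param path `.out` file.
#' @return `repeat_annotation` tibble: `chrom`, `start`, `end`, `class`,
#'   `name`, `strand`.
#' @export
parse_repeatmasker <- function(path) {
  lines <- readLines(path)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  class = character(), name = character(),
                  strand = character())
  class(empty) <- c("repeat_annotation", class(empty))
  if (length(lines) == 0) return(empty)
  toks <- strsplit(trimws(lines), "\\s+")
  is_data <- vapply(toks, function(t) {
    length(t) >= 11 && grepl("^\\d+$", t[1])
  }, logical(1))
  toks <- toks[is_data & nzchar(trimws(lines))]
  if (length(toks) == 0) return(empty)
  bad <- 0L
  rows <- lapply(toks, function(t) {
    qbegin <- suppressWarnings(as.numeric(t[6]))
    qend <- suppressWarnings(as.numeric(t[7]))
    if (is.na(qbegin) || is.na(qend) || qend < qbegin) {
      bad <<- bad + 1L
      return(NULL)
    }
    tibble(chrom = t[5], start = qbegin - 1, end = qend,
           class = sub("/.*$", "", t[11]), name = t[10], strand = t[9])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (bad > 0) warning(bad, " malformed line(s) skipped")
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("repeat_annotation", class(out))
  out
}

#' Windowed repeat-class densities
#'
#' For each window and repeat class, the fraction of window bp covered by
#' elements of that class. Overlapping elements of the same class are merged
#' before coverage counting (so duplicated hits do not double-count);
#' different classes are measured as independent tracks. Elements spanning a
#' window boundary contribute proportionally to both windows.
#'
#' @param annotation a `repeat_annotation`.
#' @param windows tibble `chrom`, `start`, `end`, e.g. from
#'   [tile_windows()].
#' @return long tibble: `chrom`, `start`, `end`, `class`, `density`, with a
#'   row per window for every class present in the annotation.
#' @export
window_density <- function(annotation, windows) {
  classes <- sort(unique(annotation$class))
  out <- windows[rep(seq_len(nrow(windows)), length(classes)), ]
  out$class <- rep(classes, each = nrow(windows))
  out$density <- 0
  for (cl in classes) {
    for (ch in unique(windows$chrom)) {
      a <- annotation[annotation$class == cl & annotation$chrom == ch, ]
      wi <- which(windows$chrom == ch)
      if (nrow(a) == 0 || length(wi) == 0) next
      merged <- IRanges::reduce(IRanges::IRanges(start = a$start + 1,
                                                 end = a$end))
      wr <- IRanges::IRanges(start = windows$start[wi] + 1,
                             end = windows$end[wi])
      ov <- IRanges::findOverlaps(wr, merged)
      if (length(ov) == 0) next
      inter <- IRanges::pintersect(wr[S4Vectors::queryHits(ov)],
                                   merged[S4Vectors::subjectHits(ov)])
      cov <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      rows <- (match(cl, classes) - 1) * nrow(windows) +
        wi[as.integer(names(cov))]
      out$density[rows] <- as.numeric(cov) /
        (out$end[rows] - out$start[rows])
    }
  }
  rownames(out) <- NULL
  out
}

#' Z-score repeat densities and contrast MRR vs FRR
#'
#' Transforms each class's window densities to Z-scores against the
#' genome-wide mean and standard deviation of that class (so each class has
#' mean 0, SD 1 across all windows), joins the region class covering each
#' window's midpoint, and summarises the MRR and FRR distributions per repeat
#' class together with a positional trend table (density against the signed
#' distance from the window midpoint to the chromosome's FRR|MRR junction,
#' positive into the MRR).
#'
#' @param densities output of [window_density()].
#' @param classification a `region_classification`.
#' @return list with `windows` (densities plus `z` and `region`), `summary`
#'   (per repeat class: mean Z and mean density in FRR and MRR windows and
#'   their difference), and `trend`. Classes with zero genome-wide SD get
#'   `NA` Z-scores and are listed in the `degenerate` element.
#' @export
zscore_and_contrast <- function(densities, classification) {
  d <- densities
  degenerate <- character()
  d$z <- NA_real_
  for (cl in unique(d$class)) {
    i <- d$class == cl
    mu <- mean(d$density[i]); s <- sd(d$density[i])
    if (!is.finite(s) || s == 0) {
      degenerate <- c(degenerate, cl)
      next
    }
    d$z[i] <- (d$density[i] - mu) / s
  }
  d$region <- join_window_class(d, classification)

  dd <- d[d$region %in% c("FRR", "MRR"), ]
  sm <- lapply(split(dd, dd$class), function(x) {
    f <- x$region == "FRR"
    tibble(class = x$class[1],
           n_frr = sum(f), n_mrr = sum(!f),
           mean_z_frr = mean(x$z[f]), mean_z_mrr = mean(x$z[!f]),
           mean_density_frr = mean(x$density[f]),
           mean_density_mrr = mean(x$density[!f]),
           z_diff = mean(x$z[f]) - mean(x$z[!f]))
  })
  summary <- do.call(rbind, sm)
  rownames(summary) <- NULL

  trend <- d
  trend$dist_mb <- NA_real_
  for (ch in unique(d$chrom)) {
    ci <- classification[classification$chrom == ch, ]
    jxn <- ci$end[ci$class == "FRR" & ci$end %in% ci$start[ci$class == "MRR"]]
    if (length(jxn) == 0) {
      jxn <- ci$start[ci$class == "FRR" &
                        ci$start %in% ci$end[ci$class == "MRR"]]
    }
    if (length(jxn) == 0) next
    wi <- trend$chrom == ch
    mid <- (trend$start[wi] + trend$end[wi]) / 2
    sgn <- ifelse(join_window_class(trend[wi, ], ci) == "MRR", 1, -1)
    trend$dist_mb[wi] <- sgn * abs(mid - jxn[1]) / 1e6
  }
  list(windows = d, summary = summary,
       trend = trend[, c("chrom", "start", "end", "class", "density", "z",
                         "region", "dist_mb")],
       degenerate = degenerate)
}
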