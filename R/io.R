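# readers/writers for the interchange formats the modules consume and emit

#' Write pooled allele counts to a VCF 4.2 file
#'
#' Emits one record per biallelic SNP with per-pool allelic depths in the
#' sample `AD` field (samples `male_pool`, `female_pool`).
#'
#' @param variants a `pool_variants` tibble (see [simulate_pools()]).
#' @param path output path (plain text `.vcf`).
#' @param chrom_lengths optional named vector used for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(variants, path, chrom_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sexrec",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">'
  )
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "male_pool", "female_pool",
                      sep = "\t"))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tAD\t%d,%d\t%d,%d",
                  variants$chrom, as.integer(variants$pos),
                  paste0(variants$chrom, ":", variants$pos),
                  variants$ref, variants$alt,
                  as.integer(variants$m_ref), as.integer(variants$m_alt),
                  as.integer(variants$f_ref), as.integer(variants$f_alt))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read pooled allele counts from a VCF with per-pool AD fields
#'
#' Parses a VCF (via \pkg{vcfR}) whose first two samples are the male and
#' female pools carrying `AD` ref,alt depths, and returns the `pool_variants`
#' table used by [compute_daf()]. Multiallelic records are kept (with the
#' full ALT string) so the downstream scan can skip and count them.
#'
#' @param path VCF file.
#' @return `pool_variants` tibble.
#' @export
read_pool_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  split2 <- function(x, i) {
    as.integer(vapply(strsplit(x, ","), function(p) p[i], ""))
  }
  fix <- vcfR::getFIX(v)
  out <- tibble(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    m_ref = split2(ad[, 1], 1), m_alt = split2(ad[, 1], 2),
    f_ref = split2(ad[, 2], 1), f_alt = split2(ad[, 2], 2)
  )
  class(out) <- c("pool_variants", class(out))
  out
}

#' Read pooled allele counts from a 6-column TSV
#'
#' Columns: chrom, pos, male ref depth, male alt depth, female ref depth,
#' female alt depth (header optional; detected from the first line).
#'
#' @param path TSV file.
#' @return `pool_variants` tibble (ref/alt bases set to `N` placeholders).
#' @export
read_pool_tsv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\S+\t\\d+\t\\d+", first)
  d <- utils::read.delim(path, header = has_header,
                         stringsAsFactors = FALSE)
  colnames(d) <- c("chrom", "pos", "m_ref", "m_alt", "f_ref", "f_alt")
  out <- tibble(chrom = as.character(d$chrom), pos = d$pos,
                ref = "N", alt = "N",
                m_ref = d$m_ref, m_alt = d$m_alt,
                f_ref = d$f_ref, f_alt = d$f_alt)
  class(out) <- c("pool_variants", class(out))
  out
}

#' Write a repeat annotation in RepeatMasker `.out` format
#'
#' Produces the standard 15-column whitespace-aligned dialect with the usual
#' three header lines, the format [parse_repeatmasker()] reads back.
#'
#' @param annotation a `repeat_annotation` tibble (0-based half-open
#'   coordinates; converted to the 1-based inclusive `.out` convention).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(annotation, path) {
  hdr <- c(
    paste("  SW  perc perc perc  query     position in query    matching",
          "     repeat           position in  repeat"),
    paste("score  div. del. ins.  sequence  begin     end    (left)  repeat",
          "     class/family   begin  end (left)   ID"),
    ""
  )
  if (nrow(annotation) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  fam <- ifelse(annotation$class %in% c("Simple_repeat", "Low_complexity",
                                        "Satellite", "Unknown"),
                annotation$class,
                paste0(annotation$class, "/", annotation$name))
  body <- sprintf(
    "%5d %5.1f %4.1f %4.1f  %-8s %8d %8d (%d) %s %-10s %-14s %6d %5d (%d) %5d",
    1000L + seq_len(nrow(annotation)) %% 9000L,
    5 + ((seq_len(nrow(annotation)) * 7L) %% 200L) / 10, 0.5, 0.5,
    annotation$chrom,
    as.integer(annotation$start + 1), as.integer(annotation$end), 0L,
    annotation$strand, annotation$name, fam,
    1L, as.integer(annotation$end - annotation$start), 0L,
    seq_len(nrow(annotation))
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param intervals tibble with `chrom`, `start`, `end` and optionally a name
#'   column (`class` or `name`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  name <- if ("class" %in% names(intervals)) intervals$class
    else if ("name" %in% names(intervals)) intervals$name else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     name), path)
  invisible(path)
}

#' Write an insertion locus allele pair as FASTA
#'
#' @param locus an `insertion_locus` (see [simulate_insertion_locus()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_insertion_fasta <- function(locus, path) {
  seqs <- Biostrings::DNAStringSet(c(
    with_insertion = locus$with_insertion,
    empty_site = locus$empty
  ))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
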