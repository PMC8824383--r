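# shared fixtures: small genomes and hand-built objects used across tests

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_cfg <- function(seed = 42, ...) {
  sim_config(
    seed = seed,
    n_chromosomes = 3,
    chrom_lengths = c(chr1 = 6e6, chr2 = 5e6, chr3 = 4e6),
    ...
  )
}

# a phased pedigree built by hand: one chromosome, evenly spaced markers,
# phase vectors supplied per meiosis
manual_pedigree <- function(phases, parent_sex = "male", spacing = 1e5) {
  n_mark <- nrow(phases)
  meioses <- tibble::tibble(
    meiosis_id = colnames(phases),
    offspring = colnames(phases),
    parent = ifelse(parent_sex == "male", "sire", "dam1"),
    parent_sex = parent_sex
  )
  structure(list(
    markers = tibble::tibble(chrom = "chr1", pos = seq_len(n_mark) * spacing,
                             id = paste0("chr1_m", seq_len(n_mark))),
    phases = list(chr1 = phases),
    meioses = meioses,
    chrom_lengths = c(chr1 = (n_mark + 1) * spacing)
  ), class = "phased_pedigree")
}

# a genetic_maps object built directly from an event list
manual_maps <- function(events, chrom_lengths, n_meioses = c(male = 100, female = 100),
                        spacing = 1e5) {
  markers <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    tibble::tibble(chrom = ch,
                   pos = seq(spacing, chrom_lengths[[ch]], by = spacing))
  }))
  maps <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    mpos <- markers$pos[markers$chrom == ch]
    inc <- function(sex) {
      e <- events$pos[events$chrom == ch & events$parent_sex == sex]
      100 * tabulate(findInterval(e, mpos), nbins = length(mpos) - 1) /
        n_meioses[[sex]]
    }
    tibble::tibble(chrom = ch, pos = mpos,
                   male_cm = c(0, cumsum(inc("male"))),
                   female_cm = c(0, cumsum(inc("female"))))
  }))
  structure(list(maps = maps, events = events, n_meioses = n_meioses,
                 chrom_lengths = chrom_lengths),
            class = "genetic_maps")
}

# events spread uniformly for one sex over an interval
uniform_events <- function(chrom, from, to, n, sex) {
  tibble::tibble(
    meiosis_id = paste0("m", seq_len(n)), parent_sex = sex, chrom = chrom,
    left_pos = NA_real_, right_pos = NA_real_,
    pos = seq(from + (to - from) / (2 * n), to - (to - from) / (2 * n),
              length.out = n)
  )
}

# an insertion locus assembled by hand (flanks chosen per test)
manual_locus <- function(left, motif, element, right, strand = "+") {
  structure(list(
    with_insertion = paste0(left, motif, element, motif, right),
    empty = paste0(left, motif, right),
    insertion_start = nchar(left) + nchar(motif) + 1L,
    insertion_end = nchar(left) + nchar(motif) + nchar(element),
    strand = strand,
    tsd = if (nzchar(motif)) motif else NULL
  ), class = "insertion_locus")
}
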