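#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults mirror the
#' study conditions the package is designed around: pools of ten full siblings
#' per sex sequenced to ~30x, a pedigree of three parents and 90 offspring, and
#' twelve expression samples of which seven are XY and five XX.
#'
#' @param seed integer seed governing all generator randomness. Every
#'   `simulate_*()` function derives its own deterministic sub-stream from it,
#'   so outputs are byte-identical across runs with the same configuration.
#' @param pool_size individuals per sex pool.
#' @param mean_depth mean sequencing depth (reads per site per pool).
#' @param snp_density expected SNPs per bp in the pooled-DNA simulation.
#' @param n_offspring pedigree offspring count (meioses per parental sex).
#' @param n_xy,n_xx expression sample counts per genetic sex.
#' @param n_genes background genes in the expression matrix (one additional
#'   male-only gene is always added).
#' @param expr_sigma log2-scale standard deviation of expression noise.
#' @param expr_allele_depth mean read depth per sample at expressed SNPs.
#' @param expr_dropout probability a SNP x sample cell has no coverage.
#' @param n_expr_snps number of Y-stratum SNPs carried into the expressed
#'   allele-count matrices.
#' @param imbalance_spikes number of allelically imbalanced SNPs spiked into
#'   the expressed allele counts (half X-higher, half Y-higher).
#' @param marker_spacing pedigree marker spacing in bp.
#' @param missing_rate fraction of pedigree phase calls masked as missing.
#' @param depth_mode `"poisson"` for Poisson depths with binomial allele
#'   sampling; `"exact"` for the infinite-depth limit in which observed allele
#'   frequencies equal pool frequencies exactly.
#' @param y_frac fraction of Y-stratum SNPs that are X/Y-divergent (Y allele at
#'   frequency 0.5 in the male pool, absent from females).
#' @param pedigree `"halfsib"` (one sire, two dams) or `"fullsib"`.
#' @param n_chromosomes number of chromosomes in the synthetic genome.
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   overrides the default layout.
#' @param cm_per_sex genetic map length (cM) per chromosome and sex.
#' @param female_cm,male_cm per-sex overrides of `cm_per_sex`; a zero
#'   disables recombination for that sex (its regions drop out of the
#'   region truth).
#' @param window_bp analysis window width the genome is laid out on; region
#'   boundaries fall on this grid.
#' @param site_spacing bp between simulated pileup sites.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       pool_size = 10L,
                       mean_depth = 30,
                       snp_density = 1e-4,
                       n_offspring = 90L,
                       n_xy = 7L,
                       n_xx = 5L,
                       n_genes = 2000L,
                       expr_sigma = 0.4,
                       expr_allele_depth = 30,
                       expr_dropout = 0.1,
                       n_expr_snps = 200L,
                       imbalance_spikes = 6L,
                       marker_spacing = 1e5,
                       missing_rate = 0.02,
                       depth_mode = c("poisson", "exact"),
                       y_frac = 0.6,
                       pedigree = c("halfsib", "fullsib"),
                       n_chromosomes = 24L,
                       chrom_lengths = NULL,
                       cm_per_sex = 49,
                       female_cm = NULL,
                       male_cm = NULL,
                       window_bp = 5e5,
                       site_spacing = 10) {
  depth_mode <- match.arg(depth_mode)
  pedigree <- match.arg(pedigree)
  cfg <- list(
    seed = as.integer(seed), pool_size = as.integer(pool_size),
    mean_depth = mean_depth, snp_density = snp_density,
    n_offspring = as.integer(n_offspring), n_xy = as.integer(n_xy),
    n_xx = as.integer(n_xx), n_genes = as.integer(n_genes),
    expr_sigma = expr_sigma, expr_allele_depth = expr_allele_depth,
    expr_dropout = expr_dropout, n_expr_snps = as.integer(n_expr_snps),
    imbalance_spikes = as.integer(imbalance_spikes),
    marker_spacing = marker_spacing, missing_rate = missing_rate,
    depth_mode = depth_mode, y_frac = y_frac, pedigree = pedigree,
    n_chromosomes = as.integer(n_chromosomes), chrom_lengths = chrom_lengths,
    cm_per_sex = cm_per_sex,
    female_cm = if (is.null(female_cm)) cm_per_sex else female_cm,
    male_cm = if (is.null(male_cm)) cm_per_sex else male_cm,
    window_bp = window_bp,
    site_spacing = site_spacing
  )
  with(cfg, {
    stopifnot(
      pool_size >= 1, mean_depth > 0, snp_density > 0, n_offspring >= 1,
      n_xy >= 2, n_xx >= 2, n_genes >= 1, expr_sigma > 0, marker_spacing > 0,
      missing_rate >= 0, missing_rate < 1, y_frac > 0, y_frac <= 1,
      n_chromosomes >= 2, cm_per_sex > 0, female_cm >= 0, male_cm >= 0,
      window_bp > 0, site_spacing >= 1
    )
  })
  structure(cfg, class = "sim_config")
}

default_chrom_lengths <- function(config) {
  if (!is.null(config$chrom_lengths)) {
    lens <- config$chrom_lengths
    if (is.null(names(lens))) names(lens) <- paste0("chr", seq_along(lens))
    return(lens)
  }
  n <- config$n_chromosomes
  w <- config$window_bp
  sex_idx <- sex_chrom_index(config)
  # decreasing lengths on the window grid, ~600 Mb for the 24-chromosome default
  other <- round(seq(35e6, 15e6, length.out = n - 1) / w) * w
  lens <- numeric(n)
  lens[-sex_idx] <- other
  lens[sex_idx] <- 27e6
  names(lens) <- paste0("chr", seq_len(n))
  lens
}

sex_chrom_index <- function(config) {
  n <- config$n_chromosomes
  if (n >= 13) 13L else as.integer(ceiling(n / 2))
}

#' Simulate a genome layout with sex-specific recombination landscapes
#'
#' Builds a multi-chromosome genome in which every chromosome is tiled by one
#' female-only (FRR) and one male-only (MRR) recombination region, and exactly
#' one chromosome is the sex chromosome whose FRR doubles as the
#' non-recombining Y stratum. Region boundaries lie on the analysis window
#' grid. Each chromosome carries `cm_per_sex` centimorgans per sex, uniformly
#' spread over that sex's region. A centromere is placed at the middle of each
#' FRR.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (class `genome_spec`: `chromosomes`,
#'   `sex_chromosome`, `y_stratum`, `landscape`, `centromeres`) and `truth`
#'   (class `truth_set` holding `region_truth` and the sex-chromosome
#'   identity; later `simulate_*()` calls extend it).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$window_bp
  lens <- default_chrom_lengths(config)
  if (any(lens < w)) {
    stop("all chromosomes must be at least one analysis window long")
  }
  sex_chrom <- names(lens)[sex_chrom_index(config)]

  grid <- function(x) round(x / w) * w
  rows <- lapply(seq_along(lens), function(i) {
    ch <- names(lens)[i]
    L <- lens[[i]]
    if (ch == sex_chrom) {
      frr <- c(0, grid(L * 15 / 27)) # sex chromosome: X/Y-linked head region
    } else if (i %% 2 == 1) {
      frr <- c(0, grid(L * 0.7))
    } else {
      frr <- c(L - grid(L * 0.7), L)
    }
    mrr <- if (frr[1] == 0) c(frr[2], L) else c(0, frr[1])
    tibble(
      chrom = ch,
      frr_start = frr[1], frr_end = frr[2],
      mrr_start = mrr[1], mrr_end = mrr[2],
      female_cm = config$female_cm, male_cm = config$male_cm
    )
  })
  landscape <- do.call(rbind, rows)

  sex_row <- landscape[landscape$chrom == sex_chrom, ]
  centromeres <- tibble(
    chrom = landscape$chrom,
    pos = grid((landscape$frr_start + landscape$frr_end) / 2)
  )
  genome <- structure(list(
    chromosomes = tibble(chrom = names(lens), length = unname(lens)),
    sex_chromosome = sex_chrom,
    y_stratum = c(sex_row$frr_start, sex_row$frr_end),
    landscape = landscape,
    centromeres = centromeres,
    window_bp = w
  ), class = "genome_spec")

  region_truth <- rbind(
    tibble(chrom = landscape$chrom, start = landscape$frr_start,
           end = landscape$frr_end, class = "FRR",
           cm = landscape$female_cm),
    tibble(chrom = landscape$chrom, start = landscape$mrr_start,
           end = landscape$mrr_end, class = "MRR", cm = landscape$male_cm)
  )
  region_truth <- region_truth[region_truth$end > region_truth$start &
                                 region_truth$cm > 0, ]
  region_truth$cm <- NULL
  region_truth <- region_truth[order(match(region_truth$chrom, names(lens)),
                                     region_truth$start), ]
  truth <- structure(list(
    sex_chromosome = sex_chrom,
    y_stratum = genome$y_stratum,
    region_truth = region_truth,
    y_snp_ids = character(),
    sample_sexes = NULL,
    crossovers = NULL,
    de_gene = NULL,
    imbalance = NULL
  ), class = "truth_set")

  list(genome = genome, truth = truth)
}

region_of <- function(genome, chrom, sex) {
  row <- genome$landscape[genome$landscape$chrom == chrom, ]
  if (sex == "female") c(row$frr_start, row$frr_end) else c(row$mrr_start, row$mrr_end)
}

#' Simulate male and female pooled-DNA allele counts
#'
#' Emulates equimolar DNA pools of full siblings from a single cross. At
#' autosomal (and non-divergent sex-chromosome) SNPs the parents' genotypes are
#' drawn from a shared population frequency, each pooled individual inherits
#' one allele per parent, and both pools therefore sample the same four
#' parental haplotypes. Y-stratum SNPs marked X/Y-divergent carry the Y allele
#' on the sire's Y haplotype only, so the male pool has expected alternate
#' frequency 0.5 and the female pool 0. Read depths are Poisson around
#' `mean_depth` with binomial allele sampling, or exact pool frequencies in
#' `depth_mode = "exact"`.
#'
#' @param genome,truth output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return list with `variants` (a `pool_variants` tibble: `chrom`, `pos`,
#'   `ref`, `alt`, `m_ref`, `m_alt`, `f_ref`, `f_alt`) and `truth` with
#'   `y_snp_ids` (ids `"chrom:pos"` of the divergent Y-stratum SNPs) filled in.
#' @export
simulate_pools <- function(genome, truth, config = sim_config()) {
  stopifnot(inherits(genome, "genome_spec"), inherits(truth, "truth_set"))
  if (config$pool_size < 1) stop("pool size must be >= 1")
  if (config$snp_density <= 0) stop("snp_density must be > 0")
  withr::with_seed(substream(config$seed, 1L), {
    lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
    nsnp <- pmax(1L, rpois(length(lens), lens * config$snp_density))
    chrom <- rep(names(lens), nsnp)
    pos <- unlist(lapply(seq_along(lens), function(i) {
      sort(sample.int(lens[[i]], nsnp[i]))
    }), use.names = FALSE)

    ystr <- genome$y_stratum
    on_stratum <- chrom == genome$sex_chromosome &
      pos > ystr[1] & pos <= ystr[2]
    divergent <- on_stratum & runif(length(pos)) < config$y_frac

    np <- config$pool_size
    n <- length(pos)
    # segregating sites: parental genotypes from a shared population frequency
    p0 <- runif(n, 0.05, 0.95)
    g_sire <- rbinom(n, 2, p0)
    g_dam <- rbinom(n, 2, p0)
    if (config$depth_mode == "exact") {
      # infinite-depth, infinite-pool limit: observed frequencies equal their
      # parental expectations, so autosomal maleAF == femaleAF exactly
      freq_m <- freq_f <- (g_sire + g_dam) / 4
      freq_m[divergent] <- 0.5
      freq_f[divergent] <- 0
    } else {
      alt_m <- rbinom(n, np, g_sire / 2) + rbinom(n, np, g_dam / 2)
      alt_f <- rbinom(n, np, g_sire / 2) + rbinom(n, np, g_dam / 2)
      # divergent Y-stratum sites: every male is X/Y heterozygous, females X/X
      alt_m[divergent] <- np
      alt_f[divergent] <- 0L
      freq_m <- alt_m / (2 * np)
      freq_f <- alt_f / (2 * np)
    }

    if (config$depth_mode == "exact") {
      d_m <- rep(2L * np * 100L, n)
      d_f <- d_m
      am <- as.integer(round(freq_m * d_m))
      af <- as.integer(round(freq_f * d_f))
    } else {
      d_m <- rpois(n, config$mean_depth)
      d_f <- rpois(n, config$mean_depth)
      am <- rbinom(n, d_m, freq_m)
      af <- rbinom(n, d_f, freq_f)
    }

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")

    variants <- tibble(
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      m_ref = d_m - am, m_alt = am, f_ref = d_f - af, f_alt = af
    )
    class(variants) <- c("pool_variants", class(variants))
    truth$y_snp_ids <- paste0(chrom[divergent], ":", pos[divergent])
    list(variants = variants, truth = truth)
  })
}

#' Simulate a phased pedigree with sex-specific crossovers
#'
#' Places crossovers for every parental meiosis as a Poisson process whose
#' intensity is the parent sex's recombination landscape (no interference),
#' then records the grandparental phase each offspring carries at every marker.
#' Markers are evenly spaced; a configurable fraction of phase calls is masked
#' as missing.
#'
#' @param genome a `genome_spec`.
#' @param config a [sim_config()]. `pedigree = "halfsib"` uses one sire and two
#'   dams with the offspring split between them; `"fullsib"` uses a single
#'   pair. Either way each offspring contributes one paternal and one maternal
#'   meiosis.
#' @return list with `pedigree` (class `phased_pedigree`: `markers`, `phases`
#'   (per-chromosome character matrices, values `"A"`/`"B"`/`NA`), `meioses`,
#'   `chrom_lengths`) and `crossovers` (truth tibble: `meiosis_id`,
#'   `parent_sex`, `chrom`, `pos`).
#' @export
simulate_pedigree <- function(genome, config = sim_config()) {
  stopifnot(inherits(genome, "genome_spec"))
  withr::with_seed(substream(config$seed, 2L), {
    n_off <- config$n_offspring
    off <- sprintf("off%03d", seq_len(n_off))
    dams <- if (config$pedigree == "halfsib") {
      rep(c("dam1", "dam2"), length.out = n_off)
    } else {
      rep("dam1", n_off)
    }
    meioses <- rbind(
      tibble(offspring = off, parent = "sire", parent_sex = "male"),
      tibble(offspring = off, parent = dams, parent_sex = "female")
    )
    meioses$meiosis_id <- paste0(meioses$offspring, ".", meioses$parent)

    lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
    markers_list <- lapply(names(lens), function(ch) {
      pos <- seq(config$marker_spacing, lens[[ch]], by = config$marker_spacing)
      tibble(chrom = ch, pos = pos, id = paste0(ch, "_m", seq_along(pos)))
    })
    markers <- do.call(rbind, markers_list)

    xo <- vector("list", length(lens))
    phases <- setNames(vector("list", length(lens)), names(lens))
    for (ci in seq_along(lens)) {
      ch <- names(lens)[ci]
      mpos <- markers$pos[markers$chrom == ch]
      mat <- matrix(NA_character_, nrow = length(mpos), ncol = nrow(meioses),
                    dimnames = list(NULL, meioses$meiosis_id))
      ev <- vector("list", nrow(meioses))
      for (k in seq_len(nrow(meioses))) {
        sex <- meioses$parent_sex[k]
        reg <- region_of(genome, ch, sex)
        cm <- if (sex == "female") {
          genome$landscape$female_cm[genome$landscape$chrom == ch]
        } else {
          genome$landscape$male_cm[genome$landscape$chrom == ch]
        }
        nev <- rpois(1, cm / 100)
        epos <- sort(runif(nev, reg[1], reg[2]))
        start <- sample(c("A", "B"), 1)
        parity <- findInterval(mpos, epos) %% 2
        ph <- ifelse(parity == 0, start, setdiff(c("A", "B"), start))
        if (config$missing_rate > 0) {
          ph[runif(length(ph)) < config$missing_rate] <- NA_character_
        }
        mat[, k] <- ph
        if (nev > 0) {
          ev[[k]] <- tibble(meiosis_id = meioses$meiosis_id[k],
                            parent_sex = sex, chrom = ch, pos = epos)
        }
      }
      phases[[ch]] <- mat
      xo[[ci]] <- do.call(rbind, ev[!vapply(ev, is.null, TRUE)])
    }
    crossovers <- do.call(rbind, xo[!vapply(xo, is.null, TRUE)])
    pedigree <- structure(list(
      markers = markers, phases = phases,
      meioses = meioses[, c("meiosis_id", "offspring", "parent", "parent_sex")],
      chrom_lengths = lens
    ), class = "phased_pedigree")
    list(pedigree = pedigree, crossovers = crossovers)
  })
}

#' Simulate expression counts and expressed allele counts
#'
#' Generates a gene expression count matrix for `n_xy + n_xx` samples with one
#' male-only gene (high in every XY sample, near zero in XX) on a background of
#' sex-independent genes with log-normal noise, plus expressed allele counts at
#' Y-stratum SNPs: XY samples express both the X and the Y allele (balanced
#' unless spiked as imbalanced), XX samples only the X allele.
#'
#' @param truth a `truth_set`; its `y_snp_ids` (if present) supply the SNP
#'   coordinates for the allele-count matrices.
#' @param config a [sim_config()].
#' @return list with `counts` (genes x samples), `ref_counts`/`alt_counts`
#'   (SNPs x samples; alt is the Y allele), and `truth` extended with
#'   `sample_sexes`, `de_gene` and the spiked `imbalance` table.
#' @export
simulate_expression <- function(truth, config = sim_config()) {
  stopifnot(inherits(truth, "truth_set"))
  if (config$n_xy < 2 || config$n_xx < 2) {
    stop("at least two samples per sex are required")
  }
  withr::with_seed(substream(config$seed, 3L), {
    ns <- config$n_xy + config$n_xx
    samples <- sprintf("s%02d", seq_len(ns))
    sexes <- sample(c(rep("XY", config$n_xy), rep("XX", config$n_xx)))
    names(sexes) <- samples
    is_xy <- sexes == "XY"

    ng <- config$n_genes
    genes <- sprintf("gene%04d", seq_len(ng))
    mu <- runif(ng, 4, 10) # log2 mean expression
    noise <- matrix(rnorm(ng * ns, 0, config$expr_sigma), ng, ns)
    counts <- round(2^(mu + noise))
    de_gene <- "gene_msd"
    de_row <- ifelse(is_xy,
                     round(2^(8 + rnorm(ns, 0, config$expr_sigma))),
                     rpois(ns, 0.1))
    counts <- rbind(counts, de_row)
    dimnames(counts) <- list(c(genes, de_gene), samples)

    # expressed allele counts at Y-stratum SNPs
    if (length(truth$y_snp_ids) >= config$n_expr_snps) {
      snp_ids <- sort(sample(truth$y_snp_ids, config$n_expr_snps))
    } else if (length(truth$y_snp_ids) > 0) {
      snp_ids <- sort(truth$y_snp_ids)
    } else {
      snp_ids <- paste0(truth$sex_chromosome %||% "chr13", ":",
                        sort(sample.int(15e6, config$n_expr_snps)))
    }
    nsnp <- length(snp_ids)
    n_spike <- min(config$imbalance_spikes, nsnp)
    spike_idx <- if (n_spike > 0) sample.int(nsnp, n_spike) else integer()
    spike_dir <- rep(c("X-higher", "Y-higher"), length.out = n_spike)
    frac <- rep(0.5, nsnp)
    frac[spike_idx] <- ifelse(spike_dir == "X-higher", 0.15, 0.85)

    tot <- matrix(rpois(nsnp * ns, config$expr_allele_depth), nsnp, ns)
    tot[matrix(runif(nsnp * ns) < config$expr_dropout, nsnp, ns)] <- 0L
    alt <- matrix(0L, nsnp, ns)
    for (j in which(is_xy)) alt[, j] <- rbinom(nsnp, tot[, j], frac)
    ref <- tot - alt
    dimnames(ref) <- dimnames(alt) <- list(snp_ids, samples)

    truth$sample_sexes <- sexes
    truth$de_gene <- de_gene
    truth$imbalance <- tibble(snp = snp_ids[spike_idx], direction = spike_dir)
    list(counts = counts, ref_counts = ref, alt_counts = alt, truth = truth)
  })
}

#' Simulate a pileup-like site table with region-specific diversity
#'
#' Emits one site every `site_spacing` bp. A site is polymorphic with the
#' probability that makes the expected per-site heterozygosity equal the true
#' nucleotide diversity configured for its region class (minor allele
#' frequencies are uniform on 0.1-0.5). Depths are Poisson, allele read counts
#' binomial, and a small fraction of sites carries low mapping quality to
#' exercise the MQ filter.
#'
#' @param genome a `genome_spec`.
#' @param config a [sim_config()].
#' @param pi_by_region named vector of true per-site diversity per region
#'   class, e.g. `c(FRR = 0.002, MRR = 0.004)`.
#' @param chroms chromosomes to simulate (default all).
#' @return `pileup` tibble: `chrom`, `pos`, `depth`, `count_major`,
#'   `count_minor`, `mq`.
#' @export
simulate_pileup <- function(genome, config = sim_config(),
                            pi_by_region = c(FRR = 0.002, MRR = 0.004),
                            chroms = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  if (any(pi_by_region < 0 | pi_by_region > 0.5)) {
    stop("pi values must lie in [0, 0.5]")
  }
  withr::with_seed(substream(config$seed, 4L), {
    chroms <- chroms %||% genome$chromosomes$chrom
    mean_he_unif <- 0.3933333 # E[2p(1-p)], p ~ U(0.1, 0.5)
    out <- lapply(chroms, function(ch) {
      L <- genome$chromosomes$length[genome$chromosomes$chrom == ch]
      pos <- seq(config$site_spacing, L, by = config$site_spacing)
      row <- genome$landscape[genome$landscape$chrom == ch, ]
      cls <- ifelse(pos > row$frr_start & pos <= row$frr_end, "FRR", "MRR")
      pi_true <- unname(pi_by_region[cls])
      pi_true[is.na(pi_true)] <- 0
      theta <- pi_true / mean_he_unif
      poly <- runif(length(pos)) < theta
      p <- ifelse(poly, runif(length(pos), 0.1, 0.5), 0)
      d <- rpois(length(pos), config$mean_depth)
      minor <- rbinom(length(pos), d, p)
      mq <- ifelse(runif(length(pos)) < 0.05,
                   sample(0:19, length(pos), replace = TRUE), 60L)
      tibble(chrom = ch, pos = pos, depth = d,
             count_major = pmax(d - minor, minor),
             count_minor = pmin(d - minor, minor), mq = mq)
    })
    pileup <- do.call(rbind, out)
    class(pileup) <- c("pileup", class(pileup))
    pileup
  })
}

#' Simulate a repeat annotation with region-biased class densities
#'
#' Scatters repeat elements of the configured classes along each chromosome
#' with Poisson counts whose rates differ between FRR and MRR as configured
#' (default: SINEs twice as dense in FRRs, simple/low-complexity repeats twice
#' as dense in MRRs, other classes unbiased). Elements are truncated at region
#' ends so they never extend past the chromosome.
#'
#' @param genome a `genome_spec`.
#' @param config a [sim_config()].
#' @param classes tibble with `class`, `rate_per_mb` (elements per Mb in an
#'   MRR) and `frr_bias` (FRR rate multiplier); defaults as above.
#' @param mean_length mean element length (bp).
#' @return `repeat_annotation` tibble: `chrom`, `start` (0-based), `end`,
#'   `class`, `name`, `strand`. Write to RepeatMasker `.out` format with
#'   [write_repeatmasker_out()].
#' @export
simulate_repeats <- function(genome, config = sim_config(),
                             classes = NULL, mean_length = 300) {
  stopifnot(inherits(genome, "genome_spec"))
  classes <- classes %||% tibble(
    class = c("SINE", "LINE", "LTR", "Simple_repeat", "Low_complexity", "DNA"),
    rate_per_mb = c(20, 15, 10, 20, 15, 10),
    frr_bias = c(2, 1, 1, 0.5, 0.5, 1)
  )
  if (any(classes$frr_bias < 0)) stop("class bias factors must be >= 0")
  withr::with_seed(substream(config$seed, 5L), {
    out <- list()
    for (ci in seq_len(nrow(genome$landscape))) {
      row <- genome$landscape[ci, ]
      regions <- rbind(
        c(row$frr_start, row$frr_end, TRUE),
        c(row$mrr_start, row$mrr_end, FALSE)
      )
      for (ri in 1:2) {
        r0 <- regions[ri, 1]; r1 <- regions[ri, 2]
        if (r1 <= r0) next
        for (k in seq_len(nrow(classes))) {
          rate <- classes$rate_per_mb[k] *
            (if (regions[ri, 3] == 1) classes$frr_bias[k] else 1)
          nel <- rpois(1, rate * (r1 - r0) / 1e6)
          if (nel == 0) next
          st <- sort(floor(runif(nel, r0, r1 - 1)))
          len <- 50 + rpois(nel, mean_length - 50)
          en <- pmin(st + len, r1)
          out[[length(out) + 1L]] <- tibble(
            chrom = row$chrom, start = st, end = en,
            class = classes$class[k],
            name = paste0(tolower(classes$class[k]), "_elem"),
            strand = sample(c("+", "C"), nel, replace = TRUE)
          )
        }
      }
    }
    ann <- if (length(out)) do.call(rbind, out) else
      tibble(chrom = character(), start = numeric(), end = numeric(),
             class = character(), name = character(), strand = character())
    ann <- ann[order(match(ann$chrom, genome$chromosomes$chrom), ann$start), ]
    class(ann) <- c("repeat_annotation", class(ann))
    ann
  })
}

#' Simulate an LTR insertion locus with an optional target-site duplication
#'
#' Constructs a pair of alleles for one locus: an insertion-bearing allele in
#' which an LTR-style element (starting `TG`, ending `CA` on its own strand) is
#' flanked by an exact 4-6 nt target-site duplication, and the empty-site
#' allele carrying a single copy of the duplicated motif. When `tsd = FALSE`
#' the flanks are rejection-sampled so that no accidental 4-6-mer duplication
#' borders the insertion, making the locus a clean negative control.
#'
#' @param config a [sim_config()] (its seed is combined with `locus_id`).
#' @param locus_id integer distinguishing loci generated under one config.
#' @param tsd logical; generate a target-site duplication?
#' @param tsd_len TSD length (4-6); sampled if `NULL` and `tsd` is `TRUE`.
#' @param insertion_length,flank_length element and flank sizes in bp.
#' @param minus_strand if `TRUE` the element is inserted in reverse-complement
#'   orientation (its `TG`/`CA` boundaries appear on the minus strand).
#' @return object of class `insertion_locus`: `with_insertion`, `empty`,
#'   `insertion_start`/`insertion_end` (1-based, inclusive, on the bearing
#'   allele), `strand`, `tsd` (motif or `NULL`).
#' @export
simulate_insertion_locus <- function(config = sim_config(), locus_id = 1L,
                                     tsd = TRUE, tsd_len = NULL,
                                     insertion_length = 300,
                                     flank_length = 100,
                                     minus_strand = FALSE) {
  stopifnot(insertion_length >= 4, flank_length >= 6)
  if (!is.null(tsd_len) && (tsd_len < 4 || tsd_len > 6)) {
    stop("TSD length must be between 4 and 6")
  }
  withr::with_seed(substream(config$seed, 6L) + as.integer(locus_id), {
    k <- if (tsd) (tsd_len %||% sample(4:6, 1)) else 0L
    element <- paste0("TG", random_dna(insertion_length - 4), "CA")
    if (minus_strand) element <- reverse_complement(element)
    repeat {
      left <- random_dna(flank_length)
      right <- random_dna(flank_length)
      motif <- if (tsd) random_dna(k) else ""
      up <- paste0(left, motif)
      down <- paste0(motif, right)
      # forbid accidental flanking duplications longer than (or instead of)
      # the intended motif, so truth is unambiguous at this locus
      clean <- TRUE
      for (kk in 4:6) {
        if (tsd && kk == k) next
        u <- substr(up, nchar(up) - kk + 1, nchar(up))
        d <- substr(down, 1, kk)
        if (u == d) clean <- FALSE
      }
      if (!tsd) {
        for (kk in 4:6) {
          u <- substr(left, flank_length - kk + 1, flank_length)
          d <- substr(right, 1, kk)
          if (u == d) clean <- FALSE
        }
      }
      if (clean) break
    }
    with_ins <- paste0(left, motif, element, motif, right)
    empty <- paste0(left, motif, right)
    structure(list(
      with_insertion = with_ins,
      empty = empty,
      insertion_start = flank_length + k + 1L,
      insertion_end = flank_length + k + nchar(element),
      strand = if (minus_strand) "-" else "+",
      tsd = if (tsd) motif else NULL
    ), class = "insertion_locus")
  })
}
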