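test_that("default genome layout has 24 chromosomes and a 15-Mb Y stratum", {
  g <- simulate_genome(sim_config(seed = 1))
  expect_equal(nrow(g$genome$chromosomes), 24)
  expect_equal(g$genome$sex_chromosome, "chr13")
  expect_equal(g$genome$y_stratum, c(0, 15e6))
  sex_len <- g$genome$chromosomes$length[g$genome$chromosomes$chrom == "chr13"]
  expect_equal(sex_len, 27e6)
  # FRR and MRR are disjoint and tile each chromosome
  for (i in seq_len(nrow(g$genome$landscape))) {
    r <- g$genome$landscape[i, ]
    L <- g$genome$chromosomes$length[g$genome$chromosomes$chrom == r$chrom]
    spans <- sort(c(r$frr_start, r$frr_end, r$mrr_start, r$mrr_end))
    expect_equal(spans[1], 0)
    expect_equal(spans[4], L)
    expect_equal(spans[2], spans[3]) # contiguous, non-overlapping
  }
  # centromeres sit inside the FRR
  cen <- merge(g$genome$centromeres, g$genome$landscape, by = "chrom")
  expect_true(all(cen$pos >= cen$frr_start & cen$pos <= cen$frr_end))
})

test_that("degenerate and invalid genome configurations are handled", {
  g0 <- simulate_genome(tiny_cfg(male_cm = 0))
  expect_false("MRR" %in% g0$truth$region_truth$class)
  expect_true("FRR" %in% g0$truth$region_truth$class)
  expect_error(
    simulate_genome(sim_config(n_chromosomes = 2,
                               chrom_lengths = c(chr1 = 4e5, chr2 = 2e6))),
    "window"
  )
})

test_that("generators are deterministic given the seed", {
  cfg <- tiny_cfg(seed = 9)
  g <- simulate_genome(cfg)
  expect_identical(serialize(simulate_genome(cfg), NULL),
                   serialize(simulate_genome(cfg), NULL))
  expect_identical(simulate_pools(g$genome, g$truth, cfg)$variants,
                   simulate_pools(g$genome, g$truth, cfg)$variants)
  p <- simulate_pools(g$genome, g$truth, cfg)
  expect_identical(simulate_expression(p$truth, cfg)$counts,
                   simulate_expression(p$truth, cfg)$counts)
  a1 <- simulate_repeats(g$genome, cfg)
  a2 <- simulate_repeats(g$genome, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_repeatmasker_out(a1, f1); write_repeatmasker_out(a2, f2)
  expect_identical(readLines(f1), readLines(f2)) # byte-identical files
})

test_that("pool allele frequencies hit their infinite-depth limits", {
  cfg <- tiny_cfg(depth_mode = "exact")
  g <- simulate_genome(cfg)
  p <- simulate_pools(g$genome, g$truth, cfg)
  v <- compute_daf(p$variants)
  ids <- paste0(v$chrom, ":", v$pos)
  y <- ids %in% p$truth$y_snp_ids
  expect_true(all(v$male_af[y] == 0.5))
  expect_true(all(v$female_af[y] == 0))
  expect_true(all(v$male_af[!y] == v$female_af[!y]))
})

test_that("pool depths match the configured mean and error scales as depth^(-1/2)", {
  cfg <- tiny_cfg(seed = 3, snp_density = 7e-4) # ~10k SNPs
  g <- simulate_genome(cfg)
  p <- simulate_pools(g$genome, g$truth, cfg)
  d <- (p$variants$m_ref + p$variants$m_alt + p$variants$f_ref +
          p$variants$f_alt) / 2
  expect_gt(length(d), 8000)
  expect_lt(abs(mean(d) - cfg$mean_depth) / cfg$mean_depth, 0.05)

  # Y-stratum SNPs have true male frequency 0.5; the observed-AF RMSE around
  # it must shrink like 1/sqrt(depth)
  rmse_at <- function(depth) {
    cfg_d <- tiny_cfg(seed = 5, snp_density = 7e-4, mean_depth = depth)
    gd <- simulate_genome(cfg_d)
    pd <- simulate_pools(gd$genome, gd$truth, cfg_d)
    v <- compute_daf(pd$variants, min_depth = 1)
    y <- paste0(v$chrom, ":", v$pos) %in% pd$truth$y_snp_ids
    sqrt(mean((v$male_af[y] - 0.5)^2, na.rm = TRUE))
  }
  r <- vapply(c(10, 100, 1000), rmse_at, numeric(1))
  expect_gt(r[1] / r[2], 2.4)  # ~sqrt(10) = 3.16
  expect_lt(r[1] / r[2], 4.2)
  expect_gt(r[2] / r[3], 2.4)
  expect_lt(r[2] / r[3], 4.2)
})

test_that("pedigree crossovers respect the sex-specific landscapes", {
  cfg <- tiny_cfg(seed = 2)
  g <- simulate_genome(cfg)
  pd <- simulate_pedigree(g$genome, cfg)
  xo <- merge(pd$crossovers, g$genome$landscape, by = "chrom")
  f <- xo$parent_sex == "female"
  expect_true(all(xo$pos[f] >= xo$frr_start[f] & xo$pos[f] <= xo$frr_end[f]))
  expect_true(all(xo$pos[!f] >= xo$mrr_start[!f] & xo$pos[!f] <= xo$mrr_end[!f]))
  # no male events inside the Y stratum (the sex chromosome's FRR)
  sex <- g$genome$sex_chromosome
  ystr <- g$genome$y_stratum
  expect_equal(sum(!f & xo$chrom == sex &
                     xo$pos >= ystr[1] & xo$pos < ystr[2]), 0)
})

test_that("crossover counts over meioses are binomially calibrated", {
  # 10-cM chromosomes, 100 offspring: per-sex events ~ Binomial(100, 0.1)
  cfg <- tiny_cfg(seed = 8, cm_per_sex = 10, n_offspring = 100)
  g <- simulate_genome(cfg)
  pd <- simulate_pedigree(g$genome, cfg)
  for (ch in g$genome$chromosomes$chrom) {
    for (sx in c("male", "female")) {
      n <- sum(pd$crossovers$chrom == ch & pd$crossovers$parent_sex == sx)
      expect_lt(abs(n - 10), 3 * sqrt(100 * 0.1 * 0.9) + 1e-9)
    }
  }
})

test_that("expression matrices separate the sexes as designed", {
  cfg <- tiny_cfg(seed = 4)
  g <- simulate_genome(cfg)
  p <- simulate_pools(g$genome, g$truth, cfg)
  e <- simulate_expression(p$truth, cfg)
  xx <- names(e$truth$sample_sexes)[e$truth$sample_sexes == "XX"]
  xy <- names(e$truth$sample_sexes)[e$truth$sample_sexes == "XY"]
  expect_equal(length(xy), 7)
  expect_equal(length(xx), 5)
  # XX samples never express the Y allele
  expect_true(all(e$alt_counts[, xx] == 0))
  # the male-only gene: high in every XY sample, ~zero in XX
  expect_true(all(e$counts[e$truth$de_gene, xy] > 50))
  expect_true(all(e$counts[e$truth$de_gene, xx] < 5))
  expect_error(tiny_cfg(n_xx = 1))
})

test_that("pileup generator respects degenerate diversity settings", {
  cfg <- tiny_cfg(site_spacing = 100)
  g <- simulate_genome(cfg)
  pu <- simulate_pileup(g$genome, cfg, pi_by_region = c(FRR = 0, MRR = 0),
                        chroms = "chr1")
  expect_true(all(pu$count_minor == 0))
  expect_error(simulate_pileup(g$genome, cfg,
                               pi_by_region = c(FRR = 0.7, MRR = 0.1)),
               "0, 0.5")
})

test_that("repeat generator honours zero rates and round-trips the parser", {
  cfg <- tiny_cfg(seed = 6)
  g <- simulate_genome(cfg)
  none <- simulate_repeats(g$genome, cfg,
                           classes = tibble::tibble(class = "SINE",
                                                    rate_per_mb = 0,
                                                    frr_bias = 1))
  expect_equal(nrow(none), 0)
  f <- tempfile()
  write_repeatmasker_out(none, f)
  expect_equal(nrow(parse_repeatmasker(f)), 0)

  ann <- simulate_repeats(g$genome, cfg)
  expect_true(all(ann$end > ann$start))
  lens <- setNames(g$genome$chromosomes$length, g$genome$chromosomes$chrom)
  expect_true(all(ann$end <= lens[ann$chrom]))
  write_repeatmasker_out(ann, f)
  back <- parse_repeatmasker(f)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$class, ann$class)
})

test_that("insertion loci carry their configured TSD and boundaries", {
  cfg <- tiny_cfg(seed = 7)
  loc <- simulate_insertion_locus(cfg, locus_id = 1, tsd_len = 4)
  expect_equal(nchar(loc$tsd), 4)
  expect_identical(find_tsd(loc), loc$tsd)
  expect_equal(check_ltr_boundaries(loc), "plus")

  neg <- simulate_insertion_locus(cfg, locus_id = 2, tsd = FALSE)
  expect_null(neg$tsd)
  expect_null(find_tsd(neg))

  # TG..CA is orientation-symmetric, so an antisense insertion still reads
  # TG..CA on the plus strand and passes the boundary check
  mn <- simulate_insertion_locus(cfg, locus_id = 3, minus_strand = TRUE)
  expect_equal(check_ltr_boundaries(mn), "plus")
  expect_identical(find_tsd(mn), mn$tsd)
})
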