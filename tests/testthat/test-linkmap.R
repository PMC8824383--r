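phase_mat <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, lapply(cols, function(s) strsplit(s, "")[[1]]))
  m[m == "."] <- NA
  colnames(m) <- paste0("off", seq_along(cols), ".sire")
  m
}

test_that("crossover detection follows the phase-switch and support rules", {
  ped <- manual_pedigree(phase_mat("AAAABBBB", "AAAAAAAA", "AAABAAAA",
                                   "AAABBBAA", "AA.ABBBB"))
  ev <- detect_crossovers(ped, min_support = 2)
  e1 <- ev[ev$meiosis_id == "off1.sire", ]
  expect_equal(nrow(e1), 1)               # single clean switch
  expect_equal(e1$left_pos, 4e5)
  expect_equal(e1$right_pos, 5e5)
  expect_equal(e1$pos, 4.5e5)
  expect_equal(sum(ev$meiosis_id == "off2.sire"), 0)  # no switch
  expect_equal(sum(ev$meiosis_id == "off3.sire"), 0)  # singleton blip filtered
  expect_equal(sum(ev$meiosis_id == "off4.sire"), 2)  # double switch kept
  # missing marker skipped; switch still found across it
  e5 <- ev[ev$meiosis_id == "off5.sire", ]
  expect_equal(nrow(e5), 1)
  expect_equal(e5$left_pos, 4e5)

  sparse <- manual_pedigree(phase_mat("A......."))
  expect_warning(detect_crossovers(sparse), "fewer than 2")
})

test_that("map increments are recombinant fractions times 100", {
  # 10 events among 100 female meioses in one interval -> +10 cM female
  ev <- tibble::tibble(
    meiosis_id = paste0("m", 1:10), parent_sex = "female", chrom = "chr1",
    left_pos = 3e5, right_pos = 4e5, pos = 3.5e5
  )
  maps <- manual_maps(ev, c(chr1 = 1e6))
  m <- maps$maps
  expect_equal(max(m$female_cm), 10)
  expect_equal(m$female_cm[m$pos == 3e5], 0)
  expect_equal(m$female_cm[m$pos == 4e5], 10)
  expect_equal(max(m$male_cm), 0)
  # additivity: total equals the sum of increments
  expect_equal(max(m$female_cm), sum(diff(m$female_cm)))
})

test_that("cumulative curves are monotone and respect one-sided landscapes", {
  ev <- rbind(uniform_events("chr1", 0, 1.5e6, 30, "female"),
              uniform_events("chr1", 1.5e6, 3e6, 30, "male"))
  maps <- manual_maps(ev, c(chr1 = 3e6))
  cc <- cumulative_curves(maps)
  expect_true(all(diff(cc$female_prop) >= 0))
  expect_true(all(diff(cc$male_prop) >= 0))
  expect_equal(max(cc$female_prop), 1)
  # female curve saturates at the midpoint, male is flat before it
  expect_equal(cc$female_prop[cc$pos == 1.5e6], 1)
  expect_equal(cc$male_prop[cc$pos == 1.5e6], 0)
  # a sex with no events is flagged undefined
  maps2 <- manual_maps(uniform_events("chr1", 0, 3e6, 10, "female"),
                       c(chr1 = 3e6))
  cc2 <- cumulative_curves(maps2)
  expect_true(all(is.na(cc2$male_prop)))
  expect_match(attr(cc2, "undefined"), "chr1:male")
})

test_that("window classification rules distinguish FRR, MRR, BR and NR", {
  # chr1: female-only first Mb (rate 2 cM/Mb), male-only second Mb
  ev <- rbind(uniform_events("chr1", 0, 1e6, 2, "female"),
              uniform_events("chr1", 1e6, 2e6, 2, "male"),
              # chr2: both sexes at 1 cM/Mb -> BR; no events later -> NR
              uniform_events("chr2", 0, 1e6, 2, "female"),
              uniform_events("chr2", 0, 1e6, 2, "male"))
  maps <- manual_maps(ev, c(chr1 = 2e6, chr2 = 4e6))
  cl <- classify_regions(maps, max_nr_gap = 0, refine = FALSE)
  c1 <- cl[cl$chrom == "chr1", ]
  expect_equal(c1$class[c1$start == 0], "FRR")
  expect_equal(c1$class[c1$end == 2e6], "MRR")
  c2 <- cl[cl$chrom == "chr2", ]
  expect_equal(c2$class[c2$start == 0], "BR")
  expect_equal(c2$class[c2$end == 4e6], "NR")
  # classification is idempotent/deterministic
  expect_identical(cl, classify_regions(maps, max_nr_gap = 0, refine = FALSE))
})

test_that("simulated landscapes are recovered from detected events", {
  cfg <- tiny_cfg(seed = 31, n_offspring = 90)
  g <- simulate_genome(cfg)
  pd <- simulate_pedigree(g$genome, cfg)
  ev <- detect_crossovers(pd$pedigree)
  maps <- build_sex_maps(ev, pd$pedigree)

  # per-sex totals within 3 binomial SDs of the simulated 49 cM
  for (ch in g$genome$chromosomes$chrom) {
    m <- maps$maps[maps$maps$chrom == ch, ]
    tol <- 3 * 100 * sqrt(90 * 0.49) / 90
    expect_lt(abs(max(m$female_cm) - 49), tol)
    expect_lt(abs(max(m$male_cm) - 49), tol)
  }

  # male map flat over the Y stratum
  sex <- g$genome$sex_chromosome
  ms <- maps$maps[maps$maps$chrom == sex, ]
  ystr <- g$genome$y_stratum
  expect_equal(max(ms$male_cm[ms$pos <= ystr[2]]), 0)

  # female curve flat after the stratum end, male flat before
  cc <- cumulative_curves(maps)
  cs <- cc[cc$chrom == sex, ]
  expect_equal(min(cs$female_prop[cs$pos >= ystr[2]]), 1)
  expect_equal(max(cs$male_prop[cs$pos <= ystr[2]]), 0)

  # exact recovery where truth events are well separated and interior
  spacing <- cfg$marker_spacing
  for (mid in sample(unique(pd$pedigree$meioses$meiosis_id), 40)) {
    for (ch in c("chr1", "chr2")) {
      tr <- sort(pd$crossovers$pos[pd$crossovers$meiosis_id == mid &
                                     pd$crossovers$chrom == ch])
      L <- g$genome$chromosomes$length[g$genome$chromosomes$chrom == ch]
      clean <- length(tr) == 0 ||
        (all(diff(c(0, tr, L)) > 3 * spacing))
      if (!clean) next
      det <- ev[ev$meiosis_id == mid & ev$chrom == ch, ]
      expect_equal(nrow(det), length(tr))
    }
  }
})

test_that("detected crossover count matches simulation without phase errors", {
  cfg <- tiny_cfg(seed = 33, missing_rate = 0, cm_per_sex = 5)
  g <- simulate_genome(cfg)
  pd <- simulate_pedigree(g$genome, cfg)
  ev <- detect_crossovers(pd$pedigree)
  # truth events within min_support markers of a chromosome end (or of each
  # other) are undetectable by construction; all others must be found
  spacing <- cfg$marker_spacing
  lens <- setNames(g$genome$chromosomes$length, g$genome$chromosomes$chrom)
  eligible <- 0L
  for (k in seq_len(nrow(pd$crossovers))) {
    x <- pd$crossovers[k, ]
    same <- pd$crossovers$pos[pd$crossovers$meiosis_id == x$meiosis_id &
                                pd$crossovers$chrom == x$chrom]
    near_other <- any(abs(same - x$pos) > 0 & abs(same - x$pos) <= 3 * spacing)
    near_end <- x$pos <= 3 * spacing || x$pos >= lens[[x$chrom]] - 3 * spacing
    if (!near_other && !near_end) eligible <- eligible + 1L
  }
  expect_gte(nrow(ev), eligible)
  expect_lte(nrow(ev), nrow(pd$crossovers))
})

test_that("region statistics compute ratios, totals and centromere coincidence", {
  # MRR a third of the FRR length with equal total cM -> rate ratio 3
  cl <- tibble::tibble(
    chrom = "chr1", start = c(0, 3e6), end = c(3e6, 4e6),
    class = c("FRR", "MRR"),
    female_cm = c(30, 0), male_cm = c(0, 30),
    length_mb = c(3, 1),
    female_rate = c(10, 0), male_rate = c(0, 30)
  )
  st <- region_rate_stats(cl, centromeres = tibble::tibble(chrom = "chr1",
                                                           pos = 1e6))
  expect_equal(st$per_chrom$rate_ratio, 3)
  expect_true(st$per_chrom$centromere_in_frr)
  expect_equal(sum(st$genome$pct), 100)
  expect_equal(st$genome$mb[st$genome$class == "FRR"], 3)

  # missing class leaves the ratio undefined
  st2 <- region_rate_stats(cl[1, ])
  expect_true(is.na(st2$per_chrom$rate_ratio))
})
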