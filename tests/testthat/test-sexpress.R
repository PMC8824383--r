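test_that("allele-ratio matrix applies coverage and retention rules", {
  ref <- rbind(s1 = c(10, 10, 0, 5), s2 = c(10, 0, 0, 5))
  ref <- t(ref); alt <- matrix(c(10, 0, 0, 0, 10, 0, 0, 0), 4, 2)
  rownames(ref) <- rownames(alt) <- paste0("chr13:", 1:4)
  colnames(ref) <- colnames(alt) <- c("s1", "s2")
  # snp1: both alleles seen; snp2 alt never seen -> dropped;
  # snp3 never covered -> dropped (no allele seen); snp4 alt never seen
  rm <- build_allele_ratio_matrix(ref, alt)
  expect_equal(rownames(rm), "chr13:1")
  expect_equal(unname(rm["chr13:1", ]), c(0.5, 0.5))
  # min_reads turns thin cells into missing
  rm2 <- build_allele_ratio_matrix(ref, alt, min_reads = 25)
  expect_true(all(is.na(rm2)))
  expect_warning(build_allele_ratio_matrix(ref, alt, snps = "chr13:99"),
                 "absent")
})

test_that("genetic sexing separates XX from XY and ignores ordering", {
  set.seed(2)
  n_snp <- 40
  xy <- vapply(1:4, function(i) rbinom(n_snp, 30, 0.5) / 30, numeric(n_snp))
  xx <- matrix(0, n_snp, 3)
  m <- cbind(xy, xx)
  dimnames(m) <- list(paste0("chr13:", seq_len(n_snp)),
                      c(paste0("m", 1:4), paste0("f", 1:3)))
  res <- assign_genetic_sex(m)
  expect_equal(unname(res$sexes[paste0("m", 1:4)]), rep("XY", 4))
  expect_equal(unname(res$sexes[paste0("f", 1:3)]), rep("XX", 3))
  expect_gt(res$confidence, 0.3)

  perm <- m[sample(nrow(m)), sample(ncol(m))]
  res2 <- assign_genetic_sex(perm)
  expect_equal(res2$sexes[names(res$sexes)], res$sexes)

  # two samples, one all-zero and one balanced
  m2 <- cbind(a = rep(0, 10), b = rep(0.5, 10))
  rownames(m2) <- paste0("chr13:", 1:10)
  r2 <- assign_genetic_sex(m2)
  expect_equal(unname(r2$sexes), c("XX", "XY"))

  expect_error(assign_genetic_sex(cbind(a = rep(0.5, 5), b = rep(0.5, 5))),
               "indistinguishable")
})

test_that("de_scan handles constant genes and is label-swap antisymmetric", {
  set.seed(3)
  counts <- rbind(
    flat = rep(100, 8),
    up = c(rep(400, 4), rep(100, 4)),
    matrix(rpois(40 * 8, 200), 40, 8, dimnames = list(paste0("g", 1:40), NULL))
  )
  colnames(counts) <- paste0("s", 1:8)
  labels <- setNames(rep(c("XY", "XX"), each = 4), colnames(counts))
  de <- de_scan(counts, labels, normalize = "none")
  flat <- de[de$gene == "flat", ]
  expect_equal(flat$log2_ratio, 0)
  expect_equal(flat$p, 1)
  expect_equal(de$gene[1], "up")

  swapped <- setNames(ifelse(labels == "XY", "XX", "XY"), names(labels))
  de2 <- de_scan(counts, swapped, normalize = "none")
  j <- match(de$gene, de2$gene)
  expect_equal(de2$log2_ratio[j], -de$log2_ratio)
  expect_equal(de2$p[j], de$p)

  # zero variance but different means: p collapses to the floor, not > 0.05
  expect_lt(de[de$gene == "up", ]$p, 1e-10)
  expect_error(de_scan(counts, setNames(c("XY", rep("XX", 7)), colnames(counts))),
               "two samples")
})

test_that("allelic imbalance requires full sign consistency", {
  xy <- paste0("m", 1:7)
  base <- matrix(10, 3, 7, dimnames = list(paste0("chr13:", 1:3), xy))
  ref <- base; alt <- base
  alt[1, ] <- 20              # Y-higher in all 7
  alt[2, ] <- c(rep(20, 6), 5) # 6 of 7 -> inconsistent
  alt[3, 1] <- 10              # tie in sample 1 -> not flagged
  alt[3, 2:7] <- 20
  res <- call_allelic_imbalance(ref, alt, xy)
  expect_true(res$imbalanced[res$snp == "chr13:1"])
  expect_equal(res$direction[res$snp == "chr13:1"], "Y-higher")
  expect_false(res$imbalanced[res$snp == "chr13:2"])
  expect_false(res$imbalanced[res$snp == "chr13:3"])

  # X-higher direction
  ref2 <- base; alt2 <- base; ref2[1, ] <- 30
  res2 <- call_allelic_imbalance(ref2, alt2, xy)
  expect_equal(res2$direction[res2$snp == "chr13:1"], "X-higher")

  # retained set shrinks as min_informative rises
  set.seed(4)
  refr <- matrix(rpois(50 * 7, 8), 50, 7,
                 dimnames = list(paste0("chr13:", 1:50), xy))
  altr <- matrix(rpois(50 * 7, 8), 50, 7, dimnames = dimnames(refr))
  n_at <- vapply(1:7, function(k) {
    nrow(call_allelic_imbalance(refr, altr, xy, min_informative = k))
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("spiked imbalanced SNPs are recovered with their directions at depth", {
  cfg <- tiny_cfg(seed = 21, expr_allele_depth = 500, expr_dropout = 0,
                  n_expr_snps = 40)
  g <- simulate_genome(cfg)
  p <- simulate_pools(g$genome, g$truth, cfg)
  e <- simulate_expression(p$truth, cfg)
  xy <- names(e$truth$sample_sexes)[e$truth$sample_sexes == "XY"]
  res <- call_allelic_imbalance(e$ref_counts, e$alt_counts, xy)
  hit <- merge(e$truth$imbalance, res, by = "snp")
  expect_equal(nrow(hit), nrow(e$truth$imbalance))
  expect_true(all(hit$imbalanced))
  expect_equal(hit$direction.y, hit$direction.x)
})

test_that("qPCR efficiency and ddCt calculations match their definitions", {
  expect_equal(qpcr_efficiency(-3.3219), 1, tolerance = 1e-4)
  expect_equal(qpcr_efficiency(-10), 10^0.1 - 1)
  # inverse identity: slope = -1/log10(1+E)
  E <- 0.924
  expect_equal(qpcr_efficiency(-1 / log10(1 + E)), E)
  expect_error(qpcr_efficiency(0), "nonzero")

  ct_t <- c(a = 25, b = 26, c = 23)
  ct_r <- c(a = 20, b = 20, c = 20)
  rel <- ddct_relative_expression(ct_t, ct_r)
  expect_equal(unname(rel["c"]), 1)       # lowest dCt is the calibrator
  expect_equal(unname(rel["a"]), 0.25)    # ddCt = 2
  expect_equal(unname(rel["b"]), 0.125)   # ddCt = 3
  expect_equal(unname(ddct_relative_expression(ct_t, ct_r,
                                               calibrator = "a")["a"]), 1)
  # ddCt = 1 -> 0.5; ddCt = -2 -> 4
  r2 <- ddct_relative_expression(c(x = 21, y = 20, z = 18),
                                 c(x = 10, y = 10, z = 10),
                                 calibrator = "y")
  expect_equal(unname(r2), c(0.5, 1, 4))
  # all equal dCt -> all 1
  expect_equal(unname(ddct_relative_expression(c(a = 22, b = 22),
                                               c(a = 20, b = 20))),
               c(1, 1))
  expect_warning(ddct_relative_expression(c(a = 25, b = 26), c(a = 20)),
                 "excluded")
})
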