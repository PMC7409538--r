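test_that("count_reads matches the quadratic oracle (any-overlap)", {
  set.seed(50)
  for (i in 1:30) {
    nf <- sample(2:8, 1)
    starts <- sort(sample(seq(0, 9000, by = 100), nf))
    feats <- gi("chr1", starts, starts + 80)
    feats$peak_id <- sprintf("p%d", seq_len(nf))
    rs <- sample.int(10000, 200, replace = TRUE)
    reads <- mk_reads("chr1", rs, rs + sample(10:60, 200, replace = TRUE))
    cm <- count_reads(feats, list(reads))
    expect_equal(unname(cm$counts[, 1]), oracle_count(feats, reads$reads))
  }
})

test_that("count_reads trivial and error cases", {
  feats <- gi("chr1", c(100, 300), c(200, 400))
  feats$peak_id <- c("a", "b")
  inside <- mk_reads("chr1", 150, 160)
  nowhere <- mk_reads("chr1", 250, 260)
  cm <- count_reads(feats, list(inside, nowhere))
  expect_equal(unname(cm$counts[, 1]), c(1, 0))
  expect_equal(unname(cm$counts[, 2]), c(0, 0))
  overlapping <- gi("chr1", c(100, 150), c(200, 250))
  overlapping$peak_id <- c("a", "b")
  expect_error(count_reads(overlapping, list(inside)), "disjoint")
})

test_that("exonic and strand-aware counting restrict correctly", {
  gs <- toy_genes()
  # gA: exons [2000,3000) and [4000,5000), strand +
  r_ex <- gi("chr1", c(2100, 4100, 3500), c(2200, 4200, 3600), "+")  # 2 exonic, 1 intronic
  r_anti <- gi("chr1", 2100, 2200, "-")
  rs <- read_set("s", "c", "A", "RNAseq", rbind(r_ex, r_anti))
  both <- count_reads(gs, list(rs), mode = "exonic", strand = "both")
  sense <- count_reads(gs, list(rs), mode = "exonic", strand = "sense")
  anti <- count_reads(gs, list(rs), mode = "exonic", strand = "antisense")
  expect_equal(both$counts["gA", 1], 3)
  expect_equal(sense$counts["gA", 1], 2)
  expect_equal(anti$counts["gA", 1], 1)
})

test_that("median-of-ratios size factors match the worked example", {
  counts <- matrix(c(10, 30, 50, 20, 60, 100), ncol = 2,
                   dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  cm <- count_matrix(counts, data.frame(sample_id = c("s1", "s2"),
                                        condition = c("a", "b"),
                                        replicate = c("A", "A")))
  cm <- size_factors(cm)
  expect_equal(unname(cm$size_factors), c(1 / sqrt(2), sqrt(2)))
  # identical columns -> all ones; single sample -> 1
  cm2 <- count_matrix(cbind(s1 = c(5L, 7L), s2 = c(5L, 7L)),
                      data.frame(sample_id = c("s1", "s2"),
                                 condition = c("a", "b"), replicate = "A"))
  expect_equal(unname(size_factors(cm2)$size_factors), c(1, 1))
  cm3 <- count_matrix(matrix(1:3, dimnames = list(NULL, "s1")),
                      data.frame(sample_id = "s1", condition = "a",
                                 replicate = "A"))
  expect_equal(unname(size_factors(cm3)$size_factors), 1)
  # no all-positive feature -> warned fallback to total-count
  cm4 <- count_matrix(cbind(s1 = c(0L, 8L), s2 = c(4L, 0L)),
                      data.frame(sample_id = c("s1", "s2"),
                                 condition = c("a", "b"), replicate = "A"))
  expect_warning(sf <- size_factors(cm4), "total-count")
  expect_equal(unname(sf$size_factors), c(1, 1) * c(8, 4) / exp(mean(log(c(8, 4)))),
               tolerance = 1e-12)
  # scaling one sample by c multiplies its factor by c
  cm5 <- count_matrix(counts * matrix(c(1, 3), 3, 2, byrow = TRUE),
                      cm$samples)
  sf5 <- size_factors(cm5)$size_factors
  expect_equal(unname(sf5[2] / sf5[1]), 3 * sqrt(2) * sqrt(2), tolerance = 1e-9)
})

test_that("dispersion estimation: floor, Poisson consistency, NB recovery", {
  # constant counts -> zero variance -> floor
  cmc <- count_matrix(matrix(100L, 5, 4, dimnames = list(letters[1:5], paste0("s", 1:4))),
                      data.frame(sample_id = paste0("s", 1:4),
                                 condition = rep(c("a", "b"), each = 2),
                                 replicate = as.character(c(1, 2, 1, 2))))
  cmc <- size_factors(cmc)
  a <- estimate_dispersion(cmc, w = 1)
  expect_true(all(a <= 1e-7))
  set.seed(60)
  cmp <- size_factors(nb_counts(2000, mu = 100, alpha = 0))
  ap <- estimate_dispersion(cmp)
  expect_lte(median(ap), 0.01)
  cmn <- size_factors(nb_counts(2000, mu = 100, alpha = 0.2, n_per_group = 3))
  an <- estimate_dispersion(cmn)
  expect_gte(median(an), 0.1)
  expect_lte(median(an), 0.4)
})

test_that("wald_test trivial and degenerate cases", {
  cm <- size_factors(count_matrix(
    matrix(c(10L, 0L, 10L, 0L, 10L, 0L, 10L, 0L), 2, 4,
           dimnames = list(c("same", "zero"), paste0("s", 1:4))),
    data.frame(sample_id = paste0("s", 1:4),
               condition = rep(c("ctl", "trt"), each = 2),
               replicate = as.character(c(1, 2, 1, 2)))))
  res <- wald_test(cm, contrast_spec("trt", "ctl"), alpha = 0.05)
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$p, c(1, 1))
  expect_error(wald_test(cm, contrast_spec("missing", "ctl"), 0.05),
               "not present")
})

test_that("wald_test recovers a planted log2FC = 2 with small bias", {
  set.seed(61)
  lfc <- c(rep(2, 200), rep(0, 1800))
  cm <- size_factors(nb_counts(2000, mu = 100, alpha = 0.05, lfc = lfc))
  res <- wald_test(cm, contrast_spec("trt", "ctl"), alpha = 0.05)
  expect_lt(abs(mean(res$log2fc[1:200]) - 2), 0.15)
})

test_that("bh_fdr matches hand computation and the literal-definition oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.007), 0.007)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(62)
  for (i in 1:50) {
    p <- round(runif(sample(1:30, 1)), 3)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("classification applies the |log2FC| > 1, FDR < 0.1 rule", {
  res <- data.frame(id = c("a", "b", "c", "d"),
                    log2fc = c(1.5, 0.5, -2.0, -1.2),
                    q = c(0.05, 0.01, 0.2, 0.09))
  out <- classify_differential(res, contrast_spec("t", "c"))
  expect_equal(out$class, c("gain", "unchanged", "unchanged", "loss"))
})

test_that("null NB simulation has controlled error rates", {
  set.seed(63)
  cm <- size_factors(nb_counts(2000, mu = 100, alpha = 0.05))
  res <- differential_test(cm, contrast_spec("trt", "ctl"))
  expect_lte(mean(res$q < 0.1), 0.01)
  expect_gte(mean(res$p < 0.05), 0.03)
  expect_lte(mean(res$p < 0.05), 0.08)
})
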