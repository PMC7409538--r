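test_that("feature_distribution percentages behave", {
  fd <- feature_distribution(c("intron", "intron", "intron"))
  expect_equal(fd$percent[fd$category == "intron"], 100)
  expect_equal(sum(fd$percent), 100, tolerance = 1e-9)
  fd2 <- feature_distribution(c("promoter-TSS", "promoter-TSS", "TTS", "TTS"))
  expect_equal(fd2$percent[fd2$category == "promoter-TSS"], 50)
  expect_warning(fd3 <- feature_distribution(character(0)), "empty")
  expect_true(all(fd3$count == 0))
  set.seed(70)
  for (i in 1:20) {
    cats <- sample(feature_categories(), sample(2:50, 1), replace = TRUE)
    expect_equal(sum(feature_distribution(cats)$percent), 100, tolerance = 1e-9)
  }
})

test_that("welch_t matches stats::t.test and handles ties", {
  set.seed(71)
  for (i in 1:100) {
    x <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    got <- welch_t(x, y)
    want <- t.test(x, y)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(want$parameter), tolerance = 1e-12)
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
  }
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
})

test_that("distance_tests detects planted proximity differences", {
  set.seed(72)
  annot <- data.frame(
    peak_id = sprintf("p%03d", 1:60),
    neighbor_distance = c(abs(rnorm(20, 500, 100)), abs(rnorm(40, 5000, 1000))),
    class = c(rep("gain", 20), rep("unchanged", 40)))
  out <- distance_tests(annot)
  expect_lt(out$tests$p[out$tests$comparison == "gain-vs-unchanged"], 0.01)
  expect_lt(out$tests$t[1], 0) # gains nearer
  one <- annot; one$class[1:20] <- "unchanged"; one$class[1] <- "loss"
  expect_warning(distance_tests(one), "skipped")
})

test_that("chromosome_density_ratio handles zero classes and sentinels", {
  annot <- data.frame(
    peak_id = paste0("p", 1:7),
    chrom = c(rep("chr1", 4), rep("chr2", 2), "chr3"),
    neighbor_distance = c(100, 200, 300, 400, 5000, 6000, 700),
    class = c("gain", "gain", "unchanged", "unchanged", "unchanged",
              "unchanged", "gain"))
  out <- chromosome_density_ratio(annot)
  expect_equal(out$gain_ratio[out$chrom == "chr1"], 1)
  expect_equal(out$gain_ratio[out$chrom == "chr2"], 0)  # zero gains
  expect_true(is.na(out$gain_ratio[out$chrom == "chr3"])) # zero unchanged
})

test_that("overlap_fisher matches exact enumeration", {
  # N=10, |A|=5, |B|=4, overlap 4 -> p = C(5,4) C(5,0) / C(10,4) = 1/42
  u <- sprintf("x%02d", 1:10)
  got <- overlap_fisher(u[1:5], u[2:5], u)
  expect_equal(got$p, 5 / choose(10, 4), tolerance = 1e-12)
  expect_equal(got$n_overlap, 4)
  # A = B = universe -> p = 1
  expect_equal(overlap_fisher(u, u, u)$p, 1)
  expect_error(overlap_fisher(c("zz"), u[1], u), "subsets")
  set.seed(73)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    uu <- sprintf("e%03d", seq_len(N))
    a <- sample(uu, sample.int(N, 1))
    b <- sample(uu, sample.int(N, 1))
    got <- overlap_fisher(a, b, uu)
    want <- oracle_hyper(N, length(a), length(b), got$n_overlap)
    expect_equal(got$p, min(1, want), tolerance = 1e-10)
  }
})

test_that("overlap_fisher p decreases as overlap grows at fixed margins", {
  u <- sprintf("u%03d", 1:100)
  ps <- vapply(0:20, function(k) {
    a <- u[1:30]
    b <- c(u[seq_len(k)], u[31:(50 - k)])
    overlap_fisher(a, b, u)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("tss_tts_split reflects construction", {
  annot <- data.frame(peak_id = paste0("p", 1:10),
                      nearer_end = c(rep("TSS", 7), rep("TTS", 3)))
  out <- tss_tts_split(annot, list(all = annot$peak_id,
                                   tts_only = paste0("p", 8:10)))
  expect_equal(out$tss_fraction[out$subset == "all"], 0.7)
  expect_equal(out$tts_fraction[out$subset == "tts_only"], 1)
})

test_that("gc_cpg_profile computes GC% and CpG% per definition", {
  asm <- genome_assembly(c(chr1 = 12), sequence = c(chr1 = "GCGCACGTAAAA"))
  p1 <- gi("chr1", 0, 4)   # GCGC
  p2 <- gi("chr1", 4, 8)   # ACGT
  out <- gc_cpg_profile(rbind(p1, p2), asm, flank = 2)
  expect_equal(out$per_peak$gc_percent, c(100, 50))
  # ACGT: one CG among 3 dinucleotides
  expect_equal(out$per_peak$cpg_percent[2], 100 / 3)
  expect_error(gc_cpg_profile(p1, genome_assembly(c(chr1 = 12))), "sequence")
})

test_that("peaks in GC-rich promoters show the planted GC contrast", {
  cfg <- sim_config(seed = 74, chrom_length = 4e5, n_genes = 30, n_peaks = 12,
                    peak_mix = c(TSS = 0.5, TTS = 0, intron = 0,
                                 intergenic = 0.5),
                    peak_length = 600, n_gain = 0, n_loss = 0, n_antisense = 0)
  gen <- simulate_genome(cfg)
  tr <- driploop:::plant_peaks(gen$assembly, gen$genes, cfg)
  prof <- gc_cpg_profile(tr$peaks, gen$assembly, flank = 500)
  tss_gc <- prof$per_peak$gc_percent[tr$peaks$class == "TSS"]
  bg_gc <- prof$per_peak$gc_percent[tr$peaks$class == "intergenic"]
  # promoter GC 0.6 vs background 0.4, peak center at the TSS (half the
  # 600-bp peak inside the 1.1-kb promoter window): expect a clear gap
  expect_gt(mean(tss_gc) - mean(bg_gc), 8)
})

test_that("metagene profile is flat for uniform coverage and localizes TTS reads", {
  gs <- toy_genes()
  set.seed(75)
  s <- sort(sample.int(19900, 4000))
  uni <- mk_reads("chr1", s, s + 50)
  prof <- metagene_profile(list(uni), gs, mode = "all")
  body <- prof[prof$region == "body", "c1"]
  expect_lt(stats::sd(body) / mean(body), 0.8)
  # reads only at gA's TTS (gene end, + strand) -> peak at right body edge
  tts <- mk_reads("chr1", rep(4950, 50), rep(4990, 50), sample_id = "s2",
                  condition = "c2")
  prof2 <- metagene_profile(list(tts), gs, mode = "all")
  expect_equal(which.max(prof2$c2), max(which(prof2$region == "body")))
  # subtracting a condition from itself zeroes the profile
  prof3 <- metagene_profile(list(uni), gs, mode = "all", subtract = "c1")
  expect_true(all(prof3$c1 == 0))
})

test_that("metagene intergenic mode drops gene-body reads", {
  gs <- toy_genes()
  inside <- mk_reads("chr1", 2500, 2560)
  outside <- mk_reads("chr1", 6000, 6060)
  prof_in <- metagene_profile(list(inside), gs, mode = "intergenic")
  expect_equal(sum(prof_in$c1), 0)
  prof_out <- metagene_profile(list(outside), gs, mode = "intergenic")
  expect_gt(sum(prof_out$c1), 0)
})

test_that("sample_qc: correlation oracle, duplicated sample, PCA variance", {
  counts <- matrix(c(5L, 10L, 80L, 20L, 7L, 12L, 90L, 25L, 50L, 60L, 10L, 70L),
                   nrow = 4,
                   dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  cm <- count_matrix(counts, data.frame(sample_id = paste0("s", 1:3),
                                        condition = c("a", "a", "b"),
                                        replicate = c("1", "2", "1")))
  qc <- sample_qc(cm)
  y <- log2(normalized_counts(size_factors(cm)) + 1)
  expect_equal(qc$correlation[1, 2], oracle_pearson(y[, 1], y[, 2]),
               tolerance = 1e-12)
  # duplicated sample correlates at 1
  counts2 <- cbind(counts, s4 = counts[, 3])
  cm2 <- count_matrix(counts2, data.frame(sample_id = c(paste0("s", 1:3), "s4"),
                                          condition = c("a", "a", "b", "b"),
                                          replicate = c("1", "2", "1", "2")))
  qc2 <- sample_qc(cm2)
  expect_equal(qc2$correlation["s3", "s4"], 1)
  expect_true(sum(qc2$var_explained[1:2]) >= max(qc2$var_explained[-(1:2)], 0))
})
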