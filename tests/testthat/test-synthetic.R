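# The generator's defaults are the stated study design; these tests run it at
# reduced scale (shorter chromosome, fewer genes/peaks) for speed and check
# determinism, planted-signal calibration and truth serialization.

small_cfg <- function(seed = 2, ...) {
  sim_config(seed = seed, chrom_length = 5e5, n_genes = 25, n_peaks = 12,
             n_gain = 4, n_loss = 1, n_antisense = 3, rnaseq_depth = 2e4, ...)
}

test_that("identical config and seed give bit-identical outputs; seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  write_simulation(simulate_all(small_cfg(seed = 2)), d1)
  write_simulation(simulate_all(small_cfg(seed = 2)), d2)
  write_simulation(simulate_all(small_cfg(seed = 3)), d3)
  files <- setdiff(list.files(d1, recursive = TRUE), "manifest.json")
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  expect_false(identical(unname(tools::md5sum(file.path(d1, "reads/siCTL_A.bed"))),
                         unname(tools::md5sum(file.path(d3, "reads/siCTL_A.bed")))))
})

test_that("promoter windows hit the target GC within 3 binomial SEs", {
  cfg <- small_cfg(seed = 4, n_genes = 40)
  gen <- simulate_genome(cfg)
  g <- gen$genes$genes
  n_bp <- 0; n_gc <- 0
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") { s <- g$tss[i] - 1000; e <- g$tss[i] + 100 }
    else { s <- g$tss[i] - 99; e <- g$tss[i] + 1001 }
    sq <- Biostrings::subseq(gen$assembly$sequence[[g$chrom[i]]], s + 1, e)
    n_gc <- n_gc + sum(Biostrings::letterFrequency(sq, c("C", "G")))
    n_bp <- n_bp + (e - s)
  }
  se <- sqrt(0.6 * 0.4 / n_bp)
  expect_lt(abs(n_gc / n_bp - cfg$promoter_gc), 3 * se)
  # promoter CpG rate roughly double the i.i.d. background rate
  bg_rate <- cfg$background_gc^2 / 4
  prom_cpg <- mean(vapply(seq_len(min(nrow(g), 20)), function(i) {
    if (g$strand[i] == "+") { s <- g$tss[i] - 1000; e <- g$tss[i] + 100 }
    else { s <- g$tss[i] - 99; e <- g$tss[i] + 1001 }
    sq <- Biostrings::subseq(gen$assembly$sequence[[g$chrom[i]]], s + 1, e)
    Biostrings::countPattern("CG", sq) / (e - s - 1)
  }, numeric(1)))
  expect_gt(prom_cpg, 1.5 * cfg$promoter_gc^2 / 4)
})

test_that("planted DRIP peak counts match Poisson-gamma expectations", {
  # expectation: background 0.01 reads/bp, enrichment 8 => 2-kb peak ~ 160
  # reads in a control IP; average over seeds to beat replicate overdispersion
  obs <- vapply(1:6, function(s) {
    cfg <- small_cfg(seed = 10 + s, n_peaks = 6, n_gain = 0, n_loss = 0,
                     n_antisense = 0)
    gen <- simulate_genome(cfg)
    dr <- simulate_drip_reads(gen$assembly, gen$genes, cfg)
    pk <- dr$truth$peaks
    mean(oracle_count(pk, dr$read_sets[["siCTL_A"]]$reads))
  }, numeric(1))
  expected <- 0.01 * 2000 * 8
  tol <- 4 * sqrt(expected * (1 + 0.05 * expected) / (6 * 6))
  expect_lt(abs(mean(obs) - expected), tol)
})

test_that("RNase-H control retains ~rho of peak signal and input has none", {
  cfg <- small_cfg(seed = 21, n_peaks = 8, n_gain = 0, n_loss = 0,
                   n_antisense = 0)
  gen <- simulate_genome(cfg)
  dr <- simulate_drip_reads(gen$assembly, gen$genes, cfg)
  pk <- dr$truth$peaks
  rh <- mean(oracle_count(pk, dr$read_sets[["rnaseh"]]$reads))
  bg <- 0.01 * 2000
  sig <- 0.01 * 2000 * 7          # (enrichment - 1) x background
  expect_lt(abs(rh - (bg + 0.05 * sig)), 4 * sqrt(bg + 0.05 * sig))
  inp <- mean(oracle_count(pk, dr$read_sets[["input"]]$reads))
  expect_lt(abs(inp - bg), 4 * sqrt(bg))
})

test_that("zero rates produce empty read sets", {
  cfg <- small_cfg(seed = 5, background_rate = 0, input_rate = 0, n_peaks = 0,
                   n_gain = 0, n_loss = 0, n_antisense = 0, make_sequence = FALSE)
  gen <- simulate_genome(cfg)
  dr <- simulate_drip_reads(gen$assembly, gen$genes, cfg)
  expect_true(all(vapply(dr$read_sets, function(x) x$library_size, numeric(1)) == 0))
})

test_that("RNA-seq gene counts scale with expression and antisense reads are
           on the opposite strand", {
  cfg <- small_cfg(seed = 6, n_de_genes = 0)
  sim <- simulate_all(cfg)
  g <- sim$genes$genes
  expr <- sim$truth$expression
  cm <- count_reads(sim$genes, sim$rnaseq[1:3], mode = "exonic", strand = "sense")
  exlen <- tapply(sim$genes$exons$end - sim$genes$exons$start,
                  sim$genes$exons$gene_id, sum)[g$gene_id]
  w <- expr[g$gene_id] * as.numeric(exlen)
  counts <- rowMeans(cm$counts)
  # strong rank agreement between configured weights and realized counts
  expect_gt(cor(w, counts, method = "spearman"), 0.95)
  # antisense loci: reads within the planted window in the planted condition
  # are predominantly on the strand opposite the gene
  anti <- sim$truth$antisense
  win <- driploop:::antisense_truth_windows(anti, sim$genes)
  kd_reads <- do.call(rbind, lapply(
    Filter(function(x) x$condition == anti$condition[1], sim$rnaseq),
    function(x) x$reads))
  for (i in seq_len(nrow(win))) {
    gstrand <- g$strand[g$gene_id == win$gene_id[i]]
    hit <- kd_reads[kd_reads$chrom == win$chrom[i] &
                      kd_reads$start < win$end[i] &
                      kd_reads$end > win$start[i], ]
    expect_gt(mean(hit$strand != gstrand), 0.75)
  }
})

test_that("truth table round-trips losslessly through the directory format", {
  d <- withr::local_tempdir()
  sim <- simulate_all(small_cfg(seed = 8))
  write_simulation(sim, d)
  back <- read_simulation(d)
  expect_equal(back$truth$peaks$start, sim$truth$peaks$start)
  expect_equal(back$truth$lfc, sim$truth$lfc)
  expect_equal(back$truth$antisense$gene_id, sim$truth$antisense$gene_id)
  expect_equal(back$config$seed, sim$config$seed)
  expect_equal(back$drip[["siCTL_A"]]$library_size,
               sim$drip[["siCTL_A"]]$library_size)
})

test_that("impossible gene placement raises a helpful error", {
  cfg <- small_cfg(seed = 9, chrom_length = 5e4, n_genes = 100)
  expect_error(simulate_genome(cfg), "reduce n_genes")
})
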