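drip_fixture <- function(seed = 30, ...) {
  cfg <- sim_config(seed = seed, chrom_length = 1e6, n_genes = 40, n_peaks = 10,
                    n_gain = 3, n_loss = 1, n_antisense = 0,
                    make_sequence = FALSE, ...)
  gen <- simulate_genome(cfg)
  dr <- simulate_drip_reads(gen$assembly, gen$genes, cfg)
  list(cfg = cfg, assembly = gen$assembly, genes = gen$genes,
       truth = dr$truth, rs = dr$read_sets)
}

test_that("null IP (rate identical to input) yields no peaks", {
  fx <- drip_fixture(seed = 31, n_peaks = 0, n_gain = 0, n_loss = 0)
  pk <- call_broad_peaks(fx$rs[["siCTL_A"]], fx$rs[["input"]], fx$assembly)
  expect_lte(sum(pk$end - pk$start), 0.001 * sum(fx$assembly$chrom_lengths))
  expect_lte(nrow(pk), 2)
})

test_that("a single 2-kb region at 10x background yields one covering peak", {
  fx <- drip_fixture(seed = 32, n_peaks = 1, peak_enrichment = 10,
                     nb_dispersion = 0, n_gain = 0, n_loss = 0,
                     peak_mix = c(TSS = 0, TTS = 0, intron = 0, intergenic = 1))
  pk <- call_broad_peaks(fx$rs[["siCTL_A"]], fx$rs[["input"]], fx$assembly)
  tr <- fx$truth$peaks
  expect_equal(nrow(pk), 1)
  cov <- sum(pmax(0, pmin(pk$end, tr$end) - pmax(pk$start, tr$start)))
  expect_gte(cov / (tr$end - tr$start), 0.8)
  expect_true(all(pk$qvalue < 0.1))
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
})

test_that("simulator peaks (with replicate overdispersion) are all recovered", {
  fx <- drip_fixture(seed = 32)
  pk <- call_broad_peaks(fx$rs[["siCTL_A"]], fx$rs[["input"]], fx$assembly)
  tr <- fx$truth$peaks
  for (i in seq_len(nrow(tr))) {
    cov <- sum(pmax(0, pmin(pk$end, tr$end[i]) - pmax(pk$start, tr$start[i])))
    expect_gte(cov / (tr$end[i] - tr$start[i]), 0.5)
  }
})

test_that("empty IP yields no peaks; empty input errors", {
  fx <- drip_fixture(seed = 33, n_peaks = 0)
  empty_ip <- mk_reads(character(0), numeric(0), numeric(0))
  expect_equal(nrow(call_broad_peaks(empty_ip, fx$rs[["input"]], fx$assembly)), 0)
  expect_error(call_broad_peaks(fx$rs[["siCTL_A"]], empty_ip, fx$assembly),
               "input library")
})

test_that("consensus construction: support, merging, min_support, idempotence", {
  p1 <- data.frame(chrom = "chr1", start = 100, end = 300, sample_id = "s1")
  p2 <- data.frame(chrom = "chr1", start = 100, end = 300, sample_id = "s2")
  cons <- build_consensus(list(p1, p2))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$support, 2)
  # two non-overlapping peaks in different samples
  p3 <- data.frame(chrom = "chr1", start = 1000, end = 1200, sample_id = "s2")
  cons2 <- build_consensus(list(p1, p3))
  expect_equal(nrow(cons2), 2)
  expect_equal(cons2$support, c(1, 1))
  expect_equal(nrow(build_consensus(list(p1, p3), min_support = 2)), 0)
  # chained overlaps A-B, B-C merge transitively with support {A,B,C}
  pa <- data.frame(chrom = "chr1", start = 0, end = 100, sample_id = "A")
  pb <- data.frame(chrom = "chr1", start = 50, end = 150, sample_id = "B")
  pc <- data.frame(chrom = "chr1", start = 120, end = 220, sample_id = "C")
  cons3 <- build_consensus(list(pa, pb, pc))
  expect_equal(nrow(cons3), 1)
  expect_equal(cons3$support, 3)
  expect_equal(cons3$samples, "A,B,C")
  # rebuilding from its own output is identity
  again <- build_consensus(list(cbind(cons3[, c("chrom", "start", "end")],
                                      sample_id = "x")))
  expect_equal(again[, c("chrom", "start", "end")],
               cons3[, c("chrom", "start", "end")])
})

test_that("RNase-H sensitivity flags simulator peaks as hybrids", {
  fx <- drip_fixture(seed = 34)
  pk <- fx$truth$peaks
  pk$peak_id <- pk$peak
  out <- rnaseh_sensitivity(pk, fx$rs[["siCTL_A"]], fx$rs[["rnaseh"]])
  expect_gte(mean(out$hybrid), 0.95)
  # rnaseh rate equal to ip rate -> ratio ~ 1 -> not hybrid
  same <- rnaseh_sensitivity(pk, fx$rs[["siCTL_A"]], fx$rs[["siCTL_B"]])
  expect_true(all(!same$hybrid))
  # zero rnaseh reads inside peaks (comparable library) -> ratio ~ 0 -> hybrid
  far <- mk_reads("chr1", seq(1, 5000, by = 1), seq(2, 5001, by = 1),
                  assay = "DRIP-RNaseH")
  stopifnot(!any(pk$start < 5100)) # fixture peaks lie beyond the decoy reads
  none <- rnaseh_sensitivity(pk, fx$rs[["siCTL_A"]], far)
  expect_true(all(none$hybrid))
})
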