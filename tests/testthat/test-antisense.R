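test_that("intergenic mask complements gene bodies exactly", {
  asm <- tiny_assembly()
  gs <- toy_genes()
  mask <- intergenic_mask(asm, gs)
  # mask + gene union tile the genome disjointly
  bodies <- merge_intervals(gi(gs$genes$chrom, gs$genes$start, gs$genes$end))
  tot <- sum(mask$end - mask$start) + sum(bodies$end - bodies$start)
  expect_equal(tot, sum(asm$chrom_lengths))
  both <- rbind(mask[, c("chrom", "start", "end")],
                bodies[, c("chrom", "start", "end")])
  expect_equal(sum(merge_intervals(both)$end - merge_intervals(both)$start), tot)
  # no genes -> whole genome; gene covering everything -> empty
  empty_gs <- gene_set(data.frame(gene_id = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  strand = character()),
                       data.frame(gene_id = character(), start = numeric(),
                                  end = numeric()))
  m0 <- intergenic_mask(asm, empty_gs)
  expect_equal(sum(m0$end - m0$start), sum(asm$chrom_lengths))
  full_gs <- gene_set(data.frame(gene_id = "g", chrom = "chr1", start = 0,
                                 end = 2e4, strand = "+"),
                      data.frame(gene_id = "g", start = 0, end = 2e4))
  expect_equal(nrow(intergenic_mask(asm, full_gs)), 0)
})

test_that("mask vs per-base oracle on random fixtures", {
  set.seed(80)
  asm <- tiny_assembly(c(chr1 = 5000))
  for (i in 1:20) {
    gs <- random_gene_set(sample(1:6, 1), chrom_len = 5000)
    mask <- intergenic_mask(asm, gs)
    covered <- rep(FALSE, 5000)
    for (j in seq_len(nrow(gs$genes))) {
      covered[(gs$genes$start[j] + 1):gs$genes$end[j]] <- TRUE
    }
    in_mask <- rep(FALSE, 5000)
    for (j in seq_len(nrow(mask))) in_mask[(mask$start[j] + 1):mask$end[j]] <- TRUE
    expect_equal(in_mask, !covered)
  }
})

test_that("flank window coordinates follow strand and masking", {
  # + strand gene at [10000, 13000) with empty upstream: TSS-upstream full
  # window [5000, 10000), adjacent [8000, 10000)
  asm <- tiny_assembly(c(chr1 = 4e4))
  g1 <- gene_set(data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                            end = 13000, strand = "+"),
                 data.frame(gene_id = "g1", start = 10000, end = 13000))
  mask <- intergenic_mask(asm, g1)
  ann <- data.frame(peak_id = "pk1", chrom = "chr1", start = 9500, end = 10500,
                    nearest_gene = "g1")
  win <- make_flank_windows(ann, g1, mask)
  up_full <- win[win$side == "TSS-upstream" & win$kind == "full", ]
  expect_equal(up_full$start, 5000); expect_equal(up_full$end, 10000)
  up_adj <- win[win$side == "TSS-upstream" & win$kind == "adjacent", ]
  expect_equal(up_adj$start, 8000); expect_equal(up_adj$end, 10000)
  dn_full <- win[win$side == "TTS-downstream" & win$kind == "full", ]
  expect_equal(dn_full$start, 13000); expect_equal(dn_full$end, 18000)

  # neighboring gene at [7000, 9000) cuts the full window to two pieces
  g2 <- gene_set(rbind(g1$genes[, names(g1$genes)],
                       within(g1$genes, { gene_id <- "g0"; start <- 7000
                       end <- 9000; tss <- 7000; tts <- 8999 })),
                 rbind(g1$exons, data.frame(gene_id = "g0", start = 7000,
                                            end = 9000)))
  mask2 <- intergenic_mask(asm, g2)
  win2 <- make_flank_windows(ann, g2, mask2)
  up2 <- win2[win2$side == "TSS-upstream" & win2$kind == "full", ]
  expect_equal(sort(up2$start), c(5000, 9000))
  expect_equal(sort(up2$end), c(7000, 10000))

  # - strand gene: upstream lies to the right of the gene
  g3 <- gene_set(data.frame(gene_id = "g3", chrom = "chr1", start = 10000,
                            end = 13000, strand = "-"),
                 data.frame(gene_id = "g3", start = 10000, end = 13000))
  ann3 <- data.frame(peak_id = "pk1", chrom = "chr1", start = 12800,
                     end = 13400, nearest_gene = "g3")
  win3 <- make_flank_windows(ann3, g3, intergenic_mask(asm, g3))
  up3 <- win3[win3$side == "TSS-upstream" & win3$kind == "full", ]
  expect_equal(up3$start, 13000); expect_equal(up3$end, 18000)
  # windows never overlap gene bodies
  for (w in list(win, win2, win3)) {
    expect_true(all(w$end <= 10000 | w$start >= 13000 | w$start >= w$end))
  }
})

test_that("four antisense thresholds gate hits as published", {
  base <- data.frame(window_id = "g1|TSS-upstream", gene_id = "g1",
                     side = "TSS-upstream", peak_id = "pk1", peak_distance = 0,
                     log2fc_full = 1, log2fc_adjacent = 0.8, q_adjacent = 0.2,
                     treat_mean_adjacent = 20, antisense_read_fraction = 0.9,
                     n_treat_reads = 40, stringsAsFactors = FALSE)
  peak_ok <- data.frame(id = "pk1", log2fc = 1.2, q = 0.05)
  gene_ok <- data.frame(id = "g1", log2fc = 0.3, q = 0.5)
  hit <- call_antisense_hits(base, peak_ok, gene_ok)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$orientation, "antisense")
  # (2) gene lfc 2.5 -> rejected
  gene_up <- within(gene_ok, log2fc <- 2.5)
  expect_equal(nrow(call_antisense_hits(base, peak_ok, gene_up)), 0)
  # (1) window lfc negative -> rejected
  neg <- within(base, log2fc_adjacent <- -0.2)
  expect_equal(nrow(call_antisense_hits(neg, peak_ok, gene_ok)), 0)
  # (3) peak lfc below 1 -> rejected
  weak <- within(peak_ok, log2fc <- 0.8)
  expect_equal(nrow(call_antisense_hits(base, weak, gene_ok)), 0)
  # (4) peak q above 0.1 -> rejected
  insig <- within(peak_ok, q <- 0.2)
  expect_equal(nrow(call_antisense_hits(base, insig, gene_ok)), 0)
  # min_mean filter
  low <- within(base, treat_mean_adjacent <- 2)
  expect_equal(nrow(call_antisense_hits(low, peak_ok, gene_ok)), 0)
  # strict gene mode rejects significant up-regulation below the literal cutoff
  gene_sig <- data.frame(id = "g1", log2fc = 1.5, q = 0.01)
  expect_equal(nrow(call_antisense_hits(base, peak_ok, gene_sig)), 1)
  expect_equal(nrow(call_antisense_hits(base, peak_ok, gene_sig,
                                        strict_gene = TRUE)), 0)
})

test_that("orientation classification follows the strand-purity rule", {
  expect_equal(orient_transcription("TSS-upstream", 1, 10), "antisense")
  expect_equal(orient_transcription("TTS-downstream", 0, 10), "sense-readthrough")
  expect_equal(orient_transcription("TSS-upstream", 0.5, 10), "ambiguous")
  expect_equal(orient_transcription("TTS-downstream", 0.5, 10), "ambiguous")
  expect_equal(orient_transcription("TSS-upstream", 0.75, 10), "antisense")
  expect_warning(out <- orient_transcription("TSS-upstream", NA, 0), "zero")
  expect_equal(out, "ambiguous")
})

test_that("intergenic_diff recovers a planted antisense fold change", {
  cfg <- sim_config(seed = 81, chrom_length = 1e6, n_genes = 40, n_peaks = 12,
                    conditions = c("siCTL", "siDDX5"), n_gain = 6, n_loss = 0,
                    n_antisense = 4, rnaseq_depth = 5e4, make_sequence = FALSE)
  sim <- simulate_all(cfg)
  mask <- intergenic_mask(sim$assembly, sim$genes)
  anti <- sim$truth$antisense
  g <- sim$genes$genes
  ann <- data.frame(peak_id = paste0("tp", seq_len(nrow(anti))),
                    chrom = g$chrom[match(anti$gene_id, g$gene_id)],
                    start = g$tss[match(anti$gene_id, g$gene_id)] - 100,
                    end = g$tss[match(anti$gene_id, g$gene_id)] + 100,
                    nearest_gene = anti$gene_id)
  win <- make_flank_windows(ann, sim$genes, mask)
  gcm <- size_factors(count_reads(sim$genes, sim$rnaseq, mode = "exonic",
                                  strand = "sense"))
  wt <- intergenic_diff(win, sim$rnaseq, contrast_spec("siDDX5", "siCTL"),
                        gcm$size_factors, sim$genes, mask)
  up <- wt[wt$side == "TSS-upstream", ]
  expect_true(all(up$log2fc_adjacent > 0))
  expect_true(all(up$antisense_read_fraction >= 0.75))
  # unstranded reads are rejected
  bad <- sim$rnaseq
  bad[[1]]$reads$strand <- "."
  expect_error(intergenic_diff(win, bad, contrast_spec("siDDX5", "siCTL"),
                               gcm$size_factors, sim$genes, mask), "stranded")
})
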