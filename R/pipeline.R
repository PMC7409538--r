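# Orchestration: simulate -> run -> report. A run executes per-sample peak
# calling vs input, consensus construction, RNase-H flagging, read counting,
# NB Wald differential per contrast with gain/loss classification, landscape
# annotation tables, RNA-seq differential expression, and antisense detection,
# writing one TSV per analysis table plus a machine-readable summary JSON and
# a manifest. Every number in the summary is recomputable from the TSVs.

stage_log <- function(stage, t0) {
  message(sprintf("[driploop] %-22s %6.1fs", stage,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a study and write it to disk
#'
#' @param config `sim_config` (or a path to a config JSON with sim fields).
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg$peak_mix <- unlist(cfg$peak_mix)
    config <- do.call(sim_config, cfg)
  }
  sim <- simulate_all(config)
  write_simulation(sim, out_dir)
  invisible(out_dir)
}

#' Run the full analysis pipeline on a simulation directory
#'
#' @param sim_dir Directory written by [run_simulation()] (or
#'   [write_simulation()]).
#' @param out_dir Results directory (created).
#' @param params Optional overrides: bin, q_cut, merge_gap, min_length,
#'   local_bg, min_support, rnaseh_threshold, filter_rnaseh, lfc_threshold,
#'   fdr_threshold (DRIP), rna_fdr_threshold, min_mean, purity.
#' @return list with all in-memory results (also written to `out_dir`).
#' @export
run_pipeline <- function(sim_dir, out_dir, params = list()) {
  p <- utils::modifyList(list(
    bin = 100, q_cut = 0.1, merge_gap = 500, min_length = 200, local_bg = 5000,
    min_support = 1, rnaseh_threshold = 0.5, filter_rnaseh = FALSE,
    lfc_threshold = 1, fdr_threshold = 0.1, rna_fdr_threshold = 0.05,
    min_mean = 5, purity = 0.75), params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  sim <- read_simulation(sim_dir)
  cfg <- sim$config
  conditions <- cfg$conditions
  control <- cfg$control
  kds <- setdiff(conditions, control)
  stage_log("load", t0)

  ips <- Filter(function(x) x$assay == "DRIP-IP", sim$drip)
  input <- Filter(function(x) x$assay == "DRIP-input", sim$drip)[[1]]
  rnaseh <- Filter(function(x) x$assay == "DRIP-RNaseH", sim$drip)[[1]]

  calls <- lapply(ips, function(ip)
    call_broad_peaks(ip, input, sim$assembly, bin = p$bin, q_cut = p$q_cut,
                     merge_gap = p$merge_gap, min_length = p$min_length,
                     local_bg = p$local_bg))
  for (nm in names(calls)) {
    ci <- calls[[nm]]
    if (nrow(ci) > 0) {
      write_bed(data.frame(chrom = ci$chrom, start = ci$start, end = ci$end,
                           name = sprintf("%s_pk%04d", nm, seq_len(nrow(ci))),
                           score = round(ci$fold_enrichment, 3), strand = "."),
                file.path(out_dir, paste0("peaks_", nm, ".bed")))
    }
  }
  stage_log("callpeaks", t0)

  cons <- build_consensus(calls, min_support = p$min_support)
  pooled_ip <- read_set("pooled_ip", "pooled", "A", "DRIP-IP",
                        do.call(rbind, lapply(ips, function(x) x$reads)))
  cons <- rnaseh_sensitivity(cons, pooled_ip, rnaseh, threshold = p$rnaseh_threshold)
  if (p$filter_rnaseh) cons <- cons[cons$hybrid, , drop = FALSE]
  write_tsv(cons, file.path(out_dir, "consensus_peaks.tsv"))
  write_bed(data.frame(chrom = cons$chrom, start = cons$start, end = cons$end,
                       name = cons$peak_id, score = cons$support, strand = "."),
            file.path(out_dir, "consensus_peaks.bed"))
  stage_log("consensus", t0)

  cm <- size_factors(count_reads(cons, ips))
  write_tsv(data.frame(peak_id = rownames(cm$counts), cm$counts,
                       check.names = FALSE),
            file.path(out_dir, "peak_counts.tsv"))
  alpha <- estimate_dispersion(cm)
  diffs <- list()
  for (kd in kds) {
    ct <- contrast_spec(kd, control, lfc_threshold = p$lfc_threshold,
                        fdr_threshold = p$fdr_threshold)
    diffs[[kd]] <- classify_differential(wald_test(cm, ct, alpha), ct)
    write_tsv(diffs[[kd]], file.path(out_dir, paste0("differential_", kd, ".tsv")))
  }
  stage_log("differential", t0)

  fmap <- build_feature_map(sim$genes, sim$assembly)
  annot <- annotate_peaks(cons, sim$genes, fmap, mode = "endpoint")
  annot_int <- annotate_peaks(cons, sim$genes, fmap, mode = "interval")
  for (kd in kds) annot[[paste0("class_", kd)]] <- diffs[[kd]]$class
  write_tsv(annot, file.path(out_dir, "annotation.tsv"))
  stage_log("annotate", t0)

  feature_tables <- list()
  any_gain <- Reduce(`|`, lapply(kds, function(kd) diffs[[kd]]$class == "gain"))
  any_change <- Reduce(`|`, lapply(kds, function(kd) diffs[[kd]]$class != "unchanged"))
  feature_tables[["unchanged"]] <- feature_distribution(
    annot$feature_category[!any_change])
  for (kd in kds) {
    feature_tables[[paste0("gain_", kd)]] <- feature_distribution(
      annot$feature_category[diffs[[kd]]$class == "gain"])
  }
  fd_all <- do.call(rbind, lapply(names(feature_tables), function(nm) {
    cbind(subset = nm, feature_tables[[nm]])
  }))
  write_tsv(fd_all, file.path(out_dir, "feature_distribution.tsv"))

  dist_tables <- list(); chrom_tables <- list()
  for (kd in kds) {
    ai <- annot_int; ai$class <- diffs[[kd]]$class
    dt <- distance_tests(ai)
    if (nrow(dt$tests) > 0) dist_tables[[kd]] <- cbind(contrast = kd, dt$tests)
    chrom_tables[[kd]] <- cbind(contrast = kd, chromosome_density_ratio(ai))
  }
  if (length(dist_tables) > 0) {
    write_tsv(do.call(rbind, dist_tables), file.path(out_dir, "distance_tests.tsv"))
  }
  write_tsv(do.call(rbind, chrom_tables), file.path(out_dir, "chromosome_ratios.tsv"))

  # pairwise overlap tests among gain sets and among loss sets
  ovl <- list()
  for (cls in c("gain", "loss")) {
    sets <- lapply(kds, function(kd) diffs[[kd]]$id[diffs[[kd]]$class == cls])
    names(sets) <- kds
    if (length(kds) >= 2) {
      prs <- utils::combn(kds, 2, simplify = FALSE)
      for (pr in prs) {
        ft <- overlap_fisher(sets[[pr[1]]], sets[[pr[2]]], cons$peak_id)
        ovl[[length(ovl) + 1]] <- data.frame(
          class = cls, set_a = pr[1], set_b = pr[2], n_a = ft$n_a, n_b = ft$n_b,
          n_overlap = ft$n_overlap, n_universe = ft$n_universe,
          odds_ratio = ft$odds_ratio, p_fisher = ft$p, stringsAsFactors = FALSE)
      }
    }
  }
  ovl <- if (length(ovl)) do.call(rbind, ovl) else
    data.frame(class = character(), set_a = character(), set_b = character(),
               n_a = integer(), n_b = integer(), n_overlap = integer(),
               n_universe = integer(), odds_ratio = numeric(), p_fisher = numeric())
  write_tsv(ovl, file.path(out_dir, "overlap_tests.tsv"))

  split_sets <- c(list(all = cons$peak_id),
                  stats::setNames(lapply(kds, function(kd)
                    diffs[[kd]]$id[diffs[[kd]]$class == "gain"]),
                    paste0("gain_", kds)))
  splits <- tss_tts_split(annot, split_sets)
  write_tsv(splits, file.path(out_dir, "tss_tts_split.tsv"))
  stage_log("landscape", t0)

  gc_tab <- NULL
  if (!is.null(sim$assembly$sequence)) {
    gcp <- gc_cpg_profile(cons, sim$assembly)
    gc_tab <- gcp$per_peak
    write_tsv(gc_tab, file.path(out_dir, "gc_cpg_per_peak.tsv"))
    write_tsv(gcp$positional, file.path(out_dir, "nucleotide_positional.tsv"))
  }
  meta <- metagene_profile(ips, sim$genes, mode = "all")
  write_tsv(meta, file.path(out_dir, "metagene_all.tsv"))
  qc <- sample_qc(cm)
  write_tsv(data.frame(sample_id = rownames(qc$correlation), qc$correlation,
                       check.names = FALSE),
            file.path(out_dir, "qc_correlation.tsv"))
  write_tsv(qc$pca, file.path(out_dir, "qc_pca.tsv"))
  stage_log("qc", t0)

  # RNA-seq gene-level differential expression
  rna <- sim$rnaseq
  gcm <- size_factors(count_reads(sim$genes, rna, mode = "exonic", strand = "sense"))
  galpha <- estimate_dispersion(gcm)
  gene_diffs <- list()
  for (kd in kds) {
    ct <- contrast_spec(kd, control, lfc_threshold = p$lfc_threshold,
                        fdr_threshold = p$rna_fdr_threshold)
    gene_diffs[[kd]] <- classify_differential(wald_test(gcm, ct, galpha), ct)
    write_tsv(gene_diffs[[kd]], file.path(out_dir, paste0("rnaseq_differential_", kd, ".tsv")))
  }
  stage_log("rnaseq", t0)

  mask <- intergenic_mask(sim$assembly, sim$genes)
  anti_hits <- list(); window_tables <- list()
  for (kd in kds) {
    gain_ann <- annot[diffs[[kd]]$class == "gain", , drop = FALSE]
    win <- make_flank_windows(gain_ann, sim$genes, mask)
    if (nrow(win) == 0) next
    ct <- contrast_spec(kd, control)
    wt <- intergenic_diff(win, rna, ct, gcm$size_factors, sim$genes, mask)
    window_tables[[kd]] <- cbind(contrast = kd, wt)
    hits <- call_antisense_hits(wt, diffs[[kd]], gene_diffs[[kd]],
                                min_mean = p$min_mean, purity = p$purity)
    if (nrow(hits) > 0) anti_hits[[kd]] <- cbind(contrast = kd, hits)
  }
  if (length(window_tables) > 0) {
    write_tsv(do.call(rbind, window_tables), file.path(out_dir, "antisense_windows.tsv"))
  }
  anti <- if (length(anti_hits)) do.call(rbind, anti_hits) else
    data.frame(contrast = character())
  write_tsv(anti, file.path(out_dir, "antisense_hits.tsv"))
  stage_log("antisense", t0)

  genome_bp <- sum(sim$assembly$chrom_lengths)
  cons_bp <- sum(cons$end - cons$start)
  per_contrast <- lapply(kds, function(kd) {
    d <- diffs[[kd]]
    gain <- d$class == "gain"; loss <- d$class == "loss"
    list(condition = kd,
         n_gain = sum(gain), n_loss = sum(loss),
         gain_bp = sum((cons$end - cons$start)[gain]),
         loss_bp = sum((cons$end - cons$start)[loss]),
         n_unchanged = sum(d$class == "unchanged"),
         rna_up = sum(gene_diffs[[kd]]$class == "gain"),
         rna_down = sum(gene_diffs[[kd]]$class == "loss"),
         antisense_hits = if (kd %in% names(anti_hits)) nrow(anti_hits[[kd]]) else 0L)
  })
  summary <- list(
    n_consensus_peaks = nrow(cons),
    consensus_bp = cons_bp,
    genome_bp = genome_bp,
    genome_fraction = cons_bp / genome_bp,
    hybrid_fraction = mean(cons$hybrid),
    contrasts = per_contrast,
    overlaps = ovl,
    tss_tts_split = splits,
    params = p)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(kind = "driploop-results", sim_dir = sim_dir,
                   seed = cfg$seed, params = p,
                   checksums = stats::setNames(
                     lapply(files, function(f) unname(tools::md5sum(file.path(out_dir, f)))),
                     files),
                   wall_clock_s = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log("done", t0)
  invisible(list(consensus = cons, annotation = annot, counts = cm,
                 differential = diffs, gene_differential = gene_diffs,
                 feature_tables = feature_tables, overlaps = ovl,
                 splits = splits, qc = qc, antisense = anti,
                 summary = summary, out_dir = out_dir))
}

#' Render a plain-text report from a results directory
#'
#' Renders the peak, differential, landscape and antisense tables; when the
#' originating simulation directory (with truth.json) is available, adds
#' truth-vs-called confusion tables.
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @param sim_dir Optional simulation directory for truth comparison.
#' @return Character vector of report lines (also written to report.txt).
#' @export
render_report <- function(results_dir, sim_dir = NULL) {
  sj <- file.path(results_dir, "summary.json")
  if (!file.exists(sj)) stop("summary.json not found in ", results_dir)
  s <- jsonlite::read_json(sj, simplifyVector = TRUE)
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add("== driploop report ==")
  add(sprintf("Consensus peaks: %d covering %s bp (%.2f%% of genome); hybrid fraction %.2f",
              s$n_consensus_peaks, format(s$consensus_bp, big.mark = ","),
              100 * s$genome_fraction, s$hybrid_fraction))
  add("")
  add("-- Differential R-loop signal per knockdown --")
  ct <- as.data.frame(s$contrasts)
  for (i in seq_len(nrow(ct))) {
    add(sprintf("%10s: %d gains (%s bp), %d losses (%s bp), %d unchanged; RNA up/down %d/%d; antisense hits %d",
                ct$condition[i], ct$n_gain[i], format(ct$gain_bp[i], big.mark = ","),
                ct$n_loss[i], format(ct$loss_bp[i], big.mark = ","),
                ct$n_unchanged[i], ct$rna_up[i], ct$rna_down[i],
                ct$antisense_hits[i]))
  }
  add("")
  add("-- Pairwise overlaps (hypergeometric enrichment) --")
  ov <- as.data.frame(s$overlaps)
  for (i in seq_len(nrow(ov))) {
    add(sprintf("%s %s vs %s: overlap %d of %d/%d (p = %.3g)",
                ov$class[i], ov$set_a[i], ov$set_b[i], ov$n_overlap[i],
                ov$n_a[i], ov$n_b[i], ov$p_fisher[i]))
  }
  add("")
  add("-- TSS/TTS proximity split --")
  sp <- as.data.frame(s$tss_tts_split)
  for (i in seq_len(nrow(sp))) {
    add(sprintf("%14s: n = %4d, TSS %.0f%% / TTS %.0f%%", sp$subset[i], sp$n[i],
                100 * sp$tss_fraction[i], 100 * sp$tts_fraction[i]))
  }
  fd <- file.path(results_dir, "feature_distribution.tsv")
  if (file.exists(fd)) {
    add("", "-- Feature-category distribution (percent) --")
    f <- utils::read.delim(fd)
    for (sub in unique(f$subset)) {
      fi <- f[f$subset == sub & f$count > 0, ]
      add(sprintf("%14s: %s", sub,
                  paste(sprintf("%s %.1f%%", fi$category, fi$percent), collapse = ", ")))
    }
  }
  if (!is.null(sim_dir) && file.exists(file.path(sim_dir, "truth.json"))) {
    add("", "-- Truth vs called (confusion) --")
    truth <- jsonlite::read_json(file.path(sim_dir, "truth.json"), simplifyVector = TRUE)
    tp <- as.data.frame(truth$peaks)
    cons <- utils::read.delim(file.path(results_dir, "consensus_peaks.tsv"))
    hit <- vapply(seq_len(nrow(tp)), function(i) {
      any(cons$chrom == tp$chrom[i] & cons$start < tp$end[i] & cons$end > tp$start[i])
    }, logical(1))
    add(sprintf("Planted peaks recovered in consensus: %d / %d", sum(hit), nrow(tp)))
    kds <- setdiff(names(tp), c("chrom", "center", "gene_id", "class", "start",
                                "end", "peak"))
    for (kd in kds) {
      dfp <- file.path(results_dir, paste0("differential_", kd, ".tsv"))
      if (!file.exists(dfp)) next
      d <- utils::read.delim(dfp)
      cons_class <- d$class[match(cons$peak_id, d$id)]
      called_gain <- vapply(seq_len(nrow(tp)), function(i) {
        any(cons$chrom == tp$chrom[i] & cons$start < tp$end[i] &
              cons$end > tp$start[i] & cons_class == "gain")
      }, logical(1))
      add(sprintf("%10s: true gains called gain %d / %d", kd,
                  sum(called_gain & tp[[kd]] > 0), sum(tp[[kd]] > 0)))
    }
  }
  writeLines(L, file.path(results_dir, "report.txt"))
  invisible(L)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config <json> --out <dir> [--seed <int>]`,
#' `run --sim <dir> --out <dir>`, `report <results-dir> [--sim <dir>]`.
#' Returns an exit code (0 ok, 1 user error, 2 internal error) rather than
#' quitting, so it is testable in-process; the installed
#' `inst/cli/driploop.R` wrapper maps it onto the process exit status.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code.
#' @export
driploop_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  if (length(args) == 0) {
    message("usage: driploop <simulate|run|report> ...")
    return(1L)
  }
  cmd <- args[1]
  tryCatch({
    if (cmd == "simulate") {
      out <- get_opt("--out"); cfg_path <- get_opt("--config")
      seed <- get_opt("--seed")
      if (is.null(out)) { message("simulate: --out required"); return(1L) }
      config <- if (is.null(cfg_path)) {
        sim_config(seed = if (is.null(seed)) 1 else as.integer(seed))
      } else {
        cl <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
        if (!is.null(cl$peak_mix)) cl$peak_mix <- unlist(cl$peak_mix)
        if (!is.null(seed)) cl$seed <- as.integer(seed)
        do.call(sim_config, cl)
      }
      run_simulation(config, out)
      0L
    } else if (cmd == "run") {
      sim <- get_opt("--sim"); out <- get_opt("--out")
      if (is.null(sim) || is.null(out)) { message("run: --sim and --out required"); return(1L) }
      if (!dir.exists(sim)) { message("run: simulation dir not found: ", sim); return(1L) }
      run_pipeline(sim, out)
      0L
    } else if (cmd == "report") {
      if (length(args) < 2) { message("report: results dir required"); return(1L) }
      rep <- render_report(args[2], sim_dir = get_opt("--sim"))
      cat(rep, sep = "\n")
      0L
    } else {
      message("unknown subcommand: ", cmd)
      1L
    }
  }, error = function(e) {
    message("driploop error: ", conditionMessage(e))
    2L
  })
}
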