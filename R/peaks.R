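# Broad enrichment peak calling versus input. A deterministic Poisson
# local-background caller stands in for the cited broad-mode caller: the genome
# is tiled into fixed bins, the expected IP count per bin is the larger of the
# genome-wide and the local (5-kb window) input rate scaled by the library-size
# ratio, per-bin Poisson upper-tail p-values are BH-corrected genome-wide, and
# significant bins are merged into broad peaks.

#' Call broad enrichment peaks for one IP sample versus input
#'
#' @param ip,input `read_set`s on the same assembly (input library > 0).
#' @param assembly `genome_assembly`.
#' @param bin Bin width, bp.
#' @param q_cut BH q-value cutoff for significant bins.
#' @param merge_gap Bins closer than this are merged into one peak, bp.
#' @param min_length Peaks shorter than this are dropped, bp.
#' @param local_bg Width of the local input background window, bp.
#' @return data.frame of peak calls: chrom, start, end, sample_id, summit,
#'   fold_enrichment, qvalue.
#' @export
call_broad_peaks <- function(ip, input, assembly, bin = 100, q_cut = 0.1,
                             merge_gap = 500, min_length = 200,
                             local_bg = 5000) {
  if (input$library_size == 0) stop("input library is empty; cannot scale")
  scale <- ip$library_size / input$library_size
  per_chrom <- list()
  total_bins <- sum(ceiling(assembly$chrom_lengths / bin))
  genome_rate <- input$library_size / total_bins
  w <- max(1L, round(local_bg / bin))
  for (ch in assembly$chrom_names) {
    L <- assembly$chrom_lengths[[ch]]
    nb <- ceiling(L / bin)
    kr <- ip$reads[ip$reads$chrom == ch, , drop = FALSE]
    ki <- input$reads[input$reads$chrom == ch, , drop = FALSE]
    k_ip <- tabulate(pmin(kr$start %/% bin + 1, nb), nbins = nb)
    k_in <- tabulate(pmin(ki$start %/% bin + 1, nb), nbins = nb)
    # centered running mean of input counts over the local window
    cs <- cumsum(c(0, k_in))
    half <- w %/% 2
    lo <- pmax(seq_len(nb) - half, 1)
    hi <- pmin(seq_len(nb) + (w - half - 1), nb)
    local_rate <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    lambda <- pmax(genome_rate, local_rate) * scale
    per_chrom[[ch]] <- data.frame(chrom = ch, bin = seq_len(nb) - 1,
                                  k_ip = k_ip, lambda = lambda)
  }
  bins <- do.call(rbind, per_chrom)
  cand <- bins$k_ip > 0
  p <- rep(NA_real_, nrow(bins))
  p[cand] <- stats::ppois(bins$k_ip[cand] - 1, bins$lambda[cand],
                          lower.tail = FALSE)
  q <- rep(NA_real_, nrow(bins))
  q[cand] <- bh_fdr(p[cand])
  sig <- which(!is.na(q) & q < q_cut)
  if (length(sig) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      sample_id = character(), summit = numeric(),
                      fold_enrichment = numeric(), qvalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  sb <- bins[sig, , drop = FALSE]
  sb$start <- sb$bin * bin
  sb$end <- pmin(sb$start + bin, assembly$chrom_lengths[sb$chrom])
  merged <- merge_intervals(sb[, c("chrom", "start", "end")], max_gap = merge_gap)
  merged <- merged[(merged$end - merged$start) >= min_length, , drop = FALSE]
  if (nrow(merged) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      sample_id = character(), summit = numeric(),
                      fold_enrichment = numeric(), qvalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- merged
  out$sample_id <- ip$sample_id
  out$summit <- NA_real_; out$fold_enrichment <- NA_real_; out$qvalue <- NA_real_
  for (i in seq_len(nrow(out))) {
    inpk <- bins$chrom == out$chrom[i] &
      bins$bin * bin >= out$start[i] & bins$bin * bin < out$end[i]
    bb <- bins[inpk, , drop = FALSE]
    top <- which.max(bb$k_ip)
    out$summit[i] <- bb$bin[top] * bin + bin %/% 2
    ip_count <- sum(bb$k_ip)
    in_exp <- sum(bb$lambda)
    out$fold_enrichment[i] <- ip_count / max(in_exp, 1e-9)
    qq <- q[inpk]
    out$qvalue[i] <- min(qq[!is.na(qq)], 1)
  }
  out$strand <- NULL
  out
}

#' RNase-H sensitivity of peaks
#'
#' Ratio of library-normalized RNase-H to IP signal within each peak
#' (pseudocount 1 read on both); a peak is flagged a genuine DNA/RNA hybrid
#' when the ratio falls below `threshold` (signal destroyed by RNase H).
#'
#' @param peaks Interval data.frame of (consensus) peaks.
#' @param ip `read_set` (pooled IP or a representative IP).
#' @param rnaseh RNase-H control `read_set`.
#' @param threshold Hybrid flag cutoff on the ratio.
#' @return `peaks` with columns rnaseh_ratio and hybrid added.
#' @export
rnaseh_sensitivity <- function(peaks, ip, rnaseh, threshold = 0.5) {
  if (nrow(peaks) == 0) {
    peaks$rnaseh_ratio <- numeric(0); peaks$hybrid <- logical(0)
    return(peaks)
  }
  cnt <- function(rs) count_reads_in_intervals(peaks, rs$reads)
  k_ip <- cnt(ip); k_rh <- cnt(rnaseh)
  ratio <- ((k_rh + 1) / max(rnaseh$library_size, 1)) /
    ((k_ip + 1) / max(ip$library_size, 1))
  peaks$rnaseh_ratio <- ratio
  peaks$hybrid <- ratio < threshold
  peaks
}

#' Build consensus peaks across samples
#'
#' Union of all per-sample peak intervals merged at gap 0; each merged peak
#' records the set of contributing samples (>= 1 bp overlap). Peaks supported
#' by fewer than `min_support` samples are removed. Ids are assigned in
#' coordinate order and are stable across reruns.
#'
#' @param peak_lists List of per-sample peak call data.frames
#'   (from [call_broad_peaks()]).
#' @param min_support Minimum number of supporting samples (default 1: the
#'   plain union).
#' @return data.frame: peak_id, chrom, start, end, support, samples.
#' @export
build_consensus <- function(peak_lists, min_support = 1) {
  all_pk <- do.call(rbind, lapply(peak_lists, function(x)
    x[, c("chrom", "start", "end", "sample_id"), drop = FALSE]))
  if (is.null(all_pk) || nrow(all_pk) == 0) {
    return(data.frame(peak_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), support = integer(),
                      samples = character(), stringsAsFactors = FALSE))
  }
  merged <- merge_intervals(all_pk[, c("chrom", "start", "end")], max_gap = 0)
  merged$support <- 0L
  merged$samples <- ""
  for (i in seq_len(nrow(merged))) {
    hit <- all_pk$chrom == merged$chrom[i] &
      all_pk$start < merged$end[i] & all_pk$end > merged$start[i]
    sams <- sort(unique(all_pk$sample_id[hit]))
    merged$support[i] <- length(sams)
    merged$samples[i] <- paste(sams, collapse = ",")
  }
  merged <- merged[merged$support >= min_support, , drop = FALSE]
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  merged$peak_id <- sprintf("peak%05d", seq_len(nrow(merged)))
  rownames(merged) <- NULL
  merged[, c("peak_id", "chrom", "start", "end", "support", "samples")]
}
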