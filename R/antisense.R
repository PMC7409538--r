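# Detection of intergenic antisense transcription next to R-loop gain peaks.
# For every gene nearest to a gain peak, 5-kb flanking windows upstream of the
# TSS and downstream of the TTS (intergenic-restricted, with a 2-kb
# gene-adjacent subwindow) are quantified from intergenic stranded RNA-seq
# reads; hits must satisfy the four thresholds: (1) adjacent-window log2FC
# > 0, (2) nearest-gene expression log2FC < 2, (3) associated peak log2FC > 1,
# (4) associated peak FDR < 0.1. Orientation is classified from the strand
# purity of the window reads.

#' Intergenic mask: complement of the union of gene bodies
#' @param assembly `genome_assembly`.
#' @param gs `gene_set`.
#' @return Sorted disjoint interval data.frame.
#' @export
intergenic_mask <- function(assembly, gs) {
  g <- gs$genes
  pieces <- lapply(assembly$chrom_names, function(ch) {
    L <- assembly$chrom_lengths[[ch]]
    gc <- g[g$chrom == ch, , drop = FALSE]
    if (nrow(gc) == 0) return(data.frame(chrom = ch, start = 0, end = L,
                                         strand = ".", stringsAsFactors = FALSE))
    body <- merge_intervals(gi(gc$chrom, gc$start, gc$end))
    comp <- interval_complement_within(body[, c("start", "end")], 0, L)
    if (nrow(comp) == 0) return(NULL)
    data.frame(chrom = ch, start = comp$start, end = comp$end, strand = ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) empty_gi() else out
}

#' Filter reads to intergenic space
#' @param reads Read interval data.frame.
#' @param mask Output of [intergenic_mask()] — equivalently, a read is kept
#'   iff it overlaps no gene body by >= 1 bp.
#' @param gs `gene_set` (used directly when `mask` is NULL).
#' @param assembly Needed when `mask` is NULL.
#' @return Filtered reads.
#' @export
intergenic_reads <- function(reads, mask = NULL, gs = NULL, assembly = NULL) {
  if (is.null(mask)) mask <- intergenic_mask(assembly, gs)
  keep <- logical(nrow(reads))
  for (ch in unique(reads$chrom)) {
    ri <- which(reads$chrom == ch)
    mch <- mask[mask$chrom == ch, , drop = FALSE]
    # a read is intergenic iff fully inside the mask (mask pieces abut gene
    # bodies, so overlap with a body = crossing a mask boundary)
    idx <- findInterval(reads$start[ri], mch$start)
    inside <- idx >= 1 & reads$end[ri] <= mch$end[pmax(idx, 1)] &
      reads$start[ri] >= mch$start[pmax(idx, 1)]
    keep[ri] <- idx >= 1 & inside
  }
  reads[keep, , drop = FALSE]
}

#' Build intergenic flank windows for genes implicated by gain peaks
#'
#' One TSS-upstream and one TTS-downstream window per distinct nearest gene of
#' any gain peak. Windows are strand-aware (upstream = 5' of the gene), both
#' the full (`full` bp) and gene-adjacent (`adjacent` bp) windows are
#' intersected with the intergenic mask, windows with masked length below
#' `min_masked` are dropped, and each retained window records the nearest gain
#' peak within `full` bp.
#'
#' @param gain_annot Annotation rows ([annotate_peaks()]) of gain peaks.
#' @param gs `gene_set`.
#' @param mask [intergenic_mask()] output.
#' @param full,adjacent Window sizes, bp.
#' @param min_masked Minimum surviving masked width, bp.
#' @return data.frame of window pieces: window_id, gene_id, side, kind
#'   (full/adjacent), chrom, start, end, peak_id, peak_distance.
#' @export
make_flank_windows <- function(gain_annot, gs, mask, full = 5000,
                               adjacent = 2000, min_masked = 200) {
  genes_hit <- unique(gain_annot$nearest_gene)
  genes_hit <- genes_hit[!is.na(genes_hit)]
  g <- gs$genes
  rows <- list()
  for (gid in genes_hit) {
    gg <- g[g$gene_id == gid, ]
    plus <- gg$strand == "+"
    for (side in c("TSS-upstream", "TTS-downstream")) {
      up <- side == "TSS-upstream"
      if (up == plus) { # window left of the gene
        fs <- gg$start - full; fe <- gg$start
        as_ <- gg$start - adjacent; ae <- gg$start
      } else {          # window right of the gene
        fs <- gg$end; fe <- gg$end + full
        as_ <- gg$end; ae <- gg$end + adjacent
      }
      fs <- max(0, fs); as_ <- max(0, as_)
      mch <- mask[mask$chrom == gg$chrom, , drop = FALSE]
      fp <- intersect_with_mask(fs, fe, mch$start, mch$end)
      ap <- intersect_with_mask(as_, ae, mch$start, mch$end)
      if (is.null(fp) || nrow(fp) == 0 || sum(fp$end - fp$start) < min_masked) next
      # nearest gain peak within `full` bp of the (unmasked) full window span
      cand <- gain_annot[gain_annot$chrom == gg$chrom, , drop = FALSE]
      if (nrow(cand) == 0) next
      pd <- interval_distance(cand[, c("chrom", "start", "end")],
                              gi(gg$chrom, fs, max(fe, fs + 1)))
      ok <- which(!is.na(pd) & pd <= full)
      if (length(ok) == 0) next
      best <- ok[order(pd[ok], cand$peak_id[ok])][1]
      wid <- paste0(gid, "|", side)
      add <- function(pieces, kind) {
        if (is.null(pieces) || nrow(pieces) == 0) return(NULL)
        data.frame(window_id = wid, gene_id = gid, side = side, kind = kind,
                   chrom = gg$chrom, start = pieces$start, end = pieces$end,
                   peak_id = cand$peak_id[best], peak_distance = pd[best],
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- add(fp, "full")
      rows[[length(rows) + 1]] <- add(ap, "adjacent")
    }
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(window_id = character(), gene_id = character(),
                      side = character(), kind = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      peak_id = character(), peak_distance = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Differential intergenic signal in flank windows
#'
#' Counts intergenic reads in each window (full and adjacent separately),
#' reuses the gene-level size factors (windows are too few and signal-biased
#' to self-normalize), and runs the NB Wald test per window. Also reports the
#' antisense read fraction: the fraction of the treatment condition's
#' adjacent-window reads lying on the strand opposite the gene.
#'
#' @param windows [make_flank_windows()] output.
#' @param rnaseq List of stranded RNA-seq `read_set`s.
#' @param contrast `contrast_spec` (treatment knockdown vs control).
#' @param gene_size_factors Named per-sample size factors from the gene-level
#'   count matrix.
#' @param gs `gene_set` (for gene strands).
#' @param mask [intergenic_mask()] output.
#' @return data.frame per window: window_id, gene_id, side, peak_id,
#'   peak_distance, full/adjacent log2fc and q, treat_mean_adjacent,
#'   antisense_read_fraction, n_treat_reads.
#' @export
intergenic_diff <- function(windows, rnaseq, contrast, gene_size_factors,
                            gs, mask) {
  if (any(vapply(rnaseq, function(x) any(!x$reads$strand %in% c("+", "-")),
                 logical(1)))) {
    stop("stranded RNA-seq reads required")
  }
  if (nrow(windows) == 0) {
    return(data.frame(window_id = character(), gene_id = character(),
                      side = character(), peak_id = character(),
                      peak_distance = numeric(), log2fc_full = numeric(),
                      log2fc_adjacent = numeric(), q_adjacent = numeric(),
                      treat_mean_adjacent = numeric(),
                      antisense_read_fraction = numeric(),
                      n_treat_reads = numeric(), stringsAsFactors = FALSE))
  }
  inter <- lapply(rnaseq, function(rs) {
    rs$reads <- intergenic_reads(rs$reads, mask = mask)
    rs
  })
  count_kind <- function(kind) {
    feat <- windows[windows$kind == kind, , drop = FALSE]
    feat$feature_id <- feat$window_id
    cm <- count_reads(feat, inter, mode = "any-overlap", allow_overlap = TRUE)
    cm$size_factors <- gene_size_factors[cm$samples$sample_id]
    cm
  }
  cm_full <- count_kind("full")
  cm_adj <- count_kind("adjacent")
  alpha_full <- estimate_dispersion(cm_full)
  alpha_adj <- estimate_dispersion(cm_adj)
  res_full <- wald_test(cm_full, contrast, alpha_full)
  res_adj <- wald_test(cm_adj, contrast, alpha_adj)
  q_adj <- normalized_counts(cm_adj)
  ti <- which(cm_adj$samples$condition == contrast$treatment)
  treat_mean <- rowMeans(q_adj[, ti, drop = FALSE])
  # strand purity of the treatment condition's adjacent-window reads
  wmeta <- unique(windows[, c("window_id", "gene_id", "side", "peak_id",
                              "peak_distance", "chrom")])
  g <- gs$genes
  frac <- rep(NA_real_, nrow(wmeta)); n_tr <- numeric(nrow(wmeta))
  treat_rs <- Filter(function(x) x$condition == contrast$treatment, inter)
  for (i in seq_len(nrow(wmeta))) {
    pieces <- windows[windows$window_id == wmeta$window_id[i] &
                        windows$kind == "adjacent", , drop = FALSE]
    gstrand <- g$strand[g$gene_id == wmeta$gene_id[i]]
    opp <- 0; tot <- 0
    for (rs in treat_rs) {
      r <- rs$reads[rs$reads$chrom == wmeta$chrom[i], , drop = FALSE]
      for (j in seq_len(nrow(pieces))) {
        hit <- r$start < pieces$end[j] & r$end > pieces$start[j]
        tot <- tot + sum(hit)
        opp <- opp + sum(hit & r$strand != gstrand)
      }
    }
    n_tr[i] <- tot
    frac[i] <- if (tot > 0) opp / tot else NA_real_
  }
  mfull <- match(wmeta$window_id, res_full$id)
  madj <- match(wmeta$window_id, res_adj$id)
  data.frame(window_id = wmeta$window_id, gene_id = wmeta$gene_id,
             side = wmeta$side, peak_id = wmeta$peak_id,
             peak_distance = wmeta$peak_distance,
             log2fc_full = res_full$log2fc[mfull],
             log2fc_adjacent = res_adj$log2fc[madj],
             q_adjacent = res_adj$q[madj],
             treat_mean_adjacent = treat_mean[madj],
             antisense_read_fraction = frac,
             n_treat_reads = n_tr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Orientation class of a window's transcription
#'
#' TSS-upstream windows are `antisense` when >= `purity` of the reads lie on
#' the strand opposite the gene; TTS-downstream windows are
#' `sense-readthrough` when >= `purity` lie on the gene's strand; everything
#' else (including zero-read windows) is `ambiguous`.
#'
#' @param side `"TSS-upstream"` or `"TTS-downstream"`.
#' @param antisense_fraction Fraction of reads opposite the gene strand.
#' @param n_reads Number of reads the fraction is based on.
#' @param purity Strand-purity cutoff (default 0.75).
#' @return Character orientation class (vectorised).
#' @export
orient_transcription <- function(side, antisense_fraction, n_reads,
                                 purity = 0.75) {
  out <- rep("ambiguous", length(side))
  zero <- n_reads == 0 | is.na(antisense_fraction)
  if (any(zero)) warning("window(s) with zero reads classified ambiguous")
  tssa <- !zero & side == "TSS-upstream" & antisense_fraction >= purity
  ttsr <- !zero & side == "TTS-downstream" & (1 - antisense_fraction) >= purity
  out[tssa] <- "antisense"
  out[ttsr] <- "sense-readthrough"
  out
}

#' Call antisense hits with the four thresholds
#'
#' Hit iff (1) adjacent-window log2FC > 0, (2) nearest-gene expression log2FC
#' < `gene_lfc_max` (strict mode additionally requires the gene not to be a
#' significant up-regulation: not (log2FC > 1 and q < 0.05)), (3) associated
#' peak log2FC > 1, (4) associated peak q < 0.1; plus peak-to-window distance
#' <= 5 kb (enforced during window construction) and treatment-condition mean
#' normalized adjacent-window count >= `min_mean`.
#'
#' @param window_table [intergenic_diff()] output.
#' @param peak_result Classified peak differential table (same contrast).
#' @param gene_result Classified gene differential table (same contrast).
#' @param min_mean Minimum treatment-condition mean normalized window count.
#' @param gene_lfc_max Threshold (2) cutoff (default 2, the literal rule).
#' @param strict_gene Apply the stricter "not up-regulated" reading too.
#' @param purity Strand-purity cutoff for orientation.
#' @return data.frame of hits with all threshold columns and orientation,
#'   ordered by (gene_id, side).
#' @export
call_antisense_hits <- function(window_table, peak_result, gene_result,
                                min_mean = 5, gene_lfc_max = 2,
                                strict_gene = FALSE, purity = 0.75) {
  w <- window_table
  pm <- match(w$peak_id, peak_result$id)
  gm <- match(w$gene_id, gene_result$id)
  if (nrow(w) > 0 && all(is.na(pm))) stop("window peaks not found in peak_result (contrast mismatch?)")
  w$peak_log2fc <- peak_result$log2fc[pm]
  w$peak_q <- peak_result$q[pm]
  w$gene_log2fc <- gene_result$log2fc[gm]
  w$gene_q <- gene_result$q[gm]
  w$gene_log2fc[is.na(w$gene_log2fc)] <- 0
  w$gene_q[is.na(w$gene_q)] <- 1
  pass <- !is.na(w$log2fc_adjacent) & w$log2fc_adjacent > 0 &     # (1)
    w$gene_log2fc < gene_lfc_max &                                # (2)
    !is.na(w$peak_log2fc) & w$peak_log2fc > 1 &                   # (3)
    !is.na(w$peak_q) & w$peak_q < 0.1 &                           # (4)
    w$treat_mean_adjacent >= min_mean
  if (strict_gene) {
    pass <- pass & !(w$gene_log2fc > 1 & w$gene_q < 0.05)
  }
  hits <- w[pass, , drop = FALSE]
  hits <- hits[order(hits$gene_id, hits$side), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$peak_id, hits$gene_id, hits$side)), ,
               drop = FALSE]
  hits$orientation <- if (nrow(hits) > 0) {
    orient_transcription(hits$side, hits$antisense_read_fraction,
                         hits$n_treat_reads, purity)
  } else character(0)
  rownames(hits) <- NULL
  hits
}
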