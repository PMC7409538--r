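# Genome-landscape statistics over classified consensus peaks: annotation to
# nearest/second-nearest genes, feature-category distributions, distance and
# chromosome gene-density analyses, set-overlap enrichment, TSS/TTS proximity
# splits, GC/CpG profiles, metagene coverage, and sample-level QC.

#' Annotate consensus peaks with genes and feature categories
#'
#' For each peak: nearest gene (rank 1) and neighbor (second nearest, rank 2)
#' with distances, feature category of the peak midpoint, and whether the peak
#' midpoint lies nearer the nearest gene's TSS or TTS.
#'
#' @param peaks Consensus peak data.frame (peak_id, chrom, start, end).
#' @param gs `gene_set`.
#' @param fmap `feature_map`.
#' @param mode Distance definition for gene ranking (see [nearest_genes()]).
#' @return data.frame: peak_id, chrom, start, end, nearest_gene,
#'   nearest_distance, neighbor_gene, neighbor_distance, feature_category,
#'   nearer_end, end_distance.
#' @export
annotate_peaks <- function(peaks, gs, fmap, mode = "endpoint") {
  n <- nrow(peaks)
  out <- peaks[, c("peak_id", "chrom", "start", "end"), drop = FALSE]
  out$nearest_gene <- NA_character_; out$nearest_distance <- NA_real_
  out$neighbor_gene <- NA_character_; out$neighbor_distance <- NA_real_
  out$nearer_end <- NA_character_; out$end_distance <- NA_real_
  for (i in seq_len(n)) {
    nn <- nearest_genes(peaks[i, ], gs, mode = mode, k = 2)
    if (nrow(nn) >= 1) {
      out$nearest_gene[i] <- nn$gene_id[1]
      out$nearest_distance[i] <- nn$distance[1]
      g1 <- gs$genes[gs$genes$gene_id == nn$gene_id[1], ]
      st <- tss_tts_side(peaks[i, ], g1)
      out$nearer_end[i] <- st$side
      out$end_distance[i] <- st$distance
    }
    if (nrow(nn) >= 2) {
      out$neighbor_gene[i] <- nn$gene_id[2]
      out$neighbor_distance[i] <- nn$distance[2]
    }
  }
  out$feature_category <- assign_feature(peaks, fmap)
  out
}

#' Feature-category distribution of a peak subset
#' @param categories Character vector of feature categories (one per peak).
#' @return data.frame(category, count, percent); percentages sum to 100.
#' @export
feature_distribution <- function(categories) {
  lv <- feature_categories()
  if (length(categories) == 0) {
    warning("empty peak subset")
    return(data.frame(category = lv, count = 0L, percent = NA_real_))
  }
  cnt <- table(factor(categories, levels = lv))
  data.frame(category = lv, count = as.integer(cnt),
             percent = 100 * as.numeric(cnt) / sum(cnt),
             stringsAsFactors = FALSE)
}

#' Welch two-sample t-test (unequal variances)
#' @param x,y Numeric samples (length >= 2 each).
#' @return list(t, df, p) with Welch-Satterthwaite degrees of freedom.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("welch_t needs >= 2 observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  sx <- vx / nx; sy <- vy / ny
  t <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (nx - 1) + sy^2 / (ny - 1))
  if (!is.finite(t)) { t <- 0; df <- nx + ny - 2 }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Neighbor-distance comparisons between peak classes
#'
#' Distances to the second-nearest gene (interval mode) per class, compared
#' gain-vs-unchanged and loss-vs-unchanged by Welch's t-test.
#'
#' @param annot Annotation table from [annotate_peaks()] run with
#'   `mode = "interval"` (or any table with neighbor_distance), plus a
#'   `class` column for the contrast of interest.
#' @return list(distances = per-class list, tests = data.frame).
#' @export
distance_tests <- function(annot) {
  stopifnot("class" %in% names(annot))
  d <- split(annot$neighbor_distance[!is.na(annot$neighbor_distance)],
             annot$class[!is.na(annot$neighbor_distance)])
  tests <- list()
  for (cl in intersect(c("gain", "loss"), names(d))) {
    if (length(d[[cl]]) < 2 || length(d[["unchanged"]]) < 2) {
      warning("class ", cl, " has < 2 peaks; comparison skipped")
      next
    }
    wt <- welch_t(d[[cl]], d[["unchanged"]])
    tests[[cl]] <- data.frame(comparison = paste0(cl, "-vs-unchanged"),
                              t = wt$t, df = wt$df, p = wt$p,
                              mean_class = mean(d[[cl]]),
                              mean_unchanged = mean(d[["unchanged"]]),
                              stringsAsFactors = FALSE)
  }
  list(distances = d,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(comparison = character(), t = numeric(), df = numeric(),
                    p = numeric(), mean_class = numeric(),
                    mean_unchanged = numeric()))
}

#' Per-chromosome gain/loss-to-unchanged ratios vs gene density proxy
#'
#' For each chromosome: (gain count / unchanged count), (loss count /
#' unchanged count) and the mean neighbor distance over all consensus peaks
#' of the chromosome (an inverse gene-density proxy). 0/0 is reported as NA.
#'
#' @param annot Annotation table with `class` and `neighbor_distance`.
#' @return data.frame per chromosome.
#' @export
chromosome_density_ratio <- function(annot) {
  chroms <- sort(unique(annot$chrom))
  out <- lapply(chroms, function(ch) {
    a <- annot[annot$chrom == ch, , drop = FALSE]
    n_g <- sum(a$class == "gain"); n_l <- sum(a$class == "loss")
    n_u <- sum(a$class == "unchanged")
    data.frame(chrom = ch,
               gain_ratio = if (n_u == 0) NA_real_ else n_g / n_u,
               loss_ratio = if (n_u == 0) NA_real_ else n_l / n_u,
               mean_neighbor_distance = mean(a$neighbor_distance, na.rm = TRUE),
               n_peaks = nrow(a), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fisher / hypergeometric overlap enrichment between two peak sets
#'
#' One-sided enrichment p-value: the hypergeometric upper tail
#' `P(X >= |A intersect B|)` for drawing |B| items from a universe containing
#' |A| marked items, computed by log-space summation. The odds ratio comes
#' from the 2x2 table.
#'
#' @param a,b Character vectors of ids, both subsets of `universe`.
#' @param universe Character vector of all ids.
#' @return list(n_a, n_b, n_overlap, n_universe, odds_ratio, p).
#' @export
overlap_fisher <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop("overlap sets must be subsets of the universe")
  }
  N <- length(universe); nA <- length(a); nB <- length(b)
  k <- length(intersect(a, b))
  kmax <- min(nA, nB)
  if (k > kmax) stop("overlap exceeds set sizes")
  # log-space hypergeometric upper tail
  terms <- vapply(k:kmax, function(x) {
    lchoose(nA, x) + lchoose(N - nA, nB - x) - lchoose(N, nB)
  }, numeric(1))
  mx <- max(terms)
  p <- min(1, exp(mx) * sum(exp(terms - mx)))
  tab <- c(k, nA - k, nB - k, N - nA - nB + k)
  or <- (tab[1] * tab[4]) / max(tab[2] * tab[3], .Machine$double.eps)
  list(n_a = nA, n_b = nB, n_overlap = k, n_universe = N,
       odds_ratio = or, p = p)
}

#' TSS/TTS proximity split
#'
#' Fraction of peaks whose midpoint lies nearer the nearest gene's TSS than
#' its TTS, per named subset of peak ids.
#'
#' @param annot Annotation table (needs peak_id, nearer_end).
#' @param subsets Named list of peak-id vectors.
#' @return data.frame(subset, n, tss_fraction, tts_fraction).
#' @export
tss_tts_split <- function(annot, subsets) {
  out <- lapply(names(subsets), function(nm) {
    a <- annot[annot$peak_id %in% subsets[[nm]] & !is.na(annot$nearer_end), ,
               drop = FALSE]
    n <- nrow(a)
    f <- if (n == 0) NA_real_ else mean(a$nearer_end == "TSS")
    data.frame(subset = nm, n = n, tss_fraction = f, tts_fraction = 1 - f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' GC%, CpG% and positional nucleotide frequencies around peaks
#'
#' Per-peak GC percent and CpG dinucleotide percent over the peak interval,
#' plus position-dependent A/C/G/T frequencies over +/- `flank` bp of peak
#' centers averaged across peaks (N bases excluded from denominators).
#'
#' @param peaks Interval data.frame.
#' @param assembly `genome_assembly` with sequence.
#' @param flank Half-width of the positional profile, bp.
#' @return list(per_peak = data.frame(peak GC/CpG), positional = data.frame
#'   with position (relative to center) and A/C/G/T frequencies).
#' @export
gc_cpg_profile <- function(peaks, assembly, flank = 2000) {
  if (is.null(assembly$sequence)) stop("assembly has no sequence")
  n <- nrow(peaks)
  gc <- numeric(n); cpg <- numeric(n)
  width <- 2 * flank
  base_counts <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  cov_counts <- numeric(width)
  for (i in seq_len(n)) {
    seqch <- assembly$sequence[[peaks$chrom[i]]]
    s <- peaks$start[i]; e <- peaks$end[i]
    sub <- Biostrings::subseq(seqch, s + 1, e)
    acgt <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
    tot <- sum(acgt)
    gc[i] <- if (tot > 0) 100 * sum(acgt[c("C", "G")]) / tot else NA_real_
    L <- e - s
    cpg[i] <- if (L > 1) {
      100 * Biostrings::countPattern("CG", sub) / (L - 1)
    } else NA_real_
    mid <- interval_midpoint(peaks[i, ])
    ws <- mid - flank; we <- mid + flank
    cs <- max(0, ws); ce <- min(length(seqch), we)
    if (ce <= cs) next
    wseq <- as.character(Biostrings::subseq(seqch, cs + 1, ce))
    chars <- strsplit(wseq, "")[[1]]
    pos <- (cs - ws + 1):(cs - ws + length(chars))
    for (b in c("A", "C", "G", "T")) {
      hit <- pos[chars == b]
      if (length(hit)) base_counts[b, hit] <- base_counts[b, hit] + 1
    }
    good <- pos[chars %in% c("A", "C", "G", "T")]
    cov_counts[good] <- cov_counts[good] + 1
  }
  denom <- pmax(cov_counts, 1)
  positional <- data.frame(position = seq_len(width) - flank - 1,
                           t(base_counts) / denom)
  names(positional)[2:5] <- c("A", "C", "G", "T")
  list(per_peak = data.frame(peak_id = if ("peak_id" %in% names(peaks))
    peaks$peak_id else seq_len(n),
    gc_percent = gc, cpg_percent = cpg,
    stringsAsFactors = FALSE),
    positional = positional)
}

#' Metagene coverage profile
#'
#' Gene bodies scaled to `body_bins` bins with `flank`/`flank_bins` bp flanks
#' either side, strand-oriented (TSS on the left); read midpoints are
#' assigned to bins and converted to reads-per-million, averaged over genes.
#' `mode = "intergenic"` keeps only reads overlapping no gene body;
#' `"intronic"` keeps only reads overlapping an intron. Per-condition profiles
#' are the mean over the condition's samples; `subtract` removes the named
#' condition's profile bin-wise.
#'
#' @param readsets List of `read_set`s.
#' @param gs `gene_set`.
#' @param mode `"all"`, `"intergenic"` or `"intronic"`.
#' @param flank Flank width, bp.
#' @param body_bins,flank_bins Bin counts (defaults 50 and 25).
#' @param subtract Optional condition label to subtract bin-wise.
#' @return data.frame: bin index, region label, one column per condition.
#' @export
metagene_profile <- function(readsets, gs, mode = c("all", "intergenic", "intronic"),
                             flank = 5000, body_bins = 50, flank_bins = 25,
                             subtract = NULL) {
  mode <- match.arg(mode)
  g <- gs$genes
  if (nrow(g) == 0) stop("no genes")
  nbins <- body_bins + 2 * flank_bins
  body <- merge_intervals(gi(g$chrom, g$start, g$end))
  introns <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    ex <- gs$exons[gs$exons$gene_id == g$gene_id[i], , drop = FALSE]
    ic <- interval_complement_within(ex[order(ex$start), ], g$start[i], g$end[i])
    if (nrow(ic) == 0) return(NULL)
    data.frame(chrom = g$chrom[i], start = ic$start, end = ic$end)
  }))
  profiles <- list()
  for (rs in readsets) {
    r <- rs$reads
    if (mode == "intergenic") {
      keep <- logical(nrow(r))
      for (ch in unique(r$chrom)) {
        ri <- which(r$chrom == ch)
        bch <- body[body$chrom == ch, , drop = FALSE]
        keep[ri] <- !overlaps_sorted(r$start[ri], r$end[ri], bch$start, bch$end)
      }
      r <- r[keep, , drop = FALSE]
    } else if (mode == "intronic") {
      keep <- logical(nrow(r))
      if (!is.null(introns)) {
        im <- merge_intervals(gi(introns$chrom, introns$start, introns$end))
        for (ch in unique(r$chrom)) {
          ri <- which(r$chrom == ch)
          ich <- im[im$chrom == ch, , drop = FALSE]
          keep[ri] <- overlaps_sorted(r$start[ri], r$end[ri], ich$start, ich$end)
        }
      }
      r <- r[keep, , drop = FALSE]
    }
    mids <- interval_midpoint(r)
    prof <- matrix(0, nrow(g), nbins)
    for (ch in unique(g$chrom)) {
      ri <- which(r$chrom == ch)
      mch <- sort(mids[ri])
      for (gi2 in which(g$chrom == ch)) {
        gs_ <- g$start[gi2]; ge_ <- g$end[gi2]
        lo <- gs_ - flank; hi <- ge_ + flank
        j1 <- findInterval(lo - 0.5, mch) + 1
        j2 <- findInterval(hi - 0.5, mch)
        if (j2 < j1) next
        m <- mch[j1:j2]
        binv <- integer(length(m))
        left <- m < gs_
        right <- m >= ge_
        bodym <- !left & !right
        binv[left] <- pmin(flank_bins,
                           floor((m[left] - lo) / (flank / flank_bins)) + 1)
        binv[bodym] <- flank_bins +
          pmin(body_bins, floor((m[bodym] - gs_) / ((ge_ - gs_) / body_bins)) + 1)
        binv[right] <- flank_bins + body_bins +
          pmin(flank_bins, floor((m[right] - ge_) / (flank / flank_bins)) + 1)
        tb <- tabulate(binv, nbins)
        if (g$strand[gi2] == "-") tb <- rev(tb)
        prof[gi2, ] <- prof[gi2, ] + tb
      }
    }
    rpm <- colMeans(prof) * 1e6 / max(rs$library_size, 1)
    profiles[[rs$sample_id]] <- list(condition = rs$condition, rpm = rpm)
  }
  conds <- unique(vapply(profiles, function(x) x$condition, character(1)))
  mat <- vapply(conds, function(cc) {
    rows <- Filter(function(x) x$condition == cc, profiles)
    Reduce(`+`, lapply(rows, function(x) x$rpm)) / length(rows)
  }, numeric(nbins))
  mat <- matrix(mat, ncol = length(conds), dimnames = list(NULL, conds))
  if (!is.null(subtract)) {
    if (!subtract %in% conds) stop("subtract condition not found")
    mat <- mat - mat[, subtract]
  }
  region <- c(rep("upstream", flank_bins), rep("body", body_bins),
              rep("downstream", flank_bins))
  data.frame(bin = seq_len(nbins), region = region, mat, check.names = FALSE)
}

#' Sample QC: correlation matrix and PCA
#'
#' Transforms normalized counts as `log2(q + 1)`, reports the Pearson
#' correlation matrix over all features and PC1/PC2 sample coordinates from
#' an SVD of the `n_top` most variable features (centered per feature), with
#' variance-explained fractions.
#'
#' @param cm `count_matrix` (size factors computed here if absent).
#' @param n_top Number of most-variable features for the PCA.
#' @return list(correlation, pca = data.frame(sample_id, condition, PC1, PC2),
#'   var_explained).
#' @export
sample_qc <- function(cm, n_top = 500) {
  if (ncol(cm$counts) < 2) stop("need >= 2 samples")
  if (nrow(cm$counts) < 2) stop("need >= 2 features")
  if (is.null(cm$size_factors)) cm <- size_factors(cm)
  y <- log2(normalized_counts(cm) + 1)
  corr <- stats::cor(y)
  v <- apply(y, 1, stats::var)
  top <- utils::head(order(v, decreasing = TRUE), min(n_top, nrow(y)))
  yt <- y[top, , drop = FALSE]
  yt <- yt - rowMeans(yt)
  sv <- svd(t(yt))
  var_frac <- sv$d^2 / sum(sv$d^2)
  pcs <- sv$u %*% diag(sv$d)
  data.frame(sample_id = colnames(y))
  list(correlation = corr,
       pca = data.frame(sample_id = colnames(y),
                        condition = cm$samples$condition,
                        PC1 = pcs[, 1], PC2 = if (ncol(pcs) >= 2) pcs[, 2] else 0,
                        stringsAsFactors = FALSE),
       var_explained = var_frac)
}
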