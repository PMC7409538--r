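# Coordinate model: all intervals are 0-based half-open [start, end), BED-style,
# carried as plain data.frames with columns chrom, start, end (and optionally
# strand, "." when unstranded). GTF I/O converts to 1-based inclusive at the
# file boundary only.

#' Construct a genomic interval table
#'
#' Builds the package's standard interval container: a data.frame with columns
#' `chrom`, `start`, `end`, `strand`, using 0-based half-open coordinates.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends (`end > start`).
#' @param strand Strand per interval: `"+"`, `"-"` or `"."` (default).
#' @return A data.frame with columns chrom, start, end, strand.
#' @export
gi <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  bad <- df$start < 0 | df$end <= df$start
  if (any(bad)) {
    stop("invalid interval(s): need 0 <= start < end (rows ",
         paste(which(bad), collapse = ", "), ")")
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  df
}

empty_gi <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Interval midpoint
#'
#' Midpoint base of an interval; for even lengths this is
#' `start + floor(length / 2)` (deterministic convention used throughout).
#'
#' @param x Interval data.frame (see [gi()]).
#' @return Numeric vector of midpoint base coordinates (0-based).
#' @export
interval_midpoint <- function(x) {
  x$start + floor((x$end - x$start) / 2)
}

#' Merge intervals
#'
#' Sorts intervals and merges any two on the same chromosome whose gap
#' (`next start - previous end`) is at most `max_gap`. With `max_gap = 0`
#' book-ended intervals merge (half-open coordinates: a gap of exactly 0).
#'
#' @param intervals Interval data.frame.
#' @param max_gap Maximum bridged gap in bp (>= 0).
#' @return Sorted, disjoint interval data.frame (strand dropped to ".").
#' @export
merge_intervals <- function(intervals, max_gap = 0) {
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0) {
    stop("max_gap must be a single non-negative number")
  }
  if (nrow(intervals) == 0) return(empty_gi())
  o <- order(intervals$chrom, intervals$start, intervals$end)
  x <- intervals[o, , drop = FALSE]
  n <- nrow(x)
  # running max of end within chromosome, shifted by one
  cm <- stats::ave(x$end, x$chrom, FUN = cummax)
  prev_end <- c(-Inf, cm[-n])
  same_chrom <- c(FALSE, x$chrom[-1] == x$chrom[-n])
  new_run <- !(same_chrom & (x$start - prev_end) <= max_gap)
  grp <- cumsum(new_run)
  out <- data.frame(
    chrom = x$chrom[!duplicated(grp)],
    start = tapply(x$start, grp, min),
    end = tapply(x$end, grp, max),
    strand = ".",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Distance between two intervals
#'
#' 0 when the intervals overlap, otherwise the gap in bp between the nearest
#' ends; `NA` when the intervals lie on different chromosomes (the
#' cross-chromosome sentinel). Vectorised over rows.
#'
#' @param a,b Interval data.frames of equal row count (or one of them 1-row).
#' @return Numeric vector of distances (NA = different chromosomes).
#' @export
interval_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- if (nrow(a) == 1) rep(1L, n) else seq_len(n)
  idx_b <- if (nrow(b) == 1) rep(1L, n) else seq_len(n)
  a <- a[idx_a, , drop = FALSE]; b <- b[idx_b, , drop = FALSE]
  d <- pmax(a$start, b$start) - pmin(a$end, b$end)
  d <- pmax(d, 0)
  d[a$chrom != b$chrom] <- NA_real_
  d
}

#' Nearest and second-nearest genes for a peak
#'
#' Ranks genes by distance to the peak. In `endpoint` mode the distance is the
#' smaller of |peak midpoint - TSS| and |peak midpoint - TTS| (the "nearest =
#' gene whose TSS or TTS lies nearest" convention); in `interval` mode it is
#' the bedtools-closest-style gap between the peak and the gene body (0 when
#' overlapping). Only genes on the peak's chromosome are considered. Ties are
#' broken by (gene start, gene_id) so output is deterministic.
#'
#' @param peak One-row interval data.frame.
#' @param genes A [gene_set()] or its `$genes` data.frame.
#' @param mode `"endpoint"` or `"interval"`.
#' @param k Number of ranks to return (default 2: nearest + neighbor).
#' @return data.frame with columns gene_id, distance, rank (possibly < k rows).
#' @export
nearest_genes <- function(peak, genes, mode = c("endpoint", "interval"), k = 2) {
  mode <- match.arg(mode)
  g <- if (inherits(genes, "gene_set")) genes$genes else genes
  g <- g[g$chrom == peak$chrom[1], , drop = FALSE]
  if (nrow(g) == 0) {
    return(data.frame(gene_id = character(), distance = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  if (mode == "endpoint") {
    mid <- interval_midpoint(peak[1, ])
    d <- pmin(abs(mid - g$tss), abs(mid - g$tts))
  } else {
    d <- pmax(pmax(peak$start[1], g$start) - pmin(peak$end[1], g$end), 0)
  }
  o <- order(d, g$start, g$gene_id)
  take <- utils::head(o, k)
  data.frame(gene_id = g$gene_id[take], distance = d[take],
             rank = seq_along(take), stringsAsFactors = FALSE)
}

#' Is a peak nearer the TSS or the TTS of a gene?
#'
#' Compares |peak midpoint - TSS| with |peak midpoint - TTS|; the smaller wins,
#' exact ties go to TSS (deterministic rule).
#'
#' @param peak One-row interval data.frame.
#' @param gene One-row gene data.frame (columns chrom, tss, tts).
#' @return list(side = "TSS" or "TTS", distance = bp)
#' @export
tss_tts_side <- function(peak, gene) {
  if (peak$chrom[1] != gene$chrom[1]) {
    stop("tss_tts_side: peak and gene on different chromosomes")
  }
  mid <- interval_midpoint(peak[1, ])
  d_tss <- abs(mid - gene$tss[1])
  d_tts <- abs(mid - gene$tts[1])
  if (d_tss <= d_tts) list(side = "TSS", distance = d_tss)
  else list(side = "TTS", distance = d_tts)
}

# Vectorised midpoint-based TSS/TTS side for annotation tables.
tss_tts_side_vec <- function(mid, tss, tts) {
  d_tss <- abs(mid - tss)
  d_tts <- abs(mid - tts)
  side <- ifelse(d_tss <= d_tts, "TSS", "TTS")
  list(side = side, distance = pmin(d_tss, d_tts))
}

# Intersect a set of query intervals with a sorted disjoint mask (both on one
# chromosome, plain start/end vectors). Returns data.frame(start, end, query)
# of intersection pieces.
intersect_with_mask <- function(qs, qe, ms, me) {
  if (length(ms) == 0 || length(qs) == 0) {
    return(data.frame(start = numeric(), end = numeric(), query = integer()))
  }
  out <- vector("list", length(qs))
  for (i in seq_along(qs)) {
    lo <- pmax(qs[i], ms); hi <- pmin(qe[i], me)
    keep <- hi > lo
    out[[i]] <- data.frame(start = lo[keep], end = hi[keep],
                           query = rep.int(i, sum(keep)))
  }
  do.call(rbind, out)
}

# TRUE for each query interval that overlaps (>= 1 bp) a sorted disjoint
# interval set on the same chromosome.
overlaps_sorted <- function(qs, qe, ms, me) {
  if (length(ms) == 0) return(rep(FALSE, length(qs)))
  if (length(qs) == 0) return(logical(0))
  idx <- findInterval(qs, ms)
  hit_left <- idx >= 1 & qs < me[pmax(idx, 1)]
  nxt <- idx + 1
  hit_right <- nxt <= length(ms) & ms[pmin(nxt, length(ms))] < qe
  hit_left | hit_right
}
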