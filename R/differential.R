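# Counting, normalization and negative-binomial Wald testing shared by DRIP
# peaks, genes and intergenic windows. The model is deliberately transparent:
# method-of-moments dispersion with geometric shrinkage toward an a0/mu + a1
# trend, delta-method standard errors for log2 fold changes, and
# Benjamini-Hochberg FDR. Gains/losses use |log2FC| > 1 at FDR < 0.1; RNA-seq
# differential expression uses FDR < 0.05.

# Count reads overlapping each of a set of disjoint sorted intervals on one
# strand-agnostic pass. A read overlaps iff >= 1 bp; a read spanning several
# intervals is counted once in each.
count_reads_in_intervals <- function(features, reads) {
  n <- nrow(features)
  out <- numeric(n)
  for (ch in unique(features$chrom)) {
    fi <- which(features$chrom == ch)
    f <- features[fi, , drop = FALSE]
    o <- order(f$start)
    r <- reads[reads$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0) next
    rs <- sort(r$start); re <- sort(r$end)
    # reads with start < f$end minus reads with end <= f$start
    n1 <- findInterval(f$end[o] - 0.5, rs)
    n2 <- findInterval(f$start[o] + 0.5, re)
    out[fi[o]] <- n1 - n2
  }
  out
}

#' Count matrix container
#'
#' @param counts Integer matrix, features x samples (dimnames required).
#' @param samples data.frame with columns sample_id, condition, replicate in
#'   column order of `counts`.
#' @param size_factors Optional positive numeric vector per sample.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, size_factors = NULL) {
  stopifnot(ncol(counts) == nrow(samples),
            identical(colnames(counts), samples$sample_id))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(list(counts = counts, samples = samples,
                 size_factors = size_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples",
      if (is.null(x$size_factors)) "(no size factors)" else "(normalized)", "\n")
  invisible(x)
}

#' Normalized counts (counts / size factor)
#' @param cm `count_matrix` with size factors.
#' @return Numeric matrix.
#' @export
normalized_counts <- function(cm) {
  if (is.null(cm$size_factors)) stop("size factors not computed")
  sweep(cm$counts, 2, cm$size_factors, "/")
}

#' Count reads in features across samples
#'
#' `any-overlap` counts a read into every feature it overlaps by >= 1 bp
#' (features must be disjoint); `exonic` counts reads overlapping the exon
#' union of each gene; `strand` further restricts to reads on the gene's
#' strand ("sense") or the opposite strand ("antisense").
#'
#' @param features For `any-overlap`: interval data.frame with a feature id
#'   column (`peak_id`/`feature_id`/`name`, else rownames); duplicated ids are
#'   treated as multi-part features (a read counts once per feature). For
#'   `exonic`: a `gene_set`.
#' @param readsets List of `read_set`s.
#' @param mode Counting mode.
#' @param strand `"both"`, `"sense"` or `"antisense"` (exonic mode).
#' @param allow_overlap Permit spatially overlapping features (each read still
#'   counts at most once per feature); default errors, since consensus peaks
#'   are disjoint by construction.
#' @return `count_matrix`.
#' @export
count_reads <- function(features, readsets,
                        mode = c("any-overlap", "exonic"),
                        strand = c("both", "sense", "antisense"),
                        allow_overlap = FALSE) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  samples <- data.frame(
    sample_id = vapply(readsets, function(x) x$sample_id, character(1)),
    condition = vapply(readsets, function(x) x$condition, character(1)),
    replicate = vapply(readsets, function(x) x$replicate, character(1)),
    stringsAsFactors = FALSE)
  if (mode == "any-overlap") {
    id <- if ("feature_id" %in% names(features)) features$feature_id
    else if ("peak_id" %in% names(features)) features$peak_id
    else if ("name" %in% names(features)) features$name
    else rownames(features)
    multi <- anyDuplicated(id) > 0
    if (!multi && nrow(features) > 1) {
      o <- order(features$chrom, features$start)
      f <- features[o, , drop = FALSE]
      ov <- c(FALSE, f$chrom[-1] == f$chrom[-nrow(f)] & f$start[-1] < f$end[-nrow(f)])
      if (any(ov)) {
        if (!allow_overlap) stop("features must be disjoint in any-overlap mode")
        multi <- TRUE # per-feature scan handles overlapping features exactly
      }
    }
    mats <- vapply(readsets, function(rs) {
      if (!multi) return(count_reads_in_intervals(features, rs$reads))
      vapply(unique(id), function(u) {
        part <- features[id == u, , drop = FALSE]
        count_distinct_overlapping(part, rs$reads)
      }, numeric(1))
    }, numeric(if (multi) length(unique(id)) else nrow(features)))
    mats <- matrix(mats, ncol = length(readsets))
    rownames(mats) <- if (multi) unique(id) else id
  } else {
    gs <- features
    stopifnot(inherits(gs, "gene_set"))
    mats <- vapply(readsets, function(rs) {
      count_exonic(gs, rs$reads, strand)
    }, numeric(nrow(gs$genes)))
    mats <- matrix(mats, ncol = length(readsets))
    rownames(mats) <- gs$genes$gene_id
  }
  colnames(mats) <- samples$sample_id
  count_matrix(mats, samples)
}

# Distinct reads overlapping the union of (possibly several) interval pieces.
count_distinct_overlapping <- function(parts, reads) {
  hit <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(parts))) {
    hit <- hit | (reads$chrom == parts$chrom[i] &
                    reads$start < parts$end[i] & reads$end > parts$start[i])
  }
  sum(hit)
}

# Reads overlapping each gene's exon union (once per gene), with optional
# strand restriction relative to the gene.
count_exonic <- function(gs, reads, strand = "both") {
  g <- gs$genes
  out <- numeric(nrow(g))
  for (ch in unique(g$chrom)) {
    gidx <- which(g$chrom == ch)
    r <- reads[reads$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0) next
    o <- order(r$start)
    r <- r[o, , drop = FALSE]
    for (i in gidx) {
      if (strand == "both") keep <- TRUE
      else if (strand == "sense") keep <- r$strand == g$strand[i]
      else keep <- r$strand != g$strand[i]
      # candidates overlapping gene body
      j1 <- findInterval(g$start[i] + 0.5, r$end) + 1
      j2 <- findInterval(g$end[i] - 0.5, r$start)
      if (j2 < j1) next
      cand <- r[j1:j2, , drop = FALSE]
      ck <- if (isTRUE(keep)) rep(TRUE, nrow(cand)) else keep[j1:j2]
      cand <- cand[ck & cand$start < g$end[i] & cand$end > g$start[i], , drop = FALSE]
      if (nrow(cand) == 0) next
      ex <- gs$exons[gs$exons$gene_id == g$gene_id[i], , drop = FALSE]
      hit <- rep(FALSE, nrow(cand))
      for (k in seq_len(nrow(ex))) {
        hit <- hit | (cand$start < ex$end[k] & cand$end > ex$start[k])
      }
      out[i] <- sum(hit)
    }
  }
  out
}

#' Per-sample size factors
#'
#' `median-of-ratios`: for each sample the median over features (with positive
#' geometric mean) of count / geometric mean, rescaled so the factors have
#' geometric mean 1. Falls back to `total-count` (factors proportional to
#' library totals) with a warning when no feature has all-positive counts.
#'
#' @param cm `count_matrix`.
#' @param method `"median-of-ratios"` or `"total-count"`.
#' @return `count_matrix` with `size_factors` set.
#' @export
size_factors <- function(cm, method = c("median-of-ratios", "total-count")) {
  method <- match.arg(method)
  k <- cm$counts
  if (ncol(k) == 1) {
    cm$size_factors <- stats::setNames(1, colnames(k))
    return(cm)
  }
  if (method == "median-of-ratios") {
    pos <- rowSums(k > 0) == ncol(k)
    if (!any(pos)) {
      warning("no feature with all-positive counts; falling back to total-count")
      return(size_factors(cm, "total-count"))
    }
    lgm <- rowMeans(log(k[pos, , drop = FALSE]))
    s <- apply(k[pos, , drop = FALSE], 2, function(col) {
      stats::median(exp(log(col) - lgm))
    })
  } else {
    tot <- colSums(k)
    if (all(tot == 0)) stop("all-zero count matrix")
    s <- tot / mean(tot)
  }
  s <- s / exp(mean(log(s)))
  cm$size_factors <- stats::setNames(s, colnames(k))
  cm
}

#' Per-feature NB dispersion estimates
#'
#' Method-of-moments estimate from normalized counts pooled within conditions,
#' `alpha_hat = max(alpha_min, (s2 - mu) / mu^2)`, shrunk geometrically toward
#' a least-squares `a0/mu + a1` trend fitted over features with mean > 1:
#' `alpha = exp(w log alpha_hat + (1 - w) log alpha_trend)`.
#'
#' With two replicates per condition the feature-wise moment estimate is
#' extremely noisy (and floored at `alpha_min` whenever the sample variance
#' falls below the mean, which happens for a large share of features); mixing
#' it in geometrically drags dispersions toward zero and breaks Wald Type-I
#' control. The default is therefore full shrinkage to the trend (`w = 0`),
#' which restores calibration; `w > 0` re-enables per-feature mixing for
#' designs with more replicates.
#'
#' @param cm `count_matrix` with size factors.
#' @param w Shrinkage weight on the feature-wise estimate (default 0: pure
#'   trend; see Details).
#' @param alpha_min Dispersion floor.
#' @return Numeric vector of dispersions (one per feature), with the trend
#'   coefficients in `attr(, "trend")`.
#' @export
estimate_dispersion <- function(cm, w = 0, alpha_min = 1e-8) {
  q <- normalized_counts(cm)
  cond <- cm$samples$condition
  n_rep <- table(cond)
  if (all(n_rep < 2)) {
    warning("no condition has replicates; dispersion set to trend prior 0.1")
    out <- rep(0.1, nrow(q))
    attr(out, "trend") <- c(a0 = 0, a1 = 0.1)
    return(out)
  }
  mu_bar <- rowMeans(q)
  # pooled within-condition variance
  ss <- 0; df <- 0
  for (cc in names(n_rep)) {
    idx <- which(cond == cc)
    if (length(idx) < 2) next
    m <- rowMeans(q[, idx, drop = FALSE])
    ss <- ss + rowSums((q[, idx, drop = FALSE] - m)^2)
    df <- df + (length(idx) - 1)
  }
  s2 <- ss / df
  alpha_hat <- pmax(alpha_min, (s2 - mu_bar) / pmax(mu_bar, 1e-9)^2)
  fit_idx <- which(mu_bar > 1)
  if (length(fit_idx) >= 2) {
    X <- cbind(a0 = 1 / mu_bar[fit_idx], a1 = 1)
    coefs <- stats::lm.fit(X, alpha_hat[fit_idx])$coefficients
    coefs[is.na(coefs)] <- 0
  } else {
    coefs <- c(a0 = 0, a1 = stats::median(alpha_hat))
  }
  alpha_tr <- pmax(coefs[1] / pmax(mu_bar, 1e-9) + coefs[2], alpha_min)
  out <- exp(w * log(alpha_hat) + (1 - w) * log(alpha_tr))
  out <- pmax(out, alpha_min)
  attr(out, "trend") <- coefs
  out
}

#' Contrast specification
#' @param treatment,control Condition labels.
#' @param lfc_threshold,fdr_threshold Classification thresholds
#'   (DRIP default 1 and 0.1; RNA-seq differential expression uses 0.05).
#' @param pseudocount Added to both condition means in the log2 ratio.
#' @return list of class `contrast_spec`.
#' @export
contrast_spec <- function(treatment, control, lfc_threshold = 1,
                          fdr_threshold = 0.1, pseudocount = 0.5) {
  stopifnot(lfc_threshold > 0, fdr_threshold > 0)
  structure(list(treatment = treatment, control = control,
                 lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
                 pseudocount = pseudocount), class = "contrast_spec")
}

#' Negative-binomial Wald test for one contrast
#'
#' Per feature: `log2fc = log2((mu_t + eps) / (mu_c + eps))` from
#' condition-mean normalized counts; `Var(q_ij) = mu / s_j + alpha mu^2`
#' propagated by the delta method,
#' `se = sqrt(V_t / mu_t^2 + V_c / mu_c^2) / ln 2` with
#' `V = (1/n^2) sum_j Var(q_ij)`; `z = log2fc / se`; two-sided normal p.
#' Features with zero counts in every sample get p = q = 1 and are excluded
#' from the BH correction.
#'
#' @param cm `count_matrix` with size factors.
#' @param contrast `contrast_spec`.
#' @param alpha Dispersion vector from [estimate_dispersion()] (recycled if
#'   length 1).
#' @return data.frame: id, base_mean, log2fc, se, z, p, q (classification via
#'   [classify_differential()]).
#' @export
wald_test <- function(cm, contrast, alpha) {
  cond <- cm$samples$condition
  ti <- which(cond == contrast$treatment)
  ci <- which(cond == contrast$control)
  if (length(ti) == 0 || length(ci) == 0) {
    stop("contrast conditions not present in count matrix")
  }
  q <- normalized_counts(cm)
  alpha <- rep_len(alpha, nrow(q))
  eps <- contrast$pseudocount
  mu_t <- rowMeans(q[, ti, drop = FALSE])
  mu_c <- rowMeans(q[, ci, drop = FALSE])
  log2fc <- log2((mu_t + eps) / (mu_c + eps))
  s <- cm$size_factors
  vcond <- function(mu, idx) {
    v <- outer(mu, 1 / s[idx]) + alpha * mu^2
    rowSums(v) / length(idx)^2
  }
  V_t <- vcond(mu_t, ti)
  V_c <- vcond(mu_c, ci)
  se <- sqrt(V_t / (mu_t + eps)^2 + V_c / (mu_c + eps)^2) / log(2)
  se[se == 0] <- NA_real_
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[is.na(p)] <- 1
  allzero <- rowSums(cm$counts) == 0
  p[allzero] <- 1
  qv <- rep(1, length(p))
  if (any(!allzero)) qv[!allzero] <- bh_fdr(p[!allzero])
  data.frame(id = rownames(q), base_mean = rowMeans(q),
             log2fc = log2fc, se = se, z = z, p = p, q = qv,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR
#'
#' `q_i = min over {j : p_j >= p_i} of (m p_j / rank_j)`, clipped to 1.
#' @param p Numeric p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
}

#' Classify features as gain / loss / unchanged
#'
#' gain iff log2fc > threshold and q < fdr; loss iff log2fc < -threshold and
#' q < fdr; otherwise unchanged.
#'
#' @param result [wald_test()] output.
#' @param contrast `contrast_spec` carrying the thresholds.
#' @return `result` with a `class` column.
#' @export
classify_differential <- function(result, contrast) {
  cl <- rep("unchanged", nrow(result))
  sig <- result$q < contrast$fdr_threshold
  cl[sig & result$log2fc > contrast$lfc_threshold] <- "gain"
  cl[sig & result$log2fc < -contrast$lfc_threshold] <- "loss"
  result$class <- cl
  result
}

#' Full differential pipeline for one contrast
#' @param cm `count_matrix` (size factors computed here if absent).
#' @param contrast `contrast_spec`.
#' @param alpha Optional precomputed dispersions.
#' @return Classified data.frame (see [wald_test()]).
#' @export
differential_test <- function(cm, contrast, alpha = NULL) {
  if (is.null(cm$size_factors)) cm <- size_factors(cm)
  if (is.null(alpha)) alpha <- estimate_dispersion(cm)
  classify_differential(wald_test(cm, contrast, alpha), contrast)
}
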