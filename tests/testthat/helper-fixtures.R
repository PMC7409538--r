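# Fixtures and independent brute-force oracles. Oracles are deliberately
# naive (per-base / quadratic / literal-definition) and never share code with
# the implementation paths they check.

# ---- random fixtures --------------------------------------------------------

random_intervals <- function(n, max_coord = 200, chroms = c("chrA", "chrB")) {
  s <- sample.int(max_coord - 2, n, replace = TRUE)
  w <- sample.int(20, n, replace = TRUE)
  gi(sample(chroms, n, replace = TRUE), s, pmin(s + w, max_coord))
}

# Random gene set on a toy genome; genes may overlap (feature-map priorities
# must resolve that).
random_gene_set <- function(n_genes, chrom_len = 2e4, chroms = "chr1") {
  rows <- list(); exrows <- list()
  for (i in seq_len(n_genes)) {
    ch <- sample(chroms, 1)
    len <- sample(500:3000, 1)
    s <- sample.int(chrom_len - len - 1, 1)
    strand <- sample(c("+", "-"), 1)
    bio <- sample(c("coding", "noncoding"), 1, prob = c(0.85, 0.15))
    k <- sample(1:3, 1)
    bnd <- sort(sample(seq(40, len - 40, by = 20), 2 * k - 2))
    es <- s + c(0, bnd)[seq(1, 2 * k - 1, by = 2)]
    ee <- s + c(bnd, len)[seq(1, 2 * k - 1, by = 2)]
    id <- sprintf("g%03d", i)
    if (bio == "coding") {
      cs <- es[1] + floor((ee[1] - es[1]) / 2)
      ce <- es[k] + ceiling((ee[k] - es[k]) / 2)
      if (ce <= cs) { cs <- es[1]; ce <- ee[k] }
    } else { cs <- NA_real_; ce <- NA_real_ }
    rows[[i]] <- data.frame(gene_id = id, chrom = ch, start = s, end = s + len,
                            strand = strand, biotype = bio,
                            cds_start = cs, cds_end = ce,
                            stringsAsFactors = FALSE)
    exrows[[i]] <- data.frame(gene_id = id, start = es, end = ee,
                              stringsAsFactors = FALSE)
  }
  gene_set(do.call(rbind, rows), do.call(rbind, exrows))
}

tiny_assembly <- function(lens = c(chr1 = 2e4)) genome_assembly(lens)

# Small deterministic gene set used across tests: two + and one - strand gene.
toy_genes <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    start = c(2000, 8000, 14000),
    end = c(5000, 11000, 17000),
    strand = c("+", "-", "+"),
    biotype = c("coding", "coding", "noncoding"),
    cds_start = c(2500, 8500, NA),
    cds_end = c(4500, 10500, NA),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    start = c(2000, 4000, 8000, 10000, 14000),
    end = c(3000, 5000, 9000, 11000, 17000),
    stringsAsFactors = FALSE)
  gene_set(genes, exons)
}

# ---- oracles ----------------------------------------------------------------

# Literal repeated pairwise merging until fixed point.
oracle_merge <- function(x, max_gap) {
  x <- x[, c("chrom", "start", "end")]
  if (nrow(x) == 0) return(x)
  rows <- split(x, seq_len(nrow(x)))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (i >= j || is.null(rows[[i]]) || is.null(rows[[j]])) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap <= max_gap) {
          rows[[i]] <- data.frame(chrom = a$chrom, start = min(a$start, b$start),
                                  end = max(a$end, b$end))
          rows[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end")]
  rownames(out) <- NULL
  out
}

# Per-base distance oracle: 0 if the intervals share a base, else the number
# of bases strictly between the closest base pair (the half-open gap).
oracle_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_real_)
  ia <- a$start:(a$end - 1); ib <- b$start:(b$end - 1)
  d <- min(abs(outer(ia, ib, "-")))
  if (d == 0) 0 else d - 1
}

# Full scan of all genes for both ranks.
oracle_nearest <- function(peak, gs, mode) {
  g <- gs$genes[gs$genes$chrom == peak$chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  mid <- peak$start + floor((peak$end - peak$start) / 2)
  d <- vapply(seq_len(nrow(g)), function(i) {
    if (mode == "endpoint") min(abs(mid - g$tss[i]), abs(mid - g$tts[i]))
    else max(max(peak$start, g$start[i]) - min(peak$end, g$end[i]), 0)
  }, numeric(1))
  o <- order(d, g$start, g$gene_id)
  data.frame(gene_id = g$gene_id[o], distance = d[o])
}

# Direct per-base labeling with the same window definitions but independent
# bookkeeping: paint categories base by base following the priority order.
oracle_feature_map <- function(gs, assembly, promoter_up = 1000,
                               promoter_down = 100, tts_up = 100,
                               tts_down = 1000) {
  cats <- feature_categories()
  prio <- stats::setNames(seq_along(cats), cats) # 1 = highest
  out <- lapply(assembly$chrom_names, function(ch) {
    L <- assembly$chrom_lengths[[ch]]
    lab <- rep("intergenic", L)
    pr <- rep(prio[["intergenic"]], L)
    setbase <- function(pos, cat) {
      pos <- pos[pos >= 1 & pos <= L]
      better <- prio[[cat]] < pr[pos]
      lab[pos[better]] <<- cat
      pr[pos[better]] <<- prio[[cat]]
    }
    g <- gs$genes[gs$genes$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      body <- (g$start[i] + 1):g$end[i]
      if (g$biotype[i] == "noncoding") {
        setbase(body, "noncoding")
      } else {
        setbase(body, "intron")
        ex <- gs$exons[gs$exons$gene_id == g$gene_id[i], , drop = FALSE]
        for (j in seq_len(nrow(ex))) setbase((ex$start[j] + 1):ex$end[j], "exon")
        if (!is.na(g$cds_start[i])) {
          for (j in seq_len(nrow(ex))) {
            epos <- (ex$start[j] + 1):ex$end[j]
            left <- epos[epos <= g$cds_start[i]]
            right <- epos[epos > g$cds_end[i]]
            if (g$strand[i] == "+") {
              setbase(left, "5'UTR"); setbase(right, "3'UTR")
            } else {
              setbase(left, "3'UTR"); setbase(right, "5'UTR")
            }
          }
        }
      }
      if (g$strand[i] == "+") {
        setbase((g$tts[i] - tts_up + 1):(g$tts[i] + tts_down), "TTS")
        setbase((g$tss[i] - promoter_up + 1):(g$tss[i] + promoter_down), "promoter-TSS")
      } else {
        setbase((g$tts[i] - tts_down + 2):(g$tts[i] + tts_up + 1), "TTS")
        setbase((g$tss[i] - promoter_down + 2):(g$tss[i] + promoter_up + 1), "promoter-TSS")
      }
    }
    lab
  })
  names(out) <- assembly$chrom_names
  out
}

# Quadratic read-in-feature counting.
oracle_count <- function(features, reads) {
  vapply(seq_len(nrow(features)), function(i) {
    sum(reads$chrom == features$chrom[i] &
          reads$start < features$end[i] & reads$end > features$start[i])
  }, numeric(1))
}

# Literal-definition BH: q_i = min over {j: p_j >= p_i} of m p_j / rank_j.
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(m * p[js] / rank(p, ties.method = "max")[js]))
  }, numeric(1))
}

# Hypergeometric upper tail by explicit summation with base choose().
oracle_hyper <- function(N, nA, nB, k) {
  ks <- k:min(nA, nB)
  sum(choose(nA, ks) * choose(N - nA, nB - ks)) / choose(N, nB)
}

# Pearson correlation from the raw definition.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Build a read_set quickly from vectors.
mk_reads <- function(chrom, start, end, strand = ".", sample_id = "s1",
                     condition = "c1", replicate = "A", assay = "DRIP-IP") {
  read_set(sample_id, condition, replicate, assay,
           gi(chrom, start, end, strand))
}

# NB count matrix generator for differential tests.
nb_counts <- function(n_feat, mu, alpha, n_per_group = 2,
                      lfc = rep(0, n_feat),
                      conditions = c("ctl", "trt")) {
  ns <- n_per_group * 2
  counts <- matrix(0L, n_feat, ns)
  cond <- rep(conditions, each = n_per_group)
  for (j in seq_len(ns)) {
    m <- if (cond[j] == conditions[2]) mu * 2^lfc else rep_len(mu, n_feat)
    counts[, j] <- if (alpha > 0) {
      stats::rnbinom(n_feat, mu = m, size = 1 / alpha)
    } else stats::rpois(n_feat, m)
  }
  rownames(counts) <- sprintf("f%05d", seq_len(n_feat))
  colnames(counts) <- paste0(cond, "_", rep(seq_len(n_per_group), 2))
  count_matrix(counts, data.frame(sample_id = colnames(counts),
                                  condition = cond,
                                  replicate = as.character(rep(seq_len(n_per_group), 2)),
                                  stringsAsFactors = FALSE))
}
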