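# Seeded simulator of a DRIP-seq / RNA-seq study: synthetic genome with
# GC/CpG-elevated promoters, non-overlapping gene models, planted R-loop
# peaks with per-condition gains/losses, an input and an RNase-H control,
# and stranded RNA-seq with planted intergenic antisense loci. All outputs
# are deterministic functions of (config, seed) through named substreams,
# so adding a stage never perturbs another stage's draws.

#' Derive a reproducible substream seed from a master seed and a name
#' @param seed Master integer seed.
#' @param name Substream name.
#' @return Integer in [1, 2^31 - 2].
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% (2^31 - 2) + 1)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  force(expr)
}

#' Simulation configuration
#'
#' Defaults describe the demo-scale study emulated throughout: one 10-Mb
#' chromosome, 300 genes, four siRNA conditions (control + three knockdowns)
#' with two DRIP replicates and three RNA-seq replicates each, 100 planted
#' R-loop peaks at 8x enrichment over a 0.01 reads/bp background, per-condition
#' gains at log2FC = 2 and losses at -2, NB dispersion 0.05, and an RNase-H
#' control retaining a residual fraction rho = 0.05 of peak signal.
#'
#' @param seed Master seed; every random draw descends from it.
#' @param ... Overrides for any default field.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_chroms = 1,
    chrom_length = 1e7,
    n_genes = 300,
    gene_meanlog = log(8000), gene_sdlog = 0.5,
    gene_min_len = 1500, gene_max_len = 40000,
    min_spacing = 3000,
    noncoding_frac = 0.1,
    make_sequence = TRUE,
    promoter_gc = 0.6, background_gc = 0.4,
    n_peaks = 100,
    peak_mix = c(TSS = 0.4, TTS = 0.3, intron = 0.2, intergenic = 0.1),
    peak_length = 2000,
    background_rate = 0.01,
    input_rate = 0.01,
    peak_enrichment = 8,
    conditions = c("siCTL", "siDDX5", "siXRN2", "siPRMT5"),
    control = "siCTL",
    replicates = 2,
    n_gain = 25, gain_lfc = 2,
    n_loss = 5, loss_lfc = -2,
    gene_density_weights = NULL, # per-chromosome gene apportioning weights
    gain_placement = NULL,       # prefer gains at peaks of this class
    gain_chroms = NULL,          # restrict preferred gains to these chromosomes
    nb_dispersion = 0.05,
    rnaseh_rho = 0.05,
    read_length = 75,
    rna_replicates = 3,
    rnaseq_depth = 2e5,
    rna_background_rate = 0.001,
    nascent_intron_fraction = 0.1,
    rna_read_length = 100,
    n_de_genes = 30, de_lfc_range = c(1, 2.5),
    n_antisense = 10,
    antisense_fold = 4,
    antisense_length = 2000,
    antisense_side = "TSS-upstream",
    antisense_condition = NULL, # default: first knockdown
    antisense = NULL            # or explicit data.frame(gene_id, side, condition, fold, length)
  )
  over <- list(...)
  # JSON round-trips write NULL fields as {} / []; treat those as unset
  over <- Filter(function(x) !(is.list(x) && length(x) == 0) && length(x) > 0, over)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (is.null(cfg$antisense_condition)) {
    cfg$antisense_condition <- setdiff(cfg$conditions, cfg$control)[1]
  }
  cfg$peak_mix <- unlist(cfg$peak_mix)
  if (is.null(names(cfg$peak_mix))) {
    # JSON round-trips drop names from atomic vectors; positions are fixed
    if (length(cfg$peak_mix) != 4) stop("peak_mix needs 4 named entries")
    names(cfg$peak_mix) <- c("TSS", "TTS", "intron", "intergenic")
  }
  stopifnot(cfg$background_rate >= 0, cfg$peak_enrichment > 0,
            cfg$chrom_length > 0, cfg$n_genes >= 0,
            cfg$control %in% cfg$conditions)
  structure(cfg, class = "sim_config")
}

random_dna_bytes <- function(L, gc) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  charToRaw("ACGT")[sample.int(4, L, replace = TRUE, prob = prob)]
}

# Base composition for promoter sequence such that after CpG boosting the
# realized GC equals the target (the boost replaces some A/T after C with G).
promoter_base_gc <- function(target) {
  f <- function(gcp) {
    pG <- gcp / 2
    gcp + (gcp / 2) * (pG / (1 - pG)) * (1 - gcp) - target
  }
  stats::uniroot(f, c(0.05, 0.95))$root
}

# Promoter sequence with GC = gc_target and ~doubled CpG dinucleotide rate:
# i.i.d. draw at an adjusted composition, then positions following a C that
# are not already G are flipped to G with probability pG/(1-pG), which doubles
# P(G | previous = C).
promoter_dna_bytes <- function(L, gc_target) {
  gcp <- promoter_base_gc(gc_target)
  b <- random_dna_bytes(L, gcp)
  if (L < 2) return(b)
  pG <- gcp / 2
  s <- pG / (1 - pG)
  prevC <- which(b[-L] == charToRaw("C"))
  cand <- prevC + 1
  cand <- cand[b[cand] != charToRaw("G")]
  flip <- cand[stats::runif(length(cand)) < s]
  b[flip] <- charToRaw("G")
  b
}

#' Simulate a genome assembly and gene models
#'
#' Genes are placed uniformly without overlap and with a minimum intergenic
#' spacing; sequence (optional) is i.i.d. at `background_gc` except promoter
#' windows, drawn at `promoter_gc` with a doubled CpG dinucleotide rate.
#' Deterministic given `config$seed`.
#'
#' @param config `sim_config`.
#' @return list(assembly = `genome_assembly`, genes = `gene_set`).
#' @export
simulate_genome <- function(config) {
  cfg <- config
  with_substream(cfg$seed, "genome", {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
    # apportion genes across chromosomes (uneven densities via weights)
    wts <- if (is.null(cfg$gene_density_weights)) rep(1, cfg$n_chroms)
    else rep_len(cfg$gene_density_weights, cfg$n_chroms)
    n_per <- diff(round(cfg$n_genes * cumsum(c(0, wts)) / sum(wts)))
    genes_list <- list(); exons_list <- list()
    gid <- 0
    for (ci in seq_along(chroms)) {
      n <- n_per[ci]
      if (n == 0) next
      L <- lens[[ci]]
      glen <- round(pmin(pmax(stats::rlnorm(n, cfg$gene_meanlog, cfg$gene_sdlog),
                              cfg$gene_min_len), cfg$gene_max_len))
      extra <- L - sum(glen) - (n + 1) * cfg$min_spacing
      if (extra < 0) {
        stop("genes cannot be placed without overlap on ", chroms[ci],
             "; reduce n_genes or gene lengths")
      }
      w <- stats::rexp(n + 1)
      gaps <- cfg$min_spacing + extra * w / sum(w)
      starts <- round(cumsum(gaps[seq_len(n)]) + cumsum(c(0, glen[-n])))
      ends <- starts + glen
      strand <- sample(c("+", "-"), n, replace = TRUE)
      biotype <- ifelse(stats::runif(n) < cfg$noncoding_frac, "noncoding", "coding")
      for (i in seq_len(n)) {
        gid <- gid + 1
        id <- sprintf("gene%04d", gid)
        len <- glen[i]
        k <- if (len < 3000) 1L else sample(2:6, 1)
        nparts <- 2L * k - 1L
        parts <- stats::rexp(nparts) + 0.3
        widths <- floor(len * parts / sum(parts))
        widths[1] <- widths[1] + (len - sum(widths))
        widths <- pmax(widths, 20)
        widths[1] <- widths[1] - (sum(widths) - len)
        bnd <- cumsum(c(0, widths))
        es <- starts[i] + bnd[seq(1, nparts, by = 2)]
        ee <- starts[i] + bnd[seq(1, nparts, by = 2) + 1]
        exons_list[[length(exons_list) + 1]] <-
          data.frame(gene_id = id, start = es, end = ee, stringsAsFactors = FALSE)
        if (biotype[i] == "coding") {
          cs <- es[1] + floor((ee[1] - es[1]) / 2)
          ce <- es[length(es)] + ceiling((ee[length(ee)] - es[length(es)]) / 2)
          if (ce <= cs) { cs <- es[1]; ce <- ee[length(ee)] }
        } else {
          cs <- NA_real_; ce <- NA_real_
        }
        genes_list[[length(genes_list) + 1]] <- data.frame(
          gene_id = id, chrom = chroms[ci], start = starts[i], end = ends[i],
          strand = strand[i], biotype = biotype[i],
          cds_start = cs, cds_end = ce, stringsAsFactors = FALSE)
      }
    }
    genes <- if (length(genes_list) > 0) do.call(rbind, genes_list) else
      data.frame(gene_id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(), biotype = character(),
                 cds_start = numeric(), cds_end = numeric())
    exons <- if (length(exons_list) > 0) do.call(rbind, exons_list) else
      data.frame(gene_id = character(), start = numeric(), end = numeric())
    gs <- gene_set(genes, exons)
    seq <- NULL
    if (cfg$make_sequence) {
      seqs <- lapply(chroms, function(ch) {
        b <- random_dna_bytes(lens[[ch]], cfg$background_gc)
        gc <- gs$genes[gs$genes$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(gc))) {
          if (gc$strand[i] == "+") {
            ps <- gc$tss[i] - 1000; pe <- gc$tss[i] + 100
          } else {
            ps <- gc$tss[i] - 99; pe <- gc$tss[i] + 1001
          }
          ps <- max(0, ps); pe <- min(lens[[ch]], pe)
          if (pe > ps) b[(ps + 1):pe] <- promoter_dna_bytes(pe - ps, cfg$promoter_gc)
        }
        rawToChar(b)
      })
      seq <- Biostrings::DNAStringSet(stats::setNames(unlist(seqs), chroms))
    }
    list(assembly = genome_assembly(lens, seq), genes = gs)
  })
}

# Plant peak placements and the per-condition true log2FC matrix.
plant_peaks <- function(assembly, gs, config) {
  cfg <- config
  with_substream(cfg$seed, "plant_peaks", {
    if (cfg$n_peaks == 0) {
      pk <- data.frame(chrom = character(), center = numeric(),
                       gene_id = character(), class = character(),
                       start = numeric(), end = numeric(), peak = character(),
                       stringsAsFactors = FALSE)
      return(list(peaks = pk,
                  lfc = matrix(0, 0, length(cfg$conditions),
                               dimnames = list(NULL, cfg$conditions))))
    }
    half <- floor(cfg$peak_length / 2)
    counts <- round(cfg$n_peaks * cfg$peak_mix / sum(cfg$peak_mix))
    counts[1] <- counts[1] + (cfg$n_peaks - sum(counts))
    g <- gs$genes
    placements <- list()
    used_genes <- character(0)
    pick_genes <- function(n, pool) {
      pool <- setdiff(pool, used_genes)
      if (length(pool) < n) stop("not enough genes to place peaks; reduce n_peaks")
      sample(pool, n)
    }
    if (counts[["TSS"]] > 0) {
      ids <- pick_genes(counts[["TSS"]], g$gene_id)
      used_genes <- c(used_genes, ids)
      gi2 <- g[match(ids, g$gene_id), ]
      placements$TSS <- data.frame(chrom = gi2$chrom, center = gi2$tss,
                                   gene_id = ids, class = "TSS", stringsAsFactors = FALSE)
    }
    if (counts[["TTS"]] > 0) {
      ids <- pick_genes(counts[["TTS"]], g$gene_id)
      used_genes <- c(used_genes, ids)
      gi2 <- g[match(ids, g$gene_id), ]
      placements$TTS <- data.frame(chrom = gi2$chrom, center = gi2$tts,
                                   gene_id = ids, class = "TTS", stringsAsFactors = FALSE)
    }
    if (counts[["intron"]] > 0) {
      ok <- g$gene_id[(g$end - g$start) > cfg$peak_length + 2000]
      ids <- pick_genes(counts[["intron"]], ok)
      used_genes <- c(used_genes, ids)
      gi2 <- g[match(ids, g$gene_id), ]
      lo <- gi2$start + half + 500; hi <- gi2$end - half - 500
      placements$intron <- data.frame(
        chrom = gi2$chrom,
        center = floor(lo + stats::runif(length(ids)) * (hi - lo)),
        gene_id = ids, class = "intron", stringsAsFactors = FALSE)
    }
    if (counts[["intergenic"]] > 0) {
      # intergenic gaps with margin around gene bodies
      margin <- 1500
      gaps <- list()
      for (ch in assembly$chrom_names) {
        gc2 <- g[g$chrom == ch, , drop = FALSE]
        body <- merge_intervals(gi(rep(ch, nrow(gc2) + 0), gc2$start, gc2$end))
        bs <- c(body$start, assembly$chrom_lengths[[ch]])
        be <- c(0, body$end)
        gs2 <- be + margin; ge2 <- bs - margin
        keep <- (ge2 - gs2) >= cfg$peak_length + 200
        if (any(keep)) gaps[[ch]] <- data.frame(chrom = ch, start = gs2[keep],
                                                end = ge2[keep])
      }
      gaps <- do.call(rbind, gaps)
      if (is.null(gaps) || nrow(gaps) == 0) stop("no intergenic space for peaks")
      idx <- sample.int(nrow(gaps), counts[["intergenic"]],
                        replace = counts[["intergenic"]] > nrow(gaps),
                        prob = gaps$end - gaps$start)
      lo <- gaps$start[idx] + half; hi <- gaps$end[idx] - half
      placements$intergenic <- data.frame(
        chrom = gaps$chrom[idx],
        center = floor(lo + stats::runif(length(idx)) * (hi - lo)),
        gene_id = NA_character_, class = "intergenic", stringsAsFactors = FALSE)
    }
    pk <- do.call(rbind, placements)
    pk$start <- pmax(0, pk$center - half)
    pk$end <- pk$start + cfg$peak_length
    pk <- pk[order(pk$chrom, pk$start), ]
    pk$peak <- sprintf("truth%03d", seq_len(nrow(pk)))
    rownames(pk) <- NULL
    # verify disjoint
    if (nrow(merge_intervals(pk)) < nrow(pk)) {
      stop("planted peaks overlap; reduce n_peaks or peak_length")
    }
    # per-condition true log2FC
    kds <- setdiff(cfg$conditions, cfg$control)
    lfc <- matrix(0, nrow(pk), length(cfg$conditions),
                  dimnames = list(pk$peak, cfg$conditions))
    for (kd in kds) {
      gain_pool <- pk$peak
      gains <- character(0)
      if (kd == cfg$antisense_condition && cfg$n_antisense > 0) {
        tss_peaks <- pk$peak[pk$class == "TSS"]
        n_at_tss <- min(max(cfg$n_antisense, 0), length(tss_peaks))
        gains <- sample(tss_peaks, n_at_tss)
      }
      if (!is.null(cfg$gain_placement) || !is.null(cfg$gain_chroms)) {
        pref <- pk$peak
        if (!is.null(cfg$gain_placement)) pref <- intersect(pref, pk$peak[pk$class %in% cfg$gain_placement])
        if (!is.null(cfg$gain_chroms)) pref <- intersect(pref, pk$peak[pk$chrom %in% cfg$gain_chroms])
        pref <- setdiff(pref, gains)
        n_pref <- min(cfg$n_gain - length(gains), length(pref))
        if (n_pref > 0) gains <- c(gains, sample(pref, n_pref))
      }
      rest <- setdiff(gain_pool, gains)
      n_more <- max(cfg$n_gain - length(gains), 0)
      gains <- c(gains, sample(rest, min(n_more, length(rest))))
      losses <- sample(setdiff(pk$peak, gains), min(cfg$n_loss, nrow(pk) - length(gains)))
      lfc[gains, kd] <- cfg$gain_lfc
      lfc[losses, kd] <- cfg$loss_lfc
    }
    list(peaks = pk, lfc = lfc)
  })
}

uniform_starts <- function(n, lo, hi) {
  # integer start positions uniform in [lo, hi] (hi >= lo)
  floor(lo + stats::runif(n) * (hi - lo + 1 - 1e-9))
}

sample_background_reads <- function(assembly, rate, read_len) {
  pieces <- lapply(assembly$chrom_names, function(ch) {
    L <- assembly$chrom_lengths[[ch]]
    n <- stats::rpois(1, rate * L)
    if (n == 0) return(NULL)
    s <- uniform_starts(n, 0, max(0, L - read_len))
    data.frame(chrom = ch, start = s, end = s + read_len, strand = ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) empty_gi() else out
}

#' Simulate DRIP-seq read sets
#'
#' One IP per condition x replicate, one pooled input (background only) and
#' one pooled RNase-H control (background plus residual fraction `rnaseh_rho`
#' of peak signal). Within a planted peak the IP read rate is
#' `background_rate * enrichment * 2^log2FC(peak, condition)` with a
#' gamma-distributed replicate multiplier (mean 1, variance `nb_dispersion`),
#' i.e. replicate counts are negative-binomially over-dispersed.
#'
#' @param assembly `genome_assembly`.
#' @param gs `gene_set`.
#' @param config `sim_config`.
#' @param truth Result of the internal peak-planting step (made automatically
#'   by [simulate_all()]).
#' @return list(read_sets = list of `read_set`, truth = planted peak table).
#' @export
simulate_drip_reads <- function(assembly, gs, config, truth = NULL) {
  cfg <- config
  if (is.null(truth)) truth <- plant_peaks(assembly, gs, cfg)
  pk <- truth$peaks; lfc <- truth$lfc
  rl <- cfg$read_length
  rs <- list()
  for (cond in cfg$conditions) {
    for (rep_i in seq_len(cfg$replicates)) {
      rs[[length(rs) + 1]] <- with_substream(cfg$seed, paste("drip", cond, rep_i), {
        reads <- sample_background_reads(assembly, cfg$background_rate, rl)
        if (nrow(pk) > 0) {
          gam <- if (cfg$nb_dispersion > 0) {
            stats::rgamma(nrow(pk), shape = 1 / cfg$nb_dispersion,
                          scale = cfg$nb_dispersion)
          } else rep(1, nrow(pk))
          m <- cfg$peak_enrichment * 2^lfc[, cond] * gam
          extra_n <- stats::rpois(nrow(pk), cfg$background_rate * pmax(m - 1, 0) *
                                    (pk$end - pk$start))
          keep <- extra_n > 0
          if (any(keep)) {
            idx <- rep.int(which(keep), extra_n[keep])
            s <- uniform_starts(length(idx), pk$start[idx],
                                pmax(pk$start[idx], pk$end[idx] - rl))
            reads <- rbind(reads, data.frame(chrom = pk$chrom[idx], start = s,
                                             end = s + rl, strand = ".",
                                             stringsAsFactors = FALSE))
          }
        }
        reads <- reads[order(reads$chrom, reads$start), ]
        rownames(reads) <- NULL
        read_set(paste0(cond, "_", c("A", "B", "C", "D", "E")[rep_i]),
                 cond, c("A", "B", "C", "D", "E")[rep_i], "DRIP-IP", reads)
      })
    }
  }
  rs[[length(rs) + 1]] <- with_substream(cfg$seed, "drip input", {
    reads <- sample_background_reads(assembly, cfg$input_rate, rl)
    reads <- reads[order(reads$chrom, reads$start), ]; rownames(reads) <- NULL
    read_set("input", "pooled", "A", "DRIP-input", reads)
  })
  rs[[length(rs) + 1]] <- with_substream(cfg$seed, "drip rnaseh", {
    reads <- sample_background_reads(assembly, cfg$background_rate, rl)
    if (nrow(pk) > 0) {
      sig <- cfg$rnaseh_rho * cfg$background_rate * (cfg$peak_enrichment - 1) *
        (pk$end - pk$start)
      extra_n <- stats::rpois(nrow(pk), pmax(sig, 0))
      keep <- extra_n > 0
      if (any(keep)) {
        idx <- rep.int(which(keep), extra_n[keep])
        s <- uniform_starts(length(idx), pk$start[idx],
                            pmax(pk$start[idx], pk$end[idx] - rl))
        reads <- rbind(reads, data.frame(chrom = pk$chrom[idx], start = s,
                                         end = s + rl, strand = ".",
                                         stringsAsFactors = FALSE))
      }
    }
    reads <- reads[order(reads$chrom, reads$start), ]; rownames(reads) <- NULL
    read_set("rnaseh", "pooled", "A", "DRIP-RNaseH", reads)
  })
  names(rs) <- vapply(rs, function(x) x$sample_id, character(1))
  list(read_sets = rs, truth = truth)
}

# Decide RNA-side planted effects: gene expression, DE genes per knockdown,
# and antisense loci (attached to genes hosting TSS gain peaks of the
# antisense condition unless given explicitly).
plant_rna_effects <- function(assembly, gs, config, truth) {
  cfg <- config
  with_substream(cfg$seed, "plant_rna", {
    g <- gs$genes
    expr <- stats::setNames(stats::rlnorm(nrow(g), log(5), 1), g$gene_id)
    kds <- setdiff(cfg$conditions, cfg$control)
    anti <- cfg$antisense
    if (is.null(anti) && cfg$n_antisense > 0) {
      host_peaks <- truth$peaks[truth$peaks$class == "TSS" &
                                  truth$lfc[truth$peaks$peak, cfg$antisense_condition] > 0, ,
                                drop = FALSE]
      hosts <- host_peaks$gene_id[!is.na(host_peaks$gene_id)]
      hosts <- utils::head(hosts, cfg$n_antisense)
      if (length(hosts) < cfg$n_antisense) {
        warning("only ", length(hosts), " antisense loci could be planted")
      }
      anti <- data.frame(gene_id = hosts, side = cfg$antisense_side,
                         condition = cfg$antisense_condition,
                         fold = cfg$antisense_fold, length = cfg$antisense_length,
                         stringsAsFactors = FALSE)
    }
    if (is.null(anti)) {
      anti <- data.frame(gene_id = character(), side = character(),
                         condition = character(), fold = numeric(),
                         length = numeric(), stringsAsFactors = FALSE)
    }
    # antisense windows must be intergenic
    if (nrow(anti) > 0) {
      win <- antisense_truth_windows(anti, gs)
      body <- merge_intervals(gi(g$chrom, g$start, g$end))
      for (i in seq_len(nrow(win))) {
        bch <- body[body$chrom == win$chrom[i], ]
        if (any(overlaps_sorted(win$start[i], win$end[i], bch$start, bch$end))) {
          stop("antisense locus for gene ", win$gene_id[i], " overlaps a gene body")
        }
      }
    }
    de <- list()
    for (kd in kds) {
      pool <- setdiff(g$gene_id, anti$gene_id)
      ids <- sample(pool, min(cfg$n_de_genes, length(pool)))
      if (length(ids) == 0) next
      de[[kd]] <- data.frame(
        gene_id = ids, condition = kd,
        lfc = sample(c(-1, 1), length(ids), replace = TRUE) *
          stats::runif(length(ids), cfg$de_lfc_range[1], cfg$de_lfc_range[2]),
        stringsAsFactors = FALSE)
    }
    de <- if (length(de) > 0) do.call(rbind, de) else
      data.frame(gene_id = character(), condition = character(), lfc = numeric())
    rownames(de) <- NULL
    list(expression = expr, de_genes = de, antisense = anti)
  })
}

# Genomic window of each antisense locus (strand-aware: TSS-upstream is 5' of
# the gene; TTS-downstream is 3' of the gene).
antisense_truth_windows <- function(anti, gs) {
  g <- gs$genes[match(anti$gene_id, gs$genes$gene_id), ]
  up <- anti$side == "TSS-upstream"
  plus <- g$strand == "+"
  start <- ifelse(up,
                  ifelse(plus, g$start - anti$length, g$end),
                  ifelse(plus, g$end, g$start - anti$length))
  end <- start + anti$length
  data.frame(gene_id = anti$gene_id, chrom = g$chrom, start = start, end = end,
             strand = ifelse(up,
                             ifelse(plus, "-", "+"),       # antisense strand
                             ifelse(plus, "+", "-")),      # read-through: sense
             side = anti$side, stringsAsFactors = FALSE)
}

#' Simulate stranded RNA-seq read sets
#'
#' Exonic reads per gene proportional to expression x exonic length on the
#' gene's strand; intronic reads at `nascent_intron_fraction` of the gene
#' rate; a uniform intergenic background with random strand; and planted
#' antisense loci emitting opposite-strand reads upstream of the TSS (or
#' sense-strand reads downstream of the TTS for the read-through class) at
#' `fold` x the local intergenic background in the planted condition and 1x in
#' all others.
#'
#' @inheritParams simulate_drip_reads
#' @param effects Result of the internal RNA-effect planting (made
#'   automatically by [simulate_all()]).
#' @return list(read_sets, effects).
#' @export
simulate_rnaseq_reads <- function(assembly, gs, config, truth = NULL, effects = NULL) {
  cfg <- config
  if (is.null(truth)) truth <- plant_peaks(assembly, gs, cfg)
  if (is.null(effects)) effects <- plant_rna_effects(assembly, gs, cfg, truth)
  g <- gs$genes
  rl <- cfg$rna_read_length
  expr <- effects$expression
  exlen_tab <- tapply(gs$exons$end - gs$exons$start, gs$exons$gene_id, sum)
  exlen <- stats::setNames(as.numeric(exlen_tab[g$gene_id]), g$gene_id)
  exlen[is.na(exlen)] <- 0
  w_ctl <- expr * exlen
  denom <- sum(w_ctl)
  anti_win <- if (nrow(effects$antisense) > 0)
    antisense_truth_windows(effects$antisense, gs) else NULL
  rs <- list()
  for (cond in cfg$conditions) {
    lfc_g <- stats::setNames(rep(0, nrow(g)), g$gene_id)
    de_c <- effects$de_genes[effects$de_genes$condition == cond, , drop = FALSE]
    lfc_g[de_c$gene_id] <- de_c$lfc
    mu_g <- cfg$rnaseq_depth * w_ctl * 2^lfc_g / denom
    for (rep_i in seq_len(cfg$rna_replicates)) {
      rs[[length(rs) + 1]] <- with_substream(cfg$seed, paste("rna", cond, rep_i), {
        gam <- if (cfg$nb_dispersion > 0) {
          stats::rgamma(nrow(g), shape = 1 / cfg$nb_dispersion,
                        scale = cfg$nb_dispersion)
        } else rep(1, nrow(g))
        n_ex <- stats::rpois(nrow(g), mu_g * gam)
        n_in <- stats::rpois(nrow(g), mu_g * gam * cfg$nascent_intron_fraction)
        pieces <- list()
        for (i in which(n_ex + n_in > 0)) {
          id <- g$gene_id[i]
          ex <- gs$exons[gs$exons$gene_id == id, , drop = FALSE]
          if (n_ex[i] > 0 && nrow(ex) > 0) {
            ei <- sample.int(nrow(ex), n_ex[i], replace = TRUE,
                             prob = ex$end - ex$start)
            s <- uniform_starts(n_ex[i], ex$start[ei],
                                pmax(ex$start[ei], ex$end[ei] - rl))
            pieces[[length(pieces) + 1]] <- data.frame(
              chrom = g$chrom[i], start = s, end = pmin(s + rl, g$end[i]),
              strand = g$strand[i], stringsAsFactors = FALSE)
          }
          if (n_in[i] > 0) {
            intr <- interval_complement_within(ex, g$start[i], g$end[i])
            if (nrow(intr) > 0) {
              ii <- sample.int(nrow(intr), n_in[i], replace = TRUE,
                               prob = intr$end - intr$start)
              s <- uniform_starts(n_in[i], intr$start[ii],
                                  pmax(intr$start[ii], intr$end[ii] - rl))
              pieces[[length(pieces) + 1]] <- data.frame(
                chrom = g$chrom[i], start = s, end = pmin(s + rl, g$end[i]),
                strand = g$strand[i], stringsAsFactors = FALSE)
            }
          }
        }
        bg <- sample_background_reads(assembly, cfg$rna_background_rate, rl)
        if (nrow(bg) > 0) bg$strand <- sample(c("+", "-"), nrow(bg), replace = TRUE)
        pieces[[length(pieces) + 1]] <- bg
        if (!is.null(anti_win)) {
          fold <- ifelse(effects$antisense$condition == cond, effects$antisense$fold, 1)
          n_a <- stats::rpois(nrow(anti_win),
                              cfg$rna_background_rate * (anti_win$end - anti_win$start) * fold)
          for (i in which(n_a > 0)) {
            s <- uniform_starts(n_a[i], anti_win$start[i],
                                max(anti_win$start[i], anti_win$end[i] - rl))
            pieces[[length(pieces) + 1]] <- data.frame(
              chrom = anti_win$chrom[i], start = s,
              end = pmin(s + rl, anti_win$end[i]),
              strand = anti_win$strand[i], stringsAsFactors = FALSE)
          }
        }
        reads <- do.call(rbind, pieces)
        if (is.null(reads) || nrow(reads) == 0) {
          reads <- data.frame(chrom = character(), start = numeric(),
                              end = numeric(), strand = character())
        }
        reads <- reads[order(reads$chrom, reads$start), ]
        rownames(reads) <- NULL
        read_set(paste0("rna_", cond, "_", rep_i), cond, as.character(rep_i),
                 "RNAseq", reads)
      })
    }
  }
  names(rs) <- vapply(rs, function(x) x$sample_id, character(1))
  list(read_sets = rs, effects = effects)
}

# Complement of sorted sub-intervals within [lo, hi).
interval_complement_within <- function(x, lo, hi) {
  if (nrow(x) == 0) return(data.frame(start = lo, end = hi))
  x <- x[order(x$start), , drop = FALSE]
  s <- c(lo, x$end); e <- c(x$start, hi)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' Run the whole simulator
#'
#' @param config `sim_config`.
#' @return list(config, assembly, genes, truth, drip, rnaseq) where `truth`
#'   bundles planted peaks (+ per-condition log2FC), antisense loci, DE genes
#'   and expression levels.
#' @export
simulate_all <- function(config) {
  gen <- simulate_genome(config)
  truth <- plant_peaks(gen$assembly, gen$genes, config)
  drip <- simulate_drip_reads(gen$assembly, gen$genes, config, truth)
  effects <- plant_rna_effects(gen$assembly, gen$genes, config, truth)
  rna <- simulate_rnaseq_reads(gen$assembly, gen$genes, config, truth, effects)
  list(config = config, assembly = gen$assembly, genes = gen$genes,
       truth = list(peaks = truth$peaks, lfc = truth$lfc,
                    antisense = effects$antisense, de_genes = effects$de_genes,
                    expression = effects$expression),
       drip = drip$read_sets, rnaseq = rna$read_sets)
}

#' Write a simulation to disk
#'
#' Emits genome FASTA (when sequence present), chrom.sizes, genes as GTF and
#' BED12, one BED6 per sample under reads/, truth.json, config.json and a
#' manifest with per-file checksums.
#'
#' @param sim Result of [simulate_all()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  files <- character(0)
  if (!is.null(sim$assembly$sequence)) {
    write_fasta(sim$assembly, file.path(dir, "genome.fa"))
    files <- c(files, "genome.fa")
  }
  write_chrom_sizes(sim$assembly$chrom_lengths, file.path(dir, "chrom.sizes"))
  write_gtf(sim$genes, file.path(dir, "genes.gtf"))
  write_bed12(sim$genes, file.path(dir, "genes.bed12"))
  files <- c(files, "chrom.sizes", "genes.gtf", "genes.bed12")
  samples <- list()
  for (rs in c(sim$drip, sim$rnaseq)) {
    f <- file.path("reads", paste0(rs$sample_id, ".bed"))
    r <- rs$reads
    r$name <- "."; r$score <- 0
    write_bed(r, file.path(dir, f))
    files <- c(files, f)
    samples[[length(samples) + 1]] <- list(
      sample_id = rs$sample_id, condition = rs$condition,
      replicate = rs$replicate, assay = rs$assay,
      library_size = rs$library_size, file = f)
  }
  truth <- sim$truth
  truth_json <- list(
    seed = sim$config$seed,
    peaks = cbind(truth$peaks,
                  as.data.frame(truth$lfc[truth$peaks$peak, , drop = FALSE])),
    antisense = truth$antisense,
    de_genes = truth$de_genes,
    expression = data.frame(gene_id = names(truth$expression),
                            expression = as.numeric(truth$expression))
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "truth.json", "config.json")
  manifest <- list(kind = "driploop-simulation", seed = sim$config$seed,
                   samples = samples,
                   checksums = stats::setNames(
                     lapply(files, function(f) unname(tools::md5sum(file.path(dir, f)))),
                     files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a simulation directory back into memory
#' @param dir Directory written by [write_simulation()].
#' @return list like [simulate_all()]'s (truth fields from truth.json).
#' @export
read_simulation <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$peak_mix <- unlist(cfg$peak_mix)
  config <- do.call(sim_config, cfg[setdiff(names(cfg), "seed")] |>
                      (\(x) c(list(seed = cfg$seed), x))())
  lens <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  fa <- file.path(dir, "genome.fa")
  assembly <- if (file.exists(fa)) read_fasta_assembly(fa) else genome_assembly(lens)
  genes <- read_gtf(file.path(dir, "genes.gtf"))
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  drip <- list(); rnaseq <- list()
  for (s in man$samples) {
    reads <- read_bed(file.path(dir, s$file))
    rs <- read_set(s$sample_id, s$condition, s$replicate, s$assay,
                   reads[, c("chrom", "start", "end", "strand")])
    if (s$assay == "RNAseq") rnaseq[[s$sample_id]] <- rs else drip[[s$sample_id]] <- rs
  }
  pk <- as.data.frame(truth_raw$peaks)
  lfc <- as.matrix(pk[, config$conditions, drop = FALSE])
  rownames(lfc) <- pk$peak
  list(config = config, assembly = assembly, genes = genes,
       truth = list(peaks = pk[, setdiff(names(pk), config$conditions)],
                    lfc = lfc,
                    antisense = as.data.frame(truth_raw$antisense),
                    de_genes = as.data.frame(truth_raw$de_genes),
                    expression = stats::setNames(truth_raw$expression$expression,
                                                 truth_raw$expression$gene_id)),
       drip = drip, rnaseq = rnaseq)
}
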