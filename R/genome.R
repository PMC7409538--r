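#' Genome assembly container
#'
#' Chromosome names, lengths and (optionally) sequence. Sequence is held as a
#' `Biostrings::DNAStringSet` named by chromosome.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp > 0).
#' @param sequence Optional `DNAStringSet` (or named character vector) whose
#'   widths match `chrom_lengths`.
#' @return Object of class `genome_assembly`.
#' @export
genome_assembly <- function(chrom_lengths, sequence = NULL) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths))) {
    stop("chrom_lengths must be uniquely named")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (!is.null(sequence)) {
    if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
    if (!setequal(names(sequence), names(chrom_lengths))) {
      stop("sequence names must match chromosome names")
    }
    sequence <- sequence[names(chrom_lengths)]
    if (!all(Biostrings::width(sequence) == unname(chrom_lengths))) {
      stop("sequence widths must equal chromosome lengths")
    }
  }
  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = chrom_lengths,
                 sequence = sequence),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp",
      if (is.null(x$sequence)) "(no sequence)" else "(with sequence)", "\n")
  invisible(x)
}

#' Gene model container
#'
#' One transcript per gene. `genes` must have columns gene_id, chrom, start,
#' end, strand (+/-), biotype ("coding"/"noncoding"), and optionally
#' cds_start/cds_end (0-based half-open, NA for noncoding). TSS/TTS are
#' derived from strand: TSS = start for +, end - 1 for -; TTS the opposite end.
#' `exons` has columns gene_id, start, end (non-overlapping within a gene).
#'
#' @param genes Gene body data.frame.
#' @param exons Exon data.frame.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (!"biotype" %in% names(genes)) genes$biotype <- rep("coding", nrow(genes))
  if (!"cds_start" %in% names(genes)) genes$cds_start <- rep(NA_real_, nrow(genes))
  if (!"cds_end" %in% names(genes)) genes$cds_end <- rep(NA_real_, nrow(genes))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$tts <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  if (nrow(genes) == 0) {
    genes$tss <- numeric(0); genes$tts <- numeric(0)
  }
  ge <- merge(exons, genes[, c("gene_id", "start", "end")],
              by = "gene_id", suffixes = c("", ".gene"))
  if (any(ge$start < ge$start.gene | ge$end > ge$end.gene)) {
    stop("exons must lie within their gene body")
  }
  o <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' A sample's aligned reads
#'
#' @param sample_id Sample identifier.
#' @param condition Condition label (e.g. "siCTL").
#' @param replicate Replicate label.
#' @param assay One of "DRIP-IP", "DRIP-input", "DRIP-RNaseH", "RNAseq".
#' @param reads Interval data.frame of aligned reads (strand "." for DRIP).
#' @return Object of class `read_set`; `library_size` is `nrow(reads)`.
#' @export
read_set <- function(sample_id, condition, replicate, assay, reads) {
  assay <- match.arg(assay, c("DRIP-IP", "DRIP-input", "DRIP-RNaseH", "RNAseq"))
  if (assay == "RNAseq" && !all(reads$strand %in% c("+", "-"))) {
    stop("RNA-seq reads must be stranded (+/-)")
  }
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = replicate, assay = assay,
                 reads = reads, library_size = nrow(reads)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set %s [%s %s/%s]: %d reads\n", x$sample_id, x$assay,
              x$condition, x$replicate, x$library_size))
  invisible(x)
}

## ---------------------------------------------------------------- file I/O

#' Read / write a chromosome sizes table (two-column TSV: name, length)
#' @param path File path.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$length), df$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_lengths Named numeric vector.
#' @export
write_chrom_sizes <- function(chrom_lengths, path) {
  utils::write.table(data.frame(names(chrom_lengths), format(chrom_lengths, scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BED6 interval files
#'
#' BED6 columns: chrom, start, end, name, score, strand. Coordinates pass
#' through unchanged (both sides 0-based half-open).
#' @param path File path.
#' @return Interval data.frame with extra columns name, score.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4, 6)))
  data.table::setnames(dt, seq_len(ncol(dt)),
                       c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(dt))])
  df <- as.data.frame(dt)
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  df
}

#' @rdname read_bed
#' @param x Interval data.frame (optional name/score columns).
#' @export
write_bed <- function(x, path) {
  dt <- data.table::data.table(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genome assembly's sequence as FASTA
#' @param assembly `genome_assembly` with sequence.
#' @param path Output path.
#' @export
write_fasta <- function(assembly, path) {
  if (is.null(assembly$sequence)) stop("assembly has no sequence")
  Biostrings::writeXStringSet(assembly$sequence, path, width = 70)
  invisible(path)
}

#' Read a FASTA + chromosome sizes into a genome assembly
#' @param fasta Path to FASTA.
#' @return `genome_assembly` with sequence.
#' @export
read_fasta_assembly <- function(fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_assembly(stats::setNames(Biostrings::width(seqs), names(seqs)), seqs)
}

#' Write gene models as GTF
#'
#' Emits gene, exon and CDS lines, 1-based inclusive coordinates per the GTF
#' standard. One transcript per gene (transcript_id = gene_id + ".t1").
#' @param gs `gene_set`.
#' @param path Output path.
#' @export
write_gtf <- function(gs, path) {
  g <- gs$genes
  tid <- paste0(g$gene_id, ".t1")
  attr_of <- function(gene_id, transcript_id, biotype) {
    paste0("gene_id \"", gene_id, "\"; transcript_id \"", transcript_id,
           "\"; gene_biotype \"", biotype, "\";")
  }
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- c(
    sprintf("%s\tdriploop\tgene\t%s\t%s\t.\t%s\t.\t%s",
            g$chrom, fmt(g$start + 1), fmt(g$end), g$strand,
            attr_of(g$gene_id, tid, g$biotype))
  )
  e <- merge(gs$exons, g[, c("gene_id", "chrom", "strand", "biotype")], by = "gene_id")
  e <- e[order(match(e$gene_id, g$gene_id), e$start), ]
  lines <- c(lines,
             sprintf("%s\tdriploop\texon\t%s\t%s\t.\t%s\t.\t%s",
                     e$chrom, fmt(e$start + 1), fmt(e$end), e$strand,
                     attr_of(e$gene_id, paste0(e$gene_id, ".t1"), e$biotype)))
  cds <- g[!is.na(g$cds_start), , drop = FALSE]
  if (nrow(cds) > 0) {
    lines <- c(lines,
               sprintf("%s\tdriploop\tCDS\t%s\t%s\t.\t%s\t.\t%s",
                       cds$chrom, fmt(cds$cds_start + 1), fmt(cds$cds_end), cds$strand,
                       attr_of(cds$gene_id, paste0(cds$gene_id, ".t1"), cds$biotype)))
  }
  writeLines(lines, path)
  invisible(path)
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, " \"[^\"]*\""), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(paste0(key, " \""), attrs)
  out[hit] <- sub(paste0(key, " \"([^\"]*)\""), "\\1", m)
  out
}

#' Read gene models from GTF, keeping the longest transcript per gene
#'
#' Parses gene/exon/CDS lines. When a gene has several transcripts, only the
#' longest (by genomic span of its exons) is retained.
#' @param path GTF path.
#' @return `gene_set`.
#' @export
read_gtf <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", quote = "",
                          col.names = c("chrom", "source", "feature", "start",
                                        "end", "score", "strand", "frame", "attrs"))
  df <- as.data.frame(dt)
  df$gene_id <- gtf_attr(df$attrs, "gene_id")
  df$transcript_id <- gtf_attr(df$attrs, "transcript_id")
  df$biotype <- gtf_attr(df$attrs, "gene_biotype")
  ex <- df[df$feature == "exon", , drop = FALSE]
  # longest transcript per gene by exon span
  span <- stats::aggregate(cbind(s = ex$start, e = ex$end),
                           by = list(gene_id = ex$gene_id, transcript_id = ex$transcript_id),
                           FUN = function(x) x[1])
  span$s <- tapply(ex$start, paste(ex$gene_id, ex$transcript_id), min)[paste(span$gene_id, span$transcript_id)]
  span$e <- tapply(ex$end, paste(ex$gene_id, ex$transcript_id), max)[paste(span$gene_id, span$transcript_id)]
  span$len <- span$e - span$s
  span <- span[order(span$gene_id, -span$len, span$transcript_id), ]
  keep_tx <- span$transcript_id[!duplicated(span$gene_id)]
  ex <- ex[ex$transcript_id %in% keep_tx, , drop = FALSE]
  gsub_first <- function(v) v[1]
  genes <- data.frame(
    gene_id = tapply(ex$gene_id, ex$gene_id, gsub_first),
    chrom = tapply(ex$chrom, ex$gene_id, gsub_first),
    start = as.numeric(tapply(ex$start, ex$gene_id, min)) - 1,
    end = as.numeric(tapply(ex$end, ex$gene_id, max)),
    strand = tapply(ex$strand, ex$gene_id, gsub_first),
    biotype = tapply(ifelse(is.na(ex$biotype), "coding", ex$biotype), ex$gene_id, gsub_first),
    stringsAsFactors = FALSE
  )
  cds <- df[df$feature == "CDS" & df$transcript_id %in% keep_tx, , drop = FALSE]
  if (nrow(cds) > 0) {
    cs <- tapply(cds$start, cds$gene_id, min) - 1
    ce <- tapply(cds$end, cds$gene_id, max)
    genes$cds_start <- as.numeric(cs[genes$gene_id])
    genes$cds_end <- as.numeric(ce[genes$gene_id])
  }
  exons <- data.frame(gene_id = ex$gene_id, start = ex$start - 1, end = ex$end,
                      stringsAsFactors = FALSE)
  gene_set(genes, exons)
}

#' Write gene models as BED12
#'
#' Blocks are exons; thickStart/thickEnd is the CDS (or the gene start for
#' noncoding genes, the BED12 convention for no thick region).
#' @param gs `gene_set`.
#' @param path Output path.
#' @export
write_bed12 <- function(gs, path) {
  g <- gs$genes
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  rows <- vapply(seq_len(nrow(g)), function(i) {
    e <- gs$exons[gs$exons$gene_id == g$gene_id[i], , drop = FALSE]
    e <- e[order(e$start), ]
    thick_s <- if (is.na(g$cds_start[i])) g$start[i] else g$cds_start[i]
    thick_e <- if (is.na(g$cds_end[i])) g$start[i] else g$cds_end[i]
    paste(g$chrom[i], fmt(g$start[i]), fmt(g$end[i]), g$gene_id[i], 0, g$strand[i],
          fmt(thick_s), fmt(thick_e), "0", nrow(e),
          paste0(paste(fmt(e$end - e$start), collapse = ","), ","),
          paste0(paste(fmt(e$start - g$start[i]), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read gene models from BED12
#' @param path BED12 path.
#' @return `gene_set`.
#' @export
read_bed12 <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  df <- as.data.frame(dt)
  names(df)[1:12] <- c("chrom", "start", "end", "gene_id", "score", "strand",
                       "thick_start", "thick_end", "rgb", "n_blocks",
                       "block_sizes", "block_starts")
  exons <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    bs <- as.numeric(strsplit(df$block_sizes[i], ",")[[1]])
    bo <- as.numeric(strsplit(df$block_starts[i], ",")[[1]])
    data.frame(gene_id = df$gene_id[i], start = df$start[i] + bo,
               end = df$start[i] + bo + bs, stringsAsFactors = FALSE)
  }))
  genes <- data.frame(gene_id = df$gene_id, chrom = df$chrom, start = df$start,
                      end = df$end, strand = df$strand,
                      biotype = "coding",
                      cds_start = ifelse(df$thick_end > df$thick_start, df$thick_start, NA_real_),
                      cds_end = ifelse(df$thick_end > df$thick_start, df$thick_end, NA_real_),
                      stringsAsFactors = FALSE)
  genes$biotype[is.na(genes$cds_start)] <- "noncoding"
  gene_set(genes, exons)
}
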