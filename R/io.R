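#' Read a BED file of genomic intervals
#'
#' Accepts the 3-column (chrom, start, end), 4-column (+ name) and 6-column
#' (+ name, score, strand) dialects; all lines in one file must have the
#' same column count.  Coordinates are 0-based half-open as in BED.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(data.frame(chrom = character(),
                                        start = numeric(), end = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (length(unique(nc)) != 1)
    stop("mixed column counts in ", path, " (line ",
         which(nc != nc[1])[1], ")")
  if (!nc[1] %in% c(3L, 4L, 6L))
    stop("unsupported BED column count ", nc[1], " in ", path)
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": ", lines[bad[1]])
  out <- data.frame(chrom = m[, 1], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (nc[1] >= 4L) out$name <- m[, 4]
  if (nc[1] == 6L) {
    out$score <- suppressWarnings(as.numeric(m[, 5]))
    out$strand <- m[, 6]
  }
  out
}

#' Write intervals to BED
#'
#' Writes 3, 4 or 6 columns depending on which of `name`, `score`, `strand`
#' are present; the round trip through [read_bed()] is lossless.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(intervals)) {
    cols <- c(cols, "name")
    if (all(c("score", "strand") %in% names(intervals)))
      cols <- c(cols, "score", "strand")
  }
  df <- intervals[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write chromatin domains as BED
#'
#' State goes in the BED name field and the domain mean signal in the score
#' field.
#'
#' @param domains domain data.frame (or a `chromseg_fit`).
#' @param path output file.
#' @export
write_domains_bed <- function(domains, path) {
  if (inherits(domains, "chromseg_fit")) domains <- domains$domains
  out <- data.frame(chrom = domains$chrom, start = domains$start,
                    end = domains$end, name = domains$state,
                    score = round(ifelse(is.na(domains$mean_signal), 0,
                                         domains$mean_signal), 4),
                    strand = ".", stringsAsFactors = FALSE)
  write_bed(out, path)
}

#' Read probe signals
#'
#' Accepts a 4-column BEDGraph (chrom, start, end, value; 0-based starts)
#' or a 3-column tab table (chrom, 1-based position, signal), detected by
#' column count.  A header line is tolerated in the 3-column form.
#'
#' @param path file path.
#' @return probe-signal data.frame (`chrom`, 1-based `position`, `signal`),
#'   sorted by chromosome and position.
#' @export
read_signal_table <- function(path) {
  first <- readLines(path, n = 1)
  nc <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (nc == 4) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "start", "end", "signal"),
                     stringsAsFactors = FALSE)
    out <- data.frame(chrom = df$chrom, position = df$start + 1,
                      signal = df$signal, stringsAsFactors = FALSE)
  } else if (nc == 3) {
    header <- is.na(suppressWarnings(
      as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][2])))
    df <- read.table(path, sep = "\t", header = header,
                     stringsAsFactors = FALSE)
    names(df) <- c("chrom", "position", "signal")
    out <- df
  } else stop("expected 3-column signal table or 4-column BEDGraph: ", path)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  .validate_probe_signals(out)
  out
}

#' Write probe signals as BEDGraph
#'
#' Each point probe becomes a `span`-bp interval starting at its 0-based
#' position.
#'
#' @param signals probe-signal data.frame.
#' @param path output file.
#' @param span interval width in bp (default 1).
#' @export
write_signal_bedgraph <- function(signals, path, span = 1) {
  df <- data.frame(chrom = signals$chrom, start = signals$position - 1,
                   end = signals$position - 1 + span,
                   signal = signals$signal)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF/GFF
#'
#' Imports via rtracklayer, groups exon records by transcript, keeps the
#' longest transcript per gene (configurable), and derives 0-based
#' half-open spans.  CDS records of the kept transcripts are retained so
#' UTRs can be derived.  Genes without exon records are skipped with a
#' warning.
#'
#' @param path GTF/GFF file.
#' @param transcript_choice `"longest"` (default) or `"first"`.
#' @return a [gene_models()] object.
#' @export
read_gtf <- function(path, transcript_choice = c("longest", "first")) {
  transcript_choice <- match.arg(transcript_choice)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  ex <- gr[md$type == "exon"]
  if (!length(ex)) stop("no exon records in ", path)
  exd <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                    start = GenomicRanges::start(ex) - 1,
                    end = GenomicRanges::end(ex),
                    strand = as.character(GenomicRanges::strand(ex)),
                    gene_id = S4Vectors::mcols(ex)$gene_id,
                    transcript_id = S4Vectors::mcols(ex)$transcript_id,
                    stringsAsFactors = FALSE)
  cds_gr <- gr[md$type == "CDS"]
  cdsd <- if (length(cds_gr)) data.frame(
    start = GenomicRanges::start(cds_gr) - 1,
    end = GenomicRanges::end(cds_gr),
    gene_id = S4Vectors::mcols(cds_gr)$gene_id,
    transcript_id = S4Vectors::mcols(cds_gr)$transcript_id,
    stringsAsFactors = FALSE) else NULL
  genes <- list(); exons <- list(); cds <- list()
  for (gid in unique(exd$gene_id)) {
    ge <- exd[exd$gene_id == gid, , drop = FALSE]
    tx_len <- tapply(ge$end - ge$start, ge$transcript_id, sum)
    tx <- if (transcript_choice == "longest")
      names(tx_len)[which.max(tx_len)] else names(tx_len)[1]
    te <- ge[ge$transcript_id == tx, , drop = FALSE]
    te <- te[order(te$start), , drop = FALSE]
    genes[[gid]] <- data.frame(gene_id = gid, chrom = te$chrom[1],
                               strand = te$strand[1],
                               start = min(te$start), end = max(te$end),
                               stringsAsFactors = FALSE)
    exons[[gid]] <- data.frame(gene_id = gid, start = te$start,
                               end = te$end, stringsAsFactors = FALSE)
    if (!is.null(cdsd)) {
      tc <- cdsd[cdsd$transcript_id == tx, , drop = FALSE]
      if (nrow(tc))
        cds[[gid]] <- data.frame(gene_id = gid, start = min(tc$start),
                                 end = max(tc$end), stringsAsFactors = FALSE)
    }
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons),
              if (length(cds)) do.call(rbind, cds) else NULL)
}

#' Write gene models as GTF
#'
#' Emits one transcript per gene with exon and (if present) CDS records;
#' 1-based inclusive coordinates as in GTF.
#'
#' @param models a [gene_models()] object.
#' @param path output file.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  lines <- character(0)
  cds_by <- if (!is.null(models$cds)) split(models$cds, models$cds$gene_id)
            else list()
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                     g$gene_id, g$gene_id)
    ex <- models$exons[models$exons$gene_id == g$gene_id, , drop = FALSE]
    lines <- c(lines, sprintf("%s\tchromseg\texon\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, ex$start + 1, ex$end, g$strand, attrs))
    cd <- cds_by[[g$gene_id]]
    if (!is.null(cd))
      lines <- c(lines, sprintf("%s\tchromseg\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                g$chrom, cd$start + 1, cd$end, g$strand,
                                attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-delimited expression matrix
#'
#' First column gene ids, remaining columns one per sample, header line
#' required.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}
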