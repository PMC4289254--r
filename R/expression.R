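#' Gene model container
#'
#' Bundles gene spans, exons and optional CDS spans into a validated
#' `gene_models` object.  Exons are sorted and must not overlap within a
#' gene; introns, promoters and UTRs are derived on demand by
#' [gene_elements()].
#'
#' @param genes data.frame: `gene_id`, `chrom`, `strand` ("+"/"-"),
#'   `start`, `end` (0-based half-open transcript span).
#' @param exons data.frame: `gene_id`, `start`, `end`.
#' @param cds optional data.frame: `gene_id`, `start`, `end` (one CDS span
#'   per gene); enables UTR derivation.
#' @return object of class `gene_models` (list with `genes`, `exons`,
#'   `cds`).
#' @export
gene_models <- function(genes, exons, cds = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  for (g in split(exons, exons$gene_id)) {
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stop("overlapping exons in gene ", g$gene_id[1])
  }
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' Derive structural gene elements
#'
#' Computes per-gene promoter, exon, intron and (when CDS spans are
#' available) 5'UTR and 3'UTR intervals.  The promoter is the `promoter_width`
#' bp immediately upstream of the annotated TSS, strand-aware: for a minus
#' strand gene it lies downstream of the span in genome coordinates.
#'
#' @param models a [gene_models()] object.
#' @param promoter_width promoter length in bp (default 500).
#' @return data.frame: `gene_id`, `element` (promoter/exon/intron/
#'   utr5/utr3), `chrom`, `start`, `end`.
#' @export
gene_elements <- function(models, promoter_width = 500) {
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  ex_by_gene <- split(models$exons, models$exons$gene_id)
  cds_by_gene <- if (!is.null(models$cds))
    split(models$cds, models$cds$gene_id) else list()
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- ex_by_gene[[g$gene_id]]
    out <- list(data.frame(gene_id = g$gene_id, element = "exon",
                           chrom = g$chrom, start = ex$start, end = ex$end,
                           stringsAsFactors = FALSE))
    if (nrow(ex) > 1) {
      out <- c(out, list(data.frame(gene_id = g$gene_id, element = "intron",
                                    chrom = g$chrom,
                                    start = ex$end[-nrow(ex)],
                                    end = ex$start[-1],
                                    stringsAsFactors = FALSE)))
    }
    prom <- if (g$strand == "+") c(g$start - promoter_width, g$start)
            else c(g$end, g$end + promoter_width)
    out <- c(out, list(data.frame(gene_id = g$gene_id, element = "promoter",
                                  chrom = g$chrom, start = max(prom[1], 0),
                                  end = prom[2], stringsAsFactors = FALSE)))
    cds <- cds_by_gene[[g$gene_id]]
    if (!is.null(cds) && nrow(cds)) {
      cs <- min(cds$start); ce <- max(cds$end)
      left <- .clip_intervals(ex$start, ex$end, g$start, cs)
      right <- .clip_intervals(ex$start, ex$end, ce, g$end)
      u5 <- if (g$strand == "+") left else right
      u3 <- if (g$strand == "+") right else left
      for (nm in c("utr5", "utr3")) {
        u <- if (nm == "utr5") u5 else u3
        if (nrow(u))
          out <- c(out, list(data.frame(gene_id = g$gene_id, element = nm,
                                        chrom = g$chrom, start = u$start,
                                        end = u$end,
                                        stringsAsFactors = FALSE)))
      }
    }
    rows[[i]] <- do.call(rbind, out)
  }
  res <- do.call(rbind, rows)
  res <- res[res$start < res$end, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.clip_intervals <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo); e <- pmin(ends, hi)
  keep <- s < e
  data.frame(start = s[keep], end = e[keep])
}

#' Introns of a gene model set
#'
#' @param models a [gene_models()] object.
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `length`.
#' @export
gene_introns <- function(models) {
  el <- gene_elements(models)
  ir <- el[el$element == "intron", c("gene_id", "chrom", "start", "end"),
           drop = FALSE]
  ir$length <- ir$end - ir$start
  rownames(ir) <- NULL
  ir
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = count / (length / 1000) / (library_size / 1e6)`.
#'
#' @param counts vector or gene x sample matrix of read counts.
#' @param gene_lengths gene lengths in bp (recycled over samples).
#' @param library_sizes mapped reads per sample (scalar for a vector of
#'   counts, one per column for a matrix).
#' @return RPKM values with the shape of `counts`.
#' @examples
#' compute_rpkm(10, 1000, 1e6)   # 10
#' compute_rpkm(250, 2500, 5e6)  # 20
#' @export
compute_rpkm <- function(counts, gene_lengths, library_sizes) {
  if (any(counts < 0)) stop("read counts must be >= 0")
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (is.matrix(counts)) {
    sweep(counts / (gene_lengths / 1000), 2, library_sizes / 1e6, `/`)
  } else {
    counts / (gene_lengths / 1000) / (library_sizes / 1e6)
  }
}

#' Classify genes as active or silent from multi-sample RPKM
#'
#' A gene is active when its RPKM reaches the threshold in every sample
#' ("at least 1 in all five samples" under the defaults), silent otherwise.
#'
#' @param rpkm gene x sample matrix (rownames are gene ids).
#' @param threshold RPKM threshold (default 1).
#' @param n_samples required sample count (default 5).
#' @return named character vector of "active"/"silent" labels.
#' @export
classify_activity <- function(rpkm, threshold = 1, n_samples = 5L) {
  rpkm <- as.matrix(rpkm)
  if (ncol(rpkm) != n_samples)
    stop("expected ", n_samples, " samples, got ", ncol(rpkm))
  bad <- which(!stats::complete.cases(rpkm))
  if (length(bad))
    stop("missing sample value for gene(s): ",
         paste(head(rownames(rpkm)[bad], 5L), collapse = ", "))
  setNames(ifelse(apply(rpkm, 1, min) >= threshold, "active", "silent"),
           rownames(rpkm))
}

#' Gene and intron size categories
#'
#' Genes: less than 1 kb, 1-4 kb (inclusive), more than 4 kb.  Introns:
#' up to 80 bp, 81-200 bp, 201 bp-1 kb, 1-10 kb, more than 10 kb (the
#' category bounds form a partition of the positive integers).
#'
#' @param length_bp numeric vector of lengths.
#' @return factor of category labels.
#' @export
gene_size_category <- function(length_bp) {
  cut(length_bp, breaks = c(0, 999, 4000, Inf),
      labels = c("<1kb", "1-4kb", ">4kb"), include.lowest = TRUE)
}

#' @rdname gene_size_category
#' @export
intron_size_category <- function(length_bp) {
  cut(length_bp, breaks = c(0, 80, 200, 1000, 10000, Inf),
      labels = c("<=80bp", "81-200bp", "201bp-1kb", "1-10kb", ">10kb"),
      include.lowest = TRUE)
}

#' Chromatin composition of gene structural elements by activity
#'
#' For intergenic spacers, whole genes, and each structural element
#' (promoter, exon, intron, UTRs), stratified by gene activity, the
#' percentage of cumulative element bp lying in open, closed and neutral
#' domains.  Intergenic space is the complement of gene spans within the
#' domain-covered span.
#'
#' @param domains domain data.frame from [segment_2cm()]/[segment_3cm()].
#' @param models a [gene_models()] object.
#' @param activity named activity vector from [classify_activity()].
#' @param promoter_width promoter length in bp (default 500).
#' @return data.frame: `group` (activity class or "intergenic"), `element`,
#'   `state`, `pct`, `bp`.
#' @export
element_overlap <- function(domains, models, activity,
                            promoter_width = 500) {
  stopifnot(inherits(models, "gene_models"))
  el <- gene_elements(models, promoter_width)
  genes <- models$genes
  act <- activity[genes$gene_id]
  rows <- list()
  add <- function(group, element, intervals) {
    states <- unique(domains$state)
    if (!nrow(intervals)) return()
    intervals$label <- "x"
    s <- cumulative_overlap(domains, intervals)
    bp <- unclass(s)[, "x"]
    pct <- contribution_to_state(s)[, "x"]
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, element = element, state = states,
      pct = unname(pct[states]), bp = unname(bp[states]),
      stringsAsFactors = FALSE)
  }
  for (a in unique(act)) {
    ids <- genes$gene_id[act == a]
    g <- genes[genes$gene_id %in% ids, , drop = FALSE]
    add(a, "gene", g[, c("chrom", "start", "end")])
    ea <- el[el$gene_id %in% ids, , drop = FALSE]
    for (e in unique(ea$element))
      add(a, e, ea[ea$element == e, c("chrom", "start", "end"), drop = FALSE])
  }
  # intergenic: domain span minus gene spans (promoters, lying outside the
  # transcript, remain part of intergenic space)
  span_gr <- .as_granges(domains[, c("chrom", "start", "end")])
  gene_gr <- .as_granges(genes[, c("chrom", "start", "end")])
  inter <- GenomicRanges::setdiff(span_gr, gene_gr, ignore.strand = TRUE)
  if (length(inter)) {
    idf <- data.frame(chrom = as.character(GenomicRanges::seqnames(inter)),
                      start = GenomicRanges::start(inter) - 1,
                      end = GenomicRanges::end(inter))
    add("intergenic", "intergenic", idf)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chromatin composition by gene or intron size category
#'
#' Assigns each gene (or intron) to its size category and reports, per
#' category and activity class, the percentage of pooled bp in each domain
#' state.
#'
#' @param domains domain data.frame.
#' @param models a [gene_models()] object.
#' @param activity named activity vector.
#' @param what `"gene"` or `"intron"`.
#' @return data.frame: `category`, `group`, `state`, `pct`, `bp`.
#' @export
size_category_analysis <- function(domains, models, activity,
                                   what = c("gene", "intron")) {
  what <- match.arg(what)
  if (what == "gene") {
    iv <- models$genes[, c("gene_id", "chrom", "start", "end")]
    iv$category <- gene_size_category(iv$end - iv$start)
  } else {
    iv <- gene_introns(models)
    iv$category <- intron_size_category(iv$length)
  }
  iv$group <- activity[iv$gene_id]
  rows <- list()
  for (cat in levels(iv$category)) for (a in unique(iv$group)) {
    sub <- iv[iv$category == cat & iv$group == a, , drop = FALSE]
    if (!nrow(sub)) next
    sub$label <- "x"
    s <- cumulative_overlap(domains, sub[, c("chrom", "start", "end",
                                             "label")])
    pct <- contribution_to_state(s)[, "x"]
    bp <- unclass(s)[, "x"]
    states <- unique(domains$state)
    rows[[length(rows) + 1]] <- data.frame(
      category = cat, group = a, state = states,
      pct = unname(pct[states]), bp = unname(bp[states]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# cumulative covered-bp function for merged sorted intervals
.cov_fun <- function(starts, ends) {
  cum <- c(0, cumsum(ends - starts))
  function(x) {
    i <- findInterval(x, starts)
    base <- cum[i + 1]
    inside <- i >= 1 & x < ends[pmax(i, 1)]
    base[inside] <- cum[i[inside]] + (x[inside] - starts[i[inside]])
    base[i == 0] <- 0
    base
  }
}

.merged_state <- function(domains, state) {
  d <- domains[domains$state == state, , drop = FALSE]
  gr <- .as_granges(d[, c("chrom", "start", "end")])
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Positional chromatin profile within introns
#'
#' Divides each intron into non-overlapping 100 bp windows and pools the
#' windows by their position relative to the 5' and 3' intron ends.  For
#' every offset the cumulative open and closed bp are accumulated and the
#' open:closed ratio and fractions derived.  Intended for the long-intron
#' classes (1-10 kb and >10 kb) of active genes; the caller selects the
#' introns.
#'
#' Window offsets are genome-oriented here (offset 0 at the lower
#' coordinate for the 5' profile); for strand-symmetric pooled statistics
#' this matches transcript orientation on average.
#'
#' @param domains domain data.frame.
#' @param introns data.frame (`chrom`, `start`, `end`).
#' @param window window size in bp (default 100).
#' @param max_offset largest window offset to report (default: all).
#' @return list of data.frames `profile5`, `profile3`, `combined`, each
#'   with `offset` (windows from the end), `open_bp`, `closed_bp`,
#'   `open_fraction`, `closed_fraction`, `open_closed_ratio`.
#' @export
intron_profile <- function(domains, introns, window = 100,
                           max_offset = NULL) {
  if (!nrow(introns)) stop("no qualifying introns")
  open_iv <- .merged_state(domains, "open")
  closed_iv <- .merged_state(domains, "closed")
  cov <- list()
  for (chrom in unique(introns$chrom)) {
    o <- open_iv[open_iv$chrom == chrom, , drop = FALSE]
    c_ <- closed_iv[closed_iv$chrom == chrom, , drop = FALSE]
    cov[[chrom]] <- list(open = .cov_fun(o$start, o$end),
                         closed = .cov_fun(c_$start, c_$end))
  }
  acc <- new.env()
  bump <- function(key, off, open_bp, closed_bp) {
    k <- paste0(key, off)
    cur <- get0(k, envir = acc, ifnotfound = c(0, 0))
    assign(k, cur + c(open_bp, closed_bp), envir = acc)
  }
  max_off_seen <- -1L
  for (i in seq_len(nrow(introns))) {
    chrom <- introns$chrom[i]
    st <- introns$start[i]; en <- introns$end[i]
    nwin <- floor((en - st) / window)
    if (nwin < 1) next
    w <- seq_len(nwin) - 1L
    a <- st + w * window; b <- a + window
    ob <- cov[[chrom]]$open(b) - cov[[chrom]]$open(a)
    cb <- cov[[chrom]]$closed(b) - cov[[chrom]]$closed(a)
    off3 <- nwin - 1L - w
    for (j in seq_len(nwin)) {
      bump("5_", w[j], ob[j], cb[j])
      bump("3_", off3[j], ob[j], cb[j])
    }
    max_off_seen <- max(max_off_seen, nwin - 1L)
  }
  lim <- if (is.null(max_offset)) max_off_seen else
    min(max_offset, max_off_seen)
  mk <- function(prefix) {
    off <- 0:lim
    m <- t(vapply(off, function(o)
      get0(paste0(prefix, o), envir = acc, ifnotfound = c(0, 0)),
      numeric(2)))
    tot <- m[, 1] + m[, 2]
    data.frame(offset = off, open_bp = m[, 1], closed_bp = m[, 2],
               open_fraction = ifelse(tot > 0, m[, 1] / tot, NA_real_),
               closed_fraction = ifelse(tot > 0, m[, 2] / tot, NA_real_),
               open_closed_ratio = ifelse(m[, 2] > 0, m[, 1] / m[, 2], Inf))
  }
  p5 <- mk("5_"); p3 <- mk("3_")
  comb <- p5
  comb$open_bp <- p5$open_bp + p3$open_bp
  comb$closed_bp <- p5$closed_bp + p3$closed_bp
  tot <- comb$open_bp + comb$closed_bp
  comb$open_fraction <- ifelse(tot > 0, comb$open_bp / tot, NA_real_)
  comb$closed_fraction <- ifelse(tot > 0, comb$closed_bp / tot, NA_real_)
  comb$open_closed_ratio <- ifelse(comb$closed_bp > 0,
                                   comb$open_bp / comb$closed_bp, Inf)
  list(profile5 = p5, profile3 = p3, combined = comb)
}

#' Tissue-specificity index tau
#'
#' `tau = sum(1 - x_i / max(x)) / (N - 1)` over an expression vector across
#' N tissues: 1 for expression confined to one tissue, 0 for uniform
#' expression.  Higher tau means narrower expression breadth.
#'
#' @param x non-negative expression vector, length >= 2.
#' @return value in \[0, 1\]; `NA` for an all-zero vector.
#' @examples
#' tau(c(1, 0, 0, 0))  # 1
#' tau(c(5, 5, 5))     # 0
#' tau(c(1, 0.5))      # 0.5
#' @export
tau <- function(x) {
  if (length(x) < 2) stop("tau needs expression in at least 2 tissues")
  if (any(x < 0)) stop("expression values must be >= 0")
  xm <- max(x)
  if (xm == 0) return(NA_real_)
  sum(1 - x / xm) / (length(x) - 1)
}

#' Chromatin class of gene clusters
#'
#' A cluster is "open" when its span lies entirely within open domains,
#' "closed" when entirely within closed domains, and "mixed" otherwise —
#' including any neutral bp inside the span (so under a three-configuration
#' segmentation a neutral interruption makes a cluster mixed).
#'
#' @param clusters data.frame: `cluster_id`, `chrom`, `start`, `end`.
#' @param domains domain data.frame.
#' @return data.frame: `cluster_id`, `chromatin_class`, per-state bp
#'   columns; class counts in attribute `counts`.
#' @export
cluster_chromatin_class <- function(clusters, domains) {
  if (any(duplicated(clusters$cluster_id)))
    stop("duplicated cluster ids")
  res <- data.frame(cluster_id = clusters$cluster_id,
                    chromatin_class = NA_character_,
                    open_bp = 0, closed_bp = 0, neutral_bp = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    if (length(unique(cl$chrom)) != 1)
      stop("cluster ", cl$cluster_id, " spans multiple chromosomes")
    span_len <- cl$end - cl$start
    span <- data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
                       label = "span")
    s <- cumulative_overlap(domains, span)
    bp <- setNames(unclass(s)[, "span"], rownames(s))
    for (st in c("open", "closed", "neutral"))
      res[[paste0(st, "_bp")]][i] <- if (st %in% names(bp)) bp[st] else 0
    res$chromatin_class[i] <-
      if (res$open_bp[i] == span_len) "open"
      else if (res$closed_bp[i] == span_len) "closed"
      else "mixed"
  }
  attr(res, "counts") <- table(factor(res$chromatin_class,
                                      levels = c("open", "closed", "mixed")))
  res
}

#' Compare tissue specificity between open- and closed-cluster genes
#'
#' Two-sided Welch t-test and two-sided Mann-Whitney U test on the tau
#' values of genes from uninterrupted open versus closed chromatin
#' clusters.
#'
#' @param tau_open,tau_closed tau values of the two gene groups (length >=
#'   2 each).
#' @return list: `t_p`, `u_p`, `mean_open`, `mean_closed`, `n_open`,
#'   `n_closed`, `t_statistic`, `u_statistic`.
#' @export
compare_cluster_tau <- function(tau_open, tau_closed) {
  if (length(tau_open) < 2 || length(tau_closed) < 2)
    stop("need >= 2 genes per group")
  if (sd(c(tau_open, tau_closed)) == 0)
    stop("degenerate groups: all tau values identical")
  tt <- t.test(tau_open, tau_closed)       # Welch by default
  ut <- suppressWarnings(wilcox.test(tau_open, tau_closed, exact = FALSE))
  list(t_p = tt$p.value, u_p = ut$p.value,
       mean_open = mean(tau_open), mean_closed = mean(tau_closed),
       n_open = length(tau_open), n_closed = length(tau_closed),
       t_statistic = unname(tt$statistic), u_statistic = unname(ut$statistic))
}
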