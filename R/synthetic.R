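#' Configuration for the synthetic genome generator
#'
#' Bundles and validates the parameters of the synthetic tiling-array study.
#' The defaults describe the study conditions used throughout the package's
#' own tests: a 5 Mb single-chromosome genome tiled at 35 bp (the resolution
#' of a high-density tiling array), alternating open/closed domains with
#' exponentially distributed lengths of mean 15 kb, signal means of +0.8 and
#' -0.8 log2 units, and Gaussian probe noise with SD 0.8 (signal-to-noise
#' ratio 1).
#'
#' @param genome_length bp per chromosome.
#' @param n_chromosomes number of chromosomes (all of `genome_length`).
#' @param probe_spacing bp between probe starts; probes are treated as points.
#' @param domain_mean_length mean of the exponential domain-length draw, bp.
#'   Adjacent same-state domains are merged, so the realized mean is larger
#'   (about 2x for two equally weighted states).
#' @param domain_state_weights named probabilities over open/closed/neutral;
#'   must sum to 1.
#' @param open_signal_mean,closed_signal_mean,neutral_signal_mean per-state
#'   signal means, log2 units.  Open must be positive and closed negative
#'   (the open-positive sign convention).
#' @param noise_sd Gaussian probe noise SD, log2 units.
#' @param n_expression_samples expression samples used by the activity
#'   criterion (five in the design this emulates).
#' @param n_tissues tissues in the expression-breadth (tau) vectors.
#' @param rng_seed integer seed; all generator randomness flows through it
#'   (each generator stage uses a fixed offset of this seed, so stages are
#'   independently reproducible).
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(genome_length = 5e6,
                             n_chromosomes = 1L,
                             probe_spacing = 35,
                             domain_mean_length = 15000,
                             domain_state_weights = c(open = 0.5, closed = 0.5,
                                                      neutral = 0),
                             open_signal_mean = 0.8,
                             closed_signal_mean = -0.8,
                             neutral_signal_mean = 0,
                             noise_sd = 0.8,
                             n_expression_samples = 5L,
                             n_tissues = 10L,
                             rng_seed = 1L) {
  w <- domain_state_weights
  if (is.null(names(w))) names(w) <- c("open", "closed", "neutral")[seq_along(w)]
  w <- w[c("open", "closed", "neutral")]
  w[is.na(w)] <- 0
  names(w) <- c("open", "closed", "neutral")
  if (genome_length < 1 || probe_spacing < 1)
    stop("genome_length and probe_spacing must be positive")
  if (domain_mean_length < probe_spacing)
    stop("domain_mean_length must be >= probe_spacing")
  if (abs(sum(w) - 1) > 1e-8) stop("domain_state_weights must sum to 1")
  if (!(open_signal_mean > 0 && closed_signal_mean < 0))
    stop("need open_signal_mean > 0 > closed_signal_mean (open-positive convention)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cfg <- list(genome_length = genome_length,
              n_chromosomes = as.integer(n_chromosomes),
              probe_spacing = probe_spacing,
              domain_mean_length = domain_mean_length,
              domain_state_weights = w,
              open_signal_mean = open_signal_mean,
              closed_signal_mean = closed_signal_mean,
              neutral_signal_mean = neutral_signal_mean,
              noise_sd = noise_sd,
              n_expression_samples = as.integer(n_expression_samples),
              n_tissues = as.integer(n_tissues),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "synthetic_config"
  cfg
}

.state_means <- function(config) {
  c(open = config$open_signal_mean,
    closed = config$closed_signal_mean,
    neutral = config$neutral_signal_mean)
}

#' Simulate planted chromatin domains and probe signals
#'
#' Draws, per chromosome, a partition into open/closed/neutral domains
#' (exponential lengths, i.i.d. states by weight, adjacent same-state domains
#' merged, last domain truncated at the chromosome end) and emits evenly
#' spaced point probes whose signal is Normal(state mean, noise SD).
#'
#' @param config a [synthetic_config()].
#' @return list with `truth` — list holding `domains`, a data.frame
#'   (`chrom`, `start`, `end`, `state`; 0-based half-open, tiling each
#'   chromosome) — and `signals`, a probe-signal data.frame (`chrom`,
#'   1-based `position`, `signal`).
#' @export
simulate_probe_signals <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed)
  L <- config$genome_length
  means <- .state_means(config)
  dom_list <- sig_list <- vector("list", config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    doms <- .draw_domains(L, config$domain_mean_length,
                          config$domain_state_weights)
    doms$chrom <- chrom
    pos <- seq(1, L, by = config$probe_spacing)       # 1-based probe starts
    idx <- findInterval(pos - 1, doms$start)          # domain of each probe
    sig <- rnorm(length(pos), mean = means[doms$state[idx]],
                 sd = config$noise_sd)
    dom_list[[ci]] <- doms[, c("chrom", "start", "end", "state")]
    sig_list[[ci]] <- data.frame(chrom = chrom, position = pos, signal = sig,
                                 stringsAsFactors = FALSE)
  }
  truth <- list(domains = do.call(rbind, dom_list))
  rownames(truth$domains) <- NULL
  signals <- do.call(rbind, sig_list)
  rownames(signals) <- NULL
  list(truth = truth, signals = signals)
}

# exponential lengths, i.i.d. states, merge same-state neighbours, truncate
.draw_domains <- function(L, mean_len, weights) {
  states <- names(weights)[weights > 0]
  w <- weights[weights > 0]
  lens <- st <- list(); tot <- 0; i <- 0
  while (tot < L) {
    i <- i + 1
    lens[[i]] <- max(1, round(rexp(1, rate = 1 / mean_len)))
    st[[i]] <- sample(states, 1L, prob = w)
    tot <- tot + lens[[i]]
  }
  lens <- unlist(lens); st <- unlist(st)
  keep <- c(TRUE, st[-1] != st[-length(st)])
  grp <- cumsum(keep)
  lens <- as.vector(tapply(lens, grp, sum))
  st <- st[keep]
  end <- pmin(cumsum(lens), L)
  start <- c(0, end[-length(end)])
  ok <- start < end
  data.frame(start = start[ok], end = end[ok], state = st[ok],
             stringsAsFactors = FALSE)
}

#' Simulate annotation tracks correlated with planted domains
#'
#' Emulates the external annotation inputs of the analysis: a LAD track
#' covering a fraction of the closed-truth bp (plus a leak fraction of
#' open-truth bp), a chromatin-state track whose labels correlate with the
#' truth, and per-modification enriched/depleted interval tracks.
#'
#' Coverage is implemented per truth domain: each closed domain contributes a
#' random sub-interval of `lad_coverage` times its length, so genome-wide
#' LAD-in-closed bp over closed bp equals `lad_coverage` up to rounding.
#'
#' @param truth ground truth from [simulate_probe_signals()].
#' @param config the [synthetic_config()] used to generate it.
#' @param lad_coverage,lad_leak fraction of closed-truth (resp. open-truth)
#'   bp covered by the LAD track, each in \[0, 1\].
#' @param n_states number of chromatin-state labels (default 9); labels
#'   1..ceiling(n/2) are open-associated, the rest closed-associated.
#' @param state_assoc probability a domain is labelled from its matching
#'   state group.
#' @param modifications character vector of modification names.
#' @param mod_assoc probability a modification's enriched interval falls in
#'   an open-truth domain (depleted intervals use the complement).
#' @return named list of annotation tracks; each track is a data.frame
#'   (`chrom`, `start`, `end`, `label`) with a `kind` attribute in
#'   `state`, `LAD`, `modification_enriched`, `modification_depleted`.
#' @export
simulate_annotations <- function(truth, config,
                                 lad_coverage = 0.9, lad_leak = 0.05,
                                 n_states = 9L, state_assoc = 0.8,
                                 modifications = c("H3K4me3", "H3K9me3",
                                                   "H3K27me3"),
                                 mod_assoc = 0.8) {
  stopifnot(inherits(config, "synthetic_config"))
  fr <- c(lad_coverage, lad_leak, state_assoc, mod_assoc)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  set.seed(config$rng_seed + 1L)
  doms <- truth$domains
  open_d <- doms[doms$state == "open", , drop = FALSE]
  closed_d <- doms[doms$state == "closed", , drop = FALSE]

  lad <- rbind(.subintervals(closed_d, lad_coverage),
               .subintervals(open_d, lad_leak))
  if (nrow(lad)) lad$label <- "LAD"
  else lad <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), label = character())
  attr(lad, "kind") <- "LAD"

  half <- ceiling(n_states / 2)
  open_states <- paste0("state", seq_len(half))
  closed_states <- paste0("state", seq(half + 1, n_states))
  lab <- character(nrow(doms))
  for (i in seq_len(nrow(doms))) {
    match_open <- doms$state[i] == "open"
    if (doms$state[i] == "neutral") match_open <- runif(1) < 0.5
    use_open <- if (runif(1) < state_assoc) match_open else !match_open
    pool <- if (use_open) open_states else closed_states
    lab[i] <- sample(pool, 1L)
  }
  states <- data.frame(chrom = doms$chrom, start = doms$start, end = doms$end,
                       label = lab, stringsAsFactors = FALSE)
  attr(states, "kind") <- "state"

  tracks <- list(LAD = lad, chromatin_states = states)
  for (m in modifications) {
    enr <- rbind(.subintervals(open_d, 0.5 * mod_assoc),
                 .subintervals(closed_d, 0.5 * (1 - mod_assoc)))
    dep <- rbind(.subintervals(closed_d, 0.5 * mod_assoc),
                 .subintervals(open_d, 0.5 * (1 - mod_assoc)))
    for (tr in c("enr", "dep")) {
      x <- get(tr)
      x$label <- m
      attr(x, "kind") <- if (tr == "enr") "modification_enriched"
                         else "modification_depleted"
      tracks[[paste0(m, if (tr == "enr") "_enriched" else "_depleted")]] <- x
    }
  }
  tracks
}

# one random sub-interval of `frac` of each domain's length
.subintervals <- function(doms, frac) {
  if (!nrow(doms) || frac <= 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  len <- round((doms$end - doms$start) * frac)
  keep <- len >= 1
  doms <- doms[keep, , drop = FALSE]; len <- len[keep]
  off <- floor(runif(nrow(doms)) * (doms$end - doms$start - len + 1))
  data.frame(chrom = doms$chrom, start = doms$start + off,
             end = doms$start + off + len, stringsAsFactors = FALSE)
}

#' Simulate gene models, expression and gene clusters over a planted genome
#'
#' Places non-overlapping genes wholly inside truth domains, with lengths
#' spanning the three gene size categories and introns spanning the five
#' intron size categories.  Genes in open domains are planted active
#' (RPKM of at least 1 in all samples), genes in closed domains silent, with probability
#' `coupling` (flipped otherwise).  Additionally places clusters of
#' `cluster_size` genes inside single large open or closed domains and
#' attaches multi-tissue expression vectors whose planted tissue-specificity
#' (tau) is higher for closed-cluster genes by `tau_shift`.
#'
#' @param truth ground truth from [simulate_probe_signals()].
#' @param config the [synthetic_config()] used to generate it.
#' @param n_genes genes to attempt to place (fewer if the genome is full).
#' @param coupling probability that domain state determines activity
#'   (1 = deterministic open=active / closed=silent).
#' @param n_clusters,cluster_size testis-biased-style gene clusters to plant
#'   (at least 3 genes each).
#' @param tau_base planted mean tau of open-cluster genes.
#' @param tau_shift planted tau excess of closed-cluster genes.
#' @param tau_sd between-gene SD of planted tau.
#' @return list with `genes` (a `gene_models` object), `expression`
#'   (list: `rpkm` gene x sample matrix, `counts`, `gene_lengths`,
#'   `library_sizes`), `clusters` (data.frame `cluster_id`, `chrom`, `start`,
#'   `end`, `truth_class`, and `members` list-column), `tissue_expression`
#'   (cluster-gene x tissue matrix), `gene_activity` (named planted labels),
#'   `cluster_assignments` (named planted classes).
#' @export
simulate_genes_and_expression <- function(truth, config,
                                          n_genes = 200L,
                                          coupling = 1.0,
                                          n_clusters = 10L,
                                          cluster_size = 4L,
                                          tau_base = 0.5,
                                          tau_shift = 0.3,
                                          tau_sd = 0.1) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_expression_samples < 5L)
    stop("the activity criterion is defined over five samples; ",
         "n_expression_samples must be >= 5")
  if (cluster_size < 3L) stop("clusters need >= 3 member genes")
  set.seed(config$rng_seed + 2L)

  doms <- truth$domains
  doms <- doms[doms$state %in% c("open", "closed"), , drop = FALSE]
  doms <- doms[order(doms$chrom, doms$start), , drop = FALSE]
  # gene blueprints: size category x intron structure
  genes <- list(); exons <- list(); cds <- list()
  activity <- character(); gid <- 0L
  cursor <- setNames(rep(0, length(unique(doms$chrom))), unique(doms$chrom))
  placed_per_dom <- new.env()

  place_in <- function(dom, len) {
    # leftmost free slot with 100 bp margin
    key <- paste(dom$chrom, dom$start)
    used <- get0(key, envir = placed_per_dom, ifnotfound = dom$start + 100)
    if (used + len + 100 > dom$end) return(NULL)
    assign(key, used + len + 200, envir = placed_per_dom)
    used
  }

  dom_order <- sample(nrow(doms))
  bp_cats <- c("small", "medium", "large")
  for (di in dom_order) {
    if (gid >= n_genes) break
    dom <- doms[di, ]
    cat <- sample(bp_cats, 1L, prob = c(0.3, 0.4, 0.3))
    bp <- .gene_blueprint(cat)
    start0 <- place_in(dom, bp$length)
    if (is.null(start0)) next
    gid <- gid + 1L
    id <- sprintf("gene%04d", gid)
    strand <- sample(c("+", "-"), 1L)
    ex <- bp$exons + start0
    genes[[gid]] <- data.frame(gene_id = id, chrom = dom$chrom,
                               strand = strand, start = start0,
                               end = start0 + bp$length,
                               stringsAsFactors = FALSE)
    exons[[gid]] <- data.frame(gene_id = id, start = ex[, 1], end = ex[, 2],
                               stringsAsFactors = FALSE)
    cds[[gid]] <- data.frame(gene_id = id, start = bp$cds[1] + start0,
                             end = bp$cds[2] + start0, stringsAsFactors = FALSE)
    match_state <- runif(1) < coupling
    open_dom <- dom$state == "open"
    activity[id] <- if (xor(open_dom, !match_state)) "active" else "silent"
  }
  if (gid == 0L) {
    genes <- list(data.frame(gene_id = character(), chrom = character(),
                             strand = character(), start = numeric(),
                             end = numeric()))
    exons <- list(data.frame(gene_id = character(), start = numeric(),
                             end = numeric()))
    cds <- list(NULL)
  }
  gm <- gene_models(do.call(rbind, genes), do.call(rbind, exons),
                    do.call(rbind, cds))

  ns <- config$n_expression_samples
  rpkm <- matrix(numeric(), 0, ns)
  if (length(activity))
    rpkm <- t(vapply(activity, function(a) {
      if (a == "active") 1 + rexp(ns, rate = 1 / 9) else runif(ns, 0, 0.9)
    }, numeric(ns)))
  colnames(rpkm) <- paste0("sample", seq_len(ns))
  lib <- round(runif(ns, 8e6, 2e7))
  glen <- setNames(gm$genes$end - gm$genes$start, gm$genes$gene_id)
  glen <- glen[rownames(rpkm)]
  counts <- round(sweep(rpkm * (glen / 1000), 2, lib / 1e6, `*`))

  clu <- .place_clusters(doms, placed_per_dom, n_clusters, cluster_size)
  tau_targets <- numeric(); tissue_rows <- list()
  if (nrow(clu$clusters)) {
    for (k in seq_len(nrow(clu$clusters))) {
      cl <- clu$clusters[k, ]
      t0 <- if (cl$truth_class == "closed") tau_base + tau_shift else tau_base
      for (g in clu$clusters$members[[k]]) {
        tg <- min(max(t0 + rnorm(1, sd = tau_sd), 0), 1)
        tau_targets[g] <- tg
        v <- numeric(config$n_tissues)
        top <- sample(config$n_tissues, 1L)
        v[top] <- 100
        v[-top] <- 100 * (1 - tg)
        tissue_rows[[g]] <- v
      }
    }
  }
  tissue <- if (length(tissue_rows)) do.call(rbind, tissue_rows) else
    matrix(numeric(), 0, config$n_tissues)
  if (nrow(tissue)) colnames(tissue) <- paste0("tissue", seq_len(config$n_tissues))

  list(genes = gm,
       expression = list(rpkm = rpkm, counts = counts,
                         gene_lengths = glen, library_sizes = lib),
       clusters = clu$clusters,
       tissue_expression = tissue,
       gene_activity = activity,
       cluster_assignments = setNames(clu$clusters$truth_class,
                                      clu$clusters$cluster_id))
}

# exon layout (0-based offsets within the gene), CDS span, total length;
# introns drawn to cover the five size categories across blueprints
.gene_blueprint <- function(cat) {
  intron_pool <- switch(cat,
    small  = list(c(45, 80), c(81, 200)),
    medium = list(c(81, 200), c(201, 1000)),
    large  = list(c(201, 1000), c(1001, 10000), c(10001, 25000)))
  n_ex <- switch(cat, small = sample(1:2, 1), medium = sample(2:4, 1),
                 large = sample(3:5, 1))
  ex_len <- round(runif(n_ex, 120, 450))
  in_len <- if (n_ex > 1) {
    vapply(sample(intron_pool, n_ex - 1, replace = TRUE),
           function(r) round(runif(1, r[1], r[2])), numeric(1))
  } else numeric(0)
  starts <- cumsum(c(0, head(ex_len, -1) + in_len))
  ex <- cbind(starts, starts + ex_len)
  total <- ex[n_ex, 2]
  cds <- c(ex[1, 1] + min(60, floor(ex_len[1] / 2)),
           ex[n_ex, 2] - min(60, floor(ex_len[n_ex] / 2)))
  list(exons = ex, cds = cds, length = total)
}

.place_clusters <- function(doms, placed_per_dom, n_clusters, cluster_size) {
  need <- cluster_size * 1200 + 400       # ~1 kb genes + 200 bp gaps
  out <- list(); k <- 0L
  big <- doms[doms$end - doms$start > need + 2000, , drop = FALSE]
  big <- big[sample(nrow(big)), , drop = FALSE]
  for (di in seq_len(nrow(big))) {
    if (k >= n_clusters) break
    dom <- big[di, ]
    key <- paste(dom$chrom, dom$start)
    used <- get0(key, envir = placed_per_dom, ifnotfound = dom$start + 100)
    if (used + need > dom$end) next
    k <- k + 1L
    members <- sprintf("clgene%03d_%02d", k, seq_len(cluster_size))
    gstart <- used + (seq_len(cluster_size) - 1) * 1200
    assign(key, used + need, envir = placed_per_dom)
    out[[k]] <- data.frame(cluster_id = sprintf("cluster%02d", k),
                           chrom = dom$chrom, start = gstart[1],
                           end = gstart[cluster_size] + 1000,
                           truth_class = dom$state, stringsAsFactors = FALSE)
    out[[k]]$members <- I(list(members))
  }
  clusters <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = character(), chrom = character(),
               start = numeric(), end = numeric(),
               truth_class = character(), members = I(list()))
  list(clusters = clusters)
}
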