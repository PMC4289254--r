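# Independent oracles and small fixture builders shared across tests.

# per-base membership oracle for interval overlap on a single chromosome
# of length L; intervals are 0-based half-open data.frames (start, end)
per_base_overlap_bp <- function(a, b, L) {
  va <- logical(L); vb <- logical(L)
  for (i in seq_len(nrow(a))) va[seq(a$start[i] + 1, a$end[i])] <- TRUE
  for (i in seq_len(nrow(b))) vb[seq(b$start[i] + 1, b$end[i])] <- TRUE
  sum(va & vb)
}

per_base_bp <- function(a, L) {
  va <- logical(L)
  for (i in seq_len(nrow(a))) va[seq(a$start[i] + 1, a$end[i])] <- TRUE
  sum(va)
}

# random non-degenerate interval set on [0, L)
random_intervals <- function(n, L, max_len = NULL) {
  if (is.null(max_len)) max_len <- max(2, L %/% 10)
  start <- sample.int(L - 2, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = "chr1", start = start,
             end = pmin(start + len, L))
}

# build a capped series directly from a +1/-1 value vector (unit fixtures
# for the sliding-window statistic, bypassing the SD filter)
make_capped <- function(values, chrom = "chr1", spacing = 10) {
  df <- data.frame(chrom = chrom,
                   position = seq_along(values) * spacing,
                   signal = values * 2, capped = values,
                   stringsAsFactors = FALSE)
  attr(df, "mean") <- 0
  attr(df, "sd") <- 1
  class(df) <- c("capped_series", "data.frame")
  df
}

# brute-force transition detection: compute d by direct mean() at every
# probe, threshold, and collapse runs by scanning (independent of the
# cumsum-based implementation)
brute_force_transitions <- function(series, n, d_cutoff) {
  d <- rep(NA_real_, nrow(series))
  for (chrom in unique(series$chrom)) {
    rows <- which(series$chrom == chrom)
    v <- series$capped[rows]
    L <- length(v)
    if (L < 2 * n) next
    for (i in n:(L - n)) {
      d[rows[i]] <- abs(mean(v[(i - n + 1):i]) - mean(v[(i + 1):(i + n)]))
    }
  }
  over <- !is.na(d) & d >= d_cutoff
  trans <- integer(0)
  i <- 1
  chrom_f <- as.integer(factor(series$chrom, levels = unique(series$chrom)))
  while (i <= length(over)) {
    if (over[i]) {
      j <- i
      while (j + 1 <= length(over) && over[j + 1] &&
             chrom_f[j + 1] == chrom_f[i]) j <- j + 1
      run <- i:j
      trans <- c(trans, run[which.max(d[run])])
      i <- j + 1
    } else i <- i + 1
  }
  list(d = d, transitions = trans)
}

# fixpoint pairwise-merge oracle for peak consolidation: repeatedly merge
# any adjacent same-sign pair with gap < threshold, then label leftover
# gaps neutral
oracle_consolidate <- function(peaks, threshold, span = NULL) {
  p <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  out <- list()
  for (chrom in unique(p$chrom)) {
    q <- p[p$chrom == chrom, c("start", "end", "sign"), drop = FALSE]
    repeat {
      merged <- FALSE
      if (nrow(q) >= 2) {
        for (i in seq_len(nrow(q) - 1)) {
          if (q$sign[i] == q$sign[i + 1] &&
              q$start[i + 1] - q$end[i] < threshold) {
            q$end[i] <- q$end[i + 1]
            q <- q[-(i + 1), , drop = FALSE]
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }
    segs <- data.frame(chrom = chrom, start = q$start, end = q$end,
                       state = ifelse(q$sign > 0, "open", "closed"))
    gaps <- if (nrow(q) > 1)
      data.frame(chrom = chrom, start = q$end[-nrow(q)],
                 end = q$start[-1], state = "neutral") else NULL
    sp <- if (!is.null(span)) span[span$chrom == chrom, , drop = FALSE] else NULL
    flank <- NULL
    if (!is.null(sp) && nrow(sp)) {
      flank <- rbind(
        data.frame(chrom = chrom, start = sp$start[1], end = q$start[1],
                   state = "neutral"),
        data.frame(chrom = chrom, start = q$end[nrow(q)], end = sp$end[1],
                   state = "neutral"))
    }
    res <- rbind(segs, gaps, flank)
    res <- res[res$start < res$end, , drop = FALSE]
    out[[chrom]] <- res[order(res$start), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# state lookup per base for a tiling domain set (single chromosome)
state_at <- function(domains, pos0) {
  domains <- domains[order(domains$start), , drop = FALSE]
  idx <- findInterval(pos0, domains$start)
  s <- rep(NA_character_, length(pos0))
  ok <- idx >= 1 & pos0 < domains$end[pmax(idx, 1)]
  s[ok] <- domains$state[idx[ok]]
  s
}

# tiny deterministic alternating-domain signal for fast planted tests
planted_signal <- function(n_domains = 10, domain_probes = 120,
                           mean_abs = 1, noise_sd = 0, spacing = 35,
                           seed = 1) {
  set.seed(seed)
  states <- rep(c("open", "closed"), length.out = n_domains)
  mu <- ifelse(states == "open", mean_abs, -mean_abs)
  sig <- rnorm(n_domains * domain_probes,
               mean = rep(mu, each = domain_probes), sd = noise_sd)
  pos <- seq(1, by = spacing, length.out = length(sig))
  truth <- data.frame(chrom = "chr1",
                      start = (seq_len(n_domains) - 1) * domain_probes *
                        spacing,
                      end = seq_len(n_domains) * domain_probes * spacing,
                      state = states)
  list(signals = data.frame(chrom = "chr1", position = pos, signal = sig),
       truth = truth)
}
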