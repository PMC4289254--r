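#' Filter probes by signal deviation and cap to signs
#'
#' First step of the two-configuration model.  The mean and SD of the log2
#' differential signal are taken over all input probes genome-wide; probes
#' whose signal lies strictly within one SD of that mean are discarded as
#' uninformative, and each retained probe is capped to +1 (positive signal,
#' open) or -1 (negative signal, closed).  A retained probe with signal
#' exactly 0 — possible only when the genome-wide mean itself exceeds one SD
#' in magnitude — caps to -1.
#'
#' @param signals probe-signal data.frame (`chrom`, `position`, `signal`).
#' @return object of class `capped_series`: a data.frame `chrom`,
#'   `position`, `signal` (raw), `capped` (+1/-1), restricted to retained
#'   probes and ordered by chromosome and position; attributes `mean` and
#'   `sd` record the filter statistics.
#' @export
filter_and_cap <- function(signals) {
  .validate_probe_signals(signals)
  if (nrow(signals) < 2L) stop("need at least 2 probes to define the SD")
  m <- mean(signals$signal)
  s <- sd(signals$signal)
  if (s == 0) stop("degenerate input: all probe signals identical (SD = 0)")
  keep <- abs(signals$signal - m) >= s
  if (!any(keep))
    stop("empty series: every probe lies within 1 SD of the mean")
  out <- signals[keep, , drop = FALSE]
  out$capped <- ifelse(out$signal > 0, 1, -1)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mean") <- m
  attr(out, "sd") <- s
  class(out) <- c("capped_series", "data.frame")
  out
}

#' Sliding-window transition statistic
#'
#' For each retained probe, the statistic d is the absolute difference
#' between the mean capped value of the n probes up to and including it and
#' the mean of the n probes after it (flanks counted in retained-probe units,
#' within the probe's chromosome).  Probes with fewer than n retained probes
#' on either side get `NA`.
#'
#' @param series a [filter_and_cap()] result.
#' @param n flank size in retained probes.
#' @return numeric vector of d values aligned with `series` rows; `NA` where
#'   the statistic is undefined.
#' @export
transition_statistic <- function(series, n) {
  stopifnot(inherits(series, "capped_series"), n >= 1)
  unsplit(lapply(split(series$capped, series$chrom), .d_stat, n = n),
          series$chrom)
}

.d_stat <- function(v, n) {
  L <- length(v)
  d <- rep(NA_real_, L)
  if (L < 2 * n) return(d)
  cs <- cumsum(v)
  i <- seq(n, L - n)                       # left flank [i-n+1, i], right (i, i+n]
  left <- (cs[i] - c(0, cs)[i - n + 1]) / n
  right <- (cs[i + n] - cs[i]) / n
  d[i] <- abs(left - right)
  d
}

#' Permute capped values across retained probe slots
#'
#' Shuffles the capped values uniformly at random across all retained probe
#' slots genome-wide (optionally within each chromosome), leaving positions
#' and chromosome structure unchanged.  This is the null model of the
#' permutation calibration: a genome with the same value multiset but no
#' spatial organisation.
#'
#' @param series a [filter_and_cap()] result.
#' @param per_chromosome shuffle within chromosomes instead of genome-wide.
#' @return a `capped_series` with permuted `capped` values.
#' @export
permute_series <- function(series, per_chromosome = FALSE) {
  stopifnot(inherits(series, "capped_series"))
  if (!nrow(series)) stop("empty series")
  if (per_chromosome) {
    series$capped <- unsplit(lapply(split(series$capped, series$chrom),
                                    sample), series$chrom)
  } else {
    series$capped <- sample(series$capped)
  }
  series
}

#' Two-configuration model parameters
#'
#' @param n flank size in retained probes (default 48).
#' @param d_cutoff transition-statistic cutoff (default 0.8).
#' @param n_permutations permutations for the calibration (default 100).
#' @param alpha significance level required of the real-vs-permuted contrast
#'   (default 0.05).
#' @param per_chromosome_shuffle permute within chromosomes.
#' @return list of class `twocm_params`.
#' @export
twocm_params <- function(n = 48L, d_cutoff = 0.8, n_permutations = 100L,
                         alpha = 0.05, per_chromosome_shuffle = FALSE) {
  stopifnot(n >= 1, d_cutoff >= 0, n_permutations >= 1,
            alpha > 0, alpha <= 1)
  structure(list(n = as.integer(n), d_cutoff = d_cutoff,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 per_chromosome_shuffle = per_chromosome_shuffle),
            class = "twocm_params")
}

#' Calibrate the transition cutoff against permutations and detect transitions
#'
#' For each (n, d) setting on a grid, counts probes with d >= cutoff in the
#' real series and in each permuted series.  The empirical p-value of a
#' setting is the fraction of permutations whose count reaches the real
#' count; a setting is admissible when p < alpha.  Among admissible settings
#' the most discriminating one — maximising the ratio of the real count to
#' the mean permuted count — is selected, and the transition probes under it
#' are returned after collapsing consecutive supra-cutoff probes to the
#' probe with maximal d (ties: leftmost).
#'
#' @param series a [filter_and_cap()] result.
#' @param params a [twocm_params()]; its `n` and `d_cutoff` seed the default
#'   one-point grid.
#' @param grid optional data.frame with columns `n`, `d_cutoff` to search
#'   over instead.
#' @param seed integer seed for the permutations.
#' @return list with `transitions` (integer row indices into `series` of the
#'   collapsed transition probes under the selected setting), `selected`
#'   (row of the report), and `report` — one row per setting with the real
#'   count, mean permuted count, their ratio and the empirical p.
#' @export
calibrate_2cm <- function(series, params = twocm_params(), grid = NULL,
                          seed = 1L) {
  stopifnot(inherits(series, "capped_series"))
  if (is.null(grid))
    grid <- data.frame(n = params$n, d_cutoff = params$d_cutoff)
  set.seed(seed)
  perms <- replicate(params$n_permutations,
                     permute_series(series, params$per_chromosome_shuffle),
                     simplify = FALSE)
  report <- grid
  report$real_count <- NA_real_
  report$mean_permuted_count <- NA_real_
  report$p_value <- NA_real_
  d_real_by_n <- list()
  for (g in seq_len(nrow(grid))) {
    n <- grid$n[g]; dc <- grid$d_cutoff[g]
    key <- as.character(n)
    if (is.null(d_real_by_n[[key]]))
      d_real_by_n[[key]] <- transition_statistic(series, n)
    d_real <- d_real_by_n[[key]]
    real_count <- sum(d_real >= dc, na.rm = TRUE)
    perm_counts <- vapply(perms, function(p)
      sum(transition_statistic(p, n) >= dc, na.rm = TRUE), numeric(1))
    report$real_count[g] <- real_count
    report$mean_permuted_count[g] <- mean(perm_counts)
    report$p_value[g] <- mean(perm_counts >= real_count)
  }
  report$ratio <- report$real_count / pmax(report$mean_permuted_count,
                                           .Machine$double.eps)
  admissible <- which(report$p_value < params$alpha & report$real_count > 0)
  if (!length(admissible)) {
    cond <- simpleError(paste0(
      "no (n, d) setting separates the series from its permutations at alpha = ",
      params$alpha))
    cond$report <- report
    stop(cond)
  }
  sel <- admissible[which.max(report$ratio[admissible])]
  d_sel <- d_real_by_n[[as.character(report$n[sel])]]
  trans <- collapse_transitions(series, d_sel, report$d_cutoff[sel])
  list(transitions = trans, selected = report[sel, , drop = FALSE],
       report = report)
}

#' Collapse runs of supra-cutoff probes to single transition probes
#'
#' Consecutive retained probes whose d reaches the cutoff are treated as one
#' boundary; the run is represented by its probe of maximal d (leftmost on
#' ties).
#'
#' @param series a [filter_and_cap()] result.
#' @param d vector from [transition_statistic()] aligned with `series`.
#' @param d_cutoff cutoff.
#' @return integer row indices into `series`.
#' @export
collapse_transitions <- function(series, d, d_cutoff) {
  over <- !is.na(d) & d >= d_cutoff
  # runs must not span chromosomes
  chrom_f <- as.integer(factor(series$chrom, levels = unique(series$chrom)))
  idx <- which(over)
  if (!length(idx)) return(integer(0))
  new_run <- c(TRUE, diff(idx) != 1L | diff(chrom_f[idx]) != 0L)
  run_id <- cumsum(new_run)
  vapply(split(idx, run_id),
         function(ii) ii[which.max(d[ii])], integer(1), USE.NAMES = FALSE)
}

#' Assemble alternating open/closed domains from transition probes
#'
#' Transition probes cut each chromosome's probe-covered span into segments;
#' a segment is called open when the mean raw log2 signal of the original
#' probes inside it is positive, closed otherwise, and adjacent same-state
#' segments are merged.  Segment boundaries fall midway between a transition
#' probe and the next retained probe.  The result tiles the probe-covered
#' span ([first probe, last probe + 1), 0-based half-open) of every
#' chromosome.
#'
#' @param series a [filter_and_cap()] result.
#' @param transitions integer row indices into `series` (from
#'   [calibrate_2cm()] or [collapse_transitions()]).
#' @param raw_signals the original unfiltered probe-signal data.frame.
#' @return data.frame of domains: `chrom`, `start`, `end` (0-based
#'   half-open), `state` (open/closed), `model` ("2CM"), `mean_signal`.
#' @export
assemble_domains_2cm <- function(series, transitions, raw_signals) {
  stopifnot(inherits(series, "capped_series"))
  .validate_probe_signals(raw_signals)
  out <- list()
  for (chrom in unique(raw_signals$chrom)) {
    raw <- raw_signals[raw_signals$chrom == chrom, , drop = FALSE]
    span <- c(raw$position[1] - 1, raw$position[nrow(raw)])   # 0-based half-open
    rows <- which(series$chrom == chrom)
    tr <- sort(intersect(transitions, rows))
    cuts <- numeric(0)
    for (t in tr) {
      nxt <- if ((t + 1) %in% rows) series$position[t + 1] else NA
      cuts <- c(cuts,
                if (is.na(nxt)) series$position[t]            # last retained probe
                else (series$position[t] - 1 + nxt - 1) / 2)  # midpoint, 0-based
    }
    bounds <- unique(c(span[1], sort(cuts), span[2]))
    bounds <- bounds[bounds >= span[1] & bounds <= span[2]]
    segs <- data.frame(start = head(bounds, -1), end = tail(bounds, -1))
    segs <- segs[segs$start < segs$end, , drop = FALSE]
    pos0 <- raw$position - 1
    seg_of <- findInterval(pos0, segs$start)
    ms <- vapply(seq_len(nrow(segs)),
                 function(i) mean(raw$signal[seg_of == i]), numeric(1))
    ms[is.nan(ms)] <- 0
    segs$state <- ifelse(ms > 0, "open", "closed")
    segs$mean_signal <- ms
    # merge adjacent same-state segments (bp-weighted mean signal)
    grp <- cumsum(c(TRUE, segs$state[-1] != segs$state[-nrow(segs)]))
    w <- segs$end - segs$start
    merged <- data.frame(
      chrom = chrom,
      start = as.vector(tapply(segs$start, grp, min)),
      end = as.vector(tapply(segs$end, grp, max)),
      state = as.vector(tapply(segs$state, grp, `[`, 1)),
      model = "2CM",
      mean_signal = as.vector(tapply(seq_len(nrow(segs)), grp, function(ii)
        sum(ms[ii] * w[ii]) / sum(w[ii]))),
      stringsAsFactors = FALSE)
    out[[chrom]] <- merged
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the two-configuration chromatin model
#'
#' Runs the full 2CM pipeline: 1-SD filtering and sign capping of the probe
#' signals, permutation calibration of the sliding-window transition
#' statistic, collapse of supra-cutoff runs to transition probes, and
#' assembly of alternating open/closed domains tiling the probe-covered
#' span of each chromosome.
#'
#' @param signals probe-signal data.frame (`chrom`, `position`, `signal`).
#' @param params a [twocm_params()] (defaults are the model's standard
#'   operating point: n = 48, d = 0.8, 100 permutations, alpha = 0.05).
#' @param grid optional (n, d_cutoff) grid for the calibration search.
#' @param seed integer seed for the permutations.
#' @return object of class `c("chromseg_2cm", "chromseg_fit")` with
#'   components `domains`, `transitions` (data.frame of transition probes),
#'   `calibration`, `series` (the capped series), `params`, `seed`.
#' @seealso [segment_3cm()], [cumulative_overlap()]
#' @examples
#' cfg <- synthetic_config(genome_length = 3e5, rng_seed = 7)
#' sim <- simulate_probe_signals(cfg)
#' fit <- segment_2cm(sim$signals, seed = 7)
#' summary(fit)
#' @export
segment_2cm <- function(signals, params = twocm_params(), grid = NULL,
                        seed = 1L) {
  series <- filter_and_cap(signals)
  cal <- calibrate_2cm(series, params, grid = grid, seed = seed)
  domains <- assemble_domains_2cm(series, cal$transitions, signals)
  trans <- series[cal$transitions, c("chrom", "position"), drop = FALSE]
  trans$d <- transition_statistic(series, cal$selected$n)[cal$transitions]
  rownames(trans) <- NULL
  structure(list(domains = domains, transitions = trans,
                 calibration = cal$report, selected = cal$selected,
                 series = series, params = params, seed = seed,
                 signals = signals),
            class = c("chromseg_2cm", "chromseg_fit"))
}
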