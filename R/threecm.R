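#' Three-configuration model parameters
#'
#' @param posterior_cutoff peak-state posterior probability above which a
#'   probe belongs to a peak (default 0.5).
#' @param fdr empirical false discovery rate for peak filtering (default
#'   0.1).
#' @param gap_percentile percentile of pooled inter-peak distances used as
#'   the consolidation gap threshold (default 95).
#' @param gap_threshold_override fixed gap threshold in bp, bypassing the
#'   percentile computation (see [gap_threshold_fly]).
#' @param n_permutations value-shuffled replicates for the FDR estimate.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return list of class `threecm_params`.
#' @export
threecm_params <- function(posterior_cutoff = 0.5, fdr = 0.1,
                           gap_percentile = 95,
                           gap_threshold_override = NULL,
                           n_permutations = 10L,
                           max_iter = 200L, tol = 1e-4) {
  stopifnot(posterior_cutoff >= 0, posterior_cutoff < 1,
            fdr > 0, gap_percentile > 0, gap_percentile <= 100,
            n_permutations >= 1, max_iter >= 1, tol > 0)
  structure(list(posterior_cutoff = posterior_cutoff, fdr = fdr,
                 gap_percentile = gap_percentile,
                 gap_threshold_override = gap_threshold_override,
                 n_permutations = as.integer(n_permutations),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "threecm_params")
}

#' Consolidation gap threshold observed in the Drosophila genome
#'
#' The 95th percentile of inter-peak distances in the fly genome (16721 bp),
#' usable as `gap_threshold_override` in [threecm_params()] when
#' reproducing fly-scale domain consolidation without recomputing the
#' percentile.
#' @export
gap_threshold_fly <- 16721

# ---- HMM core -------------------------------------------------------------

# EM fit of a 2-state Gaussian HMM over a list of per-chromosome signal
# vectors.  State 2 is the peak state (larger mean after fitting).
.fit_hmm <- function(xs, max_iter = 200L, tol = 1e-4) {
  all_x <- unlist(xs, use.names = FALSE)
  s <- sd(all_x)
  top <- mean(all_x[all_x >= quantile(all_x, 0.9, type = 7)])
  mu <- c(0, top)
  sigma <- c(s, s)
  pi0 <- c(0.9, 0.1)
  A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll <- 0
    xi <- matrix(0, 2, 2); n_k <- sx <- sxx <- numeric(2)
    gfirst <- numeric(2); nchr <- 0
    for (x in xs) {
      fb <- .fb_gauss(x, mu, sigma, pi0, A)
      ll <- ll + fb$loglik
      xi <- xi + fb$xi
      n_k <- n_k + fb$n_k; sx <- sx + fb$sx; sxx <- sxx + fb$sxx
      gfirst <- gfirst + fb$gamma_first; nchr <- nchr + 1
    }
    trace <- c(trace, ll)
    mu <- sx / n_k
    sigma <- pmax(sqrt(pmax(sxx / n_k - mu^2, 0)), s * 1e-3)
    A <- xi / rowSums(xi)
    pi0 <- gfirst / nchr
    pi0 <- pmin(pmax(pi0, 1e-6), 1 - 1e-6); pi0 <- pi0 / sum(pi0)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "HMM EM did not converge in %d iterations (last loglik %.4f)",
      max_iter, tail(trace, 1)))
    cond$trace <- trace
    stop(cond)
  }
  if (mu[2] < mu[1]) {      # enforce state 2 = peak
    mu <- rev(mu); sigma <- rev(sigma); pi0 <- rev(pi0)
    A <- A[2:1, 2:1]
  }
  list(mu = mu, sigma = sigma, pi0 = pi0, A = A, loglik = tail(trace, 1),
       iterations = length(trace))
}

.hmm_posterior <- function(x, fit) {
  .fb_gauss(x, fit$mu, fit$sigma, fit$pi0, fit$A)$gamma1
}

# peaks of one sign from per-probe posteriors on one chromosome
.runs_to_peaks <- function(chrom, pos, sig, post, cutoff, sign) {
  over <- post > cutoff
  if (!any(over)) return(NULL)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  pos0 <- pos - 1
  n <- length(pos)
  out <- lapply(keep, function(k) {
    j1 <- starts[k]; j2 <- ends[k]
    st <- if (j1 == 1) pos0[1] else (pos0[j1 - 1] + pos0[j1]) / 2
    en <- if (j2 == n) pos0[n] + 1 else (pos0[j2] + pos0[j2 + 1]) / 2
    data.frame(chrom = chrom, start = st, end = en, sign = sign,
               posterior = max(post[j1:j2]),
               score = sign * mean(sig[j1:j2]),
               area = abs(sum(sig[j1:j2])),
               n_probes = j2 - j1 + 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call signal peaks with a two-state Gaussian hidden Markov model
#'
#' Fits a background/peak HMM by expectation-maximisation (background mean
#' initialised at 0, peak mean at the mean of the top decile of signals,
#' equal variances from the global SD, 0.99 self-transition prior) and
#' applies it twice — to the signal for positive (open) peaks and to its
#' negation for negative (closed) peaks.  A peak is a maximal run of probes
#' whose peak-state posterior exceeds `posterior_cutoff`; peak spans extend
#' to the midpoints between boundary probes and their neighbours.  When
#' positive and negative peaks overlap, the one with the lower maximal
#' posterior is dropped.
#'
#' @param signals probe-signal data.frame (`chrom`, `position`, `signal`).
#' @param posterior_cutoff posterior threshold (default 0.5).
#' @param max_iter,tol EM controls.
#' @param min_probes chromosomes with fewer probes are skipped with a
#'   warning (default 10).
#' @return data.frame of peaks (`chrom`, `start`, `end`, `sign`,
#'   `posterior`, `score`, `n_probes`), sorted, with the fitted HMM
#'   parameter sets attached as attribute `hmm` (for reuse by
#'   [filter_peaks_fdr()]).  Constant signals yield zero peaks.
#' @export
call_peaks_hmm <- function(signals, posterior_cutoff = 0.5,
                           max_iter = 200L, tol = 1e-4, min_probes = 10L) {
  .validate_probe_signals(signals)
  by_chr <- split(signals, signals$chrom)
  short <- vapply(by_chr, nrow, integer(1)) < min_probes
  if (any(short)) {
    warning("skipping chromosomes with < ", min_probes, " probes: ",
            paste(names(by_chr)[short], collapse = ", "))
    by_chr <- by_chr[!short]
  }
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), sign = numeric(),
                      posterior = numeric(), score = numeric(),
                      n_probes = integer())
  if (!length(by_chr)) return(empty)
  xs <- lapply(by_chr, `[[`, "signal")
  if (sd(unlist(xs, use.names = FALSE)) == 0) {
    attr(empty, "hmm") <- NULL
    return(empty)
  }
  fit_pos <- .fit_hmm(xs, max_iter, tol)
  fit_neg <- .fit_hmm(lapply(xs, `-`), max_iter, tol)
  peaks <- list()
  for (chrom in names(by_chr)) {
    d <- by_chr[[chrom]]
    peaks[[paste0(chrom, "+")]] <- .runs_to_peaks(
      chrom, d$position, d$signal,
      .hmm_posterior(d$signal, fit_pos), posterior_cutoff, +1)
    peaks[[paste0(chrom, "-")]] <- .runs_to_peaks(
      chrom, d$position, d$signal,
      .hmm_posterior(-d$signal, fit_neg), posterior_cutoff, -1)
  }
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks)) peaks <- empty
  peaks <- .resolve_overlaps(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  attr(peaks, "hmm") <- list(pos = fit_pos, neg = fit_neg,
                             posterior_cutoff = posterior_cutoff)
  peaks
}

# drop the lower-posterior peak wherever opposite-sign peaks overlap
.resolve_overlaps <- function(peaks) {
  if (nrow(peaks) < 2) return(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$start,
                       -peaks$posterior), , drop = FALSE]
  drop <- logical(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == chrom)
    idx <- idx[order(peaks$start[idx])]
    last_end <- -Inf; last_i <- NA
    for (i in idx) {
      if (drop[i]) next
      if (peaks$start[i] < last_end) {
        if (peaks$posterior[i] <= peaks$posterior[last_i]) {
          drop[i] <- TRUE
          next
        } else drop[last_i] <- TRUE
      }
      last_end <- peaks$end[i]; last_i <- i
    }
  }
  peaks[!drop, , drop = FALSE]
}

#' Filter peaks by an empirical permutation false discovery rate
#'
#' Estimates, for each candidate peak-area threshold t, the expected number
#' of peaks of area at least t arising from a genome with no spatial
#' signal: probe values are shuffled genome-wide and peak calling is re-run
#' with the already fitted HMM parameters.  The peak area — the absolute
#' summed signal over the peak's probes — is length-aware, which is what
#' separates real peaks from the short same-sign runs a shuffled genome
#' produces (whose per-probe mean signal is similar to a real peak's).
#' FDR(t) is the mean permuted count over the real count; peaks are
#' retained above the smallest t with FDR(t) at or below the target.
#'
#' @param peaks result of [call_peaks_hmm()] (its `hmm` attribute supplies
#'   the fitted model; it is refitted if absent).
#' @param signals the probe signals the peaks were called on.
#' @param fdr target FDR (default 0.1); values >= 1 retain all peaks.
#' @param n_permutations shuffled replicates (default 10).
#' @param seed integer seed for the shuffles.
#' @return the retained subset of `peaks`, with attribute `fdr_table`
#'   (threshold, real and mean permuted counts, FDR estimate).
#' @export
filter_peaks_fdr <- function(peaks, signals, fdr = 0.1,
                             n_permutations = 10L, seed = 1L) {
  if (!nrow(peaks)) return(peaks)
  if (fdr >= 1) return(peaks)
  hmm <- attr(peaks, "hmm")
  cutoff <- if (!is.null(hmm)) hmm$posterior_cutoff else 0.5
  set.seed(seed)
  by_chr <- split(signals, signals$chrom)
  if (is.null(hmm)) {
    xs <- lapply(by_chr, `[[`, "signal")
    hmm <- list(pos = .fit_hmm(xs), neg = .fit_hmm(lapply(xs, `-`)),
                posterior_cutoff = cutoff)
  }
  if (is.null(peaks$area)) peaks$area <- abs(peaks$score) * peaks$n_probes
  thresholds <- sort(unique(peaks$area))
  perm_counts <- matrix(0, n_permutations, length(thresholds))
  pooled <- signals$signal
  for (p in seq_len(n_permutations)) {
    shuf <- sample(pooled)
    off <- 0
    pk <- list()
    for (chrom in names(by_chr)) {
      d <- by_chr[[chrom]]
      x <- shuf[off + seq_len(nrow(d))]
      off <- off + nrow(d)
      pk[[paste0(chrom, "+")]] <- .runs_to_peaks(
        chrom, d$position, x, .hmm_posterior(x, hmm$pos), cutoff, +1)
      pk[[paste0(chrom, "-")]] <- .runs_to_peaks(
        chrom, d$position, x, .hmm_posterior(-x, hmm$neg), cutoff, -1)
    }
    pk <- do.call(rbind, pk)
    sc <- if (is.null(pk)) numeric(0) else pk$area
    perm_counts[p, ] <- vapply(thresholds,
                               function(t) sum(sc >= t), numeric(1))
  }
  real_counts <- vapply(thresholds,
                        function(t) sum(peaks$area >= t), numeric(1))
  fdr_hat <- pmin(colMeans(perm_counts) / pmax(real_counts, 1), 1)
  tab <- data.frame(threshold = thresholds, real_count = real_counts,
                    mean_permuted_count = colMeans(perm_counts),
                    fdr = fdr_hat)
  ok <- which(fdr_hat <= fdr)
  out <- if (length(ok)) {
    t_min <- thresholds[min(ok)]
    peaks[peaks$area >= t_min, , drop = FALSE]
  } else peaks[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hmm") <- hmm
  attr(out, "fdr_table") <- tab
  out
}

#' Gap threshold from the percentile of inter-peak distances
#'
#' Inter-peak distance is the bp gap between the end of one peak and the
#' start of the next on the same chromosome; gaps are pooled genome-wide and
#' the requested percentile is taken with linear interpolation between order
#' statistics (quantile type 7).
#'
#' @param peaks data.frame of peaks (`chrom`, `start`, `end`), sorted or
#'   not.
#' @param gap_percentile percentile in (0, 100\] (default 95).
#' @return gap threshold in bp.
#' @examples
#' # peaks of width 1 whose consecutive gaps are 10, 20, ..., 100 bp
#' st <- cumsum(c(0, seq(10, 100, 10) + 1))
#' pk <- data.frame(chrom = "chr1", start = st, end = st + 1)
#' gap_threshold(pk)  # 95.5
#' @export
gap_threshold <- function(peaks, gap_percentile = 95) {
  gaps <- numeric(0)
  for (chrom in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == chrom, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) >= 2) gaps <- c(gaps, p$start[-1] - p$end[-nrow(p)])
  }
  if (!length(gaps))
    stop("fewer than 2 peaks on every chromosome; supply ",
         "gap_threshold_override (e.g. gap_threshold_fly)")
  unname(quantile(gaps, gap_percentile / 100, type = 7))
}

#' Consolidate same-sign peak clusters into open/closed/neutral domains
#'
#' Adjacent peaks on a chromosome are joined (together with the gap between
#' them) into one domain when they have the same sign and their edge-to-edge
#' distance is below the threshold.  Any gap that cannot be joined —
#' opposite signs, or gap at or above the threshold — becomes a neutral
#' domain, as do the regions between the span limits and the outermost
#' peaks.  Signs map +1 to open and -1 to closed; the result tiles the span
#' of each chromosome.
#'
#' @param peaks sorted non-overlapping peaks (`chrom`, `start`, `end`,
#'   `sign`, optionally `score`).
#' @param threshold gap threshold in bp.
#' @param spans optional data.frame (`chrom`, `start`, `end`) of the
#'   probe-covered span per chromosome; defaults to the outermost peaks, in
#'   which case no flanking neutral domains are emitted.
#' @return data.frame of domains (`chrom`, `start`, `end`, `state`,
#'   `model` = "3CM", `mean_signal`).
#' @export
consolidate_peaks <- function(peaks, threshold, spans = NULL) {
  if (!nrow(peaks))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character(),
                      model = character(), mean_signal = numeric()))
  out <- list()
  for (chrom in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == chrom, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (any(p$start[-1] < p$end[-nrow(p)]))
      stop("overlapping peaks on ", chrom, "; upstream contract violated")
    sc <- if ("score" %in% names(p)) p$score else p$sign
    span <- if (!is.null(spans)) {
      s <- spans[spans$chrom == chrom, , drop = FALSE]
      if (nrow(s)) c(s$start[1], s$end[1]) else c(p$start[1], p$end[nrow(p)])
    } else c(p$start[1], p$end[nrow(p)])
    segs <- list(); si <- 0
    emit <- function(start, end, state, ms) {
      if (start < end) {
        si <<- si + 1
        segs[[si]] <<- data.frame(chrom = chrom, start = start, end = end,
                                  state = state, model = "3CM",
                                  mean_signal = ms,
                                  stringsAsFactors = FALSE)
      }
    }
    emit(span[1], p$start[1], "neutral", NA_real_)
    cur_start <- p$start[1]; cur_end <- p$end[1]
    cur_sign <- p$sign[1]
    cur_w <- p$end[1] - p$start[1]; cur_ws <- sc[1] * cur_w
    for (i in seq_len(nrow(p))[-1]) {
      gap <- p$start[i] - cur_end
      w <- p$end[i] - p$start[i]
      if (p$sign[i] == cur_sign && gap < threshold) {
        cur_end <- p$end[i]
        cur_w <- cur_w + w; cur_ws <- cur_ws + sc[i] * w
      } else {
        emit(cur_start, cur_end, if (cur_sign > 0) "open" else "closed",
             cur_ws / cur_w)
        emit(cur_end, p$start[i], "neutral", NA_real_)
        cur_start <- p$start[i]; cur_end <- p$end[i]
        cur_sign <- p$sign[i]; cur_w <- w; cur_ws <- sc[i] * w
      }
    }
    emit(cur_start, cur_end, if (cur_sign > 0) "open" else "closed",
         cur_ws / cur_w)
    emit(cur_end, span[2], "neutral", NA_real_)
    out[[chrom]] <- do.call(rbind, segs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the three-configuration chromatin model
#'
#' Runs the full 3CM pipeline: HMM peak calling on the signal and its
#' negation, empirical-FDR peak filtering, gap-threshold estimation from
#' the inter-peak distance distribution (or a fixed override), and
#' consolidation of same-sign peak clusters into open/closed domains with
#' neutral segments elsewhere.
#'
#' @param signals probe-signal data.frame (`chrom`, `position`, `signal`).
#' @param params a [threecm_params()].
#' @param seed integer seed for the FDR permutations.
#' @return object of class `c("chromseg_3cm", "chromseg_fit")` with
#'   components `domains`, `peaks` (FDR-filtered), `raw_peaks`, `hmm`
#'   (fitted parameter sets), `gap_threshold`, `fdr_table`, `params`,
#'   `seed`.
#' @seealso [segment_2cm()]
#' @examples
#' cfg <- synthetic_config(genome_length = 3e5, rng_seed = 7)
#' sim <- simulate_probe_signals(cfg)
#' fit <- segment_3cm(sim$signals, seed = 7)
#' summary(fit)
#' @export
segment_3cm <- function(signals, params = threecm_params(), seed = 1L) {
  .validate_probe_signals(signals)
  raw_peaks <- call_peaks_hmm(signals, params$posterior_cutoff,
                              params$max_iter, params$tol)
  peaks <- filter_peaks_fdr(raw_peaks, signals, params$fdr,
                            params$n_permutations, seed = seed)
  if (!nrow(peaks))
    stop("no peaks survive FDR filtering; nothing to consolidate")
  thr <- if (!is.null(params$gap_threshold_override))
    params$gap_threshold_override
  else gap_threshold(peaks, params$gap_percentile)
  spans <- do.call(rbind, lapply(split(signals, signals$chrom), function(d)
    data.frame(chrom = d$chrom[1], start = d$position[1] - 1,
               end = d$position[nrow(d)], stringsAsFactors = FALSE)))
  domains <- consolidate_peaks(peaks, thr, spans = spans)
  structure(list(domains = domains, peaks = peaks, raw_peaks = raw_peaks,
                 hmm = attr(raw_peaks, "hmm"), gap_threshold = thr,
                 fdr_table = attr(peaks, "fdr_table"), params = params,
                 seed = seed, signals = signals),
            class = c("chromseg_3cm", "chromseg_fit"))
}
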