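#' Compute per-probe differential DNase I sensitivity signals
#'
#' Averages replicate intensities within the treated (DNase I-digested) and
#' control (undigested) groups on the linear scale and takes the log2 ratio
#' control/treated.  Sequences depleted in the treated sample — open
#' chromatin, preferentially nicked by the nuclease — therefore get positive
#' values; sequences overrepresented in the treated sample (closed chromatin)
#' get negative values.
#'
#' Averaging happens on linear intensities before the log transform, not on
#' per-replicate log ratios.  Upstream array normalisation is assumed done;
#' the function accepts any positive intensity scale.
#'
#' @param treated data.frame with columns `chrom`, `position` and one or more
#'   replicate intensity columns (DNase I-treated sample).
#' @param control data.frame of the same layout for the undigested control.
#' @return data.frame with columns `chrom`, `position`, `signal` where
#'   `signal = log2(mean control) - log2(mean treated)`, ordered by
#'   chromosome then position.
#' @examples
#' tr <- data.frame(chrom = "chr2L", position = c(1, 36),
#'                  r1 = c(1, 8), r2 = c(1, 8))
#' ct <- data.frame(chrom = "chr2L", position = c(1, 36),
#'                  r1 = c(4, 2), r2 = c(4, 4))
#' compute_differential_signal(tr, ct)$signal  # +2 (open), log2(3) - 3
#' @export
compute_differential_signal <- function(treated, control) {
  tr <- .check_intensity_table(treated, "treated")
  ct <- .check_intensity_table(control, "control")
  key_t <- paste(tr$chrom, tr$position)
  key_c <- paste(ct$chrom, ct$position)
  if (length(key_t) != length(key_c) || !setequal(key_t, key_c)) {
    bad <- c(setdiff(key_t, key_c), setdiff(key_c, key_t))
    stop("probe sets differ between groups; offending probes: ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  ct <- ct[match(key_t, key_c), , drop = FALSE]
  mt <- rowMeans(tr[, -(1:2), drop = FALSE])
  mc <- rowMeans(ct[, -(1:2), drop = FALSE])
  out <- data.frame(chrom = tr$chrom, position = tr$position,
                    signal = log2(mc) - log2(mt),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  .validate_probe_signals(out)
  out
}

.check_intensity_table <- function(x, what) {
  if (!is.data.frame(x) || ncol(x) < 3L)
    stop(what, " table needs chrom, position and >= 1 replicate column")
  names(x)[1:2] <- c("chrom", "position")
  vals <- as.matrix(x[, -(1:2), drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("non-positive or non-finite intensity in ", what, " table")
  x
}

# shared contract for probe-signal data.frames: chrom/position/signal,
# positions strictly increasing within a chromosome, finite signal
.validate_probe_signals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "position", "signal") %in% names(x)))
  if (any(!is.finite(x$signal))) stop("non-finite probe signal")
  for (p in split(x$position, x$chrom))
    if (is.unsorted(p, strictly = TRUE))
      stop("probe positions not strictly increasing within a chromosome")
  invisible(x)
}
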