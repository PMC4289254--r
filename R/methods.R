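#' @export
print.chromseg_fit <- function(x, ...) {
  model <- if (inherits(x, "chromseg_2cm")) "two-configuration (2CM)"
           else "three-configuration (3CM)"
  cat("Chromatin compactness segmentation —", model, "model\n")
  d <- x$domains
  cat(sprintf("  %d domains on %d chromosome(s), %.2f Mb covered\n",
              nrow(d), length(unique(d$chrom)),
              sum(d$end - d$start) / 1e6))
  tab <- tapply(d$end - d$start, d$state, sum)
  pct <- 100 * tab / sum(tab)
  cat("  state composition:",
      paste(sprintf("%s %.1f%%", names(pct), pct), collapse = ", "), "\n")
  if (inherits(x, "chromseg_2cm")) {
    cat(sprintf("  %d transition probes (n = %d, d >= %.2f, p = %.3g)\n",
                nrow(x$transitions), x$selected$n, x$selected$d_cutoff,
                x$selected$p_value))
  } else {
    cat(sprintf("  %d peaks after FDR %.2f; gap threshold %.0f bp\n",
                nrow(x$peaks), x$params$fdr, x$gap_threshold))
  }
  invisible(x)
}

#' @export
summary.chromseg_fit <- function(object, ...) {
  d <- object$domains
  len <- d$end - d$start
  out <- list(
    model = if (inherits(object, "chromseg_2cm")) "2CM" else "3CM",
    n_domains = nrow(d),
    state_bp = tapply(len, d$state, sum),
    state_pct = 100 * tapply(len, d$state, sum) / sum(len),
    mean_length = tapply(len, d$state, mean),
    median_length = tapply(len, d$state, median),
    max_length = max(len))
  class(out) <- "summary.chromseg_fit"
  out
}

#' @export
print.summary.chromseg_fit <- function(x, ...) {
  cat(sprintf("%s segmentation: %d domains\n", x$model, x$n_domains))
  states <- names(x$state_bp)
  df <- data.frame(state = states,
                   bp = as.numeric(x$state_bp),
                   pct = round(as.numeric(x$state_pct), 1),
                   mean_bp = round(as.numeric(x$mean_length)),
                   median_bp = round(as.numeric(x$median_length)))
  print(df, row.names = FALSE)
  cat("largest domain:", x$max_length, "bp\n")
  invisible(x)
}

#' @export
as.data.frame.chromseg_fit <- function(x, ...) x$domains

#' Plot a segmentation over its probe signal
#'
#' Shows the raw probe signal for one chromosome (optionally a window) with
#' the fitted domains as a coloured band: open above zero in red, closed in
#' blue, neutral in grey.
#'
#' @param x a `chromseg_fit`.
#' @param chrom chromosome to draw (default: first).
#' @param xlim optional bp window.
#' @param ... passed to [plot()].
#' @export
plot.chromseg_fit <- function(x, chrom = NULL, xlim = NULL, ...) {
  sig <- x$signals
  if (is.null(chrom)) chrom <- sig$chrom[1]
  s <- sig[sig$chrom == chrom, , drop = FALSE]
  if (!is.null(xlim)) s <- s[s$position >= xlim[1] & s$position <= xlim[2], ]
  plot(s$position, s$signal, pch = ".", col = "grey40",
       xlab = paste0(chrom, " position (bp)"),
       ylab = "log2 differential signal", ...)
  abline(h = 0, col = "grey70")
  d <- x$domains[x$domains$chrom == chrom, , drop = FALSE]
  cols <- c(open = rgb(0.85, 0.2, 0.2, 0.9), closed = rgb(0.2, 0.3, 0.85, 0.9),
            neutral = rgb(0.6, 0.6, 0.6, 0.9))
  y <- max(s$signal) * 1.05
  rect(d$start + 1, y, d$end, y + 0.15 * abs(y),
       col = cols[d$state], border = NA)
  legend("bottomright", fill = cols[unique(d$state)],
         legend = unique(d$state), bty = "n", cex = 0.8)
  invisible(x)
}
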