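#' @importFrom GenomicRanges GRanges reduce intersect setdiff width seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors Rle
NULL

# data.frame (chrom, start, end) -> merged GRanges; 0-based half-open in,
# 1-based closed inside GRanges
.as_granges <- function(df) {
  if (!nrow(df)) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)))
}

.bp <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))

.bp_intersect <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  .bp(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
}

#' Cumulative base-pair overlap between domains and an annotation track
#'
#' For every domain state and every track label, the total bp in the
#' intersection of the merged union of domains with that state and the
#' merged union of intervals with that label, optionally restricted to a
#' scope (a chromosome subset or arbitrary mask intervals, e.g.
#' heterochromatic compartments).  Duplicated or overlapping intervals
#' within one label are merged first, so no bp is double-counted.
#'
#' @param domains data.frame of domains (`chrom`, `start`, `end`, `state`;
#'   0-based half-open).
#' @param track annotation track: data.frame (`chrom`, `start`, `end`,
#'   `label`); a missing `label` column is treated as a single label named
#'   after the track's `kind` attribute or `"track"`.
#' @param scope `NULL` for genome-wide, a character vector of chromosome
#'   names, or a data.frame of mask intervals (`chrom`, `start`, `end`).
#' @param on_unknown_chrom `"warn"` (skip track intervals on chromosomes
#'   absent from the domains, with a warning) or `"error"`.
#' @return object of class `overlap_summary`: a state x label matrix of bp
#'   with attributes `state_bp` (total bp per state within scope) and
#'   `label_bp` (total bp per label within scope).
#' @export
cumulative_overlap <- function(domains, track, scope = NULL,
                               on_unknown_chrom = c("warn", "error")) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  if (!"label" %in% names(track)) {
    track$label <- if (!is.null(attr(track, "kind"))) attr(track, "kind")
                   else "track"
  }
  known <- unique(domains$chrom)
  bad <- !track$chrom %in% known
  if (any(bad)) {
    msg <- paste0("track intervals on chromosomes absent from domains: ",
                  paste(unique(track$chrom[bad]), collapse = ", "))
    if (on_unknown_chrom == "error") stop(msg)
    warning(msg, "; skipped")
    track <- track[!bad, , drop = FALSE]
  }
  mask <- NULL
  if (!is.null(scope)) {
    if (is.character(scope)) {
      domains <- domains[domains$chrom %in% scope, , drop = FALSE]
      track <- track[track$chrom %in% scope, , drop = FALSE]
    } else {
      mask <- .as_granges(scope)
    }
  }
  states <- unique(domains$state)
  labels <- unique(track$label)
  state_gr <- lapply(setNames(states, states), function(s) {
    g <- .as_granges(domains[domains$state == s, , drop = FALSE])
    if (!is.null(mask)) GenomicRanges::intersect(g, mask, ignore.strand = TRUE)
    else g
  })
  label_gr <- lapply(setNames(labels, labels), function(l) {
    g <- .as_granges(track[track$label == l, , drop = FALSE])
    if (!is.null(mask)) GenomicRanges::intersect(g, mask, ignore.strand = TRUE)
    else g
  })
  m <- matrix(0, length(states), length(labels),
              dimnames = list(states, labels))
  for (s in states) for (l in labels)
    m[s, l] <- .bp_intersect(state_gr[[s]], label_gr[[l]])
  structure(m,
            state_bp = vapply(state_gr, .bp, numeric(1)),
            label_bp = vapply(label_gr, .bp, numeric(1)),
            class = c("overlap_summary", "matrix"))
}

#' Fraction of each domain state lying in each annotation label
#'
#' Row-normalised view of an [cumulative_overlap()] summary: each cell is
#' the percentage of that domain state's bp covered by the label.  Rows sum
#' to at most 100 (tracks need not cover the genome).  States with zero bp
#' give `NA` cells.
#'
#' @param summary an `overlap_summary`.
#' @return percentage matrix (states x labels).
#' @export
fraction_of_domains_in_track <- function(summary) {
  stopifnot(inherits(summary, "overlap_summary"))
  tot <- attr(summary, "state_bp")[rownames(summary)]
  out <- sweep(unclass(summary), 1, tot, `/`) * 100
  out[tot == 0, ] <- NA_real_
  attr(out, "state_bp") <- attr(out, "label_bp") <- NULL
  out
}

#' Contribution of each annotation label to each domain state
#'
#' Column-normalised twin of [fraction_of_domains_in_track()]: each cell is
#' the percentage of that label's bp falling in the domain state.  Labels
#' with zero bp give `NA` cells.
#'
#' @param summary an `overlap_summary`.
#' @return percentage matrix (states x labels).
#' @export
contribution_to_state <- function(summary) {
  stopifnot(inherits(summary, "overlap_summary"))
  tot <- attr(summary, "label_bp")[colnames(summary)]
  out <- sweep(unclass(summary), 2, tot, `/`) * 100
  out[, tot == 0] <- NA_real_
  attr(out, "state_bp") <- attr(out, "label_bp") <- NULL
  out
}

#' Enriched/depleted region coverage per histone modification
#'
#' For each modification with paired enriched and depleted interval tracks,
#' the percentage of each domain state's bp lying in the enriched regions
#' and in the depleted regions.  A modification missing one side of the
#' pair is computed for the available side and flagged in the `incomplete`
#' attribute.
#'
#' @param domains domain data.frame.
#' @param enriched_tracks,depleted_tracks named lists of track data.frames;
#'   names are modification identifiers.
#' @return data.frame with columns `modification`, `state`,
#'   `enriched_pct`, `depleted_pct`.
#' @export
modification_enrichment_profile <- function(domains, enriched_tracks,
                                            depleted_tracks) {
  mods <- union(names(enriched_tracks), names(depleted_tracks))
  states <- unique(domains$state)
  incomplete <- character(0)
  rows <- list()
  for (m in mods) {
    enr <- enriched_tracks[[m]]; dep <- depleted_tracks[[m]]
    if (is.null(enr) || is.null(dep)) incomplete <- c(incomplete, m)
    pct <- function(track) {
      if (is.null(track) || !nrow(track)) return(setNames(
        rep(if (is.null(track)) NA_real_ else 0, length(states)), states))
      track$label <- m
      f <- fraction_of_domains_in_track(
        cumulative_overlap(domains, track))
      setNames(f[states, m], states)
    }
    e <- pct(enr); d <- pct(dep)
    rows[[m]] <- data.frame(modification = m, state = states,
                            enriched_pct = unname(e[states]),
                            depleted_pct = unname(d[states]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(incomplete)) attr(out, "incomplete") <- incomplete
  out
}
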