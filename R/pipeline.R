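#' Run the full segmentation and association pipeline
#'
#' Executes, from a single configuration, the stages: probe-signal loading
#' (or synthetic simulation), 2CM and/or 3CM segmentation, cumulative
#' overlap against annotation tracks, and the expression analyses.  All
#' stage outputs are written to `output_dir` as tab-delimited tables and
#' BED files, together with a YAML run manifest recording the parameters
#' and seed; reruns with the same configuration and seed are byte-identical.
#'
#' The configuration is a list (or a YAML file readable with
#' [read_run_config()]) with elements:
#' \describe{
#'   \item{signals}{path to a signal table/BEDGraph, or a probe-signal
#'     data.frame.  Omit to simulate (`simulate = TRUE`).}
#'   \item{simulate}{logical; use the synthetic generator with parameters
#'     in `synthetic` (passed to [synthetic_config()]).}
#'   \item{models}{character subset of `c("2CM", "3CM")`.}
#'   \item{twocm, threecm}{parameter lists passed to [twocm_params()] /
#'     [threecm_params()].}
#'   \item{tracks}{named list of BED paths (or data.frames) to overlap
#'     against.}
#'   \item{genes}{GTF path or `gene_models` object.}
#'   \item{expression}{path to an RPKM matrix or a matrix; enables the
#'     expression stage (requires `genes`).}
#'   \item{seed}{integer; every stochastic stage draws from it.}
#'   \item{output_dir}{where to write results.}
#' }
#'
#' @param config configuration list or path to a YAML file.
#' @return (invisibly) list with the fitted models and all computed tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  if (is.null(cfg$output_dir)) stop("config error [io]: output_dir required")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  models <- if (is.null(cfg$models)) c("2CM", "3CM") else cfg$models
  res <- list(config = cfg, seed = seed)

  # --- signals ---------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sc <- do.call(synthetic_config,
                  c(cfg$synthetic, list(rng_seed = seed)))
    sim <- simulate_probe_signals(sc)
    res$truth <- sim$truth
    signals <- sim$signals
  } else if (!is.null(cfg$signals)) {
    signals <- if (is.character(cfg$signals)) read_signal_table(cfg$signals)
               else cfg$signals
  } else stop("config error [signal]: provide signals or simulate = TRUE")
  res$signals <- signals

  # --- segmentation ----------------------------------------------------
  domains <- list()
  if ("2CM" %in% models) {
    p2 <- do.call(twocm_params, as.list(cfg$twocm))
    fit2 <- tryCatch(segment_2cm(signals, p2, seed = seed + 1L),
                     error = function(e) stop("stage error [2CM]: ",
                                              conditionMessage(e)))
    res$fit_2cm <- fit2
    domains$`2CM` <- fit2$domains
    write_domains_bed(fit2, file.path(cfg$output_dir, "domains_2cm.bed"))
    write.table(fit2$calibration,
                file.path(cfg$output_dir, "calibration_2cm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("3CM" %in% models) {
    p3 <- do.call(threecm_params, as.list(cfg$threecm))
    fit3 <- tryCatch(segment_3cm(signals, p3, seed = seed + 2L),
                     error = function(e) stop("stage error [3CM]: ",
                                              conditionMessage(e)))
    res$fit_3cm <- fit3
    domains$`3CM` <- fit3$domains
    write_domains_bed(fit3, file.path(cfg$output_dir, "domains_3cm.bed"))
  }

  # --- overlap ---------------------------------------------------------
  if (!is.null(cfg$tracks)) {
    res$overlap <- list()
    for (model in names(domains)) {
      for (tn in names(cfg$tracks)) {
        track <- cfg$tracks[[tn]]
        if (is.character(track)) {
          track <- read_bed(track)
          names(track)[names(track) == "name"] <- "label"
        }
        s <- cumulative_overlap(domains[[model]], track)
        res$overlap[[paste(model, tn, sep = ".")]] <- s
        base <- file.path(cfg$output_dir,
                          paste0("overlap_", tolower(model), "_", tn))
        write.table(as.data.frame(unclass(s)), paste0(base, "_bp.tsv"),
                    sep = "\t", quote = FALSE)
        write.table(as.data.frame(fraction_of_domains_in_track(s)),
                    paste0(base, "_pct_of_state.tsv"),
                    sep = "\t", quote = FALSE)
      }
    }
  }

  # --- expression ------------------------------------------------------
  if (!is.null(cfg$expression)) {
    if (is.null(cfg$genes))
      stop("config error [expression]: gene models required")
    gm <- if (is.character(cfg$genes)) read_gtf(cfg$genes) else cfg$genes
    rpkm <- if (is.character(cfg$expression))
      read_expression_matrix(cfg$expression) else cfg$expression
    activity <- classify_activity(rpkm,
                                  n_samples = ncol(rpkm))
    res$activity <- activity
    for (model in names(domains)) {
      eo <- element_overlap(domains[[model]], gm, activity)
      res[[paste0("elements_", tolower(model))]] <- eo
      write.table(eo, file.path(cfg$output_dir,
                                paste0("elements_", tolower(model), ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(seed = seed, models = models,
                   twocm = as.list(cfg$twocm), threecm = as.list(cfg$threecm),
                   synthetic = cfg$synthetic,
                   package_version = as.character(utils::packageVersion("chromseg")))
  yaml::write_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  invisible(res)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
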