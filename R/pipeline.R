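#' End-to-end run configuration
#'
#' Bundles the per-stage settings of a full analysis run. Defaults follow the
#' headline analysis: 1-40 Hz band, k = 8 states, 10,000 permutations,
#' absolute connectivity threshold 0.2.
#'
#' @param synth A [synth_config()] (used when `input_dir` is `NULL`).
#' @param input_dir Optional directory of epochs (as written by
#'   [write_epochs()]); overrides `synth`.
#' @param band Band-pass edges in Hz.
#' @param decimate Keep every `decimate`-th sample for the dPL/eigenvector
#'   stages.
#' @param edge_samples Samples trimmed per epoch edge before the dPL stage;
#'   `NULL` trims one carrier period (`sampling_rate / carrier_freq`,
#'   rounded), falling back to one period of the band's centre when the
#'   carrier is unknown.
#' @param k Number of phase-locking states.
#' @param n_init k-means restarts.
#' @param n_perm Permutation iterations.
#' @param perm_scheme `"paired"` or `"unpaired"` label shuffling.
#' @param threshold_mode,threshold_value Connectivity graph thresholding.
#' @param clf A [cnn_config()].
#' @param clf_seeds Training repetitions per feature kind.
#' @param run_clf Run the classifier stage (the slowest stage).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return Object of class `leida_run_config`.
#' @export
run_config <- function(synth = synth_config(), input_dir = NULL,
                       band = c(1, 40), decimate = 1, edge_samples = NULL,
                       k = 8, n_init = 20, n_perm = 10000,
                       perm_scheme = "paired",
                       threshold_mode = "absolute", threshold_value = 0.2,
                       clf = cnn_config(), clf_seeds = 3, run_clf = TRUE,
                       seed = 1) {
  structure(as.list(environment()), class = "leida_run_config")
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  s <- utf8ToInt(as.character(json))
  sprintf("%08x", sum(s * (seq_along(s) %% 97 + 1)) %% 4294967291)
}

#' Run the full pipeline
#'
#' Executes synthesis (or epoch loading), band-pass filtering, Hilbert phase,
#' dPL, leading eigenvectors, pooled clustering into states, occupancy
#' permutation tests with FDR, graph-metric comparison and (optionally) the
#' CNN feature-set comparison, writing every stage artifact plus a
#' machine-readable summary to `out_dir`. Identical config and seed give an
#' identical summary.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("leida_run_"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "leida_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (verbose) message(sprintf(...))
  stage <- "init"
  hash <- config_hash(config)
  cfg_out <- unclass(config)
  cfg_out$config_hash <- hash
  jsonlite::write_json(cfg_out, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  tryCatch({
    ## stage: data
    stage <- "synth"
    if (is.null(config$input_dir)) {
      log("[synth] generating %d subjects x 2 conditions",
          config$synth$n_subjects)
      synth_cfg <- config$synth
      synth_cfg$seed <- derive_seed(config$seed, "synth")
      dataset <- generate_dataset(synth_cfg)
      epochs <- dataset$epochs
      carrier <- synth_cfg$carrier_freq
      fs <- synth_cfg$sampling_rate
      write_epochs(dataset, file.path(out_dir, "epochs"), "tsv")
    } else {
      log("[synth] reading epochs from %s", config$input_dir)
      loaded <- read_epochs(config$input_dir)
      epochs <- loaded$epochs
      dataset <- NULL
      fs <- epochs[[1]]$sampling_rate
      carrier <- NULL
    }
    edge <- config$edge_samples
    if (is.null(edge)) {
      f_ref <- carrier %||% mean(config$band)
      edge <- max(1L, round(fs / f_ref))
    }

    ## stage: phase -> dPL -> eigenvectors
    stage <- "phase"
    log("[phase] filtering %g-%g Hz, edge trim %d samples, decimation %d",
        config$band[1], config$band[2], edge, config$decimate)
    dpls <- list(); eigs <- list(); conns <- list()
    for (key in names(epochs)) {
      filt <- bandpass_filter(epochs[[key]], config$band[1], config$band[2])
      ph <- instantaneous_phase(filt)
      dpls[[key]] <- compute_dpl(ph, decimate = config$decimate,
                                 edge_samples = edge)
      eigs[[key]] <- leading_eigenvector(dpls[[key]])
      conns[[key]] <- time_average_connectivity(dpls[[key]])
    }
    dir.create(file.path(out_dir, "eigenvectors"), showWarnings = FALSE)
    for (key in names(eigs)) {
      write_eigs(eigs[[key]],
                 file.path(out_dir, "eigenvectors", paste0(key, ".tsv.gz")))
    }

    ## stage: states
    stage <- "cluster"
    log("[cluster] pooling %d epochs, k = %d", length(eigs), config$k)
    pool <- pool_eigenvectors(eigs)
    model <- cluster_eigenvectors(pool, config$k, n_init = config$n_init,
                                  seed = derive_seed(config$seed, "cluster"))
    metrics <- compute_state_metrics(model, pool, sampling_rate = fs,
                                     decimate = config$decimate)
    write_state_model(model, file.path(out_dir, "state_model.json"))
    utils::write.table(metrics$occupancy, file.path(out_dir, "occupancy.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(metrics$dwell, file.path(out_dir, "dwell.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(metrics$transitions,
                       file.path(out_dir, "transitions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    ## stage: occupancy inference
    stage <- "test"
    log("[test] permutation test, %d iterations (%s scheme)",
        config$n_perm, config$perm_scheme)
    contrast <- occupancy_contrast(metrics)
    ptab <- permutation_test(contrast, n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "perm"),
                             scheme = config$perm_scheme)
    utils::write.table(ptab, file.path(out_dir, "occupancy_tests.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    ## stage: graphs
    stage <- "graph"
    log("[graph] %s threshold %.3g", config$threshold_mode,
        config$threshold_value)
    records <- lapply(names(conns), function(key) {
      g <- build_graph(conns[[key]], config$threshold_mode,
                       config$threshold_value)
      graph_metrics(g, conns[[key]],
                    seed = derive_seed(config$seed, "modularity"))
    })
    rec_tab <- graph_records_table(records)
    gcomp <- compare_graph_conditions(rec_tab[rec_tab$condition == "A", ],
                                      rec_tab[rec_tab$condition == "B", ])
    utils::write.table(rec_tab, file.path(out_dir, "graph_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(gcomp, file.path(out_dir, "graph_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    ## stage: classifier
    clf_tab <- NULL
    if (isTRUE(config$run_clf)) {
      stage <- "classify"
      log("[classify] 3 feature kinds x %d seeds", config$clf_seeds)
      fsets <- list(
        raw = build_features("raw", unname(epochs),
                             decimate = config$decimate, edge_samples = edge),
        dpl_flat = build_features("dpl_flat", unname(dpls)),
        eigenvector = build_features("eigenvector", unname(eigs))
      )
      cfg <- config$clf
      cfg$seed <- derive_seed(config$seed, "clf")
      clf_tab <- compare_feature_sets(fsets, cfg, n_seeds = config$clf_seeds)
      utils::write.table(clf_tab, file.path(out_dir, "classifier.tsv"),
                        sep = "\t", row.names = FALSE, quote = FALSE)
    }

    stage <- "summary"
    summary <- list(
      config_hash = hash, seed = config$seed,
      n_epochs = length(epochs), k = config$k,
      edge_samples = edge, decimate = config$decimate,
      inertia = model$inertia,
      occupancy_tests = ptab[, c("state", "t_obs", "p_raw", "p_fdr")],
      n_significant_fdr = sum(ptab$p_fdr < 0.05),
      graph_comparison = gcomp,
      classifier = clf_tab
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
    log("[done] %s", out_dir)
    invisible(summary)
  }, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
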