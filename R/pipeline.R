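#' Run configuration for the full analysis
#'
#' Either point at real inputs (`ct_path`, `annotation_path`, and
#' optionally `target_map_path` / `gene_sets_path`) or supply a synthetic
#' cohort via `synthetic = cohort_config(...)` — never both. The global
#' `seed` is mandatory and drives every stochastic stage through
#' stage-derived seeds, so single stages can be rerun reproducibly.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed.
#' @param ct_path,annotation_path,target_map_path,gene_sets_path Input
#'   file paths (real-data mode).
#' @param synthetic A [cohort_config()] (synthetic mode).
#' @param max_ct Detection cutoff in cycles.
#' @param detection_threshold Low-detection filter cutoff.
#' @param comparisons Named list of class-label vectors compared against
#'   RLN (default: grouped lymphomas, nTFHL, nPTCL).
#' @param lr_grid,rf_grid Tuning grids.
#' @param cv Cross-validation layout ([cv_spec()]); the inner fold count
#'   is taken as given for the logistic models and forced to 3 for the
#'   random forest.
#' @param enrichment An [enrichment_config()].
#' @param alpha DE significance threshold.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed,
                       ct_path = NULL, annotation_path = NULL,
                       target_map_path = NULL, gene_sets_path = NULL,
                       synthetic = NULL,
                       max_ct = 35, detection_threshold = 0.10,
                       comparisons = list(grouped = c("nTFHL", "nPTCL"),
                                          nTFHL = "nTFHL", nPTCL = "nPTCL"),
                       lr_grid = mirpanel::lr_grid(),
                       rf_grid = mirpanel::rf_grid(),
                       cv = cv_spec(),
                       enrichment = enrichment_config(),
                       alpha = 0.05) {
  if (missing(seed)) stop_mp("`seed` is mandatory")
  real <- !is.null(ct_path)
  if (real == !is.null(synthetic)) {
    stop_mp("supply either real input paths or a synthetic cohort config, not both")
  }
  if (real && is.null(annotation_path)) stop_mp("real-data mode needs `annotation_path`")
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         ct_path = ct_path, annotation_path = annotation_path,
         target_map_path = target_map_path, gene_sets_path = gene_sets_path,
         synthetic = synthetic, max_ct = max_ct,
         detection_threshold = detection_threshold,
         comparisons = comparisons, lr_grid = lr_grid, rf_grid = rf_grid,
         cv = cv, enrichment = enrichment, alpha = alpha),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [run_config()];
#' `synthetic` holds [cohort_config()] fields (plus an optional `effects`
#' list of `{mirna, class, shift}` records), `cv` holds [cv_spec()]
#' fields, `lr_grid` / `rf_grid` / `enrichment` their constructors'
#' fields.
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @param seed Optional override of the configured seed.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    eff <- NULL
    if (!is.null(s$effects)) {
      eff <- do.call(rbind, lapply(s$effects, as.data.frame))
      s$effects <- NULL
    }
    s <- lapply(s, function(v) if (is.list(v)) unlist(v) else v)
    if (!is.null(eff)) s$effects <- eff
    syn <- do.call(cohort_config, s)
  }
  args <- list(
    out_dir = out_dir %||% y$out_dir %||% ".",
    seed = seed %||% y$seed,
    ct_path = y$ct_path, annotation_path = y$annotation_path,
    target_map_path = y$target_map_path, gene_sets_path = y$gene_sets_path,
    synthetic = syn
  )
  for (key in c("max_ct", "detection_threshold", "alpha")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$comparisons)) args$comparisons <- lapply(y$comparisons, unlist)
  # yaml returns mixed-type sequences as lists; flatten every scalar field
  flat <- function(x) lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  if (!is.null(y$lr_grid)) args$lr_grid <- do.call(lr_grid, flat(y$lr_grid))
  if (!is.null(y$rf_grid)) args$rf_grid <- do.call(rf_grid, flat(y$rf_grid))
  if (!is.null(y$cv)) args$cv <- do.call(cv_spec, flat(y$cv))
  if (!is.null(y$enrichment)) args$enrichment <- do.call(enrichment_config, flat(y$enrichment))
  if (is.null(args$seed)) stop_mp("config must set `seed` (or pass --seed)")
  do.call(run_config, args)
}

#' Run the full analysis end to end
#'
#' Executes the whole chain: cohort acquisition (read or simulate),
#' spike-in + low-detection + global-mean normalization, QC clustering
#' and PCA, three differential-expression tables, one binary logistic
#' nested CV per comparison, a 3-class random-forest nested CV with
#' confusion matrix and fold-aggregated permutation importance, the
#' common stable panel, the unique/shared DE partition, and per-subtype
#' target-gene enrichment. Every table is written as CSV (models as
#' JSON) into `cfg$out_dir`, and a `manifest.json` records the seed, a
#' config hash, and a checksum per artifact. Reruns with the same config
#' and seed are byte-identical. On a stage failure a `FAILED` marker
#' naming the stage is left next to the partial outputs.
#'
#' @param cfg A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                   artifacts = list(), stages = list())
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    manifest$artifacts[[name]] <<- fnv1a_file(path)
    path
  }
  log_stage <- function(name, info) {
    manifest$stages[[name]] <<- info
    message(sprintf("[mirpanel] %s: %s", name,
                    paste(names(info), unlist(info), sep = "=", collapse = " ")))
  }
  on_fail <- function(e) {
    writeLines(paste("stage:", stage, "-", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop_mp(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
  }

  tryCatch({
    stage <- "input"
    if (!is.null(cfg$synthetic)) {
      syn <- cfg$synthetic
      syn$seed <- derive_seed(cfg$seed, "cohort")
      sim <- simulate_cohort(syn)
      m <- sim$ct; ann <- sim$annotation
      emit("ct_matrix.csv", function(p) write_ct_matrix(m, p))
      emit("annotations.csv", function(p)
        utils::write.csv(as.data.frame(ann), p, row.names = FALSE, quote = FALSE))
      map <- if (!is.null(cfg$target_map_path)) read_target_map(cfg$target_map_path)
             else simulate_target_map(
               n_mirnas = syn$n_mirnas, n_genes = 2000,
               seed = derive_seed(cfg$seed, "target_map"),
               mirna_ids = mirna_ids(m)[!m$is_spike_in])
      gsets <- if (!is.null(cfg$gene_sets_path)) read_gmt(cfg$gene_sets_path)
               else simulate_gene_sets(map, n_null_sets = 50,
                                       seed = derive_seed(cfg$seed, "gene_sets"))
    } else {
      m <- read_ct_matrix(cfg$ct_path, max_ct = cfg$max_ct)
      ann <- read_sample_annotations(cfg$annotation_path)
      map <- if (!is.null(cfg$target_map_path)) read_target_map(cfg$target_map_path) else NULL
      gsets <- if (!is.null(cfg$gene_sets_path)) read_gmt(cfg$gene_sets_path) else NULL
    }
    log_stage("input", list(mirnas = nrow(m$ct), samples = ncol(m$ct)))

    stage <- "normalize"
    chain <- normalize_chain(m, min_fraction = cfg$detection_threshold)
    nm <- chain$normalized
    emit("normalized_matrix.csv", function(p) write_normalized_matrix(nm, p))
    emit("removed_mirnas.csv", function(p)
      utils::write.csv(data.frame(mirna_id = chain$removed_ids), p,
                       row.names = FALSE, quote = FALSE))
    log_stage("normalize", list(retained = nrow(nm$values),
                                removed = length(chain$removed_ids)))

    stage <- "qc"
    cl <- hierarchical_cluster(nm, "samples")
    emit("cluster_samples.csv", function(p)
      utils::write.csv(data.frame(step = seq_along(cl$height),
                                  left = cl$merge[, 1], right = cl$merge[, 2],
                                  height = cl$height), p, row.names = FALSE, quote = FALSE))
    pca <- pca_summary(nm)
    emit("pca_summary.csv", function(p)
      utils::write.csv(data.frame(component = seq_along(pca$variance_fraction),
                                  variance_fraction = pca$variance_fraction),
                       p, row.names = FALSE, quote = FALSE))
    log_stage("qc", list(pc12 = round(sum(pca$variance_fraction[1:2]), 3)))

    stage <- "diffexpr"
    de <- lapply(names(cfg$comparisons), function(nmc) {
      differential_expression(nm, ann, cfg$comparisons[[nmc]],
                              alpha = cfg$alpha, comparison = nmc)
    })
    names(de) <- names(cfg$comparisons)
    for (nmc in names(de)) {
      emit(sprintf("de_%s.csv", nmc), function(p) write_de_result(de[[nmc]], p))
    }
    if (length(de) >= 2L) {
      part <- de_set_partition(de)
      emit("de_partition.csv", function(p) {
        set <- c(rep(paste0("unique_", names(part$unique)), lengths(part$unique)),
                 rep("shared", length(part$shared)))
        ids <- c(unlist(part$unique, use.names = FALSE), part$shared)
        utils::write.csv(data.frame(set = as.character(set),
                                    mirna_id = as.character(ids %||% character(0))),
                         p, row.names = FALSE, quote = FALSE)
      })
    } else part <- NULL
    log_stage("diffexpr", lapply(de, function(d) sum(d$significant)))

    stage <- "classify_lr"
    lr <- lapply(names(cfg$comparisons), function(nmc) {
      spec <- cfg$cv
      spec$seed <- derive_seed(cfg$seed, paste0("lr_", nmc))
      nested_cv_logistic(nm, ann, positive = cfg$comparisons[[nmc]],
                         grid = cfg$lr_grid, spec = spec)
    })
    names(lr) <- names(cfg$comparisons)
    for (nmc in names(lr)) {
      emit(sprintf("lr_%s.json", nmc), function(p) write_model_result(lr[[nmc]], p))
      manifest$artifacts[[sprintf("lr_%s_predictions.csv", nmc)]] <-
        fnv1a_file(file.path(cfg$out_dir, sprintf("lr_%s_predictions.csv", nmc)))
    }
    emit("common_panel.csv", function(p)
      utils::write.csv(data.frame(mirna_id = common_panel(lr)), p,
                       row.names = FALSE, quote = FALSE))
    log_stage("classify_lr", lapply(lr, function(r) round(r$mean_auc, 3)))

    stage <- "classify_rf"
    rf_spec <- cfg$cv
    rf_spec$inner_folds <- 3L
    rf_spec$seed <- derive_seed(cfg$seed, "rf")
    rf <- nested_cv_random_forest(nm, ann, grid = cfg$rf_grid, spec = rf_spec)
    emit("rf_model.json", function(p) write_model_result(rf$model, p))
    manifest$artifacts[["rf_model_predictions.csv"]] <-
      fnv1a_file(file.path(cfg$out_dir, "rf_model_predictions.csv"))
    emit("rf_confusion.csv", function(p) write_confusion_matrix(rf$confusion, p))
    imp <- nested_rf_importance(rf, nm, ann, seed = derive_seed(cfg$seed, "imp"))
    emit("rf_importance.csv", function(p)
      utils::write.csv(as.data.frame(imp), p, row.names = FALSE, quote = FALSE))
    log_stage("classify_rf", list(macro_auc = round(rf$model$mean_auc, 3)))

    stage <- "enrich"
    if (!is.null(map) && !is.null(gsets) && !is.null(part)) {
      ecfg <- cfg$enrichment
      panel <- rownames(nm$values)
      for (nmc in setdiff(names(part$unique), "grouped")) {
        ecfg$seed <- derive_seed(cfg$seed, paste0("enrich_", nmc))
        er <- enrich_all(part$unique[[nmc]], gsets, map, ecfg, panel = panel)
        emit(sprintf("enrichment_%s.csv", nmc), function(p)
          write_enrichment_result(er, p))
      }
      log_stage("enrich", list(sets = length(gsets$sets)))
    }

    stage <- "manifest"
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
  }, error = on_fail)
}

config_hash <- function(cfg) {
  flat <- utils::capture.output(utils::str(cfg, digits.d = 12, list.len = 1000))
  fnv1a_hex(fnv1a(paste(flat, collapse = "\n")))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `normalize`, `de`, `classify`, `enrich`,
#' `run-all`; each takes `--config <yaml>`, optional `--seed <int>` and
#' `--out <dir>` overrides. `--version` prints the package and
#' config-schema versions. Returns (rather than calls) the exit status so
#' it is testable; the installed `inst/scripts/mirpanel` wrapper passes
#' it to `quit()`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 success, 1 runtime failure,
#'   2 usage error.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mirpanel <simulate|normalize|de|classify|enrich|run-all>",
    "--config <yaml> [--seed <int>] [--out <dir>]")
  if (length(args) == 0L) { message(usage); return(invisible(2L)) }
  if (args[1] == "--version") {
    message(sprintf("mirpanel %s (config schema 1)",
                    as.character(utils::packageVersion("mirpanel"))))
    return(invisible(0L))
  }
  cmd <- args[1]
  known <- c("simulate", "normalize", "de", "classify", "enrich", "run-all")
  if (!cmd %in% known) { message("unknown subcommand: ", cmd); message(usage); return(invisible(2L)) }
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    flag <- rest[i]
    if (!flag %in% c("--config", "--seed", "--out")) {
      message("unknown flag: ", flag); message(usage); return(invisible(2L))
    }
    if (i == length(rest)) { message("missing value for ", flag); return(invisible(2L)) }
    opts[[sub("^--", "", flag)]] <- rest[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$config)) { message("--config is required"); message(usage); return(invisible(2L)) }
  status <- tryCatch({
    cfg <- read_run_config(opts$config, out_dir = opts$out,
                           seed = if (!is.null(opts$seed)) as.integer(opts$seed))
    run_stage(cmd, cfg)
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

# one pipeline stage (or everything) from a run_config
run_stage <- function(cmd, cfg) {
  if (cmd == "run-all") { run_full_analysis(cfg); return(invisible()) }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  acquire <- function() {
    if (!is.null(cfg$synthetic)) {
      syn <- cfg$synthetic
      syn$seed <- derive_seed(cfg$seed, "cohort")
      sim <- simulate_cohort(syn)
      list(ct = sim$ct, ann = sim$annotation)
    } else {
      list(ct = read_ct_matrix(cfg$ct_path, max_ct = cfg$max_ct),
           ann = read_sample_annotations(cfg$annotation_path))
    }
  }
  if (cmd == "simulate") {
    if (is.null(cfg$synthetic)) stop_mp("simulate needs a synthetic config")
    d <- acquire()
    write_ct_matrix(d$ct, file.path(cfg$out_dir, "ct_matrix.csv"))
    utils::write.csv(as.data.frame(d$ann), file.path(cfg$out_dir, "annotations.csv"),
                     row.names = FALSE, quote = FALSE)
    return(invisible())
  }
  d <- acquire()
  chain <- normalize_chain(d$ct, min_fraction = cfg$detection_threshold)
  nm <- chain$normalized
  if (cmd == "normalize") {
    write_normalized_matrix(nm, file.path(cfg$out_dir, "normalized_matrix.csv"))
    return(invisible())
  }
  if (cmd == "de") {
    for (nmc in names(cfg$comparisons)) {
      de <- differential_expression(nm, d$ann, cfg$comparisons[[nmc]],
                                    alpha = cfg$alpha, comparison = nmc)
      write_de_result(de, file.path(cfg$out_dir, sprintf("de_%s.csv", nmc)))
    }
    return(invisible())
  }
  if (cmd == "classify") {
    for (nmc in names(cfg$comparisons)) {
      spec <- cfg$cv
      spec$seed <- derive_seed(cfg$seed, paste0("lr_", nmc))
      res <- nested_cv_logistic(nm, d$ann, positive = cfg$comparisons[[nmc]],
                                grid = cfg$lr_grid, spec = spec)
      write_model_result(res, file.path(cfg$out_dir, sprintf("lr_%s.json", nmc)))
    }
    return(invisible())
  }
  if (cmd == "enrich") {
    if (is.null(cfg$target_map_path) && is.null(cfg$synthetic)) {
      stop_mp("enrich needs a target map (or synthetic mode)")
    }
    map <- if (!is.null(cfg$target_map_path)) read_target_map(cfg$target_map_path)
           else simulate_target_map(n_mirnas = cfg$synthetic$n_mirnas, n_genes = 2000,
                                    seed = derive_seed(cfg$seed, "target_map"),
                                    mirna_ids = mirna_ids(d$ct)[!d$ct$is_spike_in])
    gsets <- if (!is.null(cfg$gene_sets_path)) read_gmt(cfg$gene_sets_path)
             else simulate_gene_sets(map, n_null_sets = 50,
                                     seed = derive_seed(cfg$seed, "gene_sets"))
    de <- lapply(names(cfg$comparisons), function(nmc)
      differential_expression(nm, d$ann, cfg$comparisons[[nmc]],
                              alpha = cfg$alpha, comparison = nmc))
    names(de) <- names(cfg$comparisons)
    part <- if (length(de) >= 2) de_set_partition(de) else
      list(unique = lapply(de, significant_mirnas))
    ecfg <- cfg$enrichment
    for (nmc in setdiff(names(part$unique), "grouped")) {
      ecfg$seed <- derive_seed(cfg$seed, paste0("enrich_", nmc))
      er <- enrich_all(part$unique[[nmc]], gsets, map, ecfg,
                       panel = rownames(nm$values))
      write_enrichment_result(er, file.path(cfg$out_dir, sprintf("enrichment_%s.csv", nmc)))
    }
    return(invisible())
  }
  stop_mp("unhandled subcommand: ", cmd)
}
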