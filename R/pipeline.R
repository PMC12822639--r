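# Pipeline orchestration: config validation with defaults, and the
# end-to-end run (simulate/load -> preprocess -> features -> explore ->
# classify -> oneclass) with a machine-readable manifest.

default_config <- function() {
  list(
    seed = 1L,
    input = NULL,                       # NULL -> simulate
    input_dialect = "wide-csv",
    design = list(counts = c(Plantae = 37, Fungi = 24, Arthropoda = 12,
                             Bacteria = 10, Oomycetes = 4, Amoebae = 3,
                             Prototaxites = 12),
                  grid_lo = 650, grid_hi = 4000, grid_step = 4),
    recipe = "atr-paper",
    features = list(mode = "height"),
    explore = list(pcs = 10L, nboot = 100L, confidence = 0.99,
                   remove_outliers = TRUE),
    tasks = c("vs-bacteria", "vs-fungi", "vs-chitinous", "vs-plants"),
    classify = list(test_fraction = 0.30, lda_threshold = 0.95,
                    smote_k = 5L, smote_imbalance = 1.25,
                    C_grid = c(0.01, 0.1, 1, 10, 100),
                    gamma_grid = c(0.001, 0.01, 0.1, 1)),
    oneclass = list(alpha = 0.05, components = "auto", mode = "robust"),
    out_dir = "ftirtax-output")
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML or JSON file path, a list, or nothing (all defaults).
#' Every missing setting is filled with its default; all validation errors
#' are collected and reported together rather than fail-fast. An empty file
#' yields the fully defaulted configuration.
#'
#' @param config Path to a YAML/JSON file, a list of overrides, or `NULL`.
#' @return The normalized configuration list (class `pipeline_config`), or
#'   an error listing every problem found.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s",
                                           config), call. = FALSE)
    parsed <- tryCatch(
      if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                         simplifyVector = TRUE)
      else yaml::read_yaml(config),
      error = function(e) stop(sprintf("cannot parse %s: %s", config,
                                       conditionMessage(e)), call. = FALSE))
    config <- if (is.null(parsed)) list() else parsed
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(config$design) && !is.null(config$design$counts)) {
    cc <- unlist(config$design$counts)
    cfg$design$counts <- cc
  }
  errors <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  chk(all(names(cfg$design$counts) %in% TAXON_CLASSES),
      sprintf("unknown class in design counts: %s",
              paste(setdiff(names(cfg$design$counts), TAXON_CLASSES),
                    collapse = ", ")))
  chk(all(cfg$design$counts >= 0), "design counts must be >= 0")
  chk(cfg$recipe %in% c("atr-paper", "benchtop-paper", "synchrotron-paper",
                        "synchrotron-ratio") || is.list(cfg$recipe),
      sprintf("unknown recipe '%s'", cfg$recipe))
  chk(cfg$features$mode %in% c("height", "area"),
      "features mode must be 'height' or 'area'")
  chk(is.numeric(cfg$explore$confidence) && cfg$explore$confidence > 0 &&
        cfg$explore$confidence < 1, "explore confidence must be in (0, 1)")
  bad_tasks <- setdiff(cfg$tasks, names(TASK_NEGATIVES))
  chk(length(bad_tasks) == 0,
      sprintf("unknown task(s): %s", paste(bad_tasks, collapse = ", ")))
  chk(is.numeric(cfg$classify$test_fraction) &&
        cfg$classify$test_fraction > 0 && cfg$classify$test_fraction < 1,
      "test_fraction must be in (0, 1)")
  chk(is.numeric(cfg$oneclass$alpha) && cfg$oneclass$alpha > 0 &&
        cfg$oneclass$alpha < 1, "oneclass alpha must be in (0, 1)")
  chk(cfg$oneclass$mode %in% c("moments", "robust"),
      "oneclass mode must be 'moments' or 'robust'")
  if (!is.null(cfg$input)) chk(file.exists(cfg$input),
                               sprintf("input file not found: %s", cfg$input))
  if (length(errors))
    stop(paste0("invalid configuration:\n  - ",
                paste(errors, collapse = "\n  - ")), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

metrics_as_list <- function(m) {
  list(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
       f1 = m$f1, mcc = m$mcc)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load), preprocess, band-feature
#' extraction, exploration (PCA, bootstrap stability, T2/Q screening with
#' optional outlier removal, CCA), the requested binary classification
#' tasks, and the one-class model, writing CSV tables and JSON reports plus
#' a manifest listing every artifact with its MD5 hash and the seeds used.
#' Reruns with the same configuration produce byte-identical outputs.
#'
#' @param config Anything accepted by [validate_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the manifest path and stage results.
#' @export
run_pipeline <- function(config = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  stage_seed <- function(i) derive_seed(cfg$seed, 1000L + i)

  # 1. simulate or load --------------------------------------------------
  note("[simulate] building dataset")
  raw <- if (is.null(cfg$input)) {
    design <- study_design(
      counts = cfg$design$counts,
      grid = seq(cfg$design$grid_lo, cfg$design$grid_hi,
                 by = cfg$design$grid_step),
      seed = stage_seed(1L))
    generate_dataset(design, default_profiles())
  } else {
    load_spectra(cfg$input, cfg$input_dialect)
  }
  f <- file.path(cfg$out_dir, "spectra_raw.csv")
  save_spectra(raw, f, "wide-csv")
  files <- c(files, f)

  # 2. preprocess ---------------------------------------------------------
  note("[preprocess] recipe %s",
       if (is.character(cfg$recipe)) cfg$recipe else "<custom>")
  proc <- apply_recipe(raw, cfg$recipe)
  f <- file.path(cfg$out_dir, "spectra_preprocessed.csv")
  save_spectra(proc, f, "wide-csv")
  files <- c(files, f)

  # 3. band features ------------------------------------------------------
  note("[features] extracting band matrix")
  bands <- default_band_table()
  bm <- extract_band_matrix(proc, bands, cfg$features$mode)
  ratios <- vapply(proc$spectra, function(s)
    tryCatch(ch3_ch2_ratio(s, cfg$features$mode)$ratio, error = function(e)
      NA_real_), numeric(1))
  feat_df <- data.frame(sample_id = rownames(bm), taxon = proc$labels,
                        bm, ratio = round(ratios, 10),
                        chain_length = round(
                          ifelse(is.na(ratios) | ratios <= 0, NA,
                                 estimate_chain_length(pmax(ratios, 1e-12))),
                          10), check.names = FALSE)
  f <- file.path(cfg$out_dir, "features.csv")
  write_csv_plain(feat_df, f)
  files <- c(files, f)

  # 4. explore ------------------------------------------------------------
  note("[explore] PCA, stability, outlier screening, CCA")
  x <- as_matrix(proc)
  pcs <- min(cfg$explore$pcs, nrow(x) - 1L, ncol(x))
  pca <- fit_pca(x, pcs)
  scree <- data.frame(pc = seq_len(pcs),
                      eigenvalue = pca$eigenvalues,
                      explained = pca$explained_variance,
                      cumulative = pca$cumulative_variance)
  files <- c(files, write_csv_plain(
    scree, file.path(cfg$out_dir, "pca_scree.csv")))
  files <- c(files, write_csv_plain(
    data.frame(sample_id = rownames(x), taxon = proc$labels,
               round(pca$scores, 10)),
    file.path(cfg$out_dir, "pca_scores.csv")))
  files <- c(files, write_csv_plain(
    data.frame(wavenumber = proc$wavenumbers, round(pca$loadings, 10)),
    file.path(cfg$out_dir, "pca_loadings.csv")))
  stab <- bootstrap_stability(x, pcs, cfg$explore$nboot, stage_seed(4L))
  files <- c(files, write_csv_plain(
    data.frame(pc = seq_len(pcs), mean_cosine = round(stab$mean_cosine, 10)),
    file.path(cfg$out_dir, "pca_stability.csv")))
  out_rep <- detect_outliers(pca, x, cfg$explore$confidence)
  files <- c(files, write_csv_plain(
    data.frame(sample_id = rownames(x), taxon = proc$labels,
               t2 = round(out_rep$t2, 10), q = round(out_rep$q, 10),
               flagged = out_rep$flags),
    file.path(cfg$out_dir, "outlier_report.csv")))
  clean <- if (isTRUE(cfg$explore$remove_outliers))
    remove_outliers_and_recompile(proc, out_rep) else proc
  bm_clean <- extract_band_matrix(clean, bands, cfg$features$mode)
  cca <- fit_cca(clean$onehot, bm_clean, scaling = 1)
  files <- c(files, write_csv_plain(
    data.frame(axis = names(cca$eigenvalues),
               eigenvalue = round(cca$eigenvalues, 10),
               constrained_inertia = round(cca$constrained_inertia, 10),
               total_inertia = round(cca$total_inertia, 10)),
    file.path(cfg$out_dir, "cca_eigenvalues.csv")))
  files <- c(files, write_csv_plain(
    data.frame(sample_id = rownames(bm_clean), taxon = clean$labels,
               round(cca$site_scores, 10)),
    file.path(cfg$out_dir, "cca_site_scores.csv")))

  # 5. classify -----------------------------------------------------------
  task_results <- list()
  for (task in cfg$tasks) {
    note("[classify] %s", task)
    res <- run_binary_task(clean, task, config = c(
      cfg$classify, list(seed = stage_seed(5L), preprocess = FALSE)))
    task_results[[task]] <- res
    rep <- list(task = task, n_train = res$audit$n_train,
                n_test = res$audit$n_test,
                model = res$model$kind,
                best_C = res$audit$best_C, best_gamma = res$audit$best_gamma,
                train = metrics_as_list(res$train_metrics),
                test = metrics_as_list(res$test_metrics),
                confusion = list(
                  TP = unname(res$test_metrics$confusion["TP"]),
                  FN = unname(res$test_metrics$confusion["FN"]),
                  FP = unname(res$test_metrics$confusion["FP"]),
                  TN = unname(res$test_metrics$confusion["TN"])))
    f <- file.path(cfg$out_dir, sprintf("classify_%s.json", task))
    jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    files <- c(files, f)
  }

  # 6. oneclass -----------------------------------------------------------
  note("[oneclass] DD-SIMCA on %s", POSITIVE_CLASS)
  xc <- as_matrix(clean)
  is_target <- clean$labels == POSITIVE_CLASS
  if (sum(is_target) >= 4L) {
    xt <- xc[is_target, , drop = FALSE]
    a <- cfg$oneclass$components
    if (identical(a, "auto")) {
      sel <- select_components_by_sensitivity(
        xt, candidates = 1:3, alpha = cfg$oneclass$alpha,
        mode = cfg$oneclass$mode)
      a <- sel$chosen
    }
    dd <- fit_ddsimca(xt, as.integer(a), cfg$oneclass$alpha,
                      cfg$oneclass$mode)
    alien <- xc[!is_target, , drop = FALSE]
    spec <- specificity(dd, alien, clean$labels[!is_target])
    dec <- predict_membership(dd, xc)
    files <- c(files, write_csv_plain(
      data.frame(sample_id = rownames(xc), taxon = clean$labels,
                 sd = round(dec$sd, 10), od = round(dec$od, 10),
                 c = round(dec$c, 10), accepted = dec$accepted),
      file.path(cfg$out_dir, "oneclass_decisions.csv")))
    oc_report <- list(
      n_components = dd$n_components, mode = dd$mode, alpha = dd$alpha,
      n_sd = dd$n_sd, n_od = dd$n_od, c_crit = dd$c_crit,
      n_train_outliers = sum(dd$train_outlier_flags),
      sensitivity_train = mean(
        predict_membership(dd, xt)$accepted),
      specificity_pooled = spec$pooled,
      specificity_per_class = as.list(spec$per_class))
    f <- file.path(cfg$out_dir, "oneclass_report.json")
    jsonlite::write_json(oc_report, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, f)
  } else {
    warning("too few target samples for one-class modelling; stage skipped",
            call. = FALSE)
    dd <- NULL; spec <- NULL
  }

  # manifest --------------------------------------------------------------
  manifest <- list(
    seed = cfg$seed,
    stage_seeds = list(simulate = stage_seed(1L), explore = stage_seed(4L),
                       classify = stage_seed(5L)),
    config = cfg[setdiff(names(cfg), c("input", "out_dir"))],
    artifacts = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  note("[done] manifest: %s", mf)
  invisible(list(manifest = mf, files = files, tasks = task_results,
                 oneclass = dd, specificity = spec))
}
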