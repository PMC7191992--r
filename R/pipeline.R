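# Pipeline orchestration: a validated run configuration, staged execution
# (normalize -> features/cluster -> PPKC -> select -> classify -> h2), CSV
# outputs with a JSON run manifest.

#' Build and validate a run configuration
#'
#' @param out_dir output directory for all stage outputs.
#' @param seed single integer seed from which every stage seed derives.
#' @param k_range cluster numbers (default 2:10).
#' @param n_restarts k-means restarts.
#' @param split_fractions training fractions for the classification stage.
#' @param n_iterations protocol iterations per split.
#' @param n_forests,n_trees random-forest selection effort.
#' @param min_levels feature-set consolidation rule.
#' @param efa_normalize,invert_foreground optional flags.
#' @param simulate optional [population_design()] to generate inputs; when
#'   `NULL` the caller must supply images to [run_pipeline()].
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, k_range = 2:10, n_restarts = 25,
                       split_fractions = c(0.8, 0.5, 0.2),
                       n_iterations = 10, n_forests = 100, n_trees = 2000,
                       min_levels = 3, efa_normalize = FALSE,
                       invert_foreground = FALSE, simulate = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            all(k_range >= 2), length(k_range) >= 1,
            all(split_fractions > 0 & split_fractions < 1),
            n_iterations >= 1, n_restarts >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 k_range = k_range, n_restarts = n_restarts,
                 split_fractions = split_fractions,
                 n_iterations = n_iterations, n_forests = n_forests,
                 n_trees = n_trees, min_levels = min_levels,
                 efa_normalize = efa_normalize,
                 invert_foreground = invert_foreground,
                 simulate = simulate),
            class = "run_config")
}

write_stage_csv <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# berryshape %s | seed %d",
                     as.character(utils::packageVersion("berryshape")),
                     seed), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Run the full phenotyping pipeline
#'
#' Executes the stages in order on the supplied (or simulated) images and
#' writes `pixels.csv`, `meta.csv`, `features.csv`, `criteria.csv`,
#' `assignments.csv` (ordinal classes per k after PPKC),
#' `progression_k*.csv`, `feature_sets.json`, `evaluation.csv`, `h2.csv`
#' and `manifest.json` under the configured output directory. A stage
#' failure keeps earlier outputs and records the failure point in the
#' manifest.
#'
#' @param config a [run_config()].
#' @param images list of `normalized_image` (ignored when the config
#'   carries a simulation design).
#' @param records metadata data.frame matching `images`.
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(config, images = NULL, records = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   config = config[setdiff(names(config),
                                           c("simulate"))],
                   stages = list())
  res <- list()
  fail <- NULL
  stage <- function(name, expr) {
    if (!is.null(fail)) return(invisible(NULL))
    out <- tryCatch(expr, error = function(e) {
      fail <<- list(stage = name, message = conditionMessage(e))
      NULL
    })
    manifest$stages[[name]] <<- if (is.null(fail)) "ok" else "failed"
    out
  }

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_population(config$simulate))
    if (!is.null(sim)) {
      images <- sim$images; records <- sim$records
      write_stage_csv(sim$truth, file.path(config$out_dir, "truth.csv"),
                      config$seed)
    }
  }
  if (is.null(fail) && (is.null(images) || is.null(records)))
    fail <- list(stage = "validate", message = "no images or records")
  if (is.null(fail) &&
      !all(c("sample_id", "genotype", "harvest", "block") %in%
             names(records)))
    fail <- list(stage = "validate",
                 message = "records must have sample_id, genotype, harvest, block")

  blocks <- stage("features", {
    b <- extract_feature_blocks(images)
    write_stage_csv(records, file.path(config$out_dir, "meta.csv"),
                    config$seed)
    b
  })
  fm <- stage("features", if (!is.null(blocks)) {
    f <- fit_feature_models(blocks)
    write_stage_csv(f$features, file.path(config$out_dir, "features.csv"),
                    config$seed)
    f
  })
  hist <- stage("cluster", if (!is.null(blocks)) {
    h <- cluster_history(blocks$pixels, k_range = config$k_range,
                         n_restarts = config$n_restarts,
                         seed = config$seed)
    write_stage_csv(selection_criteria(h, blocks$pixels),
                    file.path(config$out_dir, "criteria.csv"),
                    config$seed)
    h
  })
  pk <- stage("ppkc", if (!is.null(hist)) {
    p <- ppkc(hist, orient_stat = blocks$linear[, "SI"])
    asn <- data.frame(sample_id = blocks$sample_id,
                      do.call(cbind, p$ordinal_assignments))
    write_stage_csv(asn, file.path(config$out_dir, "assignments.csv"),
                    config$seed)
    for (k in config$k_range[config$k_range >= 3]) {
      M <- build_progression_matrix(hist, k)
      write_stage_csv(data.frame(attr(M, "row_index"), unclass(M)),
                      file.path(config$out_dir,
                                sprintf("progression_k%d.csv", k)),
                      config$seed)
    }
    p
  })
  sets <- stage("select", if (!is.null(pk) && !is.null(fm)) {
    imp <- list()
    for (k in config$k_range) {
      imp[[paste0("k", k)]] <- rf_importance(
        fm$features, pk$ordinal_assignments[[paste0("k", k)]],
        n_forests = config$n_forests, n_trees = config$n_trees,
        seed = config$seed + k)
    }
    fs <- select_across_k(imp, min_levels = min(config$min_levels,
                                                length(config$k_range)))
    jsonlite::write_json(fs[c("large", "medium", "small", "thresholds")],
                         file.path(config$out_dir, "feature_sets.json"),
                         auto_unbox = TRUE, digits = NA)
    fs
  })
  stage("classify", if (!is.null(sets) && !is.null(blocks)) {
    fnames <- if (length(sets$large)) sets$large else NULL  # NULL = all
    rows <- list()
    for (fr in config$split_fractions) {
      for (k in config$k_range) {
        ev <- evaluate_protocol(blocks, k,
                                feature_names = fnames,
                                fraction_train = fr,
                                n_iterations = config$n_iterations,
                                seed = config$seed,
                                n_restarts = config$n_restarts)
        m <- ev$mean
        m$k <- k; m$fraction_train <- fr
        rows[[length(rows) + 1L]] <- m
      }
    }
    tab <- do.call(rbind, rows)
    write_stage_csv(tab, file.path(config$out_dir, "evaluation.csv"),
                    config$seed)
    tab
  })
  stage("h2", if (!is.null(fm) && !is.null(pk)) {
    hq <- h2_features(fm$features, records)
    ho <- h2_classes(pk$ordinal_assignments, records)
    write_stage_csv(hq, file.path(config$out_dir, "h2.csv"), config$seed)
    write_stage_csv(ho, file.path(config$out_dir, "h2_classes.csv"),
                    config$seed)
    list(quantitative = hq, ordinal = ho)
  })

  manifest$failure <- fail
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(fail))
    warning(sprintf("pipeline stopped at stage '%s': %s", fail$stage,
                    fail$message))
  invisible(list(blocks = blocks, features = fm, history = hist,
                 ppkc = pk, sets = sets, failure = fail))
}
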