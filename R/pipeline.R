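#' Assemble a pipeline configuration
#'
#' A fully serialisable description of one end-to-end run: phantom
#' parameters, radiomics settings, penalty policy, split ratio and seed.
#' A run is reproducible bit-for-bit from the configuration alone: the
#' root seed is forked deterministically per stage (phantom noise, split,
#' CV folds), so e.g. changing the model list never perturbs phantom
#' noise.
#'
#' @param phantom a [phantom_params].
#' @param radiomics a [radiomics_config].
#' @param lambda `"cv"` or a fixed LASSO penalty.
#' @param train_frac training fraction of dataset 1 (default 0.7).
#' @param seed root seed.
#' @param models classifier kinds to evaluate.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_params(),
                            radiomics = radiomics_config(),
                            lambda = "cv", train_frac = 0.7, seed = 1L,
                            models = c("SVM", "KNN", "LDA",
                                       "DecisionTree")) {
  structure(list(phantom = phantom, radiomics = radiomics, lambda = lambda,
                 train_frac = train_frac, seed = as.integer(seed),
                 models = models),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the [pipeline_config] arguments,
#'   with `phantom` and `radiomics` as nested maps of their parameters.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_params, lapply(y$phantom %||% list(), unlist))
  rc <- do.call(radiomics_config, y$radiomics %||% list())
  pipeline_config(phantom = ph, radiomics = rc,
                  lambda = y$lambda %||% "cv",
                  train_frac = y$train_frac %||% 0.7,
                  seed = y$seed %||% 1L,
                  models = y$models %||% c("SVM", "KNN", "LDA",
                                           "DecisionTree"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Phantom cohort generation, semi-quantitative panel, 930-feature
#' extraction (streamed subject by subject, so volumes are never all held
#' in memory), stratified 7:3 split of dataset 1 (dataset 2 is entirely a
#' second test set), signature fit on the training set, index-level ROC
#' evaluation and the classifier comparison.
#'
#' @param config a [pipeline_config].
#' @param out_dir optional directory; when given, the manifest, SUR table,
#'   feature table, signature JSON, report tables and a run log are
#'   persisted there.
#' @param progress print progress dots during extraction.
#' @return List: `manifest`, `semiquant`, `features`, `signature`,
#'   `scores` (the assembled per-subject analysis table), `index_report`,
#'   `model_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "phantom"
  res <- tryCatch({
    atlas <- build_atlas()
    man <- cohort_manifest(config$phantom)
    sq_rows <- vector("list", nrow(man))
    ft_rows <- vector("list", nrow(man))
    for (i in seq_len(nrow(man))) {
      set.seed(man$seed[i])
      s <- simulate_subject(config$phantom, man$group[i], man$scanner[i],
                            atlas = atlas, id = man$id[i])
      sq_rows[[i]] <- semiquant_panel(s, atlas)
      ft_rows[[i]] <- feature_vector(s, atlas, config$radiomics)
      if (progress && i %% 10 == 0) cat(".")
    }
    if (progress) cat("\n")
    sq <- do.call(rbind, sq_rows)
    ft <- do.call(rbind, ft_rows)
    stage <- "split"
    if (length(unique(man$group)) < 2L)
      stop("both NC and PD are required for the split", call. = FALSE)
    d1 <- man$scanner == "dataset1"
    sp <- stratified_split(man$id[d1], man$group[d1],
                           train_frac = config$train_frac,
                           seed = config$seed + 1L)
    set <- ifelse(!d1, "test2", ifelse(man$id %in% sp$train, "train",
                                       "test1"))
    stage <- "signature"
    tr <- set == "train"
    sig <- fit_signature(ft[tr, , drop = FALSE],
                         as.numeric(man$group[tr] == "PD"),
                         lambda = config$lambda, seed = config$seed + 2L)
    sig_score <- score_signature(sig, ft)
    stage <- "evaluate"
    tab <- cbind(man[, c("id", "group", "scanner")],
                 set = set, as.data.frame(sq),
                 signature_score = sig_score)
    index_report <- evaluate_indices(
      tab, c("SUR_caudate", "SUR_putamen", "SUR_pallidum", "CR_putamen",
             "CR_pallidum", "signature_score"))
    model_report <- train_and_evaluate(tab, kinds = config$models)
    list(manifest = man, semiquant = cbind(man[, c("id", "group",
                                                   "scanner")],
                                           as.data.frame(sq)),
         features = ft, signature = sig, scores = tab,
         index_report = index_report, model_report = model_report)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(res$manifest, "manifest.tsv")
    wt(res$semiquant, "surs.tsv")
    ftab <- cbind(res$manifest[, c("id", "group", "scanner")],
                  as.data.frame(res$features, check.names = FALSE))
    wt(ftab, "features.tsv")
    wt(res$scores, "scores.tsv")
    wt(res$index_report, "index_report.tsv")
    wt(res$model_report, "model_report.tsv")
    write_signature(res$signature, file.path(out_dir, "signature.json"))
    writeLines(c(sprintf("striatomics %s",
                         as.character(utils::packageVersion("striatomics"))),
                 sprintf("R %s", R.version.string),
                 sprintf("seed %d", config$seed),
                 sprintf("cohort sizes %s",
                         paste(config$phantom$sizes, collapse = "/")),
                 sprintf("lambda %s", format(res$signature$lambda))),
               file.path(out_dir, "run_log.txt"))
  }
  res
}
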