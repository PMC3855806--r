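# End-to-end orchestration: training-set construction, featurization,
# selection, cross-validation, final model, manifold ranking, differential
# expression and candidate intersection, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter and input path. When `fasta` is `NULL` the
#' pipeline runs on synthetic data drawn from `synth`; otherwise proteins
#' are read from `fasta`/`annotations` and the positive seeds from
#' `seed_ids`. A single global seed fans out to per-stage seeds by fixed
#' offsets so stages are individually reproducible.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed.
#' @param fasta,annotations Optional input paths (FASTA + annotation TSV).
#' @param seed_ids Ids of the positive seed proteins (required with `fasta`).
#' @param expression Optional path to a paired expression TSV; synthesized
#'   in synthetic mode when `NULL`.
#' @param secretory_ids Optional ids predicted blood-secretory (an external
#'   evidence list); defaults to all proteins.
#' @param synth A [synth_spec()] for synthetic mode.
#' @param descriptor A [descriptor_config()].
#' @param trainset A [trainset_spec()].
#' @param ranking A [ranking_config()].
#' @param q_cutoff,n_perm,perf_tolerance Feature-selection parameters.
#' @param cv_folds,cv_repeats Cross-validation parameters.
#' @param fc_threshold,p_threshold Differential-expression cutoffs.
#' @param run_deg Run the expression branch (default `TRUE`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            fasta = NULL, annotations = NULL,
                            seed_ids = NULL, expression = NULL,
                            secretory_ids = NULL,
                            synth = synth_spec(),
                            descriptor = descriptor_config(),
                            trainset = trainset_spec(),
                            ranking = ranking_config(),
                            q_cutoff = 0.005, n_perm = 10000,
                            perf_tolerance = 0.01,
                            cv_folds = 10, cv_repeats = 10,
                            fc_threshold = 1.5, p_threshold = 0.05,
                            run_deg = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full prediction pipeline
#'
#' Executes, in order: training-set construction, featurization, two-stage
#' feature selection, repeated cross-validation, final model training,
#' manifold ranking of all proteins, differential expression (optional) and
#' candidate intersection. Each stage writes a TSV under `out_dir`; a
#' manifest records every stage's output file, its MD5 hash, wall time and
#' the global seed, so a rerun at the same seed is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Manifest tibble (stage, output, md5, seconds, seed), invisibly
#'   also written to `manifest.tsv`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  stage <- function(name, outfile, f) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(f(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    path <- file.path(config$out_dir, outfile)
    write_table(res, path)
    manifest[[name]] <<- tibble::tibble(
      stage = name, output = outfile,
      md5 = unname(tools::md5sum(path)),
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      seed = config$seed)
    res
  }

  synthetic <- is.null(config$fasta)
  if (synthetic) {
    proteins <- generate_sequences(config$synth, config$seed)
    seed_ids <- proteins$id[proteins$label == 1]
  } else {
    proteins <- annotate_proteins(read_fasta(config$fasta),
                                  read_annotations(config$annotations))
    seed_ids <- config$seed_ids
    if (is.null(seed_ids)) stop("seed_ids required with a FASTA input", call. = FALSE)
  }

  train <- stage("trainset", "trainset.tsv", function() {
    tr <- build_trainset(proteins[proteins$id %in% seed_ids, ], proteins,
                         spec = config$trainset)
    tr[, c("id", "label")]
  })

  features <- stage("featurize", "features.tsv", function() {
    featurize(proteins[, c("id", "sequence")], config$descriptor)
  })

  train_feats <- features[match(train$id, features$id), ]
  sel <- NULL
  stage("select", "selection.tsv", function() {
    sel <<- select_features(train_feats, train$label,
                            q_cutoff = config$q_cutoff,
                            n_perm = config$n_perm,
                            perf_tolerance = config$perf_tolerance,
                            cv_folds = config$cv_folds,
                            seed = config$seed + 1L)
    sel$table
  })
  sel_cols <- c("id", sel$table$feature[sel$table$selected])

  cv <- NULL
  stage("cv", "cv_metrics.tsv", function() {
    cv <<- cross_validate(train_feats[, sel_cols], train$label,
                          folds = config$cv_folds,
                          repeats = config$cv_repeats,
                          seed = config$seed + 2L)
    cv$per_repeat
  })

  model <- NULL
  stage("train", "model.tsv", function() {
    model <<- train_svm(train_feats[, sel_cols], train$label)
    tibble::tibble(term = c(names(model$weights), "(bias)"),
                   weight = c(unname(model$weights), model$bias))
  })

  ranking <- NULL
  stage("rank", "ranking.tsv", function() {
    Xs <- as_feature_matrix(features[, sel_cols])
    Xs <- scale(Xs)
    Xs[, apply(is.na(Xs), 2, any)] <- 0  # constant columns carry no geometry
    W <- build_affinity(Xs, config$ranking)
    ranking <<- manifold_rank(W, positive_ids = train$id[train$label == 1],
                              config = config$ranking)
    tibble::as_tibble(ranking)
  })

  deg_ids <- character(0)
  if (config$run_deg) {
    expr <- if (!is.null(config$expression)) {
      if (!file.exists(config$expression)) {
        stop("stage 'deg' failed: expression input not found: ",
             config$expression, call. = FALSE)
      }
      read_table(config$expression)
    } else if (synthetic) {
      generate_expression(config$synth, config$seed + 3L,
                          gene_ids = proteins$id)$expression
    } else {
      stop("stage 'deg' failed: deg enabled but no expression input given",
           call. = FALSE)
    }
    deg_tab <- stage("deg", "deg.tsv", function() {
      differential_expression(expr, fc_threshold = config$fc_threshold,
                              p_threshold = config$p_threshold)
    })
    deg_ids <- deg_tab$gene_id[deg_tab$de]
  }

  stage("candidates", "candidates.tsv", function() {
    predicted <- features$id[predict(model, features) == 1]
    secretory <- config$secretory_ids
    if (is.null(secretory)) secretory <- proteins$id
    intersect_candidates(deg_ids, secretory, predicted, ranking = ranking)
  })

  manifest <- dplyr::bind_rows(manifest)
  write_table(manifest, file.path(config$out_dir, "manifest.tsv"))
  manifest
}
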