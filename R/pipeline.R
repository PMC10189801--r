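# Config-driven orchestration: simulate -> tracks -> dataset -> train ->
# evaluate -> profile -> explain, with a run manifest and idempotent re-runs.

.known_stages <- c("simulate", "tracks", "dataset", "train", "evaluate",
                   "profile", "explain")

#' Validate a pipeline configuration
#'
#' Schema violations raise before any compute. See the package vignette for
#' the config layout; configs are JSON files (or equivalent R lists).
#'
#' @param config List or path to a JSON config file.
#' @return The validated config list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config needs out_dir")
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (is.null(config$stages)) config$stages <- .known_stages
  bad <- setdiff(config$stages, .known_stages)
  if (length(bad)) stop("unknown stage: ", bad[1])
  if (is.null(config$simulate$profile)) config$simulate$profile <- "motif_driven"
  if (!config$simulate$profile %in% c("motif_driven", "annotation_driven",
                                      "neighbor_driven"))
    stop("invalid simulate.profile: ", config$simulate$profile)
  ds <- config$dataset
  if (is.null(ds)) ds <- list()
  ds$context <- if (is.null(ds$context)) "ALL" else ds$context
  if (!ds$context %in% c("CG", "CHG", "CHH", "ALL"))
    stop("invalid dataset.context: ", ds$context)
  ds$kind <- if (is.null(ds$kind)) "sequence" else ds$kind
  if (!ds$kind %in% c("sequence", "neighbor", "combined"))
    stop("invalid dataset.kind: ", ds$kind)
  ds$n <- if (is.null(ds$n)) 6000L else as.integer(ds$n)
  ds$W_s <- if (is.null(ds$W_s)) 200L else as.integer(ds$W_s)
  ds$W_p <- if (is.null(ds$W_p)) 20L else as.integer(ds$W_p)
  ds$with_annotations <- isTRUE(ds$with_annotations)
  config$dataset <- ds
  tr <- config$train
  if (is.null(tr)) tr <- list()
  tr$model <- if (is.null(tr$model)) {
    switch(ds$kind, sequence = "amps_cnn", neighbor = "neighbor_mlp",
           combined = "combined")
  } else tr$model
  if (!tr$model %in% c("amps_cnn", "neighbor_mlp", "combined",
                       "random_forest"))
    stop("invalid train.model: ", tr$model)
  tr$epochs <- if (is.null(tr$epochs)) 20L else as.integer(tr$epochs)
  tr$batch_size <- if (is.null(tr$batch_size)) 32L else as.integer(tr$batch_size)
  tr$learning_rate <- if (is.null(tr$learning_rate)) 0.001 else tr$learning_rate
  config$train <- tr
  ex <- config$explain
  if (is.null(ex)) ex <- list()
  ex$n_per_class <- if (is.null(ex$n_per_class)) 200L else
    as.integer(ex$n_per_class)
  ex$width <- if (is.null(ex$width)) 50L else as.integer(ex$width)
  config$explain <- ex
  config
}

.config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline from a config
#'
#' Executes the requested stages in order with all randomness derived from the
#' root seed, records a manifest (config snapshot + digest, seeds, per-stage
#' timings, input digests, output paths, package version), and skips stages
#' whose outputs already exist from a previous run with an identical config.
#'
#' @param config List or path to a JSON config file (see [validate_config()]).
#' @return The manifest list, invisibly written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- .config_digest(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
             error = function(e) NULL)
  manifest <- list(package_version = as.character(utils::packageVersion("methpred")),
                   config = config, config_digest = digest,
                   seed = config$seed, stages = list(), outputs = list())
  reuse_ok <- !is.null(prev) && identical(prev$config_digest, digest)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, outputs, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    if (reuse_ok && all(file.exists(file.path(out_dir, outputs)))) {
      manifest$stages[[name]] <<- list(status = "skipped", outputs = outputs)
    } else {
      fun()
      manifest$stages[[name]] <<- list(
        status = "run", outputs = outputs,
        seconds = round(proc.time()[["elapsed"]] - t0, 3))
    }
    paths <- file.path(out_dir, outputs)
    manifest$outputs[[name]] <<-
      list(paths = outputs,
           md5 = unname(tools::md5sum(paths[file.exists(paths)])))
    invisible(NULL)
  }

  fixture_dir <- "fixture"
  load_fixture <- function() {
    if (is.null(state$fixture))
      state$fixture <- make_fixture(config$simulate$profile,
                                    seed = config$seed)
    state$fixture
  }
  run_stage("simulate",
            file.path(fixture_dir, c("genome.fa", "features.gff3",
                                     "repeats.bed", "cytosine_report.tsv",
                                     "truth.tsv", "config.json")),
            function() write_fixture(load_fixture(),
                                     file.path(out_dir, fixture_dir)))
  run_stage("tracks", "tracks.rds", function() {
    fx <- load_fixture()
    tracks <- build_tracks(fx$features, fx$genome)
    saveRDS(tracks, file.path(out_dir, "tracks.rds"))
    state$tracks <- tracks
  })
  get_tracks <- function() {
    if (is.null(state$tracks)) {
      p <- file.path(out_dir, "tracks.rds")
      state$tracks <- if (file.exists(p)) readRDS(p) else {
        fx <- load_fixture()
        build_tracks(fx$features, fx$genome)
      }
    }
    state$tracks
  }
  run_stage("dataset", "split.rds", function() {
    fx <- load_fixture()
    ds_cfg <- config$dataset
    tracks <- if (ds_cfg$with_annotations) get_tracks() else NULL
    dset <- switch(ds_cfg$kind,
      sequence = build_sequence_dataset(fx$genome, fx$calls, ds_cfg$context,
                                        ds_cfg$n, ds_cfg$W_s, tracks,
                                        seed = config$seed),
      neighbor = build_neighbor_dataset(fx$calls, ds_cfg$context, ds_cfg$n,
                                        ds_cfg$W_p, seed = config$seed),
      combined = build_combined_dataset(fx$genome, fx$calls, ds_cfg$context,
                                        ds_cfg$n, ds_cfg$W_s, tracks,
                                        ds_cfg$W_p, seed = config$seed))
    split <- split_80_10_10(dset, seed = config$seed)
    saveRDS(split, file.path(out_dir, "split.rds"))
    state$split <- split
  })
  get_split <- function() {
    if (is.null(state$split))
      state$split <- readRDS(file.path(out_dir, "split.rds"))
    state$split
  }
  run_stage("train", "model.rds", function() {
    split <- get_split()
    ds_cfg <- config$dataset
    a <- if (ds_cfg$with_annotations) 3L else 0L
    model <- switch(config$train$model,
      amps_cnn = build_amps_cnn(ds_cfg$W_s, a, seed = config$seed),
      neighbor_mlp = build_neighbor_mlp(ds_cfg$W_p, seed = config$seed),
      combined = build_combined(ds_cfg$W_s, a, ds_cfg$W_p,
                                seed = config$seed),
      random_forest = build_random_forest(seed = config$seed))
    cfg <- train_config(batch_size = config$train$batch_size,
                        epochs = config$train$epochs,
                        learning_rate = config$train$learning_rate,
                        seed = config$seed)
    model <- train_model(model, split, cfg)
    saveRDS(model, file.path(out_dir, "model.rds"))
    state$model <- model
  })
  get_model <- function() {
    if (is.null(state$model))
      state$model <- readRDS(file.path(out_dir, "model.rds"))
    state$model
  }
  run_stage("evaluate", "metrics.json", function() {
    split <- get_split()
    model <- get_model()
    pred <- predict(model, split$test)
    m <- compute_metrics(split$test$y, pred$call)
    jsonlite::write_json(unclass(m), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  run_stage("profile", "gene_profile.tsv", function() {
    fx <- load_fixture()
    genes <- fx$features[fx$features$feature_type == "gene"]
    prof <- if (nrow(genes) == 0L)
      data.table::data.table(context = character(), orientation = character(),
                             bin = integer(), M = numeric(), genes = integer(),
                             total_length = numeric())
    else data.table::rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx)
      gene_profile(fx$calls, genes, ctx)))
    data.table::fwrite(prof, file.path(out_dir, "gene_profile.tsv"),
                       sep = "\t")
  })
  run_stage("explain", "motif_candidates.fa", function() {
    model <- get_model()
    if (model$kind %in% c("amps_cnn", "combined")) {
      split <- get_split()
      cand <- select_candidates(model, split$test,
                                n_per_class = config$explain$n_per_class,
                                width = config$explain$width)
      export_fasta(cand, file.path(out_dir, "motif_candidates.fa"))
    } else {
      message("explain stage skipped: model is not convolutional")
      writeLines(character(0), file.path(out_dir, "motif_candidates.fa"))
    }
  })
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
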