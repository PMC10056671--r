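#' Run the full batch-correction pipeline
#'
#' Sequential orchestration of all stages: (optionally) simulate or load a
#' dataset, preprocess, build the anchor set and training mapping, train the
#' adversarial autoencoder, apply the correction, and evaluate. Every stage's
#' seed and configuration is recorded in a run manifest; with fixed seeds two
#' runs produce identical evaluation reports.
#'
#' @param config Either a path to a YAML file or a list, with sections:
#'   \describe{
#'     \item{`simulation`}{arguments for [simulation_config()] (omit when
#'       `input` is given)}
#'     \item{`input`}{list with `path` and `format` for [read_matrix()]}
#'     \item{`pipeline`}{arguments for [pipeline_config()]}
#'     \item{`anchor`}{`mode` (`"balanced"`, `"max_std"`, `"custom"`),
#'       optional `batch_id`, `max_per_type`, `seed`}
#'     \item{`train`}{arguments for [aae_config()] except `n_genes`}
#'     \item{`evaluate`}{`n_pcs`, `seed`}
#'   }
#' @param outdir Optional output directory; when given, the corrected
#'   matrix (`corrected` mtx_dir), `report.json` and `manifest.json` are
#'   written there.
#' @param verbose Log stage progress to stderr.
#' @return List with `data`, `prep`, `anchors`, `mapping`, `model`,
#'   `correction`, `report` (a `MetricReport`) and `manifest`.
#' @export
run_all <- function(config, outdir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (verbose) message("[imaae] ", ...)
  manifest <- list(tool_version = as.character(utils::packageVersion("imaae")),
                   started = format(Sys.time(), usetz = TRUE),
                   stages = list())
  stamp <- function(stage, cfg)
    manifest$stages[[stage]] <<- list(config = cfg,
                                      time = format(Sys.time(), usetz = TRUE))

  if (!is.null(config$input)) {
    say("reading input ", config$input$path)
    data <- read_matrix(config$input$path, config$input$format)
    stamp("input", config$input)
  } else {
    sim_cfg <- do.call(simulation_config, config$simulation %||% list())
    say("simulating: ", sim_cfg$scenario, " scenario, ",
        sim_cfg$n_batches, " batches")
    data <- simulate_counts(sim_cfg)
    stamp("simulate", unclass(sim_cfg)[setdiff(names(sim_cfg),
                                               "type_presence")])
  }

  pipe_cfg <- do.call(pipeline_config, config$pipeline %||% list())
  say("preprocessing ", nrow(data$values), " cells x ",
      ncol(data$values), " genes")
  prep <- preprocess(data, pipe_cfg)
  stamp("preprocess", unclass(pipe_cfg))

  acfg <- config$anchor %||% list()
  mode <- acfg$mode %||% "balanced"
  max_per_type <- acfg$max_per_type %||% 1000
  aseed <- acfg$seed %||% pipe_cfg$random_seed
  say("anchor mode: ", mode)
  anchors <- switch(mode,
    balanced = select_anchor_balanced(prep$matrix, prep$graph,
                                      max_per_type, aseed),
    max_std = select_anchor_max_std(prep$matrix, max_per_type, aseed),
    custom = select_anchor_custom(prep$matrix, acfg$batch_id,
                                  max_per_type, aseed),
    stop("unknown anchor mode '", mode, "'"))
  mapping <- build_training_mapping(prep$matrix, anchors, prep$graph,
                                    seed = aseed)
  stamp("anchor", list(mode = mode, max_per_type = max_per_type,
                       seed = aseed))

  tcfg_args <- config$train %||% list()
  tcfg_args$n_genes <- ncol(prep$matrix$values)
  model_cfg <- do.call(aae_config, tcfg_args)
  say("training: ", model_cfg$epochs, " epochs, latent ",
      model_cfg$latent_dim, ", mode ", model_cfg$mode)
  model <- train_aae(prep$matrix, mapping, anchors, model_cfg)
  stamp("train", unclass(model$config))

  say("applying correction")
  correction <- apply_correction(model, prep$matrix, mapping)
  stamp("correct", list())

  ecfg <- config$evaluate %||% list()
  say("evaluating")
  report <- evaluate_all(correction, prep$matrix$batch,
                         prep$matrix$cell_type,
                         n_pcs = ecfg$n_pcs %||% 50,
                         seed = ecfg$seed %||% pipe_cfg$random_seed)
  stamp("evaluate", list(n_pcs = ecfg$n_pcs %||% 50,
                         seed = ecfg$seed %||% pipe_cfg$random_seed))
  manifest$finished <- format(Sys.time(), usetz = TRUE)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    corr <- prep$matrix
    corr$values <- correction$corrected_expression
    write_matrix(corr, file.path(outdir, "corrected"), "mtx_dir")
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(file.path(outdir, "report.json"),
               list.files(file.path(outdir, "corrected"),
                          full.names = TRUE))
    manifest$file_hashes <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
  }

  list(data = data, prep = prep, anchors = anchors, mapping = mapping,
       model = model, correction = correction, report = report,
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
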