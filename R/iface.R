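# Run configuration and end-to-end commands.  Every artifact-producing
# run writes a JSON manifest (resolved config, seeds, package version,
# wall time) sufficient to re-run it identically.

.defaultConfig <- function() {
    list(
        seed = 1L,
        outDir = "stridenet-out",
        dataset = NULL,   # CSV path; NULL generates from the block below
        generator = list(nSin = 32L, nConst = 3L,
                         magnitudeScale = 1, noiseScale = 1),
        network = list(nHidden = 3L,
                       activations = list(uae = "tanh", tae = "linear",
                                          expander = "elu")),
        training = list(epochs = list(uae = 1000L, tae = 500L,
                                      expander = 2000L),
                        learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, nRepeats = 10L),
        sweep = list(axis = "layers", epochs = 2000L, nHidden = 3L),
        evaluate = list(checkpoint = NULL, dataset = NULL),
        surface = list(min = 0, max = 300, step = 1, checkpoint = NULL)
    )
}

.mergeConfig <- function(defaults, user, path = "") {
    for (nm in names(user)) {
        if (!nm %in% names(defaults)) {
            hint <- agrep(nm, names(defaults), max.distance = 2, value = TRUE)
            stop("unknown config key '", paste0(path, nm), "'",
                 if (length(hint)) paste0("; did you mean '", hint[1L], "'?")
                 else "")
        }
        if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
            !is.null(names(defaults[[nm]]))) {
            defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]],
                                           paste0(path, nm, "$"))
        } else {
            defaults[[nm]] <- user[[nm]]
        }
    }
    defaults
}

#' Parse a run configuration
#'
#' Starts from the defaults -- which reproduce the selected final
#' configuration: 3 hidden layers, middle activations tanh/linear/elu and
#' 1000/500/2000 epochs for UAE/TAE/expander -- then overlays a YAML (or
#' JSON) file and/or a list of overrides.  Unknown keys are rejected with
#' a spelling suggestion.
#'
#' @param path optional YAML/JSON config file.
#' @param overrides optional named list merged last.
#' @return the resolved configuration (class `RunConfig`).
#' @export
parseRunConfig <- function(path = NULL, overrides = list()) {
    cfg <- .defaultConfig()
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        user <- yaml::read_yaml(path)
        if (!is.null(user)) cfg <- .mergeConfig(cfg, user)
    }
    if (length(overrides)) cfg <- .mergeConfig(cfg, overrides)
    cfg$seed <- as.integer(cfg$seed)
    structure(cfg, class = "RunConfig")
}

.writeManifest <- function(outDir, command, config, artifacts, t0) {
    manifest <- list(
        command = command,
        config = unclass(config),
        artifacts = artifacts,
        package = as.character(utils::packageVersion("stridenet")),
        rVersion = as.character(getRversion()),
        wallTimeSec = as.numeric(Sys.time()) - t0
    )
    path <- file.path(outDir, paste0("manifest_", command, ".json"))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    path
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint as JSON
#'
#' Serializes a [StrideModel-class] including all parameter values and tie
#' structure; a tied autoencoder is restored with its decoder sharing the
#' encoder's weight storage.
#'
#' @param model a [StrideModel-class].
#' @param path JSON file path.
#' @return `saveModel` returns `path` invisibly; `loadModel` the restored
#'   model.
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "StrideModel"))
    obj <- list(type = model@type, nHidden = model@nHidden,
                middleActivation = model@middleActivation, seed = model@seed,
                decoder = serializeNetwork(model@decoder))
    if (!is.null(model@encoder))
        obj$encoder <- serializeNetwork(model@encoder)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    tied <- identical(obj$type, "tae")
    enc <- NULL; env <- NULL
    if (!is.null(obj$encoder) && length(obj$encoder)) {
        enc <- deserializeNetwork(obj$encoder)
        if (tied) env <- enc@params
    }
    dec <- deserializeNetwork(obj$decoder, env = env)
    new("StrideModel", type = obj$type, encoder = enc, decoder = dec,
        nHidden = as.integer(obj$nHidden),
        middleActivation = obj$middleActivation,
        seed = as.integer(obj$seed))
}

# ---- commands --------------------------------------------------------------

.obtainDataset <- function(config) {
    if (!is.null(config$dataset)) return(readGaitDataset(config$dataset))
    g <- config$generator
    generateGaitDataset(g$nSin, g$nConst, seed = config$seed,
                        magnitudeScale = g$magnitudeScale,
                        noiseScale = g$noiseScale)
}

.trainOne <- function(type, data, config) {
    net <- config$network
    tr <- config$training
    model <- strideModel(type, net$nHidden, net$activations[[type]],
                         seed = config$seed)
    cfg <- trainConfig(epochs = tr$epochs[[type]],
                       learningRate = tr$learningRate, beta1 = tr$beta1,
                       beta2 = tr$beta2, epsilon = tr$epsilon,
                       nRepeats = 1L, seed = config$seed)
    fit <- fitModel(model, splitTrainHoldout(data)$train, cfg)
    list(model = model, lossHistory = fit$lossHistory)
}

#' Run one pipeline command
#'
#' * `generate` -- write the synthetic dataset CSV (+ JSON sidecar).
#' * `train` -- train the three final networks on the train split; write
#'   one checkpoint JSON and loss-history CSV per network.
#' * `tune` -- run the sweep named by `config$sweep$axis`; write the tidy
#'   sweep CSV and the selected best settings.
#' * `evaluate` -- score a checkpoint on the holdout split; write the
#'   per-model r table.
#' * `surface` -- write the mean-to-series surface CSV of a checkpoint.
#' * `repro` -- chain generate, reduced-repeat layer and activation
#'   sweeps, final training, holdout evaluation and surfaces.
#'
#' Every command writes a manifest JSON into `config$outDir` and returns
#' its artifact paths invisibly; failures raise ordinary R errors (the
#' command-line wrapper converts them into a nonzero exit status).
#'
#' @param name command name.
#' @param config a [parseRunConfig()] result.
#' @return invisibly, a named list of artifact paths.
#' @export
runCommand <- function(name = c("generate", "train", "tune", "evaluate",
                                "surface", "repro"),
                       config = parseRunConfig()) {
    name <- match.arg(name)
    t0 <- as.numeric(Sys.time())
    out <- config$outDir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    artifacts <- list()
    if (name == "generate") {
        gd <- .obtainDataset(config)
        artifacts$dataset <- file.path(out, "dataset.csv")
        writeGaitDataset(gd, artifacts$dataset)
    } else if (name == "train") {
        gd <- .obtainDataset(config)
        for (type in c("uae", "tae", "expander")) {
            message("training ", type, " ...")
            res <- .trainOne(type, gd, config)
            ck <- file.path(out, paste0("checkpoint_", type, ".json"))
            saveModel(res$model, ck)
            lh <- file.path(out, paste0("loss_", type, ".csv"))
            utils::write.csv(data.frame(epoch = seq_along(res$lossHistory),
                                        loss = res$lossHistory),
                             lh, row.names = FALSE)
            artifacts[[paste0("checkpoint_", type)]] <- ck
            artifacts[[paste0("loss_", type)]] <- lh
        }
    } else if (name == "tune") {
        gd <- .obtainDataset(config)
        tr <- config$training
        cfg <- trainConfig(epochs = config$sweep$epochs,
                           learningRate = tr$learningRate, beta1 = tr$beta1,
                           beta2 = tr$beta2, epsilon = tr$epsilon,
                           nRepeats = tr$nRepeats, seed = config$seed)
        axis <- config$sweep$axis
        sw <- switch(axis,
            layers = sweepLayers(gd, cfg),
            activations = sweepActivations(gd, config$sweep$nHidden, cfg),
            epochs = sweepEpochs(gd, config = cfg),
            stop("unknown sweep axis: ", axis))
        artifacts$sweep <- file.path(out, paste0("sweep_", axis, ".csv"))
        writeSweepCSV(sw, artifacts$sweep)
        artifacts$best <- file.path(out, paste0("best_", axis, ".json"))
        jsonlite::write_json(selectBest(sw), artifacts$best,
                             auto_unbox = TRUE, digits = NA)
    } else if (name == "evaluate") {
        ck <- config$evaluate$checkpoint
        if (is.null(ck) || !file.exists(ck %||% ""))
            stop("evaluate needs an existing checkpoint ",
                 "(config$evaluate$checkpoint); train first")
        model <- loadModel(ck)
        dpath <- config$evaluate$dataset %||% config$dataset
        gd <- if (!is.null(dpath)) readGaitDataset(dpath)
              else .obtainDataset(config)
        tab <- evaluateHoldout(model, splitTrainHoldout(gd)$holdout)
        artifacts$holdout <- file.path(out, "holdout_r.csv")
        utils::write.csv(tab, artifacts$holdout, row.names = FALSE)
    } else if (name == "surface") {
        ck <- config$surface$checkpoint
        if (is.null(ck) || !file.exists(ck %||% ""))
            stop("surface needs an existing checkpoint ",
                 "(config$surface$checkpoint); train first")
        model <- loadModel(ck)
        sp <- surfaceProfile(model, config$surface$min, config$surface$max,
                             config$surface$step)
        artifacts$surface <- file.path(out, "surface.csv")
        writeSurfaceCSV(sp, artifacts$surface)
    } else if (name == "repro") {
        gd <- .obtainDataset(config)
        artifacts$dataset <- file.path(out, "dataset.csv")
        writeGaitDataset(gd, artifacts$dataset)
        tr <- config$training
        cfg <- trainConfig(epochs = config$sweep$epochs,
                           learningRate = tr$learningRate, beta1 = tr$beta1,
                           beta2 = tr$beta2, epsilon = tr$epsilon,
                           nRepeats = tr$nRepeats, seed = config$seed)
        message("layer sweep ...")
        swL <- sweepLayers(gd, cfg)
        artifacts$sweep_layers <- file.path(out, "sweep_layers.csv")
        writeSweepCSV(swL, artifacts$sweep_layers)
        message("activation sweep ...")
        swA <- sweepActivations(gd, config$sweep$nHidden, cfg)
        artifacts$sweep_activation <- file.path(out, "sweep_activation.csv")
        writeSweepCSV(swA, artifacts$sweep_activation)
        holdTabs <- list()
        for (type in c("uae", "tae", "expander")) {
            message("final training: ", type, " ...")
            res <- .trainOne(type, gd, config)
            ck <- file.path(out, paste0("checkpoint_", type, ".json"))
            saveModel(res$model, ck)
            artifacts[[paste0("checkpoint_", type)]] <- ck
            tab <- evaluateHoldout(res$model,
                                   splitTrainHoldout(gd)$holdout)
            holdTabs[[type]] <- stats::setNames(
                tab[, c("model_id", "r")], c("model_id", paste0("r_", type)))
            sp <- surfaceProfile(res$model, config$surface$min,
                                 config$surface$max, config$surface$step)
            sf <- file.path(out, paste0("surface_", type, ".csv"))
            writeSurfaceCSV(sp, sf)
            artifacts[[paste0("surface_", type)]] <- sf
        }
        hold <- Reduce(function(a, b) merge(a, b, by = "model_id"), holdTabs)
        artifacts$holdout <- file.path(out, "holdout_r.csv")
        utils::write.csv(hold, artifacts$holdout, row.names = FALSE)
    }
    artifacts$manifest <- .writeManifest(out, name, config, artifacts, t0)
    invisible(artifacts)
}
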