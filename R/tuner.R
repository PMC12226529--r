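# Architecture tuning studies: layer count, middle-layer activation, and
# epoch count, each aggregated as the mean holdout Pearson r per cost
# model over repeated trainings with fresh networks.
#
# Every sweep cell reuses the same base seed, so repeat k of any cell
# draws its fresh network from seed (base + k - 1).  This makes cells
# comparable repeat-for-repeat and makes the linear activation cell of the
# activation study bit-identical to the matching cell of the layer study.

.activationGrid <- c("linear", "relu", "elu", "sigmoid", "silu", "mish", "tanh")

#' Epoch grid of the epoch-count study
#'
#' 250 to 3000 in steps of 250, then 3500 to 10000 in steps of 500:
#' 26 settings in total.
#'
#' @return integer vector of length 26.
#' @export
epochGrid <- function() as.integer(c(seq(250, 3000, by = 250),
                                     seq(3500, 10000, by = 500)))

#' Aggregate repeat records into mean correlations
#'
#' @param records non-empty list of `TrialRecord`s from [runRepeats()].
#' @return list with `perModel` (named mean r per cost model, averaged
#'   over repeats, NA r values from degenerate outputs dropped) and
#'   `overall` (unweighted mean of the per-model means).
#' @export
aggregateMeanR <- function(records) {
    records <- Filter(function(rec) is.null(rec$error) && !is.null(rec$r),
                      records)
    if (!length(records)) stop("no successful repeat records to aggregate")
    rmat <- do.call(rbind, lapply(records, `[[`, "r"))
    perModel <- colMeans(rmat, na.rm = TRUE)
    list(perModel = perModel, overall = mean(perModel))
}

.runSweep <- function(axis, grid, cells, data, config) {
    perModel <- list(); overall <- list()
    for (cell in cells) {
        cfg <- config
        cfg$epochs <- as.integer(cell$epochs)
        recs <- runRepeats(cell$network, data, cfg,
                           nHidden = cell$nHidden,
                           middleActivation = cell$activation)
        agg <- aggregateMeanR(recs)
        perModel[[length(perModel) + 1L]] <- data.frame(
            network = cell$network, setting = cell$setting,
            model_id = names(agg$perModel),
            mean_r = as.numeric(agg$perModel), row.names = NULL)
        overall[[length(overall) + 1L]] <- data.frame(
            network = cell$network, setting = cell$setting,
            mean_r = agg$overall, row.names = NULL)
    }
    new("SweepResult", axis = axis, grid = grid,
        perModel = do.call(rbind, perModel),
        overall = do.call(rbind, overall))
}

#' Layer-count study
#'
#' Trains each requested network family with 1, 2 and 3 hidden layers of
#' the arithmetic-sequence widths, all activations linear, and aggregates
#' holdout mean r over repeats.
#'
#' @param data a full [GaitDataset-class].
#' @param config a [trainConfig()]; `epochs` (default 2000) and
#'   `nRepeats` apply to every cell.
#' @param types network families to include.
#' @return a [SweepResult-class] with `axis = "layers"`, grid 1:3.
#' @export
sweepLayers <- function(data, config = trainConfig(),
                        types = c("uae", "tae", "expander")) {
    cells <- list()
    for (ty in types) for (nh in 1:3)
        cells[[length(cells) + 1L]] <- list(
            network = ty, setting = nh, nHidden = nh,
            activation = "linear", epochs = config$epochs)
    .runSweep("layers", 1:3, cells, data, config)
}

#' Middle-activation study
#'
#' Sweeps the activation of the designated middle stage (the 50-unit stage
#' at depth 2, the 66-unit stage at depth 3 -- applied on both encoder and
#' decoder side where present) over the linear baseline plus the six
#' nonlinearities; every other stage stays linear.
#'
#' @param data a full [GaitDataset-class].
#' @param nHidden 2 or 3.
#' @param config a [trainConfig()].
#' @param types network families to include.
#' @return a [SweepResult-class] with `axis = "activation"`.
#' @export
sweepActivations <- function(data, nHidden = 3L, config = trainConfig(),
                             types = c("uae", "tae", "expander")) {
    if (!nHidden %in% c(2L, 3L))
        stop("the activation study uses 2 or 3 hidden layers")
    cells <- list()
    for (ty in types) for (act in .activationGrid)
        cells[[length(cells) + 1L]] <- list(
            network = ty, setting = act, nHidden = nHidden,
            activation = act, epochs = config$epochs)
    .runSweep("activation", .activationGrid, cells, data, config)
}

#' Epoch-count study
#'
#' Evaluates the selected per-network architectures (3 hidden layers with
#' tanh, linear and elu middle activations for UAE, TAE and expander by
#' default) over the 26-point epoch grid of [epochGrid()].
#'
#' @param data a full [GaitDataset-class].
#' @param bestSpecs named list mapping network family to its middle
#'   activation.
#' @param config a [trainConfig()].
#' @param grid epoch settings to evaluate; defaults to the full
#'   [epochGrid()] protocol.
#' @return a [SweepResult-class] with `axis = "epochs"`.
#' @export
sweepEpochs <- function(data,
                        bestSpecs = list(uae = "tanh", tae = "linear",
                                         expander = "elu"),
                        config = trainConfig(), grid = epochGrid()) {
    cells <- list()
    for (ty in names(bestSpecs)) for (ep in grid)
        cells[[length(cells) + 1L]] <- list(
            network = ty, setting = ep, nHidden = 3L,
            activation = bestSpecs[[ty]], epochs = ep)
    .runSweep("epochs", grid, cells, data, config)
}

#' Pick the best setting from a sweep
#'
#' Returns, per network family, the setting maximizing the overall mean r.
#' Exact ties break toward the cheaper setting: fewer layers, fewer
#' epochs, or linear before any nonlinearity (the grid is ordered that
#' way, and the first maximum wins).
#'
#' @param sweep a [SweepResult-class].
#' @param network optional single family to select for.
#' @return the chosen setting (named list over families when `network` is
#'   not given and several are present).
#' @export
selectBest <- function(sweep, network = NULL) {
    stopifnot(is(sweep, "SweepResult"), nrow(sweep@overall) > 0L)
    ov <- sweep@overall
    pick <- function(df) {
        df <- df[order(match(df$setting, sweep@grid)), , drop = FALSE]
        df$setting[which.max(df$mean_r)]
    }
    nets <- unique(ov$network)
    if (!is.null(network)) {
        if (!network %in% nets) stop("no results for network ", network)
        return(pick(ov[ov$network == network, , drop = FALSE]))
    }
    if (length(nets) == 1L) return(pick(ov))
    stats::setNames(lapply(nets, function(n)
        pick(ov[ov$network == n, , drop = FALSE])), nets)
}

#' @describeIn SweepResult compact summary
#' @param object a `SweepResult`
#' @export
setMethod("show", "SweepResult", function(object) {
    cat("SweepResult <", object@axis, ">  ",
        length(object@grid), " settings x ",
        length(unique(object@perModel$network)), " network(s)\n", sep = "")
    print(object@overall)
    invisible(NULL)
})

#' Write a sweep result as tidy CSV
#'
#' Columns: `network`, `axis`, `setting`, `model_id`, `mean_r`; the
#' per-network overall rows use `model_id = "overall"`.
#'
#' @param sweep a [SweepResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSweepCSV <- function(sweep, path) {
    stopifnot(is(sweep, "SweepResult"))
    pm <- sweep@perModel
    ov <- sweep@overall
    ov$model_id <- "overall"
    df <- rbind(pm[, c("network", "setting", "model_id", "mean_r")],
                ov[, c("network", "setting", "model_id", "mean_r")])
    df <- cbind(df[, c("network"), drop = FALSE], axis = sweep@axis,
                df[, c("setting", "model_id", "mean_r")])
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
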