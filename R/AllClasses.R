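#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' GaitDataset: a labelled collection of within-stride cost series
#'
#' A `GaitDataset` extends [SummarizedExperiment::SummarizedExperiment].
#' The single assay, `"cost"`, is a 100 x N matrix of within-stride
#' metabolic cost series in watts: rows are gait-cycle phase points
#' (1--100% of the cycle), columns are individual series, one per
#' (walking condition, cost model) pair.  `colData` carries, per series:
#'
#' * `condition_id` -- walking-condition label,
#' * `model_id` -- one of the 10 cost-model channel labels,
#' * `split` -- `"train"` (perturbed conditions) or `"holdout"` (the single
#'   unperturbed condition reserved for validation),
#' * `mean` -- the cached stride mean of the series, W,
#' * `perturb_kind`, `peak_timing`, `magnitude` -- the perturbation applied
#'   to the condition (sinusoidal bump timing in % of cycle; magnitude as a
#'   fraction of body weight).
#'
#' The validity method enforces exactly 100 phase rows, finite values, and
#' that each cached `mean` matches the recomputed column mean.
#'
#' @seealso [generateGaitDataset()], [splitTrainHoldout()], [strideMeans()]
#' @export
setClass("GaitDataset", contains = "SummarizedExperiment")

setValidity("GaitDataset", function(object) {
    msg <- character()
    if (!"cost" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'cost' is required")
    if (nrow(object) != 100L)
        msg <- c(msg, "a gait cycle must have exactly 100 phase samples")
    cd <- colData(object)
    need <- c("condition_id", "model_id", "split", "mean")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
    if (!length(msg)) {
        x <- assay(object, "cost")
        if (!all(is.finite(x)))
            msg <- c(msg, "cost values must be finite")
        else {
            m <- colMeans(x)
            rel <- abs(m - cd$mean) / pmax(abs(m), 1)
            if (any(rel > 1e-9))
                msg <- c(msg, "cached stride means disagree with recomputed column means")
        }
        if (!all(cd$split %in% c("train", "holdout")))
            msg <- c(msg, "split must be 'train' or 'holdout'")
    }
    if (length(msg)) msg else TRUE
})

#' DenseNetwork: a stack of affine stages with activations
#'
#' A fully connected network held as an ordered list of stages.  Each stage
#' is a list with elements `wid` and `bid` (the names of the weight matrix
#' and bias vector inside the shared parameter environment), `transposed`
#' (whether the stage applies the transpose of the stored matrix -- used by
#' tied decoders, which view the encoder's weights), `activation`, and the
#' `nIn`/`nOut` dimensions.  Parameters live in an environment so that a
#' tied decoder built with [tieDecoder()] shares storage with its encoder:
#' mutating an encoder weight changes the decoder's transposed view.
#'
#' @slot role one of `"encoder"`, `"decoder"`, `"expander"`.
#' @slot stages ordered list of affine stages as described above.
#' @slot params environment mapping parameter ids to matrices/vectors.
#' @seealso [buildNetwork()], [tieDecoder()], [forwardPass()]
#' @export
setClass("DenseNetwork", representation(
    role = "character",
    stages = "list",
    params = "environment"
))

setValidity("DenseNetwork", function(object) {
    msg <- character()
    if (!object@role %in% c("encoder", "decoder", "expander"))
        msg <- c(msg, "role must be encoder, decoder or expander")
    st <- object@stages
    if (!length(st)) msg <- c(msg, "network needs at least one stage")
    for (k in seq_along(st)) {
        s <- st[[k]]
        W <- get0(s$wid, envir = object@params)
        b <- get0(s$bid, envir = object@params)
        if (is.null(W) || is.null(b)) {
            msg <- c(msg, sprintf("stage %d parameters missing from environment", k))
            next
        }
        d <- if (isTRUE(s$transposed)) rev(dim(W)) else dim(W)
        if (!identical(as.integer(d), c(s$nOut, s$nIn)))
            msg <- c(msg, sprintf("stage %d weight shape does not match declared dims", k))
        if (length(b) != s$nOut)
            msg <- c(msg, sprintf("stage %d bias length does not match output dim", k))
        if (k > 1L && st[[k - 1L]]$nOut != s$nIn)
            msg <- c(msg, sprintf("stage %d input dim does not chain from stage %d", k, k - 1L))
        if (!s$activation %in% names(.activations))
            msg <- c(msg, sprintf("stage %d has unknown activation '%s'", k, s$activation))
    }
    if (length(msg)) msg else TRUE
})

#' StrideModel: one of the three trainable mean-to-series architectures
#'
#' Bundles the networks making up one modelling approach:
#' * `"uae"` -- untied autoencoder: independent encoder and decoder, trained
#'   jointly with the mean-pinned reconstruction loss;
#' * `"tae"` -- tied autoencoder: the decoder's weights are live transposes
#'   of the encoder's (biases independent);
#' * `"expander"` -- a decoder-shaped network trained alone on
#'   mean-to-series pairs.
#'
#' After training, prediction always goes through the decoder/expander via
#' [expandMean()].
#'
#' @slot type `"uae"`, `"tae"` or `"expander"`.
#' @slot encoder a [DenseNetwork-class] or `NULL` (expander).
#' @slot decoder a [DenseNetwork-class].
#' @slot nHidden number of hidden layers (1--3).
#' @slot middleActivation activation of the designated middle stage.
#' @slot seed integer seed the initial parameters were drawn from.
#' @seealso [strideModel()], [fitModel()], [countParameters()]
#' @export
setClass("StrideModel", representation(
    type = "character",
    encoder = "ANY",
    decoder = "DenseNetwork",
    nHidden = "integer",
    middleActivation = "character",
    seed = "integer"
))

setValidity("StrideModel", function(object) {
    msg <- character()
    if (!object@type %in% c("uae", "tae", "expander"))
        msg <- c(msg, "type must be uae, tae or expander")
    if (object@type == "expander" && !is.null(object@encoder))
        msg <- c(msg, "expander carries no encoder")
    if (object@type != "expander" && !is(object@encoder, "DenseNetwork"))
        msg <- c(msg, "autoencoder types need an encoder")
    if (!object@nHidden %in% 1:3)
        msg <- c(msg, "nHidden must be 1, 2 or 3")
    if (length(msg)) msg else TRUE
})

#' SweepResult: aggregated outcome of one tuning study
#'
#' @slot axis `"layers"`, `"activation"` or `"epochs"`.
#' @slot grid the ordered settings evaluated.
#' @slot perModel data.frame with columns `network`, `setting`, `model_id`,
#'   `mean_r` (mean Pearson r over repeats).
#' @slot overall data.frame with columns `network`, `setting`, `mean_r`
#'   (unweighted mean of the 10 per-model means).
#' @seealso [sweepLayers()], [sweepActivations()], [sweepEpochs()],
#'   [selectBest()]
#' @export
setClass("SweepResult", representation(
    axis = "character",
    grid = "vector",
    perModel = "data.frame",
    overall = "data.frame"
))

#' SurfaceProfile: network outputs over a grid of mean-cost inputs
#'
#' Row k holds the length-100 series produced by feeding `meanGrid[k]` watts
#' into a trained decoder or expander; columns are gait phase 1--100%.
#'
#' @slot meanGrid strictly increasing mean-cost inputs, W.
#' @slot values `length(meanGrid)` x 100 output matrix, W.
#' @slot network free-text tag of the network profiled.
#' @seealso [surfaceProfile()]
#' @export
setClass("SurfaceProfile", representation(
    meanGrid = "numeric",
    values = "matrix",
    network = "character"
))

setValidity("SurfaceProfile", function(object) {
    msg <- character()
    if (is.unsorted(object@meanGrid, strictly = TRUE))
        msg <- c(msg, "meanGrid must be strictly increasing")
    if (nrow(object@values) != length(object@meanGrid))
        msg <- c(msg, "values must have one row per grid point")
    if (ncol(object@values) != 100L)
        msg <- c(msg, "values must have 100 phase columns")
    if (length(msg)) msg else TRUE
})
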