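# Architecture arithmetic and network construction.
#
# Widths follow an arithmetic sequence from 100 neurons (the series length)
# down to 1 (the stride mean): 100-1, 100-50-1 and 100-66-33-1 for 1, 2 and
# 3 hidden layers.  Decoders and expanders use the reversed sequence.
# Encoders additionally carry an input-facing 100-unit stage ahead of the
# tabled sequence.

.hiddenRows <- list(
    `1` = c(100L, 1L),
    `2` = c(100L, 50L, 1L),
    `3` = c(100L, 66L, 33L, 1L)
)

#' Layer widths for a given depth and network role
#'
#' Returns the ordered layer widths of the arithmetic-sequence
#' architectures.  Encoders get the 100-to-1 sequence preceded by the
#' input-facing 100-unit stage; decoders and expanders get the reversed
#' (1-to-100) sequence.
#'
#' @param nHidden number of hidden layers, 1 to 3.
#' @param role `"encoder"`, `"decoder"` or `"expander"`.
#' @return integer vector of layer widths, input side first.
#' @examples
#' layerSizes(2, "decoder")  # 1 50 100
#' layerSizes(3, "encoder")  # 100 100 66 33 1
#' @export
layerSizes <- function(nHidden, role = c("encoder", "decoder", "expander")) {
    role <- match.arg(role)
    if (length(nHidden) != 1L || !nHidden %in% 1:3)
        stop("nHidden must be 1, 2 or 3")
    row <- .hiddenRows[[as.character(nHidden)]]
    if (role == "encoder") c(100L, row) else rev(row)
}

# The stage carrying the swept ("middle") activation: the one producing the
# intermediate width of the arithmetic sequence (50 neurons at depth 2,
# 66 at depth 3).  Depth 1 has no such stage.
.middleWidth <- function(nHidden) switch(as.character(nHidden),
    `1` = NA_integer_, `2` = 50L, `3` = 66L)

#' Architecture specification for one network
#'
#' A light container validated against the arithmetic-sequence width table.
#' `middleActivation` is placed on the stage producing the intermediate
#' width (50 neurons at depth 2, 66 at depth 3); every other stage is
#' linear, and the final stage of a decoder/expander is always linear so
#' the output can scale to any cost model, including negative-valued ones.
#'
#' @param role `"encoder"`, `"decoder"` or `"expander"`.
#' @param nHidden number of hidden layers, 1 to 3.
#' @param middleActivation activation id for the designated middle stage.
#' @param tied flag marking a decoder built by weight tying.
#' @return a list of class `NetSpec` with fields `role`, `nHidden`,
#'   `widths`, `activations` (per stage) and `tied`.
#' @export
netSpec <- function(role = c("encoder", "decoder", "expander"),
                    nHidden = 3L, middleActivation = "linear",
                    tied = FALSE) {
    role <- match.arg(role)
    widths <- layerSizes(nHidden, role)
    if (!middleActivation %in% names(.activations))
        stop("unknown activation: ", middleActivation)
    nStages <- length(widths) - 1L
    acts <- rep("linear", nStages)
    mw <- .middleWidth(nHidden)
    if (!is.na(mw)) {
        hit <- which(widths[-1L] == mw)
        acts[hit] <- middleActivation
    }
    # final decoder/expander stage must stay linear
    if (role != "encoder") acts[nStages] <- "linear"
    structure(list(role = role, nHidden = as.integer(nHidden),
                   widths = widths, activations = acts, tied = tied),
              class = "NetSpec")
}

# Glorot-style fan-balanced uniform init for weights; biases drawn
# uniformly at 1/sqrt(fanIn) scale so no two stages share bias values.
.initStageParams <- function(nIn, nOut) {
    lim <- sqrt(6 / (nIn + nOut))
    W <- matrix(stats::runif(nOut * nIn, -lim, lim), nOut, nIn)
    b <- stats::runif(nOut, -1, 1) / sqrt(nIn)
    list(W = W, b = b)
}

# per-session counter so every parameter environment gets a distinct id,
# letting countParameters() deduplicate shared storage across compositions
.envCounter <- new.env(parent = emptyenv())

.newParamEnv <- function() {
    n <- (get0("n", envir = .envCounter) %||% 0L) + 1L
    assign("n", n, envir = .envCounter)
    e <- new.env(parent = emptyenv())
    assign(".envId", paste0("env", n), envir = e)
    e
}

#' Build a network from a specification
#'
#' Realizes the affine stages with seeded random initial parameters
#' (fan-balanced uniform weights, small uniform biases).  The same seed
#' always reproduces the same initial parameters.
#'
#' @param spec a [netSpec()] object.
#' @param seed integer seed for the initial parameters.
#' @return a [DenseNetwork-class].
#' @export
buildNetwork <- function(spec, seed = 1L) {
    stopifnot(inherits(spec, "NetSpec"))
    widths <- spec$widths
    env <- .newParamEnv()
    stages <- vector("list", length(widths) - 1L)
    withSeed(seed, {
        for (k in seq_along(stages)) {
            nIn <- widths[k]; nOut <- widths[k + 1L]
            p <- .initStageParams(nIn, nOut)
            wid <- paste0("W", k); bid <- paste0("b", k)
            assign(wid, p$W, envir = env)
            assign(bid, p$b, envir = env)
            stages[[k]] <- list(wid = wid, bid = bid, transposed = FALSE,
                                activation = spec$activations[k],
                                nIn = as.integer(nIn), nOut = as.integer(nOut))
        }
    })
    new("DenseNetwork", role = spec$role, stages = stages, params = env)
}

#' Tie a decoder to an encoder
#'
#' Builds the tied decoder of a tied-weight autoencoder: the encoder's
#' stages are mirrored in reverse order -- including the input-facing
#' 100-unit stage -- and each mirrored stage applies the live transpose of
#' its source weight matrix.  Weight storage is shared (mutating the
#' encoder weight changes the decoder's view and vice versa); biases are
#' independent fresh parameters.  For a 3-hidden-layer encoder this yields
#' the 1-33-66-100-100 decoder stack whose independent parameters, together
#' with the encoder's, number 19310.
#'
#' The mirrored stage producing width w inherits the encoder's activation
#' at width w, except the final output stage which is always linear.
#'
#' @param encoder a [DenseNetwork-class] with role `"encoder"`.
#' @param seed integer seed for the decoder's fresh bias parameters.
#' @return a [DenseNetwork-class] decoder sharing weight storage with
#'   `encoder`.
#' @export
tieDecoder <- function(encoder, seed = 1L) {
    stopifnot(is(encoder, "DenseNetwork"))
    if (encoder@role != "encoder")
        stop("tieDecoder needs an encoder network")
    validObject(encoder)
    enc <- encoder@stages
    L <- length(enc)
    # activation by produced width on the encoder side
    actByWidth <- stats::setNames(
        vapply(enc, `[[`, "", "activation"),
        vapply(enc, `[[`, 0L, "nOut"))
    stages <- vector("list", L)
    withSeed(seed, {
        for (k in seq_len(L)) {
            src <- enc[[L + 1L - k]]
            nIn <- src$nOut; nOut <- src$nIn
            bid <- paste0("tb", k)
            assign(bid, stats::runif(nOut, -1, 1) / sqrt(nIn),
                   envir = encoder@params)
            act <- if (k == L) "linear"
                   else actByWidth[[as.character(nOut)]] %||% "linear"
            stages[[k]] <- list(wid = src$wid, bid = bid, transposed = TRUE,
                                activation = act,
                                nIn = as.integer(nIn), nOut = as.integer(nOut))
        }
    })
    new("DenseNetwork", role = "decoder", stages = stages,
        params = encoder@params)
}

.stageWeight <- function(stage, env) {
    W <- get(stage$wid, envir = env)
    if (isTRUE(stage$transposed)) t(W) else W
}

#' Run a network forward
#'
#' Applies the affine stages and activations in order.  `input` may be a
#' vector (one sample) or a matrix with samples in columns.
#'
#' @param net a [DenseNetwork-class].
#' @param input numeric vector of length `nIn`, or an `nIn` x N matrix.
#' @return numeric vector (vector input) or `nOut` x N matrix.
#' @aliases forwardPass
#' @export
setMethod("forwardPass", "DenseNetwork", function(net, input) {
    vecIn <- is.null(dim(input))
    A <- if (vecIn) matrix(as.numeric(input), ncol = 1L) else input
    if (nrow(A) != net@stages[[1L]]$nIn)
        stop("input dimension ", nrow(A), " does not match network input ",
             net@stages[[1L]]$nIn)
    for (s in net@stages) {
        Z <- .stageWeight(s, net@params) %*% A + get(s$bid, envir = net@params)
        A <- activation(s$activation, Z)
    }
    if (vecIn && ncol(A) == 1L) as.numeric(A) else A
})

# forward pass retaining pre-activations and activations for backprop;
# stages may come from more than one network (encoder chained to decoder)
.forwardCache <- function(stages, env, A0) {
    L <- length(stages)
    Zs <- vector("list", L); As <- vector("list", L + 1L)
    As[[1L]] <- A0
    for (k in seq_len(L)) {
        s <- stages[[k]]
        Zs[[k]] <- .stageWeight(s, env) %*% As[[k]] + get(s$bid, envir = env)
        As[[k + 1L]] <- activation(s$activation, Zs[[k]])
    }
    list(Z = Zs, A = As)
}

#' Count the independent trainable parameters
#'
#' Counts every independent weight and bias exactly once across a network
#' or a composition of networks.  Tied (transpose-shared) weights are
#' counted once even when they appear in both an encoder and its tied
#' decoder.  For the 3-hidden-layer family the counts are 9010 (expander),
#' 28021 (untied autoencoder) and 19310 (tied autoencoder).
#'
#' @param object a [DenseNetwork-class], a [StrideModel-class], or a list
#'   of `DenseNetwork`s.
#' @return integer number of independent scalars.
#' @aliases countParameters
#' @export
setMethod("countParameters", "DenseNetwork", function(object) {
    .countParamList(list(object))
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "list", function(object) {
    stopifnot(all(vapply(object, is, TRUE, "DenseNetwork")))
    .countParamList(object)
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "StrideModel", function(object) {
    nets <- if (is.null(object@encoder)) list(object@decoder)
            else list(object@encoder, object@decoder)
    .countParamList(nets)
})

.countParamList <- function(nets) {
    seen <- character()
    total <- 0L
    for (net in nets) {
        envId <- get(".envId", envir = net@params)
        for (s in net@stages) {
            for (id in c(s$wid, s$bid)) {
                key <- paste0(envId, "/", id)
                if (key %in% seen) next
                seen <- c(seen, key)
                total <- total + length(get(id, envir = net@params))
            }
        }
    }
    as.integer(total)
}

#' @describeIn DenseNetwork compact stage summary
#' @param object a `DenseNetwork`
#' @export
setMethod("show", "DenseNetwork", function(object) {
    cat("DenseNetwork <", object@role, "> ", length(object@stages),
        " stage(s), ", countParameters(object),
        " independent parameters\n", sep = "")
    for (k in seq_along(object@stages)) {
        s <- object@stages[[k]]
        cat(sprintf("  [%d] %d -> %d  %s%s\n", k, s$nIn, s$nOut,
                    s$activation, if (isTRUE(s$transposed)) "  (tied, W^T)" else ""))
    }
    invisible(NULL)
})

# ---- serialization ---------------------------------------------------------

#' Serialize / restore a network as a JSON-ready list
#'
#' Captures stage shapes, activation ids, tie structure and flattened
#' parameter values; `deserializeNetwork` rebuilds an identical network.
#' Tied decoders must be serialized together with their encoder through
#' [saveModel()]/[loadModel()] so the shared storage is reconstructed.
#'
#' @param net a [DenseNetwork-class].
#' @return a plain list safe for [jsonlite::toJSON()].
#' @export
serializeNetwork <- function(net) {
    stopifnot(is(net, "DenseNetwork"))
    ids <- unique(unlist(lapply(net@stages, function(s) c(s$wid, s$bid))))
    params <- lapply(ids, function(id) {
        v <- get(id, envir = net@params)
        list(dim = dim(v) %||% length(v), values = as.numeric(v))
    })
    names(params) <- ids
    list(role = net@role,
         stages = lapply(net@stages, function(s)
             s[c("wid", "bid", "transposed", "activation", "nIn", "nOut")]),
         params = params)
}

#' @rdname serializeNetwork
#' @param obj a list as produced by `serializeNetwork`.
#' @param env optionally, an existing parameter environment to populate
#'   (used to re-link tied networks).
#' @export
deserializeNetwork <- function(obj, env = NULL) {
    if (is.null(env)) env <- .newParamEnv()
    for (id in names(obj$params)) {
        p <- obj$params[[id]]
        d <- unlist(p$dim)
        v <- as.numeric(unlist(p$values))
        assign(id, if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v,
               envir = env)
    }
    stages <- lapply(obj$stages, function(s)
        list(wid = s$wid, bid = s$bid, transposed = isTRUE(s$transposed),
             activation = s$activation,
             nIn = as.integer(s$nIn), nOut = as.integer(s$nOut)))
    new("DenseNetwork", role = obj$role, stages = stages, params = env)
}
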