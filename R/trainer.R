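# Training: mean-pinned autoencoder loss, expander loss, full-batch Adam
# with hand-rolled backpropagation (gradients of tied stages accumulate
# into the single shared weight matrix), and the repeat protocol that
# rebuilds fresh networks for every repetition.

#' Training configuration
#'
#' Full-batch Adam settings plus the repeat protocol.  Adam moment
#' parameters default to the optimizer's canonical values (learning rate
#' 1e-3, beta1 0.9, beta2 0.999, epsilon 1e-8); no minibatching is used,
#' so one epoch is exactly one gradient step over all training series.
#'
#' @param epochs number of full-batch Adam steps (>= 0).
#' @param learningRate Adam step size.
#' @param beta1,beta2 Adam moment decay rates, in (0, 1).
#' @param epsilon Adam denominator stabilizer.
#' @param nRepeats number of independent trainings in [runRepeats()].
#' @param seed base seed; repeat k uses `seed + k - 1`.
#' @return a list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 2000L, learningRate = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                        nRepeats = 50L, seed = 1L) {
    stopifnot(epochs >= 0, nRepeats >= 1,
              beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
    structure(list(epochs = as.integer(epochs), learningRate = learningRate,
                   beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                   batchMode = "full_batch",
                   nRepeats = as.integer(nRepeats), seed = as.integer(seed)),
              class = "TrainConfig")
}

#' Construct one of the three trainable architectures
#'
#' * `"uae"` -- untied autoencoder: independent encoder (100-unit input
#'   stage plus the 100-to-1 arithmetic sequence) and decoder (reversed
#'   sequence), trained jointly with [lossAutoencoder()].
#' * `"tae"` -- tied autoencoder: decoder weights are live transposes of
#'   the encoder weights ([tieDecoder()]); biases independent.
#' * `"expander"` -- decoder-shaped network trained alone with
#'   [lossExpander()] on (stride mean, series) pairs.
#'
#' @param type architecture family.
#' @param nHidden hidden layers, 1 to 3.
#' @param middleActivation activation of the middle (50- or 66-unit) stage,
#'   applied on both the encoder and decoder side where present; all other
#'   stages are linear and the output stage is always linear.
#' @param seed integer seed for the initial parameters.
#' @return a [StrideModel-class].
#' @examples
#' countParameters(strideModel("expander", 3, seed = 1))  # 9010
#' @export
strideModel <- function(type = c("uae", "tae", "expander"), nHidden = 3L,
                        middleActivation = "linear", seed = 1L) {
    type <- match.arg(type)
    seed <- as.integer(seed)
    decSeed <- .deriveSeed(seed, 104729L)
    if (type == "expander") {
        enc <- NULL
        dec <- buildNetwork(netSpec("expander", nHidden, middleActivation), seed)
    } else {
        enc <- buildNetwork(netSpec("encoder", nHidden, middleActivation), seed)
        dec <- if (type == "tae") tieDecoder(enc, decSeed)
               else buildNetwork(netSpec("decoder", nHidden, middleActivation),
                                 decSeed)
    }
    new("StrideModel", type = type, encoder = enc, decoder = dec,
        nHidden = as.integer(nHidden),
        middleActivation = middleActivation, seed = seed)
}

#' @describeIn StrideModel compact summary
#' @param object a `StrideModel`
#' @export
setMethod("show", "StrideModel", function(object) {
    cat("StrideModel <", toupper(object@type), ">  ", object@nHidden,
        " hidden layer(s), middle activation '", object@middleActivation,
        "', ", countParameters(object), " trainable parameters\n", sep = "")
    invisible(NULL)
})

# ---- losses ----------------------------------------------------------------

.asSeriesMatrix <- function(X) {
    if (is(X, "GaitDataset")) return(assay(X, "cost"))
    X <- as.matrix(X)
    if (nrow(X) != 100L)
        stop("series matrix must have 100 phase rows")
    X
}

#' Mean-pinned autoencoder loss
#'
#' For N training series, the loss is
#' \deqn{\sum_{j=1}^{N} \left[ (\bar X_j - Z_j)^2 +
#'   \frac{1}{100}\sum_{i=1}^{100} (X_{ji} - \tilde X_{ji})^2 \right],}
#' i.e. a squared pin of the scalar latent to the stride mean plus the
#' per-series phase-mean squared reconstruction error, summed (not
#' averaged) over series.
#'
#' @param X 100 x N matrix of original series (or a [GaitDataset-class]).
#' @param means length-N stride means.
#' @param Z length-N latent scalars.
#' @param Xtilde 100 x N matrix of reconstructions.
#' @return scalar loss.
#' @export
lossAutoencoder <- function(X, means, Z, Xtilde) {
    X <- .asSeriesMatrix(X); Xtilde <- .asSeriesMatrix(Xtilde)
    Z <- as.numeric(Z); means <- as.numeric(means)
    if (!identical(dim(X), dim(Xtilde)) || length(Z) != ncol(X) ||
        length(means) != ncol(X))
        stop("inconsistent shapes in autoencoder loss")
    sum((means - Z)^2) + sum((X - Xtilde)^2) / 100
}

#' Expander loss
#'
#' The reconstruction part of the autoencoder loss alone:
#' \deqn{\frac{1}{100} \sum_{j=1}^{N} \sum_{i=1}^{100}
#'   (X_{ji} - \tilde X_{ji})^2,} summed over series, averaged over the
#' 100 phase points.
#'
#' @param X 100 x N matrix of original series (or a [GaitDataset-class]).
#' @param Xtilde 100 x N matrix of reconstructions.
#' @return scalar loss.
#' @export
lossExpander <- function(X, Xtilde) {
    X <- .asSeriesMatrix(X); Xtilde <- .asSeriesMatrix(Xtilde)
    if (!identical(dim(X), dim(Xtilde)))
        stop("inconsistent shapes in expander loss")
    sum((X - Xtilde)^2) / 100
}

# ---- backprop + Adam -------------------------------------------------------

# A training chain is a list of stages, each annotated with the parameter
# environment it lives in, so encoder and decoder of an untied autoencoder
# (separate environments) train in one pass while tied stages (same
# environment, same wid) accumulate their gradient into shared storage.
.buildChain <- function(model) {
    annotate <- function(net) lapply(net@stages, function(s) {
        s$env <- net@params
        s$key_w <- paste0(get(".envId", envir = net@params), "/", s$wid)
        s$key_b <- paste0(get(".envId", envir = net@params), "/", s$bid)
        s
    })
    if (model@type == "expander") {
        list(stages = annotate(model@decoder), latentIndex = NA_integer_)
    } else {
        encSt <- annotate(model@encoder)
        list(stages = c(encSt, annotate(model@decoder)),
             latentIndex = length(encSt))
    }
}

.chainForwardCache <- function(stages, A0) {
    L <- length(stages)
    Zs <- vector("list", L); As <- vector("list", L + 1L)
    As[[1L]] <- A0
    for (k in seq_len(L)) {
        s <- stages[[k]]
        Zs[[k]] <- .stageWeight(s, s$env) %*% As[[k]] + get(s$bid, envir = s$env)
        As[[k + 1L]] <- if (s$activation == "linear") Zs[[k]]
                        else activation(s$activation, Zs[[k]])
    }
    list(Z = Zs, A = As)
}

#' Fit a model with full-batch Adam
#'
#' Runs `config$epochs` full-batch gradient steps minimizing
#' [lossAutoencoder()] (UAE/TAE; gradients flow through tied weight views
#' and are accumulated once per shared matrix) or [lossExpander()]
#' (expander).  Parameters are updated in place in the model's parameter
#' environment(s).  Training is deterministic given the model's initial
#' parameters, the data and the configuration.
#'
#' @param model a [StrideModel-class].
#' @param data a [GaitDataset-class] (typically the training split) or a
#'   list with elements `X` (100 x N matrix) and `means` (length N).
#' @param config a [trainConfig()].
#' @return invisibly, a list with elements `model` and `lossHistory`
#'   (per-epoch loss, length `config$epochs`).
#' @export
fitModel <- function(model, data, config = trainConfig()) {
    stopifnot(is(model, "StrideModel"), inherits(config, "TrainConfig"))
    if (is(data, "GaitDataset")) {
        X <- assay(data, "cost"); means <- as.numeric(colData(data)$mean)
    } else {
        X <- .asSeriesMatrix(data$X); means <- as.numeric(data$means)
    }
    N <- ncol(X)
    if (N < 1L) stop("training data is empty")
    chain <- .buildChain(model)
    stages <- chain$stages
    latent <- chain$latentIndex
    A0 <- if (model@type == "expander") matrix(means, 1L, N) else X
    meansRow <- matrix(means, 1L, N)

    # unique parameters of the chain (shared keys once)
    keys <- list()
    for (s in stages) {
        if (is.null(keys[[s$key_w]])) keys[[s$key_w]] <- list(env = s$env, id = s$wid)
        if (is.null(keys[[s$key_b]])) keys[[s$key_b]] <- list(env = s$env, id = s$bid)
    }
    mState <- lapply(keys, function(k) get(k$id, envir = k$env) * 0)
    vState <- mState
    history <- numeric(config$epochs)
    b1 <- config$beta1; b2 <- config$beta2
    lr <- config$learningRate; eps <- config$epsilon

    for (epoch in seq_len(config$epochs)) {
        fc <- .chainForwardCache(stages, A0)
        L <- length(stages)
        Xt <- fc$A[[L + 1L]]
        recon <- sum((X - Xt)^2) / 100
        loss <- if (is.na(latent)) recon else {
            Zlat <- fc$A[[latent + 1L]]
            sum((meansRow - Zlat)^2) + recon
        }
        if (!is.finite(loss))
            stop("non-finite loss at epoch ", epoch,
                 "; training diverged (try a smaller learning rate)")
        history[epoch] <- loss

        grads <- lapply(mState, function(g) NULL)
        G <- (2 / 100) * (Xt - X)            # dL/dA_L
        for (k in rev(seq_len(L))) {
            s <- stages[[k]]
            delta <- if (s$activation == "linear") G
                     else G * activationGrad(s$activation, fc$Z[[k]])
            gW <- delta %*% t(fc$A[[k]])
            if (isTRUE(s$transposed)) gW <- t(gW)
            gb <- rowSums(delta)
            grads[[s$key_w]] <- if (is.null(grads[[s$key_w]])) gW
                                else grads[[s$key_w]] + gW
            grads[[s$key_b]] <- if (is.null(grads[[s$key_b]])) gb
                                else grads[[s$key_b]] + gb
            W <- get(s$wid, envir = s$env)
            G <- if (isTRUE(s$transposed)) W %*% delta else crossprod(W, delta)
            if (!is.na(latent) && k == latent + 1L)
                G <- G + 2 * (fc$A[[latent + 1L]] - meansRow)
        }

        corr1 <- 1 - b1^epoch
        corr2 <- 1 - b2^epoch
        for (key in names(keys)) {
            g <- grads[[key]]
            if (is.null(g)) next
            mState[[key]] <- b1 * mState[[key]] + (1 - b1) * g
            vState[[key]] <- b2 * vState[[key]] + (1 - b2) * g^2
            k <- keys[[key]]
            val <- get(k$id, envir = k$env) -
                lr * (mState[[key]] / corr1) /
                (sqrt(vState[[key]] / corr2) + eps)
            assign(k$id, val, envir = k$env)
        }
    }
    invisible(list(model = model, lossHistory = history))
}

# ---- repeat protocol -------------------------------------------------------

#' Repeat the training protocol with fresh networks
#'
#' For each repetition a brand-new model is created with a fresh derived
#' seed (`config$seed + repeat - 1`), fitted on the training split, scored
#' per cost model on the holdout split with Pearson r, and released.
#' Failures in individual repeats are recorded in the corresponding record
#' rather than aborting the batch.
#'
#' @param type architecture family (`"uae"`, `"tae"`, `"expander"`).
#' @param data a full [GaitDataset-class]; the train/holdout split is taken
#'   from its `split` column.
#' @param config a [trainConfig()]; `nRepeats` controls the number of
#'   repetitions.
#' @param nHidden,middleActivation architecture settings passed to
#'   [strideModel()].
#' @param keepModels keep the trained model objects in the records
#'   (default drops them, mirroring the train-score-delete protocol).
#' @return a list of `TrialRecord` lists with fields `repeat_index`,
#'   `seed`, `r` (named per-model holdout correlations), `lossHistory`,
#'   `finalLoss` and `error`.
#' @export
runRepeats <- function(type, data, config = trainConfig(),
                       nHidden = 3L, middleActivation = "linear",
                       keepModels = FALSE) {
    stopifnot(is(data, "GaitDataset"), config$nRepeats >= 1L)
    parts <- splitTrainHoldout(data)
    records <- vector("list", config$nRepeats)
    for (k in seq_len(config$nRepeats)) {
        seedK <- .deriveSeed(config$seed, k - 1L)
        rec <- list(repeat_index = k, seed = seedK, r = NULL,
                    lossHistory = NULL, finalLoss = NA_real_, error = NULL)
        res <- tryCatch({
            model <- strideModel(type, nHidden, middleActivation, seed = seedK)
            fit <- fitModel(model, parts$train, config)
            rtab <- evaluateHoldout(model@decoder, parts$holdout)
            list(model = model, fit = fit, rtab = rtab)
        }, error = function(e) e)
        if (inherits(res, "error")) {
            rec$error <- conditionMessage(res)
        } else {
            rec$r <- stats::setNames(res$rtab$r, res$rtab$model_id)
            rec$lossHistory <- res$fit$lossHistory
            rec$finalLoss <- if (length(res$fit$lossHistory))
                utils::tail(res$fit$lossHistory, 1L) else NA_real_
            if (keepModels) rec$model <- res$model
        }
        records[[k]] <- structure(rec, class = "TrialRecord")
    }
    records
}

#' Tidy table of repeat results
#'
#' @param records list of `TrialRecord`s from [runRepeats()].
#' @return data.frame with columns `repeat_index`, `model_id`, `r`,
#'   `final_loss`.
#' @export
trialTable <- function(records) {
    do.call(rbind, lapply(records, function(rec) {
        if (!is.null(rec$error) || is.null(rec$r)) return(NULL)
        data.frame(repeat_index = rec$repeat_index,
                   model_id = names(rec$r),
                   r = as.numeric(rec$r),
                   final_loss = rec$finalLoss,
                   row.names = NULL)
    }))
}

# ---- OLS oracle ------------------------------------------------------------

#' Closed-form least-squares oracle for all-linear expanders
#'
#' Any all-linear expander computes an affine map from the stride mean to
#' the 100 phase values.  The global minimum of the expander loss over all
#' such maps is attained by 100 independent ordinary least-squares
#' regressions of each phase sample on the stride mean.  This provides an
#' independent optimum against which trained all-linear expanders are
#' checked.
#'
#' @param data a [GaitDataset-class] (typically the training split) or a
#'   list with `X` and `means`; at least two distinct means required.
#' @return list with `slope` (length 100), `intercept` (length 100) and
#'   `loss` (the minimal [lossExpander()] value).
#' @export
olsExpanderOracle <- function(data) {
    if (is(data, "GaitDataset")) {
        X <- assay(data, "cost"); m <- as.numeric(colData(data)$mean)
    } else {
        X <- .asSeriesMatrix(data$X); m <- as.numeric(data$means)
    }
    if (stats::var(m) == 0)
        stop("all training means identical; regression is degenerate")
    mc <- m - mean(m)
    a <- as.numeric((X %*% mc) / sum(mc^2))
    c0 <- rowMeans(X) - a * mean(m)
    pred <- outer(a, m) + c0
    list(slope = a, intercept = c0, loss = sum((X - pred)^2) / 100)
}
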