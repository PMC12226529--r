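# Shared fixtures: small seeded datasets and a hand-built toy GaitDataset.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

# small but structurally complete dataset: 6 sinusoidal + 1 constant
# perturbed conditions + 1 unperturbed, all 10 models
smallDataset <- function(seed = 1L, ...) {
    generateGaitDataset(6L, 1L, seed = seed, ...)
}

# build a GaitDataset directly from a value matrix and labels
toyDataset <- function(values, condition_id, model_id, split) {
    info <- DataFrame(condition_id = condition_id, model_id = model_id,
                      split = split, mean = colMeans(values),
                      row.names = paste(condition_id, model_id, sep = "."))
    colnames(values) <- rownames(info)
    rownames(values) <- sprintf("p%03d", 1:100)
    new("GaitDataset", SummarizedExperiment(
        assays = list(cost = values), colData = info,
        rowData = DataFrame(phase = 1:100)))
}

# explicit affine composition of an all-linear network: the independent
# oracle for deep-linear equivalence (slope matrix A, offset c)
composeAffine <- function(net) {
    A <- diag(net@stages[[1L]]$nIn)
    c0 <- numeric(net@stages[[1L]]$nIn) * 0
    for (s in net@stages) {
        W <- get(s$wid, envir = net@params)
        if (isTRUE(s$transposed)) W <- t(W)
        b <- get(s$bid, envir = net@params)
        c0 <- as.numeric(W %*% c0 + b)
        A <- W %*% A
    }
    list(A = A, c = c0)
}
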