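# Validation: Pearson correlation between true and estimated series, the
# two-sided significance threshold for r, holdout scoring, and the
# mean-to-series surface map of a trained decoder/expander.

#' Pearson correlation between two series
#'
#' Standard product-moment correlation, computed on the raw series without
#' detrending or normalization.  Constant inputs make r undefined and are
#' rejected with a diagnostic.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return correlation in \[-1, 1\].
#' @examples
#' pearsonR(1:10, 1:10)         # 1
#' pearsonR(1:10, 7 - (1:10))   # -1
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("series lengths differ")
    if (length(x) < 3L) stop("need at least 3 samples")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("Pearson r is undefined for a constant series")
    stats::cor(x, y)
}

#' Two-sided critical value of the Pearson correlation
#'
#' The smallest |r| significant at level `alpha` for `n` paired samples:
#' \deqn{r^* = t^* / \sqrt{t^{*2} + n - 2}} with \eqn{t^*} the
#' \eqn{1 - \alpha/2} quantile of the t distribution on \eqn{n - 2}
#' degrees of freedom.  For the 100-point gait cycle at alpha = 0.05 this
#' gives 0.1966: any reconstruction correlating above that threshold is a
#' significant fit.
#'
#' @param n number of paired samples (>= 3).
#' @param alpha two-sided significance level in (0, 1).
#' @return the critical correlation.
#' @examples
#' round(criticalR(100, 0.05), 4)  # 0.1966
#' @export
criticalR <- function(n, alpha = 0.05) {
    if (n < 3L) stop("need n >= 3")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    tq <- stats::qt(1 - alpha / 2, df = n - 2)
    tq / sqrt(tq^2 + n - 2)
}

#' Expand a stride mean into a within-stride series
#'
#' Feeds a single scalar mean into a trained decoder or expander and
#' returns the length-100 estimated series.  No clipping is applied.
#'
#' @param net a [DenseNetwork-class] with scalar input (decoder/expander).
#' @param mean stride-average cost, W (one scalar).
#' @return numeric length-100 estimated series, W.
#' @aliases expandMean
#' @export
setMethod("expandMean", "DenseNetwork", function(net, mean) {
    if (net@stages[[1L]]$nIn != 1L)
        stop("expandMean needs a network with scalar input")
    if (length(mean) != 1L || !is.finite(mean))
        stop("mean must be a single finite scalar")
    forwardPass(net, as.numeric(mean))
})

#' @rdname expandMean
#' @export
setMethod("expandMean", "StrideModel", function(net, mean) {
    expandMean(net@decoder, mean)
})

#' Score a network on the holdout condition
#'
#' For each cost model in the holdout split, expands that model's stride
#' mean through the network and correlates the estimate with the true
#' series.  A constant (degenerate) network output yields `NA` with a
#' warning for that model rather than an error.
#'
#' @param net a [DenseNetwork-class] or [StrideModel-class].
#' @param holdout a [GaitDataset-class] holding one series per cost model.
#' @return data.frame with columns `model_id`, `mean`, `r`.
#' @aliases evaluateHoldout
#' @export
setMethod("evaluateHoldout", "DenseNetwork", function(net, holdout) {
    stopifnot(is(holdout, "GaitDataset"))
    cd <- colData(holdout)
    if (anyDuplicated(cd$model_id))
        stop("holdout must contain one series per cost model")
    X <- assay(holdout, "cost")
    r <- vapply(seq_len(ncol(X)), function(j) {
        est <- expandMean(net, cd$mean[j])
        if (stats::sd(est) == 0) {
            warning("constant network output for model ", cd$model_id[j],
                    "; r undefined", call. = FALSE)
            return(NA_real_)
        }
        pearsonR(X[, j], est)
    }, numeric(1L))
    data.frame(model_id = as.character(cd$model_id),
               mean = as.numeric(cd$mean), r = r, row.names = NULL)
})

#' @rdname evaluateHoldout
#' @export
setMethod("evaluateHoldout", "StrideModel", function(net, holdout) {
    evaluateHoldout(net@decoder, holdout)
})

#' Surface profile of the learned mean-to-series map
#'
#' Evaluates the network over an arithmetic grid of mean-cost inputs
#' (default 0 to 300 W in 1 W steps) and stacks the outputs into a
#' grid x 100 matrix, the numeric equivalent of the surface plots used to
#' inspect what shape the network assigns to each mean level.
#'
#' @param net a [DenseNetwork-class] or [StrideModel-class] with scalar
#'   input.
#' @param meanMin,meanMax,step grid limits and spacing, W
#'   (`meanMin < meanMax`, `step > 0`).
#' @param tag label stored with the profile.
#' @return a [SurfaceProfile-class].
#' @aliases surfaceProfile
#' @export
setMethod("surfaceProfile", "DenseNetwork",
    function(net, meanMin = 0, meanMax = 300, step = 1, tag = "network") {
        if (!(meanMin < meanMax) || step <= 0)
            stop("need meanMin < meanMax and a positive step")
        grid <- seq(meanMin, meanMax, by = step)
        out <- forwardPass(net, matrix(grid, nrow = 1L))
        new("SurfaceProfile", meanGrid = grid, values = t(out), network = tag)
    })

#' @rdname surfaceProfile
#' @export
setMethod("surfaceProfile", "StrideModel",
    function(net, meanMin = 0, meanMax = 300, step = 1, tag = "network") {
        if (identical(tag, "network")) tag <- toupper(net@type)
        surfaceProfile(net@decoder, meanMin, meanMax, step, tag)
    })

#' @describeIn SurfaceProfile compact summary
#' @param object a `SurfaceProfile`
#' @export
setMethod("show", "SurfaceProfile", function(object) {
    cat("SurfaceProfile <", object@network, ">  ",
        length(object@meanGrid), " mean levels x 100 phases, means ",
        min(object@meanGrid), "-", max(object@meanGrid), " W\n", sep = "")
    invisible(NULL)
})

#' Write a surface profile as CSV
#'
#' First column is the mean-cost input, remaining columns the 100 gait
#' phase percentages.
#'
#' @param profile a [SurfaceProfile-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSurfaceCSV <- function(profile, path) {
    stopifnot(is(profile, "SurfaceProfile"))
    df <- data.frame(mean_W = profile@meanGrid, profile@values)
    colnames(df) <- c("mean_W", sprintf("phase_%03d", 1:100))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
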