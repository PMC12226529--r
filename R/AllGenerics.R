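#' @rdname forwardPass
#' @export
setGeneric("forwardPass", function(net, input) standardGeneric("forwardPass"))

#' @rdname countParameters
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname expandMean
#' @export
setGeneric("expandMean", function(net, mean) standardGeneric("expandMean"))

#' @rdname evaluateHoldout
#' @export
setGeneric("evaluateHoldout", function(net, holdout) standardGeneric("evaluateHoldout"))

#' @rdname surfaceProfile
#' @export
setGeneric("surfaceProfile",
    function(net, meanMin = 0, meanMax = 300, step = 1, tag = "network")
        standardGeneric("surfaceProfile"))

#' @rdname splitTrainHoldout
#' @export
setGeneric("splitTrainHoldout", function(dataset) standardGeneric("splitTrainHoldout"))

#' @rdname strideMeans
#' @export
setGeneric("strideMeans", function(object) standardGeneric("strideMeans"))
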