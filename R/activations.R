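# Elementwise activations and their derivatives.  All operate on vectors or
# matrices.  elu uses alpha = 1; silu(x) = x * sigmoid(x);
# mish(x) = x * tanh(softplus(x)).  softplus is computed in its
# overflow-stable form pmax(x, 0) + log1p(exp(-|x|)).

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

.activations <- list(
    linear  = function(x) x,
    relu    = function(x) pmax(x, 0),
    elu     = function(x) { i <- x < 0; x[i] <- expm1(x[i]); x },
    sigmoid = function(x) stats::plogis(x),
    silu    = function(x) x * stats::plogis(x),
    mish    = function(x) x * tanh(.softplus(x)),
    tanh    = function(x) tanh(x)
)

.activationGrads <- list(
    linear  = function(x) array(1, dim = dim(x) %||% length(x)),
    relu    = function(x) (x > 0) * 1,
    elu     = function(x) { i <- x < 0; x[!i] <- 1; x[i] <- exp(x[i]); x },
    sigmoid = function(x) { s <- stats::plogis(x); s * (1 - s) },
    silu    = function(x) { s <- stats::plogis(x); s + x * s * (1 - s) },
    mish    = function(x) {
        t <- tanh(.softplus(x))
        t + x * (1 - t^2) * stats::plogis(x)
    },
    tanh    = function(x) 1 - tanh(x)^2
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Activation functions used by the networks
#'
#' Evaluates one of the seven supported activations elementwise: `linear`
#' (identity) plus the six nonlinearities `relu`, `elu` (alpha = 1),
#' `sigmoid`, `silu`, `mish` and `tanh`.
#'
#' @param name activation identifier.
#' @param x numeric vector or matrix.
#' @return `x` transformed elementwise.
#' @examples
#' activation("silu", 1)   # ~0.73106
#' activation("mish", 0)   # 0
#' @export
activation <- function(name, x) {
    if (!is.character(name) || length(name) != 1L || !name %in% names(.activations))
        stop("unknown activation: ", paste(name, collapse = ", "))
    .activations[[name]](x)
}

activationGrad <- function(name, x) {
    if (!name %in% names(.activationGrads))
        stop("unknown activation: ", name)
    .activationGrads[[name]](x)
}

#' The supported activation identifiers
#'
#' @return character vector: `linear` followed by the six nonlinear names.
#' @export
activationNames <- function() names(.activations)
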