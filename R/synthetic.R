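# Synthetic stand-in for a simulated perturbed-walking experiment.
#
# Real training data of this shape comes from neuromuscular walking
# simulations run under robotic waist-tether perturbations, with ten
# literature cost models turned into within-stride cost channels.  That
# pipeline is far outside desk scale, and the networks only ever see
# (series, stride-mean) pairs, so this module emulates the *structure* of
# such an experiment: per-model smooth base profiles (sums of Gaussian
# bumps over gait phase), a localized perturbation response whose height
# scales with perturbation magnitude and whose sign varies with peak
# timing, and smooth correlated noise from a low-order random Fourier
# series.  One channel (Margaria-like) dips below zero, one (EMG-Sum-like)
# carries ~5x the default noise amplitude.

.phase <- 1:100

.gaussBump <- function(center, height, sd) {
    height * exp(-0.5 * ((.phase - center) / sd)^2)
}

#' Default registry of the ten synthetic cost-model channels
#'
#' Each entry defines one cost-model channel: a target unperturbed stride
#' mean (W), 2--4 Gaussian bumps over gait phase (stance / push-off / swing
#' humps), a perturbation-response gain, a noise amplitude (W), and flags.
#' The `Margaria` channel is sign-unrestricted (its mid-cycle dip goes
#' below 0 W); the `EMGSum` channel carries five times the default noise
#' amplitude.  Target means span 45--255 W so the pooled mean-to-series
#' map is learnable and training means cover at least 50--250 W.
#'
#' @return a named list of 10 model profiles.
#' @export
defaultModelRegistry <- function() {
    mk <- function(model_id, targetMean, bumps, perturbGain,
                   noiseSd = 1.5, signUnrestricted = FALSE,
                   highNoise = FALSE) {
        list(model_id = model_id, targetMean = targetMean,
             bumps = bumps, perturbGain = perturbGain, noiseSd = noiseSd,
             signUnrestricted = signUnrestricted, highNoise = highNoise)
    }
    b <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE,
                              dimnames = list(NULL, c("center", "height", "sd")))
    reg <- list(
        mk("Margaria",       45, b(15,  40, 6,   50, -70, 5,   75, 30, 7),
           perturbGain = 1.0, signUnrestricted = TRUE),
        mk("Houdijk",        68.3, b(12,  35, 7,   55,  45, 9), perturbGain = 0.8),
        mk("MargariaCOM",    91.7, b(8,   50, 5,   48,  35, 8,   80, 25, 6),
           perturbGain = 1.2),
        mk("EMGSum",        115, b(10,  60, 5,   60,  50, 8), perturbGain = 1.3,
           noiseSd = 7.5, highNoise = TRUE),
        mk("MinettiJoint",  138.3, b(20,  45, 8,   52,  55, 6,   85, 30, 5),
           perturbGain = 0.9),
        mk("Lichtwark",     161.7, b(14,  55, 6,   45,  40, 10,  78, 45, 6),
           perturbGain = 1.1),
        mk("KimJoint",      185, b(10,  65, 6,   58,  60, 7), perturbGain = 0.7),
        mk("Bhargava",      208.3, b(16,  50, 7,   50,  65, 8,   82, 40, 6),
           perturbGain = 1.0),
        mk("MargariaJoint", 231.7, b(9,   70, 5,   46,  50, 9,   76, 55, 6),
           perturbGain = 1.2),
        mk("Umberger",      255, b(13,  60, 7,   54,  70, 8,   88, 35, 5),
           perturbGain = 0.8)
    )
    names(reg) <- vapply(reg, `[[`, "", "model_id")
    reg
}

#' Perturbation specification for one walking condition
#'
#' @param kind `"sinusoidal"` (waist-tether force bump with a peak timing),
#'   `"constant"` (uniform force), or `"none"` (the unperturbed condition).
#' @param peak_timing percent of gait cycle in \[1, 100\] at which a
#'   sinusoidal perturbation peaks; `NA` otherwise.
#' @param magnitude peak force as a fraction of body weight in \[0, 0.24\];
#'   must be 0 exactly when `kind = "none"` and positive otherwise.
#' @return a list of class `PerturbationSpec`.
#' @export
perturbationSpec <- function(kind = c("sinusoidal", "constant", "none"),
                             peak_timing = NA_real_, magnitude = 0) {
    kind <- match.arg(kind)
    if (kind == "none" && magnitude != 0)
        stop("unperturbed condition must have magnitude 0")
    if (kind != "none" && (magnitude <= 0 || magnitude > 0.24))
        stop("perturbation magnitude must be in (0, 0.24]")
    if (kind == "sinusoidal" &&
        (is.na(peak_timing) || peak_timing < 1 || peak_timing > 100))
        stop("sinusoidal perturbations need a peak timing in [1, 100]")
    if (kind != "sinusoidal") peak_timing <- NA_real_
    structure(list(kind = kind, peak_timing = peak_timing,
                   magnitude = magnitude), class = "PerturbationSpec")
}

# Layout of the default condition set: peak timings spanning the whole
# cycle; magnitudes cycling over four levels up to 24% body weight.
.conditionLayout <- function(nSin, nConst) {
    magLevels <- c(0.06, 0.12, 0.18, 0.24)
    peaks <- round(seq(1, 100, length.out = nSin))
    conds <- list()
    for (k in seq_len(nSin)) {
        conds[[sprintf("sin%02d", k)]] <- perturbationSpec(
            "sinusoidal", peak_timing = peaks[k],
            magnitude = magLevels[(k - 1L) %% 4L + 1L])
    }
    for (k in seq_len(nConst)) {
        conds[[sprintf("const%02d", k)]] <- perturbationSpec(
            "constant", magnitude = magLevels[4L - (k - 1L) %% 3L])
    }
    conds[["unperturbed"]] <- perturbationSpec("none")
    conds
}

.baseProfile <- function(prof) {
    bumps <- rowSums(apply(prof$bumps, 1L, function(r)
        .gaussBump(r[["center"]], r[["height"]], r[["sd"]])))
    prof$targetMean - mean(bumps) + bumps
}

# Localized response to a perturbation.  Height scales linearly with
# magnitude; its sign follows cos(2*pi*peak/100) so perturbations peaking
# early/late in the cycle raise the cost while mid-cycle ones lower it,
# placing the unperturbed stride mean inside the training-mean envelope.
.perturbResponse <- function(prof, spec, magnitudeScale = 1) {
    mag <- spec$magnitude * magnitudeScale
    if (spec$kind == "none" || mag == 0) return(numeric(100L))
    relMag <- mag / 0.24
    if (spec$kind == "sinusoidal") {
        sgn <- cos(2 * pi * spec$peak_timing / 100)
        .gaussBump(spec$peak_timing, prof$perturbGain * relMag * 35 * sgn, 8)
    } else {
        rep(prof$perturbGain * relMag * 6 * spec$sign, 100L)
    }
}

# Smooth correlated noise: 4-harmonic random Fourier series with no
# constant term, so the noise never shifts the stride mean.
.fourierNoise <- function(noiseSd, scale = 1) {
    coefs <- stats::rnorm(8L, 0, noiseSd * scale / 2)
    v <- numeric(100L)
    for (h in 1:4) {
        v <- v + coefs[2L * h - 1L] * cos(2 * pi * h * .phase / 100) +
                 coefs[2L * h] * sin(2 * pi * h * .phase / 100)
    }
    v
}

#' Generate a seeded synthetic gait dataset
#'
#' Builds the full condition x model grid: `nSin` sinusoidally perturbed
#' walking conditions (peak timings spanning the gait cycle, magnitudes
#' cycling over 6/12/18/24% body weight), `nConst` constant-force
#' conditions, and one unperturbed condition tagged as the holdout split.
#' Every condition yields one length-100 cost series per registry model:
#' base profile + perturbation response + seeded smooth noise.  Identical
#' seeds give bit-identical datasets.
#'
#' @param nSin number of sinusoidal perturbation conditions (>= 1).
#' @param nConst number of constant-force conditions (>= 0).
#' @param registry model registry with exactly 10 profiles, as returned by
#'   [defaultModelRegistry()].
#' @param seed integer seed.
#' @param magnitudeScale multiplier applied to every perturbation magnitude
#'   (0 collapses all perturbed series onto the unperturbed base; useful
#'   for identity checks).
#' @param noiseScale multiplier for the noise amplitude (0 disables noise).
#' @return a [GaitDataset-class] with `(nSin + nConst + 1) * 10` series.
#' @examples
#' gd <- generateGaitDataset(4, 1, seed = 7)
#' dim(gd)            # 100 x 60
#' table(colData(gd)$split)
#' @export
generateGaitDataset <- function(nSin = 32L, nConst = 3L,
                                registry = defaultModelRegistry(),
                                seed = 1L, magnitudeScale = 1,
                                noiseScale = 1) {
    if (nSin < 1L) stop("need at least one sinusoidal condition")
    if (nConst < 0L) stop("nConst must be non-negative")
    if (length(registry) != 10L)
        stop("registry must provide exactly 10 model profiles, got ",
             length(registry))
    conds <- .conditionLayout(nSin, nConst)
    # alternate the sign of constant-force responses so both directions occur
    cIdx <- 0L
    for (nm in names(conds)) {
        if (conds[[nm]]$kind == "constant") {
            cIdx <- cIdx + 1L
            conds[[nm]]$sign <- (-1)^(cIdx + 1L)
        }
    }
    bases <- lapply(registry, .baseProfile)
    nSeries <- length(conds) * length(registry)
    values <- matrix(0, 100L, nSeries)
    info <- data.frame(condition_id = character(nSeries),
                       model_id = character(nSeries),
                       split = character(nSeries),
                       mean = numeric(nSeries),
                       perturb_kind = character(nSeries),
                       peak_timing = numeric(nSeries),
                       magnitude = numeric(nSeries))
    j <- 0L
    withSeed(seed, {
        for (cn in names(conds)) {
            spec <- conds[[cn]]
            for (mn in names(registry)) {
                j <- j + 1L
                prof <- registry[[mn]]
                v <- bases[[mn]] +
                     .perturbResponse(prof, spec, magnitudeScale) +
                     .fourierNoise(prof$noiseSd, noiseScale)
                values[, j] <- v
                info$condition_id[j] <- cn
                info$model_id[j] <- mn
                info$split[j] <- if (spec$kind == "none") "holdout" else "train"
                info$mean[j] <- mean(v)
                info$perturb_kind[j] <- spec$kind
                info$peak_timing[j] <- spec$peak_timing
                info$magnitude[j] <- spec$magnitude * magnitudeScale
            }
        }
    })
    rownames(values) <- sprintf("p%03d", .phase)
    colnames(values) <- paste(info$condition_id, info$model_id, sep = ".")
    se <- SummarizedExperiment(
        assays = list(cost = values),
        colData = DataFrame(info, row.names = colnames(values)),
        rowData = DataFrame(phase = .phase),
        metadata = list(generator = list(
            nSin = as.integer(nSin), nConst = as.integer(nConst),
            seed = as.integer(seed), magnitudeScale = magnitudeScale,
            noiseScale = noiseScale,
            models = names(registry)))
    )
    new("GaitDataset", se)
}

#' Stride mean of one within-stride series
#'
#' The arithmetic mean of the 100 phase samples -- the quantity measurable
#' in humans by indirect calorimetry.
#'
#' @param series numeric vector of exactly 100 within-stride cost samples.
#' @return the mean, W.
#' @examples
#' strideMean(rep(3, 100))  # 3
#' strideMean(1:100)        # 50.5
#' @export
strideMean <- function(series) {
    if (!is.numeric(series) || length(series) != 100L)
        stop("a within-stride series must have exactly 100 samples")
    mean(series)
}

#' Cached stride means of every series in a dataset
#'
#' @param object a [GaitDataset-class].
#' @return named numeric vector of stride means, W.
#' @aliases strideMeans
#' @export
setMethod("strideMeans", "GaitDataset", function(object) {
    stats::setNames(colData(object)$mean, colnames(object))
})

#' Split a dataset into training and holdout parts
#'
#' The perturbed conditions form the training set; the single unperturbed
#' condition is the holdout reserved for validating trained networks.
#'
#' @param dataset a [GaitDataset-class] with exactly one unperturbed
#'   (holdout-tagged) condition.
#' @return list with elements `train` and `holdout`, both `GaitDataset`s
#'   partitioning the input.
#' @aliases splitTrainHoldout
#' @export
setMethod("splitTrainHoldout", "GaitDataset", function(dataset) {
    cd <- colData(dataset)
    hc <- unique(cd$condition_id[cd$split == "holdout"])
    if (length(hc) != 1L)
        stop("expected exactly one unperturbed holdout condition, found ",
             length(hc))
    list(train = dataset[, cd$split == "train"],
         holdout = dataset[, cd$split == "holdout"])
})

# ---- delimited-text round trip --------------------------------------------

#' Write / read a gait dataset as delimited text
#'
#' One CSV row per series with columns `condition_id`, `model_id`, `split`,
#' `mean`, `v001`..`v100`, plus a JSON sidecar (`<path>.json`) recording
#' the generator configuration, seed and per-condition perturbations.
#'
#' @param dataset a [GaitDataset-class].
#' @param path CSV file path.
#' @return `writeGaitDataset` returns `path` invisibly; `readGaitDataset`
#'   returns the reconstructed [GaitDataset-class].
#' @export
writeGaitDataset <- function(dataset, path) {
    stopifnot(is(dataset, "GaitDataset"))
    x <- t(assay(dataset, "cost"))
    colnames(x) <- sprintf("v%03d", .phase)
    cd <- as.data.frame(colData(dataset))
    out <- cbind(cd[, c("condition_id", "model_id", "split", "mean")], x)
    utils::write.csv(out, path, row.names = FALSE)
    side <- list(
        generator = metadata(dataset)$generator,
        conditions = unique(cd[, intersect(
            c("condition_id", "perturb_kind", "peak_timing", "magnitude"),
            colnames(cd)), drop = FALSE])
    )
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    invisible(path)
}

#' @rdname writeGaitDataset
#' @export
readGaitDataset <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    vcols <- sprintf("v%03d", .phase)
    stopifnot(all(vcols %in% colnames(df)))
    values <- t(as.matrix(df[, vcols]))
    rownames(values) <- sprintf("p%03d", .phase)
    info <- df[, c("condition_id", "model_id", "split", "mean")]
    sidePath <- paste0(path, ".json")
    meta <- list()
    if (file.exists(sidePath)) {
        side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
        meta$generator <- side$generator
        if (!is.null(side$conditions)) {
            cc <- side$conditions
            m <- match(info$condition_id, cc$condition_id)
            info$perturb_kind <- cc$perturb_kind[m]
            info$peak_timing <- suppressWarnings(as.numeric(cc$peak_timing[m]))
            info$magnitude <- cc$magnitude[m]
        }
    }
    colnames(values) <- paste(info$condition_id, info$model_id, sep = ".")
    se <- SummarizedExperiment(
        assays = list(cost = values),
        colData = DataFrame(info, row.names = colnames(values)),
        rowData = DataFrame(phase = .phase),
        metadata = meta)
    new("GaitDataset", se)
}
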