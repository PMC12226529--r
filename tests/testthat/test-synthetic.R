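test_that("default layout yields the full condition x model grid", {
    gd <- generateGaitDataset(32, 3, seed = 7)
    cd <- colData(gd)
    expect_identical(dim(gd), c(100L, 360L))
    expect_identical(length(unique(cd$condition_id)), 36L)
    expect_identical(length(unique(cd$condition_id[cd$split == "holdout"])), 1L)
    expect_identical(sum(cd$split == "holdout"), 10L)
    expect_identical(sort(unique(cd$model_id)),
                     sort(names(defaultModelRegistry())))
    # all series finite, exactly 100 phase samples
    expect_true(all(is.finite(assay(gd, "cost"))))
    # training means cover at least 50-250 W
    tm <- cd$mean[cd$split == "train"]
    expect_lt(min(tm), 50)
    expect_gt(max(tm), 250)
})

test_that("datasets are bit-reproducible under a seed and differ across seeds", {
    a <- generateGaitDataset(5, 1, seed = 42)
    b <- generateGaitDataset(5, 1, seed = 42)
    c <- generateGaitDataset(5, 1, seed = 43)
    expect_identical(assay(a, "cost"), assay(b, "cost"))
    expect_false(identical(assay(a, "cost"), assay(c, "cost")))
})

test_that("zero-scaled perturbation and noise collapse onto the base profiles", {
    gd <- generateGaitDataset(1, 0, seed = 3, magnitudeScale = 0,
                              noiseScale = 0)
    X <- assay(gd, "cost")
    cd <- colData(gd)
    for (m in unique(cd$model_id)) {
        cols <- which(cd$model_id == m)
        expect_equal(X[, cols[1L]], X[, cols[2L]])
    }
})

test_that("cached stride means equal recomputed means", {
    gd <- smallDataset(seed = 9)
    expect_equal(as.numeric(colData(gd)$mean),
                 as.numeric(colMeans(assay(gd, "cost"))),
                 tolerance = 1e-9)
    expect_equal(unname(strideMeans(gd)),
                 as.numeric(colData(gd)$mean))
})

test_that("stride mean is the plain arithmetic mean with a length guard", {
    expect_equal(strideMean(rep(3, 100)), 3)
    expect_equal(strideMean(1:100), 50.5)
    expect_equal(strideMean(rep(c(1, -1), each = 50)), 0)
    expect_error(strideMean(1:99), "100 samples")
    expect_error(strideMean(letters), "100 samples")
})

test_that("the sign-unrestricted channel dips below zero in nearly all conditions", {
    gd <- generateGaitDataset(32, 3, seed = 11)
    cd <- colData(gd)
    X <- assay(gd, "cost")
    reg <- defaultModelRegistry()
    signFree <- names(reg)[vapply(reg, `[[`, TRUE, "signUnrestricted")]
    expect_length(signFree, 1L)
    neg <- vapply(unique(cd$condition_id), function(cn) {
        j <- which(cd$condition_id == cn & cd$model_id == signFree)
        any(X[, j] < 0)
    }, TRUE)
    expect_gte(mean(neg), 0.9)
    # sign-restricted channels stay non-negative at default settings
    posModel <- setdiff(names(reg), signFree)[1L]
    expect_true(all(X[, cd$model_id == posModel] > 0))
})

test_that("the high-noise channel is substantially noisier than the rest", {
    reg <- defaultModelRegistry()
    noisy <- names(reg)[vapply(reg, `[[`, TRUE, "highNoise")]
    expect_length(noisy, 1L)
    expect_equal(reg[[noisy]]$noiseSd / reg[["Bhargava"]]$noiseSd, 5)
})

test_that("holdout stride means sit inside the training envelope per model", {
    gd <- generateGaitDataset(32, 3, seed = 13)
    cd <- colData(gd)
    for (m in unique(cd$model_id)) {
        tm <- cd$mean[cd$split == "train" & cd$model_id == m]
        hm <- cd$mean[cd$split == "holdout" & cd$model_id == m]
        expect_gte(hm, min(tm))
        expect_lte(hm, max(tm))
    }
})

test_that("train/holdout split partitions the dataset", {
    gd <- generateGaitDataset(32, 3, seed = 1)
    parts <- splitTrainHoldout(gd)
    expect_identical(ncol(parts$train), 350L)
    expect_identical(ncol(parts$holdout), 10L)
    expect_setequal(c(colnames(parts$train), colnames(parts$holdout)),
                    colnames(gd))
    # minimal two-condition dataset
    gd2 <- generateGaitDataset(1, 0, seed = 2)
    parts2 <- splitTrainHoldout(gd2)
    expect_identical(ncol(parts2$train), 10L)
    expect_identical(ncol(parts2$holdout), 10L)
    # no or duplicated unperturbed conditions are rejected
    expect_error(splitTrainHoldout(parts$train), "exactly one")
})

test_that("perturbation specs enforce their invariants", {
    expect_error(perturbationSpec("none", magnitude = 0.1), "magnitude 0")
    expect_error(perturbationSpec("sinusoidal", magnitude = 0.3,
                                  peak_timing = 50), "0, 0.24")
    expect_error(perturbationSpec("sinusoidal", magnitude = 0.1), "peak timing")
    expect_error(perturbationSpec("constant", magnitude = 0), "0, 0.24")
    sp <- perturbationSpec("sinusoidal", peak_timing = 30, magnitude = 0.12)
    expect_s3_class(sp, "PerturbationSpec")
})

test_that("generator rejects malformed requests", {
    expect_error(generateGaitDataset(0, 3, seed = 1), "at least one")
    expect_error(generateGaitDataset(4, -1, seed = 1), "non-negative")
    expect_error(generateGaitDataset(4, 1, registry = defaultModelRegistry()[1:4],
                                     seed = 1), "exactly 10")
})

test_that("CSV round trip preserves the dataset", {
    gd <- smallDataset(seed = 17)
    path <- tempfile(fileext = ".csv")
    writeGaitDataset(gd, path)
    expect_true(file.exists(paste0(path, ".json")))
    gd2 <- readGaitDataset(path)
    expect_equal(assay(gd2, "cost"), assay(gd, "cost"), tolerance = 1e-12)
    expect_identical(as.character(colData(gd2)$model_id),
                     as.character(colData(gd)$model_id))
    expect_identical(as.character(colData(gd2)$split),
                     as.character(colData(gd)$split))
    expect_equal(metadata(gd2)$generator$seed, 17L)
    parts <- splitTrainHoldout(gd2)
    expect_identical(ncol(parts$holdout), 10L)
})
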