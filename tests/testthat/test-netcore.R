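test_that("layer widths follow the arithmetic-sequence table", {
    expect_identical(layerSizes(1, "expander"), c(1L, 100L))
    expect_identical(layerSizes(2, "decoder"), c(1L, 50L, 100L))
    expect_identical(layerSizes(3, "decoder"), c(1L, 33L, 66L, 100L))
    expect_identical(layerSizes(2, "encoder"), c(100L, 100L, 50L, 1L))
    expect_identical(layerSizes(3, "encoder"), c(100L, 100L, 66L, 33L, 1L))
    expect_error(layerSizes(4, "encoder"), "1, 2 or 3")
    expect_error(layerSizes(0, "expander"), "1, 2 or 3")
})

test_that("activations match their defining formulas", {
    expect_equal(activation("elu", 0), 0)
    expect_equal(activation("tanh", 0), 0)
    expect_equal(activation("mish", 0), 0)
    for (x in c(-2, 0, 3.5)) expect_equal(activation("linear", x), x)
    expect_equal(activation("silu", 1), 1 / (1 + exp(-1)), tolerance = 1e-10)
    expect_equal(activation("silu", 1), 0.73106, tolerance = 1e-5)
    expect_equal(activation("elu", -1), expm1(-1))
    expect_equal(activation("mish", 2), 2 * tanh(log1p(exp(2))), tolerance = 1e-12)
    expect_error(activation("swishh", 1), "unknown activation")
    expect_length(activationNames(), 7L)
})

test_that("network building is seed-deterministic", {
    sp <- netSpec("expander", 3, "elu")
    n1 <- buildNetwork(sp, seed = 11)
    n2 <- buildNetwork(sp, seed = 11)
    n3 <- buildNetwork(sp, seed = 12)
    for (k in 1:3) {
        expect_identical(get(paste0("W", k), envir = n1@params),
                         get(paste0("W", k), envir = n2@params))
    }
    expect_false(identical(get("W1", envir = n1@params),
                           get("W1", envir = n3@params)))
    shapes <- lapply(buildNetwork(netSpec("expander", 3), 1)@stages,
                     function(s) c(s$nOut, s$nIn))
    expect_identical(shapes, list(c(33L, 1L), c(66L, 33L), c(100L, 66L)))
})

test_that("middle activation lands on the designated stage only", {
    sp <- netSpec("expander", 3, "elu")
    expect_identical(sp$activations, c("linear", "elu", "linear"))
    sp2 <- netSpec("encoder", 2, "tanh")
    expect_identical(sp2$activations, c("linear", "tanh", "linear"))
    # output stage of a decoder stays linear even at depth 2
    sp3 <- netSpec("decoder", 2, "relu")
    expect_identical(sp3$activations, c("relu", "linear"))
})

test_that("tied decoder mirrors all encoder stages with live transposed views", {
    enc <- buildNetwork(netSpec("encoder", 3), seed = 5)
    dec <- tieDecoder(enc, seed = 6)
    shapes <- lapply(dec@stages, function(s) c(s$nOut, s$nIn))
    expect_identical(shapes, list(c(33L, 1L), c(66L, 33L),
                                  c(100L, 66L), c(100L, 100L)))
    # shared-storage contract: mutating an encoder weight mutates the view
    W2 <- get("W2", envir = enc@params)
    W2[3, 7] <- 1234.5
    assign("W2", W2, envir = enc@params)
    dstage <- dec@stages[[3L]]   # mirrors encoder stage 2
    expect_identical(dstage$wid, "W2")
    Wview <- stridenet:::.stageWeight(dstage, dec@params)
    expect_equal(Wview[7, 3], 1234.5)
    # biases are independent parameters, not copies of any encoder bias
    encB <- lapply(1:4, function(k) get(paste0("b", k), envir = enc@params))
    for (k in 1:4) {
        db <- get(dec@stages[[k]]$bid, envir = dec@params)
        for (eb in encB)
            if (length(eb) == length(db)) expect_false(identical(eb, db))
    }
    expect_error(tieDecoder(buildNetwork(netSpec("expander", 2), 1)),
                 "encoder")
})

test_that("parameter counts match the closed form, counting tied weights once", {
    expect_identical(countParameters(strideModel("expander", 3, seed = 1)), 9010L)
    expect_identical(countParameters(strideModel("uae", 3, seed = 1)), 28021L)
    expect_identical(countParameters(strideModel("tae", 3, seed = 1)), 19310L)
    expect_identical(countParameters(buildNetwork(netSpec("expander", 1), 1)), 200L)
    # closed form per network: sum(in*out + out) over stages
    enc <- buildNetwork(netSpec("encoder", 3), 2)
    expect_identical(countParameters(enc),
                     as.integer(100 * 100 + 100 + 66 * 100 + 66 +
                                33 * 66 + 33 + 1 * 33 + 1))
    # composition with shared weights: encoder + tied decoder
    dec <- tieDecoder(enc, 3)
    expect_identical(countParameters(list(enc, dec)),
                     19011L + (33L + 66L + 100L + 100L))
})

test_that("forward pass applies stages sequentially and checks dimensions", {
    net <- buildNetwork(netSpec("expander", 2), seed = 9)
    # zeroed parameters give a zero output
    for (s in net@stages) {
        assign(s$wid, get(s$wid, envir = net@params) * 0, envir = net@params)
        assign(s$bid, get(s$bid, envir = net@params) * 0, envir = net@params)
    }
    expect_equal(forwardPass(net, 5), rep(0, 100))
    expect_error(forwardPass(net, c(1, 2)), "dimension")
    out <- forwardPass(buildNetwork(netSpec("expander", 3), 4), 150)
    expect_length(out, 100L)
    expect_true(all(is.finite(out)))
})

test_that("all-linear networks equal their explicitly composed affine map", {
    withSeed(21, {
        for (role in c("expander", "decoder")) {
            net <- buildNetwork(netSpec(role, 3), seed = sample.int(100, 1))
            aff <- composeAffine(net)
            for (i in 1:10) {
                x <- runif(1, -300, 300)
                expect_equal(forwardPass(net, x),
                             as.numeric(aff$A * x + aff$c),
                             tolerance = 1e-6)
            }
        }
        enc <- buildNetwork(netSpec("encoder", 3), 31)
        aff <- composeAffine(enc)
        X <- matrix(rnorm(100 * 10, 100, 30), 100, 10)
        expect_equal(as.numeric(forwardPass(enc, X)),
                     as.numeric(aff$A %*% X + aff$c),
                     tolerance = 1e-6)
    })
})

test_that("tied views stay transposes after parameter updates", {
    m <- strideModel("tae", 3, seed = 7)
    gd <- smallDataset(seed = 2)
    fitModel(m, splitTrainHoldout(gd)$train,
             trainConfig(epochs = 20L))
    for (k in seq_along(m@decoder@stages)) {
        s <- m@decoder@stages[[k]]
        expect_identical(stridenet:::.stageWeight(s, m@decoder@params),
                         t(get(s$wid, envir = m@encoder@params)))
    }
})

test_that("network serialization round-trips, preserving tie structure", {
    m <- strideModel("tae", 2, seed = 13)
    path <- tempfile(fileext = ".json")
    saveModel(m, path)
    m2 <- loadModel(path)
    expect_equal(forwardPass(m2@decoder, 120), forwardPass(m@decoder, 120))
    expect_identical(countParameters(m2), countParameters(m))
    # restored decoder still views the restored encoder's storage
    W1 <- get("W1", envir = m2@encoder@params)
    W1[1, 1] <- -42
    assign("W1", W1, envir = m2@encoder@params)
    last <- m2@decoder@stages[[length(m2@decoder@stages)]]
    expect_equal(stridenet:::.stageWeight(last, m2@decoder@params)[1, 1], -42)
    # untied model round-trip keeps encoder and decoder independent
    u <- strideModel("uae", 2, seed = 14)
    saveModel(u, path)
    u2 <- loadModel(path)
    expect_equal(forwardPass(u2@decoder, 80), forwardPass(u@decoder, 80))
    expect_false(identical(get(".envId", envir = u2@encoder@params),
                           get(".envId", envir = u2@decoder@params)))
})
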