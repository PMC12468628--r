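smallNetConfig <- function(...)
  netConfig(growth_rate = 2L, upsample_features = 3L, n_levels = 2L,
            input_shape = 8L, dropout_rate = 0, precision = "double", ...)

test_that("construction validates the input-shape divisibility contract", {
  expect_error(netConfig(n_levels = 4L, input_shape = 20L), "divisible")
  expect_silent(netConfig(n_levels = 3L, input_shape = 32L))
})

test_that("output preserves shape and is non-negative, eval is deterministic", {
  cfg <- netConfig(growth_rate = 4L, upsample_features = 8L, n_levels = 3L,
                   input_shape = 32L)
  net <- buildNetwork(cfg, seed = 3)
  mask <- array(0L, rep(32L, 3)); mask[14:18, 14:18, 14:18] <- 2L
  y1 <- predictDose(net, mask)
  expect_identical(dim(y1), rep(32L, 3))
  expect_true(all(y1 >= 0) && all(is.finite(y1)))
  # dropout disabled at inference: identical outputs
  expect_identical(y1, predictDose(net, mask))
  # zero input still yields finite non-negative output
  y0 <- predictDose(net, array(0L, rep(32L, 3)))
  expect_true(all(is.finite(y0)) && all(y0 >= 0))
  expect_error(predictDose(net, array(0L, rep(16L, 3))), "shape")
  expect_error(predictDose(net, array(3L, rep(32L, 3))), "codes")
})

test_that("a full-resolution 128-cube input is supported end to end", {
  cfg <- netConfig(growth_rate = 2L, upsample_features = 4L, n_levels = 5L,
                   input_shape = 128L)
  net <- buildNetwork(cfg, seed = 1)
  mask <- array(0L, rep(128L, 3)); mask[60:68, 60:68, 60:68] <- 2L
  y <- predictDose(net, mask)
  expect_identical(dim(y), rep(128L, 3))
  expect_true(all(y >= 0))
})

test_that("parameter count matches an independent layer-by-layer count", {
  # hand count for growth 2, upsample 3, levels 2, 1 input channel:
  # enc0: 1->2 (carried 3), down0: 3->2 (5 at the bottom), enc1: 5->2
  # (7), up0: 7->3, concat with skip (3) -> dec0: 6->2, final tensor 8,
  # out: 8->1 ; params = sum(27 * cin * cout + cout)
  hand <- (27 * 1 * 2 + 2) + (27 * 3 * 2 + 2) + (27 * 5 * 2 + 2) +
    (27 * 7 * 3 + 3) + (27 * 6 * 2 + 2) + (27 * 8 * 1 + 1)
  cfg <- smallNetConfig()
  net <- buildNetwork(cfg, seed = 1)
  expect_equal(nParams(net), hand)
  expect_equal(attr(expectedFeatureCounts(cfg), "n_params"), hand)
  # construction is deterministic across repeated builds
  expect_equal(nParams(buildNetwork(cfg, seed = 9)), hand)
})

test_that("compiled feature bookkeeping matches the dense-growth arithmetic", {
  for (cfg in list(smallNetConfig(),
                   netConfig(growth_rate = 4L, upsample_features = 8L,
                             n_levels = 3L, input_shape = 16L))) {
    net <- buildNetwork(cfg, seed = 1)
    audit <- featureAudit(net)
    expected <- expectedFeatureCounts(cfg)
    expect_equal(audit$layer, expected$layer)
    expect_equal(audit$cin, expected$cin)
    expect_equal(audit$cout, expected$cout)
  }
})

test_that("identical seeds give identical weights; weights round-trip", {
  cfg <- smallNetConfig()
  w1 <- networkWeights(buildNetwork(cfg, seed = 5))
  w2 <- networkWeights(buildNetwork(cfg, seed = 5))
  expect_identical(w1, w2)
  net <- buildNetwork(cfg, seed = 6)
  networkWeights(net) <- w1
  expect_identical(networkWeights(net), w1)
  ckpt <- tempfile(fileext = ".rds")
  saveCheckpoint(net, ckpt)
  net2 <- loadCheckpoint(ckpt)
  expect_identical(networkWeights(net2), w1)
  mask <- array(0L, rep(8L, 3)); mask[4:5, 4:5, 4:5] <- 2L
  expect_identical(predictDose(net, mask), predictDose(net2, mask))
})

test_that("back-propagated gradients match finite differences", {
  cfg <- smallNetConfig()
  net <- buildNetwork(cfg, seed = 2)
  set.seed(2)
  x <- array(sample(0:2, 512, TRUE), rep(8L, 3))
  lossOf <- function() {
    y <- predictDose(net, x)
    0.5 * sum(y^2)
  }
  y <- GKDosePredict:::netForwardTrain(net, x, seed = 1)
  GKDosePredict:::netZeroGrad(net)
  GKDosePredict:::netBackward(net, y) # dL/dy = y for L = 0.5 sum y^2
  grads <- GKDosePredict:::cppNetGrads(net@ptr)
  wl <- networkWeights(net)
  h <- 1e-5
  set.seed(3)
  for (li in sample(seq_along(wl), 4)) {
    for (j in sample(length(wl[[li]]$W), 3)) {
      wp <- wl; wp[[li]]$W[j] <- wp[[li]]$W[j] + h
      networkWeights(net) <- wp
      f1 <- lossOf()
      wp[[li]]$W[j] <- wp[[li]]$W[j] - 2 * h
      networkWeights(net) <- wp
      f0 <- lossOf()
      networkWeights(net) <- wl
      fd <- (f1 - f0) / (2 * h)
      expect_equal(grads[[li]]$W[j], fd, tolerance = 1e-5)
    }
  }
})
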