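# R-side surface of the compiled hierarchically dense U-Net.

#' Expected feature-map bookkeeping of a network configuration
#'
#' Pure channel arithmetic of the dense-growth architecture: every dense
#' convolution and dense down-sampling operation adds `growth_rate` new
#' features to the carried (copied or max-pooled) features; every U-Net
#' up-sampling returns `upsample_features` features that are concatenated
#' with the same-level skip tensor. Used as the construction-time audit in
#' the tests and to predict the parameter count.
#'
#' @param config a [NetConfig-class].
#' @param in_channels input channels (1: the label-coded mask).
#' @return data.frame with one row per convolution (layer, cin, cout) plus
#'   an `n_params` attribute.
#' @export
expectedFeatureCounts <- function(config, in_channels = 1L) {
  L <- config@n_levels
  g <- config@growth_rate
  U <- config@upsample_features
  rows <- list()
  add <- function(layer, cin, cout)
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, cin = cin,
                                             cout = cout)
  c_ <- in_channels
  skip <- integer(L)
  for (l in seq_len(L) - 1L) {
    add(paste0("enc", l), c_, g)
    c_ <- c_ + g
    skip[l + 1L] <- c_
    if (l < L - 1L) {
      add(paste0("down", l), c_, g)
      c_ <- c_ + g
    }
  }
  for (l in rev(seq_len(L - 1L) - 1L)) {
    add(paste0("up", l), c_, U)
    c_ <- U + skip[l + 1L]
    add(paste0("dec", l), c_, g)
    c_ <- c_ + g
  }
  add("out", c_, 1L)
  df <- do.call(rbind, rows)
  # enc/down/up/dec grouped ordering, matching the compiled layer order
  target <- c(paste0("enc", seq_len(L) - 1L),
              paste0("down", seq_len(L - 1L) - 1L),
              paste0("up", seq_len(L - 1L) - 1L),
              paste0("dec", seq_len(L - 1L) - 1L), "out")
  df <- df[match(target, df$layer), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_params") <- sum(27 * df$cin * df$cout + df$cout)
  df
}

#' Build a hierarchically dense 3D U-Net
#'
#' Constructs the compiled network and initializes its weights (He-scaled
#' normal, zero biases) from `seed`, so construction is fully
#' deterministic. The parameter count is a pure function of the
#' configuration.
#'
#' @param config a [NetConfig-class].
#' @param seed weight-initialization seed.
#' @return An [HDUNet-class] handle.
#' @export
buildNetwork <- function(config = netConfig(), seed = 1L) {
  validObject(config)
  ptr <- cppNetCreate(config@n_levels, config@growth_rate,
                      config@upsample_features, 1L,
                      rep(config@input_shape, 3L), config@dropout_rate,
                      config@precision)
  wl <- cppNetGetWeights(ptr)
  wl <- withLocalSeed(seed, {
    lapply(wl, function(lay) {
      fan_in <- nrow(lay$W)
      list(W = matrix(rnorm(length(lay$W), 0, sqrt(2 / fan_in)),
                      nrow(lay$W), ncol(lay$W)),
           b = rep(0, length(lay$b)))
    })
  })
  cppNetSetWeights(ptr, wl)
  new("HDUNet", ptr = ptr, config = config, n_params = cppNetNParams(ptr))
}

#' Number of trainable parameters
#' @param net an [HDUNet-class].
#' @return Numeric count.
#' @export
nParams <- function(net) net@n_params

#' Per-layer channel audit of a built network
#' @param net an [HDUNet-class].
#' @return data.frame with layer, cin, cout.
#' @export
featureAudit <- function(net) cppNetLayerInfo(net@ptr)

#' Predict a normalized dose volume from a label mask
#'
#' Runs the network in inference mode (dropout disabled, deterministic).
#' The input is the single-channel label mask with raw codes 0/1/2; the
#' output is a non-negative volume on the fraction-of-Rx scale with the
#' same shape.
#'
#' @param net an [HDUNet-class].
#' @param input_mask 3D array with codes in {0, 1, 2}.
#' @return 3D numeric array of predicted dose (fraction of Rx).
#' @export
predictDose <- function(net, input_mask) {
  edge <- net@config@input_shape
  if (!identical(dim(input_mask), rep(edge, 3L)))
    stop("input shape does not match the network configuration")
  if (!all(input_mask %in% c(0, 1, 2)))
    stop("input mask codes must be 0, 1 or 2")
  cppNetForward(net@ptr, as.numeric(input_mask), FALSE, 0)
}

# training-mode forward (dropout active, caches retained for backward)
netForwardTrain <- function(net, input_mask, seed)
  cppNetForward(net@ptr, as.numeric(input_mask), TRUE, seed)

netBackward <- function(net, grad_out) cppNetBackward(net@ptr, grad_out)
netZeroGrad <- function(net) cppNetZeroGrad(net@ptr)
netAdamStep <- function(net, lr, scale, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8)
  cppNetAdamStep(net@ptr, lr, scale, beta1, beta2, eps)

#' Read or replace the network weights
#'
#' @param net an [HDUNet-class].
#' @return Named list of layers, each with a weight matrix `W`
#'   ((27 * cin) x cout) and bias vector `b`.
#' @export
networkWeights <- function(net) cppNetGetWeights(net@ptr)

#' @rdname networkWeights
#' @param value weight list as returned by `networkWeights()`.
#' @export
`networkWeights<-` <- function(net, value) {
  cppNetSetWeights(net@ptr, value)
  net
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint carries the configuration and all weights, so
#' [loadCheckpoint()] can rebuild the handle without further context.
#'
#' @param net an [HDUNet-class].
#' @param path file path.
#' @return `loadCheckpoint()` returns an [HDUNet-class].
#' @export
saveCheckpoint <- function(net, path) {
  obj <- list(config = list(growth_rate = net@config@growth_rate,
                            upsample_features = net@config@upsample_features,
                            n_levels = net@config@n_levels,
                            input_shape = net@config@input_shape,
                            dropout_rate = net@config@dropout_rate,
                            kernel_size = net@config@kernel_size,
                            precision = net@config@precision),
              weights = networkWeights(net),
              package_version = as.character(utils::packageVersion(
                "GKDosePredict")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(netConfig, obj$config)
  net <- buildNetwork(cfg, seed = 0L)
  networkWeights(net) <- obj$weights
  net
}
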