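# Cross-validated training loop with the exponential learning-rate
# schedule, shuffle-without-replacement epoch sampling and on-the-fly
# augmentation.

#' Random fold assignment
#'
#' Near-equal random partition of lesion ids into `n_folds` disjoint,
#' exhaustive folds, deterministic under the seed.
#'
#' @param lesion_ids character or other vector of ids.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return Integer fold index per id (named when ids are named/character).
#' @export
splitFolds <- function(lesion_ids, n_folds, seed = 1L) {
  n <- length(lesion_ids)
  if (n < n_folds) stop("fewer lesions than folds")
  folds <- withLocalSeed(seed, {
    f <- rep(seq_len(n_folds), length.out = n)
    sample(f, n)
  })
  names(folds) <- as.character(lesion_ids)
  folds
}

#' Learning rate at a given batch index
#'
#' Stepwise exponential decay:
#' `lr(b) = lr_initial * factor^floor(b / decay_every)` for 0-based batch
#' index b.
#'
#' @param config a [TrainConfig-class].
#' @param batch_index 0-based global batch counter.
#' @return Learning rate.
#' @export
learningRateAt <- function(config, batch_index) {
  config@lr_initial *
    config@lr_decay_factor^(batch_index %/% config@lr_decay_every)
}

#' Train one fold
#'
#' Trains a freshly initialized network on `train_spaces`, evaluating the
#' mean composite loss on `val_spaces` once per epoch. Each epoch draws
#' samples without replacement from a shuffled queue that reshuffles when
#' exhausted, so the training data are seen approximately once per epoch
#' when `batches_per_epoch * batch_size` matches the training-set size
#' (pass `batches_per_epoch = NA` to derive it). All randomness (weight
#' init, sampling, augmentation, dropout) is derived from the master seed.
#'
#' @param train_spaces,val_spaces lists of [TumorSpace-class]; must be
#'   disjoint.
#' @param net_config a [NetConfig-class].
#' @param loss_config a [LossConfig-class]; use [mseBaselineConfig()] for
#'   the plain-MSE comparator.
#' @param train_config a [TrainConfig-class].
#' @param policy an [AugmentPolicy-class], or NULL to disable augmentation.
#' @param verbose print per-epoch losses.
#' @return list with `net`, `history` (epoch, train_loss, val_loss, lr)
#'   and the configurations used.
#' @export
trainFold <- function(train_spaces, val_spaces, net_config = netConfig(),
                      loss_config = lossConfig(),
                      train_config = trainConfig(),
                      policy = augmentPolicy(), verbose = FALSE) {
  ids_tr <- vapply(train_spaces, function(s) s@lesion_id, character(1))
  ids_va <- vapply(val_spaces, function(s) s@lesion_id, character(1))
  if (length(intersect(ids_tr, ids_va)) > 0)
    stop("training and validation sets overlap")
  n_tr <- length(train_spaces)
  bpe <- train_config@batches_per_epoch
  if (is.na(bpe)) bpe <- max(1L, ceiling(n_tr / train_config@batch_size))

  net <- buildNetwork(net_config, seed = train_config@seed + 1L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  batch_counter <- 0L

  withLocalSeed(train_config@seed, {
    queue <- sample(n_tr)
    draw <- function() {
      if (length(queue) == 0L) queue <<- sample(n_tr)
      i <- queue[1L]
      queue <<- queue[-1L]
      i
    }
    for (epoch in seq_len(train_config@epochs)) {
      epoch_losses <- numeric(bpe)
      for (b in seq_len(bpe)) {
        lr <- learningRateAt(train_config, batch_counter)
        netZeroGrad(net)
        bl <- 0
        for (s in seq_len(train_config@batch_size)) {
          sp <- train_spaces[[draw()]]
          mask <- sp@input_mask
          dose <- sp@dose_norm
          if (!is.null(policy)) {
            aug <- augmentPair(mask, dose, policy)
            mask <- aug$mask
            dose <- aug$dose
          }
          pred <- netForwardTrain(net, mask,
                                  seed = floor(runif(1) * 2^31))
          loss <- totalLoss(pred, dose, loss_config)
          if (!is.finite(loss))
            stop(sprintf(
              "non-finite loss at epoch %d batch %d (lesion %s, lr %.3g)",
              epoch, b, sp@lesion_id, lr))
          bl <- bl + loss
          netBackward(net, totalLossGradient(pred, dose, loss_config))
        }
        netAdamStep(net, lr, 1 / train_config@batch_size)
        epoch_losses[b] <- bl / train_config@batch_size
        batch_counter <- batch_counter + 1L
      }
      vl <- if (length(val_spaces))
        mean(vapply(val_spaces, function(sp)
          totalLoss(predictDose(net, sp@input_mask), sp@dose_norm,
                    loss_config), numeric(1)))
      else NA_real_
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = mean(epoch_losses),
                                  val_loss = vl,
                                  lr = learningRateAt(train_config,
                                                      batch_counter - 1L)))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        mean(epoch_losses), vl))
    }
  })
  list(net = net, history = history, net_config = net_config,
       loss_config = loss_config, train_config = train_config)
}

#' Predict dose volumes for a list of tumor spaces
#'
#' @param net an [HDUNet-class].
#' @param spaces list of [TumorSpace-class].
#' @return Named list of predicted normalized dose arrays.
#' @export
predictSpaces <- function(net, spaces) {
  out <- lapply(spaces, function(sp) predictDose(net, sp@input_mask))
  names(out) <- vapply(spaces, function(sp) sp@lesion_id, character(1))
  out
}

#' Run k-fold cross-validated training
#'
#' Thin driver over [splitFolds()] and [trainFold()]: trains one network
#' per fold and returns out-of-fold predictions for every lesion.
#'
#' @inheritParams trainFold
#' @param spaces list of [TumorSpace-class].
#' @param folds optional precomputed fold assignment.
#' @return list with `predictions` (named list of arrays), `folds`, and
#'   per-fold training `history` data frames.
#' @export
crossValidate <- function(spaces, net_config = netConfig(),
                          loss_config = lossConfig(),
                          train_config = trainConfig(),
                          policy = augmentPolicy(), folds = NULL,
                          verbose = FALSE) {
  ids <- vapply(spaces, function(s) s@lesion_id, character(1))
  if (is.null(folds))
    folds <- splitFolds(ids, train_config@n_folds, train_config@seed)
  preds <- list()
  histories <- list()
  for (f in sort(unique(folds))) {
    tr <- spaces[folds != f]
    va <- spaces[folds == f]
    fit <- trainFold(tr, va, net_config, loss_config, train_config, policy,
                     verbose = verbose)
    preds <- c(preds, predictSpaces(fit$net, va))
    histories[[as.character(f)]] <- fit$history
  }
  list(predictions = preds[ids], folds = folds, history = histories)
}
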