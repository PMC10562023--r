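# Training protocol and evaluation: 3:1 train/test split via 4-fold
# cross-validation with 20% of the training portion held out for validation,
# Adam on an MSE loss averaged over the nine outputs (labels on a [0,1]
# scale), weights taken from the epoch with the smallest validation loss,
# and per-criterion MAE / Pearson r / within-3% fraction averaged over folds.

#' Training configuration
#'
#' Defaults follow the standard protocol: 200 epochs, batch size 4, Adam
#' with learning rate 0.001, MSE loss averaged uniformly over the nine
#' outputs on [0, 1]-scaled GPR labels.
#'
#' @param epochs,batchSize,learningRate,beta1,beta2,epsilon Adam/loop
#'   settings.
#' @param seed RNG seed for shuffling and dropout.
#' @return a list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 200L, batchSize = 4L, learningRate = 0.001,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                        seed = 1L) {
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "trainConfig")
}

#' Cross-validation fold plan
#'
#' Assigns plan ids to `k` disjoint, exhaustive test folds by a seeded
#' shuffle (no stratification) and, within each fold, holds out 20% (by
#' default) of the training portion as validation data. With 96 plans and
#' k = 4 this yields 24 test / 58 train / 14 validation per fold.
#'
#' @param ids vector of plan identifiers.
#' @param k number of folds.
#' @param valFraction fraction of the training portion used for validation.
#' @param seed shuffle seed.
#' @return a list of class `FoldPlan`: `k`, `assignments` (id -> fold), and
#'   per-fold lists `test`, `train`, `val`.
#' @export
makeFolds <- function(ids, k = 4L, valFraction = 0.2, seed = 1L) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < k) stop("need at least k = ", k, " plans to make ", k, " folds")
  set.seed(seed)
  shuffled <- sample(ids)
  fold <- rep(seq_len(k), length.out = n)
  assignments <- setNames(fold[match(ids, shuffled)], ids)
  folds <- lapply(seq_len(k), function(f) {
    test <- shuffled[fold == f]
    rest <- shuffled[fold != f]
    rest <- sample(rest)
    nval <- round(valFraction * length(rest))
    list(test = test, val = rest[seq_len(nval)],
         train = rest[-seq_len(nval)])
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 folds = folds, seed = as.integer(seed)),
            class = "FoldPlan")
}

#' @export
print.FoldPlan <- function(x, ...) {
  cat(sprintf("FoldPlan: %d folds over %d plans (seed %d)\n", x$k,
              length(x$assignments), x$seed))
  for (f in seq_len(x$k))
    cat(sprintf("  fold %d: %d test / %d train / %d val\n", f,
                length(x$folds[[f]]$test), length(x$folds[[f]]$train),
                length(x$folds[[f]]$val)))
  invisible(x)
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  corr1 <- 1 - cfg$beta1^state$t
  corr2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - cfg$learningRate *
      (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + cfg$epsilon)
  }
  list(params = params, state = state)
}

.BN_MOMENTUM <- 0.9

.mseLoss <- function(yhat, y) mean((yhat - y)^2)

#' Train a network
#'
#' Runs the standard protocol on already-normalized inputs: seeded shuffling
#' into mini-batches, Adam updates on the MSE loss over the nine [0,1]-scaled
#' outputs, batch-norm running statistics with momentum 0.9, and per-epoch
#' validation loss in inference mode. The returned network carries the
#' weights of the epoch with the smallest validation loss (ties broken
#' toward the earlier epoch) and the full training log.
#'
#' @param net a [GprNet-class].
#' @param train,val lists with elements `inputs` (list of named lists of
#'   matrices) and `labels` (`n x 9` matrix of GPRs in percent).
#' @param cfg a [trainConfig()].
#' @return the trained [GprNet-class] with `trainLog` and `bestEpoch` set.
#' @export
trainModel <- function(net, train, val, cfg = trainConfig()) {
  nTrain <- length(train$inputs)
  if (!nTrain || !length(val$inputs))
    stop("training and validation sets must both be non-empty")
  if (any(!is.finite(unlist(lapply(train$inputs, function(s)
        vapply(s, function(m) sum(m), numeric(1)))))) ||
      any(!is.finite(train$labels)))
    stop("training diverged: non-finite values in the training inputs/labels")
  yTrain <- t(train$labels) / 100 # 9 x n, [0,1] scale
  yVal <- t(val$labels) / 100
  set.seed(cfg$seed)
  adam <- .adamInit(net@params)
  bestLoss <- Inf; bestParams <- net@params; bestBn <- net@bn
  bestEpoch <- NA_integer_
  log <- data.frame(epoch = integer(), trainLoss = numeric(),
                    valLoss = numeric())
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(nTrain)
    starts <- seq(1L, nTrain, by = cfg$batchSize)
    epochLoss <- 0
    for (b in starts) {
      take <- perm[b:min(b + cfg$batchSize - 1L, nTrain)]
      fwd <- .netForward(net, train$inputs[take], training = TRUE)
      loss <- .mseLoss(fwd$yhat, yTrain[, take, drop = FALSE])
      if (!is.finite(loss)) stop("training diverged: non-finite loss")
      epochLoss <- epochLoss + loss * length(take)
      grads <- .netBackward(net, train$inputs[take], fwd,
                            yTrain[, take, drop = FALSE])
      upd <- .adamStep(net@params, grads, adam, cfg)
      net@params <- upd$params; adam <- upd$state
      net@bn$mean <- .BN_MOMENTUM * net@bn$mean +
        (1 - .BN_MOMENTUM) * fwd$mu
      net@bn$var <- .BN_MOMENTUM * net@bn$var +
        (1 - .BN_MOMENTUM) * fwd$va
    }
    valFwd <- .netForward(net, val$inputs, training = FALSE)
    valLoss <- .mseLoss(valFwd$yhat, yVal)
    if (!is.finite(valLoss)) stop("training diverged: non-finite loss")
    log <- rbind(log, data.frame(epoch = epoch,
                                 trainLoss = epochLoss / nTrain,
                                 valLoss = valLoss))
    if (valLoss < bestLoss) { # strict: ties keep the earlier epoch
      bestLoss <- valLoss
      bestParams <- net@params
      bestBn <- net@bn
      bestEpoch <- epoch
    }
  }
  net@params <- bestParams
  net@bn <- bestBn
  net@trainLog <- log
  net@bestEpoch <- bestEpoch
  net
}

#' Evaluation report over cross-validation folds
#'
#' For each criterion: mean absolute error (percentage points), Pearson r,
#' and the fraction of predictions within 3 percentage points of the
#' measurement, each computed per fold on the pooled test predictions and
#' then averaged (mean +/- SD) over folds. A fold with zero variance in
#' either vector gets `NA` r with an explanatory flag instead of a
#' propagated NaN.
#'
#' @param folds list with one element per fold, each a list of `measured`
#'   and `predicted` `n x 9` matrices (GPR in percent).
#' @return an object of class `EvalReport`: `summary` data.frame
#'   (per-criterion mean/SD of the three metrics), `perFold` raw metric
#'   matrices, and `flags` (character vector of degeneracy notes).
#' @export
evaluateGpr <- function(folds) {
  crit <- gammaCriteria()$label
  nf <- length(folds)
  mae <- matrix(NA_real_, nf, 9L); r <- matrix(NA_real_, nf, 9L)
  frac3 <- matrix(NA_real_, nf, 9L)
  flags <- character()
  for (f in seq_len(nf)) {
    meas <- folds[[f]]$measured; pred <- folds[[f]]$predicted
    if (nrow(meas) < 2L)
      stop("need at least 2 (measured, predicted) pairs per fold")
    err <- pred - meas
    mae[f, ] <- colMeans(abs(err))
    frac3[f, ] <- colMeans(abs(err) <= 3)
    for (j in seq_len(9L)) {
      if (sd(meas[, j]) == 0 || sd(pred[, j]) == 0) {
        flags <- c(flags, sprintf(
          "fold %d, %s: r undefined (zero variance)", f, crit[j]))
      } else r[f, j] <- cor(meas[, j], pred[, j])
    }
  }
  summ <- data.frame(
    criterion = crit,
    mae_mean = colMeans(mae), mae_sd = apply(mae, 2L, sd),
    r_mean = colMeans(r), r_sd = apply(r, 2L, sd),
    frac3_mean = colMeans(frac3), frac3_sd = apply(frac3, 2L, sd),
    row.names = NULL)
  structure(list(summary = summ,
                 perFold = list(mae = mae, r = r, frac3 = frac3),
                 folds = folds, flags = flags),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, digits = 3, ...) {
  cat(sprintf("EvalReport over %d fold(s):\n", nrow(x$perFold$mae)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-7s MAE %5.2f +/- %4.2f %%   r %5.2f +/- %4.2f   within +/-3%%: %4.1f%%\n",
                s$criterion[i], s$mae_mean[i], s$mae_sd[i], s$r_mean[i],
                s$r_sd[i], 100 * s$frac3_mean[i]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize an evaluation report as JSON
#'
#' @param report an `EvalReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportReportJson <- function(report, path) {
  jsonlite::write_json(list(summary = report$summary, flags = report$flags),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
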