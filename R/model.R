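# The multi-branch GPR prediction network. Every input image gets its own
# light branch of three 3x3 convolution stages (first one same-padded, the
# later two valid) each followed by 3x3/3 max pooling, then a 20-unit
# embedding. Branch embeddings are fused by elementwise addition, passed
# through ReLU -> batch norm -> dropout -> a 20x20 affine, and read out by
# nine parallel 20->1 heads, one per gamma criterion.

.VARIANT_BRANCHES <- list(
  model1 = c("sagittal", "coronal", "axial", "mlpm"),
  model2 = c("sagittal", "coronal", "axial"),
  model3 = "surface")

.STANDARD_SHAPES <- list(
  sagittal = c(68L, 146L), coronal = c(64L, 200L), axial = c(143L, 242L),
  mlpm = c(110L, 178L), surface = c(220L, 680L))

.EMBED_DIM <- 20L
.CONV_CHANNELS <- 16L

#' Multi-branch GPR prediction network
#'
#' See [buildNetwork()]. Parameters live in `params` as plain arrays (conv
#' weights `3 x 3 x Cin x Cout`); `bn` carries the batch-norm running
#' statistics; `trainLog` and `bestEpoch` are filled by [trainModel()].
#'
#' @slot variant one of `"model1"` (three dose planes + MLPM), `"model2"`
#'   (dose planes only), `"model3"` (surface dose map only).
#' @slot inputShapes named list of `c(rows, cols)` per branch.
#' @slot params named list of weight arrays.
#' @slot bn batch-norm running mean/variance.
#' @slot dropoutRate dropout probability on the fused embedding.
#' @slot criteria the nine criterion labels naming the outputs.
#' @slot seed seed used for weight initialization.
#' @slot trainLog per-epoch train/validation loss (empty before training).
#' @slot bestEpoch epoch whose weights are held (NA before training).
#' @export
setClass("GprNet",
  representation(variant = "character", inputShapes = "list",
                 params = "list", bn = "list", dropoutRate = "numeric",
                 criteria = "character", seed = "integer",
                 trainLog = "data.frame", bestEpoch = "integer"))

setMethod("show", "GprNet", function(object) {
  cat(sprintf("GprNet '%s': %d branch(es) -> 9 criteria\n", object@variant,
              length(object@inputShapes)))
  for (nm in names(object@inputShapes))
    cat(sprintf("  %-8s input %d x %d\n", nm, object@inputShapes[[nm]][1],
                object@inputShapes[[nm]][2]))
  cat(sprintf("  %d trainable parameters, dropout %.2f\n",
              sum(parameterManifest(object)$count), object@dropoutRate))
  if (!is.na(object@bestEpoch))
    cat(sprintf("  trained: best validation epoch %d\n", object@bestEpoch))
})

#' Per-branch feature-map shapes
#'
#' The shape arithmetic of one branch: a same-padded 3x3 convolution keeps
#' the input size, each 3x3/stride-3 pool maps n to `floor((n - 3)/3) + 1`,
#' and the later valid convolutions subtract 2 per axis. Errors if any stage
#' would under-run the 3x3 kernel.
#'
#' @param inputShape `c(rows, cols)` of the branch input.
#' @return named list of `c(rows, cols)` for conv1, pool1, conv2, pool2,
#'   conv3, pool3.
#' @export
branchShapes <- function(inputShape) {
  feasible <- function(n) {
    if (any(n < 3L))
      stop("input shape incompatible with the conv/pooling arithmetic of ",
           "the three branch stages (both axes must be >= 51)")
    n
  }
  pool <- function(n) (feasible(n) - 3L) %/% 3L + 1L
  conv_valid <- function(n) feasible(n) - 2L
  s <- as.integer(inputShape)
  out <- list(conv1 = s)
  out$pool1 <- pool(out$conv1)
  out$conv2 <- conv_valid(out$pool1)
  out$pool2 <- pool(out$conv2)
  out$conv3 <- conv_valid(out$pool2)
  out$pool3 <- pool(out$conv3)
  out
}

.glorot <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

#' Build the prediction network
#'
#' Constructs the multi-branch network with nine outputs for the chosen
#' input configuration. Weights are Glorot-uniform, biases zero, batch-norm
#' scale 1 / shift 0; initialization is deterministic given `seed`.
#'
#' @param variant `"model1"`, `"model2"` or `"model3"`.
#' @param inputShapes optional named list overriding the standard input
#'   shapes (each branch must survive the three conv/pool stages, i.e. both
#'   axes at least 51 pixels).
#' @param dropoutRate dropout probability (default 0.3).
#' @param seed initialization seed.
#' @return a [GprNet-class].
#' @export
buildNetwork <- function(variant = c("model1", "model2", "model3"),
                         inputShapes = NULL, dropoutRate = 0.3,
                         seed = 1L) {
  variant <- match.arg(variant)
  branches <- .VARIANT_BRANCHES[[variant]]
  shapes <- .STANDARD_SHAPES[branches]
  if (!is.null(inputShapes)) {
    for (nm in names(inputShapes)) shapes[[nm]] <- as.integer(inputShapes[[nm]])
    shapes <- shapes[branches]
  }
  set.seed(seed)
  params <- list()
  for (nm in branches) {
    bs <- branchShapes(shapes[[nm]]) # errors on infeasible shapes
    flat <- prod(bs$pool3) * .CONV_CHANNELS
    params[[paste0(nm, ".W1")]] <- .glorot(c(3, 3, 1, .CONV_CHANNELS),
                                           9, 9 * .CONV_CHANNELS)
    params[[paste0(nm, ".b1")]] <- numeric(.CONV_CHANNELS)
    for (k in 2:3) {
      params[[paste0(nm, ".W", k)]] <-
        .glorot(c(3, 3, .CONV_CHANNELS, .CONV_CHANNELS),
                9 * .CONV_CHANNELS, 9 * .CONV_CHANNELS)
      params[[paste0(nm, ".b", k)]] <- numeric(.CONV_CHANNELS)
    }
    params[[paste0(nm, ".A1")]] <- matrix(
      runif(.EMBED_DIM * flat, -sqrt(6 / (flat + .EMBED_DIM)),
            sqrt(6 / (flat + .EMBED_DIM))), .EMBED_DIM, flat)
    params[[paste0(nm, ".A1b")]] <- numeric(.EMBED_DIM)
  }
  params$bnGamma <- rep(1, .EMBED_DIM)
  params$bnBeta <- numeric(.EMBED_DIM)
  params$A2 <- matrix(runif(.EMBED_DIM^2, -sqrt(6 / 40), sqrt(6 / 40)),
                      .EMBED_DIM, .EMBED_DIM)
  params$A2b <- numeric(.EMBED_DIM)
  params$headsW <- matrix(runif(.EMBED_DIM * 9L, -sqrt(6 / 21), sqrt(6 / 21)),
                          .EMBED_DIM, 9L)
  params$headsb <- numeric(9L)
  new("GprNet", variant = variant, inputShapes = shapes, params = params,
      bn = list(mean = numeric(.EMBED_DIM), var = rep(1, .EMBED_DIM)),
      dropoutRate = dropoutRate, criteria = gammaCriteria()$label,
      seed = as.integer(seed), trainLog = data.frame(),
      bestEpoch = NA_integer_)
}

#' Trainable parameter count of a named layer
#'
#' Layer names follow the architecture table: `"<branch>.Convolution_k"`,
#' `"<branch>.Affine_1"`, `"Affine_2"`, `"Affine_3"` (one head; all nine are
#' identical), `"BatchNormalization"`.
#'
#' @param net a [GprNet-class].
#' @param layerName layer to count.
#' @return integer count of weights + biases.
#' @export
countParameters <- function(net, layerName) {
  m <- parameterManifest(net)
  i <- match(layerName, m$layer)
  if (is.na(i)) stop("unknown layer: ", layerName)
  m$count[i]
}

#' Audit table of layer parameter counts
#'
#' @param net a [GprNet-class].
#' @return data.frame with columns `layer` and `count`.
#' @export
parameterManifest <- function(net) {
  rows <- list()
  for (nm in names(net@inputShapes)) {
    for (k in 1:3) {
      w <- net@params[[paste0(nm, ".W", k)]]
      rows[[paste0(nm, ".Convolution_", k)]] <- length(w) + dim(w)[4]
    }
    a1 <- net@params[[paste0(nm, ".A1")]]
    rows[[paste0(nm, ".Affine_1")]] <- length(a1) + nrow(a1)
  }
  rows[["BatchNormalization"]] <- 2L * .EMBED_DIM
  rows[["Affine_2"]] <- length(net@params$A2) + .EMBED_DIM
  rows[["Affine_3"]] <- .EMBED_DIM + 1L # one 20 -> 1 head
  data.frame(layer = names(rows), count = as.integer(unlist(rows)),
             row.names = NULL)
}

# ---- forward / backward -------------------------------------------------

# weights of one branch as the flat list the fused C++ kernels expect
.branchParams <- function(params, nm) {
  list(W1 = params[[paste0(nm, ".W1")]], b1 = params[[paste0(nm, ".b1")]],
       W2 = params[[paste0(nm, ".W2")]], b2 = params[[paste0(nm, ".b2")]],
       W3 = params[[paste0(nm, ".W3")]], b3 = params[[paste0(nm, ".b3")]],
       A1 = params[[paste0(nm, ".A1")]], A1b = params[[paste0(nm, ".A1b")]])
}

.BN_EPS <- 1e-5

# forward pass over a batch. inputs: list (length B) of named lists of
# matrices. training = TRUE uses batch statistics and dropout (drawing the
# mask from the R RNG); inference uses running statistics, no dropout.
.netForward <- function(net, inputs, training = FALSE) {
  branches <- names(net@inputShapes)
  B <- length(inputs)
  E <- matrix(0, .EMBED_DIM, B)
  bp <- lapply(branches, function(nm) .branchParams(net@params, nm))
  names(bp) <- branches
  for (s in seq_len(B))
    for (nm in branches)
      E[, s] <- E[, s] + .branchEmbed(inputs[[s]][[nm]], bp[[nm]])
  h <- pmax(E, 0)
  if (training) {
    mu <- rowMeans(h)
    va <- rowMeans((h - mu)^2)
  } else {
    mu <- net@bn$mean
    va <- net@bn$var
  }
  xhat <- (h - mu) / sqrt(va + .BN_EPS)
  y <- net@params$bnGamma * xhat + net@params$bnBeta
  if (training && net@dropoutRate > 0) {
    mask <- matrix((runif(.EMBED_DIM * B) >= net@dropoutRate) /
                     (1 - net@dropoutRate), .EMBED_DIM, B)
  } else mask <- NULL
  z <- if (is.null(mask)) y else y * mask
  a2 <- net@params$A2 %*% z + net@params$A2b
  yhat <- t(net@params$headsW) %*% a2 + net@params$headsb
  list(yhat = yhat, E = E, h = h, mu = mu, va = va,
       xhat = xhat, mask = mask, z = z, a2 = a2)
}

# backward pass for mean-squared-error loss over the 9 x B output block;
# returns the gradient list (same names as params)
.netBackward <- function(net, inputs, fwd, target) {
  B <- length(inputs)
  branches <- names(net@inputShapes)
  dyhat <- 2 * (fwd$yhat - target) / length(target)
  grads <- lapply(net@params, function(p) array(0, dim = dim(p) %||% length(p)))
  grads <- lapply(grads, function(g) if (length(dim(g)) == 1L) as.vector(g) else g)
  grads$headsW <- fwd$a2 %*% t(dyhat)
  grads$headsb <- rowSums(dyhat)
  da2 <- net@params$headsW %*% dyhat
  grads$A2 <- da2 %*% t(fwd$z)
  grads$A2b <- rowSums(da2)
  dz <- t(net@params$A2) %*% da2
  dy <- if (is.null(fwd$mask)) dz else dz * fwd$mask
  grads$bnGamma <- rowSums(dy * fwd$xhat)
  grads$bnBeta <- rowSums(dy)
  dxhat <- dy * net@params$bnGamma
  inv_sd <- 1 / sqrt(fwd$va + .BN_EPS)
  dh <- (inv_sd / B) * (B * dxhat - rowSums(dxhat) -
                          fwd$xhat * rowSums(dxhat * fwd$xhat))
  dE <- dh * (fwd$E > 0)
  bp <- lapply(branches, function(nm) .branchParams(net@params, nm))
  names(bp) <- branches
  for (s in seq_len(B)) {
    de <- dE[, s]
    for (nm in branches) {
      g <- .branchGrads(inputs[[s]][[nm]], bp[[nm]], de)
      for (fld in names(g)) {
        key <- paste0(nm, ".", fld)
        grads[[key]] <- grads[[key]] + g[[fld]]
      }
    }
  }
  grads
}

#' Predict gamma passing rates
#'
#' Deterministic inference-mode forward pass (dropout off, batch norm on its
#' running statistics). Inputs are normalized network images, one matrix per
#' branch of the variant.
#'
#' @param net a [GprNet-class].
#' @param inputs a named list of matrices (single plan) or a list of such
#'   lists (several plans).
#' @return numeric matrix `n x 9` of predicted GPRs in percent, columns
#'   named by criterion.
#' @export
predictGpr <- function(net, inputs) {
  if (!is.null(names(inputs)) && is.matrix(inputs[[1]]))
    inputs <- list(inputs)
  need <- names(net@inputShapes)
  for (s in seq_along(inputs)) {
    miss <- setdiff(need, names(inputs[[s]]))
    if (length(miss))
      stop("missing input branch(es): ", paste(miss, collapse = ", "))
    for (nm in need) {
      d <- dim(inputs[[s]][[nm]])
      if (!all(d == net@inputShapes[[nm]]))
        stop(sprintf("input '%s' has shape %d x %d, expected %d x %d",
                     nm, d[1], d[2], net@inputShapes[[nm]][1],
                     net@inputShapes[[nm]][2]))
    }
  }
  out <- t(.netForward(net, inputs, training = FALSE)$yhat) * 100
  colnames(out) <- net@criteria
  out
}
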