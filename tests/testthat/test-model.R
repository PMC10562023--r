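# network construction: shape conformance, parameter counts, prediction

# the reference per-branch feature-map sizes (rows x cols after each stage)
.tableShapes <- list(
  sagittal = list(conv1 = c(68, 146), pool1 = c(22, 48), conv2 = c(20, 46),
                  pool2 = c(6, 15), conv3 = c(4, 13), pool3 = c(1, 4)),
  coronal = list(conv1 = c(64, 200), pool1 = c(21, 66), conv2 = c(19, 64),
                 pool2 = c(6, 21), conv3 = c(4, 19), pool3 = c(1, 6)),
  axial = list(conv1 = c(143, 242), pool1 = c(47, 80), conv2 = c(45, 78),
               pool2 = c(15, 26), conv3 = c(13, 24), pool3 = c(4, 8)),
  mlpm = list(conv1 = c(110, 178), pool1 = c(36, 59), conv2 = c(34, 57),
              pool2 = c(11, 19), conv3 = c(9, 17), pool3 = c(3, 5)),
  surface = list(conv1 = c(220, 680), pool1 = c(73, 226), conv2 = c(71, 224),
                 pool2 = c(23, 74), conv3 = c(21, 72), pool3 = c(7, 24)))

test_that("branch shape arithmetic reproduces every reference stage size", {
  for (nm in names(.tableShapes)) {
    got <- branchShapes(.tableShapes[[nm]]$conv1)
    expect_equal(lapply(got, as.numeric), .tableShapes[[nm]],
                 info = nm)
  }
  expect_error(branchShapes(c(20, 50)), "incompatible")
})

test_that("layer parameter counts match the reference architecture", {
  net <- buildNetwork("model1")
  for (nm in c("sagittal", "coronal", "axial", "mlpm"))
    for (k in 1:3)
      expect_equal(countParameters(net, sprintf("%s.Convolution_%d", nm, k)),
                   if (k == 1L) 160L else 2320L)
  expect_equal(countParameters(net, "sagittal.Affine_1"), 1300L)
  expect_equal(countParameters(net, "coronal.Affine_1"), 1940L)
  expect_equal(countParameters(net, "axial.Affine_1"), 10260L)
  expect_equal(countParameters(net, "mlpm.Affine_1"), 4820L)
  expect_equal(countParameters(net, "Affine_2"), 420L)
  expect_equal(countParameters(net, "Affine_3"), 21L)
  expect_equal(countParameters(buildNetwork("model3"), "surface.Affine_1"),
               53780L)
  expect_error(countParameters(net, "no-such-layer"), "unknown layer")
})

test_that("variants carry the documented branch sets", {
  expect_named(buildNetwork("model1")@inputShapes,
               c("sagittal", "coronal", "axial", "mlpm"))
  expect_named(buildNetwork("model2")@inputShapes,
               c("sagittal", "coronal", "axial"))
  expect_named(buildNetwork("model3")@inputShapes, "surface")
})

test_that("inference is deterministic and finite, and shapes are enforced", {
  net <- buildNetwork("model3", seed = 3)
  x <- list(surface = matrix(0, 220, 680))
  p1 <- predictGpr(net, x)
  p2 <- predictGpr(net, x)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  expect_equal(dim(p1), c(1L, 9L))
  expect_error(predictGpr(net, list(surface = matrix(0, 10, 10))), "shape")
  expect_error(predictGpr(buildNetwork("model2"),
                          list(sagittal = matrix(0, 68, 146))), "missing input")
})

test_that("fused branch kernels agree with the layer-by-layer primitives", {
  set.seed(42)
  net <- buildNetwork("model1", inputShapes = smallShapes(), seed = 7)
  x <- matrix(runif(52 * 52), 52, 52)
  bp <- vmatqa:::.branchParams(net@params, "sagittal")
  e <- vmatqa:::.branchEmbed(x, bp)
  # recompute through the exported primitives
  a <- array(x, c(52, 52, 1))
  c1 <- vmatqa:::.conv2dForward(a, bp$W1, bp$b1, 1L)
  p1 <- vmatqa:::.maxpoolForward(c1)
  c2 <- vmatqa:::.conv2dForward(p1$y, bp$W2, bp$b2, 0L)
  p2 <- vmatqa:::.maxpoolForward(c2)
  c3 <- vmatqa:::.conv2dForward(p2$y, bp$W3, bp$b3, 0L)
  p3 <- vmatqa:::.maxpoolForward(c3)
  expect_equal(e, as.vector(bp$A1 %*% as.vector(p3$y)) + bp$A1b,
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through the whole network", {
  set.seed(13)
  shapes <- smallShapes()
  net <- buildNetwork("model1", inputShapes = shapes, dropoutRate = 0.3,
                      seed = 5)
  B <- 2L
  inputs <- lapply(seq_len(B), function(s)
    lapply(shapes, function(d) matrix(runif(prod(d)), d[1], d[2])))
  target <- matrix(runif(9 * B), 9, B)
  lossAt <- function(n) {
    set.seed(99) # replay the same dropout mask
    fwd <- vmatqa:::.netForward(n, inputs, training = TRUE)
    mean((fwd$yhat - target)^2)
  }
  set.seed(99)
  fwd <- vmatqa:::.netForward(net, inputs, training = TRUE)
  grads <- vmatqa:::.netBackward(net, inputs, fwd, target)
  eps <- 1e-6
  for (nm in c("sagittal.W1", "mlpm.W2", "axial.W3", "coronal.b2",
               "mlpm.A1", "A2", "headsW", "bnGamma", "bnBeta")) {
    p <- net@params[[nm]]
    for (i in sample(length(p), min(4L, length(p)))) {
      up <- net; up@params[[nm]][i] <- p[i] + eps
      dn <- net; dn@params[[nm]][i] <- p[i] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})
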