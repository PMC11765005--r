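test_that("forward pass composes layer maps", {
  idnet <- feedforward_net(layer_spec(diag(3)), layer_spec(diag(3)))
  expect_equal(ffn_forward(idnet, c(1, -2, 3))[[3]], c(1, -2, 3))
  bnet <- feedforward_net(layer_spec(matrix(0, 2, 3), c(1, -1), "tanh"))
  expect_equal(ffn_forward(bnet, rnorm(3))[[2]], tanh(c(1, -1)))
  # all-identity multilayer equals the single product matrix
  set.seed(41)
  W1 <- matrix(rnorm(12), 3); W2 <- matrix(rnorm(6), 2)
  net <- feedforward_net(layer_spec(W1), layer_spec(W2))
  x <- rnorm(4)
  expect_equal(ffn_forward(net, x)[[3]], as.numeric(W2 %*% W1 %*% x))
  expect_error(ffn_forward(net, rnorm(5)), "length 4")
  expect_error(feedforward_net(layer_spec(W2), layer_spec(W1)),
               "input dim")
})

test_that("transported generators match the chain rule and an FD oracle", {
  set.seed(42)
  T0 <- matrix(rnorm(16), 4)
  x0 <- rnorm(4)
  idnet <- feedforward_net(layer_spec(diag(4)), layer_spec(diag(4)))
  pg <- propagate_generator(idnet, T0, x0)
  expect_equal(pg$transported[[3]], T0)
  W <- matrix(rnorm(12), 3)
  one <- feedforward_net(layer_spec(W))
  expect_equal(propagate_generator(one, T0, x0)$transported[[2]],
               W %*% T0)
  # tanh Jacobian is diag(1 - tanh^2) at the pre-activation
  tnet <- feedforward_net(layer_spec(W, c(0.1, 0, -0.2), "tanh"))
  pre <- as.numeric(W %*% x0 + c(0.1, 0, -0.2))
  expect_equal(propagate_generator(tnet, T0, x0)$jacobians[[1]],
               1 - tanh(pre)^2)
  # oracle: transported tangent == d/deps of the layer activations
  for (seed in 1:4) {
    net <- random_net(c(5, 7, 6, 5), seed)
    set.seed(seed + 100)
    T0 <- matrix(rnorm(25), 5); x0 <- rnorm(5)
    pg <- propagate_generator(net, T0, x0)
    e <- 1e-5
    xs_p <- ffn_forward(net, x0 + e * (T0 %*% x0))
    xs_m <- ffn_forward(net, x0 - e * (T0 %*% x0))
    for (l in 2:4) {
      fd <- (xs_p[[l]] - xs_m[[l]]) / (2 * e)
      expect_lt(max(abs(fd - as.numeric(pg$transported[[l]] %*% x0))),
                1e-5)
    }
  }
})

test_that("invariance residuals certify null-space layers", {
  set.seed(43)
  # tangents spanning a 2-dim subspace of R^6
  tang <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:2] %*% matrix(rnorm(10), 2)
  ly <- construct_invariant_layer(tang, width = 3)
  expect_lt(max(abs(ly$W %*% tang)), 1e-10)
  expect_equal(qr(ly$W)$rank, 3)
  net <- feedforward_net(ly, layer_spec(matrix(rnorm(9), 3), 0, "tanh"))
  inputs <- matrix(rnorm(18), 6)
  rep_inv <- invariance_residual(net, inputs, tangents = tang[, 1:3])
  expect_lt(rep_inv$residual[1], 1e-8)
  expect_equal(attr(rep_inv, "first_satisfied"), 1L)
  # identity net: nothing annihilates the tangent
  idnet <- feedforward_net(layer_spec(diag(6)))
  T0 <- matrix(rnorm(36), 6)
  x <- rnorm(6)
  r <- invariance_residual(idnet, matrix(x), T0 = T0)
  expect_equal(r$residual[1], sqrt(sum((T0 %*% x)^2)))
  # absolute homogeneity in the generator
  r2 <- invariance_residual(idnet, matrix(x), T0 = 2 * T0)
  expect_equal(r2$residual, 2 * r$residual)
  expect_error(construct_invariant_layer(tang, width = 5),
               "complement")
})

test_that("equivariance residual is zero only for symmetric maps", {
  T0 <- matrix(c(0, 1, -1, 0), 2)
  idnet <- feedforward_net(layer_spec(diag(2)), layer_spec(diag(2)))
  x <- matrix(rnorm(6), 2)
  expect_equal(equivariance_residual(idnet, x, T0 = T0), 0)
  set.seed(44)
  gen <- feedforward_net(layer_spec(matrix(rnorm(4), 2)))
  expect_gt(equivariance_residual(gen, x, T0 = T0), 1e-4)
  tall <- feedforward_net(layer_spec(matrix(rnorm(6), 3)))
  expect_error(equivariance_residual(tall, x, T0 = T0), "autoencoder")
})

test_that("first-order check separates invariant from generic nets", {
  w <- small_world()
  thetas <- c(-0.4, 0.4)
  inputs <- t(orbit_sample(w, matrix(thetas, ncol = 1)))
  tangents <- sapply(thetas, function(th) orbit_tangent(w, th))
  inv_layer <- construct_invariant_layer(tangents, width = 20)
  set.seed(45)
  top <- layer_spec(matrix(rnorm(20 * 12, sd = 0.4), 12), 0, "tanh")
  invnet <- feedforward_net(inv_layer, top)
  r <- invariance_residual(invnet, inputs, tangents = tangents)
  expect_lt(r$residual[1], 1e-8)
  # walk the rendered orbit: the annihilated linear response leaves the
  # quadratic orbit remainder
  foc <- first_order_check(
    invnet, inputs[, 2],
    perturb = function(e) as.numeric(generate_frame(w, 0.4 + e)))
  expect_equal(foc$slope, 2, tolerance = 0.1)
  gen <- random_net(c(64, 30, 12), 46)
  foc2 <- first_order_check(
    gen, inputs[, 2],
    perturb = function(e) as.numeric(generate_frame(w, 0.4 + e)))
  expect_equal(foc2$slope, 1, tolerance = 0.1)
  # generator-matrix path: exact exponential orbit in input space
  T0 <- matrix(c(0, 1, -1, 0), 2)
  rotnet <- feedforward_net(layer_spec(diag(2)),
                            layer_spec(matrix(rnorm(4), 2), 0, "tanh"))
  foc3 <- first_order_check(rotnet, c(1, 0), T0 = T0)
  expect_equal(foc3$slope, 1, tolerance = 0.1)
  expect_error(first_order_check(gen, inputs[, 2],
                                 tangent = tangents[, 2],
                                 eps_grid = c(1e-3, 5e-4)), "decades")
})

test_that("networks round-trip through layered weight files", {
  net <- random_net(c(4, 5, 4), 47, acts = c("relu", "identity"))
  f <- withr::local_tempfile(fileext = ".net")
  write_ffn(net, f)
  back <- read_ffn(f)
  expect_equal(length(back$layers), 2)
  for (l in 1:2) {
    expect_equal(back$layers[[l]]$W, net$layers[[l]]$W)
    expect_equal(back$layers[[l]]$b, net$layers[[l]]$b)
    expect_identical(back$layers[[l]]$activation,
                     net$layers[[l]]$activation)
  }
})
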