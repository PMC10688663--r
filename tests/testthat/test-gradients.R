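# Finite-difference verification of every backward pass.  Each check
# perturbs a handful of randomly chosen coordinates and compares the
# analytic gradient against a central difference.

grad_probe <- function(fwd, bwd_grad, x, n_probe = 4, tol = 1e-6, seed = 99) {
  set.seed(seed)
  for (k in seq_len(n_probe)) {
    i <- sample(length(x), 1)
    num <- num_grad(fwd, x, i)
    expect_equal(bwd_grad[i], num, tolerance = tol)
  }
}

test_that("depthwise and dense convolution gradients are exact", {
  set.seed(10)
  x <- array(rnorm(6 * 8 * 3 * 2), c(6, 8, 3, 2))
  for (d in 1:3) {
    w <- array(rnorm(27), c(3, 3, 3))
    g <- array(rnorm(length(x)), dim(x))  # random upstream gradient
    fw <- lwseg:::nn_dwconv_fwd(x, w, d)
    bw <- lwseg:::nn_dwconv_bwd(fw, g)
    loss_x <- function(xx) sum(lwseg:::nn_dwconv_fwd(xx, w, d)$y * g)
    loss_w <- function(ww) sum(lwseg:::nn_dwconv_fwd(x, ww, d)$y * g)
    grad_probe(loss_x, bw$gx, x, seed = d)
    grad_probe(loss_w, bw$gw, w, seed = d + 50)
  }
  w2 <- array(rnorm(7 * 7 * 1 * 1), c(7, 7, 1, 1))
  x1 <- array(rnorm(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  g1 <- array(rnorm(length(x1) / 1), c(6, 6, 1, 2))
  fw <- lwseg:::nn_conv2d_fwd(x1, w2, b = 0.3)
  bw <- lwseg:::nn_conv2d_bwd(fw, g1)
  grad_probe(function(xx) sum(lwseg:::nn_conv2d_fwd(xx, w2, b = 0.3)$y * g1),
             bw$gx, x1)
  grad_probe(function(ww) sum(lwseg:::nn_conv2d_fwd(x1, ww, b = 0.3)$y * g1),
             bw$gw, w2)
})

test_that("pointwise convolution and SSPDC gradients are exact", {
  set.seed(11)
  x <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
  w <- matrix(rnorm(3 * 4), 3, 4)
  b <- rnorm(4)
  g <- array(rnorm(5 * 4 * 4 * 2), c(5, 4, 4, 2))
  fw <- lwseg:::nn_pwconv_fwd(x, w, b)
  bw <- lwseg:::nn_pwconv_bwd(fw, g)
  grad_probe(function(xx) sum(lwseg:::nn_pwconv_fwd(xx, w, b)$y * g), bw$gx, x)
  grad_probe(function(ww) sum(lwseg:::nn_pwconv_fwd(x, ww, b)$y * g), bw$gw, w)
  expect_equal(bw$gb, lwseg:::channel_sum(g, 20, 4, 2), tolerance = 1e-10)

  dw <- replicate(3, array(rnorm(27), c(3, 3, 3)), simplify = FALSE)
  pw <- matrix(rnorm(9 * 5), 9, 5)
  pb <- rnorm(5)
  gs <- array(rnorm(5 * 4 * 5 * 2), c(5, 4, 5, 2))
  fs <- lwseg:::nn_sspdc_fwd(x, dw[[1]], dw[[2]], dw[[3]], pw, pb)
  bs <- lwseg:::nn_sspdc_bwd(fs, gs)
  grad_probe(function(xx)
    sum(lwseg:::nn_sspdc_fwd(xx, dw[[1]], dw[[2]], dw[[3]], pw, pb)$y * gs),
    bs$gx, x)
  grad_probe(function(ww)
    sum(lwseg:::nn_sspdc_fwd(x, dw[[1]], dw[[2]], dw[[3]], ww, pb)$y * gs),
    bs$gpw, pw)
})

test_that("batch norm, pooling and bilinear gradients are exact", {
  set.seed(12)
  x <- array(rnorm(4 * 6 * 3 * 2), c(4, 6, 3, 2))
  gm <- rnorm(3) + 1; bt <- rnorm(3)
  g <- array(rnorm(length(x)), dim(x))
  fw <- lwseg:::nn_bn_fwd(x, gm, bt, TRUE, rep(0, 3), rep(1, 3))
  bw <- lwseg:::nn_bn_bwd(fw, g)
  f <- function(xx) sum(lwseg:::nn_bn_fwd(xx, gm, bt, TRUE, rep(0, 3), rep(1, 3))$y * g)
  grad_probe(f, bw$gx, x, tol = 1e-5)
  grad_probe(function(gg) sum(lwseg:::nn_bn_fwd(x, gg, bt, TRUE, rep(0, 3), rep(1, 3))$y * g),
             bw$ggamma, gm)

  # pooling: gradient routes to argmax only (ties absent with continuous data)
  fp <- lwseg:::nn_maxpool_fwd(x)
  gp <- array(rnorm(length(fp$y)), dim(fp$y))
  bp <- lwseg:::nn_maxpool_bwd(fp, gp)
  grad_probe(function(xx) sum(lwseg:::nn_maxpool_fwd(xx)$y * gp), bp$gx, x)

  fu <- lwseg:::nn_unpool_fwd(fp$y, fp$code)
  gu <- array(rnorm(length(fu$y)), dim(fu$y))
  bu <- lwseg:::nn_unpool_bwd(fu, gu)
  grad_probe(function(pp) sum(lwseg:::nn_unpool_fwd(pp, fp$code)$y * gu),
             bu$gx, fp$y)

  fb <- lwseg:::nn_bilinear2x_fwd(x)
  gb <- array(rnorm(length(fb$y)), dim(fb$y))
  bb <- lwseg:::nn_bilinear2x_bwd(fb, gb)
  grad_probe(function(xx) sum(lwseg:::nn_bilinear2x_fwd(xx)$y * gb), bb$gx, x)
})

test_that("LHA gradients are exact", {
  set.seed(13)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  ck <- rnorm(3); cb <- 0.2; sk <- matrix(rnorm(49), 7, 7); sb <- -0.1
  g <- array(rnorm(length(x)), dim(x))
  fw <- lwseg:::nn_lha_fwd(x, ck, cb, sk, sb)
  bw <- lwseg:::nn_lha_bwd(fw, g)
  grad_probe(function(xx) sum(lwseg:::nn_lha_fwd(xx, ck, cb, sk, sb)$y * g),
             bw$gx, x, tol = 1e-5)
  grad_probe(function(kk) sum(lwseg:::nn_lha_fwd(x, kk, cb, sk, sb)$y * g),
             bw$gck, ck)
  grad_probe(function(kk) sum(lwseg:::nn_lha_fwd(x, ck, cb, kk, sb)$y * g),
             bw$gsk, sk)
  expect_equal(num_grad(function(v) sum(lwseg:::nn_lha_fwd(x, ck, v, sk, sb)$y * g),
                        cb, 1), bw$gcb, tolerance = 1e-6)
  expect_equal(num_grad(function(v) sum(lwseg:::nn_lha_fwd(x, ck, cb, sk, v)$y * g),
                        sb, 1), bw$gsb, tolerance = 1e-6)
})

test_that("focal loss gradient matches finite differences", {
  set.seed(14)
  y <- rbinom(40, 1, 0.3)
  p <- runif(40, 0.05, 0.95)
  g <- lwseg:::wbce_focal_grad(y, p)
  for (i in sample(40, 6)) {
    num <- num_grad(function(pp) wbce_focal_loss(y, pp), p, i, eps = 1e-6)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
  # gamma = 0 edge case stays finite
  expect_true(all(is.finite(lwseg:::wbce_focal_grad(y, p, gamma = 0))))
})

test_that("end-to-end gradients are exact for both architectures", {
  set.seed(15)
  x <- array(rnorm(32 * 32 * 5 * 2), c(32, 32, 5, 2))
  y <- array(rbinom(32 * 32 * 2, 1, 0.3), c(32, 32, 2))
  for (arch in c("lw_segnet", "lw_unet")) {
    spec <- arch_spec(arch, widths = c(4, 6, 8, 10), input_size = 32)
    init <- lwseg:::lw_init_params(spec, seed = 1, input_size = 32)
    fw <- lwseg:::net_forward(init$plan, init$params, init$state, x, TRUE)
    gp <- array(lwseg:::wbce_focal_grad(y, fw$p), dim(fw$p))
    gr <- lwseg:::net_backward(init$plan, init$params, fw$caches, gp)
    f <- function(params)
      wbce_focal_loss(y, lwseg:::net_forward(init$plan, params, init$state,
                                             x, TRUE)$p)
    for (nm in sample(names(init$params), 4)) {
      pa <- init$params
      i <- sample(length(pa[[nm]]), 1)
      num <- num_grad(function(v) { pa[[nm]][i] <- v; f(pa) }, pa[[nm]][i], 1)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("%s %s[%d]", arch, nm, i))
    }
  }
})
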