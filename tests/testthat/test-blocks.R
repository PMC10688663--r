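# Building blocks: attention gates, SSPDC, pooling/unpooling, upsampling.

test_that("channel attention matches hand-evaluated cases and sigmoid bounds", {
  # all-zero input -> sigmoid(0) = 0.5 everywhere
  z <- array(0, c(4, 4, 5))
  expect_equal(channel_attention(z, lha_params(c(0.3, -1, 2), 0)),
               rep(0.5, 5))
  # band 1 constant 1, identity-centre kernel: max = avg = 1, logit 2
  x <- array(0, c(6, 6, 5)); x[, , 1] <- 1
  a <- channel_attention(x, lha_params(c(0, 1, 0), 0))
  expect_equal(a, c(1 / (1 + exp(-2)), 0.5, 0.5, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(a[1], 0.8807971, tolerance = 1e-6)
  # random input: length C, strictly inside (0, 1)
  set.seed(1)
  r <- array(rnorm(5 * 5 * 8), c(5, 5, 8))
  ar <- channel_attention(r, lha_params(rnorm(3), rnorm(1), matrix(rnorm(49), 7, 7)))
  expect_length(ar, 8)
  expect_true(all(ar > 0 & ar < 1))
})

test_that("spatial attention matches hand-evaluated cases and keeps shape", {
  p0 <- lha_params(spatial_kernel = matrix(rnorm(49), 7, 7))
  z <- array(0, c(5, 7, 3))
  expect_equal(spatial_attention(z, p0), matrix(0.5, 5, 7))
  # 1x1 spatial input, channels (2, 4); centre-tap kernel: sigmoid(4 + 3)
  k <- matrix(0, 7, 7); k[4, 4] <- 1
  x <- array(c(2, 4), c(1, 1, 2))
  expect_equal(spatial_attention(x, lha_params(spatial_kernel = k))[1, 1],
               1 / (1 + exp(-7)), tolerance = 1e-12)
  expect_equal(spatial_attention(x, lha_params(spatial_kernel = k))[1, 1],
               0.9990889, tolerance = 1e-6)
  # same-padding contract
  set.seed(2)
  r <- array(rnorm(9 * 12 * 4), c(9, 12, 4))
  expect_identical(dim(spatial_attention(r, p0)), c(9L, 12L))
})

test_that("apply_lha composes both gates multiplicatively", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  zerop <- lha_params(c(0, 0, 0), 0, matrix(0, 7, 7), 0)
  # both gates uniformly 0.5 -> 0.25 * input
  expect_equal(apply_lha(x, zerop), 0.25 * x, tolerance = 1e-12)
  # shape preserved; zero input stays zero
  p <- lha_params(rnorm(3), 0.2, matrix(rnorm(49), 7, 7), -0.1)
  expect_identical(dim(apply_lha(x, p)), dim(x))
  expect_equal(apply_lha(array(0, dim(x)), p), array(0, dim(x)))
  # gates in (0,1) never increase any activation's magnitude
  expect_true(all(abs(apply_lha(x, p)) <= abs(x)))
  # explicit composition identity
  ca <- channel_attention(x, p); sa <- spatial_attention(x, p)
  expect_equal(apply_lha(x, p), x * rep(ca, each = 64) * as.vector(sa),
               tolerance = 1e-12)
})

test_that("attention operations reject non-finite input", {
  x <- array(1, c(4, 4, 2)); x[2, 2, 1] <- NaN
  expect_error(channel_attention(x), "non-finite")
  expect_error(spatial_attention(x), "non-finite")
  expect_error(apply_lha(x), "non-finite")
})

test_that("SSPDC preserves shape, passes through identity kernels, maps channels", {
  set.seed(4)
  x <- array(rnorm(10 * 12 * 5), c(10, 12, 5))
  # identity branches + averaging pointwise -> exact pass-through
  expect_equal(sspdc_forward(x, sspdc_params(5)), x, tolerance = 1e-12)
  # constant input -> spatially constant away from borders (here: centre tap
  # kernels make it constant everywhere)
  cst <- array(2, c(8, 8, 3))
  out <- sspdc_forward(cst, sspdc_params(3))
  expect_equal(out, cst, tolerance = 1e-12)
  # channel contract: C_in = 5 -> C_out = 8, spatial shape kept
  p <- sspdc_params(5, 8,
                    dw = replicate(3, array(rnorm(45), c(3, 3, 5)),
                                   simplify = FALSE),
                    pw = matrix(rnorm(15 * 8), 15, 8), bias = rnorm(8))
  y <- sspdc_forward(x, p)
  expect_identical(dim(y), c(10L, 12L, 8L))
  # channel mismatch is a configuration error
  expect_error(sspdc_forward(array(0, c(4, 4, 3)), p), "channels")
})

test_that("max pooling matches the exhaustive window oracle and breaks ties row-major", {
  expect_equal(maxpool_with_indices(matrix(c(1, 3, 2, 4), 2))$values[1, 1, 1], 4)
  mp <- maxpool_with_indices(matrix(c(1, 3, 2, 4), 2))
  expect_equal(c(mp$indices$row[1, 1, 1], mp$indices$col[1, 1, 1]), c(1L, 1L))
  # all-equal window: first occurrence in row-major order -> (0, 0)
  tie <- maxpool_with_indices(matrix(5, 2, 2))
  expect_equal(tie$values[1, 1, 1], 5)
  expect_equal(c(tie$indices$row[1, 1, 1], tie$indices$col[1, 1, 1]), c(0L, 0L))
  # random grids up to 32x32 against the brute-force oracle
  set.seed(5)
  for (n in c(8L, 16L, 32L)) {
    m <- matrix(sample(1:9, n * n, replace = TRUE), n)  # many ties
    got <- maxpool_with_indices(m)
    expect_equal(got$values[, , 1], oracle_maxpool(m))
    # stored positions must index the pooled value on the pre-pool grid
    for (i in seq_len(n / 2)) for (j in seq_len(n / 2)) {
      expect_equal(m[got$indices$row[i, j, 1] + 1, got$indices$col[i, j, 1] + 1],
                   got$values[i, j, 1])
    }
  }
  expect_error(maxpool_with_indices(matrix(0, 3, 4)), "even")
})

test_that("unpooling is the sparse inverse of pooling", {
  up <- max_unpool(matrix(4), list(row = matrix(1L), col = matrix(1L)))
  expect_equal(up[, , 1], matrix(c(0, 0, 0, 4), 2))
  set.seed(6)
  # non-negative activations, as produced by the ReLU stages that feed the
  # pooling layers (the sparse round trip zero-fills, so it inverts pooling
  # exactly on non-negative maps)
  x <- array(abs(rnorm(16 * 16 * 3)), c(16, 16, 3))
  mp <- maxpool_with_indices(x)
  up <- max_unpool(mp$values, mp$indices)
  # nonzeros exactly at argmax positions, pool o unpool is the identity
  expect_equal(sum(up != 0), length(mp$values))
  expect_equal(maxpool_with_indices(up)$values, mp$values)
  # composing pool then unpool restores H x W
  expect_identical(dim(up), dim(x))
  # an out-of-window index is rejected
  bad <- mp$indices; bad$row[1, 1, 1] <- 5L
  expect_error(max_unpool(mp$values, bad), "window")
})

test_that("bilinear 2x upsampling follows the half-pixel convention", {
  # constants are preserved at double size
  expect_equal(bilinear_upsample2x(matrix(3, 4, 4)),
               array(3, c(8, 8, 1)), tolerance = 1e-12)
  # 1x1 input extrapolates its single sample
  expect_equal(bilinear_upsample2x(matrix(7)), array(7, c(2, 2, 1)))
  # 1-D ramp (0, 1): closed-form weights of the half-pixel convention
  ramp <- matrix(c(0, 1), 1, 2)
  expect_equal(as.vector(bilinear_upsample2x(ramp)[1, , 1]),
               c(0, 0.25, 0.75, 1), tolerance = 1e-12)
  # round trip of shapes with pooling
  set.seed(7)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  expect_identical(dim(bilinear_upsample2x(maxpool_with_indices(x)$values)),
                   dim(x))
})

test_that("block operations are deterministic", {
  set.seed(8)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  p <- lha_params(rnorm(3), 0.3, matrix(rnorm(49), 7, 7), -0.2)
  sp <- sspdc_params(4, 6, dw = replicate(3, array(rnorm(36), c(3, 3, 4)),
                                          simplify = FALSE),
                     pw = matrix(rnorm(12 * 6), 12, 6), bias = rnorm(6))
  expect_identical(apply_lha(x, p), apply_lha(x, p))
  expect_identical(sspdc_forward(x, sp), sspdc_forward(x, sp))
  expect_identical(bilinear_upsample2x(x), bilinear_upsample2x(x))
  expect_identical(maxpool_with_indices(x), maxpool_with_indices(x))
})
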