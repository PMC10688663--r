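# Radiometric conversion, tiling, splitting, augmentation and tile I/O.

test_that("radiometric conversion is the per-band affine map", {
  expect_equal(to_radiance(matrix(200, 2, 2), gain = 0.5, bias = 3),
               matrix(103, 2, 2))
  x <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(to_radiance(x, gain = rep(1, 3), bias = rep(0, 3)), x)
  g <- c(0.1, 0.2, 0.3); b <- c(1, -1, 0.5)
  a2 <- array(runif(length(x)), dim(x))
  # affine property: L(a + b) + L(0) = L(a) + L(b)
  expect_equal(to_radiance(x + a2, g, b) + to_radiance(x * 0, g, b),
               to_radiance(x, g, b) + to_radiance(a2, g, b), tolerance = 1e-12)
  expect_error(to_radiance(x, gain = c(1, 2)), "gains")
})

test_that("tile origins follow floor division on the scene size", {
  expect_equal(nrow(tile_origins(c(1024, 1024), 512)), 4)
  expect_equal(nrow(tile_origins(c(8076, 27058), 512)), 15 * 52)
  org <- tile_origins(c(1100, 1700), 512)
  expect_true(all(org$row0 %% 512 == 0) && all(org$col0 %% 512 == 0))
  expect_error(tile_origins(c(100, 800), 512), "smaller than one tile")
  # mirror policy covers the whole scene
  expect_equal(nrow(tile_origins(c(1100, 1700), 512, "mirror")), 3 * 4)
})

test_that("tiling cuts aligned records and mosaicking restores the covered region", {
  set.seed(50)
  img <- array(runif(96 * 130 * 5), c(96, 130, 5))
  sm <- matrix(rbinom(96 * 130, 1, 0.2), 96)
  rm_ <- matrix(rbinom(96 * 130, 1, 0.3), 96)
  recs <- tile_scene(img, sm, rm_, tile = 32, scene = "sc1")
  expect_length(recs, 3 * 4)
  rebuilt <- array(NA_real_, c(96, 128, 5))
  for (r in recs) {
    expect_true(all(r$origin %% 32 == 0))
    ri <- r$origin[1] + 1:32; ci <- r$origin[2] + 1:32
    rebuilt[ri, ci, ] <- r$image
    expect_equal(r$stand_mask, sm[ri, ci])
    expect_equal(r$row_mask, rm_[ri, ci])
  }
  expect_equal(rebuilt, img[, 1:128, ])
  expect_error(tile_scene(array(0, c(16, 16, 5)), tile = 32), "smaller")
})

test_that("split counts use round-half-up with the test remainder", {
  s <- split_dataset(sprintf("t%04d", 1:3800), seed = 3)
  expect_equal(as.vector(table(s$split)[c("train", "validation", "test")]),
               c(2280, 380, 1140))
  s10 <- split_dataset(letters[1:10], seed = 1)
  expect_equal(as.vector(table(s10$split)[c("train", "validation", "test")]),
               c(6, 1, 3))
  # N = 35: round-half-up gives 21 train (0.6*35 = 21), 4 validation
  # (0.1*35 = 3.5 -> 4), 10 test
  s35 <- split_dataset(sprintf("x%02d", 1:35), seed = 1)
  expect_equal(as.vector(table(s35$split)[c("train", "validation", "test")]),
               c(21, 4, 10))
  expect_error(split_dataset(letters[1:20], ratios = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(split_dataset(letters[1:5]), "at least 10")
})

test_that("splits are seeded, disjoint, covering, and stratified per scene", {
  ids <- sprintf("t%03d", 1:100)
  a <- split_dataset(ids, seed = 42)
  b <- split_dataset(ids, seed = 42)
  expect_identical(a, b)
  c_ <- split_dataset(ids, seed = 43)
  expect_false(identical(a$split, c_$split))
  expect_identical(sort(a$id), sort(ids))
  expect_equal(as.vector(table(c_$split)[c("train", "validation", "test")]),
               c(60, 10, 30))
  # stratified: each scene independently 6:1:3
  strata <- rep(c("A", "B"), c(40, 60))
  st <- split_dataset(ids, seed = 7, strata = strata)
  expect_equal(as.vector(table(st$split[strata == "A"])[c("train", "validation", "test")]),
               c(24, 4, 12))
  expect_equal(as.vector(table(st$split[strata == "B"])[c("train", "validation", "test")]),
               c(36, 6, 18))
})

test_that("augmentation ops are involutive/cyclic and preserve mask alignment", {
  set.seed(51)
  rec <- tile_scene(array(runif(32 * 32 * 5), c(32, 32, 5)),
                    matrix(rbinom(1024, 1, 0.3), 32),
                    matrix(rbinom(1024, 1, 0.4), 32), tile = 32)[[1]]
  h2 <- augment(augment(rec, "hflip")[[1]], "hflip")[[1]]
  expect_equal(h2$image, rec$image)
  expect_equal(h2$stand_mask, rec$stand_mask)
  v2 <- augment(augment(rec, "vflip")[[1]], "vflip")[[1]]
  expect_equal(v2$image, rec$image)
  r4 <- rec
  for (i in 1:4) r4 <- augment(r4, "rot90")[[1]]
  expect_equal(r4$image, rec$image)
  expect_equal(r4$row_mask, rec$row_mask)
  # rot180 equals two rot90s
  expect_equal(augment(rec, "rot180")[[1]]$image,
               augment(augment(rec, "rot90")[[1]], "rot90")[[1]]$image)
  # flips and right-angle rotations never change the foreground count
  for (op in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    a <- augment(rec, op)[[1]]
    expect_equal(sum(a$stand_mask), sum(rec$stand_mask), label = op)
    expect_true(all(a$stand_mask %in% c(0, 1)))
  }
  # a k-op plan yields k aligned records; resample keeps masks binary
  plan <- list("hflip", list(op = "resample", factor = 1.2), "rot270",
               list(op = "resample", factor = 0.85))
  out <- augment(rec, plan, seed = 9)
  expect_length(out, 4)
  for (o in out) {
    expect_identical(dim(o$image), dim(rec$image))
    expect_true(all(o$stand_mask %in% c(0, 1)))
    expect_true(all(o$row_mask %in% c(0, 1)))
  }
  expect_error(augment(rec, "shear"), "unknown")
})

test_that("tile datasets round-trip through TIFF/PNG plus manifest", {
  set.seed(52)
  recs <- easy_synth_records(4, size = 32, seed = 52)
  # pad with dummy ids so the split has >= 10 entries, then assign
  asg <- split_dataset(c(vapply(recs, `[[`, "", "id"), paste0("pad", 1:6)),
                       seed = 1)
  recs <- assign_split(recs, asg)
  dir <- file.path(tempdir(), "lwseg-io-test")
  unlink(dir, recursive = TRUE)
  manifest <- write_tile_dataset(recs, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_tile_dataset(dir)
  expect_length(back, 4)
  for (i in seq_along(recs)) {
    j <- which(vapply(back, `[[`, "", "id") == recs[[i]]$id)
    expect_length(j, 1)
    expect_equal(back[[j]]$image, recs[[i]]$image, tolerance = 1e-6)  # float32
    expect_equal(back[[j]]$stand_mask, recs[[i]]$stand_mask)
    expect_equal(back[[j]]$row_mask, recs[[i]]$row_mask)
    expect_equal(back[[j]]$split, recs[[i]]$split)
  }
  test_only <- read_tile_dataset(dir, split = "test")
  expect_true(all(vapply(test_only, `[[`, "", "split") == "test"))
})
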