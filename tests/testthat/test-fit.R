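# Training orchestration: reproducibility, run logs, evaluation,
# checkpoints, and configuration handling.

small_fit <- function(seed = 1, epochs = 3, records = NULL) {
  records <- records %||% easy_synth_records(8, size = 32, seed = 60)
  lw_fit(records, architecture = "lw_unet", widths = c(4, 6, 8, 10),
         epochs = epochs, batch_size = 4, lr = 1e-3, seed = seed)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("training is reproducible from (config, seed)", {
  m1 <- small_fit(seed = 5)
  m2 <- small_fit(seed = 5)
  expect_equal(m1$history$train_loss, m2$history$train_loss, tolerance = 1e-12)
  expect_identical(m1$config_hash, m2$config_hash)
  m3 <- small_fit(seed = 6)
  expect_false(isTRUE(all.equal(m1$history$train_loss, m3$history$train_loss)))
})

test_that("the run log has one row per epoch with monotone indices", {
  m <- small_fit(epochs = 4)
  expect_equal(nrow(m$history), 4)
  expect_equal(m$history$epoch, 1:4)
  expect_true(all(diff(m$history$step) > 0))
  expect_true(all(is.finite(m$history$train_loss)))
})

test_that("training loss trends downward over the first epochs", {
  recs <- easy_synth_records(16, size = 32, seed = 61)
  m <- lw_fit(recs, architecture = "lw_unet", widths = c(4, 6, 8, 10),
              epochs = 6, batch_size = 8, lr = 3e-3, seed = 2)
  l <- m$history$train_loss
  ma <- stats::filter(l, rep(1 / 3, 3), sides = 1)[3:6]  # 3-epoch moving average
  expect_true(all(diff(ma) < 0))
})

test_that("validation monitoring and empty-partition errors work", {
  recs <- easy_synth_records(10, size = 32, seed = 62)
  asg <- split_dataset(vapply(recs, `[[`, "", "id"), seed = 1)
  recs <- assign_split(recs, asg)
  m <- lw_fit(recs, architecture = "lw_unet", widths = c(4, 6, 8, 10),
              epochs = 2, batch_size = 4, lr = 1e-3, seed = 3)
  expect_true(all(is.finite(m$history$val_loss)))
  expect_true(all(m$history$val_iou >= 0 & m$history$val_iou <= 1))
  only_val <- Filter(function(r) r$split == "validation", recs)
  expect_error(lw_fit(only_val, widths = c(4, 6, 8, 10)), "no training tiles")
})

test_that("evaluation is self-consistent and pools counts additively", {
  recs <- easy_synth_records(6, size = 32, seed = 63)
  m <- small_fit(records = recs, epochs = 2)
  # score the model against its own thresholded predictions -> all metrics 1
  pm <- predict(m, recs, type = "mask")
  self_rec <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]; r$stand_mask <- pm[, , i]; r
  })
  rep_self <- lw_evaluate(m, self_rec)
  expect_equal(unlist(rep_self[c("precision", "recall", "iou", "f1",
                                 "overall_accuracy", "miou")]),
               c(precision = 1, recall = 1, iou = 1, f1 = 1,
                 overall_accuracy = 1, miou = 1))
  # pooled counts equal the sum of per-tile counts
  micro <- lw_evaluate(m, recs)
  counts <- attr(micro, "counts")
  per_tile <- lapply(seq_along(recs), function(i)
    confusion(pm[, , i], recs[[i]]$stand_mask))
  pooled <- Reduce(`+`, per_tile)
  expect_equal(unclass(counts), unclass(pooled))
})

test_that("predict handles records, arrays and single tiles consistently", {
  recs <- easy_synth_records(3, size = 32, seed = 64)
  m <- small_fit(records = recs, epochs = 1)
  p_list <- predict(m, recs)
  p_arr <- predict(m, lwseg:::records_to_arrays(recs, "stand")$x)
  expect_equal(p_list, p_arr)
  p_one <- predict(m, recs[[1]])
  expect_equal(p_one, p_arr[, , 1])
  expect_equal(forward_segment(m, recs[[1]]$image), p_one)
  mk <- predict(m, recs[[1]], type = "mask")
  expect_true(all(mk %in% c(0, 1)))
  expect_equal(mk, (p_one >= 0.5) * 1)
})

test_that("checkpoints round-trip exactly", {
  recs <- easy_synth_records(4, size = 32, seed = 65)
  m <- small_fit(records = recs, epochs = 1)
  path <- tempfile(fileext = ".rds")
  lw_save(m, path)
  m2 <- lw_load(path)
  expect_identical(class(m2), "lwseg")
  expect_equal(predict(m2, recs[[2]]), predict(m, recs[[2]]))
  expect_identical(m2$spec$widths, m$spec$widths)
  expect_identical(m2$config_hash, m$config_hash)
})

test_that("train configs validate and round-trip through YAML", {
  cfg <- train_config(architecture = "lw_segnet", task = "row",
                      widths = c(4, 6, 8, 10), epochs = 2, batch_size = 4,
                      learning_rate = 1e-3, seed = 9)
  expect_s3_class(cfg, "train_config")
  expect_equal(cfg$loss$alpha, 0.25)
  expect_error(train_config(architecture = "vgg16"), "architecture")
  expect_error(train_config(learning_rate = 0))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(architecture = "lw_segnet", task = "row",
                        widths = c(4, 6, 8, 10), epochs = 2, batch_size = 4,
                        learning_rate = 0.001,
                        loss = list(alpha = 0.3, gamma = 1), seed = 9), path)
  back <- read_train_config(path)
  expect_equal(back$architecture, "lw_segnet")
  expect_equal(back$loss$alpha, 0.3)
  expect_equal(back$loss$gamma, 1)
  # defaults fill unstated fields
  yaml::write_yaml(list(architecture = "lw_unet"), path)
  d <- read_train_config(path)
  expect_equal(d$epochs, 50L)
  expect_equal(d$batch_size, 32L)
  expect_equal(d$learning_rate, 1e-4)
})

test_that("the simulate-train-evaluate pipeline runs end to end from disk", {
  dir <- file.path(tempdir(), "lwseg-e2e")
  unlink(dir, recursive = TRUE)
  cfg <- field_sim_config(size = 32, seed = 8, noise_sd = 0.005,
                          glint_rate = 0)
  lw_simulate(cfg, 12, dir, regime = "medium", seed = 4)
  ck <- tempfile(fileext = ".rds")
  tc <- train_config(architecture = "lw_unet", widths = c(4, 6, 8, 10),
                     epochs = 2, batch_size = 4, learning_rate = 1e-3,
                     seed = 5, manifest = dir, checkpoint = ck)
  m <- lw_train(tc)
  expect_true(file.exists(ck))
  recs <- read_tile_dataset(dir, split = "test")
  rep_ <- lw_evaluate(lw_load(ck), recs)
  expect_s3_class(rep_, "metric_report")
  expect_true(all(unlist(rep_) >= 0 & unlist(rep_) <= 1))
})

test_that("model object prints, summarizes and exposes coefficients", {
  m <- small_fit(epochs = 1)
  expect_output(print(m), "lw_unet")
  expect_output(print(summary(m)), "analytic parameters")
  cf <- coef(m)
  expect_true(is.list(cf) && length(cf) > 100)
  expect_identical(lwseg:::param_tally(cf),
                   as.integer(count_parameters(m$spec)$parameters))
})
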