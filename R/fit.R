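# Model fitting: Adam training of an architecture on tile records under the
# focal-weighted BCE objective, plus the standard S3 methods on the fitted
# object ("lwseg").

#' @keywords internal
records_to_arrays <- function(records, task = c("stand", "row")) {
  task <- match.arg(task)
  stopifnot(length(records) >= 1L)
  d <- dim(records[[1]]$image)
  x <- array(0, c(d[1], d[2], d[3], length(records)))
  y <- array(0, c(d[1], d[2], length(records)))
  field <- if (task == "stand") "stand_mask" else "row_mask"
  for (i in seq_along(records)) {
    di <- dim(records[[i]]$image)
    if (!all(di == d)) stop("tile ", records[[i]]$id, ": shape mismatch")
    x[, , , i] <- records[[i]]$image
    y[, , i] <- records[[i]][[field]]
  }
  list(x = x, y = y)
}

#' @keywords internal
adam_step <- function(params, grads, mstate, vstate, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
    vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (mstate[[nm]] / bc1) / (sqrt(vstate[[nm]] / bc2) + eps)
  }
  list(params = params, m = mstate, v = vstate)
}

#' Fit a lightweight segmentation network
#'
#' Trains LW-Segnet or LW-Unet on a set of tile records by minimizing the
#' focal-weighted binary cross-entropy with Adam.  All randomness (weight
#' initialization, epoch shuffling) derives from `seed`, so runs are
#' reproducible bit-for-bit.
#'
#' @param records list of tile records (from [make_dataset()],
#'   [tile_scene()] or [read_tile_dataset()]) with `split` fields; records
#'   marked `"train"` are trained on and `"validation"` monitored.  Records
#'   with split `"unassigned"` count as training data.
#' @param architecture `"lw_segnet"` or `"lw_unet"`, or an [arch_spec()].
#' @param task which mask to learn: `"stand"` (seedling stands) or `"row"`
#'   (seedling rows).
#' @param widths per-stage channel widths when `architecture` is a name;
#'   small ladders (e.g. `c(8, 16, 24, 32)`) train in minutes on a CPU.
#' @param epochs training epochs (the field protocol uses 50).
#' @param batch_size minibatch size (field protocol: 32).
#' @param lr Adam learning rate (field protocol: 1e-4).
#' @param loss a [loss_config()] (alpha = 0.25, gamma = 2 by default).
#' @param seed integer seed controlling init and shuffling.
#' @param stop_train_iou optional early-stop: end training once the
#'   thresholded training IoU reaches this value (checked every
#'   `iou_check_every` steps).
#' @param iou_check_every step interval for the early-stop check.
#' @param verbose print one line per epoch.
#' @return An object of class `"lwseg"` with the trained parameters, the
#'   architecture spec, the loss configuration and a per-epoch run log
#'   (`history`).
#' @seealso [predict.lwseg()], [lw_evaluate()], [lw_save()]
#' @export
lw_fit <- function(records, architecture = c("lw_unet", "lw_segnet"),
                   task = c("stand", "row"), widths = NULL, epochs = 50L,
                   batch_size = 32L, lr = 1e-4, loss = loss_config(),
                   seed = 1L, stop_train_iou = NULL, iou_check_every = 10L,
                   verbose = FALSE) {
  task <- match.arg(task)
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 1L,
            inherits(loss, "loss_config"))
  train_rec <- Filter(function(r) r$split %in% c("train", "unassigned"), records)
  val_rec <- Filter(function(r) r$split == "validation", records)
  if (length(train_rec) < 1L) stop("no training tiles in `records`")
  d <- dim(train_rec[[1]]$image)
  spec <- if (inherits(architecture, "lwseg_arch")) architecture
          else arch_spec(match.arg(architecture), widths = widths,
                         input_channels = d[3], input_size = d[1])
  if (d[1] != d[2] || d[1] %% 16L != 0L)
    stop("tiles must be square with size divisible by 16")
  if (d[3] != spec$input_channels)
    stop(sprintf("tiles have %d bands but the spec expects %d",
                 d[3], spec$input_channels))

  tr <- records_to_arrays(train_rec, task)
  va <- if (length(val_rec)) records_to_arrays(val_rec, task) else NULL
  n_train <- length(train_rec)

  init <- lw_init_params(spec, seed = derive_seed(seed, 0L), input_size = d[1])
  plan <- init$plan
  params <- init$params
  state <- init$state
  mstate <- lapply(params, function(p) p * 0)
  vstate <- mstate
  tstep <- 0L
  history <- NULL
  stopped <- FALSE

  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample.int(n_train))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n_train, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n_train)]
      xb <- tr$x[, , , idx, drop = FALSE]
      yb <- tr$y[, , idx, drop = FALSE]
      fw <- net_forward(plan, params, state, xb, training = TRUE)
      state <- fw$state
      p <- fw$p
      lo <- wbce_focal_loss(yb, p, cfg = loss)
      if (!is.finite(lo))
        stop("non-finite training loss at epoch ", ep,
             " (step ", tstep + 1L, "); try a lower learning rate")
      gp <- array(wbce_focal_grad(yb, p, loss$alpha, loss$gamma, loss$eps),
                  dim(p))
      grads <- net_backward(plan, params, fw$caches, gp)
      tstep <- tstep + 1L
      upd <- adam_step(params, grads, mstate, vstate, tstep, lr)
      params <- upd$params; mstate <- upd$m; vstate <- upd$v
      ep_loss <- ep_loss + lo
      nb <- nb + 1L
      if (!is.null(stop_train_iou) && tstep %% iou_check_every == 0L) {
        iou <- batch_iou(plan, params, state, tr$x, tr$y)
        if (iou >= stop_train_iou) { stopped <- TRUE; break }
      }
    }
    train_iou <- batch_iou(plan, params, state, tr$x, tr$y)
    val_loss <- NA_real_; val_iou <- NA_real_
    if (!is.null(va)) {
      pv <- net_forward(plan, params, state, va$x, training = FALSE)$p
      val_loss <- wbce_focal_loss(va$y, pv, cfg = loss)
      val_iou <- seg_metrics(confusion((pv >= 0.5) * 1, va$y))$iou
    }
    history <- rbind(history,
                     data.frame(epoch = ep, step = tstep,
                                train_loss = ep_loss / nb,
                                train_iou = train_iou,
                                val_loss = val_loss, val_iou = val_iou))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  train IoU %.3f%s", ep,
                      ep_loss / nb, train_iou,
                      if (!is.null(va)) sprintf("  val IoU %.3f", val_iou) else ""))
    if (stopped) break
  }

  structure(list(spec = spec, task = task, params = params, state = state,
                 plan = plan, loss = loss, seed = as.integer(seed),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs_run = nrow(history), steps_run = tstep,
                 history = history,
                 config_hash = config_hash(spec, task, lr, batch_size, seed)),
            class = "lwseg")
}

#' @keywords internal
batch_iou <- function(plan, params, state, x, y) {
  p <- net_forward(plan, params, state, x, training = FALSE)$p
  seg_metrics(confusion((p >= 0.5) * 1, y))$iou
}

# Short fingerprint of the run configuration, embedded in logs/checkpoints.
#' @keywords internal
config_hash <- function(spec, task, lr, batch_size, seed) {
  s <- paste(spec$name, paste(spec$widths, collapse = ","), task, lr,
             batch_size, seed, sep = "|")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 4294967291)
}

#' Pixel-wise foreground probabilities for new tiles
#'
#' Runs the fitted network in inference mode (batch-norm running
#' statistics) and returns per-pixel foreground probabilities, or the
#' thresholded binary mask (`p >= 0.5`).
#'
#' @param object a fitted `"lwseg"` model.
#' @param newdata a tile record, a list of tile records, an H x W x C
#'   array (single tile) or an H x W x C x N batch.
#' @param type `"prob"` or `"mask"`.
#' @param batch_size tiles per forward pass.
#' @param ... unused.
#' @return An H x W matrix for a single tile, else an H x W x N array.
#' @export
predict.lwseg <- function(object, newdata, type = c("prob", "mask"),
                          batch_size = 8L, ...) {
  type <- match.arg(type)
  single <- FALSE
  if (inherits(newdata, "tile_record")) { newdata <- list(newdata) }
  if (is.list(newdata)) {
    x <- records_to_arrays(newdata, object$task)$x
    single <- length(newdata) == 1L
  } else if (is.array(newdata) && length(dim(newdata)) == 3L) {
    x <- array(newdata, c(dim(newdata), 1L)); single <- TRUE
  } else if (is.array(newdata) && length(dim(newdata)) == 4L) {
    x <- newdata
  } else stop("`newdata` must be tile records or an image array")
  d <- dim(x)
  if (d[3] != object$spec$input_channels)
    stop(sprintf("expected %d bands, got %d", object$spec$input_channels, d[3]))
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input size must be divisible by 16")
  N <- d[4]
  out <- array(0, c(d[1], d[2], N))
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    out[, , idx] <- net_forward(object$plan, object$params, object$state,
                                x[, , , idx, drop = FALSE],
                                training = FALSE)$p
  }
  if (type == "mask") out <- (out >= 0.5) * 1
  if (single) out <- out[, , 1] else out
}

#' Segment one tile into a foreground probability map
#'
#' Functional form of [predict.lwseg()] for a single tile.
#'
#' @param model a fitted `"lwseg"` model.
#' @param tile an H x W x C array (H, W divisible by 16).
#' @return H x W matrix of foreground probabilities in [0, 1].
#' @export
forward_segment <- function(model, tile) {
  stopifnot(inherits(model, "lwseg"))
  predict(model, tile, type = "prob")
}

#' @export
print.lwseg <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<lwseg> %s (%s task)  widths %s  %d params\n",
              x$spec$name, x$task, paste(x$spec$widths, collapse = "/"),
              param_tally(x$params)))
  cat(sprintf("  trained %d epochs (%d steps), final loss %.5f, train IoU %.3f\n",
              x$epochs_run, x$steps_run, h$train_loss, h$train_iou))
  cat(sprintf("  config %s  seed %d\n", x$config_hash, x$seed))
  invisible(x)
}

#' @export
summary.lwseg <- function(object, ...) {
  prof <- lw_profile(object$spec, input_size = object$spec$input_size)
  out <- list(model = object, profile = prof,
              tally = param_tally(object$params))
  class(out) <- "summary.lwseg"
  out
}

#' @export
print.summary.lwseg <- function(x, ...) {
  print(x$model)
  cat(sprintf("  analytic parameters %s (tally %s), %.1f GFLOPs @ %d\n",
              format(x$profile$parameters, big.mark = ","),
              format(x$tally, big.mark = ","), x$profile$gflops,
              x$profile$input_size))
  invisible(x)
}

#' @export
coef.lwseg <- function(object, ...) object$params

#' Training-history plot
#'
#' Loss (and IoU when available) against epoch.
#'
#' @param x a fitted `"lwseg"` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lwseg <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = x$spec$name, ...)
  graphics::plot(h$epoch, h$train_iou, type = "l", xlab = "epoch",
                 ylab = "IoU", ylim = c(0, 1), main = "train / validation IoU")
  if (any(is.finite(h$val_iou)))
    graphics::lines(h$epoch, h$val_iou, lty = 2)
  invisible(x)
}

#' Evaluate a fitted model on a tile partition
#'
#' Predicts every requested tile, thresholds at 0.5, and reports metrics.
#' With `average = "micro"` (default) confusion counts are pooled over all
#' tiles before computing metrics once; `"macro"` averages per-tile metric
#' values instead.
#'
#' @param model a fitted `"lwseg"` model.
#' @param records list of tile records.
#' @param split restrict to one partition (`"test"`, `"validation"`,
#'   `"train"`); `NULL` evaluates all records.
#' @param average `"micro"` or `"macro"`.
#' @param batch_size tiles per forward pass.
#' @return A `"metric_report"`; the pooled `"confusion_counts"` are attached
#'   as attribute `"counts"` for micro-averaging.
#' @export
lw_evaluate <- function(model, records, split = NULL,
                        average = c("micro", "macro"), batch_size = 8L) {
  average <- match.arg(average)
  stopifnot(inherits(model, "lwseg"))
  if (!is.null(split)) records <- Filter(function(r) r$split %in% split, records)
  if (!length(records)) stop("no tiles in the requested partition")
  da <- records_to_arrays(records, model$task)
  pm <- predict(model, da$x, type = "mask", batch_size = batch_size)
  if (length(dim(pm)) == 2L) pm <- array(pm, c(dim(pm), 1L))
  if (average == "micro") {
    total <- confusion(pm, da$y)
    rep <- seg_metrics(total)
    attr(rep, "counts") <- total
    return(rep)
  }
  per <- lapply(seq_len(dim(pm)[3]), function(i)
    unlist(seg_metrics(confusion(pm[, , i], da$y[, , i]))))
  avg <- colMeans(do.call(rbind, per))
  structure(as.list(avg), class = "metric_report")
}

# ---- checkpointing -----------------------------------------------------

#' Save / load a fitted model
#'
#' A checkpoint is a single-file container (RDS) holding the weights, the
#' architecture spec with its calibrated widths, the training
#' configuration, the batch-norm running statistics and the run log,
#' versioned for forward compatibility.
#'
#' @param model a fitted `"lwseg"` model.
#' @param path file path (conventionally `.rds`).
#' @return `lw_save` returns `path` invisibly; `lw_load` the restored model.
#' @export
lw_save <- function(model, path) {
  stopifnot(inherits(model, "lwseg"))
  obj <- unclass(model)
  obj$checkpoint_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname lw_save
#' @param path file path of a checkpoint written by `lw_save`.
#' @export
lw_load <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$checkpoint_version) || obj$checkpoint_version != 1L)
    stop("unrecognized checkpoint version")
  obj$checkpoint_version <- NULL
  class(obj) <- "lwseg"
  obj
}
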