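# Execution of a layer plan: forward pass (training or inference) and the
# matching backward pass.  Activations are H x W x C x N batches.  Skip
# connections are handled by stage bookkeeping: LW-Segnet stores pooling
# argmax codes per encoder stage and replays them in the decoder's sparse
# unpooling; LW-Unet stores the pre-pool encoder activations and
# concatenates them after bilinear upsampling.

#' @keywords internal
net_forward <- function(plan, params, state, x, training = FALSE) {
  caches <- vector("list", length(plan))
  pool_codes <- list()
  skip_acts <- list()
  cur <- x
  for (li in seq_along(plan)) {
    e <- plan[[li]]
    nm <- e$name
    if (e$op == "lha") {
      cc <- nn_lha_fwd(cur, params[[paste0(nm, ".ck")]],
                       params[[paste0(nm, ".cb")]],
                       params[[paste0(nm, ".sk")]],
                       params[[paste0(nm, ".sb")]])
      cur <- cc$y
    } else if (e$op == "sspdc") {
      cc <- nn_sspdc_fwd(cur, params[[paste0(nm, ".dw1")]],
                         params[[paste0(nm, ".dw2")]],
                         params[[paste0(nm, ".dw3")]],
                         params[[paste0(nm, ".pw")]],
                         params[[paste0(nm, ".pwb")]])
      cur <- cc$y
    } else if (e$op == "bn") {
      cc <- nn_bn_fwd(cur, params[[paste0(nm, ".g")]],
                      params[[paste0(nm, ".b")]], training,
                      state[[paste0(nm, ".rm")]],
                      state[[paste0(nm, ".rv")]])
      if (training) {
        state[[paste0(nm, ".rm")]] <- cc$run_mean
        state[[paste0(nm, ".rv")]] <- cc$run_var
      }
      cur <- cc$y
    } else if (e$op == "relu") {
      cc <- nn_relu_fwd(cur)
      cur <- cc$y
    } else if (e$op %in% c("pool", "pool_ind")) {
      if (e$op == "pool") skip_acts[[e$stage]] <- cur
      cc <- nn_maxpool_fwd(cur)
      if (e$op == "pool_ind") pool_codes[[e$stage]] <- cc$code
      cur <- cc$y
    } else if (e$op == "unpool") {
      cc <- nn_unpool_fwd(cur, pool_codes[[e$stage]])
      cur <- cc$y
    } else if (e$op == "upsample") {
      cc <- nn_bilinear2x_fwd(cur)
      cur <- cc$y
    } else if (e$op == "concat") {
      skip <- skip_acts[[e$stage]]
      dmc <- dim(cur)
      cc <- list(n_up = dmc[3], n_skip = dim(skip)[3], stage = e$stage)
      out <- array(0, c(dmc[1], dmc[2], dmc[3] + dim(skip)[3], dmc[4]))
      out[, , seq_len(dmc[3]), ] <- cur
      out[, , dmc[3] + seq_len(dim(skip)[3]), ] <- skip
      cur <- out
    } else if (e$op == "head") {
      cc <- nn_pwconv_fwd(cur, params[[paste0(nm, ".w")]],
                          params[[paste0(nm, ".b")]])
      z <- cc$y
      # two-class softmax: foreground probability from the logit difference
      p <- sigmoid(z[, , 2, , drop = FALSE] - z[, , 1, , drop = FALSE])
      cc$p <- p
      cur <- p
    } else stop("unknown op: ", e$op)
    caches[[li]] <- cc
  }
  dmp <- dim(cur)
  list(p = array(cur, c(dmp[1], dmp[2], dmp[4])), caches = caches,
       state = state)
}

# Backward pass: `gp` is the gradient of the scalar loss w.r.t. the
# foreground probability map (H x W x N).  Returns gradients as a named
# list aligned with `params`.
#' @keywords internal
net_backward <- function(plan, params, caches, gp) {
  grads <- list()
  skip_grads <- list()
  dmp <- dim(gp)
  g <- NULL
  for (li in rev(seq_along(plan))) {
    e <- plan[[li]]
    nm <- e$name
    cc <- caches[[li]]
    if (e$op == "head") {
      p <- cc$p
      ds <- array(gp, dim(p)) * p * (1 - p)
      gz <- array(0, c(dim(p)[1], dim(p)[2], 2L, dim(p)[4]))
      gz[, , 1, ] <- -ds
      gz[, , 2, ] <- ds
      out <- nn_pwconv_bwd(cc, gz)
      grads[[paste0(nm, ".w")]] <- out$gw
      grads[[paste0(nm, ".b")]] <- out$gb
      g <- out$gx
    } else if (e$op == "lha") {
      out <- nn_lha_bwd(cc, g)
      grads[[paste0(nm, ".ck")]] <- out$gck
      grads[[paste0(nm, ".cb")]] <- out$gcb
      grads[[paste0(nm, ".sk")]] <- out$gsk
      grads[[paste0(nm, ".sb")]] <- out$gsb
      g <- out$gx
    } else if (e$op == "sspdc") {
      out <- nn_sspdc_bwd(cc, g)
      grads[[paste0(nm, ".dw1")]] <- out$gdw1
      grads[[paste0(nm, ".dw2")]] <- out$gdw2
      grads[[paste0(nm, ".dw3")]] <- out$gdw3
      grads[[paste0(nm, ".pw")]] <- out$gpw
      grads[[paste0(nm, ".pwb")]] <- out$gpwb
      g <- out$gx
    } else if (e$op == "bn") {
      out <- nn_bn_bwd(cc, g)
      grads[[paste0(nm, ".g")]] <- out$ggamma
      grads[[paste0(nm, ".b")]] <- out$gbeta
      g <- out$gx
    } else if (e$op == "relu") {
      g <- nn_relu_bwd(cc, g)$gx
    } else if (e$op %in% c("pool", "pool_ind")) {
      g <- nn_maxpool_bwd(cc, g)$gx
      if (e$op == "pool" && !is.null(skip_grads[[e$stage]]))
        g <- g + skip_grads[[e$stage]]
    } else if (e$op == "unpool") {
      g <- nn_unpool_bwd(cc, g)$gx
    } else if (e$op == "upsample") {
      g <- nn_bilinear2x_bwd(cc, g)$gx
    } else if (e$op == "concat") {
      skip_grads[[cc$stage]] <- g[, , cc$n_up + seq_len(cc$n_skip), , drop = FALSE]
      g <- g[, , seq_len(cc$n_up), , drop = FALSE]
    }
  }
  grads
}
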