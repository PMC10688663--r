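# Declarative architecture specifications for the two networks, the layer
# plan they expand into, analytic parameter/FLOP profiling, and parameter
# initialization.  A single layer plan drives building, profiling and the
# forward/backward passes, so the analytic counts and the framework's own
# tally can be compared as genuinely independent routes.
#
# LW-Segnet: 4 encoder stages with (2, 1, 1, 5) SSPDC convolutions and
# index-recording max pooling; 4 decoder stages with (5, 1, 1, 2)
# convolutions fed by sparse unpooling from the stored indices.  LW-Unet:
# symmetric 2-convolution stages, plain pooling, bilinear 2x upsampling and
# concatenation skips.  Every stage opens with an LHA module; every
# convolution is followed by batch norm and ReLU; the head is a 1x1
# convolution to 2 classes under a softmax.
#
# Per-stage channel widths are explicit configuration.  The shipped defaults
# are calibrated once so that the analytic parameter counts land on the
# 11.0 M (LW-Segnet) and 10.6 M (LW-Unet) budgets at 5 input bands, and are
# never re-fit at run time.  The LW-Unet ladder is deliberately bottom-heavy
# so that its total FLOPs stay below LW-Segnet's at equal input size.

SEGNET_ENC_CONVS <- c(2L, 1L, 1L, 5L)
SEGNET_DEC_CONVS <- c(5L, 1L, 1L, 2L)
UNET_CONVS <- c(2L, 2L, 2L, 2L)

#' Default calibrated width ladders
#'
#' @param name `"lw_segnet"` or `"lw_unet"`.
#' @return Integer vector of 4 encoder output widths.
#' @export
default_widths <- function(name = c("lw_segnet", "lw_unet")) {
  name <- match.arg(name)
  switch(name,
         lw_segnet = c(78L, 156L, 312L, 620L),
         lw_unet = c(40L, 80L, 160L, 1607L))
}

#' Architecture specification
#'
#' Declares one of the two lightweight encoder-decoder networks together
#' with its per-stage widths, input band count, class count and nominal
#' input size.  Models, parameter counts and FLOP counts are all derived
#' from this single description.
#'
#' @param name `"lw_segnet"` or `"lw_unet"`.
#' @param widths integer vector of 4 encoder output channel widths
#'   (decoder widths mirror them).  Defaults to the calibrated ladder for
#'   the chosen architecture.
#' @param input_channels number of spectral bands (default 5).
#' @param classes number of output classes (binary segmentation: 2).
#' @param input_size nominal square input size in pixels; must be divisible
#'   by 16 (four 2x pooling stages).
#' @return An object of class `"lwseg_arch"`.
#' @examples
#' spec <- arch_spec("lw_unet", widths = c(8, 16, 24, 32), input_size = 64)
#' count_parameters(spec)$parameters
#' @export
arch_spec <- function(name = c("lw_segnet", "lw_unet"), widths = NULL,
                      input_channels = 5L, classes = 2L, input_size = 512L) {
  name <- match.arg(name)
  widths <- as.integer(widths %||% default_widths(name))
  if (length(widths) != 4L || any(widths < 1L))
    stop("`widths` must be 4 positive integers")
  input_size <- as.integer(input_size)
  if (input_size < 16L || input_size %% 16L != 0L)
    stop("`input_size` must be a positive multiple of 16 (four pooling stages)")
  stopifnot(input_channels >= 1L, classes == 2L)
  structure(list(name = name, widths = widths,
                 input_channels = as.integer(input_channels),
                 classes = as.integer(classes), input_size = input_size,
                 enc_convs = if (name == "lw_segnet") SEGNET_ENC_CONVS else UNET_CONVS,
                 dec_convs = if (name == "lw_segnet") SEGNET_DEC_CONVS else UNET_CONVS),
            class = "lwseg_arch")
}

#' @export
print.lwseg_arch <- function(x, ...) {
  cat(sprintf("<lwseg_arch> %s  widths %s  bands %d  input %dx%d\n",
              x$name, paste(x$widths, collapse = "/"), x$input_channels,
              x$input_size, x$input_size))
  invisible(x)
}

# Expand a spec into the ordered layer plan.  Each entry records the
# operation kind, a unique name (the parameter name prefix), channel counts
# and output resolution, plus stage bookkeeping for skips.
#' @keywords internal
arch_plan <- function(spec, input_size = spec$input_size) {
  input_size <- as.integer(input_size)
  if (input_size %% 16L != 0L || input_size < 16L)
    stop("input size must be a positive multiple of 16")
  w <- spec$widths
  plan <- list()
  add <- function(op, name, cin, cout, res, stage = NA_integer_) {
    plan[[length(plan) + 1L]] <<- list(op = op, name = name,
                                       cin = as.integer(cin),
                                       cout = as.integer(cout),
                                       res = as.integer(res),
                                       stage = stage)
  }
  conv_block <- function(prefix, i, cin, cout, res) {
    add("sspdc", sprintf("%s_c%d", prefix, i), cin, cout, res)
    add("bn", sprintf("%s_c%d_bn", prefix, i), cout, cout, res)
    add("relu", sprintf("%s_c%d_relu", prefix, i), cout, cout, res)
  }

  res <- input_size
  cin <- spec$input_channels
  # encoder
  for (k in 1:4) {
    prefix <- sprintf("e%d", k)
    add("lha", paste0(prefix, "_lha"), cin, cin, res, k)
    for (i in seq_len(spec$enc_convs[k])) {
      cout <- w[k]
      conv_block(prefix, i, cin, cout, res)
      cin <- cout
    }
    add(if (spec$name == "lw_segnet") "pool_ind" else "pool",
        paste0(prefix, "_pool"), cin, cin, res %/% 2L, k)
    res <- res %/% 2L
  }
  # decoder
  for (j in 1:4) {
    k <- 5L - j                       # matching encoder stage
    target <- if (j < 4L) w[4L - j] else w[1L]
    prefix <- sprintf("d%d", j)
    res <- res * 2L
    if (spec$name == "lw_segnet") {
      add("unpool", paste0(prefix, "_unpool"), cin, cin, res, k)
      add("lha", paste0(prefix, "_lha"), cin, cin, res, k)
      n <- spec$dec_convs[j]
      for (i in seq_len(n)) {
        cout <- if (i < n) cin else target
        conv_block(prefix, i, cin, cout, res)
        cin <- cout
      }
    } else {
      add("upsample", paste0(prefix, "_up"), cin, cin, res, k)
      add("concat", paste0(prefix, "_cat"), cin, cin + w[k], res, k)
      cin <- cin + w[k]
      add("lha", paste0(prefix, "_lha"), cin, cin, res, k)
      for (i in seq_len(spec$dec_convs[j])) {
        cout <- target
        conv_block(prefix, i, cin, cout, res)
        cin <- cout
      }
    }
  }
  add("head", "head", cin, spec$classes, res)
  plan
}

# Learnable parameters of one plan entry, by analytic formula.
#' @keywords internal
layer_param_count <- function(e) {
  switch(e$op,
         lha = (3L + 1L) + (49L + 1L),
         sspdc = 3L * 9L * e$cin + 3L * e$cin * e$cout + e$cout,
         bn = 2L * e$cout,
         head = e$cin * e$cout + e$cout,
         0L)
}

# Analytic FLOPs of one plan entry at its recorded resolution.  Convention:
# one multiply-accumulate in a convolution costs 2 FLOPs; batch norm, ReLU,
# pooling, unpooling, interpolation, sigmoid gates and softmax cost 1 FLOP
# per output element; reductions cost 1 FLOP per element read.  Only terms
# proportional to the pixel count are charged — the channel gate's O(C)
# vector convolution is excluded — so totals scale exactly with H*W.
#' @keywords internal
layer_flop_count <- function(e) {
  hw <- as.double(e$res)^2
  switch(e$op,
         sspdc = 2 * 9 * e$cin * hw * 3 + 2 * (3 * e$cin) * e$cout * hw,
         bn = ,
         relu = hw * e$cout,
         pool = ,
         pool_ind = ,
         unpool = ,
         upsample = hw * e$cout,
         lha = {
           C <- e$cin
           ch <- 2 * hw * C + hw * C                       # reductions + scale
           sp <- 2 * hw * C + hw + 2 * 49 * hw + hw + hw * C
           ch + sp
         },
         head = 2 * e$cin * e$cout * hw + e$cout * hw,
         0)
}

#' Analytic parameter count of an architecture
#'
#' Sums closed-form per-layer parameter formulas over the layer plan:
#' a depthwise 3x3 kernel contributes `9 C` weights, a pointwise fusion
#' `3 C_in C_out + C_out`, batch norm `2 C`, and each LHA module 54.
#' The result equals the exact number of trainable values allocated when
#' the model is built.
#'
#' @param spec an [arch_spec()].
#' @param by_layer return a per-layer data frame instead of totals.
#' @return A `"model_profile"` object (parameter part filled in), or a
#'   data frame when `by_layer = TRUE`.
#' @export
count_parameters <- function(spec, by_layer = FALSE) {
  stopifnot(inherits(spec, "lwseg_arch"))
  plan <- arch_plan(spec)
  if (by_layer) {
    return(data.frame(name = vapply(plan, `[[`, "", "name"),
                      op = vapply(plan, `[[`, "", "op"),
                      c_in = vapply(plan, `[[`, 0L, "cin"),
                      c_out = vapply(plan, `[[`, 0L, "cout"),
                      res = vapply(plan, `[[`, 0L, "res"),
                      params = vapply(plan, function(e) as.double(layer_param_count(e)), 0)))
  }
  total <- sum(vapply(plan, function(e) as.double(layer_param_count(e)), 0))
  model_profile(spec, parameters = total)
}

#' Analytic FLOP count of an architecture
#'
#' Per-layer closed-form counts at the given input size, with one
#' multiply-accumulate costing 2 FLOPs and elementwise layers 1 FLOP per
#' output element.  Both networks are fully convolutional, so the total
#' scales exactly with the pixel count.
#'
#' @param spec an [arch_spec()].
#' @param input_size square input size in pixels (multiple of 16); defaults
#'   to the spec's declared size.
#' @param by_layer return a per-layer data frame instead of totals.
#' @return A `"model_profile"` object (FLOP part filled in), or a data
#'   frame when `by_layer = TRUE`.
#' @export
count_flops <- function(spec, input_size = spec$input_size, by_layer = FALSE) {
  stopifnot(inherits(spec, "lwseg_arch"))
  plan <- arch_plan(spec, input_size)
  if (by_layer) {
    df <- count_parameters(spec, by_layer = TRUE)
    df$res <- vapply(plan, `[[`, 0L, "res")
    df$flops <- vapply(plan, layer_flop_count, 0)
    return(df)
  }
  total <- sum(vapply(plan, layer_flop_count, 0))
  model_profile(spec, flops = total, input_size = input_size)
}

#' @keywords internal
model_profile <- function(spec, parameters = NA_real_, flops = NA_real_,
                          input_size = spec$input_size) {
  structure(list(architecture = spec$name,
                 input_size = input_size,
                 parameters = parameters,
                 parameters_million = round(parameters / 1e6, 1),
                 flops = flops,
                 gflops = round(flops / 1e9, 1)),
            class = "model_profile")
}

#' @export
print.model_profile <- function(x, ...) {
  cat(sprintf("<model_profile> %s @ %dx%d\n", x$architecture,
              x$input_size, x$input_size))
  if (!is.na(x$parameters))
    cat(sprintf("  parameters: %s (%.1f M)\n",
                format(x$parameters, big.mark = ","), x$parameters_million))
  if (!is.na(x$flops))
    cat(sprintf("  flops:      %s (%.1f GFLOPs)\n",
                format(x$flops, big.mark = ","), x$gflops))
  invisible(x)
}

#' Full efficiency profile of an architecture
#'
#' Computes both the analytic parameter count and the analytic FLOP count
#' at the given input size.
#'
#' @param arch an [arch_spec()] or an architecture name.
#' @param input_size square input size in pixels.
#' @param widths optional width ladder when `arch` is a name.
#' @return A `"model_profile"` with both parts filled in.
#' @export
lw_profile <- function(arch = c("lw_segnet", "lw_unet"), input_size = 512L,
                       widths = NULL) {
  spec <- if (inherits(arch, "lwseg_arch")) arch
          else arch_spec(match.arg(arch), widths = widths,
                         input_size = input_size)
  p <- count_parameters(spec)
  f <- count_flops(spec, input_size)
  out <- model_profile(spec, parameters = p$parameters, flops = f$flops,
                       input_size = as.integer(input_size))
  out
}

#' Relative complexity increase between two profiles
#'
#' Percentage increase of one model's GFLOPs (or any scalar complexity
#' figure) over another's, rounded to one decimal: `100 * (a / b - 1)`.
#'
#' @param a,b `"model_profile"` objects or plain GFLOP numbers; `a` is
#'   compared against baseline `b`.
#' @return Percentage increase, one decimal.
#' @examples
#' profile_compare(58.7, 32.1)  # 82.9
#' @export
profile_compare <- function(a, b) {
  ga <- if (inherits(a, "model_profile")) a$gflops else as.numeric(a)
  gb <- if (inherits(b, "model_profile")) b$gflops else as.numeric(b)
  stopifnot(gb > 0)
  round(100 * (ga / gb - 1), 1)
}

# ---- parameter allocation ---------------------------------------------

# Allocate and initialize all trainable parameters (He-style normal init
# for convolution weights, unit/zero batch-norm affine) plus the batch-norm
# running statistics.  Names are "<layer>.<slot>".
#' @keywords internal
lw_init_params <- function(spec, seed = 1L, input_size = spec$input_size) {
  plan <- arch_plan(spec, input_size)
  params <- list()
  state <- list()
  with_seed(seed, {
    for (e in plan) {
      nm <- e$name
      if (e$op == "lha") {
        params[[paste0(nm, ".ck")]] <- stats::rnorm(3, sd = 0.1)
        params[[paste0(nm, ".cb")]] <- 0
        params[[paste0(nm, ".sk")]] <- matrix(stats::rnorm(49, sd = 0.05), 7, 7)
        params[[paste0(nm, ".sb")]] <- 0
      } else if (e$op == "sspdc") {
        for (b in 1:3)
          params[[sprintf("%s.dw%d", nm, b)]] <-
            array(stats::rnorm(9 * e$cin, sd = sqrt(2 / 9)), c(3, 3, e$cin))
        params[[paste0(nm, ".pw")]] <-
          matrix(stats::rnorm(3 * e$cin * e$cout, sd = sqrt(2 / (3 * e$cin))),
                 3 * e$cin, e$cout)
        params[[paste0(nm, ".pwb")]] <- rep(0, e$cout)
      } else if (e$op == "bn") {
        params[[paste0(nm, ".g")]] <- rep(1, e$cout)
        params[[paste0(nm, ".b")]] <- rep(0, e$cout)
        state[[paste0(nm, ".rm")]] <- rep(0, e$cout)
        state[[paste0(nm, ".rv")]] <- rep(1, e$cout)
      } else if (e$op == "head") {
        params[[paste0(nm, ".w")]] <-
          matrix(stats::rnorm(e$cin * e$cout, sd = sqrt(2 / e$cin)),
                 e$cin, e$cout)
        params[[paste0(nm, ".b")]] <- rep(0, e$cout)
      }
    }
  })
  list(plan = plan, params = params, state = state)
}

# The framework's own trainable-parameter tally: the exact number of values
# held in the allocated parameter arrays.
#' @keywords internal
param_tally <- function(params) sum(vapply(params, length, 0L))
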