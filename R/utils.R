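# Internal helpers shared across modules.

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-item child seeds below 2^31 derived from a master seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 10007) %% 2147483647)
}

# Round half up: round(0.5) -> 1, matching the split bookkeeping convention.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a feature map to a 3-d H x W x C array (matrices become C = 1) and
# validate it. Used by all user-facing block operations.
#' @keywords internal
as_feature_map <- function(fm, arg = "fm") {
  if (is.matrix(fm)) fm <- array(fm, c(dim(fm), 1L))
  if (!is.array(fm) || length(dim(fm)) != 3L)
    stop(sprintf("`%s` must be an H x W x C array (or an H x W matrix)", arg))
  if (any(dim(fm) < 1L))
    stop(sprintf("`%s` must have H, W, C >= 1", arg))
  if (!all(is.finite(fm)))
    stop(sprintf("`%s` contains non-finite values", arg))
  storage.mode(fm) <- "double"
  fm
}

# Promote a single feature map to a batch of one: H x W x C x 1.
#' @keywords internal
fm_batch1 <- function(fm) array(fm, c(dim(fm), 1L))
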