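#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif rpois rlnorm qnorm pnorm sd cor median
#'   model.matrix p.adjust t.test setNames
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage RNG streams derived from one master seed, kept
# inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(
    screen = 101L, panel = 211L, image = 307L, expression = 401L,
    donor = 503L, efficacy = 601L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% (.Machine$integer.max - 1L)) + 1L
}

# Multiplicative lognormal noise with unit mean and the given coefficient
# of variation; cv = 0 degenerates to exactly 1.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Truncated-normal draws by inverse-CDF; exact at sd -> 0 (point mass).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  if (x < min) abort(sprintf("`%s` must be >= %s.", name, min))
  invisible(x)
}

require_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
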