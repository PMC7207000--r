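#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats quantile rnorm runif rpois rbinom rbeta plogis qlogis
#'   p.adjust pt sd var predict
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clip01 <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

# Convert an effect stated in percentage points to a logit offset anchored
# at 50% methylation, where d points equals qlogis(0.5 + d/100) logit units.
points_to_logit <- function(points) qlogis(clip01(0.5 + points / 100, 1e-6, 1 - 1e-6))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
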