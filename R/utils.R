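#' @importFrom rlang abort warn inform %||%
#' @importFrom stats median sd cor rnorm runif rbinom quantile predict pnorm
#' @importFrom utils head
NULL
# (rlang's %||% is imported above; no local redefinition)

# Evaluate expr under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic per-stage child seed from one global seed; keeps every stage
# independently reproducible. Result stays inside the 32-bit integer range.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

stopf <- function(fmt, ..., class = "mgoscav_error") {
  abort(sprintf(fmt, ...), class = class)
}
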