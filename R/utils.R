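#' @keywords internal
#' @importFrom stats rnorm runif
#' @importFrom utils capture.output
"_PACKAGE"

BEHAVIORS <- c("pa", "snack", "oha", "insulin")

# improvement orientation on the native scale: +1 if a larger raw change is an
# improvement, -1 if a smaller one is (snack kilocalories)
ORIENT <- c(pa = 1, snack = -1, oha = 1, insulin = 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || !hi_ok)
    stop_param(field, sprintf("must be a fraction in [0,%s)", if (allow_one) "1]" else "1"))
  invisible(x)
}

# Independent deterministic pseudo-random streams per pipeline stage, derived
# from one master seed.  Changing how many draws one stage uses must not
# perturb any other stage, so each stage re-seeds from its own derived value.
stage_seed <- function(seed, stage) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_param("seed", "must be a single integer")
  offsets <- c(cohort = 101L, items = 211L, dropout = 307L,
               scenario = 401L, impute = 503L, power = 601L, cli = 701L)
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  s <- (abs(as.numeric(seed)) * 48271 + offsets[[stage]]) %% (2^31 - 1)
  as.integer(s)
}

# Evaluate `expr` with a temporary RNG state so calibration or fixture code
# does not perturb the caller's stream.
with_preserved_seed <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
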