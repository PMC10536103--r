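#' @keywords internal
#' @importFrom stats runif rnorm rexp lm coef confint
#' @importFrom utils read.csv write.csv modifyList
"_PACKAGE"

# Valid signal units: the recordings mix potential traces (volts) and
# DPV current traces (microamperes), so every trace carries its unit.
.units <- c("volt", "microampere")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic generators in the package funnel through this so that a
# given seed yields byte-identical output regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  if (nonnegative && x < 0) stopf("`%s` must be >= 0", name)
  invisible(x)
}

check_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || !(unit %in% .units)) {
    stopf("`unit` must be one of: %s", paste(.units, collapse = ", "))
  }
  unit
}
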