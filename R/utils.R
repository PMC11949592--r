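# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Structured log line: stage, elapsed, message
#' @noRd
log_line <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s %s", stage,
                  format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_square_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) stopf("%s must be a numeric matrix", what)
  if (nrow(m) != ncol(m)) stopf("%s must be square, got %d x %d", what, nrow(m), ncol(m))
  if (any(!is.finite(m))) stopf("%s contains non-finite entries", what)
  asym <- max(abs(m - t(m)))
  if (asym > tol) stopf("%s is asymmetric beyond tolerance (max |m - t(m)| = %.3g)", what, asym)
  invisible(TRUE)
}
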