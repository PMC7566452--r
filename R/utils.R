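`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
tb_log <- function(..., level = "info") {
  lev <- getOption("tlsbiomass.log_level", "warn")
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (ranks[[lev]] <= ranks[[level]]) message("[tlsbiomass] ", sprintf(...))
  invisible(NULL)
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stream index.
#' @noRd
sub_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647)
}

# Evaluate expr with its own RNG stream, leaving the caller's RNG untouched.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("'%s' must be >= %g", name, lower)
  if (x > upper) stopf("'%s' must be <= %g", name, upper)
  invisible(x)
}
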