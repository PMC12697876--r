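#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (nonneg && x < 0) stop_field(field, "must be >= 0")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_field(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

# seed handling: generators are bit-reproducible given `seed`; NULL leaves the
# RNG stream alone so callers can manage it themselves
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_count(seed, "seed", min = 0L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

is_row_stochastic <- function(P, tol = 1e-9) {
  is.matrix(P) && all(P >= -tol) && all(abs(rowSums(P) - 1) <= tol)
}
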