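# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to run with the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  set.seed(as.integer(seed))
  expr
}

# abort with a classed condition so tests can assert on error class
bench_abort <- function(message, class) {
  stop(structure(
    class = c(class, "eegbench_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    bench_abort(sprintf("`%s` must be a single finite number", name),
                "eegbench_parameter_error")
  }
  invisible(x)
}

# polynomial coefficients (increasing powers of z^-1) of prod_j (1 - r_j z^-1)
poly_from_roots <- function(r) {
  co <- 1 + 0i
  for (ri in r) co <- c(co, 0) - c(0, ri * co)
  co
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
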