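#' @keywords internal
#' @useDynLib ecodiv, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores the previous state, so seeded package functions do not disturb
#' the caller's RNG stream. A `NULL` seed evaluates `expr` unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# consistent error helper: all package errors carry class "ecodiv_error"
stop_ecodiv <- function(msg, class) {
  stop(structure(class = c(class, "ecodiv_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
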