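#' @keywords internal
#' @useDynLib scdr, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(msg, class = "scdr_invalid_input") {
  stop(structure(class = c(class, "scdr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_config <- function(msg) stop_invalid(msg, class = "scdr_invalid_config")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, config = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    msg <- sprintf("`%s` must be a finite number in %s%s, %s]",
                   name, if (strict_lower) "(" else "[", lower, upper)
    if (config) stop_config(msg) else stop_invalid(msg)
  }
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# derive a stream of sub-seeds from one master seed, all < 2^31
derive_seeds <- function(seed, n, salt = 0L) {
  (as.numeric(seed) * 48271 + salt * 1013904223 + seq_len(n) * 69621) %%
    2147483647
}

sigmoid <- function(x) 1 / (1 + exp(-x))

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}
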