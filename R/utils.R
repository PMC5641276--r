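#' @keywords internal
"_PACKAGE"

## RNG discipline: every stochastic entry point takes an explicit `seed` and
## evaluates under withr::with_seed so the global RNG stream is untouched.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a reproducible child seed from a master seed and a stage name
#'
#' Stable string hash (31-base polynomial, modulo 2^31 - 1) combined with the
#' master seed, so that adding a stage to a pipeline never perturbs the seeds
#' of the other stages.
#'
#' @param master integer master seed.
#' @param key character stage name.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  m <- 2147483647
  h <- 0
  for (v in utf8ToInt(as.character(key))) h <- (h * 31 + v) %% m
  s <- ((as.numeric(master) %% m) * 48271 + h) %% m
  as.integer(if (s < 1) 1 else s)
}

## squared-difference upper-triangle sum helpers used by amova/structure
upper_tri_vals <- function(m) m[upper.tri(m)]

## structured JSON-lines logger; `con` may be NULL (silent)
log_event <- function(log_path, event, ...) {
  if (is.null(log_path)) return(invisible(NULL))
  rec <- c(list(event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, sep = "", append = TRUE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
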