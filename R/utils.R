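#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_rate <- function(x, name) {
  stop_if_not(is_scalar_number(x) && x >= 0 && x <= 1,
              sprintf("`%s` must be a single number in [0, 1]", name))
  invisible(x)
}

CONDITIONS <- c("NORM", "nTNBC", "TNBC")

DE_COMPARISONS <- c("NORM_vs_nTNBC", "NORM_vs_TNBC", "nTNBC_vs_TNBC")
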