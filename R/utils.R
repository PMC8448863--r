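#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pnorm pt quantile rnorm runif sd setNames
#' @importFrom utils head modifyList
NULL

# Run `code` under a fixed RNG seed without leaking global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-stage seed fan-out from one global seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483647L)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, lower = 0) {
  stop_if_not_scalar_number(x, name, lower = lower)
  if (x != round(x)) stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# RGB [0,1] array (rows x cols x 3) -> luminance matrix (Rec. 601 weights).
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
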