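#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif setNames predict sd quantile median dnorm glm binomial coef
#' @importFrom utils read.delim write.csv read.csv head
NULL

.molapprove_env <- new.env(parent = emptyenv())

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their own seed from the run
#' seed through this helper so that stages stay independently reproducible.
#' Results are kept below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  abort_if(!is_count(seed), "`seed` must be a single non-negative integer")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((seed * 2654435L + h * 97L) %% .Machine$integer.max)
}
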