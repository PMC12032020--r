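#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd prcomp p.adjust qt pt rnorm pnorm quantile hclust
#'   cutree as.dist lm residuals
#' @importFrom utils write.table read.table head
NULL

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Correlations are clipped just inside +/-1 so Fisher z stays finite for
## duplicated series without changing the ordering of any finite values.
COR_CLIP <- 1 - 1e-6

fisher_z <- function(r) atanh(clip(r, -COR_CLIP, COR_CLIP))

#' Derive a stage-specific child seed from a global seed
#'
#' A stable integer hash of (seed, stage name) so each stage of a seeded
#' pipeline gets its own reproducible RNG stream and can be rerun in
#' isolation. Results stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param name character stage name.
#' @return an integer seed.
#' @export
child_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

## Evaluate expr with a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
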