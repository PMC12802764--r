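# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic thinning of an index vector to at most n entries
thin_index <- function(idx, n) {
  if (length(idx) <= n) return(idx)
  idx[unique(round(seq(1, length(idx), length.out = n)))]
}

#' Logit transform
#'
#' @param p fraction strictly inside (0, 1).
#' @return `log(p / (1 - p))`.
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit is defined only on (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

#' Inverse logit
#'
#' @param x real number(s).
#' @return `1 / (1 + exp(-x))`.
#' @export
expit <- function(x) stats::plogis(x)
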