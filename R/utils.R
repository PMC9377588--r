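#' @keywords internal
"_PACKAGE"

# logit / inverse logit on the open interval
logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the global RNG, runs `expr`, then restores the previous
#' `.Random.seed`, so package functions are deterministic given their
#' `seed` argument without disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
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

# derive a child seed from a base seed and a stream index, kept < 2^31
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483587) + 1L
}

# zero-truncated Poisson draws with rate chosen so the untruncated mean is
# `mean_count` when mean_count > 1 is requested; simple rejection-free
# inverse-cdf via repeated qpois on shifted uniforms
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  lambda <- rep_len(lambda, n)
  p0 <- exp(-lambda)
  u <- runif(n, min = p0, max = 1)
  qpois(u, lambda)
}

# linear-interpolation percentile (type 7), the convention used throughout
pctile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
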