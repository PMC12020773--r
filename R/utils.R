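#' @importFrom stats approx coef lm model.matrix optimize pnorm qnorm qt
#' @importFrom stats quantile rbinom rmultinom rnorm rpois runif sd var
#' @importFrom stats complete.cases setNames as.formula resid residuals predict
#' @importFrom utils modifyList
NULL

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  expr
}

# Deterministic per-stage seed derived from one global seed; kept < 2^31.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + offset * 1009) %% 2147483647)
}

stopifnot_named <- function(cond, field, msg) {
  if (!isTRUE(cond)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Draw from a normal, resampling (not truncating) until inside [lo, hi].
rnorm_bounded <- function(n, mean, sd, lo = -Inf, hi = Inf, max_tries = 1000L) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > max_tries) stop("resampling cap reached while enforcing bounds")
    x[bad] <- rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                    if (length(sd) > 1) sd[bad] else sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items;
#' 1 means identical partitions, values near 0 mean chance-level agreement.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)
  (sij - expected) / (max_index - expected)
}
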