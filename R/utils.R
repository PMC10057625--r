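`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run an expression under a temporary RNG seed
#'
#' If `seed` is `NULL` the expression runs on the current RNG stream;
#' otherwise the global seed is set and the previous RNG state restored
#' afterwards, so seeded generators do not disturb the caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Population central moments. Skewness m3/m2^1.5 and raw kurtosis m4/m2^2
# (normal => 3). Degenerate (zero-variance) input maps to 0 so feature
# vectors stay finite.
population_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) {
    return(list(mean = m, variance = 0, sd = 0, skewness = 0, kurtosis = 0))
  }
  list(mean = m, variance = m2, sd = sqrt(m2),
       skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2)
}

#' Vectorised Welch two-sample t-test
#'
#' Operates columnwise on two matrices (rows = replicates). Sample
#' variances, Welch-Satterthwaite degrees of freedom, two-sided p-values.
#' Zero-variance columns: p = 1 when the means agree, p = 0 otherwise.
#' @noRd
welch_t_cols <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t_stat), df),
              ifelse(m1 == m2, 1, 0))
  list(t = t_stat, df = df, p = p, mean1 = m1, mean2 = m2,
       var1 = v1, var2 = v2, n1 = n1, n2 = n2)
}

# Resample a waveform to `n_out` samples by linear interpolation over a
# common [0, 1] abscissa.
resample_linear <- function(y, n_out) {
  n <- length(y)
  if (n == n_out) return(as.numeric(y))
  approx(seq(0, 1, length.out = n), y, xout = seq(0, 1, length.out = n_out))$y
}
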