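#' @importFrom stats rnorm runif sd var cov ks.test wilcox.test t.test qnorm pnorm dnorm setNames
#' @importFrom utils head tail
#' @importFrom data.table data.table as.data.table fread fwrite rbindlist setnames copy set
NULL

# Deterministic seed splitting: every random draw in the package flows from a
# user-supplied master seed through this function, so identical seeds give
# identical results and sub-streams (subject, repeat, chunk...) are decoupled.
# Knuth-style multiplicative hash folded into [0, 2^31 - 2].
split_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    h <- (h * 48271 + kk + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; global RNG state
# is restored afterwards so library code never disturbs the user's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Centered running mean with shrinking windows at the edges.
# x: numeric vector; w: odd window length in samples (w = 1 returns x).
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sample SD per row of a matrix (n - 1 denominator), no apply overhead.
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' @useDynLib startreact, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
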