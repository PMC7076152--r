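#' @keywords internal
"_PACKAGE"

## Run `expr` under a private RNG stream: set.seed(seed) without disturbing
## the caller's .Random.seed. All stochastic code in the package goes through
## this, so a single master seed makes every run reproducible.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Frobenius norm of a matrix or array.
fnorm <- function(x) sqrt(sum(x^2))

## Strict upper-triangle index pairs (i < j) in row-major order:
## (1,2),(1,3),...,(1,N),(2,3),...  Returns a 2-column integer matrix.
upper_pairs <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

## Vectorize the strict upper triangle of a symmetric matrix in the
## row-major (i < j) order of upper_pairs().
upper_vec <- function(W) {
  t(W)[lower.tri(W)]
}

## Inverse of upper_vec for a symmetric matrix with zero diagonal.
upper_unvec <- function(v, n) {
  W <- matrix(0, n, n)
  tW <- t(W)
  tW[lower.tri(tW)] <- v
  W <- t(tW)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

## Parse "2^-3" style power notation used on hyper-parameter grids;
## plain numerics pass through.
parse_power <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- vapply(x, function(s) {
    if (grepl("^\\s*2\\^", s)) {
      2^as.numeric(sub("^\\s*2\\^", "", s))
    } else {
      as.numeric(s)
    }
  }, numeric(1))
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
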