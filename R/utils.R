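#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the prior
#' RNG state afterwards, so seeded helpers do not disturb a caller's random
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as a named seam so every FDR
#' correction in the package goes through one code path; `NA` entries are
#' passed through untouched.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

## row-wise sample sd of a matrix, denominator n - 1
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1))
}

## center each column, scale to unit L2 norm; zero-variance columns -> NA cols
normalize_frames <- function(x) {
  xc <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(xc^2))
  bad <- nrm < .Machine$double.eps^0.5
  nrm[bad] <- 1
  out <- sweep(xc, 2L, nrm, "/")
  out[, bad] <- NA_real_
  attr(out, "degenerate") <- which(bad)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
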