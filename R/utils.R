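#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return the geometric mean of `x`.
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of the
#' platform's report tables), unlike base `round()` which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 31-bit stream seed from a base seed and a string key, so each
# gene/component gets an independent reproducible substream and adding a gene
# does not reshuffle the others.
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer(h)
}

# Run fn() under a derived substream seed without disturbing the caller's RNG.
with_substream <- function(seed, key, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, key))
  fn()
}

# lexicographic, locale-independent sort for gene lists
sort_genes <- function(x) sort(unique(as.character(x)), method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
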