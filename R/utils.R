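# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's
#' RNG state, so no function in the package leaks hidden global randomness.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  code
}

# scalar argument checks -----------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

#' Cosine similarity of two complex maps, modulo a global phase
#'
#' `|<a, b>| / (||a|| ||b||)` over the jointly finite entries. Equal to 1
#' exactly when `b = c * a` for some complex scalar `c`, which makes it the
#' natural recovery score for complex loadings that are only defined up to a
#' global phase rotation.
#'
#' @param a,b Complex vectors or matrices of equal length (NAs ignored pairwise).
#' @return A value in \[0, 1\].
#' @export
complex_map_similarity <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  stopifnot(length(a) == length(b))
  ok <- is.finite(Re(a)) & is.finite(Re(b))
  a <- a[ok]; b <- b[ok]
  na <- sqrt(sum(Mod(a)^2)); nb <- sqrt(sum(Mod(b)^2))
  if (na == 0 || nb == 0) stop("zero-norm map in similarity")
  Mod(sum(Conj(a) * b)) / (na * nb)
}

# Pearson correlation of the strict upper triangles of two square matrices.
upper_tri_cor <- function(a, b) {
  ut <- upper.tri(a)
  stats::cor(a[ut], b[ut], use = "complete.obs")
}

# Hann (raised-cosine) window of length n.
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}
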