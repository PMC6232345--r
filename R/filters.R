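#' Construct the Daubechies-7 quadrature mirror filter pair
#'
#' Builds the orthonormal Daubechies scaling (low-pass) filter with
#' `n_moments` vanishing moments by spectral factorization: the roots of the
#' Daubechies polynomial \eqn{P(y) = \sum_{k=0}^{N-1} \binom{N-1+k}{k} y^k}
#' are mapped into the z-plane, the minimum-phase (inside unit circle) roots
#' are retained, and the filter is assembled as
#' \eqn{c\,(1+z)^N \prod_k (z - z_k)} with \eqn{\sum h = \sqrt 2}. The
#' high-pass partner is the quadrature mirror
#' \eqn{g_n = (-1)^n h_{L-1-n}}.
#'
#' With the default `n_moments = 7` the pair has length 14 and satisfies, to
#' near machine precision, the orthonormality conditions
#' \eqn{\sum h = \sqrt 2}, \eqn{\sum h^2 = 1}, \eqn{\langle h, g\rangle = 0},
#' and double-shift orthogonality \eqn{\sum_n h_n h_{n+2j} = \delta_j}.
#'
#' @param n_moments Number of vanishing moments (7 gives the 14-tap pair used
#'   throughout this package).
#' @return An object of class `filter_pair`: a list with elements `lowpass`
#'   (`h`), `highpass` (`g`), `length`, and `n_moments`.
#' @export
#' @examples
#' fp <- db7_filters()
#' length(fp$lowpass)      # 14
#' sum(fp$lowpass) - sqrt(2)
db7_filters <- function(n_moments = 7L) {
  N <- as.integer(n_moments)
  if (is.na(N) || N < 1L) stop("`n_moments` must be a positive integer", call. = FALSE)
  pc <- choose(N - 1 + 0:(N - 1), 0:(N - 1))
  # q(z) = z^(N-1) P((2 - z - 1/z)/4), ascending powers 0..2N-2
  q <- rep(0, 2 * N - 1)
  for (k in 0:(N - 1)) {
    m <- 2 * k
    zk <- choose(m, 0:m) * (-1)^(m - (0:m))   # (z - 1)^(2k)
    term <- pc[k + 1] * (-1)^k / 4^k * zk
    sh <- N - 1 - k
    q[(sh + 1):(sh + m + 1)] <- q[(sh + 1):(sh + m + 1)] + term
  }
  roots <- polyroot(q)
  inside <- roots[Mod(roots) < 1]
  if (length(inside) != N - 1) {
    stop("spectral factorization failed: expected ", N - 1,
         " minimum-phase roots, got ", length(inside), call. = FALSE)
  }
  coef <- 1 + 0i
  for (ri in inside) coef <- c(0, coef) - ri * c(coef, 0)
  for (i in seq_len(N)) coef <- c(0, coef) + c(coef, 0)   # times (1 + z)^N
  h <- Re(coef)
  h <- h * sqrt(2) / sum(h)
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  structure(
    list(lowpass = h, highpass = g, length = L, n_moments = N),
    class = "filter_pair"
  )
}

#' @export
print.filter_pair <- function(x, ...) {
  cat("<filter_pair> Daubechies, ", x$n_moments, " vanishing moments, length ",
      x$length, "\n", sep = "")
  invisible(x)
}
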