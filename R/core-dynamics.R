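#' Activation-to-rate transfer
#'
#' Firing rates are a thresholded, rescaled hyperbolic tangent of the
#' activation: `f = tanh(beta * (a - alpha))` for `a >= alpha` and 0 below
#' threshold, so rates lie in \[0, 1).
#'
#' @param a numeric activation vector.
#' @param alpha activation threshold.
#' @param beta slope of the transfer function; must be positive.
#' @return firing-rate vector, same length as `a`, values in \[0, 1).
#' @export
#' @examples
#' rate_transfer(c(-1, 0, 0.2, 5), alpha = 0, beta = 2)
rate_transfer <- function(a, alpha = 0, beta = 1) {
  if (beta <= 0) stop("`beta` must be > 0")
  f <- tanh(beta * (a - alpha))
  f[a < alpha] <- 0
  f
}

#' One explicit-Euler step of leaky rate dynamics
#'
#' Integrates `tau * da/dt = -a + sum_j g_j W_j f_j` with a forward Euler
#' step of size `dt`. Each input is a list with elements `gain`, `W` (weight
#' matrix, or `NULL` for a one-to-one projection) and `f` (presynaptic rate
#' vector).
#'
#' @param a activation vector at the current step.
#' @param inputs list of inputs; each element is `list(gain =, W =, f =)`.
#' @param tau membrane time constant in seconds.
#' @param dt integration step in seconds; requires `0 < dt <= tau`.
#' @return updated activation vector.
#' @export
euler_step <- function(a, inputs = list(), tau, dt) {
  if (dt <= 0) stop("`dt` must be > 0")
  if (dt > tau) stop("`dt` must not exceed `tau` (explicit Euler stability)")
  drive <- numeric(length(a))
  for (inp in inputs) {
    f <- inp$f
    if (is.null(inp$W)) {
      if (length(f) != length(a)) {
        stop("one-to-one input length does not match layer size")
      }
      drive <- drive + inp$gain * f
    } else {
      if (ncol(inp$W) != length(f)) {
        stop("weight matrix columns do not match presynaptic rate length")
      }
      drive <- drive + inp$gain * as.numeric(inp$W %*% f)
    }
  }
  a + (dt / tau) * (-a + drive)
}

#' Global inhibition matrix
#'
#' Uniform within-layer inhibition: every entry `1/N`, so each neuron is
#' inhibited by the layer mean (row-stochastic all-ones matrix over N).
#'
#' @param n layer size; must be >= 1.
#' @return `n x n` matrix with all entries `1/n`.
#' @export
global_inhibition_matrix <- function(n) {
  if (n < 1) stop("`n` must be >= 1")
  matrix(1 / n, n, n)
}

#' Lateral inhibition matrix
#'
#' Inhibition from each neuron spread equally over all *other* neurons in the
#' layer: zero diagonal, off-diagonal entries `1/(N-1)`.
#'
#' @param n layer size; must be >= 2.
#' @return `n x n` matrix, zero diagonal, rows summing to 1.
#' @export
lateral_inhibition_matrix <- function(n) {
  if (n < 2) stop("`n` must be >= 2 for lateral inhibition")
  m <- matrix(1 / (n - 1), n, n)
  diag(m) <- 0
  m
}
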