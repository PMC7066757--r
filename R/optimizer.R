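# Robbins-Monro adaptive stochastic gradient descent.

#' Stochastic gradient descent with a decaying Robbins-Monro gain
#'
#' Iterates `x_{k+1} = x_k - gamma(k) g_k` with gain
#' `gamma(k) = a / (A + k)^alpha`, where `g_k` is the stochastic gradient
#' returned by `cost_and_gradient(x, k)`. The only stopping rule is the
#' iteration budget.
#'
#' @param cost_and_gradient function of `(x, iteration)` returning a list
#'   with elements `value` and `gradient`.
#' @param x0 initial parameter vector.
#' @param max_iterations iteration budget; 0 returns `x0` untouched.
#' @param a,A,alpha gain constants. Drivers auto-scale `a` so the first
#'   step moves the image by about one voxel.
#' @param tail_average fraction of the final iterates averaged into
#'   `par_avg` (Polyak-Ruppert averaging, which removes the random-walk
#'   jitter of the last stochastic iterates; 0 disables it).
#' @return list with `par` (final parameters), `par_avg` (tail-averaged
#'   parameters; equal to `par` when averaging is disabled), `trace` (cost
#'   value per iteration) and `iterations`.
#' @export
asgd_minimize <- function(cost_and_gradient, x0, max_iterations,
                          a = 1, A = 50, alpha = 0.602,
                          tail_average = 0.5) {
  x <- as.numeric(x0)
  max_iterations <- as.integer(max_iterations)
  trace <- numeric(max_iterations)
  if (max_iterations < 1L)
    return(list(par = x, par_avg = x, trace = numeric(0), iterations = 0L))
  n_avg <- min(max_iterations, max(1L, ceiling(tail_average *
                                                 max_iterations)))
  from <- max_iterations - n_avg
  xsum <- numeric(length(x))
  for (k in seq_len(max_iterations) - 1L) {
    cg <- cost_and_gradient(x, k)
    g <- cg$gradient
    if (any(!is.finite(g)))
      stop("non-finite stochastic gradient at iteration ", k)
    x <- x - (a / (A + k)^alpha) * g
    trace[k + 1L] <- cg$value
    if (k >= from) xsum <- xsum + x
  }
  list(par = x, par_avg = if (tail_average > 0) xsum / n_avg else x,
       trace = trace, iterations = max_iterations)
}
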