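#' Vector-autoregression generator with a known causality graph
#'
#' Order-1 VAR: `x^t = A x^{t-1} + eps`, `eps ~ N(0, noise_sd^2)`. The
#' nonzero pattern of the coefficient matrix is the ground-truth directed
#' causality graph: `A[i, j] != 0` means series j drives series i. Viewed as
#' a relational-inference problem, every ordered pair is an edge of one of
#' two types — "causal" (coefficient present) or "null".
#'
#' @param n_series number of series.
#' @param adjacency binary matrix; `adjacency[i, j] = 1` when j causes i.
#'   Diagonal entries describe self-dependence and are not graph edges.
#' @param coefficients coefficient matrix aligned with `adjacency`; zero
#'   wherever `adjacency` is zero. Default `0.4 * adjacency`.
#' @param noise_sd innovation standard deviation.
#' @param n_steps series length `T`.
#' @return a `var_spec` list.
#' @export
var_spec <- function(n_series, adjacency, coefficients = NULL,
                     noise_sd = 0.1, n_steps = 200L) {
  adjacency <- matrix(as.numeric(adjacency != 0), n_series, n_series)
  if (is.null(coefficients)) coefficients <- 0.4 * adjacency
  stopifnot(all(coefficients[adjacency == 0] == 0), noise_sd > 0)
  rho <- max(Mod(eigen(coefficients, only.values = TRUE)$values))
  if (rho >= 0.98) {
    stop("coefficient matrix has spectral radius ", signif(rho, 4),
         " >= 0.98; the process would not be stationary")
  }
  structure(list(n_series = as.integer(n_series), adjacency = adjacency,
                 coefficients = coefficients, noise_sd = noise_sd,
                 n_steps = as.integer(n_steps)), class = "var_spec")
}

#' @rdname var_spec
#' @param spec a `var_spec`.
#' @param seed integer seed.
#' @param x0 optional initial value vector (defaults to a standard normal
#'   draw under the same seed).
#' @return a `series_trajectory`: `values` (`T x N`), first-difference
#'   `increments` (`(T-1) x N`), and the ground-truth `graph` over all
#'   ordered pairs with types 1 = null, 2 = causal.
#' @export
simulate_var <- function(spec, seed = 1L, x0 = NULL) {
  N <- spec$n_series
  T_ <- spec$n_steps
  A <- spec$coefficients
  vals <- withr::with_seed(seed, {
    x <- if (is.null(x0)) stats::rnorm(N) else x0
    out <- matrix(0, T_, N)
    out[1L, ] <- x
    for (t in 2:T_) {
      x <- as.numeric(A %*% x) + stats::rnorm(N, 0, spec$noise_sd)
      out[t, ] <- x
    }
    out
  })
  edges <- .all_pairs(N)
  tt <- ifelse(spec$adjacency[edges] != 0, 2L, 1L)
  graph <- interaction_graph(N, edges, true_types = tt, K = 2L)
  structure(list(values = vals,
                 increments = vals[-1L, , drop = FALSE] - vals[-T_, , drop = FALSE],
                 graph = graph, spec = spec),
            class = "series_trajectory")
}
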