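#' Enumerate the joint edge-type realizations of one subgraph
#'
#' A subgraph with in-degree `g` and `K` interaction types has exactly
#' `K^g` joint assignments. They are enumerated in deterministic mixed-radix
#' order: realization `r` (1-based) assigns slot `j` the type
#' `((r - 1) %/% K^(j - 1)) %% K + 1`, so slot 1 varies fastest and the
#' index-to-assignment map is a bijection.
#'
#' The exact enumeration is what makes the collective posterior tractable
#' only for sparse neighbourhoods (cost `O(N K^g)`); a configurable cap
#' guards against accidental blow-ups.
#'
#' @param K number of types (>= 1).
#' @param degree subgraph in-degree (>= 1).
#' @param cap maximum admissible `K^degree`.
#' @return a `realization_table`: list with `K`, `degree` and `phi`, the
#'   `K^degree x degree` integer matrix whose row `r` is the assignment of
#'   realization `r` (the phi lookup: `phi[r, j]` is the type of slot `j`).
#' @examples
#' enumerate_realizations(2, 2)$phi
#' @export
enumerate_realizations <- function(K, degree, cap = 262144L) {
  stopifnot(K >= 1L, degree >= 1L)
  n <- K^degree
  if (n > cap) {
    stop("K^degree = ", n, " exceeds the enumeration cap (", cap, "); ",
         "use the evolving per-edge recursion or reduce the neighbourhood")
  }
  idx <- seq_len(n) - 1L
  phi <- vapply(seq_len(degree), function(j) {
    as.integer((idx %/% K^(j - 1L)) %% K + 1L)
  }, integer(n))
  phi <- matrix(as.integer(phi), n, degree)
  structure(list(K = as.integer(K), degree = as.integer(degree), phi = phi),
            class = "realization_table")
}

#' Priors over subgraph realizations
#'
#' One prior table per distinct in-degree; nodes index into the table for
#' their degree. `uniform_prior()` builds the flat initialization.
#'
#' @param K number of types.
#' @param degrees integer vector of distinct in-degrees present in the data.
#' @return a `realization_prior`: named list (by degree) of probability
#'   vectors over the corresponding realization tables.
#' @export
uniform_prior <- function(K, degrees) {
  tabs <- lapply(degrees, function(g) {
    n <- K^g
    rep(1 / n, n)
  })
  names(tabs) <- as.character(degrees)
  structure(list(K = as.integer(K), tables = tabs), class = "realization_prior")
}

# floor-and-renormalize, guarding the log in the Q function
.floor_probs <- function(p, eps = 1e-8) {
  p <- pmax(p, eps)
  p / sum(p)
}

# numerically stable log(sum(exp(x))) over rows of a matrix
.logsumexp_rows <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}
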