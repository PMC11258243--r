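#' Evolving-topology collective relational inference
#'
#' When nodes interact with different neighbours at different times, the
#' fixed-subgraph enumeration no longer applies. Instead each directed pair
#' that ever interacts carries a categorical posterior over the `K` types,
#' updated sequentially: at every time step, the posterior of each active
#' edge is multiplied by the likelihood of the observed increment with all
#' other active edges of the same receiver marginalized out under their
#' current (factorized) posteriors. The edge type itself never changes over
#' time — only the active edge set does — so a re-appearing edge resumes its
#' posterior.
#'
#' @name evolving_cri
NULL

.edge_key <- function(i, j) paste0(i, ",", j)

# registry of every directed pair active at any time step
.edge_registry <- function(traj) {
  keys <- unique(unlist(lapply(traj$neighbors, function(e) {
    .edge_key(e[, 1L], e[, 2L])
  })))
  sort(keys)
}

#' Initialize per-edge type posteriors from the prior
#'
#' Every edge that is ever active starts at the type prior `tau` (the
#' zero-information state). Rows are independent copies.
#'
#' @param traj an `evolving_trajectory` (its per-step neighbour lists define
#'   the edge registry), or a character vector of `"i,j"` edge keys.
#' @param tau type prior (length `K`, sums to 1).
#' @return an `edge_posterior` matrix (edges x K, rows named `"i,j"`).
#' @export
init_edge_posteriors <- function(traj, tau) {
  stopifnot(abs(sum(tau) - 1) < 1e-8)
  keys <- if (is.character(traj)) traj else .edge_registry(traj)
  P <- matrix(tau, length(keys), length(tau), byrow = TRUE,
              dimnames = list(keys, NULL))
  structure(P, class = c("edge_posterior", "matrix"))
}

# evolving states at one step as feature matrices
.evolving_states <- function(traj, t) {
  N <- dim(traj$positions)[2L]
  d <- dim(traj$positions)[3L]
  pos <- matrix(traj$positions[t, , ], N, d)
  vel <- matrix(traj$velocities[t, , ], N, d)
  cbind(pos, vel, traj$masses)
}

#' One sequential posterior update (all edges active at step `t`)
#'
#' Synchronous semantics: every update at step `t` reads the posterior state
#' from before `t`, and all updated rows are written together, so the order
#' of nodes within a step is irrelevant. For each active edge of receiver
#' `i`, the update multiplies the edge's current posterior by the increment
#' likelihood with the other active edges marginalized out under the
#' factorized joint (enumerating the `K^{|active|}` co-realizations).
#'
#' @param posteriors an `edge_posterior` matrix.
#' @param traj an `evolving_trajectory`.
#' @param t time-step index (uses states and increments at `t`).
#' @param bank an [edge_bank()] (physics mode).
#' @param sigma2 likelihood variance.
#' @param cap maximum admissible `K^degree` enumeration size.
#' @return the updated `edge_posterior` matrix.
#' @export
sequential_update <- function(posteriors, traj, t, bank, sigma2,
                              cap = 262144L) {
  edges <- traj$neighbors[[t]]
  if (!nrow(edges)) return(posteriors)
  S <- .evolving_states(traj, t)
  N <- dim(traj$positions)[2L]
  d <- dim(traj$positions)[3L]
  tgt_all <- matrix(traj$increments[t, , ], N, d)
  K <- ncol(posteriors)
  logP <- log(pmax(posteriors, 1e-300))
  recv <- sort(unique(edges[, 1L]))
  deg <- tabulate(edges[, 1L], N)
  newrows <- list()
  for (g in sort(unique(deg[recv]))) {
    nodes <- recv[deg[recv] == g]
    tab <- enumerate_realizations(K, g, cap = cap)
    ni <- length(nodes)
    # slot-major edge layout for this degree group
    eidx <- matrix(0L, ni, g)   # registry row of each (receiver, slot)
    Xi <- matrix(0, ni * g, ncol(S)); Xj <- Xi
    for (a in seq_len(ni)) {
      i <- nodes[a]
      js <- sort(edges[edges[, 1L] == i, 2L])
      eidx[a, ] <- match(.edge_key(i, js), rownames(posteriors))
      rows <- (seq_len(g) - 1L) * ni + a
      Xi[rows, ] <- matrix(S[i, ], g, ncol(S), byrow = TRUE)
      Xj[rows, ] <- S[js, , drop = FALSE]
    }
    if (any(is.na(eidx))) stop("active edge missing from the posterior registry")
    msgs <- lapply(seq_len(K), function(k) .net_forward(bank, k, cbind(Xi, Xj)))
    slot <- function(M, j) M[(j - 1L) * ni + seq_len(ni), , drop = FALSE]
    tgt <- tgt_all[nodes, , drop = FALSE]
    mass <- traj$masses[nodes]
    const <- -0.5 * d * log(2 * pi * sigma2)
    lognew <- array(-Inf, c(ni, g, K))
    for (z in seq_len(nrow(tab$phi))) {
      s <- 0
      logw <- 0
      for (j in seq_len(g)) {
        k <- tab$phi[z, j]
        s <- s + slot(msgs[[k]], j)
        logw <- logw + logP[cbind(eidx[, j], k)]
      }
      R <- s / mass - tgt
      ls <- logw + const - rowSums(R * R) / (2 * sigma2)
      for (j in seq_len(g)) {
        k <- tab$phi[z, j]
        cur <- lognew[, j, k]
        m <- pmax(cur, ls)
        lognew[, j, k] <- ifelse(is.infinite(m) & m < 0, -Inf,
                                 m + log(exp(cur - m) + exp(ls - m)))
      }
    }
    for (j in seq_len(g)) {
      lp <- lognew[, j, , drop = TRUE]
      lp <- matrix(lp, ni, K)
      p <- exp(lp - apply(lp, 1L, max))
      p <- p / rowSums(p)
      for (a in seq_len(ni)) newrows[[length(newrows) + 1L]] <-
          list(row = eidx[a, j], p = p[a, ])
    }
  }
  for (nr in newrows) posteriors[nr$row, ] <- nr$p
  if (any(abs(rowSums(posteriors) - 1) > 1e-8)) {
    stop("posterior normalization lost during sequential update")
  }
  posteriors
}

#' Analytic type-prior update
#'
#' The type prior maximizing the expected log-prior term of the evolving Q
#' function is the average per-edge posterior, floored and renormalized.
#'
#' @param posteriors an `edge_posterior` matrix (`p*`).
#' @param eps probability floor.
#' @return numeric prior vector of length `K`.
#' @export
update_tau <- function(posteriors, eps = 1e-8) {
  .floor_probs(colMeans(posteriors), eps)
}

#' Expected complete-data log-likelihood of the evolving model
#'
#' `sum_edges E_{z ~ p*}[log tau_z]` plus the expected increment
#' log-likelihood over all requested steps, the expectation taken under the
#' product of the per-edge posteriors. Exact enumeration while `K^degree`
#' is at most `cap`; beyond that, realizations are sampled from the
#' posterior product under a fixed seed.
#'
#' @inheritParams sequential_update
#' @param tau type prior.
#' @param steps time steps of the data term (default all).
#' @param n_samples Monte Carlo size above the cap.
#' @param seed seed for the sampled fallback.
#' @return scalar.
#' @export
q_evolving <- function(posteriors, tau, bank, traj, sigma2, steps = NULL,
                       cap = 1024L, n_samples = 256L, seed = 1L) {
  T_ <- dim(traj$positions)[1L]
  if (is.null(steps)) steps <- seq_len(T_ - 1L)
  prior_term <- sum(posteriors %*% log(tau))
  N <- dim(traj$positions)[2L]
  d <- dim(traj$positions)[3L]
  K <- ncol(posteriors)
  data_term <- 0
  for (t in steps) {
    edges <- traj$neighbors[[t]]
    if (!nrow(edges)) next
    S <- .evolving_states(traj, t)
    tgt_all <- matrix(traj$increments[t, , ], N, d)
    const <- -0.5 * d * log(2 * pi * sigma2)
    for (i in sort(unique(edges[, 1L]))) {
      js <- sort(edges[edges[, 1L] == i, 2L])
      g <- length(js)
      eix <- match(.edge_key(i, js), rownames(posteriors))
      Xi <- matrix(S[i, ], g, ncol(S), byrow = TRUE)
      Xj <- S[js, , drop = FALSE]
      msg <- lapply(seq_len(K), function(k) .net_forward(bank, k, cbind(Xi, Xj)))
      if (K^g <= cap) {
        tab <- enumerate_realizations(K, g)
        for (z in seq_len(nrow(tab$phi))) {
          s <- 0; w <- 1
          for (j in seq_len(g)) {
            k <- tab$phi[z, j]
            s <- s + msg[[k]][j, ]
            w <- w * posteriors[eix[j], k]
          }
          R <- s / traj$masses[i] - tgt_all[i, ]
          data_term <- data_term + w * (const - sum(R * R) / (2 * sigma2))
        }
      } else {
        draws <- withr::with_seed(seed + t, {
          vapply(seq_len(n_samples), function(r) {
            zz <- vapply(seq_len(g), function(j) {
              sample.int(K, 1L, prob = posteriors[eix[j], ])
            }, integer(1L))
            s <- 0
            for (j in seq_len(g)) s <- s + msg[[zz[j]]][j, ]
            R <- s / traj$masses[i] - tgt_all[i, ]
            const - sum(R * R) / (2 * sigma2)
          }, numeric(1L))
        })
        data_term <- data_term + mean(draws)
      }
    }
  }
  prior_term + data_term
}

#' Decode per-edge types from the sequential posteriors
#'
#' Componentwise argmax with the lowest-index tie-break.
#'
#' @param posteriors an `edge_posterior` matrix.
#' @return named integer vector of types, keyed by `"i,j"`.
#' @export
decode_edge_types_evolving <- function(posteriors) {
  out <- apply(posteriors, 1L, which.max)
  stats::setNames(as.integer(out), rownames(posteriors))
}

#' Fit the evolving-topology model
#'
#' Each epoch re-runs the sequential posterior recursion from the
#' `tau`-initialized state over the training steps in time order (the
#' recursion conditions on the current network parameters, so stale
#' posteriors from earlier epochs would mix parameter generations), then
#' updates `tau` analytically and sweeps Adam minibatches over the expected
#' data term of the evolving Q function. When validation steps are given,
#' the model with the best one-step acceleration error is returned.
#'
#' @param traj an `evolving_trajectory`.
#' @param K number of types.
#' @param config a [cri_config()] (`mode` must be `"physics"`).
#' @param train_steps,val_steps time-step indices (targets `1..T-1`);
#'   default: all steps train.
#' @return an `ecri_fit`: `bank`, `tau`, `posteriors` (`p*`), decoded
#'   `types`, `history`.
#' @export
fit_evolving_cri <- function(traj, K, config = cri_config(),
                             train_steps = NULL, val_steps = NULL) {
  stopifnot(config$mode == "physics")
  T_ <- dim(traj$positions)[1L]
  if (is.null(train_steps)) train_steps <- seq_len(T_ - 1L)
  train_steps <- sort(train_steps)
  seeds <- .spawn_seeds(config$seed, 2L + config$epochs)
  p <- 2L * dim(traj$positions)[3L] + 1L
  d <- dim(traj$positions)[3L]
  bank <- edge_bank(K, p, d, hidden = config$hidden, mode = "physics",
                    activation = config$activation, seed = seeds[1L])
  if (length(train_steps)) {
    probe <- train_steps[unique(pmax(1L, round(seq(1L, length(train_steps),
                                                   length.out = 25L))))]
    XX <- do.call(rbind, lapply(probe, function(t) {
      S <- .evolving_states(traj, t)
      e <- traj$neighbors[[t]]
      cbind(S[e[, 1L], , drop = FALSE], S[e[, 2L], , drop = FALSE])
    }))
    bank <- .bank_set_normalization(bank, XX)
  }
  tau <- rep(1 / K, K)
  keys <- .edge_registry(traj)
  opt_state <- NULL
  gstep <- 0L
  hist <- data.frame(epoch = integer(0L), val_mae_acc = numeric(0L))
  best <- list(val = Inf, bank = bank, tau = tau, post = NULL, epoch = 0L)
  posteriors <- init_edge_posteriors(keys, tau)
  interleave <- config$e_refresh == "batch"
  for (ep in seq_len(config$epochs)) {
    posteriors <- init_edge_posteriors(keys, tau)
    if (interleave) {
      # online pass: after absorbing step t into the posteriors, the
      # networks take one gradient step on step t's data weighted by the
      # just-updated (never stale) per-edge posteriors
      if (is.null(opt_state)) {
        opt_state <- lapply(seq_len(K), function(k) {
          adam_new(length(mlp_flatten(bank$nets[[k]])))
        })
      }
      for (t in train_steps) {
        posteriors <- sequential_update(posteriors, traj, t, bank, config$sigma2)
        r <- .evolving_step_grad(traj, t, posteriors, bank, config$sigma2)
        if (!r$nrows) next
        gstep <- gstep + 1L
        lr <- if (is.null(config$lr_decay)) config$lr else {
          config$lr / (1 + gstep / config$lr_decay)
        }
        for (k in seq_len(K)) {
          st <- adam_step(opt_state[[k]], mlp_flatten(bank$nets[[k]]),
                          r$grads[[k]] / r$nrows, lr = lr)
          opt_state[[k]] <- st$state
          bank$nets[[k]] <- mlp_unflatten(bank$nets[[k]], st$theta)
        }
      }
      tau <- update_tau(posteriors, config$prior_floor)
    } else {
      for (t in train_steps) {
        posteriors <- sequential_update(posteriors, traj, t, bank, config$sigma2)
      }
      tau <- update_tau(posteriors, config$prior_floor)
      res <- .m_step_evolving(traj, train_steps, posteriors, bank,
                              config$sigma2, opt_state, config,
                              seeds[2L + ep], gstep)
      bank <- res$bank
      opt_state <- res$opt_state
      gstep <- res$gstep
    }
    vm <- NA_real_
    if (!is.null(val_steps) &&
        (ep %% config$val_every == 0L || ep == config$epochs)) {
      types <- decode_edge_types_evolving(posteriors)
      vm <- mae_acceleration(bank, types, traj, steps = val_steps)
      if (vm < best$val) {
        best <- list(val = vm, bank = bank, tau = tau, post = posteriors,
                     epoch = ep)
      }
    }
    hist[nrow(hist) + 1L, ] <- list(ep, vm)
    if (config$verbose) message(sprintf("epoch %3d  val mae %.5g", ep, vm))
  }
  if (!is.null(val_steps) && is.finite(best$val)) {
    bank <- best$bank; tau <- best$tau; posteriors <- best$post
  }
  structure(list(bank = bank, tau = tau, posteriors = posteriors,
                 types = decode_edge_types_evolving(posteriors),
                 history = hist, config = config, K = K,
                 best_epoch = if (is.null(val_steps)) NA_integer_ else best$epoch),
            class = "ecri_fit")
}

# gradients of the expected data term at one time step, weighted by the
# product of the current per-edge posteriors
.evolving_step_grad <- function(traj, t, posteriors, bank, sigma2) {
  K <- bank$K
  N <- dim(traj$positions)[2L]
  d <- dim(traj$positions)[3L]
  logP <- log(pmax(posteriors, 1e-300))
  edges <- traj$neighbors[[t]]
  grads <- lapply(seq_len(K), function(k) NULL)
  nrows <- 0L
  if (!nrow(edges)) return(list(grads = grads, nrows = 0L))
  S <- .evolving_states(traj, t)
  tgt_all <- matrix(traj$increments[t, , ], N, d)
  recv <- sort(unique(edges[, 1L]))
  deg <- tabulate(edges[, 1L], N)
  for (g in sort(unique(deg[recv]))) {
    nodes <- recv[deg[recv] == g]
    tab <- enumerate_realizations(K, g)
    ni <- length(nodes)
    eidx <- matrix(0L, ni, g)
    Xi <- matrix(0, ni * g, ncol(S)); Xj <- Xi
    for (a in seq_len(ni)) {
      i <- nodes[a]
      js <- sort(edges[edges[, 1L] == i, 2L])
      eidx[a, ] <- match(.edge_key(i, js), rownames(posteriors))
      rows <- (seq_len(g) - 1L) * ni + a
      Xi[rows, ] <- matrix(S[i, ], g, ncol(S), byrow = TRUE)
      Xj[rows, ] <- S[js, , drop = FALSE]
    }
    EdgeB <- cbind(Xi, Xj)
    outs <- lapply(seq_len(K), function(k) .net_forward(bank, k, EdgeB, cache = TRUE))
    slot <- function(M, j) M[(j - 1L) * ni + seq_len(ni), , drop = FALSE]
    tgt <- tgt_all[nodes, , drop = FALSE]
    mass <- traj$masses[nodes]
    dY <- lapply(seq_len(K), function(k) matrix(0, ni * g, d))
    for (z in seq_len(nrow(tab$phi))) {
      s <- 0; logw <- 0
      for (j in seq_len(g)) {
        k <- tab$phi[z, j]
        s <- s + slot(outs[[k]], j)
        logw <- logw + logP[cbind(eidx[, j], k)]
      }
      w <- exp(logw)
      R <- s / mass - tgt
      wR <- (w / (sigma2 * mass)) * R
      for (j in seq_len(g)) {
        k <- tab$phi[z, j]
        rows <- (j - 1L) * ni + seq_len(ni)
        dY[[k]][rows, ] <- dY[[k]][rows, ] + wR
      }
    }
    for (k in seq_len(K)) {
      gk <- mlp_backward(bank$nets[[k]], outs[[k]], dY[[k]])
      flat <- .grad_flatten(gk)
      grads[[k]] <- if (is.null(grads[[k]])) flat else grads[[k]] + flat
    }
    nrows <- nrows + ni
  }
  list(grads = grads, nrows = nrows)
}

# Adam minibatch sweep on the expected data term, weights from p*
.m_step_evolving <- function(traj, steps, posteriors, bank, sigma2,
                             opt_state, config, sweep_seed, gstep) {
  K <- bank$K
  minibatch <- config$minibatch
  if (is.null(opt_state)) {
    opt_state <- lapply(seq_len(K), function(k) adam_new(length(mlp_flatten(bank$nets[[k]]))))
  }
  N <- dim(traj$positions)[2L]
  steps_per_batch <- max(1L, floor(minibatch / N))
  shuffled <- withr::with_seed(sweep_seed, sample(steps))
  batches <- split(shuffled, ceiling(seq_along(shuffled) / steps_per_batch))
  for (bt in batches) {
    grads <- lapply(seq_len(K), function(k) NULL)
    nrows <- 0L
    for (t in bt) {
      r <- .evolving_step_grad(traj, t, posteriors, bank, sigma2)
      if (!r$nrows) next
      nrows <- nrows + r$nrows
      for (k in seq_len(K)) {
        grads[[k]] <- if (is.null(grads[[k]])) r$grads[[k]] else grads[[k]] + r$grads[[k]]
      }
    }
    if (!nrows) next
    gstep <- gstep + 1L
    lr <- if (is.null(config$lr_decay)) config$lr else {
      config$lr / (1 + gstep / config$lr_decay)
    }
    for (k in seq_len(K)) {
      st <- adam_step(opt_state[[k]], mlp_flatten(bank$nets[[k]]),
                      grads[[k]] / nrows, lr = lr)
      opt_state[[k]] <- st$state
      bank$nets[[k]] <- mlp_unflatten(bank$nets[[k]], st$theta)
    }
  }
  list(bank = bank, opt_state = opt_state, gstep = gstep)
}
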