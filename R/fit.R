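#' Training configuration for the collective EM procedure
#'
#' Defaults follow the training setup used throughout: Adam with learning
#' rate 0.001, isotropic likelihood variance `sigma2 = 0.01`, uniform prior
#' initialization and seeded small-random network initialization. `epochs`
#' and the network width are scaled to the problem at hand; the reference
#' configuration for the full-size benchmarks is 500 epochs with three
#' hidden layers of 128 units, while the desk-scale presets in this package
#' use fewer epochs and narrower nets (see the vignette).
#'
#' @param epochs EM epochs; each epoch is one E step followed by one M-step
#'   sweep over minibatches of (node, time) pairs.
#' @param lr Adam learning rate (also the initial step length in
#'   line-search mode).
#' @param sigma2 Gaussian likelihood variance. Grid-searched per experiment
#'   in practice; typical grid `{1e-3, 1e-2, 1e-1}`.
#' @param hidden hidden widths of every edge network.
#' @param mode `"physics"` (force sum / mass) or `"mpnn"`.
#' @param activation hidden nonlinearity of the networks.
#' @param msg_dim,node_hidden message width and node-network widths
#'   (`"mpnn"` only).
#' @param minibatch (node, time) pairs per Adam step; `Inf` for a single
#'   full-batch step per epoch.
#' @param e_refresh `"batch"` (default): the subgraph posteriors entering
#'   each gradient step are recomputed for that step's node-sims under the
#'   current parameters, so no step ever uses stale responsibilities — the
#'   direct stochastic analogue of alternating one exact E step with one
#'   gradient ascent step. `"epoch"`: one full E step per epoch with the
#'   posteriors held fixed over the whole minibatch sweep.
#' @param ns_batch node-sims per stochastic E/M step (`e_refresh =
#'   "batch"`).
#' @param lr_decay if not `NULL`, the learning rate of global step `s` is
#'   `lr / (1 + s / lr_decay)` (hyperbolic decay); `NULL` keeps it fixed.
#' @param n_init number of independent initializations probed before the
#'   main run (stochastic regime only). Each candidate is trained for
#'   `init_epochs` epochs and the one with the best marginal likelihood
#'   continues. EM occasionally fails to break the type symmetry from an
#'   unlucky initialization; collapsed probes are far behind in marginal
#'   likelihood, so a short probe phase screens them out.
#' @param init_epochs probe length (epochs) when `n_init > 1`.
#' @param line_search if `TRUE`, the M step is one full-batch gradient step
#'   halved until the Q function does not decrease, which guarantees a
#'   non-decreasing marginal likelihood (generalized EM); slower but used
#'   for convergence diagnostics.
#' @param prior_floor probability floor applied to priors.
#' @param seed master seed; all randomness (initialization, minibatch
#'   shuffles) derives from it.
#' @param val_every validate (and checkpoint the best model) every this
#'   many epochs.
#' @param horizon rollout horizon of the validation state error.
#' @param verbose print progress.
#' @return a `cri_config` list.
#' @export
cri_config <- function(epochs = 100L, lr = 1e-3, sigma2 = 0.01,
                       hidden = c(64, 64), mode = c("physics", "mpnn"), activation = "elu",
                       msg_dim = 16L, node_hidden = c(64), minibatch = 512L,
                       e_refresh = c("batch", "epoch"), ns_batch = 32L,
                       lr_decay = NULL, n_init = 1L, init_epochs = 20L,
                       line_search = FALSE, prior_floor = 1e-8, seed = 1L,
                       val_every = 10L, horizon = 10L, verbose = FALSE) {
  e_refresh <- match.arg(e_refresh)
  mode <- match.arg(mode)
  stopifnot(epochs >= 1L, lr > 0, sigma2 > 0, prior_floor > 0)
  structure(as.list(environment()), class = "cri_config")
}

.update_priors_mat <- function(post, eps) {
  tabs <- lapply(post, function(P) .floor_probs(colMeans(P), eps))
  tabs
}

#' Fit the collective relational inference model (fixed topology)
#'
#' Alternates the exact subgraph E step with the analytic prior update and
#' gradient M step for `config$epochs` epochs, recording the marginal
#' log-likelihood per epoch. When validation data are supplied, the model
#' with the best validation rollout state error is returned (type accuracy
#' is never used for selection — ground-truth types are not available in
#' practice). Deterministic given `config$seed`.
#'
#' @param train an `ri_dataset` of training simulations.
#' @param K number of interaction types (assumed known).
#' @param config a [cri_config()].
#' @param val optional `ri_dataset` used for model selection.
#' @return a `cri_fit`: the selected `bank` and `priors`, final train
#'   `posteriors`, decoded train `types`, and a per-epoch `history` data
#'   frame (epoch, marginal log-likelihood, Q, validation state error).
#' @export
fit_cri <- function(train, K, config = cri_config(), val = NULL) {
  arrays <- .build_arrays(train)
  seeds <- .spawn_seeds(config$seed, 2L + config$epochs)
  bank <- edge_bank(K, arrays$p, arrays$d, hidden = config$hidden,
                    mode = config$mode, msg_dim = config$msg_dim,
                    node_hidden = config$node_hidden,
                    activation = config$activation, seed = seeds[1L])
  bank <- .bank_set_normalization(
    bank, do.call(rbind, lapply(arrays$groups, `[[`, "EdgeX")))
  # pre-normalized inputs for the stochastic path (the normalization is
  # fixed for the whole fit, so this is purely a cached transform)
  for (g in names(arrays$groups)) {
    arrays$groups[[g]]$EdgeXn <- .bank_input(bank, arrays$groups[[g]]$EdgeX)
  }
  degrees <- vapply(arrays$groups, `[[`, integer(1L), "degree")
  priors <- uniform_prior(K, degrees)
  val_arrays <- if (!is.null(val)) .build_arrays(val)
  opt_state <- NULL
  hist <- data.frame(epoch = integer(0L), marginal_ll = numeric(0L),
                     q = numeric(0L), val_mae_state = numeric(0L))
  best <- list(val = Inf, bank = bank, priors = priors, epoch = 0L)
  stochastic <- !config$line_search && config$e_refresh == "batch" &&
    config$mode == "physics"
  gstep <- 0L
  if (stochastic && config$n_init > 1L) {
    cand_seeds <- .spawn_seeds(seeds[2L], config$n_init)
    best_probe <- NULL
    for (ci in seq_len(config$n_init)) {
      b <- edge_bank(K, arrays$p, arrays$d, hidden = config$hidden,
                     mode = config$mode, activation = config$activation,
                     seed = cand_seeds[ci])
      b$in_center <- bank$in_center; b$in_scale <- bank$in_scale
      pr <- uniform_prior(K, degrees)
      st <- list(bank = b, priors = pr, opt_state = NULL, gstep = 0L)
      probe_seeds <- .spawn_seeds(cand_seeds[ci], config$init_epochs)
      for (pe in seq_len(config$init_epochs)) {
        st <- .stochastic_epoch(arrays, st$bank, st$priors, config,
                                st$opt_state, probe_seeds[pe], st$gstep)
      }
      mll <- .marginal_ll(arrays, st$bank, st$priors, config$sigma2)
      if (is.null(best_probe) || mll > best_probe$mll) {
        best_probe <- c(st, list(mll = mll))
      }
    }
    bank <- best_probe$bank
    priors <- best_probe$priors
    opt_state <- best_probe$opt_state
    gstep <- best_probe$gstep
  }
  for (ep in seq_len(config$epochs)) {
    if (stochastic) {
      res <- .stochastic_epoch(arrays, bank, priors, config, opt_state,
                               seeds[2L + ep], gstep)
      bank <- res$bank
      priors <- res$priors
      opt_state <- res$opt_state
      gstep <- res$gstep
      mll <- .marginal_ll(arrays, bank, priors, config$sigma2)
      qv <- NA_real_
    } else {
      post <- .posterior_matrices(arrays, bank, priors, config$sigma2)
      mll <- .marginal_ll(arrays, bank, priors, config$sigma2)
      priors$tables <- .update_priors_mat(post, config$prior_floor)
      res <- .m_step(arrays, post, bank, config$sigma2, opt_state,
                     config$lr, config$line_search,
                     if (config$line_search) Inf else config$minibatch,
                     sweep_seed = seeds[2L + ep])
      bank <- res$bank
      opt_state <- res$opt_state
      qv <- if (is.na(res$q_term)) NA_real_ else {
        res$q_term + sum(vapply(names(post), function(g) {
          sum(post[[g]] %*% log(priors$tables[[g]]))
        }, numeric(1L)))
      }
    }
    vm <- NA_real_
    if (!is.null(val) && (ep %% config$val_every == 0L || ep == config$epochs)) {
      vm <- .validate(val_arrays, val, bank, priors, config)
      if (vm < best$val) {
        best <- list(val = vm, bank = bank, priors = priors, epoch = ep)
      }
    }
    hist[nrow(hist) + 1L, ] <- list(ep, mll, qv, vm)
    if (config$verbose) {
      message(sprintf("epoch %3d  marginal ll %.3f  val %.4g", ep, mll, vm))
    }
  }
  if (!is.null(val) && is.finite(best$val)) {
    bank <- best$bank
    priors <- best$priors
  }
  post <- .posterior_matrices(arrays, bank, priors, config$sigma2)
  posteriors <- .package_posteriors(arrays, post, train, K = K)
  types <- decode_edge_types(posteriors, train)
  structure(list(bank = bank, priors = priors, posteriors = posteriors,
                 types = types, history = hist, config = config, K = K,
                 best_epoch = if (is.null(val)) NA_integer_ else best$epoch),
            class = "cri_fit")
}

.validate <- function(val_arrays, val, bank, priors, config) {
  post <- .posterior_matrices(val_arrays, bank, priors, config$sigma2)
  posteriors <- .package_posteriors(val_arrays, post, val, K = bank$K)
  types <- decode_edge_types(posteriors, val)
  mae_state(bank, types, val, horizon = config$horizon)
}

#' @export
print.cri_fit <- function(x, ...) {
  cat("Collective relational inference fit\n")
  cat("  K =", x$K, " decoder:", x$bank$mode, "\n")
  cat("  epochs:", nrow(x$history),
      " final marginal log-lik:", format(utils::tail(x$history$marginal_ll, 1L)), "\n")
  if (!is.na(x$best_epoch)) cat("  selected epoch (validation):", x$best_epoch, "\n")
  invisible(x)
}

# One pass over the training node-sims in seeded random order: for every
# batch the subgraph posteriors are recomputed under the current parameters
# (fresh responsibilities), one Adam step is taken per edge network, and the
# realization prior tracks the posteriors through an exponential moving
# average (its analytic M-step solution evaluated online).
.stochastic_epoch <- function(arrays, bank, priors, config, opt_state,
                              sweep_seed, gstep, prior_ema = 0.05) {
  K <- bank$K
  if (is.null(opt_state)) {
    opt_state <- lapply(seq_len(K), function(k) {
      adam_new(length(mlp_flatten(bank$nets[[k]])))
    })
  }
  order_by_group <- withr::with_seed(sweep_seed, {
    lapply(arrays$groups, function(grp) sample(grp$ns))
  })
  for (gname in names(arrays$groups)) {
    grp <- arrays$groups[[gname]]
    tab <- enumerate_realizations(K, grp$degree)
    ord <- order_by_group[[gname]]
    nbatch <- ceiling(length(ord) / config$ns_batch)
    nrows_all <- grp$ns * grp$Tn
    for (b in seq_len(nbatch)) {
      idx <- ord[((b - 1L) * config$ns_batch + 1L):min(b * config$ns_batch,
                                                       length(ord))]
      rows <- as.integer(outer(seq_len(grp$Tn), (idx - 1L) * grp$Tn, `+`))
      er <- as.integer(outer(rows, (seq_len(grp$degree) - 1L) * nrows_all, `+`))
      EdgeB <- grp$EdgeXn[er, , drop = FALSE]
      res <- .cpp_phys_grad(bank$nets, EdgeB, grp$target[rows, , drop = FALSE],
                            grp$mass[rows], tab$phi, matrix(0),
                            log(priors$tables[[gname]]), TRUE, grp$Tn,
                            config$sigma2, arrays$d)
      priors$tables[[gname]] <- .floor_probs(
        (1 - prior_ema) * priors$tables[[gname]] +
          prior_ema * colMeans(res$post), config$prior_floor)
      gstep <- gstep + 1L
      lr <- if (is.null(config$lr_decay)) config$lr else {
        config$lr / (1 + gstep / config$lr_decay)
      }
      nb <- length(rows)
      for (k in seq_len(K)) {
        st <- adam_step(opt_state[[k]], mlp_flatten(bank$nets[[k]]),
                        res$grads[[k]] / nb, lr = lr)
        opt_state[[k]] <- st$state
        bank$nets[[k]] <- mlp_unflatten(bank$nets[[k]], st$theta)
      }
    }
  }
  list(bank = bank, priors = priors, opt_state = opt_state, gstep = gstep)
}
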