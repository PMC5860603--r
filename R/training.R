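#' Training configuration
#'
#' Defaults mirror the tool's conventions: 10 labels, single-component
#' Gaussians, minibatch training on 1% of the genome per round, 1.5% of
#' the genome held out for validation, 100 EM rounds.
#'
#' @param num_labels Number of labels K.
#' @param num_components Mixture components per (label, track).
#' @param regime `"minibatch"` (fresh random region each round) or
#'   `"fixed"` (one region set per instance, sampled at round 0).
#' @param training_fraction Proportion of genome bins trained on per
#'   round (minibatch) or in total (fixed).
#' @param validation_fraction Proportion of genome bins held out from
#'   all training.
#' @param max_rounds Maximum EM rounds. Minibatch always runs them all;
#'   the fixed regime may stop early on convergence.
#' @param num_instances Independent random starts.
#' @param seed Master seed; determines the validation split, every
#'   initialization and every round's minibatch through named child
#'   streams.
#' @param tol Fixed-regime convergence tolerance: relative change in
#'   training log-likelihood below `tol` for 2 consecutive rounds stops
#'   the instance.
#' @param min_length Hard minimum segment length, bins.
#' @param expected_length Soft expected segment length L, bins; sets the
#'   initial self-transition probability `1 - 1/L`.
#' @param fixed_variance Freeze variances at their initial values
#'   (single-component models only).
#' @param weight_pseudocount Optional symmetric Dirichlet pseudocount
#'   added to component weights in the M-step (0 = pure maximum
#'   likelihood; component death is instead handled by re-seeding).
#' @param transition_prior Optional strength of the soft-length
#'   pseudocount prior on transition rows (0 = pure maximum likelihood).
#' @return A `saga_config`.
#' @export
saga_config <- function(num_labels = 10L, num_components = 1L,
                        regime = c("minibatch", "fixed"),
                        training_fraction = 0.01,
                        validation_fraction = 0.015,
                        max_rounds = 100L, num_instances = 1L, seed = 1L,
                        tol = 1e-5, min_length = 1L, expected_length = 100,
                        fixed_variance = FALSE, weight_pseudocount = 0,
                        transition_prior = 0) {
  regime <- match.arg(regime)
  cfg <- list(num_labels = as.integer(num_labels),
              num_components = as.integer(num_components),
              regime = regime,
              training_fraction = as.numeric(training_fraction),
              validation_fraction = as.numeric(validation_fraction),
              max_rounds = as.integer(max_rounds),
              num_instances = as.integer(num_instances),
              seed = as.integer(seed), tol = as.numeric(tol),
              min_length = as.integer(min_length),
              expected_length = as.numeric(expected_length),
              fixed_variance = isTRUE(fixed_variance),
              weight_pseudocount = as.numeric(weight_pseudocount),
              transition_prior = as.numeric(transition_prior))
  stopifnot(cfg$num_labels >= 1L, cfg$num_components >= 1L,
            cfg$max_rounds >= 1L, cfg$num_instances >= 1L,
            cfg$training_fraction > 0, cfg$training_fraction < 1,
            cfg$validation_fraction > 0, cfg$validation_fraction < 1,
            cfg$min_length >= 1L, cfg$expected_length >= 1)
  structure(cfg, class = "saga_config")
}

#' Read a training configuration from a YAML file
#'
#' Keys are the argument names of [saga_config()]; unknown keys are an
#' error so typos do not pass silently.
#'
#' @param path YAML file path.
#' @return A `saga_config`.
#' @export
read_saga_config <- function(path) {
  if (!file.exists(path)) stop_usage("config file not found: %s", path)
  x <- yaml::read_yaml(path)
  bad <- setdiff(names(x), names(formals(saga_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(saga_config, x)
}

#' Sample one minibatch of training chunks
#'
#' Draws chunks uniformly at random without replacement from the
#' training pool until their total bin count first reaches
#' `fraction` of the genome's bins. Uses (and advances) the current RNG
#' state; [saga_fit()] wraps each round's draw in its own named seed
#' stream. Re-drawn independently each round, so across rounds sampling
#' is with replacement.
#'
#' @param store An `obs_store`.
#' @param fraction Minibatch fraction of genome bins.
#' @param pool Chunk ids eligible for training (must exclude all
#'   validation chunks).
#' @return Sorted integer vector of chunk ids.
#' @export
sample_minibatch <- function(store, fraction, pool) {
  if (!length(pool)) stop("empty training pool")
  bins <- store$chunk_table$n_bins[match(pool, store$chunk_table$id)]
  target <- fraction * store$total_bins
  ord <- sample(seq_along(pool))
  k <- which(cumsum(bins[ord]) >= target)[1L]
  if (is.na(k)) k <- length(pool)   # fraction saturates the pool
  sort(pool[ord[seq_len(k)]])
}

store_var_floor <- function(store, factor = 1e-4) {
  # floor at a small multiple of the global per-track data variance
  v <- vapply(seq_along(store$track_names), function(t) {
    x <- unlist(lapply(store$chunks, function(m) m[, t]), use.names = FALSE)
    stats::var(x, na.rm = TRUE)
  }, 0)
  v[!is.finite(v) | v <= 0] <- 1
  factor * v
}

# deterministic, evenly spaced subsample of observed per-track values
# (used for quantile-based initialization and re-seeding)
store_track_values <- function(store, ids = NULL, cap = 100000L) {
  ids <- ids %||% store$chunk_table$id
  lapply(seq_along(store$track_names), function(t) {
    x <- unlist(lapply(store$chunks[ids], function(m) m[, t]),
                use.names = FALSE)
    x <- x[!is.na(x)]
    if (length(x) > cap) x <- x[round(seq(1, length(x), length.out = cap))]
    x
  })
}

#' One EM round on a region set
#'
#' E-step by exact [forward_backward()] on every region chunk; M-step by
#' closed-form updates: responsibility-weighted means per (label, track,
#' component), variances pooled across labels per (track, component)
#' with a variance floor, weights from responsibilities (optionally with
#' a Dirichlet pseudocount), transitions and the initial distribution
#' from expected counts (optionally with a soft-length pseudocount
#' prior). A label receiving zero total responsibility is re-seeded by
#' perturbation (with a message) rather than crashing.
#'
#' @param params Current [saga_params()].
#' @param store An `obs_store`.
#' @param region_ids Chunk ids to train on (non-empty).
#' @param var_floor Per-track variance floor; computed from the region
#'   data if `NULL`.
#' @param weight_pseudocount,transition_prior See [saga_config()].
#' @return List: `params` (updated), `loglik` (total, nats, of the
#'   *input* parameters on these regions), `loglik_per_bin`, `n_bins`
#'   (bins with at least one observed track), `reseeded` (label
#'   indices).
#' @export
em_round <- function(params, store, region_ids, var_floor = NULL,
                     weight_pseudocount = 0, transition_prior = 0) {
  if (!length(region_ids)) stop("em_round needs a non-empty region set")
  e <- params$emission; tr <- params$transitions
  K <- e$K; T_ <- e$T; C <- e$C
  if (is.null(var_floor)) {
    v <- vapply(seq_len(T_), function(t) {
      x <- unlist(lapply(store$chunks[region_ids], function(m) m[, t]),
                  use.names = FALSE)
      stats::var(x, na.rm = TRUE)
    }, 0)
    v[!is.finite(v) | v <= 0] <- 1
    var_floor <- 1e-4 * v
  }
  S0 <- array(0, c(K, T_, C)); S1 <- S0; S2 <- S0
  xi_sum <- matrix(0, K, K)
  pi_sum <- numeric(K)
  ll <- 0; n_obs_bins <- 0L
  for (id in region_ids) {
    values <- store$chunks[[id]]
    terms <- emission_component_terms(params, values)
    E <- emission_logdens_matrix(params, values, terms)
    ex <- expand_transitions(tr)
    res <- fb_core(E[, ex$label_of_state, drop = FALSE], ex$log_pi, ex$log_A)
    M <- matrix(0, ex$S, K)
    M[cbind(seq_len(ex$S), ex$label_of_state)] <- 1
    gamma <- res$gamma %*% M
    for (l in seq_len(K)) {
      sm <- ex$phase_m_states[l]
      xi_sum[l, l] <- xi_sum[l, l] + res$xi[sm, sm]
      for (lp in seq_len(K))
        if (lp != l)
          xi_sum[l, lp] <- xi_sum[l, lp] + res$xi[sm, ex$phase_1_states[lp]]
    }
    pi_sum <- pi_sum + gamma[1L, ]
    ll <- ll + res$loglik
    n_obs_bins <- n_obs_bins +
      sum(rowSums(!is.na(values)) > 0L)
    for (t in seq_len(T_)) {
      tt <- terms[[t]]
      x <- values[tt$obs, t]
      for (l in seq_len(K)) {
        g <- gamma[tt$obs, l]
        for (cc in seq_len(C)) {
          rc <- g * exp(tt$arr[tt$obs, l, cc] - tt$logdens[tt$obs, l])
          S0[l, t, cc] <- S0[l, t, cc] + sum(rc)
          S1[l, t, cc] <- S1[l, t, cc] + sum(rc * x)
          S2[l, t, cc] <- S2[l, t, cc] + sum(rc * x * x)
        }
      }
    }
  }

  new_means <- e$means; new_w <- e$weights; new_var <- e$variances
  denom_ok <- S0 > 1e-12
  new_means[denom_ok] <- (S1 / S0)[denom_ok]
  if (weight_pseudocount > 0) {
    wnum <- S0 + weight_pseudocount
    wden <- apply(wnum, c(1L, 2L), sum)
    for (cc in seq_len(C)) new_w[, , cc] <- wnum[, , cc] / wden
  } else {
    wden <- apply(S0, c(1L, 2L), sum)
    for (cc in seq_len(C))
      new_w[, , cc] <- ifelse(wden > 1e-12, S0[, , cc] / wden,
                              e$weights[, , cc])
  }
  if (!(e$fixed_variance && C == 1L)) {
    for (t in seq_len(T_)) for (cc in seq_len(C)) {
      num <- sum(S2[, t, cc] - 2 * new_means[, t, cc] * S1[, t, cc] +
                   new_means[, t, cc]^2 * S0[, t, cc])
      den <- sum(S0[, t, cc])
      if (den > 1e-12)
        new_var[t, cc] <- max(num / den, var_floor[t])
    }
  }

  # transitions / initial distribution
  new_A <- tr$A
  L <- tr$expected_length
  if (transition_prior > 0) {
    prior <- matrix(transition_prior * (1 / L) / max(K - 1L, 1L), K, K)
    diag(prior) <- transition_prior * (1 - 1 / L)
    cnt <- xi_sum + prior
  } else cnt <- xi_sum
  rs <- rowSums(cnt)
  for (l in seq_len(K))
    if (rs[l] > 1e-12) new_A[l, ] <- cnt[l, ] / rs[l]
  new_pi <- if (sum(pi_sum) > 1e-12) pi_sum / sum(pi_sum) else tr$initial

  # component-death guard: re-seed dead labels from jittered data values
  tot_resp <- apply(S0, 1L, sum)
  reseeded <- which(tot_resp < 1e-8)
  if (length(reseeded)) {
    vals <- store_track_values(store, region_ids, cap = 10000L)
    for (l in reseeded) {
      for (t in seq_len(T_)) {
        x <- vals[[t]]
        if (!length(x)) x <- 0
        q <- stats::quantile(x, probs = stats::runif(C), names = FALSE,
                             type = 7)
        new_means[l, t, ] <- q + stats::rnorm(C, 0, 0.1 * sqrt(new_var[t, ]))
      }
      new_w[l, , ] <- 1 / C
    }
    message("re-seeded label(s) with zero responsibility: ",
            paste(reseeded - 1L, collapse = ", "))
  }

  em <- mixture_emission(new_w, new_means, new_var,
                         fixed_variance = e$fixed_variance)
  trn <- transition_model(new_pi, new_A, expected_length = L,
                          min_length = tr$min_length)
  list(params = saga_params(em, trn, resolution = params$resolution,
                            track_names = params$track_names,
                            label_names = params$label_names),
       loglik = ll, loglik_per_bin = ll / max(n_obs_bins, 1L),
       n_bins = n_obs_bins, reseeded = reseeded)
}

#' Held-out validation log-likelihood
#'
#' Sum of exact forward log-likelihoods over the validation chunks,
#' divided by the number of bins with at least one observed track — a
#' pure function of (parameters, chunks), so minibatch rounds of
#' different sizes stay comparable in nats per bin.
#'
#' @param params A [saga_params()].
#' @param store An `obs_store`.
#' @param ids Validation chunk ids.
#' @return Log-likelihood per bin (nats).
#' @export
validation_loglik <- function(params, store, ids) {
  if (!length(ids)) stop("no validation chunks")
  ex <- expand_transitions(params$transitions)
  ll <- 0; nb <- 0L
  for (id in ids) {
    values <- store$chunks[[id]]
    E <- emission_logdens_matrix(params, values)
    ll <- ll + forward_loglik_core(E[, ex$label_of_state, drop = FALSE],
                                   ex$log_pi, ex$log_A)
    nb <- nb + sum(rowSums(!is.na(values)) > 0L)
  }
  ll / max(nb, 1L)
}

# quantile-based random initialization; uses the current RNG state
init_params <- function(store, cfg, track_values, var_floor) {
  K <- cfg$num_labels; C <- cfg$num_components
  T_ <- length(store$track_names)
  w <- array(1 / C, c(K, T_, C))
  mu <- array(0, c(K, T_, C))
  v <- matrix(1, T_, C)
  for (t in seq_len(T_)) {
    x <- track_values[[t]]
    if (!length(x)) x <- 0
    sdx <- stats::sd(x)
    if (!is.finite(sdx) || sdx <= 0) sdx <- 1
    slots <- K * C
    q <- stats::quantile(x, probs = (seq_len(slots) - 0.5) / slots,
                         names = FALSE, type = 7)
    q <- q + stats::rnorm(slots, 0, 0.1 * sdx)
    mu[, t, ] <- matrix(q[sample.int(slots)], K, C)
    v[t, ] <- max(stats::var(x), var_floor[t] / 1e-4 * 1e-2, 1e-8)
  }
  L <- cfg$expected_length
  A <- matrix(if (K > 1L) (1 / L) / (K - 1L) else 0, K, K)
  diag(A) <- if (K > 1L) 1 - 1 / L else 1
  em <- mixture_emission(w, mu, v, fixed_variance = cfg$fixed_variance)
  tr <- transition_model(rep(1 / K, K), A,
                         expected_length = L, min_length = cfg$min_length)
  saga_params(em, tr, resolution = store$layout$resolution,
              track_names = store$track_names)
}

#' Fit the segmentation model
#'
#' The central fitting routine: runs `num_instances` independent EM
#' random starts on the training pool, computes the held-out validation
#' log-likelihood after every round, and returns the parameters from the
#' (instance, round) pair with the maximal validation likelihood — not
#' necessarily the last round, since minibatch training has no
#' convergence guarantee.
#'
#' One master seed determines the validation split, every
#' initialization and every round's minibatch through named child
#' streams, so a fixed seed gives bit-identical results and adding
#' instances does not perturb existing ones.
#'
#' @param store An `obs_store` from [build_obs_store()].
#' @param ... Arguments forwarded to [saga_config()] (ignored when
#'   `config` is given).
#' @param config A ready-made [saga_config()].
#' @return A `saga_fit` object with components `params` (the winner),
#'   `trace` (a `saga_trace` data.frame: per instance and round the
#'   training and validation log-likelihood per bin and the winner
#'   flag), `split`, `config`. Methods: `print`, `summary`, `coef`,
#'   `logLik`, `predict` (Viterbi annotation), `simulate`, `plot`
#'   (likelihood traces).
#' @seealso [annotate_genome()], [label_fit_report()]
#' @export
saga_fit <- function(store, ..., config = NULL) {
  stopifnot(inherits(store, "obs_store"))
  cfg <- config %||% saga_config(...)
  stopifnot(inherits(cfg, "saga_config"))
  split <- split_validation(store, cfg$validation_fraction,
                            seed = derive_seed(cfg$seed, "split"))
  pool <- split$training
  pool_bins <- sum(store$chunk_table$n_bins[match(pool, store$chunk_table$id)])
  if (cfg$training_fraction * store$total_bins > pool_bins)
    warning("training fraction exceeds the training pool; using all of it")
  var_floor <- store_var_floor(store)
  track_values <- store_track_values(store, pool)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  rows <- list()
  regions_log <- list()
  best <- list(vll = -Inf, params = NULL, instance = NA_integer_,
               round = NA_integer_)
  n_ok <- 0L
  for (i in seq_len(cfg$num_instances)) {
    inst <- tryCatch({
      set.seed(derive_seed(cfg$seed, "init", i))
      params <- init_params(store, cfg, track_values, var_floor)
      regions <- NULL
      prev_ll <- NA_real_
      slow <- 0L
      inst_rows <- list()
      inst_regions <- list()
      inst_best <- list(vll = -Inf, params = NULL, instance = i,
                        round = NA_integer_)
      for (r in seq_len(cfg$max_rounds)) {
        set.seed(derive_seed(cfg$seed, "batch", i, r))
        if (cfg$regime == "minibatch" || is.null(regions))
          regions <- sample_minibatch(store, cfg$training_fraction, pool)
        stepr <- em_round(params, store, regions, var_floor = var_floor,
                          weight_pseudocount = cfg$weight_pseudocount,
                          transition_prior = cfg$transition_prior)
        params <- stepr$params
        vll <- validation_loglik(params, store, split$validation)
        if (!is.finite(stepr$loglik_per_bin) || !is.finite(vll))
          stop("non-finite likelihood in instance ", i, ", round ", r)
        inst_rows[[r]] <- data.frame(instance = i, round = r,
                                     n_region_bins = stepr$n_bins,
                                     train_ll_per_bin = stepr$loglik_per_bin,
                                     validation_ll_per_bin = vll)
        inst_regions[[r]] <- regions
        if (vll > inst_best$vll)
          inst_best <- list(vll = vll, params = params, instance = i,
                            round = r)
        if (cfg$regime == "fixed") {
          rel <- abs(stepr$loglik_per_bin - prev_ll) /
            (abs(prev_ll) + 1e-12)
          prev_ll <- stepr$loglik_per_bin
          slow <- if (is.finite(rel) && rel < cfg$tol) slow + 1L else 0L
          if (slow >= 2L) break
        }
      }
      list(rows = inst_rows, regions = inst_regions, best = inst_best)
    }, error = function(e) {
      warning("instance ", i, " aborted: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(inst)) {
      n_ok <- n_ok + 1L
      rows <- c(rows, inst$rows)
      regions_log[[i]] <- inst$regions
      if (inst$best$vll > best$vll) best <- inst$best
    }
  }
  if (n_ok == 0L) stop("all training instances failed")
  if (is.null(best$params)) stop("no finite validation likelihood recorded")

  trace <- do.call(rbind, rows)
  trace$winner <- trace$instance == best$instance & trace$round == best$round
  attr(trace, "regions") <- regions_log
  class(trace) <- c("saga_trace", "data.frame")

  structure(list(params = best$params, trace = trace, config = cfg,
                 split = split, layout = store$layout,
                 track_names = store$track_names,
                 winner = list(instance = best$instance, round = best$round,
                               validation_ll_per_bin = best$vll),
                 var_floor = var_floor, call = match.call()),
            class = "saga_fit")
}

#' Write a training trace as TSV
#'
#' Columns: instance, round, n_region_bins, train_ll_per_bin,
#' validation_ll_per_bin, winner — ready for plotting likelihood
#' progression against round.
#'
#' @param trace A `saga_trace` (from `fit$trace`).
#' @param path Output path.
#' @export
write_training_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  df$train_ll_per_bin <- fmt_num(df$train_ll_per_bin)
  df$validation_ll_per_bin <- fmt_num(df$validation_ll_per_bin)
  df$winner <- as.integer(df$winner)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
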