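#' @export
print.saga_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("saga_fit: %s training, %d instance(s), %d round(s) max\n",
              cfg$regime, cfg$num_instances, cfg$max_rounds))
  print(x$params)
  cat(sprintf(
    "winner: instance %d, round %d (validation log-likelihood %.6f nats/bin)\n",
    x$winner$instance, x$winner$round, x$winner$validation_ll_per_bin))
  invisible(x)
}

#' @export
summary.saga_fit <- function(object, ...) {
  tr <- as.data.frame(object$trace)
  s <- list(config = object$config, winner = object$winner,
            n_rounds = stats::aggregate(round ~ instance, tr, max),
            final_validation = stats::aggregate(
              validation_ll_per_bin ~ instance, tr, function(v) v[length(v)]),
            split = object$split)
  class(s) <- "summary.saga_fit"
  s
}

#' @export
print.summary.saga_fit <- function(x, ...) {
  cat(sprintf("%s training, %d label(s), %d component(s)\n",
              x$config$regime, x$config$num_labels,
              x$config$num_components))
  print(x$split)
  cat("rounds completed per instance:\n")
  print(x$n_rounds, row.names = FALSE)
  cat(sprintf(
    "winner: instance %d, round %d, validation %.6f nats/bin\n",
    x$winner$instance, x$winner$round, x$winner$validation_ll_per_bin))
  invisible(x)
}

#' @export
coef.saga_fit <- function(object, ...) {
  e <- object$params$emission
  list(means = e$means, variances = e$variances, weights = e$weights,
       transition = object$params$transitions$A,
       initial = object$params$transitions$initial)
}

#' @export
logLik.saga_fit <- function(object, ...) {
  e <- object$params$emission
  K <- e$K; T_ <- e$T; C <- e$C
  npar <- K * T_ * C + T_ * C + K * T_ * (C - 1L) + K * (K - 1L) + (K - 1L)
  structure(object$winner$validation_ll_per_bin,
            df = npar, class = "logLik")
}

#' @export
simulate.saga_fit <- function(object, nsim = 1, seed = NULL, ...,
                              missing_rate = 0) {
  seed <- seed %||% object$config$seed
  lay <- object$layout
  lapply(seq_len(nsim), function(i) {
    spec <- simulation_spec(
      num_labels = object$params$emission$K,
      num_tracks = object$params$emission$T,
      num_components = object$params$emission$C,
      chrom_lengths = stats::setNames(lay$lengths, lay$chroms),
      resolution = lay$resolution,
      expected_length = object$params$transitions$expected_length,
      min_length = object$params$transitions$min_length,
      missing_rate = missing_rate,
      seed = derive_seed(seed, "simfit", i))
    simulate_genome(object$params, spec)
  })
}

#' Plot training and validation likelihood traces
#'
#' Log-likelihood progression against round for every instance:
#' training per-bin likelihood dashed, validation solid, with the
#' winning (instance, round) circled.
#'
#' @param x A `saga_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.saga_fit <- function(x, ...) {
  tr <- as.data.frame(x$trace)
  rng <- range(c(tr$train_ll_per_bin, tr$validation_ll_per_bin))
  graphics::plot(NA, xlim = range(tr$round), ylim = rng,
                 xlab = "EM round", ylab = "log-likelihood (nats/bin)",
                 main = sprintf("%s training", x$config$regime), ...)
  for (i in unique(tr$instance)) {
    s <- tr[tr$instance == i, ]
    graphics::lines(s$round, s$train_ll_per_bin, lty = 2, col = i)
    graphics::lines(s$round, s$validation_ll_per_bin, lty = 1, col = i)
  }
  w <- tr[tr$winner, ]
  graphics::points(w$round, w$validation_ll_per_bin, col = "red", cex = 1.6)
  invisible(x)
}
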