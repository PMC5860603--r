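#' Gaussian-mixture emission parameters
#'
#' Per-label diagonal Gaussian-mixture emissions over tracks. There are
#' `C` mean parameters for every (label, track) pair and `C` variances
#' for every track: variances are tied (shared) across labels per
#' (track, component). With `C = 1` and `fixed_variance = TRUE` the
#' single per-track variance is frozen during training.
#'
#' @param weights K x T x C array of component weights; each `[l, t, ]`
#'   slice sums to 1.
#' @param means K x T x C array of component means (signal units).
#' @param variances T x C matrix of component variances, shared across
#'   labels.
#' @param fixed_variance Logical; freeze variances during the M-step
#'   (only meaningful for `C = 1`).
#' @return A `mixture_emission` object.
#' @export
mixture_emission <- function(weights, means, variances,
                             fixed_variance = FALSE) {
  if (is.matrix(weights)) weights <- array(weights, c(dim(weights), 1L))
  if (is.matrix(means)) means <- array(means, c(dim(means), 1L))
  if (is.vector(variances)) variances <- matrix(variances, ncol = 1L)
  d <- dim(means)
  if (!identical(dim(weights), d))
    stop("weights and means must have identical K x T x C dimensions")
  if (!identical(dim(variances), d[2:3]))
    stop("variances must be a T x C matrix")
  obj <- structure(list(K = d[1L], T = d[2L], C = d[3L],
                        weights = weights, means = means,
                        variances = variances,
                        fixed_variance = isTRUE(fixed_variance)),
                   class = "mixture_emission")
  validate_emission(obj)
  obj
}

validate_emission <- function(e) {
  if (any(!is.finite(e$weights)) || any(e$weights < 0))
    stop("mixture weights must be finite and non-negative")
  sums <- apply(e$weights, c(1L, 2L), sum)
  if (any(abs(sums - 1) > 1e-12))
    stop("mixture weights must sum to 1 per (label, track)")
  if (any(!is.finite(e$means))) stop("means must be finite")
  # zero variance is representable (degenerate generative models); the
  # variance floor keeps fitted parameters strictly positive
  if (any(!is.finite(e$variances) | e$variances < 0))
    stop("variances must be non-negative")
  invisible(e)
}

#' Label transition structure with length constraints
#'
#' A Markov chain over labels gives geometric segment lengths; on top of
#' that, a hard minimum segment length `min_length` (enforced
#' structurally through duration-phase states) and a soft expected
#' length `expected_length` (sets the self-transition probability
#' `1 - 1/L` at initialization/simulation) shape the length
#' distribution.
#'
#' @param initial Initial label distribution (length K).
#' @param A K x K label transition matrix (rows sum to 1).
#' @param expected_length Soft constraint L, in bins (>= 1).
#' @param min_length Hard constraint m, in bins (>= 1).
#' @return A `transition_model`.
#' @export
transition_model <- function(initial, A, expected_length = 100,
                             min_length = 1L) {
  A <- as.matrix(A)
  K <- length(initial)
  if (!all(dim(A) == K)) stop("A must be K x K")
  if (any(!is.finite(initial)) || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-12)
    stop("initial distribution must sum to 1")
  if (any(!is.finite(A)) || any(A < 0) ||
      any(abs(rowSums(A) - 1) > 1e-12))
    stop("transition rows must sum to 1")
  if (min_length < 1L) stop("min_length must be >= 1")
  if (expected_length < 1) stop("expected_length must be >= 1")
  structure(list(K = K, initial = as.numeric(initial), A = A,
                 expected_length = as.numeric(expected_length),
                 min_length = as.integer(min_length)),
            class = "transition_model")
}

#' Full segmentation model parameters
#'
#' @param emission A [mixture_emission()].
#' @param transitions A [transition_model()] with matching label count.
#' @param resolution Base pairs per bin the model operates at.
#' @param track_names Optional track names (length T).
#' @param label_names Optional label names; default `"0" ... "K-1"`.
#' @return A `saga_params` object.
#' @export
saga_params <- function(emission, transitions, resolution = 1,
                        track_names = NULL, label_names = NULL) {
  stopifnot(inherits(emission, "mixture_emission"),
            inherits(transitions, "transition_model"))
  if (emission$K != transitions$K)
    stop("emission and transition label counts disagree")
  if (is.null(track_names)) track_names <- paste0("track", seq_len(emission$T))
  if (length(track_names) != emission$T) stop("bad track_names length")
  if (is.null(label_names)) label_names <- as.character(seq_len(emission$K) - 1L)
  if (length(label_names) != emission$K) stop("bad label_names length")
  structure(list(emission = emission, transitions = transitions,
                 resolution = as.numeric(resolution),
                 track_names = as.character(track_names),
                 label_names = as.character(label_names)),
            class = "saga_params")
}

#' @export
print.saga_params <- function(x, ...) {
  e <- x$emission
  cat(sprintf(
    "segmentation model: %d labels, %d track(s), %d mixture component(s)\n",
    e$K, e$T, e$C))
  cat(sprintf("  resolution %g bp; min segment length %d bins; expected length %g bins\n",
              x$resolution, x$transitions$min_length,
              x$transitions$expected_length))
  if (e$fixed_variance) cat("  variances fixed (not updated in training)\n")
  invisible(x)
}

# --- emission densities ----------------------------------------------------

# Per-track component log terms: list over tracks of n x K x C arrays of
# log(w) + log N(x; mu, sigma^2); NA rows where the track is missing.
# Also the per-track per-label mixture log density (LSE over components).
emission_component_terms <- function(params, values) {
  e <- params$emission
  if (any(e$variances == 0))
    stop("emission densities need strictly positive variances")
  n <- nrow(values)
  lapply(seq_len(e$T), function(t) {
    x <- values[, t]
    bad <- !is.na(x) & (!is.finite(x) | is.nan(x))
    if (any(bad)) stop("non-finite observed signal value")
    obs <- !is.na(x)
    arr <- array(NA_real_, c(n, e$K, e$C))
    for (l in seq_len(e$K))
      for (cc in seq_len(e$C))
        arr[obs, l, cc] <- log(e$weights[l, t, cc]) +
          stats::dnorm(x[obs], e$means[l, t, cc],
                       sqrt(e$variances[t, cc]), log = TRUE)
    ld <- matrix(NA_real_, n, e$K)
    for (l in seq_len(e$K)) {
      m <- arr[obs, l, , drop = FALSE]
      dim(m) <- c(sum(obs), e$C)
      ld[obs, l] <- lse_cols(m)
    }
    list(arr = arr, logdens = ld, obs = obs)
  })
}

# n x K matrix of per-bin per-label emission log densities, summed over
# observed tracks (missing tracks marginalize out and contribute 0).
emission_logdens_matrix <- function(params, values, terms = NULL) {
  if (is.null(terms)) terms <- emission_component_terms(params, values)
  n <- nrow(values)
  out <- matrix(0, n, params$emission$K)
  for (t in seq_along(terms)) {
    ld <- terms[[t]]$logdens
    ld[is.na(ld)] <- 0
    out <- out + ld
  }
  out
}

#' Per-bin emission log density for one label
#'
#' Sum over observed tracks of the log mixture density; missing tracks
#' (`NA`) contribute 0, i.e. they are marginalized out under conditional
#' independence given the label. Computed stably in the log domain.
#'
#' @param params A [saga_params()].
#' @param label Label index (1-based).
#' @param x Numeric vector of length T (one observation row), `NA` for
#'   missing cells.
#' @return Log density in nats.
#' @examples
#' em <- mixture_emission(array(1, c(1, 1, 1)), array(0, c(1, 1, 1)),
#'                        matrix(1 / (2 * pi)))
#' tr <- transition_model(1, matrix(1), 10, 1)
#' emission_log_density(saga_params(em, tr), 1, 0)  # exactly 0
#' @export
emission_log_density <- function(params, label, x) {
  e <- params$emission
  if (label < 1L || label > e$K) stop("invalid label index")
  if (length(x) != e$T) stop("observation row must have length T")
  vals <- matrix(x, nrow = 1L)
  E <- emission_logdens_matrix(params, vals)
  E[1L, label]
}

#' Theoretical CDF of a label's mixture on one track
#'
#' The model-implied ("theoretical") signal distribution for a label on
#' a track: a weighted sum of Gaussian CDFs. Non-decreasing with limits
#' 0 and 1.
#'
#' @inheritParams emission_log_density
#' @param track Track index (1-based).
#' @param x Numeric vector of evaluation points.
#' @return Vector of probabilities.
#' @export
mixture_cdf <- function(params, label, track, x) {
  e <- params$emission
  if (label < 1L || label > e$K) stop("invalid label index")
  if (track < 1L || track > e$T) stop("invalid track index")
  out <- numeric(length(x))
  for (cc in seq_len(e$C))
    out <- out + e$weights[label, track, cc] *
      stats::pnorm(x, e$means[label, track, cc],
                   sqrt(e$variances[track, cc]))
  out
}

# --- state-space expansion --------------------------------------------------

# The hard minimum-length constraint m is realized by m duration-phase
# states per label: phases 1..m-1 advance deterministically, phase m
# carries the label-level transition probabilities. At chunk boundaries
# the constraint is relaxed (initial mass enters at phase m; any phase
# may end the chunk) so chunked inference composes over the genome.
expand_transitions <- function(trans) {
  K <- trans$K
  m <- trans$min_length
  S <- K * m
  A <- matrix(0, S, S)
  pi0 <- numeric(S)
  state <- function(l, p) (l - 1L) * m + p
  for (l in seq_len(K)) {
    pi0[state(l, m)] <- trans$initial[l]
    if (m > 1L)
      for (p in seq_len(m - 1L)) A[state(l, p), state(l, p + 1L)] <- 1
    A[state(l, m), state(l, m)] <- trans$A[l, l]
    for (lp in seq_len(K))
      if (lp != l) A[state(l, m), state(lp, 1L)] <- trans$A[l, lp]
  }
  list(log_A = log(A), log_pi = log(pi0), K = K, m = m, S = S,
       label_of_state = rep(seq_len(K), each = m),
       phase_m_states = state(seq_len(K), m),
       phase_1_states = state(seq_len(K), 1L))
}

chunk_values <- function(chunk) {
  if (is.matrix(chunk)) chunk else chunk$values
}

#' Exact forward-backward inference on one chunk
#'
#' Computes the exact marginal log-likelihood of the chunk under the
#' (length-constraint-expanded) chain, per-bin label posteriors, expected
#' label transition counts and per-cell component responsibilities — the
#' E-step sufficient statistics. All computation is in the natural-log
#' domain with log-sum-exp, so underflow is structurally impossible.
#'
#' @param chunk A bins x tracks numeric matrix (`NA` = missing cell).
#' @param params A [saga_params()].
#' @param responsibilities Return the bins x K x T x C component
#'   responsibility array (default `TRUE`).
#' @return A `chunk_posteriors` list: `loglik`, `loglik_backward`,
#'   `gamma` (bins x K), `xi` (K x K expected transition counts, summed
#'   over positions), `xi_update` (transition events at the label level,
#'   excluding forced phase advances) and optionally `resp`.
#' @export
forward_backward <- function(chunk, params, responsibilities = TRUE) {
  values <- chunk_values(chunk)
  ex <- expand_transitions(params$transitions)
  terms <- emission_component_terms(params, values)
  E <- emission_logdens_matrix(params, values, terms)
  Eexp <- E[, ex$label_of_state, drop = FALSE]
  res <- fb_core(Eexp, ex$log_pi, ex$log_A)
  M <- matrix(0, ex$S, ex$K)
  M[cbind(seq_len(ex$S), ex$label_of_state)] <- 1
  gamma <- res$gamma %*% M
  xi <- t(M) %*% res$xi %*% M
  xiu <- matrix(0, ex$K, ex$K)
  for (l in seq_len(ex$K)) {
    sm <- ex$phase_m_states[l]
    xiu[l, l] <- res$xi[sm, sm]
    for (lp in seq_len(ex$K))
      if (lp != l) xiu[l, lp] <- res$xi[sm, ex$phase_1_states[lp]]
  }
  out <- list(loglik = res$loglik, loglik_backward = res$loglik_backward,
              gamma = gamma, xi = xi, xi_update = xiu)
  if (responsibilities)
    out$resp <- component_responsibilities(params, terms, gamma)
  structure(out, class = "chunk_posteriors")
}

# bins x K x T x C responsibilities: gamma[i,l] * P(component c | x, l, t).
# NA where the cell is missing.
component_responsibilities <- function(params, terms, gamma) {
  e <- params$emission
  n <- nrow(gamma)
  r <- array(NA_real_, c(n, e$K, e$T, e$C))
  for (t in seq_len(e$T)) {
    tt <- terms[[t]]
    for (l in seq_len(e$K))
      for (cc in seq_len(e$C))
        r[tt$obs, l, t, cc] <- gamma[tt$obs, l] *
          exp(tt$arr[tt$obs, l, cc] - tt$logdens[tt$obs, l])
  }
  r
}

#' Viterbi decoding of one chunk
#'
#' Maximum-probability label path honoring the hard minimum-length
#' constraint (relaxed at chunk edges). Ties are broken deterministically
#' towards the lowest state index.
#'
#' @inheritParams forward_backward
#' @return List with `path` (integer labels, 1-based) and `score`
#'   (path log probability plus emission log density, nats).
#' @export
viterbi <- function(chunk, params) {
  values <- chunk_values(chunk)
  ex <- expand_transitions(params$transitions)
  E <- emission_logdens_matrix(params, values)
  res <- viterbi_core(E[, ex$label_of_state, drop = FALSE],
                      ex$log_pi, ex$log_A)
  list(path = ex$label_of_state[res$path + 1L], score = res$score)
}

# --- serialization ----------------------------------------------------------

#' Write / read model parameters as versioned structured text
#'
#' A human-readable tab-separated schema carrying every parameter at full
#' precision (`%.17g`), so `read_saga_params(write_saga_params(p))` is a
#' bit-exact round trip.
#'
#' @param params A [saga_params()].
#' @param path File path.
#' @return `read_saga_params` returns the `saga_params`.
#' @export
write_saga_params <- function(params, path) {
  stopifnot(inherits(params, "saga_params"))
  e <- params$emission; tr <- params$transitions
  ln <- c(
    "sagahmm_params\t1",
    paste0("resolution\t", fmt_num(params$resolution)),
    paste0("num_labels\t", e$K),
    paste0("num_tracks\t", e$T),
    paste0("num_components\t", e$C),
    paste0("min_length\t", tr$min_length),
    paste0("expected_length\t", fmt_num(tr$expected_length)),
    paste0("fixed_variance\t", if (e$fixed_variance) "1" else "0"),
    paste0("tracks\t", paste(params$track_names, collapse = "\t")),
    paste0("labels\t", paste(params$label_names, collapse = "\t")),
    paste0("pi\t", paste(fmt_num(tr$initial), collapse = "\t")))
  for (l in seq_len(e$K))
    ln <- c(ln, paste0("A\t", l - 1L, "\t",
                       paste(fmt_num(tr$A[l, ]), collapse = "\t")))
  for (t in seq_len(e$T))
    ln <- c(ln, paste0("variance\t", t - 1L, "\t",
                       paste(fmt_num(e$variances[t, ]), collapse = "\t")))
  for (l in seq_len(e$K))
    for (t in seq_len(e$T)) {
      ln <- c(ln, paste0("weight\t", l - 1L, "\t", t - 1L, "\t",
                         paste(fmt_num(e$weights[l, t, ]), collapse = "\t")))
      ln <- c(ln, paste0("mean\t", l - 1L, "\t", t - 1L, "\t",
                         paste(fmt_num(e$means[l, t, ]), collapse = "\t")))
    }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_saga_params
#' @export
read_saga_params <- function(path) {
  if (!file.exists(path)) stop_usage("parameter file not found: %s", path)
  lines <- readLines(path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (!length(f) || f[[1L]][1L] != "sagahmm_params")
    stop(path, " is not a sagahmm parameter file")
  if (f[[1L]][2L] != "1")
    stop("unsupported parameter file schema version: ", f[[1L]][2L])
  key <- vapply(f, `[[`, "", 1L)
  get1 <- function(k) {
    i <- which(key == k)
    if (length(i) != 1L) stop("parameter file missing field: ", k)
    f[[i]][-1L]
  }
  K <- as.integer(get1("num_labels"))
  T_ <- as.integer(get1("num_tracks"))
  C <- as.integer(get1("num_components"))
  w <- array(NA_real_, c(K, T_, C)); mu <- array(NA_real_, c(K, T_, C))
  v <- matrix(NA_real_, T_, C)
  A <- matrix(NA_real_, K, K)
  for (i in which(key == "A")) {
    l <- as.integer(f[[i]][2L]) + 1L
    A[l, ] <- as.numeric(f[[i]][-(1:2)])
  }
  for (i in which(key == "variance")) {
    t <- as.integer(f[[i]][2L]) + 1L
    v[t, ] <- as.numeric(f[[i]][-(1:2)])
  }
  for (i in which(key %in% c("weight", "mean"))) {
    l <- as.integer(f[[i]][2L]) + 1L
    t <- as.integer(f[[i]][3L]) + 1L
    x <- as.numeric(f[[i]][-(1:3)])
    if (key[i] == "weight") w[l, t, ] <- x else mu[l, t, ] <- x
  }
  if (anyNA(w) || anyNA(mu) || anyNA(v) || anyNA(A))
    stop(path, ": incomplete parameter file")
  em <- mixture_emission(w, mu, v,
                         fixed_variance = get1("fixed_variance") == "1")
  tr <- transition_model(as.numeric(get1("pi")), A,
                         expected_length = as.numeric(get1("expected_length")),
                         min_length = as.integer(get1("min_length")))
  saga_params(em, tr, resolution = as.numeric(get1("resolution")),
              track_names = get1("tracks"), label_names = get1("labels"))
}
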