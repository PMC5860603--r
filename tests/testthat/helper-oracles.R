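# Independent oracles and small fixture builders. Everything here is a
# deliberately naive re-implementation (no log-domain tricks, no shared
# code with the package internals) used to freeze expected values.

# random valid parameters with unstructured stochastic matrices
rand_params <- function(K, T_ = 1L, C = 1L, m = 1L, seed = 1L,
                        resolution = 1) {
  set.seed(seed)
  w <- array(runif(K * T_ * C, 0.2, 1), c(K, T_, C))
  ws <- apply(w, c(1, 2), sum)
  for (cc in seq_len(C)) w[, , cc] <- w[, , cc] / ws
  mu <- array(rnorm(K * T_ * C, 0, 2), c(K, T_, C))
  v <- matrix(runif(T_ * C, 0.3, 2), T_, C)
  A <- matrix(runif(K * K, 0.2, 1), K, K)
  A <- A / rowSums(A)
  p0 <- runif(K, 0.2, 1)
  saga_params(mixture_emission(w, mu, v),
              transition_model(p0 / sum(p0), A, expected_length = 5,
                               min_length = m),
              resolution = resolution)
}

# random observation matrix with missing cells
rand_obs <- function(n, T_, missing = 0.1, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * T_, 0, 2), n, T_)
  x[matrix(runif(n * T_) < missing, n, T_)] <- NA
  x
}

# plain-arithmetic per-label mixture density of one observation row
oracle_row_density <- function(params, x) {
  e <- params$emission
  sapply(seq_len(e$K), function(l) {
    d <- 1
    for (t in seq_len(e$T)) {
      if (is.na(x[t])) next
      d <- d * sum(e$weights[l, t, ] *
                     dnorm(x[t], e$means[l, t, ], sqrt(e$variances[t, ])))
    }
    d
  })
}

# Brute-force enumeration over all label paths, tracking the duration
# phase explicitly: a label change is only allowed once the current
# segment has run for at least min_length bins, except that the first
# and last segments of a chunk may be truncated by the chunk edge.
# Returns the exact marginal log-likelihood and the best path score.
oracle_enumerate <- function(values, params) {
  n <- nrow(values)
  K <- params$emission$K
  m <- params$transitions$min_length
  logA <- log(params$transitions$A)
  logpi <- log(params$transitions$initial)
  E <- log(t(apply(values, 1L, function(row)
    oracle_row_density(params, row))))
  if (K == 1L) E <- matrix(E, ncol = 1L)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  P <- nrow(paths)
  lp <- logpi[paths[, 1L]] + E[1L, paths[, 1L]]
  phase <- rep(m, P)            # chunk-start relaxation: enter at phase m
  if (n > 1L) for (j in 2:n) {
    same <- paths[, j] == paths[, j - 1L]
    at_m <- phase >= m
    step <- rep(-Inf, P)
    step[same & !at_m] <- 0                       # forced phase advance
    i <- same & at_m
    step[i] <- logA[cbind(paths[i, j - 1L], paths[i, j])]
    i <- !same & at_m
    step[i] <- logA[cbind(paths[i, j - 1L], paths[i, j])]
    lp <- lp + step + E[j, paths[, j]]
    phase <- ifelse(same, pmin(phase + 1L, m), 1L)
  }
  mx <- max(lp)
  list(loglik = mx + log(sum(exp(lp - mx))), best = mx,
       best_path = paths[which.max(lp), ])
}

# brute-force per-position interval overlap
oracle_overlap_label <- function(annotation, chrom, pos) {
  df <- as.data.frame(annotation)
  for (i in seq_len(nrow(df)))
    if (df$chrom[i] == chrom && pos >= df$start[i] && pos < df$end[i])
      return(df$label[i])
  NA_character_
}

# manual type-7 empirical quantile
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# random small annotation over one or two chromosomes
rand_annotation <- function(seed, labels = c("0", "1", "2")) {
  set.seed(seed)
  chroms <- c("chrA", "chrB")[seq_len(sample(2, 1))]
  segs <- do.call(rbind, lapply(chroms, function(ch) {
    cuts <- sort(sample(1:99, sample(2:6, 1)))
    bounds <- c(0, cuts * 10, 1000)
    data.frame(chrom = ch, start = bounds[-length(bounds)],
               end = bounds[-1],
               label = sample(labels, length(bounds) - 1, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  # merge adjacent equal labels so the annotation invariant holds
  keep <- rep(TRUE, nrow(segs))
  for (i in seq_len(nrow(segs))[-1]) {
    if (segs$chrom[i] == segs$chrom[i - 1] &&
        segs$label[i] == segs$label[i - 1]) {
      segs$start[i] <- segs$start[i - 1]
      keep[i - 1] <- FALSE
    }
  }
  segs <- segs[keep, , drop = FALSE]
  rownames(segs) <- NULL
  structure(segs, label_names = labels,
            class = c("saga_annotation", "data.frame"))
}

# small ready-made observation store from a simulated genome
sim_store <- function(params, spec, chunk_size = 200L) {
  sim <- simulate_genome(params, spec)
  layout <- genome_layout(spec$chrom_lengths, resolution = spec$resolution,
                          chunk_size = chunk_size)
  store <- build_obs_store(sim$tracks, layout)
  list(store = store, sim = sim, layout = layout)
}
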