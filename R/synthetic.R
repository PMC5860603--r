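#' Simulation specification
#'
#' Conditions for generating a ground-truth model and a synthetic
#' multi-track genome with the statistical structure the segmentation
#' model assumes: a Markov label path with geometric (plus minimum
#' length) segment durations and per-label Gaussian-mixture emissions
#' with label-tied variances.
#'
#' @param num_labels,num_tracks,num_components Counts (K, T, C).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param resolution Base pairs per bin.
#' @param expected_length Expected segment length L in bins; sets the
#'   self-transition probability `1 - 1/L`.
#' @param min_length Hard minimum segment length in bins.
#' @param mean_separation Pairwise separation of component means, in
#'   units of the per-track emission standard deviation (> 0 for
#'   identifiable scenarios).
#' @param missing_rate Per-cell missing probability in \[0, 1).
#' @param seed Integer seed.
#' @return A `simulation_spec`.
#' @export
simulation_spec <- function(num_labels = 3L, num_tracks = 2L,
                            num_components = 1L,
                            chrom_lengths = c(chrSim = 1e6),
                            resolution = 10, expected_length = 50,
                            min_length = 1L, mean_separation = 3,
                            missing_rate = 0.05, seed = 1L) {
  spec <- list(num_labels = as.integer(num_labels),
               num_tracks = as.integer(num_tracks),
               num_components = as.integer(num_components),
               chrom_lengths = chrom_lengths,
               resolution = as.numeric(resolution),
               expected_length = as.numeric(expected_length),
               min_length = as.integer(min_length),
               mean_separation = as.numeric(mean_separation),
               missing_rate = as.numeric(missing_rate),
               seed = as.integer(seed))
  stopifnot(spec$num_labels >= 1L, spec$num_tracks >= 1L,
            spec$num_components >= 1L, all(spec$chrom_lengths > 0),
            spec$resolution >= 1, spec$expected_length >= 1,
            spec$min_length >= 1L, spec$mean_separation > 0,
            spec$missing_rate >= 0, spec$missing_rate < 1)
  if (is.null(names(spec$chrom_lengths)))
    names(spec$chrom_lengths) <- paste0("chrSim", seq_along(chrom_lengths))
  structure(spec, class = "simulation_spec")
}

#' Draw a random ground-truth model
#'
#' Component means are placed on a jittered grid whose spacing
#' guarantees pairwise separation of at least `mean_separation` standard
#' deviations; transition rows are valid stochastic vectors with
#' self-transition `1 - 1/L`. Deterministic given the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A [saga_params()].
#' @export
random_params <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(spec$seed, "params"))
  K <- spec$num_labels; T_ <- spec$num_tracks; C <- spec$num_components
  v <- matrix(stats::runif(T_ * C, 0.5, 1.5), T_, C)
  mu <- array(0, c(K, T_, C))
  for (t in seq_len(T_)) {
    sd_t <- sqrt(max(v[t, ]))
    slots <- K * C
    # spacing (sep + 0.5) sd with +-0.2 sd jitter keeps every pairwise
    # gap >= sep * sd
    base <- (seq_len(slots) - 1) * (spec$mean_separation + 0.5) * sd_t
    base <- base + stats::runif(slots, -0.2, 0.2) * sd_t
    base <- base - mean(base)
    mu[, t, ] <- matrix(base[sample.int(slots)], K, C)
  }
  w <- array(stats::runif(K * T_ * C, 0.5, 1.5), c(K, T_, C))
  wsum <- apply(w, c(1L, 2L), sum)
  for (cc in seq_len(C)) w[, , cc] <- w[, , cc] / wsum
  L <- spec$expected_length
  if (K > 1L) {
    A <- matrix(0, K, K)
    for (l in seq_len(K)) {
      off <- stats::runif(K - 1L, 0.5, 1.5)
      A[l, -l] <- off / sum(off) * (1 / L)
      A[l, l] <- 1 - 1 / L
    }
    p0 <- stats::runif(K, 0.5, 1.5)
  } else {
    A <- matrix(1, 1L, 1L)
    p0 <- 1
  }
  em <- mixture_emission(w, mu, v)
  tr <- transition_model(p0 / sum(p0), A, expected_length = L,
                         min_length = spec$min_length)
  saga_params(em, tr, resolution = spec$resolution,
              track_names = paste0("track", seq_len(T_)))
}

#' A deliberately bimodal ground truth (single track)
#'
#' Named preset exercising non-normal emissions: one signal track where
#' every label emits from two well-separated Gaussian components, so a
#' single-component fit cannot capture the within-label distribution.
#'
#' @param num_labels Labels K.
#' @param gap_within Distance between a label's two modes (sd units).
#' @param gap_between Distance between consecutive labels' mode pairs
#'   (sd units).
#' @param sd Component standard deviation.
#' @param expected_length Expected segment length in bins.
#' @param resolution Base pairs per bin.
#' @return A [saga_params()] with `C = 2`, `T = 1`.
#' @export
bimodal_params <- function(num_labels = 2L, gap_within = 4, gap_between = 8,
                           sd = 1, expected_length = 30, resolution = 10) {
  K <- as.integer(num_labels)
  mu <- array(0, c(K, 1L, 2L))
  for (l in seq_len(K)) {
    base <- (l - 1L) * gap_between * sd
    mu[l, 1L, ] <- c(base, base + gap_within * sd)
  }
  w <- array(0.5, c(K, 1L, 2L))
  v <- matrix(sd^2, 1L, 2L)
  L <- expected_length
  A <- matrix(if (K > 1L) (1 / L) / (K - 1L) else 0, K, K)
  diag(A) <- if (K > 1L) 1 - 1 / L else 1
  em <- mixture_emission(w, mu, v)
  tr <- transition_model(rep(1 / K, K), A, expected_length = L)
  saga_params(em, tr, resolution = resolution, track_names = "signal")
}

# run-length label path sampler honoring the minimum segment length:
# run length = m + Geometric(1 - a_ll), labels change per the off-
# diagonal transition probabilities; the last run is truncated at the
# chromosome end
sample_label_path <- function(trans, n) {
  K <- trans$K; m <- trans$min_length
  labs <- integer(0); lens <- integer(0)
  l <- sample.int(K, 1L, prob = trans$initial)
  tot <- 0L
  while (tot < n) {
    a <- trans$A[l, l]
    len <- if (a >= 1 || K == 1L) n - tot
           else m + stats::rgeom(1L, 1 - a)
    len <- min(len, n - tot)
    labs <- c(labs, l); lens <- c(lens, len)
    tot <- tot + len
    if (tot < n && K > 1L) {
      cand <- seq_len(K)[-l]
      probs <- trans$A[l, -l]
      l <- cand[sample.int(K - 1L, 1L, prob = probs / sum(probs))]
    }
  }
  rep.int(labs, lens)
}

#' Simulate a synthetic genome from a model
#'
#' Samples a label path per chromosome from the transition model, draws
#' each observed bin's track values from the label's mixture, and
#' injects missing cells at the specified rate. Optionally writes the
#' generated data as the same plain-text files the tool consumes:
#' bedGraph per track, a chromosome-sizes TSV, the truth annotation as
#' BED4 and the generating parameters — all readable back bit-exactly at
#' matching resolution.
#'
#' @param params Generating [saga_params()].
#' @param spec A [simulation_spec()] (chromosome lengths, resolution,
#'   missing rate, seed).
#' @param dir Optional output directory for the file bundle.
#' @return List: `tracks` (named list of `binned_track`s), `truth`
#'   (`saga_annotation`), `labels` (per-chromosome 1-based label index
#'   vectors), `files` (paths, when `dir` is given).
#' @export
simulate_genome <- function(params, spec, dir = NULL) {
  stopifnot(inherits(params, "saga_params"),
            inherits(spec, "simulation_spec"))
  e <- params$emission
  layout <- genome_layout(spec$chrom_lengths, resolution = spec$resolution)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(spec$seed, "genome"))
  labels <- list(); tracks <- rep(list(list()), e$T)
  segs <- list()
  len <- spec$chrom_lengths
  res <- spec$resolution
  for (ch in layout$chroms) {
    nb <- layout$n_bins[[ch]]
    path <- sample_label_path(params$transitions, nb)
    labels[[ch]] <- path
    for (t in seq_len(e$T)) {
      x <- numeric(nb)
      for (l in seq_len(e$K)) {
        idx <- which(path == l)
        if (!length(idx)) next
        comp <- if (e$C == 1L) rep(1L, length(idx))
                else sample.int(e$C, length(idx), replace = TRUE,
                                prob = e$weights[l, t, ])
        x[idx] <- stats::rnorm(length(idx), e$means[l, t, comp],
                               sqrt(e$variances[t, comp]))
      }
      if (spec$missing_rate > 0)
        x[stats::runif(nb) < spec$missing_rate] <- NA_real_
      tracks[[t]][[ch]] <- x
    }
    r <- rle(path)
    ends_bin <- cumsum(r$lengths)
    segs[[ch]] <- data.frame(
      chrom = ch, start = (ends_bin - r$lengths) * res,
      end = pmin(ends_bin * res, len[[ch]]),
      label = params$label_names[r$values], stringsAsFactors = FALSE)
  }
  tracks <- lapply(tracks, function(tr)
    structure(tr, resolution = res, class = "binned_track"))
  names(tracks) <- params$track_names
  truth <- new_annotation(do.call(rbind, segs), resolution = res,
                          label_names = params$label_names)
  out <- list(tracks = tracks, truth = truth, labels = labels,
              layout = layout)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (t in seq_len(e$T)) {
      p <- file.path(dir, paste0(params$track_names[t], ".bedGraph"))
      write_binned_track(tracks[[t]], layout, p)
      files[[params$track_names[t]]] <- p
    }
    files$sizes <- file.path(dir, "chrom.sizes")
    writeLines(sprintf("%s\t%s", layout$chroms, fmt_int(layout$lengths)),
               files$sizes)
    files$truth <- file.path(dir, "truth.bed")
    write_bed(truth, files$truth)
    files$params <- file.path(dir, "params.tsv")
    write_saga_params(params, files$params)
    out$files <- files
  }
  out
}

#' Write a binned track as bedGraph
#'
#' One interval per non-missing bin, values at full precision, so
#' re-reading at the same resolution reproduces the bins bit-exactly.
#'
#' @param track A `binned_track`.
#' @param layout Its [genome_layout()].
#' @param path Output path.
#' @export
write_binned_track <- function(track, layout, path) {
  res <- layout$resolution
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in layout$chroms) {
    x <- track[[ch]]
    obs <- which(!is.na(x))
    if (!length(obs)) next
    starts <- (obs - 1) * res
    ends <- pmin(obs * res, layout$lengths[match(ch, layout$chroms)])
    writeLines(sprintf("%s\t%s\t%s\t%s", ch, fmt_int(starts),
                       fmt_int(ends), fmt_num(x[obs])), con)
  }
  invisible(path)
}
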