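#' One-sample Kolmogorov-Smirnov statistic
#'
#' Supremum distance between the empirical CDF of a sample and a
#' theoretical CDF: with the sample sorted,
#' `D = max_i max(i/n - F(x_(i)), F(x_(i)) - (i-1)/n)`. Smaller D means
#' closer fit.
#'
#' @param sample Non-empty numeric vector.
#' @param cdf A vectorized non-decreasing function with limits 0 and 1.
#' @return D in \[0, 1\].
#' @export
ks_statistic <- function(sample, cdf) {
  n <- length(sample)
  if (n == 0L) stop("empty sample")
  if (any(!is.finite(sample))) stop("non-finite sample values")
  x <- sort(sample)
  F_ <- cdf(x)
  i <- seq_len(n)
  max(pmax(i / n - F_, F_ - (i - 1) / n))
}

#' Per-label goodness of fit between empirical and theoretical
#' distributions
#'
#' For every label in the annotation, compares the empirical
#' distribution of the track's datapoints assigned to that label against
#' the label's theoretical mixture CDF from the model, using the
#' one-sample KS statistic D. Labels with empty samples are skipped and
#' reported. All datapoints of a label are used (bins weighted equally)
#' unless `max_n` subsamples for speed.
#'
#' @param annotation A `saga_annotation`.
#' @param track A `binned_track` of the evaluated signal.
#' @param params The fitted [saga_params()].
#' @param layout The shared [genome_layout()].
#' @param track_index Which model track the signal corresponds to.
#' @param max_n Optional cap on per-label sample size (with `seed`).
#' @param seed Seed for the optional subsample.
#' @return A `saga_ks` data.frame (label, track, n, D) with a `summary`
#'   attribute holding mean, median and best (minimum) D across labels
#'   with non-empty samples, plus the skipped labels.
#' @export
label_fit_report <- function(annotation, track, params, layout,
                             track_index = 1L, max_n = NULL, seed = 1L) {
  stopifnot(inherits(params, "saga_params"))
  label_names <- params$label_names
  rows <- list()
  skipped <- character()
  for (l in seq_along(label_names)) {
    x <- label_signal_sample(annotation, track, label_names[l], layout)
    if (!length(x)) {
      skipped <- c(skipped, label_names[l])
      next
    }
    if (!is.null(max_n) && length(x) > max_n) {
      old <- get_rng_state(); set.seed(as.integer(seed))
      x <- sample(x, max_n)
      restore_rng_state(old)
    }
    D <- ks_statistic(x, function(q)
      mixture_cdf(params, l, track_index, q))
    rows[[length(rows) + 1L]] <- data.frame(
      label = label_names[l], track = params$track_names[track_index],
      n = length(x), D = D, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), track = character(), n = integer(),
               D = numeric())
  structure(df,
            summary = list(mean_D = mean(df$D), median_D = stats::median(df$D),
                           best_D = if (nrow(df)) min(df$D) else NA_real_,
                           skipped = skipped),
            class = c("saga_ks", "data.frame"))
}

#' @export
print.saga_ks <- function(x, ...) {
  print(as.data.frame(x))
  s <- attr(x, "summary")
  cat(sprintf("mean D %.4g, median D %.4g, best D %.4g\n",
              s$mean_D, s$median_D, s$best_D))
  if (length(s$skipped))
    cat("labels with empty samples:", paste(s$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a per-label fit report as TSV
#' @param report A `saga_ks` from [label_fit_report()].
#' @param path Output path.
#' @export
write_fit_report <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- attr(report, "summary")
  cat(sprintf("# mean_D\t%s\n# median_D\t%s\n# best_D\t%s\n",
              fmt_num(s$mean_D), fmt_num(s$median_D), fmt_num(s$best_D)),
      file = path, append = TRUE)
  invisible(path)
}

#' Paired quantiles for a QQ comparison
#'
#' Empirical sample quantiles against theoretical quantiles of a CDF at
#' probabilities `(i - 0.5) / num_points`. A perfect fit puts every
#' point on the identity line. Theoretical quantiles are obtained by
#' numerically inverting the CDF (monotone bisection via `uniroot`).
#'
#' @inheritParams ks_statistic
#' @param num_points Number of probability points.
#' @return data.frame with columns `p`, `theoretical`, `empirical` —
#'   plot-ready.
#' @export
qq_points <- function(sample, cdf, num_points = 100L) {
  if (!length(sample)) stop("empty sample")
  p <- (seq_len(num_points) - 0.5) / num_points
  theo <- vapply(p, function(pp) invert_cdf(cdf, pp), 0)
  emp <- stats::quantile(sample, probs = p, names = FALSE, type = 7)
  data.frame(p = p, theoretical = theo, empirical = emp)
}

invert_cdf <- function(cdf, p, tol = 1e-10) {
  lo <- -1; hi <- 1
  while (cdf(lo) > p && lo > -1e12) lo <- lo * 2
  while (cdf(hi) < p && hi < 1e12) hi <- hi * 2
  stats::uniroot(function(x) cdf(x) - p, c(lo, hi), tol = tol)$root
}

#' Most-upstream TSS per gene
#'
#' Strand-aware reduction of a transcript/gene BED to one transcription
#' start site per gene name: the minimum start on `+`, the maximum end
#' on `-`. Sourcing and activity labelling of the TSSs (e.g. CAGE
#' support) is the caller's responsibility.
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (BED6-like, 0-based half-open).
#' @return data.frame of single-base intervals `chrom`, `start`, `end`,
#'   `name`, one row per gene.
#' @export
most_upstream_tss <- function(genes) {
  stopifnot(all(c("chrom", "start", "end", "name", "strand") %in%
                  names(genes)))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  out <- lapply(split(genes, genes$name), function(g) {
    if (g$strand[1L] == "+") {
      i <- which.min(g$start)
      pos <- g$start[i]
    } else {
      i <- which.max(g$end)
      pos <- g$end[i] - 1
    }
    data.frame(chrom = g$chrom[i], start = pos, end = pos + 1,
               name = g$name[1L], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$chrom, df$start), , drop = FALSE]
}

# label assigned by the annotation to single-base positions; NA where
# no segment covers the position
overlap_labels <- function(annotation, pos) {
  df <- as.data.frame(annotation)
  out <- rep(NA_character_, nrow(pos))
  for (ch in unique(pos$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    sel <- which(pos$chrom == ch)
    if (!nrow(s)) next
    idx <- findInterval(pos$start[sel], s$start)
    hit <- idx >= 1L & pos$start[sel] < s$end[pmax(idx, 1L)]
    out[sel[hit]] <- s$label[idx[hit]]
  }
  out
}

#' TSS active/inactive discrimination by annotation label
#'
#' Treats the segments of each label as predictions of active
#' transcription start sites. For a label: TP = positive TSSs overlapped
#' by a segment of that label, FP = negative TSSs overlapped, FN =
#' positive TSSs overlapped by other labels. TSSs covered by no segment
#' are counted and reported separately, never silently dropped. The
#' label with the best precision is identified and its recall reported
#' (ties broken by higher recall, then lower label index).
#'
#' @param annotation A `saga_annotation` covering the TSS positions.
#' @param positives,negatives Single-base BED-like data.frames (columns
#'   `chrom`, `start`, `end`) or paths to BED files: TSSs with and
#'   without activity support, one most-upstream TSS per gene.
#' @return A `tss_eval` data.frame (label, TP, FP, FN, precision,
#'   recall) with attributes `best_label`, `best_precision`,
#'   `best_recall`, `uncovered_positives`, `uncovered_negatives`.
#' @export
tss_precision_recall <- function(annotation, positives, negatives) {
  if (is.character(positives)) positives <- as.data.frame(read_bed(positives))
  if (is.character(negatives)) negatives <- as.data.frame(read_bed(negatives))
  if (!nrow(positives)) stop_usage("no positive TSSs supplied")
  if (!nrow(negatives)) stop_usage("no negative TSSs supplied")
  labs <- attr(annotation, "label_names")
  lp <- overlap_labels(annotation, positives)
  ln <- overlap_labels(annotation, negatives)
  covered_pos <- sum(!is.na(lp))
  rows <- lapply(seq_along(labs), function(i) {
    tp <- sum(lp == labs[i], na.rm = TRUE)
    fp <- sum(ln == labs[i], na.rm = TRUE)
    fn <- covered_pos - tp
    data.frame(label = labs[i], TP = tp, FP = fp, FN = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  cand <- which(!is.na(df$precision))
  best <- NA_integer_
  if (length(cand)) {
    pr <- df$precision[cand]
    top <- cand[pr == max(pr)]
    if (length(top) > 1L) {
      rc <- df$recall[top]
      rc[is.na(rc)] <- -Inf
      top <- top[rc == max(rc)]
    }
    best <- top[1L]
  }
  structure(df,
            best_label = if (is.na(best)) NA_character_ else df$label[best],
            best_precision = if (is.na(best)) NA_real_ else df$precision[best],
            best_recall = if (is.na(best)) NA_real_ else df$recall[best],
            uncovered_positives = sum(is.na(lp)),
            uncovered_negatives = sum(is.na(ln)),
            class = c("tss_eval", "data.frame"))
}

#' @export
print.tss_eval <- function(x, ...) {
  print(as.data.frame(x))
  cat(sprintf("best-precision label: %s (precision %.3f, recall %.3f)\n",
              attr(x, "best_label"), attr(x, "best_precision"),
              attr(x, "best_recall")))
  if (attr(x, "uncovered_positives") + attr(x, "uncovered_negatives") > 0)
    cat(sprintf("uncovered TSSs: %d positive, %d negative\n",
                attr(x, "uncovered_positives"),
                attr(x, "uncovered_negatives")))
  invisible(x)
}

#' Write a TSS evaluation as TSV
#' @param eval_ A `tss_eval`.
#' @param path Output path.
#' @export
write_tss_eval <- function(eval_, path) {
  utils::write.table(as.data.frame(eval_), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("# best_label\t%s\n# best_precision\t%s\n# best_recall\t%s\n# uncovered_positives\t%d\n# uncovered_negatives\t%d\n",
              attr(eval_, "best_label"), fmt_num(attr(eval_, "best_precision")),
              fmt_num(attr(eval_, "best_recall")),
              attr(eval_, "uncovered_positives"),
              attr(eval_, "uncovered_negatives")),
      file = path, append = TRUE)
  invisible(path)
}

#' Optimal label matching between two labelings
#'
#' Finds the label permutation maximizing the diagonal of a confusion
#' matrix (exhaustive search over permutations; label counts in this
#' model are small by design). Used to score recovery of a known ground
#' truth, where learned labels are only identified up to permutation.
#'
#' @param confusion K x K matrix: `confusion[i, j]` = bins with true
#'   label i and predicted label j.
#' @return List: `perm` (perm\[j\] = true label matched to predicted
#'   label j), `accuracy` (matched diagonal mass over total).
#' @export
best_label_matching <- function(confusion) {
  K <- nrow(confusion)
  stopifnot(ncol(confusion) == K)
  if (K > 8L) stop("exhaustive matching supports K <= 8")
  perms <- all_permutations(K)
  score <- apply(perms, 1L, function(p)
    sum(confusion[cbind(p, seq_len(K))]))
  p <- as.integer(perms[which.max(score), ])
  list(perm = p, accuracy = max(score) / sum(confusion))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}
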