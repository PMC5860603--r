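# Annotation container: ordered, non-overlapping labelled segments in
# 0-based half-open genome coordinates (BED-compatible).
new_annotation <- function(df, resolution = NA_real_, label_names = NULL) {
  rownames(df) <- NULL
  structure(df, resolution = resolution,
            label_names = label_names %||% sort(unique(df$label)),
            class = c("saga_annotation", "data.frame"))
}

#' @export
as.data.frame.saga_annotation <- function(x, ...) {
  data.frame(chrom = as.character(x$chrom), start = as.numeric(x$start),
             end = as.numeric(x$end), label = as.character(x$label),
             stringsAsFactors = FALSE)
}

#' @export
print.saga_annotation <- function(x, ...) {
  cat(sprintf("annotation: %d segment(s) on %d chromosome(s), %d label(s)\n",
              nrow(x), length(unique(x$chrom)),
              length(attr(x, "label_names"))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Genome-wide Viterbi annotation
#'
#' Decodes every chunk with [viterbi()] and stitches the per-bin label
#' paths into maximal same-label segments in genome coordinates. Runs of
#' equal labels are merged across chunk boundaries within a chromosome
#' (the merge is cosmetic: inference itself stays per-chunk, so segment
#' boundaries at chunk joins are approximate). Segment boundaries are
#' multiples of the resolution except at chromosome ends.
#'
#' @param store An `obs_store`.
#' @param params A [saga_params()] sharing the store's resolution and
#'   track set.
#' @return A `saga_annotation`.
#' @export
annotate_genome <- function(store, params) {
  stopifnot(inherits(store, "obs_store"), inherits(params, "saga_params"))
  if (!isTRUE(all.equal(params$resolution, store$layout$resolution)))
    stop("store and params disagree on resolution")
  if (params$emission$T != length(store$track_names))
    stop("store and params disagree on track count")
  tab <- store$chunk_table
  res <- store$layout$resolution
  len <- stats::setNames(store$layout$lengths, store$layout$chroms)
  segs <- list()
  for (ch in store$layout$chroms) {
    ids <- tab$id[tab$chrom == ch]
    if (!length(ids)) next
    path <- unlist(lapply(ids, function(id) {
      if (is.null(store$chunks[[id]])) stop("missing chunk ", id)
      viterbi(store$chunks[[id]], params)$path
    }), use.names = FALSE)
    r <- rle(path)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    segs[[ch]] <- data.frame(
      chrom = ch,
      start = starts_bin * res,
      end = pmin(ends_bin * res, len[[ch]]),
      label = params$label_names[r$values],
      stringsAsFactors = FALSE)
  }
  new_annotation(do.call(rbind, segs), resolution = res,
                 label_names = params$label_names)
}

#' @export
predict.saga_fit <- function(object, store, ...) {
  annotate_genome(store, object$params)
}

#' Per-bin label indices implied by an annotation
#'
#' The inverse of segment stitching: a per-chromosome integer vector of
#' 1-based label indices (`NA` where the annotation has no segment).
#'
#' @param annotation A `saga_annotation` (or BED-like data.frame).
#' @param layout The [genome_layout()] the annotation lives on.
#' @param label_names Label name vector fixing the index order; defaults
#'   to the annotation's own.
#' @return Named list of integer vectors, one per chromosome.
#' @export
annotation_bin_labels <- function(annotation, layout, label_names = NULL) {
  df <- as.data.frame(annotation)
  label_names <- label_names %||% attr(annotation, "label_names") %||%
    sort(unique(df$label))
  res <- layout$resolution
  out <- lapply(stats::setNames(layout$chroms, layout$chroms), function(ch) {
    v <- rep(NA_integer_, layout$n_bins[[ch]])
    s <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(s)) {
      fb <- floor(s$start / res) + 1L
      lb <- ceiling(s$end / res)
      li <- match(s$label, label_names)
      for (i in seq_len(nrow(s))) v[fb[i]:lb[i]] <- li[i]
    }
    v
  })
  out
}

#' Empirical signal sample for one label
#'
#' All non-missing bin values of a track that fall inside segments
#' carrying the given label — the empirical distribution the model's
#' theoretical mixture is judged against. A label occupying no segment
#' yields an empty sample, not an error.
#'
#' @param annotation A `saga_annotation`.
#' @param track A `binned_track` on the same layout.
#' @param label Label name (character) or 1-based index.
#' @param layout The shared [genome_layout()].
#' @return Numeric vector of signal values.
#' @export
label_signal_sample <- function(annotation, track, label, layout) {
  label_names <- attr(annotation, "label_names")
  if (is.numeric(label)) label <- label_names[label]
  bl <- annotation_bin_labels(annotation, layout, label_names)
  li <- match(label, label_names)
  out <- lapply(layout$chroms, function(ch) {
    x <- track[[ch]][which(bl[[ch]] == li)]
    x[!is.na(x)]
  })
  unlist(out, use.names = FALSE)
}
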