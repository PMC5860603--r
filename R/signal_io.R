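#' Read a chromosome-sizes table
#'
#' Two-column whitespace-separated text: chromosome name, length in base
#' pairs (the conventional `.chrom.sizes` layout).
#'
#' @param path Path to the sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path))
    stop_usage("chromosome sizes file not found: %s", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (anyDuplicated(df$chrom)) stop("duplicated chromosome names in ", path)
  if (any(!is.finite(df$length) | df$length <= 0))
    stop("chromosome lengths must be positive in ", path)
  stats::setNames(df$length, df$chrom)
}

#' Genome layout: binning and chunking geometry
#'
#' Fixes the working resolution (base pairs per bin) and the chunk size
#' (bins per inference chunk). Every chromosome is tiled by consecutive
#' chunks; the last chunk of a chromosome may be shorter.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp,
#'   or a path to a chromosome-sizes file.
#' @param resolution Base pairs per bin (>= 1).
#' @param chunk_size Bins per chunk (>= 2).
#' @return A `saga_layout` object.
#' @examples
#' genome_layout(c(chr1 = 1e5, chr2 = 5e4), resolution = 10)
#' @export
genome_layout <- function(chrom_sizes, resolution = 1, chunk_size = 10000L) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(!is.finite(chrom_sizes) | chrom_sizes <= 0))
    stop("chromosome lengths must be positive")
  resolution <- as.numeric(resolution)
  chunk_size <- as.integer(chunk_size)
  if (length(resolution) != 1L || !is.finite(resolution) || resolution < 1)
    stop("resolution must be a single value >= 1")
  if (length(chunk_size) != 1L || is.na(chunk_size) || chunk_size < 2L)
    stop("chunk_size must be >= 2")
  structure(list(chroms = names(chrom_sizes),
                 lengths = as.numeric(chrom_sizes),
                 resolution = resolution,
                 chunk_size = chunk_size,
                 n_bins = stats::setNames(
                   as.integer(ceiling(chrom_sizes / resolution)),
                   names(chrom_sizes))),
            class = "saga_layout")
}

#' @export
print.saga_layout <- function(x, ...) {
  cat(sprintf("genome layout: %d chromosome(s), %s bp, %d bins\n",
              length(x$chroms), fmt_int(sum(x$lengths)), sum(x$n_bins)))
  cat(sprintf("  resolution %g bp/bin, chunk size %d bins\n",
              x$resolution, x$chunk_size))
  invisible(x)
}

total_bins <- function(layout) sum(layout$n_bins)

# detect bedGraph vs wiggle from the extension, falling back to content
sniff_signal_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bedgraph", "bg")) return("bedGraph")
  if (ext %in% c("wig", "wiggle")) return("wig")
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^(track|browser|#)", first) & nzchar(first)]
  if (length(first) &&
      grepl("^(fixedStep|variableStep)", first[1L])) "wig" else "bedGraph"
}

#' Read a signal track and bin it onto a genome layout
#'
#' Accepts 4-column bedGraph or fixedStep/variableStep wiggle. Each bin's
#' value is the mean of the covered base values within the bin; bases not
#' covered by any interval are missing, and a bin with no covered bases is
#' missing (`NA`). A partial last bin is averaged over the bases it
#' actually covers. Overlapping intervals are a hard error: malformed
#' input must not silently change results.
#'
#' @param path Path to a bedGraph or wiggle file.
#' @param layout A [genome_layout()].
#' @param format `"auto"` (default), `"bedGraph"` or `"wig"`.
#' @return A `binned_track`: a per-chromosome list of numeric bin vectors
#'   (`NA` = missing), with the resolution attached.
#' @export
read_signal_track <- function(path, layout,
                              format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_usage("signal file not found: %s", path)
  if (format == "auto") format <- sniff_signal_format(path)
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (nrow(df) == 0L) {
    iv <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), value = numeric())
  } else {
    iv <- data.frame(chrom = as.character(df$seqnames),
                     start = as.numeric(df$start) - 1,  # to 0-based half-open
                     end = as.numeric(df$end),
                     value = as.numeric(df$score))
  }
  bin_intervals(iv, layout, source = path)
}

# Core binning: 0-based half-open intervals -> per-chromosome bin means.
# Single-interval bins take the interval value verbatim (bit-exact round
# trips for bin-aligned input); multi-interval bins take the coverage-
# weighted mean of covered bases.
bin_intervals <- function(iv, layout, source = "input") {
  bad <- !(iv$chrom %in% layout$chroms)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "%s: line/record %d refers to unknown chromosome '%s' (%s:%s-%s)",
      source, i, iv$chrom[i], iv$chrom[i], fmt_int(iv$start[i]),
      fmt_int(iv$end[i])))
  }
  len <- stats::setNames(layout$lengths, layout$chroms)
  oob <- iv$start < 0 | iv$end > len[iv$chrom] | iv$start >= iv$end
  if (any(oob)) {
    i <- which(oob)[1L]
    stop(sprintf("%s: line/record %d has invalid interval %s:%s-%s",
                 source, i, iv$chrom[i], fmt_int(iv$start[i]),
                 fmt_int(iv$end[i])))
  }
  if (any(!is.finite(iv$value)))
    stop(source, ": non-finite signal value at line/record ",
         which(!is.finite(iv$value))[1L])
  res <- layout$resolution
  out <- lapply(stats::setNames(layout$chroms, layout$chroms), function(ch) {
    nb <- layout$n_bins[[ch]]
    vals <- rep(NA_real_, nb)
    sel <- iv$chrom == ch
    if (!any(sel)) return(vals)
    s <- iv$start[sel]; e <- iv$end[sel]; v <- iv$value[sel]
    o <- order(s)
    s <- s[o]; e <- e[o]; v <- v[o]
    if (length(s) > 1L && any(e[-length(e)] > s[-1L])) {
      i <- which(e[-length(e)] > s[-1L])[1L]
      stop(sprintf(
        "%s: overlapping intervals on %s near base %s (hard error)",
        source, ch, fmt_int(s[i + 1L])))
    }
    fb <- floor(s / res)              # first bin, 0-based
    lb <- floor((e - 1) / res)        # last bin
    nper <- as.integer(lb - fb + 1)
    idx <- rep.int(seq_along(s), nper)
    bins <- fb[idx] + (sequence(nper) - 1)
    ps <- pmax(s[idx], bins * res)
    pe <- pmin(e[idx], (bins + 1) * res)
    w <- pe - ps
    sv <- rowsum(v[idx] * w, bins)
    sw <- rowsum(w, bins)
    cnt <- rowsum(rep(1, length(bins)), bins)
    b <- as.numeric(rownames(sv)) + 1
    vals[b] <- sv[, 1L] / sw[, 1L]
    # bins covered by exactly one interval piece: take the value verbatim
    single <- cnt[, 1L] == 1
    if (any(single)) {
      first_piece <- !duplicated(bins)
      vals[bins[first_piece][single] + 1] <- v[idx][first_piece][single]
    }
    vals
  })
  structure(out, resolution = res, class = "binned_track")
}

#' Assemble an observation store from binned tracks
#'
#' Partitions the binned genome into fixed-size inference chunks (the
#' unit of forward-backward/Viterbi inference). No chunk spans a
#' chromosome boundary; concatenating chunk values reproduces the binned
#' tracks exactly.
#'
#' @param tracks A named list of `binned_track`s (or a single one).
#' @param layout The [genome_layout()] the tracks were binned on.
#' @return An `obs_store`.
#' @export
build_obs_store <- function(tracks, layout) {
  if (inherits(tracks, "binned_track")) tracks <- list(track1 = tracks)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- paste0("track", seq_along(tracks))
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (!identical(names(tr), layout$chroms) ||
        !all(lengths(tr) == layout$n_bins))
      stop("track '", nm, "' does not match the layout")
    for (ch in layout$chroms) {
      x <- tr[[ch]]
      if (any(!is.na(x) & !is.finite(x)))
        stop("track '", nm, "' has non-finite observed values on ", ch)
    }
  }
  cs <- layout$chunk_size
  tabs <- lapply(layout$chroms, function(ch) {
    nb <- layout$n_bins[[ch]]
    starts <- seq.int(1L, nb, by = cs)
    data.frame(chrom = ch, start_bin = starts,
               n_bins = pmin(cs, nb - starts + 1L),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab$id <- seq_len(nrow(tab))
  res <- layout$resolution
  len <- stats::setNames(layout$lengths, layout$chroms)
  tab$start <- (tab$start_bin - 1) * res
  tab$end <- pmin((tab$start_bin - 1 + tab$n_bins) * res, len[tab$chrom])
  tab <- tab[, c("id", "chrom", "start_bin", "n_bins", "start", "end")]
  rownames(tab) <- NULL
  chunks <- lapply(seq_len(nrow(tab)), function(i) {
    rows <- seq.int(tab$start_bin[i], length.out = tab$n_bins[i])
    m <- vapply(tracks, function(tr) tr[[tab$chrom[i]]][rows],
                numeric(tab$n_bins[i]))
    if (tab$n_bins[i] == 1L) m <- matrix(m, nrow = 1L,
                                         dimnames = list(NULL, names(tracks)))
    m
  })
  structure(list(layout = layout, track_names = names(tracks),
                 chunk_table = tab, chunks = chunks,
                 total_bins = sum(tab$n_bins)),
            class = "obs_store")
}

#' @export
print.obs_store <- function(x, ...) {
  cat(sprintf(
    "observation store: %d chunk(s), %d bins, %d track(s) [%s]\n",
    nrow(x$chunk_table), x$total_bins, length(x$track_names),
    paste(x$track_names, collapse = ", ")))
  print(x$layout)
  invisible(x)
}

#' Split chunks into a training pool and a held-out validation set
#'
#' Validation chunks are drawn uniformly at random without replacement
#' until their total bin count first reaches `fraction` of the genome's
#' bins, so the realized fraction is within one chunk of the request.
#' Whole chunks only: training and validation likelihoods then use the
#' same inference unit.
#'
#' @param store An [build_obs_store()] result.
#' @param fraction Requested validation proportion of genome bins, in (0,1).
#' @param seed Integer seed; the split is a pure function of it.
#' @return A `chunk_split` with `training` and `validation` chunk id sets.
#' @export
split_validation <- function(store, fraction, seed) {
  stopifnot(inherits(store, "obs_store"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  tab <- store$chunk_table
  n <- nrow(tab)
  target <- fraction * store$total_bins
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  k <- which(cumsum(tab$n_bins[ord]) >= target)[1L]
  if (is.na(k)) k <- n
  if (k >= n)
    stop("validation fraction leaves no training chunk")
  val <- sort(ord[seq_len(k)])
  structure(list(training = setdiff(tab$id, val), validation = val,
                 fraction = fraction,
                 realized = sum(tab$n_bins[val]) / store$total_bins,
                 seed = as.integer(seed)),
            class = "chunk_split")
}

#' @export
print.chunk_split <- function(x, ...) {
  cat(sprintf(
    "chunk split: %d training / %d validation chunks (%.3f%% held out, requested %.3f%%)\n",
    length(x$training), length(x$validation), 100 * x$realized,
    100 * x$fraction))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Write / read a BED4 annotation
#'
#' BED convention throughout: 0-based half-open coordinates; columns are
#' chrom, start, end, label name. Writing requires sorted, non-overlapping
#' segments; `read_bed(write_bed(a))` reproduces `a` and re-writing is
#' byte-stable.
#'
#' @param annotation A `saga_annotation` or a data.frame with columns
#'   `chrom`, `start`, `end`, `label`.
#' @param path Output (or input) file path.
#' @return `read_bed` returns a `saga_annotation`; `write_bed` returns
#'   `path` invisibly.
#' @export
write_bed <- function(annotation, path) {
  df <- as.data.frame(annotation)
  if (nrow(df)) {
    check_segments_sorted(df)
    lines <- sprintf("%s\t%s\t%s\t%s", df$chrom, fmt_int(df$start),
                     fmt_int(df$end), as.character(df$label))
  } else lines <- character()
  writeLines(lines, path)
  invisible(path)
}

check_segments_sorted <- function(df) {
  if (any(df$start >= df$end)) stop("segment with start >= end")
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    if (is.unsorted(s$start, strictly = TRUE) ||
        any(s$end[-nrow(s)] > s$start[-1L]))
      stop("segments on ", ch, " are unsorted or overlapping")
  }
  invisible(TRUE)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_usage("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  idx <- which(keep)
  if (!length(idx))
    return(new_annotation(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), label = character(),
                                     stringsAsFactors = FALSE)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("%s: malformed BED at line %d (need >= 3 fields)",
                 path, idx[which(nf < 3L)[1L]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- !is.finite(start) | !is.finite(end) | start < 0 | start >= end
  if (any(bad))
    stop(sprintf("%s: malformed BED coordinates at line %d", path,
                 idx[which(bad)[1L]]))
  label <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  new_annotation(data.frame(chrom = chrom, start = start, end = end,
                            label = label, stringsAsFactors = FALSE))
}

#' Persist / load an observation store
#'
#' The store is persisted as a single versioned binary container keyed by
#' chunk id (an RDS serialization with a format header), so a binned
#' genome can be reused across training and annotation runs without
#' re-reading the signal files.
#'
#' @param store An `obs_store`.
#' @param path File path.
#' @return `read_obs_store` returns the `obs_store`.
#' @export
write_obs_store <- function(store, path) {
  stopifnot(inherits(store, "obs_store"))
  saveRDS(list(magic = "sagahmm_obs_store", version = 1L,
               payload = unclass(store)), path)
  invisible(path)
}

#' @rdname write_obs_store
#' @export
read_obs_store <- function(path) {
  if (!file.exists(path)) stop_usage("observation store not found: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$magic, "sagahmm_obs_store"))
    stop(path, " is not an observation store")
  if (!identical(obj$version, 1L))
    stop("unsupported observation store version: ", obj$version)
  structure(obj$payload, class = "obs_store")
}
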