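## Per-base position tracks.  A track stores a contiguous real-valued signal
## along one chromosome; the coordinate of value j is origin + j - 1 and, for
## window-derived signals, refers to the CENTER l of the 50-bp window
## S_l = X[l-24 .. l+25] (l is the 25th base).  Missing values are NA.

#' Per-base signal track along one chromosome
#'
#' @param values Numeric vector (NA = missing), length >= 1.
#' @param chrom Chromosome identifier.
#' @param origin 1-based coordinate of the first value.
#' @return An object of class `"position_track"`.
#' @examples
#' tr <- position_track(sin(2 * pi * (1:50) / 10.4), "chrI", origin = 25)
#' @export
position_track <- function(values, chrom = "chr", origin = 1L) {
  if (!is.numeric(values) || length(values) < 1L) {
    stop("`values` must be a numeric vector of length >= 1")
  }
  if (length(chrom) != 1L || is.na(chrom)) stop("`chrom` must be a single identifier")
  if (length(origin) != 1L || is.na(origin) || origin != as.integer(origin)) {
    stop("`origin` must be a single integer coordinate")
  }
  structure(list(chrom = as.character(chrom), origin = as.integer(origin),
                 values = as.numeric(values)),
            class = "position_track")
}

#' @export
length.position_track <- function(x) length(x$values)

#' @export
print.position_track <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<position track> %s:%d-%d (%d positions, %d missing)\n",
              x$chrom, x$origin, x$origin + n - 1L, n, sum(is.na(x$values))))
  invisible(x)
}

#' @rdname position_track
#' @param track A `position_track`.
#' @return `track_positions()`: integer vector of 1-based coordinates.
#' @export
track_positions <- function(track) {
  stopifnot(inherits(track, "position_track"))
  track$origin + seq_along(track$values) - 1L
}

#' @export
as.data.frame.position_track <- function(x, ...) {
  data.frame(chrom = x$chrom, pos = track_positions(x), value = x$values)
}

# coerce numeric input to a track (shared-chrom default); pass tracks through
.as_track <- function(x, chrom = "chr", origin = 1L) {
  if (inherits(x, "position_track")) x else position_track(x, chrom, origin)
}

# error unless all tracks share chrom/origin/length
.check_coregistered <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  ref <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (!identical(t$chrom, ref$chrom) || t$origin != ref$origin ||
        length(t$values) != length(ref$values)) {
      stop("tracks are not co-registered (chrom/origin/length mismatch)")
    }
  }
  invisible(ref)
}

#' Standardise a track to mean 0, sd 1
#'
#' Centers and scales the non-missing values; missing positions stay missing.
#'
#' @param track A [position_track()] (or numeric vector).
#' @return Normalised track of the same geometry.
#' @export
normalize_track <- function(track) {
  tr <- .as_track(track)
  v <- tr$values
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values to normalise")
  s <- sd(v[ok])
  if (!is.finite(s) || s <= 0) stop("track has zero spread; cannot normalise")
  position_track((v - mean(v[ok])) / s, tr$chrom, tr$origin)
}

.track_format <- function(path, format) {
  format <- match.arg(format, c("auto", "tsv", "bedgraph", "wig"))
  if (format != "auto") return(format)
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         "tsv" = "tsv", "txt" = "tsv",
         "bedgraph" = "bedgraph", "bg" = "bedgraph",
         "wig" = "wig", "wiggle" = "wig",
         stop("cannot infer track format from extension: ", path))
}

#' Read and write position tracks
#'
#' Supported formats: plain TSV with header `chrom, pos, value` (`pos` is the
#' 1-based window-center coordinate), bedGraph (0-based half-open, one base
#' per record, missing positions omitted) and wiggle.  bedGraph and wiggle go
#' through `rtracklayer`; a write/read round-trip preserves coordinates and
#' values.  Files mixing chromosomes are rejected.
#'
#' @param track A [position_track()].
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"tsv"`, `"bedgraph"`, `"wig"`.
#' @return `read_track()` returns a [position_track()]; `write_track()` the
#'   path, invisibly.
#' @export
write_track <- function(track, path, format = "auto") {
  stopifnot(inherits(track, "position_track"))
  format <- .track_format(path, format)
  if (format == "tsv") {
    write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    v <- track$values
    ok <- !is.na(v)
    if (!any(ok)) stop("cannot write an all-missing track to ", format)
    gr <- GenomicRanges::GRanges(
      seqnames = track$chrom,
      ranges = IRanges::IRanges(start = track_positions(track)[ok], width = 1L),
      score = v[ok])
    rtracklayer::export(gr, path, format = if (format == "bedgraph") "bedGraph" else "wig")
  }
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path, format = "auto") {
  format <- .track_format(path, format)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos", "value") %in% names(df))) {
      stop("track TSV must have columns chrom, pos, value: ", path)
    }
    chrom <- unique(df$chrom); pos <- df$pos; val <- df$value
  } else {
    gr <- rtracklayer::import(path, format = if (format == "bedgraph") "bedGraph" else "wig")
    chrom <- as.character(unique(GenomicRanges::seqnames(gr)))
    pos <- GenomicRanges::start(gr)
    val <- gr$score
  }
  if (length(chrom) != 1L) stop("multi-chromosome track files are not supported: ", path)
  if (length(pos) == 0L) stop("empty track file: ", path)
  o <- order(pos)
  pos <- pos[o]; val <- val[o]
  values <- rep(NA_real_, max(pos) - min(pos) + 1L)
  values[pos - min(pos) + 1L] <- val
  position_track(values, chrom, min(pos))
}
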