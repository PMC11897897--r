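## Genome/sequence I/O, the 50-bp window convention, and the artificial-
## chromosome workflow for reference-free libraries.  Internal coordinates
## are 1-based inclusive with the window center l defined by
## S_l = X[l-24 .. l+25]; BED/bedGraph files follow their 0-based half-open
## standards.

WINDOW_SIZE <- 50L
WINDOW_UP <- 24L    # bases upstream of the center within S_l
WINDOW_DOWN <- 25L  # bases downstream

#' Read a FASTA file into a named sequence vector
#'
#' Sequences are uppercased; lowercase and line-wrapped input are accepted.
#' Duplicate headers, empty files and non-`ACGTN` letters are rejected.
#'
#' @param path FASTA file path.
#' @return Named character vector (one element per record).
#' @export
read_fasta <- function(path) {
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA file ", path, ": ",
                               conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      # Biostrings silently drops invalid letters; treat that as malformed
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("FASTA sequences must use the alphabet A, C, G, T, N: ", path,
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out))) stop("duplicate FASTA headers in ", path)
  if (any(nchar(out) == 0L)) stop("empty sequence record in ", path)
  if (any(grepl("[^ACGTN]", out))) {
    stop("FASTA sequences must use the alphabet A, C, G, T, N: ", path)
  }
  out
}

#' Write a named sequence vector to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (`ACGTN`).
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract 50-bp windows around center coordinates
#'
#' The window centered at l is `S_l = X[l-24 .. l+25]` (l is its 25th base),
#' so valid centers satisfy `25 <= l <= L - 25`.
#'
#' @param genome Named character vector (e.g. from [read_fasta()]).
#' @param chrom Chromosome name.
#' @param centers Integer vector of center coordinates.
#' @return A [sequence_set()] with ids `chrom:center`; the centers are kept
#'   in attribute `"centers"`.
#' @export
extract_windows <- function(genome, chrom, centers) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  L <- nchar(genome[[chrom]])
  bad <- centers < WINDOW_UP + 1L | centers > L - WINDOW_DOWN
  if (any(bad)) {
    stop("window centers out of range [25, L-25] for ", chrom, ": ",
         paste(centers[bad], collapse = ", "))
  }
  seqs <- substring(genome[[chrom]], centers - WINDOW_UP, centers + WINDOW_DOWN)
  out <- sequence_set(paste0(chrom, ":", centers), seqs)
  attr(out, "centers") <- as.integer(centers)
  out
}

#' Concatenate a 50-bp library into an artificial chromosome
#'
#' Shuffles the records with a seeded permutation and concatenates them into
#' one synthetic chromosome, recording where each record landed.  This is the
#' workflow that lets the smoothing estimator run on reference-free libraries.
#'
#' @param set A [sequence_set()] of 50-bp records.
#' @param ordering_seed Integer seed for the shuffle.
#' @return List with `sequence` (the concatenated chromosome) and `index`
#'   (`data.frame` of `id`, `rank`, `start`, `center`; record at rank r spans
#'   positions `(r-1)*50+1 .. r*50` with center `start + 24`).
#' @export
concat_library <- function(set, ordering_seed = 1L) {
  stopifnot(inherits(set, "sequence_set"))
  if (any(nchar(set$sequence) != WINDOW_SIZE)) {
    stop("all library records must be exactly 50 bp")
  }
  set.seed(ordering_seed)
  perm <- sample.int(nrow(set))
  start <- (seq_len(nrow(set)) - 1L) * WINDOW_SIZE + 1L
  list(sequence = paste0(set$sequence[perm], collapse = ""),
       index = data.frame(id = set$id[perm], rank = seq_len(nrow(set)),
                          start = start, center = start + WINDOW_UP,
                          stringsAsFactors = FALSE))
}

#' Map an artificial-chromosome track back to per-record scores
#'
#' Each record receives the track value at its center coordinate; missing
#' track values propagate as missing scores.
#'
#' @param track A [position_track()] along the concatenated chromosome.
#' @param index The `index` component of [concat_library()].
#' @return `data.frame` with columns `id` and `score`.
#' @export
map_back <- function(track, index) {
  stopifnot(inherits(track, "position_track"),
            all(c("id", "center") %in% names(index)))
  pos <- index$center - track$origin + 1L
  if (any(pos < 1L | pos > length(track$values))) {
    stop("track does not cover all index centers")
  }
  data.frame(id = index$id, score = track$values[pos], stringsAsFactors = FALSE)
}

#' Read and write loop-seq library tables
#'
#' Delimited text with a required header; the delimiter is auto-detected
#' among tab and comma.  Required columns: `id`, `sequence`, `c26`, `c29`,
#' `c31`; an optional `c0hat` column carries an externally reported
#' intrinsic-cyclizability estimate.
#'
#' @param path File path.
#' @return `data.frame` with the library columns.
#' @export
read_library_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty library table: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("id", "sequence", "c26", "c29", "c31")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("library table missing required column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' @rdname read_library_table
#' @param df Library `data.frame`.
#' @param sep Field delimiter (`"\t"` or `","`).
#' @export
write_library_table <- function(df, path, sep = "\t") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read nucleosome dyad positions from BED
#'
#' BED is 0-based half-open; single-base dyad records are converted to
#' 1-based coordinates.
#'
#' @param path BED file path.
#' @param chrom Optional chromosome filter.
#' @return Integer vector of 1-based dyad coordinates.
#' @export
read_dyads_bed <- function(path, chrom = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(chrom)) gr <- gr[GenomicRanges::seqnames(gr) == chrom]
  if (length(gr) == 0L) stop("no dyad records", if (!is.null(chrom)) paste0(" on ", chrom))
  GenomicRanges::start(gr)
}

#' Write dyad positions to BED
#'
#' @param dyads Integer vector of 1-based positions.
#' @param chrom Chromosome name.
#' @param path Output path.
#' @export
write_dyads_bed <- function(dyads, chrom, path) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = dyads, width = 1L))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
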