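#' Read a bedGraph signal track
#'
#' Four-column bedGraph (chrom, start, end, value) with 0-based half-open
#' intervals on disk; intervals are converted to the package-internal
#' 1-based inclusive convention. `track ...` and `#` lines are skipped.
#'
#' @param path bedGraph file.
#' @param sample_id identifier for the track (defaults to the file name).
#' @param assay assay type (`ChIP`, `DNase`, `ATAC`) or `NA`.
#' @param mark histone mark identifier or `NA`.
#' @return a `signal_track`: data.frame with `start`, `end`, `value` and
#'   metadata attributes.
#' @export
read_bedgraph <- function(path, sample_id = basename(path),
                          assay = NA_character_, mark = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep)) {
    df <- data.frame(chromosome = character(0), start = numeric(0),
                     end = numeric(0), value = numeric(0))
  } else {
    con <- textConnection(lines[keep])
    on.exit(close(con))
    df <- utils::read.table(con, sep = "\t",
                            col.names = c("chromosome", "start", "end", "value"),
                            colClasses = c("character", "numeric", "numeric",
                                           "numeric"))
    df$start <- df$start + 1  # to 1-based inclusive
  }
  signal_track(sample_id, df$start, df$end, df$value,
               chromosome = if (nrow(df)) df$chromosome[1L] else NA_character_,
               assay = assay, mark = mark)
}

#' Construct a signal track
#'
#' @param sample_id sample identifier.
#' @param start,end interval bounds, 1-based inclusive, sorted and
#'   non-overlapping.
#' @param value non-negative finite signal per interval (or a methylation
#'   fraction in `[0, 1]` for methylation tracks).
#' @param chromosome chromosome identifier.
#' @param assay,mark,age_label optional metadata.
#' @return data.frame of class `signal_track`.
#' @export
signal_track <- function(sample_id, start, end, value,
                         chromosome = NA_character_, assay = NA_character_,
                         mark = NA_character_, age_label = NA_character_) {
  if (any(end < start)) stop("interval end < start")
  if (any(!is.finite(value))) stop("track values must be finite")
  if (any(value < 0)) stop("track values must be non-negative")
  o <- order(start)
  start <- start[o]; end <- end[o]; value <- value[o]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)]))
    stop("track intervals overlap")
  df <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   value = as.numeric(value))
  attr(df, "sample_id") <- sample_id
  attr(df, "chromosome") <- chromosome
  attr(df, "assay") <- assay
  attr(df, "mark") <- mark
  attr(df, "age_label") <- age_label
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Construct a methylation-fraction track
#'
#' Like [signal_track()] but values are per-interval mean methylation
#' fractions and must lie in `[0, 1]`.
#'
#' @inheritParams signal_track
#' @return data.frame of class `c("methylation_track", "signal_track")`.
#' @export
methylation_track <- function(sample_id, start, end, value,
                              chromosome = NA_character_,
                              age_label = NA_character_) {
  if (any(value < 0 | value > 1))
    stop("methylation fractions must lie in [0, 1]")
  tr <- signal_track(sample_id, start, end, value, chromosome = chromosome,
                     age_label = age_label)
  class(tr) <- c("methylation_track", class(tr))
  tr
}

#' Write a signal track as bedGraph
#'
#' @param track a [signal_track].
#' @param path output file.
#' @param chromosome chromosome name (defaults to the track's).
#' @export
write_bedgraph <- function(track, path, chromosome = NULL) {
  chromosome <- chromosome %||% attr(track, "chromosome") %||% "chrS"
  df <- data.frame(chromosome, as.integer(track$start - 1),
                   as.integer(track$end),
                   formatC(track$value, format = "fg", digits = 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write segment calls as BED6
#'
#' The support fraction is scaled to 0-1000 in the score column.
#'
#' @param calls a `segment_calls` data.frame (see
#'   [call_consensus_segments()]).
#' @param path output file.
#' @param chromosome chromosome name.
#' @param strand strand character for the BED records.
#' @export
write_segments_bed <- function(calls, path, chromosome = "chrS",
                               strand = ".") {
  score <- as.integer(round(pmin(pmax(calls$support, 0), 1) * 1000))
  df <- data.frame(chromosome, as.integer(calls$start - 1),
                   as.integer(calls$end), calls$label, score, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
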