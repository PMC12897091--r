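## Microsatellite panel: locus definitions and read-to-locus assignment.

#' Load a microsatellite panel from a BED-like TSV file
#'
#' The panel file is tab-delimited with columns
#' `chrom  start  end  locus_id  gene  repeat_unit` in BED coordinate
#' convention (0-based, half-open); lines starting with `#` are comments.
#' Coordinates are converted once, at this boundary, to the internal
#' 1-based inclusive convention matching SAM `POS`.
#'
#' @param path Path to the panel TSV.
#' @param name Optional panel name (defaults to the file name).
#' @return A data.frame of class `msq_panel` with columns `locus_id`,
#'   `gene`, `chrom`, `start`, `end` (1-based inclusive) and `repeat_unit`,
#'   sorted by `(chrom, start)`.
#' @export
load_panel <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  rowno <- which(keep)
  if (length(lines) == 0L) {
    warning("empty panel file: ", path, call. = FALSE)
    return(as_panel(data.frame(chrom = character(0), start = integer(0),
                               end = integer(0), locus_id = character(0),
                               gene = character(0),
                               repeat_unit = character(0),
                               stringsAsFactors = FALSE),
                    bed = TRUE, name = name))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L)) {
    stop("panel format error at line ", rowno[which(nf < 6L)[1]],
         ": 6 tab-separated columns required (chrom start end locus_id ",
         "gene repeat_unit)", call. = FALSE)
  }
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L))),
    locus_id = vapply(parts, `[[`, "", 4L),
    gene = vapply(parts, `[[`, "", 5L),
    repeat_unit = toupper(vapply(parts, `[[`, "", 6L)),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
  if (length(bad)) {
    stop("panel format error at line ", rowno[bad[1]],
         ": start/end must be integers with start < end (BED convention)",
         call. = FALSE)
  }
  as_panel(df, bed = TRUE, name = name)
}

#' Build a panel object from a data.frame
#'
#' @param df Data.frame with columns `chrom`, `start`, `end`, `locus_id`,
#'   `gene`, `repeat_unit`.
#' @param bed If `TRUE`, `start`/`end` are BED (0-based half-open) and are
#'   converted to 1-based inclusive; if `FALSE` they are taken as already
#'   1-based inclusive.
#' @param name Panel name.
#' @return A `msq_panel` data.frame.
#' @export
as_panel <- function(df, bed = FALSE, name = "panel") {
  need <- c("chrom", "start", "end", "locus_id", "gene", "repeat_unit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[need]
  if (bed && nrow(df)) {
    df$start <- df$start + 1L   # BED half-open -> 1-based inclusive
  }
  if (nrow(df)) {
    if (anyDuplicated(df$locus_id)) {
      stop("duplicate locus_id in panel: ",
           df$locus_id[anyDuplicated(df$locus_id)], call. = FALSE)
    }
    if (any(!nzchar(df$repeat_unit))) {
      stop("empty repeat_unit in panel", call. = FALSE)
    }
    if (any(df$start > df$end)) stop("locus with start > end", call. = FALSE)
    short <- (df$end - df$start + 1L) < nchar(df$repeat_unit)
    if (any(short)) {
      stop("locus shorter than its repeat unit: ",
           df$locus_id[which(short)[1]], call. = FALSE)
    }
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("msq_panel", "data.frame"), panel_name = name)
}

#' @export
print.msq_panel <- function(x, ...) {
  cat("Microsatellite panel '", attr(x, "panel_name"), "': ",
      nrow(x), " loci, ", length(unique(x$gene)), " genes\n", sep = "")
  NextMethod()
}

#' Reads fully covering a flanked locus interval
#'
#' Amplicon reads are expected to span whole repeat tracts; a read is
#' assigned to a locus only if its reference span
#' `[pos, pos + reference-consumed length - 1]` fully covers
#' `[start - flank, end + flank]` on the locus chromosome. The default one
#' base of flank makes insertions anchored immediately before the first
#' repeat base observable.
#'
#' @param reads A filtered `msq_reads` table.
#' @param locus One panel row (list or one-row data.frame) with `chrom`,
#'   `start`, `end`.
#' @param flank Non-negative integer flank, default 1.
#' @return The subset of `reads` assigned to the locus.
#' @export
reads_for_locus <- function(reads, locus, flank = 1L) {
  stopifnot(is.data.frame(reads), flank >= 0L)
  if (is.data.frame(locus)) locus <- as.list(locus)
  if (nrow(reads) == 0L) return(reads)
  lo <- locus$start - flank
  hi <- locus$end + flank
  span_end <- reads$pos +
    vapply(reads$cigar, cigar_reference_length, 0L, USE.NAMES = FALSE) - 1L
  keep <- reads$rname == locus$chrom & reads$pos <= lo & span_end >= hi
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("msq_reads", "data.frame")
  out
}

#' Count valid reads per panel locus
#'
#' @param reads A filtered `msq_reads` table.
#' @param panel A `msq_panel`.
#' @param flank Flank passed to [reads_for_locus()].
#' @return Named integer vector, one count per `locus_id` (panel order).
#'   A read covering several loci is counted once for each.
#' @export
count_valid_reads <- function(reads, panel, flank = 1L) {
  n <- vapply(seq_len(nrow(panel)), function(i) {
    nrow(reads_for_locus(reads, panel[i, ], flank = flank))
  }, 0L)
  stats::setNames(n, panel$locus_id)
}
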