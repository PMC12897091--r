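## Aligned-read model: SAM record parsing, FLAG decoding, validity filters.

#' SAM FLAG bits understood by the model
#'
#' Named integer vector mapping alignment property names to SAM FLAG bit
#' masks. Only the bits relevant to read filtering and basic bookkeeping are
#' modeled; unknown high bits are ignored by [decode_flag()].
#'
#' @format Named integer vector.
#' @export
SAM_FLAG_BITS <- c(
  paired        = 0x1L,
  proper_pair   = 0x2L,
  unmapped      = 0x4L,
  mate_unmapped = 0x8L,
  reverse       = 0x10L,
  mate_reverse  = 0x20L,
  first_in_pair = 0x40L,
  second_in_pair = 0x80L,
  secondary     = 0x100L,
  qc_fail       = 0x200L,
  duplicate     = 0x400L,
  supplementary = 0x800L
)

## CIGAR operation classes (SAM v1 table)
.CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")
.CIGAR_REF_OPS   <- c("M", "D", "N", "=", "X")

## Fast internal CIGAR parser: list(op = character, len = integer).
.cigar_ops <- function(cigar) {
  if (cigar == "*" || cigar == "") {
    return(list(op = character(0), len = integer(0)))
  }
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("invalid CIGAR string: '", cigar, "'", call. = FALSE)
  }
  toks <- substring(cigar, m, m + attr(m, "match.length") - 1L)
  n <- nchar(toks)
  len <- as.integer(substr(toks, 1L, n - 1L))
  if (any(len < 1L)) stop("invalid CIGAR string (zero-length op): '",
                          cigar, "'", call. = FALSE)
  list(op = substr(toks, n, n), len = len)
}

#' Parse a CIGAR string into an operation table
#'
#' @param cigar CIGAR string, e.g. `"2S10M1I5M"`. `"*"` (unavailable) yields
#'   a zero-row table.
#' @return A data.frame with columns `op` (character, one of
#'   `M I D N S H P = X`) and `len` (integer, >= 1), one row per operation in
#'   order.
#' @examples
#' parse_cigar("2S3M")
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  ops <- .cigar_ops(cigar)
  data.frame(op = ops$op, len = ops$len, stringsAsFactors = FALSE)
}

#' Query length implied by a CIGAR string
#'
#' Sum of lengths of query-consuming operations (M, I, S, =, X); must equal
#' `nchar(seq)` for a well-formed record.
#'
#' @param cigar CIGAR string or a parsed operation table.
#' @return Integer.
#' @export
cigar_query_length <- function(cigar) {
  ops <- if (is.data.frame(cigar) || is.list(cigar)) cigar
         else .cigar_ops(cigar)
  sum(ops$len[ops$op %in% .CIGAR_QUERY_OPS])
}

#' Reference span implied by a CIGAR string
#'
#' Sum of lengths of reference-consuming operations (M, D, N, =, X): the
#' number of reference bases covered by the alignment.
#'
#' @inheritParams cigar_query_length
#' @return Integer.
#' @export
cigar_reference_length <- function(cigar) {
  ops <- if (is.data.frame(cigar) || is.list(cigar)) cigar
         else .cigar_ops(cigar)
  sum(ops$len[ops$op %in% .CIGAR_REF_OPS])
}

.validate_cigar_shape <- function(ops, context = "") {
  if (nrow(ops) == 0L) return(invisible(TRUE))
  ## H only at the outermost ends, S only at ends inside any H
  inner <- ops$op
  nh <- length(inner)
  is_h <- inner == "H"
  if (any(is_h) && !all(which(is_h) %in% c(1L, nh))) {
    stop("CIGAR H operations must be terminal", context, call. = FALSE)
  }
  core <- inner[!is_h]
  is_s <- core == "S"
  if (any(is_s) && !all(which(is_s) %in% c(1L, length(core)))) {
    stop("CIGAR S operations must be terminal", context, call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse one SAM alignment line
#'
#' Parses a tab-delimited SAM record (11 mandatory fields plus optional
#' typed tags) into an aligned-read record. Only the `MD:Z:` and `NM:i:`
#' tags are retained; others are ignored. Header lines (starting `@`) are
#' rejected.
#'
#' @param line A single SAM record as a character scalar.
#' @return A list of class `msq_read` with fields `qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar` (string), `seq`, `md` (string or `NA`), `nm`
#'   (integer or `NA`).
#' @examples
#' parse_sam_record("r1\t0\tchr5\t100\t60\t4M\t*\t0\t0\tACGT\tFFFF\tMD:Z:4\tNM:i:0")
#' @export
parse_sam_record <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  if (startsWith(line, "@")) {
    stop("header line passed to parse_sam_record()", call. = FALSE)
  }
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11L) {
    stop("malformed SAM record: ", length(f),
         " fields (11 required)", call. = FALSE)
  }
  flag <- suppressWarnings(as.integer(f[2]))
  pos <- suppressWarnings(as.integer(f[4]))
  mapq <- suppressWarnings(as.integer(f[5]))
  if (is.na(flag) || flag < 0L) stop("invalid FLAG field: '", f[2], "'",
                                     call. = FALSE)
  if (is.na(pos) || pos < 0L) stop("invalid POS field: '", f[4], "'",
                                   call. = FALSE)
  if (is.na(mapq) || mapq < 0L || mapq > 255L) {
    stop("invalid MAPQ field: '", f[5], "'", call. = FALSE)
  }
  cigar <- f[6]
  ops <- parse_cigar(cigar)  # errors on malformed tokens
  .validate_cigar_shape(ops, paste0(" (read '", f[1], "')"))
  seq <- f[10]
  if (seq != "*" && nrow(ops) > 0L &&
      cigar_query_length(ops) != nchar(seq)) {
    stop("CIGAR query length ", cigar_query_length(ops),
         " does not match SEQ length ", nchar(seq),
         " (read '", f[1], "')", call. = FALSE)
  }
  md <- NA_character_
  nm <- NA_integer_
  if (length(f) > 11L) {
    tags <- f[12:length(f)]
    md_hit <- grep("^MD:Z:", tags, value = TRUE)
    if (length(md_hit)) md <- sub("^MD:Z:", "", md_hit[1])
    nm_hit <- grep("^NM:i:", tags, value = TRUE)
    if (length(nm_hit)) {
      nm <- suppressWarnings(as.integer(sub("^NM:i:", "", nm_hit[1])))
      if (is.na(nm) || nm < 0L) stop("invalid NM tag: '", nm_hit[1], "'",
                                     call. = FALSE)
    }
  }
  structure(
    list(qname = f[1], flag = flag, rname = f[3], pos = pos, mapq = mapq,
         cigar = cigar, seq = seq, md = md, nm = nm),
    class = "msq_read"
  )
}

#' Read an alignment file into a read table
#'
#' Reads a SAM text file (header lines skipped) into a data.frame with one
#' row per record. BAM input is accepted when the `Rsamtools` package is
#' available; records are converted to the same table layout.
#'
#' @param path Path to a `.sam` (text) or `.bam` file.
#' @return A data.frame of class `msq_reads` with columns `qname`, `flag`,
#'   `rname`, `pos`, `mapq`, `cigar`, `seq`, `md`, `nm`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("BAM input requires the Rsamtools package; convert to SAM text",
           call. = FALSE)
    }
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
      tag = c("MD", "NM"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    df <- data.frame(
      qname = as.character(b$qname), flag = as.integer(b$flag),
      rname = as.character(b$rname), pos = as.integer(b$pos),
      mapq = as.integer(b$mapq), cigar = as.character(b$cigar),
      seq = as.character(b$seq),
      md = as.character(b$tag$MD), nm = as.integer(b$tag$NM),
      stringsAsFactors = FALSE)
    class(df) <- c("msq_reads", "data.frame")
    return(df)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  recs <- lapply(lines, parse_sam_record)
  as_read_table(recs)
}

## Cheap row iterator over a read table (avoids data.frame `[i, ]` cost
## in per-read loops).
.read_rows <- function(reads) {
  lapply(seq_len(nrow(reads)), function(i) {
    list(qname = reads$qname[i], flag = reads$flag[i],
         rname = reads$rname[i], pos = reads$pos[i], mapq = reads$mapq[i],
         cigar = reads$cigar[i], seq = reads$seq[i], md = reads$md[i],
         nm = reads$nm[i])
  })
}

#' Bind parsed read records into a read table
#'
#' @param records List of `msq_read` records (from [parse_sam_record()]).
#' @return Data.frame of class `msq_reads`.
#' @export
as_read_table <- function(records) {
  if (length(records) == 0L) {
    df <- data.frame(qname = character(0), flag = integer(0),
                     rname = character(0), pos = integer(0),
                     mapq = integer(0), cigar = character(0),
                     seq = character(0), md = character(0),
                     nm = integer(0), stringsAsFactors = FALSE)
    class(df) <- c("msq_reads", "data.frame")
    return(df)
  }
  df <- data.frame(
    qname = vapply(records, `[[`, "", "qname"),
    flag = vapply(records, `[[`, 0L, "flag"),
    rname = vapply(records, `[[`, "", "rname"),
    pos = vapply(records, `[[`, 0L, "pos"),
    mapq = vapply(records, `[[`, 0L, "mapq"),
    cigar = vapply(records, `[[`, "", "cigar"),
    seq = vapply(records, `[[`, "", "seq"),
    md = vapply(records, `[[`, NA_character_, "md"),
    nm = vapply(records, `[[`, NA_integer_, "nm"),
    stringsAsFactors = FALSE)
  class(df) <- c("msq_reads", "data.frame")
  df
}

#' Decode a SAM FLAG bitfield into property names
#'
#' @param flag Non-negative integer FLAG value.
#' @return Character vector of set property names (see [SAM_FLAG_BITS]);
#'   empty for a plain mapped primary read. Unknown high bits are ignored.
#' @examples
#' decode_flag(2048)  # "supplementary"
#' decode_flag(260)   # "unmapped" "secondary"
#' @export
decode_flag <- function(flag) {
  stopifnot(length(flag) == 1L, !is.na(flag), flag >= 0)
  names(SAM_FLAG_BITS)[bitwAnd(as.integer(flag), SAM_FLAG_BITS) != 0L]
}

#' Encode property names back into a FLAG bitfield
#'
#' Inverse of [decode_flag()] on the modeled bit set.
#'
#' @param properties Character vector of property names.
#' @return Integer FLAG value.
#' @export
encode_flag <- function(properties) {
  if (length(properties) == 0L) return(0L)
  bad <- setdiff(properties, names(SAM_FLAG_BITS))
  if (length(bad)) stop("unknown flag properties: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  sum(SAM_FLAG_BITS[unique(properties)])
}

#' Construct a read filter policy
#'
#' Validity criteria for reads entering microsatellite analysis: a minimum
#' mapping quality (default 60, the maximum confidence reported by common
#' short-read aligners) and a set of disqualifying FLAG bits. By default
#' unmapped (0x4), secondary (0x100) and supplementary (0x800) alignments
#' are excluded; duplicate (0x400) and QC-fail (0x200) filtering can be
#' switched on.
#'
#' @param min_mapq Minimum MAPQ retained, in `[0, 255]`.
#' @param drop_duplicates Also exclude duplicate-marked reads (0x400)?
#' @param drop_qc_fail Also exclude QC-fail reads (0x200)?
#' @return A list of class `msq_filter_policy` with `min_mapq` and
#'   `forbidden_flags` (named integer vector of bit masks).
#' @export
read_filter_policy <- function(min_mapq = 60L, drop_duplicates = FALSE,
                               drop_qc_fail = FALSE) {
  min_mapq <- as.integer(min_mapq)
  stopifnot(length(min_mapq) == 1L, !is.na(min_mapq),
            min_mapq >= 0L, min_mapq <= 255L)
  forbidden <- SAM_FLAG_BITS[c("unmapped", "secondary", "supplementary")]
  if (drop_duplicates) forbidden <- c(forbidden, SAM_FLAG_BITS["duplicate"])
  if (drop_qc_fail) forbidden <- c(forbidden, SAM_FLAG_BITS["qc_fail"])
  structure(list(min_mapq = min_mapq, forbidden_flags = forbidden),
            class = "msq_filter_policy")
}

#' Test whether a read passes the filter policy
#'
#' A read passes iff its MAPQ is at least `policy$min_mapq` and none of the
#' policy's forbidden FLAG bits are set. Reads without a usable alignment
#' (CIGAR `"*"` or missing SEQ) fail regardless.
#'
#' @param read An `msq_read` record, or a one-row `msq_reads` table.
#' @param policy A policy from [read_filter_policy()].
#' @return Logical scalar.
#' @export
passes_filters <- function(read, policy = read_filter_policy()) {
  if (is.data.frame(read)) {
    stopifnot(nrow(read) == 1L)
    read <- as.list(read)
  }
  if (is.na(read$cigar) || read$cigar == "*" ||
      is.na(read$seq) || read$seq == "*") {
    return(FALSE)
  }
  if (read$mapq < policy$min_mapq) return(FALSE)
  all(bitwAnd(read$flag, policy$forbidden_flags) == 0L)
}

#' Filter a read table by a policy
#'
#' Vectorised application of [passes_filters()]. Idempotent and
#' contractive: re-filtering the result returns it unchanged.
#'
#' @param reads An `msq_reads` table.
#' @param policy A policy from [read_filter_policy()].
#' @return The subset of `reads` passing the policy, same class; the number
#'   of dropped reads is attached as attribute `n_dropped`.
#' @export
filter_reads <- function(reads, policy = read_filter_policy()) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) {
    attr(reads, "n_dropped") <- 0L
    return(reads)
  }
  unusable <- is.na(reads$cigar) | reads$cigar == "*" |
    is.na(reads$seq) | reads$seq == "*"
  bad_flag <- rep(FALSE, nrow(reads))
  for (m in policy$forbidden_flags) {
    bad_flag <- bad_flag | bitwAnd(reads$flag, m) != 0L
  }
  keep <- !unusable & !bad_flag & reads$mapq >= policy$min_mapq
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("msq_reads", "data.frame")
  attr(out, "n_dropped") <- sum(!keep)
  out
}
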