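## Reference reconstruction from CIGAR + MD, without an external FASTA.
##
## SAM files record only differences to the reference; the reference bases
## over a read's span can be recovered from SEQ, the CIGAR string and the
## MD tag. A read whose MD shows no mismatches/deletions and whose CIGAR
## has no indels is itself a verbatim copy of the reference.

#' Parse an MD tag into tokens
#'
#' MD grammar (SAM optional-fields specification):
#' `[0-9]+ ( ( [A-Z] | \^[A-Z]+ ) [0-9]+ )*` — a match-run length, then
#' alternating mismatch/deletion tokens and match-run lengths. Zero-length
#' match runs are preserved (e.g. `"0A5"` starts with a mismatch).
#'
#' @param md MD tag value (the part after `MD:Z:`).
#' @return Data.frame with columns `kind` (`"match_run"`, `"mismatch_base"`
#'   or `"deletion_bases"`), `length` (match-run length, `NA` otherwise)
#'   and `bases` (mismatch/deleted reference bases, `NA` for match runs).
#' @examples
#' parse_md("10A5^AC6")
#' @export
parse_md <- function(md) {
  stopifnot(is.character(md), length(md) == 1L, !is.na(md))
  tok <- .md_tokens(md)
  data.frame(kind = tok$kind, length = tok$length, bases = tok$bases,
             stringsAsFactors = FALSE)
}

## Fast internal MD tokenizer: list(kind, length, bases) vectors.
.md_tokens <- function(md) {
  pat <- "[0-9]+|\\^[A-Za-z]+|[A-Za-z]"
  m <- gregexpr(pat, md)[[1]]
  toks <- if (m[1] == -1L) character(0)
          else substring(md, m, m + attr(m, "match.length") - 1L)
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(md)) {
    bad <- if (m[1] == -1L) 1L else {
      covered <- unlist(Map(seq, m, m + attr(m, "match.length") - 1L))
      setdiff(seq_len(nchar(md)), covered)[1]
    }
    stop("invalid MD tag '", md, "' at offset ", bad, call. = FALSE)
  }
  kind <- ifelse(grepl("^[0-9]", toks), "match_run",
                 ifelse(startsWith(toks, "^"), "deletion_bases",
                        "mismatch_base"))
  ## alternation: every non-match token must be followed by a match run,
  ## and the string must start with a match run
  expect_num <- TRUE
  for (i in seq_along(kind)) {
    is_num <- kind[i] == "match_run"
    if (is_num != expect_num) {
      stop("invalid MD tag '", md, "': token ", i, " ('", toks[i],
           "') violates the alternating number/edit grammar", call. = FALSE)
    }
    expect_num <- !is_num
  }
  if (kind[length(kind)] != "match_run") {
    stop("invalid MD tag '", md, "': must end with a match-run length",
         call. = FALSE)
  }
  list(
    kind = kind,
    length = ifelse(kind == "match_run", suppressWarnings(as.integer(toks)),
                    NA_integer_),
    bases = ifelse(kind == "match_run", NA_character_,
                   toupper(sub("^\\^", "", toks))))
}

## Joint CIGAR/MD walk over one read. Returns the reconstructed reference
## over the ref-consumed span plus every edit event with its reference
## anchor. This single walker backs both reconstruct_reference() and
## extract_mutations(); tests check it against an independent per-base
## oracle.
.cigar_md_walk <- function(read) {
  if (is.data.frame(read)) read <- as.list(read)
  if (is.na(read$md)) {
    stop("read '", read$qname, "' has no MD tag; cannot walk", call. = FALSE)
  }
  ops <- .cigar_ops(read$cigar)
  md <- .md_tokens(read$md)
  fail <- function(why) {
    stop("CIGAR/MD inconsistency for read '", read$qname, "' (CIGAR '",
         read$cigar, "', MD '", read$md, "'): ", why, call. = FALSE)
  }
  ti <- 1L                      # MD token index
  trem <- if (length(md$kind)) md$length[1] else NA_integer_  # bases left in run
  pop <- function() {
    ti <<- ti + 1L
    trem <<- if (ti <= nmd && md$kind[ti] == "match_run")
      md$length[ti] else NA_integer_
  }
  qi <- 1L                      # next query base (1-based in SEQ)
  rp <- read$pos                # next reference coordinate
  ref <- character(0)
  ev_kind <- character(0); ev_pos <- integer(0)
  ev_len <- integer(0); ev_bases <- character(0); ev_ref <- character(0)
  has_n <- FALSE

  nmd <- length(md$kind)
  for (k in seq_len(length(ops$op))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op == "S") {
      qi <- qi + len
    } else if (op %in% c("H", "P")) {
      ## consume nothing
    } else if (op == "I") {
      ev_kind <- c(ev_kind, "insertion")
      ev_pos <- c(ev_pos, rp - 1L)       # anchored to the base it follows
      ev_len <- c(ev_len, len)
      ev_bases <- c(ev_bases, substr(read$seq, qi, qi + len - 1L))
      ev_ref <- c(ev_ref, NA_character_)
      qi <- qi + len
    } else if (op == "D") {
      while (ti <= nmd && md$kind[ti] == "match_run" &&
             md$length[ti] == 0L) pop()
      if (ti > nmd || md$kind[ti] != "deletion_bases") {
        fail("CIGAR deletion without matching MD '^' token")
      }
      delb <- md$bases[ti]
      if (nchar(delb) != len) fail(sprintf(
        "deletion length %d vs MD '^%s'", len, delb))
      ref <- c(ref, delb)
      ev_kind <- c(ev_kind, "deletion")
      ev_pos <- c(ev_pos, rp)
      ev_len <- c(ev_len, len)
      ev_bases <- c(ev_bases, delb)
      ev_ref <- c(ev_ref, delb)
      rp <- rp + len
      pop()
    } else if (op == "N") {
      ref <- c(ref, strrep("N", len))
      rp <- rp + len
      has_n <- TRUE
    } else if (op %in% c("M", "=", "X")) {
      need <- len
      while (need > 0L) {
        if (ti > nmd) fail("MD exhausted before CIGAR")
        if (md$kind[ti] == "match_run") {
          if (trem == 0L) { pop(); next }
          take <- min(trem, need)
          ref <- c(ref, substr(read$seq, qi, qi + take - 1L))
          qi <- qi + take; rp <- rp + take
          need <- need - take; trem <- trem - take
          if (trem == 0L) pop()
        } else if (md$kind[ti] == "mismatch_base") {
          refb <- md$bases[ti]
          ref <- c(ref, refb)
          ev_kind <- c(ev_kind, "substitution")
          ev_pos <- c(ev_pos, rp)
          ev_len <- c(ev_len, 1L)
          ev_bases <- c(ev_bases, substr(read$seq, qi, qi))
          ev_ref <- c(ev_ref, refb)
          qi <- qi + 1L; rp <- rp + 1L
          need <- need - 1L
          pop()
        } else {
          fail("MD deletion token inside a CIGAR match run")
        }
      }
    } else {
      stop("unsupported CIGAR operation '", op, "'", call. = FALSE)
    }
  }
  ## only zero-length match runs may remain
  while (ti <= nmd && md$kind[ti] == "match_run" &&
         md$length[ti] == 0L) pop()
  if (ti <= nmd) fail("MD tokens left over after CIGAR walk")

  list(
    ref = paste(ref, collapse = ""),
    start = read$pos,
    has_n = has_n,
    events = data.frame(kind = ev_kind, ref_pos = ev_pos, length = ev_len,
                        bases = ev_bases, ref_bases = ev_ref,
                        stringsAsFactors = FALSE))
}

#' Is a read an exact copy of the reference?
#'
#' A read counts as a reference read only if it is free of mismatches *and*
#' indels: its MD tag (when present) contains no mismatch or deletion
#' tokens, and its CIGAR contains no `I`, `D` or `X` operations. Terminal
#' soft/hard clips are permitted — clipped bases are not part of the
#' alignment. With no MD tag the CIGAR alone decides; with neither, the
#' read is not usable as a reference (with a warning).
#'
#' @param read An `msq_read` or one-row `msq_reads` table.
#' @return Logical scalar.
#' @export
is_reference_read <- function(read) {
  if (is.data.frame(read)) read <- as.list(read)
  if ((is.na(read$cigar) || read$cigar == "*") && is.na(read$md)) {
    warning("read '", read$qname, "' has neither CIGAR nor MD information",
            call. = FALSE)
    return(FALSE)
  }
  ops <- parse_cigar(read$cigar)
  if (nrow(ops) == 0L || any(ops$op %in% c("I", "D", "X", "N"))) {
    return(FALSE)
  }
  if (!all(ops$op %in% c("M", "=", "S", "H"))) return(FALSE)
  if (is.na(read$md)) return(TRUE)   # CIGAR-only decision
  md <- parse_md(read$md)
  all(md$kind == "match_run")
}

#' Reconstruct the reference sequence underlying one read
#'
#' Walks the CIGAR string and MD tag jointly: soft-clipped and inserted
#' read bases are dropped, aligned bases are copied from the read but
#' overwritten by the MD tag's reference letters at mismatches, and deleted
#' reference bases are restored from MD `^` tokens.
#'
#' @param read An `msq_read` or one-row `msq_reads` table with CIGAR and MD.
#' @return A list of class `msq_refwindow`: `chrom`, `start` (= read POS),
#'   `seq` (reference bases over the read's reference span).
#' @examples
#' r <- parse_sam_record("r1\t0\tchr1\t10\t60\t2M1D2M\t*\t0\t0\tACGT\tFFFF\tMD:Z:2^A2\tNM:i:1")
#' reconstruct_reference(r)$seq  # "ACAGT"
#' @export
reconstruct_reference <- function(read) {
  if (is.data.frame(read)) read <- as.list(read)
  w <- .cigar_md_walk(read)
  stopifnot(nchar(w$ref) == cigar_reference_length(read$cigar))
  structure(list(chrom = read$rname, start = w$start, seq = w$ref),
            class = "msq_refwindow")
}

#' Determine the reference sequence over a locus window
#'
#' Looks for a mutation-free read among those assigned to the locus; if one
#' exists its (trivially reconstructed) sequence is used directly.
#' Otherwise every covering read is reconstructed and a per-position
#' majority consensus is taken, with ties broken toward the base supported
#' by the highest-MAPQ read, then lexicographically.
#'
#' @param reads `msq_reads` assigned to the locus (see [reads_for_locus()]).
#' @param locus One panel row.
#' @param flank Flank width, as used for assignment (default 1).
#' @return A list of class `msq_locus_reference`: `chrom`, `start`
#'   (window start), `seq` (window reference), `provenance`
#'   (`"direct"` or `"reconstructed_consensus"`), `n_support`,
#'   `n_ambiguous` (positions where the consensus was not unanimous).
#' @export
build_locus_reference <- function(reads, locus, flank = 1L) {
  if (is.data.frame(locus)) locus <- as.list(locus)
  wstart <- locus$start - flank
  wend <- locus$end + flank
  if (nrow(reads) == 0L) {
    stop("no reads cover locus '", locus$locus_id,
         "'; no reference available", call. = FALSE)
  }
  cut_window <- function(rw) {
    substr(rw$seq, wstart - rw$start + 1L, wend - rw$start + 1L)
  }
  rows <- .read_rows(reads)
  is_ref <- vapply(rows, is_reference_read, TRUE)
  if (any(is_ref)) {
    rw <- reconstruct_reference(rows[[which(is_ref)[1]]])
    return(structure(list(chrom = locus$chrom, start = wstart,
                          seq = cut_window(rw), provenance = "direct",
                          n_support = sum(is_ref), n_ambiguous = 0L),
                     class = "msq_locus_reference"))
  }
  wlen <- wend - wstart + 1L
  mats <- matrix(NA_character_, nrow = nrow(reads), ncol = wlen)
  for (i in seq_len(nrow(reads))) {
    mats[i, ] <- strsplit(cut_window(reconstruct_reference(rows[[i]])),
                          "")[[1]]
  }
  mapq <- reads$mapq
  cons <- character(wlen)
  n_amb <- 0L
  for (j in seq_len(wlen)) {
    tab <- table(mats[, j])
    top <- names(tab)[tab == max(tab)]
    if (length(tab) > 1L) n_amb <- n_amb + 1L
    if (length(top) == 1L) {
      cons[j] <- top
    } else {
      ## tie: highest-MAPQ supporting read, then lexicographic
      best_mapq <- vapply(top, function(b) max(mapq[mats[, j] == b]), 0L)
      top <- top[best_mapq == max(best_mapq)]
      cons[j] <- sort(top)[1]
    }
  }
  structure(list(chrom = locus$chrom, start = wstart,
                 seq = paste(cons, collapse = ""),
                 provenance = "reconstructed_consensus",
                 n_support = nrow(reads), n_ambiguous = n_amb),
            class = "msq_locus_reference")
}
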