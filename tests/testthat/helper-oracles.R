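# Independent oracles, deliberately implemented differently from the
# package: a per-base (not token-run) CIGAR/MD walk, a pairwise-ordering
# AUC, and a random mutation-plan generator for round-trip properties.

# Per-base oracle walk. Expands the CIGAR into single-base operations and
# the MD tag into a per-reference-base annotation stream ("=" match,
# "A".."T" mismatch reference base, "^A" deleted reference base), then
# zips the two. Returns the reconstructed reference and the event list.
oracle_walk <- function(read) {
  if (is.data.frame(read)) read <- as.list(read)
  toks <- regmatches(read$cigar,
                     gregexpr("[0-9]+[MIDNSHP=X]", read$cigar))[[1]]
  lens <- as.integer(sub(".$", "", toks))
  ops1 <- rep(sub("^[0-9]+", "", toks), lens)   # one op per base

  md <- read$md
  stream <- character(0)
  while (nchar(md) > 0L) {
    if (grepl("^[0-9]", md)) {
      n <- as.integer(sub("^([0-9]+).*", "\\1", md))
      stream <- c(stream, rep("=", n))
      md <- sub("^[0-9]+", "", md)
    } else if (grepl("^\\^", md)) {
      bases <- sub("^\\^([A-Za-z]+).*", "\\1", md)
      stream <- c(stream, paste0("^", strsplit(bases, "")[[1]]))
      md <- sub("^\\^[A-Za-z]+", "", md)
    } else {
      stream <- c(stream, substr(md, 1, 1))
      md <- sub("^.", "", md)
    }
  }

  sq <- strsplit(read$seq, "")[[1]]
  qi <- 1L; rp <- read$pos; si <- 1L
  ref <- character(0)
  ev <- list()
  runs <- rle(ops1)
  for (r in seq_along(runs$values)) {
    op <- runs$values[r]; len <- runs$lengths[r]
    if (op == "S") qi <- qi + len
    else if (op %in% c("H", "P")) NULL
    else if (op == "I") {
      ev[[length(ev) + 1L]] <- list(kind = "insertion", ref_pos = rp - 1L,
                                    length = len,
                                    bases = paste(sq[qi:(qi + len - 1L)],
                                                  collapse = ""))
      qi <- qi + len
    } else if (op == "D") {
      db <- stream[si:(si + len - 1L)]
      stopifnot(all(startsWith(db, "^")))
      db <- sub("^\\^", "", db)
      ref <- c(ref, db)
      ev[[length(ev) + 1L]] <- list(kind = "deletion", ref_pos = rp,
                                    length = len,
                                    bases = paste(db, collapse = ""))
      si <- si + len; rp <- rp + len
    } else if (op == "N") {
      ref <- c(ref, rep("N", len)); rp <- rp + len
    } else {  # M / = / X, base by base
      for (b in seq_len(len)) {
        ann <- stream[si]
        stopifnot(!startsWith(ann, "^"))
        if (ann == "=") {
          ref <- c(ref, sq[qi])
        } else {
          ref <- c(ref, ann)
          ev[[length(ev) + 1L]] <- list(kind = "substitution", ref_pos = rp,
                                        length = 1L, bases = sq[qi])
        }
        si <- si + 1L; qi <- qi + 1L; rp <- rp + 1L
      }
    }
  }
  stopifnot(si == length(stream) + 1L)
  events <- if (length(ev)) {
    data.frame(kind = vapply(ev, `[[`, "", "kind"),
               ref_pos = vapply(ev, function(e) as.integer(e$ref_pos), 0L),
               length = vapply(ev, function(e) as.integer(e$length), 0L),
               bases = vapply(ev, `[[`, "", "bases"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(kind = character(0), ref_pos = integer(0),
               length = integer(0), bases = character(0),
               stringsAsFactors = FALSE)
  }
  list(ref = paste(ref, collapse = ""), events = events)
}

# Window filter mirroring the documented anchoring rules, applied to a
# planned event table (the generator's ground truth).
oracle_window_events <- function(events, wstart, wend) {
  if (nrow(events) == 0L) return(events)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    k <- events$kind[i]; p <- events$ref_pos[i]; len <- events$length[i]
    if (k == "substitution") p >= wstart && p <= wend
    else if (k == "deletion") p <= wend && (p + len - 1L) >= wstart
    else p >= wstart - 1L && p <= wend
  }, TRUE)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force AUC: fraction of positive-negative pairs correctly ordered,
# ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Random non-overlapping mutation plan over a reference window.
random_mutation_spec <- function(win, n_events) {
  wstart <- win$start
  wend <- win$start + nchar(win$seq) - 1L
  taken <- integer(0)     # sub/del footprint
  del_fp <- integer(0)    # deletion footprint padded by one base
  anchors <- integer(0)
  rows <- list()
  for (i in seq_len(n_events)) {
    kind <- sample(c("insertion", "deletion", "substitution"), 1L)
    if (kind == "insertion") {
      cand <- setdiff((wstart - 1L):wend, c(anchors, taken))
      if (!length(cand)) next
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      len <- sample(1:3, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, ref_pos = p, length = len,
        bases = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = ""), stringsAsFactors = FALSE)
      anchors <- c(anchors, p)
    } else {
      len <- if (kind == "substitution") 1L else sample(1:3, 1L)
      cand <- wstart:(wend - len + 1L)
      blocked <- if (kind == "deletion") c(taken, anchors, del_fp)
                 else c(taken, anchors)
      cand <- cand[vapply(cand, function(p) {
        fp <- if (kind == "deletion") (p - 1L):(p + len) else p
        !any(fp %in% blocked)
      }, TRUE)]
      if (!length(cand)) next
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      if (kind == "substitution") {
        refb <- substr(win$seq, p - wstart + 1L, p - wstart + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, ref_pos = p, length = 1L, bases = alt,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, ref_pos = p, length = len, bases = NA_character_,
          stringsAsFactors = FALSE)
      }
      taken <- c(taken, p:(p + len - 1L))
      if (kind == "deletion") del_fp <- c(del_fp, (p - 1L):(p + len))
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), ref_pos = integer(0),
               length = integer(0), bases = character(0),
               stringsAsFactors = FALSE)
}

# Random reference window with an embedded homopolymer tract; returns the
# window plus the tract coordinates.
random_window <- function(chrom = "chrT", min_tract = 8L, max_tract = 14L) {
  flank <- sample(5:12, 1L)
  tract_len <- sample(min_tract:max_tract, 1L)
  unit <- sample(c("A", "T"), 1L)
  others <- setdiff(c("A", "C", "G", "T"), unit)
  start <- sample(50:5000, 1L)
  fl <- function(n) paste(sample(others, n, replace = TRUE), collapse = "")
  win <- ref_window(chrom, start,
                    paste0(fl(flank), strrep(unit, tract_len), fl(flank)))
  list(win = win, wstart = start + flank,
       wend = start + flank + tract_len - 1L)
}

# Canonical event key for set comparison (order-insensitive).
event_key <- function(ev) {
  if (nrow(ev) == 0L) return(character(0))
  sort(sprintf("%s@%d+%d", ev$kind, ev$ref_pos, ev$length))
}
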