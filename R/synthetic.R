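## Synthetic aligned reads with mutually consistent SEQ/CIGAR/MD/NM.
##
## Stand-in for non-deposited patient data: amplicon-style reads over
## mononucleotide repeat loci, with slippage-style unit-length indels at a
## class-dependent rate (high for MSI-like samples, low for MSS-like) and
## a constant per-base substitution error. Every generated read round-trips
## through the CIGAR/MD walker: the reconstructed reference equals the
## declared one and the extracted events equal the planned ones.

#' Declare a reference window for read synthesis
#'
#' @param chrom Chromosome name.
#' @param start 1-based coordinate of the first base of `seq`.
#' @param seq Reference bases over the window.
#' @return List of class `msq_refwindow`.
#' @export
ref_window <- function(chrom, start, seq) {
  stopifnot(nchar(seq) > 0L, start >= 1L)
  structure(list(chrom = chrom, start = as.integer(start),
                 seq = toupper(seq)), class = "msq_refwindow")
}

.validate_mutation_spec <- function(events, window) {
  if (nrow(events) == 0L) return(invisible(TRUE))
  stopifnot(all(events$kind %in% c("insertion", "deletion", "substitution")),
            all(events$length >= 1L))
  wstart <- window$start
  wend <- window$start + nchar(window$seq) - 1L
  occ <- integer(0)   # reference positions consumed by sub/del events
  anchors <- integer(0)
  del_iv <- NULL      # deletion intervals, to reject adjacent deletions
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]; p <- events$ref_pos[i]; len <- events$length[i]
    if (k == "insertion") {
      if (p < wstart - 1L || p > wend) {
        stop("insertion anchor ", p, " outside window", call. = FALSE)
      }
      anchors <- c(anchors, p)
    } else {
      if (k == "substitution" && len != 1L) {
        stop("substitution events must have length 1", call. = FALSE)
      }
      if (p < wstart || p + len - 1L > wend) {
        stop(k, " at ", p, " outside window", call. = FALSE)
      }
      occ <- c(occ, p:(p + len - 1L))
      if (k == "deletion") del_iv <- rbind(del_iv, c(p, p + len - 1L))
    }
  }
  if (!is.null(del_iv) && nrow(del_iv) > 1L) {
    del_iv <- del_iv[order(del_iv[, 1]), , drop = FALSE]
    ## adjacent deletions would merge into one CIGAR op yet keep two MD
    ## '^' tokens — require at least one matched base between them
    if (any(del_iv[-1, 1] - del_iv[-nrow(del_iv), 2] < 2L)) {
      stop("adjacent deletion events (no matched base between them)",
           call. = FALSE)
    }
  }
  if (anyDuplicated(occ)) stop("overlapping mutation events", call. = FALSE)
  if (anyDuplicated(anchors)) {
    stop("two insertions share an anchor", call. = FALSE)
  }
  if (any(anchors %in% occ)) {
    stop("insertion anchored on a substituted/deleted base", call. = FALSE)
  }
  invisible(TRUE)
}

#' Synthesize one aligned read from a reference window and a mutation plan
#'
#' Emits a read whose SEQ, CIGAR, MD and NM fields are mutually consistent:
#' [reconstruct_reference()] inverts it exactly over the aligned span, and
#' NM equals the number of substituted plus inserted plus deleted bases.
#'
#' @param window A [ref_window()]; the read aligns over the whole window.
#' @param events Data.frame of planned events with columns `kind`
#'   (`insertion`/`deletion`/`substitution`), `ref_pos` (insertions: the
#'   reference base the insertion follows; deletions/substitutions: first
#'   affected base), `length`, `bases` (inserted bases; substitution: the
#'   observed base, must differ from the reference; deletions: ignored —
#'   taken from the reference). Events must not overlap on the reference.
#' @param soft_clip Integer `c(left, right)` soft-clip lengths; clipped
#'   bases are drawn uniformly from ACGT (uses the RNG when nonzero).
#' @param qname Read name.
#' @param mapq,flag SAM fields, default 60 and 0.
#' @return An `msq_read` record.
#' @export
make_read <- function(window, events = NULL, soft_clip = c(0L, 0L),
                      qname = "read", mapq = 60L, flag = 0L) {
  stopifnot(inherits(window, "msq_refwindow"))
  if (is.null(events)) {
    events <- data.frame(kind = character(0), ref_pos = integer(0),
                         length = integer(0), bases = character(0),
                         stringsAsFactors = FALSE)
  }
  .validate_mutation_spec(events, window)
  ref <- window$seq
  wstart <- window$start
  wend <- wstart + nchar(ref) - 1L
  ref_at <- function(a, b) substr(ref, a - wstart + 1L, b - wstart + 1L)

  ## order: by reference position; an insertion anchored at p is applied
  ## after the base at p has been consumed, so it sorts after a deletion or
  ## substitution starting at p never arises (validated above)
  if (nrow(events)) {
    events <- events[order(events$ref_pos,
                           events$kind == "insertion"), , drop = FALSE]
  }
  cig_op <- character(0); cig_len <- integer(0)
  add_op <- function(op, len) {
    if (len == 0L) return()
    n <- length(cig_op)
    if (n > 0L && cig_op[n] == op) {
      cig_len[n] <<- cig_len[n] + len
    } else {
      cig_op <<- c(cig_op, op); cig_len <<- c(cig_len, len)
    }
  }
  seq_parts <- character(0)
  md_parts <- character(0)
  md_count <- 0L
  flush_md <- function() {
    md_parts <<- c(md_parts, as.character(md_count))
    md_count <<- 0L
  }
  nm <- 0L
  p <- wstart
  match_through <- function(upto) {
    if (upto < p) return()
    len <- upto - p + 1L
    seq_parts <<- c(seq_parts, ref_at(p, upto))
    md_count <<- md_count + len
    add_op("M", len)
    p <<- upto + 1L
  }
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]; ep <- events$ref_pos[i]
    len <- events$length[i]; b <- events$bases[i]
    if (k == "insertion") {
      stopifnot(nchar(b) == len)
      match_through(ep)
      seq_parts <- c(seq_parts, toupper(b))
      add_op("I", len)
      nm <- nm + len
    } else if (k == "deletion") {
      match_through(ep - 1L)
      flush_md()
      md_parts <- c(md_parts, paste0("^", ref_at(ep, ep + len - 1L)))
      add_op("D", len)
      nm <- nm + len
      p <- ep + len
    } else {  # substitution
      refb <- ref_at(ep, ep)
      b <- toupper(b)
      stopifnot(nchar(b) == 1L, b != refb)
      match_through(ep - 1L)
      flush_md()
      md_parts <- c(md_parts, refb)
      seq_parts <- c(seq_parts, b)
      add_op("M", 1L)
      nm <- nm + 1L
      p <- ep + 1L
    }
  }
  match_through(wend)
  flush_md()

  soft_clip <- as.integer(soft_clip)
  stopifnot(length(soft_clip) == 2L, all(soft_clip >= 0L))
  clip_bases <- function(n) {
    if (n == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }
  left <- clip_bases(soft_clip[1])
  right <- clip_bases(soft_clip[2])
  if (soft_clip[1] > 0L) {
    cig_op <- c("S", cig_op); cig_len <- c(soft_clip[1], cig_len)
  }
  if (soft_clip[2] > 0L) {
    cig_op <- c(cig_op, "S"); cig_len <- c(cig_len, soft_clip[2])
  }
  structure(
    list(qname = qname, flag = as.integer(flag), rname = window$chrom,
         pos = wstart, mapq = as.integer(mapq),
         cigar = paste0(cig_len, cig_op, collapse = ""),
         seq = paste0(left, paste(seq_parts, collapse = ""), right),
         md = paste(md_parts, collapse = ""), nm = nm),
    class = "msq_read")
}

#' Format reads as SAM text lines
#'
#' @param reads An `msq_reads` table or list of `msq_read` records.
#' @param chrom_lengths Named integer vector for `@SQ` header lines; when
#'   `NULL`, each chromosome's length is the largest coordinate spanned
#'   plus 100.
#' @return Character vector of SAM lines (header + records).
#' @export
format_sam <- function(reads, chrom_lengths = NULL) {
  if (!is.data.frame(reads)) reads <- as_read_table(reads)
  if (is.null(chrom_lengths)) {
    if (nrow(reads)) {
      span_end <- reads$pos + vapply(reads$cigar, cigar_reference_length,
                                     0L, USE.NAMES = FALSE) - 1L
      chrom_lengths <- vapply(split(span_end, reads$rname), max, 0L) + 100L
    } else {
      chrom_lengths <- integer(0)
    }
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    tags <- character(0)
    if (!is.na(r$nm)) tags <- c(tags, sprintf("NM:i:%d", r$nm))
    if (!is.na(r$md)) tags <- c(tags, sprintf("MD:Z:%s", r$md))
    paste(c(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0, 0,
            r$seq, strrep("F", nchar(r$seq)), tags), collapse = "\t")
  }, "")
  c(hdr, body)
}

#' The three functional test scenarios
#'
#' Returns fixed fixtures probing the positional bookkeeping of
#' [extract_mutations()]:
#' \describe{
#'   \item{case1}{an indel strictly upstream of the repeat tract: query
#'     offsets shift but no in-window event may be reported.}
#'   \item{case2}{three independent indels inside the tract: each must be
#'     counted separately.}
#'   \item{case3}{a repeat-unit insertion anchored immediately before the
#'     first repeat base: a tract-length change, counted as one event.}
#' }
#'
#' @return Named list of bundles, each with `read`, `window`
#'   (`c(wstart, wend)`) and `expected_events` (data.frame `kind`,
#'   `ref_pos`, `length`).
#' @export
test_case_fixtures <- function() {
  ## amplicon: 10 bp flank + 12 x A tract at [100, 111] + 10 bp flank
  win <- ref_window("chr2", 90L,
                    paste0("GCTGCTGCTG", strrep("A", 12), "CGTCGTCGTC"))
  tract <- c(100L, 111L)
  no_events <- data.frame(kind = character(0), ref_pos = integer(0),
                          length = integer(0), stringsAsFactors = FALSE)
  ev <- function(kind, ref_pos, length, bases) {
    data.frame(kind = kind, ref_pos = ref_pos, length = length,
               bases = bases, stringsAsFactors = FALSE)
  }
  list(
    case1 = list(
      read = make_read(win, ev("deletion", 95L, 1L, NA_character_),
                       qname = "tc1_upstream_del"),
      window = tract,
      expected_events = no_events),
    case2 = list(
      read = make_read(win, rbind(ev("insertion", 102L, 1L, "A"),
                                  ev("deletion", 105L, 1L, NA_character_),
                                  ev("insertion", 108L, 1L, "A")),
                       qname = "tc2_three_indels"),
      window = tract,
      expected_events = data.frame(
        kind = c("insertion", "deletion", "insertion"),
        ref_pos = c(102L, 105L, 108L), length = c(1L, 1L, 1L),
        stringsAsFactors = FALSE)),
    case3 = list(
      read = make_read(win, ev("insertion", 99L, 1L, "A"),
                       qname = "tc3_tract_start_ins"),
      window = tract,
      expected_events = data.frame(kind = "insertion", ref_pos = 99L,
                                   length = 1L, stringsAsFactors = FALSE))
  )
}

#' Cohort simulation model
#'
#' Defaults emulate a clearly separable validation cohort: 16 MSI-like and
#' 15 MSS-like samples (one of the 32 excluded as not evaluable), 200
#' amplicon reads per locus, a per-read slippage-indel probability of 0.6
#' at MSI loci versus 0.02 at MSS loci, and a 0.002 per-base substitution
#' error.
#'
#' @param n_msi,n_mss Sample counts per class.
#' @param reads_per_locus Read depth at every panel locus.
#' @param indel_rate_msi,indel_rate_mss Per-read probability of one
#'   repeat-unit slippage indel inside the tract.
#' @param sub_error_rate Per-base substitution error over the amplicon.
#' @param clip_prob Probability a read carries 1–3 soft-clipped bases at
#'   either end.
#' @param flank_len Reference flank simulated on each side of the tract.
#' @param seed Base RNG seed for the cohort.
#' @return List of class `msq_cohort_model`.
#' @export
cohort_model <- function(n_msi = 16L, n_mss = 15L, reads_per_locus = 200L,
                         indel_rate_msi = 0.6, indel_rate_mss = 0.02,
                         sub_error_rate = 0.002, clip_prob = 0.1,
                         flank_len = 15L, seed = 1L) {
  stopifnot(reads_per_locus >= 1L,
            indel_rate_msi >= 0, indel_rate_msi <= 1,
            indel_rate_mss >= 0, indel_rate_mss <= 1,
            sub_error_rate >= 0, sub_error_rate <= 1, flank_len >= 2L)
  structure(list(n_msi = as.integer(n_msi), n_mss = as.integer(n_mss),
                 reads_per_locus = as.integer(reads_per_locus),
                 indel_rate_msi = indel_rate_msi,
                 indel_rate_mss = indel_rate_mss,
                 sub_error_rate = sub_error_rate, clip_prob = clip_prob,
                 flank_len = as.integer(flank_len), seed = as.integer(seed)),
            class = "msq_cohort_model")
}

## Deterministic amplicon reference for one locus: repeat tract filled with
## its unit, flanks cycled from a fixed non-repeat alphabet so that the
## flank never extends the homopolymer run.
.locus_amplicon <- function(locus, flank_len) {
  unit <- locus$repeat_unit
  tract_len <- locus$end - locus$start + 1L
  tract <- strrep(unit, ceiling(tract_len / nchar(unit)))
  tract <- substr(tract, 1L, tract_len)
  others <- setdiff(c("C", "G", "T", "A"), substr(unit, 1L, 1L))
  flank <- paste(rep_len(others, flank_len), collapse = "")
  ref_window(locus$chrom, locus$start - flank_len,
             paste0(flank, tract, rev_string(flank)))
}

rev_string <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

## One random read over a locus amplicon per the class model.
.simulate_locus_read <- function(win, locus, rate, model, qname) {
  unit_len <- nchar(locus$repeat_unit)
  events <- NULL
  if (stats::runif(1) < rate) {
    if (stats::runif(1) < 0.5 && (locus$end - locus$start + 1L) > unit_len) {
      dp <- sample(locus$start:(locus$end - unit_len + 1L), 1L)
      events <- data.frame(kind = "deletion", ref_pos = dp,
                           length = unit_len, bases = NA_character_,
                           stringsAsFactors = FALSE)
    } else {
      ip <- sample((locus$start - 1L):(locus$end - 1L), 1L)
      events <- data.frame(kind = "insertion", ref_pos = ip,
                           length = unit_len, bases = locus$repeat_unit,
                           stringsAsFactors = FALSE)
    }
  }
  ## substitution noise anywhere on the amplicon, avoiding indel footprint
  wend <- win$start + nchar(win$seq) - 1L
  n_sub <- stats::rbinom(1L, nchar(win$seq), model$sub_error_rate)
  if (n_sub > 0L) {
    avoid <- integer(0)
    if (!is.null(events)) {
      avoid <- if (events$kind[1] == "deletion")
        events$ref_pos[1]:(events$ref_pos[1] + events$length[1] - 1L)
      else events$ref_pos[1]
    }
    cand <- setdiff(win$start:wend, avoid)
    sp <- sample(cand, min(n_sub, length(cand)))
    for (p in sp) {
      refb <- substr(win$seq, p - win$start + 1L, p - win$start + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      events <- rbind(events, data.frame(
        kind = "substitution", ref_pos = p, length = 1L, bases = alt,
        stringsAsFactors = FALSE))
    }
  }
  clip <- c(0L, 0L)
  if (stats::runif(1) < model$clip_prob) {
    side <- sample(1:2, 1L)
    clip[side] <- sample(1:3, 1L)
  }
  make_read(win, events, soft_clip = clip, qname = qname)
}

#' Simulate one sample's aligned reads over a panel
#'
#' Draws `reads_per_locus` full-coverage amplicon reads per panel locus,
#' mutated per the class model, and writes a valid SAM file (deterministic
#' for a fixed seed).
#'
#' @param panel A `msq_panel`.
#' @param class `"MSI"` or `"MSS"`.
#' @param model A [cohort_model()].
#' @param sample_id Sample name (becomes the read-name prefix).
#' @param path Output SAM path; `NULL` returns the read table only.
#' @param seed Optional seed applied before generation.
#' @return The `msq_reads` table, invisibly when `path` is given.
#' @export
simulate_sample <- function(panel, class = c("MSI", "MSS"),
                            model = cohort_model(), sample_id = "sample",
                            path = NULL, seed = NULL) {
  class <- match.arg(class)
  stopifnot(inherits(model, "msq_cohort_model"), nrow(panel) > 0L)
  if (!is.null(seed)) set.seed(seed)
  rate <- if (class == "MSI") model$indel_rate_msi else model$indel_rate_mss
  reads <- vector("list", nrow(panel) * model$reads_per_locus)
  k <- 0L
  for (i in seq_len(nrow(panel))) {
    locus <- as.list(panel[i, ])
    win <- .locus_amplicon(locus, model$flank_len)
    for (j in seq_len(model$reads_per_locus)) {
      k <- k + 1L
      reads[[k]] <- .simulate_locus_read(
        win, locus, rate, model,
        qname = sprintf("%s_%s_r%04d", sample_id, locus$locus_id, j))
    }
  }
  tab <- as_read_table(reads)
  if (!is.null(path)) {
    writeLines(format_sam(tab), path)
    return(invisible(tab))
  }
  tab
}

#' Simulate a cohort and score it through the full pipeline
#'
#' Generates one SAM file per sample, runs filtering, locus assignment and
#' scoring on each, and returns the calibration table (scores plus truth
#' labels). Deterministic for a fixed model seed.
#'
#' @param model A [cohort_model()].
#' @param panel A `msq_panel`.
#' @param dir Directory for the per-sample SAM files and the scores TSV;
#'   `NULL` keeps everything in memory.
#' @param flank,granularity,aggregate Scoring parameters (see
#'   [compute_panel_metrics()], [compute_sample_score()]).
#' @return Data.frame with `sample_id`, `label` (`MSI`/`MSS`),
#'   `pct_mutated_reads`, `pct_total_mutations`.
#' @export
simulate_cohort <- function(model = cohort_model(), panel, dir = NULL,
                            flank = 1L, granularity = "event",
                            aggregate = "gene_pooled") {
  set.seed(model$seed)
  classes <- c(rep("MSI", model$n_msi), rep("MSS", model$n_mss))
  ids <- sprintf("%s%02d", tolower(classes),
                 c(seq_len(model$n_msi), seq_len(model$n_mss)))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    path <- if (is.null(dir)) NULL else
      file.path(dir, paste0(ids[i], ".sam"))
    reads <- simulate_sample(panel, classes[i], model, ids[i], path = NULL)
    if (!is.null(path)) writeLines(format_sam(reads), path)
    filtered <- filter_reads(reads)
    metrics <- compute_panel_metrics(filtered, panel, flank = flank,
                                     granularity = granularity)
    score <- compute_sample_score(metrics, ids[i], aggregate = aggregate)
    rows[[i]] <- data.frame(
      sample_id = ids[i], label = classes[i],
      pct_mutated_reads = score$mean_pct_mutated_reads,
      pct_total_mutations = score$mean_pct_total_mutations,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(dir)) {
    utils::write.table(out, file.path(dir, "cohort_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
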