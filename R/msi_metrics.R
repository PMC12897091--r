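## Per-locus mutation extraction and the two sample-level instability
## metrics:
##   pct_mutated_reads   = 100 * (reads with >=1 in-window event) / reads
##   pct_total_mutations = 100 * (sum of in-window events) / reads
## The second may exceed 100% when reads carry several events each.

#' Extract mutation events inside a reference window from one read
#'
#' Walks the read's CIGAR and MD tag jointly, tracking the reference
#' coordinate, and returns the events anchored inside the window.
#' Anchoring rules: a substitution is in iff its reference position lies in
#' `[wstart, wend]`; a deletion is in iff *any* deleted base lies in the
#' window; an insertion (anchored to the reference base it follows) is in
#' iff its anchor lies in `[wstart - 1, wend]`, so that an insertion
#' immediately before the first repeat base — a tract-length change — is
#' counted. Upstream or downstream events shift query offsets but produce
#' no window events.
#'
#' @param read An `msq_read` or one-row `msq_reads` table.
#' @param window Integer vector `c(wstart, wend)`, 1-based inclusive
#'   reference coordinates of the repeat tract.
#' @param granularity `"event"` (default): one event per contiguous
#'   insertion or deletion run; `"base"`: each inserted/deleted base counts
#'   as its own event. Substitutions are always per base.
#' @return Data.frame with columns `kind` (`insertion`/`deletion`/
#'   `substitution`), `ref_pos` (anchor), `length`, `bases` (inserted or
#'   deleted bases; observed base for substitutions) and `ref_bases`.
#' @export
extract_mutations <- function(read, window, granularity = c("event", "base")) {
  granularity <- match.arg(granularity)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  ev <- .cigar_md_walk(read)$events
  wstart <- window[1]; wend <- window[2]
  if (nrow(ev) == 0L) return(ev)
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    keep[i] <- switch(ev$kind[i],
      substitution = ev$ref_pos[i] >= wstart && ev$ref_pos[i] <= wend,
      deletion = ev$ref_pos[i] <= wend &&
        (ev$ref_pos[i] + ev$length[i] - 1L) >= wstart,
      insertion = ev$ref_pos[i] >= (wstart - 1L) && ev$ref_pos[i] <= wend)
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  if (granularity == "base" && nrow(ev)) {
    pieces <- lapply(seq_len(nrow(ev)), function(i) {
      if (ev$kind[i] == "substitution" || ev$length[i] == 1L) {
        return(ev[i, , drop = FALSE])
      }
      n <- ev$length[i]
      data.frame(kind = ev$kind[i],
                 ref_pos = if (ev$kind[i] == "deletion")
                   ev$ref_pos[i] + 0:(n - 1L) else rep(ev$ref_pos[i], n),
                 length = 1L,
                 bases = strsplit(ev$bases[i], "")[[1]],
                 ref_bases = if (is.na(ev$ref_bases[i])) NA_character_
                   else strsplit(ev$ref_bases[i], "")[[1]],
                 stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, pieces)
    rownames(ev) <- NULL
  }
  ev
}

#' Per-locus instability metrics
#'
#' Counts, over the reads assigned to a locus, how many carry at least one
#' mutation event inside the repeat tract and how many events occur in
#' total, and forms the two percentages relative to locus depth.
#'
#' @param reads `msq_reads` assigned to the locus (full coverage contract,
#'   see [reads_for_locus()]).
#' @param locus One panel row (`locus_id`, `gene`, `start`, `end`).
#' @param granularity Passed to [extract_mutations()].
#' @return One-row data.frame: `locus_id`, `gene`, `n_total_reads`,
#'   `n_mutated_reads`, `n_mutation_events`, `pct_mutated_reads`,
#'   `pct_total_mutations`, `covered` (FALSE when depth is zero; the
#'   percentages are then `NA` and the locus is excluded from sample
#'   means).
#' @export
compute_locus_metrics <- function(reads, locus,
                                  granularity = c("event", "base")) {
  granularity <- match.arg(granularity)
  if (is.data.frame(locus)) locus <- as.list(locus)
  n <- nrow(reads)
  if (n == 0L) {
    return(data.frame(locus_id = locus$locus_id, gene = locus$gene,
                      n_total_reads = 0L, n_mutated_reads = 0L,
                      n_mutation_events = 0L,
                      pct_mutated_reads = NA_real_,
                      pct_total_mutations = NA_real_,
                      covered = FALSE, stringsAsFactors = FALSE))
  }
  window <- c(locus$start, locus$end)
  rows <- .read_rows(reads)
  per_read <- vapply(rows, function(r) {
    nrow(extract_mutations(r, window, granularity = granularity))
  }, 0L)
  n_mut <- sum(per_read > 0L)
  n_ev <- sum(per_read)
  data.frame(locus_id = locus$locus_id, gene = locus$gene,
             n_total_reads = n, n_mutated_reads = n_mut,
             n_mutation_events = n_ev,
             pct_mutated_reads = 100 * n_mut / n,
             pct_total_mutations = 100 * n_ev / n,
             covered = TRUE, stringsAsFactors = FALSE)
}

#' Per-locus metrics for every locus of a panel
#'
#' @param reads A filtered `msq_reads` table (whole sample).
#' @param panel A `msq_panel`.
#' @param flank Flank for read assignment.
#' @param granularity Passed to [extract_mutations()].
#' @return Data.frame with one row per panel locus (see
#'   [compute_locus_metrics()]).
#' @export
compute_panel_metrics <- function(reads, panel, flank = 1L,
                                  granularity = c("event", "base")) {
  granularity <- match.arg(granularity)
  ## reference span computed once for the whole table, reused per locus
  span_end <- if (nrow(reads)) reads$pos +
    vapply(reads$cigar, cigar_reference_length, 0L, USE.NAMES = FALSE) - 1L
  else integer(0)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    locus <- as.list(panel[i, ])
    keep <- reads$rname == locus$chrom &
      reads$pos <= (locus$start - flank) & span_end >= (locus$end + flank)
    lr <- reads[keep, , drop = FALSE]
    class(lr) <- c("msq_reads", "data.frame")
    compute_locus_metrics(lr, locus, granularity = granularity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate locus metrics into a sample-level instability score
#'
#' Default aggregation pools raw counts per gene over that gene's covered
#' loci (sum of reads, mutated reads and events), forms the gene's two
#' percentages, then takes the unweighted mean across genes with coverage.
#' `aggregate = "locus_mean"` instead averages locus-level percentages per
#' gene before the cross-gene mean.
#'
#' @param metrics Locus metrics table from [compute_panel_metrics()].
#' @param sample_id Sample identifier carried into the result.
#' @param aggregate `"gene_pooled"` (default) or `"locus_mean"`.
#' @return A list of class `msq_sample_score`: `sample_id`,
#'   `mean_pct_mutated_reads`, `mean_pct_total_mutations`, `n_genes_used`,
#'   `gene_metrics` (per-gene table), `locus_metrics`.
#' @export
compute_sample_score <- function(metrics, sample_id = "sample",
                                 aggregate = c("gene_pooled", "locus_mean")) {
  aggregate <- match.arg(aggregate)
  cov <- metrics[metrics$covered, , drop = FALSE]
  if (nrow(cov) == 0L) {
    stop("no covered gene for sample '", sample_id,
         "'; sample not evaluable", call. = FALSE)
  }
  genes <- unique(cov$gene)
  gm <- lapply(genes, function(g) {
    sub <- cov[cov$gene == g, , drop = FALSE]
    if (aggregate == "gene_pooled") {
      nt <- sum(sub$n_total_reads)
      data.frame(gene = g, n_loci = nrow(sub), n_total_reads = nt,
                 pct_mutated_reads = 100 * sum(sub$n_mutated_reads) / nt,
                 pct_total_mutations = 100 * sum(sub$n_mutation_events) / nt,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, n_loci = nrow(sub),
                 n_total_reads = sum(sub$n_total_reads),
                 pct_mutated_reads = mean(sub$pct_mutated_reads),
                 pct_total_mutations = mean(sub$pct_total_mutations),
                 stringsAsFactors = FALSE)
    }
  })
  gm <- do.call(rbind, gm)
  structure(list(
    sample_id = sample_id,
    mean_pct_mutated_reads = mean(gm$pct_mutated_reads),
    mean_pct_total_mutations = mean(gm$pct_total_mutations),
    n_genes_used = nrow(gm),
    gene_metrics = gm,
    locus_metrics = metrics), class = "msq_sample_score")
}

#' @export
print.msq_sample_score <- function(x, ...) {
  cat("MSI sample score for '", x$sample_id, "' (", x$n_genes_used,
      " genes)\n", sep = "")
  cat(sprintf("  mean %% mutated reads:   %.2f\n", x$mean_pct_mutated_reads))
  cat(sprintf("  mean %% total mutations: %.2f\n",
              x$mean_pct_total_mutations))
  invisible(x)
}
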