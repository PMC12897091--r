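## End-to-end orchestration: parse -> filter -> assign -> reference ->
## extract -> score -> classify, plus calibration and concordance entry
## points and a small subcommand-style CLI.

.msq_log <- function(verbose, ...) {
  if (verbose) message("[msquant] ", sprintf(...))
}

#' Run the per-sample scoring workflow
#'
#' Reads an alignment file, applies the validity filters, assigns reads to
#' panel loci, verifies that a reference is obtainable per locus, computes
#' locus and sample metrics and (when cutoffs are supplied) the two MSI
#' calls. Stage counts are logged; outputs are deterministic for fixed
#' inputs.
#'
#' @param alignments Path to a SAM (or BAM, with Rsamtools) file.
#' @param panel A `msq_panel` or path to a panel TSV.
#' @param sample_id Sample identifier; defaults to the alignment file stem.
#' @param out_dir Optional output directory: writes
#'   `<sample>_locus_metrics.tsv`, `<sample>_score.json` and, with
#'   cutoffs, `<sample>_calls.tsv`.
#' @param min_mapq,drop_duplicates,drop_qc_fail Filter policy (see
#'   [read_filter_policy()]).
#' @param flank Locus assignment flank.
#' @param granularity,aggregate Scoring modes (see [extract_mutations()],
#'   [compute_sample_score()]).
#' @param cutoffs Optional named numeric,
#'   `c(pct_mutated_reads = ..., pct_total_mutations = ...)`; each present
#'   entry produces an [classify_msi()] call.
#' @param verbose Log stage counts to the console.
#' @return List of class `msq_run`: `sample_id`, `counts` (reads total /
#'   passing / dropped, loci covered / uncovered / without reference),
#'   `locus_metrics`, `reference_provenance`, `score`
#'   (`msq_sample_score`), `calls` (data.frame or `NULL`).
#' @export
run_sample <- function(alignments, panel, sample_id = NULL, out_dir = NULL,
                       min_mapq = 60L, drop_duplicates = FALSE,
                       drop_qc_fail = FALSE, flank = 1L,
                       granularity = "event", aggregate = "gene_pooled",
                       cutoffs = NULL, verbose = TRUE) {
  if (is.character(panel)) panel <- load_panel(panel)
  if (nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(alignments))
  }
  reads <- read_alignments(alignments)
  policy <- read_filter_policy(min_mapq, drop_duplicates, drop_qc_fail)
  filtered <- filter_reads(reads, policy)
  n_dropped <- attr(filtered, "n_dropped")
  .msq_log(verbose, "sample %s: %d reads, %d pass filters (%d dropped)",
           sample_id, nrow(reads), nrow(filtered), n_dropped)

  locus_rows <- vector("list", nrow(panel))
  prov <- character(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    locus <- panel[i, ]
    lr <- reads_for_locus(filtered, locus, flank = flank)
    if (nrow(lr) == 0L) {
      prov[i] <- "uncovered"
    } else {
      ref <- build_locus_reference(lr, locus, flank = flank)
      prov[i] <- ref$provenance
    }
    locus_rows[[i]] <- compute_locus_metrics(lr, locus,
                                             granularity = granularity)
  }
  metrics <- do.call(rbind, locus_rows)
  rownames(metrics) <- NULL
  n_uncov <- sum(!metrics$covered)
  .msq_log(verbose, "loci: %d covered, %d uncovered",
           nrow(panel) - n_uncov, n_uncov)
  if (all(!metrics$covered)) {
    stop("no evaluable loci for sample '", sample_id, "'", call. = FALSE)
  }
  score <- compute_sample_score(metrics, sample_id, aggregate = aggregate)

  calls <- NULL
  if (!is.null(cutoffs)) {
    pieces <- list()
    if (!is.na(cutoffs["pct_mutated_reads"])) {
      pieces$m1 <- classify_msi(score$mean_pct_mutated_reads,
                                cutoffs[["pct_mutated_reads"]],
                                metric = "pct_mutated_reads",
                                sample_id = sample_id)
    }
    if (!is.na(cutoffs["pct_total_mutations"])) {
      pieces$m2 <- classify_msi(score$mean_pct_total_mutations,
                                cutoffs[["pct_total_mutations"]],
                                metric = "pct_total_mutations",
                                sample_id = sample_id)
    }
    calls <- do.call(rbind, unname(pieces))
    if (!is.null(calls) && nrow(calls) == 2L) {
      attr(calls, "metrics_agree") <- calls$call[1] == calls$call[2]
    }
  }
  res <- structure(list(
    sample_id = sample_id,
    counts = list(reads_total = nrow(reads),
                  reads_passing = nrow(filtered),
                  reads_dropped = n_dropped,
                  loci_covered = nrow(panel) - n_uncov,
                  loci_uncovered = n_uncov),
    locus_metrics = metrics,
    reference_provenance = stats::setNames(prov, panel$locus_id),
    score = score, calls = calls), class = "msq_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      metrics, file.path(out_dir, paste0(sample_id, "_locus_metrics.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(sample_id = sample_id,
           mean_pct_mutated_reads = score$mean_pct_mutated_reads,
           mean_pct_total_mutations = score$mean_pct_total_mutations,
           n_genes_used = score$n_genes_used,
           counts = res$counts),
      file.path(out_dir, paste0(sample_id, "_score.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(calls)) {
      utils::write.table(
        calls, file.path(out_dir, paste0(sample_id, "_calls.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  res
}

#' Calibrate classification cutoffs from a scored, labeled cohort
#'
#' Runs ROC/Youden calibration independently for the two instability
#' metrics on a table of per-sample scores with reference labels.
#'
#' @param scores Data.frame with columns `sample_id`, `pct_mutated_reads`,
#'   `pct_total_mutations`, and a label column (`label` or
#'   `reference_label`, values `MSI`/`MSS`) — or a path to such a TSV.
#' @param out Optional path for the calibration JSON.
#' @param candidates Threshold dialect, see [roc_curve()].
#' @return List of class `msq_calibration`, one entry per metric with
#'   `auc`, `cutoff`, `youden_j`, `sensitivity`, `specificity`, and the
#'   ROC point tables.
#' @export
run_calibrate <- function(scores, out = NULL,
                          candidates = c("observed", "midpoint")) {
  candidates <- match.arg(candidates)
  if (is.character(scores)) {
    scores <- utils::read.delim(scores, stringsAsFactors = FALSE)
  }
  lab_col <- intersect(c("label", "reference_label"), names(scores))[1]
  if (is.na(lab_col)) stop("scores table needs a 'label' column",
                           call. = FALSE)
  need <- c("pct_mutated_reads", "pct_total_mutations")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("scores table missing: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  labels <- .as_binary_labels(scores[[lab_col]])
  calib <- lapply(need, function(metric) {
    roc <- roc_curve(scores[[metric]], labels, candidates = candidates)
    opt <- youden_optimal_cutoff(roc)
    list(metric = metric, auc = roc$auc, cutoff = opt$cutoff,
         youden_j = opt$youden_j, sensitivity = opt$sensitivity,
         specificity = opt$specificity, roc = roc)
  })
  names(calib) <- need
  res <- structure(calib, class = "msq_calibration")
  if (!is.null(out)) {
    jsonlite::write_json(
      lapply(calib, function(x) x[c("metric", "auc", "cutoff", "youden_j",
                                    "sensitivity", "specificity")]),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.msq_calibration <- function(x, ...) {
  for (m in x) {
    cat(sprintf("%s: AUC %.4f, cutoff %.4f (J = %.4f, sens %.3f, spec %.3f)\n",
                m$metric, m$auc, m$cutoff, m$youden_j, m$sensitivity,
                m$specificity))
  }
  invisible(x)
}

#' Concordance report against a reference assay
#'
#' Accepts either explicit 2x2 counts or a table of paired calls
#' (columns `test` and `reference`, values `MSI`/`MSS`; or a path to such
#' a TSV) and reports sensitivity, specificity and concordance.
#'
#' @param tp,fp,fn,tn Explicit cell counts.
#' @param calls Data.frame or TSV path with `test` and `reference` columns.
#' @param out Optional path for the report JSON.
#' @return The [concordance_stats()] list.
#' @export
run_concord <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                        calls = NULL, out = NULL) {
  if (!is.null(calls)) {
    if (is.character(calls)) {
      calls <- utils::read.delim(calls, stringsAsFactors = FALSE)
    }
    if (nrow(calls) == 0L) stop("empty calls table", call. = FALSE)
    tab <- contingency_table(test = calls$test, reference = calls$reference)
  } else {
    tab <- contingency_table(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  res <- concordance_stats(tab)
  if (!is.null(out)) {
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  res
}

#' Command-line entry point
#'
#' Subcommand-style interface: `run`, `calibrate`, `concord`, `simulate`.
#' Invoked from the installed script
#' `system.file("cli", "msquant.R", package = "msquant")` as
#' `Rscript msquant.R <subcommand> [--flag value ...]`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
msquant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: msquant <run|calibrate|concord|simulate> [options]",
    "  run       --alignments F --panel F [--out-dir D] [--min-mapq N]",
    "            [--flank N] [--cutoff-mutated-reads X] [--cutoff-total-mutations X]",
    "  calibrate --scores F [--out F]",
    "  concord   (--tp N --fp N --fn N --tn N | --calls F) [--out F]",
    "  simulate  --panel F --out-dir D [--seed N] [--n-msi N] [--n-mss N]",
    "            [--reads-per-locus N] [--indel-rate-msi X] [--indel-rate-mss X]",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      stop("malformed option: ", rest[i], call. = FALSE)
    }
    opts[[gsub("-", "_", key)]] <- rest[i + 1L]
    i <- i + 2L
  }
  num <- function(k, default = NULL) {
    if (is.null(opts[[k]])) default else as.numeric(opts[[k]])
  }
  switch(cmd,
    run = {
      cutoffs <- c(pct_mutated_reads = num("cutoff_mutated_reads", NA),
                   pct_total_mutations = num("cutoff_total_mutations", NA))
      if (all(is.na(cutoffs))) cutoffs <- NULL
      run_sample(opts$alignments, opts$panel,
                 out_dir = opts$out_dir,
                 min_mapq = num("min_mapq", 60),
                 flank = num("flank", 1),
                 cutoffs = cutoffs)
    },
    calibrate = {
      print(run_calibrate(opts$scores, out = opts$out))
    },
    concord = {
      res <- if (!is.null(opts$calls)) {
        run_concord(calls = opts$calls, out = opts$out)
      } else {
        run_concord(tp = num("tp"), fp = num("fp"), fn = num("fn"),
                    tn = num("tn"), out = opts$out)
      }
      message(sprintf("sensitivity %.2f%%  specificity %.2f%%  concordance %.2f%%",
                      res$sensitivity, res$specificity, res$concordance))
    },
    simulate = {
      model <- cohort_model(
        n_msi = num("n_msi", 16), n_mss = num("n_mss", 15),
        reads_per_locus = num("reads_per_locus", 200),
        indel_rate_msi = num("indel_rate_msi", 0.6),
        indel_rate_mss = num("indel_rate_mss", 0.02),
        seed = num("seed", 1))
      panel <- load_panel(opts$panel)
      dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
      simulate_cohort(model, panel, dir = opts$out_dir)
    },
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
  )
  invisible(0L)
}

#' Path to the bundled demonstration panel
#'
#' A small synthetic 10-locus panel over MSI-relevant genes (ACVR2A,
#' RNF43, TGFBR2, HSP110, BRAF, KIT, TET2) with invented coordinates —
#' for demonstrations and tests only, not for clinical use.
#'
#' @return File path of the panel TSV.
#' @export
demo_panel_path <- function() {
  system.file("extdata", "demo_panel_synthetic.tsv", package = "msquant",
              mustWork = TRUE)
}
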