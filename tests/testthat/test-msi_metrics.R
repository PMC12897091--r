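# Shared fixture: 10 bp flank + 12 x A tract at [100, 111] + 10 bp flank
tract_window <- function() {
  ref_window("chr2", 90L,
             paste0("GCTGCTGCTG", strrep("A", 12), "CGTCGTCGTC"))
}

test_that("extract_mutations applies the documented anchoring rules", {
  win <- tract_window()
  tract <- c(100L, 111L)

  # upstream indel: query offsets shift, no window event
  up <- make_read(win, data.frame(kind = "deletion", ref_pos = 95L,
                                  length = 1L, bases = NA))
  expect_equal(nrow(extract_mutations(up, tract)), 0L)

  # substitution at wend is in; at wend + 1 out
  at_end <- make_read(win, data.frame(kind = "substitution",
                                      ref_pos = 111L, length = 1L,
                                      bases = "G"))
  expect_equal(extract_mutations(at_end, tract)$kind, "substitution")
  past_end <- make_read(win, data.frame(kind = "substitution",
                                        ref_pos = 112L, length = 1L,
                                        bases = "A"))
  expect_equal(nrow(extract_mutations(past_end, tract)), 0L)

  # insertion anchored at wstart - 1 is in (tract-length change);
  # at wstart - 2 out
  ins <- function(p) make_read(win, data.frame(
    kind = "insertion", ref_pos = p, length = 1L, bases = "A"))
  expect_equal(nrow(extract_mutations(ins(99L), tract)), 1L)
  expect_equal(nrow(extract_mutations(ins(98L), tract)), 0L)

  # deletion spanning the window edge counts once if any base is inside
  edge_del <- make_read(win, data.frame(kind = "deletion", ref_pos = 98L,
                                        length = 3L, bases = NA))
  got <- extract_mutations(edge_del, tract)
  expect_equal(got$kind, "deletion")
  expect_equal(got$ref_pos, 98L)
})

test_that("per-base granularity splits indel runs", {
  win <- tract_window()
  rd <- make_read(win, data.frame(kind = "deletion", ref_pos = 103L,
                                  length = 3L, bases = NA))
  expect_equal(nrow(extract_mutations(rd, c(100L, 111L))), 1L)
  per_base <- extract_mutations(rd, c(100L, 111L), granularity = "base")
  expect_equal(nrow(per_base), 3L)
  expect_equal(per_base$ref_pos, 103:105)
  expect_true(all(per_base$length == 1L))
})

test_that("extract_mutations matches the planned in-window sublist", {
  set.seed(401)
  for (i in 1:120) {
    rw <- random_window()
    spec <- random_mutation_spec(rw$win, sample(0:5, 1))
    rd <- make_read(rw$win, spec, soft_clip = c(sample(0:2, 1), 0L),
                    qname = paste0("p", i))
    got <- extract_mutations(rd, c(rw$wstart, rw$wend))
    want <- oracle_window_events(spec, rw$wstart, rw$wend)
    expect_equal(event_key(got), event_key(want))
    # and the raw walk agrees with the per-base oracle on all events
    expect_equal(event_key(extract_mutations(
      rd, c(rd$pos, rd$pos + cigar_reference_length(rd$cigar)))),
      event_key(oracle_walk(rd)$events))
  }
})

test_that("shift-invariance: upstream indels never alter window events", {
  win <- tract_window()
  tract <- c(100L, 111L)
  set.seed(402)
  for (i in 1:40) {
    base_spec <- random_mutation_spec(
      list(start = 100L, seq = strrep("A", 12)), sample(1:3, 1))
    if (nrow(base_spec) == 0L) next
    upstream <- data.frame(
      kind = sample(c("insertion", "deletion"), 1L),
      ref_pos = sample(91:96, 1L), length = 1L,
      bases = sample(c("C", "G"), 1L), stringsAsFactors = FALSE)
    if (upstream$kind == "deletion") upstream$bases <- NA_character_
    plain <- make_read(win, base_spec)
    shifted <- make_read(win, rbind(upstream, base_spec))
    expect_equal(event_key(extract_mutations(shifted, tract)),
                 event_key(extract_mutations(plain, tract)))
  }
})

test_that("compute_locus_metrics forms the two percentages", {
  win <- tract_window()
  locus <- list(locus_id = "L", gene = "G", chrom = "chr2",
                start = 100L, end = 111L, repeat_unit = "A")
  one_del <- data.frame(kind = "deletion", ref_pos = 104L, length = 1L,
                        bases = NA_character_)
  two_ev <- rbind(one_del, data.frame(kind = "insertion", ref_pos = 108L,
                                      length = 1L, bases = "A"))
  # 10 reads: 4 mutated carrying 7 events in total
  reads <- as_read_table(c(
    lapply(1:3, function(i) make_read(win, two_ev, qname = paste0("t", i))),
    list(make_read(win, one_del, qname = "s1")),
    lapply(1:6, function(i) make_read(win, qname = paste0("c", i)))))
  m <- compute_locus_metrics(reads, locus)
  expect_equal(m$n_total_reads, 10L)
  expect_equal(m$n_mutated_reads, 4L)
  expect_equal(m$n_mutation_events, 7L)
  expect_equal(m$pct_mutated_reads, 40)
  expect_equal(m$pct_total_mutations, 70)

  # no mutated reads -> 0 / 0
  clean <- as_read_table(lapply(1:5, function(i)
    make_read(win, qname = paste0("c", i))))
  m0 <- compute_locus_metrics(clean, locus)
  expect_equal(m0$pct_mutated_reads, 0)
  expect_equal(m0$pct_total_mutations, 0)

  # many events per read: pct_total_mutations legitimately exceeds 100
  six_ev <- data.frame(
    kind = rep(c("insertion", "substitution"), 3),
    ref_pos = c(100L, 102L, 103L, 105L, 106L, 108L),
    length = 1L,
    bases = c("A", "G", "A", "G", "A", "G"), stringsAsFactors = FALSE)
  busy <- as_read_table(lapply(1:5, function(i)
    make_read(win, six_ev, qname = paste0("b", i))))
  m6 <- compute_locus_metrics(busy, locus)
  expect_equal(m6$pct_total_mutations, 600)
  expect_equal(m6$pct_mutated_reads, 100)

  # zero coverage -> flagged uncovered
  mu <- compute_locus_metrics(clean[0, ], locus)
  expect_false(mu$covered)
  expect_true(is.na(mu$pct_mutated_reads))
})

test_that("monotonicity: event reads raise, clean reads lower", {
  win <- tract_window()
  locus <- list(locus_id = "L", gene = "G", chrom = "chr2",
                start = 100L, end = 111L, repeat_unit = "A")
  del <- data.frame(kind = "deletion", ref_pos = 104L, length = 1L,
                    bases = NA_character_)
  base <- as_read_table(list(make_read(win, del, qname = "m"),
                             make_read(win, qname = "c")))
  m_base <- compute_locus_metrics(base, locus)
  with_mut <- as_read_table(list(make_read(win, del, qname = "m"),
                                 make_read(win, qname = "c"),
                                 make_read(win, del, qname = "m2")))
  m_mut <- compute_locus_metrics(with_mut, locus)
  expect_gte(m_mut$n_mutated_reads, m_base$n_mutated_reads)
  expect_gte(m_mut$n_mutation_events, m_base$n_mutation_events)
  with_clean <- as_read_table(list(make_read(win, del, qname = "m"),
                                   make_read(win, qname = "c"),
                                   make_read(win, qname = "c2")))
  m_clean <- compute_locus_metrics(with_clean, locus)
  expect_lte(m_clean$pct_mutated_reads, m_base$pct_mutated_reads)
  expect_lte(m_clean$pct_total_mutations, m_base$pct_total_mutations)
})

test_that("compute_sample_score pools per gene then averages genes", {
  mk_metrics <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r) {
      data.frame(locus_id = r[[1]], gene = r[[2]],
                 n_total_reads = r[[3]], n_mutated_reads = r[[4]],
                 n_mutation_events = r[[5]],
                 pct_mutated_reads = 100 * r[[4]] / max(r[[3]], 1),
                 pct_total_mutations = 100 * r[[5]] / max(r[[3]], 1),
                 covered = r[[3]] > 0, stringsAsFactors = FALSE)
    }))
  }
  # single gene, single locus: sample score = locus percentages
  s1 <- compute_sample_score(mk_metrics(list("L1", "G1", 10L, 4L, 7L)))
  expect_equal(s1$mean_pct_mutated_reads, 40)
  expect_equal(s1$mean_pct_total_mutations, 70)

  # two genes at 20 and 60 -> mean 40
  s2 <- compute_sample_score(mk_metrics(list("L1", "G1", 10L, 2L, 2L),
                                        list("L2", "G2", 10L, 6L, 6L)))
  expect_equal(s2$mean_pct_mutated_reads, 40)

  # uncovered gene excluded from the mean
  s3 <- compute_sample_score(mk_metrics(list("L1", "G1", 10L, 5L, 5L),
                                        list("L2", "G2", 0L, 0L, 0L)))
  expect_equal(s3$mean_pct_mutated_reads, 50)
  expect_equal(s3$n_genes_used, 1L)

  # gene pooling: two loci of one gene pool counts (30 reads, 3 mutated)
  s4 <- compute_sample_score(mk_metrics(list("L1", "G1", 20L, 1L, 1L),
                                        list("L2", "G1", 10L, 2L, 2L)))
  expect_equal(s4$mean_pct_mutated_reads, 100 * 3 / 30)
  # locus-mean mode averages the two locus percentages instead
  s4b <- compute_sample_score(mk_metrics(list("L1", "G1", 20L, 1L, 1L),
                                         list("L2", "G1", 10L, 2L, 2L)),
                              aggregate = "locus_mean")
  expect_equal(s4b$mean_pct_mutated_reads, (5 + 20) / 2)

  # nothing covered -> sample failure
  expect_error(compute_sample_score(mk_metrics(list("L1", "G1", 0L, 0L, 0L))),
               "not evaluable")
})
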