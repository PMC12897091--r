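test_that("parse_md tokenizes per the MD grammar", {
  expect_equal(parse_md("4"),
               data.frame(kind = "match_run", length = 4L,
                          bases = NA_character_))
  expect_equal(parse_md("10A5^AC6")$kind,
               c("match_run", "mismatch_base", "match_run",
                 "deletion_bases", "match_run"))
  expect_equal(parse_md("10A5^AC6")$bases[c(2, 4)], c("A", "AC"))
  # leading zero-length run preserved
  tok <- parse_md("0C3")
  expect_equal(tok$kind[1], "match_run")
  expect_equal(tok$length[1], 0L)
  expect_equal(tok$bases[2], "C")
})

test_that("parse_md rejects grammar violations with an offset", {
  expect_error(parse_md("4!2"), "offset 2")
  expect_error(parse_md("AC"), "grammar")       # two mismatches, no number
  expect_error(parse_md("4A"), "end with")      # must end on a run length
  expect_error(parse_md("^AC4"), "grammar")     # must start with a number
})

test_that("is_reference_read requires no mismatches AND no indels", {
  mk <- function(cigar, md, seq = NULL) {
    ql <- cigar_query_length(cigar)
    structure(list(qname = "r", flag = 0L, rname = "chr1", pos = 1L,
                   mapq = 60L, cigar = cigar,
                   seq = if (is.null(seq)) strrep("A", ql) else seq,
                   md = md, nm = NA_integer_), class = "msq_read")
  }
  expect_true(is_reference_read(mk("20M", "20")))
  expect_true(is_reference_read(mk("2S18M", "18")))   # clips permitted
  # insertion present although MD shows no mismatch (MD cannot encode I)
  expect_false(is_reference_read(mk("10M1I9M", "19")))
  expect_false(is_reference_read(mk("20M", "9A10")))
  expect_false(is_reference_read(mk("10M1D10M", "10^A10")))
  # no MD: CIGAR decides
  expect_true(is_reference_read(mk("20M", NA_character_)))
  expect_false(is_reference_read(mk("10M1D10M", NA_character_)))
})

test_that("reconstruct_reference recovers the reference (worked cases)", {
  mk <- function(seq, cigar, md, pos = 100L) {
    structure(list(qname = "r", flag = 0L, rname = "chr1", pos = pos,
                   mapq = 60L, cigar = cigar, seq = seq, md = md,
                   nm = NA_integer_), class = "msq_read")
  }
  # identity
  expect_equal(reconstruct_reference(mk("ACGT", "4M", "4"))$seq, "ACGT")
  # inserted base removed
  expect_equal(reconstruct_reference(mk("ACTGT", "2M1I2M", "4"))$seq,
               "ACGT")
  # deleted base restored
  expect_equal(reconstruct_reference(mk("ACGT", "2M1D2M", "2^A2"))$seq,
               "ACAGT")
  # read base replaced by reference base at a mismatch
  expect_equal(reconstruct_reference(mk("AGT", "3M", "1A1"))$seq, "AAT")
  # soft clips dropped; start stays at POS
  rw <- reconstruct_reference(mk("TTACGT", "2S4M", "4"))
  expect_equal(rw$seq, "ACGT")
  expect_equal(rw$start, 100L)
  # each worked case agrees with the independent per-base oracle
  for (r in list(mk("ACGT", "4M", "4"), mk("ACTGT", "2M1I2M", "4"),
                 mk("ACGT", "2M1D2M", "2^A2"), mk("AGT", "3M", "1A1"),
                 mk("TTACGT", "2S4M", "4"))) {
    expect_equal(reconstruct_reference(r)$seq, oracle_walk(r)$ref)
  }
})

test_that("CIGAR/MD inconsistencies raise reconstruction errors", {
  mk <- function(seq, cigar, md) {
    structure(list(qname = "bad", flag = 0L, rname = "chr1", pos = 1L,
                   mapq = 60L, cigar = cigar, seq = seq, md = md,
                   nm = NA_integer_), class = "msq_read")
  }
  expect_error(reconstruct_reference(mk("ACGT", "4M", "2")),
               "MD exhausted")
  expect_error(reconstruct_reference(mk("ACGT", "4M", "6")),
               "left over")
  expect_error(reconstruct_reference(mk("ACGT", "2M1D2M", "4")),
               "without matching MD")
  expect_error(reconstruct_reference(mk("ACGT", "2M2D2M", "2^A2")),
               "deletion length")
  expect_error(reconstruct_reference(mk("ACGT", "4M", NA_character_)),
               "no MD tag")
})

test_that("build_locus_reference prefers a direct reference read", {
  locus <- list(locus_id = "L", gene = "G", chrom = "chr1",
                start = 105L, end = 114L, repeat_unit = "A")
  win <- ref_window("chr1", 100L, paste0("GCGC", strrep("A", 10), "TCTC"))
  mut <- data.frame(kind = "deletion", ref_pos = 108L, length = 1L,
                    bases = NA_character_)
  reads <- as_read_table(list(
    make_read(win, mut, qname = "m1"),
    make_read(win, qname = "clean"),
    make_read(win, mut, qname = "m2")))
  ref <- build_locus_reference(reads, locus, flank = 1L)
  expect_equal(ref$provenance, "direct")
  expect_equal(ref$n_support, 1L)
  expect_equal(ref$start, 104L)
  expect_equal(ref$seq, substr(win$seq, 5, 16))   # 104..115
})

test_that("consensus reconstruction takes the per-position majority", {
  locus <- list(locus_id = "L", gene = "G", chrom = "chr1",
                start = 105L, end = 114L, repeat_unit = "A")
  win <- ref_window("chr1", 100L, paste0("GCGC", strrep("A", 10), "TCTC"))
  mut <- data.frame(kind = "deletion", ref_pos = 108L, length = 1L,
                    bases = NA_character_)
  # no mutation-free read: every read has an in-tract deletion
  reads3 <- as_read_table(list(
    make_read(win, mut, qname = "m1"),
    make_read(win, mut, qname = "m2"),
    make_read(win, mut, qname = "m3")))
  ref <- build_locus_reference(reads3, locus, flank = 1L)
  expect_equal(ref$provenance, "reconstructed_consensus")
  expect_equal(ref$n_support, 3L)
  expect_equal(ref$seq, substr(win$seq, 5, 16))  # unanimous consensus
  expect_equal(ref$n_ambiguous, 0L)

  # 2:1 discordance: majority base wins, ambiguity reported
  win_alt <- ref_window("chr1", 100L,
                        paste0("GCGC", "AAAAGAAAAA", "TCTC"))
  sub <- data.frame(kind = "substitution", ref_pos = 103L, length = 1L,
                    bases = "T")  # keeps reads from being reference reads
  reads21 <- as_read_table(list(
    make_read(win, sub, qname = "a"),
    make_read(win, sub, qname = "b"),
    make_read(win_alt, sub, qname = "c")))   # disagrees at pos 108
  ref21 <- build_locus_reference(reads21, locus, flank = 1L)
  expect_equal(ref21$provenance, "reconstructed_consensus")
  expect_equal(substr(ref21$seq, 108 - ref21$start + 1L,
                      108 - ref21$start + 1L), "A")
  expect_equal(ref21$n_ambiguous, 1L)

  expect_error(build_locus_reference(reads21[0, ], locus), "no reads")
})

test_that("round-trip: reconstruction recovers the generating reference", {
  set.seed(301)
  for (i in 1:150) {
    rw <- random_window()
    spec <- random_mutation_spec(rw$win, sample(0:4, 1))
    clip <- c(sample(0:3, 1), sample(0:3, 1))
    rd <- make_read(rw$win, spec, soft_clip = clip,
                    qname = paste0("rt", i))
    expect_equal(reconstruct_reference(rd)$seq, rw$win$seq)
    # length invariant
    expect_equal(nchar(reconstruct_reference(rd)$seq),
                 cigar_reference_length(rd$cigar))
    # MD/NM bookkeeping: NM equals mismatches + inserted + deleted bases
    recomputed <- sum(with(oracle_walk(rd)$events,
                           ifelse(kind == "substitution", 1L, length)))
    expect_equal(rd$nm, recomputed)
  }
})
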