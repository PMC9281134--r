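# helper: a top-two table for one query from interval specs
tt_row <- function(subject_id, q_start, q_end, s_lo, s_hi, strand = "+",
                   evalue = 1e-50, rank = 1L, query_id = "tx1") {
  tibble::tibble(query_id, subject_id, rank, q_start = as.integer(q_start),
                 q_end = as.integer(q_end), s_lo = as.integer(s_lo),
                 s_hi = as.integer(s_hi), strand, best_evalue = evalue,
                 best_bitscore = 200, n_hits = 1L)
}

test_that("top_two_subjects ranks, merges and truncates to two", {
  # single subject in, single subject out
  one <- top_two_subjects(hit_row("q", "sA"))
  expect_equal(nrow(one), 1)

  # ranking by e-value
  two <- top_two_subjects(dplyr::bind_rows(
    hit_row("q", "sB", evalue = 1e-20, bitscore = 100),
    hit_row("q", "sA", evalue = 1e-50, bitscore = 200)))
  expect_equal(two$subject_id, c("sA", "sB"))

  # three subjects: only the best two kept
  three <- top_two_subjects(dplyr::bind_rows(
    hit_row("q", "sA", evalue = 1e-50),
    hit_row("q", "sB", evalue = 1e-30),
    hit_row("q", "sC", evalue = 1e-10)))
  expect_setequal(three$subject_id, c("sA", "sB"))

  # fragmented hits of one subject merge to a spanning interval
  merged <- top_two_subjects(dplyr::bind_rows(
    hit_row("q", "sA", q_start = 1, q_end = 200, s_start = 1, s_end = 200),
    hit_row("q", "sA", q_start = 260, q_end = 500, s_start = 260, s_end = 500)))
  expect_equal(merged$q_start, 1L)
  expect_equal(merged$q_end, 500L)

  expect_equal(nrow(top_two_subjects(hit_row()[0, ])), 0)
})

test_that("detect_chimera applies the different-regions criterion", {
  slen <- c(g1.1 = 500, g2.1 = 500)
  # overlapping but distinct regions: call with overlap 30
  call <- detect_chimera(900, dplyr::bind_rows(
    tt_row("g1.1", 1, 480, 1, 480),
    tt_row("g2.1", 451, 900, 1, 450)), slen)
  expect_equal(call$overlap_len, 30L)

  # nested intervals: same region, no call
  expect_null(detect_chimera(520, dplyr::bind_rows(
    tt_row("g1.1", 1, 500, 1, 500),
    tt_row("g2.1", 40, 480, 1, 441)), slen))

  # disjoint with a gap: negative overlap
  gap <- detect_chimera(900, dplyr::bind_rows(
    tt_row("g1.1", 1, 400, 1, 400),
    tt_row("g2.1", 501, 900, 1, 400)), slen)
  expect_equal(gap$overlap_len, -100L)

  # isoforms of one gene are never chimera evidence
  expect_null(detect_chimera(900, dplyr::bind_rows(
    tt_row("g1.1", 1, 480, 1, 480),
    tt_row("g1.2", 451, 900, 1, 450)), c(g1.1 = 500, g1.2 = 500)))

  # fewer than two subjects: nothing to call
  expect_null(detect_chimera(900, tt_row("g1.1", 1, 480, 1, 480), slen))
})

test_that("compute_split reproduces the worked splitting examples", {
  slen <- c(sub1 = 400, sub2 = 800)
  # overlap 30 < 150: midpoint of [451, 480] is 465
  mid <- compute_split(detect_chimera(900, dplyr::bind_rows(
    tt_row("sub1", 1, 480, 1, 400),
    tt_row("sub2", 451, 900, 1, 450)), slen))
  expect_equal(mid$split_kind, "midpoint")
  expect_equal(mid$split_1, 465L)

  # overlap 161 >= 150: corrected boundaries from the reference tails
  # subject 1 length 400 aligned s 1-380 (downstream tail 20) -> end 420
  # subject 2 length 800 aligned s 21-780 (upstream tail 20) -> start 220
  corr <- compute_split(detect_chimera(1000, dplyr::bind_rows(
    tt_row("sub1", 1, 400, 1, 380),
    tt_row("sub2", 240, 1000, 21, 780)), slen))
  expect_equal(corr$split_kind, "corrected_boundary")
  expect_equal(corr$split_1, 420L)
  expect_equal(corr$split_2, 220L)

  # gap of 100 < 150: split at the gap midpoint 450
  gap <- compute_split(detect_chimera(900, dplyr::bind_rows(
    tt_row("sub1", 1, 400, 1, 400),
    tt_row("sub2", 501, 900, 1, 400)), c(sub1 = 400, sub2 = 400)))
  expect_equal(gap$split_kind, "midpoint")
  expect_equal(gap$split_1, 450L)

  # minus-strand subject tails are strand-aware: subject 2 on minus strand
  # aligned s 21-780 has its *upstream* tail at the high-coordinate side
  corr_m <- compute_split(detect_chimera(1000, dplyr::bind_rows(
    tt_row("sub1", 1, 400, 1, 380),
    tt_row("sub2", 240, 1000, 21, 790, strand = "-")), slen))
  expect_equal(corr_m$split_2, 240L - (800L - 790L))  # 230, not 220 (+ strand)
})

test_that("split_transcript conserves sequence and clamps degenerate cases", {
  s <- rand_seq(900, seed = 40)
  call <- tibble::tibble(split_kind = "midpoint", split_1 = 465L,
                         split_2 = NA_integer_)
  frags <- split_transcript("tx", s, call)
  expect_equal(nchar(frags$sequence), c(465L, 435L))
  expect_equal(paste0(frags$sequence[1], frags$sequence[2]), s)
  expect_equal(frags$id, c("tx_split1", "tx_split2"))

  s2 <- rand_seq(1000, seed = 41)
  corr <- tibble::tibble(split_kind = "corrected_boundary", split_1 = 420L,
                         split_2 = 220L)
  f2 <- split_transcript("tx", s2, corr)
  expect_equal(nchar(f2$sequence), c(420L, 781L))
  # union covers the original
  expect_equal(f2$sequence[1], substr(s2, 1, 420))
  expect_equal(f2$sequence[2], substr(s2, 220, 1000))

  # degenerate: midpoint at the last base leaves the transcript unsplit
  expect_warning(
    bad <- split_transcript("tx", s, tibble::tibble(split_kind = "midpoint",
                                                    split_1 = 900L,
                                                    split_2 = NA_integer_)),
    "degenerate")
  expect_equal(nrow(bad), 1)
})

test_that("resolve_assembly replaces chimeras and passes the rest through", {
  ref <- generate_reference_gene_set(30, isoform_fraction = 0,
                                     length_range = c(900, 1600), seed = 50)
  pair <- generate_species_pair(ref, divergence = 0.02, n_chimeras = 5,
                                overlap_mix = 1, seed = 51)
  tx <- pair$species_a
  hits <- seed_extend_align(tx, ref)
  res <- resolve_assembly(tx, hits, setNames(ref$length, ref$id))
  expect_equal(nrow(res$transcripts), nrow(tx) + nrow(res$report))
  truth <- pair$truth$chimera[pair$truth$chimera$species == "A", ]
  expect_setequal(res$report$transcript_id, truth$transcript_id)

  # split positions near planted junctions for midpoint fusions
  m <- dplyr::inner_join(res$report, truth,
                         by = c(transcript_id = "transcript_id"))
  expect_true(all(abs(m$split_1[m$split_kind == "midpoint"] -
                        m$junction[m$split_kind == "midpoint"]) <= 10))

  # no chimeras detected: output identical to input
  clean <- generate_species_pair(ref, divergence = 0.02, n_chimeras = 0,
                                 seed = 52)
  h2 <- seed_extend_align(clean$species_a, ref)
  res2 <- resolve_assembly(clean$species_a, h2, setNames(ref$length, ref$id))
  expect_equal(res2$transcripts$sequence, clean$species_a$sequence)
  expect_equal(nrow(res2$report), 0)

  # idempotence: re-resolving the resolved set makes no further splits
  h3 <- seed_extend_align(res$transcripts, ref)
  res3 <- resolve_assembly(res$transcripts, h3, setNames(ref$length, ref$id))
  expect_equal(nrow(res3$report), 0)
})
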