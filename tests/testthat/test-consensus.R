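## minimal hand-written SAM text for alignment-loading tests
write_test_sam <- function(lines, chrom_len = c(chr1 = 10000)) {
  path <- tempfile(fileext = ".sam")
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len), chrom_len)
  )
  writeLines(c(header, lines), path)
  path
}

sam_line <- function(qname, flag, chrom, pos1, cigar, seq, mate_pos1 = pos1,
                     mapq = 60) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t0\t%s\t%s",
          qname, flag, chrom, pos1, mapq, cigar, mate_pos1, seq,
          strrep("?", nchar(seq)))
}

test_that("a proper pair loads with the correct fragment interval", {
  sam <- write_test_sam(c(
    sam_line("p1", 99L, "chr1", 101, "6M", "ACGTAC", 120),
    sam_line("p1", 147L, "chr1", 120, "6M", "TTGCAA", 101)
  ))
  pairs <- load_alignments(sam)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$frag_start, 100L)
  expect_equal(pairs$frag_end, 125L)
  expect_identical(pairs$orientation, "F1R2")
  expect_identical(pairs$r1_seq, "ACGTAC")
})

test_that("discordant pairs are excluded and counted", {
  sam <- write_test_sam(c(
    sam_line("p1", 99L, "chr1", 101, "6M", "ACGTAC"),
    sam_line("p1", 147L, "chr2", 120, "6M", "TTGCAA"),
    sam_line("p2", 65L, "chr1", 300, "6M", "ACGTAC", 350),
    sam_line("p2", 129L, "chr1", 350, "6M", "TTGCAA", 300)
  ), chrom_len = c(chr1 = 10000, chr2 = 10000))
  ## p1: mates on different chromosomes; p2: mates on the same strand
  pairs <- load_alignments(sam)
  expect_equal(nrow(pairs), 0L)
  d <- attr(pairs, "discards")
  expect_equal(unname(d["different_chrom"]), 1L)
  expect_equal(unname(d["same_strand"]), 1L)
})

test_that("deletions project as N and insertions are dropped", {
  sam <- write_test_sam(c(
    sam_line("p1", 99L, "chr1", 101, "3M2D3M", "ACGTAC", 130),
    sam_line("p1", 147L, "chr1", 130, "2M2I4M", "GGTTCCAA", 101)
  ))
  pairs <- load_alignments(sam)
  expect_identical(pairs$r1_seq, "ACGNNTAC")
  expect_identical(pairs$r2_seq, "GGCCAA")
  expect_equal(pairs$frag_end, 135L)
})

test_that("grouping is exact on the fragment key and conserves records", {
  p <- rbind(
    fixture_pair("c", 100, 300, "F1R2", strrep("A", 50), strrep("A", 50),
                 qname = "a"),
    fixture_pair("c", 100, 300, "F2R1", strrep("A", 50), strrep("A", 50),
                 qname = "b"),
    fixture_pair("c", 100, 301, "F1R2", strrep("A", 50), strrep("A", 50),
                 qname = "d")
  )
  gp <- group_spg(p)
  spg <- attr(gp, "spg")
  expect_equal(nrow(spg), 2L)
  expect_equal(spg[frag_end == 300, n_f1r2], 1L)
  expect_equal(spg[frag_end == 300, n_f2r1], 1L)
  expect_equal(sum(spg$n_f1r2 + spg$n_f2r1), nrow(p))

  sim <- local({
    g <- make_genome(1e5, 0.5, seed = 3)
    fr <- shear_fragments(g, 300, overhang_probs = c(1, 0, 0), seed = 4)
    sample_and_sequence(end_repair(fr),
                        library_params(n_molecules = 250, seed = 5))
  })
  gp2 <- group_spg(sim$pairs)
  expect_equal(sum(attr(gp2, "spg")$n_f1r2 + attr(gp2, "spg")$n_f2r1),
               nrow(sim$pairs))
  expect_equal(uniqueN(gp2$spg_id), nrow(attr(gp2, "spg")))
})

test_that("strand consensus matches the exhaustive majority oracle", {
  ## family of up to 3 pairs; R1 carries the variable base at position 0,
  ## R2 contributes a fixed base at position 1
  build_family <- function(bases) {
    rbindlist(lapply(seq_along(bases), function(i) {
      fixture_pair("c", 10, 12, "F1R2", bases[i], "A",
                   r1_pos0 = 10, r2_pos0 = 11, qname = paste0("q", i))
    }))
  }
  for (size in 1:3) {
    combos <- do.call(expand.grid,
                      c(rep(list(BASES4), size),
                        list(stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(combos))) {
      bases <- unname(unlist(combos[r, ]))
      fam <- build_family(bases)
      got <- strand_consensus(fam)
      expect_identical(got$bases[1], oracle_call(bases),
                       label = paste(bases, collapse = ","))
      expect_equal(got$depth[1], size)
    }
  }
  ## spec example: {A,A,C} against threshold 0.8 is ambiguous
  got <- strand_consensus(build_family(c("A", "A", "C")),
                          agreement_threshold = 0.8)
  expect_identical(got$bases[1], "N")
  ## a fraction exactly at the threshold is accepted
  got <- strand_consensus(build_family(c("A", "A", "C", "C", "A")),
                          agreement_threshold = 0.6)
  expect_identical(got$bases[1], "A")
})

test_that("duplex consensus requires both orientations and agreement", {
  one <- fixture_pair("c", 10, 14, "F1R2", "ACGT", "ACGT", r1_pos0 = 10,
                      r2_pos0 = 10)
  expect_null(duplex_consensus(one))

  both <- rbind(
    one,
    fixture_pair("c", 10, 14, "F2R1", "ACGT", "ACGT", r1_pos0 = 10,
                 r2_pos0 = 10, qname = "q2")
  )
  dc <- duplex_consensus(both)
  expect_identical(dc$seq, "ACGT")
  expect_identical(dc$flags, "RRRR")

  ## strand-discordant base -> N with a conflict flag, never a call
  conf <- rbind(
    one,
    fixture_pair("c", 10, 14, "F2R1", "AGGT", "AGGT", r1_pos0 = 10,
                 r2_pos0 = 10, qname = "q2")
  )
  dc2 <- duplex_consensus(conf)
  expect_identical(dc2$seq, "ANGT")
  expect_identical(dc2$flags, "RCRR")
})

test_that("the vectorized caller agrees with the per-group reference", {
  g <- make_genome(1e5, 0.5, seed = 11)
  fr <- shear_fragments(g, 250, seed = 12)
  fr <- apply_ss_damage(fr, damage_params(p_ds = 5e-3), seed = 13)
  sim <- sample_and_sequence(
    end_repair(fr),
    library_params(n_molecules = 200, dup_mean = 3, seq_error_rate = 5e-3,
                   pcr_error_rate = 1e-3, seed = 14)
  )
  dcs <- call_duplex_consensus(sim$pairs)
  gp <- group_spg(sim$pairs)
  done <- 0L
  for (sid in unique(dcs$spg_id)) {
    ref <- duplex_consensus(gp[spg_id == sid])
    row <- dcs[spg_id == sid]
    expect_identical(row$seq, ref$seq)
    expect_identical(row$flags, ref$flags)
    done <- done + 1L
  }
  expect_equal(done, nrow(dcs))
  ## conservation: SP-Gs with both orientations present all got called
  spg <- attr(gp, "spg")
  expect_equal(nrow(dcs), sum(spg$n_f1r2 >= 1L & spg$n_f2r1 >= 1L))
})

test_that("planted strand-discordant damage never becomes a call", {
  g <- make_genome(1e5, 0.5, seed = 21)
  fr <- shear_fragments(g, 400, overhang_probs = c(1, 0, 0), seed = 22)
  fr <- apply_ss_damage(fr, damage_params(p_oxog_ss = 0, p_iz_ss = 0,
                                          p_deamc_ss = 0, p_ds = 0.02),
                        seed = 23)
  sim <- sample_and_sequence(
    end_repair(fr),
    library_params(n_molecules = 350, dup_mean = 3, seq_error_rate = 0,
                   pcr_error_rate = 0, seed = 24)
  )
  expect_gt(nrow(sim$substitutions), 0L)
  expect_true(all(!sim$substitutions$concordant))
  dcs <- call_duplex_consensus(sim$pairs)
  mm <- dcs_mismatch(dcs, g)
  expect_equal(mm$n_mis, 0L)
  ## the damaged positions show up as strand conflicts, not calls
  expect_gt(sum(lengths(regmatches(dcs$flags, gregexpr("C", dcs$flags)))),
            0L)
})

test_that("consensus SAM round trip preserves sequences and flags", {
  g <- make_genome(1e5, 0.5, seed = 31)
  fr <- shear_fragments(g, 100, seed = 32)
  sim <- sample_and_sequence(end_repair(fr),
                             library_params(n_molecules = 80, seed = 33))
  dcs <- call_duplex_consensus(sim$pairs)
  path <- tempfile(fileext = ".sam")
  write_dcs(dcs, path, g$length)
  back <- read_dcs(path)
  expect_equal(nrow(back), nrow(dcs))
  setorder(dcs, start, end)
  expect_equal(back$start, dcs$start)
  expect_identical(back$seq, dcs$seq)
  expect_identical(back$flags, dcs$flags)

  ## an empty set still writes a valid, loadable SAM
  empty <- dcs[0]
  p2 <- tempfile(fileext = ".sam")
  write_dcs(empty, p2, g$length)
  expect_equal(nrow(read_dcs(p2)), 0L)
})
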