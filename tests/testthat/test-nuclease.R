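test_that("model construction validates names and parameters", {
  expect_error(nuclease_model("xyz"), "unknown nuclease")
  m <- nuclease_model("recjf")
  expect_equal(m$p_gap(1e6), 0)
  expect_equal(m$p_nick(1e6), 0)
  expect_error(nuclease_model("recjf", p_nick_max = 0.5), "exonuclease")
  s1 <- nuclease_model("s1")
  u <- c(0, 1, 3, 10, 100)
  expect_true(all(diff(s1$p_overhang(u)) > 0))    # monotone in units
  expect_true(all(s1$p_overhang(u) <= 1))
  expect_equal(s1$p_overhang(0), 0)
  expect_error(s1$p_overhang(-1), "units")
})

test_that("zero units leave fragments untouched", {
  g <- tiny_genome(30000, seed = 1)
  fr <- shear_fragments(g, 150, nick_rate = 1e-3, gap_rate = 1e-3, seed = 2)
  fr <- apply_ss_damage(fr, damage_params(), seed = 3)
  dig <- digest_nuclease(fr, nuclease_model("s1"), units = 0, seed = 4)
  expect_equal(nrow(dig), nrow(fr))
  setorder(dig, molecule_id)
  cmp <- copy(fr); setorder(cmp, molecule_id)
  expect_equal(dig$start, cmp$start)
  expect_equal(dig$end, cmp$end)
  expect_identical(dig$lesions, cmp$lesions)
})

test_that("saturating endonuclease digestion removes every SS lesion", {
  g <- make_genome(5e4, 0.5, seed = 5)
  fr <- shear_fragments(g, 500, nick_rate = 1e-3, gap_rate = 1e-3, seed = 6)
  fr <- apply_ss_damage(fr, damage_params(p_oxog_ss = 0.05, p_iz_ss = 0.02,
                                          p_deamc_ss = 0.02, p_ds = 1e-3),
                        seed = 7)
  expect_gt(n_lesions(fr, c("overhang", "gap", "nick_adjacent")), 0L)
  dig <- digest_nuclease(fr, nuclease_model("s1"), units = 1e6, seed = 8)
  expect_equal(n_lesions(dig, c("overhang", "gap", "nick_adjacent")), 0L)
  ## double-strand damage is no nuclease substrate
  expect_gt(n_lesions(dig, "ds"), 0L)
  ## all emitted material is overhang-free and long enough
  expect_true(all(dig$oh_len_l == 0L & dig$oh_len_r == 0L))
  expect_true(all(dig$end - dig$start >= 50L))
})

test_that("the 5'->3' exonuclease model acts on 5' overhangs only", {
  g <- tiny_genome(20000, seed = 9)
  ## fixture of five 3'-overhang-only fragments: RecJf must not touch them
  frs <- lapply(0:4, function(i) {
    fixture_fragment(g, 1000 + i * 700, 1350 + i * 700,
                     oh_kind_l = "three_prime", oh_len_l = 5L,
                     oh_kind_r = "three_prime", oh_len_r = 7L,
                     molecule_id = i + 1L)
  })
  fr <- do.call(rbind_fragments, frs)
  dig <- digest_nuclease(fr, nuclease_model("recjf"), units = 1e6, seed = 1)
  setorder(dig, molecule_id)
  expect_equal(dig$start, fr$start)
  expect_equal(dig$end, fr$end)
  expect_identical(dig$oh_kind_l, fr$oh_kind_l)
  expect_identical(dig$oh_len_r, fr$oh_len_r)

  ## on a mixed population it removes 5' overhang lesions but not gap ones
  frm <- shear_fragments(g, 300, gap_rate = 2e-3, seed = 10)
  frm <- apply_ss_damage(frm, damage_params(p_oxog_ss = 0.05, p_ds = 0),
                         seed = 11)
  digm <- digest_nuclease(frm, nuclease_model("recjf"), units = 1e6,
                          seed = 12)
  n5 <- 0L
  for (i in seq_len(nrow(digm))) {
    les <- digm$lesions[[i]]
    if (is.null(les)) next
    ov <- les[les$region_kind == "overhang"]
    if (nrow(ov) == 0L) next
    ## any surviving overhang lesion must sit on a 3' overhang
    for (j in seq_len(nrow(ov))) {
      on_left <- ov$pos[j] < digm$start[i] + digm$oh_len_l[i]
      kind <- if (on_left) digm$oh_kind_l[i] else digm$oh_kind_r[i]
      expect_identical(kind, "three_prime")
    }
    n5 <- n5 + 1L
  }
  expect_gt(n_lesions(digm, "gap"), 0L)
})

test_that("gap cleavage splits fragments with correct bookkeeping", {
  g <- tiny_genome(20000, seed = 13)
  les <- data.table(pos = c(2105L, 2440L), strand = c("-", "+"),
                    ref_ds = c("G", "G"), alt_ds = c("T", "T"),
                    lesion = "oxoG", region_kind = c("gap", "overhang"),
                    anchor = NA_integer_)
  fr <- fixture_fragment(
    g, 2000, 2500, oh_kind_r = "five_prime", oh_len_r = 8L,
    gaps = data.table(strand = "+", gstart = 2100L, gend = 2110L),
    lesions = les[2:1]  # order must not matter
  )
  dig <- digest_nuclease(fr, nuclease_model("s1", p_oh_max = 0),
                         units = 1e6, seed = 14)
  setorder(dig, start)
  expect_equal(nrow(dig), 2L)
  expect_equal(dig$start, c(2000L, 2110L))
  expect_equal(dig$end, c(2100L, 2500L))
  expect_identical(dig$lineage, c("1.1", "1.2"))
  expect_true(all(dig$molecule_id != 1L))
  ## the gap lesion went with the released template; the overhang lesion
  ## stays on the right-hand product, whose overhang was not excised
  expect_equal(n_lesions(dig, "gap"), 0L)
  expect_equal(n_lesions(dig, "overhang"), 1L)
  expect_identical(dig$oh_kind_r, c("blunt", "five_prime"))

  ## a product shorter than the emission threshold is dropped
  fr2 <- fixture_fragment(
    g, 2000, 2500,
    gaps = data.table(strand = "+", gstart = 2030L, gend = 2040L)
  )
  dig2 <- digest_nuclease(fr2, nuclease_model("s1"), units = 1e6,
                          seed = 15, min_emit_len = 50L)
  expect_equal(nrow(dig2), 1L)
  expect_equal(c(dig2$start, dig2$end), c(2040L, 2500L))
})

test_that("nick cleavage splits at the nick and discards its flap lesions", {
  g <- tiny_genome(20000, seed = 16)
  fr <- fixture_fragment(
    g, 3000, 3400,
    nicks = data.table(strand = "+", pos = 3200L),
    lesions = data.table(pos = 3201L, strand = "-", ref_ds = "G",
                         alt_ds = "T", lesion = "oxoG",
                         region_kind = "nick_adjacent", anchor = 3200L)
  )
  s1 <- nuclease_model("s1")
  dig <- digest_nuclease(fr, s1, units = 1e6, seed = 17)
  setorder(dig, start)
  expect_equal(nrow(dig), 2L)
  expect_equal(dig$end[1], 3200L)
  expect_equal(dig$start[2], 3200L)
  expect_equal(n_lesions(dig), 0L)

  ## an MBN-like enzyme leaves most nicks alone at moderate units
  p_mbn <- nuclease_model("mbn")$p_nick(10)
  p_s1 <- s1$p_nick(10)
  expect_lt(p_mbn, p_s1 / 5)
})

test_that("surviving SS-lesion count is monotone in units (common draws)", {
  g <- make_genome(5e4, 0.5, seed = 18)
  fr <- shear_fragments(g, 400, nick_rate = 1e-3, gap_rate = 5e-4,
                        seed = 19)
  fr <- apply_ss_damage(fr, damage_params(p_oxog_ss = 0.05, p_iz_ss = 0.02,
                                          p_deamc_ss = 0.02, p_ds = 0),
                        seed = 20)
  surv <- vapply(c(0, 1, 3, 10, 30, 100, 1000), function(u) {
    d <- digest_nuclease(fr, nuclease_model("s1"), units = u, seed = 21)
    n_lesions(d, c("overhang", "gap", "nick_adjacent"))
  }, numeric(1))
  expect_true(all(diff(surv) <= 0))
  expect_lt(surv[length(surv)], surv[1])
})
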