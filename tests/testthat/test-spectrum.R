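test_that("clipping masks fragment ends symmetrically", {
  g <- tiny_genome(2000, seed = 1)
  seq30 <- substring(g$seq, 101, 130)
  dcs <- fixture_dcs(g$name, 100, 130, seq30)
  expect_identical(clip_ends(dcs, 0)$seq, dcs$seq)          # identity
  c5 <- clip_ends(dcs, 5)
  expect_identical(c5$seq,
                   paste0(strrep("N", 5), substring(seq30, 6, 25),
                          strrep("N", 5)))
  expect_identical(substring(c5$flags, 1, 5), "KKKKK")
  ## 2k >= length blanks the whole consensus
  c20 <- clip_ends(dcs, 20)
  expect_identical(c20$seq, strrep("N", 30))
  cnt <- count_substitutions(c20, g)
  expect_true(all(cnt$denominators == 0))
  expect_error(frequencies(cnt), "denominators")
  expect_error(clip_ends(dcs, -1), "k")
})

test_that("substitution counting distinguishes reference and read frames", {
  g <- tiny_genome(2000, seed = 2)
  start <- 200L; end <- 500L
  ref <- substring(g$seq, start + 1, end)

  ## plant a G>T at a left-half G (forward-read territory)
  gl <- which(strsplit(ref, "")[[1]] == "G" & seq_len(300) <= 150)[1]
  seq_l <- `substr<-`(ref, gl, gl, "T")
  dcs_l <- fixture_dcs(g$name, start, end, seq_l)
  for (fr in c("reference", "fragment")) {
    cnt <- count_substitutions(dcs_l, g, frame = fr)
    expect_equal(cnt$counts["G", "T"], 1L, info = fr)
    expect_equal(sum(cnt$counts[row(cnt$counts) != col(cnt$counts)]), 1)
  }

  ## the same event in the right half is complemented in fragment frame:
  ## sequenced on the reverse read, a reference G>T reads as C>A
  gr <- which(strsplit(ref, "")[[1]] == "G" & seq_len(300) > 160)[1]
  seq_r <- `substr<-`(ref, gr, gr, "T")
  dcs_r <- fixture_dcs(g$name, start, end, seq_r)
  cnt_ref <- count_substitutions(dcs_r, g, frame = "reference")
  expect_equal(cnt_ref$counts["G", "T"], 1L)
  cnt_frag <- count_substitutions(dcs_r, g, frame = "fragment")
  expect_equal(cnt_frag$counts["C", "A"], 1L)
  expect_equal(cnt_frag$counts["G", "T"], 0L)

  ## denominators: every non-N base counts toward its (frame) ref base
  expect_equal(sum(cnt_ref$denominators), 300)
  expect_equal(sum(cnt_frag$denominators), 300)
  ## 6-type pooling is frame-invariant
  f_ref <- frequencies(cnt_ref)$freq6
  f_frag <- frequencies(cnt_frag)$freq6
  expect_equal(f_ref[f_ref$type == "G:C>T:A", "count"],
               f_frag[f_frag$type == "G:C>T:A", "count"])

  ## an identical consensus yields zero counts and full denominators
  cnt0 <- count_substitutions(fixture_dcs(g$name, start, end, ref), g)
  expect_true(all(cnt0$counts[row(cnt0$counts) != col(cnt0$counts)] == 0))
  expect_equal(sum(cnt0$denominators), 300)
})

test_that("known-variant masking removes positions from both sides", {
  g <- tiny_genome(2000, seed = 3)
  start <- 100L; end <- 400L
  ref <- substring(g$seq, start + 1, end)
  gl <- which(strsplit(ref, "")[[1]] == "G")[1]
  dcs <- fixture_dcs(g$name, start, end, `substr<-`(ref, gl, gl, "T"))

  ## empty mask: unchanged
  cnt <- count_substitutions(dcs, g, frame = "reference",
                             mask = data.table(chrom = character(),
                                               start = integer(),
                                               end = integer()))
  expect_equal(cnt$counts["G", "T"], 1L)

  ## mask exactly the planted position: count and denominator both drop
  m <- data.table(chrom = g$name, start = start + gl - 1L,
                  end = start + gl)
  cnt_m <- count_substitutions(dcs, g, frame = "reference", mask = m)
  expect_equal(cnt_m$counts["G", "T"], 0L)
  expect_equal(sum(cnt_m$denominators), 299)

  ## mask covering everything zeroes counts and denominators
  all_m <- data.table(chrom = g$name, start = 0L, end = g$length)
  cnt_all <- count_substitutions(dcs, g, mask = all_m)
  expect_true(all(cnt_all$counts == 0) && all(cnt_all$denominators == 0))

  ## malformed BED lines are rejected with their line number
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\tfoo\t20"), bad)
  expect_error(read_bed_mask(bad), "line 2")
})

test_that("frequency arithmetic reproduces published pooled values", {
  mk <- function(f12) {
    ## equal per-base denominators, counts back-derived from frequencies
    D <- 1e8
    cm <- matrix(0, 4, 4, dimnames = list(BASES4, BASES4))
    for (nm in names(f12)) {
      ro <- strsplit(nm, ">")[[1]]
      cm[ro[1], ro[2]] <- f12[[nm]] * D / 1e6
    }
    substitution_counts(cm, setNames(rep(D, 4), BASES4))
  }
  ## single-class arithmetic
  sp <- frequencies(mk(c("G>T" = 0.18)))
  expect_equal(sp$freq12[sp$freq12$type == "G>T", freq_per_mb], 0.18)

  ## strand-resolved control frequencies pool to the published 6-type
  ## values: 0.18/0.021 -> 0.10, 0.28/0.013 -> 0.15, 0.062/0.096 -> 0.08
  sp <- frequencies(mk(c(
    "G>T" = 0.18, "C>A" = 0.021, "G>C" = 0.28, "C>G" = 0.013,
    "G>A" = 0.062, "C>T" = 0.096
  )))
  f6 <- setNames(sp$freq6$freq_per_mb, sp$freq6$type)
  expect_equal(round(unname(f6["G:C>T:A"]), 2), 0.10)
  expect_equal(round(unname(f6["G:C>C:G"]), 2), 0.15)
  expect_equal(round(unname(f6["G:C>A:T"]), 2), 0.08)

  ## zero-denominator classes are missing, not zero
  cm <- matrix(0, 4, 4, dimnames = list(BASES4, BASES4))
  cm["G", "T"] <- 5
  sp2 <- frequencies(substitution_counts(
    cm, c(A = 0, C = 1e6, G = 1e6, T = 0)
  ))
  expect_true(is.na(sp2$freq6[sp2$freq6$type == "A:T>T:A", freq_per_mb]))
  expect_false(is.na(sp2$freq6[sp2$freq6$type == "G:C>T:A", freq_per_mb]))
})

test_that("denominators, N, clipped and masked positions conserve totals", {
  g <- make_genome(5e4, 0.5, seed = 5)
  fr <- shear_fragments(g, 150, seed = 6)
  sim <- sample_and_sequence(
    end_repair(apply_ss_damage(fr, damage_params(), seed = 7)),
    library_params(n_molecules = 120, seq_error_rate = 5e-3, seed = 8)
  )
  dcs <- clip_ends(call_duplex_consensus(sim$pairs), 10)
  cnt <- count_substitutions(dcs, g, frame = "reference")
  n_nonN <- sum(nchar(gsub("N", "", dcs$seq)))
  expect_equal(sum(cnt$denominators), n_nonN)
  total <- sum(dcs$end - dcs$start)
  n_N <- sum(nchar(dcs$seq)) - n_nonN
  expect_equal(sum(cnt$denominators) + n_N, total)
})

test_that("spectrum TSV round trip preserves values", {
  cm <- matrix(0, 4, 4, dimnames = list(BASES4, BASES4))
  cm["G", "T"] <- 7; cm["C", "G"] <- 2
  sp <- frequencies(substitution_counts(cm, setNames(rep(2e6, 4), BASES4)),
                    label = "x", replicate = 2L)
  path <- tempfile(fileext = ".tsv")
  write_spectrum_tsv(sp, path)
  back <- read_spectrum_tsv(path)
  expect_equal(back$freq12$freq_per_mb, sp$freq12$freq_per_mb)
  expect_equal(back$freq6$freq_per_mb, sp$freq6$freq_per_mb)
  expect_identical(back$meta$label, "x")
})

test_that("identical groups compare null; Dunnett k=1 equals Student's t", {
  mk_tab <- function(vals) {
    ## spectrum table with the same frequency for every type
    cm <- matrix(0, 4, 4, dimnames = list(BASES4, BASES4))
    cm["G", "T"] <- vals * 1e2
    frequencies(substitution_counts(cm, setNames(rep(1e8, 4), BASES4)))
  }
  a <- lapply(c(1, 2, 3), mk_tab)
  cmp <- compare_groups(a, a, test = "ttest")
  expect_true(all(cmp$log2_fold_change == 0))
  expect_true(all(cmp$p_value == 1))

  set.seed(1)
  x <- rnorm(4, 10); y <- rnorm(4, 12)
  d <- dunnett_pvalue(list(x), y)
  expect_equal(d$p_adj,
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-9)

  ## replicate-count guards
  expect_error(compare_groups(a[1], a, test = "ttest"), "replicates")
  expect_error(dunnett_pvalue(list(c(1, 2), c(1, 2, 3)), c(1)), "replicates")
})

test_that("Dunnett adjustment matches a Monte-Carlo max-|t| oracle", {
  ## fixed fixture: two treatment groups of 3 vs one control of 3
  ctrl <- c(10.0, 10.4, 9.6)
  g1 <- c(10.9, 11.3, 10.7)
  g2 <- c(10.2, 10.6, 9.9)
  d <- dunnett_pvalue(list(g1, g2), ctrl)

  ## oracle: simulate the null distribution of max |t_j| with the same
  ## group structure and pooled-variance statistics
  set.seed(99)
  B <- 2e5
  n <- 3L; k <- 2L
  obs <- matrix(rnorm(B * n * (k + 1)), ncol = n * (k + 1))
  m0 <- rowMeans(obs[, 1:n])
  gm <- vapply(seq_len(k), function(j) {
    rowMeans(obs[, (j * n + 1):(j * n + n)])
  }, numeric(B))
  dev <- function(cols) {
    sub <- obs[, cols, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }
  ss <- dev(1:n) + dev((n + 1):(2 * n)) + dev((2 * n + 1):(3 * n))
  s2 <- ss / (3 * n - 3)
  tmax <- pmax(
    abs(gm[, 1] - m0) / sqrt(s2 * (2 / n)),
    abs(gm[, 2] - m0) / sqrt(s2 * (2 / n))
  )
  p_mc <- vapply(abs(d$tstat), function(t0) mean(tmax >= t0), numeric(1))
  expect_lt(max(abs(d$p_adj - p_mc)), 0.005)
})

test_that("Dunnett agrees with an established many-to-one implementation", {
  skip_if_not_installed("multcomp")
  set.seed(7)
  vals <- list(ctrl = rnorm(4, 10), a = rnorm(4, 11), b = rnorm(4, 10.2),
               c = rnorm(4, 9.5))
  d <- dunnett_pvalue(vals[c("a", "b", "c")], vals$ctrl)
  df <- data.frame(
    y = unlist(vals, use.names = FALSE),
    g = factor(rep(c("ctrl", "a", "b", "c"), each = 4),
               levels = c("ctrl", "a", "b", "c"))
  )
  fit <- multcomp::glht(stats::aov(y ~ g, data = df),
                        linfct = multcomp::mcp(g = "Dunnett"))
  p_ref <- summary(fit)$test$pvalues
  expect_lt(max(abs(d$p_adj - as.numeric(p_ref))), 0.002)
})

test_that("fold changes stay finite through the frequency pseudocount", {
  mk_tab <- function(v) {
    cm <- matrix(0, 4, 4, dimnames = list(BASES4, BASES4))
    cm["G", "T"] <- v
    frequencies(substitution_counts(cm, setNames(rep(1e6, 4), BASES4)))
  }
  tr <- lapply(c(3, 4, 5), mk_tab)   # freq 3..5 per Mb
  ct <- lapply(c(0, 0, 0), mk_tab)   # zero frequency in controls
  cmp <- compare_groups(tr, ct, test = "ttest", pseudocount = 0.001)
  gt <- cmp[cmp$type == "G:C>T:A"]
  expect_true(is.finite(gt$log2_fold_change))
  expect_equal(gt$log2_fold_change, log2((2 + 0.001) / 0.001),
               tolerance = 1e-6)
  expect_equal(gt$neg_log10_p, -log10(gt$p_value))
})
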