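## Substitution classes ------------------------------------------------------

TYPES12 <- {
  x <- expand.grid(ref = BASES, obs = BASES, stringsAsFactors = FALSE)
  x <- x[x$ref != x$obs, ]
  x <- x[order(match(x$ref, c("G", "C", "A", "T"))), ]
  paste0(x$ref, ">", x$obs)
}

## 6-type classes pool each substitution with its reverse complement
TYPES6 <- c("G:C>T:A", "G:C>C:G", "G:C>A:T", "A:T>T:A", "A:T>C:G", "A:T>G:C")
.SIX_MAP <- list(
  "G:C>T:A" = c("G>T", "C>A"), "G:C>C:G" = c("G>C", "C>G"),
  "G:C>A:T" = c("G>A", "C>T"), "A:T>T:A" = c("A>T", "T>A"),
  "A:T>C:G" = c("A>C", "T>G"), "A:T>G:C" = c("A>G", "T>C")
)

#' Clip fragment ends of consensus sequences
#'
#' Masks the `k` positions adjacent to each fragment end as `N`, removing
#' them from both the substitution numerator and the denominator — the
#' in-silico analogue of trimming the first bases of each read, which for a
#' fragment-coordinate consensus acts at the fragment ends.
#'
#' @param dcs A `dcs_set`.
#' @param k Bases to mask at each end (>= 0); `2k >=` fragment length masks
#'   the whole consensus.
#' @return A new `dcs_set` (flags of masked positions set to `K`).
#' @export
clip_ends <- function(dcs, k) {
  stopifnot(inherits(dcs, "dcs_set"))
  if (!is.numeric(k) || length(k) != 1L || k < 0) {
    stop_arg("`k` must be a single number >= 0")
  }
  k <- as.integer(k)
  if (k == 0L) return(copy(dcs))
  out <- copy(dcs)
  len <- out$end - out$start
  keepn <- pmax(0L, len - 2L * k)
  out[, seq := paste0(
    strrep("N", pmin(k, len)),
    substring(seq, k + 1L, k + keepn),
    strrep("N", pmin(k, pmax(0L, len - k)))
  )]
  out[, flags := paste0(
    strrep("K", pmin(k, len)),
    substring(flags, k + 1L, k + keepn),
    strrep("K", pmin(k, pmax(0L, len - k)))
  )]
  out[]
}

#' Read a known-variant mask in BED format
#'
#' Three-column BED (chrom, start, end; 0-based half-open).  Extra columns
#' are ignored; malformed lines are reported with their line number.
#'
#' @param path BED file path.
#' @return A `data.table` with `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(path) {
  if (!file.exists(path)) stop_arg("no such BED file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_arg("malformed BED line ", i, " in ", path,
               ": expected at least 3 tab-separated fields")
    }
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0L || e < s) {
      stop_arg("malformed BED line ", i, " in ", path,
               ": bad interval '", f[2], "'-'", f[3], "'")
    }
    j <- j + 1L
    out[[j]] <- data.table(chrom = f[1], start = s, end = e)
  }
  if (j == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  }
  rbindlist(out[seq_len(j)])
}

## explode a dcs_set into per-position observations
.dcs_positions <- function(dcs, genome) {
  len <- dcs$end - dcs$start
  obs <- dna_to_code(paste(dcs$seq, collapse = ""))
  row <- rep.int(seq_len(nrow(dcs)), len)
  offset <- sequence(len) - 1L
  pos <- dcs$start[row] + offset
  keep <- !is.na(obs)
  row <- row[keep]; pos <- pos[keep]; obs <- obs[keep]
  d_left <- pos - dcs$start[row]
  d_right <- dcs$end[row] - 1L - pos
  data.table(
    row = row, pos = pos, obs = obs,
    ref = genome$code[pos + 1L],
    fwd = d_left <= d_right
  )
}

#' Count strand-resolved base substitutions in consensus sequences
#'
#' Compares non-`N` dsDCS bases with the reference and tallies a 4x4
#' ref-by-observed matrix plus per-reference-base denominators (all non-`N`
#' aligned bases, matches included).
#'
#' Counting frame:
#' * `"reference"` — classes follow the reference plus strand.
#' * `"fragment"` (default) — classes follow the orientation in which each
#'   base was *sequenced*: positions nearer the left fragment end come from
#'   the forward-sequenced read and keep reference orientation; positions
#'   nearer the right end come from the reverse read and are complemented
#'   (ties at the exact midpoint side with the forward read).  This is the
#'   frame in which end-repair guanine artifacts show their characteristic
#'   G>T / G>C excess over C>A / C>G.
#'
#' @param dcs A `dcs_set` (apply [clip_ends()] first if desired).
#' @param genome The `ref_genome` the consensus coordinates refer to.
#' @param frame `"fragment"` or `"reference"`.
#' @param mask Optional known-variant mask (`data.table` from
#'   [read_bed_mask()]); masked positions count toward neither numerator
#'   nor denominator.
#' @return Object of class `substitution_counts`: list with `counts`
#'   (4x4 integer matrix, ref x obs), `denominators` (named by base),
#'   `frame`, `n_consensus`.
#' @export
count_substitutions <- function(dcs, genome,
                                frame = c("fragment", "reference"),
                                mask = NULL) {
  stopifnot(inherits(dcs, "dcs_set"), inherits(genome, "ref_genome"))
  frame <- match.arg(frame)
  if (nrow(dcs) && (max(dcs$end) > genome$length || min(dcs$start) < 0L)) {
    stop_arg("consensus coordinates fall outside the reference")
  }
  counts <- matrix(0L, 4L, 4L, dimnames = list(ref = BASES, obs = BASES))
  denom <- setNames(rep(0, 4L), BASES)
  if (nrow(dcs)) {
    po <- .dcs_positions(dcs, genome)
    if (!is.null(mask) && nrow(mask)) {
      m <- as.data.table(mask)[chrom == dcs$chrom[1]]
      if (nrow(m)) {
        masked <- rep(FALSE, genome$length)
        for (i in seq_len(nrow(m))) {
          masked[(m$start[i] + 1L):min(m$end[i], genome$length)] <- TRUE
        }
        po <- po[!masked[pos + 1L]]
      }
    }
    if (frame == "fragment") {
      po[fwd == FALSE, `:=`(ref = 5L - ref, obs = 5L - obs)]
    }
    tab <- po[, .N, by = .(ref, obs)]
    counts[cbind(tab$ref, tab$obs)] <- tab$N
    dd <- po[, .N, by = ref]
    denom[dd$ref] <- dd$N
  }
  structure(
    list(counts = counts, denominators = denom, frame = frame,
         n_consensus = nrow(dcs)),
    class = "substitution_counts"
  )
}

#' Build a `substitution_counts` object from explicit tallies
#'
#' Useful for worked examples and for re-deriving pooled 6-type frequencies
#' from published strand-resolved tables.
#'
#' @param counts 4x4 matrix (rows = reference base A,C,G,T order or named;
#'   cols = observed base); off-diagonal entries are substitution counts.
#' @param denominators Named numeric vector of total read bases per
#'   reference base.
#' @param frame Frame label.
#' @return A `substitution_counts` object.
#' @export
substitution_counts <- function(counts, denominators,
                                frame = "fragment") {
  m <- matrix(0, 4L, 4L, dimnames = list(ref = BASES, obs = BASES))
  m[rownames(counts), colnames(counts)] <- counts
  d <- setNames(rep(0, 4L), BASES)
  d[names(denominators)] <- denominators
  if (any(m < 0) || any(d < 0)) stop_arg("counts must be non-negative")
  if (sum(m[row(m) != col(m)]) > sum(d)) {
    stop_arg("substitution count exceeds the total base count")
  }
  structure(
    list(counts = m, denominators = d, frame = frame, n_consensus = NA),
    class = "substitution_counts"
  )
}

#' Substitution frequencies per 10^6 bases
#'
#' Strand-resolved (12-type) frequencies divide each substitution count by
#' the total consensus bases mapped to that reference base; pooled (6-type)
#' frequencies merge each class with its reverse complement, summing both
#' numerators and denominators.  Classes with zero denominator are reported
#' as missing (`NA`), not 0.
#'
#' @param x A `substitution_counts` object.
#' @param label,replicate Optional sample metadata.
#' @return Object of class `spectrum_table`: list with data.tables `freq12`
#'   (`type`, `ref`, `obs`, `count`, `denom`, `freq_per_mb`) and `freq6`,
#'   plus `meta`.
#' @export
frequencies <- function(x, label = NA_character_, replicate = NA_integer_) {
  stopifnot(inherits(x, "substitution_counts"))
  if (all(x$denominators == 0)) {
    stop_arg("all denominators are zero: no aligned consensus bases")
  }
  f12 <- rbindlist(lapply(strsplit(TYPES12, ">"), function(ro) {
    cnt <- x$counts[ro[1], ro[2]]
    den <- x$denominators[ro[1]]
    data.table(
      type = paste0(ro[1], ">", ro[2]), ref = ro[1], obs = ro[2],
      count = as.numeric(cnt), denom = as.numeric(den),
      freq_per_mb = if (den > 0) cnt / den * 1e6 else NA_real_
    )
  }))
  f6 <- rbindlist(lapply(TYPES6, function(t6) {
    parts <- .SIX_MAP[[t6]]
    ro <- strsplit(parts, ">")
    cnt <- sum(vapply(ro, function(p) x$counts[p[1], p[2]], numeric(1)))
    den <- sum(x$denominators[vapply(ro, `[`, character(1), 1L)])
    data.table(
      type = t6, count = cnt, denom = den,
      freq_per_mb = if (den > 0) cnt / den * 1e6 else NA_real_
    )
  }))
  structure(
    list(freq12 = f12, freq6 = f6,
         meta = list(label = label, replicate = replicate,
                     frame = x$frame)),
    class = "spectrum_table"
  )
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("<spectrum_table>", x$meta$label %||% "", "\n")
  print(x$freq6)
  invisible(x)
}

#' Write / read spectrum tables as TSV
#'
#' Long format: one row per mutation type per table, with `basis` column
#' distinguishing 12-type from 6-type rows.  Frequencies are stored at full
#' precision; round only for display.
#'
#' @param spec A `spectrum_table`.
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_table"))
  a <- copy(spec$freq12)[, basis := "12"]
  b <- copy(spec$freq6)[, basis := "6"]
  long <- rbind(a[, .(basis, type, count, denom, freq_per_mb)],
                b[, .(basis, type, count, denom, freq_per_mb)])
  long[, `:=`(label = spec$meta$label, replicate = spec$meta$replicate)]
  tmp <- paste0(path, ".tmp")
  fwrite(long, tmp, sep = "\t")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  long <- fread(path, sep = "\t")
  f12 <- long[long$basis == "12"]
  f6 <- long[long$basis == "6"]
  f12[, `:=`(ref = sub(">.*", "", type), obs = sub(".*>", "", type))]
  structure(
    list(
      freq12 = f12[, .(type, ref, obs, count, denom, freq_per_mb)],
      freq6 = f6[, .(type, count, denom, freq_per_mb)],
      meta = list(label = long$label[1], replicate = long$replicate[1],
                  frame = NA_character_)
    ),
    class = "spectrum_table"
  )
}

## Group comparison ----------------------------------------------------------

#' Dunnett many-to-one adjusted p-values
#'
#' Two-sided adjusted p-values for comparing k treatment groups against one
#' shared control, using the equicorrelated multivariate-t distribution of
#' the maximum |t| statistic (correlation
#' `rho_ij = sqrt(n_i n_j / ((n_i+n0)(n_j+n0)))`, df = N - k - 1).  With a
#' single treatment group this reduces exactly to Student's two-sample
#' equal-variance t test.
#'
#' @param groups List of numeric vectors, one per treatment group.
#' @param control Numeric vector of control observations.
#' @return A list with `estimate` (mean differences), `tstat`, `p_adj`
#'   and `df`.
#' @export
dunnett_pvalue <- function(groups, control) {
  if (!is.list(groups)) groups <- list(groups)
  k <- length(groups)
  n0 <- length(control)
  ni <- lengths(groups)
  if (n0 < 2L || any(ni < 2L)) {
    stop_arg("at least 2 replicates per group are required")
  }
  N <- n0 + sum(ni)
  df <- N - (k + 1L)
  m0 <- mean(control)
  mi <- vapply(groups, mean, numeric(1))
  ss <- sum((control - m0)^2) +
    sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  s2 <- ss / df
  if (s2 <= 0) {
    ## all observations identical within groups: no sampling variance
    p <- ifelse(abs(mi - m0) > 0, 0, 1)
    return(list(estimate = mi - m0, tstat = ifelse(mi == m0, 0, Inf) *
                  sign(mi - m0), p_adj = p, df = df))
  }
  tstat <- (mi - m0) / sqrt(s2 * (1 / ni + 1 / n0))
  lam <- sqrt(ni / (ni + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  p_adj <- vapply(abs(tstat), function(tt) {
    if (!is.finite(tt)) return(0)
    pr <- .pmvt_box(tt, corr, df)
    max(0, min(1, 1 - pr))
  }, numeric(1))
  list(estimate = mi - m0, tstat = tstat, p_adj = p_adj, df = df)
}

## P(max_j |T_j| <= t) for equicorrelated multivariate t; exact in one
## dimension, quasi-Monte-Carlo above (with a locally fixed RNG state so
## repeated calls give identical output)
.pmvt_box <- function(t, corr, df) {
  k <- nrow(corr)
  if (k == 1L) return(stats::pt(t, df) - stats::pt(-t, df))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20260927L)
  as.numeric(mvtnorm::pmvt(
    lower = rep(-t, k), upper = rep(t, k), df = df, corr = corr,
    algorithm = mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 100000L)
  ))
}

## pull one frequency matrix (types x replicates) out of spectrum tables
.freq_matrix <- function(tabs, which) {
  stopifnot(length(tabs) >= 1L)
  cols <- lapply(tabs, function(s) {
    stopifnot(inherits(s, "spectrum_table"))
    tb <- s[[which]]
    setNames(tb$freq_per_mb, tb$type)
  })
  types <- names(cols[[1]])
  m <- vapply(cols, function(x) x[types], numeric(length(types)))
  matrix(m, nrow = length(types), dimnames = list(types, NULL))
}

#' Compare substitution spectra between exposure groups
#'
#' Per mutation type, compares per-replicate frequencies of treatment
#' group(s) against a control group with a two-sided equal-variance
#' Student's t test (or Welch by flag), or with Dunnett's many-to-one test
#' when several treatment groups share one control.  Fold changes use a
#' frequency pseudocount so they stay finite at zero frequency:
#' `log2((mean_treat + eps) / (mean_ctrl + eps))`.
#'
#' @param treat A list of `spectrum_table`s (one treatment group), or a
#'   named list of such lists (several groups; required only for Dunnett
#'   with k > 1).
#' @param ctrl List of control `spectrum_table`s (>= 2 replicates).
#' @param test `"ttest"` or `"dunnett"`.
#' @param which `"freq6"` (default) or `"freq12"` — the table the test is
#'   applied to.
#' @param pseudocount Frequency floor epsilon, per 10^6 bp.
#' @param welch Use Welch's unequal-variance t instead of Student's.
#' @return A `data.table`: `type`, `group`, `n_treat`, `n_ctrl`,
#'   `mean_treat`, `sd_treat`, `mean_ctrl`, `sd_ctrl`, `log2_fold_change`,
#'   `p_value`, `neg_log10_p`, `test_name`.
#' @export
compare_groups <- function(treat, ctrl, test = c("ttest", "dunnett"),
                           which = c("freq6", "freq12"),
                           pseudocount = 0.001, welch = FALSE) {
  test <- match.arg(test)
  which <- match.arg(which)
  multi <- is.list(treat) && length(treat) > 0L &&
    is.list(treat[[1]]) && !inherits(treat[[1]], "spectrum_table")
  tgroups <- if (multi) treat else list(treatment = treat)
  if (is.null(names(tgroups)) || any(!nzchar(names(tgroups)))) {
    names(tgroups) <- paste0("group", seq_along(tgroups))
  }
  if (test == "ttest" && length(tgroups) > 1L) {
    stop_arg("use test = 'dunnett' for several treatment groups")
  }
  mc <- .freq_matrix(ctrl, which)
  mts <- lapply(tgroups, .freq_matrix, which = which)
  n0 <- ncol(mc)
  if (n0 < 2L || any(vapply(mts, ncol, integer(1)) < 2L)) {
    stop_arg("at least 2 replicates per group are required")
  }
  if (test == "dunnett" &&
      length(unique(vapply(mts, ncol, integer(1)))) != 1L) {
    stop_arg("Dunnett's test requires equal replicate structure across ",
             "treatment groups")
  }
  types <- rownames(mc)
  out <- vector("list", length(types))
  for (ti in seq_along(types)) {
    x0 <- mc[ti, ]
    xs <- lapply(mts, function(m) m[ti, ])
    if (anyNA(x0) || any(vapply(xs, anyNA, logical(1)))) {
      out[[ti]] <- data.table(
        type = types[ti], group = names(tgroups),
        n_treat = lengths(xs), n_ctrl = n0,
        mean_treat = NA_real_, sd_treat = NA_real_,
        mean_ctrl = NA_real_, sd_ctrl = NA_real_,
        log2_fold_change = NA_real_, p_value = NA_real_,
        neg_log10_p = NA_real_,
        test_name = if (test == "dunnett") "dunnett" else
          if (welch) "welch_t" else "student_t"
      )
      next
    }
    if (test == "dunnett") {
      dn <- dunnett_pvalue(xs, x0)
      pv <- dn$p_adj
      nm <- "dunnett"
    } else {
      x1 <- xs[[1]]
      if (sd(c(x1 - mean(x1), x0 - mean(x0))) == 0) {
        pv <- if (mean(x1) == mean(x0)) 1 else 0
      } else {
        pv <- stats::t.test(x1, x0, var.equal = !welch)$p.value
      }
      nm <- if (welch) "welch_t" else "student_t"
    }
    out[[ti]] <- data.table(
      type = types[ti], group = names(tgroups),
      n_treat = lengths(xs), n_ctrl = n0,
      mean_treat = vapply(xs, mean, numeric(1)),
      sd_treat = vapply(xs, sd, numeric(1)),
      mean_ctrl = mean(x0), sd_ctrl = sd(x0),
      log2_fold_change = log2(
        (vapply(xs, mean, numeric(1)) + pseudocount) /
          (mean(x0) + pseudocount)
      ),
      p_value = pv,
      neg_log10_p = -log10(pmax(pv, .Machine$double.xmin)),
      test_name = nm
    )
  }
  rbindlist(out)
}
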