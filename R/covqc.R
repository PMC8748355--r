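#' Coverage summary of consensus bases over the genome
#'
#' Depth counts non-`N` dsDCS bases per reference position.  Mean, SD and
#' CV are computed over per-position depth across the whole genome (the
#' binned histogram is descriptive only; a per-bin variant of the summary
#' statistics is available via `per_bin = TRUE`).  The covered rate is the
#' fraction of *all* genomic positions carrying at least one dsDCS base.
#'
#' @param dcs A `dcs_set`.
#' @param genome_length Reference length in bases.
#' @param n_bins Number of histogram sections the genome is divided into.
#' @param per_bin If `TRUE`, mean/SD/CV are computed over per-bin mean
#'   depths instead of per-position depth.
#' @return Object of class `coverage_summary`: list with `covered_rate`,
#'   `mean`, `sd`, `cv`, `n_positions`, and `hist`
#'   (`bin_start`, `bin_end`, `mean_depth`).
#' @export
coverage_summary <- function(dcs, genome_length, n_bins = 50000L,
                             per_bin = FALSE) {
  stopifnot(inherits(dcs, "dcs_set"))
  genome_length <- as.integer(genome_length)
  depth <- integer(genome_length)
  if (nrow(dcs)) {
    len <- dcs$end - dcs$start
    obs <- dna_to_code(paste(dcs$seq, collapse = ""))
    row <- rep.int(seq_len(nrow(dcs)), len)
    pos <- dcs$start[row] + sequence(len) - 1L
    pos <- pos[!is.na(obs)]
    if (length(pos) && (min(pos) < 0L || max(pos) >= genome_length)) {
      stop_arg("consensus coordinates fall outside the reference")
    }
    depth <- tabulate(pos + 1L, nbins = genome_length)
  }
  coverage_from_depth(depth, n_bins = n_bins, per_bin = per_bin)
}

#' Coverage statistics from a per-position depth vector
#'
#' The computational core of [coverage_summary()], usable directly on a
#' precomputed depth profile.
#'
#' @param depth Integer/numeric vector of per-position depth.
#' @param n_bins Number of histogram sections.
#' @param per_bin Compute mean/SD/CV over per-bin means instead.
#' @return A `coverage_summary`.
#' @export
coverage_from_depth <- function(depth, n_bins = 50000L, per_bin = FALSE) {
  L <- length(depth)
  if (L == 0L) stop_arg("empty depth vector")
  if (L < n_bins) {
    warning("genome shorter than n_bins; using width-1 bins")
    n_bins <- L
  }
  width <- ceiling(L / n_bins)
  bin <- (seq_len(L) - 1L) %/% width
  dtb <- data.table(bin = bin, depth = as.numeric(depth))
  hist <- dtb[, .(mean_depth = mean(depth)), by = bin]
  hist[, `:=`(bin_start = bin * width,
              bin_end = pmin((bin + 1L) * width, L))]
  basis <- if (per_bin) hist$mean_depth else as.numeric(depth)
  mu <- mean(basis)
  sdv <- if (length(basis) > 1L) sd(basis) else 0
  covered <- mean(depth > 0)
  structure(
    list(
      covered_rate = covered,
      mean = mu,
      sd = sdv,
      cv = if (mu > 0) sdv / mu else NA_real_,
      n_positions = L,
      per_bin = per_bin,
      hist = hist[, .(bin_start, bin_end, mean_depth)]
    ),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(
    "<coverage_summary> covered %.1f%%, depth mean %.1f, sd %.1f, cv %s\n",
    100 * x$covered_rate, x$mean, x$sd,
    if (is.na(x$cv)) "NA" else sprintf("%.3f", x$cv)
  ))
  invisible(x)
}

#' Per-cycle base composition of sequenced reads
#'
#' Proportion of each of the four bases at each cycle (base position in the
#' read *as sequenced*), forward and reverse reads kept separate.  `N`
#' bases are excluded from the denominator of their cycle.  Nuclease
#' terminal-base preferences surface here as first-cycle composition bias.
#'
#' @param reads Character vector of read sequences as sequenced, or a FASTQ
#'   path; typically called once for R1 and once for R2.
#' @param n_cycles Number of cycles to report; defaults to the longest
#'   read, and is truncated (with a warning) if it exceeds it.
#' @return A matrix `proportion[cycle, base]` with rows summing to 1 for
#'   every cycle with at least one observation; attribute `n_obs` gives the
#'   per-cycle denominators.
#' @export
cycle_composition <- function(reads, n_cycles = NULL) {
  if (length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                       format = "fastq"))
  }
  if (!length(reads)) stop_arg("no reads supplied")
  maxlen <- max(nchar(reads))
  if (is.null(n_cycles)) n_cycles <- maxlen
  if (n_cycles > maxlen) {
    warning("n_cycles exceeds the longest read; truncating to ", maxlen)
    n_cycles <- maxlen
  }
  prop <- matrix(NA_real_, nrow = n_cycles, ncol = 4L,
                 dimnames = list(cycle = seq_len(n_cycles), base = BASES))
  nobs <- integer(n_cycles)
  for (i in seq_len(n_cycles)) {
    b <- .code_lookup[utf8ToInt(paste(substring(reads, i, i),
                                      collapse = ""))]
    b <- b[!is.na(b)]
    nobs[i] <- length(b)
    if (length(b)) prop[i, ] <- tabulate(b, nbins = 4L) / length(b)
  }
  attr(prop, "n_obs") <- nobs
  prop
}

#' Same-position-group misassignment report
#'
#' Without molecular barcodes, two distinct molecules that happen to share
#' fragment coordinates land in one SP-G and can mask true mutations.  In
#' truth mode (simulated reads carry `molecule_id`), counts SP-Gs whose
#' members stem from two or more molecules.  The companion closed form
#' [misassignment_expected()] gives the birthday-collision estimate.
#'
#' @param pairs Read-pair records with a `molecule_id` column.
#' @return List with `n_spg`, `n_spg_multi_molecule`, `rate`.
#' @export
misassignment_report <- function(pairs) {
  p <- as.data.table(pairs)
  if (!"molecule_id" %in% names(p) || all(is.na(p$molecule_id))) {
    stop_arg("truth mode requires a molecule_id column; use ",
             "misassignment_expected() for the analytic estimate")
  }
  g <- p[, .(n_mol = uniqueN(molecule_id)), by = .(chrom, frag_start,
                                                   frag_end)]
  n_spg <- nrow(g)
  n_multi <- sum(g$n_mol >= 2L)
  list(
    n_spg = n_spg,
    n_spg_multi_molecule = n_multi,
    rate = if (n_spg > 0) n_multi / n_spg else NA_real_
  )
}

#' Distinguishable fragment-coordinate count of a shearing model
#'
#' Effective number of equally likely `(start, end)` coordinate pairs,
#' `1 / sum(p^2)`, under the truncated-normal length model of
#' [shear_fragments()] with uniform placement: the collision probability of
#' two independent fragments equals `1 / N_eff`.
#'
#' @param genome_length Reference length (bp).
#' @param size_mean,size_sd,min_len Shearing parameters.
#' @return Effective coordinate count (numeric).
#' @export
effective_coordinate_count <- function(genome_length, size_mean = 350,
                                       size_sd = 50, min_len = 50) {
  lens <- seq.int(max(min_len, 1L),
                  min(genome_length,
                      as.integer(ceiling(size_mean + 8 * size_sd))))
  w <- stats::dnorm(lens, size_mean, size_sd)
  w <- w / sum(w)
  q <- sum(w^2 / (genome_length - lens + 1))
  1 / q
}

#' Expected SP-G misassignment under the birthday-collision model
#'
#' Throws `k` molecules into the coordinate cells of the shearing model
#' (Poisson occupancy per length class) and returns the expected fraction
#' of occupied coordinate cells holding two or more molecules, together
#' with the classical any-collision probability
#' `1 - exp(-k (k - 1) / (2 N))`.
#'
#' @param k Number of distinct sampled molecules.
#' @param genome_length,size_mean,size_sd,min_len Shearing model (see
#'   [effective_coordinate_count()]).
#' @return List with `rate` (expected multi-molecule SP-G fraction),
#'   `p_any_collision`, and `n_coords` (effective coordinate count).
#' @export
misassignment_expected <- function(k, genome_length, size_mean = 350,
                                   size_sd = 50, min_len = 50) {
  lens <- seq.int(max(min_len, 1L),
                  min(genome_length,
                      as.integer(ceiling(size_mean + 8 * size_sd))))
  w <- stats::dnorm(lens, size_mean, size_sd)
  w <- w / sum(w)
  cells <- genome_length - lens + 1          # cells per length class
  lam <- k * (w / cells)                     # occupancy rate per cell
  occupied <- sum(cells * (1 - exp(-lam)))
  multi <- sum(cells * (1 - exp(-lam) - lam * exp(-lam)))
  neff <- effective_coordinate_count(genome_length, size_mean, size_sd,
                                     min_len)
  list(
    rate = if (occupied > 0) multi / occupied else 0,
    p_any_collision = 1 - exp(-k * (k - 1) / (2 * neff)),
    n_coords = neff
  )
}
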