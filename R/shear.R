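#' Shear a genome into duplex fragments with single-strand features
#'
#' Emulates acoustic shearing: fragment lengths are drawn from a truncated
#' normal (peak size / spread configurable), each fragment end independently
#' receives a blunt end, a 5' overhang or a 3' overhang, and the
#' double-stranded core may carry nicks and gaps.  Coordinates are 0-based
#' half-open on the reference; `start`/`end` delimit the *outer* extent of
#' the molecule including overhangs.
#'
#' Overhang lengths are zero-truncated geometric with mean `overhang_mean`
#' (sonication leaves overhangs of poorly characterized, sometimes
#' surprisingly large, length; the mean is a tunable model input).  Nick and
#' gap counts per fragment are Poisson with per-bp rates over the core.
#'
#' @param genome A `ref_genome`.
#' @param n Number of fragments.
#' @param size_mean,size_sd Fragment length distribution (bp).
#' @param min_len Minimum fragment length; shorter draws are resampled.
#' @param overhang_probs Length-3 numeric `(blunt, five_prime, three_prime)`
#'   probabilities for each end; defaults to 1/3 each.
#' @param overhang_mean Mean overhang length (bp, zero-truncated geometric).
#' @param nick_rate,gap_rate Per-bp Poisson rates of nicks / gaps in the
#'   double-stranded core.
#' @param gap_mean Mean gap length (bp, zero-truncated geometric).
#' @param seed Integer seed.
#'
#' @return A `data.table` of class `duplex_fragments` with one row per
#'   molecule: `molecule_id`, `lineage`, `start`, `end`, `oh_kind_l`,
#'   `oh_len_l`, `oh_kind_r`, `oh_len_r`, and list-columns `nicks`
#'   (`strand`,`pos`), `gaps` (`strand`,`gstart`,`gend`) and `lesions`
#'   (empty until [apply_ss_damage()]); attribute `chrom` records the
#'   reference name.
#' @export
shear_fragments <- function(genome, n,
                            size_mean = 350, size_sd = 50, min_len = 50,
                            overhang_probs = c(1, 1, 1) / 3,
                            overhang_mean = 8,
                            nick_rate = 0, gap_rate = 0, gap_mean = 6,
                            seed = 1L) {
  stopifnot(inherits(genome, "ref_genome"), n >= 1)
  if (length(overhang_probs) != 3L || abs(sum(overhang_probs) - 1) > 1e-8) {
    stop_arg("`overhang_probs` must be 3 probabilities summing to 1")
  }
  if (size_mean < 4 * overhang_mean) {
    stop_arg("`size_mean` must be at least 4x the mean overhang length")
  }
  set.seed(as.integer(seed))
  L <- genome$length

  ## fragment lengths: truncated normal by resampling (never emit truncated)
  lens <- integer(0)
  while (length(lens) < n) {
    cand <- as.integer(round(rnorm(n, size_mean, size_sd)))
    cand <- cand[cand >= min_len & cand <= L]
    lens <- c(lens, cand)
  }
  lens <- lens[seq_len(n)]
  starts <- as.integer(floor(runif(n) * (L - lens + 1)))

  kinds <- c("blunt", "five_prime", "three_prime")
  kl <- kinds[sample.int(3L, n, replace = TRUE, prob = overhang_probs)]
  kr <- kinds[sample.int(3L, n, replace = TRUE, prob = overhang_probs)]
  ol <- ifelse(kl == "blunt", 0L, rztgeom(n, overhang_mean))
  or <- ifelse(kr == "blunt", 0L, rztgeom(n, overhang_mean))
  ## overhangs may not swallow the fragment: cap so a ds core of >= 2 bp
  ## remains, demoting to blunt where the cap hits zero
  cap <- pmax(0L, as.integer(floor((lens - 2L) / 2)))
  ol <- pmin(ol, cap); or <- pmin(or, cap)
  kl[ol == 0L] <- "blunt"; kr[or == 0L] <- "blunt"

  frags <- data.table(
    molecule_id = seq_len(n),
    lineage = as.character(seq_len(n)),
    start = starts,
    end = starts + lens,
    oh_kind_l = kl, oh_len_l = as.integer(ol),
    oh_kind_r = kr, oh_len_r = as.integer(or),
    nicks = vector("list", n),
    gaps = vector("list", n),
    lesions = vector("list", n),
    repaired = FALSE
  )

  core_start <- frags$start + frags$oh_len_l
  core_end <- frags$end - frags$oh_len_r
  core_len <- pmax(0L, core_end - core_start)

  if (nick_rate > 0) {
    n_nick <- rpois(n, nick_rate * core_len)
    n_nick[core_len < 3L] <- 0L
    idx <- which(n_nick > 0L)
    for (i in idx) {
      ## strictly inside the core
      p <- core_start[i] + 1L +
        as.integer(floor(runif(n_nick[i]) * (core_len[i] - 2L)))
      frags$nicks[[i]] <- data.table(
        strand = sample(c("+", "-"), n_nick[i], replace = TRUE),
        pos = p
      )
    }
  }
  if (gap_rate > 0) {
    n_gap <- rpois(n, gap_rate * core_len)
    n_gap[core_len < 6L] <- 0L
    idx <- which(n_gap > 0L)
    for (i in idx) {
      glen <- pmin(rztgeom(n_gap[i], gap_mean), core_len[i] - 4L)
      gs <- core_start[i] + 2L +
        as.integer(floor(runif(n_gap[i]) * (core_len[i] - glen - 3L)))
      frags$gaps[[i]] <- data.table(
        strand = sample(c("+", "-"), n_gap[i], replace = TRUE),
        gstart = gs, gend = gs + as.integer(glen)
      )
    }
  }

  setattr(frags, "chrom", genome$name)
  setattr(frags, "genome_code", genome$code)
  setattr(frags, "genome_seq", genome$seq)
  setattr(frags, "class", c("duplex_fragments", class(frags)))
  frags[]
}

## Enumerate the single-stranded regions of one fragment row.
##
## Returns a data.table(strand, rstart, rend, region_kind, anchor):
##  * a 5' overhang is single-stranded on the protruding strand
##    (left end: plus strand; right end: minus strand);
##  * a 3' overhang protrudes on the other strand of the same end;
##  * a gap on strand s leaves the opposite strand single-stranded as the
##    fill-in template;
##  * a nick on strand s frays, exposing a window of the opposite strand
##    (anchor = nick position, half-width `nick_halfwidth`).
frag_ss_regions <- function(fr, nick_halfwidth = 2L) {
  out <- list()
  if (fr$oh_len_l > 0L) {
    out[[length(out) + 1L]] <- data.table(
      strand = if (fr$oh_kind_l == "five_prime") "+" else "-",
      rstart = fr$start, rend = fr$start + fr$oh_len_l,
      region_kind = "overhang", anchor = NA_integer_
    )
  }
  if (fr$oh_len_r > 0L) {
    out[[length(out) + 1L]] <- data.table(
      strand = if (fr$oh_kind_r == "five_prime") "-" else "+",
      rstart = fr$end - fr$oh_len_r, rend = fr$end,
      region_kind = "overhang", anchor = NA_integer_
    )
  }
  gp <- fr$gaps[[1]]
  if (!is.null(gp) && nrow(gp)) {
    out[[length(out) + 1L]] <- data.table(
      strand = ifelse(gp$strand == "+", "-", "+"),
      rstart = gp$gstart, rend = gp$gend,
      region_kind = "gap", anchor = NA_integer_
    )
  }
  nk <- fr$nicks[[1]]
  if (!is.null(nk) && nrow(nk)) {
    cs <- fr$start + fr$oh_len_l
    ce <- fr$end - fr$oh_len_r
    out[[length(out) + 1L]] <- data.table(
      strand = ifelse(nk$strand == "+", "-", "+"),
      rstart = pmax(cs, nk$pos - nick_halfwidth),
      rend = pmin(ce, nk$pos + nick_halfwidth + 1L),
      region_kind = "nick_adjacent", anchor = nk$pos
    )
  }
  if (!length(out)) {
    return(data.table(
      strand = character(), rstart = integer(), rend = integer(),
      region_kind = character(), anchor = integer()
    ))
  }
  rbindlist(out)
}
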