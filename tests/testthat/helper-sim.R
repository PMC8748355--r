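## Shared fixture builders -- everything is generated in code.

library(data.table)

BASES4 <- c("A", "C", "G", "T")
compbase <- function(b) chartr("ACGT", "TGCA", b)
revcomp_chr <- function(s) {
  vapply(strsplit(chartr("ACGT", "TGCA", s), ""), function(x)
    paste(rev(x), collapse = ""), character(1))
}

## small deterministic genome
tiny_genome <- function(len = 3000, gc = 0.5, seed = 42) {
  make_genome(len, gc, seed = seed)
}

## hand-built duplex_fragments table (bypasses shear_fragments) so single
## molecules with exactly known structure can be fed to damage/digest/repair
fixture_fragment <- function(genome, start, end,
                             oh_kind_l = "blunt", oh_len_l = 0L,
                             oh_kind_r = "blunt", oh_len_r = 0L,
                             nicks = NULL, gaps = NULL, lesions = NULL,
                             molecule_id = 1L) {
  fr <- data.table(
    molecule_id = as.integer(molecule_id),
    lineage = as.character(molecule_id),
    start = as.integer(start), end = as.integer(end),
    oh_kind_l = oh_kind_l, oh_len_l = as.integer(oh_len_l),
    oh_kind_r = oh_kind_r, oh_len_r = as.integer(oh_len_r),
    nicks = list(nicks), gaps = list(gaps), lesions = list(lesions),
    repaired = FALSE
  )
  setattr(fr, "chrom", genome$name)
  setattr(fr, "genome_code", genome$code)
  setattr(fr, "genome_seq", genome$seq)
  setattr(fr, "class", c("duplex_fragments", class(fr)))
  fr
}

rbind_fragments <- function(...) {
  parts <- list(...)
  out <- rbindlist(parts)
  for (a in c("chrom", "genome_code", "genome_seq")) {
    setattr(out, a, attr(parts[[1]], a, exact = TRUE))
  }
  setattr(out, "class", c("duplex_fragments", class(out)))
  out
}

## total lesions in a fragment table, optionally by region kind
n_lesions <- function(frags, kinds = NULL) {
  sum(vapply(frags$lesions, function(x) {
    if (is.null(x)) return(0L)
    if (is.null(kinds)) nrow(x) else sum(x$region_kind %in% kinds)
  }, integer(1)))
}

## one synthetic read-pair record (consensus-caller input) built by hand
fixture_pair <- function(chrom, start, end, orientation, r1_seq, r2_seq,
                         r1_pos0 = start, r2_pos0 = end - nchar(r2_seq),
                         qname = "q", molecule_id = NA_integer_) {
  data.table(
    qname = qname, chrom = chrom,
    frag_start = as.integer(start), frag_end = as.integer(end),
    orientation = orientation,
    r1_pos0 = as.integer(r1_pos0), r1_seq = r1_seq,
    r2_pos0 = as.integer(r2_pos0), r2_seq = r2_seq,
    molecule_id = molecule_id
  )
}

## independent majority-consensus oracle for one base multiset: returns the
## called base or "N" under the family agreement rule
oracle_call <- function(bases, threshold = NULL) {
  if (is.null(threshold)) threshold <- if (length(bases) <= 2) 1.0 else 0.8
  tab <- table(bases)
  top <- names(tab)[which.max(tab)]
  if (max(tab) / length(bases) >= threshold - 1e-9) top else "N"
}

## hand-built consensus set
fixture_dcs <- function(chrom, start, end, seq, flags = NULL) {
  if (is.null(flags)) flags <- chartr("ACGTN", "RRRRI", seq)
  d <- data.table(
    spg_id = seq_along(start), chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    n_f1r2 = 1L, n_f2r1 = 1L, seq = seq, flags = flags
  )
  setattr(d, "class", c("dcs_set", class(d)))
  d
}

## mismatch statistics of a dcs_set against the reference: resolved,
## non-N positions only
dcs_mismatch <- function(dcs, genome) {
  n_pos <- 0L; n_mis <- 0L
  for (i in seq_len(nrow(dcs))) {
    obs <- strsplit(dcs$seq[i], "")[[1]]
    ref <- strsplit(substring(genome$seq, dcs$start[i] + 1L, dcs$end[i]),
                    "")[[1]]
    ok <- obs != "N"
    n_pos <- n_pos + sum(ok)
    n_mis <- n_mis + sum(obs[ok] != ref[ok])
  }
  list(n_pos = n_pos, n_mis = n_mis,
       rate = if (n_pos > 0) n_mis / n_pos else NA_real_)
}

## raw per-read mismatch rate against the reference
raw_mismatch <- function(pairs, genome) {
  n_pos <- 0L; n_mis <- 0L
  for (m in c("r1", "r2")) {
    sq <- pairs[[paste0(m, "_seq")]]
    p0 <- pairs[[paste0(m, "_pos0")]]
    ref <- substring(genome$seq, p0 + 1L, p0 + nchar(sq))
    for (i in seq_along(sq)) {
      a <- strsplit(sq[i], "")[[1]]; b <- strsplit(ref[i], "")[[1]]
      ok <- a != "N"
      n_pos <- n_pos + sum(ok)
      n_mis <- n_mis + sum(a[ok] != b[ok])
    }
  }
  list(n_pos = n_pos, n_mis = n_mis, rate = n_mis / n_pos)
}

## count planted concordant substitutions recovered as confident dsDCS calls
recovered_artifacts <- function(dcs, truth_subs) {
  if (nrow(truth_subs) == 0L || nrow(dcs) == 0L) return(0L)
  tr <- unique(truth_subs[truth_subs$concordant == TRUE,
                          c("pos", "ref", "alt")])
  hits <- 0L
  for (i in seq_len(nrow(dcs))) {
    inside <- tr$pos - 1L >= dcs$start[i] & tr$pos - 1L < dcs$end[i]
    if (!any(inside)) next
    off <- tr$pos[inside] - dcs$start[i]   # 1-based offset into seq
    obs <- substring(dcs$seq[i], off, off)
    hits <- hits + sum(obs == tr$alt[inside])
  }
  hits
}

## frequency of one 12-type class from a dcs_set
freq_of <- function(dcs, genome, type, frame = "fragment", clip = 0) {
  sp <- frequencies(count_substitutions(clip_ends(dcs, clip), genome,
                                        frame = frame))
  sp$freq12[sp$freq12$type == type, ]
}
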