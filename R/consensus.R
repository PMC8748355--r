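#' Load aligned read pairs from SAM/BAM
#'
#' Reads primary, mapped, properly mated alignments and reduces each pair to
#' one record keyed by its fragment interval: the outermost reference
#' coordinates covered by the two mates (0-based half-open).  Mate sequences
#' are projected onto the reference (insertions dropped, deleted reference
#' positions reported as `N`), so downstream consensus operates purely in
#' reference coordinates; the caller analyzes base substitutions only.
#'
#' Discordant pairs — mates on different references, mates on the same
#' strand, unmapped or missing mates, or below `min_mapq` — are excluded
#' and tallied in the `discards` attribute.
#'
#' @param path SAM or BAM file with header (`@SQ` required).
#' @param min_mapq Minimum mapping quality for both mates.
#' @return A `data.table` of read-pair records: `qname`, `chrom`,
#'   `frag_start`, `frag_end`, `orientation` (`F1R2`/`F2R1`), `r1_pos0`,
#'   `r1_seq`, `r2_pos0`, `r2_seq`, `molecule_id` (parsed from simulator
#'   read names, `NA` otherwise); attribute `discards` holds the named
#'   discard counts.
#' @export
load_alignments <- function(path, min_mapq = 0L) {
  if (!file.exists(path)) stop_arg("no such alignment file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) {
        stop_arg("cannot parse SAM '", path, "' (a header with @SQ lines ",
                 "for every reference is required): ", conditionMessage(e))
      }
    )
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
    )
  )[[1]]
  dt <- data.table(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq)
  )
  discards <- c(secondary = 0L, unmapped = 0L, unpaired = 0L,
                different_chrom = 0L, same_strand = 0L, low_mapq = 0L)

  sec <- bitwAnd(dt$flag, 256L) != 0L | bitwAnd(dt$flag, 2048L) != 0L
  discards["secondary"] <- sum(sec)
  dt <- dt[!sec]
  unm <- bitwAnd(dt$flag, 4L) != 0L | is.na(dt$pos)
  discards["unmapped"] <- sum(unm)
  dt <- dt[!unm]

  dt[, `:=`(
    is_rev = bitwAnd(flag, 16L) != 0L,
    is_first = bitwAnd(flag, 64L) != 0L,
    width = cigar_ref_width(cigar)
  )]

  ## pair up by name
  dt[, n_in_pair := .N, by = qname]
  bad <- dt$n_in_pair != 2L
  discards["unpaired"] <- length(unique(dt$qname[bad]))
  dt <- dt[!bad]
  if (nrow(dt)) {
    chk <- dt[, .(
      two_chrom = rname[1] != rname[2],
      same_str = is_rev[1] == is_rev[2],
      lowq = min(mapq) < min_mapq,
      no_first = sum(is_first) != 1L
    ), by = qname]
    discards["different_chrom"] <- sum(chk$two_chrom)
    discards["same_strand"] <- sum(chk$same_str & !chk$two_chrom)
    discards["low_mapq"] <- sum(chk$lowq & !chk$two_chrom & !chk$same_str)
    keep_q <- chk[!(two_chrom | same_str | lowq | no_first), qname]
    dt <- dt[qname %in% keep_q]
  }

  if (nrow(dt)) {
    dt[, seq := project_to_reference(seq, cigar)]
    r1 <- dt[is_first == TRUE]
    r2 <- dt[is_first == FALSE]
    setkey(r1, qname); setkey(r2, qname)
    pairs <- r1[r2]
    pairs <- data.table(
      qname = pairs$qname,
      chrom = pairs$rname,
      frag_start = pmin(pairs$pos, pairs$i.pos) - 1L,
      frag_end = pmax(pairs$pos + pairs$width,
                      pairs$i.pos + pairs$i.width) - 1L,
      orientation = ifelse(pairs$is_rev, "F2R1", "F1R2"),
      r1_pos0 = pairs$pos - 1L, r1_seq = pairs$seq,
      r2_pos0 = pairs$i.pos - 1L, r2_seq = pairs$i.seq,
      molecule_id = suppressWarnings(
        as.integer(sub("^m(\\d+):.*$", "\\1", pairs$qname))
      )
    )
  } else {
    pairs <- data.table(
      qname = character(), chrom = character(), frag_start = integer(),
      frag_end = integer(), orientation = character(),
      r1_pos0 = integer(), r1_seq = character(),
      r2_pos0 = integer(), r2_seq = character(), molecule_id = integer()
    )
  }
  setorder(pairs, chrom, frag_start, frag_end, orientation, qname)
  setattr(pairs, "discards", discards)
  pairs[]
}

## reference-space width of each cigar
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

## project query sequences onto the reference: M/=/X copy, I/S consume query
## only, D/N leave 'N' placeholders; output length == reference width
project_to_reference <- function(seq, cigar) {
  simple <- grepl("^\\d+M$", cigar)
  out <- seq
  for (i in which(!simple)) {
    ops <- GenomicAlignments::explodeCigarOps(cigar[i])[[1]]
    ls <- GenomicAlignments::explodeCigarOpLengths(cigar[i])[[1]]
    q <- strsplit(seq[i], "", fixed = TRUE)[[1]]
    ref <- character(0)
    qi <- 1L
    for (k in seq_along(ops)) {
      op <- ops[k]; l <- ls[k]
      if (op %in% c("M", "=", "X")) {
        ref <- c(ref, q[qi:(qi + l - 1L)]); qi <- qi + l
      } else if (op %in% c("I", "S")) {
        qi <- qi + l
      } else if (op %in% c("D", "N")) {
        ref <- c(ref, rep("N", l))
      }
    }
    out[i] <- paste(ref, collapse = "")
  }
  out
}

#' Group read pairs into same-position groups (SP-Gs)
#'
#' Read pairs sharing an identical fragment interval `(chrom, frag_start,
#' frag_end)` — the UMI-free proxy for "same source molecule" — form one
#' SP-G, split into two orientation families.
#'
#' @param pairs Read-pair records from [load_alignments()] or a simulation.
#' @return The records, ordered by key, with an `spg_id` column; attribute
#'   `spg` holds the per-group summary (`spg_id`, key, family sizes).
#' @export
group_spg <- function(pairs) {
  p <- as.data.table(pairs)
  setorder(p, chrom, frag_start, frag_end, orientation, qname)
  p[, spg_id := rleid(chrom, frag_start, frag_end)]
  spg <- p[, .(
    chrom = chrom[1], frag_start = frag_start[1], frag_end = frag_end[1],
    n_f1r2 = sum(orientation == "F1R2"),
    n_f2r1 = sum(orientation == "F2R1")
  ), by = spg_id]
  setattr(p, "spg", spg)
  p[]
}

## agreement threshold rule: strict unanimity for tiny families, 0.8 above
.agreement_for <- function(famsize, agreement_threshold = NULL) {
  if (!is.null(agreement_threshold)) {
    rep(agreement_threshold, length(famsize))
  } else {
    ifelse(famsize <= 2L, 1.0, 0.8)
  }
}

#' Per-family strand consensus (reference implementation)
#'
#' For one orientation family of one SP-G, calls per reference position the
#' base shared by at least `agreement_threshold` of the covering reads, `N`
#' otherwise (including zero coverage).  A fraction exactly equal to the
#' threshold is accepted.
#'
#' @param family Read-pair records of a single family (same fragment key).
#' @param agreement_threshold Fraction in (0, 1\], or `NULL` for the default
#'   size-dependent rule (unanimity for families of 1–2 pairs, 0.8 above).
#' @return List with `start`, `end`, `bases` (character vector over
#'   `A,C,G,T,N`) and `depth` (covering reads per position).
#' @export
strand_consensus <- function(family, agreement_threshold = NULL) {
  stopifnot(nrow(family) >= 1L)
  start <- family$frag_start[1]; end <- family$frag_end[1]
  len <- end - start
  thr <- .agreement_for(nrow(family), agreement_threshold)[1]
  counts <- matrix(0L, nrow = 4L, ncol = len)
  for (i in seq_len(nrow(family))) {
    for (m in 1:2) {
      p0 <- if (m == 1L) family$r1_pos0[i] else family$r2_pos0[i]
      sq <- if (m == 1L) family$r1_seq[i] else family$r2_seq[i]
      code <- dna_to_code(sq)
      ok <- !is.na(code)
      idx <- (p0 - start) + seq_along(code)
      ok <- ok & idx >= 1L & idx <= len
      for (j in which(ok)) {
        counts[code[j], idx[j]] <- counts[code[j], idx[j]] + 1L
      }
    }
  }
  depth <- colSums(counts)
  top <- apply(counts, 2L, which.max)
  topn <- counts[cbind(top, seq_len(len))]
  bases <- ifelse(depth > 0L & topn >= thr * depth - 1e-9,
                  BASES[top], "N")
  list(start = start, end = end, bases = bases, depth = as.integer(depth))
}

#' Duplex consensus for a single SP-G (reference implementation)
#'
#' Requires read pairs from *both* orientation families (at least
#' `min_family_size` each); per position, emits the base on which both
#' strand consensuses agree, and `N` elsewhere — flagged `strand_conflict`
#' where the two strands confidently disagree (e.g. single-strand damage),
#' `insufficient` where either side is uncovered or ambiguous.
#'
#' @param spg_pairs Read-pair records of one SP-G.
#' @param min_family_size Minimum pairs per orientation family.
#' @param agreement_threshold See [strand_consensus()].
#' @return `NULL` if either family is too small; otherwise a list with
#'   `chrom`, `start`, `end`, `seq` (character scalar) and `flags`
#'   (per-position `R`esolved / `C`onflict / `I`nsufficient string).
#' @export
duplex_consensus <- function(spg_pairs, min_family_size = 1L,
                             agreement_threshold = NULL) {
  f1 <- spg_pairs[spg_pairs$orientation == "F1R2", ]
  f2 <- spg_pairs[spg_pairs$orientation == "F2R1", ]
  if (nrow(f1) < min_family_size || nrow(f2) < min_family_size ||
      nrow(f1) == 0L || nrow(f2) == 0L) {
    return(NULL)
  }
  c1 <- strand_consensus(f1, agreement_threshold)
  c2 <- strand_consensus(f2, agreement_threshold)
  both <- c1$bases != "N" & c2$bases != "N"
  agree <- both & c1$bases == c2$bases
  conflict <- both & !agree
  bases <- ifelse(agree, c1$bases, "N")
  flags <- ifelse(agree, "R", ifelse(conflict, "C", "I"))
  list(
    chrom = spg_pairs$chrom[1], start = c1$start, end = c1$end,
    seq = paste(bases, collapse = ""), flags = paste(flags, collapse = "")
  )
}

#' Call double-strand consensus sequences over all SP-Gs
#'
#' Vectorized engine producing one double-strand consensus (dsDCS) per SP-G
#' that has read pairs in both orientations.  Equivalent to applying
#' [duplex_consensus()] group by group.
#'
#' @param pairs Read-pair records ([load_alignments()] output or
#'   `sim$pairs`).
#' @param min_family_size Minimum pairs per orientation family (the method's
#'   only hard requirement is presence of both read directions, i.e. 1).
#' @param agreement_threshold See [strand_consensus()].
#' @return A `data.table` of class `dcs_set`: `spg_id`, `chrom`, `start`,
#'   `end`, `n_f1r2`, `n_f2r1`, `seq`, `flags`.  Consensus pairs retain
#'   their SP-G fragment coordinates (no re-mapping).
#' @export
call_duplex_consensus <- function(pairs, min_family_size = 1L,
                                  agreement_threshold = NULL) {
  p <- group_spg(pairs)
  spg <- attr(p, "spg", exact = TRUE)
  keep_spg <- spg[spg$n_f1r2 >= pmax(1L, min_family_size) &
                    spg$n_f2r1 >= pmax(1L, min_family_size)]
  if (nrow(keep_spg) == 0L) {
    return(structure(
      data.table(spg_id = integer(), chrom = character(), start = integer(),
                 end = integer(), n_f1r2 = integer(), n_f2r1 = integer(),
                 seq = character(), flags = character()),
      class = c("dcs_set", class(data.table()))
    ))
  }
  p <- p[spg_id %in% keep_spg$spg_id]

  ## long per-base table: both mates of every pair
  fam_i <- ifelse(p$orientation == "F1R2", 1L, 2L)
  mk_long <- function(pos0, seqs) {
    nc <- nchar(seqs)
    code <- dna_to_code(paste(seqs, collapse = ""))
    list(
      spg = rep.int(p$spg_id, nc),
      fam = rep.int(fam_i, nc),
      pos = rep.int(pos0, nc) + sequence(nc) - 1L,
      base = code
    )
  }
  l1 <- mk_long(p$r1_pos0, p$r1_seq)
  l2 <- mk_long(p$r2_pos0, p$r2_seq)
  long <- data.table(
    spg = c(l1$spg, l2$spg), fam = c(l1$fam, l2$fam),
    pos = c(l1$pos, l2$pos), base = c(l1$base, l2$base)
  )
  long <- long[!is.na(base)]

  cnt <- long[, .N, by = .(spg, fam, pos, base)]
  tot <- cnt[, .(tot = sum(N)), by = .(spg, fam, pos)]
  setorder(cnt, spg, fam, pos, -N, base)
  top <- unique(cnt, by = c("spg", "fam", "pos"))
  top <- top[tot, on = .(spg, fam, pos)]

  fs <- p[, .(famsize = .N), by = .(spg_id, orientation)]
  fs[, fam := ifelse(orientation == "F1R2", 1L, 2L)]
  top <- top[fs[, .(spg = spg_id, fam, famsize)], on = .(spg, fam)]
  top[, thr := .agreement_for(famsize, agreement_threshold)]
  top[, cons := ifelse(N >= thr * tot - 1e-9, base, NA_integer_)]

  wide <- dcast(top, spg + pos ~ fam, value.var = "cons")
  setnames(wide, c("1", "2"), c("b1", "b2"), skip_absent = TRUE)
  if (!"b1" %in% names(wide)) wide[, b1 := NA_integer_]
  if (!"b2" %in% names(wide)) wide[, b2 := NA_integer_]
  wide[, `:=`(
    resolved = !is.na(b1) & !is.na(b2) & b1 == b2,
    conflict = !is.na(b1) & !is.na(b2) & b1 != b2
  )]

  ## assemble per-SPG strings
  meta <- keep_spg
  setorder(meta, spg_id)
  meta[, len := frag_end - frag_start]
  offs <- c(0L, cumsum(meta$len))
  total <- offs[length(offs)]
  seq_chars <- rep.int(78L, total)     # 'N'
  flag_chars <- rep.int(73L, total)    # 'I'
  spg_row <- match(wide$spg, meta$spg_id)
  gidx <- offs[spg_row] + (wide$pos - meta$frag_start[spg_row]) + 1L
  ok <- gidx >= 1L & gidx <= total
  res_i <- ok & wide$resolved
  seq_chars[gidx[res_i]] <- c(65L, 67L, 71L, 84L)[wide$b1[res_i]]
  flag_chars[gidx[res_i]] <- 82L       # 'R'
  con_i <- ok & wide$conflict
  flag_chars[gidx[con_i]] <- 67L       # 'C'

  big_seq <- intToUtf8(seq_chars)
  big_flag <- intToUtf8(flag_chars)
  starts1 <- offs[-length(offs)] + 1L
  ends1 <- offs[-1L]
  dcs <- data.table(
    spg_id = meta$spg_id,
    chrom = meta$chrom,
    start = meta$frag_start,
    end = meta$frag_end,
    n_f1r2 = meta$n_f1r2,
    n_f2r1 = meta$n_f2r1,
    seq = substring(big_seq, starts1, ends1),
    flags = substring(big_flag, starts1, ends1)
  )
  setattr(dcs, "class", c("dcs_set", class(dcs)))
  dcs[]
}

#' Write double-strand consensus sequences to SAM
#'
#' One single-end SAM record per dsDCS, keyed by its SP-G coordinates
#' (re-mapping is intentionally omitted; consensus pairs keep their
#' fragment-interval coordinates).  Unresolved positions are emitted as `N`.
#'
#' @param dcs A `dcs_set`.
#' @param path Output SAM path.
#' @param genome_length Reference length for the `@SQ` header.
#' @return The path, invisibly.
#' @export
write_dcs <- function(dcs, path, genome_length) {
  stopifnot(inherits(dcs, "dcs_set"))
  chrom <- if (nrow(dcs)) dcs$chrom[1] else "unknown"
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(genome_length)),
    "@PG\tID:duplexsim\tPN:duplexsim"
  )
  body <- character(0)
  if (nrow(dcs)) {
    w <- dcs$end - dcs$start
    body <- sprintf(
      "dcs:%s:%d-%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tXF:Z:%s",
      dcs$chrom, dcs$start, dcs$end, dcs$chrom, dcs$start + 1L, w,
      dcs$seq, strrep("?", w), dcs$flags
    )
  }
  write_lines_atomic(c(header, body), path)
  invisible(path)
}

#' Read a dsDCS SAM back into a `dcs_set`
#'
#' Per-position flags are restored from the `XF` tag when present (files
#' written by [write_dcs()]); otherwise `N` positions are marked
#' insufficient.
#'
#' @param path SAM/BAM written by [write_dcs()] (or compatible single-end
#'   records).
#' @return A `dcs_set`.
#' @export
read_dcs <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "cigar", "seq"),
      tag = "XF"
    )
  )[[1]]
  n <- length(res$qname)
  seqs <- as.character(res$seq)
  flags <- res$tag$XF
  if (is.null(flags)) flags <- rep(NA_character_, n)
  flags <- ifelse(is.na(flags),
                  chartr("ACGTN", "RRRRI", seqs),
                  flags)
  dcs <- data.table(
    spg_id = seq_len(n),
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + cigar_ref_width(res$cigar),
    n_f1r2 = NA_integer_, n_f2r1 = NA_integer_,
    seq = seqs, flags = flags
  )
  setorder(dcs, chrom, start, end)
  dcs[, spg_id := seq_len(.N)]
  setattr(dcs, "class", c("dcs_set", class(dcs)))
  dcs[]
}

#' Export dsDCS as FASTQ for external re-mapping
#'
#' Escape hatch for users who want to re-align consensus sequences with an
#' external aligner rather than trust SP-G coordinates.
#'
#' @param dcs A `dcs_set`.
#' @param path Output FASTQ path.
#' @return The path, invisibly.
#' @export
export_dcs_fastq <- function(dcs, path) {
  stopifnot(inherits(dcs, "dcs_set"))
  nm <- sprintf("dcs:%s:%d-%d", dcs$chrom, dcs$start, dcs$end)
  write_lines_atomic(
    as.vector(rbind(paste0("@", nm), dcs$seq, "+", strrep("?", nchar(dcs$seq)))),
    path
  )
  invisible(path)
}
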