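#' Library and sequencing parameters
#'
#' @param n_molecules Number of distinct molecules sampled into the library,
#'   or `NULL` to derive it from `ligated_amount * molecules_per_unit`.
#' @param ligated_amount Relative amount of ligated product subjected to
#'   PCR (the dilution axis; the study design uses 156, 78, 39 and 20
#'   relative units).
#' @param molecules_per_unit Sampled molecules per relative amount unit.
#' @param dup_mean Mean PCR duplicate count per sampled molecule per strand
#'   (zero-truncated geometric, support >= 1).
#' @param read_length Read length in bases (paired-end, both mates).
#' @param seq_error_rate Per-base sequencing error rate, independent across
#'   reads (default Q30-equivalent, 1e-3).
#' @param pcr_error_rate Per-base early-PCR error rate; such errors are
#'   shared by every duplicate of one strand family of one molecule.
#' @param seed Integer seed.
#' @return A list of class `library_params`.
#' @export
library_params <- function(n_molecules = NULL, ligated_amount = NULL,
                           molecules_per_unit = 100,
                           dup_mean = 3, read_length = 100L,
                           seq_error_rate = 1e-3, pcr_error_rate = 1e-3,
                           seed = 1L) {
  if (is.null(n_molecules) && is.null(ligated_amount)) {
    stop_arg("give `n_molecules` or `ligated_amount`")
  }
  if (dup_mean < 1) stop_arg("`dup_mean` must be >= 1")
  structure(
    list(
      n_molecules = if (!is.null(n_molecules)) as.integer(n_molecules),
      ligated_amount = ligated_amount,
      molecules_per_unit = molecules_per_unit,
      dup_mean = dup_mean, read_length = as.integer(read_length),
      seq_error_rate = seq_error_rate, pcr_error_rate = pcr_error_rate,
      seed = as.integer(seed)
    ),
    class = "library_params"
  )
}

## apply point substitutions (1-based offsets within the string) to seqs
.apply_edits <- function(seqs, row, at, alt) {
  for (k in seq_along(row)) {
    i <- row[k]
    seqs[i] <- `substr<-`(seqs[i], at[k], at[k], alt[k])
  }
  seqs
}

#' Sample molecules and sequence them to paired-end reads
#'
#' Molecules are sampled from the repaired fragment pool without
#' replacement, in proportion to the ligated amount.  Both strands of each
#' molecule enter the library: the top (reference-plus) strand yields
#' F1R2 read pairs, the bottom strand F2R1 pairs, each with a zero-truncated
#' geometric number of PCR duplicates.  Early-PCR errors are drawn once per
#' strand family and shared by all its duplicates; sequencing errors are
#' independent per read base.  Reads longer than the fragment are truncated
#' (and flagged in the truth table).
#'
#' @param frags End-repaired `duplex_fragments`.
#' @param lib A [library_params()] object.
#' @return A list of class `sim_reads`:
#' \describe{
#'   \item{reads}{per-read table (`qname`, `molecule_id`, `strand_family`,
#'     `mate`, `flag`, `pos0`, `seq` in reference-forward orientation).}
#'   \item{pairs}{read-pair records as used by the consensus caller
#'     (see [load_alignments()]).}
#'   \item{molecules}{sampled-molecule truth table.}
#'   \item{substitutions}{planted-substitution truth table (1-based `pos`,
#'     `ref`/`alt` on the reference plus strand, provenance columns).}
#'   \item{chrom, genome_length}{reference metadata.}
#' }
#' @export
sample_and_sequence <- function(frags, lib) {
  stopifnot(inherits(frags, "duplex_fragments"),
            inherits(lib, "library_params"))
  if (!all(frags$repaired)) {
    stop_arg("fragments must be end-repaired before sequencing")
  }
  gseq <- attr(frags, "genome_seq", exact = TRUE)
  chrom <- attr(frags, "chrom", exact = TRUE)
  if (is.null(gseq)) stop_arg("fragments lack the genome sequence")
  set.seed(lib$seed)

  k <- lib$n_molecules %||%
    as.integer(round(lib$ligated_amount * lib$molecules_per_unit))
  if (k < 1L) stop_arg("library would contain no molecules")
  if (k > nrow(frags)) {
    warning("requested ", k, " molecules but only ", nrow(frags),
            " fragments are available; using all")
    k <- nrow(frags)
  }
  take <- sort(sample.int(nrow(frags), k))
  mol <- frags[take]
  rl <- lib$read_length

  ## ---- per-strand-family duplex sequences (reference-forward frame) ----
  lens <- mol$end - mol$start
  base_seq <- substring(gseq, mol$start + 1L, mol$end)
  has_conc <- vapply(mol$subs_conc, Negate(is.null), logical(1))
  for (i in which(has_conc)) {
    sc <- mol$subs_conc[[i]]
    base_seq[i] <- str_assign(base_seq[i], sc$pos - mol$start[i] + 1L,
                              sc$alt_plus)
  }
  seq_top <- base_seq       # strand "+" family, plus-frame
  seq_bot <- base_seq       # strand "-" family, plus-frame representation
  has_disc <- vapply(mol$subs_disc, Negate(is.null), logical(1))
  for (i in which(has_disc)) {
    sd_ <- mol$subs_disc[[i]]
    plus_side <- sd_$strand == "+"
    if (any(plus_side)) {
      seq_top[i] <- str_assign(seq_top[i],
                               sd_$pos[plus_side] - mol$start[i] + 1L,
                               sd_$alt_plus[plus_side])
    }
    if (any(!plus_side)) {
      seq_bot[i] <- str_assign(seq_bot[i],
                               sd_$pos[!plus_side] - mol$start[i] + 1L,
                               sd_$alt_plus[!plus_side])
    }
  }

  ## early-PCR errors, per strand family, shared by its duplicates
  if (lib$pcr_error_rate > 0) {
    for (sf in 1:2) {
      npcr <- rbinom(k, lens, lib$pcr_error_rate)
      for (i in which(npcr > 0L)) {
        at <- sample.int(lens[i], npcr[i])
        s <- if (sf == 1L) seq_top[i] else seq_bot[i]
        refc <- dna_to_code(substring(s, 1L, lens[i]))[at]
        alt <- BASES[sample_other_base(refc)]
        s <- str_assign(s, at, alt)
        if (sf == 1L) seq_top[i] <- s else seq_bot[i] <- s
      }
    }
  }

  ## ---- duplicates and reads --------------------------------------------
  n_top <- rztgeom(k, lib$dup_mean)
  n_bot <- rztgeom(k, lib$dup_mean)
  mol_idx <- c(rep.int(seq_len(k), n_top), rep.int(seq_len(k), n_bot))
  fam <- rep(c("top", "bottom"), c(sum(n_top), sum(n_bot)))
  dup_no <- c(
    unlist(lapply(n_top, seq_len), use.names = FALSE),
    unlist(lapply(n_bot, seq_len), use.names = FALSE)
  )
  np <- length(mol_idx)

  rl_eff <- pmin(rl, lens[mol_idx])
  fam_seq <- ifelse(fam == "top", seq_top[mol_idx], seq_bot[mol_idx])
  fwd_seq <- substring(fam_seq, 1L, rl_eff)
  rev_seq <- substring(fam_seq, lens[mol_idx] - rl_eff + 1L, lens[mol_idx])
  fwd_pos0 <- mol$start[mol_idx]
  rev_pos0 <- mol$end[mol_idx] - rl_eff

  qname <- sprintf("m%d:%s:%d", mol$molecule_id[mol_idx],
                   ifelse(fam == "top", "t", "b"), dup_no)
  is_top <- fam == "top"
  ## top strand: R1 forward (flag 99) + R2 reverse (147)
  ## bottom strand: R1 reverse (83) + R2 forward (163)
  reads <- data.table(
    qname = rep(qname, 2L),
    molecule_id = rep(mol$molecule_id[mol_idx], 2L),
    strand_family = rep(fam, 2L),
    mate = rep(1:2, each = np),
    flag = c(ifelse(is_top, 99L, 83L), ifelse(is_top, 147L, 163L)),
    pos0 = c(ifelse(is_top, fwd_pos0, rev_pos0),
             ifelse(is_top, rev_pos0, fwd_pos0)),
    seq = c(ifelse(is_top, fwd_seq, rev_seq),
            ifelse(is_top, rev_seq, fwd_seq))
  )

  ## independent sequencing errors
  if (lib$seq_error_rate > 0) {
    rlen <- nchar(reads$seq)
    nerr <- rbinom(nrow(reads), rlen, lib$seq_error_rate)
    hit <- which(nerr > 0L)
    if (length(hit)) {
      row <- rep.int(hit, nerr[hit])
      at <- unlist(lapply(hit, function(i) sample.int(rlen[i], nerr[i])),
                   use.names = FALSE)
      refc <- dna_to_code(paste(substring(reads$seq[row], at, at),
                                collapse = ""))
      alt <- BASES[sample_other_base(refc)]
      reads[, seq := .apply_edits(seq, row, at, alt)]
    }
  }

  ## ---- truth tables ------------------------------------------------------
  molecules <- data.table(
    molecule_id = mol$molecule_id, lineage = mol$lineage,
    chrom = chrom, start = mol$start, end = mol$end,
    n_top = n_top, n_bottom = n_bot,
    truncated = lens < rl
  )
  subs <- list()
  for (i in seq_len(k)) {
    for (col in c("subs_conc", "subs_disc")) {
      s <- mol[[col]][[i]]
      if (is.null(s) || !nrow(s)) next
      subs[[length(subs) + 1L]] <- data.table(
        molecule_id = mol$molecule_id[i], chrom = chrom,
        pos = s$pos + 1L, ref = s$ref_plus, alt = s$alt_plus,
        strand = s$strand, lesion = s$lesion, region_kind = s$region_kind,
        concordant = col == "subs_conc"
      )
    }
  }
  subs <- if (length(subs)) rbindlist(subs) else data.table(
    molecule_id = integer(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), strand = character(),
    lesion = character(), region_kind = character(), concordant = logical()
  )

  res <- structure(
    list(
      reads = reads[],
      molecules = molecules,
      substitutions = subs,
      chrom = chrom,
      genome_length = nchar(gseq)
    ),
    class = "sim_reads"
  )
  res$pairs <- reads_to_pairs(res)
  res
}

## reshape the per-read table into read-pair records (the consensus input)
reads_to_pairs <- function(sim) {
  r <- sim$reads
  w <- dcast(
    r, qname + molecule_id + strand_family ~ mate,
    value.var = c("pos0", "seq")
  )
  nc <- nchar(w$seq_1); nc2 <- nchar(w$seq_2)
  pairs <- data.table(
    qname = w$qname,
    chrom = sim$chrom,
    frag_start = pmin(w$pos0_1, w$pos0_2),
    frag_end = pmax(w$pos0_1 + nc, w$pos0_2 + nc2),
    orientation = ifelse(w$strand_family == "top", "F1R2", "F2R1"),
    r1_pos0 = w$pos0_1, r1_seq = w$seq_1,
    r2_pos0 = w$pos0_2, r2_seq = w$seq_2,
    molecule_id = w$molecule_id
  )
  setorder(pairs, frag_start, frag_end, orientation, qname)
  pairs[]
}

#' Write simulated reads to FASTQ, truth SAM and truth tables
#'
#' Emits `<prefix>_R1.fastq` / `<prefix>_R2.fastq` (4-line records,
#' constant Q30 qualities), `<prefix>.sam` (truth alignments, 1-based
#' positions, proper-pair flags, no aligner involved), and
#' `<prefix>_truth_molecules.tsv` / `<prefix>_truth_subs.tsv`.
#'
#' @param sim A `sim_reads` object.
#' @param outdir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Named list of written paths, invisibly.
#' @export
write_sim_reads <- function(sim, outdir, prefix = "sim") {
  stopifnot(inherits(sim, "sim_reads"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  r <- copy(sim$reads)
  setorder(r, qname, mate)

  qual <- function(s) strrep("?", nchar(s))  # Phred+33 '?' = Q30
  as_sequenced <- function(seqs, flags) {
    rev <- bitwAnd(flags, 16L) != 0L
    out <- seqs
    if (any(rev)) out[rev] <- revcomp(seqs[rev])
    out
  }

  paths <- list(
    r1 = file.path(outdir, paste0(prefix, "_R1.fastq")),
    r2 = file.path(outdir, paste0(prefix, "_R2.fastq")),
    sam = file.path(outdir, paste0(prefix, ".sam")),
    molecules = file.path(outdir, paste0(prefix, "_truth_molecules.tsv")),
    substitutions = file.path(outdir, paste0(prefix, "_truth_subs.tsv"))
  )
  for (m in 1:2) {
    rm_ <- r[mate == m]
    sq <- as_sequenced(rm_$seq, rm_$flag)
    write_lines_atomic(
      as.vector(rbind(paste0("@", rm_$qname), sq, "+", qual(sq))),
      if (m == 1L) paths$r1 else paths$r2
    )
  }

  ## SAM: mates interleaved per qname, reference-forward SEQ
  r[, width := nchar(seq)]
  mate_pos <- r[, .(p1 = pos0[mate == 1L], p2 = pos0[mate == 2L],
                    w1 = width[mate == 1L], w2 = width[mate == 2L]),
                by = qname]
  r <- merge(r, mate_pos, by = "qname", sort = FALSE)
  r[, `:=`(
    mpos = ifelse(mate == 1L, p2, p1),
    tlen0 = pmax(p1 + w1, p2 + w2) - pmin(p1, p2)
  )]
  r[, tlen := ifelse(bitwAnd(flag, 16L) != 0L, -tlen0, tlen0)]
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", sim$chrom, sim$genome_length),
    "@PG\tID:duplexsim\tPN:duplexsim"
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
    r$qname, r$flag, sim$chrom, r$pos0 + 1L, 60L, r$width,
    r$mpos + 1L, r$tlen, r$seq, vapply(r$width, function(w)
      strrep("?", w), character(1))
  )
  write_lines_atomic(c(header, body), paths$sam)

  fwrite(sim$molecules, paths$molecules, sep = "\t")
  fwrite(sim$substitutions, paths$substitutions, sep = "\t")
  invisible(paths)
}
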