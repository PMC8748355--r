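#' End-repair fragments: fill in 5' overhangs and gaps, chew back 3' ends
#'
#' Models the library-prep end-repair step.  A 5' overhang is filled in
#' using the protruding strand as template, so any lesion on it miscodes
#' into the newly synthesized strand and becomes a *concordant* duplex
#' substitution per the damage manifestation map (8-oxoG -> G>T, Iz -> G>C,
#' deaminated C -> C>T, on the damaged strand).  A 3' overhang is chewed
#' back, removing its lesions and shortening the fragment.  Gaps are filled
#' over their (possibly damaged) single-stranded template, and nicks are
#' resynthesized 5'->3' over the frayed window before ligation; lesions in
#' either become concordant the same way.  Strand-discordant damage in the
#' double-stranded core stays on its single strand.  The result is blunt
#' and nick-free.
#'
#' @param frags A `duplex_fragments` table (damaged and/or digested).
#' @return A `duplex_fragments` table with `repaired = TRUE`, overhangs
#'   removed, and two list-columns describing the realized duplex:
#'   `subs_conc` — concordant substitutions (`pos`, `strand`, `ref_ds`,
#'   `alt_ds`, `ref_plus`, `alt_plus`, `lesion`, `region_kind`) present on
#'   both strands; `subs_disc` — discordant ones present only on `strand`.
#' @export
end_repair <- function(frags) {
  stopifnot(inherits(frags, "duplex_fragments"))
  if (any(frags$repaired)) stop_arg("fragments are already end-repaired")
  n <- nrow(frags)

  ## 3' overhangs are chewed back: the fragment shrinks to the ds core on
  ## that side; 5' overhangs are filled and keep the outer coordinate
  chew_l <- ifelse(frags$oh_kind_l == "three_prime", frags$oh_len_l, 0L)
  chew_r <- ifelse(frags$oh_kind_r == "three_prime", frags$oh_len_r, 0L)
  new_start <- frags$start + chew_l
  new_end <- frags$end - chew_r

  subs_conc <- vector("list", n)
  subs_disc <- vector("list", n)
  has_les <- which(vapply(
    frags$lesions, function(x) !is.null(x) && nrow(x) > 0L, logical(1)
  ))
  for (i in has_les) {
    les <- frags$lesions[[i]]
    les <- les[les$pos >= new_start[i] & les$pos < new_end[i]]
    if (nrow(les) == 0L) next
    plus_ref <- ifelse(les$strand == "+", les$ref_ds, comp_base(les$ref_ds))
    plus_alt <- ifelse(les$strand == "+", les$alt_ds, comp_base(les$alt_ds))
    les <- les[, .(pos, strand, ref_ds, alt_ds, lesion, region_kind)]
    les[, `:=`(ref_plus = plus_ref, alt_plus = plus_alt)]
    conc <- les[region_kind %in% c("overhang", "gap", "nick_adjacent")]
    disc <- les[region_kind == "ds"]
    if (nrow(conc)) subs_conc[[i]] <- conc
    if (nrow(disc)) subs_disc[[i]] <- disc
  }

  res <- data.table(
    molecule_id = frags$molecule_id,
    lineage = frags$lineage,
    start = new_start,
    end = new_end,
    oh_kind_l = "blunt", oh_len_l = 0L,
    oh_kind_r = "blunt", oh_len_r = 0L,
    nicks = vector("list", n),
    gaps = vector("list", n),
    lesions = vector("list", n),
    repaired = TRUE,
    subs_conc = subs_conc,
    subs_disc = subs_disc
  )
  setattr(res, "chrom", attr(frags, "chrom", exact = TRUE))
  setattr(res, "genome_code", attr(frags, "genome_code", exact = TRUE))
  setattr(res, "genome_seq", attr(frags, "genome_seq", exact = TRUE))
  setattr(res, "class", c("duplex_fragments", class(res)))
  res[]
}
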