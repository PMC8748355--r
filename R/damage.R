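#' Damage model parameters
#'
#' Per-base lesion probabilities inside single-stranded (SS) regions, plus a
#' rate of strand-discordant damage in double-stranded (ds) regions.  SS
#' guanine oxidation products miscode during fill-in and are fixed into both
#' strands at end repair; ds damage stays on one strand and is rejected by
#' duplex consensus.  The manifestation map records the substitution each
#' lesion produces on the damaged strand: 8-oxoG pairs with adenine (G>T),
#' 2-aminoimidazolone (Iz) drives G>C, cytosine deamination reads as C>T.
#'
#' @param p_oxog_ss,p_iz_ss,p_deamc_ss Per-eligible-base lesion
#'   probabilities within SS regions (eligible base: G on the SS strand for
#'   oxoG/Iz, C for deamination).  Realistic values are well below 0.05;
#'   the full \[0, 1\] range is accepted so that certainty configurations
#'   can be used in validation.
#' @param p_ds Per-base probability of strand-discordant damage in the ds
#'   core (random substitution on one random strand).
#' @param nick_halfwidth Half-width (bp) of the frayed, damage-exposed
#'   window on the strand opposite a nick.
#' @return A list of class `damage_params`.
#' @export
damage_params <- function(p_oxog_ss = 0.02, p_iz_ss = 0.005,
                          p_deamc_ss = 0, p_ds = 1e-4,
                          nick_halfwidth = 2L) {
  p <- c(p_oxog_ss, p_iz_ss, p_deamc_ss, p_ds)
  if (any(p < 0) || any(p > 1)) {
    stop_arg("damage probabilities must lie in [0, 1]")
  }
  structure(
    list(
      p_oxog_ss = p_oxog_ss, p_iz_ss = p_iz_ss, p_deamc_ss = p_deamc_ss,
      p_ds = p_ds, nick_halfwidth = as.integer(nick_halfwidth),
      ## lesion -> (eligible base on damaged strand, substituted base)
      manifestation = list(
        oxoG  = c(ref = "G", alt = "T"),
        iz    = c(ref = "G", alt = "C"),
        deamC = c(ref = "C", alt = "T")
      )
    ),
    class = "damage_params"
  )
}

## eligible-base code on the *reference plus strand* for a lesion whose
## damaged strand is `strand`: G on "+" is code 3, G on "-" sits at a
## reference C (code 2), etc.
.plus_code_for <- function(base, strand) {
  code <- match(base, BASES)
  ifelse(strand == "+", code, 5L - code)
}

## fast single-fragment SS-region enumerator over plain vectors; returns a
## list of parallel vectors (strand, rstart, rend, kind, anchor)
.ss_regions_one <- function(start, end, oh_kind_l, oh_len_l,
                            oh_kind_r, oh_len_r, nicks, gaps,
                            nick_halfwidth = 2L) {
  s <- character(0); rs <- integer(0); re <- integer(0)
  kd <- character(0); an <- integer(0)
  if (oh_len_l > 0L) {
    s <- c(s, if (oh_kind_l == "five_prime") "+" else "-")
    rs <- c(rs, start); re <- c(re, start + oh_len_l)
    kd <- c(kd, "overhang"); an <- c(an, NA_integer_)
  }
  if (oh_len_r > 0L) {
    s <- c(s, if (oh_kind_r == "five_prime") "-" else "+")
    rs <- c(rs, end - oh_len_r); re <- c(re, end)
    kd <- c(kd, "overhang"); an <- c(an, NA_integer_)
  }
  if (!is.null(gaps) && nrow(gaps)) {
    s <- c(s, ifelse(gaps$strand == "+", "-", "+"))
    rs <- c(rs, gaps$gstart); re <- c(re, gaps$gend)
    kd <- c(kd, rep("gap", nrow(gaps)))
    an <- c(an, rep(NA_integer_, nrow(gaps)))
  }
  if (!is.null(nicks) && nrow(nicks)) {
    cs <- start + oh_len_l; ce <- end - oh_len_r
    s <- c(s, ifelse(nicks$strand == "+", "-", "+"))
    rs <- c(rs, pmax(cs, nicks$pos - nick_halfwidth))
    re <- c(re, pmin(ce, nicks$pos + nick_halfwidth + 1L))
    kd <- c(kd, rep("nick_adjacent", nrow(nicks)))
    an <- c(an, nicks$pos)
  }
  list(strand = s, rstart = rs, rend = re, region_kind = kd, anchor = an)
}

#' Enumerate the single-stranded regions of one fragment
#'
#' A 5' overhang is single-stranded on the protruding strand (left end:
#' plus; right end: minus) and a 3' overhang on the opposite strand of the
#' same end; a gap on strand *s* leaves the opposite strand single-stranded
#' as the fill-in template; a nick frays, exposing a window of the opposite
#' strand around the nick.
#'
#' @param frag One row of a `duplex_fragments` table.
#' @param nick_halfwidth Frayed-window half-width in bp.
#' @return A `data.table` with columns `strand`, `rstart`, `rend`
#'   (0-based half-open), `region_kind` and `anchor`.
#' @export
frag_ss_regions <- function(frag, nick_halfwidth = 2L) {
  stopifnot(nrow(frag) == 1L)
  as.data.table(.ss_regions_one(
    frag$start, frag$end, frag$oh_kind_l, frag$oh_len_l,
    frag$oh_kind_r, frag$oh_len_r,
    frag$nicks[[1]], frag$gaps[[1]], nick_halfwidth
  ))
}

#' Place single-strand-confined damage on fragments
#'
#' Lesions are drawn independently per eligible base inside each SS region
#' (overhangs, gap templates, nick-adjacent frayed windows); strand-
#' discordant damage is drawn over the double-stranded core.  Fragments with
#' no SS region receive no SS lesions.
#'
#' @param frags A `duplex_fragments` table (not yet end-repaired).
#' @param params A [damage_params()] object.
#' @param seed Integer seed.
#' @return The fragments with the `lesions` list-column filled:
#'   `pos` (0-based reference coordinate), `strand` (damaged strand),
#'   `ref_ds`/`alt_ds` (damaged-strand bases), `lesion`, `region_kind`,
#'   `anchor` (nick position for nick-adjacent lesions).
#' @export
apply_ss_damage <- function(frags, params = damage_params(), seed = 1L) {
  stopifnot(inherits(frags, "duplex_fragments"),
            inherits(params, "damage_params"))
  if (any(frags$repaired)) {
    stop_arg("fragments are already end-repaired; damage must come first")
  }
  set.seed(as.integer(seed))
  gcode <- attr(frags, "genome_code", exact = TRUE)
  if (is.null(gcode)) {
    stop_arg("fragments lack genome codes; re-attach with with_genome()")
  }

  n <- nrow(frags)
  v_start <- frags$start; v_end <- frags$end
  v_okl <- frags$oh_kind_l; v_oll <- frags$oh_len_l
  v_okr <- frags$oh_kind_r; v_olr <- frags$oh_len_r
  l_nicks <- frags$nicks; l_gaps <- frags$gaps

  ss_specs <- list(
    list(lesion = "oxoG", p = params$p_oxog_ss, base = "G", alt = "T"),
    list(lesion = "iz", p = params$p_iz_ss, base = "G", alt = "C"),
    list(lesion = "deamC", p = params$p_deamc_ss, base = "C", alt = "T")
  )
  ss_specs <- Filter(function(x) x$p > 0, ss_specs)

  ## accumulate hits across fragments, split into the list-column at the end
  a_frag <- list(); a_pos <- list(); a_str <- list(); a_ref <- list()
  a_alt <- list(); a_les <- list(); a_kind <- list(); a_anchor <- list()
  push <- function(i, pos, str, ref, alt, les, kind, anchor) {
    k <- length(a_frag) + 1L
    a_frag[[k]] <<- rep.int(i, length(pos)); a_pos[[k]] <<- pos
    a_str[[k]] <<- str; a_ref[[k]] <<- ref; a_alt[[k]] <<- alt
    a_les[[k]] <<- les; a_kind[[k]] <<- kind; a_anchor[[k]] <<- anchor
  }

  for (i in seq_len(n)) {
    if (length(ss_specs)) {
      reg <- .ss_regions_one(v_start[i], v_end[i], v_okl[i], v_oll[i],
                             v_okr[i], v_olr[i], l_nicks[[i]], l_gaps[[i]],
                             params$nick_halfwidth)
      for (r in seq_along(reg$strand)) {
        if (reg$rend[r] <= reg$rstart[r]) next
        ppos <- seq.int(reg$rstart[r], reg$rend[r] - 1L)
        pcode <- gcode[ppos + 1L]
        for (spec in ss_specs) {
          want <- .plus_code_for(spec$base, reg$strand[r])
          elig <- ppos[pcode == want]
          if (!length(elig)) next
          hit <- elig[runif(length(elig)) < spec$p]
          if (!length(hit)) next
          push(i, hit, rep(reg$strand[r], length(hit)),
               rep(spec$base, length(hit)), rep(spec$alt, length(hit)),
               rep(spec$lesion, length(hit)),
               rep(reg$region_kind[r], length(hit)),
               rep(reg$anchor[r], length(hit)))
        }
      }
    }
    if (params$p_ds > 0) {
      cs <- v_start[i] + v_oll[i]; ce <- v_end[i] - v_olr[i]
      clen <- ce - cs
      if (clen > 0L) {
        k <- rbinom(1L, clen, params$p_ds)
        if (k > 0L) {
          dpos <- cs + sample.int(clen, k) - 1L
          dstr <- sample(c("+", "-"), k, replace = TRUE)
          pcode <- gcode[dpos + 1L]
          scode <- ifelse(dstr == "+", pcode, 5L - pcode)
          altc <- sample_other_base(scode)
          push(i, dpos, dstr, BASES[scode], BASES[altc],
               rep("ds", k), rep("ds", k), rep(NA_integer_, k))
        }
      }
    }
  }

  lesions <- vector("list", n)
  if (length(a_frag)) {
    all_les <- data.table(
      frag = unlist(a_frag), pos = unlist(a_pos), strand = unlist(a_str),
      ref_ds = unlist(a_ref), alt_ds = unlist(a_alt),
      lesion = unlist(a_les), region_kind = unlist(a_kind),
      anchor = unlist(a_anchor)
    )
    sp <- split(all_les, by = "frag", keep.by = FALSE)
    lesions[as.integer(names(sp))] <- sp
  }
  out <- copy(frags)
  set(out, j = "lesions", value = lesions)
  out[]
}

#' Attach genome base codes to a fragment table
#'
#' Fragment tables carry the genome as attributes; operations that create
#' fresh tables (or file round-trips) may need them re-attached.
#'
#' @param frags A `duplex_fragments` table.
#' @param genome The `ref_genome` the fragments were sheared from.
#' @return The fragments with the genome attached as attributes.
#' @export
with_genome <- function(frags, genome) {
  stopifnot(inherits(genome, "ref_genome"))
  if (!is.null(attr(frags, "chrom", exact = TRUE)) &&
      attr(frags, "chrom") != genome$name) {
    stop_arg("fragments were sheared from '", attr(frags, "chrom"),
             "', not '", genome$name, "'")
  }
  setattr(frags, "genome_code", genome$code)
  setattr(frags, "genome_seq", genome$seq)
  setattr(frags, "chrom", genome$name)
  frags
}
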