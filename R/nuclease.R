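#' Single-strand-specific nuclease models
#'
#' Activity is expressed as saturating probabilities per substrate:
#' `p(units) = p_max * (1 - exp(-units / k))`, monotone non-decreasing in
#' enzyme units and bounded by `p_max <= 1`.  Units map onto probabilities,
#' not biochemical rate constants.
#'
#' Built-in models:
#' * `"s1"` — SS-endonuclease; excises overhangs, cleaves gaps, and
#'   attacks nicks efficiently; cutting shows a terminal-base preference
#'   (`end_bias`) that enriches G at the first sequenced base.
#' * `"mbn"` — SS-endonuclease (mung-bean-nuclease-like); like S1 on
#'   overhangs and gaps but with much weaker nick activity.
#' * `"recjf"` — SS-exonuclease, 5'->3'; removes 5' overhangs only, no
#'   internal gap or nick activity, no terminal bias.
#' * `"none"` — inert control.
#'
#' @param name One of `"s1"`, `"mbn"`, `"recjf"`, `"none"`.
#' @param p_oh_max,k_oh Overhang-excision saturation and unit constant.
#' @param p_gap_max,k_gap Gap-cleavage parameters.
#' @param p_nick_max,k_nick Nick-cleavage parameters.
#' @param end_bias Optional named weights over `A,C,G,T` preferring the
#'   post-cut 5'-terminal base, or `NULL` for unbiased cutting.
#' @param bias_window Maximum extra bases trimmed to satisfy the terminal
#'   preference.
#' @return A list of class `nuclease_model` with parameter fields and
#'   probability functions `p_overhang(units)`, `p_gap(units)`,
#'   `p_nick(units)`.
#' @export
nuclease_model <- function(name = c("s1", "mbn", "recjf", "none"),
                           p_oh_max = NULL, k_oh = NULL,
                           p_gap_max = NULL, k_gap = NULL,
                           p_nick_max = NULL, k_nick = NULL,
                           end_bias = NULL, bias_window = 3L) {
  if (!is.character(name) || !all(name %in% c("s1", "mbn", "recjf", "none"))) {
    stop_arg("unknown nuclease model: ", paste(name, collapse = ", "))
  }
  name <- match.arg(name)
  def <- switch(name,
    s1 = list(p_oh_max = 1, k_oh = 3, p_gap_max = 1, k_gap = 5,
              p_nick_max = 1, k_nick = 8,
              directionality = "endo", five_prime_only = FALSE,
              end_bias = c(A = 1, C = 1, G = 4, T = 1)),
    mbn = list(p_oh_max = 1, k_oh = 3, p_gap_max = 1, k_gap = 5,
               p_nick_max = 0.25, k_nick = 40,
               directionality = "endo", five_prime_only = FALSE,
               end_bias = c(A = 1, C = 2.5, G = 2.5, T = 1)),
    recjf = list(p_oh_max = 1, k_oh = 5, p_gap_max = 0, k_gap = Inf,
                 p_nick_max = 0, k_nick = Inf,
                 directionality = "exo5to3", five_prime_only = TRUE,
                 end_bias = NULL),
    none = list(p_oh_max = 0, k_oh = Inf, p_gap_max = 0, k_gap = Inf,
                p_nick_max = 0, k_nick = Inf,
                directionality = "endo", five_prime_only = FALSE,
                end_bias = NULL)
  )
  m <- def
  m$p_oh_max <- p_oh_max %||% def$p_oh_max
  m$k_oh <- k_oh %||% def$k_oh
  m$p_gap_max <- p_gap_max %||% def$p_gap_max
  m$k_gap <- k_gap %||% def$k_gap
  m$p_nick_max <- p_nick_max %||% def$p_nick_max
  m$k_nick <- k_nick %||% def$k_nick
  if (!missing(end_bias)) m$end_bias <- end_bias
  m$bias_window <- as.integer(bias_window)
  m$name <- name
  if (name == "recjf" && (m$p_gap_max > 0 || m$p_nick_max > 0)) {
    stop_arg("a 5'->3' SS-exonuclease model has no gap or nick activity")
  }
  pmaxs <- c(m$p_oh_max, m$p_gap_max, m$p_nick_max)
  if (any(pmaxs < 0) || any(pmaxs > 1)) {
    stop_arg("saturation probabilities must lie in [0, 1]")
  }
  sat <- function(pm, k) {
    force(pm); force(k)
    function(units) {
      if (any(units < 0)) stop_arg("`units` must be >= 0")
      if (pm == 0) rep(0, length(units)) else pm * (1 - exp(-units / k))
    }
  }
  m$p_overhang <- sat(m$p_oh_max, m$k_oh)
  m$p_gap <- sat(m$p_gap_max, m$k_gap)
  m$p_nick <- sat(m$p_nick_max, m$k_nick)
  structure(m, class = "nuclease_model")
}

#' @export
print.nuclease_model <- function(x, ...) {
  cat(sprintf(
    "<nuclease_model> %s: p_oh<=%.2f (k=%g), p_gap<=%.2f, p_nick<=%.2f%s\n",
    x$name, x$p_oh_max, x$k_oh, x$p_gap_max, x$p_nick_max,
    if (!is.null(x$end_bias)) ", terminal bias" else ""
  ))
  invisible(x)
}

## choose extra trim 0..w so the post-cut 5'-terminal base follows the bias
## weights; u is a pre-drawn uniform so the choice is units-independent
.bias_offset <- function(term_codes, bias, u) {
  w <- bias[BASES[term_codes]]
  cw <- cumsum(w) / sum(w)
  findInterval(u, cw, left.open = TRUE)
}

#' Digest fragments with a single-strand-specific nuclease
#'
#' Each overhang is excised with probability `p_overhang(units)` (RecJf-like
#' models act on 5' overhangs only); each gap is cleaved with probability
#' `p_gap(units)`, removing the single-stranded template and splitting the
#' fragment; each nick is cleaved with `p_nick(units)`, splitting at the
#' nick and discarding its frayed-window lesions.  Lesions residing on
#' excised or released material are discarded with it.  Fragments shorter
#' than `min_emit_len` after splitting are dropped.  Random draws are laid
#' out per substrate before any probability is applied, so runs at different
#' `units` with the same `seed` share common random numbers and the
#' surviving-lesion count is monotone in `units`.
#'
#' @param frags A `duplex_fragments` table (damaged, not yet end-repaired).
#' @param model A [nuclease_model()].
#' @param units Enzyme amount (arbitrary units, >= 0).
#' @param seed Integer seed.
#' @param min_emit_len Minimum emitted fragment length (bp).
#' @return A new `duplex_fragments` table.  Unsplit fragments keep their
#'   `molecule_id`; split products receive fresh ids and dotted `lineage`
#'   suffixes (`"12.1"`, `"12.2"`).
#' @export
digest_nuclease <- function(frags, model, units, seed = 1L,
                            min_emit_len = 50L) {
  stopifnot(inherits(frags, "duplex_fragments"))
  if (!inherits(model, "nuclease_model")) {
    stop_arg("`model` must be a nuclease_model object")
  }
  if (!is.numeric(units) || length(units) != 1L || units < 0) {
    stop_arg("`units` must be a single number >= 0")
  }
  if (any(frags$repaired)) stop_arg("digestion must precede end repair")
  set.seed(as.integer(seed))
  gcode <- attr(frags, "genome_code", exact = TRUE)
  if (is.null(gcode)) stop_arg("fragments lack genome codes")

  n <- nrow(frags)
  p_oh <- model$p_overhang(units)
  p_gap <- model$p_gap(units)
  p_nick <- model$p_nick(units)

  ## pre-draw: fixed layout independent of units (common random numbers)
  u_end <- matrix(runif(4L * n), nrow = 4L)   # cut_l, cut_r, bias_l, bias_r
  n_gaps <- vapply(frags$gaps, function(g) if (is.null(g)) 0L else nrow(g),
                   integer(1))
  n_nicks <- vapply(frags$nicks, function(g) if (is.null(g)) 0L else nrow(g),
                    integer(1))
  u_gap_all <- runif(sum(n_gaps))
  u_nick_all <- runif(sum(n_nicks))
  gap_off <- c(0L, cumsum(n_gaps))
  nick_off <- c(0L, cumsum(n_nicks))

  v_start <- frags$start; v_end <- frags$end
  v_okl <- frags$oh_kind_l; v_oll <- frags$oh_len_l
  v_okr <- frags$oh_kind_r; v_olr <- frags$oh_len_r
  v_id <- frags$molecule_id; v_lin <- frags$lineage

  out <- vector("list", n)
  next_id <- max(v_id) + 1L

  for (i in seq_len(n)) {
    s <- v_start[i]; e <- v_end[i]
    okl <- v_okl[i]; oll <- v_oll[i]
    okr <- v_okr[i]; olr <- v_olr[i]
    nk <- frags$nicks[[i]]; gp <- frags$gaps[[i]]; les <- frags$lesions[[i]]
    changed <- FALSE

    ## --- overhang excision ------------------------------------------------
    elig_l <- oll > 0L && (!model$five_prime_only || okl == "five_prime")
    elig_r <- olr > 0L && (!model$five_prime_only || okr == "five_prime")
    if (elig_l && u_end[1L, i] < p_oh) {
      s <- s + oll
      if (!is.null(model$end_bias) && model$bias_window > 0L) {
        w <- min(model$bias_window, e - s - 2L)
        if (w > 0L) {
          term <- gcode[s + 0:w + 1L]       # plus-strand 5' terminal bases
          s <- s + .bias_offset(term, model$end_bias, u_end[3L, i])
        }
      }
      okl <- "blunt"; oll <- 0L; changed <- TRUE
    }
    if (elig_r && u_end[2L, i] < p_oh) {
      e <- e - olr
      if (!is.null(model$end_bias) && model$bias_window > 0L) {
        w <- min(model$bias_window, e - s - 2L)
        if (w > 0L) {
          term <- 5L - gcode[e - 0:w]       # minus-strand 5' terminal bases
          e <- e - .bias_offset(term, model$end_bias, u_end[4L, i])
        }
      }
      okr <- "blunt"; olr <- 0L; changed <- TRUE
    }

    ## --- gap / nick cleavage ----------------------------------------------
    cut_a <- integer(0); cut_b <- integer(0)
    cleaved_nick_pos <- integer(0)
    if (!is.null(gp) && nrow(gp)) {
      u <- u_gap_all[(gap_off[i] + 1L):gap_off[i + 1L]]
      inside <- gp$gstart > s & gp$gend < e
      hit <- inside & u < p_gap
      if (any(hit)) {
        cut_a <- c(cut_a, gp$gstart[hit]); cut_b <- c(cut_b, gp$gend[hit])
        changed <- TRUE
      }
      gp <- gp[inside & !hit]
      if (nrow(gp) == 0L) gp <- NULL
    }
    if (!is.null(nk) && nrow(nk)) {
      u <- u_nick_all[(nick_off[i] + 1L):nick_off[i + 1L]]
      inside <- nk$pos > s & nk$pos < e
      hit <- inside & u < p_nick
      if (any(hit)) {
        cleaved_nick_pos <- nk$pos[hit]
        cut_a <- c(cut_a, cleaved_nick_pos); cut_b <- c(cut_b, cleaved_nick_pos)
        changed <- TRUE
      }
      nk <- nk[inside & !hit]
      if (nrow(nk) == 0L) nk <- NULL
    }

    ## --- assemble segments -------------------------------------------------
    if (!changed) { out[[i]] <- list(unchanged = i); next }
    if (length(cut_a)) {
      o <- order(cut_a)
      cut_a <- cut_a[o]; cut_b <- cut_b[o]
      seg_s <- integer(0); seg_e <- integer(0)
      cur <- s
      for (j in seq_along(cut_a)) {
        if (cut_a[j] > cur) { seg_s <- c(seg_s, cur); seg_e <- c(seg_e, cut_a[j]) }
        cur <- max(cur, cut_b[j])
      }
      if (e > cur) { seg_s <- c(seg_s, cur); seg_e <- c(seg_e, e) }
    } else {
      seg_s <- s; seg_e <- e
    }
    if (!is.null(les) && length(cleaved_nick_pos)) {
      les <- les[!(les$region_kind == "nick_adjacent" &
                     les$anchor %in% cleaved_nick_pos)]
      if (nrow(les) == 0L) les <- NULL
    }

    keep <- (seg_e - seg_s) >= min_emit_len
    seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
    if (!length(seg_s)) { out[[i]] <- NULL; next }

    nseg <- length(seg_s)
    rows <- vector("list", nseg)
    for (j in seq_len(nseg)) {
      ss <- seg_s[j]; ee <- seg_e[j]
      first <- ss == s; last <- ee == e
      sub_nk <- if (!is.null(nk)) nk[nk$pos > ss & nk$pos < ee] else NULL
      if (!is.null(sub_nk) && nrow(sub_nk) == 0L) sub_nk <- NULL
      sub_gp <- if (!is.null(gp)) gp[gp$gstart > ss & gp$gend < ee] else NULL
      if (!is.null(sub_gp) && nrow(sub_gp) == 0L) sub_gp <- NULL
      sub_les <- if (!is.null(les)) les[les$pos >= ss & les$pos < ee] else NULL
      if (!is.null(sub_les) && nrow(sub_les) == 0L) sub_les <- NULL
      rows[[j]] <- list(
        molecule_id = if (nseg == 1L) v_id[i] else next_id + j - 1L,
        lineage = if (nseg == 1L) v_lin[i] else paste0(v_lin[i], ".", j),
        start = ss, end = ee,
        oh_kind_l = if (first) okl else "blunt",
        oh_len_l = if (first) oll else 0L,
        oh_kind_r = if (last) okr else "blunt",
        oh_len_r = if (last) olr else 0L,
        nicks = list(sub_nk), gaps = list(sub_gp), lesions = list(sub_les),
        repaired = FALSE
      )
    }
    if (nseg > 1L) next_id <- next_id + nseg
    out[[i]] <- list(rows = rows)
  }

  ## materialize: unchanged rows are copied wholesale, modified ones rebuilt
  unchanged_idx <- integer(0)
  new_rows <- list()
  for (i in seq_len(n)) {
    o <- out[[i]]
    if (is.null(o)) next
    if (!is.null(o$unchanged)) {
      unchanged_idx <- c(unchanged_idx, o$unchanged)
    } else {
      new_rows <- c(new_rows, o$rows)
    }
  }
  parts <- list()
  if (length(unchanged_idx)) parts[[1]] <- frags[unchanged_idx]
  if (length(new_rows)) {
    parts[[length(parts) + 1L]] <- rbindlist(
      lapply(new_rows, as.data.table)
    )
  }
  res <- if (length(parts)) rbindlist(parts, use.names = TRUE) else
    frags[0]
  setorder(res, start, end, molecule_id)
  setattr(res, "chrom", attr(frags, "chrom", exact = TRUE))
  setattr(res, "genome_code", gcode)
  setattr(res, "genome_seq", attr(frags, "genome_seq", exact = TRUE))
  if (!inherits(res, "duplex_fragments")) {
    setattr(res, "class", c("duplex_fragments", class(res)))
  }
  res[]
}
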