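## Run configuration ---------------------------------------------------------

.config_schema <- list(
  seed = NULL,
  replicates = NULL,
  genome = c("length", "gc", "name"),
  shear = c("n_fragments", "size_mean", "size_sd", "min_len",
            "p_blunt", "p_five_prime", "p_three_prime", "overhang_mean",
            "nick_rate", "gap_rate", "gap_mean"),
  damage = c("p_oxog_ss", "p_iz_ss", "p_deamc_ss", "p_ds",
             "nick_halfwidth"),
  digest = c("nucleases", "units", "min_emit_len"),
  library = c("ligated_amounts", "molecules_per_unit", "dup_mean",
              "read_length", "seq_error_rate", "pcr_error_rate"),
  consensus = c("min_family_size", "agreement_threshold"),
  spectrum = c("frame", "clip", "mask", "pseudocount"),
  covqc = c("n_bins")
)

.default_config <- function() {
  list(
    seed = 1L,
    replicates = 1L,
    genome = list(length = 50000L, gc = 0.52, name = "chrSim"),
    shear = list(n_fragments = 5000L, size_mean = 350, size_sd = 50,
                 min_len = 50L, p_blunt = 1 / 3, p_five_prime = 1 / 3,
                 p_three_prime = 1 / 3, overhang_mean = 8,
                 nick_rate = 5e-4, gap_rate = 2e-4, gap_mean = 6),
    damage = list(p_oxog_ss = 0.02, p_iz_ss = 0.005, p_deamc_ss = 0,
                  p_ds = 1e-4, nick_halfwidth = 2L),
    digest = list(nucleases = "none", units = 0, min_emit_len = 50L),
    library = list(ligated_amounts = 78, molecules_per_unit = 25,
                   dup_mean = 3, read_length = 100L,
                   seq_error_rate = 1e-3, pcr_error_rate = 1e-3),
    consensus = list(min_family_size = 1L, agreement_threshold = NULL),
    spectrum = list(frame = "fragment", clip = 0L, mask = NULL,
                    pseudocount = 0.001),
    covqc = list(n_bins = 500L)
  )
}

#' Build a validated run configuration
#'
#' Merges user settings over the defaults; unknown keys (at either level)
#' are rejected so typos cannot silently fall back to defaults.
#'
#' @param x A nested list of settings (possibly empty), e.g. from
#'   [yaml::read_yaml()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (!is.list(x)) stop_arg("configuration must be a list")
  cfg <- .default_config()
  bad <- setdiff(names(x), names(.config_schema))
  if (length(bad)) {
    stop_arg("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  for (sec in names(x)) {
    if (is.null(.config_schema[[sec]])) {
      cfg[[sec]] <- x[[sec]]
      next
    }
    if (!is.list(x[[sec]])) {
      stop_arg("configuration section '", sec, "' must be a mapping")
    }
    badk <- setdiff(names(x[[sec]]), .config_schema[[sec]])
    if (length(badk)) {
      stop_arg("unknown key(s) in '", sec, "': ",
               paste(badk, collapse = ", "))
    }
    cfg[[sec]][names(x[[sec]])] <- x[[sec]]
  }
  with(cfg$shear, {
    if (abs(p_blunt + p_five_prime + p_three_prime - 1) > 1e-6) {
      stop_arg("overhang kind probabilities must sum to 1")
    }
  })
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Derive a stage seed from the global seed
#'
#' Deterministic per-stage seeds keep the pipeline stages independently
#' reproducible; results stay within the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param counter Stage counter (any small integer).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483629)
}

## Simulation pipeline for one condition cell --------------------------------

#' Simulate one library condition end to end
#'
#' Shear, damage, digest, end-repair and sequence one library under a run
#' configuration, for a given nuclease/units/amount/replicate cell.
#'
#' @param cfg A `run_config`.
#' @param genome A `ref_genome` (shared across cells).
#' @param nuclease,units,amount Condition coordinates.
#' @param rep_i Replicate index (drives the derived seeds).
#' @return A `sim_reads` object.
#' @export
simulate_condition <- function(cfg, genome, nuclease = "none", units = 0,
                               amount = NULL, rep_i = 1L) {
  stopifnot(inherits(cfg, "run_config"))
  amount <- amount %||% cfg$library$ligated_amounts[1]
  base <- stage_seed(
    cfg$seed,
    1000L * rep_i + 17L * match(nuclease, c("none", "s1", "mbn", "recjf")) +
      as.integer(round(units)) %% 997L + as.integer(round(amount))
  )
  sh <- cfg$shear
  frags <- shear_fragments(
    genome, sh$n_fragments, size_mean = sh$size_mean, size_sd = sh$size_sd,
    min_len = sh$min_len,
    overhang_probs = c(sh$p_blunt, sh$p_five_prime, sh$p_three_prime),
    overhang_mean = sh$overhang_mean, nick_rate = sh$nick_rate,
    gap_rate = sh$gap_rate, gap_mean = sh$gap_mean,
    seed = stage_seed(base, 1L)
  )
  dm <- cfg$damage
  dp <- damage_params(dm$p_oxog_ss, dm$p_iz_ss, dm$p_deamc_ss, dm$p_ds,
                      dm$nick_halfwidth)
  frags <- apply_ss_damage(frags, dp, seed = stage_seed(base, 2L))
  if (nuclease != "none" && units > 0) {
    frags <- digest_nuclease(frags, nuclease_model(nuclease), units,
                             seed = stage_seed(base, 3L),
                             min_emit_len = cfg$digest$min_emit_len)
  }
  frags <- end_repair(frags)
  lib <- library_params(
    ligated_amount = amount,
    molecules_per_unit = cfg$library$molecules_per_unit,
    dup_mean = cfg$library$dup_mean,
    read_length = cfg$library$read_length,
    seq_error_rate = cfg$library$seq_error_rate,
    pcr_error_rate = cfg$library$pcr_error_rate,
    seed = stage_seed(base, 4L)
  )
  sample_and_sequence(frags, lib)
}

#' Run a full condition-grid experiment
#'
#' For every cell of the grid (nuclease model x units x ligated amount x
#' replicate) runs simulate -> consensus -> spectrum -> coverage QC, then
#' compares every treated condition against the untreated control cell
#' (nuclease `"none"` or `units == 0`) when both have at least two
#' replicates.  Deterministic for a fixed configuration.
#'
#' @param cfg A `run_config`.
#' @param outdir Optional output directory; when given, writes
#'   `spectra.tsv`, `comparisons.tsv` and `coverage.tsv` (atomically).
#' @return List with `spectra`, `comparisons`, `coverage` data.tables and
#'   the `config`.
#' @export
run_experiment <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  genome <- make_genome(cfg$genome$length, cfg$genome$gc,
                        seed = stage_seed(cfg$seed, 0L),
                        name = cfg$genome$name)
  mask <- if (!is.null(cfg$spectrum$mask)) read_bed_mask(cfg$spectrum$mask)

  nucs <- cfg$digest$nucleases
  units_v <- cfg$digest$units
  amounts <- cfg$library$ligated_amounts
  reps <- seq_len(cfg$replicates)

  grid <- CJ(nuclease = nucs, units = units_v, amount = amounts,
             rep_i = reps, sorted = FALSE)
  ## a unit dose is meaningless for the untreated model: collapse to 0
  grid[nuclease == "none", units := 0]
  grid <- unique(grid)

  spectra <- list(); coverage <- list(); specs <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i]
    sim <- simulate_condition(cfg, genome, g$nuclease, g$units, g$amount,
                              g$rep_i)
    dcs <- call_duplex_consensus(
      sim$pairs, min_family_size = cfg$consensus$min_family_size,
      agreement_threshold = cfg$consensus$agreement_threshold
    )
    dcs_c <- clip_ends(dcs, cfg$spectrum$clip)
    cnt <- count_substitutions(dcs_c, genome, frame = cfg$spectrum$frame,
                               mask = mask)
    label <- sprintf("%s_u%g_a%g", g$nuclease, g$units, g$amount)
    sp <- frequencies(cnt, label = label, replicate = g$rep_i)
    specs[[i]] <- sp
    spectra[[i]] <- cbind(
      data.table(nuclease = g$nuclease, units = g$units,
                 amount = g$amount, replicate = g$rep_i),
      sp$freq6
    )
    cov <- coverage_summary(dcs, genome$length, n_bins = cfg$covqc$n_bins)
    coverage[[i]] <- data.table(
      nuclease = g$nuclease, units = g$units, amount = g$amount,
      replicate = g$rep_i, covered_rate = cov$covered_rate,
      mean = cov$mean, sd = cov$sd, cv = cov$cv
    )
  }
  spectra <- rbindlist(spectra)
  coverage <- rbindlist(coverage)

  ## comparisons vs the untreated control, per amount
  comparisons <- list()
  cells <- unique(grid[, .(nuclease, units, amount)])
  for (am in unique(cells$amount)) {
    ctrl_cell <- cells[amount == am & (nuclease == "none" | units == 0)]
    if (nrow(ctrl_cell) == 0L) next
    ctrl_cell <- ctrl_cell[1]
    ctrl_idx <- which(grid$nuclease == ctrl_cell$nuclease &
                        grid$units == ctrl_cell$units &
                        grid$amount == am)
    if (length(ctrl_idx) < 2L) next
    for (ci in seq_len(nrow(cells))) {
      cc <- cells[ci]
      if (cc$amount != am ||
          (cc$nuclease == ctrl_cell$nuclease &&
             cc$units == ctrl_cell$units)) next
      tr_idx <- which(grid$nuclease == cc$nuclease &
                        grid$units == cc$units & grid$amount == am)
      if (length(tr_idx) < 2L) next
      cmp <- compare_groups(specs[tr_idx], specs[ctrl_idx],
                            test = "ttest",
                            pseudocount = cfg$spectrum$pseudocount)
      comparisons[[length(comparisons) + 1L]] <- cbind(
        data.table(nuclease = cc$nuclease, units = cc$units, amount = am),
        cmp
      )
    }
  }
  comparisons <- if (length(comparisons)) rbindlist(comparisons) else
    data.table(
      nuclease = character(), units = numeric(), amount = numeric(),
      type = character(), group = character(), n_treat = integer(),
      n_ctrl = integer(), mean_treat = numeric(), sd_treat = numeric(),
      mean_ctrl = numeric(), sd_ctrl = numeric(),
      log2_fold_change = numeric(), p_value = numeric(),
      neg_log10_p = numeric(), test_name = character()
    )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("spectra", "comparisons", "coverage")) {
      obj <- get(nm)
      tmp <- file.path(outdir, paste0(nm, ".tsv.tmp"))
      fwrite(obj, tmp, sep = "\t")
      file.rename(tmp, file.path(outdir, paste0(nm, ".tsv")))
    }
  }
  list(spectra = spectra, comparisons = comparisons, coverage = coverage,
       config = cfg)
}
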