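#' Generate a random reference genome
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content, standing in
#' for a small bacterial reference at desk scale.
#'
#' @param length Genome length in bases (>= 1000).
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the sequence is deterministic given
#'   `(length, gc, seed)`.
#' @param name Sequence name used in FASTA/SAM headers.
#'
#' @return An object of class `ref_genome`: a list with elements `name`,
#'   `seq` (character scalar over A/C/G/T), `code` (integer encoding),
#'   `length`, `gc_target` and `gc` (realized GC fraction).
#' @examples
#' g <- make_genome(2000, 0.5, seed = 1)
#' g$gc
#' @export
make_genome <- function(length, gc, seed, name = "chrSim") {
  if (!is.numeric(length) || length < 1000) {
    stop_arg("`length` must be >= 1000 bases")
  }
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop_arg("`gc` must lie strictly between 0 and 1")
  }
  length <- as.integer(length)
  set.seed(as.integer(seed))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  code <- sample.int(4L, length, replace = TRUE, prob = p)
  g <- structure(
    list(
      name = name,
      seq = code_to_dna(code),
      code = code,
      length = length,
      gc_target = gc,
      gc = mean(code == 2L | code == 3L)
    ),
    class = "ref_genome"
  )
  g
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf(
    "<ref_genome> %s: %d bp, GC %.3f (target %.3f)\n",
    x$name, x$length, x$gc, x$gc_target
  ))
  invisible(x)
}

#' Write a reference genome to FASTA
#'
#' @param genome A `ref_genome`.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "ref_genome"))
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' Only the first sequence is used; the pipeline models a single replicon.
#'
#' @param path FASTA path.
#' @return A `ref_genome`.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop_arg("no sequences in FASTA: ", path)
  s <- toupper(as.character(x[[1]]))
  code <- dna_to_code(s)
  if (anyNA(code)) {
    ## tolerate Ns at read time but keep them out of the model
    stop_arg("reference contains non-ACGT characters: ", path)
  }
  structure(
    list(
      name = sub("\\s.*$", "", names(x)[1]),
      seq = s,
      code = code,
      length = nchar(s),
      gc_target = NA_real_,
      gc = mean(code == 2L | code == 3L)
    ),
    class = "ref_genome"
  )
}
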