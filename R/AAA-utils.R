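## Internal helpers: base encoding, complements, small distributions.
##
## Bases are encoded as integers 1=A, 2=C, 3=G, 4=T throughout the hot paths;
## the complement of code b is 5 - b.  N and anything non-ACGT maps to NA.

BASES <- c("A", "C", "G", "T")

.code_lookup <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x[utf8ToInt("a")] <- 1L; x[utf8ToInt("c")] <- 2L
  x[utf8ToInt("g")] <- 3L; x[utf8ToInt("t")] <- 4L
  x
})

## DNA string -> integer codes (vector input allowed; returns one vector for
## the concatenation -- callers track offsets)
dna_to_code <- function(s) {
  if (length(s) != 1L) s <- paste(s, collapse = "")
  .code_lookup[utf8ToInt(s)]
}

## integer codes -> DNA string; NA -> N
code_to_dna <- function(code) {
  ch <- c(65L, 67L, 71L, 84L)[code]          # A C G T
  ch[is.na(ch)] <- 78L                       # N
  intToUtf8(ch)
}

comp_code <- function(code) 5L - code

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

revcomp <- function(s) {
  vapply(s, function(x) {
    code_to_dna(rev(comp_code(dna_to_code(x))))
  }, character(1), USE.NAMES = FALSE)
}

## zero-truncated geometric on {1, 2, ...} with mean m (m >= 1)
rztgeom <- function(n, mean) {
  stopifnot(mean >= 1)
  if (mean == 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / mean)
}

## replace single characters inside a string at 1-based offsets
str_assign <- function(s, at, ch) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  v[at] <- ch
  paste(v, collapse = "")
}

## pick, for each row of a matrix of weights over ACGT, a base != ref
sample_other_base <- function(ref_code, n = length(ref_code)) {
  shift <- sample.int(3L, n, replace = TRUE)
  ((ref_code - 1L + shift) %% 4L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## write lines atomically: tmp file then rename
write_lines_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wb")
  closed <- FALSE
  on.exit(if (!closed) try(close(con), silent = TRUE), add = TRUE)
  writeLines(lines, con, sep = "\n")
  close(con)
  closed <- TRUE
  if (!file.rename(tmp, path)) {
    stop("failed to move temporary file onto ", path)
  }
  invisible(path)
}

stop_arg <- function(...) stop(..., call. = FALSE)
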