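# Low-level sequence and RNG helpers shared across modules.
# Sequences are plain uppercase ACGT character scalars internally; Biostrings
# objects appear only at I/O boundaries (fast substring/byte ops dominate).

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded package functions never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

#' Random DNA sequence
#' @param n length in bases.
#' @return character scalar of length-`n` uppercase DNA.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x character scalar (uppercase ACGTN).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

# byte vector of a string (A=65 C=67 G=71 T=84)
seq_bytes <- function(x) utf8ToInt(x)

# number of mismatching positions between equal-length strings
mismatch_count <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# 1-based offsets at which equal-length strings disagree
mismatch_positions <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(integer())
  which(utf8ToInt(a) != utf8ToInt(b))
}

# substitute bases at 1-based positions
substitute_bases <- function(seq, pos, base) {
  if (length(pos) == 0L) return(seq)
  b <- utf8ToInt(seq)
  b[pos] <- utf8ToInt(paste(base, collapse = ""))
  intToUtf8(b)
}

# a base different from `ref`, chosen uniformly (vectorized)
mutate_base <- function(ref) {
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), "")
  unname(alt)
}

# all k-mers of `seq` starting at `starts`
kmers_at <- function(seq, starts, k) substring(seq, starts, starts + k - 1L)

stop_if_not_scalar_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
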