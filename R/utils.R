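# internal helpers shared across modules

#' Reverse complement of a DNA string
#'
#' @param x single character string over A/C/G/T/N.
#' @return reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# split a DNA string into a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# split an in-frame DNA string into codons; errors unless length is 0 mod 3
codons_of <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# validate a sequence alphabet; ambiguity codes other than N are rejected
check_alphabet <- function(seq, allow_gap = FALSE, what = "sequence") {
  ok <- c("A", "C", "G", "T", "N", if (allow_gap) "-")
  bad <- setdiff(unique(chars(seq)), ok)
  if (length(bad) > 0L) {
    stop(what, " contains unsupported characters: ",
         paste(bad, collapse = ", "),
         " (only A/C/G/T/N", if (allow_gap) "/-", " are accepted)",
         call. = FALSE)
  }
  invisible(seq)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
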