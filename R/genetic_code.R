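#' Genetic code table with synonymous-family structure
#'
#' Builds a genetic code object from the NCBI translation table id, keyed for
#' codon-usage work: the codon to amino-acid map, the stop set, and the
#' synonymous families (codons sharing an amino acid) with their sizes.
#' The default, table 5, is the invertebrate mitochondrial code: TAA/TAG are
#' the only stops, TGA codes Trp, ATA codes Met and AGA/AGG code Ser, which
#' leaves 62 sense codons.
#'
#' @param id NCBI genetic code id (integer or string). Default 5.
#' @return an object of class `genetic_code`: list with `id`, `map` (named
#'   character vector codon -> one-letter amino acid, `"*"` for stops),
#'   `stops`, `sense` (sense codons), `families` (list amino acid -> codons)
#'   and `family_size` (named integer vector per sense codon).
#' @examples
#' code <- genetic_code(5)
#' length(code$sense)     # 62
#' code$map[["TGA"]]      # "W"
#' @export
genetic_code <- function(id = 5) {
  map <- Biostrings::getGeneticCode(as.character(id))
  names(map) <- toupper(chartr("U", "T", names(map)))
  stops <- names(map)[map == "*"]
  sense <- names(map)[map != "*"]
  families <- split(sense, map[sense])
  family_size <- setNames(
    vapply(map[sense], function(aa) length(families[[aa]]), integer(1)),
    sense
  )
  structure(
    list(id = as.integer(id), map = map, stops = stops, sense = sense,
         families = families, family_size = family_size),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$id, "—", length(x$sense), "sense codons,",
      length(x$stops), "stops (", paste(x$stops, collapse = ", "), ")\n")
  sizes <- table(vapply(x$families, length, integer(1)))
  cat("Synonymous family sizes:",
      paste(sprintf("%s x %s", sizes, names(sizes)), collapse = ", "), "\n")
  invisible(x)
}
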