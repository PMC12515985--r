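# GenBank flat-file input/output for annotated mitogenomes.
#
# Covers the subset of the format that mitogenome records use: LOCUS /
# ACCESSION / SOURCE-ORGANISM headers, a FEATURES table with CDS / tRNA /
# rRNA keys, `complement(...)` and `join(...)` locations (origin-spanning
# joins on circular genomes included), /gene, /product and /transl_table
# qualifiers, and the ORIGIN sequence block. GenBank's 1-based inclusive
# coordinates are kept as-is internally.

#' Read a GenBank flat file into a mito_genome
#'
#' Gene labels are normalized to the canonical 37-gene vocabulary via the
#' synonym table ([mito_gene_vocabulary()]); unknown labels are kept with
#' category unchanged but gene label `"other"` and a warning, not an error.
#' Ambiguity codes other than N in the sequence are rejected.
#'
#' @param path path to a GenBank flat file containing one record.
#' @return a [mito_genome].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path, call. = FALSE)

  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) {
    stop("malformed GenBank record: no LOCUS line (line 1: '",
         lines[1], "')", call. = FALSE)
  }
  locus <- lines[locus_i[1]]
  m <- regmatches(locus,
                  regexec("^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp", locus))[[1]]
  if (length(m) != 3L) {
    stop("malformed LOCUS line: '", locus, "'", call. = FALSE)
  }
  accession <- m[2]
  declared_len <- as.integer(m[3])
  topology <- if (grepl("circular", locus, ignore.case = TRUE)) {
    "circular"
  } else {
    "linear"
  }

  acc_i <- grep("^ACCESSION\\s+\\S", lines)
  if (length(acc_i) > 0L) {
    accession <- sub("^ACCESSION\\s+(\\S+).*$", "\\1", lines[acc_i[1]])
  }
  org_i <- grep("^\\s+ORGANISM\\s+", lines)
  organism <- if (length(org_i) > 0L) {
    sub("^\\s+ORGANISM\\s+", "", lines[org_i[1]])
  } else {
    "unknown"
  }

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) {
    stop("malformed GenBank record: no ORIGIN sequence block", call. = FALSE)
  }
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i) > 0L) end_i[end_i > origin_i[1]][1] else
    length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[0-9 \t]", "", paste(seq_lines, collapse = "")))
  sequence <- chartr("U", "T", sequence)
  if (!nzchar(sequence)) {
    stop("GenBank record has an empty sequence block", call. = FALSE)
  }
  check_alphabet(sequence, what = paste0("sequence of ", accession))
  if (nchar(sequence) != declared_len) {
    warning("LOCUS declares ", declared_len, " bp but ORIGIN holds ",
            nchar(sequence), " bp; using the ORIGIN length")
  }

  feat_i <- grep("^FEATURES", lines)
  features <- empty_feature_table()
  if (length(feat_i) > 0L) {
    fl <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    features <- parse_feature_block(fl, nchar(sequence))
  }
  mito_genome(sequence, features, accession = accession,
              organism = organism, topology = topology)
}

empty_feature_table <- function() {
  data.frame(gene = character(0), category = character(0),
             strand = character(0), codon_table = integer(0),
             label_raw = character(0),
             intervals = I(list()), stringsAsFactors = FALSE)
}

parse_feature_block <- function(fl, seqlen) {
  # a feature header has its key at column 6; continuations are indented to
  # column 22 (location continuations and /qualifier lines)
  is_header <- grepl("^ {5}\\S", fl)
  starts <- which(is_header)
  keep_keys <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")
  rows <- list()
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    i1 <- if (k < length(starts)) starts[k + 1L] - 1L else length(fl)
    key <- trimws(substr(fl[i0], 6, 20))
    body <- trimws(c(substr(fl[i0], 21, nchar(fl[i0])),
                     trimws(fl[seq_len(i1 - i0) + i0])))
    # location = leading lines up to the first /qualifier
    qual_at <- grep("^/", body)
    loc_end <- if (length(qual_at) > 0L) qual_at[1] - 1L else length(body)
    location <- paste(body[seq_len(loc_end)], collapse = "")
    quals <- parse_qualifiers(body[-seq_len(loc_end)])
    if (key %in% c("source", "gene", "misc_feature", "D-loop")) next
    category <- if (key %in% names(keep_keys)) keep_keys[[key]] else "other"

    loc <- parse_location(location, seqlen, key)
    raw <- quals[["gene"]] %||% quals[["product"]] %||% ""
    gene <- normalize_gene_label(raw)
    if (is.na(gene)) {
      if (nzchar(raw)) {
        warning("unknown gene label '", raw, "' kept as 'other'")
      }
      gene <- "other"
    }
    codon_table <- as.integer(quals[["transl_table"]] %||% "5")
    rows[[length(rows) + 1L]] <- list(
      gene = gene, category = category, strand = loc$strand,
      codon_table = codon_table, label_raw = raw, intervals = loc$intervals
    )
  }
  if (length(rows) == 0L) return(empty_feature_table())
  out <- data.frame(
    gene = vapply(rows, `[[`, "", "gene"),
    category = vapply(rows, `[[`, "", "category"),
    strand = vapply(rows, `[[`, "", "strand"),
    codon_table = vapply(rows, `[[`, 0L, "codon_table"),
    label_raw = vapply(rows, `[[`, "", "label_raw"),
    stringsAsFactors = FALSE
  )
  out$intervals <- I(lapply(rows, `[[`, "intervals"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_qualifiers <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

parse_location <- function(loc, seqlen, key = "feature") {
  s <- gsub("[<> \t]", "", loc)
  strand <- "H"
  if (grepl("^complement\\(", s)) {
    strand <- "L"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^(join|order)\\(", s)) {
    s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0L || any(!grepl("^\\d+(\\.\\.\\d+)?$", parts))) {
    stop("cannot parse ", key, " location '", loc, "'", call. = FALSE)
  }
  iv <- t(vapply(parts, function(p) {
    xy <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(xy) == 1L) xy <- c(xy, xy)
    xy
  }, integer(2)))
  dimnames(iv) <- list(NULL, c("start", "end"))
  if (any(iv[, 1] < 1L) || any(iv[, 2] > seqlen) || any(iv[, 1] > iv[, 2])) {
    stop(key, " location '", loc, "' is outside sequence bounds [1, ",
         seqlen, "]", call. = FALSE)
  }
  list(strand = strand, intervals = iv)
}

#' Write a mito_genome as a GenBank flat file
#'
#' Emits the subset of the format that [read_genbank()] consumes, so that a
#' write/read round trip preserves coordinates, strands and labels.
#'
#' @param genome a [mito_genome].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "mito_genome"))
  n <- nchar(genome$sequence)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", other = "misc_RNA")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %d bp    DNA     %s INV 01-JAN-2000",
            genome$accession, n, genome$topology))
  w("DEFINITION  ", genome$organism, " mitochondrion.")
  w("ACCESSION   ", genome$accession)
  w("SOURCE      ", genome$organism)
  w("  ORGANISM  ", genome$organism)
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     %-16s%s", "source", paste0("1..", n)))
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    iv <- f$intervals[[i]]
    loc <- paste(sprintf("%d..%d", iv[, 1], iv[, 2]), collapse = ",")
    if (nrow(iv) > 1L) loc <- paste0("join(", loc, ")")
    if (f$strand[i] == "L") loc <- paste0("complement(", loc, ")")
    w(sprintf("     %-16s%s", key_of[[f$category[i]]], loc))
    w(sprintf('                     /gene="%s"', f$gene[i]))
    if (nzchar(f$label_raw[i]) && f$label_raw[i] != f$gene[i]) {
      w(sprintf('                     /product="%s"', f$label_raw[i]))
    }
    if (f$category[i] == "PCG") {
      w(sprintf("                     /transl_table=%d", f$codon_table[i]))
    }
  }
  w("ORIGIN")
  s <- tolower(genome$sequence)
  for (pos in seq(1L, n, by = 60L)) {
    starts <- seq(pos, min(pos + 59L, n), by = 10L)
    blk <- substring(s, starts, pmin(starts + 9L, n))
    w(sprintf("%9d %s", pos, paste(blk, collapse = " ")))
  }
  w("//")
  invisible(path)
}
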