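# Canonical 37-gene mitochondrial vocabulary and synonym normalization.
# Published mitogenome records differ in gene naming (COI vs COX1, ND2 vs
# NAD2, 16S vs rrnL, trnL(CUN) vs trnL1 ...); everything is normalized to one
# canonical label set at parse time.

.mito_pcgs <- c("ATP6", "ATP8", "COX1", "COX2", "COX3", "CYTB",
                "NAD1", "NAD2", "NAD3", "NAD4", "NAD4L", "NAD5", "NAD6")

.mito_trnas <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnE", "trnQ",
                 "trnG", "trnH", "trnI", "trnK", "trnM", "trnF", "trnP",
                 "trnT", "trnW", "trnY", "trnV",
                 "trnL1", "trnL2", "trnS1", "trnS2")

.mito_rrnas <- c("rrnS", "rrnL")

#' Canonical mitochondrial gene vocabulary
#'
#' The 37 canonical gene labels used throughout the package: 13 protein-coding
#' genes, 22 tRNAs (Leu and Ser each twice: trnL1 = Leu(CUN), trnL2 =
#' Leu(UUR), trnS1 = Ser(AGN), trnS2 = Ser(UCN)) and 2 rRNAs.
#'
#' @return named list with elements `PCG`, `tRNA`, `rRNA`.
#' @export
mito_gene_vocabulary <- function() {
  list(PCG = .mito_pcgs, tRNA = .mito_trnas, rRNA = .mito_rrnas)
}

# amino-acid three-letter -> one-letter, for tRNA product labels
.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.gene_synonyms <- c(
  # cytochrome oxidase
  COI = "COX1", COII = "COX2", COIII = "COX3",
  CO1 = "COX1", CO2 = "COX2", CO3 = "COX3",
  COX1 = "COX1", COX2 = "COX2", COX3 = "COX3",
  COXI = "COX1", COXII = "COX2", COXIII = "COX3",
  # NADH dehydrogenase
  ND1 = "NAD1", ND2 = "NAD2", ND3 = "NAD3", ND4 = "NAD4",
  ND4L = "NAD4L", ND5 = "NAD5", ND6 = "NAD6",
  NAD1 = "NAD1", NAD2 = "NAD2", NAD3 = "NAD3", NAD4 = "NAD4",
  NAD4L = "NAD4L", NAD5 = "NAD5", NAD6 = "NAD6",
  NADH1 = "NAD1", NADH2 = "NAD2", NADH3 = "NAD3", NADH4 = "NAD4",
  NADH4L = "NAD4L", NADH5 = "NAD5", NADH6 = "NAD6",
  # ATP synthase
  ATP6 = "ATP6", ATP8 = "ATP8", ATPASE6 = "ATP6", ATPASE8 = "ATP8",
  # cytochrome b
  CYTB = "CYTB", COB = "CYTB", CYB = "CYTB", CTYB = "CYTB",
  # rRNAs
  RRNS = "rrnS", RRNL = "rrnL", `12S` = "rrnS", `16S` = "rrnL",
  `12SRRNA` = "rrnS", `16SRRNA` = "rrnL",
  `S-RRNA` = "rrnS", `L-RRNA` = "rrnL", SRRNA = "rrnS", LRRNA = "rrnL",
  `12SRIBOSOMALRNA` = "rrnS", `16SRIBOSOMALRNA` = "rrnL",
  SMALLSUBUNITRIBOSOMALRNA = "rrnS", LARGESUBUNITRIBOSOMALRNA = "rrnL"
)

# normalize one raw gene/product label to the canonical vocabulary; returns
# NA_character_ when unknown
normalize_gene_label <- function(label) {
  if (!is_string(label) || !nzchar(label)) return(NA_character_)
  key <- toupper(gsub("[ _]", "", label))
  if (key %in% names(.gene_synonyms)) {
    return(unname(.gene_synonyms[[key]]))
  }
  # tRNA spellings: trnK, tRNA-Lys, trnL1, trnL(CUN), trnL-CUN, tRNA-Leu (CUN)
  # one-letter forms first: trnK, trnL1, trnS2 (note trnA itself uppercases
  # to TRNA, which the prefix rule below would swallow)
  m1 <- regmatches(key, regexec("^TRN([A-Z])([12])?$", key))[[1]]
  if (length(m1) > 0L) {
    cand <- paste0("trn", m1[2], m1[3])
    if (cand %in% .mito_trnas) return(cand)
  }
  if (grepl("^TRNA?-?", key)) {
    body <- sub("^TRNA?-?", "", key)
    anticodon <- NA_character_
    m <- regmatches(body, regexec("\\(?([ACGU]{3})\\)?$", body))[[1]]
    if (length(m) == 2L && !body %in% names(.aa3to1)) {
      anticodon <- m[2]
      body <- sub("[-(]?[ACGU]{3}\\)?$", "", body)
    }
    aa <- if (body %in% names(.aa3to1)) {
      unname(.aa3to1[[body]])
    } else if (nchar(body) %in% c(1L, 2L) &&
               substr(body, 1, 1) %in% .aa3to1) {
      body  # already one-letter, maybe with 1/2 suffix
    } else {
      NA_character_
    }
    if (is.na(aa)) return(NA_character_)
    if (aa %in% c("L", "S") && nchar(aa) == 1L) {
      # disambiguate the duplicated Leu/Ser tRNAs from the anticodon
      if (!is.na(anticodon)) {
        aa <- switch(paste0(aa, ":", anticodon),
                     # Leu(CUN) family anticodon UAG; Leu(UUR) anticodon UAA
                     "L:UAG" = "L1", "L:CUN" = "L1",
                     "L:UAA" = "L2", "L:UUR" = "L2",
                     # Ser(AGN) anticodon UCU/GCU; Ser(UCN) anticodon UGA
                     "S:GCU" = "S1", "S:UCU" = "S1", "S:AGN" = "S1",
                     "S:UGA" = "S2", "S:UCN" = "S2",
                     aa)
      }
      if (nchar(aa) == 1L) return(NA_character_)  # ambiguous without number
    }
    cand <- paste0("trn", aa)
    if (cand %in% .mito_trnas) return(cand)
    return(NA_character_)
  }
  NA_character_
}

# category implied by a canonical label
gene_category <- function(gene) {
  ifelse(gene %in% .mito_pcgs, "PCG",
         ifelse(gene %in% .mito_trnas, "tRNA",
                ifelse(gene %in% .mito_rrnas, "rRNA", "other")))
}
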