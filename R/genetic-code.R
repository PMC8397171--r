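#' Genetic code with synonymous codon families
#'
#' Builds a codon table plus the synonymous-family partition used for RSCU
#' and codons-per-thousand statistics. The default is NCBI translation
#' table 5 (invertebrate mitochondrial: ATA = Met, TGA = Trp, AGA/AGG = Ser).
#' Leucine is split into the Leu1 (CTN) and Leu2 (TTR) families and serine
#' into Ser1 (AGN) and Ser2 (TCN), the conventional presentation for
#' mitochondrial codon-usage plots.
#'
#' @param table_id NCBI genetic-code table number (default 5).
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `codons` (named character vector mapping all 64 codons, DNA alphabet,
#'   to one-letter amino acids with `*` for stops), `stops` (stop codons),
#'   and `families` (named list partitioning the sense codons).
#' @examples
#' gc5 <- genetic_code()
#' gc5$codons[["TGA"]]   # "W" under the invertebrate mitochondrial code
#' gc5$families$Leu1     # CTT CTC CTA CTG
#' @export
genetic_code <- function(table_id = 5) {
  tbl <- Biostrings::getGeneticCode(as.character(table_id))
  codons <- as.character(tbl)
  names(codons) <- names(tbl)
  stops <- names(codons)[codons == "*"]
  sense <- codons[codons != "*"]

  aa3 <- c(F = "Phe", L = "Leu", I = "Ile", M = "Met", V = "Val",
           S = "Ser", P = "Pro", T = "Thr", A = "Ala", Y = "Tyr",
           H = "His", Q = "Gln", N = "Asn", K = "Lys", D = "Asp",
           E = "Glu", C = "Cys", W = "Trp", R = "Arg", G = "Gly")
  fam_of <- function(codon) {
    aa <- sense[[codon]]
    if (aa == "L") {
      if (substr(codon, 1, 2) == "CT") "Leu1" else "Leu2"
    } else if (aa == "S") {
      if (substr(codon, 1, 2) == "AG") "Ser1" else "Ser2"
    } else {
      aa3[[aa]]
    }
  }
  fams <- vapply(names(sense), fam_of, character(1))
  families <- split(names(sense), fams)

  structure(
    list(table_id = table_id, codons = codons, stops = stops,
         families = families),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$table_id, "-", length(x$families),
      "synonymous families,", length(x$stops), "stop codons\n")
  invisible(x)
}

# family name for each codon, NA for stops
codon_family <- function(code, codons) {
  fam <- rep(NA_character_, length(codons))
  for (f in names(code$families)) {
    fam[codons %in% code$families[[f]]] <- f
  }
  fam
}
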