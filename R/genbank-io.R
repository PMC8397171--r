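# Minimal GenBank flat-file reader/writer for annotated mitogenomes.
# Covers the subset this pipeline emits: a single circular record with
# CDS/tRNA/rRNA/D-loop features, plain or complement() locations, and an
# optional ORIGIN block. join() and wrap-spanning locations are rejected.

gb_feature_keys <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")

#' Read a GenBank flat file into a mitogenome record
#'
#' @param path GenBank flat-file path.
#' @param species optional species label; defaults to the ORGANISM/LOCUS
#'   name in the file.
#' @return a [mito_record()]; `sequence` is NULL when the file has no
#'   ORIGIN block.
#' @export
read_genbank <- function(path, species = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("not a GenBank flat file: no LOCUS line")
  locus_fields <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  glen <- suppressWarnings(as.integer(locus_fields[3]))
  if (is.null(species)) {
    org <- grep("^\\s+ORGANISM", lines, value = TRUE)
    species <- if (length(org) > 0) trimws(sub("^\\s+ORGANISM", "", org[1]))
               else locus_fields[2]
  }

  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0) stop("no FEATURES block")
  origin_at <- grep("^ORIGIN", lines)
  feat_end <- if (length(origin_at) > 0) origin_at[1] - 1 else {
    slashes <- grep("^//", lines)
    if (length(slashes) > 0) slashes[1] - 1 else length(lines)
  }
  fl <- lines[(feat_start[1] + 1):feat_end]

  # feature header lines start at column 6; qualifiers are indented further
  hdr <- grepl("^\\s{1,10}\\S+\\s+\\S", fl) & !grepl("^\\s*/", fl) &
         grepl("[0-9]", fl)
  key <- sub("^\\s*(\\S+)\\s+.*$", "\\1", fl)
  is_feat <- hdr & key %in% c(gb_feature_keys, "gene", "source")

  idx <- which(is_feat)
  feats <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    j <- if (k < length(idx)) idx[k + 1] - 1 else length(fl)
    this_key <- key[i]
    if (this_key %in% c("source", "gene")) next  # gene lines duplicate CDS/tRNA
    loc <- sub("^\\s*\\S+\\s+", "", fl[i])
    if (grepl("join|order", loc)) {
      stop("join()/multi-segment locations are not supported (feature '",
           this_key, " ", loc, "')")
    }
    strand <- "F"
    if (grepl("^complement\\(", loc)) {
      strand <- "R"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1]]
    if (length(m) != 3) stop("cannot parse location '", loc, "'")
    quals <- fl[(i + 1):j][grepl("^\\s*/", fl[(i + 1):j])]
    getq <- function(name) {
      hit <- grep(paste0("^\\s*/", name, "="), quals, value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      gsub("\"", "", sub(paste0("^\\s*/", name, "="), "", trimws(hit[1])))
    }
    gene <- getq("gene")
    if (is.na(gene) && this_key == "D-loop") gene <- "control_region"
    if (is.na(gene)) gene <- getq("product")
    if (is.na(gene)) stop("feature without /gene or /product qualifier")
    feats[[length(feats) + 1]] <- list(
      gene = gene, strand = strand,
      start = as.integer(m[2]), end = as.integer(m[3]),
      anticodon = getq("anticodon_seq"),
      anticodon_start = suppressWarnings(as.numeric(getq("anticodon_start"))),
      anticodon_end = suppressWarnings(as.numeric(getq("anticodon_end"))),
      start_codon = getq("start_codon"), stop_codon = getq("stop_codon"))
  }
  if (length(feats) == 0) stop("no features found")
  gene <- canonical_gene_name(vapply(feats, `[[`, "", "gene"))
  features <- data.frame(
    gene = gene,
    category = gene_category(gene),
    strand = vapply(feats, `[[`, "", "strand"),
    start = vapply(feats, `[[`, 0L, "start"),
    end = vapply(feats, `[[`, 0L, "end"),
    size_declared = NA_real_,
    anticodon = vapply(feats, `[[`, "", "anticodon"),
    anticodon_start = vapply(feats, function(x)
      if (is.null(x$anticodon_start)) NA_real_ else x$anticodon_start, 0),
    anticodon_end = vapply(feats, function(x)
      if (is.null(x$anticodon_end)) NA_real_ else x$anticodon_end, 0),
    start_codon = vapply(feats, `[[`, "", "start_codon"),
    stop_codon = vapply(feats, `[[`, "", "stop_codon"),
    ign_declared = NA_real_,
    stringsAsFactors = FALSE
  )
  features <- features[order(features$start), , drop = FALSE]

  sequence <- NULL
  if (length(origin_at) > 0) {
    endrec <- grep("^//", lines)
    endrec <- if (length(endrec) > 0) endrec[1] - 1 else length(lines)
    seq_lines <- lines[(origin_at[1] + 1):endrec]
    sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines,
                                                        collapse = "")))
    if (!is.na(glen) && nchar(sequence) != glen) {
      stop("ORIGIN sequence length ", nchar(sequence),
           " disagrees with LOCUS length ", glen)
    }
  }
  glen_eff <- if (!is.na(glen)) glen else max(features$end)
  ann <- mito_annotation(species, features, genome_length = glen_eff)
  mito_record(ann, sequence)
}

#' Write a mitogenome record as a GenBank flat file
#'
#' @param rec a `mito_record`.
#' @param path output path.
#' @param locus_name LOCUS identifier (defaults to a species-derived slug).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(rec, path, locus_name = NULL) {
  ann <- rec$annotation
  if (is.null(locus_name)) {
    locus_name <- gsub("[^A-Za-z0-9]", "_", ann$species)
  }
  out <- c(sprintf("LOCUS       %s %d bp    DNA     circular INV",
                   locus_name, ann$genome_length),
           sprintf("DEFINITION  %s mitochondrion, complete genome.",
                   ann$species),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", ann$genome_length))
  f <- ann$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$category[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control = "D-loop")
    loc <- paste0(f$start[i], "..", f$end[i])
    if (f$strand[i] == "R") loc <- paste0("complement(", loc, ")")
    out <- c(out, sprintf("     %-15s %s", key, loc),
             sprintf("                     /gene=\"%s\"", f$gene[i]))
    if (!is.na(f$anticodon[i])) {
      out <- c(out,
        sprintf("                     /anticodon_seq=\"%s\"", f$anticodon[i]),
        sprintf("                     /anticodon_start=%d",
                as.integer(f$anticodon_start[i])),
        sprintf("                     /anticodon_end=%d",
                as.integer(f$anticodon_end[i])))
    }
    if (!is.na(f$start_codon[i])) {
      out <- c(out, sprintf("                     /start_codon=\"%s\"",
                            f$start_codon[i]))
    }
    if (!is.na(f$stop_codon[i])) {
      out <- c(out, sprintf("                     /stop_codon=\"%s\"",
                            f$stop_codon[i]))
    }
  }
  if (!is.null(rec$sequence)) {
    out <- c(out, "ORIGIN")
    s <- tolower(rec$sequence)
    n <- nchar(s)
    for (pos in seq(1, n, by = 60)) {
      chunk <- substr(s, pos, min(pos + 59, n))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", pos, paste(blocks, collapse = " ")))
    }
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Write per-gene FASTA
#'
#' Extracts the sense-strand sequence of each requested feature and writes
#' a FASTA file via Biostrings.
#'
#' @param rec a `mito_record` with sequence.
#' @param path output FASTA path.
#' @param genes canonical gene names (default: all features).
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(rec, path, genes = NULL) {
  if (is.null(genes)) genes <- rec$annotation$features$gene
  seqs <- vapply(genes, function(g) feature_sequence(rec, g), character(1))
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- genes
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_seqs <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(xs)), names(xs))
}
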