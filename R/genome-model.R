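#' @importFrom utils read.delim write.table read.csv head tail
#' @importFrom stats setNames as.dist aggregate uniroot reorder
NULL

.lepmito_env <- new.env(parent = emptyenv())

# canonical 37-gene set + control region
.PCG_ORDER <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
                "nad5", "nad4", "nad4L", "nad6", "cob", "nad1")

gene_synonym_map <- function() {
  if (is.null(.lepmito_env$synonyms)) {
    path <- system.file("extdata", "gene_synonyms.csv", package = "lepmito")
    syn <- read.csv(path, stringsAsFactors = FALSE)
    .lepmito_env$synonyms <- setNames(syn$canonical, syn$synonym)
  }
  .lepmito_env$synonyms
}

#' Canonicalize mitochondrial gene names
#'
#' Maps common aliases (COI, ND2, lrRNA, D-loop, trnL(CUN), ...) onto the
#' canonical identifiers used throughout the package (cox1, nad2, rrnL,
#' control_region, trnL1, ...). Unknown names are an error: a silently
#' misjoined gene would corrupt every downstream stage, the supermatrix
#' above all.
#'
#' @param x character vector of gene labels.
#' @return character vector of canonical names.
#' @export
canonical_gene_name <- function(x) {
  syn <- gene_synonym_map()
  key <- trimws(gsub("\\*", "", x))
  # collapse internal whitespace, tolerate "trnL2 (UUR)" spacing
  key <- gsub("\\s+\\(", "(", key)
  out <- syn[key]
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop("unknown gene name(s): ", paste(bad, collapse = ", "),
         "; accepted names include: ",
         paste(head(unique(names(syn)), 20), collapse = ", "), ", ...",
         call. = FALSE)
  }
  unname(out)
}

#' @rdname canonical_gene_name
#' @export
gene_category <- function(x) {
  ifelse(grepl("^trn", x), "tRNA",
         ifelse(grepl("^rrn", x), "rRNA",
                ifelse(x == "control_region", "control", "PCG")))
}

#' Construct a mitogenome annotation
#'
#' The unit of all accounting: an ordered list of features on a circular
#' genome, in 1-based inclusive forward-strand coordinates. Reverse-strand
#' ("R") features are stored in the same coordinate system; only sequence
#' extraction reverse-complements.
#'
#' @param species free-text species label.
#' @param features data.frame with columns `gene`, `category`, `strand`,
#'   `start`, `end` and optionally `size_declared`, `anticodon`,
#'   `anticodon_start`, `anticodon_end`, `start_codon`, `stop_codon`,
#'   `ign_declared`.
#' @param genome_length genome size in bp; defaults to `max(end)`.
#' @param circular logical, default TRUE.
#' @return object of class `mito_annotation`.
#' @export
mito_annotation <- function(species, features, genome_length = NULL,
                            circular = TRUE) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  opt <- c("size_declared", "anticodon", "anticodon_start", "anticodon_end",
           "start_codon", "stop_codon", "ign_declared")
  for (col in opt) {
    if (is.null(features[[col]])) {
      features[[col]] <- if (col %in% c("anticodon", "start_codon",
                                        "stop_codon")) NA_character_
                         else NA_real_
    }
  }
  if (any(features$end < features$start)) {
    stop("feature with end < start (wrap-spanning features are not supported)")
  }
  if (is.null(genome_length)) genome_length <- max(features$end)
  if (genome_length < max(features$end)) {
    stop("genome_length (", genome_length, ") smaller than max feature end (",
         max(features$end), ")")
  }
  rownames(features) <- NULL
  structure(
    list(species = species, genome_length = as.integer(genome_length),
         circular = circular, features = features),
    class = "mito_annotation"
  )
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat("Mitogenome annotation:", x$species, "-", x$genome_length, "bp,",
      nrow(x$features), "features",
      if (x$circular) "(circular)" else "(linear)", "\n")
  tab <- table(x$features$category)
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Computed feature sizes
#'
#' @param ann a `mito_annotation`.
#' @return integer vector `end - start + 1`, named by gene.
#' @export
feature_sizes <- function(ann) {
  setNames(as.integer(ann$features$end - ann$features$start + 1),
           ann$features$gene)
}

#' Attach a sequence to an annotation
#'
#' @param annotation a `mito_annotation`.
#' @param sequence single nucleotide string over A,C,G,T,N (forward /
#'   majority strand), or NULL for an annotation-only record.
#' @return object of class `mito_record`.
#' @export
mito_record <- function(annotation, sequence = NULL) {
  stopifnot(inherits(annotation, "mito_annotation"))
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != annotation$genome_length) {
      stop("sequence length (", nchar(sequence),
           ") != genome_length (", annotation$genome_length, ")")
    }
    if (grepl("[^ACGTN]", sequence)) {
      stop("sequence contains characters outside A,C,G,T,N")
    }
  }
  structure(list(annotation = annotation, sequence = sequence),
            class = "mito_record")
}

#' @export
print.mito_record <- function(x, ...) {
  print(x$annotation)
  cat("  sequence:",
      if (is.null(x$sequence)) "absent" else paste0(nchar(x$sequence), " bp"),
      "\n")
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# "1-68", "10,442-11,593", en-dash tolerated
parse_location <- function(loc, row_label = loc) {
  clean <- gsub(",", "", trimws(loc))
  clean <- gsub("–", "-", clean)  # en-dash
  m <- regmatches(clean, regexec("^([0-9]+)-([0-9]+)$", clean))[[1]]
  if (length(m) != 3) {
    stop("malformed location '", loc, "' in row '", row_label, "'",
         call. = FALSE)
  }
  c(start = as.integer(m[2]), end = as.integer(m[3]))
}

parse_anticodon <- function(x, row_label = x) {
  x <- trimws(x)
  if (is.na(x) || x == "") {
    return(list(anticodon = NA_character_, start = NA_real_, end = NA_real_))
  }
  clean <- gsub(",", "", x)
  clean <- gsub("–", "-", clean)
  m <- regmatches(clean,
                  regexec("^([ACGTU]{3})\\s*([0-9]+)-([0-9]+)$", clean))[[1]]
  if (length(m) != 4) {
    stop("malformed anticodon '", x, "' in row '", row_label, "'",
         call. = FALSE)
  }
  list(anticodon = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Read an annotation feature table
#'
#' Reads the tab-separated annotation layout conventional for published
#' mitogenome descriptions: columns gene, direction, location
#' ("start-end", thousands separators tolerated), size, anticodon
#' ("NNN start-end"), start codon, stop codon, intergenic nucleotides.
#' The declared size and intergenic-nucleotide columns are retained for
#' cross-checking ([validate_annotation()]) but never drive computation.
#'
#' @param path TSV file path.
#' @param species species label for the annotation.
#' @param genome_length genome size in bp; defaults to the maximum feature
#'   end coordinate.
#' @return a [mito_annotation()].
#' @examples
#' tsv <- system.file("extdata", "hestina_persimilis_features.tsv",
#'                    package = "lepmito")
#' ann <- read_feature_table(tsv, species = "Hestina persimilis")
#' ann$genome_length   # 15252
#' @export
read_feature_table <- function(path, species, genome_length = NULL) {
  raw <- read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                    colClasses = "character")
  need <- c("gene", "direction", "location", "size", "anticodon",
            "start_codon", "stop_codon", "intergenic_nucleotides")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("feature table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  gene <- canonical_gene_name(raw$gene)
  if (anyDuplicated(gene)) {
    stop("duplicate gene name(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  locs <- t(vapply(seq_len(n),
                   function(i) parse_location(raw$location[i], raw$gene[i]),
                   c(start = 0L, end = 0L)))
  acs <- lapply(seq_len(n),
                function(i) parse_anticodon(raw$anticodon[i], raw$gene[i]))
  num_or_na <- function(x) {
    x <- gsub(",", "", trimws(x))
    x <- gsub("−", "-", x)  # unicode minus
    suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  }
  chr_or_na <- function(x) {
    x <- trimws(x)
    ifelse(is.na(x) | x == "", NA_character_, x)
  }
  strand <- toupper(trimws(raw$direction))
  strand[strand == ""] <- "F"  # control-region rows carry no direction
  if (!all(strand %in% c("F", "R"))) {
    stop("direction column must be F or R")
  }
  features <- data.frame(
    gene = gene,
    category = gene_category(gene),
    strand = strand,
    start = locs[, "start"],
    end = locs[, "end"],
    size_declared = num_or_na(raw$size),
    anticodon = vapply(acs, `[[`, "", "anticodon"),
    anticodon_start = vapply(acs, `[[`, 0, "start"),
    anticodon_end = vapply(acs, `[[`, 0, "end"),
    start_codon = chr_or_na(raw$start_codon),
    stop_codon = chr_or_na(raw$stop_codon),
    ign_declared = num_or_na(raw$intergenic_nucleotides),
    stringsAsFactors = FALSE
  )
  mito_annotation(species, features, genome_length = genome_length)
}

# display label used when serializing canonical names back to table form
display_gene_name <- function(x) {
  deco <- c(trnL1 = "trnL1(CUN)", trnL2 = "trnL2(UUR)",
            trnS1 = "trnS1(AGN)", trnS2 = "trnS2(UCN)",
            control_region = "Control region")
  ifelse(x %in% names(deco), deco[x], x)
}

#' Write an annotation feature table
#'
#' Inverse of [read_feature_table()]: emits the same eight columns so that
#' a parse/serialize round trip preserves every field.
#'
#' @param ann a `mito_annotation`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ann, path) {
  f <- ann$features
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, scientific = FALSE,
                                                     trim = TRUE))
  fmt_chr <- function(x) ifelse(is.na(x), "", x)
  out <- data.frame(
    gene = display_gene_name(f$gene),
    direction = ifelse(f$category == "control", "", f$strand),
    location = paste0(f$start, "-", f$end),
    size = fmt_num(f$size_declared),
    anticodon = ifelse(is.na(f$anticodon), "",
                       paste0(f$anticodon, " ", fmt_num(f$anticodon_start),
                              "-", fmt_num(f$anticodon_end))),
    start_codon = fmt_chr(f$start_codon),
    stop_codon = fmt_chr(f$stop_codon),
    intergenic_nucleotides = fmt_num(f$ign_declared),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an annotation against its own declared columns
#'
#' Surfaces internal inconsistencies in a published annotation table:
#' declared sizes that disagree with the coordinates, anticodon positions
#' outside their gene span, tRNAs lacking an anticodon, and same-strand
#' protein-gene overlaps other than the metazoan-canonical pairs
#' (atp8/atp6, atp6/cox3, nad4L/nad4), which are genuine shared sequence
#' rather than annotation error. The validator reports and never raises.
#'
#' @param ann a `mito_annotation`.
#' @return data.frame with columns `gene`, `type`, `detail`; zero rows
#'   means the annotation is internally consistent.
#' @export
validate_annotation <- function(ann) {
  f <- ann$features
  reports <- list()
  add <- function(gene, type, detail) {
    reports[[length(reports) + 1]] <<- data.frame(
      gene = gene, type = type, detail = detail, stringsAsFactors = FALSE)
  }
  size_comp <- f$end - f$start + 1
  for (i in seq_len(nrow(f))) {
    if (is.na(f$size_declared[i])) {
      add(f$gene[i], "size_missing", "no declared size to check")
    } else if (f$size_declared[i] != size_comp[i]) {
      add(f$gene[i], "size_mismatch",
          paste0("declared ", f$size_declared[i], " vs computed ",
                 size_comp[i]))
    }
    if (!is.na(f$anticodon[i])) {
      if (f$anticodon_start[i] < f$start[i] ||
          f$anticodon_end[i] > f$end[i]) {
        add(f$gene[i], "anticodon_outside",
            paste0("anticodon at ", f$anticodon_start[i], "-",
                   f$anticodon_end[i], " outside gene span ",
                   f$start[i], "-", f$end[i]))
      }
    } else if (f$category[i] == "tRNA") {
      add(f$gene[i], "anticodon_missing", "tRNA without anticodon")
    }
    if (f$category[i] == "PCG" &&
        (is.na(f$start_codon[i]) || is.na(f$stop_codon[i]))) {
      add(f$gene[i], "codon_missing", "PCG without start/stop codon")
    }
  }
  # same-strand PCG overlaps outside the canonical overlapping pairs
  canonical_pairs <- list(c("atp8", "atp6"), c("atp6", "cox3"),
                          c("nad4L", "nad4"), c("nad4", "nad4L"))
  pcg <- f[f$category == "PCG", , drop = FALSE]
  if (nrow(pcg) >= 2) {
    pcg <- pcg[order(pcg$start), , drop = FALSE]
    for (i in seq_len(nrow(pcg) - 1)) {
      for (j in (i + 1):nrow(pcg)) {
        if (pcg$start[j] <= pcg$end[i] &&
            pcg$strand[i] == pcg$strand[j]) {
          pair <- c(pcg$gene[i], pcg$gene[j])
          is_canon <- any(vapply(canonical_pairs,
                                 function(p) all(p == pair) ||
                                   all(p == rev(pair)),
                                 logical(1)))
          if (!is_canon) {
            add(pcg$gene[i], "pcg_overlap",
                paste0("same-strand PCG overlap with ", pcg$gene[j]))
          }
        }
      }
    }
  }
  if (length(reports) == 0) {
    return(data.frame(gene = character(), type = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, reports)
}

#' Extract the sense-strand sequence of one feature
#'
#' Forward-strand ("F") features return the genomic slice as-is;
#' reverse-strand ("R") features return the reverse complement, i.e. the
#' sequence as read by the gene.
#'
#' @param rec a `mito_record` with sequence.
#' @param name canonical gene name.
#' @return nucleotide string of length `end - start + 1`.
#' @export
feature_sequence <- function(rec, name) {
  if (is.null(rec$sequence)) stop("record has no sequence")
  f <- rec$annotation$features
  i <- match(name, f$gene)
  if (is.na(i)) stop("no feature named '", name, "'")
  s <- substr(rec$sequence, f$start[i], f$end[i])
  if (f$strand[i] == "R") revcomp(s) else s
}

#' Serialize an annotation to JSON
#'
#' @param ann a `mito_annotation`.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
annotation_to_json <- function(ann, path = NULL) {
  obj <- list(species = ann$species, genome_length = ann$genome_length,
              circular = ann$circular, features = ann$features)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
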