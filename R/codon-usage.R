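# Codon extraction and usage statistics (RSCU, codons per thousand) over
# the 13 mitochondrial protein-coding genes.

#' Split a protein-coding gene into codons
#'
#' The sense-strand sequence is split into consecutive triplets. A trailing
#' 1- or 2-nt remainder is reported as a truncated stop ("T" or "TA",
#' completed to TAA by transcript polyadenylation) and excluded from the
#' codon list. The final complete triplet is classified as the stop codon
#' when it is TAA or TAG. The first triplet is the start codon; it is
#' flagged non-canonical unless it matches ATN, or CGA for cox1 (the usual
#' lepidopteran cox1 initiation codon).
#'
#' @param rec a `mito_record` with sequence.
#' @param gene canonical PCG name.
#' @param code a [genetic_code()] (used to locate in-frame internal stops).
#' @return list with `codons` (all complete triplets, in reading order),
#'   `start_codon`, `start_canonical`, `stop_codon` (complete stop triplet
#'   or NA), `truncated_stop` ("" / "T" / "TA"), and `internal_stops`
#'   (1-based codon indices of in-frame stops before the final triplet).
#' @examples
#' rec <- simulate_mitogenome(genome_template(seed = 1))$record
#' cx2 <- extract_codons(rec, "cox2")
#' cx2$truncated_stop   # "T": cox2 ends on an incomplete codon
#' @export
extract_codons <- function(rec, gene, code = genetic_code()) {
  f <- rec$annotation$features
  i <- match(gene, f$gene)
  if (is.na(i)) stop("no feature named '", gene, "'")
  if (f$category[i] != "PCG") stop("'", gene, "' is not a protein-coding gene")
  s <- feature_sequence(rec, gene)
  n <- nchar(s)
  if (n < 6) stop("gene '", gene, "' too short to contain codons (", n, " nt)")
  k <- n %/% 3
  rem <- n %% 3
  codons <- substring(s, 3 * seq_len(k) - 2, 3 * seq_len(k))
  truncated <- if (rem > 0) substr(s, 3 * k + 1, n) else ""
  start_codon <- codons[1]
  start_canonical <- grepl("^AT[ACGT]$", start_codon) ||
    (gene == "cox1" && start_codon == "CGA")
  stop_codon <- NA_character_
  if (rem == 0 && codons[k] %in% code$stops) stop_codon <- codons[k]
  body_end <- if (!is.na(stop_codon)) k - 1 else k
  internal <- which(codons[seq_len(body_end)] %in% code$stops)
  internal <- internal[internal > 1]
  list(codons = codons, start_codon = start_codon,
       start_canonical = start_canonical, stop_codon = stop_codon,
       truncated_stop = truncated, internal_stops = internal)
}

#' Pooled codon usage over the 13 protein-coding genes
#'
#' Counts codons pooled over all 13 PCGs of each record and derives RSCU
#' (relative synonymous codon usage: observed count divided by the
#' expected count under uniform usage within the synonymous family) and
#' codons-per-thousand per family. By default the start codon is counted
#' and the classified stop triplet is not; a non-ATN cox1 initiation codon
#' (CGA) is counted in the total but withheld from its RSCU family, since
#' an initiation codon read as arginine would distort the Arg family.
#' Codons containing N are skipped.
#'
#' @param recs list of `mito_record` objects (or a single record).
#' @param code a [genetic_code()].
#' @param include_start count the first codon of each gene (default TRUE).
#' @param include_stop count the classified stop triplet (default FALSE).
#' @return list of `codon_usage` objects, one per species, each with
#'   `species`, `counts` (named over sense codons), `total_codons`, `rscu`
#'   (NA for families with zero total), and `cdspt` (family
#'   codons-per-thousand summing to 1000).
#' @export
codon_usage <- function(recs, code = genetic_code(), include_start = TRUE,
                        include_stop = FALSE) {
  if (inherits(recs, "mito_record")) recs <- list(recs)
  lapply(recs, function(rec) {
    if (is.null(rec$sequence)) {
      stop("species '", rec$annotation$species, "' has no sequence")
    }
    f <- rec$annotation$features
    have <- f$gene[f$category == "PCG"]
    missing_pcg <- setdiff(.PCG_ORDER, have)
    if (length(missing_pcg) > 0) {
      stop("species '", rec$annotation$species, "' missing PCG(s): ",
           paste(missing_pcg, collapse = ", "))
    }
    sense <- names(code$codons)[!(names(code$codons) %in% code$stops)]
    counts <- setNames(integer(length(sense)), sense)
    # counts entering RSCU families (non-canonical starts withheld)
    fam_counts <- counts
    for (g in .PCG_ORDER) {
      ec <- extract_codons(rec, g, code)
      keep <- ec$codons
      if (!is.na(ec$stop_codon) && !include_stop) {
        keep <- keep[-length(keep)]
      }
      if (!include_start) keep <- keep[-1]
      keep <- keep[!grepl("N", keep)]
      keep <- keep[!(keep %in% code$stops)]  # in-frame stops never counted
      tb <- table(keep)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
      fam_keep <- keep
      if (include_start && !ec$start_canonical ||
          (include_start && g == "cox1" && ec$start_codon == "CGA")) {
        # withhold the initiation codon from its synonymous family
        drop_at <- match(ec$start_codon, fam_keep)
        if (!is.na(drop_at)) fam_keep <- fam_keep[-drop_at]
      }
      tb2 <- table(fam_keep)
      fam_counts[names(tb2)] <- fam_counts[names(tb2)] + as.integer(tb2)
    }
    total <- sum(counts)
    fam <- codon_family(code, sense)
    rscu <- setNames(rep(NA_real_, length(sense)), sense)
    cdspt <- setNames(numeric(length(code$families)), names(code$families))
    for (fname in names(code$families)) {
      members <- code$families[[fname]]
      fam_total <- sum(fam_counts[members])
      if (fam_total > 0) {
        rscu[members] <- fam_counts[members] * length(members) / fam_total
      }
      cdspt[fname] <- 1000 * sum(counts[members]) / total
    }
    structure(
      list(species = rec$annotation$species, counts = counts,
           total_codons = total, rscu = rscu, cdspt = cdspt,
           include_start = include_start, include_stop = include_stop),
      class = "codon_usage"
    )
  })
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("Codon usage:", x$species, "-", x$total_codons, "codons;",
      "top families (per thousand):\n")
  top <- sort(x$cdspt, decreasing = TRUE)[1:5]
  cat(" ", paste(names(top), round(top, 1), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Comparative codon-usage panel
#'
#' Assembles per-species usage tables into a codon x species RSCU matrix,
#' lists each species' unused sense codons, and ranks codon families by
#' codons-per-thousand.
#'
#' @param tables list of `codon_usage` objects.
#' @return list with `rscu_matrix` (codon x species), `counts_matrix`,
#'   `unused` (named list of zero-count sense codons per species), and
#'   `family_ranking` (named list of family names, most used first).
#' @export
usage_panel <- function(tables) {
  stopifnot(length(tables) >= 1)
  species <- vapply(tables, `[[`, "", "species")
  if (anyDuplicated(species)) {
    stop("duplicate species labels: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  codons <- names(tables[[1]]$counts)
  rscu <- sapply(tables, function(t) t$rscu[codons])
  cnts <- sapply(tables, function(t) t$counts[codons])
  colnames(rscu) <- colnames(cnts) <- species
  rownames(rscu) <- rownames(cnts) <- codons
  unused <- lapply(tables, function(t) names(t$counts)[t$counts == 0])
  ranking <- lapply(tables, function(t)
    names(sort(t$cdspt, decreasing = TRUE)))
  names(unused) <- names(ranking) <- species
  list(rscu_matrix = rscu, counts_matrix = cnts, unused = unused,
       family_ranking = ranking)
}

#' Export a codon-usage panel as TSV
#'
#' @param panel result of [usage_panel()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_usage_tsv <- function(panel, path) {
  m <- round(panel$rscu_matrix, 3)
  out <- data.frame(codon = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
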