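# Base-composition and skew accounting over annotated regions.

count_bases <- function(s) {
  x <- Biostrings::DNAString(s)
  cnt <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T", "N"))
  setNames(as.integer(cnt), c("A", "C", "G", "T", "N"))
}

composition_from_counts <- function(region, cnt) {
  denom <- sum(cnt[c("A", "C", "G", "T")])
  if (denom == 0) stop("region '", region, "' has no unambiguous bases")
  pc <- 100 * cnt / denom
  at <- cnt[["A"]] + cnt[["T"]]
  gc <- cnt[["G"]] + cnt[["C"]]
  data.frame(
    region = region,
    size = as.integer(sum(cnt)),
    n_count = as.integer(cnt[["N"]]),
    pct_A = pc[["A"]], pct_T = pc[["T"]],
    pct_G = pc[["G"]], pct_C = pc[["C"]],
    pct_AT = pc[["A"]] + pc[["T"]],
    pct_GC = pc[["G"]] + pc[["C"]],
    at_skew = if (at > 0) (cnt[["A"]] - cnt[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (cnt[["G"]] - cnt[["C"]]) / gc else NA_real_,
    stringsAsFactors = FALSE
  )
}

resolve_region_sequence <- function(rec, region) {
  f <- rec$annotation$features
  if (region == "whole") return(rec$sequence)
  if (region %in% c("PCGs", "PCG")) {
    genes <- f$gene[f$category == "PCG"]
  } else if (region == "tRNA") {
    genes <- f$gene[f$category == "tRNA"]
  } else if (region == "rRNA") {
    genes <- f$gene[f$category == "rRNA"]
  } else if (region %in% f$gene) {
    genes <- region
  } else {
    stop("unresolvable region '", region, "'")
  }
  if (length(genes) == 0) stop("region '", region, "' selects no features")
  paste(vapply(genes, function(g) feature_sequence(rec, g), character(1)),
        collapse = "")
}

#' Base composition by region
#'
#' One row per requested region: base percentages, A+T / G+C content and
#' the conventional AT skew (A-T)/(A+T) and GC skew (G-C)/(G+C). The
#' "whole" region is counted on the majority (J) strand; gene and category
#' regions are counted on each gene's sense strand, so reverse-strand
#' genes contribute their reading-strand composition. N bases are excluded
#' from the percentage denominator and reported in `n_count`.
#'
#' @param rec a `mito_record` with sequence.
#' @param regions character vector: "whole", "PCGs", "tRNA", "rRNA",
#'   or canonical gene names (e.g. "rrnL", "control_region").
#' @return data.frame of class `composition_table`, one row per region.
#' @examples
#' rec <- simulate_mitogenome(genome_template(seed = 1))$record
#' base_composition(rec, c("whole", "PCGs", "control_region"))
#' @export
base_composition <- function(rec,
                             regions = c("whole", "PCGs", "tRNA", "rrnL",
                                         "rrnS", "control_region")) {
  if (is.null(rec$sequence)) stop("record has no sequence")
  if (length(regions) == 0) stop("no regions requested")
  rows <- lapply(regions, function(r) {
    composition_from_counts(r, count_bases(resolve_region_sequence(rec, r)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("composition_table", "data.frame")
  out
}

#' @export
print.composition_table <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & !(names(y) %in%
                                               c("size", "n_count"))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Export a composition table as TSV
#'
#' Percentages are rounded to one decimal, the conventional precision of
#' published composition tables; skews keep three decimals.
#'
#' @param comp a `composition_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(comp, path) {
  y <- as.data.frame(comp)
  pct <- grepl("^pct_", names(y))
  y[pct] <- lapply(y[pct], round, 1)
  y[c("at_skew", "gc_skew")] <- lapply(y[c("at_skew", "gc_skew")], round, 3)
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
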