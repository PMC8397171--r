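# Signed intergenic/overlap accounting over adjacent features of a
# circular annotation. Positive values are spacers, negative values
# overlaps, zero abutting; the wrap junction closes the circle.

#' Build the junction ledger of a circular annotation
#'
#' One junction per adjacent feature pair in genome order, plus the
#' origin-wrapping junction from the last feature back to the first, each
#' carrying the signed intergenic length
#' `ign = start(downstream) - end(upstream) - 1` (computed on the circle
#' for the wrap). Summaries follow the convention of published mitogenome
#' descriptions: the control region is itself the largest non-coding
#' segment, so its two flanking junctions are excluded from the
#' spacer/overlap statistics.
#'
#' @param ann a `mito_annotation`.
#' @param rec optional `mito_record` with sequence; when present, spacer
#'   sequences (forward strand) are attached to positive junctions.
#' @return object of class `junction_ledger`: list with `species`,
#'   `junctions` (data.frame: upstream, downstream, ign, wraps_origin,
#'   excluded, spacer_sequence) and `summary` (spacer/overlap count, min,
#'   max, total).
#' @examples
#' tsv <- system.file("extdata", "hestina_persimilis_features.tsv",
#'                    package = "lepmito")
#' led <- build_ledger(read_feature_table(tsv, "Hestina persimilis"))
#' led$summary$spacer_total   # 150
#' @export
build_ledger <- function(ann, rec = NULL) {
  f <- ann$features
  if (is.unsorted(f$start)) stop("features must be sorted by start")
  if (anyDuplicated(f$gene)) stop("duplicate feature names")
  n <- nrow(f)
  up <- seq_len(n)
  down <- c(seq_len(n - 1) + 1, 1)
  wraps <- c(rep(FALSE, n - 1), TRUE)
  ign <- integer(n)
  for (k in seq_len(n)) {
    i <- up[k]; j <- down[k]
    if (!wraps[k]) {
      ign[k] <- as.integer(f$start[j] - f$end[i] - 1)
    } else {
      ign[k] <- as.integer(f$start[j] + ann$genome_length - f$end[i] - 1)
    }
  }
  excluded <- f$gene[up] == "control_region" |
              f$gene[down] == "control_region"
  spacer_seq <- rep(NA_character_, n)
  if (!is.null(rec) && !is.null(rec$sequence)) {
    for (k in seq_len(n)) {
      if (ign[k] > 0) {
        from <- f$end[up[k]] + 1
        to <- from + ign[k] - 1
        if (to <= ann$genome_length) {
          spacer_seq[k] <- substr(rec$sequence, from, to)
        } else {
          # wrap spacer: tail of the circle plus head
          spacer_seq[k] <- paste0(
            substr(rec$sequence, from, ann$genome_length),
            substr(rec$sequence, 1, to - ann$genome_length))
        }
      }
    }
  }
  junctions <- data.frame(
    upstream = f$gene[up], downstream = f$gene[down], ign = ign,
    wraps_origin = wraps, excluded = excluded,
    spacer_sequence = spacer_seq, stringsAsFactors = FALSE
  )
  keep <- junctions[!junctions$excluded, , drop = FALSE]
  sp <- keep$ign[keep$ign > 0]
  ov <- abs(keep$ign[keep$ign < 0])
  summary <- list(
    spacer_count = length(sp),
    spacer_min = if (length(sp)) min(sp) else NA_integer_,
    spacer_max = if (length(sp)) max(sp) else NA_integer_,
    spacer_total = sum(sp),
    overlap_count = length(ov),
    overlap_min = if (length(ov)) min(ov) else NA_integer_,
    overlap_max = if (length(ov)) max(ov) else NA_integer_,
    overlap_total = sum(ov)
  )
  structure(list(species = ann$species, junctions = junctions,
                 summary = summary, genome_length = ann$genome_length),
            class = "junction_ledger")
}

#' @export
print.junction_ledger <- function(x, ...) {
  s <- x$summary
  cat("Junction ledger:", x$species, "-", nrow(x$junctions), "junctions\n")
  cat(sprintf("  spacers : %d (%s-%s bp, %d bp total)\n", s$spacer_count,
              s$spacer_min, s$spacer_max, s$spacer_total))
  cat(sprintf("  overlaps: %d (%s-%s bp, %d bp total)\n", s$overlap_count,
              s$overlap_min, s$overlap_max, s$overlap_total))
  invisible(x)
}

#' Fetch one junction row by its flanking genes
#'
#' @param ledger a `junction_ledger`.
#' @param upstream,downstream canonical gene names.
#' @return one-row data.frame.
#' @export
get_junction <- function(ledger, upstream, downstream) {
  j <- ledger$junctions
  hit <- which(j$upstream == upstream & j$downstream == downstream)
  if (length(hit) == 0) {
    stop("no junction ", upstream, " -> ", downstream)
  }
  j[hit, , drop = FALSE]
}

#' Search a junction for a conserved motif
#'
#' Exact-match search on the forward (majority) strand of the junction
#' region: the spacer sequence for positive junctions, the shared overlap
#' window for negative ones.
#'
#' @param ledger a `junction_ledger`.
#' @param rec a `mito_record` with sequence.
#' @param upstream,downstream canonical gene names naming the junction.
#' @param motif nucleotide string.
#' @param search_revcomp also search the reverse complement (default
#'   FALSE; published junction motifs are quoted on the J strand).
#' @return list with `found`, `offset` (1-based within the junction
#'   window, NA when absent), `window` (the searched sequence), and `ign`.
#' @export
junction_motif <- function(ledger, rec, upstream, downstream, motif,
                           search_revcomp = FALSE) {
  if (is.null(rec$sequence)) stop("record has no sequence")
  stopifnot(nchar(motif) >= 1)
  j <- get_junction(ledger, upstream, downstream)
  f <- rec$annotation$features
  iu <- match(upstream, f$gene)
  id <- match(downstream, f$gene)
  if (j$ign > 0) {
    window <- if (!is.na(j$spacer_sequence)) j$spacer_sequence else
      substr(rec$sequence, f$end[iu] + 1, f$end[iu] + j$ign)
  } else if (j$ign < 0) {
    window <- substr(rec$sequence, f$start[id], f$end[iu])
  } else {
    return(list(found = FALSE, offset = NA_integer_, window = "",
                ign = j$ign))
  }
  pos <- regexpr(motif, window, fixed = TRUE)
  found <- pos > 0
  offset <- if (found) as.integer(pos) else NA_integer_
  if (!found && search_revcomp) {
    pos2 <- regexpr(motif, revcomp(window), fixed = TRUE)
    if (pos2 > 0) {
      found <- TRUE
      offset <- nchar(window) - (as.integer(pos2) + nchar(motif) - 1) + 1
    }
  }
  list(found = found, offset = offset, window = window, ign = j$ign)
}

#' Report the two conserved lepidopteran junction motifs
#'
#' Checks the trnS2-nad1 spacer for the conserved ATACTAA heptamer and
#' the atp8/atp6 junction for the canonical 7-bp ATGATAA overlap.
#'
#' @param ledger a `junction_ledger`.
#' @param rec a `mito_record` with sequence.
#' @return data.frame with one row per motif check: junction, motif,
#'   ign, found, offset.
#' @export
junction_motif_report <- function(ledger, rec) {
  checks <- list(
    list(up = "trnS2", down = "nad1", motif = "ATACTAA"),
    list(up = "atp8", down = "atp6", motif = "ATGATAA")
  )
  rows <- lapply(checks, function(ck) {
    m <- junction_motif(ledger, rec, ck$up, ck$down, ck$motif)
    data.frame(junction = paste0(ck$up, "-", ck$down), motif = ck$motif,
               ign = m$ign, found = m$found, offset = m$offset,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a junction ledger as TSV
#'
#' @param ledger a `junction_ledger`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ledger_tsv <- function(ledger, path) {
  write.table(ledger$junctions[, c("upstream", "downstream", "ign",
                                   "wraps_origin", "excluded")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
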