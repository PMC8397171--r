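# Dissection of the A+T-rich control region into its conserved elements:
# the ATAGA replication-origin motif with its poly-T block, the (AT)n
# microsatellite, a tandem-repeated unit, and the poly-A run abutting the
# downstream trnM.

#' Scan for perfect microsatellite runs
#'
#' Left-greedy maximal non-overlapping perfect runs of short motifs; the
#' copy number is the count of complete units.
#'
#' @param seq nucleotide string.
#' @param motifs character vector of 1-6 bp motifs (default "AT").
#' @param min_copies minimum complete copies to report (default 5).
#' @return data.frame with columns `motif`, `copies`, `start`, `length`.
#' @examples
#' microsatellite_scan("GGATATATATATGG", min_copies = 3)  # (AT)5 at 3
#' @export
microsatellite_scan <- function(seq, motifs = "AT", min_copies = 5) {
  stopifnot(min_copies >= 1)
  if (any(!nzchar(motifs))) stop("empty motif")
  if (any(nchar(motifs) > 6)) stop("microsatellite motifs are 1-6 bp")
  rows <- list()
  for (m in motifs) {
    pat <- paste0("(?:", m, ")+")
    hits <- gregexpr(pat, seq)[[1]]
    if (hits[1] == -1) next
    lens <- attr(hits, "match.length")
    copies <- lens %/% nchar(m)
    keep <- copies >= min_copies
    if (any(keep)) {
      rows[[length(rows) + 1]] <- data.frame(
        motif = m, copies = copies[keep], start = as.integer(hits[keep]),
        length = copies[keep] * nchar(m), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(motif = character(), copies = integer(),
                      start = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# validity of a candidate array: span [a, b] at unit length p over the
# 0/1 match vector m[k] = (s[k] == s[k+p]); identity over adjacent copies
# = matches / (L - p); copies = L / p (real).
# candidate search: for each (p, a), the longest valid b; global best by
# max span length, ties to smaller p then smaller start.
best_tandem_candidate <- function(chars, min_unit, max_unit, min_copies,
                                  min_identity) {
  n <- length(chars)
  best <- NULL
  for (p in min_unit:min(max_unit, n - 1)) {
    m <- as.integer(chars[seq_len(n - p)] == chars[seq_len(n - p) + p])
    S <- c(0L, cumsum(m))
    Lmin <- max(p + 1, ceiling(min_copies * p))
    if (Lmin > n) next
    for (a in seq_len(n - Lmin + 1)) {
      bs <- (a + Lmin - 1):n
      comp <- bs - p - a + 1          # number of shifted comparisons
      matches <- S[bs - p + 1] - S[a]
      ok <- matches / comp >= min_identity
      if (any(ok)) {
        b <- bs[max(which(ok))]
        L <- b - a + 1
        cand <- c(p = p, a = a, b = b, L = L)
        if (is.null(best) || L > best[["L"]] ||
            (L == best[["L"]] && (p < best[["p"]] ||
                                  (p == best[["p"]] && a < best[["a"]])))) {
          best <- cand
        }
      }
    }
  }
  best
}

consensus_unit <- function(chars, p, a, b) {
  L <- b - a + 1
  full <- L %/% p
  unit <- character(p)
  for (j in seq_len(p)) {
    col <- chars[a + (seq_len(full) - 1) * p + j - 1]
    tb <- table(col)
    unit[j] <- names(tb)[which.max(tb)]
  }
  paste(unit, collapse = "")
}

min_period <- function(unit) {
  p <- nchar(unit)
  for (d in seq_len(p)) {
    if (p %% d == 0 &&
        unit == strrep(substr(unit, 1, d), p %/% d)) return(d)
  }
  p
}

#' Detect tandem repeat arrays by self-comparison
#'
#' For each candidate unit length p, the sequence is compared against
#' itself shifted by p; a maximal array is a span whose adjacent-copy
#' identity (matching positions over span length minus p) meets
#' `min_identity` with at least `min_copies` copies (span length / p).
#' Overlapping candidates are resolved greedily by largest span, ties to
#' the smaller unit length then the smaller start; the remaining flanks
#' are then re-scanned, so reported arrays never overlap.
#'
#' @param seq nucleotide string.
#' @param min_unit,max_unit unit-length bounds in bp (defaults 2 and 50);
#'   `2 <= min_unit <= max_unit <= nchar(seq)/2` is required.
#' @param min_copies minimum (real) copy number, default 1.9.
#' @param min_identity minimum adjacent-copy identity, default 0.85.
#' @return data.frame with columns `unit_length`, `unit` (consensus),
#'   `copies`, `start`, `end`, `identity`.
#' @examples
#' tandem_repeat_scan("ACGTACGTACGT", min_unit = 2, max_unit = 6)
#' @export
tandem_repeat_scan <- function(seq, min_unit = 2, max_unit = 50,
                               min_copies = 1.9, min_identity = 0.85) {
  n <- nchar(seq)
  if (min_unit < 2) stop("min_unit must be >= 2")
  if (max_unit < min_unit) stop("max_unit must be >= min_unit")
  if (max_unit > n / 2) max_unit <- floor(n / 2)
  if (max_unit < min_unit) {
    return(data.frame(unit_length = integer(), unit = character(),
                      copies = numeric(), start = integer(),
                      end = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  chars <- strsplit(seq, "")[[1]]

  scan_segment <- function(from, to) {
    if (to - from + 1 < 2 * min_unit) return(NULL)
    seg <- chars[from:to]
    cand <- best_tandem_candidate(seg, min_unit, max_unit, min_copies,
                                  min_identity)
    if (is.null(cand)) return(NULL)
    p <- cand[["p"]]; a <- cand[["a"]]; b <- cand[["b"]]
    L <- cand[["L"]]
    m <- sum(seg[a:(b - p)] == seg[(a + p):b])
    row <- data.frame(
      unit_length = p,
      unit = consensus_unit(seg, p, a, b),
      copies = L / p,
      start = from + a - 1, end = from + b - 1,
      identity = m / (L - p),
      stringsAsFactors = FALSE)
    rbind(scan_segment(from, from + a - 2), row,
          scan_segment(from + b, to))
  }
  out <- scan_segment(1, n)
  if (is.null(out)) {
    return(data.frame(unit_length = integer(), unit = character(),
                      copies = numeric(), start = integer(),
                      end = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# longest run of `base` whose start lies in [win_from, win_to]
longest_run_from <- function(chars, base, win_from, win_to) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- r$values == base & starts >= win_from & starts <= win_to
  if (!any(hit)) return(NULL)
  i <- which(hit)[which.max(r$lengths[hit])]
  list(start = starts[i], length = r$lengths[i])
}

# longest run of `base` whose end lies in [win_from, win_to]
longest_run_to <- function(chars, base, win_from, win_to) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- r$values == base & ends >= win_from & ends <= win_to
  if (!any(hit)) return(NULL)
  i <- which(hit)[which.max(r$lengths[hit])]
  list(start = starts[i], length = r$lengths[i])
}

#' Default control-region scan parameters
#'
#' @return named list: `adjacency_window` (bp tolerance between the origin
#'   motif and the poly-T start, and between the poly-A end and the
#'   downstream gene), `min_poly_run`, `origin_motif`, microsatellite and
#'   tandem-repeat thresholds. Tandem units shorter than 10 bp and units
#'   whose minimal period is <= 2 are excluded there, so poly-runs and
#'   microsatellites are never double-reported as tandem arrays.
#' @export
control_region_params <- function() {
  list(adjacency_window = 10, min_poly_run = 5, origin_motif = "ATAGA",
       microsat_motifs = "AT", microsat_min_copies = 5,
       tandem_min_unit = 10, tandem_max_unit = 50,
       tandem_min_copies = 1.9, tandem_min_identity = 0.85,
       tandem_max_unit_period = 2)
}

#' Dissect the control region into its conserved elements
#'
#' Scans the control-region slice (forward strand, read from the
#' rrnS-proximal boundary) for: the origin-associated motif (default
#' ATAGA) and its downstream poly-T block, the (AT)n microsatellite,
#' tandem repeat arrays, and the poly-A run abutting the downstream gene
#' boundary (trnM in the canonical lepidopteran order). Every element may
#' be reported absent. Because only the extracted slice is examined, the
#' report is invariant to flanking genomic context.
#'
#' @param rec a `mito_record` with sequence and a control_region feature.
#' @param params scan parameters, see [control_region_params()].
#' @return object of class `control_region_report`.
#' @examples
#' rec <- simulate_mitogenome(genome_template(seed = 1))$record
#' dissect_control_region(rec)
#' @export
dissect_control_region <- function(rec, params = control_region_params()) {
  if (is.null(rec$sequence)) stop("record has no sequence")
  f <- rec$annotation$features
  i <- match("control_region", f$gene)
  if (is.na(i)) stop("annotation has no control_region feature")
  cr <- feature_sequence(rec, "control_region")
  n <- nchar(cr)
  chars <- strsplit(cr, "")[[1]]
  cnt <- count_bases(cr)
  pct_at <- 100 * (cnt[["A"]] + cnt[["T"]]) /
    sum(cnt[c("A", "C", "G", "T")])

  motif_pos <- regexpr(params$origin_motif, cr, fixed = TRUE)
  origin <- NULL
  if (motif_pos > 0) {
    mend <- as.integer(motif_pos) + nchar(params$origin_motif) - 1
    pt <- longest_run_from(chars, "T", mend + 1,
                           min(mend + params$adjacency_window, n))
    if (!is.null(pt) && pt$length < params$min_poly_run) pt <- NULL
    origin <- list(motif = params$origin_motif,
                   motif_start = as.integer(motif_pos),
                   polyT_start = if (is.null(pt)) NA_integer_ else pt$start,
                   polyT_length = if (is.null(pt)) NA_integer_ else pt$length)
  }

  pa <- longest_run_to(chars, "A", max(1, n - params$adjacency_window + 1), n)
  if (!is.null(pa) && pa$length < params$min_poly_run) pa <- NULL

  micro <- microsatellite_scan(cr, params$microsat_motifs,
                               params$microsat_min_copies)

  tr <- tandem_repeat_scan(cr, min_unit = params$tandem_min_unit,
                           max_unit = params$tandem_max_unit,
                           min_copies = params$tandem_min_copies,
                           min_identity = params$tandem_min_identity)
  if (nrow(tr) > 0) {
    periods <- vapply(tr$unit, min_period, integer(1))
    tr <- tr[periods > params$tandem_max_unit_period, , drop = FALSE]
  }
  if (nrow(tr) > 0) {
    # elements are disjoint classes: arrays over the poly runs or the
    # microsatellite are those elements, not tandem arrays
    spans <- list()
    if (!is.null(origin) && !is.na(origin$polyT_length)) {
      spans[[length(spans) + 1]] <- c(origin$polyT_start,
                                      origin$polyT_start +
                                        origin$polyT_length - 1)
    }
    if (!is.null(pa)) {
      spans[[length(spans) + 1]] <- c(pa$start, pa$start + pa$length - 1)
    }
    for (k in seq_len(nrow(micro))) {
      spans[[length(spans) + 1]] <- c(micro$start[k],
                                      micro$start[k] + micro$length[k] - 1)
    }
    if (length(spans) > 0) {
      # drop a call only when most of its span lies inside other elements
      clash <- vapply(seq_len(nrow(tr)), function(i) {
        covered <- sum(vapply(spans, function(sp)
          max(0, min(tr$end[i], sp[2]) - max(tr$start[i], sp[1]) + 1),
          numeric(1)))
        covered / (tr$end[i] - tr$start[i] + 1) > 0.5
      }, logical(1))
      tr <- tr[!clash, , drop = FALSE]
    }
    rownames(tr) <- NULL
  }

  structure(
    list(species = rec$annotation$species,
         span = c(start = f$start[i], end = f$end[i]),
         length = n, pct_AT = pct_at,
         origin_block = origin,
         polyA = if (is.null(pa)) NULL else
           list(start = pa$start, length = pa$length),
         microsatellites = micro,
         tandem_repeats = tr,
         params = params),
    class = "control_region_report"
  )
}

#' @export
print.control_region_report <- function(x, ...) {
  cat("Control region:", x$species, "-", x$length, "bp, AT",
      sprintf("%.1f%%\n", x$pct_AT))
  if (is.null(x$origin_block)) {
    cat("  origin motif: absent\n")
  } else {
    cat(sprintf("  origin motif %s at %d; poly-T %s\n",
                x$origin_block$motif, x$origin_block$motif_start,
                if (is.na(x$origin_block$polyT_length)) "absent" else
                  paste0(x$origin_block$polyT_length, " bp")))
  }
  cat("  poly-A:", if (is.null(x$polyA)) "absent" else
    paste0(x$polyA$length, " bp at ", x$polyA$start), "\n")
  cat("  microsatellite runs:", nrow(x$microsatellites),
      " tandem arrays:", nrow(x$tandem_repeats), "\n")
  invisible(x)
}

#' Serialize a control-region report as JSON
#'
#' @param report a `control_region_report`.
#' @param path optional output path.
#' @return JSON string (invisibly when written).
#' @export
cr_report_to_json <- function(report, path = NULL) {
  obj <- unclass(report)
  obj$params <- NULL
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Tabulate conserved control-region elements across species
#'
#' Mirrors the conventional comparative presentation: one row per species
#' with the origin motif, poly-T length, microsatellite and poly-A calls
#' side by side.
#'
#' @param reports list of `control_region_report` objects.
#' @return data.frame, one row per species.
#' @export
cr_element_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    ms <- r$microsatellites
    ms_txt <- if (nrow(ms) == 0) "absent" else
      paste0("(", ms$motif[1], ")", ms$copies[1])
    tr <- r$tandem_repeats
    tr_txt <- if (nrow(tr) == 0) "absent" else {
      k <- which.max(tr$end - tr$start)   # dominant array
      paste0(tr$unit_length[k], " bp x ", round(tr$copies[k], 1))
    }
    data.frame(
      species = r$species, length = r$length, pct_AT = round(r$pct_AT, 2),
      motif = if (is.null(r$origin_block)) "absent" else
        r$origin_block$motif,
      polyT = if (is.null(r$origin_block) ||
                  is.na(r$origin_block$polyT_length)) NA_integer_ else
        r$origin_block$polyT_length,
      microsatellite = ms_txt,
      tandem = tr_txt,
      polyA = if (is.null(r$polyA)) NA_integer_ else r$polyA$length,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
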