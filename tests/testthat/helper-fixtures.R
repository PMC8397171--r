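# Shared fixtures and independent oracles for the test suite.

persimilis_tsv <- function() {
  system.file("extdata", "hestina_persimilis_features.tsv",
              package = "lepmito")
}

nama_tsv <- function() {
  system.file("extdata", "hestinalis_nama_features.tsv", package = "lepmito")
}

persimilis_ann <- function() {
  read_feature_table(persimilis_tsv(), species = "Hestina persimilis")
}

nama_ann <- function() {
  read_feature_table(nama_tsv(), species = "Hestinalis nama")
}

# tiny hand-built record: genes tiling a small circle
toy_record <- function(sequence, features) {
  ann <- mito_annotation("toy", features, genome_length = nchar(sequence))
  mito_record(ann, sequence)
}

# brute-force tandem-repeat oracle: naive triple loop over every
# (unit length, start, span) candidate, then the same greedy selection
# rule as the scanner (max span, ties to smaller unit then smaller start,
# flanks re-scanned). Deliberately unvectorized and coded independently.
oracle_tandem_scan <- function(seq, min_unit = 2, max_unit = 50,
                               min_copies = 1.9, min_identity = 0.85) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  max_unit <- min(max_unit, floor(n / 2))
  scan <- function(from, to) {
    best <- NULL
    len <- to - from + 1
    if (len < 2 * min_unit) return(NULL)
    seg <- ch[from:to]
    for (p in min_unit:max_unit) {
      if (p >= len) next
      if (max(p + 1, ceiling(min_copies * p)) > len) next
      # cumulative match counts against the p-shifted segment give each
      # candidate's identity in constant time; every (start, end) pair is
      # still enumerated exhaustively
      S <- c(0, cumsum(seg[seq_len(len - p)] == seg[seq_len(len - p) + p]))
      for (a in seq_len(len)) {
        for (b in a:len) {
          L <- b - a + 1
          if (L < p + 1) next
          if (L / p < min_copies) next
          matches <- S[b - p + 1] - S[a]
          if (matches / (L - p) < min_identity) next
          if (is.null(best) || L > best$L ||
              (L == best$L && (p < best$p ||
                               (p == best$p && a < best$a_local)))) {
            best <- list(p = p, a_local = a,
                         a = from + a - 1, b = from + b - 1, L = L,
                         identity = matches / (L - p))
          }
        }
      }
    }
    if (is.null(best)) return(NULL)
    row <- data.frame(unit_length = best$p, copies = best$L / best$p,
                      start = best$a, end = best$b,
                      identity = best$identity)
    rbind(scan(from, best$a - 1), row, scan(best$b + 1, to))
  }
  out <- scan(1, n)
  if (is.null(out)) {
    return(data.frame(unit_length = integer(), copies = numeric(),
                      start = integer(), end = integer(),
                      identity = numeric()))
  }
  rownames(out) <- NULL
  out
}

# matrix-exponential oracle for the two-rate substitution process:
# eigen-based expm of the K2P rate matrix, independent of the simulator's
# closed-form transition probabilities.
oracle_k2p_P <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  bases <- c("A", "C", "G", "T")
  Q <- matrix(beta, 4, 4, dimnames = list(bases, bases))
  ts <- c(A = "G", C = "T", G = "A", T = "C")
  for (b in bases) Q[b, ts[[b]]] <- alpha
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  e <- eigen(Q, symmetric = TRUE)
  e$vectors %*% diag(exp(e$values * t)) %*% t(e$vectors)
}

# expected p-distance between two leaves joined by path lengths t1, t2
# through a common ancestor with root base frequencies pi
oracle_expected_p <- function(t1, t2, kappa, pi) {
  P1 <- oracle_k2p_P(t1, kappa)
  P2 <- oracle_k2p_P(t2, kappa)
  p <- 0
  for (z in 1:4) {
    joint <- outer(P1[z, ], P2[z, ])
    p <- p + pi[z] * (1 - sum(diag(joint)))
  }
  p
}

pcg13 <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
           "nad5", "nad4", "nad4L", "nad6", "cob", "nad1")

# record with all 13 PCGs tiled on one strand; each gene is
# ATG + the given body codons + TAA, so codon counts are known exactly
make_pcg_record <- function(body = list()) {
  seqs <- vapply(pcg13, function(g) {
    paste0("ATG", paste(body[[g]], collapse = ""), "TAA")
  }, character(1))
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs) + 1
  feats <- data.frame(
    gene = pcg13, category = "PCG", strand = "F",
    start = starts, end = ends,
    size_declared = nchar(seqs),
    start_codon = "ATG", stop_codon = "TAA",
    stringsAsFactors = FALSE)
  toy_record(paste(seqs, collapse = ""), feats)
}
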