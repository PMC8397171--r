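# 13-gene supermatrix assembly, pairwise distances (p / K2P with pairwise
# deletion), neighbour-joining, and monophyly queries.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Concatenate per-taxon gene blocks into a supermatrix
#'
#' Genes are concatenated in the canonical mitochondrial PCG order (nad2,
#' cox1, cox2, atp8, atp6, cox3, nad3, nad5, nad4, nad4L, nad6, cob,
#' nad1). Blocks must be pre-aligned (equal length within each gene)
#' unless an aligner callback is supplied; taxa missing a gene get an
#' all-gap block. Partition tables are emitted for the by-gene (13
#' partitions) and gene-by-codon-position (39 partitions) schemes.
#'
#' @param gene_sets named list (taxon -> named character vector of gene
#'   sequences, names from the 13-PCG set).
#' @param aligner NULL for pre-aligned input, or a function
#'   `function(named_seqs) -> named_seqs` applied per gene.
#' @return object of class `supermatrix`: list with `taxa`, `matrix`
#'   (named character vector of equal-length rows), `genes`, `partitions`
#'   (data.frame gene/start/end) and `length`.
#' @export
build_supermatrix <- function(gene_sets, aligner = NULL) {
  stopifnot(length(gene_sets) >= 1, !is.null(names(gene_sets)))
  taxa <- names(gene_sets)
  for (tx in taxa) {
    if (length(gene_sets[[tx]]) == 0) {
      stop("taxon '", tx, "' supplies no genes")
    }
    bad <- setdiff(names(gene_sets[[tx]]), .PCG_ORDER)
    if (length(bad) > 0) {
      stop("taxon '", tx, "' has non-PCG gene(s): ",
           paste(bad, collapse = ", "))
    }
  }
  genes <- .PCG_ORDER[.PCG_ORDER %in%
                      unique(unlist(lapply(gene_sets, names)))]
  blocks <- list()
  for (g in genes) {
    seqs <- lapply(gene_sets, function(gs)
      if (g %in% names(gs)) gs[[g]] else NULL)
    present <- !vapply(seqs, is.null, logical(1))
    aligned <- setNames(toupper(unlist(seqs[present])), taxa[present])
    if (!is.null(aligner)) aligned <- aligner(aligned)
    lens <- unique(nchar(aligned))
    if (length(lens) != 1) {
      off <- names(aligned)[nchar(aligned) != lens[1]]
      stop("gene '", g, "': unequal pre-aligned lengths (taxon ",
           off[1], ")")
    }
    block <- setNames(rep(strrep("-", lens), length(taxa)), taxa)
    block[names(aligned)] <- aligned
    blocks[[g]] <- block
  }
  lens <- vapply(blocks, function(b) nchar(b[[1]]), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  mat <- setNames(vapply(taxa, function(tx)
    paste(vapply(blocks, `[[`, "", tx), collapse = ""), character(1)), taxa)
  structure(
    list(taxa = taxa, matrix = mat, genes = genes,
         partitions = data.frame(gene = genes, start = unname(starts),
                                 end = unname(ends), row.names = NULL,
                                 stringsAsFactors = FALSE),
         length = sum(lens)),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$taxa), "taxa x", x$length, "bp,",
      length(x$genes), "gene partitions\n")
  invisible(x)
}

#' Pairwise distances on a supermatrix
#'
#' p (uncorrected) or K2P (Kimura two-parameter,
#' `d = -1/2 log((1-2P-Q) sqrt(1-2Q))` with P/Q the transition and
#' transversion proportions). Sites with a gap or N in either row of a
#' pair are excluded pairwise by default; `pairwise_deletion = FALSE`
#' drops every column containing any gap/N before any comparison. A pair
#' whose K2P log argument is non-positive is saturated: its entry is set
#' to `saturation_cap` and flagged.
#'
#' @param sm a `supermatrix` (or named character vector of equal-length
#'   aligned sequences).
#' @param model "p" or "K2P".
#' @param pairwise_deletion logical, default TRUE.
#' @param saturation_cap distance assigned to saturated K2P pairs.
#' @return object of class `mito_dist`: list with `taxa`, `matrix`
#'   (symmetric, zero diagonal), `model`, `saturated` (logical matrix).
#' @export
distances <- function(sm, model = c("p", "K2P"), pairwise_deletion = TRUE,
                      saturation_cap = 5) {
  model <- match.arg(model)
  seqs <- if (inherits(sm, "supermatrix")) sm$matrix else sm
  taxa <- names(seqs)
  n <- length(taxa)
  if (n < 2) stop("need at least two taxa")
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  L <- unique(lengths(chars))
  if (length(L) != 1) stop("rows of unequal length")
  good <- lapply(chars, function(c) c %in% c("A", "C", "G", "T"))
  if (!pairwise_deletion) {
    all_good <- Reduce(`&`, good)
    chars <- lapply(chars, function(c) c[all_good])
    good <- lapply(good, function(g) rep(TRUE, sum(all_good)))
  }
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- good[[i]] & good[[j]]
      m <- sum(use)
      if (m == 0) {
        stop("no comparable sites between '", taxa[i], "' and '",
             taxa[j], "'")
      }
      a <- chars[[i]][use]
      b <- chars[[j]][use]
      diff <- a != b
      ts <- sum(diff & ((a %in% PURINES) == (b %in% PURINES)))
      tv <- sum(diff) - ts
      if (model == "p") {
        d <- sum(diff) / m
      } else {
        P <- ts / m
        Q <- tv / m
        arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
        if (arg <= 0) {
          d <- saturation_cap
          sat[i, j] <- sat[j, i] <- TRUE
        } else {
          d <- -0.5 * log(arg)
        }
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(list(taxa = taxa, matrix = D, model = model, saturated = sat),
            class = "mito_dist")
}

#' @export
print.mito_dist <- function(x, ...) {
  cat("Distance matrix (", x$model, "): ", length(x$taxa), " taxa",
      if (any(x$saturated)) paste0("; ", sum(x$saturated) / 2,
                                   " saturated pair(s)") else "",
      "\n", sep = "")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape); negative branch lengths, an
#' artefact of the least-squares step on non-additive input, are clamped
#' to zero with a message.
#'
#' @param dm a `mito_dist` (or symmetric numeric matrix with dimnames).
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  D <- if (inherits(dm, "mito_dist")) dm$matrix else as.matrix(dm)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix is not symmetric")
  }
  if (nrow(D) < 3) stop("neighbour joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    message("nj_tree: clamping ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Test whether a taxon set is monophyletic
#'
#' Roots the tree at the outgroup and asks whether some edge separates
#' exactly the query set from the rest.
#'
#' @param tree a `phylo` tree.
#' @param taxa character vector of query tip labels (outgroup excluded).
#' @param outgroup tip label used to root the tree.
#' @return list with `monophyletic` (logical) and `mrca_size` (number of
#'   tips under the query set's most recent common ancestor after
#'   rooting; equals `length(taxa)` iff monophyletic).
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  labs <- tree$tip.label
  unknown <- setdiff(c(taxa, outgroup), labs)
  if (length(unknown) > 0) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  }
  if (outgroup %in% taxa) stop("outgroup cannot be part of the query set")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (length(taxa) == 1) {
    return(list(monophyletic = TRUE, mrca_size = 1L))
  }
  mono <- ape::is.monophyletic(rooted, taxa)
  node <- ape::getMRCA(rooted, taxa)
  desc <- ape::extract.clade(rooted, node)$tip.label
  list(monophyletic = mono, mrca_size = length(desc))
}

#' Export a supermatrix in relaxed PHYLIP format
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  lines <- c(paste(length(sm$taxa), sm$length),
             vapply(sm$taxa, function(tx)
               paste0(gsub("\\s+", "_", tx), "  ", sm$matrix[[tx]]),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Export a supermatrix as a NEXUS data block
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(sm, path) {
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa),
                     sm$length),
             "  FORMAT DATATYPE=DNA MISSING=N GAP=-;",
             "  MATRIX",
             vapply(sm$taxa, function(tx)
               paste0("    ", gsub("\\s+", "_", tx), "  ", sm$matrix[[tx]]),
               character(1)),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Export a RAxML-style partition file
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @param by_codon_position emit three codon-position subsets per gene
#'   (39 partitions) instead of one per gene (13).
#' @return `path`, invisibly.
#' @export
write_partition_file <- function(sm, path, by_codon_position = FALSE) {
  p <- sm$partitions
  lines <- character(0)
  for (i in seq_len(nrow(p))) {
    if (by_codon_position) {
      for (pos in 1:3) {
        lines <- c(lines, sprintf("DNA, %s_pos%d = %d-%d\\3", p$gene[i],
                                  pos, p$start[i] + pos - 1, p$end[i]))
      }
    } else {
      lines <- c(lines, sprintf("DNA, %s = %d-%d", p$gene[i], p$start[i],
                                p$end[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a RAxML-style partition file
#'
#' @param path partition file path.
#' @return data.frame with columns `gene`, `start`, `end` (codon-position
#'   subsets collapse back onto their gene rows).
#' @export
read_partition_file <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines,
                  regexec("^DNA,\\s*(\\S+)\\s*=\\s*([0-9]+)-([0-9]+)", lines))
  rows <- lapply(m, function(x) {
    if (length(x) != 4) stop("malformed partition line")
    data.frame(gene = sub("_pos[123]$", "", x[2]),
               start = as.integer(x[3]), end = as.integer(x[4]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  res <- data.frame(gene = unique(out$gene), stringsAsFactors = FALSE)
  res$start <- unname(vapply(res$gene, function(g)
    min(out$start[out$gene == g]), integer(1)))
  res$end <- unname(vapply(res$gene, function(g)
    max(out$end[out$gene == g]), integer(1)))
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export a distance matrix as TSV
#'
#' @param dm a `mito_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(dm, path) {
  out <- data.frame(taxon = dm$taxa, dm$matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
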