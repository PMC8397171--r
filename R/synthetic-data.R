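# Seeded generator of annotated circular mitogenomes and evolved sequence
# panels. The default template reproduces the canonical lepidopteran
# 37-gene layout (coordinates, strands, start/stop codons) of the
# H. persimilis annotation shipped in extdata, with per-region AT targets
# matching its published composition and a control-region element plan
# (ATAGA origin motif, 19 bp poly-T, (AT)10 microsatellite, 23 bp tandem
# unit x2, 9 bp poly-A). Every planted quantity is recorded as ground
# truth so downstream stages can be tested by plant-and-recover.

#' Default per-region AT-content targets
#'
#' Fractions (0-1) for protein-coding genes, tRNAs, rRNAs, the control
#' region and intergenic spacers, chosen to match the published
#' composition of the H. persimilis mitogenome (whole-genome AT 80.9%).
#'
#' @return named numeric vector.
#' @export
default_at_targets <- function() {
  c(PCG = 0.797, tRNA = 0.814, rrnL = 0.843, rrnS = 0.851,
    control = 0.912, spacer = 0.809)
}

#' Default control-region element plan
#'
#' @return named list: origin motif, poly-T length, microsatellite motif
#'   and copies, tandem unit length and copies, poly-A length.
#' @export
default_cr_plan <- function() {
  list(motif = "ATAGA", polyT = 19, microsat_motif = "AT",
       microsat_copies = 10, tandem_unit_length = 23, tandem_copies = 2,
       polyA = 9)
}

#' Build a genome template for the simulator
#'
#' @param layout feature layout data.frame (columns gene, category,
#'   strand, start, end, start_codon, stop_codon); defaults to the
#'   37-gene + control-region layout shipped in extdata.
#' @param genome_length genome size; defaults to `max(layout$end)`.
#' @param species species label for the simulated record.
#' @param at_targets per-region AT fractions, see [default_at_targets()].
#' @param cr_plan control-region element plan ([default_cr_plan()]) or
#'   NULL for an unstructured AT-rich control region.
#' @param plant_junction_motifs plant the canonical ATGATAA overlap at
#'   atp8/atp6 (when that junction overlaps by 7) and ATACTAA in the
#'   trnS2-nad1 spacer (default TRUE).
#' @param seed integer seed; the generator is deterministic given the
#'   template.
#' @return object of class `genome_template`.
#' @export
genome_template <- function(layout = NULL, genome_length = NULL,
                            species = "synthetic mitogenome",
                            at_targets = default_at_targets(),
                            cr_plan = default_cr_plan(),
                            plant_junction_motifs = TRUE, seed = 1) {
  if (is.null(layout)) {
    tsv <- system.file("extdata", "hestina_persimilis_features.tsv",
                       package = "lepmito")
    ann <- read_feature_table(tsv, species = species)
    layout <- ann$features[, c("gene", "category", "strand", "start",
                               "end", "start_codon", "stop_codon")]
    if (is.null(genome_length)) genome_length <- ann$genome_length
  }
  if (is.null(genome_length)) genome_length <- max(layout$end)
  if (is.unsorted(layout$start)) stop("layout must be sorted by start")
  # an overlap longer than either flanking gene is not a junction but an
  # inconsistent tiling
  sizes <- layout$end - layout$start + 1
  if (nrow(layout) > 1) {
    for (i in seq_len(nrow(layout) - 1)) {
      ov <- layout$end[i] - layout$start[i + 1] + 1
      if (ov > 0 && (ov >= sizes[i] || ov >= sizes[i + 1])) {
        stop("inconsistent template: overlap at ", layout$gene[i], "/",
             layout$gene[i + 1], " longer than a flanking gene")
      }
    }
  }
  stopifnot(all(at_targets > 0 & at_targets < 1))
  structure(
    list(layout = layout, genome_length = as.integer(genome_length),
         species = species, at_targets = at_targets, cr_plan = cr_plan,
         plant_junction_motifs = plant_junction_motifs,
         seed = as.integer(seed)),
    class = "genome_template"
  )
}

# base-sampling probabilities (A,C,G,T) for an AT fraction
at_probs <- function(at) c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)

draw_bases <- function(k, at) {
  if (k <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), k, replace = TRUE, prob = at_probs(at))
}

# sense-codon sampling profile whose conditional AT content (stop codons
# excluded) equals `target`: solve the unconditional per-base AT weight.
sense_codon_profile <- function(code, target) {
  sense <- names(code$codons)[!(names(code$codons) %in% code$stops)]
  mats <- strsplit(sense, "")
  at_count <- vapply(mats, function(b) sum(b %in% c("A", "T")), numeric(1))
  prob_for <- function(q) {
    pb <- setNames(at_probs(q), c("A", "C", "G", "T"))
    p <- vapply(mats, function(b) prod(pb[b]), numeric(1))
    p / sum(p)
  }
  f <- function(q) sum(prob_for(q) * at_count) / 3 - target
  q <- stats::uniroot(f, c(0.02, 0.98))$root
  setNames(prob_for(q), sense)
}

# independent reverse complement (no Biostrings): used for ground truth
rc_chars <- function(chars) rev(chartr("ACGT", "TGCA", chars))

#' Simulate an annotated mitogenome from a template
#'
#' Emits a sequence honouring the template layout: protein-coding genes
#' get their declared start codon, interior codons drawn codon-wise from
#' an AT-matched sense-codon profile (so no in-frame stops arise), and
#' their declared complete or truncated stop; reverse-strand features are
#' written as reverse complements; the control region is assembled from
#' the element plan; remaining gaps (spacers) are filled i.i.d. at the
#' spacer AT target. Overlapping features share sequence: bases already
#' written by an upstream feature are preserved. Deterministic given the
#' template (including its seed).
#'
#' @param tpl a [genome_template()].
#' @param code a [genetic_code()].
#' @return list with `record` (a [mito_record()]) and `truth`, the
#'   generator's ground-truth ledger: planted junction values, codon
#'   counts per gene and pooled (tallied by the generator's own
#'   independent pass over the final sequence), control-region element
#'   positions, junction-motif positions, and region AT targets.
#' @examples
#' sim <- simulate_mitogenome(genome_template(seed = 42))
#' sim$record$annotation$genome_length   # 15252
#' @export
simulate_mitogenome <- function(tpl, code = genetic_code()) {
  stopifnot(inherits(tpl, "genome_template"))
  set.seed(tpl$seed)
  lay <- tpl$layout
  n <- tpl$genome_length
  genome <- rep(NA_character_, n)
  at <- tpl$at_targets
  profile <- sense_codon_profile(code, at[["PCG"]])
  sense_codons <- names(profile)

  truth <- list(seed = tpl$seed, genome_length = n,
                at_targets = at, cr = NULL, junction_motifs = list())

  # pre-plant the atp8/atp6 overlap motif so both genes incorporate it
  if (tpl$plant_junction_motifs &&
      all(c("atp8", "atp6") %in% lay$gene)) {
    i8 <- match("atp8", lay$gene); i6 <- match("atp6", lay$gene)
    ign <- lay$start[i6] - lay$end[i8] - 1
    if (ign == -7 && lay$strand[i8] == "F" && lay$strand[i6] == "F") {
      genome[lay$start[i6]:(lay$start[i6] + 6)] <-
        strsplit("ATGATAA", "")[[1]]
      truth$junction_motifs$atp8_atp6 <- list(motif = "ATGATAA",
                                              start = lay$start[i6])
    }
  }

  write_span <- function(from, to, sense_chars, strand) {
    fwd <- if (strand == "R") rc_chars(sense_chars) else sense_chars
    idx <- from:to
    keep <- is.na(genome[idx])
    genome[idx[keep]] <<- fwd[keep]
  }

  build_pcg <- function(size, start_codon, stop_codon) {
    rem <- size %% 3
    trailing <- character(0)
    complete_stop <- NULL
    if (!is.na(stop_codon) && stop_codon %in% c("T", "TA")) {
      if (nchar(stop_codon) != rem) {
        stop("truncated stop '", stop_codon,
             "' inconsistent with gene length remainder ", rem)
      }
      trailing <- strsplit(stop_codon, "")[[1]]
    } else if (!is.na(stop_codon)) {
      complete_stop <- stop_codon
    }
    k <- size %/% 3
    body <- k - 1 - (!is.null(complete_stop))
    if (body < 0) stop("PCG too short for its codon plan")
    cods <- c(start_codon,
              sample(sense_codons, body, replace = TRUE, prob = profile),
              complete_stop)
    c(unlist(strsplit(cods, "")), trailing)
  }

  build_cr <- function(size) {
    plan <- tpl$cr_plan
    if (is.null(plan)) {
      return(list(chars = draw_bases(size, at[["control"]]), truth = NULL))
    }
    motif <- strsplit(plan$motif, "")[[1]]
    polyT <- rep("T", plan$polyT)
    micro <- rep(strsplit(plan$microsat_motif, "")[[1]],
                 plan$microsat_copies)
    unit <- draw_bases(plan$tandem_unit_length, at[["control"]])
    tandem <- rep(unit, plan$tandem_copies)
    polyA <- rep("A", plan$polyA)
    # guard bases stop planted runs from bleeding into flanking filler
    fixed <- length(motif) + length(polyT) + length(micro) +
      length(tandem) + length(polyA) + 4
    if (size < fixed + 12) stop("control region too small for its plan")
    spare <- size - fixed
    f1 <- spare %/% 3; f2 <- spare %/% 3; f3 <- spare - f1 - f2
    filler <- function(k) draw_bases(k, at[["control"]])
    nonT <- function() sample(c("A", "G", "C"), 1, prob = c(0.8, .1, .1))
    gcb <- function() sample(c("G", "C"), 1)
    chars <- c(motif, polyT, nonT(), filler(f1), "A", micro, gcb(),
               filler(f2), tandem, filler(f3), gcb(), polyA)
    stopifnot(length(chars) == size)
    micro_start <- length(motif) + length(polyT) + 1 + f1 + 1 + 1
    tandem_start <- micro_start + length(micro) + 1 + f2
    list(chars = chars,
         truth = list(
           motif = plan$motif, motif_start = 1L,
           polyT_length = plan$polyT,
           polyT_start = length(motif) + 1L,
           microsat_motif = plan$microsat_motif,
           microsat_copies = plan$microsat_copies,
           microsat_start = as.integer(micro_start),
           tandem_unit = paste(unit, collapse = ""),
           tandem_unit_length = plan$tandem_unit_length,
           tandem_copies = plan$tandem_copies,
           tandem_start = as.integer(tandem_start),
           tandem_end = as.integer(tandem_start + length(tandem) - 1),
           polyA_length = plan$polyA,
           polyA_start = as.integer(size - plan$polyA + 1)))
  }

  for (i in seq_len(nrow(lay))) {
    size <- lay$end[i] - lay$start[i] + 1
    cat_i <- lay$category[i]
    if (cat_i == "PCG") {
      sense <- build_pcg(size, lay$start_codon[i], lay$stop_codon[i])
    } else if (cat_i == "control") {
      cr <- build_cr(size)
      sense <- cr$chars
      truth$cr <- cr$truth
    } else {
      tgt <- if (lay$gene[i] %in% names(at)) at[[lay$gene[i]]] else
        if (cat_i %in% names(at)) at[[cat_i]] else at[["spacer"]]
      sense <- draw_bases(size, tgt)
    }
    write_span(lay$start[i], lay$end[i], sense, lay$strand[i])
  }

  gaps <- which(is.na(genome))
  genome[gaps] <- draw_bases(length(gaps), at[["spacer"]])

  # plant the conserved spacer motif between trnS2 and nad1
  if (tpl$plant_junction_motifs &&
      all(c("trnS2", "nad1") %in% lay$gene)) {
    is2 <- match("trnS2", lay$gene); in1 <- match("nad1", lay$gene)
    sp_from <- lay$end[is2] + 1
    sp_to <- lay$start[in1] - 1
    if (sp_to - sp_from + 1 >= 7) {
      off <- sample(seq_len(sp_to - sp_from + 1 - 6), 1)
      genome[(sp_from + off - 1):(sp_from + off + 5)] <-
        strsplit("ATACTAA", "")[[1]]
      truth$junction_motifs$trnS2_nad1 <- list(motif = "ATACTAA",
                                               offset = as.integer(off))
    }
  }

  # ground-truth junction ledger straight from the template coordinates
  m <- nrow(lay)
  ign <- c(lay$start[-1] - lay$end[-m] - 1,
           lay$start[1] + n - lay$end[m] - 1)
  truth$junctions <- data.frame(
    upstream = lay$gene, downstream = c(lay$gene[-1], lay$gene[1]),
    ign = as.integer(ign), stringsAsFactors = FALSE)

  # independent codon tally over the final sequence (no Biostrings, no
  # extract_codons): reading-strand triplets, trailing remainder dropped,
  # classified stop dropped, matching the default usage convention
  pcg_rows <- which(lay$category == "PCG")
  counts <- setNames(integer(length(sense_codons)), sense_codons)
  per_gene <- list()
  for (i in pcg_rows) {
    fwd <- genome[lay$start[i]:lay$end[i]]
    sns <- if (lay$strand[i] == "R") rc_chars(fwd) else fwd
    k <- length(sns) %/% 3
    cods <- vapply(seq_len(k), function(j)
      paste(sns[(3 * j - 2):(3 * j)], collapse = ""), character(1))
    if (cods[k] %in% code$stops) cods <- cods[-k]
    cods <- cods[!(cods %in% code$stops)]
    tb <- table(cods)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    per_gene[[lay$gene[i]]] <- length(cods)
  }
  truth$codon_counts <- counts
  truth$codons_per_gene <- unlist(per_gene)

  features <- data.frame(
    gene = lay$gene, category = lay$category, strand = lay$strand,
    start = lay$start, end = lay$end,
    size_declared = as.numeric(lay$end - lay$start + 1),
    anticodon = NA_character_, anticodon_start = NA_real_,
    anticodon_end = NA_real_,
    start_codon = lay$start_codon, stop_codon = lay$stop_codon,
    ign_declared = c(NA, ign[-m]),
    stringsAsFactors = FALSE)
  ann <- mito_annotation(tpl$species, features, genome_length = n)
  rec <- mito_record(ann, paste(genome, collapse = ""))
  list(record = rec, truth = truth)
}

#' Specification of a sequence-evolution run
#'
#' @param tree a Newick string or `phylo` object; branch lengths in
#'   expected substitutions per site.
#' @param kappa transition/transversion rate ratio (> 0, default 2).
#' @param gene_lengths named integer vector of per-gene root lengths.
#' @param at_bias root-sequence AT fraction (default 0.8).
#' @param seed integer seed.
#' @return object of class `evolution_spec`.
#' @export
evolution_spec <- function(tree, kappa = 2,
                           gene_lengths = c(nad2 = 300, cox1 = 450),
                           at_bias = 0.8, seed = 1) {
  if (is.character(tree)) {
    tree <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                     error = function(e) NULL)
    if (is.null(tree) || !inherits(tree, "phylo")) {
      stop("malformed Newick string")
    }
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must carry non-negative branch lengths")
  }
  if (length(tree$tip.label) < 3) stop("need at least 3 leaves")
  stopifnot(kappa > 0, all(gene_lengths >= 3), !is.null(names(gene_lengths)))
  structure(list(tree = tree, kappa = kappa, gene_lengths = gene_lengths,
                 at_bias = at_bias, seed = as.integer(seed)),
            class = "evolution_spec")
}

# closed-form K2P transition probabilities for branch length t (expected
# substitutions/site) and ts/tv ratio kappa; rows/cols A,C,G,T
k2p_transition_matrix <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", C = "T", G = "A", T = "C")
  P <- matrix(p_tv, 4, 4, dimnames = list(bases, bases))
  diag(P) <- p_same
  for (b in bases) P[b, ts_partner[[b]]] <- p_ts
  P
}

evolve_chars <- function(parent, P) {
  child <- character(length(parent))
  for (b in c("A", "C", "G", "T")) {
    idx <- which(parent == b)
    if (length(idx) > 0) {
      child[idx] <- sample(colnames(P), length(idx), replace = TRUE,
                           prob = P[b, ])
    }
  }
  child
}

#' Evolve per-taxon gene sequences along a guide tree
#'
#' Root sequences are drawn i.i.d. at the specified AT bias and evolved
#' along the tree under a site-independent two-rate
#' (transition/transversion) substitution process with closed-form
#' transition probabilities per branch. No indels: output per gene is
#' aligned by construction.
#'
#' @param spec an [evolution_spec()].
#' @return named list (taxon -> named character vector of gene
#'   sequences), with the guide tree attached as attribute `tree`.
#' @export
evolve_panel <- function(spec) {
  stopifnot(inherits(spec, "evolution_spec"))
  set.seed(spec$seed)
  tree <- stats::reorder(spec$tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  n_nodes <- max(tree$edge)
  out <- lapply(tree$tip.label, function(x) character(0))
  names(out) <- tree$tip.label
  for (g in names(spec$gene_lengths)) {
    L <- spec$gene_lengths[[g]]
    states <- vector("list", n_nodes)
    states[[root]] <- draw_bases(L, spec$at_bias)
    # preorder: visit edges parent-before-child
    ord <- rev(seq_len(nrow(tree$edge)))
    for (e in ord) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      P <- k2p_transition_matrix(tree$edge.length[e], spec$kappa)
      states[[child]] <- evolve_chars(states[[parent]], P)
    }
    for (i in seq_len(ntip)) {
      out[[tree$tip.label[i]]][g] <- paste(states[[i]], collapse = "")
    }
  }
  attr(out, "tree") <- spec$tree
  out
}
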