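test_that("supermatrix concatenation, gap fill and partitions are exact", {
  sizes <- feature_sizes(persimilis_ann())
  blocks <- lapply(pcg13, function(g)
    strrep("A", unname(sizes[[g]])))
  names(blocks) <- pcg13
  sm <- build_supermatrix(list(tax1 = unlist(blocks)))
  expect_equal(sm$length, 11222)
  expect_equal(sum(sm$partitions$end - sm$partitions$start + 1), sm$length)
  expect_equal(sm$partitions$gene, pcg13)

  two <- build_supermatrix(list(a = c(nad2 = "ACGT"), b = c(nad2 = "ACGT")))
  expect_equal(two$matrix[["a"]], two$matrix[["b"]])

  gs <- list(a = c(nad2 = "ACGT", nad6 = "GGCC"),
             b = c(nad2 = "TTTT"))
  sm2 <- build_supermatrix(gs)
  expect_equal(sm2$length, 8)
  expect_equal(sm2$matrix[["b"]], "TTTT----")

  # column count invariant to taxon order
  sm3 <- build_supermatrix(gs[c("b", "a")])
  expect_equal(sm3$length, sm2$length)

  expect_error(build_supermatrix(list(a = character(0))), "no genes")
  expect_error(build_supermatrix(list(a = c(nad2 = "ACGT"),
                                      b = c(nad2 = "ACG"))),
               "nad2.*b")
})

test_that("partition files round-trip and cover both schemes", {
  gs <- list(a = c(nad2 = "ACGTAA", cox1 = "ACG"))
  sm <- build_supermatrix(gs)
  pf <- tempfile()
  write_partition_file(sm, pf)
  expect_equal(read_partition_file(pf), sm$partitions)
  write_partition_file(sm, pf, by_codon_position = TRUE)
  lines <- readLines(pf)
  expect_equal(length(lines), 6)
  expect_match(lines[1], "nad2_pos1 = 1-6\\\\3")
  expect_equal(read_partition_file(pf), sm$partitions)
})

test_that("distances follow the K2P closed form and p bound", {
  # 1000 sites: 100 transitions, 50 transversions -> P=0.1, Q=0.05
  a <- strrep("A", 1000)
  b <- paste0(strrep("G", 100), strrep("C", 50), strrep("A", 850))
  pair <- setNames(c(a, b), c("x", "y"))
  dp <- distances(pair, model = "p")
  expect_equal(dp$matrix["x", "y"], 0.15)
  dk <- distances(pair, model = "K2P")
  expect_equal(dk$matrix["x", "y"], -0.5 * log(0.75 * sqrt(0.9)),
               tolerance = 1e-12)

  same <- distances(setNames(c(a, a), c("x", "y")), model = "K2P")
  expect_equal(same$matrix["x", "y"], 0)

  # K2P >= p on random pairs, and both agree with ape's reference
  set.seed(55)
  for (i in 1:100) {
    L <- 300
    s1 <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    s2 <- ifelse(runif(L) < 0.25,
                 sample(c("A", "C", "G", "T"), L, replace = TRUE), s1)
    pr <- setNames(c(paste(s1, collapse = ""), paste(s2, collapse = "")),
                   c("u", "v"))
    dk <- distances(pr, "K2P")
    dp <- distances(pr, "p")
    expect_gte(dk$matrix[1, 2], dp$matrix[1, 2])
    if (i <= 10) {
      bin <- ape::as.DNAbin(t(sapply(pr, function(x)
        strsplit(tolower(x), "")[[1]])))
      expect_equal(dk$matrix[1, 2],
                   as.matrix(ape::dist.dna(bin, "K80"))[1, 2],
                   tolerance = 1e-10)
      expect_equal(dp$matrix[1, 2],
                   as.matrix(ape::dist.dna(bin, "raw"))[1, 2],
                   tolerance = 1e-10)
    }
  }
})

test_that("gap handling, saturation and degenerate pairs behave", {
  pr <- setNames(c("AC-TA", "ACGTT"), c("x", "y"))
  d <- distances(pr, "p")          # pairwise deletion: 4 sites, 1 diff
  expect_equal(d$matrix[1, 2], 0.25)

  tri <- setNames(c("AC-TA", "ACGTA", "NNGTA"), c("x", "y", "z"))
  dc <- distances(tri, "p", pairwise_deletion = FALSE)
  expect_equal(dc$matrix["x", "y"], 0)  # only complete columns remain

  sat <- distances(setNames(c("AAAA", "GGGG"), c("x", "y")), "K2P",
                   saturation_cap = 7)
  expect_equal(sat$matrix[1, 2], 7)
  expect_true(sat$saturated[1, 2])

  expect_error(distances(setNames(c("NNNN", "AAAA"), c("x", "y")), "p"),
               "no comparable sites")
  expect_error(distances(setNames("ACGT", "x")), "two taxa")
})

test_that("neighbour joining is exact on additive distances", {
  # 4 taxa from a known tree: ((A:1,B:2):1,(C:3,D:4)) with internal 1
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(tr, ape::read.tree(
    text = "((A:1,B:2):1,C:3,D:4);"))), 0)
  # recovered branch lengths reproduce the generating tree's distances
  expect_equal(unname(as.matrix(cophenetic(tr))[rownames(D), colnames(D)]),
               unname(D), tolerance = 1e-10)

  # 3 taxa: closed-form three-point branch lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(D3)
  expect_equal(length(tr3$tip.label), 3)
  bl <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.5, 1.5, 2.5))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("NJ recovers random additive topologies (n <= 12)", {
  set.seed(77)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    njt <- nj_tree(cophenetic(tr))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), njt)), 0)
  }
})

test_that("a 5-taxon NJ tree matches exhaustive least squares", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  taxa <- letters[1:5]
  for (rep in 1:5) {
    tr <- ape::rtree(5, tip.label = taxa)
    D <- cophenetic(tr)[taxa, taxa]
    njt <- nj_tree(D)
    # least-squares fit of every unrooted 5-taxon topology
    cands <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
    ss <- vapply(cands, function(cand) {
      cand$edge.length <- rep(1, nrow(cand$edge))
      pairs <- t(combn(taxa, 2))
      X <- matrix(0, nrow(pairs), nrow(cand$edge))
      for (k in seq_len(nrow(pairs))) {
        i <- match(pairs[k, 1], cand$tip.label)
        j <- match(pairs[k, 2], cand$tip.label)
        np <- ape::nodepath(cand, i, j)
        for (e in seq_len(nrow(cand$edge))) {
          a <- cand$edge[e, 1]; b <- cand$edge[e, 2]
          hit <- FALSE
          for (q in seq_len(length(np) - 1)) {
            if ((np[q] == a && np[q + 1] == b) ||
                (np[q] == b && np[q + 1] == a)) hit <- TRUE
          }
          X[k, e] <- as.integer(hit)
        }
      }
      d <- D[cbind(pairs[, 1], pairs[, 2])]
      fit <- lm.fit(X, d)
      sum(fit$residuals^2)
    }, numeric(1))
    best <- cands[[which.min(ss)]]
    expect_equal(as.numeric(ape::dist.topo(best, njt)), 0)
  }
})

test_that("monophyly queries answer under outgroup rooting", {
  nwk <- "(((A:1,B:1):2,(C:1,D:1):1):1,E:3);"
  tr <- ape::read.tree(text = nwk)
  expect_true(is_monophyletic(tr, c("A", "B"), "E")$monophyletic)
  expect_false(is_monophyletic(tr, c("A", "C"), "E")$monophyletic)
  expect_true(is_monophyletic(tr, "A", "E")$monophyletic)
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D"), "E")$monophyletic)
  expect_error(is_monophyletic(tr, c("A", "Z"), "E"), "unknown")
  expect_error(is_monophyletic(tr, c("A", "E"), "E"), "outgroup")
})

test_that("matrix writers emit readable PHYLIP and NEXUS", {
  sm <- build_supermatrix(list("tax one" = c(nad2 = "ACGT"),
                               tax2 = c(nad2 = "TTTT")))
  pf <- tempfile()
  write_phylip(sm, pf)
  lines <- readLines(pf)
  expect_equal(lines[1], "2 4")
  expect_match(lines[2], "^tax_one  ACGT$")
  nf <- tempfile()
  write_nexus(sm, nf)
  nx <- readLines(nf)
  expect_equal(nx[1], "#NEXUS")
  expect_true(any(grepl("NTAX=2 NCHAR=4", nx)))
})
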