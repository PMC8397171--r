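test_that("feature tables parse with the published coordinate conventions", {
  ann <- persimilis_ann()
  expect_s3_class(ann, "mito_annotation")
  expect_equal(nrow(ann$features), 38)
  expect_equal(ann$genome_length, 15252)

  trnQ <- ann$features[ann$features$gene == "trnQ", ]
  expect_equal(trnQ$strand, "R")
  expect_equal(trnQ$start, 132)
  expect_equal(trnQ$end, 200)
  expect_equal(unname(feature_sizes(ann)[["trnQ"]]), 69)

  ann2 <- nama_ann()
  expect_equal(nrow(ann2$features), 38)
  expect_equal(ann2$genome_length, 15208)
  expect_equal(sum(ann2$features$category == "PCG"), 13)
  expect_equal(sum(ann2$features$category == "tRNA"), 22)

  # genome_length defaults to the maximum end coordinate
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(paste("gene", "direction", "location", "size", "anticodon",
                     "start_codon", "stop_codon", "intergenic_nucleotides",
                     sep = "\t"),
               paste("trnM", "F", "1-68", "68", "CAT 32-34", "", "", "",
                     sep = "\t")), tf)
  one <- read_feature_table(tf, "single")
  expect_equal(one$genome_length, 68)
})

test_that("locations tolerate en-dashes and thousands separators", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(paste("gene", "direction", "location", "size", "anticodon",
                     "start_codon", "stop_codon", "intergenic_nucleotides",
                     sep = "\t"),
               paste("trnQ", "R", "132–200", "69", "TTG 159-161",
                     "", "", "-3", sep = "\t"),
               paste("cob", "F", "10,442-11,593", "1152", "", "ATG", "TAA",
                     "3", sep = "\t")), tf)
  ann <- read_feature_table(tf, "dash")
  expect_equal(ann$features$start, c(132, 10442))
  expect_equal(ann$features$end, c(200, 11593))
  expect_equal(ann$features$ign_declared, c(-3, 3))
})

test_that("malformed rows and unknown genes are named errors", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(paste("gene", "direction", "location", "size", "anticodon",
                     "start_codon", "stop_codon", "intergenic_nucleotides",
                     sep = "\t"),
               paste("trnM", "F", "oops", "68", "", "", "", "",
                     sep = "\t")), tf)
  expect_error(read_feature_table(tf, "bad"), "trnM")

  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c(paste("gene", "direction", "location", "size", "anticodon",
                     "start_codon", "stop_codon", "intergenic_nucleotides",
                     sep = "\t"),
               paste("notagene", "F", "1-10", "10", "", "", "", "",
                     sep = "\t")), tf2)
  expect_error(read_feature_table(tf2, "bad"), "unknown gene")
  expect_equal(canonical_gene_name(c("COI", "lrRNA", "D-loop")),
               c("cox1", "rrnL", "control_region"))
})

test_that("parse / serialize round trip preserves every column", {
  for (maker in list(persimilis_ann, nama_ann)) {
    ann <- maker()
    tf <- tempfile(fileext = ".tsv")
    write_feature_table(ann, tf)
    back <- read_feature_table(tf, ann$species)
    expect_equal(back$features, ann$features)
    expect_equal(back$genome_length, ann$genome_length)
  }
})

test_that("validator surfaces declared-size and anticodon inconsistencies", {
  rep1 <- validate_annotation(persimilis_ann())
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$gene, "trnY")
  expect_equal(rep1$type, "anticodon_outside")

  rep2 <- validate_annotation(nama_ann())
  expect_equal(nrow(rep2), 2)
  expect_setequal(rep2$gene, c("nad2", "trnE"))
  expect_equal(rep2$type[rep2$gene == "nad2"], "size_mismatch")
  expect_match(rep2$detail[rep2$gene == "nad2"], "1013.*1014")
  expect_equal(rep2$type[rep2$gene == "trnE"], "anticodon_outside")

  clean <- mito_annotation("clean", data.frame(
    gene = c("nad2", "cox1"), category = "PCG", strand = "F",
    start = c(1, 101), end = c(99, 200),
    size_declared = c(99, 100),
    start_codon = "ATG", stop_codon = "TAA",
    stringsAsFactors = FALSE))
  expect_equal(nrow(validate_annotation(clean)), 0)

  # a same-strand PCG overlap outside the canonical pairs is flagged
  odd <- mito_annotation("odd", data.frame(
    gene = c("nad2", "cox1"), category = "PCG", strand = "F",
    start = c(1, 90), end = c(99, 200),
    size_declared = c(99, 111),
    start_codon = "ATG", stop_codon = "TAA",
    stringsAsFactors = FALSE))
  expect_true("pcg_overlap" %in% validate_annotation(odd)$type)
})

test_that("feature_sequence extracts the sense strand", {
  rec <- toy_record("ATGCGGGG", data.frame(
    gene = c("trnM", "trnI"), category = "tRNA", strand = c("F", "R"),
    start = c(1, 5), end = c(4, 8), size_declared = c(4, 4),
    anticodon = c("CAT 2-4", NA), anticodon_start = c(2, NA),
    anticodon_end = c(4, NA), stringsAsFactors = FALSE))
  expect_equal(feature_sequence(rec, "trnM"), "ATGC")
  expect_equal(feature_sequence(rec, "trnI"), "CCCC")
  # reverse complement on an asymmetric slice
  rec2 <- toy_record("ATGC", data.frame(
    gene = "trnM", category = "tRNA", strand = "R", start = 1, end = 4,
    stringsAsFactors = FALSE))
  expect_equal(feature_sequence(rec2, "trnM"), "GCAT")
  expect_error(feature_sequence(rec, "cox1"), "no feature")
  norec <- mito_record(rec$annotation, NULL)
  expect_error(feature_sequence(norec, "trnM"), "no sequence")
  # length always matches the span
  ann <- persimilis_ann()
  sim <- simulate_mitogenome(genome_template(seed = 3))
  sizes <- feature_sizes(sim$record$annotation)
  for (g in names(sizes)) {
    expect_equal(nchar(feature_sequence(sim$record, g)), unname(sizes[[g]]))
  }
})

test_that("GenBank records parse, honour complement(), and round-trip", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 30 bp    DNA     circular INV",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    "     CDS             complement(10..20)",
    "                     /gene=\"nad2\"",
    "ORIGIN",
    "        1 atgcatgcat gcatgcatgc atgcatgcat",
    "//"), gb)
  rec <- read_genbank(gb)
  f <- rec$annotation$features
  expect_equal(f$strand, "R")
  expect_equal(f$start, 10)
  expect_equal(f$end, 20)
  expect_equal(nchar(rec$sequence), 30)

  # annotation-only record: no ORIGIN, no error
  gb2 <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 30 bp    DNA     circular INV",
    "FEATURES             Location/Qualifiers",
    "     tRNA            1..30",
    "                     /gene=\"trnM\"",
    "//"), gb2)
  expect_null(read_genbank(gb2)$sequence)

  # join locations are rejected, not silently split
  gb3 <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 30 bp    DNA     circular INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(1..10,21..30)",
    "                     /gene=\"nad2\"",
    "//"), gb3)
  expect_error(read_genbank(gb3), "join")

  # generator-emitted GenBank round-trips
  sim <- simulate_mitogenome(genome_template(seed = 11))
  out <- tempfile(fileext = ".gb")
  write_genbank(sim$record, out)
  back <- read_genbank(out)
  core <- c("gene", "category", "strand", "start", "end", "start_codon",
            "stop_codon")
  expect_equal(back$annotation$features[core],
               sim$record$annotation$features[core])
  expect_equal(back$annotation$genome_length,
               sim$record$annotation$genome_length)
  expect_equal(back$sequence, sim$record$sequence)
})

test_that("annotations serialize to JSON", {
  ann <- persimilis_ann()
  js <- jsonlite::fromJSON(annotation_to_json(ann))
  expect_equal(js$genome_length, 15252)
  expect_equal(nrow(js$features), 38)
})
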