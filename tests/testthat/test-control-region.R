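cr_only_record <- function(seq) {
  toy_record(seq, data.frame(
    gene = "control_region", category = "control", strand = "F",
    start = 1, end = nchar(seq), stringsAsFactors = FALSE))
}

# a 376 bp control-region-only template: fast plant-and-recover unit
cr_template <- function(seed, plan = default_cr_plan()) {
  genome_template(layout = data.frame(
    gene = "control_region", category = "control", strand = "F",
    start = 1, end = 376, start_codon = NA_character_,
    stop_codon = NA_character_, stringsAsFactors = FALSE),
    cr_plan = plan, seed = seed)
}

test_that("microsatellite runs are maximal, left-greedy and exact", {
  runs <- microsatellite_scan("ATATATATATAT", min_copies = 3)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$copies, 6)
  expect_equal(runs$start, 1)

  expect_equal(nrow(microsatellite_scan("ATATA", min_copies = 3)), 0)

  runs2 <- microsatellite_scan("GGATATATATATGG", min_copies = 3)
  expect_equal(runs2$copies, 5)
  expect_equal(runs2$start, 3)

  # planted (AT)10 in a uniform-random 1 kb background: exactly that run
  set.seed(31)
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
              collapse = "")
  planted <- paste0(substr(bg, 1, 500), "CC", strrep("AT", 10), "CC",
                    substr(bg, 501, 1000))
  runs3 <- microsatellite_scan(planted, "AT", min_copies = 5)
  expect_equal(nrow(runs3), 1)
  expect_equal(runs3$copies, 10)
  expect_equal(runs3$start, 503)

  expect_error(microsatellite_scan("ACGT", "", 3), "empty motif")
})

test_that("tandem arrays match their defining statistics", {
  tr <- tandem_repeat_scan("ACGTACGTACGT", min_unit = 2, max_unit = 6)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$unit_length, 4)
  expect_equal(tr$unit, "ACGT")
  expect_equal(tr$copies, 3)
  expect_equal(tr$identity, 1)

  # 23 bp unit twice with one mismatch in copy 2: identity 22/23
  set.seed(17)
  unit <- paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE),
                collapse = "")
  copy2 <- unit
  substr(copy2, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                   substr(unit, 12, 12))[1]
  tr2 <- tandem_repeat_scan(paste0(unit, copy2), min_unit = 10,
                            max_unit = 23)
  expect_equal(nrow(tr2), 1)
  expect_equal(tr2$unit_length, 23)
  expect_equal(tr2$identity, 22 / 23, tolerance = 1e-12)
  expect_equal(tr2$copies, 2)

  expect_error(tandem_repeat_scan("ACGT", min_unit = 1), "min_unit")
  expect_error(tandem_repeat_scan("ACGT", min_unit = 4, max_unit = 3),
               "max_unit")
})

test_that("the scanner agrees with the exhaustive oracle on short input", {
  set.seed(92)
  cases <- list(
    list(len = 40, at = 0.5, max_unit = 12),
    list(len = 60, at = 0.9, max_unit = 15),
    list(len = 80, at = 0.8, max_unit = 20),
    list(len = 120, at = 0.9, max_unit = 20),
    list(len = 200, at = 0.9, max_unit = 12)
  )
  for (cs in cases) {
    seq <- paste(sample(c("A", "C", "G", "T"), cs$len, replace = TRUE,
                        prob = c(cs$at / 2, (1 - cs$at) / 2,
                                 (1 - cs$at) / 2, cs$at / 2)),
                 collapse = "")
    # half the cases carry a planted repeat so both code paths exercise
    # the found branch
    if (cs$len >= 80) {
      u <- substr(seq, 10, 20)
      seq <- paste0(substr(seq, 1, 30), strrep(u, 3),
                    substr(seq, 31, cs$len - 33))
      seq <- substr(seq, 1, min(nchar(seq), 200))
    }
    got <- tandem_repeat_scan(seq, min_unit = 2, max_unit = cs$max_unit)
    want <- oracle_tandem_scan(seq, min_unit = 2, max_unit = cs$max_unit)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$unit_length, want$unit_length)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$copies, want$copies)
      expect_equal(got$identity, want$identity, tolerance = 1e-12)
    }
  }
})

test_that("every planted control-region element is recovered", {
  for (s in 1:12) {
    sim <- simulate_mitogenome(cr_template(seed = s))
    gt <- sim$truth$cr
    rep <- dissect_control_region(sim$record)

    expect_equal(rep$origin_block$motif_start, gt$motif_start)
    expect_equal(rep$origin_block$polyT_length, gt$polyT_length)
    expect_equal(rep$origin_block$polyT_start, gt$polyT_start)
    expect_equal(rep$polyA$length, gt$polyA_length)
    expect_equal(rep$polyA$start, gt$polyA_start)

    ms <- rep$microsatellites
    expect_true(any(ms$start == gt$microsat_start &
                    ms$copies == gt$microsat_copies))

    tr <- rep$tandem_repeats
    planted <- tr[tr$unit_length == gt$tandem_unit_length, ]
    expect_equal(nrow(planted), 1)
    expect_lte(planted$start, gt$tandem_start)
    expect_gte(planted$end, gt$tandem_end - 2)
  }
})

test_that("elements can be absent without error", {
  # no ATAGA: origin absent, the rest still scanned
  seq <- paste0(strrep("GC", 30), strrep("AT", 6), strrep("GC", 20),
                strrep("A", 7))
  rep <- dissect_control_region(cr_only_record(seq))
  expect_null(rep$origin_block)
  expect_equal(rep$polyA$length, 7)
  expect_equal(rep$microsatellites$copies, 6)

  # all-A control region: the poly-A spans it; no microsatellite or
  # tandem calls
  repA <- dissect_control_region(cr_only_record(strrep("A", 120)))
  expect_equal(repA$polyA$length, 120)
  expect_equal(repA$polyA$start, 1)
  expect_equal(nrow(repA$microsatellites), 0)
  expect_equal(nrow(repA$tandem_repeats), 0)

  expect_error(dissect_control_region(
    mito_record(cr_only_record("AAAA")$annotation, NULL)), "no sequence")
  norc <- toy_record("AAAA", data.frame(
    gene = "trnM", category = "tRNA", strand = "F", start = 1, end = 4,
    stringsAsFactors = FALSE))
  expect_error(dissect_control_region(norc), "control_region")
})

test_that("dissection is invariant to flanking genomic context", {
  sim <- simulate_mitogenome(genome_template(seed = 13))
  in_situ <- dissect_control_region(sim$record)
  extracted <- dissect_control_region(
    cr_only_record(feature_sequence(sim$record, "control_region")))
  for (fld in c("length", "pct_AT", "origin_block", "polyA",
                "microsatellites", "tandem_repeats")) {
    expect_equal(in_situ[[fld]], extracted[[fld]], info = fld)
  }
})
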