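test_that("MAF is the ratio of discordant to concordant bases", {
  expect_equal(site_maf(c(A = 10), "A", "T"), 0)
  expect_equal(site_maf(c(A = 8, T = 2), "A", "T"), 0.25)
  expect_equal(site_maf(c(A = 5, T = 5), "A", "T"), 1.0)
  expect_error(site_maf(c(A = 0, T = 5), "A", "T"), "no base supports")
})

test_that("MAF and support ratio agree with brute arithmetic on random columns", {
  set.seed(3)
  for (i in 1:2000) {
    cnt <- stats::setNames(as.integer(sample(0:20, 4L, TRUE)), BASES4)
    present <- BASES4[cnt > 0L]
    if (!length(present)) next
    cons <- sample(present, 1L)
    other <- sample(setdiff(BASES4, cons), 1L)
    expect_equal(site_maf(cnt, cons, other), cnt[[other]] / cnt[[cons]])
    expect_equal(support_ratio(cnt, cons), cnt[[cons]] / sum(cnt) * 100)
  }
  # unanimous site: MAF 0 for every allele, support 100
  cnt <- c(A = 0L, C = 12L, G = 0L, T = 0L)
  for (al in c("A", "G", "T")) expect_equal(site_maf(cnt, "C", al), 0)
  expect_equal(support_ratio(cnt, "C"), 100)
})

test_that("heteroplasmy detection flags by strict MAF exceedance with a depth floor", {
  counts <- matrix(0L, 6L, 4L, dimnames = list(NULL, BASES4))
  counts[1L, ] <- c(8L, 0L, 0L, 2L)    # maf 0.25 -> flagged
  counts[2L, ] <- c(99L, 0L, 0L, 1L)   # maf ~0.0101 -> kept, not flagged
  counts[3L, ] <- c(20L, 0L, 0L, 0L)   # unanimous -> no row
  counts[4L, ] <- c(5L, 4L, 0L, 0L)    # depth 9 < min_depth -> no row
  counts[5L, ] <- c(9L, 1L, 0L, 0L)    # maf 1/9 > 0.10 -> flagged
  counts[6L, ] <- c(10L, 1L, 0L, 0L)   # maf 0.10, strict > -> not flagged
  pu <- make_pileup(counts)
  cons <- build_consensus(pu, "majority")
  het <- detect_heteroplasmy(pu, cons, maf_threshold = 0.10, min_depth = 10L)
  expect_equal(het$position, c(1L, 2L, 5L, 6L))
  expect_equal(het$flagged, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(het$maf[1L], 0.25)
  expect_equal(het$minor_fraction[1L], 0.2)
  expect_error(detect_heteroplasmy(pu, cons, maf_threshold = -1), "non-negative")
})

test_that("a homoplasmic genome yields an empty heteroplasmy list", {
  ref <- toy_ref(L = 300L, seed = 14L)
  sim <- simulate_reads(simulation_config(ref$sequence, depth = 30,
                                          read_length = 50L, error_rate = 0,
                                          seed = 2L), ref)
  pu <- build_pileup(sim$reads, ref)
  het <- detect_heteroplasmy(pu, build_consensus(pu, "majority"))
  expect_equal(nrow(het), 0L)
})

test_that("global aligner matches exhaustive enumeration and an independent aligner", {
  set.seed(17)
  for (i in 1:40) {
    na <- sample(1:6, 1L); nb <- sample(1:6, 1L)
    a <- paste(sample(BASES4, na, TRUE), collapse = "")
    b <- paste(sample(BASES4, nb, TRUE), collapse = "")
    got <- align_consensus_to_reference(a, reference_genome(b))
    expect_equal(got$score, brute_nw_score(a, b), info = paste(a, b))
  }
  # cross-check on longer sequences against Biostrings' global aligner
  for (i in 1:5) {
    a <- paste(sample(BASES4, 60L, TRUE), collapse = "")
    b <- paste(sample(BASES4, 55L, TRUE), collapse = "")
    got <- align_consensus_to_reference(a, reference_genome(b))
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    want <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(got$score, want)
  }
})

test_that("alignment map is an identity on equal sequences and skips deletions", {
  ref <- reference_genome("ACGTACGT")
  al <- align_consensus_to_reference("ACGTACGT", ref)
  expect_equal(al$map$consensus_pos, 1:8)
  expect_equal(al$map$ref_pos, 1:8)
  expect_length(al$ref_deleted, 0L)

  del <- align_consensus_to_reference("ACGACGT", ref)
  expect_equal(del$ref_deleted, 4L)
  expect_true(all(diff(del$map$ref_pos) > 0L))
  expect_true(all(diff(del$map$consensus_pos) > 0L))

  # degenerate all-N consensus still aligns (everything mismatches)
  nn <- align_consensus_to_reference(strrep("N", 8L), ref)
  expect_equal(nrow(nn$map), 8L)
  expect_equal(nn$score, -8)
})

test_that("variant calling labels substitutions and deletions on reference coordinates", {
  ref <- toy_ref(L = 200L, seed = 31L)
  rc <- strsplit(ref$sequence, "")[[1L]]
  stopifnot(rc[150L] != "T")
  cons <- rc; cons[150L] <- if (rc[150L] == "C") "T" else "C"
  lab <- paste0(rc[150L], 150L, cons[150L])
  v <- call_variants(align_consensus_to_reference(paste(cons, collapse = ""), ref))
  expect_equal(v$variants$label, lab)
  expect_equal(v$variants$position, 150L)
  expect_length(v$insertions, 0L)

  # identical consensus: no variants; N at a mismatch: no variant
  v0 <- call_variants(align_consensus_to_reference(ref$sequence, ref))
  expect_equal(nrow(v0$variants), 0L)
  consN <- rc; consN[150L] <- "N"
  vN <- call_variants(align_consensus_to_reference(paste(consN, collapse = ""), ref))
  expect_equal(nrow(vN$variants), 0L)

  # a dropped (deleted) base becomes a <ref><pos>d variant
  vD <- call_variants(align_consensus_to_reference(
    paste(rc[-100L], collapse = ""), ref))
  expect_equal(vD$variants$type, "deletion")
  expect_equal(vD$variants$label, paste0(rc[100L], vD$variants$position, "d"))
})

test_that("variant labels round-trip through parse and format", {
  for (lab in c("C150T", "A4282G", "A249d", "G11778A")) {
    p <- parse_variant(lab)
    expect_equal(format_variant(p$ref, p$pos, if (p$type == "deletion") NA else p$alt),
                 lab)
  }
  expect_error(parse_variant("150CT"), "unparseable")
})

test_that("annotation joins on exact allele labels and keeps unmatched variants", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("allele,disease", "C150T,example-disease",
               "C150T,second-report", "bogus!!,skipme"), csv)
  expect_warning(db <- read_annotation_csv(csv), "skipped")
  expect_equal(attr(db, "n_skipped"), 1L)
  vars <- data.frame(label = c("C150T", "A4282G"), position = c(150L, 4282L),
                     ref = c("C", "A"), alt = c("T", "G"),
                     type = "substitution", stringsAsFactors = FALSE)
  ann <- annotate_variants(vars, db)
  expect_equal(sum(ann$label == "C150T"), 2L)            # both db rows reported
  expect_true(is.na(ann$info[ann$label == "A4282G"]))    # unmatched kept
  # empty database: everything unannotated
  ann0 <- annotate_variants(vars, db[0L, ])
  expect_true(all(is.na(ann0$info)))
  # non-overlapping database: zero matches
  db2 <- data.frame(allele = "T152C", info = "x", source = "d2")
  expect_true(all(is.na(annotate_variants(vars, db2)$info)))
})

test_that("substitution spectrum counts mismatches and normalizes to 100%", {
  ref <- reference_genome(strrep("ACGT", 25L))
  sim <- simulate_reads(simulation_config(ref$sequence, depth = 20,
                                          read_length = 20L, error_rate = 0,
                                          seed = 3L), ref)
  sp0 <- substitution_spectrum(sim$reads, ref)
  expect_true(sp0$no_mismatch)
  expect_true(all(sp0$counts == 0L))

  # exactly 3 C>T and 1 G>A planted mismatches
  rc <- strsplit(ref$sequence, "")[[1L]]
  cpos <- which(rc == "C")[1:3]; gpos <- which(rc == "G")[1L]
  reads <- do.call(rbind, c(
    lapply(seq_along(cpos), function(i) make_read(cpos[i], "T", qname = paste0("c", i))),
    list(make_read(gpos, "A", qname = "g"))))
  sp <- substitution_spectrum(reads, ref)
  expect_equal(sp$total_mismatches, 4L)
  expect_equal(unname(sp$percentage["C>T"]), 75)
  expect_equal(unname(sp$percentage["G>A"]), 25)
  expect_equal(sum(sp$percentage), 100)
})

test_that("spectrum conservation and deamination dominance on simulated reads", {
  ref <- toy_ref(L = 1500L, seed = 23L)
  sim <- simulate_reads(simulation_config(
    ref$sequence, depth = 40, read_length = 60L, error_rate = 0,
    deamination = list(rate0 = 0.3, decay = 3), seed = 13L), ref)
  sp <- substitution_spectrum(sim$reads, ref,
                              filter_policy(min_base_quality = 20L))
  # every injected damage event and nothing else shows up in the spectrum
  expect_equal(sp$total_mismatches, nrow(sim$truth$damage))
  expect_equal(sum(sp$counts[c("C>T", "G>A")]), sp$total_mismatches)
  expect_gt(sum(sp$percentage[c("C>T", "G>A")]), 99.9)
})
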