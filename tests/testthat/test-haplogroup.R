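write_tree_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

toy_tree <- function() {
  parse_haplotree(write_tree_file(c(
    "R\t\t",
    "A\tR\tG5A",
    "B\tA\tT7C")))
}

test_that("variant tokens parse into substitutions, deletions and insertions", {
  s <- parse_variant_token("A73G")
  expect_equal(s[c("kind", "pos", "ref", "alt", "back")],
               list(kind = "substitution", pos = 73L, ref = "A", alt = "G",
                    back = FALSE))
  expect_true(s$scorable)
  b <- parse_variant_token("A5G!")
  expect_true(b$back)
  d <- parse_variant_token("A249d")
  expect_equal(d[c("kind", "pos", "alt")],
               list(kind = "deletion", pos = 249L, alt = "-"))
  i <- parse_variant_token("16182.1C")
  expect_equal(i$kind, "insertion")
  expect_false(i$scorable)
  expect_error(parse_variant_token("XYZ"), "unparseable")
})

test_that("tree parsing validates structure with line numbers", {
  tr <- toy_tree()
  expect_equal(tr$root, "R")
  expect_equal(unname(tr$depth[c("R", "A", "B")]), c(0L, 1L, 2L))

  expect_error(parse_haplotree(write_tree_file(c("R\t\t", "R\tR\tG5A"))),
               "line 2.*duplicate")
  expect_error(parse_haplotree(write_tree_file(c("R\t\t", "A\tZZ\tG5A"))),
               "unknown parent")
  expect_error(parse_haplotree(write_tree_file(c("A\tB\tG5A", "B\tA\tT7C"))),
               "exactly one root|cycle")
  expect_error(parse_haplotree(write_tree_file(c("R\t\t", "A\tR\t??"))),
               "line 2.*unparseable")
  ref <- reference_genome("ACGTACGTAC")
  expect_error(parse_haplotree(write_tree_file(c("R\t\t", "A\tR\tG99A")), ref),
               "line 2.*outside")
})

test_that("cumulative variants accumulate along the path; back-mutations cancel", {
  tr <- toy_tree()
  expect_equal(cumulative_variants(tr, "B")$state, c("5" = "A", "7" = "C"))
  expect_equal(cumulative_variants(tr, "A")$state, c("5" = "A"))
  expect_length(cumulative_variants(tr, "R")$state, 0L)

  tr2 <- parse_haplotree(write_tree_file(c(
    "R\t\t", "A\tR\tG5A,T7C", "B\tA\tA5G!", "C\tB\t16182.1C")))
  expect_equal(cumulative_variants(tr2, "B")$state, c("7" = "C"))
  expect_equal(cumulative_variants(tr2, "C")$insertions, "16182.1C")
  expect_equal(cumulative_variants(tr2, "C")$state, c("7" = "C"))
})

test_that("cumulative variants match a brute-force path replay on random trees", {
  set.seed(77)
  ref <- toy_ref(L = 800L, seed = 70L)
  for (rep in 1:5) {
    tr <- random_haplotree(ref, n_nodes = sample(5:20, 1L),
                           variants_per_node = sample(2:5, 1L),
                           seed = 100L + rep)
    for (nm in names(tr$nodes)) {
      # literal replay: walk up, then apply top-down
      path <- nm
      while (!is.na(tr$nodes[[path[1L]]]$parent))
        path <- c(tr$nodes[[path[1L]]]$parent, path)
      want <- character(0)
      for (p in path) for (v in tr$nodes[[p]]$variants) {
        if (v$kind == "insertion") next
        if (v$back) want <- want[names(want) != as.character(v$pos)]
        else want[as.character(v$pos)] <- v$alt
      }
      want <- want[order(as.integer(names(want)))]
      expect_identical(cumulative_variants(tr, nm)$state, want)
    }
  }
})

test_that("haplogroup scoring counts matches, mismatches and no-calls", {
  tr <- toy_tree()
  L <- 10L
  calls <- rep("N", L)
  mk_cons <- function(bases) {
    cnt <- matrix(0L, L, 4L, dimnames = list(NULL, BASES4))
    for (i in seq_len(L)) if (bases[i] %in% BASES4)
      cnt[i, bases[i]] <- 10L
    cons <- build_consensus(make_pileup(cnt), "majority")
    cons$base <- bases  # allow explicit N placement
    cons
  }
  hapB <- rep("G", L); hapB[5L] <- "A"; hapB[7L] <- "C"
  expect_equal(unname(score_haplogroup(mk_cons(hapB), tr, "B")), c(2L, 0L, 0L))
  root_state <- rep("G", L); root_state[7L] <- "T"
  expect_equal(unname(score_haplogroup(mk_cons(root_state), tr, "B")),
               c(0L, 2L, 0L))
  hapN <- hapB; hapN[7L] <- "N"
  expect_equal(unname(score_haplogroup(mk_cons(hapN), tr, "B")), c(1L, 0L, 1L))
  expect_error(score_haplogroup(mk_cons(hapB), tr, "nope"), "unknown")
})

test_that("a consensus synthesized from any node's variants ranks that node first", {
  ref <- toy_ref(L = 2000L, seed = 55L)
  tr <- random_haplotree(ref, n_nodes = 12L, variants_per_node = 4L, seed = 56L)
  for (nm in names(tr$nodes)) {
    hap <- make_haplotype(ref, cumulative_variants(tr, nm)$state)
    cnt <- matrix(0L, ref$length, 4L, dimnames = list(NULL, BASES4))
    cnt[cbind(seq_len(ref$length), match(strsplit(hap, "")[[1L]], BASES4))] <- 10L
    call <- assign_haplogroup(build_consensus(make_pileup(cnt), "majority"), tr)
    expect_equal(call$best, nm)
  }
})

test_that("error-free reads from a toy haplotype recover it at 50x", {
  ref <- toy_ref(L = 2000L, seed = 61L)
  tr <- random_haplotree(ref, n_nodes = 8L, variants_per_node = 4L, seed = 62L)
  hap <- make_haplotype(ref, cumulative_variants(tr, "HG04")$state)
  sim <- simulate_reads(simulation_config(hap, depth = 50, error_rate = 0,
                                          seed = 63L), ref)
  pu <- build_pileup(sim$reads, ref)
  expect_equal(assign_haplogroup(pu, tr)$best, "HG04")
  # reference-state reads rank the root first
  simR <- simulate_reads(simulation_config(ref$sequence, depth = 50,
                                           error_rate = 0, seed = 64L), ref)
  expect_equal(assign_haplogroup(build_pileup(simR$reads, ref), tr)$best, "ROOT")
})

test_that("P_mismatch follows the per-site mismatch/match ratio mean", {
  tr <- toy_tree()
  # defining sites of B: pos 5 expects A, pos 7 expects C
  cnt <- matrix(0L, 10L, 4L, dimnames = list(NULL, BASES4))
  cnt[5L, "A"] <- 9L; cnt[5L, "G"] <- 1L       # ratio 1/9
  cnt[7L, "C"] <- 10L                          # ratio 0
  pu <- make_pileup(cnt)
  pm <- p_mismatch(pu, tr, "B")
  expect_equal(as.numeric(pm), (1 / 9 + 0) / 2 * 100, tolerance = 1e-12)
  expect_equal(attr(pm, "k"), 2L)

  # unanimous defining sites: exactly zero
  cnt0 <- cnt; cnt0[5L, "G"] <- 0L
  expect_equal(as.numeric(p_mismatch(make_pileup(cnt0), tr, "B")), 0)

  # sites with no supporting base are dropped from k
  cntx <- cnt; cntx[7L, "C"] <- 0L; cntx[7L, "T"] <- 4L
  pmx <- p_mismatch(make_pileup(cntx), tr, "B")
  expect_equal(attr(pmx, "k"), 1L)
  expect_equal(attr(pmx, "n_excluded"), 1L)
  cnt_none <- matrix(0L, 10L, 4L, dimnames = list(NULL, BASES4))
  expect_error(p_mismatch(make_pileup(cnt_none), tr, "B"), "no scorable")
})

test_that("assignment accuracy is TP/(TP+FP)", {
  expect_equal(assignment_accuracy(letters[1:10], letters[1:10]), 1.0)
  pred <- letters[1:10]; pred[10L] <- "z"
  expect_equal(assignment_accuracy(letters[1:10], pred), 0.9)
  expect_equal(assignment_accuracy(c("a", "b"), c("x", "y")), 0.0)
  expect_error(assignment_accuracy(character(0), character(0)), "non-empty")
})

test_that("tree files round-trip through write_haplotree", {
  ref <- toy_ref(L = 500L, seed = 81L)
  tr <- random_haplotree(ref, n_nodes = 6L, variants_per_node = 3L, seed = 82L)
  path <- tempfile(fileext = ".tsv")
  write_haplotree(tr, path)
  back <- parse_haplotree(path, ref)
  expect_setequal(names(back$nodes), names(tr$nodes))
  for (nm in names(tr$nodes))
    expect_identical(cumulative_variants(back, nm)$state,
                     cumulative_variants(tr, nm)$state)
})
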