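# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately written in the most literal style possible (per-read loops,
# per-column enumeration) so it stays independent of the vectorized
# implementation paths it checks.

BASES4 <- c("A", "C", "G", "T")

toy_ref <- function(L = 3000L, seed = 99L, name = "toyMT") {
  set.seed(seed)
  reference_genome(paste(sample(BASES4, L, replace = TRUE), collapse = ""),
                   name)
}

# Minimal read-table row constructor matching read_alignments() layout.
make_read <- function(pos, seq, qual = NULL, mapq = 60L, cigar = NULL,
                      strand = "+", dup = FALSE, secondary = FALSE,
                      qname = "r") {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))           # Q40
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  data.frame(qname = qname, flag = ifelse(strand == "-", 16L, 0L),
             pos = pos, mapq = mapq, cigar = cigar, seq = seq, qual = qual,
             strand = strand, is_unmapped = FALSE, is_dup = dup,
             is_secondary = secondary, stringsAsFactors = FALSE)
}

phred_chr <- function(q) intToUtf8(q + 33L, multiple = FALSE)

# Directly assemble a Pileup object from a counts matrix (documented
# structure), for formula tests that need exact column contents.
make_pileup <- function(counts, best_quality = NULL, deletion_count = NULL,
                        raw_depth = NULL, min_bq = 30L) {
  counts <- as.matrix(counts)
  colnames(counts) <- BASES4
  L <- nrow(counts)
  if (is.null(best_quality)) {
    best_quality <- matrix(NA_integer_, L, 4L, dimnames = list(NULL, BASES4))
    best_quality[counts > 0L] <- 40L
  }
  if (is.null(deletion_count)) deletion_count <- integer(L)
  fd <- as.integer(rowSums(counts)) + deletion_count
  if (is.null(raw_depth)) raw_depth <- fd
  structure(list(counts = counts, best_quality = best_quality,
                 deletion_count = deletion_count, raw_depth = raw_depth,
                 filtered_depth = fd,
                 policy = filter_policy(min_base_quality = min_bq),
                 ref_name = "manual", length = L),
            class = "Pileup")
}

# --- brute-force pileup walker ---------------------------------------------
# Walks each read's CIGAR character by character; the only shared knowledge
# with the implementation is the SAM CIGAR definition itself.
brute_pileup <- function(reads, ref, policy) {
  L <- ref$length
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, BASES4))
  best <- matrix(NA_integer_, L, 4L, dimnames = list(NULL, BASES4))
  del <- integer(L); raw <- integer(L)
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (r$is_unmapped || r$pos < 1L) next
    if (r$mapq < policy$min_mapping_quality) next
    if (policy$exclude_duplicates && r$is_dup) next
    if (policy$exclude_secondary && r$is_secondary) next
    ops <- regmatches(r$cigar, gregexpr("[0-9]+[MIDNSHP=X]", r$cigar))[[1L]]
    rp <- r$pos; qp <- 1L
    sq <- strsplit(r$seq, "")[[1L]]
    qu <- as.integer(charToRaw(r$qual)) - 33L
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      code <- sub("[0-9]+", "", op)
      if (code %in% c("M", "=", "X")) {
        for (k in seq_len(n)) {
          b <- sq[qp]; q <- qu[qp]
          raw[rp] <- raw[rp] + 1L
          if (b %in% BASES4 && q >= policy$min_base_quality) {
            j <- match(b, BASES4)
            counts[rp, j] <- counts[rp, j] + 1L
            if (is.na(best[rp, j]) || q > best[rp, j]) best[rp, j] <- q
          }
          rp <- rp + 1L; qp <- qp + 1L
        }
      } else if (code == "D") {
        for (k in seq_len(n)) {
          del[rp] <- del[rp] + 1L
          raw[rp] <- raw[rp] + 1L
          rp <- rp + 1L
        }
      } else if (code %in% c("I", "S")) {
        qp <- qp + n
      } else if (code == "N") {
        rp <- rp + n
      }
    }
  }
  list(counts = counts, best = best, del = del, raw = raw)
}

# --- brute-force consensus enumerators -------------------------------------
brute_majority <- function(cnt, del) {
  mx <- -1L; who <- character(0)
  for (b in BASES4) if (cnt[[b]] > mx) { mx <- cnt[[b]]; who <- b }
    else if (cnt[[b]] == mx) who <- c(who, b)
  if (del > mx) return("-")
  if (mx == 0L) return("N")
  if (length(who) > 1L) return("N")
  who
}

brute_bestscore <- function(cnt, bq) {
  cand <- BASES4[cnt[BASES4] > 0L]
  if (!length(cand)) return("N")
  q <- bq[cand]
  top <- cand[q == max(q)]
  if (length(top) > 1L) "N" else top
}

brute_combined <- function(cnt, bq, del) {
  maj <- brute_majority(cnt, del)
  if (maj != "N") return(maj)
  mx <- max(cnt[BASES4])
  if (mx == 0L) return("N")
  tied <- BASES4[cnt[BASES4] == mx]
  q <- bq[tied]
  top <- tied[q == max(q)]
  if (length(top) > 1L) "N" else top
}

random_column <- function() {
  cnt <- stats::setNames(as.integer(sample(0:9, 4L, replace = TRUE)), BASES4)
  bq <- stats::setNames(as.integer(sample(30:40, 4L, replace = TRUE)), BASES4)
  bq[cnt == 0L] <- NA_integer_
  del <- sample(0:3, 1L)
  list(counts = cnt, best = bq, del = del)
}

# --- brute-force global alignment score ------------------------------------
# Plain recursion over all alignments (no DP table), feasible to ~8 bases.
brute_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    if (av[i] == bv[j]) match else mismatch)
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(av), length(bv))
}

# Same recursion with a cache so length-8 pairs stay fast; the move set and
# scoring are spelled out independently of the C++ implementation.
memo_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- if (i == 0L && j == 0L) 0 else {
      best <- -Inf
      if (i > 0L && j > 0L)
        best <- max(best, rec(i - 1L, j - 1L) +
                      if (av[i] == bv[j]) match else mismatch)
      if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
      if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
      best
    }
    memo[[key]] <- out
    out
  }
  rec(length(av), length(bv))
}

# 16-node synthetic study tree + reference shared by end-to-end tests.
study_setup <- function(seed = 2024L) {
  ref <- toy_ref(L = 16569L, seed = seed, name = "synthMT")
  tree <- random_haplotree(ref, n_nodes = 16L, variants_per_node = 6L,
                           seed = seed + 1L)
  list(ref = ref, tree = tree)
}
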