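#' Read/base filter policy
#'
#' Filters applied before a base enters the pileup: read-level mapping
#' quality, duplicate and secondary-alignment exclusion, and a per-base
#' phred threshold. A base is counted iff its phred score is `>=`
#' `min_base_quality` (so the default of 30 admits Q30 bases), its read
#' passes the read-level filters, and it is one of A/C/G/T.
#'
#' @param min_base_quality Minimum phred base quality (default 30).
#' @param min_mapping_quality Minimum mapping quality (default 20; mtDNA
#'   alignment tools rarely state one, so this is explicit and configurable).
#' @param exclude_duplicates Drop reads flagged as PCR/optical duplicates.
#' @param exclude_secondary Drop secondary alignments.
#' @return A `FilterPolicy` object.
#' @export
filter_policy <- function(min_base_quality = 30L,
                          min_mapping_quality = 20L,
                          exclude_duplicates = TRUE,
                          exclude_secondary = TRUE) {
  stopifnot(min_base_quality >= 0, min_mapping_quality >= 0)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 exclude_duplicates = isTRUE(exclude_duplicates),
                 exclude_secondary = isTRUE(exclude_secondary)),
            class = "FilterPolicy")
}

#' Read an alignment file (BAM or SAM) into a read table
#'
#' SAM input is converted on the fly with [Rsamtools::asBam()]. Only the
#' fields the profiling pipeline needs are retained. Reads are *not*
#' filtered here; filtering happens at pileup time under a [filter_policy()].
#'
#' @param path Path to a coordinate-sorted BAM or SAM file.
#' @return A data.frame with one row per alignment record: `qname`, `flag`,
#'   `pos` (1-based leftmost reference position), `mapq`, `cigar`, `seq`,
#'   `qual` (phred+33 string), `strand`, and logical `is_unmapped`,
#'   `is_dup`, `is_secondary`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  what <- c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual", "strand")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  flag <- res$flag
  data.frame(
    qname = res$qname,
    flag = flag,
    pos = ifelse(is.na(res$pos), 0L, res$pos),
    mapq = ifelse(is.na(res$mapq), 0L, res$mapq),
    cigar = ifelse(is.na(res$cigar), "", res$cigar),
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    strand = ifelse(as.character(res$strand) == "-", "-", "+"),
    is_unmapped = bitwAnd(flag, 4L) > 0L,
    is_dup = bitwAnd(flag, 1024L) > 0L,
    is_secondary = bitwAnd(flag, 256L) > 0L,
    stringsAsFactors = FALSE
  )
}

# Apply read-level filters (mapping quality, duplicate, secondary, unmapped).
filter_reads <- function(reads, policy) {
  keep <- !reads$is_unmapped & reads$pos >= 1L &
    reads$mapq >= policy$min_mapping_quality
  if (policy$exclude_duplicates) keep <- keep & !reads$is_dup
  if (policy$exclude_secondary) keep <- keep & !reads$is_secondary
  reads[keep, , drop = FALSE]
}

# Lay every read onto reference space and expand to one row per aligned
# position. CIGAR insertions/soft-clips are removed, deletions appear as "-".
# Returns a list with parallel vectors over aligned positions:
#   pos, base (single char, "-" for deletion), phred (integer, NA at
#   deletions), read_idx (row in `reads`), off5 (1-based offset from the
#   original molecule's 5' end, NA at deletions), off3 (from the 3' end),
# plus read_len (aligned query length per read).
expand_alignments <- function(reads, ref) {
  n <- nrow(reads)
  if (n == 0L) {
    return(list(pos = integer(0), base = character(0), bidx = integer(0),
                is_del = logical(0), phred = integer(0),
                read_idx = integer(0), off5 = integer(0), off3 = integer(0),
                read_len = integer(0), n_ambiguous = 0L))
  }
  cig <- reads$cigar
  slay <- GenomicAlignments::sequenceLayer(Biostrings::BStringSet(reads$seq), cig)
  qlay <- GenomicAlignments::sequenceLayer(Biostrings::BStringSet(reads$qual), cig)
  w <- Biostrings::width(slay)
  ends <- reads$pos + w - 1L
  if (any(ends > ref$length))
    stop("read(s) extend past the reference end (position ",
         max(ends), " > ", ref$length, "); circular wrap-around is not supported")
  pos <- sequence(w, from = reads$pos)
  read_idx <- rep.int(seq_len(n), w)
  bytes <- as.integer(charToRaw(paste(as.character(slay), collapse = "")))
  bidx <- match(bytes, c(65L, 67L, 71L, 84L))       # A C G T
  is_del <- bytes == 45L                            # "-"
  base <- rep.int("N", length(bytes))
  has <- !is.na(bidx)
  base[has] <- BASES[bidx[has]]
  base[is_del] <- "-"
  n_ambiguous <- sum(!has & !is_del & bytes != 78L) # anything but ACGTN-
  phred <- as.integer(charToRaw(paste(as.character(qlay), collapse = ""))) - 33L
  phred[is_del] <- NA_integer_
  # Query offset among non-deleted positions of each read, then convert to
  # molecule coordinates: reverse-strand reads were sequenced from the other
  # end, so their 5' offset runs right-to-left along the reference.
  qoff <- integer(length(base))
  nd <- !is_del
  qoff[nd] <- sequence(tabulate(read_idx[nd], nbins = n))
  read_len <- tabulate(read_idx[nd], nbins = n)
  len_here <- read_len[read_idx]
  rev_here <- (reads$strand == "-")[read_idx]
  off5 <- qoff
  if (any(rev_here))
    off5[rev_here] <- len_here[rev_here] - qoff[rev_here] + 1L
  off3 <- len_here - off5 + 1L
  off5[is_del] <- NA_integer_
  off3[is_del] <- NA_integer_
  list(pos = pos, base = base, bidx = bidx, is_del = is_del, phred = phred,
       read_idx = read_idx, off5 = off5, off3 = off3, read_len = read_len,
       n_ambiguous = n_ambiguous)
}

#' Build a quality-filtered pileup over the full reference
#'
#' Walks every filter-passing read and accumulates, per reference position,
#' the count of each base A/C/G/T whose phred score is at least
#' `policy$min_base_quality`, the best (maximum) phred score seen per base,
#' the number of spanning CIGAR deletions, and the raw (pre-quality-filter)
#' depth. `N` and IUPAC-ambiguous read bases are never counted (ambiguity
#' codes are reported once via a message); CIGAR insertions do not create
#' columns. Reads may not extend past the reference end (the mitochondrial
#' genome is circular but the coordinate frame is linear; origin-spanning
#' reads are rejected).
#'
#' @param reads Read table from [read_alignments()] or [simulate_reads()].
#' @param ref A [load_reference()] genome.
#' @param policy A [filter_policy()].
#' @return An object of class `Pileup`: list with `counts` (L x 4 integer
#'   matrix, columns A,C,G,T), `best_quality` (L x 4, `NA` where the count is
#'   zero), `deletion_count`, `raw_depth`, `filtered_depth` (all length-L
#'   integer vectors), plus `policy` and `ref_name`.
#' @export
build_pileup <- function(reads, ref, policy = filter_policy()) {
  stopifnot(inherits(ref, "ReferenceGenome"))
  L <- ref$length
  kept <- filter_reads(reads, policy)
  ex <- expand_alignments(kept, ref)
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  best <- matrix(NA_integer_, nrow = L, ncol = 4L,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  del <- integer(L)
  raw <- integer(L)
  if (length(ex$pos)) {
    raw <- tabulate(ex$pos, nbins = L)
    if (any(ex$is_del))
      del <- tabulate(ex$pos[ex$is_del], nbins = L)
    bidx <- ex$bidx
    if (ex$n_ambiguous > 0L)
      message("build_pileup: ", ex$n_ambiguous,
              " base(s) with IUPAC ambiguity codes treated as N (uncounted)")
    ok <- !is.na(bidx) & !is.na(ex$phred) & ex$phred >= policy$min_base_quality
    if (any(ok)) {
      key <- (ex$pos[ok] - 1L) * 4L + bidx[ok]
      cnt <- tabulate(key, nbins = L * 4L)
      counts <- matrix(cnt, nrow = L, ncol = 4L, byrow = TRUE,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
      o <- order(ex$phred[ok])  # ascending: last write per cell is the max
      best[cbind(ex$pos[ok][o], bidx[ok][o])] <- ex$phred[ok][o]
    }
  }
  structure(list(counts = counts, best_quality = best,
                 deletion_count = del, raw_depth = raw,
                 filtered_depth = as.integer(rowSums(counts)) + del,
                 policy = policy, ref_name = ref$name, length = L),
            class = "Pileup")
}

#' @export
print.Pileup <- function(x, ...) {
  cat("Pileup over", x$length, "positions of", x$ref_name, "\n")
  cat("  mean raw depth:", round(mean(x$raw_depth), 2),
      " mean filtered depth:", round(mean(x$filtered_depth), 2), "\n")
  invisible(x)
}

stat_block <- function(x) {
  if (length(x) == 0L || all(is.na(x)))
    return(list(mean = 0, sd = 0, min = 0, q1 = 0, median = 0, q3 = 0, max = 0))
  q <- stats::quantile(x, c(.25, .5, .75), na.rm = TRUE, names = FALSE)
  list(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
       min = min(x, na.rm = TRUE), q1 = q[1L], median = q[2L], q3 = q[3L],
       max = max(x, na.rm = TRUE))
}

#' Alignment summary statistics
#'
#' Computes the quality-control overview of an alignment: read counts,
#' distributions of raw depth, read length, per-read GC content, mapping
#' quality and base quality, and genome coverage breadth — the fraction of
#' reference positions whose raw depth strictly exceeds each threshold.
#'
#' @param reads Read table.
#' @param pileup A [build_pileup()] result over the full reference.
#' @param ref The reference genome.
#' @param depth_thresholds Breadth thresholds (default `c(10,20,30,40,50)`).
#' @return A `SummaryStats` list: `total_reads`, `mapped_reads`,
#'   `duplicate_reads`, stat blocks (`mean`/`sd`/`min`/`q1`/`median`/`q3`/
#'   `max`) for `depth`, `read_length`, `gc_content`, `mapping_quality`,
#'   `base_quality`, the named `coverage_breadth` vector, and `no_data`.
#' @export
summarize_alignment <- function(reads, pileup, ref,
                                depth_thresholds = c(10L, 20L, 30L, 40L, 50L)) {
  stopifnot(inherits(pileup, "Pileup"), pileup$length == ref$length)
  mapped <- reads[!reads$is_unmapped & reads$pos >= 1L, , drop = FALSE]
  no_data <- nrow(mapped) == 0L
  if (no_data) {
    gc <- numeric(0); lens <- integer(0); bq <- integer(0)
  } else {
    lens <- nchar(mapped$seq)
    nGC <- nchar(gsub("[^GCgc]", "", mapped$seq))
    nACGT <- nchar(gsub("[^ACGTacgt]", "", mapped$seq))  # N ignored
    gc <- ifelse(nACGT > 0L, nGC / nACGT, NA_real_)
    bq <- as.integer(charToRaw(paste(mapped$qual, collapse = ""))) - 33L
  }
  breadth <- vapply(depth_thresholds,
                    function(t) mean(pileup$raw_depth > t), numeric(1))
  names(breadth) <- paste0(">", depth_thresholds)
  structure(list(
    total_reads = nrow(reads),
    mapped_reads = nrow(mapped),
    duplicate_reads = sum(reads$is_dup),
    depth = stat_block(pileup$raw_depth),
    read_length = stat_block(lens),
    gc_content = stat_block(gc),
    mapping_quality = stat_block(if (no_data) integer(0) else mapped$mapq),
    base_quality = stat_block(bq),
    coverage_breadth = breadth,
    no_data = no_data
  ), class = "SummaryStats")
}

#' Write summary statistics as TSV and JSON
#'
#' @param stats A [summarize_alignment()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_summary <- function(stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(
    c("depth", "read_length", "gc_content", "mapping_quality", "base_quality"),
    function(k) data.frame(metric = k, as.data.frame(stats[[k]]))))
  tsv <- file.path(dir, "summary_stats.tsv")
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "summary_stats.json")
  jsonlite::write_json(unclass(stats), js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv, js))
}

#' Write per-position depth as TSV
#'
#' Columns: position, raw_depth, filtered_depth.
#' @param pileup A `Pileup`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_depth_tsv <- function(pileup, path) {
  utils::write.table(
    data.frame(position = seq_len(pileup$length),
               raw_depth = pileup$raw_depth,
               filtered_depth = pileup$filtered_depth),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
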