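#' Minor allele frequency at one pileup column
#'
#' The ratio of bases discordant with the consensus to bases concordant
#' with it: `MAF = N_diff / N_con`, where `N_diff` is the count of the
#' candidate minor allele and `N_con` the count of the consensus base. Note
#' this is a ratio to *concordant* bases, not to total depth, and exceeds 1
#' when the minor allele outnumbers the consensus; the conventional fraction
#' `N_diff / (N_diff + N_con)` is reported alongside it by
#' [detect_heteroplasmy()].
#'
#' @param counts Named integer base counts at the site.
#' @param consensus_base The consensus base at the site (must have count
#'   >= 1, otherwise the ratio is undefined and an error is raised).
#' @param allele The candidate minor allele (different from the consensus).
#' @return The MAF as a non-negative fraction.
#' @examples
#' site_maf(c(A = 8, T = 2), "A", "T")  # 0.25
#' @export
site_maf <- function(counts, consensus_base, allele) {
  stopifnot(consensus_base %in% BASES, allele %in% BASES,
            allele != consensus_base)
  cnt <- as_counts(counts)
  n_con <- cnt[[consensus_base]]
  if (n_con == 0L)
    stop("MAF undefined when no base supports the consensus")
  cnt[[allele]] / n_con
}

#' Detect heteroplasmic sites by minor allele frequency
#'
#' Scans every reference position whose consensus base is A/C/G/T and whose
#' filtered depth reaches `min_depth`, and reports each non-consensus allele
#' observed there together with its MAF (`N_diff / N_con`) and the
#' conventional minor fraction (`N_diff / (N_diff + N_con)`). A site is
#' flagged when some allele's MAF strictly exceeds `maf_threshold`
#' (heteroplasmy, contamination, or sequencing error cannot be told apart
#' at this stage; the threshold trades sensitivity against error calls).
#'
#' @param pileup A [build_pileup()] result.
#' @param consensus The [build_consensus()] result from the same pileup.
#' @param maf_threshold MAF detection threshold (default 0.10).
#' @param min_depth Minimum filtered depth for a site to be considered
#'   (default 10; without it a single discordant read at depth 2 is
#'   flagged).
#' @return A data.frame sorted by position with columns `position`,
#'   `consensus_base`, `allele`, `count`, `maf`, `minor_fraction`,
#'   `filtered_depth`, `flagged`. Homoplasmic (unanimous) sites contribute
#'   no rows.
#' @export
detect_heteroplasmy <- function(pileup, consensus, maf_threshold = 0.10,
                                min_depth = 10L) {
  stopifnot(inherits(pileup, "Pileup"), inherits(consensus, "ConsensusSequence"))
  if (!is.finite(maf_threshold) || maf_threshold < 0)
    stop("maf_threshold must be a non-negative finite fraction")
  cb <- consensus$base
  eligible <- which(cb %in% BASES & pileup$filtered_depth >= min_depth)
  out <- vector("list", 4L)
  for (k in seq_along(BASES)) {
    al <- BASES[k]
    idx <- eligible[cb[eligible] != al & pileup$counts[eligible, k] > 0L]
    if (!length(idx)) next
    n_diff <- pileup$counts[idx, k]
    n_con <- pileup$counts[cbind(idx, match(cb[idx], BASES))]
    out[[k]] <- data.frame(position = idx, consensus_base = cb[idx],
                           allele = al, count = n_diff,
                           maf = n_diff / n_con,
                           minor_fraction = n_diff / (n_diff + n_con),
                           filtered_depth = pileup$filtered_depth[idx],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(position = integer(0), consensus_base = character(0),
                      allele = character(0), count = integer(0),
                      maf = numeric(0), minor_fraction = numeric(0),
                      filtered_depth = integer(0), stringsAsFactors = FALSE)
  res <- res[order(res$position, res$allele), , drop = FALSE]
  rownames(res) <- NULL
  res$flagged <- res$maf > maf_threshold
  res
}

#' Global pairwise alignment of a consensus against the reference
#'
#' Needleman-Wunsch global alignment with fixed scoring (match +1,
#' mismatch -1, gap -2) and deterministic tie-breaking (prefer diagonal,
#' then up, then left at every cell). Used to restore positional
#' consistency between an assembled consensus (which may contain deletion
#' sites) and the reference before variant labelling.
#'
#' @param consensus_seq Consensus sequence as a character string (deletion
#'   `-` characters, if present, are dropped before alignment, as in the
#'   FASTA serialization).
#' @param ref A `ReferenceGenome`.
#' @param match,mismatch,gap Scoring parameters (documented defaults).
#' @return A list: `score`; `map`, a data.frame of aligned pairs
#'   (`consensus_pos`, `ref_pos`, `consensus_base`, `ref_base`) with both
#'   columns strictly increasing (a monotonic partial mapping);
#'   `ref_deleted`, reference positions absent from the map; and
#'   `cons_inserted`, consensus positions absent from the map.
#' @export
align_consensus_to_reference <- function(consensus_seq, ref,
                                         match = 1, mismatch = -1, gap = -2) {
  stopifnot(nchar(consensus_seq) > 0L, inherits(ref, "ReferenceGenome"))
  qs <- gsub("-", "", toupper(consensus_seq), fixed = TRUE)
  if (nchar(qs) == 0L) stop("consensus sequence is empty after dropping deletions")
  al <- nw_align_cpp(qs, ref$sequence, match, mismatch, gap)
  qchr <- strsplit(qs, "", fixed = TRUE)[[1L]]
  rchr <- ref_chars(ref)
  map <- data.frame(consensus_pos = al$query_pos, ref_pos = al$ref_pos,
                    consensus_base = qchr[al$query_pos],
                    ref_base = rchr[al$ref_pos], stringsAsFactors = FALSE)
  list(score = al$score, map = map,
       ref_deleted = setdiff(seq_len(ref$length), al$ref_pos),
       cons_inserted = setdiff(seq_len(nchar(qs)), al$query_pos),
       ref_chars = rchr)
}

#' Parse an rCRS-style variant label
#'
#' Grammar: `<ref><pos><alt>` for substitutions (C150T), `<ref><pos>d` for
#' deletions (A249d). An optional trailing `!` (PhyloTree back-mutation
#' marker) is accepted and flagged. Insertion tokens like `16182.1C` are
#' handled by [parse_variant_token()] in the haplogroup parser, not here.
#'
#' @param label Variant label string.
#' @return A list: `ref`, `pos`, `alt` (`NA` for deletions), `type`
#'   (`"substitution"` or `"deletion"`), `back` (logical).
#' @export
parse_variant <- function(label) {
  m <- regmatches(label, regexec("^([ACGT])([0-9]+)([ACGTd])(!?)$", label))[[1L]]
  if (length(m) == 0L) stop("unparseable variant label: '", label, "'")
  type <- if (m[4L] == "d") "deletion" else "substitution"
  list(ref = m[2L], pos = as.integer(m[3L]),
       alt = if (type == "deletion") NA_character_ else m[4L],
       type = type, back = m[5L] == "!")
}

#' Format a variant label
#' @param ref Reference base. @param pos 1-based position.
#' @param alt Alternate base, or `NA`/`"d"` for a deletion.
#' @return The label string, e.g. `"C150T"` or `"A249d"`.
#' @export
format_variant <- function(ref, pos, alt) {
  if (is.na(alt) || alt == "d") paste0(ref, pos, "d") else paste0(ref, pos, alt)
}

#' Call consensus-versus-reference variants
#'
#' Substitution variants are emitted for every aligned pair where the
#' consensus base is A/C/G/T and differs from the reference base; deletion
#' variants for reference positions absent from the alignment map; `N`
#' sites yield no variant (no-call semantics). Insertions relative to the
#' reference carry no reference-position label and are returned separately.
#'
#' @param alignment Result of [align_consensus_to_reference()].
#' @return A list: `variants`, a data.frame (`label`, `position`, `ref`,
#'   `alt`, `type`) sorted by position; `insertions`, an integer vector of
#'   unaligned consensus positions.
#' @export
call_variants <- function(alignment) {
  map <- alignment$map
  sub <- map[map$consensus_base %in% BASES &
               map$consensus_base != map$ref_base, , drop = FALSE]
  vars <- data.frame(
    label = c(paste0(sub$ref_base, sub$ref_pos, sub$consensus_base),
              if (length(alignment$ref_deleted))
                paste0(map_ref_base(alignment, alignment$ref_deleted),
                       alignment$ref_deleted, "d") else character(0)),
    position = c(sub$ref_pos, alignment$ref_deleted),
    ref = c(sub$ref_base, map_ref_base(alignment, alignment$ref_deleted)),
    alt = c(sub$consensus_base, rep(NA_character_,
                                    length(alignment$ref_deleted))),
    type = c(rep("substitution", nrow(sub)),
             rep("deletion", length(alignment$ref_deleted))),
    stringsAsFactors = FALSE)
  vars <- vars[order(vars$position), , drop = FALSE]
  rownames(vars) <- NULL
  list(variants = vars, insertions = alignment$cons_inserted)
}

# Reference base at given positions, from the reference kept alongside the
# alignment (deleted positions are absent from the map itself).
map_ref_base <- function(alignment, positions) {
  if (!length(positions)) return(character(0))
  alignment$ref_chars[positions]
}

#' Read a variant annotation database from CSV
#'
#' The expected layout matches customizable mtDNA annotation templates: a
#' comma-delimited file whose first column is a variant allele positioned on
#' the reference (e.g. `C150T`) and whose second column is free-text
#' information (e.g. a related-disease name). A header line is detected by
#' the first field failing to parse as a variant label. Rows whose allele
#' does not parse are skipped with a warning and counted.
#'
#' @param path CSV path.
#' @param name Database name recorded on each row (defaults to the file
#'   name).
#' @return A data.frame `allele`, `info`, `source`; the number of skipped
#'   rows is attached as attribute `n_skipped`.
#' @export
read_annotation_csv <- function(path, name = basename(path)) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2L) stop("annotation CSV needs two columns (allele, info): ", path)
  parses <- function(x) grepl("^[ACGT][0-9]+[ACGTd]!?$", x)
  if (nrow(raw) > 0L && !parses(raw[1L, 1L])) raw <- raw[-1L, , drop = FALSE]
  ok <- parses(raw[[1L]])
  if (any(!ok))
    warning(sum(!ok), " annotation row(s) with unparseable allele skipped in ",
            name)
  out <- data.frame(allele = raw[[1L]][ok], info = raw[[2L]][ok],
                    source = name, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Annotate called variants against one or more databases
#'
#' Joins on exact variant-label match. Every variant appears in the output;
#' unmatched variants carry `NA` annotation, and a variant matching several
#' database rows is reported once per match.
#'
#' @param variants Variant data.frame from [call_variants()].
#' @param db Annotation data.frame from [read_annotation_csv()] (several
#'   databases may be `rbind`-ed together).
#' @return A data.frame: variant columns plus `info` and `source`.
#' @export
annotate_variants <- function(variants, db) {
  if (is.null(db) || nrow(db) == 0L) {
    out <- variants
    out$info <- NA_character_
    out$source <- NA_character_
    return(out)
  }
  out <- merge(variants, db[, c("allele", "info", "source")],
               by.x = "label", by.y = "allele", all.x = TRUE, sort = FALSE)
  out <- out[order(out$position, out$source, out$info), , drop = FALSE]
  rownames(out) <- NULL
  out
}

SUBSTITUTION_KEYS <- as.vector(outer(BASES, BASES, function(r, a)
  paste0(r, ">", a)))[as.vector(outer(1:4, 1:4, "!="))]

#' Genome-wide base-substitution spectrum of mapped reads
#'
#' Counts every quality-filtered aligned read base that differs from the
#' reference base, keyed by the 12 ordered substitutions (reference base ->
#' read base), and normalizes to percentages over all mismatches. A heavily
#' skewed spectrum (e.g. C>T / G>A excess) indicates a sample- or
#' protocol-driven artefact such as post-mortem deamination rather than
#' natural mutation.
#'
#' @param reads Read table.
#' @param ref Reference genome.
#' @param policy A [filter_policy()].
#' @return A `SubstitutionSpectrum` list: `counts` and `percentage` (named
#'   length-12 vectors), `total_mismatches`, `total_bases` (filtered
#'   aligned A/C/G/T bases), and `no_mismatch` flag.
#' @export
substitution_spectrum <- function(reads, ref, policy = filter_policy()) {
  kept <- filter_reads(reads, policy)
  ex <- expand_alignments(kept, ref)
  rchr <- ref_chars(ref)
  ok <- which(ex$base %in% BASES & !is.na(ex$phred) &
                ex$phred >= policy$min_base_quality)
  refb <- rchr[ex$pos[ok]]
  readb <- ex$base[ok]
  counted <- refb %in% BASES
  mism <- counted & refb != readb
  counts <- stats::setNames(integer(12), SUBSTITUTION_KEYS)
  if (any(mism)) {
    tab <- table(paste0(refb[mism], ">", readb[mism]))
    counts[names(tab)] <- as.integer(tab)
  }
  total <- sum(counts)
  pct <- if (total > 0) counts / total * 100 else counts * 0
  structure(list(counts = counts, percentage = pct,
                 total_mismatches = total, total_bases = sum(counted),
                 no_mismatch = total == 0L),
            class = "SubstitutionSpectrum")
}
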