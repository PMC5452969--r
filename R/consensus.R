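BASES <- c("A", "C", "G", "T")

norm_mode <- function(mode) {
  m <- tolower(mode)
  if (m %in% c("majority")) return("majority")
  if (m %in% c("bestscore", "best-score", "best_score")) return("bestscore")
  if (m %in% c("combined", "majority+bestscore", "majority-bestscore",
               "majority_bestscore")) return("combined")
  stop("unknown consensus mode '", mode,
       "'; valid modes are: majority, bestscore, majority+bestscore")
}

as_counts <- function(counts) {
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  out[names(counts)] <- as.integer(counts)
  out
}

#' Majority-rule consensus base for one pileup column
#'
#' The most frequent filter-passing base wins; a tie for the maximum count
#' yields `N` (no call), as does an empty column. When the number of
#' spanning deletions strictly exceeds every base count the site is called
#' `-` (deletion).
#'
#' @param counts Named integer vector of base counts (subset of A,C,G,T).
#' @param deletion_count Number of reads with a deletion spanning the site.
#' @return A single character: one of A, C, G, T, N, `-`.
#' @examples
#' call_site_majority(c(A = 8, T = 2))  # "A"
#' call_site_majority(c(A = 8, T = 8))  # "N"
#' @export
call_site_majority <- function(counts, deletion_count = 0L) {
  cnt <- as_counts(counts)
  m <- max(cnt)
  if (deletion_count > m) return("-")
  if (m == 0L) return("N")
  hit <- which(cnt == m)
  if (length(hit) > 1L) return("N")
  BASES[hit]
}

#' Best-score consensus base for one pileup column
#'
#' The base carrying the single highest phred score among counted bases is
#' called regardless of read depth; if two or more bases share the maximum
#' phred score the call is `N`. Deletions carry no phred score and are
#' ignored by this rule.
#'
#' @param counts Named integer vector of base counts.
#' @param best_quality Named integer vector: maximum phred per counted base.
#' @return A single character base or `N`.
#' @examples
#' call_site_bestscore(c(A = 8, T = 2, G = 1, C = 1),
#'                     c(A = 31, T = 33, G = 30, C = 30))  # "T"
#' @export
call_site_bestscore <- function(counts, best_quality) {
  cnt <- as_counts(counts)
  bq <- rep(NA_integer_, 4L); names(bq) <- BASES
  bq[names(best_quality)] <- as.integer(best_quality)
  bq[cnt == 0L] <- NA_integer_
  if (all(is.na(bq))) return("N")
  m <- max(bq, na.rm = TRUE)
  hit <- which(!is.na(bq) & bq == m)
  if (length(hit) > 1L) return("N")
  BASES[hit]
}

#' Combined majority + best-score consensus base for one pileup column
#'
#' Majority rule has priority; a site left `N` by a count tie (with nonzero
#' depth) is re-decided among the tied bases by the highest phred score, and
#' stays `N` only if the phred scores also tie. Zero-depth sites stay `N`.
#'
#' @inheritParams call_site_bestscore
#' @param deletion_count Deletions spanning the site (majority rule only).
#' @return A single character base, `N`, or `-`.
#' @examples
#' call_site_combined(c(A = 8, T = 8), c(A = 33, T = 31))  # "A"
#' @export
call_site_combined <- function(counts, best_quality, deletion_count = 0L) {
  maj <- call_site_majority(counts, deletion_count)
  if (maj != "N") return(maj)
  cnt <- as_counts(counts)
  m <- max(cnt)
  if (m == 0L) return("N")           # zero depth: nothing to re-decide
  tied <- which(cnt == m)
  bq <- rep(NA_integer_, 4L); names(bq) <- BASES
  bq[names(best_quality)] <- as.integer(best_quality)
  bq <- bq[tied]
  if (all(is.na(bq))) return("N")
  mb <- max(bq, na.rm = TRUE)
  hit <- tied[which(!is.na(bq) & bq == mb)]
  if (length(hit) > 1L) return("N")
  BASES[hit]
}

#' Per-site support ratio of the consensus base
#'
#' The percentage of filter-passing bases at a site that agree with the
#' assembled consensus base: `(N_agree / N_depth) * 100`, where `N_depth` is
#' the filtered depth of coverage at the site. Low support flags possible
#' contamination or heteroplasmy.
#'
#' @param counts Named integer base counts at the site.
#' @param called_base The consensus base (A/C/G/T, or `-` for a deletion
#'   call, supported by `deletion_count`). `N` is an error: no support is
#'   defined for a no-call.
#' @param deletion_count Deletions spanning the site.
#' @return Percentage in `[0, 100]`, or `NA` when the filtered depth is 0.
#' @examples
#' support_ratio(c(A = 7, T = 3), "A")  # 70
#' @export
support_ratio <- function(counts, called_base, deletion_count = 0L) {
  if (called_base == "N")
    stop("support ratio is undefined for a no-call (N) site")
  stopifnot(called_base %in% c(BASES, "-"))
  cnt <- as_counts(counts)
  depth <- sum(cnt) + deletion_count
  if (depth == 0L) return(NA_real_)
  agree <- if (called_base == "-") deletion_count else cnt[[called_base]]
  (agree / depth) * 100
}

# Vectorized consensus over a whole pileup; returns the per-site data.frame.
consensus_sites <- function(pileup, mode) {
  L <- pileup$length
  cnt <- pileup$counts
  del <- pileup$deletion_count
  maxc <- pmax(cnt[, 1L], cnt[, 2L], cnt[, 3L], cnt[, 4L])
  arg <- max.col(cnt, ties.method = "first")
  n_at_max <- rowSums(cnt == maxc)
  tie <- maxc > 0L & n_at_max > 1L
  del_wins <- del > maxc

  majority <- rep("N", L)
  ok <- maxc > 0L & !tie & !del_wins
  majority[ok] <- BASES[arg[ok]]
  majority[del_wins] <- "-"

  base <- switch(mode,
    majority = majority,
    bestscore = {
      bq <- pileup$best_quality
      bq[cnt == 0L] <- NA_integer_
      bqm <- bq; bqm[is.na(bqm)] <- -1L
      maxb <- pmax(bqm[, 1L], bqm[, 2L], bqm[, 3L], bqm[, 4L])
      argb <- max.col(bqm, ties.method = "first")
      tieb <- rowSums(bqm == maxb) > 1L
      out <- rep("N", L)
      okb <- maxb >= 0L & !tieb
      out[okb] <- BASES[argb[okb]]
      out
    },
    combined = {
      out <- majority
      redo <- tie & !del_wins
      if (any(redo)) {
        bq <- pileup$best_quality
        bqm <- ifelse(cnt == maxc & cnt > 0L, bq, NA_integer_)
        bqm[is.na(bqm)] <- -1L
        maxb <- pmax(bqm[, 1L], bqm[, 2L], bqm[, 3L], bqm[, 4L])
        argb <- max.col(bqm, ties.method = "first")
        tieb <- rowSums(bqm == maxb) > 1L
        fix <- redo & maxb >= 0L & !tieb
        out[fix] <- BASES[argb[fix]]
      }
      out
    })

  fdepth <- pileup$filtered_depth
  n_agree <- integer(L)
  called <- base %in% BASES
  n_agree[called] <- cnt[cbind(which(called), match(base[called], BASES))]
  n_agree[base == "-"] <- del[base == "-"]
  support <- ifelse(base != "N" & fdepth > 0L, n_agree / fdepth * 100, NA_real_)
  data.frame(position = seq_len(L), base = base, n_agree = n_agree,
             filtered_depth = fdepth, support_pct = support,
             stringsAsFactors = FALSE)
}

#' Build the consensus sequence over the full reference
#'
#' Applies the selected site-calling rule at every reference position.
#' Valid modes: `"majority"` (most-read base; tie or no data gives `N`),
#' `"bestscore"` (highest phred score regardless of depth), and
#' `"majority+bestscore"` (majority first, count ties broken by phred).
#'
#' @param pileup A [build_pileup()] result spanning the full reference.
#' @param mode Consensus mode string (see above; `"combined"` is accepted as
#'   a synonym for `"majority+bestscore"`).
#' @return A `ConsensusSequence`: data.frame with columns `position`,
#'   `base`, `n_agree`, `filtered_depth`, `support_pct`, with attributes
#'   `mode`, `policy` and `ref_name`.
#' @export
build_consensus <- function(pileup, mode = "majority") {
  stopifnot(inherits(pileup, "Pileup"))
  mode <- norm_mode(mode)
  sites <- consensus_sites(pileup, mode)
  attr(sites, "mode") <- mode
  attr(sites, "policy") <- pileup$policy
  attr(sites, "ref_name") <- pileup$ref_name
  class(sites) <- c("ConsensusSequence", "data.frame")
  sites
}

#' Consensus as a single string (deletions kept as `-`)
#'
#' @param consensus A `ConsensusSequence`.
#' @return A character string of length equal to the reference.
#' @export
consensus_string <- function(consensus) paste(consensus$base, collapse = "")

#' Write a consensus sequence as FASTA
#'
#' Deletion (`-`) sites are dropped from the serialized sequence; `N` sites
#' are kept. The header records the calling mode, the phred threshold, and
#' the reference name.
#'
#' @param consensus A `ConsensusSequence`.
#' @param path Output FASTA path.
#' @param name Sequence name (default `"consensus"`).
#' @return Invisibly, `path`.
#' @export
write_consensus_fasta <- function(consensus, path, name = "consensus") {
  pol <- attr(consensus, "policy")
  hdr <- sprintf("%s mode=%s min_bq=%d ref=%s", name, attr(consensus, "mode"),
                 pol$min_base_quality, attr(consensus, "ref_name"))
  seq <- gsub("-", "", consensus_string(consensus), fixed = TRUE)
  set <- Biostrings::BStringSet(seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write the per-site consensus support table as TSV
#'
#' @param consensus A `ConsensusSequence`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_consensus_tsv <- function(consensus, path) {
  utils::write.table(as.data.frame(consensus), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
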