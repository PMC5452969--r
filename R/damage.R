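COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

#' Ancient-DNA damage profile
#'
#' Computes per-read-offset substitution rates anchored at the two ends of
#' the original molecule. Post-mortem cytosine deamination shows up as an
#' excess of C->T changes at the 5' end (and, on the complementary strand,
#' G->A at the 3' end) that decays into the read. For each offset `o` in
#' `1..K`: `rate_5p[o]` is the fraction of reference-C positions at 5'
#' offset `o` read as T, and `rate_3p[o]` the fraction of reference-G
#' positions at 3' offset `o` read as A. Reads aligned to the reverse
#' strand are complement-flipped first so offsets are counted in
#' original-molecule coordinates. All 12 substitution rates are reported at
#' both ends so the deamination signal can be compared with the background.
#'
#' Damage analyses conventionally use a milder base-quality cut than
#' consensus calling (damaged bases are real signal here), so the default
#' policy uses phred >= 20.
#'
#' @param reads Read table.
#' @param ref Reference genome.
#' @param policy A [filter_policy()]; default `filter_policy(min_base_quality
#'   = 20)`.
#' @param K Number of offsets from each end (default 25). If K exceeds the
#'   longest read the profile covers the available offsets with a warning.
#' @return A `DamageProfile`: list with `K`; `rate_5p` and `rate_3p`
#'   (K x 12 matrices of rates, `NA` where no eligible position exists);
#'   `n_5p`, `n_3p` (K x 12 eligible-position denominators); and
#'   `read_lengths`.
#' @export
damage_profile <- function(reads, ref, policy = filter_policy(min_base_quality = 20L),
                           K = 25L) {
  stopifnot(K >= 1L)
  kept <- filter_reads(reads, policy)
  ex <- expand_alignments(kept, ref)
  if (length(ex$read_len) && K > max(ex$read_len)) {
    warning("K = ", K, " exceeds the longest aligned read (",
            max(ex$read_len), "); profile covers available offsets only")
  }
  rchr <- ref_chars(ref)
  ok <- which(ex$base %in% BASES & !is.na(ex$phred) &
                ex$phred >= policy$min_base_quality)
  refb <- rchr[ex$pos[ok]]
  readb <- ex$base[ok]
  off5 <- ex$off5[ok]
  off3 <- ex$off3[ok]
  # Complement-flip reverse-strand reads into molecule coordinates.
  rev_here <- (kept$strand == "-")[ex$read_idx[ok]]
  refb[rev_here] <- COMPLEMENT[refb[rev_here]]
  readb[rev_here] <- COMPLEMENT[readb[rev_here]]
  use <- refb %in% BASES
  rate_mat <- function(offs) {
    num <- matrix(0L, K, 12L, dimnames = list(NULL, SUBSTITUTION_KEYS))
    den <- matrix(0L, K, 12L, dimnames = list(NULL, SUBSTITUTION_KEYS))
    inw <- use & offs <= K
    rb <- refb[inw]; db <- readb[inw]; oo <- offs[inw]
    for (k in seq_along(SUBSTITUTION_KEYS)) {
      pair <- strsplit(SUBSTITUTION_KEYS[k], ">", fixed = TRUE)[[1L]]
      at_ref <- rb == pair[1L]
      den[, k] <- tabulate(oo[at_ref], nbins = K)
      num[, k] <- tabulate(oo[at_ref & db == pair[2L]], nbins = K)
    }
    list(rate = ifelse(den > 0L, num / den, NA_real_), n = den)
  }
  m5 <- rate_mat(off5)
  m3 <- rate_mat(off3)
  structure(list(K = as.integer(K),
                 rate_5p = m5$rate, n_5p = m5$n,
                 rate_3p = m3$rate, n_3p = m3$n,
                 read_lengths = ex$read_len),
            class = "DamageProfile")
}

#' Read-length (fragmentation) summary
#'
#' Ancient DNA is fragmented, so short read/fragment lengths are a damage
#' indicator alongside terminal deamination. Lengths are binned with a
#' fixed width of 5 bases for deterministic output.
#'
#' @param reads Read table (aligned query lengths are used).
#' @return A list: `histogram` (data.frame `bin_start`, `bin_end`,
#'   `count`), `mean`, `median`, `n`.
#' @export
fragmentation_summary <- function(reads) {
  mapped <- reads[!reads$is_unmapped & reads$pos >= 1L, , drop = FALSE]
  lens <- nchar(mapped$seq)
  if (!length(lens)) {
    return(list(histogram = data.frame(bin_start = integer(0),
                                       bin_end = integer(0),
                                       count = integer(0)),
                mean = NA_real_, median = NA_real_, n = 0L))
  }
  lo <- (min(lens) %/% 5L) * 5L
  hi <- ((max(lens) %/% 5L) + 1L) * 5L
  breaks <- seq(lo, hi, by = 5L)
  cnt <- tabulate(findInterval(lens, breaks), nbins = length(breaks) - 1L)
  list(histogram = data.frame(bin_start = breaks[-length(breaks)],
                              bin_end = breaks[-1L] - 1L, count = cnt),
       mean = mean(lens), median = stats::median(lens), n = length(lens))
}

#' Write the damage profile as TSV
#'
#' One row per (end, offset) with the 12 substitution rates.
#' @param profile A `DamageProfile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_damage_tsv <- function(profile, path) {
  df5 <- data.frame(end = "5p", offset = seq_len(profile$K), profile$rate_5p,
                    check.names = FALSE)
  df3 <- data.frame(end = "3p", offset = seq_len(profile$K), profile$rate_3p,
                    check.names = FALSE)
  utils::write.table(rbind(df5, df3), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
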