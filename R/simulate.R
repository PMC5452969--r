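revcomp_chars <- function(x) rev(unname(COMPLEMENT[x]))

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defines one synthetic sequencing experiment: a host haplotype (and
#' optionally a contaminant haplotype mixed in at a fixed read fraction),
#' mean fold-coverage, single-end read length, a uniform per-base
#' sequencing error rate, and optional terminal deamination damage. The
#' defaults mirror typical Illumina-style simulation settings for mtDNA
#' benchmarking: 1% sequencing error and single-end 100-base reads.
#'
#' @param haplotype Host haplotype DNA string; must be the reference length
#'   (substitution-only haplotypes, see [make_haplotype()]).
#' @param depth Mean fold-coverage.
#' @param contaminant Optional contaminant haplotype (same length).
#' @param contamination_fraction Fraction of reads drawn from the
#'   contaminant, in `[0, 0.5]`.
#' @param read_length Read length in bases (default 100, minimum 10).
#' @param error_rate Per-base sequencing error probability in `[0, 1)`
#'   (default 0.01); errors are uniform over the three alternative bases.
#' @param base_quality Phred score assigned to correct bases (default 37).
#' @param error_quality Phred score assigned to error bases (default 37,
#'   so the quality filter does not silently remove injected errors; set
#'   lower, e.g. 15, to exercise the filter path).
#' @param deamination `NULL`, or `list(rate0 =, decay =)`: C->T at 5'
#'   molecule offset `o` with probability `rate0 * exp(-(o - 1) / decay)`,
#'   and symmetrically G->A at the 3' end. Applied before sequencing error.
#' @param seed Integer seed; mandatory, every read byte is reproducible
#'   from `(config, seed)`.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(haplotype, depth, contaminant = NULL,
                              contamination_fraction = 0,
                              read_length = 100L, error_rate = 0.01,
                              base_quality = 37L, error_quality = 37L,
                              deamination = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  stopifnot(error_rate >= 0, error_rate < 1, read_length >= 10L,
            contamination_fraction >= 0, contamination_fraction <= 0.5,
            depth > 0)
  if (contamination_fraction > 0 && is.null(contaminant))
    stop("contamination_fraction > 0 requires a contaminant haplotype")
  if (!is.null(contaminant) && nchar(contaminant) != nchar(haplotype))
    stop("contaminant haplotype length must match the host haplotype")
  if (!is.null(deamination))
    stopifnot(is.list(deamination), deamination$rate0 >= 0,
              deamination$rate0 <= 1, deamination$decay > 0)
  structure(list(haplotype = toupper(haplotype),
                 contaminant = if (is.null(contaminant)) NULL
                               else toupper(contaminant),
                 contamination_fraction = contamination_fraction,
                 depth = depth, read_length = as.integer(read_length),
                 error_rate = error_rate,
                 base_quality = as.integer(base_quality),
                 error_quality = as.integer(error_quality),
                 deamination = deamination, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Apply substitution variants to a reference to obtain a haplotype
#'
#' Substitutions only, so haplotype coordinates stay aligned with the
#' reference (no indel bookkeeping). Variants may be given as labels
#' (`"C150T"`) or as a named allele vector (position -> base) as returned
#' in `cumulative_variants()$state`; deletion states in such a vector are
#' rejected.
#'
#' @param ref A `ReferenceGenome`.
#' @param variants Character vector of substitution labels, or named
#'   position->base vector.
#' @return The haplotype DNA string (reference length preserved).
#' @export
make_haplotype <- function(ref, variants) {
  chars <- ref_chars(ref)
  if (length(variants) == 0L) return(ref$sequence)
  if (is.null(names(variants))) {
    parsed <- lapply(variants, parse_variant)
    pos <- vapply(parsed, `[[`, integer(1), "pos")
    alt <- vapply(parsed, `[[`, character(1), "alt")
    refb <- vapply(parsed, `[[`, character(1), "ref")
    if (any(vapply(parsed, `[[`, character(1), "type") != "substitution"))
      stop("haplotypes are substitution-only; deletion variants not supported")
    if (any(chars[pos] != refb))
      stop("variant reference base disagrees with the reference sequence at ",
           paste(pos[chars[pos] != refb], collapse = ", "))
  } else {
    pos <- as.integer(names(variants))
    alt <- unname(variants)
    if (any(alt == "-"))
      stop("haplotypes are substitution-only; deletion states not supported")
  }
  if (anyDuplicated(pos)) {
    dup <- unique(pos[duplicated(pos)])
    conf <- dup[vapply(dup, function(p) length(unique(alt[pos == p])) > 1L,
                       logical(1))]
    if (length(conf))
      stop("conflicting variants at position(s): ", paste(conf, collapse = ", "))
    keep <- !duplicated(pos)
    pos <- pos[keep]; alt <- alt[keep]
  }
  if (any(pos < 1L | pos > ref$length))
    stop("variant position outside the reference")
  chars[pos] <- alt
  paste(chars, collapse = "")
}

#' Simulate single-end reads with known truth
#'
#' An ART-like generator (the model is this package's own, documented
#' here): `round(depth * L / read_length)` reads with uniform start
#' positions, each drawn from the contaminant haplotype with probability
#' `contamination_fraction` and from a random strand; optional terminal
#' deamination (C->T decaying from the molecule 5' end, G->A from the 3'
#' end) is applied first, then i.i.d. sequencing errors uniform over the
#' three alternative bases. Reads are emitted pre-aligned at their true
#' positions (mapping is upstream of this toolkit's scope), never crossing
#' the linear reference end.
#'
#' @param config A [simulation_config()].
#' @param ref The `ReferenceGenome` the haplotype coordinates refer to.
#' @return A `Simulation` list: `reads` (the same table layout
#'   [read_alignments()] produces), `truth` (per-read `source`, `strand`,
#'   `start`; event tables `errors` and `damage` with molecule-coordinate
#'   offsets; `realized_depth` per reference position), and `config`.
#' @export
simulate_reads <- function(config, ref) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(ref, "ReferenceGenome"))
  L <- ref$length
  rl <- config$read_length
  if (nchar(config$haplotype) != L)
    stop("haplotype length (", nchar(config$haplotype),
         ") must equal the reference length (", L, ")")
  if (rl > L) stop("read length exceeds the reference length")
  n <- max(1L, as.integer(round(config$depth * L / rl)))
  hap_chars <- strsplit(config$haplotype, "", fixed = TRUE)[[1L]]
  con_chars <- if (is.null(config$contaminant)) NULL
               else strsplit(config$contaminant, "", fixed = TRUE)[[1L]]

  with_seed(config$seed, {
    starts <- sample.int(L - rl + 1L, n, replace = TRUE)
    from_con <- if (config$contamination_fraction > 0)
      stats::runif(n) < config$contamination_fraction else rep(FALSE, n)
    rev_read <- stats::runif(n) < 0.5

    ooff <- rep.int(seq_len(rl), n)                    # molecule offset
    ridx <- rep.int(seq_len(n), rep.int(rl, n))
    rev_here <- rev_read[ridx]
    # reference position read at molecule offset o
    posvec <- starts[ridx] + ooff - 1L
    if (any(rev_here))
      posvec[rev_here] <- starts[ridx[rev_here]] + rl - ooff[rev_here]
    base <- hap_chars[posvec]
    if (!is.null(con_chars)) {
      ci <- from_con[ridx]
      base[ci] <- con_chars[posvec[ci]]
    }
    base[rev_here] <- unname(COMPLEMENT[base[rev_here]])  # molecule strand

    dmg <- logical(length(base))
    if (!is.null(config$deamination)) {
      r0 <- config$deamination$rate0; dc <- config$deamination$decay
      p5 <- r0 * exp(-(ooff - 1L) / dc)
      p3 <- r0 * exp(-(rl - ooff) / dc)
      u5 <- stats::runif(length(base))
      u3 <- stats::runif(length(base))
      hit5 <- base == "C" & u5 < p5
      hit3 <- base == "G" & u3 < p3
      base[hit5] <- "T"
      base[hit3] <- "A"
      dmg <- hit5 | hit3
    }

    err <- stats::runif(length(base)) < config$error_rate
    if (any(err)) {
      alt3 <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                     nrow = 3L, dimnames = list(NULL, BASES))
      pick <- sample.int(3L, sum(err), replace = TRUE)
      base[err] <- alt3[cbind(pick, match(base[err], BASES))]
    }
    qual <- rep.int(config$base_quality, length(base))
    qual[err] <- config$error_quality

    # assemble per-read strings from one byte buffer (fast path)
    first <- seq.int(1L, by = rl, length.out = n)
    last <- first + rl - 1L
    mol_seq <- substring(rawToChar(as.raw(
      c(65L, 67L, 71L, 84L)[match(base, BASES)])), first, last)
    mol_qual <- substring(rawToChar(as.raw(qual + 33L)), first, last)
    # SAM stores sequence/quality in reference-forward orientation.
    seqs <- mol_seq
    quals <- mol_qual
    if (any(rev_read)) {
      seqs[rev_read] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(mol_seq[rev_read])))
      quals[rev_read] <- as.character(Biostrings::reverse(
        Biostrings::BStringSet(mol_qual[rev_read])))
    }

    reads <- data.frame(
      qname = sprintf("sim%06d", seq_len(n)),
      flag = ifelse(rev_read, 16L, 0L),
      pos = starts, mapq = 60L, cigar = paste0(rl, "M"),
      seq = seqs, qual = quals,
      strand = ifelse(rev_read, "-", "+"),
      is_unmapped = FALSE, is_dup = FALSE, is_secondary = FALSE,
      stringsAsFactors = FALSE)

    truth <- list(
      source = ifelse(from_con, "contaminant", "host"),
      strand = ifelse(rev_read, "-", "+"),
      start = starts,
      errors = data.frame(read_idx = ridx[err], offset = ooff[err],
                          ref_pos = posvec[err]),
      damage = data.frame(read_idx = ridx[dmg], offset = ooff[dmg],
                          ref_pos = posvec[dmg]),
      realized_depth = tabulate(posvec, nbins = L))

    structure(list(reads = reads, truth = truth, config = config,
                   ref_name = ref$name),
              class = "Simulation")
  })
}

#' Write simulated reads as a SAM file
#'
#' Coordinate-sorted, with `@HD`/`@SQ` header lines for the supplied
#' reference, convertible to BAM with standard tooling.
#'
#' @param sim A [simulate_reads()] result.
#' @param ref The reference genome used for the simulation.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(sim, ref, path) {
  r <- sim$reads[order(sim$reads$pos), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length),
           "@PG\tID:mitoprofile\tPN:mitoprofile")
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 r$qname, r$flag, ref$name, r$pos, r$mapq, r$cigar,
                 r$seq, r$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write the simulation truth as JSON
#'
#' @param sim A [simulate_reads()] result.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(sim, path) {
  cfg <- sim$config
  cfg$haplotype <- NULL; cfg$contaminant <- NULL  # sequences live in FASTA
  jsonlite::write_json(
    list(config = unclass(cfg),
         n_reads = nrow(sim$reads),
         n_contaminant = sum(sim$truth$source == "contaminant"),
         n_errors = nrow(sim$truth$errors),
         n_damage = nrow(sim$truth$damage),
         mean_realized_depth = mean(sim$truth$realized_depth)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate a random haplogroup tree with known defining variants
#'
#' Builds a rooted tree whose root carries the reference state and whose
#' every other node adds `variants_per_node` unique substitution variants
#' at globally distinct positions (so sister clades are well separated, as
#' macro-haplogroups are). Used to exercise haplogroup assignment offline
#' with full knowledge of the truth.
#'
#' @param ref A `ReferenceGenome`.
#' @param n_nodes Total number of haplogroups including the root.
#' @param variants_per_node Defining substitutions added on each non-root
#'   branch.
#' @param seed Integer seed.
#' @return A `HaploTree`.
#' @export
random_haplotree <- function(ref, n_nodes = 16L, variants_per_node = 6L, seed) {
  stopifnot(n_nodes >= 2L)
  need <- (n_nodes - 1L) * variants_per_node
  if (need > ref$length)
    stop("not enough reference positions for ", need, " distinct variants")
  chars <- ref_chars(ref)
  with_seed(seed, {
    pos_pool <- sample.int(ref$length, need)
    nms <- c("ROOT", sprintf("HG%02d", seq_len(n_nodes - 1L)))
    nodes <- list(ROOT = list(name = "ROOT", parent = NA, variants = list()))
    k <- 0L
    for (i in seq_len(n_nodes - 1L)) {
      parent <- nms[sample.int(i, 1L)]    # any earlier node
      toks <- character(variants_per_node)
      for (j in seq_len(variants_per_node)) {
        k <- k + 1L
        p <- pos_pool[k]
        rb <- chars[p]
        ab <- sample(setdiff(BASES, rb), 1L)
        toks[j] <- paste0(rb, p, ab)
      }
      nodes[[nms[i + 1L]]] <- list(
        name = nms[i + 1L], parent = parent,
        variants = lapply(toks, parse_variant_token))
    }
    depth <- stats::setNames(integer(length(nodes)), names(nodes))
    for (nm in names(nodes)) {
      d <- 0L; cur <- nm
      while (!is.na(nodes[[cur]]$parent)) { cur <- nodes[[cur]]$parent; d <- d + 1L }
      depth[[nm]] <- d
    }
    structure(list(nodes = nodes, root = "ROOT", depth = depth),
              class = "HaploTree")
  })
}
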