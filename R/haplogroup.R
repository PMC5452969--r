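#' Parse one PhyloTree-style variant token
#'
#' Recognized forms: substitutions `A73G`, back-mutations `A5G!` (trailing
#' `!`), deletions `A249d`, and insertions `16182.1C` (position, dot,
#' insertion index, inserted bases). Insertions are parsed and stored but
#' cannot be scored against a pileup column and are excluded from scoring.
#'
#' @param token Token string.
#' @return A list: `kind` (`"substitution"`, `"deletion"`, `"insertion"`),
#'   `pos`, `ref` (`NA` for insertions), `alt` (alternate base, `"-"` for
#'   deletions, inserted bases for insertions), `back` (logical),
#'   `scorable` (logical), `raw`.
#' @export
parse_variant_token <- function(token) {
  token <- trimws(token)
  m <- regmatches(token, regexec("^([ACGT])([0-9]+)([ACGT])(!?)$", token))[[1L]]
  if (length(m)) {
    return(list(kind = "substitution", pos = as.integer(m[3L]), ref = m[2L],
                alt = m[4L], back = m[5L] == "!", scorable = TRUE, raw = token))
  }
  m <- regmatches(token, regexec("^([ACGT])([0-9]+)d(!?)$", token))[[1L]]
  if (length(m)) {
    return(list(kind = "deletion", pos = as.integer(m[3L]), ref = m[2L],
                alt = "-", back = m[4L] == "!", scorable = TRUE, raw = token))
  }
  m <- regmatches(token, regexec("^([0-9]+)\\.([0-9]+)([ACGT]+)$", token))[[1L]]
  if (length(m)) {
    return(list(kind = "insertion", pos = as.integer(m[2L]), ref = NA_character_,
                alt = m[4L], back = FALSE, scorable = FALSE, raw = token))
  }
  stop("unparseable variant token: '", token, "'")
}

#' Parse a haplogroup tree file
#'
#' Reads the tab-delimited haplogroup tree dialect used by this package:
#' one line per haplogroup with three fields — name, parent name (empty for
#' the root), and a comma-separated list of defining-variant tokens (see
#' [parse_variant_token()]). The content is typically derived from a
#' PhyloTree build; conversion from PhyloTree's own export format is out of
#' scope and left to the user.
#'
#' @param path Path to the tree TSV.
#' @param ref Optional `ReferenceGenome`; when supplied, variant positions
#'   are validated against the reference length.
#' @return A `HaploTree`: list with `nodes` (named list, each with `name`,
#'   `parent`, `variants`), `root` (root name), and `depth` (named integer
#'   path depths, root = 0).
#' @export
parse_haplotree <- function(path, ref = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty haplogroup tree file: ", path)
  nodes <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("line ", i, ": expected at least 2 tab-separated fields")
    name <- trimws(f[1L]); parent <- trimws(f[2L])
    if (name %in% names(nodes)) stop("line ", i, ": duplicate name '", name, "'")
    toks <- character(0)
    if (length(f) >= 3L && nzchar(trimws(f[3L])))
      toks <- trimws(strsplit(f[3L], ",", fixed = TRUE)[[1L]])
    vars <- lapply(toks, function(tk)
      tryCatch(parse_variant_token(tk),
               error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                        call. = FALSE)))
    if (!is.null(ref)) {
      for (v in vars)
        if (v$pos < 1L || v$pos > ref$length)
          stop("line ", i, ": variant position ", v$pos,
               " outside reference [1, ", ref$length, "]")
    }
    nodes[[name]] <- list(name = name, parent = if (nzchar(parent)) parent else NA,
                          variants = vars)
  }
  roots <- names(nodes)[vapply(nodes, function(n) is.na(n$parent), logical(1))]
  if (length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots))
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), names(nodes))
  for (nm in names(nodes)) {
    d <- 0L; cur <- nm; seen <- character(0)
    while (!is.na(nodes[[cur]]$parent)) {
      if (cur %in% seen) stop("cycle detected through node '", nm, "'")
      seen <- c(seen, cur)
      par <- nodes[[cur]]$parent
      if (is.null(nodes[[par]]))
        stop("node '", cur, "' names unknown parent '", par, "'")
      cur <- par; d <- d + 1L
      if (d > length(nodes)) stop("cycle detected through node '", nm, "'")
    }
    depth[[nm]] <- d
  }
  structure(list(nodes = nodes, root = roots, depth = depth),
            class = "HaploTree")
}

#' @export
print.HaploTree <- function(x, ...) {
  cat("HaploTree:", length(x$nodes), "haplogroups, root =", x$root,
      ", max depth =", max(x$depth), "\n")
  invisible(x)
}

#' Effective defining-variant state along the root-to-node path
#'
#' Replays the defining variants from the root down to `name`. A later
#' back-mutation (token with `!`) cancels the earlier variant at that
#' position; a later plain variant at an already-mutated position replaces
#' it. Insertions are collected separately and never enter the positional
#' state (they cannot be scored against a pileup).
#'
#' @param tree A `HaploTree`.
#' @param name Haplogroup name.
#' @return A list: `state`, a named character vector mapping position to
#'   expected allele (A/C/G/T or `-` for a deletion); `insertions`, a
#'   character vector of insertion tokens on the path.
#' @export
cumulative_variants <- function(tree, name) {
  if (is.null(tree$nodes[[name]])) stop("unknown haplogroup: '", name, "'")
  path <- name
  while (!is.na(tree$nodes[[path[1L]]]$parent))
    path <- c(tree$nodes[[path[1L]]]$parent, path)
  state <- character(0)
  ins <- character(0)
  for (nm in path) {
    for (v in tree$nodes[[nm]]$variants) {
      if (v$kind == "insertion") { ins <- c(ins, v$raw); next }
      key <- as.character(v$pos)
      if (v$back) state <- state[names(state) != key]
      else state[key] <- v$alt
    }
  }
  if (length(state)) state <- state[order(as.integer(names(state)))]
  list(state = state, insertions = ins)
}

# Per-position called bases from a consensus or a pileup (majority rule),
# the two scoring substrates the assigner supports.
called_bases <- function(x) {
  if (inherits(x, "ConsensusSequence")) return(x$base)
  if (inherits(x, "Pileup")) return(consensus_sites(x, "majority")$base)
  stop("expected a ConsensusSequence or a Pileup")
}

#' Score one haplogroup's defining variants against called bases
#'
#' Each scorable cumulative defining variant of the node is compared with
#' the called base at its position (from a consensus, or majority-rule
#' calls when a pileup is supplied): a match when the call equals the
#' expected allele (deletions match a `-` call), a no-call when the site is
#' `N`, and a mismatch otherwise.
#'
#' @param x A `ConsensusSequence` or `Pileup`.
#' @param tree A `HaploTree`.
#' @param node_name Haplogroup to score.
#' @return Named integer vector `c(n_match, n_mismatch, n_nocall)`.
#' @export
score_haplogroup <- function(x, tree, node_name) {
  calls <- called_bases(x)
  cv <- cumulative_variants(tree, node_name)$state
  if (!length(cv))
    return(c(n_match = 0L, n_mismatch = 0L, n_nocall = 0L))
  pos <- as.integer(names(cv))
  if (any(pos > length(calls)))
    stop("defining-variant position exceeds the reference length")
  got <- calls[pos]
  nocall <- got == "N"
  match_ <- !nocall & got == unname(cv)
  c(n_match = sum(match_), n_mismatch = sum(!nocall & !match_),
    n_nocall = sum(nocall))
}

#' Assign the most likely haplogroup
#'
#' Scores every haplogroup in the tree against the called bases and ranks
#' them by `score = (n_match - n_mismatch) / max(1, n_match + n_mismatch)`,
#' ties broken by more matches, then deeper (more specific) node, then
#' lexicographic name. The scoring function is this package's own choice of
#' "most likely" and is isolated here so it can be substituted.
#'
#' @param x A `ConsensusSequence` or `Pileup` (pileup-majority is the
#'   default substrate in the pipeline).
#' @param tree A `HaploTree`.
#' @return A `HaplogroupCall`: list with `ranking` (data.frame: haplogroup,
#'   score, n_match, n_mismatch, n_nocall, k_covered, depth) and `best`.
#' @export
assign_haplogroup <- function(x, tree) {
  if (!length(tree$nodes)) stop("empty haplogroup tree")
  calls <- called_bases(x)
  nms <- names(tree$nodes)
  sc <- t(vapply(nms, function(nm) score_haplogroup_calls(calls, tree, nm),
                 integer(3)))
  k_cov <- sc[, 1L] + sc[, 2L]
  score <- (sc[, 1L] - sc[, 2L]) / pmax(1L, k_cov)
  rk <- data.frame(haplogroup = nms, score = score,
                   n_match = sc[, 1L], n_mismatch = sc[, 2L],
                   n_nocall = sc[, 3L], k_covered = k_cov,
                   depth = unname(tree$depth[nms]), stringsAsFactors = FALSE)
  o <- order(-rk$score, -rk$n_match, -rk$depth, rk$haplogroup)
  rk <- rk[o, , drop = FALSE]
  rownames(rk) <- NULL
  structure(list(ranking = rk, best = rk$haplogroup[1L]),
            class = "HaplogroupCall")
}

# score_haplogroup with calls precomputed (avoids re-deriving majority
# calls for every node).
score_haplogroup_calls <- function(calls, tree, node_name) {
  cv <- cumulative_variants(tree, node_name)$state
  if (!length(cv))
    return(c(n_match = 0L, n_mismatch = 0L, n_nocall = 0L))
  pos <- as.integer(names(cv))
  got <- calls[pos]
  nocall <- got == "N"
  match_ <- !nocall & got == unname(cv)
  c(n_match = sum(match_), n_mismatch = sum(!nocall & !match_),
    n_nocall = sum(nocall))
}

#' @export
print.HaplogroupCall <- function(x, ...) {
  cat("Best haplogroup:", x$best, "\n")
  print(utils::head(x$ranking, 5L))
  invisible(x)
}

#' Contamination indicator from haplogroup-defining sites
#'
#' Over the `k` scorable defining sites of the assigned haplogroup,
#' computes the mean per-site ratio of pileup bases inconsistent with the
#' defining allele to bases consistent with it, as a percentage:
#' `P_mismatch = [sum_i (N_mismatch_i / N_match_i) / k] * 100`. Exogenous
#' reads from another lineage raise the inconsistent counts at these sites,
#' so the indicator grows with the contamination fraction. Sites where
#' `N_match = 0` would make the ratio infinite; they are excluded from `k`
#' and their number is reported in the `n_excluded` attribute.
#'
#' @param pileup A `Pileup` (base counts are needed, not just calls).
#' @param tree A `HaploTree`.
#' @param assigned Name of the assigned haplogroup.
#' @return `P_mismatch` as a percentage, with attributes `k` (sites used)
#'   and `n_excluded`.
#' @export
p_mismatch <- function(pileup, tree, assigned) {
  stopifnot(inherits(pileup, "Pileup"))
  cv <- cumulative_variants(tree, assigned)$state
  if (!length(cv)) stop("no scorable defining sites for '", assigned, "'")
  pos <- as.integer(names(cv))
  allele <- unname(cv)
  n_match <- integer(length(pos))
  is_del <- allele == "-"
  n_match[is_del] <- pileup$deletion_count[pos[is_del]]
  n_match[!is_del] <- pileup$counts[cbind(pos[!is_del],
                                          match(allele[!is_del], BASES))]
  n_mismatch <- pileup$filtered_depth[pos] - n_match
  keep <- n_match > 0L
  if (!any(keep)) stop("no scorable defining sites (all have N_match = 0)")
  val <- mean(n_mismatch[keep] / n_match[keep]) * 100
  attr(val, "k") <- sum(keep)
  attr(val, "n_excluded") <- sum(!keep)
  val
}

#' Haplogroup assignment accuracy
#'
#' `TP / (TP + FP)` where a true positive is an exact name match between
#' the predicted and the validated haplogroup and a false positive is a
#' prediction that fails validation.
#'
#' @param truth Character vector of true haplogroup names.
#' @param predicted Character vector of predicted names (same length).
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
assignment_accuracy <- function(truth, predicted) {
  if (!length(truth) || !length(predicted))
    stop("truth and predicted must be non-empty")
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == predicted)
  tp / (tp + sum(truth != predicted))
}

#' Write a haplogroup tree in the package's TSV dialect
#'
#' @param tree A `HaploTree`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_haplotree <- function(tree, path) {
  lines <- vapply(tree$nodes, function(n) {
    toks <- vapply(n$variants, function(v) v$raw, character(1))
    paste(n$name, ifelse(is.na(n$parent), "", n$parent),
          paste(toks, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write the ranked haplogroup table as TSV
#'
#' @param call A `HaplogroupCall`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_haplogroup_tsv <- function(call, path) {
  utils::write.table(call$ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
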