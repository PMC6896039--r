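# Simplified MCscan-style segmental-duplication detection: local-alignment
# anchors between protein pairs, dynamic-programming chaining of anchors
# with monotone gene ranks into collinear blocks, and segmental calls for
# family members inside significant blocks.

# fixed Karlin-Altschul parameters for the gapped BLOSUM62 (11/1) regime;
# the resulting E-value is a calibrated proxy, not NCBI-BLAST-exact
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Local protein alignment score and proxy E-value
#'
#' Smith-Waterman with BLOSUM62, gap open 11 / extend 1 (via
#' `Biostrings::pairwiseAlignment`), plus a Karlin-Altschul E-value with
#' fixed parameters (lambda = 0.267, K = 0.041) over a declared search
#' space.
#'
#' @param a,b Amino-acid strings.
#' @param search_space Declared search-space size (query residues x
#'   database residues); defaults to `nchar(a) * nchar(b)`.
#' @return A list with `score` and `evalue`.
#' @export
local_align <- function(a, b, search_space = nchar(a) * nchar(b)) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  s <- Biostrings::score(aln)
  list(score = s, evalue = KA_K * search_space * exp(-KA_LAMBDA * s))
}

#' Find similarity anchors between positioned proteins
#'
#' All unordered protein pairs are locally aligned; pairs with a proxy
#' E-value below `e_max` become anchors. Every protein must carry a
#' genomic rank (its ordinal position on its chromosome).
#'
#' @param proteins Named character vector of protein sequences.
#' @param positions Data.frame with columns `name`, `chromosome`, `rank`
#'   (1-based ordinal position on the chromosome).
#' @param e_max Anchor E-value threshold (default 1e-6).
#' @return A data.frame of anchors: `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `rank_a`, `rank_b`, `score`, `evalue` (each reciprocal
#'   pair stored once, a < b in input order).
#' @export
find_anchors <- function(proteins, positions, e_max = 1e-6) {
  nms <- names(proteins)
  stopifnot(!is.null(nms))
  missing <- setdiff(nms, positions$name)
  if (length(missing) > 0L) {
    stop("protein(s) without genomic position: ",
         paste(missing, collapse = ", "))
  }
  pos <- positions[match(nms, positions$name), , drop = FALSE]
  n <- length(proteins)
  total_res <- sum(nchar(proteins))
  rows <- list()
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    alns <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins[js]),
      Biostrings::AAString(proteins[[i]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    ev <- KA_K * nchar(proteins[[i]]) * total_res * exp(-KA_LAMBDA * alns)
    hit <- which(ev < e_max)
    for (k in hit) {
      j <- js[k]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = nms[i], gene_b = nms[j],
        chrom_a = pos$chromosome[i], chrom_b = pos$chromosome[j],
        rank_a = pos$rank[i], rank_b = pos$rank[j],
        score = alns[k], evalue = ev[k], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chrom_a = character(0), chrom_b = character(0),
                      rank_a = integer(0), rank_b = integer(0),
                      score = numeric(0), evalue = numeric(0)))
  }
  do.call(rbind, rows)
}

# longest chain of anchors with strictly increasing rank_a and strictly
# monotone rank_b (sign = +1 increasing, -1 decreasing), rank gaps bounded
# on both axes; returns indices into the anchor data.frame
chain_dp <- function(anchors, sign, max_rank_gap) {
  ord <- order(anchors$rank_a, sign * anchors$rank_b)
  a <- anchors[ord, , drop = FALSE]
  k <- nrow(a)
  best <- rep(1L, k)
  prev <- rep(NA_integer_, k)
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      da <- a$rank_a[i] - a$rank_a[j]
      db <- sign * (a$rank_b[i] - a$rank_b[j])
      if (da > 0L && db > 0L && da <= max_rank_gap && db <= max_rank_gap &&
          best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  chain <- integer(0)
  while (!is.na(end)) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  ord[chain]
}

#' Chain anchors into collinear blocks
#'
#' Per chromosome pair, anchors are chained by dynamic programming into
#' runs with strictly monotone gene ranks on both chromosomes (decreasing
#' on one for inverted blocks) and consecutive rank gaps bounded by
#' `max_rank_gap`. Chains are extracted greedily (longest first, anchors
#' removed) until fewer than `min_anchors` remain. Block significance
#' multiplies member anchor E-values, capped at the smallest positive
#' double; blocks below `1e-10` are flagged significant.
#'
#' @param anchors Anchor data.frame from [find_anchors()].
#' @param min_anchors Minimum anchors per block (default 5).
#' @param max_rank_gap Maximum rank gap between consecutive anchors
#'   (default 25).
#' @return A list of blocks; each has `anchors` (data.frame),
#'   `chromosomes`, `orientation` (`"same"`/`"inverted"`),
#'   `block_evalue` and `significant`.
#' @export
chain_blocks <- function(anchors, min_anchors = 5L, max_rank_gap = 25L) {
  if (nrow(anchors) == 0L) return(list())
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  blocks <- list()
  for (grp in split(anchors, key)) {
    remaining <- grp
    repeat {
      if (nrow(remaining) < min_anchors) break
      fwd <- chain_dp(remaining, +1, max_rank_gap)
      rev_ <- chain_dp(remaining, -1, max_rank_gap)
      use_fwd <- length(fwd) >= length(rev_)
      idx <- if (use_fwd) fwd else rev_
      if (length(idx) < min_anchors) break
      chain <- remaining[idx, , drop = FALSE]
      ev <- max(prod(chain$evalue), .Machine$double.xmin)
      blocks[[length(blocks) + 1L]] <- list(
        anchors = chain,
        chromosomes = c(chain$chrom_a[1L], chain$chrom_b[1L]),
        orientation = if (use_fwd) "same" else "inverted",
        block_evalue = ev,
        significant = ev < 1e-10)
      remaining <- remaining[-idx, , drop = FALSE]
    }
  }
  for (b in blocks) {
    stopifnot(all(diff(b$anchors$rank_a) > 0),
              all(diff(b$anchors$rank_b) > 0) ||
                all(diff(b$anchors$rank_b) < 0))
  }
  blocks
}

#' Call segmental duplications among family members
#'
#' A family member is segmentally duplicated when it participates in an
#' anchor inside a significant block whose partner gene is also a family
#' member. Linked pairs are merged into events by connected components,
#' so A-B and B-C yield one three-member event.
#'
#' @param blocks Output of [chain_blocks()].
#' @param family_members Character vector of family gene names.
#' @return A list of events with `kind = "segmental"` and `members`.
#' @export
call_segmental <- function(blocks, family_members) {
  pairs <- list()
  for (b in blocks) {
    if (!isTRUE(b$significant)) next
    sel <- b$anchors$gene_a %in% family_members &
      b$anchors$gene_b %in% family_members
    if (any(sel)) {
      pairs[[length(pairs) + 1L]] <-
        b$anchors[sel, c("gene_a", "gene_b"), drop = FALSE]
    }
  }
  if (length(pairs) == 0L) return(list())
  pairs <- unique(do.call(rbind, pairs))
  # connected components by union-find
  nodes <- unique(c(pairs$gene_a, pairs$gene_b))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs$gene_a[i]); rb <- find(pairs$gene_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  lapply(split(nodes, roots), function(members) {
    list(kind = "segmental", members = sort(members))
  })
}
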