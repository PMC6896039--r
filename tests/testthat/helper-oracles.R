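# Independent oracles and small helpers shared across the suite.

# canonical bipartition keys of an unrooted tree, anchored on the
# alphabetically first label so keys are comparable across trees
bip_keys <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  n <- length(labs)
  anchor <- sort(labs)[1L]
  keys <- character(0)
  for (p in pp) {
    if (length(p) <= 1L || length(p) >= n - 1L) next
    s <- labs[p]
    if (anchor %in% s) s <- setdiff(labs, s)
    keys <- c(keys, paste(sort(s), collapse = "|"))
  }
  sort(unique(keys))
}

# brute-force optimal global alignment score with affine gaps
# (match +1, mismatch 0, gap of length L costs open + L * extend),
# by exhaustive recursion over all alignments of two short strings
enum_align_score <- function(a, b, open = 5, extend = 1) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, (av[i] == bv[j]) + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= length(av)) {  # gap in b
      cost <- extend + if (state == "gb") 0 else open
      best <- max(best, rec(i + 1L, j, "gb") - cost)
    }
    if (j <= length(bv)) {  # gap in a
      cost <- extend + if (state == "ga") 0 else open
      best <- max(best, rec(i, j + 1L, "ga") - cost)
    }
    best
  }
  rec(1L, 1L, "m")
}

# brute-force longest collinear chain over <= 12 anchors: enumerate all
# subsets, keep those strictly monotone on both axes (either orientation)
# with rank gaps bounded, return the maximum size
brute_longest_chain <- function(anchors, max_rank_gap = 25L) {
  k <- nrow(anchors)
  stopifnot(k <= 12L)
  best <- 0L
  for (mask in seq_len(2^k) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    if (length(idx) <= best) next
    sub <- anchors[idx, , drop = FALSE]
    sub <- sub[order(sub$rank_a), , drop = FALSE]
    da <- diff(sub$rank_a)
    db <- diff(sub$rank_b)
    ok_fwd <- all(da > 0) && all(db > 0) &&
      all(da <= max_rank_gap) && all(db <= max_rank_gap)
    ok_rev <- all(da > 0) && all(db < 0) &&
      all(da <= max_rank_gap) && all(-db <= max_rank_gap)
    if (ok_fwd || ok_rev) best <- length(idx)
  }
  best
}

# uniform background peptide over residues that cannot seed a grammar
rand_bg <- function(n) {
  paste(sample(c("A", "G", "L", "S", "T", "P", "E", "D", "K", "N", "V"),
               n, replace = TRUE), collapse = "")
}

# the seven segmentally duplicated family genes printed in the survey
SEGMENTAL_GENES <- c("PmWRKY21", "PmWRKY38", "PmWRKY56",
                     "PmWRKY25", "PmWRKY34", "PmWRKY42", "PmWRKY53")
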