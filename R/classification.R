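# Group/subgroup classification: the domain-count x zinc-finger rule,
# pairwise alignment and p-distances, a from-scratch Saitou-Nei
# neighbour-joining tree with bootstrap support, the clade rule that
# transfers subgroup labels from reference proteins, and protein
# statistics (molecular weight, isoelectric point).

#' Rule-based WRKY group classification
#'
#' Two WRKY domains give group I; a single domain with a C2HC finger gives
#' group III; a single domain with a C2H2 finger gives group II.
#'
#' @param domain_number Integer vector of domain counts.
#' @param zf_type Character vector (`"C2H2"`/`"C2HC"`), recycled with
#'   `domain_number`.
#' @return Character vector of group labels (`"I"`, `"II"`, `"III"`).
#' @examples
#' wrky_group(c(2, 1, 1), c("C2H2", "C2HC", "C2H2"))
#' @export
wrky_group <- function(domain_number, zf_type) {
  stopifnot(length(domain_number) == length(zf_type))
  if (any(domain_number < 1L)) {
    stop("classification error: member with 0 WRKY domains")
  }
  if (any(domain_number > 2L)) {
    stop("classification error: member with >2 WRKY domains; ",
         "flag for manual review")
  }
  ifelse(domain_number == 2L, "I",
         ifelse(zf_type == "C2HC", "III", "II"))
}

#' Classify one member from its detected domains
#'
#' @param member_domains A data.frame of domains for a single protein, as
#'   returned by [scan_domains()].
#' @return A list with `group` and `evidence` (a short text trail).
#' @export
classify_group <- function(member_domains) {
  n <- nrow(member_domains)
  if (is.null(n) || n == 0L) {
    stop("classification error: no WRKY domain detected")
  }
  zf <- member_domains$zf_type[n]   # C-terminal domain decides the finger
  group <- wrky_group(n, zf)
  list(group = group,
       evidence = sprintf("%d domain(s), %s zinc finger => group %s",
                          n, zf, group))
}

# substitution matrix for domain alignment: match +1, mismatch 0
identity_submat <- function() {
  m <- diag(1, length(AA_ALPHABET))
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

#' Globally align two protein sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, gap open
#' -5, gap extension -1 (a length-L gap costs 5 + L).
#'
#' @param a,b Amino-acid strings.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return A list with `a` and `b`, the aligned strings (gaps as `-`), and
#'   `score`.
#' @export
align_pair <- function(a, b, gap_open = 5, gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = identity_submat(),
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' p-distance between two aligned sequences
#'
#' Fraction of mismatching sites among compared sites; columns containing
#' a gap in either sequence are excluded.
#'
#' @param aligned A list with aligned strings `a` and `b` of equal length
#'   (as returned by [align_pair()]).
#' @return A fraction in `[0, 1]`.
#' @export
p_distance <- function(aligned) {
  ca <- strsplit(aligned$a, "")[[1L]]
  cb <- strsplit(aligned$b, "")[[1L]]
  if (length(ca) != length(cb)) stop("aligned lengths differ")
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("undefined distance: no gap-free columns to compare")
  sum(ca[keep] != cb[keep]) / sum(keep)
}

#' Pairwise p-distance matrix for a set of sequences
#'
#' Each pair is globally aligned with [align_pair()] and the p-distance
#' taken on the gap-free columns.
#'
#' @param sequences Named character vector.
#' @return A symmetric labelled distance matrix.
#' @export
p_distance_matrix <- function(sequences) {
  n <- length(sequences)
  stopifnot(n >= 2L, !is.null(names(sequences)))
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) {
    # one vectorised alignment call per row keeps the quadratic loop fast;
    # gap-free columns are exactly the match + mismatch columns
    js <- (i + 1L):n
    alns <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(sequences[js]),
      Biostrings::AAString(sequences[[i]]),
      type = "global", substitutionMatrix = identity_submat(),
      gapOpening = 5, gapExtension = 1)
    mm <- Biostrings::nmismatch(alns)
    compared <- Biostrings::nmatch(alns) + mm
    if (any(compared == 0)) {
      stop("undefined distance: no gap-free columns to compare")
    }
    d[i, js] <- d[js, i] <- mm / compared
  }
  d
}

#' Build a neighbour-joining tree
#'
#' From-scratch Saitou-Nei neighbour joining: iteratively joins the pair
#' minimising the Q criterion, with branch lengths from the standard
#' two-point formulas. Negative branch lengths are clamped to zero and
#' ties in Q are broken by the lowest (i, j) index pair, so the result is
#' fully reproducible.
#'
#' @param d A symmetric labelled distance matrix (>= 3 labels).
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (nrow(d) < 3L) stop("need at least 3 labels")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("validation error: distance matrix is not symmetric")
  }
  labels <- rownames(d)
  n_tips <- length(labels)
  # node ids: 1..n_tips are leaves; internal nodes allocated onwards
  active <- seq_len(n_tips)
  next_id <- n_tips + 1L
  edges <- matrix(numeric(0), ncol = 3L)  # parent, child, length
  D <- d
  rownames(D) <- colnames(D) <- as.character(active)
  while (length(active) > 3L) {
    n <- length(active)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # first minimum in column-major upper-triangle scan = lowest index pair
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    k <- which.min(Q)
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges,
                   c(u, active[i], max(li, 0)),
                   c(u, active[j], max(lj, 0)))
    Duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], Duk[keep]),
                c(Duk[keep], 0))
    ids <- c(active[keep], u)
    rownames(D2) <- colnames(D2) <- as.character(ids)
    D <- D2
    active <- ids
  }
  # attach the final three nodes to one internal node (three-point formulas)
  u <- next_id; next_id <- next_id + 1L
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(edges,
                 c(u, active[1L], max(la, 0)),
                 c(u, active[2L], max(lb, 0)),
                 c(u, active[3L], max(lc, 0)))
  # renumber internal nodes into ape convention: root first
  n_internal <- next_id - 1L - n_tips
  internal_ids <- (n_tips + 1L):(next_id - 1L)
  # ape expects root = n_tips + 1; our last-created node is the root
  new_id <- integer(next_id - 1L)
  new_id[seq_len(n_tips)] <- seq_len(n_tips)
  new_id[rev(internal_ids)] <- n_tips + seq_len(n_internal)
  phy <- list(edge = cbind(new_id[edges[, 1L]], new_id[edges[, 2L]]),
              edge.length = edges[, 3L],
              tip.label = labels,
              Nnode = n_internal)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

# Unrooted bipartitions of a tree: one per internal edge, canonicalised so
# the reported side never contains the first tip label.
tree_bipartitions <- function(phy) {
  n_tips <- length(phy$tip.label)
  parts <- ape::prop.part(phy)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    if (length(p) <= 1L || length(p) >= n_tips - 1L) next  # trivial splits
    side <- labs[p]
    if (phy$tip.label[1L] %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports the percentage of replicates containing each
#' internal bipartition of the original tree.
#'
#' @param alignment Named character vector of aligned, equal-length
#'   sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @return A list with `tree` (the NJ tree from the full alignment, with
#'   node support attached via `node.label`) and `support`, a named vector
#'   (bipartition key -> percent).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  stopifnot(n_reps >= 1L, length(alignment) >= 4L)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  dist_from <- function(m) {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      keep <- m[i, ] != "-" & m[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(keep)) {
        sum(m[i, keep] != m[j, keep]) / sum(keep)
      } else 1
    }
    d
  }
  full_tree <- build_nj_tree(dist_from(mat))
  splits <- tree_bipartitions(full_tree)
  counts <- stats::setNames(numeric(length(splits)), splits)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    rep_tree <- build_nj_tree(dist_from(mat[, cols, drop = FALSE]))
    hit <- intersect(splits, tree_bipartitions(rep_tree))
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  # attach to internal nodes for Newick export
  full_tree$node.label <- rep("", full_tree$Nnode)
  n_tips <- length(full_tree$tip.label)
  parts <- ape::prop.part(full_tree)
  labs <- attr(parts, "labels")
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) <= 1L || length(p) >= n_tips - 1L) next
    side <- labs[p]
    if (full_tree$tip.label[1L] %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      full_tree$node.label[k] <- format(round(support[[key]], 1))
    }
  }
  list(tree = full_tree, support = support)
}

#' Assign a subgroup by phylogenetic placement
#'
#' The query inherits the label of the references in the smallest
#' edge-bounded clade of the unrooted tree that contains the query and at
#' least one reference, provided all references in that clade agree. If
#' they conflict, or the nearest reference is farther than
#' `distance_ceiling` in patristic distance, the fallback label `IIx` is
#' returned (the "does not cluster with any reference" outcome).
#'
#' @param tree An `ape::phylo` tree containing the query and references.
#' @param query Query tip label.
#' @param reference_map Named character vector: reference tip -> subgroup.
#' @param distance_ceiling Patristic-distance ceiling (default 0.8).
#' @return A single subgroup label.
#' @export
assign_subgroup <- function(tree, query, reference_map,
                            distance_ceiling = 0.8) {
  if (!query %in% tree$tip.label) stop("query '", query, "' not in tree")
  refs <- intersect(names(reference_map), tree$tip.label)
  if (length(refs) == 0L) stop("no reference tips present in tree")
  pat <- stats::cophenetic(tree)
  if (min(pat[query, refs]) > distance_ceiling) return("IIx")
  # candidate clades: both sides of every edge
  n_tips <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  sides <- list()
  for (p in parts) {
    side <- labs[p]
    sides[[length(sides) + 1L]] <- side
    sides[[length(sides) + 1L]] <- setdiff(labs, side)
  }
  for (tip in labs) {  # pendant edges
    sides[[length(sides) + 1L]] <- tip
    sides[[length(sides) + 1L]] <- setdiff(labs, tip)
  }
  ok <- vapply(sides, function(s) query %in% s && length(intersect(s, refs)) > 0,
               logical(1))
  sides <- sides[ok]
  sizes <- lengths(sides)
  best <- sides[[which.min(sizes)]]
  labels_in <- unique(reference_map[intersect(best, refs)])
  if (length(labels_in) == 1L) unname(labels_in) else "IIx"
}

#' Assign subgroups to many query proteins
#'
#' Convenience wrapper around the full classification route: for each
#' query, a p-distance matrix over the references plus that query is
#' assembled (reference-reference distances are computed once), a
#' neighbour-joining tree is built, and [assign_subgroup()] applies the
#' clade rule.
#'
#' @param queries Named character vector of query sequences.
#' @param references Named character vector of reference sequences
#'   (default: the packaged set, [wrky_references()]).
#' @param reference_map Reference -> subgroup map (default:
#'   [wrky_reference_map()]).
#' @param distance_ceiling See [assign_subgroup()].
#' @return Named character vector of subgroup labels (one per query).
#' @export
classify_subgroups <- function(queries, references = wrky_references(),
                               reference_map = wrky_reference_map(),
                               distance_ceiling = 0.8) {
  stopifnot(!is.null(names(queries)))
  nref <- length(references)
  dref <- p_distance_matrix(references)
  labels <- character(length(queries))
  for (i in seq_along(queries)) {
    qname <- names(queries)[i]
    alns <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(references),
      Biostrings::AAString(queries[[i]]),
      type = "global", substitutionMatrix = identity_submat(),
      gapOpening = 5, gapExtension = 1)
    mm <- Biostrings::nmismatch(alns)
    dq <- mm / (Biostrings::nmatch(alns) + mm)
    d <- rbind(cbind(dref, dq), c(dq, 0))
    rownames(d) <- colnames(d) <- c(names(references), qname)
    tree <- build_nj_tree(d)
    labels[i] <- assign_subgroup(tree, qname, reference_map,
                                 distance_ceiling = distance_ceiling)
  }
  stats::setNames(labels, names(queries))
}

# average residue masses (Da); peptide mass = sum + one water
AA_MONO_AVG <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                 C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                 H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                 M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                 T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, in kDa.
#'
#' @param sequence Amino-acid string (canonical residues only; `X` has no
#'   defined mass and raises an error).
#' @return Molecular weight in kDa (full precision; round to 2 decimals
#'   for display).
#' @export
protein_mw <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(res, names(AA_MONO_AVG))
  if (length(bad) > 0L) {
    stop("mass undefined for residue(s): ", paste(unique(bad), collapse = ", "))
  }
  (sum(AA_MONO_AVG[res]) + WATER_MASS) / 1000
}

# Bjellqvist pKa values used by the ExPASy Compute pI tool (simplified:
# one N-terminal value)
PKA <- list(nterm = 7.5, cterm = 3.55,
            D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
            H = 5.98, K = 10.0, R = 12.0)

peptide_charge <- function(counts, ph) {
  pos <- 1 / (1 + 10^(ph - PKA$nterm)) +
    counts["H"] / (1 + 10^(ph - PKA$H)) +
    counts["K"] / (1 + 10^(ph - PKA$K)) +
    counts["R"] / (1 + 10^(ph - PKA$R))
  neg <- 1 / (1 + 10^(PKA$cterm - ph)) +
    counts["D"] / (1 + 10^(PKA$D - ph)) +
    counts["E"] / (1 + 10^(PKA$E - ph)) +
    counts["C"] / (1 + 10^(PKA$C - ph)) +
    counts["Y"] / (1 + 10^(PKA$Y - ph))
  unname(pos - neg)
}

#' Protein isoelectric point
#'
#' Bisection on the Henderson-Hasselbalch net charge over the termini and
#' the ionisable side chains (D, E, C, Y, H, K, R) with the Bjellqvist pKa
#' set, converged to |charge| < 1e-4.
#'
#' @param sequence Amino-acid string (canonical residues only).
#' @param tol Convergence tolerance on the net charge.
#' @return The isoelectric point (full precision).
#' @export
protein_pi <- function(sequence, tol = 1e-4) {
  if (!nzchar(sequence)) stop("empty sequence")
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(res, names(AA_MONO_AVG))
  if (length(bad) > 0L) {
    stop("pI undefined for residue(s): ", paste(unique(bad), collapse = ", "))
  }
  counts <- vapply(c("D", "E", "C", "Y", "H", "K", "R"),
                   function(a) sum(res == a), numeric(1))
  lo <- 0; hi <- 14
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    q <- peptide_charge(counts, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  stop("numerical error: pI bisection did not converge")
}

#' Summarise a WRKY family table
#'
#' @param members A family data.frame as returned by
#'   [read_family_table()].
#' @return A list with per-group and per-subgroup counts, min/max of
#'   protein length, MW and pI, and the number of non-canonical
#'   (variant) heptapeptides.
#' @examples
#' family_summary(read_family_table())$group_counts
#' @export
family_summary <- function(members) {
  stopifnot(nrow(members) >= 1L)
  groups <- wrky_group(members$domain_number, members$zf_type)
  group_counts <- vapply(c("I", "II", "III"),
                         function(g) sum(groups == g), integer(1))
  subgroup_counts <- table(members$subgroup)
  list(
    n = nrow(members),
    group_counts = group_counts,
    subgroup_counts = subgroup_counts,
    length_range = range(members$protein_length),
    mw_range = range(members$mw),
    pi_range = range(members$pi),
    n_variant_heptapeptide = sum(members$heptapeptide != "WRKYGQK")
  )
}
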