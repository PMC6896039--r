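# Chromosome localisation and duplication bookkeeping from coordinates
# alone: per-chromosome counts, tandem-repeat chains (<= 100 kb between
# neighbouring family genes), gene clusters (>= 3 genes in 200 kb), and
# the family-level duplication percentages.

#' Count family members per chromosome
#'
#' @param members Family data.frame with `name`, `chromosome`, `start`,
#'   `end` columns.
#' @return A named integer vector (chromosome -> count), in order of first
#'   appearance; scaffold-placed members count under their scaffold name.
#' @export
per_chromosome_counts <- function(members) {
  if (nrow(members) == 0L) return(stats::setNames(integer(0), character(0)))
  counts <- table(factor(members$chromosome,
                         levels = unique(members$chromosome)))
  stats::setNames(as.integer(counts), names(counts))
}

# split into per-chromosome data frames ordered by start
split_sorted <- function(members) {
  lapply(split(members, members$chromosome),
         function(d) d[order(d$start), , drop = FALSE])
}

#' Detect tandem-repeat events
#'
#' Chains consecutive family members on the same chromosome whose
#' inter-gene distance (end of the upstream gene to start of the
#' downstream gene) is at most `max_gap`. Maximal chains of two or more
#' genes become tandem events.
#'
#' @param members Family data.frame (`name`, `chromosome`, `start`, `end`).
#' @param max_gap Maximum inter-gene distance in bp (default 100 kb).
#' @return A list of events; each event is a list with `kind = "tandem"`,
#'   `members` (names ordered by position), `chromosome` and `span`
#'   (first start to last end, bp).
#' @examples
#' find_tandem(read_family_table())
#' @export
find_tandem <- function(members, max_gap = 100000) {
  events <- list()
  for (d in split_sorted(members)) {
    n <- nrow(d)
    if (n < 2L) next
    gap_ok <- d$start[-1L] - d$end[-n] <= max_gap
    run_id <- cumsum(c(TRUE, !gap_ok))
    for (run in split(seq_len(n), run_id)) {
      if (length(run) < 2L) next
      events[[length(events) + 1L]] <- list(
        kind = "tandem",
        members = d$name[run],
        chromosome = d$chromosome[1L],
        span = c(d$start[run[1L]], d$end[run[length(run)]]))
    }
  }
  events
}

#' Detect gene clusters
#'
#' A cluster is a maximal same-chromosome run of family members whose span
#' (first start to last end) is at most `window` and whose size is at
#' least `min_genes` (Holub's criterion: 3 or more genes within 200 kb).
#'
#' @param members Family data.frame.
#' @param window Maximum cluster span in bp (default 200 kb).
#' @param min_genes Minimum number of genes (default 3).
#' @return A list of events with `kind = "cluster"`.
#' @export
find_clusters <- function(members, window = 200000, min_genes = 3L) {
  events <- list()
  for (d in split_sorted(members)) {
    n <- nrow(d)
    if (n < min_genes) next
    runs <- list()
    for (i in seq_len(n)) {
      j <- i
      while (j < n && d$end[j + 1L] - d$start[i] <= window) j <- j + 1L
      if (j - i + 1L >= min_genes) runs[[length(runs) + 1L]] <- c(i, j)
    }
    if (length(runs) == 0L) next
    # keep only maximal runs (not contained in another run)
    keep <- vapply(seq_along(runs), function(k) {
      !any(vapply(seq_along(runs), function(l) {
        l != k && runs[[l]][1L] <= runs[[k]][1L] && runs[[l]][2L] >= runs[[k]][2L]
      }, logical(1)))
    }, logical(1))
    for (r in runs[keep]) {
      events[[length(events) + 1L]] <- list(
        kind = "cluster",
        members = d$name[r[1L]:r[2L]],
        chromosome = d$chromosome[1L],
        span = c(d$start[r[1L]], d$end[r[2L]]))
    }
  }
  events
}

#' Family-level duplication percentages
#'
#' Percentages of the family explained by tandem duplication, segmental
#' duplication and neither (monogenes). Counts are summed per list (a gene
#' appearing in both the tandem and segmental lists contributes to both),
#' so the involvement figure is the count-sum, with the set-union figure
#' reported alongside.
#'
#' @param tandem_events List of tandem events from [find_tandem()].
#' @param segmental_members Character vector of segmentally duplicated
#'   family gene names.
#' @param total Family size.
#' @return A list with `tandem_pct`, `segmental_pct`, `monogene_pct`,
#'   `involved_pct` (count-sum convention) and `involved_pct_union`, all
#'   rounded to 1 decimal, plus the underlying counts.
#' @export
duplication_summary <- function(tandem_events, segmental_members, total) {
  stopifnot(total >= 1L)
  tandem_genes <- unique(unlist(lapply(tandem_events, `[[`, "members")))
  n_tandem <- length(tandem_genes)
  n_seg <- length(unique(segmental_members))
  n_both <- n_tandem + n_seg
  if (n_both > total) {
    warning("tandem + segmental counts exceed the family size; ",
            "the count-sum convention permits overlap")
  }
  pct <- function(x) round(100 * x / total, 1)
  list(
    n_tandem = n_tandem,
    n_segmental = n_seg,
    tandem_pct = pct(n_tandem),
    segmental_pct = pct(n_seg),
    monogene_pct = pct(total - n_both),
    involved_pct = pct(n_both),
    involved_pct_union = pct(length(union(tandem_genes,
                                          unique(segmental_members))))
  )
}
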