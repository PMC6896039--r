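# WRKY domain detection: heptapeptide scan plus zinc-finger spacing
# grammars. All positions are 0-based residue indices.

# Zinc-finger grammars, in matching priority order. "CX4CX23HXH" reads:
# C, 4 arbitrary residues, C, 23 arbitrary residues, H, one arbitrary
# residue, H. Grammars ending in HXC define the C2HC (group III) finger.
ZF_GRAMMARS <- list(
  list(name = "CX4CX23HXH", s1 = 4L, s2 = 23L, terminal = "H"),
  list(name = "CX4CX22HXH", s1 = 4L, s2 = 22L, terminal = "H"),
  list(name = "CX5CX23HXH", s1 = 5L, s2 = 23L, terminal = "H"),
  list(name = "CX7CX23HXC", s1 = 7L, s2 = 23L, terminal = "C")
)

zf_grammar_regex <- function(g) {
  paste0("C.{", g$s1, "}C.{", g$s2, "}H.", g$terminal)
}

zf_grammar_type <- function(name) {
  if (endsWith(name, "HXC")) "C2HC" else "C2H2"
}

#' Scan a protein for WRKY heptapeptides
#'
#' Finds all non-overlapping matches of the pattern `WRKYG-X-K` (X any
#' residue), left to right. The canonical flag is set when the wildcard
#' position is `Q` (the conserved `WRKYGQK`); the variant peptide (e.g.
#' `WRKYGKK`) is recorded verbatim.
#'
#' @param sequence Amino-acid string.
#' @return A data.frame with columns `position` (0-based index of the W),
#'   `peptide` and `canonical`; zero rows when nothing matches.
#' @examples
#' scan_heptapeptide("AAWRKYGQKAA")
#' @export
scan_heptapeptide <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  m <- gregexpr("WRKYG.K", sequence)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(position = integer(0), peptide = character(0),
                      canonical = logical(0)))
  }
  peptides <- vapply(as.integer(m),
                     function(s) substr(sequence, s, s + 6L), character(1))
  data.frame(position = as.integer(m) - 1L,
             peptide = peptides,
             canonical = substr(peptides, 6L, 6L) == "Q",
             stringsAsFactors = FALSE)
}

#' Match a zinc-finger grammar at or after a position
#'
#' Tries the four spacing grammars (`CX4CX23HXH`, `CX4CX22HXH`,
#' `CX5CX23HXH`, `CX7CX23HXC`) and returns the match with the smallest
#' start index at or after `from`; grammars earlier in the list win ties.
#'
#' @param sequence Amino-acid string.
#' @param from 0-based residue index at which the search starts.
#' @return A one-row data.frame with columns `c1`, `c2`, `h1`, `terminal`
#'   (0-based indices), `zf_type` and `grammar`, or `NULL` when no grammar
#'   matches.
#' @export
match_zinc_finger <- function(sequence, from = 0L) {
  n <- nchar(sequence)
  if (from >= n) stop("'from' must be smaller than the sequence length")
  tail <- substr(sequence, from + 1L, n)
  best <- NULL
  for (g in ZF_GRAMMARS) {
    m <- regexpr(zf_grammar_regex(g), tail)
    if (m[1L] == -1L) next
    start <- from + as.integer(m) - 1L   # back to 0-based whole-sequence
    if (is.null(best) || start < best$c1) {
      c2 <- start + 1L + g$s1
      h1 <- c2 + 1L + g$s2
      best <- data.frame(c1 = start, c2 = c2, h1 = h1, terminal = h1 + 2L,
                         zf_type = zf_grammar_type(g$name),
                         grammar = g$name, stringsAsFactors = FALSE)
    }
  }
  best
}

#' Detect WRKY domains in a protein
#'
#' Each heptapeptide match is paired with the nearest downstream
#' zinc-finger match whose first cysteine starts within `max_pair_gap`
#' residues of the heptapeptide end; unpaired heptapeptides are dropped
#' with a warning. Two-domain proteins get terminal tags `N` and `C` in
#' order; single-domain proteins are tagged `single`.
#'
#' @param protein A single named or unnamed amino-acid string.
#' @param max_pair_gap Maximum residue gap between the heptapeptide end and
#'   the zinc finger's first cysteine (default 40; the full domain is then
#'   at most 7 + 40 + 33 = 80 residues, consistent with the ~60-aa WRKY
#'   domain).
#' @return A data.frame with one row per detected domain: `protein_id`,
#'   `hepta_pos`, `peptide`, `canonical`, `c1`, `c2`, `h1`, `terminal_pos`,
#'   `zf_type`, `grammar`, `terminal_tag`.
#' @export
scan_domains <- function(protein, max_pair_gap = 40L) {
  id <- if (!is.null(names(protein))) names(protein)[1L] else "protein"
  sequence <- unname(protein[[1L]])
  heptas <- scan_heptapeptide(sequence)
  empty <- data.frame(protein_id = character(0), hepta_pos = integer(0),
                      peptide = character(0), canonical = logical(0),
                      c1 = integer(0), c2 = integer(0), h1 = integer(0),
                      terminal_pos = integer(0), zf_type = character(0),
                      grammar = character(0), terminal_tag = character(0))
  if (nrow(heptas) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(heptas))) {
    hepta_end <- heptas$position[i] + 7L  # first residue after the peptide
    if (hepta_end >= nchar(sequence)) next
    zf <- match_zinc_finger(sequence, from = hepta_end)
    if (is.null(zf) || zf$c1 - hepta_end > max_pair_gap) {
      warning("heptapeptide at position ", heptas$position[i], " in '", id,
              "' has no zinc finger within ", max_pair_gap, " residues")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = id, hepta_pos = heptas$position[i],
      peptide = heptas$peptide[i], canonical = heptas$canonical[i],
      c1 = zf$c1, c2 = zf$c2, h1 = zf$h1, terminal_pos = zf$terminal,
      zf_type = zf$zf_type, grammar = zf$grammar,
      terminal_tag = NA_character_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$terminal_tag <- if (nrow(out) == 1L) "single" else {
    c("N", rep("C", nrow(out) - 1L))
  }
  out
}

#' Scan many proteins for WRKY domains
#'
#' @param proteins Named character vector of protein sequences.
#' @param max_pair_gap See [scan_domains()].
#' @return A single data.frame of all detected domains.
#' @export
scan_domains_all <- function(proteins, max_pair_gap = 40L) {
  stopifnot(!is.null(names(proteins)))
  res <- lapply(names(proteins), function(id) {
    s <- proteins[id]
    scan_domains(s, max_pair_gap = max_pair_gap)
  })
  do.call(rbind, res)
}
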