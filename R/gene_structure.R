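# Exon/intron structure inference and classification of the conserved
# introns inside WRKY domains (R-type: spliced exactly after a conserved
# arginine upstream of the zinc finger; V-type: spliced before the valine
# six residues after the zinc finger's second cysteine).

# exon lengths in translation order
exon_lengths_tx <- function(model) {
  n <- nrow(model$exons)
  idx <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  list(idx = idx,
       lens = model$exons[idx, 2L] - model$exons[idx, 1L] + 1)
}

#' Infer introns from a gene model
#'
#' Introns are the genomic gaps between consecutive exons. Phases (CDS
#' bases before the intron, mod 3) and protein contexts are computed in
#' translation order, i.e. reversed for minus-strand models.
#'
#' @param model A [gene_model()].
#' @return A data.frame with one row per intron: `gene`, `index`
#'   (translation order, 1-based), `genomic_start`, `genomic_end`, `phase`
#'   (0-2) and `protein_context` (0-based index of the residue containing
#'   the last translated base before the splice). A single-exon model
#'   yields zero rows.
#' @examples
#' m <- gene_model("g", "chr1", "+", rbind(c(1, 9), c(20, 30)))
#' infer_introns(m)
#' @export
infer_introns <- function(model) {
  n <- nrow(model$exons)
  empty <- data.frame(gene = character(0), index = integer(0),
                      genomic_start = numeric(0), genomic_end = numeric(0),
                      phase = integer(0), protein_context = integer(0))
  if (n < 2L) return(empty)
  tx <- exon_lengths_tx(model)
  before <- cumsum(tx$lens)[-n]   # CDS bases upstream of each splice
  eff <- before - model$cds_phase_offset
  phase <- as.integer(eff %% 3)
  context <- as.integer((eff - 1) %/% 3)
  # genomic span of the intron following exon k (translation order)
  g_start <- g_end <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    if (model$strand == "+") {
      g_start[k] <- model$exons[tx$idx[k], 2L] + 1
      g_end[k] <- model$exons[tx$idx[k + 1L], 1L] - 1
    } else {
      g_start[k] <- model$exons[tx$idx[k + 1L], 2L] + 1
      g_end[k] <- model$exons[tx$idx[k], 1L] - 1
    }
  }
  data.frame(gene = model$id, index = seq_len(n - 1L),
             genomic_start = g_start, genomic_end = g_end,
             phase = phase, protein_context = context,
             stringsAsFactors = FALSE)
}

#' Map a protein residue to its genomic codon span
#'
#' @param model A [gene_model()].
#' @param aa_index 0-based residue index.
#' @return A matrix with one row per contiguous genomic fragment of the
#'   codon (columns `start`, `end`); two rows when the codon is split
#'   across an exon junction.
#' @export
protein_to_genome <- function(model, aa_index) {
  tx <- exon_lengths_tx(model)
  total <- sum(tx$lens) - model$cds_phase_offset
  if (aa_index < 0 || aa_index >= total %/% 3) {
    stop("aa_index out of range (CDS encodes ", total %/% 3, " residues)")
  }
  cds_pos <- model$cds_phase_offset + 3 * aa_index + 0:2  # 0-based CDS coords
  # map each CDS position to a genomic position, walking translation order
  bounds <- cumsum(tx$lens)
  genomic <- vapply(cds_pos, function(p) {
    k <- which(p < bounds)[1L]
    within <- p - c(0, bounds)[k]
    ex <- model$exons[tx$idx[k], ]
    if (model$strand == "+") ex[1L] + within else ex[2L] - within
  }, numeric(1))
  # collapse into contiguous runs (strand-aware step of +/-1)
  step <- if (model$strand == "+") 1 else -1
  breaks <- which(diff(genomic) != step)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(genomic))
  frags <- cbind(start = pmin(genomic[starts], genomic[ends]),
                 end = pmax(genomic[starts], genomic[ends]))
  frags
}

#' Type a WRKY-domain intron as R-type, V-type or other
#'
#' Considers introns whose splice point falls inside the domain span (from
#' the heptapeptide W to the zinc finger's terminal residue). An intron is
#' R-type when the splice sits immediately after the complete codon
#' (phase 0) of an arginine located upstream of the zinc finger's first
#' cysteine; V-type when it sits immediately before the codon of the
#' residue six positions after the zinc finger's second cysteine and that
#' residue is a valine. Phase-1/2 splits and other positions are `other`;
#' a domain without any intron is `none`.
#'
#' @param domain One row of a [scan_domains()] result.
#' @param model The [gene_model()] of the encoding gene.
#' @param sequence The protein sequence (needed to check residue
#'   identities at the splice).
#' @return A list with `type` (`"R"`, `"V"`, `"other"`, `"none"`) and,
#'   when an intron was typed, `intron_index` and `context_residue`.
#' @export
type_domain_intron <- function(domain, model, sequence) {
  tx <- exon_lengths_tx(model)
  n_res <- (sum(tx$lens) - model$cds_phase_offset) %/% 3
  if (domain$terminal_pos >= n_res) {
    stop("unmappable domain: coordinates fall outside the CDS")
  }
  introns <- infer_introns(model)
  if (nrow(introns) == 0L) return(list(type = "none"))
  res <- strsplit(sequence, "")[[1L]]
  span <- c(domain$hepta_pos, domain$terminal_pos)
  fallback <- NULL
  for (i in seq_len(nrow(introns))) {
    ctx <- introns$protein_context[i]
    if (ctx < span[1L] || ctx > span[2L]) next
    if (introns$phase[i] == 0L) {
      # splice lies exactly between codons ctx and ctx + 1
      if (res[ctx + 1L] == "R" && ctx < domain$c1) {
        return(list(type = "R", intron_index = i, context_residue = ctx))
      }
      if (ctx == domain$c2 + 5L && ctx + 2L <= length(res) &&
          res[ctx + 2L] == "V") {
        return(list(type = "V", intron_index = i, context_residue = ctx))
      }
    }
    if (is.null(fallback)) {
      fallback <- list(type = "other", intron_index = i, context_residue = ctx)
    }
  }
  if (!is.null(fallback)) fallback else list(type = "none")
}
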