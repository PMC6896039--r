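# Readers and writers for the external formats the pipeline touches:
# protein FASTA, the curated family table (TSV), gene models (GFF3 subset),
# and Newick trees. Coordinates are 1-based inclusive throughout.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Read a protein FASTA file
#'
#' Sequences are uppercased and validated against the 20 canonical amino
#' acids plus `X`. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of protein sequences (names are record
#'   ids, i.e. the first whitespace-delimited token of each header).
#' @examples
#' faa <- tempfile(fileext = ".faa")
#' writeLines(c(">a", "WRKYGQK"), faa)
#' read_fasta(faa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- setdiff(strsplit(seqs[[i]], "")[[1]], AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("FASTA format error in record '", ids[[i]],
           "': illegal residue character(s) ", paste(bad, collapse = ", "))
    }
    if (nchar(seqs[[i]]) < 1L) {
      stop("FASTA format error in record '", ids[[i]], "': empty sequence")
    }
  }
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector of protein sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read the curated WRKY family table
#'
#' Parses the packaged 58-gene *Prunus mume* WRKY table (or any table with
#' the same header). Locus strings of the form `Pa1:1070280:1072953` are
#' split into chromosome, start and end (1-based inclusive).
#'
#' @param path Path to the TSV; defaults to the packaged fixture.
#' @return A data.frame with one row per family member: `name`, `gene_id`,
#'   `chromosome`, `start`, `end`, `protein_length`, `mw` (kDa), `pi`,
#'   `localization`, `est_number`, `heptapeptide`, `zf_type`
#'   (`C2H2`/`C2HC`), `domain_number`, `subgroup` (I, IIa-e, IIx, III) and
#'   `homolog` (empty string when the table has no homolog).
#' @examples
#' fam <- read_family_table()
#' nrow(fam)  # 58
#' @export
read_family_table <- function(path = system.file("extdata",
                                                 "pmume_wrky_family.tsv",
                                                 package = "wrkyfam")) {
  if (!file.exists(path)) stop("family table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  required <- c("name", "gene_id", "locus", "protein_length", "mw", "pi",
                "localization", "est_number", "heptapeptide", "zf_type",
                "domain_number", "subgroup", "homolog")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("family table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  loc <- strsplit(tab$locus, ":", fixed = TRUE)
  if (any(lengths(loc) != 3L)) {
    stop("family table format error: malformed locus string(s): ",
         paste(tab$locus[lengths(loc) != 3L], collapse = ", "))
  }
  out <- data.frame(
    name           = tab$name,
    gene_id        = tab$gene_id,
    chromosome     = vapply(loc, `[[`, character(1), 1L),
    start          = as.numeric(vapply(loc, `[[`, character(1), 2L)),
    end            = as.numeric(vapply(loc, `[[`, character(1), 3L)),
    protein_length = as.integer(tab$protein_length),
    mw             = as.numeric(tab$mw),
    pi             = as.numeric(tab$pi),
    localization   = tab$localization,
    est_number     = as.integer(tab$est_number),
    heptapeptide   = tab$heptapeptide,
    zf_type        = tab$zf_type,
    domain_number  = as.integer(tab$domain_number),
    subgroup       = tab$subgroup,
    homolog        = ifelse(is.na(tab$homolog), "", tab$homolog),
    stringsAsFactors = FALSE
  )
  bad <- which(!(out$start < out$end))
  if (length(bad) > 0L) {
    stop("family table validation error: start >= end for ",
         paste(out$name[bad], collapse = ", "))
  }
  if (any(nchar(out$heptapeptide) != 7L)) {
    stop("family table validation error: heptapeptide not 7 residues")
  }
  if (!all(out$zf_type %in% c("C2H2", "C2HC"))) {
    stop("family table validation error: unknown zinc-finger type")
  }
  if (!all(out$domain_number %in% c(1L, 2L))) {
    stop("family table validation error: domain_number outside {1,2}")
  }
  out
}

#' Construct a gene model
#'
#' A gene model is the CDS-level structure of one mRNA: chromosome, strand,
#' and an ordered set of exon (CDS) intervals in genomic coordinates.
#'
#' @param id Model identifier.
#' @param chromosome Chromosome / scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of 1-based inclusive CDS
#'   intervals; need not be pre-sorted.
#' @param cds_phase_offset Bases to skip at the start of translation (0-2).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(id, chromosome, strand, exons, cds_phase_offset = 0L) {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L])) {
    stop("gene model validation error: exon end < start in ", id)
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("gene model validation error: overlapping CDS intervals in ", id)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!cds_phase_offset %in% 0:2) stop("cds_phase_offset must be 0, 1 or 2")
  structure(list(id = id, chromosome = chromosome, strand = strand,
                 exons = exons,
                 cds_phase_offset = as.integer(cds_phase_offset)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$id, "  ", x$chromosome, " (", x$strand, "), ",
      nrow(x$exons), " exon(s), CDS ",
      sum(x$exons[, 2L] - x$exons[, 1L] + 1), " bp\n", sep = "")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Only `gene`, `mRNA` and `CDS` features are used; other feature types are
#' ignored with a warning. CDS intervals are grouped per parent mRNA and
#' sorted genomically; minus-strand models keep genomic interval order with
#' the strand flag set.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of [gene_model()] objects (names are mRNA ids).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  other <- setdiff(unique(types), c("gene", "mRNA", "CDS"))
  if (length(other) > 0L) {
    warning("ignoring GFF3 feature type(s): ", paste(other, collapse = ", "))
  }
  cds <- gr[types == "CDS"]
  if (length(cds) == 0L) stop("GFF3 format error: no CDS features in ", path)
  parents <- cds$Parent
  if (is.null(parents) || any(lengths(parents) == 0L)) {
    stop("GFF3 format error: CDS feature without a parent mRNA")
  }
  parent <- vapply(parents, `[[`, character(1), 1L)
  models <- list()
  for (id in unique(parent)) {
    sel <- cds[parent == id]
    strand <- unique(as.character(BiocGenerics::strand(sel)))
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stop("GFF3 validation error: inconsistent or missing strand for ", id)
    }
    phases <- suppressWarnings(as.integer(as.character(sel$phase)))
    exons <- cbind(BiocGenerics::start(sel), BiocGenerics::end(sel))
    ord <- order(exons[, 1L])
    exons <- exons[ord, , drop = FALSE]
    phases <- phases[ord]
    # translation-first exon carries the phase offset
    first <- if (strand == "+") 1L else nrow(exons)
    off <- phases[first]
    if (is.na(off)) off <- 0L
    models[[id]] <- gene_model(
      id = id,
      chromosome = as.character(GenomeInfoDb::seqnames(sel))[1L],
      strand = strand, exons = exons, cds_phase_offset = off)
  }
  models
}

#' Write gene models to a GFF3 file
#'
#' Emits gene, mRNA and CDS lines for each model (one mRNA per gene).
#'
#' @param models A list of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    span <- c(min(m$exons[, 1L]), max(m$exons[, 2L]))
    gid <- paste0(m$id, ".gene")
    lines <- c(lines,
      paste(m$chromosome, "wrkyfam", "gene", span[1L], span[2L], ".",
            m$strand, ".", paste0("ID=", gid), sep = "\t"),
      paste(m$chromosome, "wrkyfam", "mRNA", span[1L], span[2L], ".",
            m$strand, ".", paste0("ID=", m$id, ";Parent=", gid), sep = "\t"))
    n <- nrow(m$exons)
    # phase of each CDS piece in translation order
    idx <- if (m$strand == "+") seq_len(n) else rev(seq_len(n))
    lens <- m$exons[idx, 2L] - m$exons[idx, 1L] + 1
    before <- cumsum(c(0, lens))[seq_len(n)]
    phase <- (3 - ((before - m$cds_phase_offset) %% 3)) %% 3
    phase[1L] <- m$cds_phase_offset
    phase_genomic <- integer(n)
    phase_genomic[idx] <- phase
    for (i in seq_len(n)) {
      lines <- c(lines,
        paste(m$chromosome, "wrkyfam", "CDS", m$exons[i, 1L], m$exons[i, 2L],
              ".", m$strand, phase_genomic[i],
              paste0("ID=", m$id, ".cds", i, ";Parent=", m$id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialise a phylogenetic tree to Newick text
#'
#' @param tree An `ape::phylo` object with branch lengths; internal node
#'   labels (e.g. bootstrap support) are emitted as internal labels.
#' @return A single Newick string.
#' @export
write_newick <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label))) {
    stop("unlabeled leaf in tree")
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::write.tree(tree)
}

#' Packaged reference proteins for subgroup assignment
#'
#' Twelve reference sequences named by the AtWRKY accession set commonly
#' used to anchor subgroups I, IIa-IIe and III. The packaged sequences
#' are synthetic stand-ins generated by [gen_family_proteins()] with the
#' subgroup-appropriate domain grammars (the real accession sequences are
#' external data); the accession-to-subgroup map ships as editable YAML
#' next to the FASTA.
#'
#' @return For `wrky_references()`, a named character vector of 12
#'   sequences; for `wrky_reference_map()`, a named character vector
#'   mapping reference name to subgroup label.
#' @export
wrky_references <- function() {
  read_fasta(system.file("extdata", "atwrky_refs_synthetic.faa",
                         package = "wrkyfam"))
}

#' @rdname wrky_references
#' @export
wrky_reference_map <- function() {
  m <- yaml::read_yaml(system.file("extdata", "atwrky_refmap_synthetic.yaml",
                                   package = "wrkyfam"))
  unlist(m)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with gene ids in the first column and one column per
#'   sample.
#' @return A numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("expression matrix has negative entries")
  m
}

#' Read a qPCR Ct table from TSV
#'
#' @param path TSV with columns `gene`, `sample`, `replicate`, `ct`.
#' @return A data.frame with those columns.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "")
  required <- c("gene", "sample", "replicate", "ct")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("Ct table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  tab$ct <- as.numeric(tab$ct)
  tab
}
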