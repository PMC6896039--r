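# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes, paired with machine-readable ground truth.
# Every generator is a pure function of its spec + seed: randomness is
# drawn inside a save/restore wrapper so no global RNG state leaks.

# background residues exclude C, H and W so planted zinc-finger grammars
# and heptapeptides are the only grammar matches in a synthetic protein
BG_ALPHABET <- c("A", "R", "N", "D", "E", "Q", "G", "I", "L", "K", "M",
                 "F", "P", "S", "T", "Y", "V")
AA20 <- setdiff(AA_ALPHABET, "X")

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

bg_string <- function(n, alphabet = BG_ALPHABET) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# grammar used when planting a domain for a subgroup; the N-terminal
# domain of group I may use the 22-residue spacing variant
subgroup_grammar <- function(subgroup, terminal = "single") {
  switch(subgroup,
    I = if (terminal == "N" && stats::runif(1) < 0.5) "CX4CX22HXH"
        else "CX4CX23HXH",
    IIa = , IIb = , IId = , IIe = "CX5CX23HXH",
    IIc = , IIx = "CX4CX23HXH",
    III = "CX7CX23HXC",
    stop("unknown subgroup: ", subgroup))
}

grammar_instance <- function(name) {
  g <- ZF_GRAMMARS[[match(name, vapply(ZF_GRAMMARS, `[[`, character(1),
                                       "name"))]]
  paste0("C", bg_string(g$s1), "C", bg_string(g$s2),
         "H", bg_string(1L), g$terminal)
}

# one planted domain: heptapeptide + linker + zinc finger; returns the
# string plus 0-based offsets of its parts relative to the domain start
plant_domain <- function(subgroup, terminal = "single", variant = FALSE,
                         linker_range = c(4L, 20L)) {
  grammar <- subgroup_grammar(subgroup, terminal)
  linker <- sample(linker_range[1L]:linker_range[2L], 1L)
  hepta <- if (variant) "WRKYGKK" else "WRKYGQK"
  zf <- grammar_instance(grammar)
  g <- ZF_GRAMMARS[[match(grammar, vapply(ZF_GRAMMARS, `[[`, character(1),
                                          "name"))]]
  c1 <- 7L + linker
  list(seq = paste0(hepta, bg_string(linker), zf),
       hepta_pos = 0L, c1 = c1, c2 = c1 + 1L + g$s1,
       terminal_pos = c1 + 1L + g$s1 + 1L + g$s2 + 2L,
       grammar = grammar, zf_type = zf_grammar_type(grammar),
       peptide = hepta, canonical = !variant)
}

mutate_positions <- function(sequence, rate, alphabet = BG_ALPHABET) {
  n <- nchar(sequence)
  k <- round(rate * n)
  if (k == 0L) return(sequence)
  pos <- sample.int(n, k)
  res <- strsplit(sequence, "")[[1L]]
  res[pos] <- sample(alphabet, k, replace = TRUE)
  paste(res, collapse = "")
}

#' Generate a synthetic WRKY family with planted domains
#'
#' Each member is a background sequence (uniform over residues excluding
#' C, H and W, so no spurious grammar matches arise) with one planted
#' heptapeptide + zinc-finger domain appropriate to its subgroup -- two
#' domains for group I, the C2HC grammar for group III. The ground truth
#' records every planted domain position, grammar and variant flag.
#'
#' @param spec A list with fields `n_per_subgroup` (named integer vector
#'   over I, IIa-IIe, IIx, III), `perturbation` (fraction of residues
#'   mutated after planting, 0-0.3, default 0), `length_range` (total
#'   protein length, default c(120, 200)), `variant_fraction` (chance a
#'   planted heptapeptide is the WRKYGKK variant, default 0) and `seed`.
#' @return A list with `proteins` (named character vector) and `truth`
#'   (data.frame: one row per planted domain with `name`, `subgroup`,
#'   `domain_index`, `hepta_pos`, `c1`, `c2`, `terminal_pos`, `zf_type`,
#'   `grammar`, `canonical`).
#' @export
gen_family_proteins <- function(spec) {
  stopifnot(!is.null(spec$n_per_subgroup), !is.null(spec$seed))
  perturbation <- spec$perturbation %||% 0
  stopifnot(perturbation >= 0, perturbation <= 0.3)
  length_range <- spec$length_range %||% c(120L, 200L)
  variant_fraction <- spec$variant_fraction %||% 0
  if (length_range[1L] < 100L) {
    stop("impossible spec: length_range too short for planted domains")
  }
  with_seed(spec$seed, {
    proteins <- character(0)
    truth <- list()
    i <- 0L
    for (sg in names(spec$n_per_subgroup)) {
      for (k in seq_len(spec$n_per_subgroup[[sg]])) {
        i <- i + 1L
        name <- sprintf("syn%02d_%s", i, sg)
        target_len <- sample(length_range[1L]:length_range[2L], 1L)
        prefix <- sample(8:25, 1L)
        terminals <- if (sg == "I") c("N", "C") else "single"
        cursor <- prefix
        seqs <- bg_string(prefix)
        for (t in terminals) {
          variant <- stats::runif(1) < variant_fraction
          dom <- plant_domain(sg, terminal = t, variant = variant)
          truth[[length(truth) + 1L]] <- data.frame(
            name = name, subgroup = sg,
            domain_index = match(t, terminals),
            hepta_pos = cursor, c1 = cursor + dom$c1,
            c2 = cursor + dom$c2,
            terminal_pos = cursor + dom$terminal_pos,
            zf_type = dom$zf_type, grammar = dom$grammar,
            canonical = dom$canonical, stringsAsFactors = FALSE)
          seqs <- paste0(seqs, dom$seq)
          cursor <- nchar(seqs)
          if (t == "N") {   # spacer between the two group-I domains
            spacer <- sample(15:30, 1L)
            seqs <- paste0(seqs, bg_string(spacer))
            cursor <- nchar(seqs)
          }
        }
        if (nchar(seqs) < target_len) {
          seqs <- paste0(seqs, bg_string(target_len - nchar(seqs)))
        }
        if (perturbation > 0) seqs <- mutate_positions(seqs, perturbation)
        proteins[[name]] <- seqs
      }
    }
    list(proteins = proteins, truth = do.call(rbind, truth))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate perturbed copies of reference proteins
#'
#' Used to exercise phylogenetic subgroup assignment: each query is a copy
#' of a randomly chosen reference with a fraction of residues substituted.
#'
#' @param references Named character vector of reference sequences.
#' @param reference_map Named character vector: reference -> subgroup.
#' @param n Number of queries.
#' @param perturbation_range Per-query substitution rate drawn uniformly
#'   from this range (default 0.05-0.15).
#' @param seed Integer seed.
#' @return A list with `queries` (named vector) and `truth` (data.frame
#'   `name`, `reference`, `subgroup`, `rate`).
#' @export
gen_reference_queries <- function(references, reference_map, n,
                                  perturbation_range = c(0.05, 0.15),
                                  seed = 1L) {
  stopifnot(all(names(references) %in% names(reference_map)))
  with_seed(seed, {
    refs <- sample(names(references), n, replace = TRUE)
    rates <- stats::runif(n, perturbation_range[1L], perturbation_range[2L])
    queries <- character(n)
    for (i in seq_len(n)) {
      queries[i] <- mutate_positions(references[[refs[i]]], rates[i],
                                     alphabet = AA20)
    }
    names(queries) <- sprintf("query%03d", seq_len(n))
    list(queries = queries,
         truth = data.frame(name = names(queries), reference = refs,
                            subgroup = unname(reference_map[refs]),
                            rate = rates, stringsAsFactors = FALSE))
  })
}

# one synthetic gene: a protein with one planted domain and a gene model
# whose (single) intron realises the requested conserved-intron type
gen_intron_gene_impl <- function(id, type, strand, intron_length_range) {
  subgroup <- switch(type, R = "IIc", V = "IIb", none = "IIe",
                     stop("intron type must be R, V or none"))
  prefix <- sample(10:25, 1L)
  dom <- plant_domain(subgroup, terminal = "single")
  suffix <- sample(25:45, 1L)
  seqs <- paste0(bg_string(prefix), dom$seq, bg_string(suffix))
  hepta_pos <- prefix
  c2 <- prefix + dom$c2
  terminal_pos <- prefix + dom$terminal_pos
  n_res <- nchar(seqs)
  # residue index before the splice (0-based), phase 0
  ctx <- switch(type,
    R = hepta_pos + 1L,          # the R of WRKYGQK, upstream of zf C1
    V = c2 + 5L,                 # splice before the V at c2 + 6
    none = terminal_pos + 4L)    # intron outside the domain
  if (type == "V") {
    res <- strsplit(seqs, "")[[1L]]
    res[c2 + 6L + 1L] <- "V"     # plant the valine (1-based index)
    seqs <- paste(res, collapse = "")
  }
  stopifnot(ctx + 1L < n_res)
  intron_len <- sample(intron_length_range[1L]:intron_length_range[2L], 1L)
  cds1 <- 3L * (ctx + 1L)        # bases in exon 1 (translation order)
  cds_total <- 3L * n_res
  # translation-order coordinates within the gene (1-based)
  ex_tx <- rbind(c(1L, cds1),
                 c(cds1 + intron_len + 1L, cds_total + intron_len))
  glen <- cds_total + intron_len
  exons <- if (strand == "+") ex_tx else {
    cbind(glen - ex_tx[, 2L] + 1L, glen - ex_tx[, 1L] + 1L)[2:1, ,
                                                            drop = FALSE]
  }
  list(id = id, protein = seqs, exons = exons, glen = glen,
       intron_type = type,
       domain = data.frame(hepta_pos = hepta_pos, c1 = prefix + dom$c1,
                           c2 = c2, terminal_pos = terminal_pos,
                           zf_type = dom$zf_type, grammar = dom$grammar,
                           stringsAsFactors = FALSE))
}

#' Generate one domain-bearing gene with a planted conserved intron
#'
#' @param type `"R"`, `"V"` or `"none"` (intron outside the domain).
#' @param strand `"+"` or `"-"`.
#' @param seed Integer seed.
#' @param intron_length_range Intron length in bp (default 80-300).
#' @return A list with `model` (a [gene_model()] anchored at position 1 of
#'   chromosome `"chrS"`), `protein`, `domain` (planted coordinates) and
#'   `intron_type`.
#' @export
gen_intron_gene <- function(type = c("R", "V", "none"), strand = "+",
                            seed = 1L, intron_length_range = c(80L, 300L)) {
  type <- match.arg(type)
  with_seed(seed, {
    g <- gen_intron_gene_impl("synthetic_gene", type, strand,
                              intron_length_range)
    list(model = gene_model(g$id, "chrS", strand, g$exons),
         protein = g$protein, domain = g$domain, intron_type = g$intron_type)
  })
}

#' Generate a synthetic genome layout with planted duplication events
#'
#' Builds per-chromosome gene coordinates with planted tandem arrays
#' (inter-gene gaps drawn from a declared range), optional duplicated
#' segments (a run of genes copied to another chromosome with per-residue
#' divergence), and per-gene conserved-intron plans. All genes carry a
#' planted WRKY domain and count as family members.
#'
#' @param spec A list with fields: `seed`; `n_chromosomes` (default 2);
#'   `genes_per_chromosome` (background genes, default 8);
#'   `tandem_arrays` -- list of `list(chromosome =, size =, gap_range =)`
#'   planted after the background genes of their chromosome;
#'   `background_gap_range` (bp between non-tandem neighbours, default
#'   c(150000, 500000), deliberately above the 100-kb tandem rule);
#'   `segment` -- `NULL` or `list(length =, divergence =, from =, to =)`;
#'   `intron_plan` -- `"random"` (default) or a character vector of
#'   `"R"`/`"V"`/`"none"` recycled over genes.
#' @return A list with `family` (data.frame `name`, `chromosome`, `start`,
#'   `end`, `rank`), `proteins`, `models` (named list of [gene_model()]),
#'   and `truth` (list: `tandem` -- list of member-name vectors,
#'   `segment_pairs` -- data.frame `orig`/`copy`, `intron_types` -- named
#'   vector).
#' @export
gen_genome_layout <- function(spec) {
  stopifnot(!is.null(spec$seed))
  n_chrom <- spec$n_chromosomes %||% 2L
  n_bg <- spec$genes_per_chromosome %||% 8L
  arrays <- spec$tandem_arrays %||% list()
  bg_gap <- spec$background_gap_range %||% c(150000, 500000)
  segment <- spec$segment
  plan <- spec$intron_plan %||% "random"
  with_seed(spec$seed, {
    genes <- list()   # per gene: name, chrom, protein, exons(rel), glen, type
    plan_i <- 0L
    next_type <- function() {
      plan_i <<- plan_i + 1L
      if (identical(plan, "random")) sample(c("R", "V", "none"), 1L)
      else plan[((plan_i - 1L) %% length(plan)) + 1L]
    }
    make_gene <- function(name) {
      ty <- next_type()
      strand <- sample(c("+", "-"), 1L)
      g <- gen_intron_gene_impl(name, ty, strand, c(80L, 300L))
      g$strand <- strand
      g
    }
    chrom_genes <- vector("list", n_chrom)
    for (c_ in seq_len(n_chrom)) {
      chrom_genes[[c_]] <- lapply(seq_len(n_bg), function(k) {
        make_gene(sprintf("c%dg%02d", c_, k))
      })
    }
    truth_tandem <- list()
    for (a in arrays) {
      c_ <- a$chromosome
      members <- lapply(seq_len(a$size), function(k) {
        make_gene(sprintf("c%dt%02d_%d", c_, length(truth_tandem) + 1L, k))
      })
      for (k in seq_along(members)) {
        members[[k]]$tandem_gap <-
          if (k == 1L) NA_real_ else stats::runif(1, a$gap_range[1L],
                                                  a$gap_range[2L])
      }
      truth_tandem[[length(truth_tandem) + 1L]] <-
        vapply(members, `[[`, character(1), "id")
      chrom_genes[[c_]] <- c(chrom_genes[[c_]], members)
    }
    segment_pairs <- NULL
    if (!is.null(segment)) {
      stopifnot(segment$length <= n_bg)
      src <- chrom_genes[[segment$from]][seq_len(segment$length)]
      copies <- lapply(src, function(g) {
        cp <- g
        cp$id <- paste0(g$id, "dup")
        cp$protein <- mutate_positions(g$protein, segment$divergence,
                                       alphabet = AA20)
        cp$tandem_gap <- NA_real_
        cp
      })
      segment_pairs <- data.frame(
        orig = vapply(src, `[[`, character(1), "id"),
        copy = vapply(copies, `[[`, character(1), "id"),
        stringsAsFactors = FALSE)
      chrom_genes[[segment$to]] <- c(chrom_genes[[segment$to]], copies)
    }
    # assign coordinates
    fam <- list(); proteins <- character(0); models <- list()
    intron_types <- character(0)
    for (c_ in seq_len(n_chrom)) {
      cursor <- round(stats::runif(1, 1e4, 5e4))
      rank <- 0L
      for (g in chrom_genes[[c_]]) {
        gap <- if (!is.null(g$tandem_gap) && !is.na(g$tandem_gap)) {
          g$tandem_gap
        } else stats::runif(1, bg_gap[1L], bg_gap[2L])
        start <- round(cursor + gap)
        end <- start + g$glen - 1
        rank <- rank + 1L
        fam[[length(fam) + 1L]] <- data.frame(
          name = g$id, chromosome = paste0("chr", c_),
          start = start, end = end, rank = rank, stringsAsFactors = FALSE)
        proteins[[g$id]] <- g$protein
        models[[g$id]] <- gene_model(g$id, paste0("chr", c_),
                                     g$strand %||% "+",
                                     g$exons + start - 1)
        intron_types[[g$id]] <- g$intron_type
        cursor <- end
      }
    }
    list(family = do.call(rbind, fam), proteins = proteins, models = models,
         truth = list(tandem = truth_tandem, segment_pairs = segment_pairs,
                      intron_types = intron_types))
  })
}

#' Generate a synthetic count matrix with planted fold changes
#'
#' Negative-binomial counts for a two-condition (e.g. before/after
#' freezing) or multi-condition design: the mean of every condition after
#' the first is the baseline mean times the planted per-gene effect.
#'
#' @param n_genes Number of genes.
#' @param conditions Character vector of condition names (default
#'   `c("before", "after")`).
#' @param effects Named numeric vector of per-gene fold changes (genes not
#'   named get effect 1).
#' @param baseline_range Range of baseline mean counts per replicate
#'   library (default 20-200).
#' @param dispersion NB dispersion (default 0.1; variance = mu + mu^2 *
#'   dispersion per replicate library).
#' @param n_replicates Replicate libraries summed into each condition
#'   column (default 3, the usual pooled design).
#' @param length_range Transcript length range in bp (default 600-3000).
#' @param seed Integer seed.
#' @return A list with `counts` (matrix), `lengths` (named vector) and
#'   `truth` (data.frame `gene`, `effect`, `direction` in
#'   up/down/none at the two-fold rule).
#' @export
gen_expression_data <- function(n_genes, conditions = c("before", "after"),
                                effects = NULL,
                                baseline_range = c(20, 200),
                                dispersion = 0.1, n_replicates = 3L,
                                length_range = c(600L, 3000L), seed = 1L) {
  genes <- sprintf("gene%03d", seq_len(n_genes))
  eff <- stats::setNames(rep(1, n_genes), genes)
  if (!is.null(effects)) {
    stopifnot(all(names(effects) %in% genes), all(effects >= 0))
    eff[names(effects)] <- effects
  }
  with_seed(seed, {
    mu <- stats::runif(n_genes, baseline_range[1L], baseline_range[2L])
    counts <- matrix(0, n_genes, length(conditions),
                     dimnames = list(genes, conditions))
    draw <- function(means) {
      reps <- replicate(n_replicates,
                        stats::rnbinom(n_genes, mu = means,
                                       size = 1 / dispersion))
      rowSums(matrix(reps, nrow = n_genes))
    }
    counts[, 1L] <- draw(mu)
    for (j in seq_along(conditions)[-1L]) {
      counts[, j] <- draw(mu * eff)
    }
    lengths <- stats::setNames(
      sample(length_range[1L]:length_range[2L], n_genes, replace = TRUE),
      genes)
    truth <- data.frame(
      gene = genes, effect = unname(eff),
      direction = ifelse(eff >= 2, "up", ifelse(eff <= 0.5, "down", "none")),
      stringsAsFactors = FALSE)
    list(counts = counts, lengths = lengths, truth = truth)
  })
}

#' Generate a qPCR Ct table with planted relative expression
#'
#' Emulates the standard design: a reference gene with constant Ct, a
#' calibrator sample (the first), and `n_replicates` technical replicates
#' per cell with Gaussian cycle noise. The target Ct is shifted by
#' `-log2(RQ)` relative to its own calibrator value.
#'
#' @param genes Character vector of target gene names.
#' @param samples Character vector of sample names; the first is the
#'   calibrator.
#' @param planted_rq Matrix (genes x samples) of true relative quantities;
#'   the calibrator column must be 1.
#' @param replicate_sd Gaussian cycle noise SD (default 0.2).
#' @param n_replicates Technical replicates per cell (default 3).
#' @param reference_gene Reference gene name (default `"Actin"`).
#' @param seed Integer seed.
#' @return A data.frame with columns `gene`, `sample`, `replicate`, `ct`,
#'   carrying `reference_gene` and `calibrator_sample` attributes.
#' @export
gen_ct_data <- function(genes, samples, planted_rq, replicate_sd = 0.2,
                        n_replicates = 3L, reference_gene = "Actin",
                        seed = 1L) {
  planted_rq <- matrix(planted_rq, nrow = length(genes),
                       dimnames = list(genes, samples))
  stopifnot(all(planted_rq > 0),
            isTRUE(all.equal(unname(planted_rq[, 1L]),
                             rep(1, length(genes)))))
  with_seed(seed, {
    base <- stats::setNames(stats::runif(length(genes), 22, 28), genes)
    rows <- list()
    for (s in samples) {
      for (r in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = c(reference_gene, genes), sample = s, replicate = r,
          ct = c(20 + stats::rnorm(1, 0, replicate_sd),
                 base - log2(planted_rq[, s]) +
                   stats::rnorm(length(genes), 0, replicate_sd)),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "reference_gene") <- reference_gene
    attr(out, "calibrator_sample") <- samples[1L]
    out
  })
}
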