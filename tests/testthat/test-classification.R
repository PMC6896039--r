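test_that("the domain-count x finger rule reproduces curated groups", {
  fam <- read_family_table()
  expect_identical(wrky_group(2L, "C2H2"), "I")     # e.g. PmWRKY01
  expect_identical(wrky_group(1L, "C2HC"), "III")   # e.g. PmWRKY08
  expect_identical(wrky_group(1L, "C2H2"), "II")    # e.g. PmWRKY51
  groups <- wrky_group(fam$domain_number, fam$zf_type)
  expect_equal(sum(groups == "I") + sum(groups == "II") + sum(groups == "III"),
               nrow(fam))
  expect_error(wrky_group(0L, "C2H2"), "0 WRKY domains")
  expect_error(wrky_group(3L, "C2H2"), "manual review")

  doms <- data.frame(zf_type = c("C2H2", "C2H2"))
  expect_identical(classify_group(doms)$group, "I")
  expect_error(classify_group(doms[0, , drop = FALSE]), "no WRKY domain")
})

test_that("global alignment matches the exhaustive enumeration oracle", {
  id <- align_pair("WRKY", "WRKY")
  expect_identical(id$a, "WRKY")
  expect_identical(id$b, "WRKY")
  expect_equal(id$score, enum_align_score("WRKY", "WRKY"))

  gap <- align_pair("WRKY", "WKY")
  expect_equal(sum(strsplit(gap$b, "")[[1]] == "-"), 1L)
  expect_equal(gap$score, enum_align_score("WRKY", "WKY"))

  mis <- align_pair("AAAA", "GGGG")
  expect_equal(nchar(mis$a), 4L)
  expect_equal(mis$score, enum_align_score("AAAA", "GGGG"))

  set.seed(17)
  for (i in 1:10) {
    a <- rand_bg(sample(3:6, 1)); b <- rand_bg(sample(3:6, 1))
    expect_equal(align_pair(a, b)$score, enum_align_score(a, b), info = paste(a, b))
  }
})

test_that("p-distance excludes gap columns and flags empty overlaps", {
  expect_equal(p_distance(list(a = "WRKY", b = "WRKY")), 0)
  expect_equal(p_distance(list(a = "AAAA", b = "AAAT")), 0.25)
  expect_error(p_distance(list(a = "AA--", b = "--AA")), "undefined")
  expect_error(p_distance(list(a = "AAA", b = "AA")), "lengths differ")
})

test_that("neighbour joining matches the closed-form three-point solution", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- build_nj_tree(d)
  lens <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(lens[["a"]], 1)
  expect_equal(lens[["b"]], 1)
  expect_equal(lens[["c"]], 3)

  asym <- d; asym[1, 2] <- 3
  expect_error(build_nj_tree(asym), "not symmetric")

  zeros <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_true(all(build_nj_tree(zeros)$edge.length == 0))
})

test_that("NJ recovers the generating topology of additive matrices", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    gen <- ape::rtree(n, rooted = FALSE)
    gen$edge.length <- runif(nrow(gen$edge), 0.1, 1)
    d <- cophenetic(gen)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    tree <- build_nj_tree(d)
    expect_identical(bip_keys(tree), bip_keys(gen))
  }
})

test_that("NJ on four taxa agrees with exhaustive topology scoring", {
  # oracle: of the three unrooted quartets, additivity selects the pairing
  # with the smallest sum d(x,y) + d(z,w)
  set.seed(31)
  for (rep in 1:20) {
    gen <- ape::rtree(4, rooted = FALSE)
    gen$edge.length <- runif(nrow(gen$edge), 0.1, 1)
    d <- cophenetic(gen)[c("t1", "t2", "t3", "t4"), c("t1", "t2", "t3", "t4")]
    sums <- c(`t1|t2` = d["t1", "t2"] + d["t3", "t4"],
              `t1|t3` = d["t1", "t3"] + d["t2", "t4"],
              `t1|t4` = d["t1", "t4"] + d["t2", "t3"])
    best_pair <- strsplit(names(which.min(sums)), "\\|")[[1]]
    tree <- build_nj_tree(d)
    key <- bip_keys(tree)
    expect_length(key, 1L)
    side <- strsplit(key, "\\|")[[1]]
    expect_true(setequal(side, best_pair) ||
                  setequal(side, setdiff(colnames(d), best_pair)))
  }
})

test_that("NJ agrees with an independent implementation on random matrices", {
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    m <- matrix(runif(n * n, 0.1, 1), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
    expect_identical(bip_keys(build_nj_tree(m)),
                     bip_keys(ape::nj(as.dist(m))))
  }
})

test_that("bootstrap support separates planted clades", {
  base_a <- strrep("A", 60); base_g <- strrep("G", 60)
  mut <- function(s, k, to) {
    r <- strsplit(s, "")[[1]]; r[sample(60, k)] <- to; paste(r, collapse = "")
  }
  set.seed(7)
  aln <- c(a1 = mut(base_a, 3, "S"), a2 = mut(base_a, 3, "T"),
           a3 = mut(base_a, 2, "P"), b1 = mut(base_g, 3, "S"),
           b2 = mut(base_g, 3, "T"), b3 = mut(base_g, 2, "P"))
  bs <- bootstrap_support(aln, n_reps = 100, seed = 5)
  sep <- bs$support[["b1|b2|b3"]]
  expect_gte(sep, 95)
  expect_true(any(grepl("^1?[0-9.]+$", bs$tree$node.label)))

  one <- bootstrap_support(aln, n_reps = 1, seed = 5)
  expect_true(all(one$support %in% c(0, 100)))

  flat <- c(x1 = "AAAA", x2 = "AAAA", x3 = "AAAA", x4 = "AAAA")
  null_bs <- bootstrap_support(flat, n_reps = 5, seed = 1)
  expect_true(all(null_bs$tree$edge.length == 0))
})

test_that("subgroup assignment follows the smallest agreeing clade", {
  refs <- wrky_references()
  refmap <- wrky_reference_map()
  q <- gen_reference_queries(refs, refmap, 25, seed = 91)
  labs <- classify_subgroups(q$queries, refs, refmap)
  expect_gte(mean(labs == q$truth$subgroup), 0.95)

  # a query unrelated to every reference falls back to IIx
  set.seed(2)
  far <- c(far_query = rand_bg(120))
  expect_identical(unname(classify_subgroups(far, refs, refmap)), "IIx")

  tree <- build_nj_tree(p_distance_matrix(c(refs, far)))
  expect_error(assign_subgroup(tree, "absent", refmap), "not in tree")
})

test_that("molecular weight matches the residue-mass oracle and is additive", {
  expect_equal(protein_mw("G"), 0.0750671, tolerance = 1e-6)
  expect_equal(round(protein_mw("G"), 2), 0.08)
  expect_equal(protein_mw("GG") * 1000, 132.12, tolerance = 1e-3)
  set.seed(5)
  for (i in 1:10) {
    a <- rand_bg(sample(3:20, 1)); b <- rand_bg(sample(3:20, 1))
    expect_equal(protein_mw(paste0(a, b)),
                 protein_mw(a) + protein_mw(b) - 18.01524 / 1000)
  }
  expect_error(protein_mw("GXG"), "undefined")
  expect_error(protein_mw(""), "empty")
})

test_that("isoelectric point sits at the charge root and is monotone", {
  expect_gt(protein_pi(strrep("K", 10)), 9)
  expect_lt(protein_pi(strrep("D", 10)), 5)
  charge_at <- function(seq, ph) {
    counts <- vapply(c("D", "E", "C", "Y", "H", "K", "R"),
                     function(a) sum(strsplit(seq, "")[[1]] == a), numeric(1))
    wrkyfam:::peptide_charge(counts, ph)
  }
  set.seed(8)
  for (i in 1:15) {
    s <- paste(sample(c("A", "D", "E", "K", "R", "H", "G", "S"),
                      sample(5:30, 1), replace = TRUE), collapse = "")
    pi_val <- protein_pi(s)
    expect_lt(abs(charge_at(s, pi_val)), 1e-4)
    swap_k <- sub("G", "K", s)
    swap_d <- sub("G", "D", s)
    if (swap_k != s) expect_gte(protein_pi(swap_k), pi_val - 1e-6)
    if (swap_d != s) expect_lte(protein_pi(swap_d), pi_val + 1e-6)
  }
})

test_that("the family summary reproduces the curated statistics", {
  s <- family_summary(read_family_table())
  expect_equal(unname(s$group_counts), c(10L, 40L, 8L))
  expect_equal(s$length_range, c(162L, 884L))
  expect_equal(s$mw_range, c(18.46, 98.18))
  expect_equal(s$pi_range, c(4.90, 9.68))
  expect_equal(s$n_variant_heptapeptide, 2L)
  sub <- as.list(s$subgroup_counts)
  expect_equal(sub$IIa, 3L); expect_equal(sub$IIb, 9L)
  expect_equal(sub$IIc, 14L); expect_equal(sub$IId, 6L)
  expect_equal(sub$IIe, 7L); expect_equal(sub$IIx, 1L)
})
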