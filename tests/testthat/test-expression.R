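test_that("RPKM follows the count / length / depth formula", {
  counts <- matrix(c(100, 999900), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  lengths <- c(g1 = 1000, g2 = 5000)
  rpkm <- compute_rpkm(counts, lengths)
  expect_equal(rpkm["g1", "s1"], 100)   # 100 * 1e9 / (1000 * 1e6)

  counts["g1", ] <- 0
  expect_equal(compute_rpkm(counts, lengths)["g1", "s1"], 0)

  set.seed(4)
  c2 <- matrix(rpois(20, 50), 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  lens <- setNames(runif(5, 500, 3000), paste0("g", 1:5))
  doubled <- c2; doubled[, 2] <- doubled[, 2] * 2
  expect_equal(compute_rpkm(doubled, lens)[, 2], compute_rpkm(c2, lens)[, 2])

  zeroed <- c2; zeroed[, 3] <- 0
  expect_error(compute_rpkm(zeroed, lens), "zero column total")
})

test_that("heatmap normalisation is anchored at zero and rank-preserving", {
  expect_equal(heat_normalize(0), 0)
  expect_equal(heat_normalize(3.96), 2)   # log10(25 * 3.96 + 1) = log10(100)
  expect_error(heat_normalize(-1), "negative")

  set.seed(10)
  m <- matrix(rexp(30, 0.1), 5, 6)
  h <- heat_normalize(m)
  for (i in 1:5) expect_equal(order(h[i, ]), order(m[i, ]))
  for (j in 1:6) expect_equal(order(h[, j]), order(m[, j]))
})

test_that("the two-fold filter is antisymmetric and direction-correct", {
  fc <- fold_change_candidates(c(g1 = 10, g2 = 40, g3 = 20),
                               c(g1 = 40, g2 = 10, g3 = 21))
  expect_identical(fc$up, "g1")
  expect_identical(fc$down, "g2")

  set.seed(12)
  before <- setNames(rexp(30, 0.05), paste0("g", 1:30))
  after <- setNames(rexp(30, 0.05), paste0("g", 1:30))
  fwd <- fold_change_candidates(before, after)
  rev_ <- fold_change_candidates(after, before)
  expect_identical(fwd$up, rev_$down)
  expect_identical(fwd$down, rev_$up)
})

test_that("planted freeze-response candidates are recovered from counts", {
  eff <- setNames(c(rep(3, 6), rep(1 / 3, 11)), sprintf("gene%03d", 1:17))
  recovered <- false_pos <- integer(20)
  for (s in seq_len(20)) {
    ex <- gen_expression_data(100, effects = eff, seed = s)
    rpkm <- compute_rpkm(ex$counts, ex$lengths)
    fc <- fold_change_candidates(rpkm[, "before"], rpkm[, "after"])
    up_truth <- ex$truth$gene[ex$truth$direction == "up"]
    down_truth <- ex$truth$gene[ex$truth$direction == "down"]
    recovered[s] <- length(intersect(fc$up, up_truth)) +
      length(intersect(fc$down, down_truth))
    false_pos[s] <- length(setdiff(fc$up, up_truth)) +
      length(setdiff(fc$down, down_truth))
  }
  expect_gte(median(recovered), 16)
  expect_lt(mean(false_pos) / 83, 0.05)
})

test_that("hierarchical clustering separates planted blobs deterministically", {
  set.seed(19)
  blob1 <- matrix(rnorm(50, 0), 10, 5)
  blob2 <- matrix(rnorm(50, 20), 10, 5)
  m <- rbind(blob1, blob2)
  rownames(m) <- paste0("g", 1:20)
  cl <- hcluster_genes(m, k = 2)
  expect_length(unique(cl[1:10]), 1L)
  expect_length(unique(cl[11:20]), 1L)
  expect_true(cl[1] != cl[11])

  singletons <- hcluster_genes(m, k = 20)
  expect_length(unique(singletons), 20L)

  dup <- m; dup[2, ] <- dup[1, ]
  cl2 <- hcluster_genes(dup, k = 6)
  expect_equal(cl2[[1]], cl2[[2]])

  expect_error(hcluster_genes(m, k = 21), "exceeds")
})

test_that("2^-ddCt gives unit RQ at the calibrator and 4x for a 2-cycle drop", {
  ct <- expand.grid(gene = c("Actin", "gX"), sample = c("T0", "T1"),
                    replicate = 1:3, stringsAsFactors = FALSE)
  ct$ct <- ifelse(ct$gene == "Actin", 20,
                  ifelse(ct$sample == "T0", 26, 24))
  rq <- relative_expression(ct, "Actin", "T0")
  expect_equal(rq$rq[rq$sample == "T0"], 1)
  expect_equal(rq$rq[rq$sample == "T1"], 4)

  # a global +1 cycle shift cancels in the dCt
  shifted <- ct
  shifted$ct <- shifted$ct + ifelse(shifted$sample == "T1", 1, 0)
  shifted$ct[shifted$sample == "T1" & shifted$gene == "gX"] <- 25
  rq2 <- relative_expression(shifted, "Actin", "T0")
  expect_equal(rq2$rq[rq2$sample == "T1"], 4)

  missing_ref <- ct[!(ct$gene == "Actin" & ct$sample == "T1"), ]
  expect_error(relative_expression(missing_ref, "Actin", "T0"), "missing")
})

test_that("planted RQ is recovered from noisy Ct tables", {
  rq <- matrix(1, 1, 3, dimnames = list("gA", c("T0", "T1", "T2")))
  rq["gA", "T2"] <- 25
  errs <- numeric(50)
  for (s in seq_len(50)) {
    ct <- gen_ct_data("gA", c("T0", "T1", "T2"), rq, seed = s)
    out <- relative_expression(ct, "Actin", "T0")
    est <- out$rq[out$sample == "T2"]
    errs[s] <- abs(log2(est) - log2(25))
    expect_equal(out$rq[out$sample == "T0"], 1)
  }
  # 25-fold induction recovered within +/- 40% in most runs
  expect_gte(mean(2^errs <= 1.4), 0.9)

  exact <- gen_ct_data("gA", c("T0", "T1", "T2"), rq,
                       replicate_sd = 0, seed = 1)
  out <- relative_expression(exact, "Actin", "T0")
  expect_equal(out$rq[out$sample == "T2"], 25)
})
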