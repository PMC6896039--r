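fam <- read_family_table()

test_that("per-chromosome counts match the curated localisation", {
  counts <- per_chromosome_counts(fam)
  expect_equal(counts[["Pa1"]], 12L)
  expect_equal(counts[["Pa2"]], 11L)
  expect_equal(counts[["Pa3"]], 7L)
  expect_equal(counts[["Pa4"]], 9L)
  expect_equal(counts[["Pa5"]], 9L)
  expect_equal(counts[["Pa6"]], 3L)
  expect_equal(counts[["Pa7"]], 5L)
  expect_equal(counts[["Pa8"]], 1L)
  expect_equal(counts[["scaffold22"]], 1L)
  expect_length(per_chromosome_counts(fam[0, ]), 0L)
  expect_equal(unname(per_chromosome_counts(fam[1, ])), 1L)
})

test_that("the 100-kb rule finds exactly the four curated tandem arrays", {
  events <- find_tandem(fam)
  members <- lapply(events, `[[`, "members")
  has <- function(x) any(vapply(members, identical, logical(1), y = x))
  expect_length(events, 4L)
  expect_true(has(c("PmWRKY08", "PmWRKY09", "PmWRKY10")))
  expect_true(has(c("PmWRKY17", "PmWRKY18")))
  expect_true(has(c("PmWRKY28", "PmWRKY29")))
  expect_true(has(c("PmWRKY41", "PmWRKY42")))
  expect_equal(length(unlist(members)), 9L)

  # the PmWRKY03/PmWRKY04 gap is 184,227 bp, over the threshold
  gap <- fam$start[fam$name == "PmWRKY04"] - fam$end[fam$name == "PmWRKY03"]
  expect_equal(gap, 184227)
  expect_false(any(vapply(members, function(m) "PmWRKY03" %in% m, logical(1))))

  # numeric adjacency across chromosomes never chains
  toy <- data.frame(name = c("a", "b"), chromosome = c("c1", "c2"),
                    start = c(1000, 2000), end = c(1500, 2500))
  expect_length(find_tandem(toy), 0L)
})

test_that("the 200-kb cluster rule finds the single curated cluster", {
  clusters <- find_clusters(fam)
  expect_length(clusters, 1L)
  expect_equal(clusters[[1]]$members, c("PmWRKY08", "PmWRKY09", "PmWRKY10"))
  expect_identical(clusters[[1]]$chromosome, "Pa1")

  wide <- data.frame(name = c("a", "b", "c"), chromosome = "c1",
                     start = c(1, 120000, 240000),
                     end = c(1000, 121000, 250000))
  expect_length(find_clusters(wide), 0L)

  tight <- data.frame(name = letters[1:4], chromosome = "c1",
                      start = c(1, 40000, 80000, 120000),
                      end = c(1000, 41000, 81000, 150000))
  cl <- find_clusters(tight)
  expect_length(cl, 1L)
  expect_length(cl[[1]]$members, 4L)
})

test_that("duplication percentages follow the count-sum convention", {
  s <- duplication_summary(find_tandem(fam), SEGMENTAL_GENES, 58)
  expect_equal(s$tandem_pct, 15.5)
  expect_equal(s$segmental_pct, 12.1)
  expect_equal(s$monogene_pct, 72.4)
  expect_equal(s$involved_pct, 27.6)

  none <- duplication_summary(list(), character(0), 58)
  expect_equal(none$tandem_pct, 0)
  expect_equal(none$monogene_pct, 100)

  one <- duplication_summary(list(list(members = c("a", "b"))),
                             character(0), 10)
  expect_equal(one$tandem_pct, 20.0)

  expect_warning(
    duplication_summary(list(list(members = letters[1:8])), letters[5:10], 10),
    "count-sum")
})

test_that("event calling is invariant to input row order", {
  set.seed(61)
  shuffled <- fam[sample.int(nrow(fam)), ]
  canon <- function(ev) {
    keys <- vapply(ev, function(e) paste(e$members, collapse = "|"),
                   character(1))
    sort(keys)
  }
  expect_identical(canon(find_tandem(shuffled)), canon(find_tandem(fam)))
  expect_identical(canon(find_clusters(shuffled)), canon(find_clusters(fam)))
})

test_that("planted tandem arrays are recovered without false events", {
  hits <- 0L; false_events <- 0L
  for (s in 1:40) {
    lay <- gen_genome_layout(list(
      seed = s, genes_per_chromosome = 4,
      tandem_arrays = list(
        list(chromosome = 1, size = 3, gap_range = c(5000, 90000)),
        list(chromosome = 2, size = 2, gap_range = c(10000, 80000)))))
    got <- lapply(find_tandem(lay$family), `[[`, "members")
    planted <- lay$truth$tandem
    hits <- hits + sum(vapply(planted, function(p) {
      any(vapply(got, identical, logical(1), y = p))
    }, logical(1)))
    false_events <- false_events + (length(got) - length(planted))

    quiet <- gen_genome_layout(list(seed = s + 1000,
                                    genes_per_chromosome = 6))
    false_events <- false_events + length(find_tandem(quiet$family))
  }
  expect_equal(hits, 80L)
  expect_equal(false_events, 0L)
})

test_that("tight tandem arrays are also clusters when the window allows", {
  for (s in 1:10) {
    lay <- gen_genome_layout(list(
      seed = s, genes_per_chromosome = 3,
      background_gap_range = c(250000, 500000),
      tandem_arrays = list(
        list(chromosome = 1, size = 3, gap_range = c(5000, 40000)))))
    tandem <- lapply(find_tandem(lay$family), `[[`, "members")
    clusters <- lapply(find_clusters(lay$family), `[[`, "members")
    expect_length(clusters, 1L)
    expect_true(any(vapply(tandem, identical, logical(1), y = clusters[[1]])))
  }
})
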