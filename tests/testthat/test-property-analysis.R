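test_that("min-max normalisation maps pooled range to [0, 1]", {
  tbl <- tibble::tibble(betweenness = c(2, 4, 6), label = c(1L, 0L, 1L))
  fs <- normalize_features(tbl, "betweenness")
  expect_equal(sort(fs$values$value), c(0, 0.5, 1))
  # idempotent on already-normalised data
  tbl2 <- tibble::tibble(betweenness = c(0, 0.5, 1), label = c(1L, 0L, 1L))
  fs2 <- normalize_features(tbl2, "betweenness")
  expect_equal(sort(fs2$values$value), c(0, 0.5, 1))
})

test_that("constant columns normalise to zero with a warning", {
  tbl <- tibble::tibble(degree = rep(4, 5), label = c(1, 1, 0, 0, 0))
  expect_warning(fs <- normalize_features(tbl, "degree"), "constant")
  expect_true(all(fs$values$value == 0))
})

test_that("a planted class shift shows up in the class means", {
  tbl <- make_classification_set(200, 200, informative_columns = "closeness",
                                 effect_size = 1.5, seed = 31)
  fs <- normalize_features(tbl, feature_columns("rin"))
  sm <- fs$summary
  mean_of <- function(feat, lab) {
    sm$mean[sm$feature == feat & sm$label == lab]
  }
  expect_gt(mean_of("closeness", 1), mean_of("closeness", 0))
  # uninformative feature: means nearly equal
  expect_lt(abs(mean_of("degree", 1) - mean_of("degree", 0)), 0.1)
})

test_that("class comparison detects planted shifts and not identical samples", {
  tbl <- make_classification_set(400, 400, informative_columns = "closeness",
                                 effect_size = 0.3, noise_sd = 1, seed = 41)
  cmp <- class_distribution_compare(tbl, c("closeness", "degree"))
  expect_lt(cmp$p_value[cmp$feature == "closeness"], 0.01)

  same <- tibble::tibble(closeness = rep(c(1, 2, 3), 2),
                         label = rep(c(1, 0), each = 3))
  cmp2 <- class_distribution_compare(same, "closeness")
  expect_equal(cmp2$mean_diff, 0)
})

test_that("rank statistic handles all-tied values via the tie correction", {
  tied <- tibble::tibble(closeness = rep(1, 20),
                         label = rep(c(1, 0), each = 10))
  cmp <- class_distribution_compare(tied, "closeness")
  # all mass tied: W equals its null mean n1*n0/2, p-value degenerate
  expect_equal(cmp$statistic, 50)
  expect_equal(cmp$mean_diff, 0)
})

test_that("type-I error of the class comparison is near nominal", {
  rejections <- vapply(1:300, function(s) {
    tbl <- make_classification_set(40, 40, effect_size = 0, seed = s)
    cmp <- class_distribution_compare(tbl, "closeness")
    cmp$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("frequency histograms normalise per class over pooled bins", {
  vals <- withr::with_seed(5, stats::runif(4000))
  lab <- rep(c(1, 0), 2000)
  h <- frequency_histogram(vals, lab, n_bins = 10)
  sums <- tapply(h$frequency, h$label, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_true(all(abs(h$frequency - 0.1) < 0.05))

  # planted enrichment: positive mass concentrates in the top bins
  vals2 <- c(withr::with_seed(6, stats::rbeta(500, 5, 1)),
             withr::with_seed(7, stats::rbeta(500, 1, 5)))
  lab2 <- rep(c(1, 0), each = 500)
  h2 <- frequency_histogram(vals2, lab2, n_bins = 10)
  top <- h2[h2$bin > 8, ]
  expect_gt(sum(top$frequency[top$label == 1]),
            sum(top$frequency[top$label == 0]))
})

make_index_table <- function(values, name = "IDX1") {
  tibble::tibble(aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                 index = name, value = values)
}

test_that("constant indices classify every site residue HIGH (tie rule)", {
  labels <- tibble::tibble(structure_id = "s", chain = "A", resnum = 1:4,
                           icode = "", resname = c("ALA", "GLY", "LEU", "SER"),
                           label = c(1L, 1L, 1L, 0L))
  pr <- hqi_proportions(labels, make_index_table(rep(1, 20)))
  expect_equal(pr$high_pct, 100)
  expect_equal(pr$low_pct, 0)
})

test_that("a two-valued index splitting the alphabet gives 100% HIGH", {
  # high half: first 10 of the PSI-BLAST alphabet order used in the table
  idx <- make_index_table(rep(c(1, 0), each = 10))
  high_aas <- c("ALA", "ARG", "ASN", "ASP", "CYS")
  labels <- tibble::tibble(structure_id = "s", chain = "A", resnum = 1:5,
                           icode = "", resname = high_aas, label = 1L)
  pr <- hqi_proportions(labels, idx)
  expect_equal(pr$high_pct, 100)
})

test_that("HQI proportions match a counting oracle on random inputs", {
  for (seed in 1:20) {
    idx_vals <- withr::with_seed(seed, stats::rnorm(20))
    idx <- make_index_table(idx_vals)
    res3 <- withr::with_seed(seed + 50, {
      sample(names(drugsite:::.AA3), 30, replace = TRUE)
    })
    labels <- tibble::tibble(structure_id = "s", chain = "A", resnum = 1:30,
                             icode = "", resname = res3, label = 1L)
    pr <- hqi_proportions(labels, idx)
    # oracle: direct counting
    thr <- mean(idx_vals)
    v <- idx_vals[match(drugsite:::aa3_to_1(res3), idx$aa)]
    expect_equal(pr$high_pct, 100 * mean(v >= thr), tolerance = 1e-12)
    expect_equal(pr$high_pct + pr$low_pct, 100)
  }
})

test_that("index tables read from TSV and reject incomplete coverage", {
  f <- withr::local_tempfile(fileext = ".tsv")
  wide <- tidyr::pivot_wider(
    dplyr::bind_rows(make_index_table(1:20, "HQI1"),
                     make_index_table(20:1, "HQI2")),
    names_from = "index", values_from = "value")
  utils::write.table(wide, f, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- read_aaindex(f)
  expect_equal(sort(unique(idx$index)), c("HQI1", "HQI2"))
  expect_equal(nrow(idx), 40)

  utils::write.table(wide[-1, ], f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_aaindex(f), "missing amino acid")
})

test_that("binding-site amino-acid counts are additive over groups", {
  labels <- tibble::tibble(
    structure_id = rep(c("s1", "s2"), each = 3), chain = "A",
    resnum = rep(1:3, 2), icode = "",
    resname = c("LEU", "LEU", "GLY", "LEU", "SER", "GLY"),
    label = c(1L, 1L, 1L, 1L, 0L, 1L))
  single <- ligand_aa_frequency(labels[labels$structure_id == "s1", ])
  expect_equal(single$count[single$resname == "LEU"], 2L)
  expect_equal(single$count[single$resname == "GLY"], 1L)

  grouped <- ligand_aa_frequency(labels,
                                 grouping = c(s1 = "eco", s2 = "hsa"))
  merged <- ligand_aa_frequency(labels)
  for (rn in unique(merged$resname)) {
    expect_equal(sum(grouped$count[grouped$resname == rn]),
                 merged$count[merged$resname == rn])
  }
  # empty group: zero counts, not missing rows
  empty <- ligand_aa_frequency(dplyr::mutate(labels, label = 0L))
  expect_equal(nrow(empty), 0)
})
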