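test_that("toy two-label code matches hand-enumerated weighted means", {
  code <- two_label_code()
  tab <- aa_index_table()
  v <- stats::setNames(tab$polarity_norm, tab$code1)
  d_ka <- abs(v["K"] - v["A"])
  # 16 K-A crossing pairs: 4 transitions, 12 transversions; all other pairs
  # are synonymous (zero error). Total weight over 288 pairs: 5*96 + 192.
  expect_equal(mutational_error(code, index = "polarity", w = 5,
                                collapse = "codon")$delta,
               unname(d_ka * (5 * 4 + 12) / (5 * 96 + 192)))
  # distinct substitution types: K-A at (pos1 ti), (pos2 ti), (pos1 tv),
  # (pos2 tv), (pos3 tv) -- every type has the same error, so the weighted
  # mean collapses to d_ka itself
  rep_type <- mutational_error(code, index = "polarity", collapse = "type")
  expect_equal(rep_type$delta, unname(d_ka))
  expect_equal(rep_type$n_units, 5)
  expect_equal(rep_type$n_pairs, 288)
})

test_that("a single-label code has zero error", {
  code <- constant_code()
  expect_equal(mutational_error(code, index = "volume",
                                collapse = "codon")$delta, 0)
  expect_equal(mutational_error(code, index = "volume",
                                collapse = "type")$delta, 0)
})

test_that("w = 1 reduces the codon-level error to the plain 263-pair mean", {
  tab <- aa_index_table()
  for (ix in c("polarity", "isoelectric")) {
    expect_equal(mutational_error(sgc(), tab, ix, w = 1,
                                  collapse = "codon")$delta,
                 naive_pair_delta(sgc(), tab, ix, w = 1))
  }
})

test_that("increasing w pulls the error toward the transition mean", {
  tab <- aa_index_table()
  np <- neighbor_pairs(sgc())
  v <- stats::setNames(tab$polarity_norm, tab$code1)
  ti_mean <- mean(abs(v[np$aa1] - v[np$aa2])[np$kind == "transition"])
  gaps <- vapply(c(1, 5, 25, 125), function(w) {
    abs(mutational_error(sgc(), tab, "polarity", w = w,
                         collapse = "codon")$delta - ti_mean)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("error reports are nonnegative with consistent category counts", {
  for (collapse in c("type", "codon")) {
    rep_ <- mutational_error(sgc(), index = "hydrophobicity",
                             collapse = collapse)
    expect_gte(rep_$delta, 0)
    expect_equal(sum(rep_$categories$n), rep_$n_pairs)
    expect_equal(nrow(rep_$categories), 6)
  }
  expect_error(mutational_error(sgc(), index = "charge"), "unknown index")
  expect_error(mutational_error(sgc(), index = "polarity", w = -1),
               "positive")
})

test_that("block permutation preserves degeneracy and is label-uniform", {
  set.seed(3)
  for (i in 1:25) {
    pc <- permute_code()
    expect_equal(block_size_multiset(pc), block_size_multiset(sgc()))
    expect_setequal(unique(unclass(pc)), amino_acid_labels())
  }
  # each label occupies the AAA block about 1000/21 times over 1000 draws
  hits <- vapply(1:1000, function(i) unname(permute_code()["AAA"]),
                 character(1))
  counts <- table(factor(hits, levels = amino_acid_labels()))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("errors are invariant to the storage order of the codon map", {
  set.seed(4)
  shuffled <- sample(unclass(sgc()))
  code2 <- genetic_code(shuffled, source = "sgc")
  expect_equal(mutational_error(code2, index = "polarity")$delta,
               mutational_error(sgc(), index = "polarity")$delta)
})

test_that("permutation test plumbing: p in [0,1], z consistent, reusable null", {
  set.seed(5)
  null <- null_distribution(index = "polarity", n_perm = 200)
  pt <- permutation_pvalue(sgc(), index = "polarity", null = null)
  expect_gte(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  expect_equal(pt$z, (pt$delta - pt$null_mean) / pt$null_sd)
  expect_equal(pt$n_perm, 200)
  # a typical permuted code is unremarkable under its own null
  ps <- vapply(1:20, function(i) {
    permutation_pvalue(permute_code(), index = "polarity",
                       null = null)$p_value
  }, numeric(1))
  expect_gt(diff(range(ps)), 0.3)
  expect_error(permutation_pvalue(sgc(), index = "volume", null = null),
               "computed for index")
  expect_error(permutation_pvalue(sgc(), n_perm = 50), "at least 100")
})

test_that("per-category tests cover the six mutation classes", {
  set.seed(6)
  res <- per_category_test(sgc(), index = "polarity", n_perm = 100)
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  expect_true(all(c("position", "kind", "n", "mean_error",
                    "null_mean", "p_value") %in% names(res)))
})

test_that("optimality ratio follows the published formula", {
  expect_equal(optimality_ratio(6, 8, 10), 50)
  expect_equal(optimality_ratio(8, 8, 10), 100)
  expect_warning(out <- optimality_ratio(c(6, 11), 8, 10), "undefined")
  expect_equal(out, c(50, NA))
})
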