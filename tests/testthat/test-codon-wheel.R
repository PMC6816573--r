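test_that("the default wheel begins and ends with the published codons", {
  w <- build_wheel("AGCTTCGA", "AAA")
  expect_equal(head(w$codon, 8),
               c("AAA", "AAG", "AAC", "AAT", "GAT", "GAC", "GAG", "GAA"))
  expect_equal(tail(w$codon, 4), c("ATT", "ATC", "ATG", "ATA"))
})

test_that("wheel structure holds for every variant and start codon", {
  starts <- c("AAA", "TTT", "GCA", "CTG")
  for (v in wheel_variants()) {
    for (s in starts) {
      w <- build_wheel(v, s)
      expect_equal(w$codon[1], s)
      expect_equal(sort(w$codon), sort(codon_order()))
      # adjacent codons (incl. wrap) differ at exactly one base
      cls <- mutation_class(w$codon, c(w$codon[-1], w$codon[1]))
      expect_false(anyNA(cls$position))
      # step census: 48 third-position, 12 first, 4 second
      expect_equal(census(w$step_position, 1:3),
                   c(12L, 4L, 48L))
    }
  }
  # exhaustive census check across all 64 starts for one variant
  cens <- vapply(codon_order(), function(s) {
    unname(table(factor(build_wheel("AGCTTCGA", s)$step_position,
                        levels = 1:3)))
  }, integer(3))
  expect_true(all(cens[1, ] == 12 & cens[2, ] == 4 & cens[3, ] == 48))
  expect_error(build_wheel("AAAAAAAA"), "unknown wheel variant")
})

test_that("addresses rank synonymous classes by first encounter", {
  addr <- assign_addresses(build_wheel(), sgc())
  got <- addr$address[match(c("AAA", "AAG", "AAC", "AAT", "GAG", "GAA"),
                            addr$codon)]
  expect_equal(got, c(1L, 1L, 2L, 2L, 4L, 4L))
  expect_setequal(addr$address, 1:21)
  # all codons of one synonymous class share a single address
  for (b in synonymous_blocks(sgc())) {
    expect_equal(length(unique(addr$address[match(b, addr$codon)])), 1)
  }
  # a reference with fewer labels is rejected
  expect_error(assign_addresses(build_wheel(), constant_code()),
               "21 labels")
})

test_that("tour paths map onto codes through the addresses", {
  addr <- assign_addresses(build_wheel(), sgc())
  labs <- attr(addr, "labels")
  # Lys moved to tour position 4 lands on the address-4 block GAG/GAA
  path <- labs
  k_pos <- which(labs == "K")
  path[c(k_pos, 4)] <- path[c(4, k_pos)]
  code <- code_from_path(path, addr)
  expect_true(all(code[c("GAG", "GAA")] == "K"))
  # identity path reproduces SGC, for every wheel variant
  for (v in wheel_variants()) {
    a <- assign_addresses(build_wheel(v), sgc())
    rebuilt <- code_from_path(attr(a, "labels"), a)
    expect_identical(code_map(rebuilt), code_map(sgc()))
  }
  # any valid path preserves the block-size multiset
  set.seed(42)
  for (i in 1:20) {
    code_i <- code_from_path(sample(labs), addr)
    expect_equal(block_size_multiset(code_i), block_size_multiset(sgc()))
  }
  expect_error(code_from_path(labs[-1], addr), "invalid tour")
  expect_error(code_from_path(c(labs[-1], labs[2]), addr), "invalid tour")
})

test_that("random tours through the wheel behave like block permutations", {
  addr <- assign_addresses(build_wheel(), sgc())
  labs <- attr(addr, "labels")
  set.seed(7)
  n_draws <- 1000
  first_block <- character(n_draws)
  for (i in seq_len(n_draws)) {
    code <- code_from_path(sample(labs), addr)
    first_block[i] <- unname(code["AAA"])
  }
  # the label landing on the first block is uniform over the 21 labels
  counts <- table(factor(first_block, levels = amino_acid_labels()))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("tour length sums consecutive distances and ignores direction", {
  tab <- aa_index_table()
  v <- stats::setNames(tab$polarity_norm, tab$code1)
  expect_equal(tour_length(c("A", "C", "D"), indices = "polarity",
                           cyclic = FALSE),
               abs(v["A"] - v["C"]) + abs(v["C"] - v["D"]),
               ignore_attr = TRUE)
  addr <- assign_addresses(build_wheel(), sgc())
  path <- attr(addr, "labels")
  expect_equal(tour_length(path), tour_length(rev(path)))
  expect_gt(tour_length(path, indices = c("polarity", "volume")),
            tour_length(path, indices = "polarity") * 0)
  expect_error(tour_length(c("A", "A", "C")), "repeated")
})

test_that("wheel export table carries ranks, addresses and step classes", {
  w <- build_wheel()
  addr <- assign_addresses(w, sgc())
  tabw <- wheel_table(w, addr)
  expect_equal(names(tabw),
               c("rank", "codon", "step_position", "step_kind",
                 "address", "label"))
  expect_equal(tabw$address[tabw$codon == "GAT"], 3)
  expect_equal(tabw$label[tabw$codon == "GAT"], "D")
})
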