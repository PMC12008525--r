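test_that("unpaired index sets follow the structure", {
  S <- pairs_to_matrix(pair_map(10, rbind(c(1, 10))))
  expect_equal(unpaired_indices(S), 2:9)
  expect_equal(unpaired_indices(matrix(0, 6, 6)), 1:6)
  # the sharp-loop rule forces at least 3 unpaired bases in any non-empty structure
  set.seed(51)
  for (k in 1:50) {
    pm <- random_pair_map(sample(10:40, 1))
    if (nrow(pm$pairs) == 0) next
    expect_gte(length(unpaired_indices(pairs_to_matrix(pm))), 3L)
  }
})

test_that("noise touches only unpaired bases and keeps the structure", {
  s <- make_hairpin(1, 8, id = "n")  # L = 10, single pair {1, 10}, |B| = 8
  set.seed(52)
  out <- add_noise(s, p1 = 0)
  expect_equal(out$seq$bases, s$seq$bases)

  for (k in 1:50) {
    out <- add_noise(s, p1 = 0.10)  # round(0.8) = 1 base changed
    a <- strsplit(s$seq$bases, "")[[1]]
    b <- strsplit(out$seq$bases, "")[[1]]
    diff <- which(a != b)
    expect_length(diff, 1L)
    expect_true(diff %in% 2:9)
    expect_identical(out$structure, s$structure)
  }
})

test_that("removal deletes unpaired bases and shifts pair indices", {
  set.seed(53)
  s <- make_hairpin(1, 10, id = "r")  # L = 12, pair {1, 12}, |B| = 10
  out <- remove_bases(s, p2 = 0.10, p1 = 0)  # removes exactly 1 unpaired base
  expect_equal(length(out$seq), 11L)
  expect_true(rowfold:::pair_map_equal(matrix_to_pairs(out$structure),
                                       pair_map(11, rbind(c(1, 11)))))
  expect_length(audit_validity(out$structure), 0L)

  for (samp in make_fixture_dataset(50, motifs = c(hairpin = 1, two_stem = 1),
                                    loop_range = c(4, 10), seed = 53)) {
    out <- remove_bases(samp, p2 = 0.15, p1 = 0.10)
    B <- length(unpaired_indices(samp$structure))
    expect_equal(length(out$seq),
                 length(samp$seq) - rowfold:::round_half_up(0.15 * B))
    expect_equal(sum(out$structure), sum(samp$structure))
    expect_length(audit_validity(out$structure), 0L)
  }
})

test_that("infeasible removals degrade gracefully and stay valid", {
  # every unpaired base sits in a minimal 3-base loop: nothing can be removed
  # without creating a sharp loop, so the operator warns and removes less
  set.seed(57)
  tight <- make_hairpin(3, 3, id = "tight")       # B = the 3 loop bases
  expect_warning(out <- remove_bases(tight, p2 = 0.5, p1 = 0), "sharp loops")
  expect_length(audit_validity(out$structure), 0L)
  expect_equal(sum(out$structure), sum(tight$structure))
})

test_that("insertion adds unpaired bases at gaps and shifts pair indices", {
  set.seed(54)
  s <- make_hairpin(1, 8, id = "i")  # L = 10, pair {1, 10}
  out <- insert_bases(s, p3 = 0.10, p1 = 0)  # inserts exactly 1 base
  expect_equal(length(out$seq), 11L)
  pm <- matrix_to_pairs(out$structure)
  expect_equal(nrow(pm$pairs), 1L)
  # the pair spans its original 9 positions, plus 1 if the insertion fell inside
  expect_true((pm$pairs[1, 2] - pm$pairs[1, 1]) %in% c(9L, 10L))
  expect_length(audit_validity(out$structure), 0L)

  for (k in 1:50) {
    pmr <- random_pair_map(sample(15:40, 1))
    samp <- rna_sample(random_rna(pmr$length), pmr)
    out <- insert_bases(samp, p3 = 0.2, p1 = 0.10)
    expect_equal(length(out$seq),
                 pmr$length + rowfold:::round_half_up(0.2 * pmr$length))
    expect_equal(sum(out$structure) / 2, nrow(pmr$pairs))
    expect_length(audit_validity(out$structure), 0L)
  }
})

test_that("paired bases are never mutated by any operator", {
  samples <- make_fixture_dataset(60, motifs = c(hairpin = 1, two_stem = 1,
                                                 pseudoknot = 1),
                                  loop_range = c(4, 10), seed = 55)
  for (samp in samples) {
    pm <- matrix_to_pairs(samp$structure)
    ch <- strsplit(samp$seq$bases, "")[[1]]
    pvec <- rowfold:::partner_vector(pm)

    out <- add_noise(samp, 0.2)
    och <- strsplit(out$seq$bases, "")[[1]]
    expect_identical(och[pvec > 0], ch[pvec > 0])

    out <- remove_bases(samp, 0.2, 0.1)
    opm <- matrix_to_pairs(out$structure)
    och <- strsplit(out$seq$bases, "")[[1]]
    # the multiset of paired-base letters is conserved under removal + noise
    expect_identical(sort(och[rowfold:::partner_vector(opm) > 0]),
                     sort(ch[pvec > 0]))

    out <- insert_bases(samp, 0.2, 0.1)
    opm <- matrix_to_pairs(out$structure)
    och <- strsplit(out$seq$bases, "")[[1]]
    expect_identical(sort(och[rowfold:::partner_vector(opm) > 0]),
                     sort(ch[pvec > 0]))
  }
})

test_that("dataset augmentation gates on length and is reproducible", {
  set.seed(56)
  long <- make_hairpin(30, 140, id = "long")    # L = 200
  short <- make_hairpin(20, 60, id = "short")   # L = 100

  out <- augment_dataset(list(long, short), reps = 2, seed = 77)
  expect_length(out, 2L + 6L)  # only the long sample is augmented
  ids <- vapply(out[-(1:2)], function(s) s$seq$id, character(1))
  expect_equal(sum(grepl("noise", ids)), 2L)
  expect_equal(sum(grepl("remove", ids)), 2L)
  expect_equal(sum(grepl("insert", ids)), 2L)
  for (s in out) expect_length(audit_validity(s$structure), 0L)

  out2 <- augment_dataset(list(long, short), reps = 2, seed = 77)
  expect_identical(lapply(out, function(s) s$seq$bases),
                   lapply(out2, function(s) s$seq$bases))
})
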