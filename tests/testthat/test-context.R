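test_that("pair counting enumerates k-1 in-frame pairs per ORF, no spanning", {
  orfs <- tiny_orf_set(c(dna_from("AUG", "GCU", "GCU", "UAA"),
                         dna_from("AUG", "UAA")),
                       ids = c("a", "b"))
  obs <- pair_counts(orfs, "a")
  expect_identical(sum(obs), 3L)
  expect_identical(obs["AUG", "GCU"], 1L)
  expect_identical(obs["GCU", "GCU"], 1L)
  expect_identical(obs["GCU", "UAA"], 1L)

  # single-pair ORF: one nonzero cell
  obs_b <- pair_counts(orfs, "b")
  expect_identical(sum(obs_b), 1L)
  expect_identical(obs_b["AUG", "UAA"], 1L)

  # total pairs = total codons - number of ORFs
  both <- pair_counts(orfs)
  expect_identical(sum(both), sum(count_codons(orfs)) - 2L)
  # stop codons appear only as 3' partners
  stops <- c("UAA", "UAG", "UGA")
  expect_identical(sum(both[stops, ]), 0L)

  # excluding the terminal stop drops those pairs
  no_stop <- pair_counts(orfs, include_stop = FALSE)
  expect_identical(sum(no_stop[, stops]), 0L)
  expect_identical(sum(no_stop), 2L)
  expect_error(pair_counts(orfs, character(0)), "empty")
})

test_that("expected counts follow the independence model and keep marginals", {
  toy <- matrix(c(10, 0, 0, 10), 2, 2)
  e <- expected_counts(toy)
  expect_equal(e, matrix(5, 2, 2))
  u <- matrix(4, 3, 3)
  expect_equal(expected_counts(u), u)
  set.seed(12)
  o <- matrix(rpois(36, 20), 6, 6)
  e <- expected_counts(o)
  expect_equal(sum(e), sum(o))
  expect_equal(rowSums(o - e), rep(0, 6), tolerance = 1e-12)
  expect_equal(colSums(o - e), rep(0, 6), tolerance = 1e-12)
})

test_that("adjusted residuals match the definition-level oracle", {
  toy <- matrix(c(10, 0, 0, 10), 2, 2)
  r <- adjusted_residuals(toy)
  expect_equal(r[1, 1], 5 / sqrt(5 * 0.5 * 0.5))  # 4.4721
  expect_equal(r[1, 1], 4.472136, tolerance = 1e-6)

  # observed equal to expected: all zero
  u <- matrix(6, 4, 4)
  expect_equal(adjusted_residuals(u), matrix(0, 4, 4), ignore_attr = TRUE)

  # random 6x6 tables against a brute-force loop and against chisq stdres
  for (seed in 1:8) {
    set.seed(seed)
    o <- matrix(rpois(36, 30) + 1, 6, 6)
    r <- adjusted_residuals(o)
    expect_equal(r, adjres_oracle(o), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(r, unname(suppressWarnings(stats::chisq.test(o)$stdres)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(adjusted_residuals(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("residual magnitudes are stable under row permutation", {
  set.seed(33)
  for (i in 1:5) {
    o <- matrix(rpois(16, 25) + 1, 4, 4)
    perm <- sample(4)
    r <- adjusted_residuals(o)
    rp <- adjusted_residuals(o[perm, ])
    expect_equal(abs(rp), abs(r[perm, ]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("pearson mode returns (o-e)/sqrt(e)", {
  set.seed(2)
  o <- matrix(rpois(16, 25) + 1, 4, 4)
  e <- expected_counts(o)
  expect_equal(adjusted_residuals(o, mode = "pearson"), (o - e) / sqrt(e),
               ignore_attr = TRUE)
})

test_that("bias calls use the +/- threshold rule", {
  orfs <- generate_orfs(synthetic_spec(n_orfs = 40, seed = 5,
    length_distribution = list(type = "fixed", codons = 150)))
  ct <- pair_context_table(orfs, group_label = "all")
  calls <- bias_calls(ct)
  expect_true(all(calls$call[calls$residual > 3] == "preferred"))
  expect_true(all(calls$call[calls$residual < -3] == "avoided"))
  expect_true(all(calls$call[abs(calls$residual) <= 3] == "no-bias"))
  # a residual of 2.9 is not significant; 4.47 is preferred
  idx29 <- which.min(abs(calls$residual - 2.9))
  expect_identical(as.character(calls$call[idx29]), "no-bias")
  strict <- bias_calls(ct, threshold = max(abs(calls$residual)) + 1)
  expect_true(all(strict$call == "no-bias"))
})

test_that("top_pairs ranks by residual with lexicographic tie-breaks", {
  # build a tiny table with known residual ordering
  orfs <- tiny_orf_set(dna_from("AUG", rep(c("GCU", "GAA"), 20), "UAA"))
  ct <- pair_context_table(orfs, group_label = "toy")
  best <- top_pairs(ct, 1, "preferred")
  worst <- top_pairs(ct, 1, "avoided")
  r <- ct$residual
  expect_equal(best$residual, max(r, na.rm = TRUE))
  expect_equal(worst$residual, min(r, na.rm = TRUE))
  expect_warning(all_pairs <- top_pairs(ct, 1e5), "defined cells")
  expect_identical(nrow(all_pairs), nrow(bias_calls(ct)))

  # tie-break: symmetric table has tied residuals, order must be lexicographic
  toy <- structure(list(group_label = "t",
                        observed = matrix(0, 64, 64,
                                          dimnames = list(codons(), codons())),
                        expected = NULL, residual = NULL, n_pairs = 0),
                   class = "pair_context_table")
  toy$observed[c("GCU", "GAA"), c("GCU", "GAA")] <- matrix(c(10, 2, 2, 10), 2)
  toy$expected <- expected_counts(toy$observed)
  toy$residual <- adjusted_residuals(toy$observed, toy$expected)
  toy$n_pairs <- sum(toy$observed)
  tp <- top_pairs(toy, 2, "preferred")
  expect_identical(tp$codon5, c("GAA", "GCU"))  # equal residuals, sorted
  expect_equal(tp$residual[1], tp$residual[2])
})

test_that("differential maps flag residual differences beyond the band", {
  spec <- synthetic_spec(n_orfs = 30, seed = 8,
    length_distribution = list(type = "fixed", codons = 120))
  orfs <- generate_orfs(spec)
  a <- pair_context_table(orfs, orfs$orf_id[1:15], group_label = "A")
  b <- pair_context_table(orfs, orfs$orf_id[16:30], group_label = "B")
  self <- differential_map(a, a)
  expect_true(all(self$similar, na.rm = TRUE))
  ab <- differential_map(a, b)
  ba <- differential_map(b, a)
  expect_equal(ab$delta, -ba$delta)
  expect_identical(is.na(ab$delta), is.na(a$residual) | is.na(b$residual))
  expect_identical(unname(ab$similar[!is.na(ab$delta)]),
                   unname(abs(ab$delta[!is.na(ab$delta)]) <= 3))
  # residuals +10 vs +2 are not similar
  fake_a <- a; fake_b <- b
  fake_a$residual[1, 1] <- 10; fake_b$residual[1, 1] <- 2
  expect_false(differential_map(fake_a, fake_b)$similar[1, 1])
})

test_that("context TSV export writes calls and integer-rounded residuals", {
  orfs <- generate_orfs(synthetic_spec(n_orfs = 10, seed = 2,
    length_distribution = list(type = "fixed", codons = 110)))
  ct <- pair_context_table(orfs, group_label = "all")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_context_tsv(ct, f)
  back <- utils::read.delim(f)
  expect_true(all(c("codon5", "codon3", "observed", "expected", "residual",
                    "call", "residual_rounded") %in% names(back)))
  expect_identical(nrow(back), nrow(bias_calls(ct)))
  expect_equal(back$residual_rounded, sign(back$residual) *
                 floor(abs(back$residual) + 0.5))
})
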