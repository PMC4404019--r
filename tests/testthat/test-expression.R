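make_em <- function(values, ids = sprintf("orf%02d", seq_len(nrow(values)))) {
  colnames(values) <- CONDITIONS
  expression_matrix(ids, as.data.frame(values))
}

test_that("compute_rpkm evaluates 1e9 * C / (N * L) and is linear in reads", {
  expect_equal(compute_rpkm(1000, 1e6, 1000), 1000)
  expect_equal(compute_rpkm(0, 1e6, 1000), 0)
  expect_equal(compute_rpkm(2 * 37, 5e6, 1234),
               2 * compute_rpkm(37, 5e6, 1234))
  expect_error(compute_rpkm(10, 0, 100), "library_size")
  expect_error(compute_rpkm(10, 1e6, 0), "length_nt")
})

test_that("expression_matrix enforces the four conditions and non-negativity", {
  expect_error(expression_matrix("a", data.frame(G18 = 1, S18 = 1, G72 = 1)),
               "columns")
  expect_error(make_em(matrix(-1, 1, 4)), "negative")
  em <- expression_matrix("a", data.frame(S72 = 4, G18 = 1, S18 = 2, G72 = 3))
  expect_identical(names(em)[-1], CONDITIONS)  # reordered canonically
  expect_equal(em$S72, 4)
})

test_that("assign_bins uses half-open bins, R group, and unassigned below 1", {
  em <- make_em(rbind(c(30.5, 30.5, 30.5, 30.5),
                      c(0.2, 0.2, 0.2, 0.2),
                      c(50, 2000, 3, 70),
                      c(5407, 5407, 5407, 5407)),
                ids = c("mid", "low", "var", "rib"))
  hv <- assign_bins(em, "HV", ribosomal_ids = "rib")
  # 30.5 sits in [1,31): the integer bin labels are realized as half-open
  # real intervals, so it stays in the lowest bin
  expect_identical(as.character(hv$bin), c("1-30", NA, ">=1000", "R"))
  av <- assign_bins(em, "AV")
  expect_identical(as.character(av$bin[av$orf_id == "var"]), "101-999")
  ec <- assign_bins(em, "EC", condition = "G72")
  expect_identical(as.character(ec$bin[ec$orf_id == "var"]), "1-30")
  expect_error(assign_bins(em, "EC"), "condition")
  expect_error(assign_bins(em, "HV", ribosomal_ids = "ghost"), "ribosomal")
  # lower edges belong to their own bin (half-open convention)
  b <- assign_bins(make_em(matrix(c(1, 31, 71, 101, 1000, 999.999,
                                    rep(0.5, 18)), 6, 4)), "HV")
  expect_identical(as.character(b$bin[1:6]),
                   c("1-30", "31-70", "71-100", "101-999", ">=1000",
                     "101-999"))
})

test_that("HV bin is at least every EC bin of the same ORF", {
  set.seed(21)
  em <- make_em(matrix(stats::rlnorm(400, 4, 1.5), 100, 4))
  hv <- assign_bins(em, "HV")
  rank_of <- function(b) as.integer(factor(b, levels = levels(hv$bin)))
  for (cc in CONDITIONS) {
    ec <- assign_bins(em, "EC", condition = cc)
    both <- !is.na(hv$bin) & !is.na(ec$bin)
    expect_true(all(rank_of(hv$bin)[both] >= rank_of(ec$bin)[both]))
  }
})

test_that("summary percentages agree with the fine bins and sum to 100", {
  em <- make_em(matrix(200, 5, 4))
  expect_equal(unname(summary_bins(em, "highest")[1, ]), c(0, 0, 100))
  em1 <- make_em(matrix(50, 1, 4))
  expect_equal(unname(summary_bins(em1, "highest")[1, ]), c(0, 100, 0))

  set.seed(3)
  em <- make_em(matrix(stats::rlnorm(400, 4, 1.5), 100, 4))
  sm <- summary_bins(em, "highest")
  expect_equal(sum(sm[1, ]), 100)
  hv <- assign_bins(em, "HV")
  over100 <- hv$orf_id[hv$bin %in% c("101-999", ">=1000")]
  n_assigned <- sum(!is.na(hv$bin))
  expect_equal(unname(sm[1, ">100"]), 100 * length(over100) / n_assigned)
  pc <- summary_bins(em, "per-condition")
  expect_identical(rownames(pc), CONDITIONS)
})

test_that("fold_changes takes max/min with fixed-order tie-breaks and flags zeros", {
  em <- make_em(rbind(c(2, 4, 8, 16), c(3, 3, 3, 3), c(0, 1, 2, 3)),
                ids = c("up", "flat", "zero"))
  fc <- fold_changes(em)
  expect_equal(fc$fold_change[1], 8)
  expect_identical(fc$label[1], "[S72/G18]")
  expect_equal(fc$fold_change[2], 1)
  expect_identical(fc$label[2], "[G18/G18]")  # ties -> first condition
  expect_false(fc$defined[3])
  expect_true(is.na(fc$fold_change[3]))
  # invariant to uniform rescaling
  em10 <- make_em(10 * as.matrix(em[CONDITIONS]), ids = em$orf_id)
  expect_equal(fold_changes(em10)$fold_change, fc$fold_change)
})

test_that("fold-change bins are upper-inclusive and sum to 100", {
  expect_equal(unname(fold_change_bins(c(1.5, 3, 3, 7, 60))),
               c(20, 40, 20, 0, 20))
  expect_equal(unname(fold_change_bins(rep(1, 4))), c(100, 0, 0, 0, 0))
  expect_equal(unname(fold_change_bins(c(2, 5, 10, 50, 51))),
               c(20, 20, 20, 20, 20))  # boundaries stay in the lower bin
  expect_error(fold_change_bins(0.5), ">= 1")
  set.seed(5)
  expect_equal(sum(fold_change_bins(1 + stats::rexp(200, 0.2))), 100)
})

test_that("normalized display maps the weakest condition to 1 and round-trips", {
  em <- make_em(rbind(c(2, 4, 8, 16), c(5, 5, 5, 5), c(0, 1, 1, 1)),
                ids = c("up", "flat", "zero"))
  nd <- normalized_display(em)
  expect_equal(unlist(nd[1, CONDITIONS], use.names = FALSE), c(1, 2, 4, 8))
  expect_equal(unlist(nd[2, CONDITIONS], use.names = FALSE), rep(1, 4))
  expect_false(nd$defined[3])
  mins <- apply(as.matrix(em[CONDITIONS]), 1, min)
  expect_equal(as.matrix(nd[1:2, CONDITIONS]) * mins[1:2],
               unname(as.matrix(em[1:2, CONDITIONS])), ignore_attr = TRUE)
})

test_that("expression TSV round-trips and counts mode applies the RPKM formula", {
  em <- make_em(matrix(c(1.5, 20, 300, 4000, rep(7, 4)), 2, 4, byrow = TRUE),
                ids = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(em, f)
  back <- read_expression_tsv(f)
  expect_equal(as.matrix(back[CONDITIONS]), as.matrix(em[CONDITIONS]),
               ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#library_sizes\tG18\tS18\tG72\tS72",
               "#\t1000000\t2000000\t1000000\t1000000",
               "orf_id\treads_G18\treads_S18\treads_G72\treads_S72",
               "a\t1000\t1000\t0\t500"), f2)
  cm <- read_expression_tsv(f2, lengths = c(a = 1000))
  expect_equal(unlist(cm[1, CONDITIONS], use.names = FALSE),
               c(1000, 500, 0, 500))
  expect_error(read_expression_tsv(f2), "lengths")
})
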