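test_that("build_contingency unions categories and validates", {
  ct <- build_contingency(c(A = 40, B = 10), c(A = 50, B = 100))
  expect_equal(dim(ct$observed), c(2L, 2L))
  expect_equal(ct$n, 200)
  expect_equal(ct$observed["focal", ], c(A = 40, B = 10))

  # category present only in reference is retained with focal cell 0
  ct2 <- build_contingency(c(A = 5), c(A = 3, B = 7))
  expect_equal(ct2$observed["focal", "B"], 0)
  expect_equal(ct2$categories, c("A", "B"))

  # both-zero category removed only under drop_empty
  ct3 <- build_contingency(c(A = 5, C = 0), c(A = 3, B = 7, C = 0),
                           drop_empty = TRUE)
  expect_equal(ct3$categories, c("A", "B"))
  expect_error(build_contingency(c(A = 1), c(A = 2)), "two usable")
  expect_error(build_contingency(c(A = -1, B = 2), c(A = 1, B = 1)),
               "non-negative")
})

test_that("chi_square matches hand computation on the worked 2x2 table", {
  ct <- build_contingency(c(A = 40, B = 10), c(A = 50, B = 100))
  res <- chi_square(ct)
  # E = row x col / N: E(focal,A) = 50*90/200 = 22.5, etc.
  e <- c(22.5, 27.5, 67.5, 82.5)
  o <- c(40, 10, 50, 100)
  expect_equal(res$chi2, sum((o - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$chi2, 32.99663, tolerance = 1e-5)
  expect_equal(res$df, 1L)
})

test_that("chi_square agrees with stats::chisq.test on random 2xC tables", {
  set.seed(77)
  for (i in 1:25) {
    cc <- sample(2:8, 1)
    focal <- stats::setNames(sample(1:80, cc), letters[1:cc])
    reference <- stats::setNames(sample(1:80, cc), letters[1:cc])
    ct <- build_contingency(focal, reference)
    res <- chi_square(ct)
    ref <- suppressWarnings(stats::chisq.test(ct$observed,
                                              correct = FALSE))
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("identical compositions give chi2 = 0, p = 1, all ns", {
  ct <- build_contingency(c(A = 30, B = 60, C = 10),
                          c(A = 30, B = 60, C = 10))
  res <- chi_square(ct)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  calls <- residual_calls(ct)
  expect_true(all(calls$table$residual == 0))
  expect_true(all(calls$table$call == "ns"))

  # proportional (not just identical) compositions also give chi2 = 0
  ct2 <- build_contingency(c(A = 10, B = 20), c(A = 30, B = 60))
  expect_equal(chi_square(ct2)$chi2, 0, tolerance = 1e-12)
})

test_that("Pearson residuals and calls match hand computation", {
  ct <- build_contingency(c(A = 40, B = 10), c(A = 50, B = 100))
  res <- residual_calls(ct)
  tab <- res$table
  expect_equal(tab$residual[tab$category == "A"],
               (40 - 22.5) / sqrt(22.5), tolerance = 1e-9)
  expect_equal(tab$residual[tab$category == "B"],
               (10 - 27.5) / sqrt(27.5), tolerance = 1e-9)
  expect_equal(tab$call, c("over", "under"))
  # cross-check against chisq.test's Pearson residual matrix
  ref <- suppressWarnings(stats::chisq.test(ct$observed, correct = FALSE))
  expect_equal(tab$residual, unname(ref$residuals["focal", ]),
               tolerance = 1e-9)
})

test_that("threshold boundaries are strict: residual exactly 2 is ns", {
  fake <- build_contingency(c(A = 40, B = 10), c(A = 50, B = 100))
  res <- residual_calls(fake)
  # construct calls directly at the boundary via the exported rule:
  # patch a residual of exactly +/- 2 through a threshold equal to it
  res2 <- residual_calls(fake, threshold = abs(res$table$residual[1]))
  expect_equal(res2$table$call[1], "ns")
  res3 <- residual_calls(fake,
                         threshold = abs(res$table$residual[1]) - 1e-9)
  expect_equal(res3$table$call[1], "over")
})

test_that("adjusted residuals match chisq.test stdres", {
  ct <- build_contingency(c(A = 40, B = 10, C = 25),
                          c(A = 50, B = 100, C = 30))
  res <- residual_calls(ct, type = "adjusted")
  ref <- suppressWarnings(stats::chisq.test(ct$observed, correct = FALSE))
  expect_equal(res$table$residual, unname(ref$stdres["focal", ]),
               tolerance = 1e-9)
})

test_that("zero expected cells error and point at drop_empty", {
  ct <- build_contingency(c(A = 5, B = 0, C = 3),
                          c(A = 2, B = 0, C = 4))
  expect_error(chi_square(ct), "drop_empty")
})

test_that("chi2 is invariant under category reordering and row swap symmetry holds", {
  focal <- c(A = 12, B = 30, C = 7, D = 21)
  reference <- c(A = 25, B = 18, C = 15, D = 30)
  a <- chi_square(build_contingency(focal, reference))
  b <- chi_square(build_contingency(rev(focal), rev(reference)))
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)

  fwd <- residual_calls(build_contingency(focal, reference))
  swp <- residual_calls(build_contingency(reference, focal))
  # focal residuals of the swapped table = reference-row residuals of
  # the original, which for 2xC Pearson residuals mirror the focal row
  ref <- suppressWarnings(stats::chisq.test(
    build_contingency(focal, reference)$observed, correct = FALSE))
  expect_equal(swp$table$residual, unname(ref$residuals["reference", ]),
               tolerance = 1e-9)
  expect_equal(sum(.expected <- ref$expected), sum(focal) + sum(reference))
})

test_that("enrichment TSV and heatmap reproduce the residuals exactly", {
  we <- worked_example()
  ct <- build_contingency(we$focal, we$reference, drop_empty = TRUE)
  res <- residual_calls(ct)
  d <- withr::local_tempdir()
  f <- file.path(d, "enr.tsv")
  write_enrichment(res, f)
  back <- utils::read.delim(f)
  expect_equal(back$residual, res$table$residual, tolerance = 1e-12)
  expect_equal(back$call, res$table$call)

  results <- list(sp1 = res,
                  sp2 = residual_calls(
                    build_contingency(we$reference, we$focal,
                                      drop_empty = TRUE)))
  hm <- enrichment_heatmap(results, file.path(d, "calls.png"))
  expect_true(all(file.exists(hm$files)))
  expect_true(all(file.size(hm$files) > 0))
  expect_equal(unname(hm$residuals[res$table$category, "sp1"]),
               res$table$residual)
  expect_equal(unname(hm$calls[res$table$category, "sp1"]),
               res$table$call)
  expect_error(enrichment_heatmap(list(), file.path(d, "x.png")), "no ")
})
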