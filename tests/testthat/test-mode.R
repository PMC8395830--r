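test_that("TF stratification takes the outer 40% with a documented tie-break", {
  v10 <- setNames(c(5, 3, 8, 1, 9, 2, 7, 4, 10, 6), paste0("S", 1:10))
  s <- split_by_tf(v10)
  expect_length(s$low, 4)
  expect_length(s$high, 4)
  expect_length(intersect(s$low, s$high), 0)
  expect_setequal(s$low, names(sort(v10))[1:4])

  v25 <- setNames(runif(25), sprintf("S%02d", 1:25))
  s25 <- split_by_tf(v25)
  expect_length(s25$low, 10)
  expect_length(s25$high, 10)

  # three-way tie straddling the 40th percentile: stable (value, id) sort
  v <- setNames(c(1, 2, 3, 3, 3, 4, 5, 6, 7, 8), paste0("S", 10:1))
  oracle <- names(v)[order(v, names(v))]
  s_tie <- split_by_tf(v)
  expect_equal(s_tie$low, oracle[1:4])
  expect_equal(s_tie$high, oracle[7:10])

  expect_error(split_by_tf(setNames(rep(1, 10), paste0("S", 1:10))),
               "constant")
  expect_error(split_by_tf(setNames(1:5, paste0("S", 1:5))), "10 samples")
})

test_that("pearson correlation matches the sum formula and rejects bad input", {
  expect_equal(pearson_cor(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_cor(1:5, -(1:5)), -1)
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 5)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y), num / den)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "3 observations")
})

test_that("mode classification reproduces the reported correlation pairs", {
  expect_equal(classify_mode(-0.28, 0.14), "INP")
  expect_equal(classify_mode(0.23, 0.51), "SEI")
  expect_equal(classify_mode(-0.18, -0.06), "WAI")
  expect_equal(classify_mode(0.3, 0.3), "UNCHANGED")
  # same-sign strengthening/weakening
  expect_equal(classify_mode(-0.2, -0.6), "SAI")
  expect_equal(classify_mode(0.6, 0.2), "WEI")
  expect_equal(classify_mode(0.2, -0.6), "IPN")
  # zero takes the sign of the other group (no inversion without sign change)
  expect_equal(classify_mode(0, 0.4), "SEI")
  expect_equal(classify_mode(0, -0.4), "SAI")
  expect_equal(classify_mode(-0.4, 0), "WAI")
  expect_equal(classify_mode(0.4, 0), "WEI")
  expect_equal(classify_mode(0, 0), "UNCHANGED")
  expect_error(classify_mode(1.2, 0), "\\[-1, 1\\]")
})

test_that("classification is total and swap maps each mode to its partner", {
  g <- seq(-1, 1, length.out = 41)
  grid <- expand.grid(lo = g, hi = g)
  modes <- classify_mode(grid$lo, grid$hi)
  expect_false(anyNA(modes))
  expect_true(all(modes %in% c("SAI", "WAI", "SEI", "WEI", "IPN", "INP",
                               "UNCHANGED")))
  swapped <- classify_mode(grid$hi, grid$lo)
  partner <- c(SAI = "WAI", WAI = "SAI", SEI = "WEI", WEI = "SEI",
               IPN = "INP", INP = "IPN", UNCHANGED = "UNCHANGED")
  expect_equal(swapped, unname(partner[modes]))
})

test_that("mode annotation labels every significant triplet or reports failure", {
  co <- generate_cohort(cohort_config(
    n_tumor = 500, n_normal = 30, n_tf = 6, n_rbp = 6, n_ase = 6,
    n_de_tf = 1, n_de_rbp = 1, n_de_ase = 1,
    planted_triplets = list(planted_triplet_for_mode("SEI", 1, 1, 1),
                            planted_triplet_for_mode("IPN", 2, 2, 2)),
    seed = 19
  ))
  trip <- tibble::tibble(
    tf = c("TF001", "TF002", "TF003"),
    rbp = c("RBP001", "RBP002", "RBP003"),
    event_id = co$psi$event_id[1:3],
    significant = c(TRUE, TRUE, FALSE)
  )
  ann <- annotate_modes(trip, co$psi, co$tf_expr, co$rbp_expr, co$clinical)
  expect_equal(ann$mode[1:2], c("SEI", "IPN"))
  expect_true(is.na(ann$mode[3])) # non-significant rows are not annotated
  expect_true(all(abs(c(ann$pcc_low[1:2], ann$pcc_high[1:2])) <= 1))

  # row order does not change per-triplet labels
  ann_rev <- annotate_modes(trip[3:1, ], co$psi, co$tf_expr, co$rbp_expr,
                            co$clinical)
  expect_equal(ann_rev$mode[3:1], ann$mode)

  counts <- mode_counts(ann)
  expect_equal(sum(counts$n), 2L)
  expect_equal(counts$n[counts$mode == "SEI"], 1L)

  empty <- annotate_modes(trip[trip$significant == FALSE, ][0, ],
                          co$psi, co$tf_expr, co$rbp_expr, co$clinical)
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(mode_counts(empty)$n), 0L)

  # a constant-PSI event cannot be annotated but is reported, not dropped
  psi_bad <- co$psi
  psi_bad[1, -1] <- 0.5
  expect_message(
    ann_bad <- annotate_modes(trip[1, ], psi_bad, co$tf_expr, co$rbp_expr,
                              co$clinical),
    "undefined correlations"
  )
  expect_true(is.na(ann_bad$mode[1]))
})
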