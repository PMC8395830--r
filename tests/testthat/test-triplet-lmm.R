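test_that("the fixed-effects limit agrees with a normal-equations oracle", {
  co <- tiny_cohort(n_tumor = 80, seed = 3)
  d <- quiet(assemble_triplet_data(
    row_vec(co$psi, co$psi$event_id[1]),
    row_vec(co$rbp_expr, "RBP001"), row_vec(co$tf_expr, "TF001"),
    co$clinical
  ))
  fit <- fit_triplet_lmm(d, random_effects = character(0))
  X <- stats::model.matrix(~ rbp * tf + gender + stage, data = d)
  oracle <- ols_oracle(X, d$psi)
  got <- tidy(fit)
  expect_setequal(got$term, oracle$term)
  idx <- match(got$term, oracle$term)
  expect_equal(got$estimate, oracle$estimate[idx], tolerance = 1e-8)
  expect_equal(got$std_error, oracle$se[idx], tolerance = 1e-8)
  expect_equal(got$p_value, oracle$p[idx], tolerance = 1e-8)
})

test_that("constant PSI yields a degenerate, never-significant fit", {
  co <- tiny_cohort(seed = 5)
  psi_row <- row_vec(co$psi, co$psi$event_id[1])
  psi_row[] <- 0.5
  d <- quiet(assemble_triplet_data(psi_row, row_vec(co$rbp_expr, "RBP001"),
                                   row_vec(co$tf_expr, "TF001"), co$clinical))
  fit <- fit_triplet_lmm(d)
  expect_true(fit$degenerate)
  b <- tidy(fit)
  expect_equal(b$estimate[b$term %in% c("rbp", "tf", "rbp:tf")], rep(0, 3))
  expect_false(triplet_significant(fit))
})

test_that("the triple-significance rule applies all four clauses", {
  mk <- function(p_rbp, p_tf, p_int, b3, converged = TRUE) {
    co <- tibble::tibble(
      term = c("(Intercept)", "rbp", "tf", "rbp:tf"),
      estimate = c(0.5, 0.1, 0.1, b3),
      std_error = 0.01, statistic = 1,
      p_value = c(0.5, p_rbp, p_tf, p_int)
    )
    splicemod:::new_triplet_lmm(co, numeric(0), 0.1, converged, FALSE, 100,
                                character(0), "psi ~ rbp * tf")
  }
  expect_false(triplet_significant(mk(0.2, 0.01, 0.01, 0.4)))
  expect_true(triplet_significant(mk(0.01, 0.02, 0.03, -0.7)))
  expect_false(triplet_significant(mk(0.01, 0.01, 0.01, 0)))
  expect_false(triplet_significant(mk(0.01, 0.01, 0.01, 0.4,
                                      converged = FALSE)))
  expect_false(triplet_significant(mk(0.01, 0.01, 0.05, 0.4))) # strict <
})

test_that("enumeration is exhaustive, ordered, and matches per-fit results", {
  co <- tiny_cohort(n_tumor = 60, seed = 6)
  tfs <- c("TF002", "TF001")
  rbps <- c("RBP003", "RBP001")
  ases <- co$psi$event_id[2]
  tr <- quiet(enumerate_triplets(co$psi, co$tf_expr, co$rbp_expr, co$clinical,
                                 tfs = tfs, rbps = rbps, ases = ases))
  expect_equal(nrow(tr), 4L)
  expect_equal(tr$tf, rep(c("TF001", "TF002"), each = 2))
  expect_equal(tr$rbp, rep(c("RBP001", "RBP003"), 2))

  for (i in c(1, 4)) {
    d <- quiet(assemble_triplet_data(
      row_vec(co$psi, tr$event_id[i]), row_vec(co$rbp_expr, tr$rbp[i]),
      row_vec(co$tf_expr, tr$tf[i]), co$clinical
    ))
    f <- fit_triplet_lmm(d)
    b <- tidy(f)
    expect_equal(tr$beta3[i], b$estimate[b$term == "rbp:tf"],
                 tolerance = 1e-8)
    expect_equal(tr$p_interaction[i], b$p_value[b$term == "rbp:tf"],
                 tolerance = 1e-8)
    expect_equal(tr$significant[i], triplet_significant(f))
  }
})

test_that("shared TF/RBP symbols are skipped and order of samples is irrelevant", {
  co <- tiny_cohort(n_tumor = 60, seed = 8)
  tf2 <- co$tf_expr
  tf2$gene[1] <- "SHARED"
  rbp2 <- co$rbp_expr
  rbp2$gene[1] <- "SHARED"
  expect_message(
    tr <- suppressWarnings(enumerate_triplets(
      co$psi, tf2, rbp2, co$clinical,
      tfs = c("SHARED", "TF002"), rbps = c("SHARED", "RBP002"),
      ases = co$psi$event_id[1]
    )),
    "share a symbol"
  )
  expect_equal(nrow(tr), 3L)
  expect_false(any(tr$tf == tr$rbp))

  # permuting the sample columns leaves every estimate unchanged
  base <- quiet(enumerate_triplets(co$psi, co$tf_expr, co$rbp_expr,
                                   co$clinical, tfs = "TF001",
                                   rbps = c("RBP001", "RBP002"),
                                   ases = co$psi$event_id[1:2]))
  set.seed(1)
  perm <- sample(ncol(co$psi) - 1)
  shuffle <- function(tbl) tbl[, c(1, 1 + perm)]
  permuted <- quiet(enumerate_triplets(shuffle(co$psi), shuffle(co$tf_expr),
                                       shuffle(co$rbp_expr), co$clinical,
                                       tfs = "TF001",
                                       rbps = c("RBP001", "RBP002"),
                                       ases = co$psi$event_id[1:2]))
  expect_equal(permuted$beta3, base$beta3, tolerance = 1e-9)
  expect_equal(permuted$significant, base$significant)
})

test_that("a planted interaction is flagged significant at moderate size", {
  cfg <- cohort_config(n_tumor = 300, n_normal = 30, n_tf = 3, n_rbp = 3,
                       n_ase = 3, n_de_tf = 1, n_de_rbp = 1, n_de_ase = 1,
                       planted_triplets = list(triplet_spec(2, 2, 2)),
                       seed = 61)
  co <- generate_cohort(cfg)
  tr <- quiet(enumerate_triplets(co$psi, co$tf_expr, co$rbp_expr,
                                 co$clinical))
  hit <- tr[tr$tf == "TF002" & tr$rbp == "RBP002" &
              tr$event_id == co$psi$event_id[2], ]
  expect_true(hit$significant)
  expect_gt(hit$beta3, 0)
})
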