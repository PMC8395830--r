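test_that("cohort generation is a pure function of the configuration", {
  cfg <- cohort_config(n_tumor = 40, n_normal = 20, n_tf = 5, n_rbp = 5,
                       n_ase = 6, n_de_tf = 2, n_de_rbp = 2, n_de_ase = 2,
                       planted_triplets = list(triplet_spec(1, 2, 3)),
                       seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$psi, b$psi)
  expect_identical(a$tf_expr, b$tf_expr)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$planted, b$truth$planted)
  # PSI always in [0, 1], expression non-negative, truth consistent
  expect_true(all(as.matrix(a$psi[, -1]) >= 0 & as.matrix(a$psi[, -1]) <= 1))
  expect_true(all(as.matrix(a$tf_expr[, -1]) >= 0))
  expect_equal(a$truth$planted$event_id, a$psi$event_id[3])
})

test_that("configurations are validated", {
  expect_error(cohort_config(n_tf = 0), ">= 1")
  expect_error(cohort_config(n_tf = 3, n_de_tf = 5), "exceed")
  expect_error(cohort_config(noise_sd = -1), "non-negative")
  expect_error(triplet_spec(1, 1, 1, beta3 = 0), "beta3")
  expect_error(
    cohort_config(n_ase = 2, n_de_ase = 1,
                  planted_triplets = list(triplet_spec(1, 1, 5))),
    "exceed the configured panel sizes"
  )
})

test_that("noiseless PSI equals the logistic of the planted linear predictor", {
  sp <- triplet_spec(1, 1, 2, beta1 = 0.8, beta2 = 0.5, beta3 = 0.8)
  cfg <- cohort_config(
    n_tumor = 50, n_normal = 20, n_tf = 3, n_rbp = 3, n_ase = 4,
    n_de_tf = 1, n_de_rbp = 1, n_de_ase = 1, noise_sd = 0,
    random_effect_sds = c(0, 0, 0), gender_effect = 0, stage_effect = 0,
    planted_triplets = list(sp), seed = 21
  )
  co <- generate_cohort(cfg)
  tum <- co$clinical$sample_id[co$clinical$class == "tumor"]
  z <- function(tbl, i) {
    v <- log2(as.numeric(tbl[i, -1][, tum]) + 1)
    (v - mean(v)) / sd(v)
  }
  zt <- z(co$tf_expr, 1)
  zr <- z(co$rbp_expr, 1)
  params <- co$truth$ase_params
  eta <- params$intercept[2] + params$de_logit_shift[2] +
    sp$beta1 * zr + sp$beta2 * zt + sp$beta3 * zr * zt
  got <- as.numeric(co$psi[2, -1][, tum])
  expect_equal(got, plogis(eta), tolerance = 1e-12)
  # an unplanted event: intercept + DE shift only
  got1 <- as.numeric(co$psi[1, -1][, tum])
  expect_equal(got1, rep(plogis(params$intercept[1] + params$de_logit_shift[1]),
                         length(tum)), tolerance = 1e-12)
})

test_that("null cohorts share everything but the planted PSI rows", {
  cfg <- cohort_config(n_tumor = 40, n_normal = 20, n_tf = 4, n_rbp = 4,
                       n_ase = 5, n_de_tf = 1, n_de_rbp = 1, n_de_ase = 1,
                       planted_triplets = list(triplet_spec(1, 1, 4)),
                       seed = 33)
  full <- generate_cohort(cfg)
  null <- generate_null_cohort(cfg)
  expect_identical(full$tf_expr, null$tf_expr)
  expect_identical(full$rbp_expr, null$rbp_expr)
  expect_identical(full$clinical[, c("sample_id", "class", "gender", "stage",
                                     "age", "race", "year")],
                   null$clinical[, c("sample_id", "class", "gender", "stage",
                                     "age", "race", "year")])
  diff_rows <- vapply(seq_len(nrow(full$psi)), function(i) {
    !isTRUE(all.equal(as.numeric(full$psi[i, -1]), as.numeric(null$psi[i, -1])))
  }, logical(1))
  expect_equal(which(diff_rows), 4L)
  expect_false(null$truth$planted_active)
})

test_that("identity-link noiseless fits recover the generating coefficients", {
  sp <- triplet_spec(1, 1, 2, beta1 = 0.02, beta2 = 0.02, beta3 = 0.01)
  cfg <- cohort_config(
    n_tumor = 60, n_normal = 20, n_tf = 3, n_rbp = 3, n_ase = 2,
    n_de_tf = 1, n_de_rbp = 1, n_de_ase = 1, ase_de_logit = 0.05,
    noise_sd = 0, random_effect_sds = c(0, 0, 0), gender_effect = 0,
    stage_effect = 0, link = "identity", planted_triplets = list(sp),
    seed = 8
  )
  co <- generate_cohort(cfg)
  psi_row <- row_vec(co$psi, co$psi$event_id[2])
  expect_true(min(psi_row) > 0 && max(psi_row) < 1) # no clamping occurred
  d <- quiet(assemble_triplet_data(psi_row, row_vec(co$rbp_expr, "RBP001"),
                                   row_vec(co$tf_expr, "TF001"), co$clinical))
  fit <- quiet(fit_triplet_lmm(d, random_effects = character(0)))
  co_tbl <- tidy(fit)
  expect_equal(co_tbl$estimate[co_tbl$term == "rbp"], 0.02, tolerance = 1e-8)
  expect_equal(co_tbl$estimate[co_tbl$term == "tf"], 0.02, tolerance = 1e-8)
  expect_equal(co_tbl$estimate[co_tbl$term == "rbp:tf"], 0.01,
               tolerance = 1e-8)
})

test_that("positive risk coefficients shorten survival of high-risk samples", {
  cfg <- cohort_config(n_tumor = 400, n_normal = 20, n_tf = 3, n_rbp = 3,
                       n_ase = 3, n_de_tf = 1, n_de_rbp = 1, n_de_ase = 1,
                       planted_triplets = list(triplet_spec(1, 1, 1)),
                       risk_betas = c(ase = 1, tf = 1, rbp = 1), seed = 14)
  co <- generate_cohort(cfg)
  risk <- co$truth$risk
  clin <- co$clinical[match(risk$sample_id, co$clinical$sample_id), ]
  hi <- risk$latent_risk > median(risk$latent_risk)
  expect_lt(median(clin$os_time[hi]), median(clin$os_time[!hi]))
})

test_that("each mode recipe reproduces its intended stratified-correlation mode", {
  for (mode in c("SAI", "WAI", "SEI", "WEI", "IPN", "INP")) {
    cfg <- cohort_config(
      n_tumor = 1200, n_normal = 20, n_tf = 2, n_rbp = 2, n_ase = 2,
      n_de_tf = 1, n_de_rbp = 1, n_de_ase = 1,
      planted_triplets = list(planted_triplet_for_mode(mode, 1, 1, 1)),
      seed = 77
    )
    co <- generate_cohort(cfg)
    trip <- tibble::tibble(tf = "TF001", rbp = "RBP001",
                           event_id = co$psi$event_id[1], significant = TRUE)
    ann <- annotate_modes(trip, co$psi, co$tf_expr, co$rbp_expr, co$clinical)
    expect_equal(ann$mode, mode)
  }
})

test_that("written cohorts round-trip through the readers", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(n_tumor = 35, n_normal = 15, seed = 2)
  write_cohort(co, dir)
  psi <- read_psi(file.path(dir, "psi.tsv"))
  expect_equal(psi$event_id, co$psi$event_id)
  expect_equal(as.matrix(psi[, -1]), as.matrix(co$psi[, -1]),
               tolerance = 1e-9)
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(clin$sample_id, co$clinical$sample_id)
  expr <- read_expression(file.path(dir, "tf_expr.tsv"))
  expect_equal(expr$gene, co$tf_expr$gene)
})
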