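# shared test utilities: fixtures are generated in code, never stored

# named numeric row from a wide feature table
row_vec <- function(tbl, id) {
  i <- match(id, tbl[[1]])
  stopifnot(!is.na(i))
  setNames(as.numeric(tbl[i, -1]), names(tbl)[-1])
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# a small cohort suitable for LMM fitting (>= 30 tumor samples)
tiny_cohort <- function(n_tumor = 80, n_normal = 40, n_tf = 4, n_rbp = 4,
                        n_ase = 3, seed = 42, ...) {
  generate_cohort(cohort_config(
    n_tumor = n_tumor, n_normal = n_normal, n_tf = n_tf, n_rbp = n_rbp,
    n_ase = n_ase, n_de_tf = 1, n_de_rbp = 1, n_de_ase = 1, seed = seed, ...
  ))
}

# classical OLS of y on design X by normal equations, with t-test p-values;
# independent of lm()/lme4 code paths
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  n <- nrow(X)
  p <- ncol(X)
  sigma2 <- sum(resid^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(estimate = as.numeric(beta), se = as.numeric(se),
       statistic = as.numeric(tval),
       p = 2 * pt(-abs(as.numeric(tval)), df = n - p),
       term = colnames(X))
}
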