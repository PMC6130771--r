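test_that("the index is the expression-weighted mean of the parameter", {
  W <- matrix(c(1, 3, 2, 2), 2, dimnames = list(NULL, c("s1", "s2")))
  x <- devindex:::expr_from_matrix(c("g1", "g2"), W, "normalized_linear")
  ann <- tibble::tibble(gene_id = c("g1", "g2"), omega0 = c(1, 3))
  out <- compute_tei(x, ann, "omega0")
  expect_equal(out$tei[out$stage == "s1"], 2.5) # (1*1 + 3*3) / 4
  expect_equal(out$tei[out$stage == "s2"], 2)
  expect_equal(out$n_genes, c(2L, 2L))

  # constant parameter -> the constant, everywhere
  ann$omega0 <- c(0.7, 0.7)
  expect_equal(compute_tei(x, ann, "omega0")$tei, c(0.7, 0.7))

  # single gene -> its own value, everywhere
  one <- compute_tei(x, tibble::tibble(gene_id = "g1", omega0 = 0.3), "omega0")
  expect_equal(one$tei, c(0.3, 0.3))
  expect_equal(one$n_genes, c(1L, 1L))
})

test_that("genes lacking the parameter are excluded, never imputed", {
  W <- matrix(c(1, 1, 1, 1, 1, 1), 3, dimnames = list(NULL, c("s1", "s2")))
  x <- devindex:::expr_from_matrix(c("a", "b", "c"), W, "normalized_linear")
  ann <- tibble::tibble(gene_id = c("a", "b", "c"), omega0 = c(1, NA, 3))
  out <- compute_tei(x, ann, "omega0")
  expect_equal(out$tei, c(2, 2))
  expect_equal(out$n_genes, c(2L, 2L))
  expect_error(compute_tei(x, ann, "nope"), "no column")
})

test_that("zero total weight at a stage is an error", {
  W <- matrix(c(1, 2, 0, 0), 2, dimnames = list(NULL, c("s1", "s2")))
  x <- devindex:::expr_from_matrix(c("a", "b"), W, "normalized_linear")
  ann <- tibble::tibble(gene_id = c("a", "b"), omega0 = c(1, 2))
  expect_error(compute_tei(x, ann, "omega0"), "Zero total expression weight")
})

test_that("the index matches a loop-based oracle and stays within parameter bounds", {
  for (i in 1:20) {
    inst <- random_instance(genes = 20, stages = 5, seed = 100 + i)
    got <- compute_tei(inst$x, inst$ann, "omega0")$tei
    want <- oracle_tei(inst$W, inst$ann$omega0)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= min(inst$ann$omega0) & got <= max(inst$ann$omega0)))
  }
})

test_that("rescaling one stage's weights leaves that stage's index unchanged", {
  inst <- random_instance(seed = 7)
  base <- compute_tei(inst$x, inst$ann, "omega0")$tei
  W2 <- inst$W
  W2[, 3] <- W2[, 3] * 17.5
  x2 <- devindex:::expr_from_matrix(inst$x$gene_id, W2, "normalized_linear")
  expect_equal(compute_tei(x2, inst$ann, "omega0")$tei, base, tolerance = 1e-12)
})

test_that("bootstrap intervals behave on degenerate inputs and fixed seeds", {
  W <- matrix(c(2, 3), 1, dimnames = list(NULL, c("s1", "s2")))
  x1 <- devindex:::expr_from_matrix("a", W, "normalized_linear")
  p1 <- tei_profile(x1, tibble::tibble(gene_id = "a", omega0 = 0.4), "omega0",
    n_boot = 50, seed = 1
  )
  expect_equal(p1$ci_lower, c(0.4, 0.4))
  expect_equal(p1$ci_upper, c(0.4, 0.4))

  inst <- random_instance(seed = 9)
  constant <- tibble::tibble(gene_id = inst$x$gene_id, omega0 = rep(2.5, nrow(inst$x)))
  pc <- tei_profile(inst$x, constant, "omega0", n_boot = 50, seed = 1)
  expect_equal(pc$ci_lower, rep(2.5, 5))
  expect_equal(pc$ci_upper, rep(2.5, 5))

  a <- tei_profile(inst$x, inst$ann, "omega0", n_boot = 200, seed = 42)
  b <- tei_profile(inst$x, inst$ann, "omega0", n_boot = 200, seed = 42)
  expect_identical(a, b)
  expect_error(tei_profile(inst$x, inst$ann, "omega0", n_boot = 1), "at least 2")

  # interval brackets the point estimate and is ordered
  expect_true(all(a$ci_lower <= a$tei + 1e-12 & a$tei <= a$ci_upper + 1e-12))
})

test_that("bootstrap quantiles match an independent resampling oracle", {
  inst <- random_instance(genes = 15, stages = 3, seed = 13)
  p <- tei_profile(inst$x, inst$ann, "omega0", n_boot = 5000, seed = 3)
  set.seed(1234)
  G <- nrow(inst$W)
  reps <- replicate(5000, {
    idx <- sample.int(G, G, replace = TRUE)
    sum(inst$ann$omega0[idx] * inst$W[idx, 2]) / sum(inst$W[idx, 2])
  })
  expect_equal(p$ci_lower[2], quantile(reps, 0.025, names = FALSE), tolerance = 0.02)
  expect_equal(p$ci_upper[2], quantile(reps, 0.975, names = FALSE), tolerance = 0.02)
})

test_that("ci_ratio divides upper by lower bound and guards the domain", {
  prof <- structure(
    tibble::tibble(
      stage = c("s1", "s2"), tei = c(2.5, 3), ci_lower = c(2, 3),
      ci_upper = c(3, 3), n_genes = 5L
    ),
    param = "omega0", n_boot = 10L, level = 0.95, seed = NULL,
    class = c("tei_profile", class(tibble::tibble()))
  )
  expect_equal(ci_ratio(prof)$ci_ratio, c(1.5, 1))
  prof$ci_lower[1] <- 0
  expect_error(ci_ratio(prof), "shift-parameterize")
})
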