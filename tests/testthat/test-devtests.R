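make_calls <- function(mat, stages = paste0("s", seq_len(ncol(mat)))) {
  colnames(mat) <- stages
  out <- tibble::as_tibble(as.data.frame(mat, optional = TRUE))
  out <- tibble::add_column(out, gene_id = paste0("g", seq_len(nrow(mat))), .before = 1L)
  structure(out, class = c("expr_calls", class(tibble::tibble())))
}

test_that("pleiotropy breadth uses a strict threshold", {
  cm <- rbind(
    c(TRUE, TRUE, TRUE, FALSE, FALSE), # 3/5 = 0.6 > 0.5 -> flagged
    c(TRUE, TRUE, FALSE, FALSE, FALSE), # 2/5
    c(TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  fl <- pleiotropy_flags(make_calls(cm), 0.5)
  expect_equal(fl$pleiotropic, c(TRUE, FALSE, TRUE))

  # exactly half is not pleiotropic
  cm10 <- matrix(rep(c(TRUE, FALSE), each = 5), 1)
  expect_false(pleiotropy_flags(make_calls(cm10), 0.5)$pleiotropic)

  cm7 <- matrix(c(rep(TRUE, 7), rep(FALSE, 3)), 1)
  expect_false(pleiotropy_flags(make_calls(cm7), 0.7)$pleiotropic)
  cm8 <- matrix(c(rep(TRUE, 8), rep(FALSE, 2)), 1)
  expect_true(pleiotropy_flags(make_calls(cm8), 0.7)$pleiotropic)
})

test_that("raising the breadth threshold never adds flagged genes", {
  set.seed(17)
  for (i in 1:10) {
    cm <- matrix(runif(80) < 0.6, 10, 8)
    calls <- make_calls(cm)
    prev <- rep(TRUE, 10)
    for (th in c(0.3, 0.5, 0.7, 0.9)) {
      cur <- pleiotropy_flags(calls, th)$pleiotropic
      expect_true(all(prev | !cur)) # cur subset of prev
      prev <- cur
    }
  }
})

test_that("per-stage proportions and the goodness-of-fit test follow the GOF formula", {
  # constant proportion -> chi2 = 0, p = 1
  cm <- rbind(
    c(TRUE, TRUE, TRUE, TRUE), # flagged (breadth 1)
    c(TRUE, TRUE, TRUE, TRUE), # flagged
    c(TRUE, TRUE, TRUE, TRUE), # flagged
    c(TRUE, TRUE, TRUE, FALSE) # not flagged (0.75 > 0.5 actually) -- use 2/4
  )
  cm[4, ] <- c(TRUE, TRUE, FALSE, FALSE)
  calls <- make_calls(cm)
  flags <- pleiotropy_flags(calls, 0.9) # only full-breadth genes flagged
  pp <- pleiotropy_profile(calls, flags)
  expect_equal(pp$n_expressed, c(4L, 4L, 3L, 3L))
  expect_equal(pp$n_pleiotropic, c(3L, 3L, 3L, 3L))

  # hand-computed case: equal expressed totals, pleiotropic counts 10 and 20
  # expected counts are 15 each -> chi2 = 25/15 + 25/15 = 10/3
  n <- 60
  cm2 <- rbind(
    matrix(rep(c(TRUE, FALSE), 30), 30, 2, byrow = TRUE),
    matrix(rep(c(FALSE, TRUE), 30), 30, 2, byrow = TRUE)
  )
  calls2 <- make_calls(cm2)
  flags2 <- tibble::tibble(
    gene_id = calls2$gene_id,
    pleiotropic = c(rep(TRUE, 10), rep(FALSE, 20), rep(TRUE, 20), rep(FALSE, 10))
  )
  pp2 <- pleiotropy_profile(calls2, flags2)
  expect_equal(glance(pp2)$chi2_statistic, 10 / 3, tolerance = 1e-12)
  expect_equal(glance(pp2)$df, 1)
  expect_equal(glance(pp2)$p_value, pchisq(10 / 3, 1, lower.tail = FALSE))

  # uniform proportions give a zero statistic
  flags_all <- tibble::tibble(gene_id = calls2$gene_id, pleiotropic = TRUE)
  expect_equal(glance(pleiotropy_profile(calls2, flags_all))$chi2_statistic, 0)
  expect_equal(glance(pleiotropy_profile(calls2, flags_all))$p_value, 1)

  one_stage <- make_calls(matrix(TRUE, 3, 1))
  expect_error(
    pleiotropy_profile(one_stage, pleiotropy_flags(one_stage, 0.5)),
    "two stages"
  )
  zero <- make_calls(cbind(c(TRUE, TRUE), c(FALSE, FALSE)))
  expect_error(
    pleiotropy_profile(zero, pleiotropy_flags(zero, 0.5)),
    "zero expressed"
  )
})

test_that("group comparison reproduces the exact rank-sum distribution", {
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    omega0 = c(1, 2, 3, 10, 11, 12)
  )
  grp <- tibble::tibble(
    gene_id = ann$gene_id,
    pleiotropic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  out <- compare_param_by_group(ann, "omega0", grp)
  expect_equal(out$statistic, 0) # complete separation, W = 0
  expect_equal(out$p_value, oracle_wilcoxon_p(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(out$p_value, 0.1) # smallest attainable two-sided p at 3 vs 3

  # identical groups: p = 1 under the exact test
  ann2 <- tibble::tibble(gene_id = paste0("g", 1:6), omega0 = c(5, 1, 9, 5.5, 1.1, 9.2))
  out2 <- compare_param_by_group(ann2, "omega0", grp)
  expect_gt(out2$p_value, 0.5)

  expect_error(
    compare_param_by_group(ann, "omega0", tibble::tibble(
      gene_id = ann$gene_id, pleiotropic = rep(TRUE, 6)
    )),
    "nonempty"
  )
})

test_that("random-instance group comparisons agree with the enumeration oracle", {
  set.seed(23)
  for (i in 1:5) {
    a <- round(runif(5) * 100) / 10
    b <- round(runif(4) * 100) / 10
    ann <- tibble::tibble(gene_id = paste0("g", 1:9), omega0 = c(a, b))
    grp <- tibble::tibble(
      gene_id = ann$gene_id,
      pleiotropic = rep(c(TRUE, FALSE), c(5, 4))
    )
    got <- compare_param_by_group(ann, "omega0", grp)
    if (!anyDuplicated(c(a, b))) {
      expect_equal(got$p_value, oracle_wilcoxon_p(a, b), tolerance = 1e-12)
    }
  }
})

test_that("Tau follows its defining formula", {
  panel <- tissue_panel(tibble::tibble(
    gene_id = c("uniform", "single", "graded", "silent"),
    t1 = c(8, 0, 2, 0), t2 = c(8, 0, 4, 0), testis = c(8, 5, 8, 0)
  ))
  out <- compute_tau(panel)
  expect_equal(out$tau[out$gene_id == "uniform"], 0)
  expect_equal(out$tau[out$gene_id == "single"], 1)
  expect_equal(out$tau[out$gene_id == "graded"], 0.625) # (0.75 + 0.5 + 0)/2
  expect_false("silent" %in% out$gene_id) # unexpressed genes removed
  expect_true(out$is_testis_specific[out$gene_id == "single"])
  expect_false(out$is_testis_specific[out$gene_id == "graded"])
})

test_that("Tau is scale invariant and equivariant under tissue permutation", {
  set.seed(29)
  base <- matrix(rlnorm(40, 1, 1), 10, 4)
  make <- function(m, names) {
    colnames(m) <- names
    tissue_panel(tibble::add_column(
      tibble::as_tibble(as.data.frame(m, optional = TRUE)),
      gene_id = paste0("g", seq_len(nrow(m))), .before = 1
    ))
  }
  names4 <- c("t1", "t2", "t3", "testis")
  t0 <- compute_tau(make(base, names4))
  t_scaled <- compute_tau(make(base * 7.3, names4))
  expect_equal(t_scaled$tau, t0$tau, tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  t_perm <- compute_tau(make(base[, perm], names4[perm]))
  expect_equal(t_perm$tau, t0$tau, tolerance = 1e-12)
  expect_equal(t_perm$is_testis_specific, t0$is_testis_specific)

  expect_error(
    tissue_panel(tibble::tibble(gene_id = "a", testis = 1)),
    "two tissues"
  )
  # negative log-scale values are floored at zero
  neg <- matrix(c(-2, 5, -1, 0, 4, 1, 2, 3), 2)
  tn <- compute_tau(make(neg, names4))
  expect_true(all(tn$tau >= 0 & tn$tau <= 1))
})

test_that("retrogene medians and Spearman trend match hand values", {
  W <- rbind(
    c(1, 2, 3, 4, 5),
    c(1, 3, 2, 4, 5),
    c(1, 4, 1, 4, 5)
  )
  colnames(W) <- paste0("s", 1:5)
  x <- devindex:::expr_from_matrix(c("r1", "r2", "other"), W, "normalized_linear")
  ann <- tibble::tibble(
    gene_id = c("r1", "r2", "other"),
    is_retrogene = c(TRUE, TRUE, FALSE)
  )
  tr <- retrogene_trend(x, ann)
  expect_equal(tr$median_expression, c(1, 2.5, 2.5, 4, 5))
  expect_equal(glance(tr)$n_genes, 2L)

  # single retrogene with medians (1,3,2,4,5): rho = 1 - 6*2/(5*24) = 0.9
  tr2 <- retrogene_trend(x, ann, exclude = "r1")
  expect_equal(tr2$median_expression, c(1, 3, 2, 4, 5))
  expect_equal(glance(tr2)$rho, 0.9, tolerance = 1e-12)

  mono <- retrogene_trend(x, ann, exclude = "r2")
  expect_equal(glance(mono)$rho, 1)
  dec <- devindex:::expr_from_matrix("r1", W[1, 5:1, drop = FALSE] |>
    (\(m) {
      colnames(m) <- paste0("s", 1:5)
      m
    })(), "normalized_linear")
  expect_equal(glance(retrogene_trend(dec, ann[1, ]))$rho, -1)

  expect_error(retrogene_trend(x, ann, exclude = c("r1", "r2")), "No retrogenes")
  two_stage <- devindex:::expr_from_matrix("r1", W[1, 1:2, drop = FALSE], "normalized_linear")
  expect_error(retrogene_trend(two_stage, ann[1, ]), "three stages")
})

test_that("tiny-series Spearman p comes from exact enumeration", {
  # 4 stages, perfectly increasing medians: 2 of 24 orderings are as extreme
  W <- matrix(c(1, 2, 3, 4), 1, dimnames = list(NULL, paste0("s", 1:4)))
  x <- devindex:::expr_from_matrix("r1", W, "normalized_linear")
  ann <- tibble::tibble(gene_id = "r1", is_retrogene = TRUE)
  tr <- retrogene_trend(x, ann)
  expect_equal(glance(tr)$rho, 1)
  expect_equal(glance(tr)$p_value, 2 / 24, tolerance = 1e-12)
})

test_that("connectivity-duplicability reports rho, bins and the degenerate flag", {
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:20),
    connectivity = 1:20,
    paralog_count = 1:20
  )
  cd <- connectivity_duplicability(ann)
  expect_equal(cd$rho, 1)
  expect_equal(nrow(cd$trend), 5)
  expect_equal(cd$trend$mean_paralogs, cd$trend$mean_connectivity)

  set.seed(37)
  big <- tibble::tibble(
    gene_id = paste0("g", 1:1000),
    connectivity = rpois(1000, 10),
    paralog_count = rpois(1000, 3)
  )
  cd2 <- connectivity_duplicability(big)
  expect_lt(abs(cd2$rho), 0.1)

  tied <- tibble::tibble(
    gene_id = paste0("g", 1:12),
    connectivity = rep(3L, 12),
    paralog_count = rpois(12, 2)
  )
  cd3 <- connectivity_duplicability(tied)
  expect_true(cd3$undefined)
  expect_true(is.na(cd3$rho))

  expect_error(connectivity_duplicability(ann[1:5, ]), "At least 10")
})
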