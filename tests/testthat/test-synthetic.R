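test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_devo_data(n_genes = 150, seed = 42)
  b <- simulate_devo_data(n_genes = 150, seed = 42)
  expect_identical(a, b)
  c <- simulate_devo_data(n_genes = 150, seed = 43)
  expect_false(identical(
    devindex:::expr_matrix(a$expression),
    devindex:::expr_matrix(c$expression)
  ))
})

test_that("simulated layout matches the requested stage configuration", {
  d <- simulate_devo_data(
    n_genes = 100,
    stages = c(preMZT = 2, early = 2, middle = 1, late = 3), seed = 1
  )
  expect_equal(nrow(d$timeline), 8)
  expect_equal(as.character(d$timeline$period), rep(c("preMZT", "early", "middle", "late"), c(2, 2, 1, 3)))
  expect_equal(expr_stages(d$expression), d$timeline$stage)
  expect_equal(expr_scale(d$expression), "raw_count")
  expect_equal(nrow(d$annotation), 100)

  # preMZT may be absent entirely
  d0 <- simulate_devo_data(
    n_genes = 50,
    stages = c(preMZT = 0, early = 2, middle = 1, late = 2), seed = 1
  )
  expect_false("preMZT" %in% as.character(d0$timeline$period))

  expect_error(
    simulate_devo_data(stages = c(preMZT = 1, early = 0, middle = 1, late = 1)),
    "stages"
  )
  expect_error(simulate_devo_data(effect_size = -1), "effect_size")
  expect_error(simulate_devo_data(conn_paralog_rho = 0.4), "conn_paralog_rho")
  expect_error(simulate_devo_data(retro_late_enrichment = 0.5), "retro_late_enrichment")
})

test_that("the lognormal noise model yields a log-scale matrix", {
  d <- simulate_devo_data(n_genes = 80, noise = "lognormal", seed = 3)
  expect_equal(expr_scale(d$expression), "log_transformed")
})

test_that("hourglass coupling lowers omega0 for middle-peaking genes", {
  for (s in 1:3) {
    d <- simulate_devo_data(n_genes = 2000, seed = 100 + s)
    om <- d$annotation$omega0
    mid <- d$truth$peak_period == "middle"
    early <- d$truth$peak_period == "early"
    tt <- t.test(om[mid], om[early], alternative = "less")
    expect_lt(tt$p.value, 0.01)
  }
  # early-conservation attaches the same shift to early-peaking genes
  d2 <- simulate_devo_data(n_genes = 2000, pattern = "early_conservation", seed = 7)
  tt2 <- t.test(
    d2$annotation$omega0[d2$truth$peak_period == "early"],
    d2$annotation$omega0[d2$truth$peak_period == "middle"],
    alternative = "less"
  )
  expect_lt(tt2$p.value, 0.01)
  # under the null the groups are exchangeable
  d3 <- simulate_devo_data(n_genes = 2000, pattern = "null", seed = 9)
  tt3 <- t.test(
    d3$annotation$omega0[d3$truth$peak_period == "middle"],
    d3$annotation$omega0[d3$truth$peak_period == "early"]
  )
  expect_gt(tt3$p.value, 0.001)
})

test_that("the connectivity-paralog copula hits its target rank correlation", {
  rhos <- vapply(1:5, function(s) {
    d <- simulate_devo_data(n_genes = 2000, pattern = "null", seed = 200 + s)
    cor(d$annotation$connectivity, d$annotation$paralog_count, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - (-0.3)), 0.05)

  d0 <- simulate_devo_data(n_genes = 2000, pattern = "null", conn_paralog_rho = 0, seed = 5)
  expect_lt(abs(cor(d0$annotation$connectivity, d0$annotation$paralog_count,
    method = "spearman"
  )), 0.08)
})

test_that("retrogene flags are enriched among late-peaking genes", {
  d <- simulate_devo_data(n_genes = 5000, retro_late_enrichment = 3, seed = 11)
  frac <- tapply(d$annotation$is_retrogene, d$truth$peak_period, mean)
  expect_gt(frac[["late"]], frac[["early"]])
})

test_that("constructed testis-specific genes pass the Tau filter", {
  d <- simulate_devo_data(n_genes = 500, testis_frac = 0.2, seed = 13)
  tau <- compute_tau(d$tissue)
  expect_gt(sum(tau$is_testis_specific), 0.1 * 500)
  expect_true(all(tau$tau[tau$is_testis_specific] >= 0.8))
  # and non-specific genes are broadly expressed
  expect_lt(median(tau$tau[!tau$is_testis_specific]), 0.5)
})

test_that("zero effect size is indistinguishable from the null pattern", {
  deltas <- function(pattern, effect_size, seeds) {
    vapply(seeds, function(s) {
      d <- simulate_devo_data(
        n_genes = 200, pattern = pattern,
        effect_size = effect_size, seed = s
      )
      w <- sim_prep(d)
      delta_em(compute_tei(w, d$annotation, "omega0"), d$timeline)
    }, numeric(1))
  }
  hg0 <- deltas("hourglass", 0, 1:40)
  nul <- deltas("null", 1, 41:80)
  expect_gt(suppressWarnings(ks.test(hg0, nul))$p.value, 0.01)
})
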