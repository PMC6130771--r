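# One-time oracle: computes the worked-example expected values with plain
# loops (independent of the package implementation) and freezes them as
# JSON under inst/extdata/worked_example/. Re-typed data, not read from the
# package, so a transcription error in either place shows up as a test
# failure.

stages <- c("pm1", "e1", "e2", "m1", "l1", "l2")
period <- c("preMZT", "early", "early", "middle", "late", "late")
gene_id <- c(sprintf("g%02d", 1:11), "g_const")
vals <- rbind(
  c(16, 8, 4, 2, 1, 0),
  c(8, 4, 2, 1, 0, 0),
  c(2, 8, 16, 4, 2, 1),
  c(1, 4, 8, 2, 1, 0),
  c(0, 2, 4, 16, 4, 2),
  c(1, 2, 8, 16, 8, 2),
  c(0, 1, 2, 4, 16, 8),
  c(0, 0, 1, 2, 8, 16),
  c(1, 1, 2, 4, 8, 16),
  c(4, 4, 4, 4, 4, 4),
  c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
  c(3, 3, 3, 3, 3, 3)
)
rownames(vals) <- gene_id
colnames(vals) <- stages
omega0 <- c(0.10, 0.12, 0.08, 0.10, 0.04, 0.05, 0.20, 0.25, 0.18, 0.15, 0.30, 0.15)
phylostratum <- c(2, 3, 1, 2, 1, 1, 5, 6, 4, 3, 6, 2)
retro <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)

w <- log2(vals + 1)

tei_loop <- function(E) {
  out <- numeric(ncol(w))
  for (s in seq_len(ncol(w))) {
    num <- 0
    den <- 0
    for (i in seq_len(nrow(w))) {
      num <- num + E[i] * w[i, s]
      den <- den + w[i, s]
    }
    out[s] <- num / den
  }
  names(out) <- stages
  out
}

tei_om <- tei_loop(omega0)
tei_ps <- tei_loop(phylostratum)
delta_om <- mean(tei_om[period == "early"]) - mean(tei_om[period == "middle"])
delta_ps <- mean(tei_ps[period == "early"]) - mean(tei_ps[period == "middle"])

# pleiotropy: expressed = value > 1, pleiotropic = breadth > 0.5
calls <- vals > 1
breadth <- rowSums(calls) / ncol(calls)
pleio <- breadth > 0.5
n_expr <- colSums(calls)
n_pl <- colSums(calls & pleio)
prop <- n_pl / n_expr
expected <- sum(n_pl) * n_expr / sum(n_expr)
chi2 <- sum((n_pl - expected)^2 / expected)
p_chi2 <- pchisq(chi2, df = length(stages) - 1, lower.tail = FALSE)

# tau over the 5-tissue panel
tis <- rbind(
  c(5, 4, 5, 6, 5),
  c(6, 5, 4, 5, 5),
  c(8, 2, 1, 1, 0),
  c(4, 4, 5, 4, 4),
  c(6, 6, 5, 5, 4),
  c(5, 5, 5, 6, 5),
  c(0, 0, 0, 0, 5),
  c(1, 0, 0, 0, 8),
  c(2, 4, 8, 1, 1),
  c(8, 8, 8, 8, 8),
  c(0, 0, 0, 0, 6),
  c(2, 4, 8, 2, 3)
)
colnames(tis) <- c("brain", "gut", "muscle", "ovary", "testis")
tau <- numeric(nrow(tis))
top <- character(nrow(tis))
for (i in seq_len(nrow(tis))) {
  x <- pmax(tis[i, ], 0)
  xhat <- x / max(x)
  tau[i] <- sum(1 - xhat) / (length(x) - 1)
  top[i] <- colnames(tis)[which.max(x)]
}
testis_specific <- gene_id[top == "testis" & tau >= 0.8]

# retrogene medians (linear scale), with and without testis-gene exclusion
med_all <- apply(vals[retro, ], 2, median)
rho_all <- cor(seq_along(stages), med_all, method = "spearman")
keep <- retro & !(gene_id %in% testis_specific)
med_ex <- apply(vals[keep, , drop = FALSE], 2, median)
rho_ex <- cor(seq_along(stages), med_ex, method = "spearman")

out <- list(
  stages = stages,
  tei_omega0_log2 = as.list(setNames(tei_om, stages)),
  tei_phylostratum_log2 = as.list(setNames(tei_ps, stages)),
  delta_em_omega0 = delta_om,
  delta_em_phylostratum = delta_ps,
  pleiotropy = list(
    n_expressed = as.list(setNames(n_expr, stages)),
    n_pleiotropic = as.list(setNames(n_pl, stages)),
    proportion = as.list(setNames(prop, stages)),
    chi2 = chi2, df = length(stages) - 1, p_value = p_chi2,
    flagged = gene_id[pleio]
  ),
  tau = as.list(setNames(tau, gene_id)),
  testis_specific = testis_specific,
  retrogene = list(
    medians_all = as.list(setNames(med_all, stages)),
    rho_all = rho_all,
    medians_excl_testis = as.list(setNames(med_ex, stages)),
    rho_excl_testis = rho_ex,
    n_after_exclusion = sum(keep)
  )
)
dir.create("inst/extdata/worked_example", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(out, "inst/extdata/worked_example/expected_values.json",
  auto_unbox = TRUE, digits = NA, pretty = TRUE
)
cat("frozen\n")
str(out, max.level = 2)
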