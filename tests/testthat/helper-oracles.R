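# Independent oracles and small fixture builders. These deliberately use
# plain loops / enumeration, not the package's vectorized code paths.

# loop-based evaluation of the weighted-mean index formula
oracle_tei <- function(W, E) {
  out <- numeric(ncol(W))
  for (s in seq_len(ncol(W))) {
    num <- 0
    den <- 0
    for (i in seq_len(nrow(W))) {
      num <- num + E[i] * W[i, s]
      den <- den + W[i, s]
    }
    out[s] <- num / den
  }
  out
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  k <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(k)]) - k * (k + 1) / 2
  combos <- utils::combn(n, k)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - k * (k + 1) / 2)
  mu <- k * (n - k) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# random small expression table + matching annotation
random_instance <- function(genes = 20, stages = 5, seed = 1) {
  set.seed(seed)
  W <- matrix(rlnorm(genes * stages, 1, 1), genes, stages,
    dimnames = list(NULL, paste0("s", seq_len(stages)))
  )
  x <- devindex:::expr_from_matrix(sprintf("g%03d", seq_len(genes)), W, "normalized_linear")
  ann <- tibble::tibble(gene_id = x$gene_id, omega0 = rlnorm(genes, log(0.1), 0.5))
  list(x = x, W = W, ann = ann)
}

# a 6-stage timeline matching the default simulated layout
sim_prep <- function(d) {
  transform_expression(filter_low_mean(normalize_cpm(d$expression)), "log2")
}

expected_values <- function() {
  jsonlite::read_json(
    system.file("extdata", "worked_example", "expected_values.json", package = "devindex"),
    simplifyVector = TRUE
  )
}
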