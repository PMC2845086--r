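# Independent brute-force oracles, coded step-by-step and separately from
# the package's vectorised implementations.

# Running-sum enrichment score by explicit walk over the ranked list.
brute_es <- function(genes, scores, set, weight) {
  N <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  denom <- sum(abs(scores[hit])^weight)
  run <- 0
  profile <- numeric(N)
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + (if (denom == 0) 1 / nh else abs(scores[i])^weight / denom)
    } else {
      run <- run - 1 / (N - nh)
    }
    profile[i] <- run
  }
  # extremum: earliest position within 1 ulp of the maximum deviation
  best_abs <- max(abs(profile))
  pos <- which(abs(profile) >= best_abs * (1 - 1e-12))[1]
  list(es = profile[pos], final = run, profile = profile)
}

# Benjamini-Hochberg step-up, from the textbook definition.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Welch two-sample t from the direct formula.
brute_welch <- function(x1, x2) {
  (mean(x1) - mean(x2)) / sqrt(var(x1) / length(x1) + var(x2) / length(x2))
}

# Bare numeric values of an expression matrix (class and scale stripped).
bare <- function(x) {
  y <- unclass(x)
  attr(y, "scale") <- NULL
  y
}

# Small random expression matrix fixture.
rand_expr <- function(n_genes, n_samples, seed = NULL, scale = "log2",
                      mean = 7, sd = 1) {
  f <- function() {
    vals <- matrix(rnorm(n_genes * n_samples, mean, sd), nrow = n_genes,
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                   sprintf("s%03d", seq_len(n_samples))))
    expr_matrix(vals, scale = scale)
  }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# Two-group exchangeable labels for a matrix.
two_groups <- function(x, n_target = ncol(x) %/% 2,
                       labels = c("case", "ctrl")) {
  sample_groups(rep(labels, c(n_target, ncol(x) - n_target)),
                samples = colnames(x))
}

# A ranked list plus random set instance for ES property tests.
rand_es_instance <- function(max_n = 50) {
  N <- sample(3:max_n, 1)
  genes <- sprintf("g%03d", seq_len(N))
  scores <- sort(rnorm(N), decreasing = TRUE)
  nh <- sample(seq_len(N - 1), 1)
  set <- sample(genes, nh)
  list(genes = genes, scores = scores, set = set)
}
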