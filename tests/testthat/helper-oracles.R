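# Independent oracles used to cross-check the implementation.
# Each was written against the mathematical definition directly and is kept
# deliberately naive (explicit loops, series truncation).

# weighted kappa by explicit O(k^2) summation over the 5x5 contingency and
# weight matrices
kappa_oracle <- function(x, y, scheme = "quadratic") {
  k <- 5L
  n <- length(x)
  O <- matrix(0, k, k)
  for (i in seq_len(n)) O[x[i] + 1, y[i] + 1] <- O[x[i] + 1, y[i] + 1] + 1 / n
  px <- rowSums(O)
  py <- colSums(O)
  po <- 0
  pe <- 0
  for (i in 1:k) {
    for (j in 1:k) {
      w <- if (scheme == "quadratic") 1 - ((i - j) / (k - 1))^2
           else 1 - abs(i - j) / (k - 1)
      po <- po + w * O[i, j]
      pe <- pe + w * px[i] * py[j]
    }
  }
  (po - pe) / (1 - pe)
}

# truncated Neumann series v = sum_{n=0..N} K^n f for rho(K) < 1
neumann_oracle <- function(f, K, terms = 50) {
  v <- f
  term <- f
  for (n in seq_len(terms)) {
    term <- as.vector(K %*% term)
    v <- v + term
  }
  v
}

# Kruskal-Wallis H from the rank-sum definition with tie correction
kw_oracle <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (N + 1)
  tt <- table(x)
  H / (1 - sum(tt^3 - tt) / (N^3 - N))
}

# Pearson correlation from the covariance formula
cor_oracle <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# a full 3-rater panel for one project/period from a matrix of raw ratings
# (rows A, H, C; columns D1..D8)
panel_sheet <- function(ratings, project = "P001", period = "2026-Q1") {
  stopifnot(nrow(ratings) == 3, ncol(ratings) == 8)
  out <- tibble::tibble(project_id = project, period = period,
                        rater = c("A", "H", "C"))
  for (d in 1:8) out[[paste0("D", d)]] <- as.integer(ratings[, d])
  out
}

random_stable_K <- function() {
  repeat {
    K <- matrix(stats::runif(16, 0, 0.3), 4, 4)
    diag(K) <- 0
    if (spectral_radius(K) <= 0.9) return(coupling_matrix(K))
  }
}
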