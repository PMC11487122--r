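# Independent oracles used across tests. These stay brute-force / closed
# form and never call the code paths they check.

# Brute-force microhomology oracle: the number of distinct deletion
# placements producing the identical repaired sequence, minus one.
oracle_mh <- function(sequence, del_start, del_end) {
  n <- nchar(sequence)
  d <- del_end - del_start
  target <- paste0(substr(sequence, 1, del_start),
                   substr(sequence, del_end + 1, n))
  count <- 0L
  for (k in 0:(n - d)) {
    cand <- paste0(substr(sequence, 1, k), substr(sequence, k + d + 1, n))
    if (cand == target) count <- count + 1L
  }
  count - 1L
}

# Brute-force left-aligned placement: smallest start among equivalent ones.
oracle_leftmost_start <- function(sequence, del_start, del_end) {
  n <- nchar(sequence)
  d <- del_end - del_start
  target <- paste0(substr(sequence, 1, del_start),
                   substr(sequence, del_end + 1, n))
  for (k in 0:(n - d)) {
    cand <- paste0(substr(sequence, 1, k), substr(sequence, k + d + 1, n))
    if (cand == target) return(k)
  }
  stop("unreachable")
}

# Grid search over two mixture weights at the stated resolution, refitting
# by direct residual evaluation (no least-squares machinery).
oracle_grid_two_weights <- function(signal, profile_a, profile_b,
                                    resolution = 1e-3) {
  grid <- seq(0, 1, by = resolution)
  # expanded residual sum of squares over the full (wa, wb) grid
  ss <- sum(signal^2); aa <- sum(profile_a^2); bb <- sum(profile_b^2)
  sa <- sum(signal * profile_a); sb <- sum(signal * profile_b)
  ab <- sum(profile_a * profile_b)
  rss <- outer(grid, grid, function(wa, wb) {
    ss - 2 * wa * sa - 2 * wb * sb + wa^2 * aa + wb^2 * bb + 2 * wa * wb * ab
  })
  rss[outer(grid, grid, `+`) > 1 + 1e-12] <- Inf
  idx <- arrayInd(which.min(rss), dim(rss))
  list(weights = c(grid[idx[1]], grid[idx[2]]), rss = min(rss))
}

# Closed-form Pearson chi-square for a 2x2 table: N(ad - bc)^2 / product of
# margins.
oracle_chisq_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)  # avoid integer overflow
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Hand-computed paired t statistic on natural-log ratios.
oracle_log_ratio_t <- function(minus, plus) {
  lr <- log(plus) - log(minus)
  mean(lr) / (sd(lr) / sqrt(length(lr)))
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

truth_to_pathway <- c(uncut = "unmodified", hr = "hr",
                      nhej_deletion = "nhej", nhej_insertion = "nhej",
                      nhej_del_with_insert = "nhej", mmej_deletion = "mmej")
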