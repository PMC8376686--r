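# Small graph fixtures and cross-check utilities shared across tests.

two_node_conn <- function() connectome(matrix(c(0, 1, 1, 0), 2), c("a", "b"))

# complete graph on 4 nodes with distinct weights 1..6 (upper triangle by row)
k4_conn <- function() {
  C <- matrix(0, 4, 4)
  C[upper.tri(C)] <- 1:6
  connectome(C + t(C))
}

# random connected weighted graph via the generator, generic labels
random_conn <- function(n, sparsity = 0.5, seed = 1) {
  synth_connectome(n_regions = n, target_sparsity = sparsity, seed = seed,
                   labels = paste0("R", seq_len(n)))
}

# best-permutation agreement between two k-cluster labelings (k <= 3)
label_agreement <- function(a, b) {
  k <- max(a, b)
  perms <- if (k == 2) list(c(1, 2), c(2, 1)) else
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  max(vapply(perms, function(p) mean(p[a] == b), numeric(1)))
}

# Calinski-Harabasz recomputed through the pairwise-distance identity:
# within-cluster scatter W_g = sum of squared pairwise distances / n_g,
# an algebraically independent route from the centroid formula
ch_by_pairwise <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  d2 <- as.matrix(stats::dist(x))^2
  total <- sum(d2[upper.tri(d2)]) / n
  W <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    W <- W + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  B <- total - W
  (B / (k - 1)) / (W / (n - k))
}
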