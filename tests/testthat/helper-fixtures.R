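# Shared in-code fixtures and independent oracles.

# noiseless logistic responses
logistic_points <- function(d, c, s, x = 0:4) {
  list(x = x, y = d / (1 + 10^(s * (c - x))))
}

# tiny deterministic screen world
tiny_world <- function(n_compounds = 12, lines = c("L1", "L2", "L3"),
                       seed = 11) {
  lib <- make_library(n_compounds, seed = seed)
  truth <- make_truth(lines, lib, seed = seed + 1)
  list(lib = lib, truth = truth, lines = lines)
}

# Brute-force complete-linkage agglomeration from a distance matrix.
# Returns the cophenetic distance matrix, an order-free characterization of
# the dendrogram (merge heights + partitions at every height).
brute_force_complete_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_h
    coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Z'-factor control fixture from the QC identity: mean 100 / sd 5 negatives,
# mean 10 / sd 5 positives -> Z' = 1 - 30/90 = 2/3
zfix_neg <- c(95, 100, 105)
zfix_pos <- c(5, 10, 15)
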