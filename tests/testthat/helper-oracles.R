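# Independent oracles, kept deliberately separate from the package's own
# code paths.

# Weir & Cockerham (1984) per-site variance components, recoded directly
# from the published definitions with explicit loops over populations.
# Input: per-population genotype counts, columns AA (hom ref), Aa, aa.
wc_oracle <- function(counts) {
  r <- nrow(counts)
  n <- numeric(r); p <- numeric(r); h <- numeric(r)
  for (i in seq_len(r)) {
    n[i] <- sum(counts[i, ])
    p[i] <- (2 * counts[i, "aa"] + counts[i, "Aa"]) / (2 * n[i])  # alt freq
    h[i] <- counts[i, "Aa"] / n[i]
  }
  nbar <- 0; for (i in seq_len(r)) nbar <- nbar + n[i] / r
  ssq <- 0; for (i in seq_len(r)) ssq <- ssq + n[i]^2
  nc <- (r * nbar - ssq / (r * nbar)) / (r - 1)
  pbar <- 0; for (i in seq_len(r)) pbar <- pbar + n[i] * p[i] / (r * nbar)
  s2 <- 0; for (i in seq_len(r)) s2 <- s2 + n[i] * (p[i] - pbar)^2 / ((r - 1) * nbar)
  hbar <- 0; for (i in seq_len(r)) hbar <- hbar + n[i] * h[i] / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# dosage matrix + labels for two groups of genotype counts (AA, Aa, aa)
counts_to_matrix <- function(focal_counts, rest_counts) {
  dos <- c(rep(0, focal_counts["AA"]), rep(1, focal_counts["Aa"]),
           rep(2, focal_counts["aa"]),
           rep(0, rest_counts["AA"]), rep(1, rest_counts["Aa"]),
           rep(2, rest_counts["aa"]))
  n_f <- sum(focal_counts); n_r <- sum(rest_counts)
  G <- matrix(dos, ncol = 1,
              dimnames = list(sprintf("d%03d", seq_len(n_f + n_r)), "s1"))
  labels <- data.frame(donor = rownames(G),
                       population = c(rep("FOC", n_f), rep("OTH", n_r)))
  list(G = G, labels = labels)
}

# brute-force global edit distance (DP oracle for alignment edit counts)
edit_distance_oracle <- function(a, b) {
  drop(utils::adist(a, b))
}
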