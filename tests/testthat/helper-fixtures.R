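# Shared fixtures and independent oracles used across test files.

# Small panel built directly from a matrix, bypassing the simulator.
make_panel <- function(G, replicon = "chromosome", gene_id = NULL,
                       subpop = NULL) {
  S <- nrow(G); L <- ncol(G)
  strains <- tibble::tibble(strain_id = sprintf("s%03d", seq_len(S)))
  if (!is.null(subpop)) strains$subpop <- subpop
  sites <- tibble::tibble(
    site_id = sprintf("%s:%d", replicon, seq_len(L) * 10L),
    replicon = replicon, pos = seq_len(L) * 10L)
  if (!is.null(gene_id)) sites$gene_id <- gene_id
  genotype_panel(G, strains, sites)
}

# Reorder a panel's strains and/or sites (test-side view of the internal
# subsetting helper).
subset_panel_for_test <- function(panel, strains = NULL, sites = NULL) {
  symbiopleio:::subset_panel(panel, sites = sites, strains = strains)
}

# Explicit-inverse GLS oracle for the mixed-model scan: builds
# V = lambda K + I, inverts it directly, and fits [1, x] per site.
gls_oracle <- function(y, X, K, lambda) {
  n <- length(y)
  V <- lambda * K + diag(n)
  Vi <- solve(V)
  t(vapply(seq_len(ncol(X)), function(j) {
    D <- cbind(1, X[, j])
    DtVi <- t(D) %*% Vi
    A <- solve(DtVi %*% D)
    bh <- A %*% (DtVi %*% y)
    r <- y - D %*% bh
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 2)
    se <- sqrt(s2 * A[2, 2])
    c(beta = bh[2], se = se,
      p = 2 * pt(-abs(bh[2] / se), n - 2))
  }, numeric(3)))
}

# Brute-force neutrality oracle: direct pairwise-difference counting plus
# independently typed published constants (Tajima 1989; Fu & Li 1993,
# corrected star variants).
neutrality_oracle <- function(g) {
  n <- nrow(g)
  stopifnot(n >= 2, !anyNA(g))
  # pi by explicit pairwise loops
  pi_tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    pi_tot <- pi_tot + sum(g[i, ] != g[j, ])
  pi_tot <- pi_tot / choose(n, 2)
  counts <- colSums(g)
  seg <- counts > 0 & counts < n
  S <- sum(seg)
  eta_s <- sum(counts[seg] == 1 | counts[seg] == n - 1)
  if (S == 0)
    return(list(S = 0, pi = 0, theta_w = 0, D = NA_real_,
                Dstar = NA_real_, Fstar = NA_real_))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  theta_w <- S / a1
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  varD <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  D <- if (n == 2 || abs(pi_tot - theta_w) < 1e-14) 0 else
    (pi_tot - theta_w) / sqrt(varD)
  an1 <- a1 + 1 / n
  cn <- if (n > 2) 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
           2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
  uD <- (n / (n - 1)) * (a1 - n / (n - 1)) - vD
  denD <- uD * S + vD * S^2
  Dstar <- if (denD > 0)
    ((n / (n - 1)) * S - a1 * eta_s) / sqrt(denD) else NA_real_
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * a1 / n^2 - 8 * a2 / n) / (a1^2 + a2)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / a1 - vF
  denF <- uF * S + vF * S^2
  Fstar <- if (denF > 0)
    (pi_tot - ((n - 1) / n) * eta_s) / sqrt(denF) else NA_real_
  list(S = S, pi = pi_tot, theta_w = theta_w, D = D,
       Dstar = Dstar, Fstar = Fstar)
}

# Genes drawn under the neutral site-frequency spectrum: derived-allele
# count i chosen with probability proportional to 1/i, assigned to a random
# strain subset. Under this spectrum E[pi] = E[theta_W].
neutral_sfs_gene <- function(n, n_sites) {
  probs <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  g <- matrix(0L, n, n_sites)
  for (j in seq_len(n_sites)) {
    i <- sample.int(n - 1, 1, prob = probs)
    g[sample.int(n, i), j] <- 1L
  }
  g
}
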