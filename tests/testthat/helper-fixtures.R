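# Shared fixtures and independent mini-oracles used across the test files.
# Oracles are deliberately written as naive, direct transcriptions so they
# stay independent of the package's implementation paths.

# character alignment from haplotype strings
aln_from_strings <- function(..., ids = NULL) {
  strs <- c(...)
  mat <- do.call(rbind, strsplit(toupper(strs), ""))
  rownames(mat) <- if (is.null(ids)) paste0("h", seq_len(nrow(mat))) else ids
  mat
}

write_temp_fasta <- function(strs, ids = paste0("s", seq_along(strs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), strs)), path)
  path
}

# brute-force pairwise nucleotide diversity (per site over analyzed columns)
oracle_pi <- function(mat) {
  n <- nrow(mat)
  miss <- mat %in% c("N", "-")
  dim(miss) <- dim(mat)
  percol <- numeric(ncol(mat))
  used <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    diffs <- 0; pairs <- 0
    for (i1 in seq_len(n - 1)) for (i2 in (i1 + 1):n) {
      if (miss[i1, j] || miss[i2, j]) next
      pairs <- pairs + 1
      if (mat[i1, j] != mat[i2, j]) diffs <- diffs + 1
    }
    # a column is analyzed when >= 2 entries are callable
    if (sum(!miss[, j]) >= 2) {
      used[j] <- TRUE
      percol[j] <- if (pairs > 0) diffs / pairs else 0
    }
  }
  sum(percol[used]) / sum(used)
}

# direct transcription of the Tajima (1989) formula
oracle_tajimas_d <- function(mat) {
  n <- nrow(mat)
  seg <- apply(mat, 2, function(col) {
    obs <- col[!(col %in% c("N", "-"))]
    length(unique(obs)) >= 2
  })
  S <- sum(seg)
  k <- oracle_pi(mat) * sum(apply(mat, 2, function(col) sum(!(col %in% c("N", "-"))) >= 2))
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# direct transcription of the normalized H formula from SFS counts
oracle_h_norm <- function(counts, n) {
  i <- seq_along(counts)
  S <- sum(counts)
  an <- sum(1 / (1:(n - 1)))
  bn <- sum(1 / (1:(n - 1))^2)
  bn1 <- sum(1 / (1:n)^2)
  tp <- sum(2 * i * (n - i) * counts) / (n * (n - 1))
  tl <- sum(i * counts) / (n - 1)
  th <- S / an
  th2 <- S * (S - 1) / (an^2 + bn)
  v <- th * (n - 2) / (6 * (n - 1)) +
    th2 * (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2)
  (tp - tl) / sqrt(v)
}

# haplotype-counting r^2 between two 0/1 site vectors (complete data)
oracle_r2 <- function(x, y) {
  pA <- mean(x); pB <- mean(y); pAB <- mean(x == 1 & y == 1)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# naive Saitou-Nei neighbor joining returning an ape tree (topology oracle)
oracle_nj <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  n <- nrow(d)
  nodes <- as.list(labs)
  while (length(nodes) > 2) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- matrix(Inf, m, m)
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      q[i, j] <- (m - 2) * d[i, j] - r[i] - r[j]
    ij <- arrayInd(which.min(q), dim(q))
    i <- ij[1]; j <- ij[2]
    new <- sprintf("(%s,%s)", nodes[[i]], nodes[[j]])
    dnew <- sapply(seq_len(m)[-c(i, j)], function(k) (d[i, k] + d[j, k] - d[i, j]) / 2)
    keep <- seq_len(m)[-c(i, j)]
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    nodes <- c(nodes[keep], new)
    rownames(d2) <- colnames(d2) <- seq_len(nrow(d2))
    d <- d2
  }
  nwk <- sprintf("(%s,%s);", nodes[[1]], nodes[[2]])
  ape::read.tree(text = nwk)
}

# Tajima's D replicates from msprime (independent coalescent simulator)
msprime_tajimas_d <- function(n, theta, reps, seed) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, msprime, numpy as np",
    "n, theta, reps, seed = int(sys.argv[1]), float(sys.argv[2]), int(sys.argv[3]), int(sys.argv[4])",
    "rng = np.random.default_rng(seed)",
    "for i in range(reps):",
    "    ts = msprime.sim_ancestry(samples=n, ploidy=1, sequence_length=1,",
    "                              random_seed=int(rng.integers(1, 2**31 - 1)))",
    "    mts = msprime.sim_mutations(ts, rate=theta/2, discrete_genome=False,",
    "                                random_seed=int(rng.integers(1, 2**31 - 1)))",
    "    if mts.num_sites == 0:",
    "        continue",
    "    print(float(mts.Tajimas_D()))"), script)
  out <- system2("python", c(script, n, theta, reps, seed), stdout = TRUE)
  as.numeric(out)
}

# small neutral-locus bundle for pipeline tests
make_test_bundle <- function(dir, n_loci = 3, strata = c(M = 12, S = 16),
                             scenarios = NULL, theta = 8, coding = TRUE,
                             seed = 11, overrides = NULL,
                             sweep = list(tau = 0.01, sweep_f = 0.5,
                                          standing_k = 2)) {
  if (is.null(scenarios)) scenarios <- rep("neutral_constant", length(strata))
  st <- study_config(
    strata = data.frame(stratum = names(strata), n = as.integer(strata),
                        scenario = scenarios),
    loci = data.frame(locus_id = sprintf("g%02d", seq_len(n_loci)),
                      length = 400, theta = theta, region = "inside_2La",
                      coding = coding),
    sweep = sweep)
  simulate_multipop_study(st, dir, seed = seed, overrides = overrides)
}
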