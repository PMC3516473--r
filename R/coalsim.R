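# Neutral coalescent machinery (no recombination): genealogy simulation,
# fixed-theta and fixed-S mutation placement under infinite sites, null
# distributions of the test statistics, and clade-conditioned rejection
# sampling.  Time is measured in units of 2N generations, so with k lineages
# the waiting time to the next coalescence is Exp(k(k-1)/2) and mutations
# fall at rate theta/2 per unit branch length, giving E[S] = theta * a_n.

#' Simulate a standard coalescent genealogy
#'
#' @param n Number of tips (sampled chromosomes), `>= 2`.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return A `genealogy`: list with `n`, `parent` (length `2n - 1`, 0 for the
#'   root), `child` (`(n-1) x 2` matrix, row `j` = children of internal node
#'   `n + j`), `node_time` (coalescence times, tips at 0), `branch_length`
#'   (length `2n - 2`, edge above each non-root node), `desc_count`
#'   (descendant tips per node), `total_length` and `tmrca`.
#' @export
simulate_genealogy <- function(n, seed = NULL) {
  if (n < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  k <- n:2
  times <- cumsum(stats::rexp(n - 1, rate = k * (k - 1) / 2))
  parent <- integer(2 * n - 1)
  node_time <- numeric(2 * n - 1)
  child <- matrix(0L, n - 1, 2)
  active <- 1:n
  nact <- n
  for (j in seq_len(n - 1)) {
    pick <- sample.int(nact, 2L)
    a <- active[pick[1]]; b <- active[pick[2]]
    newn <- n + j
    node_time[newn] <- times[j]
    parent[a] <- newn; parent[b] <- newn
    child[j, 1] <- a; child[j, 2] <- b
    # swap-removal keeps 'active' allocation-free
    active[pick[1]] <- newn
    active[pick[2]] <- active[nact]
    nact <- nact - 1L
  }
  nb <- 2 * n - 2
  blen <- node_time[parent[1:nb]] - node_time[1:nb]
  desc <- c(rep(1L, n), integer(n - 1))
  for (j in seq_len(n - 1)) desc[n + j] <- desc[child[j, 1]] + desc[child[j, 2]]
  structure(list(n = n, parent = parent, child = child, node_time = node_time,
                 branch_length = blen, desc_count = desc,
                 total_length = sum(blen), tmrca = times[n - 1]),
            class = "genealogy")
}

#' Tips descending from a node
#'
#' @param g A `genealogy`.
#' @param node Node index (tips are `1..n`).
#' @return Integer vector of tip indices below (and including) `node`.
#' @export
tips_under <- function(g, node) {
  n <- g$n
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, g$child[v - n, ])
  }
  sort(out)
}

#' Drop mutations on a genealogy at fixed theta
#'
#' Places `Poisson(theta/2 * total_length)` mutations uniformly on the
#' branches (infinite-sites model: every mutation is a new site).
#'
#' @param g A [simulate_genealogy()] result.
#' @param theta Population mutation parameter `4*Ne*mu` (per locus), `> 0`.
#' @return A `simulated_sample`: list with `genealogy`, `branch` (branch
#'   carrying each mutation), `derived_count` (derived carriers per
#'   mutation), `S` and `n`.
#' @export
mutate_fixed_theta <- function(g, theta) {
  if (theta <= 0) stop("theta must be > 0")
  S <- stats::rpois(1, theta / 2 * g$total_length)
  .place_mutations(g, S)
}

#' Drop exactly S mutations on a genealogy
#'
#' Each mutation lands on a branch with probability proportional to its
#' length (the fixed-S conditioning used for clade-structure nulls).
#'
#' @param g A [simulate_genealogy()] result.
#' @param S Number of segregating sites, `>= 0`.
#' @return A `simulated_sample` (see [mutate_fixed_theta()]).
#' @export
mutate_fixed_s <- function(g, S) {
  if (S < 0) stop("S must be >= 0")
  .place_mutations(g, S)
}

.place_mutations <- function(g, S) {
  nb <- 2 * g$n - 2
  branch <- if (S > 0)
    sample.int(nb, S, replace = TRUE, prob = g$branch_length) else integer(0)
  structure(list(genealogy = g, branch = branch,
                 derived_count = g$desc_count[branch], S = S, n = g$n),
            class = "simulated_sample")
}

#' 0/1 haplotype matrix of a simulated sample
#'
#' @param smp A `simulated_sample`.
#' @return Integer matrix (`n x S`), 1 = derived.
#' @export
haplotype_matrix <- function(smp) {
  g <- smp$genealogy
  out <- matrix(0L, g$n, smp$S)
  for (m in seq_len(smp$S))
    out[tips_under(g, smp$branch[m]), m] <- 1L
  out
}

# Per-tip haplotype identity via random-weight path hashing: tips carrying
# the same mutation set accumulate bitwise-identical doubles, so grouping on
# the hash is exact.  O(n + S) instead of building the n x S matrix.
.tip_hashes <- function(g, branch) {
  nn <- 2 * g$n - 1
  wsum <- numeric(nn)
  if (length(branch)) {
    w <- stats::runif(length(branch))
    for (i in seq_along(branch)) wsum[branch[i]] <- wsum[branch[i]] + w[i]
  }
  acc <- numeric(nn)
  ch <- g$child
  for (j in (g$n - 1):1) {
    p <- g$n + j
    acc[ch[j, 1]] <- acc[p] + wsum[ch[j, 1]]
    acc[ch[j, 2]] <- acc[p] + wsum[ch[j, 2]]
  }
  acc[1:g$n]
}

# D, H_norm, F, h, kbar from a simulated sample (polarity known by
# construction).  Returns NA statistics when S = 0.
.sim_sample_stats <- function(smp) {
  n <- smp$n; S <- smp$S
  if (S == 0)
    return(list(S = 0L, kbar = 0, D = NA_real_, H = NA_real_, F = 1, h = 1L))
  cnt <- smp$derived_count
  seg <- cnt > 0L & cnt < n          # guard: root-adjacent fixations impossible
  cnt <- cnt[seg]; S <- length(cnt)
  if (S == 0)
    return(list(S = 0L, kbar = 0, D = NA_real_, H = NA_real_, F = 1, h = 1L))
  kbar <- sum(cnt * (n - cnt)) / (n * (n - 1) / 2)
  cst <- .tajima_constants(n)
  D <- (kbar - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  counts <- tabulate(cnt, nbins = n - 1)
  H <- .fay_wu_from_counts(counts, n)$H
  hash <- .tip_hashes(smp$genealogy, smp$branch[seg])
  cnt_h <- rle(sort(hash))$lengths
  list(S = S, kbar = kbar, D = D, H = H, F = sum((cnt_h / n)^2),
       h = length(cnt_h))
}

#' Null distributions of D, H and F under the standard neutral coalescent
#'
#' Simulates `reps` independent neutral samples at fixed `(n, theta)`,
#' computes Tajima's D, normalized Fay & Wu's H and Ewens-Watterson F on
#' each, and keeps the replicates with at least one segregating site (the
#' monomorphic ones are counted and excluded from p-value denominators).
#' Each retained replicate's own component p-values against the full set are
#' stored as the paired calibration sample used to set the joint HEW
#' threshold.
#'
#' @param n Sample size (chromosomes).
#' @param theta Per-locus mutation parameter.
#' @param reps Number of replicates, `>= 100`.
#' @param seed Optional integer seed.
#' @param min_defined Keep simulating (up to `20 * reps` attempts) until at
#'   least this many replicates are polymorphic; default 0, i.e. exactly
#'   `reps` replicates are drawn.  The scan sets this to `reps` so that
#'   small-theta loci still get a full-size conditioned null.
#' @return A `hew_null`: list with sorted vectors `D`, `H`, `F`, the number
#'   of defined replicates `m`, `n_S0` (monomorphic replicates), `calib`
#'   (data.frame with columns `p_H`, `p_EW`) and the generating parameters.
#' @export
null_distribution <- function(n, theta, reps, seed = NULL, min_defined = 0) {
  if (reps < 100) stop("reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  cap <- 20L * reps
  D <- H <- F_ <- numeric(cap)
  S_rep <- integer(cap)
  drawn <- 0L; m <- 0L; n_S0 <- 0L
  while (drawn < reps || (m < min_defined && drawn < cap)) {
    drawn <- drawn + 1L
    st <- .sim_sample_stats(mutate_fixed_theta(simulate_genealogy(n), theta))
    if (st$S > 0) {
      m <- m + 1L
      D[m] <- st$D; H[m] <- st$H; F_[m] <- st$F; S_rep[m] <- st$S
    } else n_S0 <- n_S0 + 1L
  }
  D <- D[seq_len(m)]; H <- H[seq_len(m)]; F_ <- F_[seq_len(m)]
  S_rep <- S_rep[seq_len(m)]
  # add-one empirical p-values of each replicate against the full set
  # (within-null pair sample; the scan replaces this with a two-level
  # calibration that re-estimates theta per replicate, see run_scan)
  p_H <- (rank(H, ties.method = "max") + 1) / (m + 1)           # P(H* <= H_i)
  p_EW <- (m + 1 - rank(F_, ties.method = "min") + 1) / (m + 1) # P(F* >= F_i)
  structure(list(n = n, theta = theta, reps = drawn, seed = seed,
                 m = m, n_S0 = n_S0,
                 D = sort(D), H = sort(H), F = sort(F_),
                 S_rep = S_rep, H_rep = H, F_rep = F_,
                 calib = data.frame(p_H = p_H, p_EW = p_EW)),
            class = "hew_null")
}

#' @export
print.hew_null <- function(x, ...) {
  cat(sprintf("<hew_null> n = %d, theta = %g, reps = %d (%d monomorphic)\n",
              x$n, x$theta, x$reps, x$n_S0))
  invisible(x)
}

#' Clade-conditioned coalescent samples (rejection sampling)
#'
#' Repeatedly simulates neutral genealogies and keeps those containing an
#' internal edge subtending `clade_size` tips (within `size_tol`); on each
#' accepted genealogy exactly `S` mutations are placed, and the partition
#' induced by the matching edge is used to compute clade-wise statistics.
#' The larger side of the partition is reported as clade A, the smaller as
#' clade B (ties: the conditioned clade is A).
#'
#' @param n Tips.
#' @param clade_size Required descendant count of the conditioning edge,
#'   `2 <= clade_size <= n - 1`.
#' @param S Segregating sites per accepted sample, `>= 1`.
#' @param reps Accepted samples required.
#' @param seed Optional integer seed.
#' @param size_tol Accept clades of size `clade_size +/- size_tol`
#'   (default 0, exact match).
#' @param max_attempts Attempt cap (default `100 * reps`).
#' @return List with `stats` (data.frame per accepted sample: sizes, number
#'   of haplotypes `h`, segregating sites `S`, mean pairwise differences
#'   `k` for clades A and B), `acceptance_rate`, `attempts` and the
#'   parameters.
#' @export
clade_conditioned_sample <- function(n, clade_size, S, reps, seed = NULL,
                                     size_tol = 0, max_attempts = 100 * reps) {
  if (clade_size < 2 || clade_size > n - 1)
    stop("clade_size must be in [2, n - 1]")
  if (S < 1) stop("S must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  res <- vector("list", reps)
  accepted <- 0L; attempts <- 0L
  lo <- clade_size - size_tol; hi <- clade_size + size_tol
  while (accepted < reps) {
    if (attempts >= max_attempts)
      stop(sprintf(
        "attempt cap %d exceeded: %d accepted (acceptance rate %.4g)",
        max_attempts, accepted, accepted / attempts))
    attempts <- attempts + 1L
    g <- simulate_genealogy(n)
    cand <- which(g$desc_count >= lo & g$desc_count <= hi)
    cand <- cand[cand > n & cand < 2 * n - 1]  # internal, non-root edges
    if (!length(cand)) next
    edge <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    accepted <- accepted + 1L
    smp <- mutate_fixed_s(g, S)
    res[[accepted]] <- .clade_stats(smp, tips_under(g, edge))
  }
  list(stats = do.call(rbind, res), acceptance_rate = reps / attempts,
       attempts = attempts, n = n, clade_size = clade_size, S = S,
       size_tol = size_tol)
}

# clade-wise h, S and mean pairwise differences for one simulated sample,
# given the tip set of the conditioned clade
.clade_stats <- function(smp, clade_tips) {
  g <- smp$genealogy; n <- g$n
  k1 <- length(clade_tips); k2 <- n - k1
  ind <- numeric(2 * n - 1)
  ind[clade_tips] <- 1
  for (j in seq_len(n - 1))
    ind[n + j] <- ind[g$child[j, 1]] + ind[g$child[j, 2]]
  c_in <- ind[smp$branch]                 # derived carriers inside the clade
  c_out <- g$desc_count[smp$branch] - c_in
  hash <- .tip_hashes(g, smp$branch)
  grp_stats <- function(k, cc, tips) {
    seg <- sum(cc > 0 & cc < k)
    kbar <- if (k >= 2) sum(cc * (k - cc)) / (k * (k - 1) / 2) else NA_real_
    h <- length(unique(hash[tips]))
    c(h = h, S = seg, k = kbar)
  }
  s1 <- grp_stats(k1, c_in, clade_tips)
  s2 <- grp_stats(k2, c_out, setdiff(seq_len(n), clade_tips))
  if (k2 > k1) { tmp <- s1; s1 <- s2; s2 <- tmp; kk <- k1; k1 <- k2; k2 <- kk }
  data.frame(size_A = k1, size_B = k2,
             h_A = s1["h"], h_B = s2["h"],
             S_A = s1["S"], S_B = s2["S"],
             k_A = s1["k"], k_B = s2["k"], row.names = NULL)
}
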