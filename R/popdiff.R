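# Differentiation between population strata: Weir-Cockerham F_ST on phased
# (haploid) samples with permutation significance, and rarefaction-corrected
# shared-polymorphism proportions.

# integer-code a character alignment (1..4 = ACGT, NA = missing)
.code_matrix <- function(mat) {
  out <- matrix(match(mat, c("A", "C", "G", "T")), nrow(mat), ncol(mat))
  rownames(out) <- rownames(mat)
  out
}

.as_mat <- function(x) if (inherits(x, "locus_alignment")) x$mat else x

# per-site, per-allele counts: 4 x L matrix
.allele_counts <- function(V) {
  L <- ncol(V)
  out <- matrix(0, 4, L)
  for (a in 1:4) out[a, ] <- colSums(V == a, na.rm = TRUE)
  out
}

# Weir-Cockerham (1984) variance components for haploid samples, summed over
# alleles and sites.  Returns the numerator and denominator of the
# ratio-of-sums estimator.
.wc_components <- function(cntA, cntB) {
  nA <- colSums(cntA); nB <- colSums(cntB)
  use <- nA >= 2 & nB >= 2
  tot <- cntA + cntB
  poly <- colSums(tot > 0) >= 2
  use <- use & poly
  if (!any(use)) return(c(num = NA_real_, den = NA_real_))
  num <- den <- 0
  r <- 2
  for (j in which(use)) {
    n1 <- nA[j]; n2 <- nB[j]; nT <- n1 + n2
    nc <- (nT - (n1^2 + n2^2) / nT) / (r - 1)
    alleles <- which(tot[, j] > 0)
    p1 <- cntA[alleles, j] / n1
    p2 <- cntB[alleles, j] / n2
    pbar <- (n1 * p1 + n2 * p2) / nT
    MSP <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
    MSG <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 - 1 + n2 - 1)
    num <- num + sum(MSP - MSG)
    den <- den + sum(MSP + (nc - 1) * MSG)
  }
  c(num = num, den = den)
}

#' Weir-Cockerham F_ST between two haplotype samples
#'
#' The 1984 method-of-moments estimator with haploid variance components
#' (phased chromosomes are the sampling unit, so there is no heterozygosity
#' term), combined across sites and alleles as a ratio of sums.  Sites
#' monomorphic over the pooled sample contribute nothing; the estimate can
#' be slightly negative under panmixia.
#'
#' @param alnA,alnB Character matrices (haplotypes x columns) or
#'   [locus_alignment()] objects with identical column sets.
#' @return F_ST estimate (numeric), `NA` if no usable polymorphic site.
#' @export
wc_fst <- function(alnA, alnB) {
  A <- .as_mat(alnA); B <- .as_mat(alnB)
  if (nrow(A) < 2 || nrow(B) < 2) stop("both samples need >= 2 haplotypes")
  if (ncol(A) != ncol(B)) stop("samples must share their columns")
  comp <- .wc_components(.allele_counts(.code_matrix(A)),
                         .allele_counts(.code_matrix(B)))
  unname(comp["num"] / comp["den"])
}

#' Permutation test of F_ST > 0
#'
#' Population labels are shuffled across the pooled haplotypes (group sizes
#' preserved) and F_ST recomputed each time;
#' `p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams wc_fst
#' @param n_perm Number of permutations, `>= 100`.
#' @param seed Optional integer seed.
#' @param alpha Significance level for the `significant` flag.
#' @return List with `fst`, `p`, `n_perm`, `significant`.
#' @export
fst_permutation_test <- function(alnA, alnB, n_perm = 1e5, seed = NULL,
                                 alpha = 0.05) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  A <- .as_mat(alnA); B <- .as_mat(alnB)
  obs <- wc_fst(A, B)
  if (is.na(obs))
    return(list(fst = NA_real_, p = NA_real_, n_perm = n_perm,
                significant = NA))
  V <- .code_matrix(rbind(A, B))
  nA <- nrow(A); nT <- nrow(V)
  cntT <- .allele_counts(V)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    idx <- sample.int(nT, nA)
    cntA <- .allele_counts(V[idx, , drop = FALSE])
    comp <- .wc_components(cntA, cntT - cntA)
    f <- comp["num"] / comp["den"]
    if (!is.na(f) && f >= obs) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  list(fst = obs, p = p, n_perm = n_perm, significant = p < alpha)
}

#' Shared-polymorphism proportion with rarefaction correction
#'
#' Both samples are repeatedly down-sampled (without replacement) to a
#' common number of chromosomes; each round records which of A's segregating
#' sites also segregate in B, and the proportion is averaged over rounds.
#' This removes the dependence of "sharedness" on unequal sample sizes.
#'
#' @inheritParams wc_fst
#' @param n_sub Rarefaction depth, `2 <= n_sub <= min(nrow(A), nrow(B))`.
#' @param reps Down-sampling rounds.
#' @param seed Optional integer seed.
#' @return Mean proportion of A's segregating sites shared with B (numeric;
#'   `NA` over rounds where A has no segregating site).
#' @export
shared_polymorphism <- function(alnA, alnB, n_sub, reps = 100, seed = NULL) {
  A <- .code_matrix(.as_mat(alnA)); B <- .code_matrix(.as_mat(alnB))
  if (n_sub < 2) stop("n_sub must be >= 2")
  if (n_sub > min(nrow(A), nrow(B)))
    stop("n_sub exceeds a sample size")
  if (!is.null(seed)) set.seed(seed)
  seg_sites <- function(V) {
    cnt <- .allele_counts(V)
    which(colSums(cnt > 0) >= 2)
  }
  props <- numeric(reps)
  for (r in seq_len(reps)) {
    sA <- seg_sites(A[sample.int(nrow(A), n_sub), , drop = FALSE])
    sB <- seg_sites(B[sample.int(nrow(B), n_sub), , drop = FALSE])
    props[r] <- if (length(sA)) mean(sA %in% sB) else NA_real_
  }
  mean(props, na.rm = TRUE)
}
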