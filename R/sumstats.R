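# Per-locus, per-population summary statistics on (silent-site) haplotype
# alignments: S, h, pi, Watterson's theta, Tajima's D, normalized Fay & Wu's
# H and the Ewens-Watterson homozygosity F.

# harmonic numbers a_n = sum_{i=1}^{n-1} 1/i, b_n = sum 1/i^2
.a_n <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1))
.b_n <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1)^2)

.is_missing <- function(x) x %in% .MISSING_CODES

# per-column allele counts over non-missing entries
.col_alleles <- function(col) {
  obs <- col[!.is_missing(col)]
  table(factor(obs, levels = c("A", "C", "G", "T")))
}

# segregating columns: >= 2 alleles among non-missing entries
.segregating_cols <- function(mat) {
  apply(mat, 2, function(col) {
    obs <- col[!.is_missing(col)]
    length(unique(obs)) >= 2
  })
}

# columns usable for per-site scaling: >= 2 non-missing entries
.analyzed_cols <- function(mat) colSums(!apply(mat, 2, .is_missing)) >= 2

#' Unfolded site-frequency spectrum
#'
#' Counts polarized biallelic segregating columns by their derived-allele
#' count.  Derived counts are computed over the non-missing entries of each
#' column; unpolarizable segregating columns are tallied separately.
#'
#' @param aln A [locus_alignment()].
#' @param polarity Output of [polarize_sites()] for the same columns.
#' @return List with `n` (chromosomes), `counts` (vector of length `n - 1`,
#'   `counts[i]` = number of sites with derived count `i`), `S` (polarized
#'   segregating sites) and `unpolarized` (segregating but unpolarizable).
#' @export
unfolded_sfs <- function(aln, polarity) {
  stopifnot(inherits(aln, "locus_alignment"), nrow(polarity) == aln$L)
  n <- aln$n
  counts <- integer(max(n - 1, 1))
  pol <- which(polarity$status == "polarized")
  for (j in pol) {
    i <- polarity$derived_count[j]
    if (i >= 1 && i <= n - 1) counts[i] <- counts[i] + 1L
  }
  list(n = n, counts = counts, S = length(pol),
       unpolarized = sum(polarity$status == "unpolarizable"))
}

#' Nucleotide diversity (pi)
#'
#' Average proportion of differing sites between haplotype pairs, computed
#' per column on the non-missing entries (pairwise complete) and scaled by
#' the number of analyzed columns.
#'
#' @param aln A [locus_alignment()] (or bare character matrix).
#' @param per_site Divide by the number of analyzed columns (default) or
#'   return the unscaled per-locus sum (mean pairwise differences).
#' @return Numeric scalar.
#' @export
nucleotide_diversity <- function(aln, per_site = TRUE) {
  mat <- if (inherits(aln, "locus_alignment")) aln$mat else aln
  if (nrow(mat) < 2) stop("nucleotide diversity needs >= 2 haplotypes")
  percol <- apply(mat, 2, function(col) {
    tab <- .col_alleles(col)
    m <- sum(tab)
    if (m < 2) return(NA_real_)
    1 - sum(tab * (tab - 1)) / (m * (m - 1))
  })
  L_an <- sum(!is.na(percol))
  if (L_an == 0) return(0)
  tot <- sum(percol, na.rm = TRUE)
  if (per_site) tot / L_an else tot
}

#' Watterson's estimator of theta
#'
#' `theta_W = S / (a_n * L)` with `a_n` the harmonic number of `n - 1` and
#' `L` the number of analyzed columns (per-site scaling) or 1 (per-locus).
#'
#' @inheritParams nucleotide_diversity
#' @return Numeric scalar.
#' @export
watterson_theta <- function(aln, per_site = TRUE) {
  mat <- if (inherits(aln, "locus_alignment")) aln$mat else aln
  n <- nrow(mat)
  if (n < 2) stop("Watterson's theta needs >= 2 haplotypes")
  S <- sum(.segregating_cols(mat))
  L_an <- if (per_site) sum(.analyzed_cols(mat)) else 1L
  if (L_an == 0) return(0)
  S / (.a_n(n) * L_an)
}

# Tajima (1989) normalizing constants
.tajima_constants <- function(n) {
  a1 <- .a_n(n); a2 <- .b_n(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (k - S/a_1) / sqrt(e1*S + e2*S*(S-1))` where `k` is the mean number
#' of pairwise differences (unscaled).  Undefined (NA) when `S = 0`.
#'
#' @inheritParams nucleotide_diversity
#' @return Numeric scalar, `NA` if no segregating sites.
#' @export
tajimas_d <- function(aln) {
  mat <- if (inherits(aln, "locus_alignment")) aln$mat else aln
  n <- nrow(mat)
  if (n < 2) stop("Tajima's D needs >= 2 haplotypes")
  S <- sum(.segregating_cols(mat))
  if (S == 0) return(NA_real_)
  k <- nucleotide_diversity(mat, per_site = FALSE)
  cst <- .tajima_constants(n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

# core of the normalized H statistic, on SFS counts (i = 1..n-1)
.fay_wu_from_counts <- function(counts, n) {
  i <- seq_along(counts)
  S <- sum(counts)
  if (S == 0) return(list(H = NA_real_, theta_pi = 0, theta_L = 0, theta_H = 0))
  theta_pi <- sum(2 * i * (n - i) * counts) / (n * (n - 1))
  theta_L <- sum(i * counts) / (n - 1)
  theta_H <- sum(2 * i^2 * counts) / (n * (n - 1))
  an <- .a_n(n); bn <- .b_n(n)
  bn1 <- bn + 1 / n^2  # sum_{i=1}^{n} 1/i^2
  th <- S / an
  th2 <- S * (S - 1) / (an^2 + bn)
  v <- th * (n - 2) / (6 * (n - 1)) +
    th2 * (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2)
  if (v <= 0) stop("numerical error: nonpositive variance in normalized H")
  list(H = (theta_pi - theta_L) / sqrt(v),
       theta_pi = theta_pi, theta_L = theta_L, theta_H = theta_H)
}

#' Normalized Fay and Wu's H
#'
#' Contrast of `theta_pi` and `theta_L` standardized by its neutral standard
#' deviation (Zeng-style normalization); large negative values indicate an
#' excess of high-frequency derived alleles.  Requires a polarized SFS.
#'
#' @param sfs Output of [unfolded_sfs()] (or a list with `counts`, `n`).
#' @param details Return the component estimators too?
#' @return The normalized H (numeric), or a list when `details = TRUE` with
#'   `H`, `theta_pi`, `theta_L`, `theta_H`.
#' @export
fay_wu_h_norm <- function(sfs, details = FALSE) {
  res <- .fay_wu_from_counts(sfs$counts, sfs$n)
  if (details) res else res$H
}

#' Ewens-Watterson haplotype homozygosity
#'
#' Distinct haplotype strings are counted over the segregating columns;
#' `F = sum(p_k^2)` over their relative frequencies.  Haplotypes with missing
#' data at any segregating column are dropped (and counted in `n_dropped`).
#'
#' @inheritParams nucleotide_diversity
#' @return List with `h` (number of distinct haplotypes), `F` (homozygosity),
#'   `n_used`, `n_dropped`.
#' @export
ew_homozygosity <- function(aln) {
  mat <- if (inherits(aln, "locus_alignment")) aln$mat else aln
  if (nrow(mat) < 1) stop("needs >= 1 haplotype")
  seg <- .segregating_cols(mat)
  sub <- mat[, seg, drop = FALSE]
  complete <- rowSums(matrix(.is_missing(sub), nrow = nrow(sub))) == 0
  sub <- sub[complete, , drop = FALSE]
  n_used <- nrow(sub)
  if (n_used == 0)
    return(list(h = 0L, F = NA_real_, n_used = 0L, n_dropped = nrow(mat)))
  key <- apply(sub, 1, paste, collapse = "")
  p <- as.numeric(table(key)) / n_used
  list(h = length(p), F = sum(p^2), n_used = n_used,
       n_dropped = nrow(mat) - n_used)
}

#' Summary statistics per population stratum
#'
#' Applies the full statistic set to each stratum of a partitioned locus,
#' by default on the silent sub-alignment.  Strata with fewer than two
#' chromosomes are skipped (with a message).
#'
#' @param aln A [locus_alignment()].
#' @param partition A `population_partition` from [attach_metadata()], or a
#'   named character vector mapping haplotype id to stratum.
#' @param outgroup Outgroup sequence (length `L`) used for polarization.
#' @param sites `"silent"` (classify and subset; needs a gene model) or
#'   `"all"`.
#' @param reference Reference haplotype for [classify_sites()].
#' @return Data.frame, one row per analyzed stratum: `locus`, `stratum`,
#'   `n`, `L_analyzed`, `S`, `h`, `pi`, `theta_w`, `D`, `H_norm`, `EW_F`,
#'   `unpolarized`, `fixed_diffs`.
#' @export
summarize_locus <- function(aln, partition, outgroup, sites = c("silent", "all"),
                            reference = 1L) {
  sites <- match.arg(sites)
  stopifnot(inherits(aln, "locus_alignment"))
  strat <- if (inherits(partition, "population_partition"))
    partition$stratum else partition
  strat <- strat[names(strat) %in% rownames(aln$mat)]
  if (sites == "silent") {
    cls <- classify_sites(aln, reference = reference)
    sub <- silent_subalignment(aln, cls)
    og <- outgroup[attr(sub, "col_map")]
  } else {
    sub <- aln
    og <- outgroup
  }
  out <- list()
  for (st in sort(unique(strat))) {
    ids <- names(strat)[strat == st]
    if (length(ids) < 2) {
      message(sprintf("summarize_locus: skipping stratum '%s' (n = %d < 2)",
                      st, length(ids)))
      next
    }
    a <- locus_alignment(sub$mat[ids, , drop = FALSE],
                         locus_id = sub$locus_id, region = sub$region)
    pol <- polarize_sites(a, og)
    sfs <- unfolded_sfs(a, pol)
    ew <- ew_homozygosity(a)
    S <- sum(.segregating_cols(a$mat))
    out[[st]] <- data.frame(
      locus = aln$locus_id, stratum = st, n = a$n,
      L_analyzed = sum(.analyzed_cols(a$mat)), S = S, h = ew$h,
      pi = nucleotide_diversity(a),
      theta_w = watterson_theta(a),
      D = if (S > 0) tajimas_d(a) else NA_real_,
      H_norm = if (sfs$S > 0) fay_wu_h_norm(sfs) else NA_real_,
      EW_F = ew$F,
      unpolarized = sfs$unpolarized,
      fixed_diffs = sum(pol$status == "fixed_diff"))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
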