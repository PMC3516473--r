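# Haplotype-structure dissection of candidate sweep loci: r^2 matrices,
# perfect-LD site sets, haplogroup delineation, neighbor-joining trees,
# sliding-window Jukes-Cantor divergence and phase-confidence QC.

# biallelic segregating columns (over non-missing entries) and their 0/1
# coding; orientation: 1 = the allele of the first non-missing haplotype
# is 0, the other allele 1 (arbitrary; r^2 is invariant to label swaps)
.biallelic_codes <- function(mat) {
  keep <- integer(0); X <- NULL; freq <- numeric(0)
  cols <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    miss <- .is_missing(col)
    alleles <- unique(col[!miss])
    if (length(alleles) != 2) next
    x <- ifelse(miss, NA_real_, as.numeric(col == alleles[2]))
    keep <- c(keep, j)
    cols[[length(cols) + 1L]] <- x
    freq <- c(freq, mean(x, na.rm = TRUE))
  }
  if (length(keep)) X <- do.call(cbind, cols)
  list(sites = keep, X = X, freq = freq)
}

#' Pairwise r-squared among segregating sites
#'
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B))` on phased
#' haplotypes, computed pairwise-complete over missing entries.  Only
#' biallelic segregating columns enter the matrix.
#'
#' @param aln A [locus_alignment()] or character matrix.
#' @param polarity Optional [polarize_sites()] output; when supplied the
#'   reported per-site frequencies are derived-allele frequencies, otherwise
#'   they are frequencies of an arbitrary allele orientation.
#' @return An `ld_matrix`: list with `sites` (original 1-based column
#'   indices), `r2` (symmetric matrix, unit diagonal) and `freq`.  With
#'   fewer than two usable sites, `r2` is a 0/1-sized matrix and the result
#'   carries `flag = "insufficient_sites"`.
#' @export
ld_r2_matrix <- function(aln, polarity = NULL) {
  mat <- .as_mat(aln)
  bc <- .biallelic_codes(mat)
  if (length(bc$sites) < 2) {
    res <- list(sites = bc$sites,
                r2 = diag(length(bc$sites)), freq = bc$freq,
                flag = "insufficient_sites")
    class(res) <- "ld_matrix"
    return(res)
  }
  freq <- bc$freq
  if (!is.null(polarity)) {
    for (k in seq_along(bc$sites)) {
      j <- bc$sites[k]
      if (polarity$status[j] == "polarized") {
        dfreq <- polarity$derived_count[j] / polarity$n_called[j]
        freq[k] <- dfreq
      }
    }
  }
  r <- stats::cor(bc$X, use = "pairwise.complete.obs")
  r2 <- r^2
  diag(r2) <- 1
  structure(list(sites = bc$sites, r2 = r2, freq = freq, flag = NULL),
            class = "ld_matrix")
}

#' Find sets of sites in (near-)perfect linkage disequilibrium
#'
#' Greedy grouping of biallelic sites whose haplotype bipartitions coincide
#' on at least `n - max_recombinants` haplotypes (allele labels are matched
#' in whichever orientation agrees best; missing entries are not counted as
#' disagreements).  Returned sets have at least `min_sites` members and are
#' ordered by size, then by physical span.
#'
#' @param aln A [locus_alignment()] or character matrix.
#' @param min_sites Minimum number of co-segregating sites (default 3).
#' @param max_recombinants Haplotypes allowed to break the pattern
#'   (default 0).
#' @return List of candidate sets; each is a list with `sites` (original
#'   column indices) and `span` (bp between first and last).  Empty list if
#'   nothing qualifies.
#' @export
find_perfect_ld_sites <- function(aln, min_sites = 3, max_recombinants = 0) {
  mat <- .as_mat(aln)
  bc <- .biallelic_codes(mat)
  ns <- length(bc$sites)
  if (ns < min_sites) return(list())
  X <- bc$X
  mismatch <- function(a, b) {
    d <- sum(X[, a] != X[, b], na.rm = TRUE)
    e <- sum(X[, a] != (1 - X[, b]), na.rm = TRUE)
    min(d, e)
  }
  assigned <- rep(FALSE, ns)
  sets <- list()
  for (s in seq_len(ns)) {
    if (assigned[s]) next
    grp <- s
    for (t in seq_len(ns)) {
      if (t == s || assigned[t]) next
      if (mismatch(s, t) <= max_recombinants) grp <- c(grp, t)
    }
    if (length(grp) >= min_sites) {
      assigned[grp] <- TRUE
      sites <- bc$sites[grp]
      sets[[length(sets) + 1L]] <- list(sites = sites,
                                        span = max(sites) - min(sites))
    }
  }
  if (!length(sets)) return(list())
  ord <- order(-vapply(sets, function(x) length(x$sites), numeric(1)),
               -vapply(sets, function(x) x$span, numeric(1)))
  sets[ord]
}

#' Split haplotypes into haplogroups from a defining site set
#'
#' Each haplotype votes with its allele at every defining site (orientations
#' harmonized against the first site); the majority vote assigns the
#' haplogroup, and any haplotype discordant at one or more defining sites is
#' flagged as a recombinant (labelled with the majority clade plus `*`).
#' The larger clade is designated A.  Fixed differences between the
#' non-recombinant cores of A and B are counted over all columns.
#'
#' @param aln A [locus_alignment()] or character matrix.
#' @param defining_sites Column indices (1-based) of the defining SNPs; all
#'   must be biallelic.
#' @return A `haplogroups` object: list with `label` (named vector, values
#'   `"A"`, `"B"`, `"A*"`, `"B*"`), `sizes`, `defining_sites`,
#'   `fixed_differences` (count) and `recombinants` (ids).
#' @export
delineate_haplogroups <- function(aln, defining_sites) {
  mat <- .as_mat(aln)
  n <- nrow(mat)
  votes <- matrix(NA_real_, n, length(defining_sites))
  ref_alleles <- NULL
  for (k in seq_along(defining_sites)) {
    col <- mat[, defining_sites[k]]
    alleles <- unique(col[!.is_missing(col)])
    if (length(alleles) != 2)
      stop(sprintf("defining site %d does not bipartition the sample (no bipartition)",
                   defining_sites[k]))
    x <- ifelse(.is_missing(col), NA_real_, as.numeric(col == alleles[2]))
    if (k == 1) votes[, k] <- x
    else {
      # orient against site 1 by majority agreement
      agree <- mean(x == votes[, 1], na.rm = TRUE)
      votes[, k] <- if (is.na(agree) || agree >= 0.5) x else 1 - x
    }
  }
  frac1 <- rowMeans(votes, na.rm = TRUE)
  side <- ifelse(frac1 >= 0.5, 1, 0)
  if (length(unique(side)) < 2)
    stop("defining sites do not bipartition the sample (no bipartition)")
  discordant <- apply(votes, 1, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) > 1
  })
  n1 <- sum(side == 1)
  a_side <- if (n1 >= n - n1) 1 else 0
  lab <- ifelse(side == a_side, "A", "B")
  lab[discordant] <- paste0(lab[discordant], "*")
  names(lab) <- rownames(mat)
  coreA <- which(lab == "A"); coreB <- which(lab == "B")
  fixed <- 0L
  for (j in seq_len(ncol(mat))) {
    a <- unique(mat[coreA, j]); a <- a[!(a %in% .MISSING_CODES)]
    b <- unique(mat[coreB, j]); b <- b[!(b %in% .MISSING_CODES)]
    if (length(a) == 1 && length(b) == 1 && a != b) fixed <- fixed + 1L
  }
  structure(list(label = lab,
                 sizes = c(A = length(coreA) + sum(lab == "A*"),
                           B = length(coreB) + sum(lab == "B*")),
                 defining_sites = defining_sites,
                 fixed_differences = fixed,
                 recombinants = names(lab)[discordant]),
            class = "haplogroups")
}

#' @export
print.haplogroups <- function(x, ...) {
  cat(sprintf("<haplogroups> A: %d, B: %d (%d recombinant), %d defining sites, %d fixed differences\n",
              x$sizes["A"], x$sizes["B"], length(x$recombinants),
              length(x$defining_sites), x$fixed_differences))
  invisible(x)
}

# Jukes-Cantor distance matrix with pairwise deletion; errors if any
# pairwise p-distance reaches the JC ceiling of 3/4.
.jc_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  miss <- matrix(.is_missing(mat), n, ncol(mat))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !miss[i, ] & !miss[j, ]
    if (!any(ok)) stop(sprintf("no comparable sites between '%s' and '%s'",
                               rownames(mat)[i], rownames(mat)[j]))
    p <- mean(mat[i, ok] != mat[j, ok])
    if (p >= 0.75)
      stop(sprintf("p-distance %.3f between '%s' and '%s' exceeds the Jukes-Cantor limit",
                   p, rownames(mat)[i], rownames(mat)[j]))
    d[i, j] <- d[j, i] <- -3 / 4 * log(1 - 4 * p / 3)
  }
  stats::as.dist(d)
}

# clamp negative NJ branch lengths to zero, moving the deficit onto the
# sister edge so path lengths through the parent are preserved
.clamp_negative_edges <- function(tree) {
  el <- tree$edge.length
  for (e in which(el < 0)) {
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent)
    sibs <- sibs[sibs != e]
    if (length(sibs)) el[sibs[1]] <- el[sibs[1]] + el[e]
    el[e] <- 0
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Neighbor-joining tree of haplotypes (plus outgroups) in Newick form
#'
#' Saitou-Nei neighbor joining on pairwise Jukes-Cantor distances
#' (pairwise-complete over missing data).  Negative branch lengths are
#' clamped to zero with the deficit redistributed to the sister edge.
#'
#' @param aln A [locus_alignment()] or character matrix of haplotypes.
#' @param outgroup_seqs Optional named list (or matrix) of additional
#'   aligned sequences (e.g. the outgroup taxa) appended before tree
#'   building.
#' @return Newick string (terminated by a semicolon).
#' @export
nj_tree <- function(aln, outgroup_seqs = NULL) {
  mat <- .as_mat(aln)
  if (!is.null(outgroup_seqs)) {
    og <- if (is.matrix(outgroup_seqs)) outgroup_seqs
    else do.call(rbind, outgroup_seqs)
    if (ncol(og) != ncol(mat)) stop("outgroup sequences must be aligned")
    mat <- rbind(mat, og)
  }
  if (nrow(mat) < 3) stop("need >= 3 sequences for a tree")
  tree <- ape::nj(.jc_dist(mat))
  tree <- .clamp_negative_edges(tree)
  ape::write.tree(tree)
}

#' Majority-rule consensus sequence of a set of haplotypes
#'
#' Per column, the most frequent non-missing allele (ties broken
#' alphabetically); all-missing columns become `N`.
#'
#' @param mat Character matrix (haplotypes x columns).
#' @return Character vector of length `ncol(mat)`.
#' @export
clade_consensus <- function(mat) {
  apply(mat, 2, function(col) {
    obs <- col[!.is_missing(col)]
    if (!length(obs)) return("N")
    tab <- sort(table(obs), decreasing = TRUE)
    cand <- names(tab)[tab == tab[1]]
    sort(cand)[1]
  })
}

#' Sliding-window Jukes-Cantor divergence
#'
#' Windows of `window` bp advance by `step` bp over the physical alignment
#' (monomorphic columns included); per window the p-distance between the
#' two sequences is computed on the mutually non-missing sites and corrected
#' as `K_JC = -(3/4) ln(1 - 4p/3)`.  Windows with `p >= 3/4` (or with no
#' comparable site) yield `NA` and are flagged.
#'
#' @param seq_a,seq_b Aligned character vectors (e.g. a clade consensus and
#'   an outgroup).
#' @param window Window size in bp (default 50).
#' @param step Shift in bp (default 10).
#' @return A `kjc_profile` data.frame: `start`, `end` (0-based half-open),
#'   `p`, `K_jc`, `flag`.
#' @export
sliding_kjc <- function(seq_a, seq_b, window = 50, step = 10) {
  if (length(seq_a) != length(seq_b)) stop("sequences must be aligned")
  L <- length(seq_a)
  if (window > L) stop("window exceeds sequence length")
  starts <- seq.int(0L, L - window, by = step)
  out <- data.frame(start = starts, end = starts + window,
                    p = NA_real_, K_jc = NA_real_, flag = "")
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):(starts[i] + window)
    a <- seq_a[idx]; b <- seq_b[idx]
    ok <- !(.is_missing(a) | .is_missing(b))
    if (!any(ok)) { out$flag[i] <- "no_sites"; next }
    p <- mean(a[ok] != b[ok])
    out$p[i] <- p
    if (p >= 0.75) out$flag[i] <- "saturated"
    else out$K_jc[i] <- -3 / 4 * log(1 - 4 * p / 3)
  }
  class(out) <- c("kjc_profile", "data.frame")
  out
}

#' Phase-confidence quality control across loci
#'
#' Phasing software reports a per-site confidence in [0.5, 1] (1 = no
#' ambiguity).  Loci are ranked by the proportion of variant sites with
#' confidence below one; the top `flag_quantile` fraction is flagged for
#' cautious interpretation.
#'
#' @param conf_tables Named list, one numeric vector of per-site confidence
#'   values per locus (or a data.frame with columns `locus` and
#'   `confidence`).
#' @param flag_quantile Fraction of loci to flag (default 0.05).
#' @return Data.frame ordered by decreasing `prop_sub_one`: `locus`,
#'   `n_sites`, `prop_sub_one`, `mean_conf_sub_one`, `flagged`.
#' @export
phase_confidence_qc <- function(conf_tables, flag_quantile = 0.05) {
  if (is.data.frame(conf_tables))
    conf_tables <- split(conf_tables$confidence, conf_tables$locus)
  vals <- unlist(conf_tables, use.names = FALSE)
  if (any(vals < 0.5 | vals > 1))
    stop("confidence values must lie in [0.5, 1]")
  rows <- lapply(names(conf_tables), function(loc) {
    v <- conf_tables[[loc]]
    sub <- v[v < 1]
    data.frame(locus = loc, n_sites = length(v),
               prop_sub_one = if (length(v)) length(sub) / length(v) else 0,
               mean_conf_sub_one = if (length(sub)) mean(sub) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$prop_sub_one, out$locus), ]
  n_flag <- max(if (any(out$prop_sub_one > 0)) 1L else 0L,
                floor(flag_quantile * nrow(out)))
  out$flagged <- seq_len(nrow(out)) <= n_flag & out$prop_sub_one > 0
  rownames(out) <- NULL
  out
}
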