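# Neutrality decisions: component Monte-Carlo p-values, the jointly
# calibrated compound HEW test, multiple-testing correction, the multilocus
# HKA polymorphism/divergence test, and clade-wise diversity tests against
# conditioned coalescent nulls.  All Monte-Carlo p-values carry the add-one
# correction (r + 1)/(m + 1) so that p = 0 is never reported.

#' Component p-values of the observed statistics against a simulated null
#'
#' Tail directions follow the sweep signature: H is left-tailed (excess of
#' high-frequency derived alleles drives H down), the Ewens-Watterson F is
#' right-tailed (sweeps raise haplotype homozygosity), Tajima's D is
#' two-tailed (smaller tail doubled, capped at 1).
#'
#' @param obs List (or one-row data.frame) with elements `H_norm`, `EW_F`
#'   and optionally `D`; `NA` components yield `NA` p-values.
#' @param null A `hew_null` from [null_distribution()] with matching `n`.
#' @return Named numeric vector `c(p_H, p_EW, p_D)`.
#' @export
component_pvalues <- function(obs, null) {
  stopifnot(inherits(null, "hew_null"))
  m <- null$m
  p_H <- if (is.null(obs$H_norm) || is.na(obs$H_norm)) NA_real_
  else (1 + sum(null$H <= obs$H_norm)) / (m + 1)
  p_EW <- if (is.null(obs$EW_F) || is.na(obs$EW_F)) NA_real_
  else (1 + sum(null$F >= obs$EW_F)) / (m + 1)
  p_D <- NA_real_
  if (!is.null(obs$D) && !is.na(obs$D)) {
    pl <- (1 + sum(null$D <= obs$D)) / (m + 1)
    pr <- (1 + sum(null$D >= obs$D)) / (m + 1)
    p_D <- min(1, 2 * min(pl, pr))
  }
  c(p_H = p_H, p_EW = p_EW, p_D = p_D)
}

#' Calibrate the joint HEW threshold
#'
#' Finds the largest componentwise threshold `t` such that, over the
#' calibration sample of null `(p_H, p_EW)` pairs, the joint event
#' `p_H <= t AND p_EW <= t` has empirical probability at most `alpha`.
#' For independent uniform components this approaches `sqrt(alpha)`; for
#' perfectly correlated components it approaches `alpha`.
#'
#' @param calibration_pairs Data.frame (or 2-column matrix) of null
#'   component p-value pairs, at least 1000 rows.
#' @param alpha Nominal size of the compound test.
#' @return The threshold `t` (numeric scalar).
#' @export
calibrate_hew_threshold <- function(calibration_pairs, alpha = 0.05) {
  cp <- as.data.frame(calibration_pairs)
  if (nrow(cp) < 1000)
    stop("need >= 1000 calibration pairs for a stable threshold")
  mx <- pmax(cp[[1]], cp[[2]])
  cand <- sort(unique(mx))
  ecdf_at <- cumsum(tabulate(match(mx, cand), nbins = length(cand))) / length(mx)
  ok <- which(ecdf_at <= alpha)
  if (!length(ok)) return(cand[1] / 2)  # below the smallest observed pair
  cand[max(ok)]
}

#' Compound HEW decision for one locus
#'
#' Rejects neutrality iff both component p-values fall at or below the
#' jointly calibrated threshold.  A monotone compound p-value is attached:
#' the add-one empirical probability, over the calibration pairs, of
#' `max(p_H*, p_EW*) <= max(p_H, p_EW)`.
#'
#' @param p_H,p_EW Component p-values of the observed locus.
#' @param threshold Calibrated joint threshold from
#'   [calibrate_hew_threshold()].
#' @param calibration_pairs The null pair sample used for the calibration.
#' @return A `hew_result` (list): `p_H`, `p_EW`, `threshold`, `reject`,
#'   `compound_p`.
#' @export
hew_test <- function(p_H, p_EW, threshold, calibration_pairs) {
  if (is.na(p_H) || is.na(p_EW))
    return(structure(list(p_H = p_H, p_EW = p_EW, threshold = threshold,
                          reject = NA, compound_p = NA_real_),
                     class = "hew_result"))
  cp <- as.data.frame(calibration_pairs)
  mx <- pmax(cp[[1]], cp[[2]])
  obs_mx <- max(p_H, p_EW)
  compound_p <- (1 + sum(mx <= obs_mx)) / (length(mx) + 1)
  structure(list(p_H = p_H, p_EW = p_EW, threshold = threshold,
                 reject = (p_H <= threshold && p_EW <= threshold),
                 compound_p = compound_p),
            class = "hew_result")
}

#' @export
print.hew_result <- function(x, ...) {
  cat(sprintf("<hew_result> p_H = %.4g, p_EW = %.4g, t = %.4g -> %s (compound p = %.4g)\n",
              x$p_H, x$p_EW, x$threshold,
              if (isTRUE(x$reject)) "REJECT" else "retain", x$compound_p))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; `NA` entries are passed through
#' untouched and do not count toward the number of tests.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- pvals
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

# --- multilocus HKA -------------------------------------------------------

# Moment fit of the one-population-plus-divergence HKA model:
#   E[S_i] = w_i * a_{n_i},  E[D_i] = w_i * (T + 1),  w_i = theta_i * L_i
# solved by the standard reduction  w_i = (S_i + D_i) / (a_i + T + 1)
# with T satisfying  sum(D) = (T + 1) * sum(w).
.hka_fit <- function(S, D, a, tol = 1e-12, max_iter = 10000) {
  T_ <- max(sum(D) / max(sum(S / a), 1e-9) , 0.1)  # crude start
  for (it in seq_len(max_iter)) {
    w <- (S + D) / (a + T_ + 1)
    T_new <- sum(D) / sum(w) - 1
    if (T_new < 0) T_new <- 0
    if (abs(T_new - T_) < tol) return(list(w = (S + D) / (a + T_new + 1), T = T_new, iters = it))
    T_ <- T_new
  }
  stop(sprintf("HKA moment fit did not converge (last residual %.3g)",
               abs(T_new - T_)))
}

.hka_x2 <- function(S, D, a, b, w, T_) {
  ES <- w * a
  ED <- w * (T_ + 1)
  VS <- ES + w^2 * b
  VD <- ED + w^2
  terms <- (S - ES)^2 / VS + (D - ED)^2 / VD
  list(x2 = sum(terms), terms = terms, ES = ES, ED = ED, VS = VS, VD = VD)
}

#' Multilocus HKA test of proportional polymorphism and divergence
#'
#' Fits a per-locus mutation parameter and a shared divergence time by the
#' moment equations `E[S_i] = theta_i L_i a_{n_i}` and
#' `E[D_i] = theta_i L_i (T + 1)` (divergence counted against a single
#' outgroup sequence, no outgroup polymorphism), computes the goodness-of-fit
#' sum `X^2` over the variance-standardized deviations, and evaluates
#' significance against coalescent simulation under the fitted model, with
#' parameters re-fitted on every simulated dataset.
#'
#' @param loci Data.frame with columns `S` (silent segregating sites), `div`
#'   (fixed differences vs the outgroup), `n` (chromosomes) and `L` (silent
#'   sites surveyed); optionally `locus` labels.
#' @param reps Simulated datasets for the empirical null of `X^2`
#'   (default `1e5`, the conventional choice for these scans).
#' @param seed Optional integer seed.
#' @return A `hka_result`: list with `fit` (per-locus data.frame: fitted
#'   `theta_L` = `theta_i * L_i`, expectations, variances, deviation terms),
#'   `T` (fitted divergence, 2N units), `x2`, `p` (add-one simulation
#'   p-value), `reps`.
#' @export
hka_test <- function(loci, reps = 1e5, seed = NULL) {
  loci <- as.data.frame(loci)
  stopifnot(all(c("S", "div", "n", "L") %in% names(loci)))
  if (nrow(loci) < 2) stop("HKA needs >= 2 loci")
  if (any(loci$S < 0) || any(loci$div < 0)) stop("counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  S <- loci$S; D <- loci$div
  a <- vapply(loci$n, .a_n, numeric(1))
  b <- vapply(loci$n, .b_n, numeric(1))
  fit <- .hka_fit(S, D, a)
  obs <- .hka_x2(S, D, a, b, fit$w, fit$T)
  # empirical null: simulate S* from the coalescent at theta_i L_i, D* as a
  # Poisson mixture over the lineage depth t* ~ Exp(1) (matches the model's
  # divergence variance w + w^2), refit, recompute X^2
  x2_sim <- numeric(reps)
  nl <- nrow(loci)
  for (r in seq_len(reps)) {
    Ssim <- Dsim <- numeric(nl)
    for (i in seq_len(nl)) {
      g <- simulate_genealogy(loci$n[i])
      Ssim[i] <- stats::rpois(1, fit$w[i] / 2 * g$total_length)
      Dsim[i] <- stats::rpois(1, fit$w[i] * (fit$T + stats::rexp(1)))
    }
    f2 <- tryCatch(.hka_fit(Ssim, Dsim, a), error = function(e) NULL)
    x2_sim[r] <- if (is.null(f2)) NA_real_
    else .hka_x2(Ssim, Dsim, a, b, f2$w, f2$T)$x2
  }
  x2_sim <- x2_sim[!is.na(x2_sim)]
  p <- (1 + sum(x2_sim >= obs$x2)) / (length(x2_sim) + 1)
  structure(list(
    fit = data.frame(locus = if ("locus" %in% names(loci)) loci$locus
                     else paste0("locus", seq_len(nl)),
                     S = S, div = D, n = loci$n, L = loci$L,
                     theta_L = fit$w, E_S = obs$ES, E_div = obs$ED,
                     var_S = obs$VS, var_div = obs$VD, deviation = obs$terms),
    T = fit$T, x2 = obs$x2, p = p, reps = length(x2_sim)),
    class = "hka_result")
}

#' @export
print.hka_result <- function(x, ...) {
  cat(sprintf("<hka_result> %d loci, T = %.4g, X^2 = %.4g, p = %.4g (%d sims)\n",
              nrow(x$fit), x$T, x$x2, x$p, x$reps))
  invisible(x)
}

#' Pick non-significant flanking neighbors for a focal HKA comparison
#'
#' The scan has no designated neutral reference loci, so a focal locus is
#' compared against its nearest upstream and downstream neighbors that did
#' not themselves reject neutrality under HEW.
#'
#' @param loci Data.frame with columns `locus`, `position` (genomic
#'   coordinate) and `hew_significant` (logical).
#' @param focal Focal locus id.
#' @return Character vector of the chosen neighbor ids (length 0-2).
#' @export
hka_select_neighbors <- function(loci, focal) {
  loci <- as.data.frame(loci)
  i <- match(focal, loci$locus)
  if (is.na(i)) stop(sprintf("focal locus '%s' not found", focal))
  pos <- loci$position
  ok <- !loci$hew_significant & loci$locus != focal
  up <- loci$locus[ok & pos < pos[i]]
  up_pos <- pos[ok & pos < pos[i]]
  down <- loci$locus[ok & pos > pos[i]]
  down_pos <- pos[ok & pos > pos[i]]
  c(if (length(up)) up[which.max(up_pos)],
    if (length(down)) down[which.min(down_pos)])
}

#' Clade-wise diversity tests against conditioned coalescent nulls
#'
#' For each clade (A = larger, B = smaller) and each of the statistics
#' `h` (haplotypes), `S` (segregating sites) and `k` (mean pairwise
#' differences), computes the left-tail add-one p-value: the fraction of
#' conditioned simulations with a value at or below the observed one
#' (diversity deficits are the sweep-consistent direction).
#'
#' @param obs List with elements `A` and `B`, each a list/row with `n`, `h`,
#'   `S`, `k` (mean pairwise differences; use `pi * L` to convert a per-site
#'   diversity).
#' @param conditioned Output of [clade_conditioned_sample()]; clade sizes
#'   must match the observed ones.
#' @return Data.frame with one row per clade and columns `p_h`, `p_S`,
#'   `p_k`.
#' @export
clade_diversity_test <- function(obs, conditioned) {
  st <- conditioned$stats
  if (!(obs$A$n %in% c(st$size_A[1], st$size_B[1])) ||
      !(obs$B$n %in% c(st$size_A[1], st$size_B[1])))
    stop("observed clade sizes do not match the conditioned simulations")
  R <- nrow(st)
  p <- function(sim, o) (1 + sum(sim <= o)) / (R + 1)
  data.frame(
    clade = c("A", "B"),
    n = c(obs$A$n, obs$B$n),
    p_h = c(p(st$h_A, obs$A$h), p(st$h_B, obs$B$h)),
    p_S = c(p(st$S_A, obs$A$S), p(st$S_B, obs$B$S)),
    p_k = c(p(st$k_A, obs$A$k), p(st$k_B, obs$B$k)))
}
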