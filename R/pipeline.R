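# Orchestration: the full HEW/F_ST scan over a study bundle and the
# haplogroup deep-dive for a single locus x stratum.  Every derived seed,
# parameter and per-stage error is recorded in the run manifest so reruns
# with the same seed are byte-identical.

.load_bundle <- function(dir) {
  need <- c("metadata.tsv", "gene_models.tsv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop(sprintf("bundle is missing %s", f))
  md <- utils::read.delim(file.path(dir, "metadata.tsv"))
  gm <- utils::read.delim(file.path(dir, "gene_models.tsv"))
  fasta <- list.files(file.path(dir, "loci"), pattern = "\\.fasta$",
                      full.names = TRUE)
  if (!length(fasta)) stop("bundle has no loci/*.fasta alignments")
  loci <- tools::file_path_sans_ext(basename(fasta))
  og <- file.path(dir, "outgroups", paste0(loci, ".fasta"))
  region <- rep("other_arm", length(loci))
  loci_tsv <- file.path(dir, "loci.tsv")
  if (file.exists(loci_tsv)) {
    lt <- utils::read.delim(loci_tsv)
    hit <- match(loci, lt$locus_id)
    region[!is.na(hit)] <- lt$region[hit[!is.na(hit)]]
  }
  list(dir = dir, metadata = md, gene_models = gm,
       loci = loci, fasta = fasta, outgroup = og, region = region)
}

.load_locus <- function(bundle, locus) {
  i <- match(locus, bundle$loci)
  if (is.na(i)) stop(sprintf("locus '%s' not in bundle", locus))
  gm <- bundle$gene_models
  gm <- gm[gm$locus_id == locus, c("exon_start", "exon_end", "frame")]
  if (!nrow(gm)) gm <- NULL
  aln <- read_fasta_alignment(bundle$fasta[i], gene_model = gm,
                              locus_id = locus, region = bundle$region[i])
  og <- if (file.exists(bundle$outgroup[i]))
    read_outgroup(bundle$outgroup[i], L = aln$L) else NULL
  list(aln = aln, outgroup = og)
}

# cache of null distributions keyed by (n, theta to 3 significant digits)
.null_cached <- function(cache, n, theta_hat, reps, seed) {
  key <- sprintf("n%d_t%.3g", n, signif(theta_hat, 3))
  if (is.null(cache[[key]]))
    cache[[key]] <- null_distribution(n, theta_hat, reps, seed = seed,
                                      min_defined = reps)
  cache[[key]]
}

.null_for_S <- function(cache, n, S, reps, seed_base) {
  .null_cached(cache, n, S / .a_n(n), reps,
               seed = .derive_seed(seed_base, n, 2000L + S))
}

# S-conditional calibration pairs for the compound test.  A tested locus is
# ranked against the fixed-theta null at its own Watterson estimate, and the
# decision threshold must reflect the joint (p_H, p_EW) distribution of
# neutral loci *with that S*: conditioning on S strengthens the dependence
# between the two components, and a pooled self-ranking of the null
# replicates understates it (measured as a 7-8% empirical size at nominal
# 5%).  The pairs are therefore drawn by fixed-S simulation at S_obs (the
# standard ms-style conditioning) and ranked against the same fixed-theta
# null the locus is tested against.
.hew_pairs <- function(cache, n, S_obs, reps, seed_base) {
  pkey <- sprintf("pairs_n%d_S%d", n, S_obs)
  if (!is.null(cache[[pkey]])) return(cache[[pkey]])
  nul <- .null_for_S(cache, n, S_obs, reps, seed_base)
  set.seed(.derive_seed(seed_base, n, 60000L + S_obs))
  H <- F_ <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- .sim_sample_stats(mutate_fixed_s(simulate_genealogy(n), S_obs))
    H[r] <- st$H; F_[r] <- st$F
  }
  # add-one tail ranks against the sorted null vectors
  p_H <- (1 + findInterval(H, nul$H)) / (nul$m + 1)
  p_EW <- (1 + nul$m - findInterval(F_, nul$F, left.open = TRUE)) /
    (nul$m + 1)
  cache[[pkey]] <- data.frame(p_H = p_H, p_EW = p_EW)
  cache[[pkey]]
}

#' Run the full selection scan over a study bundle
#'
#' For every locus x stratum: seeded down-sampling to at most `n_max`
#' chromosomes, restriction to silent sites, summary statistics, component
#' p-values against a cached neutral null at the locus's Watterson estimate,
#' the jointly calibrated compound HEW decision, and BH correction of the
#' compound p-values.  Pairwise Weir-Cockerham F_ST with permutation
#' p-values is computed per locus, plus region-grouped means.
#'
#' @param bundle_dir Directory produced by [simulate_multipop_study()] (or
#'   laid out the same way: `loci/*.fasta`, `outgroups/*.fasta`,
#'   `metadata.tsv`, `gene_models.tsv`).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param reps Coalescent replicates per null distribution (default `1e5`).
#' @param alpha Nominal size of the compound test (default 0.05).
#' @param n_max Down-sampling cap per stratum (default 100).
#' @param n_perm Label permutations per F_ST test (default `1e5`).
#' @param bh_scope `"per_stratum"` (default) or `"global"` BH correction.
#' @param strata Optional subset of stratum labels to analyze.
#' @param fst Compute the F_ST block (default TRUE).
#' @param out_dir Optional directory for TSV/JSON output.
#' @return A `hewscan_run`: list with `scan` (per locus x stratum
#'   data.frame), `fst`, `fst_region_means`, `errors`, `manifest`.
#' @export
run_scan <- function(bundle_dir, seed = 1, reps = 1e5, alpha = 0.05,
                     n_max = 100, n_perm = 1e5,
                     bh_scope = c("per_stratum", "global"),
                     strata = NULL, fst = TRUE, out_dir = NULL) {
  bh_scope <- match.arg(bh_scope)
  if (reps < 1000) stop("reps must be >= 1000 (HEW calibration needs 1000 pairs)")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  bundle <- .load_bundle(bundle_dir)
  cache <- new.env(parent = emptyenv())
  rows <- list(); errors <- list(); fst_rows <- list()
  sub_mats <- list()  # per locus: list of down-sampled silent matrices
  all_mats <- list()  # per locus: all-column matrices for F_ST
  regions <- character(0)
  for (li in seq_along(bundle$loci)) {
    locus <- bundle$loci[li]
    stage <- "load"
    res <- tryCatch({
      ld <- .load_locus(bundle, locus)
      part <- attach_metadata(ld$aln, bundle$metadata, strata = strata)
      stage <- "classify"
      cls <- classify_sites(ld$aln)
      sub <- silent_subalignment(ld$aln, cls)
      og_sub <- if (is.null(ld$outgroup)) NULL else
        ld$outgroup[attr(sub, "col_map")]
      regions[locus] <- ld$aln$region
      todo <- names(part$counts)[part$counts >= 2]
      if (!is.null(strata)) todo <- intersect(todo, strata)
      loc_rows <- list()
      for (si in seq_along(todo)) {
        st <- todo[si]
        stage <- paste0("stats:", st)
        ids <- names(part$stratum)[part$stratum == st]
        if (length(ids) > n_max) {
          set.seed(.derive_seed(seed, li, 1000L + si))
          ids <- sample(ids, n_max)
        }
        a <- locus_alignment(sub$mat[ids, , drop = FALSE], locus_id = locus)
        a_all <- ld$aln$mat[ids, , drop = FALSE]
        sub_mats[[locus]][[st]] <- a$mat
        all_mats[[locus]][[st]] <- a_all
        pol <- polarize_sites(a, og_sub)
        sfs <- unfolded_sfs(a, pol)
        ew <- ew_homozygosity(a)
        S <- sum(.segregating_cols(a$mat))
        obs <- list(
          D = if (S > 0) tajimas_d(a) else NA_real_,
          H_norm = if (sfs$S > 0) fay_wu_h_norm(sfs) else NA_real_,
          EW_F = ew$F)
        stage <- paste0("null:", st)
        theta_hat <- S / .a_n(a$n)
        if (S > 0) {
          nul <- .null_for_S(cache, a$n, S, reps, seed)
          pv <- component_pvalues(obs, nul)
          pairs <- .hew_pairs(cache, a$n, S, reps, seed)
          thr <- calibrate_hew_threshold(pairs, alpha)
          hw <- hew_test(pv["p_H"], pv["p_EW"], thr, pairs)
        } else {
          pv <- c(p_H = NA_real_, p_EW = NA_real_, p_D = NA_real_)
          hw <- list(threshold = NA_real_, reject = NA, compound_p = NA_real_)
        }
        loc_rows[[st]] <- data.frame(
          locus = locus, stratum = st, region = ld$aln$region,
          n = a$n, L_silent = a$L, S_silent = S,
          pi = nucleotide_diversity(a), theta_w = watterson_theta(a),
          theta_hat_locus = theta_hat,
          D = obs$D, H_norm = obs$H_norm, EW_F = obs$EW_F, h = ew$h,
          p_H = unname(pv["p_H"]), p_EW = unname(pv["p_EW"]),
          p_D = unname(pv["p_D"]),
          hew_threshold = hw$threshold, hew_reject = hw$reject,
          hew_compound_p = hw$compound_p)
      }
      do.call(rbind, loc_rows)
    }, error = function(e) {
      errors[[locus]] <<- sprintf("[%s] %s", stage, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[locus]] <- res
  }
  if (!length(rows))
    stop(sprintf("all loci failed; first error: %s",
                 if (length(errors)) errors[[1]] else "none recorded"))
  scan <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (bh_scope == "per_stratum") {
    scan$hew_bh_p <- NA_real_
    for (st in unique(scan$stratum)) {
      i <- scan$stratum == st
      scan$hew_bh_p[i] <- bh_adjust(scan$hew_compound_p[i])
    }
  } else {
    scan$hew_bh_p <- bh_adjust(scan$hew_compound_p)
  }
  scan$hew_significant <- !is.na(scan$hew_bh_p) & scan$hew_bh_p < alpha
  # --- pairwise F_ST with permutation significance -----------------------
  fst_df <- NULL; fst_means <- NULL
  if (fst) {
    for (locus in names(all_mats)) {
      sts <- names(all_mats[[locus]])
      if (length(sts) < 2) next
      prs <- utils::combn(sts, 2)
      for (k in seq_len(ncol(prs))) {
        a <- all_mats[[locus]][[prs[1, k]]]
        b <- all_mats[[locus]][[prs[2, k]]]
        set.seed(.derive_seed(seed, match(locus, bundle$loci), 3000L + k))
        ft <- fst_permutation_test(a, b, n_perm = n_perm)
        fst_rows[[length(fst_rows) + 1L]] <- data.frame(
          locus = locus, region = regions[locus],
          pop_a = prs[1, k], pop_b = prs[2, k],
          fst = ft$fst, p = ft$p, significant = ft$significant)
      }
    }
    if (length(fst_rows)) {
      fst_df <- do.call(rbind, fst_rows)
      fst_means <- stats::aggregate(fst ~ region + pop_a + pop_b, fst_df, mean)
    }
  }
  run <- structure(list(
    scan = scan, fst = fst_df, fst_region_means = fst_means,
    errors = errors,
    manifest = list(bundle = bundle_dir, seed = seed, reps = reps,
                    alpha = alpha, n_max = n_max, n_perm = n_perm,
                    bh_scope = bh_scope, strata = strata,
                    null_cache_keys = ls(cache))),
    class = "hewscan_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$scan, file.path(out_dir, "scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(run$fst)) {
    utils::write.table(run$fst, file.path(out_dir, "fst.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(run$fst_region_means,
                       file.path(out_dir, "fst_region_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.hewscan_run <- function(x, ...) {
  cat(sprintf("<hewscan_run> %d locus x stratum records, %d HEW-significant, %d error(s)\n",
              nrow(x$scan), sum(x$scan$hew_significant, na.rm = TRUE),
              length(x$errors)))
  invisible(x)
}

#' Size calibration experiment for the compound HEW test
#'
#' Simulates independent neutral loci (noncoding fragments, no
#' recombination), runs each through the full scan path — polarization,
#' silent-site statistics, component p-values against a cached neutral null
#' at the locus's own Watterson estimate, and the jointly calibrated
#' threshold — and reports the empirical rejection rate, which should not
#' exceed the nominal level.
#'
#' @param n_loci Number of neutral loci to simulate (default 500).
#' @param n Chromosomes per locus (default 50).
#' @param theta Per-locus mutation parameter of the generator (default 10).
#' @param null_reps Replicates per null distribution (default 2000).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer master seed.
#' @param locus_length Fragment length in bp (default 500).
#' @return List with `rejection_rate`, `n_loci` (loci with at least one
#'   segregating site), `alpha` and the per-locus `results` data.frame.
#' @export
hew_calibration_experiment <- function(n_loci = 500, n = 50, theta = 10,
                                       null_reps = 2000, alpha = 0.05,
                                       seed = 1, locus_length = 500) {
  ref <- make_reference_gene(locus_length, NULL,
                             seed = .derive_seed(seed, 1L, 7L))
  cache <- new.env(parent = emptyenv())
  a_n <- .a_n(n)
  rows <- vector("list", n_loci)
  cfg <- scenario_config("neutral_constant", n = n, theta = theta)
  for (i in seq_len(n_loci)) {
    sim <- simulate_population_sample(cfg, ref,
                                      seed = .derive_seed(seed, i, 13L))
    S <- sum(.segregating_cols(sim$aln$mat))
    if (S == 0) next
    pol <- polarize_sites(sim$aln, sim$outgroup)
    obs <- list(H_norm = fay_wu_h_norm(unfolded_sfs(sim$aln, pol)),
                EW_F = ew_homozygosity(sim$aln)$F)
    nul <- .null_for_S(cache, n, S, null_reps, seed)
    pv <- component_pvalues(obs, nul)
    pairs <- .hew_pairs(cache, n, S, null_reps, seed)
    hw <- hew_test(pv["p_H"], pv["p_EW"],
                   calibrate_hew_threshold(pairs, alpha), pairs)
    rows[[i]] <- data.frame(locus = i, S = S, p_H = hw$p_H, p_EW = hw$p_EW,
                            threshold = hw$threshold, reject = hw$reject,
                            compound_p = hw$compound_p)
  }
  results <- do.call(rbind, rows)
  list(rejection_rate = mean(results$reject), n_loci = nrow(results),
       alpha = alpha, results = results)
}

#' Haplogroup deep-dive for one locus and stratum
#'
#' Computes the LD (r^2) matrix, searches for sets of sites in perfect LD,
#' delineates haplogroups A/B from the best set, compares clade diversity
#' against clade-conditioned coalescent simulations, and attaches the NJ
#' tree (with the outgroup) and sliding-window Jukes-Cantor divergence of
#' each clade consensus from the outgroup.
#'
#' @param bundle_dir Study bundle directory.
#' @param locus,stratum Cell to analyze.
#' @param seed Integer seed for the conditioned simulations.
#' @param reps Conditioned replicates (default `1e5`).
#' @param min_sites,max_recombinants Passed to [find_perfect_ld_sites()].
#' @param window,step Sliding-window parameters (bp).
#' @return A `haplogroup_report`: list with `ld`, `defining_sets`,
#'   `haplogroups`, `clade_stats`, `clade_test`, `conditioned_acceptance`,
#'   `newick`, `kjc` (per-clade profiles and maxima).  When no defining set
#'   qualifies the report contains `message` and the later stages are NULL.
#' @export
run_haplogroup_analysis <- function(bundle_dir, locus, stratum, seed = 1,
                                    reps = 1e5, min_sites = 3,
                                    max_recombinants = 2,
                                    window = 50, step = 10) {
  bundle <- .load_bundle(bundle_dir)
  ld0 <- .load_locus(bundle, locus)
  part <- attach_metadata(ld0$aln, bundle$metadata)
  ids <- names(part$stratum)[part$stratum == stratum]
  if (length(ids) < 4) stop("stratum too small for haplogroup analysis")
  aln <- locus_alignment(ld0$aln$mat[ids, , drop = FALSE], locus_id = locus,
                         gene_model = ld0$aln$gene_model)
  pol <- if (is.null(ld0$outgroup)) NULL else polarize_sites(aln, ld0$outgroup)
  ld <- ld_r2_matrix(aln, polarity = pol)
  sets <- find_perfect_ld_sites(aln, min_sites = min_sites,
                                max_recombinants = max_recombinants)
  report <- list(locus = locus, stratum = stratum, ld = ld,
                 defining_sets = sets)
  if (!length(sets)) {
    report$message <- sprintf(
      "no set of >= %d sites in perfect LD (allowing %d recombinants) found",
      min_sites, max_recombinants)
    class(report) <- "haplogroup_report"
    return(report)
  }
  hg <- delineate_haplogroups(aln, sets[[1]]$sites)
  coreA <- names(hg$label)[hg$label == "A"]
  coreB <- names(hg$label)[hg$label == "B"]
  clade_stats <- lapply(list(A = coreA, B = coreB), function(idset) {
    if (length(idset) < 2)
      return(list(n = length(idset), S = NA_integer_, h = length(idset),
                  pi = NA_real_, k = NA_real_))
    m <- aln$mat[idset, , drop = FALSE]
    list(n = length(idset), S = sum(.segregating_cols(m)),
         h = ew_homozygosity(m)$h,
         pi = nucleotide_diversity(m),
         k = nucleotide_diversity(m, per_site = FALSE))
  })
  n_core <- length(coreA) + length(coreB)
  core_mat <- aln$mat[c(coreA, coreB), , drop = FALSE]
  S_core <- sum(.segregating_cols(core_mat))
  clade_test <- NULL; acc <- NA_real_
  csize <- min(length(coreA), length(coreB))
  if (n_core >= 4 && csize >= 2 && csize <= n_core - 2 && S_core >= 1) {
    cond <- clade_conditioned_sample(n_core, csize, S_core, reps,
                                     seed = .derive_seed(seed, 1L, 4000L))
    acc <- cond$acceptance_rate
    clade_test <- clade_diversity_test(
      list(A = list(n = clade_stats$A$n, h = clade_stats$A$h,
                    S = clade_stats$A$S, k = clade_stats$A$k),
           B = list(n = clade_stats$B$n, h = clade_stats$B$h,
                    S = clade_stats$B$S, k = clade_stats$B$k)),
      cond)
  }
  newick <- if (!is.null(ld0$outgroup))
    nj_tree(aln, outgroup_seqs = list(outgroup = ld0$outgroup))
  else nj_tree(aln)
  kjc <- NULL
  if (!is.null(ld0$outgroup)) {
    kjc <- lapply(list(A = coreA, B = coreB), function(idset) {
      prof <- sliding_kjc(clade_consensus(aln$mat[idset, , drop = FALSE]),
                          ld0$outgroup, window = window, step = step)
      list(profile = prof, max_kjc = suppressWarnings(max(prof$K_jc, na.rm = TRUE)))
    })
  }
  report <- c(report, list(haplogroups = hg, clade_stats = clade_stats,
                           clade_test = clade_test,
                           conditioned_acceptance = acc,
                           newick = newick, kjc = kjc))
  class(report) <- "haplogroup_report"
  report
}

#' @export
print.haplogroup_report <- function(x, ...) {
  cat(sprintf("<haplogroup_report> %s / %s\n", x$locus, x$stratum))
  if (!is.null(x$message)) cat(" ", x$message, "\n")
  else {
    print(x$haplogroups)
    if (!is.null(x$clade_test)) {
      cat("  clade diversity-deficit p-values:\n")
      print(x$clade_test, row.names = FALSE)
    }
  }
  invisible(x)
}
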