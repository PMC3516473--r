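# Synthetic study generator: reference gene fragments, coalescent samples
# under neutral/growth/bottleneck/sweep scenarios mapped onto sequence, and
# complete multi-stratum study bundles (FASTA + TSV + JSON manifest) that
# the pipeline can consume end to end.
#
# Sweeps are approximated genealogically: lineages surviving at the sweep
# end time are forced into (near-)simultaneous multiple mergers, which is
# the genealogical footprint the summary statistics respond to.  Growth and
# bottlenecks are piecewise-constant population-size rescalings.

.SCENARIOS <- c("neutral_constant", "growth", "bottleneck",
                "complete_sweep", "partial_sweep", "standing_sweep")

#' Scenario configuration for one simulated locus sample
#'
#' @param scenario One of `"neutral_constant"`, `"growth"`, `"bottleneck"`,
#'   `"complete_sweep"`, `"partial_sweep"`, `"standing_sweep"`.
#' @param n Chromosomes to sample.
#' @param theta Per-locus mutation parameter (`4*Ne*mu` summed over the
#'   fragment).
#' @param T_div Outgroup divergence time, units of 2N generations.
#' @param tau Sweep end time (2N units) for the sweep scenarios.
#' @param sweep_f Swept lineage fraction for `partial_sweep`, in (0, 1].
#' @param standing_k Ancestral haplotype count for `standing_sweep`.
#' @param growth_time,growth_factor Time of the (backward) size drop and
#'   ancestral/current size ratio for `growth`.
#' @param bn_start,bn_end,bn_size Bottleneck interval and relative size.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = "neutral_constant", n = 50, theta = 10,
                            T_div = 5, tau = 0.01, sweep_f = 0.5,
                            standing_k = 2, growth_time = 0.1,
                            growth_factor = 0.1, bn_start = 0.05,
                            bn_end = 0.15, bn_size = 0.1) {
  scenario <- match.arg(scenario, .SCENARIOS)
  stopifnot(n >= 2, theta > 0, T_div >= 0, tau >= 0,
            sweep_f > 0, sweep_f <= 1, standing_k >= 1,
            growth_time >= 0, growth_factor > 0,
            bn_end > bn_start, bn_size > 0)
  structure(list(scenario = scenario, n = n, theta = theta, T_div = T_div,
                 tau = tau, sweep_f = sweep_f, standing_k = standing_k,
                 growth_time = growth_time, growth_factor = growth_factor,
                 bn_start = bn_start, bn_end = bn_end, bn_size = bn_size),
            class = "scenario_config")
}

# draw the next coalescence time for k lineages from time t0 under a
# piecewise-constant relative population size (breaks/sizes; sizes[i] on
# [breaks[i], breaks[i+1]), last size extends to infinity)
.piecewise_coal_time <- function(k, t0, breaks, sizes) {
  rate0 <- k * (k - 1) / 2
  i <- findInterval(t0, breaks)
  t <- t0
  repeat {
    upper <- if (i < length(breaks)) breaks[i + 1] else Inf
    e <- stats::rexp(1, rate0 / sizes[i])
    if (t + e <= upper) return(t + e)
    t <- upper
    i <- i + 1
  }
}

# simulate a genealogy under a scenario_config; returns the same structure
# as simulate_genealogy()
.simulate_scenario_genealogy <- function(cfg) {
  n <- cfg$n
  eps <- 1e-9  # separation of the forced mergers within a sweep event
  breaks <- 0; sizes <- 1
  if (cfg$scenario == "growth") {
    breaks <- c(0, cfg$growth_time); sizes <- c(1, cfg$growth_factor)
  } else if (cfg$scenario == "bottleneck") {
    breaks <- c(0, cfg$bn_start, cfg$bn_end); sizes <- c(1, cfg$bn_size, 1)
  }
  sweep <- cfg$scenario %in% c("complete_sweep", "partial_sweep",
                               "standing_sweep")
  parent <- integer(2 * n - 1)
  node_time <- numeric(2 * n - 1)
  child <- matrix(0L, n - 1, 2)
  active <- 1:n
  t <- 0
  j <- 0L
  merge_pair <- function(i1, i2, tm) {
    j <<- j + 1L
    newn <- n + j
    node_time[newn] <<- tm
    a <- active[i1]; b <- active[i2]
    parent[a] <<- newn; parent[b] <<- newn
    child[j, ] <<- c(a, b)
    active[i1] <<- newn
    active <<- active[-i2]
    newn
  }
  sweep_done <- FALSE
  while (length(active) > 1) {
    k <- length(active)
    tc <- .piecewise_coal_time(k, t, breaks, sizes)
    if (sweep && !sweep_done && tc >= cfg$tau) {
      # execute the sweep merger at tau
      tm <- cfg$tau
      if (cfg$scenario == "complete_sweep") {
        while (length(active) > 1) { merge_pair(1L, 2L, tm); tm <- tm + eps }
      } else if (cfg$scenario == "partial_sweep") {
        m <- max(2L, round(cfg$sweep_f * k))
        m <- min(m, k)
        sel <- sample.int(length(active), m)
        # merge the selected lineages onto the first of them
        sel <- sort(sel, decreasing = TRUE)
        tgt <- sel[length(sel)]
        for (s in sel[-length(sel)]) { merge_pair(tgt, s, tm); tm <- tm + eps }
      } else { # standing_sweep
        grp <- sample.int(cfg$standing_k, length(active), replace = TRUE)
        for (gidx in unique(grp)) {
          members <- which(grp == gidx)
          while (length(members) > 1) {
            merge_pair(members[1], members[2], tm)
            tm <- tm + eps
            # lineage at members[2] removed; reindex
            grp <- grp[-members[2]]
            members <- which(grp == gidx)
          }
        }
      }
      t <- tm
      sweep_done <- TRUE
      next
    }
    pick <- sort(sample.int(k, 2L), decreasing = TRUE)
    merge_pair(pick[2], pick[1], tc)
    t <- tc
  }
  nb <- 2 * n - 2
  blen <- node_time[parent[1:nb]] - node_time[1:nb]
  desc <- c(rep(1L, n), integer(n - 1))
  for (jj in seq_len(n - 1)) desc[n + jj] <- desc[child[jj, 1]] + desc[child[jj, 2]]
  structure(list(n = n, parent = parent, child = child, node_time = node_time,
                 branch_length = blen, desc_count = desc,
                 total_length = sum(blen), tmrca = node_time[2 * n - 1]),
            class = "genealogy")
}

#' Random reference gene fragment with a valid gene model
#'
#' Generates a random sequence at the requested GC content and attaches an
#' exon model; reading frames are assigned contiguously from the first exon
#' and in-frame stop codons in the reference are recoded away.
#'
#' @param length Fragment length in bp.
#' @param exon_layout Data.frame with `exon_start`, `exon_end` (0-based
#'   half-open); `NULL` for a fully noncoding fragment.
#' @param gc GC content of the generated sequence.
#' @param seed Optional integer seed.
#' @return List with `seq` (character vector) and `gene_model` (data.frame
#'   with `exon_start`, `exon_end`, `frame`; `NULL` if no exons).
#' @export
make_reference_gene <- function(length, exon_layout = NULL, gc = 0.5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- sample(names(p), length, replace = TRUE, prob = p)
  gm <- NULL
  if (!is.null(exon_layout)) {
    gm <- as.data.frame(exon_layout)
    gm <- gm[order(gm$exon_start), , drop = FALSE]
    if (any(gm$exon_start < 0) || any(gm$exon_end > length))
      stop("invalid exon layout: outside the fragment")
    cds_len <- 0L
    gm$frame <- 0L
    for (i in seq_len(nrow(gm))) {
      gm$frame[i] <- cds_len %% 3L
      cds_len <- cds_len + (gm$exon_end[i] - gm$exon_start[i])
    }
    # recode in-frame stop codons (complete codons only)
    cds_cols <- unlist(lapply(seq_len(nrow(gm)), function(i)
      (gm$exon_start[i] + 1L):gm$exon_end[i]))
    nc <- length(cds_cols) %/% 3L
    for (ci in seq_len(nc)) {
      cols <- cds_cols[(3 * ci - 2):(3 * ci)]
      if (paste(seq[cols], collapse = "") %in% c("TAA", "TAG", "TGA"))
        seq[cols[3]] <- "C"
    }
  }
  list(seq = seq, gene_model = gm)
}

#' Simulate one population sample of a locus under a scenario
#'
#' Runs the scenario-modified coalescent, places fixed-theta mutations on
#' the genealogy, maps them onto distinct columns of the reference fragment
#' (infinite sites), and synthesizes an outgroup sequence at divergence
#' `T_div` (mutations private to the outgroup branch plus mutations on the
#' sample's stem lineage appear as fixed differences).
#'
#' @param cfg A [scenario_config()].
#' @param reference Output of [make_reference_gene()] (or a list with `seq`
#'   and `gene_model`).
#' @param seed Optional integer seed.
#' @param locus_id,region Passed to the returned [locus_alignment()].
#' @return List with `aln` (a [locus_alignment()]), `outgroup` (character
#'   vector) and `truth` (scenario, parameters, realized `S`, `tmrca`).
#' @export
simulate_population_sample <- function(cfg, reference, seed = NULL,
                                       locus_id = "locus",
                                       region = "other_arm") {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  ref <- reference$seq
  L <- length(ref)
  g <- .simulate_scenario_genealogy(cfg)
  smp <- mutate_fixed_theta(g, cfg$theta)
  S <- smp$S
  if (S > L) stop("more mutations than columns; increase length or lower theta")
  free <- sample.int(L)       # random column order; first S get the variants
  var_cols <- free[seq_len(S)]
  free <- free[-seq_len(S)]
  mat <- matrix(rep(ref, each = cfg$n), nrow = cfg$n)
  rownames(mat) <- sprintf("hap%03d", seq_len(cfg$n))
  for (m in seq_len(S)) {
    derived <- sample(setdiff(c("A", "C", "G", "T"), ref[var_cols[m]]), 1)
    mat[tips_under(g, smp$branch[m]), var_cols[m]] <- derived
  }
  outgroup <- ref
  n_og <- stats::rpois(1, cfg$theta / 2 * cfg$T_div)
  n_stem <- stats::rpois(1, cfg$theta / 2 * max(cfg$T_div - g$tmrca, 0))
  n_og <- min(n_og, length(free))
  og_cols <- if (n_og) free[seq_len(n_og)] else integer(0)
  if (n_og) free <- free[-seq_len(n_og)]
  n_stem <- min(n_stem, length(free))
  stem_cols <- if (n_stem) free[seq_len(n_stem)] else integer(0)
  for (col in og_cols)
    outgroup[col] <- sample(setdiff(c("A", "C", "G", "T"), ref[col]), 1)
  for (col in stem_cols)
    mat[, col] <- sample(setdiff(c("A", "C", "G", "T"), ref[col]), 1)
  aln <- locus_alignment(mat, locus_id = locus_id,
                         gene_model = reference$gene_model, region = region)
  list(aln = aln, outgroup = outgroup,
       truth = list(scenario = cfg$scenario, n = cfg$n, theta = cfg$theta,
                    S = S, tmrca = g$tmrca, fixed_og = n_og,
                    fixed_stem = n_stem))
}

#' Per-site phase-confidence values emulating statistical phasing output
#'
#' A fraction of variant sites receives a confidence below one (drawn
#' uniformly on [0.5, 1)), the rest are exactly 1 — mimicking phasing of
#' large samples over short windows, where most assignments are unambiguous.
#'
#' @param aln A [locus_alignment()].
#' @param error_profile List with `frac_sub_one` in [0, 1].
#' @param seed Optional integer seed.
#' @return Data.frame `site` (1-based column of each segregating site),
#'   `confidence`.
#' @export
emit_phase_confidences <- function(aln, error_profile = list(frac_sub_one = 0.3),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- error_profile$frac_sub_one
  if (is.null(f) || f < 0 || f > 1)
    stop("error_profile$frac_sub_one must be in [0, 1]")
  sites <- which(.segregating_cols(.as_mat(aln)))
  conf <- rep(1, length(sites))
  sub <- stats::runif(length(sites)) < f
  conf[sub] <- stats::runif(sum(sub), 0.5, 1 - 1e-9)
  data.frame(site = sites, confidence = conf)
}

#' Default multi-stratum study configuration
#'
#' The defaults emulate the field design this package targets: four
#' population strata (two molecular forms plus the two inversion
#' homokaryotype classes of a third subgroup) with 56-170 chromosomes each,
#' and ~500 bp gene fragments spanning an intron.  Molecular-form strata
#' default to a growth history (their fragments show negative Tajima's D),
#' the others to constant size.
#'
#' @param strata Data.frame with `stratum`, `n`, `scenario`.
#' @param loci Data.frame with `locus_id`, `length`, `theta`, `region`,
#'   `coding` (logical: attach the two-exon-plus-intron model?).
#' @param T_div Outgroup divergence (2N units).
#' @param sweep Named list of sweep parameters forwarded to
#'   [scenario_config()].
#' @return A `study_config` list.
#' @export
study_config <- function(
    strata = data.frame(
      stratum = c("M", "S", "GOUNDRY_aa", "GOUNDRY_pp"),
      n = c(94, 136, 56, 170),
      scenario = c("growth", "growth", "neutral_constant", "neutral_constant")),
    loci = data.frame(
      locus_id = sprintf("gene%02d", 1:28),
      length = 500, theta = 10,
      region = rep(c("inside_2La", "near_2La", "collinear_2L", "other_arm"),
                   each = 7),
      coding = TRUE),
    T_div = 5,
    sweep = list(tau = 0.01, sweep_f = 0.5, standing_k = 2)) {
  stopifnot(all(strata$scenario %in% .SCENARIOS))
  structure(list(strata = strata, loci = loci, T_div = T_div, sweep = sweep),
            class = "study_config")
}

# deterministic per-(locus, stratum) seed derivation from the study seed
.derive_seed <- function(seed, locus_index, stratum_index) {
  (seed + 1009L * locus_index + 31L * stratum_index) %% .Machine$integer.max
}

.write_fasta <- function(mat, path) {
  bin <- ape::as.DNAbin(mat)
  ape::write.FASTA(bin, path)
}

#' Generate a complete synthetic study bundle on disk
#'
#' For every stratum x locus a coalescent sample is simulated under the
#' stratum's scenario (optionally overridden per locus), written out as
#' FASTA alignments with one outgroup sequence per locus, a sample metadata
#' table, a gene-model table, per-site phase confidences and a JSON manifest
#' holding every derived seed and the scenario truth.
#'
#' @param study A [study_config()].
#' @param out_dir Output directory (created; must not exist or be empty).
#' @param seed Integer study-level seed; all per-sample seeds derive from it.
#' @param overrides Optional data.frame with `locus_id`, `stratum`,
#'   `scenario` rows that replace the stratum default for specific cells
#'   (how sweep loci are planted).
#' @return Invisibly, a list with `dir`, `manifest` (also written as JSON).
#' @export
simulate_multipop_study <- function(study, out_dir, seed = 1,
                                    overrides = NULL) {
  stopifnot(inherits(study, "study_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)))
    stop(sprintf("output directory '%s' is not empty", out_dir))
  dir.create(file.path(out_dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "outgroups"), showWarnings = FALSE)
  loci <- study$loci; strata <- study$strata
  truth <- list()
  gene_rows <- list(); conf_rows <- list()
  metadata <- list()
  for (si in seq_len(nrow(strata))) {
    n_ind <- ceiling(strata$n[si] / 2)
    metadata[[si]] <- data.frame(
      sample_id = sprintf("%s_%03d", strata$stratum[si], seq_len(n_ind)),
      stratum = strata$stratum[si],
      karyotype = switch(strata$stratum[si],
                         GOUNDRY_aa = "2La/2La", GOUNDRY_pp = "2L+/2L+",
                         "2La/2La"),
      year = 2007)
  }
  metadata <- do.call(rbind, metadata)
  for (li in seq_len(nrow(loci))) {
    locus <- loci$locus_id[li]
    ref_seed <- .derive_seed(seed, li, 0L)
    exons <- if (isTRUE(loci$coding[li])) {
      l <- loci$length[li]
      data.frame(exon_start = c(0L, floor(0.6 * l)),
                 exon_end = c(floor(0.4 * l), l))
    } else NULL
    ref <- make_reference_gene(loci$length[li], exons, seed = ref_seed)
    if (!is.null(ref$gene_model))
      gene_rows[[li]] <- cbind(locus_id = locus, ref$gene_model)
    mats <- list(); og <- NULL
    for (si in seq_len(nrow(strata))) {
      st <- strata$stratum[si]
      scen <- strata$scenario[si]
      if (!is.null(overrides)) {
        hit <- overrides$locus_id == locus & overrides$stratum == st
        if (any(hit)) scen <- overrides$scenario[which(hit)[1]]
      }
      cfg <- scenario_config(scenario = scen, n = strata$n[si],
                             theta = loci$theta[li], T_div = study$T_div,
                             tau = study$sweep$tau,
                             sweep_f = study$sweep$sweep_f,
                             standing_k = study$sweep$standing_k)
      s_ls <- .derive_seed(seed, li, si)
      sim <- simulate_population_sample(cfg, ref, seed = s_ls,
                                        locus_id = locus,
                                        region = loci$region[li])
      mat <- sim$aln$mat
      ids <- character(nrow(mat))
      for (r in seq_len(nrow(mat)))
        ids[r] <- sprintf("%s_%03d/%d", st, (r + 1) %/% 2, 2 - r %% 2)
      rownames(mat) <- ids
      mats[[st]] <- mat
      if (si == 1) og <- sim$outgroup  # one outgroup per locus
      truth[[sprintf("%s.%s", locus, st)]] <-
        c(list(locus = locus, stratum = st, seed = s_ls), sim$truth)
    }
    all_mat <- do.call(rbind, mats)
    .write_fasta(all_mat, file.path(out_dir, "loci", paste0(locus, ".fasta")))
    .write_fasta(matrix(og, nrow = 1, dimnames = list("outgroup", NULL)),
                 file.path(out_dir, "outgroups", paste0(locus, ".fasta")))
    aln_all <- locus_alignment(all_mat, locus_id = locus)
    conf <- emit_phase_confidences(aln_all, seed = .derive_seed(seed, li, 99L))
    if (nrow(conf)) conf_rows[[li]] <- cbind(locus_id = locus, conf)
  }
  utils::write.table(loci, file.path(out_dir, "loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(metadata, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gene_models <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(locus_id = character(), exon_start = integer(),
               exon_end = integer(), frame = integer())
  utils::write.table(gene_models, file.path(out_dir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conf_all <- if (length(conf_rows)) do.call(rbind, conf_rows) else
    data.frame(locus_id = character(), site = integer(),
               confidence = numeric())
  utils::write.table(conf_all, file.path(out_dir, "phase_confidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = seed,
                   strata = strata, loci = loci,
                   T_div = study$T_div, sweep = study$sweep,
                   overrides = overrides, truth = truth)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(list(dir = out_dir, manifest = manifest))
}
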