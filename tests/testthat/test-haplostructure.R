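# LD matrices, perfect-LD discovery, haplogroup delineation, NJ trees,
# sliding-window divergence and phase-confidence QC.

test_that("r-squared matches the haplotype-counting oracle", {
  # duplicated column -> r^2 = 1
  m <- aln_from_strings("AG", "AG", "TC", "TC", "AG", "TC")
  ld <- ld_r2_matrix(m)
  expect_equal(ld$r2[1, 2], 1)
  # the four gametes at equal frequency -> independence, r^2 = 0
  m0 <- aln_from_strings(rep(c("AG", "AC", "TG", "TC"), each = 5))
  expect_equal(ld_r2_matrix(m0)$r2[1, 2], 0)
  # random 10-haplotype fixture vs the direct frequency-count oracle
  set.seed(1)
  for (r in 1:5) {
    mm <- matrix(sample(c("A", "G"), 10 * 4, TRUE), 10, 4)
    rownames(mm) <- paste0("h", 1:10)
    ldm <- ld_r2_matrix(mm)
    if (length(ldm$sites) < 2) next
    X <- sapply(ldm$sites, function(j) as.numeric(mm[, j] == mm[1, j]))
    for (a in 1:(ncol(X) - 1)) for (b in (a + 1):ncol(X))
      expect_equal(ldm$r2[a, b], oracle_r2(X[, a], X[, b]), tolerance = 1e-12)
  }
  # fewer than 2 usable sites -> flagged empty result
  mono <- aln_from_strings("AAAA", "AAAA", "AAAT")
  expect_equal(ld_r2_matrix(mono)$flag, "insufficient_sites")
})

test_that("r-squared is symmetric and invariant to allele relabeling", {
  set.seed(2)
  m <- matrix(sample(c("A", "G"), 12 * 5, TRUE), 12, 5)
  rownames(m) <- paste0("h", 1:12)
  ld <- ld_r2_matrix(m)
  expect_equal(ld$r2, t(ld$r2))
  # swap allele labels at site 1
  m2 <- m
  m2[, ld$sites[1]] <- ifelse(m[, ld$sites[1]] == "A", "G", "A")
  expect_equal(ld_r2_matrix(m2)$r2, ld$r2, tolerance = 1e-12)
})

test_that("perfect-LD site discovery honors min_sites and recombinants", {
  # three columns with an identical 6/4 bipartition
  hap <- c(rep("A", 6), rep("T", 4))
  m <- cbind(hap, sample(c("A", "G"), 10, TRUE), hap, hap)
  rownames(m) <- paste0("h", 1:10)
  sets <- find_perfect_ld_sites(m, min_sites = 3)
  expect_length(sets, 1)
  expect_equal(sets[[1]]$sites, c(1, 3, 4))
  # no repeated partition -> nothing found
  set.seed(3)
  m2 <- aln_from_strings("AAAT", "AATA", "ATAA", "TAAA", "AAAA")
  expect_length(find_perfect_ld_sites(m2, min_sites = 2), 0)
  # pattern broken by two haplotypes is recovered with max_recombinants = 2
  hap2 <- hap; hap2[c(2, 7)] <- c("T", "A")
  m3 <- cbind(hap, hap2, hap)
  rownames(m3) <- paste0("h", 1:10)
  expect_length(find_perfect_ld_sites(m3, min_sites = 3, max_recombinants = 0), 0)
  sets3 <- find_perfect_ld_sites(m3, min_sites = 3, max_recombinants = 2)
  expect_length(sets3, 1)
  expect_equal(sets3[[1]]$sites, 1:3)
})

test_that("haplogroups are delineated with A the larger clade", {
  # 8 vs 3 split over three concordant sites, one discordant haplotype
  blockA <- matrix(rep(c("A", "C", "G"), each = 8), 8, 3, byrow = FALSE)
  blockB <- matrix(rep(c("T", "T", "T"), each = 3), 3, 3, byrow = FALSE)
  m <- rbind(blockA, blockB,
             c("A", "T", "G"))  # discordant: recombinant
  m <- cbind(m, matrix("A", 12, 2))
  rownames(m) <- paste0("h", 1:12)
  hg <- delineate_haplogroups(m, 1:3)
  expect_equal(unname(hg$sizes["A"]), 9)  # 8 core + 1 recombinant
  expect_equal(unname(hg$sizes["B"]), 3)
  expect_equal(sum(hg$label == "A*"), 1)
  expect_equal(hg$recombinants, "h12")
  expect_equal(hg$fixed_differences, 3)
  # monomorphic defining site -> explicit bipartition error
  mono <- matrix("A", 6, 4); rownames(mono) <- paste0("h", 1:6)
  expect_error(delineate_haplogroups(mono, 1), "no bipartition")
})

test_that("haplogroup site accounting is conserved on non-recombinants", {
  set.seed(4)
  ref <- make_reference_gene(300, NULL, seed = 5)
  sim <- simulate_population_sample(
    scenario_config("standing_sweep", n = 40, theta = 12, standing_k = 2,
                    tau = 0.01), ref, seed = 6)
  sets <- find_perfect_ld_sites(sim$aln, min_sites = 3, max_recombinants = 2)
  expect_gte(length(sets), 1)  # the k = 2 history leaves a defining set here
  hg <- delineate_haplogroups(sim$aln, sets[[1]]$sites)
  coreA <- names(hg$label)[hg$label == "A"]
  coreB <- names(hg$label)[hg$label == "B"]
  S_of <- function(ids) sum(hewscan:::.segregating_cols(
    sim$aln$mat[ids, , drop = FALSE]))
  S_A <- S_of(coreA); S_B <- S_of(coreB)
  S_tot <- S_of(c(coreA, coreB))
  expect_gte(S_A + S_B + hg$fixed_differences, S_tot)
})

test_that("NJ recovers additive metrics and clamps negative branches", {
  # additive 4-taxon metric from a known tree:
  # ((a:1,b:2):1,(c:3,d:4):1)  -> distances below
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 0, 0), 4, 4)
  d[4, 3] <- 7; d[3, 4] <- 7
  rownames(d) <- colnames(d) <- c("a", "b", "c", "d")
  tr <- ape::nj(as.dist(d))
  tr2 <- hewscan:::.clamp_negative_edges(tr)
  expect_identical(tr2$edge.length, tr$edge.length)  # nothing negative here
  expect_equal(unname(sort(ape::cophenetic.phylo(tr2)["a", c("b", "c", "d")])),
               c(3, 5, 6), tolerance = 1e-12)
  # clamping preserves total path length through the parent
  tr$edge.length[1] <- -0.3
  before <- tr$edge.length
  tr3 <- hewscan:::.clamp_negative_edges(tr)
  expect_true(all(tr3$edge.length >= 0))
  expect_equal(sum(tr3$edge.length), sum(before), tolerance = 1e-12)
})

test_that("nj_tree produces parseable Newick with expected shape", {
  set.seed(7)
  base <- sample(c("A", "C", "G", "T"), 300, TRUE)
  mut <- function(idx) { s <- base; s[idx] <- "T"; s }
  m <- rbind(a = mut(1:6), b = mut(3:8), c = mut(100:110), d = mut(104:118))
  nwk <- nj_tree(m)
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), c("a", "b", "c", "d"))
  expect_true(ape::is.binary(tr))
  # identical sequences -> all branch lengths zero
  same <- rbind(x = base, y = base, z = base)
  tr0 <- ape::read.tree(text = nj_tree(same))
  expect_true(all(abs(tr0$edge.length) < 1e-12))
  # 3 taxa have a unique unrooted topology
  tr3 <- ape::read.tree(text = nj_tree(m[1:3, ]))
  expect_equal(ape::Ntip(tr3), 3)
  expect_error(nj_tree(m[1:2, ]), ">= 3")
  # saturated pairs are refused by name
  sat <- rbind(p = rep("A", 100), q = rep("G", 100), r = base[1:100])
  expect_error(nj_tree(sat), "p.*q|q.*p")
})

test_that("NJ reconstructs random 8-taxon trees from their metrics", {
  skip_if_not_installed("phangorn")
  set.seed(8)
  for (r in 1:50) {
    tr <- ape::rtree(8, br = function(n) runif(n, 0.05, 1))
    d <- ape::cophenetic.phylo(tr)
    rec <- ape::nj(as.dist(d))
    rec <- hewscan:::.clamp_negative_edges(rec)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(rec)), 0)
    # and the naive in-test NJ oracle agrees on the topology
    orc <- oracle_nj(d)
    expect_equal(phangorn::RF.dist(ape::unroot(rec), ape::unroot(orc)), 0)
  }
})

test_that("sliding K_JC obeys window arithmetic and the JC closed form", {
  a <- rep("A", 500)
  b <- a
  prof0 <- sliding_kjc(a, b, window = 50, step = 10)
  expect_equal(nrow(prof0), 46)           # (500 - 50)/10 + 1
  expect_true(all(prof0$K_jc == 0))
  # p = 3/32 = 0.09375 in a window -> K_jc = -(3/4) log(1 - 4p/3) = 0.1001...
  b2 <- a; b2[1:3] <- "G"
  prof <- sliding_kjc(a, b2, window = 32, step = 32)
  expect_equal(prof$p[1], 0.09375)
  expect_equal(prof$K_jc[1], -0.75 * log(1 - 4 * 0.09375 / 3), tolerance = 1e-12)
  expect_equal(round(prof$K_jc[1], 3), 0.100)
  # saturated window flagged, not numeric
  b3 <- a; b3[1:50] <- "G"
  prof3 <- sliding_kjc(a, b3, window = 50, step = 500)
  expect_true(is.na(prof3$K_jc[1]))
  expect_equal(prof3$flag[1], "saturated")
  expect_error(sliding_kjc(a, b[1:10]), "aligned")
})

test_that("K_JC is increasing in p and never below p", {
  p <- seq(0.005, 0.74, by = 0.005)
  k <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(k) > 0))
  expect_true(all(k >= p))
  # same property via the public profile interface
  a <- rep("A", 100)
  kk <- sapply(c(5, 20, 40), function(nd) {
    b <- a; b[seq_len(nd)] <- "C"
    sliding_kjc(a, b, window = 100, step = 100)$K_jc[1]
  })
  expect_true(all(diff(kk) > 0))
})

test_that("clade consensus takes the majority allele with alphabetic ties", {
  m <- aln_from_strings("AAG", "AAG", "ATC", ids = paste0("h", 1:3))
  expect_equal(clade_consensus(m), c("A", "A", "G"))
  tie <- aln_from_strings("T", "G", ids = c("x", "y"))
  expect_equal(clade_consensus(tie), "G")   # alphabetical tie-break
  allN <- aln_from_strings("N", "N")
  expect_equal(clade_consensus(allN), "N")
})

test_that("phase-confidence QC ranks and flags as designed", {
  perfect <- setNames(rep(list(rep(1, 10)), 3), paste0("L", 1:3))
  qc <- phase_confidence_qc(perfect)
  expect_true(all(!qc$flagged))
  expect_true(all(qc$prop_sub_one == 0))
  # (1, 1, 0.78) -> proportion 1/3, mean-among-sub-one 0.78
  one <- phase_confidence_qc(list(locusX = c(1, 1, 0.78)))
  expect_equal(one$prop_sub_one, 1 / 3)
  expect_equal(one$mean_conf_sub_one, 0.78)
  # 20 loci at flag_quantile 0.05 -> exactly the worst one flagged
  set.seed(9)
  tabs <- lapply(1:20, function(i) {
    v <- rep(1, 20); v[seq_len(i)] <- runif(i, 0.5, 0.99); v
  })
  names(tabs) <- sprintf("g%02d", 1:20)
  qc20 <- phase_confidence_qc(tabs, flag_quantile = 0.05)
  expect_equal(sum(qc20$flagged), 1)
  expect_equal(qc20$locus[qc20$flagged], "g20")
  expect_error(phase_confidence_qc(list(a = c(1, 0.2))), "0.5")
})
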