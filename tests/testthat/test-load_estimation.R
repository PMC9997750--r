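test_that("median and marker-mean coverage follow their definitions", {
  tr <- depth_track("s", "g", c(3, 5, 5, 7, 100))
  expect_equal(median_genome_coverage(tr), 5)
  expect_equal(median_genome_coverage(depth_track("s", "g", rep(0, 10))), 0)
  reg <- data.frame(start = 3L, end = 4L)
  expect_equal(median_genome_coverage(depth_track("s", "g", 1:4), reg), 3.5)

  mk <- data.frame(start = 1L, end = 3L)
  expect_equal(host_marker_mean_coverage(depth_track("s", "m", c(10, 20, 30)),
                                         mk), 20)
  far <- data.frame(start = 101L, end = 103L)
  expect_error(host_marker_mean_coverage(depth_track("s", "m", rep(1, 100)),
                                         far), "outside")
})

test_that("load arithmetic and its error conditions", {
  expect_equal(symbiont_load(40, 10, 2),
               list(normalized_abundance = 4, load_per_host_cell = 2))
  expect_equal(symbiont_load(0, 15, 2),
               list(normalized_abundance = 0, load_per_host_cell = 0))
  expect_equal(symbiont_load(62, 20, 2),
               list(normalized_abundance = 3.1, load_per_host_cell = 1.55))
  expect_error(symbiont_load(10, 0, 2), "not positive")
})

test_that("accessory restriction avoids the cross-mapping bias", {
  ## 80% of positions at inflated depth 60, accessory genes at 30
  depth <- c(rep(60L, 800), rep(30L, 200))
  tr <- depth_track("s", "wA", depth)
  acc <- data.frame(start = 801L, end = 1000L)
  expect_equal(accessory_restricted_coverage(tr, acc), 30)
  expect_equal(median_genome_coverage(tr), 60)   # the biased estimator
  expect_error(accessory_restricted_coverage(tr, acc[0, ]), "not a permitted")

  ## on simulated data: equal loads, 80% shared -> whole-genome ~2x truth
  loads <- matrix(c(1, 1, 0.5, 0.5), nrow = 1,
                  dimnames = list("sp1", paste0("S", 1:4)))
  cfg <- simulation_config(seed = 21, genome_length = 20000L,
                           n_gene_families = 80L, symbiont_loads = loads)
  sim <- simulate_genomes(cfg)
  dep <- simulate_depth(cfg, sim)
  tr1 <- Filter(function(t) t$reference_id == "S1", dep)[[1]]
  mk <- Filter(function(t) t$reference_id == "host_marker", dep)[[1]]
  marker <- sim$features[sim$features$feature_id == "EF1a", ]
  mm <- host_marker_mean_coverage(mk, marker)
  truth <- 1 / cfg$ploidy
  whole <- symbiont_load(median_genome_coverage(tr1), mm, 2)$load_per_host_cell
  fm <- sim$truth$family_membership
  ids <- fm$protein_id[fm$family_id %in% sim$truth$accessory_families$S1 &
                         fm$genome_id == "S1"]
  accf <- sim$features[sim$features$feature_id %in% ids, ]
  restricted <- symbiont_load(accessory_restricted_coverage(tr1, accf),
                              mm, 2)$load_per_host_cell
  expect_gt(whole / truth, 1.5)
  expect_lt(abs(restricted - truth) / truth, 0.05)
})

make_profiles <- function(loads_per_cell) {
  ## loads_per_cell: named list sample -> named vector symbiont -> load
  rows <- do.call(rbind, lapply(names(loads_per_cell), function(s) {
    v <- loads_per_cell[[s]]
    data.frame(sample_id = s, symbiont = names(v),
               median_cov = v * 20, normalized_abundance = v * 2,
               load_per_host_cell = v, stringsAsFactors = FALSE)
  }))
  rows$present <- rows$load_per_host_cell >= 0.01
  rows$relative_abundance <- 0
  for (s in unique(rows$sample_id)) {
    sel <- rows$sample_id == s
    tot <- sum(rows$load_per_host_cell[sel])
    if (tot > 0) rows$relative_abundance[sel] <-
        rows$load_per_host_cell[sel] / tot
  }
  rows
}

test_that("profiles: relative abundances, presence, scale invariance", {
  loads <- matrix(c(2, 2, 0, 0.5,
                    0, 0, 0, 0), nrow = 2, byrow = TRUE,
                  dimnames = list(c("sp1", "sp2"), paste0("S", 1:4)))
  cfg <- simulation_config(seed = 22, genome_length = 20000L,
                           n_gene_families = 80L, symbiont_loads = loads)
  sim <- simulate_genomes(cfg)
  dep <- simulate_depth(cfg, sim)
  marker <- sim$features[sim$features$feature_id == "EF1a", ]
  fm <- sim$truth$family_membership
  acc <- lapply(c("S1", "S2"), function(g) {
    ids <- fm$protein_id[fm$family_id %in% sim$truth$accessory_families[[g]] &
                           fm$genome_id == g]
    sim$features[sim$features$feature_id %in% ids, ]
  })
  names(acc) <- c("S1", "S2")
  lc <- load_config(ploidy = 2, host_marker = marker,
                    confounded_pairs = list(list(genomes = c("S1", "S2"),
                                                 accessory = acc)))
  prof <- build_load_profiles(dep, lc)
  s1 <- prof[prof$sample_id == "sp1", ]
  expect_equal(sum(s1$relative_abundance), 1, tolerance = 1e-9)
  expect_equal(s1$load_per_host_cell,
               s1$normalized_abundance / 2, tolerance = 1e-12)
  s2 <- prof[prof$sample_id == "sp2", ]
  expect_true(all(!s2$present))
  expect_true(all(s2$relative_abundance == 0))
  ## uniform depth rescaling leaves loads unchanged
  dep2 <- lapply(dep, function(t) depth_track(t$sample_id, t$reference_id,
                                              t$depth * 3L))
  prof2 <- build_load_profiles(dep2, lc)
  expect_equal(prof2$load_per_host_cell, prof$load_per_host_cell,
               tolerance = 1e-12)
})

test_that("median estimate is robust to repeat-like depth spikes", {
  set.seed(30)
  d <- rpois(50000, 30)
  base <- median(d)
  idx <- sample(length(d), 0.05 * length(d))
  d2 <- d
  d2[idx] <- d2[idx] * 10L
  spiked <- median_genome_coverage(depth_track("s", "g", d2))
  expect_lt(abs(spiked - base) / base, 0.01)
})

test_that("sample clustering merges by Euclidean distance, order-invariant", {
  m <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 1))
  hc <- cluster_samples(m)
  expect_equal(min(hc$height), 1)           # first merge {a, c} at height 1
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("a", "c"))
  ## identical vectors merge at height zero
  hc0 <- cluster_samples(rbind(x = c(1, 2), y = c(1, 2), z = c(5, 5)))
  expect_equal(min(hc0$height), 0)
  ## permutation invariance of merge heights
  hc2 <- cluster_samples(m[c(2, 3, 1), ])
  expect_equal(sort(hc$height), sort(hc2$height))
  expect_error(cluster_samples(m[1, , drop = FALSE]), "at least 2")
})

test_that("co-infection counts come from the presence flags", {
  prof <- make_profiles(list(sp1 = c(A = 1, B = 2, C = 0),
                             sp2 = c(A = 0.5, B = 0, C = 0),
                             sp3 = c(A = 0, B = 0, C = 0)))
  co <- coinfection_summary(prof)
  expect_equal(unname(co$per_sample[c("sp1", "sp2", "sp3")]), c(2L, 1L, 0L))
  expect_equal(co$cohort$n_at_least_2, 1L)
  expect_equal(co$cohort$n_at_least_3, 0L)
})

test_that("cohort infection counts are recovered from simulated depth", {
  loads <- matrix(c(2, 0, 1, 0,
                    0.5, 0.5, 0, 0,
                    0, 0, 3, 0,
                    1, 1, 1, 1), nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("sp", 1:4), paste0("S", 1:4)))
  cfg <- simulation_config(seed = 23, genome_length = 20000L,
                           n_gene_families = 80L, symbiont_loads = loads)
  sim <- simulate_genomes(cfg)
  dep <- simulate_depth(cfg, sim)
  marker <- sim$features[sim$features$feature_id == "EF1a", ]
  fm <- sim$truth$family_membership
  acc <- lapply(c("S1", "S2"), function(g) {
    ids <- fm$protein_id[fm$family_id %in% sim$truth$accessory_families[[g]] &
                           fm$genome_id == g]
    sim$features[sim$features$feature_id %in% ids, ]
  })
  names(acc) <- c("S1", "S2")
  lc <- load_config(ploidy = 2, host_marker = marker,
                    confounded_pairs = list(list(genomes = c("S1", "S2"),
                                                 accessory = acc)))
  co <- coinfection_summary(build_load_profiles(dep, lc))
  truth_counts <- rowSums(loads > 0)
  expect_equal(unname(co$per_sample[rownames(loads)]),
               unname(as.integer(truth_counts)))
  expect_equal(co$cohort$n_at_least_2, sum(truth_counts >= 2))
  expect_equal(co$cohort$n_at_least_3, sum(truth_counts >= 3))
})
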