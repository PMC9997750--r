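test_that("shared transposase families span multiple genomes", {
  fams <- data.frame(family_id = c("f1", "f1", "f2", "f2", "f2", "f3"),
                     protein_id = paste0("p", 1:6),
                     genome_id = c("X", "Y", "X", "X", "X", "Y"),
                     stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = paste0("p", 1:6),
                      feature_class = c(rep("transposase", 5), "CDS"),
                      stringsAsFactors = FALSE)
  shared <- find_shared_te_families(fams, feats)
  expect_equal(unique(shared$family_id), "f1")

  cfg <- simulation_config(seed = 61, genome_length = 20000L,
                           n_gene_families = 80L)
  te <- simulate_te_families(cfg)
  rec <- find_shared_te_families(te$families, te$features)
  truth_shared <- names(te$truth$te_event_labels)[
    te$truth$te_event_labels %in% c("recent", "ancient")]
  expect_setequal(unique(rec$family_id), truth_shared)
})

test_that("progressive alignment matches the pairwise oracle", {
  msa <- build_msa(c(x = "ACDEFG", y = "ACEFG"))
  expect_equal(unname(msa["x"]), "ACDEFG")
  expect_equal(unname(msa["y"]), "AC-EFG")

  ident <- build_msa(c(a = "MKVLA", b = "MKVLA"))
  expect_equal(unname(ident), c("MKVLA", "MKVLA"))

  ## pairwise alignment score equals the exhaustive Gotoh optimum
  set.seed(62)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    a <- rand_aa_string(sample(20:60, 1))
    b <- mutate_exact(a, 0.2, aa)
    if (rep %% 2 == 0) b <- substr(b, 1, nchar(b) - sample(1:5, 1))
    msa <- build_msa(c(A = a, B = b))
    got <- msa_pair_score(msa["A"], msa["B"], blosum62_test)
    want <- oracle_gotoh(a, b, blosum62_test)
    expect_equal(got, want)
  }

  ## conservation: each row degaps to its input; width >= longest input
  set.seed(63)
  seqs <- c(s1 = rand_aa_string(80), s2 = rand_aa_string(90),
            s3 = rand_aa_string(85), s4 = rand_aa_string(70))
  msa <- build_msa(seqs)
  expect_true(all(nchar(msa) == nchar(msa[1])))
  expect_gte(nchar(msa[1]), max(nchar(seqs)))
  expect_equal(gsub("-", "", msa)[names(seqs)], seqs)
  expect_error(build_msa(c(only = "MKV")), "at least 2")
})

test_that("trimming removes gappy and high-entropy columns, idempotently", {
  msa <- c(a = "MK-RA", b = "MK-RC", c = "M--RD", d = "M--RE", e = "MKQRF")
  tr <- trim_alignment(msa)
  ## col3 all-gap-ish (gap fraction 0.6 > 0.5) out; col5 entropy ln5/ln20 kept
  expect_equal(unname(tr["a"]), "MKRA")
  expect_equal(trim_alignment(tr), tr)   # idempotent
  cons <- c(a = "MKVR", b = "MKVR", c = "MKVR")
  expect_equal(trim_alignment(cons), cons)
  ## a column with 8 distinct residues of 8 rows exceeds entropy 0.6
  div <- stats::setNames(paste0("MM", c("A","C","D","E","F","G","H","I")),
                         paste0("r", 1:8))
  tr2 <- trim_alignment(div)
  expect_equal(unname(nchar(tr2[1])), 2L)
  expect_error(trim_alignment(stats::setNames(c("AC", "CA", "GD", "TF"),
                                              paste0("x", 1:4)),
                              max_entropy = 0), "relax")
})

test_that("degradation flagging removes truncated near-identical copies only", {
  set.seed(64)
  base <- rand_aa_string(200)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  fam <- c(c1 = base,
           c2 = mutate_exact(base, 0.01, aa),
           c3 = mutate_exact(base, 0.02, aa),
           trunc = substr(mutate_exact(base, 0.01, aa), 61, 200),
           divergent = mutate_exact(base, 0.40, aa))
  res <- flag_degraded(fam)
  expect_true("trunc" %in% res$removed)
  expect_false("divergent" %in% res$removed)   # diverged, not degraded
  expect_false(res$untestable)

  ## simulator-truncated copies: recall and false-removal rates
  hits <- 0; possible <- 0; false_removed <- 0; kept_total <- 0
  for (s in 1:8) {
    cfg <- simulation_config(seed = 300 + s, genome_length = 20000L,
                             n_gene_families = 80L,
                             te_history = te_history_spec(
                               n_recent = 1, n_ancient = 1, n_vertical = 1,
                               degradation_rate = 0.3))
    te <- simulate_te_families(cfg)
    for (f in unique(te$families$family_id)) {
      mem <- te$proteins[te$proteins$family_id == f, ]
      res <- flag_degraded(stats::setNames(mem$residues, mem$id))
      truth <- mem$id[mem$degraded]
      possible <- possible + length(truth)
      hits <- hits + length(intersect(res$removed, truth))
      false_removed <- false_removed + length(setdiff(res$removed, truth))
      kept_total <- kept_total + nrow(mem) - length(truth)
    }
  }
  expect_gte(hits / possible, 0.9)
  expect_lte(false_removed / kept_total, 0.05)
})

test_that("Poisson-corrected distances follow the closed form", {
  msa <- c(a = paste(rep("A", 100), collapse = ""),
           b = paste(c(rep("A", 90), rep("C", 10)), collapse = ""))
  D <- protein_distance_matrix(msa)
  expect_equal(D["a", "b"], -log(0.9), tolerance = 1e-9)
  expect_equal(D["a", "a"], 0)
  ## saturation and overlap errors
  sat <- c(a = paste(rep("A", 50), collapse = ""),
           b = paste(rep("C", 50), collapse = ""))
  expect_error(protein_distance_matrix(sat), "p >= 1")
  short <- c(a = "AAAA", b = "AAAA")
  expect_error(protein_distance_matrix(short), "overlap")
  ## simulated divergence is recovered without bias (the per-draw sampling
  ## sd at 300 sites is ~0.034, so the mean over replicates is the test)
  set.seed(65)
  ds <- vapply(1:10, function(rep) {
    cfg <- simulation_config(seed = 400 + rep,
      te_history = te_history_spec(n_recent = 0, n_ancient = 1,
                                   n_vertical = 0, degradation_rate = 0,
                                   within_divergence = 0,
                                   copies_per_genome = 1))
    te <- simulate_te_families(cfg)
    msa <- build_msa(stats::setNames(te$proteins$residues, te$proteins$id))
    protein_distance_matrix(msa)[1, 2]
  }, numeric(1))
  expect_equal(mean(ds), 0.3, tolerance = 0.05 / 0.3)
  expect_true(all(abs(ds - 0.3) <= 0.1))
})

test_that("neighbor joining is exact on additive matrices", {
  ## the classic quartet: topology AB|CD with internal branch 1
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- nj_tree(D)
  expect_true(quartets_match(tr, D))
  pd <- stats::cophenetic(tr)[rownames(D), colnames(D)]
  expect_lte(max(abs(pd - D)), 1e-9)
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_equal(internal, 1, tolerance = 1e-9)

  ## n = 3 closed form
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  bl <- stats::setNames(t3$edge.length[match(1:3, t3$edge[, 2])],
                        t3$tip.label)
  expect_equal(bl[["x"]], 1)
  expect_equal(bl[["y"]], 2)
  expect_equal(bl[["z"]], 3)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b")))))
  Dd <- D; Dd["A", "B"] <- 2.9
  expect_error(nj_tree(Dd), "symmetric")

  ## random additive matrices: exact topology and branch lengths,
  ## invariance to taxon order
  for (rep in 1:25) {
    ra <- random_additive(sample(4:8, 1), seed = 600 + rep)
    tr <- nj_tree(ra$D)
    expect_true(quartets_match(tr, ra$D))
    pd <- stats::cophenetic(tr)[rownames(ra$D), colnames(ra$D)]
    expect_lte(max(abs(pd - ra$D)), 1e-9)
    perm <- sample(nrow(ra$D))
    tr2 <- nj_tree(ra$D[perm, perm])
    pd2 <- stats::cophenetic(tr2)[rownames(ra$D), colnames(ra$D)]
    expect_lte(max(abs(pd2 - ra$D)), 1e-9)
    ## cross-check against the independent NJ in ape
    ref <- ape::nj(ra$D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic and strong splits reach 95+", {
  set.seed(66)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- rand_aa_string(500)
  other <- mutate_exact(base, 0.30, aa)
  msa <- c(a1 = base, a2 = mutate_exact(base, 0.02, aa),
           b1 = other, b2 = mutate_exact(other, 0.02, aa))
  msa <- build_msa(msa)
  tr <- bootstrap_support(msa, n_replicates = 100, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
  tr2 <- bootstrap_support(msa, n_replicates = 100, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  ## duplicate sequences form a fully supported cherry; the outgroup pair
  ## is correlated so the internal branch is genuinely positive
  outg <- mutate_exact(base, 0.15, aa)
  dup <- build_msa(c(d1 = base, d2 = base,
                     e1 = outg, f1 = mutate_exact(outg, 0.08, aa)))
  trd <- bootstrap_support(dup, n_replicates = 50, seed = 1)
  supd <- suppressWarnings(as.numeric(trd$node.label))
  expect_true(100 %in% supd)
  expect_error(bootstrap_support(msa, n_replicates = 5), "at least 10")
})

test_that("sharing classification follows the distance/monophyly rules", {
  ## identical cross-genome copies: recent
  tr <- read_newick("((a:0,b:0):0.1,(c:0.4,d:0.4):0.1);")
  tr$node.label <- c("", "100", "100")
  calls <- classify_sharing(tr, c(a = "X", b = "Y", c = "X", d = "Y"))
  expect_equal(calls$classification, "recent")
  expect_equal(calls$min_cross_genome_patristic, 0)

  ## per-genome clades, sisters with full support, deep split: ancient
  tr2 <- read_newick("((x1:0.05,x2:0.05):0.3,(y1:0.05,y2:0.05):0.3);")
  tr2$node.label <- c("", "100", "100")
  calls2 <- classify_sharing(tr2, c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  expect_equal(calls2$classification, "ancient_sister")
  expect_true(calls2$monophyletic_a && calls2$monophyletic_b)
  expect_gte(calls2$sister_support, 95)

  ## same topology, weak support: unresolved
  tr3 <- tr2
  tr3$node.label <- c("", "60", "60")
  expect_equal(classify_sharing(tr3, c(x1 = "X", x2 = "X", y1 = "Y",
                                       y2 = "Y"))$classification,
               "unresolved")

  ## intermingled genomes: not monophyletic, unresolved
  tr4 <- read_newick("((x1:0.2,y1:0.2):0.2,(x2:0.2,y2:0.2):0.2);")
  tr4$node.label <- c("", "100", "100")
  calls4 <- classify_sharing(tr4, c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  expect_equal(calls4$classification, "unresolved")
  expect_false(calls4$monophyletic_a)
})

test_that("simulated TE histories are classified correctly end to end", {
  n_ok <- 0; n_tot <- 0; confusions <- 0
  for (s in 1:5) {
    cfg <- simulation_config(seed = 700 + s,
      te_history = te_history_spec(n_recent = 2, n_ancient = 2,
                                   n_vertical = 0))
    te <- simulate_te_families(cfg)
    seqs <- stats::setNames(te$proteins$residues, te$proteins$id)
    for (fam in names(te$truth$te_event_labels)) {
      mem <- te$families[te$families$family_id == fam, ]
      truth <- te$truth$te_event_labels[[fam]]
      res <- classify_te_family(seqs[mem$protein_id],
                                stats::setNames(mem$genome_id,
                                                mem$protein_id),
                                seed = s)
      cls <- if (res$untestable) "untestable" else res$calls$classification[1]
      n_tot <- n_tot + 1
      if ((truth == "recent" && cls == "recent") ||
          (truth == "ancient" && cls == "ancient_sister")) n_ok <- n_ok + 1
      if ((truth == "recent" && cls == "ancient_sister") ||
          (truth == "ancient" && cls == "recent")) confusions <- confusions + 1
    }
  }
  expect_gte(n_ok / n_tot, 0.9)
  expect_equal(confusions, 0)
})
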