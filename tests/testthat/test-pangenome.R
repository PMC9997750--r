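test_that("protein similarity search reports identity and coverage", {
  set.seed(50)
  p1 <- rand_aa_string(200)
  prots <- data.frame(id = c("a", "b", "c"),
                      residues = c(p1, p1, mutate_exact(p1, 0.10,
                        strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])),
                      stringsAsFactors = FALSE)
  edges <- all_vs_all_protein_similarity(prots)
  ab <- edges[edges$query_id == "a" & edges$subject_id == "b", ]
  expect_equal(ab$identity, 100)
  expect_equal(ab$query_coverage, 100)
  expect_equal(ab$subject_coverage, 100)
  ac <- edges[edges$query_id == "a" & edges$subject_id == "c", ]
  expect_equal(ac$identity, 90, tolerance = 0.025)

  bad <- data.frame(id = c("ok", "oops"),
                    residues = c(p1, "MKL123"), stringsAsFactors = FALSE)
  expect_error(all_vs_all_protein_similarity(bad), "oops")
})

test_that("unrelated random proteins produce no edge below e-value 0.001", {
  set.seed(51)
  prots <- data.frame(id = sprintf("r%02d", 1:12),
                      residues = replicate(12, rand_aa_string(100)),
                      stringsAsFactors = FALSE)
  edges <- all_vs_all_protein_similarity(prots)
  expect_equal(sum(edges$evalue_proxy < 1e-3), 0)
})

test_that("family clustering is single linkage (transitive closure)", {
  prots <- data.frame(id = c("a", "b", "c", "d"),
                      genome_id = c("g1", "g1", "g2", "g2"),
                      residues = "M", stringsAsFactors = FALSE)
  edge <- function(q, s) data.frame(query_id = q, subject_id = s,
                                    identity = 90, query_coverage = 95,
                                    subject_coverage = 95, score = 100,
                                    evalue_proxy = 1e-10,
                                    stringsAsFactors = FALSE)
  fams <- cluster_families(rbind(edge("a", "b"), edge("b", "c")), prots)
  expect_equal(fams$family_id[match(c("a", "b", "c"), fams$protein_id)],
               rep("a", 3))
  expect_equal(fams$family_id[fams$protein_id == "d"], "d")
  ## no passing edges: all singletons
  none <- cluster_families(edge("a", "b")[0, ], prots)
  expect_equal(none$family_id, none$protein_id)
  ## edges failing any threshold do not link
  weak <- edge("a", "b"); weak$identity <- 20
  expect_equal(cluster_families(weak, prots)$family_id[1], "a")
  weak2 <- edge("a", "b"); weak2$query_coverage <- 50
  f2 <- cluster_families(weak2, prots)
  expect_equal(f2$family_id[f2$protein_id == "b"], "b")
})

test_that("clustering equals union-find components on random graphs", {
  set.seed(52)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    ids <- sprintf("p%03d", sample(1000, n))
    n_edges <- sample(0:(2 * n), 1)
    ea <- sample(ids, n_edges, replace = TRUE)
    eb <- sample(ids, n_edges, replace = TRUE)
    keep <- ea != eb
    ea <- ea[keep]; eb <- eb[keep]
    k <- length(ea)
    edges <- data.frame(query_id = pmin(ea, eb), subject_id = pmax(ea, eb),
                        identity = rep(90, k), query_coverage = rep(95, k),
                        subject_coverage = rep(95, k), score = rep(1, k),
                        evalue_proxy = rep(1e-9, k), stringsAsFactors = FALSE)
    prots <- data.frame(id = ids, genome_id = "g",
                        residues = "M", stringsAsFactors = FALSE)
    fams <- cluster_families(edges, prots)
    oracle <- uf_components(sort(ids), edges$query_id, edges$subject_id)
    got <- stats::setNames(fams$family_id, fams$protein_id)[sort(ids)]
    expect_identical(unname(got), unname(oracle))
    ## invariance to edge order
    perm <- edges[sample(nrow(edges)), , drop = FALSE]
    fams2 <- cluster_families(perm, prots)
    expect_identical(fams2, fams)
  }
})

test_that("pangenome partition applies the 100-aa ghost filter first", {
  prots <- data.frame(
    id = c("p1a", "p1b", "p2", "p3"),
    genome_id = c("g1", "g2", "g1", "g1"),
    residues = c(rand_aa_string(150), rand_aa_string(150),
                 rand_aa_string(120), rand_aa_string(80)),
    stringsAsFactors = FALSE)
  fams <- data.frame(family_id = c("f1", "f1", "f2", "f3"),
                     protein_id = prots$id, genome_id = prots$genome_id,
                     stringsAsFactors = FALSE)
  part <- partition_pangenome(fams, prots)
  expect_equal(part$shared, "f1")
  expect_equal(part$accessory$g1, "f2")   # f3 dropped by the length filter
  expect_equal(length(part$accessory$g2), 0L)
  expect_equal(length(part$shared) + sum(lengths(part$accessory)),
               part$n_families_kept)
})

test_that("pangenome partition recovers the simulator's truth", {
  cfg <- simulation_config(seed = 53, genome_length = 20000L,
                           n_gene_families = 80L)
  sim <- simulate_genomes(cfg)
  coding <- sim$features[sim$features$feature_class %in%
                           c("CDS", "transposase") &
                           sim$features$genome_id != "host", ]
  prots <- data.frame(id = coding$feature_id, residues = coding$protein,
                      genome_id = coding$genome_id, stringsAsFactors = FALSE)
  edges <- all_vs_all_protein_similarity(prots)
  fams <- cluster_families(edges, prots)
  part <- partition_pangenome(fams, prots)
  expect_equal(length(part$shared), length(sim$truth$shared_families))
  for (g in names(part$accessory)) {
    expect_equal(length(part$accessory[[g]]),
                 length(sim$truth$accessory_families[[g]]), label = g)
  }
})

test_that("COG summary pools sparse categories and tracks de novo OGs", {
  part <- list(accessory = list(g1 = paste0("f", 1:12)),
               families_kept = data.frame(
                 family_id = paste0("f", 1:12),
                 protein_id = paste0("p", 1:12),
                 genome_id = "g1", stringsAsFactors = FALSE))
  ann <- data.frame(
    protein_id = paste0("p", 1:11),
    category = c(rep("L", 5), rep("S", 3), "V", "M", "KL"),
    stringsAsFactors = FALSE)
  sm <- summarize_accessory_cog(part, ann)$g1
  expect_equal(sm[["L"]], 5L)
  expect_equal(sm[["S"]], 3L)
  expect_equal(sm[["Other categories"]], 2L)   # V + M pooled
  expect_equal(sm[["de novo OGs"]], 1L)        # p12 unannotated
  expect_false("KL" %in% names(sm))            # ambiguous excluded
  ## empty accessory set -> empty summary
  part0 <- list(accessory = list(g1 = character()),
                families_kept = part$families_kept[0, ])
  expect_equal(length(summarize_accessory_cog(part0, ann)$g1), 0L)
})

test_that("ANI: self-identity is exactly 100 and divergence shifts it linearly", {
  set.seed(54)
  g <- data.frame(id = "gA", residues = rand_nt_string(20000),
                  stringsAsFactors = FALSE)
  self <- ani(g, g)
  expect_equal(self$ani, 100, tolerance = 1e-6)
  g2 <- data.frame(id = "gB",
                   residues = mutate_exact(g$residues, 0.03,
                                           c("A", "C", "G", "T")),
                   stringsAsFactors = FALSE)
  r <- ani(g, g2)
  expect_equal(r$ani, 97, tolerance = 0.01)
  expect_error(ani(data.frame(id = "tiny", residues = rand_nt_string(500)),
                   g), "shorter than one fragment")
  ## unrelated sequences: no passing fragments
  g3 <- data.frame(id = "gC", residues = rand_nt_string(20000),
                   stringsAsFactors = FALSE)
  expect_true(is.na(ani(g, g3)$ani))
})

test_that("AAI: reciprocal best hits, self = 100, divergence tracks identity", {
  set.seed(55)
  prots <- data.frame(id = sprintf("p%02d", 1:15),
                      residues = replicate(15, rand_aa_string(180)),
                      stringsAsFactors = FALSE)
  self <- aai(prots, prots)
  expect_equal(self$aai, 100)
  expect_equal(self$aai_orthologs_used, 15L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mut <- prots
  mut$id <- paste0("m", mut$id)
  mut$residues <- vapply(prots$residues, mutate_exact, character(1),
                         frac = 0.10, alphabet = aa)
  r <- aai(prots, mut)
  expect_equal(r$aai, 90, tolerance = 0.015)
  ## disjoint random proteomes: undefined
  other <- data.frame(id = sprintf("q%02d", 1:12),
                      residues = replicate(12, rand_aa_string(150)),
                      stringsAsFactors = FALSE)
  expect_true(is.na(aai(prots, other)$aai))
  expect_error(aai(prots[0, ], prots), "empty proteome")
})

test_that("species calls follow the strict >= 95 rule on defined metrics", {
  expect_true(species_call(list(ani = 99.79, aai = 99.47)))
  expect_false(species_call(list(ani = 93, aai = 89)))
  expect_false(species_call(list(ani = 94.9, aai = NA)))
  expect_true(species_call(list(ani = NA, aai = 96)))
  expect_error(species_call(list(ani = NA, aai = NA)), "undefined")
})
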