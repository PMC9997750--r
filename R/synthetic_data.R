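## Synthetic community generator: genomes with core/accessory family
## structure, Poisson depth with cross-mapping inflation on the confounded
## strain pair, transposase family histories (vertical / recent transfer /
## ancient split), and variant tables with known fixed-variant densities.
## Every simulator draws from its own child stream of the root seed so the
## components are individually reproducible.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT4 <- c("A", "C", "G", "T")

child_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 100000L
  (abs(as.integer(seed)) %% 2000003L) * 1009L + as.integer(h)
}

resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

rand_protein <- function(len) resample(AA20, len, replace = TRUE)
rand_nt <- function(len) resample(NT4, len, replace = TRUE)

## site-independent uniform substitution: each site is hit with probability
## 1 - exp(-d) and replaced by a uniform draw over the other residues, so the
## expected p-distance is 1 - exp(-d) and the Poisson correction
## d = -ln(1 - p) is unbiased for this process
mutate_seq <- function(chars, d, alphabet = AA20) {
  hit <- which(stats::runif(length(chars)) < 1 - exp(-d))
  for (i in hit) {
    chars[i] <- resample(setdiff(alphabet, chars[i]), 1L)
  }
  chars
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(protein_chars, codons = .codon_table()) {
  out <- character(length(protein_chars))
  for (i in seq_along(protein_chars)) {
    out[i] <- resample(codons[[protein_chars[i]]], 1L)
  }
  paste0(paste(out, collapse = ""), "TAA")
}

#' Transposase-history specification for the simulator
#'
#' Families are generated under three histories: `vertical` (copies in a
#' single genome), `recent` (a cross-genome transfer leaving near-identical
#' copies, at most one substitution apart, in donor and recipient), and
#' `ancient` (one per-genome clade each, diverged by `ancient_divergence`
#' substitutions/site — the sister-clade signature of ancient co-residence).
#'
#' @param n_recent,n_ancient,n_vertical Family counts per history class.
#' @param te_length Transposase length in amino acids (must be >= 50).
#' @param ancient_divergence Between-clade divergence, substitutions/site.
#' @param within_divergence Within-genome copy divergence for ancient and
#'   vertical families, substitutions/site.
#' @param recent_divergence Within-genome copy divergence for recent
#'   families (insertion-sequence transfers ride proliferation bursts, so
#'   all copies are near-identical), substitutions/site.
#' @param copies_per_genome Copies carried by each genome holding the family.
#' @param degradation_rate Fraction of copies truncated at one terminus.
#' @param truncation_range Truncated fraction of the protein, range.
#' @param donor,recipient Genome ids used for transfer and vertical families.
#' @return A list of class `te_history_spec`.
#' @export
te_history_spec <- function(n_recent = 2L, n_ancient = 2L, n_vertical = 2L,
                            te_length = 300L, ancient_divergence = 0.3,
                            within_divergence = 0.03,
                            recent_divergence = 0.003,
                            copies_per_genome = 3L,
                            degradation_rate = 0.2,
                            truncation_range = c(0.2, 0.4),
                            donor = "S1", recipient = "S2") {
  if (te_length < 50L) stop("te_length < 50 aa: too short to classify")
  stopifnot(ancient_divergence >= 0, degradation_rate >= 0,
            degradation_rate <= 1, copies_per_genome >= 1L)
  structure(list(n_recent = n_recent, n_ancient = n_ancient,
                 n_vertical = n_vertical, te_length = te_length,
                 ancient_divergence = ancient_divergence,
                 within_divergence = within_divergence,
                 recent_divergence = recent_divergence,
                 copies_per_genome = copies_per_genome,
                 degradation_rate = degradation_rate,
                 truncation_range = truncation_range,
                 donor = donor, recipient = recipient),
            class = "te_history_spec")
}

#' Variant-table specification for the simulator
#'
#' @param n_fixed_clear Fixed (frequency 1) variants per sample x genome
#'   placed outside transposases and introns; these define the true
#'   fixed-variant density.
#' @param n_fixed_excluded Fixed variants placed inside transposases/introns.
#' @param n_polymorphic Variants at frequency < 1, placed anywhere.
#' @param fixed_type_weights Named sampling weights over variant types for
#'   fixed variants.
#' @return A list of class `variant_spec`.
#' @export
variant_spec <- function(n_fixed_clear = 20L, n_fixed_excluded = 10L,
                         n_polymorphic = 15L,
                         fixed_type_weights = c(SNP = 0.7, deletion = 0.1,
                                                insertion = 0.1,
                                                substitution = 0.1)) {
  structure(list(n_fixed_clear = n_fixed_clear,
                 n_fixed_excluded = n_fixed_excluded,
                 n_polymorphic = n_polymorphic,
                 fixed_type_weights = fixed_type_weights),
            class = "variant_spec")
}

.default_loads <- function(n_symbionts) {
  pool <- c(1, 1, 0.5, 0.1,
            2, 0.25, 1.5, 0.5,
            0.5, 5, 0.1, 1,
            3, 0.5, 2, 0.25,
            0.1, 1.5, 5, 2,
            1.5, 3, 0.25, 0.5)
  m <- matrix(rep_len(pool, 6L * n_symbionts), nrow = 6L, byrow = TRUE)
  dimnames(m) <- list(paste0("sp", 1:6), paste0("S", seq_len(n_symbionts)))
  m
}

#' Simulation configuration
#'
#' Defaults describe the emulated study: a cohort of co-infected host
#' individuals carrying four symbionts, two of which (`S1`, `S2`) are
#' near-identical sister strains whose shared genes suffer cross-mapping
#' depth inflation; per-base depth is Poisson with rate
#' `load x host_marker_depth_mean x ploidy`, and the diploid host marker
#' track has rate `host_marker_depth_mean x ploidy`.
#'
#' @param seed Root seed; all component streams derive from it.
#' @param n_symbionts Number of symbiont genomes.
#' @param genome_length Genome length in bp (all symbionts).
#' @param n_gene_families Size of the gene-family pool.
#' @param core_fraction Fraction of the pool present in every genome.
#' @param ghost_cds_fraction Fraction of each genome's genes emitted with a
#'   protein shorter than 100 aa (ghost CDS).
#' @param host_marker_depth_mean Host marker depth per chromosome copy
#'   (reads/base).
#' @param symbiont_loads Samples x symbionts matrix of true loads; rownames
#'   are sample ids. Default: a fixed 6-sample design spanning 0.1-5.
#' @param ploidy Host chromosome number (diploid: 2).
#' @param shared_fraction_confounded_pair Fraction of each pair genome's
#'   families shared with its sister strain at >= 99 % nucleotide identity.
#' @param confounded_pair Genome ids of the sister-strain pair.
#' @param transposase_fraction Fraction of private families annotated as
#'   transposases.
#' @param n_introns Intron features per genome.
#' @param mean_protein_length Mean protein length (aa) for regular genes.
#' @param te_history A [te_history_spec()].
#' @param variant_spec A [variant_spec()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_symbionts = 4L,
                              genome_length = 50000L,
                              n_gene_families = 200L, core_fraction = 0.3,
                              ghost_cds_fraction = 0.1,
                              host_marker_depth_mean = 30,
                              symbiont_loads = NULL, ploidy = 2L,
                              shared_fraction_confounded_pair = 0.8,
                              confounded_pair = c("S1", "S2"),
                              transposase_fraction = 0.15, n_introns = 2L,
                              mean_protein_length = 150L,
                              te_history = te_history_spec(),
                              variant_spec = symbiocensus::variant_spec()) {
  stopifnot(core_fraction >= 0, core_fraction <= 1,
            ghost_cds_fraction >= 0, ghost_cds_fraction <= 1,
            shared_fraction_confounded_pair >= 0,
            shared_fraction_confounded_pair <= 1,
            host_marker_depth_mean > 0, ploidy >= 1L, n_symbionts >= 1L)
  if (is.null(symbiont_loads)) symbiont_loads <- .default_loads(n_symbionts)
  stopifnot(is.matrix(symbiont_loads), all(symbiont_loads >= 0),
            !is.null(rownames(symbiont_loads)))
  if (is.null(colnames(symbiont_loads))) {
    colnames(symbiont_loads) <- paste0("S", seq_len(ncol(symbiont_loads)))
  }
  stopifnot(ncol(symbiont_loads) == n_symbionts)
  structure(list(seed = as.integer(seed), n_symbionts = as.integer(n_symbionts),
                 genome_length = as.integer(genome_length),
                 n_gene_families = as.integer(n_gene_families),
                 core_fraction = core_fraction,
                 ghost_cds_fraction = ghost_cds_fraction,
                 host_marker_depth_mean = host_marker_depth_mean,
                 symbiont_loads = symbiont_loads, ploidy = as.integer(ploidy),
                 shared_fraction_confounded_pair =
                   shared_fraction_confounded_pair,
                 confounded_pair = confounded_pair,
                 transposase_fraction = transposase_fraction,
                 n_introns = as.integer(n_introns),
                 mean_protein_length = as.integer(mean_protein_length),
                 te_history = te_history, variant_spec = variant_spec),
            class = "simulation_config")
}

.family_layout <- function(config) {
  n <- config$n_symbionts
  genomes <- colnames(config$symbiont_loads)
  core_n <- round(config$core_fraction * config$n_gene_families)
  acc_total <- config$n_gene_families - core_n
  q <- if (n > 0L) acc_total %/% n else 0L
  pair <- config$confounded_pair
  has_pair <- n >= 2L && all(pair %in% genomes) &&
    config$shared_fraction_confounded_pair > 0
  j <- 0L
  if (has_pair && acc_total > 0L) {
    t_pair <- core_n + q
    shared_target <- round(config$shared_fraction_confounded_pair * t_pair)
    j <- shared_target - core_n
    if (j < 0L) {
      stop("shared_fraction_confounded_pair is below the core fraction of ",
           "the pair genomes; increase it or lower core_fraction")
    }
    if (j > q) {
      stop("core_fraction + accessory demands exceed n_gene_families")
    }
  }
  p_priv <- if (has_pair) q - j else q
  used <- core_n + j +
    (if (has_pair) 2L * p_priv + (n - 2L) * q else n * q)
  if (used > config$n_gene_families) {
    stop("core_fraction + accessory demands exceed n_gene_families")
  }
  list(genomes = genomes, core_n = core_n, q = q, j = j, p_priv = p_priv,
       has_pair = has_pair, pair = if (has_pair) pair else character())
}

#' Simulate symbiont genomes, annotations, and the truth table
#'
#' Each genome carries every core family plus a private accessory set; the
#' confounded pair additionally shares `shared_fraction_confounded_pair` of
#' its families at >= 99 % nucleotide identity. A fraction of genes are
#' emitted as ghost CDS (protein < 100 aa), and a fraction of private
#' families are annotated as transposases; intron features and a single-copy
#' host marker gene (elongation factor 1-alpha analogue) are included.
#'
#' @param config A [simulation_config()].
#' @return A list with `genomes` (sequence table, including the host marker
#'   contig), `features` (gene feature table) and `truth` (family
#'   membership, pair-shared family set, expected pangenome partition).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$seed, "genomes"))
  codons <- .codon_table()
  lay <- .family_layout(config)
  genomes <- lay$genomes

  fam_ids <- sprintf("fam%03d", seq_len(config$n_gene_families))
  cursor <- 0L
  take <- function(k) {
    out <- fam_ids[cursor + seq_len(k)]
    cursor <<- cursor + k
    out
  }
  core_fams <- take(lay$core_n)
  pair_joint <- if (lay$has_pair) take(lay$j) else character()
  private <- list()
  for (g in genomes) {
    k <- if (lay$has_pair && g %in% lay$pair) lay$p_priv else lay$q
    private[[g]] <- take(k)
  }

  ## per-genome family sets
  fam_sets <- lapply(genomes, function(g) {
    c(core_fams, if (lay$has_pair && g %in% lay$pair) pair_joint,
      private[[g]])
  })
  names(fam_sets) <- genomes

  ## ghost CDS and transposase labels drawn from private families
  ghost <- character()
  transposase <- character()
  is_labels <- c("IS6", "IS110", "IS256", "IS982", "IS5")
  for (g in genomes) {
    n_genes <- length(fam_sets[[g]])
    n_ghost <- round(config$ghost_cds_fraction * n_genes)
    if (n_ghost > length(private[[g]])) {
      stop("not enough private families in ", g, " to host ghost CDS")
    }
    gset <- private[[g]][seq_len(n_ghost)]
    ghost <- c(ghost, gset)
    rest <- setdiff(private[[g]], gset)
    n_te <- round(config$transposase_fraction * length(rest))
    transposase <- c(transposase, rest[seq_len(n_te)])
  }

  ## reference protein and per-genome copies for every family
  prot_of <- list()   # prot_of[[fam]][[genome]] = character vector
  nt_of <- list()
  for (fam in fam_ids[seq_len(cursor)]) {
    is_ghost <- fam %in% ghost
    len <- if (is_ghost) {
      resample(40:70, 1L)
    } else {
      max(110L, round(stats::rnorm(1L, config$mean_protein_length, 30)))
    }
    ref <- rand_protein(len)
    carriers <- genomes[vapply(fam_sets, function(s) fam %in% s, logical(1))]
    p <- list()
    nt <- list()
    if (lay$has_pair && all(lay$pair %in% carriers)) {
      a <- lay$pair[1L]; b <- lay$pair[2L]
      p[[a]] <- ref
      nt[[a]] <- reverse_translate(ref, codons)
      p[[b]] <- mutate_seq(ref, 0.001)
      nt[[b]] <- paste(mutate_seq(strsplit(nt[[a]], "")[[1L]], 0.001, NT4),
                       collapse = "")
      for (g in setdiff(carriers, lay$pair)) {
        p[[g]] <- mutate_seq(ref, 0.03)
        nt[[g]] <- reverse_translate(p[[g]], codons)
      }
    } else {
      for (g in carriers) {
        p[[g]] <- if (length(carriers) > 1L) mutate_seq(ref, 0.03) else ref
        nt[[g]] <- reverse_translate(p[[g]], codons)
      }
    }
    prot_of[[fam]] <- p
    nt_of[[fam]] <- nt
  }

  ## assemble genomes: shuffled genes separated by spacers filling the length
  feat_rows <- list()
  seq_rows <- list()
  for (g in genomes) {
    fams <- resample(fam_sets[[g]], length(fam_sets[[g]]))
    gene_nt <- vapply(fams, function(f) nt_of[[f]][[g]], character(1))
    glens <- nchar(gene_nt)
    total <- sum(glens)
    n_gaps <- length(fams) + 1L
    slack <- config$genome_length - total
    if (slack < n_gaps * 20L) {
      stop("genome_length too small for the simulated gene content (need > ",
           total + n_gaps * 20L, " bp)")
    }
    base <- slack %/% n_gaps
    extra <- slack %% n_gaps
    spacer_len <- rep(base, n_gaps)
    if (extra > 0L) spacer_len[seq_len(extra)] <- base + 1L
    pieces <- character(2L * length(fams) + 1L)
    pos <- 0L
    spacer_iv <- matrix(0L, nrow = n_gaps, ncol = 2L)
    for (i in seq_along(fams)) {
      pieces[2L * i - 1L] <- paste(rand_nt(spacer_len[i]), collapse = "")
      spacer_iv[i, ] <- c(pos + 1L, pos + spacer_len[i])
      pos <- pos + spacer_len[i]
      strand <- resample(c("+", "-"), 1L)
      nt <- gene_nt[i]
      if (strand == "-") {
        nt <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(nt)))
      }
      pieces[2L * i] <- nt
      fam <- fams[i]
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        feature_id = paste0(g, "_", fam),
        genome_id = g, contig_id = g,
        start = pos + 1L, end = pos + glens[i], strand = strand,
        feature_class = if (fam %in% transposase) "transposase" else "CDS",
        product = if (fam %in% transposase) {
          paste0(is_labels[(match(fam, fam_ids) %% length(is_labels)) + 1L],
                 " family transposase")
        } else "hypothetical protein",
        protein = paste(prot_of[[fam]][[g]], collapse = ""),
        family_id = fam, stringsAsFactors = FALSE)
      pos <- pos + glens[i]
    }
    pieces[2L * length(fams) + 1L] <-
      paste(rand_nt(spacer_len[n_gaps]), collapse = "")
    spacer_iv[n_gaps, ] <- c(pos + 1L, pos + spacer_len[n_gaps])
    seq_rows[[g]] <- paste(pieces, collapse = "")
    ## introns dropped into the widest spacers
    wide <- order(spacer_iv[, 2L] - spacer_iv[, 1L], decreasing = TRUE)
    for (k in seq_len(min(config$n_introns, n_gaps))) {
      iv <- spacer_iv[wide[k], ]
      if (iv[2L] - iv[1L] + 1L < 90L) next
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        feature_id = paste0(g, "_intron", k), genome_id = g, contig_id = g,
        start = iv[1L] + 5L, end = iv[1L] + 84L, strand = "+",
        feature_class = "intron", product = "", protein = "",
        family_id = NA_character_, stringsAsFactors = FALSE)
    }
  }

  ## host marker: single-copy EF1-alpha analogue on its own contig
  marker_prot <- rand_protein(480L)
  marker_contig <- paste(rand_nt(1500L), collapse = "")
  feat_rows[[length(feat_rows) + 1L]] <- data.frame(
    feature_id = "EF1a", genome_id = "host", contig_id = "host_marker",
    start = 30L, end = 30L + 480L * 3L + 2L, strand = "+",
    feature_class = "CDS", product = "elongation factor 1-alpha",
    protein = paste(marker_prot, collapse = ""),
    family_id = NA_character_, stringsAsFactors = FALSE)

  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL
  genome_df <- data.frame(
    id = c(genomes, "host_marker"),
    description = c(rep("simulated symbiont genome", length(genomes)),
                    "simulated host single-copy marker region"),
    residues = c(unlist(seq_rows[genomes]), marker_contig),
    stringsAsFactors = FALSE)

  gene_feats <- features[!is.na(features$family_id), , drop = FALSE]
  membership <- data.frame(protein_id = gene_feats$feature_id,
                           family_id = gene_feats$family_id,
                           genome_id = gene_feats$genome_id,
                           protein_length = nchar(gene_feats$protein),
                           ghost = gene_feats$family_id %in% ghost,
                           stringsAsFactors = FALSE)
  pair_shared <- c(if (lay$has_pair) core_fams, pair_joint)
  ## expected pangenome partition after the >= 100 aa filter
  kept <- membership[membership$protein_length >= 100L, , drop = FALSE]
  by_fam <- split(kept$genome_id, kept$family_id)
  n_gen <- vapply(by_fam, function(x) length(unique(x)), integer(1))
  shared_truth <- names(by_fam)[n_gen >= 2L]
  accessory_truth <- lapply(genomes, function(g) {
    names(by_fam)[n_gen == 1L &
                    vapply(by_fam, function(x) x[1L] == g, logical(1))]
  })
  names(accessory_truth) <- genomes

  list(genomes = genome_df, features = features,
       truth = list(family_membership = membership,
                    pair_shared_families = pair_shared,
                    shared_families = shared_truth,
                    accessory_families = accessory_truth,
                    confounded_pair = lay$pair,
                    ghost_families = ghost,
                    transposase_families = transposase))
}

#' Simulate per-base depth tracks for every sample
#'
#' Per-base depth for symbiont `g` in a sample is Poisson with rate
#' `load[sample, g] x host_marker_depth_mean x ploidy`. On genes shared by
#' the confounded pair, each strain's track receives additional,
#' independently drawn Poisson depth at the sister strain's rate — the
#' cross-mapping inflation the accessory-gene restriction corrects. The host
#' marker track is Poisson with rate `host_marker_depth_mean x ploidy`.
#'
#' @param config A [simulation_config()].
#' @param sim Output of [simulate_genomes()].
#' @return A list of [depth_track()] objects (per sample: one per symbiont
#'   genome plus a `host_marker` track).
#' @export
simulate_depth <- function(config, sim) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$seed, "depth"))
  loads <- config$symbiont_loads
  m <- config$host_marker_depth_mean
  p <- config$ploidy
  pair <- sim$truth$confounded_pair
  glens <- stats::setNames(nchar(sim$genomes$residues), sim$genomes$id)
  feats <- sim$features
  tracks <- list()
  for (s in rownames(loads)) {
    for (g in colnames(loads)) {
      L <- glens[[g]]
      lambda <- loads[s, g] * m * p
      d <- stats::rpois(L, lambda)
      if (length(pair) == 2L && g %in% pair) {
        sister <- setdiff(pair, g)
        shared <- feats$genome_id == g &
          !is.na(feats$family_id) &
          feats$family_id %in% sim$truth$pair_shared_families
        lam_sis <- loads[s, sister] * m * p
        if (lam_sis > 0 && any(shared)) {
          for (i in which(shared)) {
            idx <- feats$start[i]:feats$end[i]
            d[idx] <- d[idx] + stats::rpois(length(idx), lam_sis)
          }
        }
      }
      tracks[[length(tracks) + 1L]] <- depth_track(s, g, d)
    }
    tracks[[length(tracks) + 1L]] <-
      depth_track(s, "host_marker",
                  stats::rpois(glens[["host_marker"]], m * p))
  }
  tracks
}

#' Simulate transposase families with known evolutionary histories
#'
#' @param config A [simulation_config()] whose `te_history` field describes
#'   the family classes (see [te_history_spec()]).
#' @return A list with `proteins` (sequence table with `family_id`,
#'   `genome_id`, `degraded`), `families` (ortholog-family table),
#'   `features` (nominal transposase features) and `truth` (per-family event
#'   labels and per-copy degradation flags).
#' @export
simulate_te_families <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  spec <- config$te_history
  set.seed(child_seed(config$seed, "te"))
  labels <- c(rep("recent", spec$n_recent), rep("ancient", spec$n_ancient),
              rep("none", spec$n_vertical))
  k <- spec$copies_per_genome
  rows <- list()
  for (i in seq_along(labels)) {
    fam <- sprintf("tefam%03d", i)
    root <- rand_protein(spec$te_length)
    copies <- list()   # name -> list(genome, chars)
    add <- function(genome, chars) {
      nm <- paste0(fam, "_", genome, "_", sum(vapply(
        copies, function(x) x$genome == genome, logical(1))) + 1L)
      copies[[nm]] <<- list(genome = genome, chars = chars)
    }
    if (labels[i] == "recent") {
      donor_first <- root
      add(spec$donor, donor_first)
      for (j in seq_len(k - 1L)) {
        add(spec$donor, mutate_seq(root, spec$recent_divergence))
      }
      ## transferred copy differs from its donor source by at most 1 sub
      transferred <- donor_first
      if (resample(c(TRUE, FALSE), 1L)) {
        pos <- resample(seq_along(transferred), 1L)
        transferred[pos] <- resample(setdiff(AA20, transferred[pos]), 1L)
      }
      add(spec$recipient, transferred)
      for (j in seq_len(k - 1L)) {
        add(spec$recipient, mutate_seq(transferred, spec$recent_divergence))
      }
    } else if (labels[i] == "ancient") {
      anc_b <- mutate_seq(root, spec$ancient_divergence)
      for (j in seq_len(k)) {
        add(spec$donor, mutate_seq(root, spec$within_divergence))
        add(spec$recipient, mutate_seq(anc_b, spec$within_divergence))
      }
    } else {
      home <- if (i %% 2L == 0L) spec$recipient else spec$donor
      for (j in seq_len(k)) {
        add(home, mutate_seq(root, spec$within_divergence))
      }
    }
    ## terminal degradation of a fixed fraction of copies
    n_trunc <- round(spec$degradation_rate * length(copies))
    trunc_idx <- resample(seq_along(copies), n_trunc)
    degraded <- logical(length(copies))
    for (ti in trunc_idx) {
      chars <- copies[[ti]]$chars
      frac <- stats::runif(1L, spec$truncation_range[1L],
                           spec$truncation_range[2L])
      cut <- round(frac * length(chars))
      chars <- if (resample(c(TRUE, FALSE), 1L)) {
        chars[-seq_len(cut)]                      # 5' truncation
      } else {
        chars[seq_len(length(chars) - cut)]       # 3' truncation
      }
      copies[[ti]]$chars <- chars
      degraded[ti] <- TRUE
    }
    rows[[i]] <- data.frame(
      id = names(copies),
      residues = vapply(copies, function(x) paste(x$chars, collapse = ""),
                        character(1)),
      family_id = fam,
      genome_id = vapply(copies, function(x) x$genome, character(1)),
      degraded = degraded,
      event = labels[i],
      stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, rows)
  rownames(proteins) <- NULL
  is_labels <- c("IS6", "IS110", "IS256")
  features <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(r) {
    len_nt <- nchar(proteins$residues[r]) * 3L + 3L
    data.frame(feature_id = proteins$id[r],
               genome_id = proteins$genome_id[r],
               contig_id = paste0(proteins$genome_id[r], "_te"),
               start = 1L + (r - 1L) * 1200L, end = (r - 1L) * 1200L + len_nt,
               strand = "+", feature_class = "transposase",
               product = paste0(
                 is_labels[(match(proteins$family_id[r],
                                  unique(proteins$family_id)) %% 3L) + 1L],
                 " family transposase"),
               protein = proteins$residues[r], stringsAsFactors = FALSE)
  }))
  families <- data.frame(family_id = proteins$family_id,
                         protein_id = proteins$id,
                         genome_id = proteins$genome_id,
                         stringsAsFactors = FALSE)
  truth_events <- unique(proteins[, c("family_id", "event")])
  rownames(truth_events) <- NULL
  list(proteins = proteins, families = families, features = features,
       truth = list(te_event_labels = stats::setNames(truth_events$event,
                                                      truth_events$family_id),
                    degraded_copies = proteins$id[proteins$degraded]))
}

#' Simulate a variant table with known fixed-variant densities
#'
#' Fixed variants (frequency 1) are placed both outside and inside the
#' excluded feature classes (transposases, introns); polymorphic variants
#' (frequency < 1) land anywhere. The truth density for each sample x genome
#' is `n_fixed_clear / (genome_length / 1000)`.
#'
#' @param config A [simulation_config()].
#' @param sim Output of [simulate_genomes()].
#' @return A list with `variants` (table: sample_id, genome_id, position,
#'   variant_type, frequency) and `truth` (density table).
#' @export
simulate_variant_table <- function(config, sim) {
  stopifnot(inherits(config, "simulation_config"))
  vs <- config$variant_spec
  set.seed(child_seed(config$seed, "variants"))
  genomes <- colnames(config$symbiont_loads)
  samples <- rownames(config$symbiont_loads)
  feats <- sim$features
  types <- names(vs$fixed_type_weights)
  rows <- list()
  truth <- list()
  for (g in genomes) {
    L <- nchar(sim$genomes$residues[sim$genomes$id == g])
    excluded <- logical(L)
    fsel <- feats$genome_id == g &
      feats$feature_class %in% c("transposase", "intron")
    for (i in which(fsel)) excluded[feats$start[i]:feats$end[i]] <- TRUE
    clear_pos <- which(!excluded)
    excl_pos <- which(excluded)
    if (vs$n_fixed_excluded > 0L && length(excl_pos) == 0L) {
      stop("genome ", g, " has no transposase/intron positions to host ",
           "excluded-region variants")
    }
    for (s in samples) {
      pf <- resample(clear_pos, vs$n_fixed_clear)
      pe <- resample(excl_pos, vs$n_fixed_excluded)
      pp <- resample(setdiff(seq_len(L), c(pf, pe)), vs$n_polymorphic)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, genome_id = g,
        position = c(pf, pe, pp),
        variant_type = c(
          resample(types, vs$n_fixed_clear, replace = TRUE),
          resample(types, vs$n_fixed_excluded, replace = TRUE),
          resample(types, vs$n_polymorphic, replace = TRUE)),
        frequency = c(rep(1, vs$n_fixed_clear + vs$n_fixed_excluded),
                      round(stats::runif(vs$n_polymorphic, 0.05, 0.95), 4L)),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = s, genome_id = g,
        true_density = vs$n_fixed_clear / (L / 1000),
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  list(variants = variants, truth = do.call(rbind, truth))
}

#' Simulate per-position base counts for the toy pileup caller
#'
#' Depth is Poisson at `depth_mean`; the alternate-allele count is binomial
#' at the variant frequency on variant positions (fixed variants at 1 minus
#' the error rate) and at `error_rate` elsewhere. Sequencing-error modeling
#' is outside the generator's scope, so `error_rate` defaults to 0 — fixed
#' variants then yield an alternate fraction of exactly 1.
#'
#' @param config A [simulation_config()].
#' @param sim Output of [simulate_genomes()].
#' @param variants Variant table from [simulate_variant_table()].
#' @param depth_mean Mean sequencing depth.
#' @param error_rate Per-base error rate off variant positions.
#' @return A list of per-(sample, genome) base-count objects with fields
#'   `sample_id`, `genome_id`, `depth`, `alt_count`.
#' @export
simulate_base_counts <- function(config, sim, variants, depth_mean = 50,
                                 error_rate = 0) {
  set.seed(child_seed(config$seed, "basecounts"))
  out <- list()
  for (g in colnames(config$symbiont_loads)) {
    L <- nchar(sim$genomes$residues[sim$genomes$id == g])
    for (s in rownames(config$symbiont_loads)) {
      depth <- stats::rpois(L, depth_mean)
      alt <- stats::rbinom(L, depth, error_rate)
      v <- variants[variants$sample_id == s & variants$genome_id == g &
                      variants$variant_type == "SNP", , drop = FALSE]
      if (nrow(v) > 0L) {
        freq <- pmin(v$frequency, 1 - error_rate)
        alt[v$position] <- stats::rbinom(nrow(v), depth[v$position], freq)
      }
      out[[length(out) + 1L]] <- list(sample_id = s, genome_id = g,
                                      depth = depth, alt_count = alt)
    }
  }
  out
}

#' Run every simulator and assemble the full truth table
#'
#' @param config A [simulation_config()].
#' @return A list with `genomes`, `features`, `depth`, `te`, `variants` and
#'   a consolidated `truth` (true loads on both the normalized-abundance and
#'   per-host-cell scales, family membership, TE event labels, variant
#'   densities).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  sim <- simulate_genomes(config)
  depth <- simulate_depth(config, sim)
  te <- simulate_te_families(config)
  vt <- simulate_variant_table(config, sim)
  truth <- list(
    true_abundance = config$symbiont_loads,
    true_load_per_cell = config$symbiont_loads / config$ploidy,
    family_membership = sim$truth$family_membership,
    pair_shared_families = sim$truth$pair_shared_families,
    shared_families = sim$truth$shared_families,
    accessory_families = sim$truth$accessory_families,
    confounded_pair = sim$truth$confounded_pair,
    te_event_labels = te$truth$te_event_labels,
    degraded_copies = te$truth$degraded_copies,
    true_variant_density = vt$truth)
  list(config = config, genomes = sim$genomes, features = sim$features,
       depth = depth, te = te, variants = vt$variants, truth = truth)
}

#' Write a simulated dataset to disk in the pipeline's exchange formats
#'
#' Emits genome FASTA, GFF3 + protein FASTA per genome, depth TSV, TE
#' protein FASTA, variant TSV, and the truth table as JSON.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$genomes, file.path(dir, "genomes.fna"))
  feats <- dataset$features
  write_gff3(feats[, setdiff(names(feats), "family_id")],
             file.path(dir, "features.gff3"),
             file.path(dir, "proteins.faa"))
  write_depth_tsv(dataset$depth, file.path(dir, "depth.tsv"))
  write_fasta(dataset$te$proteins[, c("id", "residues")],
              file.path(dir, "te_proteins.faa"))
  utils::write.table(dataset$te$families, file.path(dir, "te_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_variant_tsv(dataset$variants, file.path(dir, "variants.tsv"))
  truth <- dataset$truth
  truth$true_abundance <- as.data.frame(truth$true_abundance)
  truth$true_load_per_cell <- as.data.frame(truth$true_load_per_cell)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
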