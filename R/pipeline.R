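## Orchestration: one configuration object carrying every stage threshold,
## a stage runner producing a run directory with a machine-readable
## manifest, and a one-command synthetic end-to-end demo.

.pipeline_defaults <- function() {
  list(
    input_dir = NULL, output_dir = NULL, seed = 1L,
    stages = c("pangenome", "load", "te_trace", "variants"),
    ploidy = 2L, presence_threshold = 0.01, include_zero_depth = TRUE,
    linkage = "complete",
    evalue_cutoff = 1e-3, min_identity = 35, min_overlap = 80,
    min_protein_length = 100L,
    ani_fragment_length = 1020L, ani_min_identity = 30,
    ani_min_aligned_fraction = 70,
    aai_min_identity = 30, aai_min_coverage = 70,
    recent_threshold = 0.02, support_threshold = 95,
    max_gap_fraction = 0.5, max_entropy = 0.6,
    min_te_genomes = 2L, bootstrap_replicates = 100L,
    min_coverage = 30, excluded_populations = character(),
    marker_feature_id = "EF1a", confounded_pair = c("S1", "S2"))
}

#' Pipeline configuration
#'
#' All stage thresholds with their module defaults. Unknown keys are
#' rejected with the list of valid keys. The object round-trips losslessly
#' through JSON via [save_pipeline_config()] / [load_pipeline_config()].
#'
#' @param input_dir Directory holding the exchange files (see
#'   [write_dataset()] for the layout).
#' @param output_dir Run directory for stage outputs and the manifest.
#' @param ... Overrides of the default keys.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, ...) {
  cfg <- .pipeline_defaults()
  cfg$input_dir <- input_dir
  cfg$output_dir <- output_dir
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(names(cfg), collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
save_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config,
          c(list(input_dir = raw$input_dir, output_dir = raw$output_dir),
            raw[setdiff(names(raw), c("input_dir", "output_dir"))]))
}

.stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the analysis pipeline on an input directory
#'
#' Stages run in dependency order (pangenome before load, which needs the
#' accessory gene sets of the confounded pair). Results are written under
#' `config$output_dir`, and a manifest records the package version, seed,
#' every threshold, and an MD5 hash per output file.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ind <- config$input_dir
  outd <- config$output_dir
  dir.create(outd, showWarnings = FALSE, recursive = TRUE)
  need <- function(f) {
    p <- file.path(ind, f)
    if (!file.exists(p)) stop("missing input '", f, "' in ", ind)
    p
  }
  genomes <- read_fasta(need("genomes.fna"))
  features <- read_gff3(need("features.gff3"), need("proteins.faa"),
                        genome_id = "combined")
  features$genome_id <- features$contig_id
  features$genome_id[features$contig_id == "host_marker"] <- "host"
  glens <- stats::setNames(nchar(genomes$residues), genomes$id)
  symbionts <- setdiff(genomes$id, "host_marker")
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(outd, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  partition <- NULL
  families <- NULL
  if ("pangenome" %in% config$stages) {
    .stage_log("pangenome", "clustering proteins into ortholog families")
    coding <- features[features$feature_class %in% c("CDS", "transposase") &
                         features$genome_id %in% symbionts, , drop = FALSE]
    prots <- data.frame(id = coding$feature_id, residues = coding$protein,
                        genome_id = coding$genome_id,
                        stringsAsFactors = FALSE)
    edges <- all_vs_all_protein_similarity(prots)
    families <- cluster_families(edges, prots,
                                 evalue_cutoff = config$evalue_cutoff,
                                 min_identity = config$min_identity,
                                 min_overlap = config$min_overlap)
    partition <- partition_pangenome(families, prots,
                                     min_protein_length =
                                       config$min_protein_length)
    emit(families, "families.tsv")
    part_df <- rbind(
      data.frame(family_id = partition$shared, genome_id = "shared",
                 stringsAsFactors = FALSE),
      do.call(rbind, lapply(names(partition$accessory), function(g) {
        if (length(partition$accessory[[g]]) == 0L) return(NULL)
        data.frame(family_id = partition$accessory[[g]], genome_id = g,
                   stringsAsFactors = FALSE)
      })))
    emit(part_df, "pangenome_partition.tsv")
  }

  if ("load" %in% config$stages) {
    .stage_log("load", "estimating per-sample symbiont loads")
    if (is.null(partition)) stop("stage 'load' needs stage 'pangenome' ",
                                 "(accessory gene sets of the confounded pair)")
    tracks <- read_depth_tsv(file.path(ind, "depth.tsv"), glens)
    marker <- features[features$feature_id == config$marker_feature_id, ,
                       drop = FALSE]
    if (nrow(marker) != 1L) stop("host marker feature '",
                                 config$marker_feature_id, "' not found")
    pair <- intersect(config$confounded_pair, symbionts)
    cps <- list()
    if (length(pair) == 2L) {
      acc <- lapply(pair, function(g) {
        fams <- partition$accessory[[g]]
        ids <- families$protein_id[families$family_id %in% fams &
                                     families$genome_id == g]
        features[features$feature_id %in% ids, , drop = FALSE]
      })
      names(acc) <- pair
      cps <- list(list(genomes = pair, accessory = acc))
    }
    lc <- load_config(ploidy = config$ploidy, host_marker = marker,
                      confounded_pairs = cps,
                      presence_threshold = config$presence_threshold,
                      include_zero_depth = config$include_zero_depth)
    profiles <- build_load_profiles(tracks, lc)
    emit(profiles, "load_profiles.tsv")
    hc <- cluster_samples(profiles, method = config$linkage)
    writeLines(write_newick(ape::as.phylo(hc)),
               file.path(outd, "sample_dendrogram.nwk"))
    outputs <- c(outputs, file.path(outd, "sample_dendrogram.nwk"))
    co <- coinfection_summary(profiles)
    jsonlite::write_json(co, file.path(outd, "coinfection.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(outd, "coinfection.json"))
  }

  if ("te_trace" %in% config$stages) {
    .stage_log("te_trace", "classifying shared transposase families")
    te_fam <- utils::read.delim(need("te_families.tsv"),
                                stringsAsFactors = FALSE)
    te_prot <- read_fasta(need("te_proteins.faa"))
    te_feats <- data.frame(feature_id = te_fam$protein_id,
                           feature_class = "transposase",
                           stringsAsFactors = FALSE)
    shared <- find_shared_te_families(te_fam, te_feats,
                                      min_genomes = config$min_te_genomes)
    seqs_all <- stats::setNames(te_prot$residues, te_prot$id)
    rows <- list()
    trees <- character()
    for (fam in unique(shared$family_id)) {
      mem <- shared[shared$family_id == fam, , drop = FALSE]
      res <- classify_te_family(
        seqs_all[mem$protein_id],
        stats::setNames(mem$genome_id, mem$protein_id),
        n_replicates = config$bootstrap_replicates, seed = config$seed,
        recent_threshold = config$recent_threshold,
        support_threshold = config$support_threshold,
        max_gap_fraction = config$max_gap_fraction,
        max_entropy = config$max_entropy)
      if (res$untestable) {
        rows[[fam]] <- data.frame(family_id = fam, genome_a = NA,
                                  genome_b = NA,
                                  classification = "untestable",
                                  min_cross_genome_patristic = NA,
                                  sister_support = NA,
                                  stringsAsFactors = FALSE)
      } else {
        cl <- res$calls
        cl$family_id <- fam
        rows[[fam]] <- cl[, c("family_id", "genome_a", "genome_b",
                              "classification",
                              "min_cross_genome_patristic",
                              "sister_support")]
        trees <- c(trees, paste0(fam, " ", write_newick(res$tree)))
      }
    }
    emit(do.call(rbind, rows), "te_transfer_calls.tsv")
    writeLines(trees, file.path(outd, "te_trees.nwk"))
    outputs <- c(outputs, file.path(outd, "te_trees.nwk"))
  }

  if ("variants" %in% config$stages) {
    .stage_log("variants", "summarizing fixed-variant densities")
    variants <- read_variant_tsv(need("variants.tsv"))
    tracks <- read_depth_tsv(file.path(ind, "depth.tsv"), glens)
    gates <- gate_samples(tracks, min_coverage = config$min_coverage,
                          excluded_populations =
                            config$excluded_populations)
    vs <- variant_summary_table(variants, features, glens, gates = gates)
    emit(vs$table, "variant_summary.tsv")
  }

  manifest <- list(
    package = "symbiocensus",
    version = as.character(utils::packageVersion("symbiocensus")),
    seed = config$seed,
    thresholds = unclass(config)[setdiff(names(unclass(config)),
                                         c("input_dir", "output_dir"))],
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' One-command synthetic end-to-end demo
#'
#' Simulates a dataset, writes it in the exchange formats, runs the full
#' pipeline on it, and checks the stage outputs against the simulator's
#' truth table (load recovery, TE classification, variant density).
#'
#' @param dir Working directory (inputs under `dir/input`, results under
#'   `dir/run`).
#' @param seed Root seed.
#' @return List with the manifest and the recovery checks.
#' @export
run_demo <- function(dir = tempfile("symbiocensus_demo"), seed = 1L) {
  ds <- simulate_dataset(simulation_config(seed = seed))
  ind <- file.path(dir, "input")
  write_dataset(ds, ind)
  cfg <- pipeline_config(ind, file.path(dir, "run"), seed = seed)
  manifest <- run_pipeline(cfg)
  profiles <- utils::read.delim(file.path(dir, "run", "load_profiles.tsv"),
                                stringsAsFactors = FALSE)
  truth_load <- ds$truth$true_load_per_cell
  err <- vapply(seq_len(nrow(profiles)), function(i) {
    tl <- truth_load[profiles$sample_id[i], profiles$symbiont[i]]
    if (tl == 0) return(abs(profiles$load_per_host_cell[i]))
    abs(profiles$load_per_host_cell[i] - tl) / tl
  }, numeric(1))
  calls <- utils::read.delim(file.path(dir, "run", "te_transfer_calls.tsv"),
                             stringsAsFactors = FALSE)
  lab <- ds$truth$te_event_labels[calls$family_id]
  agree <- mean((calls$classification == "recent" & lab == "recent") |
                  (calls$classification == "ancient_sister" &
                     lab == "ancient"))
  vsum <- utils::read.delim(file.path(dir, "run", "variant_summary.tsv"),
                            stringsAsFactors = FALSE)
  vt <- ds$truth$true_variant_density
  key <- paste(vt$sample_id, vt$genome_id)
  dens_err <- max(abs(vsum$mutations_per_kb -
                        vt$true_density[match(paste(vsum$sample_id,
                                                    vsum$genome_id), key)]))
  checks <- list(load_mean_rel_error = mean(err),
                 te_shared_family_agreement = agree,
                 variant_density_max_abs_error = dens_err)
  list(manifest = manifest, checks = checks, dir = dir)
}
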