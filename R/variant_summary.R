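## Downstream variant filtering and summaries: coverage gating, exclusion
## of non-fixed variants and of variants in transposases/introns, and
## mutations/kb with variant-type composition. A toy pileup caller lets the
## synthetic data exercise the filters end to end.

#' Read / write the variant TSV dialect
#'
#' Columns: `sample_id`, `genome_id`, `position`, `variant_type`,
#' `frequency` — a deliberate simplification of a full variant caller's
#' output carrying exactly the fields the downstream filters need.
#'
#' @param path TSV path.
#' @return Data.frame of variant records.
#' @export
read_variant_tsv <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "genome_id", "position", "variant_type",
                  "frequency") %in% names(v)))
  stopifnot(all(v$frequency > 0), all(v$frequency <= 1))
  v
}

#' @rdname read_variant_tsv
#' @param variants Variant record table.
#' @export
write_variant_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Annotate variants with the feature class they overlap
#'
#' Overlap is computed on 1-based inclusive intervals; the excluded classes
#' (transposase, intron) take precedence over plain CDS when features
#' overlap.
#'
#' @param variants Variant table.
#' @param features Feature table.
#' @return `variants` with an `overlapping_feature_class` column
#'   (`none` when no feature covers the position).
#' @export
annotate_variant_features <- function(variants, features) {
  prio <- c(transposase = 1L, intron = 2L, CDS = 3L, other = 4L)
  cls <- character(nrow(variants))
  for (g in unique(variants$genome_id)) {
    fs <- features[features$genome_id == g, , drop = FALSE]
    vsel <- which(variants$genome_id == g)
    for (i in vsel) {
      pos <- variants$position[i]
      hit <- fs$feature_class[fs$start <= pos & fs$end >= pos]
      cls[i] <- if (length(hit) == 0L) {
        "none"
      } else {
        hit[order(prio[hit])][1L]
      }
    }
  }
  variants$overlapping_feature_class <- cls
  variants
}

#' Gate samples on coverage and population
#'
#' A sample x genome cell is included iff its median depth is at least
#' `min_coverage` and the sample's population is not excluded (e.g. the
#' population the reference genomes were assembled from).
#'
#' @param tracks List of [depth_track()] objects.
#' @param populations Named character vector: sample id -> population.
#' @param min_coverage Median-depth floor.
#' @param excluded_populations Populations removed outright.
#' @return Data.frame: `sample_id`, `genome_id`, `median_depth`, `included`.
#' @export
gate_samples <- function(tracks, populations = NULL, min_coverage = 30,
                         excluded_populations = character()) {
  rows <- lapply(tracks, function(tr) {
    med <- median_genome_coverage(tr)
    pop <- if (!is.null(populations)) populations[[tr$sample_id]] else NA
    data.frame(sample_id = tr$sample_id, genome_id = tr$reference_id,
               median_depth = med,
               included = med >= min_coverage &&
                 !(isTRUE(pop %in% excluded_populations)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep fixed variants outside transposases and introns
#'
#' Variants at frequency below 1 (within 1e-9) are removed, as are variants
#' overlapping transposase or intron features.
#'
#' @param variants Variant table (annotated with
#'   [annotate_variant_features()] if `features` is `NULL`).
#' @param features Optional feature table used to annotate on the fly.
#' @return The kept variant records.
#' @export
filter_variants <- function(variants, features = NULL) {
  if (!("overlapping_feature_class" %in% names(variants))) {
    if (is.null(features)) {
      stop("variants lack overlapping_feature_class and no features given")
    }
    variants <- annotate_variant_features(variants, features)
  }
  keep <- abs(variants$frequency - 1) <= 1e-9 &
    !(variants$overlapping_feature_class %in% c("transposase", "intron"))
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutation density and variant-type composition
#'
#' @param kept Kept variant records for one sample x genome.
#' @param genome_length Genome length in bp.
#' @return List: `n_variants_kept`, `mutations_per_kb`, `type_proportions`.
#' @export
summarize_variants <- function(kept, genome_length) {
  stopifnot(genome_length > 0)
  n <- nrow(kept)
  props <- if (n > 0L) {
    tab <- table(kept$variant_type)
    stats::setNames(as.numeric(tab) / n, names(tab))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  list(n_variants_kept = n,
       mutations_per_kb = n / (genome_length / 1000),
       type_proportions = props)
}

#' Per-sample and per-genome variant summary table
#'
#' Applies the fixed-variant and feature filters per sample x genome, the
#' coverage/population gate, and reports the density averaged both over
#' sample x genome cells and over samples.
#'
#' @param variants Variant table.
#' @param features Feature table.
#' @param genome_lengths Named vector of genome lengths.
#' @param gates Optional output of [gate_samples()].
#' @return List with `table` (one row per sample x genome) and `averages`
#'   (`mean_over_cells`, `mean_over_samples` per genome).
#' @export
variant_summary_table <- function(variants, features, genome_lengths,
                                  gates = NULL) {
  variants <- annotate_variant_features(variants, features)
  combos <- unique(variants[, c("sample_id", "genome_id")])
  rows <- list()
  for (r in seq_len(nrow(combos))) {
    s <- combos$sample_id[r]; g <- combos$genome_id[r]
    included <- TRUE
    if (!is.null(gates)) {
      hit <- gates$included[gates$sample_id == s & gates$genome_id == g]
      included <- length(hit) > 0L && hit[1L]
    }
    sel <- variants[variants$sample_id == s & variants$genome_id == g, ,
                    drop = FALSE]
    kept <- filter_variants(sel)
    sm <- summarize_variants(kept, genome_lengths[[g]])
    rows[[r]] <- data.frame(sample_id = s, genome_id = g,
                            n_variants_kept = sm$n_variants_kept,
                            mutations_per_kb = sm$mutations_per_kb,
                            sample_included = included,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  inc <- tab[tab$sample_included, , drop = FALSE]
  averages <- lapply(split(inc, inc$genome_id), function(d) {
    list(mean_over_cells = mean(d$mutations_per_kb),
         mean_over_samples = mean(tapply(d$mutations_per_kb, d$sample_id,
                                         mean)))
  })
  list(table = tab, averages = averages)
}

#' Toy pileup caller for synthetic base counts
#'
#' Calls a fixed SNP wherever the alternate-allele fraction and depth clear
#' their floors; the reported frequency is the alternate fraction. Stands
#' in for an external variant caller so the synthetic data can exercise the
#' downstream filters end to end.
#'
#' @param base_counts List with `sample_id`, `genome_id`, `depth`,
#'   `alt_count` (per-position integer vectors), as produced by
#'   [simulate_base_counts()].
#' @param min_alt_fraction Alternate-fraction floor for a call.
#' @param min_depth Depth floor for a call.
#' @return Variant record table (type `SNP`).
#' @export
toy_pileup_caller <- function(base_counts, min_alt_fraction = 0.95,
                              min_depth = 10L) {
  depth <- base_counts$depth
  alt <- base_counts$alt_count
  frac <- ifelse(depth > 0L, alt / depth, 0)
  hit <- which(depth >= min_depth & frac >= min_alt_fraction)
  data.frame(sample_id = rep(base_counts$sample_id, length(hit)),
             genome_id = rep(base_counts$genome_id, length(hit)),
             position = hit,
             variant_type = rep("SNP", length(hit)),
             frequency = frac[hit],
             stringsAsFactors = FALSE)
}
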