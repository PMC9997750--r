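## Symbiont load estimation: median symbiont depth normalized by the mean
## depth of a single-copy host marker gene, divided by host ploidy, with an
## accessory-gene restriction for confounded near-identical strain pairs.

region_positions <- function(track_length, regions) {
  stopifnot(nrow(regions) > 0L)
  if (any(regions$end > track_length | regions$start < 1L)) {
    stop("region outside the reference (length ", track_length, ")")
  }
  pos <- unique(unlist(mapply(seq, regions$start, regions$end,
                              SIMPLIFY = FALSE)))
  if (length(pos) == 0L) stop("empty region union")
  pos
}

#' Median genome coverage for one sample
#'
#' Median per-base depth over the whole genome, or over the union of the
#' given regions. Zero-depth positions are included by default (medians are
#' taken across the whole genome); even position counts use the mean of the
#' two central values.
#'
#' @param track A [depth_track()].
#' @param regions Optional gene-feature table restricting the positions.
#' @param include_zero_depth Include zero-depth positions in the median?
#' @return The median depth (numeric scalar).
#' @export
median_genome_coverage <- function(track, regions = NULL,
                                   include_zero_depth = TRUE) {
  d <- track$depth
  if (!is.null(regions)) {
    d <- d[region_positions(length(d), regions)]
  }
  if (!include_zero_depth) {
    d <- d[d > 0L]
    if (length(d) == 0L) return(0)
  }
  stats::median(d)
}

#' Mean coverage of the host marker gene
#'
#' @param track Host marker [depth_track()].
#' @param marker Single-row feature table for the marker gene.
#' @return Arithmetic mean depth over the marker interval.
#' @export
host_marker_mean_coverage <- function(track, marker) {
  stopifnot(nrow(marker) == 1L)
  pos <- region_positions(length(track$depth), marker)
  mean(track$depth[pos])
}

#' Normalized abundance and per-host-cell load
#'
#' Normalized abundance is the symbiont median coverage divided by the host
#' marker mean coverage; the per-host-cell load divides that by the host
#' chromosome number.
#'
#' @param median_cov Symbiont median coverage.
#' @param host_marker_mean Host marker mean coverage (> 0).
#' @param ploidy Host chromosome number.
#' @return List with `normalized_abundance` and `load_per_host_cell`.
#' @export
symbiont_load <- function(median_cov, host_marker_mean, ploidy = 2L) {
  if (host_marker_mean <= 0) {
    stop("host marker mean coverage is not positive; sample unusable")
  }
  stopifnot(ploidy >= 1L)
  ab <- median_cov / host_marker_mean
  list(normalized_abundance = ab, load_per_host_cell = ab / ploidy)
}

#' Accessory-restricted median coverage for a confounded strain pair
#'
#' For near-identical sister strains, reads cross-map on shared genes and
#' inflate whole-genome coverage; the median is therefore taken over the
#' strain's accessory genes only.
#'
#' @param track A [depth_track()] for one pair member.
#' @param accessory_genes Feature table of that genome's accessory genes.
#' @param include_zero_depth Include zero-depth positions?
#' @return Median depth over accessory-gene positions.
#' @export
accessory_restricted_coverage <- function(track, accessory_genes,
                                          include_zero_depth = TRUE) {
  if (is.null(accessory_genes) || nrow(accessory_genes) == 0L) {
    stop("empty accessory gene set: whole-genome coverage is not a ",
         "permitted fallback for a confounded strain pair")
  }
  median_genome_coverage(track, regions = accessory_genes,
                         include_zero_depth = include_zero_depth)
}

#' Load-estimation configuration
#'
#' @param ploidy Host chromosome number (diploid hosts: 2).
#' @param host_marker Single-row feature table locating the host marker on
#'   its reference; its `contig_id` names the marker depth track.
#' @param confounded_pairs List of lists, each with `genomes` (two genome
#'   ids) and `accessory` (named list of per-genome accessory feature
#'   tables).
#' @param presence_threshold Per-host-cell load at or above which a symbiont
#'   is called present.
#' @param include_zero_depth Include zero-depth positions in medians?
#' @return A list of class `load_config`.
#' @export
load_config <- function(ploidy = 2L, host_marker, confounded_pairs = list(),
                        presence_threshold = 0.01,
                        include_zero_depth = TRUE) {
  stopifnot(ploidy >= 1L, presence_threshold >= 0)
  structure(list(ploidy = as.integer(ploidy), host_marker = host_marker,
                 confounded_pairs = confounded_pairs,
                 presence_threshold = presence_threshold,
                 include_zero_depth = include_zero_depth),
            class = "load_config")
}

#' Build per-sample load profiles
#'
#' Applies the accessory restriction to configured confounded pairs and the
#' whole-genome median otherwise, normalizes by the host marker mean, and
#' derives per-host-cell loads, relative abundances, and presence calls.
#'
#' @param tracks List of [depth_track()] objects: per sample, one track per
#'   symbiont genome plus the host marker track.
#' @param config A [load_config()].
#' @return Data.frame with one row per (sample, symbiont): `sample_id`,
#'   `symbiont`, `median_cov`, `normalized_abundance`, `load_per_host_cell`,
#'   `relative_abundance`, `present`.
#' @export
build_load_profiles <- function(tracks, config) {
  stopifnot(inherits(config, "load_config"))
  marker_ref <- config$host_marker$contig_id[1L]
  samples <- unique(vapply(tracks, `[[`, character(1), "sample_id"))
  refs <- unique(vapply(tracks, `[[`, character(1), "reference_id"))
  symbionts <- setdiff(refs, marker_ref)
  acc_of <- list()
  for (cp in config$confounded_pairs) {
    for (g in cp$genomes) acc_of[[g]] <- cp$accessory[[g]]
  }
  find_track <- function(s, ref) {
    for (tr in tracks) {
      if (tr$sample_id == s && tr$reference_id == ref) return(tr)
    }
    NULL
  }
  rows <- list()
  for (s in samples) {
    mt <- find_track(s, marker_ref)
    if (is.null(mt)) stop("missing host marker track for sample ", s)
    marker_mean <- host_marker_mean_coverage(mt, config$host_marker)
    for (g in symbionts) {
      tr <- find_track(s, g)
      if (is.null(tr)) stop("missing depth track for sample ", s,
                            ", genome ", g)
      med <- if (g %in% names(acc_of)) {
        accessory_restricted_coverage(tr, acc_of[[g]],
                                      config$include_zero_depth)
      } else {
        median_genome_coverage(tr,
                               include_zero_depth = config$include_zero_depth)
      }
      ld <- symbiont_load(med, marker_mean, config$ploidy)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, symbiont = g, median_cov = med,
        normalized_abundance = ld$normalized_abundance,
        load_per_host_cell = ld$load_per_host_cell,
        stringsAsFactors = FALSE)
    }
  }
  prof <- do.call(rbind, rows)
  prof$present <- prof$load_per_host_cell >= config$presence_threshold
  prof$relative_abundance <- 0
  for (s in unique(prof$sample_id)) {
    sel <- prof$sample_id == s
    tot <- sum(prof$load_per_host_cell[sel])
    if (tot > 0) {
      prof$relative_abundance[sel] <- prof$load_per_host_cell[sel] / tot
    }
  }
  prof[, c("sample_id", "symbiont", "median_cov", "normalized_abundance",
           "load_per_host_cell", "relative_abundance", "present")]
}

#' Hierarchically cluster samples by their abundance vectors
#'
#' Agglomerative clustering on the Euclidean distance matrix between
#' per-sample abundance vectors (complete linkage by default).
#'
#' @param profiles Output of [build_load_profiles()], or a numeric matrix of
#'   samples x symbionts.
#' @param value Profile column to cluster on.
#' @param method Linkage passed to [stats::hclust()].
#' @return An `hclust` object over the samples.
#' @export
cluster_samples <- function(profiles, value = "load_per_host_cell",
                            method = "complete") {
  m <- if (is.matrix(profiles)) {
    profiles
  } else {
    stats::xtabs(stats::reformulate(c("sample_id", "symbiont"), value),
                 data = profiles)
  }
  if (nrow(m) < 2L) stop("need at least 2 samples to cluster")
  stats::hclust(stats::dist(m, method = "euclidean"), method = method)
}

#' Co-infection summary
#'
#' Counts symbionts called present per sample and the number of samples
#' carrying at least 2 and at least 3 symbionts.
#'
#' @param profiles Output of [build_load_profiles()].
#' @return List with `per_sample` (named counts) and `cohort`
#'   (`n_at_least_2`, `n_at_least_3`).
#' @export
coinfection_summary <- function(profiles) {
  per_sample <- tapply(profiles$present, profiles$sample_id, sum)
  per_sample <- stats::setNames(as.integer(per_sample), names(per_sample))
  list(per_sample = per_sample,
       cohort = list(n_at_least_2 = sum(per_sample >= 2L),
                     n_at_least_3 = sum(per_sample >= 3L)))
}
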