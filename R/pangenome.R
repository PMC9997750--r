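## Ortholog-family clustering over an all-against-all protein similarity
## graph (single linkage = connected components), core/accessory pangenome
## partition with the ghost-CDS length filter, accessory COG summaries, and
## fragment-based ANI / reciprocal-best-hit AAI species delimitation.
## Similarity searches run through NCBI BLAST+ (blastp/blastn).

.blast_exe <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) {
    stop("'", name, "' not found on PATH; NCBI BLAST+ is required ",
         "(see SystemRequirements)")
  }
  path
}

.as_seq_df <- function(x, what = "sequence") {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "residues") %in% names(x)))
    return(x)
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0(what, seq_along(x))
    return(data.frame(id = ids, residues = unname(x),
                      stringsAsFactors = FALSE))
  }
  stop("expected a sequence data.frame or named character vector")
}

.check_aa <- function(proteins) {
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYXBZJUO*]+$", proteins$residues)
  if (!all(ok)) {
    stop("non-amino-acid characters in protein(s): ",
         paste(proteins$id[!ok], collapse = ", "))
  }
  invisible(proteins)
}

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "qlen", "slen",
                 "bitscore", "evalue")

.run_blast <- function(prog, query_df, subject_df, dbtype, extra = character()) {
  wd <- tempfile("blast")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  qf <- file.path(wd, "query.fa")
  sf <- file.path(wd, "subject.fa")
  write_fasta(query_df, qf)
  write_fasta(subject_df, sf)
  db <- file.path(wd, "db")
  out <- file.path(wd, "hits.tsv")
  status <- system2(.blast_exe("makeblastdb"),
                    c("-in", sf, "-dbtype", dbtype, "-out", db),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("makeblastdb failed")
  args <- c("-query", qf, "-db", db, "-out", out,
            "-outfmt", shQuote(paste("6", paste(.blast_cols, collapse = " "))),
            "-num_threads", "1", extra)
  status <- system2(.blast_exe(prog), args, stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop(prog, " failed")
  if (file.info(out)$size == 0) {
    hits <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.blast_cols)), .blast_cols))
  } else {
    hits <- utils::read.delim(out, header = FALSE, stringsAsFactors = FALSE)
    names(hits) <- .blast_cols
  }
  hits
}

.best_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$qseqid), , drop = FALSE]
}

#' All-against-all protein similarity edges
#'
#' Runs a blastp all-against-all search and reports one undirected edge per
#' protein pair with a local alignment, keeping the better-scoring of the
#' two directions. Coverages are the aligned fraction of each protein.
#'
#' @param proteins Protein table (`id`, `residues`, optionally `genome_id`)
#'   or named character vector.
#' @param evalue_max E-value ceiling for reporting edges (filtering to the
#'   clustering threshold happens in [cluster_families()]).
#' @param max_proteins Safety guard: refuse larger inputs unless raised.
#' @return Data.frame of edges: `query_id`, `subject_id` (lexicographically
#'   ordered), `identity`, `query_coverage`, `subject_coverage`, `score`,
#'   `evalue_proxy`.
#' @export
all_vs_all_protein_similarity <- function(proteins, evalue_max = 10,
                                          max_proteins = 5000L) {
  proteins <- .as_seq_df(proteins, "prot")
  stopifnot(nrow(proteins) >= 2L)
  if (nrow(proteins) > max_proteins) {
    stop("refusing all-against-all on ", nrow(proteins),
         " proteins; raise max_proteins to override")
  }
  .check_aa(proteins)
  hits <- .run_blast("blastp", proteins, proteins, "prot",
                     c("-evalue", format(evalue_max), "-seg", "no",
                       "-max_target_seqs", "10000"))
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      identity = numeric(), query_coverage = numeric(),
                      subject_coverage = numeric(), score = numeric(),
                      evalue_proxy = numeric(), stringsAsFactors = FALSE))
  }
  ## best HSP per directed pair, then best direction per unordered pair
  key_dir <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  hits <- hits[order(key_dir, -hits$bitscore), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$qseqid, hits$sseqid, sep = "\r")), ,
               drop = FALSE]
  a <- pmin(hits$qseqid, hits$sseqid)
  b <- pmax(hits$qseqid, hits$sseqid)
  key <- paste(a, b, sep = "\r")
  hits <- hits[order(key, -hits$bitscore), , drop = FALSE]
  keep <- !duplicated(paste(pmin(hits$qseqid, hits$sseqid),
                            pmax(hits$qseqid, hits$sseqid), sep = "\r"))
  hits <- hits[keep, , drop = FALSE]
  flip <- hits$qseqid > hits$sseqid
  edges <- data.frame(
    query_id = ifelse(flip, hits$sseqid, hits$qseqid),
    subject_id = ifelse(flip, hits$qseqid, hits$sseqid),
    identity = hits$pident,
    query_coverage = 100 * hits$length /
      ifelse(flip, hits$slen, hits$qlen),
    subject_coverage = 100 * hits$length /
      ifelse(flip, hits$qlen, hits$slen),
    score = hits$bitscore,
    evalue_proxy = hits$evalue,
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  edges
}

#' Single-linkage ortholog families from a similarity graph
#'
#' Families are the connected components of the graph whose edges pass the
#' e-value, identity and overlap thresholds; isolated proteins become
#' singleton families. Family ids are the lexicographically smallest member
#' id, so output is deterministic and invariant to edge order.
#'
#' @param edges Edge table from [all_vs_all_protein_similarity()].
#' @param proteins Protein table (defines the vertex set and genome labels).
#' @param evalue_cutoff Edges must have e-value strictly below this.
#' @param min_identity Minimum percent identity.
#' @param min_overlap Minimum percent coverage of both proteins.
#' @return Data.frame: `family_id`, `protein_id`, `genome_id`.
#' @export
cluster_families <- function(edges, proteins, evalue_cutoff = 1e-3,
                             min_identity = 35, min_overlap = 80) {
  proteins <- .as_seq_df(proteins, "prot")
  pass <- edges$evalue_proxy < evalue_cutoff &
    edges$identity >= min_identity &
    pmin(edges$query_coverage, edges$subject_coverage) >= min_overlap
  g <- igraph::graph_from_data_frame(
    edges[pass, c("query_id", "subject_id"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = proteins$id))
  comp <- igraph::components(g)$membership
  fam_name <- tapply(names(comp), comp, function(ids) min(ids))
  out <- data.frame(
    family_id = unname(fam_name[as.character(comp[proteins$id])]),
    protein_id = proteins$id,
    genome_id = if ("genome_id" %in% names(proteins)) {
      proteins$genome_id
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE)
  out[order(out$family_id, out$protein_id), ]
}

#' Partition a pangenome into shared and accessory families
#'
#' Proteins shorter than `min_protein_length` (ghost CDS and transposase
#' remnants) are removed first; a family is accessory to a genome iff all
#' its remaining members belong to that genome, and shared iff its remaining
#' members span at least two genomes.
#'
#' @param families Family table from [cluster_families()].
#' @param proteins Protein table providing lengths (`residues` or a
#'   `protein_length` column).
#' @param min_protein_length Length filter in amino acids.
#' @return List with `shared` (family ids), `accessory` (named list of
#'   family ids per genome), `families_kept` (filtered family table) and
#'   `n_families_kept`.
#' @export
partition_pangenome <- function(families, proteins,
                                min_protein_length = 100L) {
  proteins <- if (is.data.frame(proteins) &&
                  "protein_length" %in% names(proteins)) {
    proteins
  } else {
    p <- .as_seq_df(proteins, "prot")
    p$protein_length <- nchar(p$residues)
    p
  }
  genomes <- unique(families$genome_id)
  stopifnot(length(genomes) >= 2L)
  len <- stats::setNames(proteins$protein_length, proteins$id)
  keep <- len[families$protein_id] >= min_protein_length
  kept <- families[keep, , drop = FALSE]
  gone <- setdiff(genomes, unique(kept$genome_id))
  if (length(gone) > 0L) {
    warning("genome(s) with no proteins left after the length filter: ",
            paste(gone, collapse = ", "))
  }
  by_fam <- split(kept$genome_id, kept$family_id)
  n_gen <- vapply(by_fam, function(x) length(unique(x)), integer(1))
  shared <- names(by_fam)[n_gen >= 2L]
  accessory <- lapply(genomes, function(g) {
    names(by_fam)[n_gen == 1L &
                    vapply(by_fam, function(x) x[1L] == g, logical(1))]
  })
  names(accessory) <- genomes
  list(shared = shared, accessory = accessory, families_kept = kept,
       n_families_kept = length(by_fam))
}

#' Summarize accessory gene content by COG category
#'
#' Counts accessory families per genome by unambiguous single-letter COG
#' category; families whose only annotations are multi-letter (ambiguous)
#' are excluded, unannotated families are counted as "de novo OGs", and
#' categories with count <= 2 are pooled into "Other categories".
#'
#' @param partition Output of [partition_pangenome()].
#' @param annotations Data.frame `protein_id`, `category` (may be partial).
#' @return Named list per genome of named integer count vectors.
#' @export
summarize_accessory_cog <- function(partition, annotations) {
  cat_of <- stats::setNames(annotations$category, annotations$protein_id)
  fams <- partition$families_kept
  out <- list()
  for (g in names(partition$accessory)) {
    counts <- integer()
    n_denovo <- 0L
    for (fam in partition$accessory[[g]]) {
      members <- fams$protein_id[fams$family_id == fam]
      cats <- cat_of[members]
      cats <- cats[!is.na(cats) & nzchar(cats)]
      if (length(cats) == 0L) {
        n_denovo <- n_denovo + 1L
        next
      }
      unambig <- cats[nchar(cats) == 1L]
      if (length(unambig) == 0L) next   # only ambiguous annotations
      cat1 <- names(sort(table(unambig), decreasing = TRUE))[1L]
      counts[cat1] <- (if (cat1 %in% names(counts)) counts[[cat1]] else 0L) + 1L
    }
    pooled <- integer()
    other <- 0L
    for (nm in sort(names(counts))) {
      if (counts[[nm]] > 2L) pooled[nm] <- counts[[nm]] else {
        other <- other + counts[[nm]]
      }
    }
    if (other > 0L) pooled[["Other categories"]] <- other
    if (n_denovo > 0L) pooled[["de novo OGs"]] <- n_denovo
    out[[g]] <- pooled
  }
  out
}

#' Fragment-based average nucleotide identity (ANI)
#'
#' The query genome is cut into consecutive fragments which are aligned
#' locally against the subject genome; fragments aligned at or above the
#' identity cutoff over at least the given fraction of their length are
#' kept, and one-way ANI is their mean identity. The reported ANI is the
#' mean of the two one-way values; it is `NA` when no fragment passes.
#'
#' @param genome_a,genome_b Genome sequences (single-row sequence table,
#'   named character, or plain string).
#' @param fragment_length Fragment size in bp.
#' @param min_identity Minimum percent identity per fragment.
#' @param min_aligned_fraction Minimum aligned percent of fragment length.
#' @return List: `genome_pair`, `ani`, `ani_fragments_used`.
#' @export
ani <- function(genome_a, genome_b, fragment_length = 1020L,
                min_identity = 30, min_aligned_fraction = 70) {
  a <- .as_seq_df(genome_a, "genomeA")[1L, ]
  b <- .as_seq_df(genome_b, "genomeB")[1L, ]
  one_way <- function(q, s) {
    L <- nchar(q$residues)
    if (L < fragment_length) {
      stop("genome ", q$id, " is shorter than one fragment (",
           fragment_length, " bp)")
    }
    starts <- seq(1L, L - fragment_length + 1L, by = fragment_length)
    frags <- data.frame(
      id = paste0("frag", starts),
      residues = substring(q$residues, starts, starts + fragment_length - 1L),
      stringsAsFactors = FALSE)
    hits <- .run_blast("blastn", frags, s, "nucl",
                       c("-task", "blastn", "-evalue", "1e-15",
                         "-dust", "no", "-xdrop_gap", "150",
                         "-penalty", "-1", "-reward", "1",
                         "-gapopen", "5", "-gapextend", "2",
                         "-max_target_seqs", "5"))
    best <- .best_per_query(hits)
    keep <- best$pident >= min_identity &
      best$length >= (min_aligned_fraction / 100) * fragment_length
    list(ani = if (any(keep)) mean(best$pident[keep]) else NA_real_,
         n = sum(keep))
  }
  ab <- one_way(a, b)
  ba <- one_way(b, a)
  val <- mean(c(ab$ani, ba$ani))   # NA if either direction is undefined
  list(genome_pair = c(a$id, b$id), ani = unname(val),
       ani_fragments_used = ab$n + ba$n)
}

#' Reciprocal-best-hit average amino acid identity (AAI)
#'
#' Best blastp hits in both directions are intersected into reciprocal best
#' hit (RBH) pairs, filtered by identity and coverage, and AAI is the
#' unweighted mean identity over the pairs (averaging the two directions of
#' each pair). Undefined (`NA`) with fewer than `min_orthologs` RBH pairs.
#'
#' @param proteome_a,proteome_b Protein tables.
#' @param min_identity Minimum percent identity per RBH pair.
#' @param min_coverage Minimum percent query coverage in each direction.
#' @param min_orthologs Minimum RBH pairs for a defined AAI.
#' @return List: `aai`, `aai_orthologs_used`.
#' @export
aai <- function(proteome_a, proteome_b, min_identity = 30,
                min_coverage = 70, min_orthologs = 10L) {
  a <- .check_aa(.as_seq_df(proteome_a, "protA"))
  b <- .check_aa(.as_seq_df(proteome_b, "protB"))
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty proteome")
  opts <- c("-evalue", "1e-5", "-seg", "no", "-max_target_seqs", "50")
  fwd <- .best_per_query(.run_blast("blastp", a, b, "prot", opts))
  rev <- .best_per_query(.run_blast("blastp", b, a, "prot", opts))
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    return(list(aai = NA_real_, aai_orthologs_used = 0L))
  }
  rev_best <- stats::setNames(rev$qseqid, rev$sseqid)
  fwd$rbh <- !is.na(rev_best[fwd$qseqid]) &
    rev_best[fwd$qseqid] == fwd$sseqid
  pairs <- fwd[fwd$rbh, , drop = FALSE]
  if (nrow(pairs) > 0L) {
    rk <- paste(pairs$sseqid, pairs$qseqid, sep = "\r")
    rev_key <- paste(rev$qseqid, rev$sseqid, sep = "\r")
    ridx <- match(rk, rev_key)
    pident2 <- rev$pident[ridx]
    cov_f <- 100 * pairs$length / pairs$qlen
    cov_r <- 100 * rev$length[ridx] / rev$qlen[ridx]
    ok <- pairs$pident >= min_identity & pident2 >= min_identity &
      cov_f >= min_coverage & cov_r >= min_coverage
    pairs <- pairs[ok, , drop = FALSE]
    pident2 <- pident2[ok]
  }
  if (nrow(pairs) < min_orthologs) {
    return(list(aai = NA_real_, aai_orthologs_used = nrow(pairs)))
  }
  list(aai = mean((pairs$pident + pident2) / 2),
       aai_orthologs_used = nrow(pairs))
}

#' Same-species call from ANI/AAI
#'
#' Two genomes are called the same species iff every defined metric is at
#' or above its threshold (conventionally 95 %).
#'
#' @param identity List with fields `ani` and/or `aai` (either may be `NA`).
#' @param ani_threshold,aai_threshold Percent thresholds.
#' @return Logical scalar.
#' @export
species_call <- function(identity, ani_threshold = 95, aai_threshold = 95) {
  ani_v <- identity$ani
  aai_v <- identity$aai
  if ((is.null(ani_v) || is.na(ani_v)) && (is.null(aai_v) || is.na(aai_v))) {
    stop("both ANI and AAI are undefined; no species call possible")
  }
  ok <- TRUE
  if (!is.null(ani_v) && !is.na(ani_v)) ok <- ok && ani_v >= ani_threshold
  if (!is.null(aai_v) && !is.na(aai_v)) ok <- ok && aai_v >= aai_threshold
  ok
}

#' Full genome-pair identity comparison
#'
#' Convenience wrapper computing ANI, AAI and the species call for one pair.
#'
#' @param genome_a,genome_b Genome sequences.
#' @param proteome_a,proteome_b Protein tables.
#' @param ... Passed to [species_call()].
#' @return An identity-result list with `genome_pair`, `ani`,
#'   `ani_fragments_used`, `aai`, `aai_orthologs_used`, `same_species_call`.
#' @export
compare_genomes <- function(genome_a, genome_b, proteome_a, proteome_b, ...) {
  r_ani <- ani(genome_a, genome_b)
  r_aai <- aai(proteome_a, proteome_b)
  res <- c(r_ani, r_aai)
  res$same_species_call <- species_call(res, ...)
  res
}
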