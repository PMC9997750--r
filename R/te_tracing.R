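## Transposase "contact tracing": shared-family detection, degradation
## filtering, progressive multiple alignment, entropy/gap trimming,
## Poisson-corrected distances, neighbor joining with nonparametric
## bootstrap, and classification of cross-genome sharing as recent transfer
## versus ancient sister-clade co-residence.

.blosum_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$m <- e$BLOSUM62[AA20, AA20]
  }
  .blosum_env$m
}

msa_to_matrix <- function(msa) {
  stopifnot(length(unique(nchar(msa))) == 1L)
  m <- do.call(rbind, strsplit(msa, ""))
  rownames(m) <- names(msa)
  m
}

matrix_to_msa <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Detect transposase families shared across genomes
#'
#' Restricts ortholog families to members annotated as transposases and
#' keeps families whose transposase members span at least `min_genomes`
#' genomes.
#'
#' @param families Family table (`family_id`, `protein_id`, `genome_id`).
#' @param features Feature table supplying `feature_class` per protein.
#' @param min_genomes Minimum number of distinct genomes.
#' @return Family table restricted to shared transposase families.
#' @export
find_shared_te_families <- function(families, features, min_genomes = 2L) {
  cls <- stats::setNames(features$feature_class, features$feature_id)
  te <- families[!is.na(cls[families$protein_id]) &
                   cls[families$protein_id] == "transposase", , drop = FALSE]
  by_fam <- split(te$genome_id, te$family_id)
  shared <- names(by_fam)[vapply(by_fam, function(x) length(unique(x)),
                                 integer(1)) >= min_genomes]
  out <- te[te$family_id %in% shared, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.kmer_set <- function(chars, k = 3L) {
  n <- length(chars)
  if (n < k) return(paste(chars, collapse = ""))
  unique(vapply(seq_len(n - k + 1L),
                function(i) paste(chars[i:(i + k - 1L)], collapse = ""),
                character(1)))
}

.profile_freq <- function(m) {
  ## 20 x ncol frequency matrix; gaps contribute nothing
  f <- matrix(0, nrow = length(AA20), ncol = ncol(m), dimnames = list(AA20))
  for (a in AA20) f[a, ] <- colMeans(m == a)
  f
}

.merge_alignments <- function(ma, mb, gap_open = 11, gap_extend = 1) {
  B <- .blosum62()
  M <- t(.profile_freq(ma)) %*% B %*% .profile_freq(mb)
  path <- nw_profile_path(M, gap_open, gap_extend)
  expand <- function(m, idx) {
    out <- matrix("-", nrow = nrow(m), ncol = length(idx),
                  dimnames = list(rownames(m)))
    nz <- idx > 0L
    out[, nz] <- m[, idx[nz], drop = FALSE]
    out
  }
  rbind(expand(ma, path$a), expand(mb, path$b))
}

#' Progressive multiple sequence alignment
#'
#' Pairwise k-mer distances feed a neighbor-joining guide tree whose
#' postorder drives profile-profile alignment (BLOSUM62, affine gap open
#' 11 / extend 1, terminal gaps free so truncated copies align with clean
#' overhangs). Every input residue is preserved: each output row degaps to
#' its input sequence.
#'
#' @param sequences Named character vector (or sequence table) of two or
#'   more amino-acid sequences.
#' @return Named character vector of equal-length aligned sequences.
#' @export
build_msa <- function(sequences) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$residues, sequences$id)
  }
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences to align")
  chars <- strsplit(toupper(sequences), "")
  rowm <- lapply(seq_len(n), function(i) {
    matrix(chars[[i]], nrow = 1L, dimnames = list(names(sequences)[i]))
  })
  names(rowm) <- names(sequences)
  if (n == 2L) {
    return(matrix_to_msa(.merge_alignments(rowm[[1L]], rowm[[2L]])))
  }
  sets <- lapply(chars, .kmer_set)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      D[i, j] <- D[j, i] <-
        1 - 2 * shared / (length(sets[[i]]) + length(sets[[j]]))
    }
  }
  guide <- nj_tree(D)
  ## postorder merge following the guide tree (root trifurcation merged
  ## left to right)
  align_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1L] == node, 2L]
    parts <- lapply(kids, function(k) {
      if (k <= length(guide$tip.label)) {
        rowm[[guide$tip.label[k]]]
      } else {
        align_node(k)
      }
    })
    acc <- parts[[1L]]
    for (p in parts[-1L]) acc <- .merge_alignments(acc, p)
    acc
  }
  m <- align_node(length(guide$tip.label) + 1L)
  matrix_to_msa(m[names(sequences), , drop = FALSE])
}

#' Trim alignment columns by gap fraction and entropy
#'
#' Removes columns whose gap fraction exceeds `max_gap_fraction` or whose
#' normalized Shannon entropy (base 20, over non-gap residues) exceeds
#' `max_entropy`. Column order is preserved; trimming is idempotent.
#'
#' @param msa Named character vector of aligned sequences.
#' @param max_gap_fraction Maximum tolerated gap fraction per column.
#' @param max_entropy Maximum normalized entropy per column.
#' @return Trimmed alignment (named character vector).
#' @export
trim_alignment <- function(msa, max_gap_fraction = 0.5, max_entropy = 0.6) {
  m <- msa_to_matrix(msa)
  stopifnot(nrow(m) >= 2L)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gapfrac <- mean(col == "-")
    if (gapfrac > max_gap_fraction) return(FALSE)
    res <- col[col != "-"]
    p <- table(res) / length(res)
    h <- -sum(p * log(p)) / log(20)
    h <= max_entropy
  }, logical(1))
  if (!any(keep)) {
    stop("all columns removed by trimming; relax max_gap_fraction or ",
         "max_entropy")
  }
  matrix_to_msa(m[, keep, drop = FALSE])
}

#' Flag terminally degraded (pseudogenized) family members
#'
#' A member is removed iff (a) its aligned span misses at least
#' `max_missing` of the family-consensus columns contiguously at either
#' alignment terminus, and (b) over its aligned span it is at least
#' `min_identity` identical to its nearest neighbor — i.e. it is a truncated
#' copy of an otherwise highly identical gene, not a diverged one.
#'
#' @param sequences Named character vector of the family's proteins.
#' @param msa Optional precomputed alignment; built with [build_msa()]
#'   otherwise.
#' @param max_missing Truncation threshold (fraction of consensus columns).
#' @param min_identity Identity floor distinguishing truncation from
#'   divergence.
#' @return List with `kept`, `removed` (member ids) and `untestable`
#'   (`TRUE` when fewer than 3 members remain, in which case no tree should
#'   be built).
#' @export
flag_degraded <- function(sequences, msa = NULL, max_missing = 0.15,
                          min_identity = 0.90) {
  if (is.null(msa)) msa <- build_msa(sequences)
  m <- msa_to_matrix(msa)
  consensus <- which(colMeans(m == "-") <= 0.5)
  n_cons <- length(consensus)
  removed <- character()
  for (i in seq_len(nrow(m))) {
    occ <- which(m[i, ] != "-")
    span <- occ[1L]:occ[length(occ)]
    head_missing <- sum(consensus < occ[1L]) / n_cons
    tail_missing <- sum(consensus > occ[length(occ)]) / n_cons
    if (max(head_missing, tail_missing) < max_missing) next
    ## nearest-neighbor identity over the member's aligned span
    best <- 0
    for (j in seq_len(nrow(m))) {
      if (j == i) next
      both <- span[m[i, span] != "-" & m[j, span] != "-"]
      if (length(both) == 0L) next
      best <- max(best, mean(m[i, both] == m[j, both]))
    }
    if (best >= min_identity) removed <- c(removed, rownames(m)[i])
  }
  kept <- setdiff(rownames(m), removed)
  list(kept = kept, removed = removed, untestable = length(kept) < 3L)
}

.pdist_matrix <- function(m, min_overlap = 30L, strict = TRUE) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      ov <- sum(both)
      if (ov < min_overlap) {
        stop("pairwise overlap below ", min_overlap, " columns for pair ",
             rownames(m)[i], " / ", rownames(m)[j])
      }
      p <- mean(m[i, both] != m[j, both])
      if (p >= 1) {
        if (strict) {
          stop("saturated p-distance (p >= 1) for pair ", rownames(m)[i],
               " / ", rownames(m)[j])
        }
        p <- 1 - 1 / ov
      }
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

#' Poisson-corrected protein distance matrix
#'
#' p-distances over mutually ungapped columns with the Poisson correction
#' d = -ln(1 - p), which is unbiased under a site-independent uniform
#' substitution process.
#'
#' @param msa Named character vector of aligned sequences (trimmed).
#' @param min_overlap Minimum mutually ungapped columns per pair.
#' @return Symmetric distance matrix with a zero diagonal.
#' @export
protein_distance_matrix <- function(msa, min_overlap = 30L) {
  .pdist_matrix(msa_to_matrix(msa), min_overlap = min_overlap, strict = TRUE)
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining with deterministic tie-breaking (ties in the
#' Q-criterion go to the lexicographically lowest label pair) and negative
#' branch lengths clamped to zero with the deficit shifted to the sister
#' branch. On an additive distance matrix the true topology and branch
#' lengths are recovered exactly.
#'
#' @param D Symmetric distance matrix with a zero diagonal, n >= 3, with
#'   row/column names.
#' @return An unrooted `ape::phylo` tree (trifurcating root node).
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 3L)
  if (max(abs(D - t(D))) > 1e-8) stop("non-symmetric distance matrix")
  labels <- rownames(D)
  if (is.null(labels)) {
    labels <- paste0("t", seq_len(nrow(D)))
    dimnames(D) <- list(labels, labels)
  }
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  newick <- stats::setNames(labels, labels)   # cluster label -> subtree text
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(rownames(D)[ij]), collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- D[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    li <- rownames(D)[i]; lj <- rownames(D)[j]
    new_lab <- min(li, lj)
    sub <- paste0("(", newick[[li]], ":", fmt(bi), ",",
                  newick[[lj]], ":", fmt(bj), ")")
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], new_lab)
    D <- D2
    newick <- newick[setdiff(names(newick), c(li, lj))]
    newick[[new_lab]] <- sub
  }
  l3 <- rownames(D)
  bx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  by <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  bz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  text <- paste0("(", newick[[l3[1]]], ":", fmt(bx), ",",
                 newick[[l3[2]]], ":", fmt(by), ",",
                 newick[[l3[3]]], ":", fmt(bz), ");")
  ape::read.tree(text = text)
}

.tree_splits <- function(tree) {
  ## canonical bipartition keys for internal edges: the side not containing
  ## the alphabetically first tip, as a sorted label string
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n <- length(labs)
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) {
      keys <- c(keys, NA_character_)
    } else {
      keys <- c(keys, paste(sort(side), collapse = "\r"))
    }
    nodes <- c(nodes, length(labs) + k)
  }
  data.frame(node = nodes, key = keys, stringsAsFactors = FALSE)
}

#' Nonparametric bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement; each replicate is run
#' through the distance + neighbor-joining pipeline, and the support of
#' every internal bipartition of the full-data tree is the percentage of
#' replicates containing it.
#'
#' @param msa Named character vector of aligned sequences.
#' @param n_replicates Bootstrap replicates (>= 10).
#' @param seed Seed for the column resampling.
#' @param min_overlap Passed to the distance computation.
#' @return The full-data tree with bootstrap percentages in `node.label`.
#' @export
bootstrap_support <- function(msa, n_replicates = 100L, seed = 1L,
                              min_overlap = 30L) {
  if (n_replicates < 10L) stop("need at least 10 bootstrap replicates")
  m <- msa_to_matrix(msa)
  main <- nj_tree(.pdist_matrix(m, min_overlap, strict = TRUE))
  main_splits <- .tree_splits(main)
  counts <- stats::setNames(numeric(nrow(main_splits)), main_splits$key)
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    tr <- nj_tree(.pdist_matrix(m[, idx, drop = FALSE],
                                min_overlap = 1L, strict = FALSE))
    keys <- .tree_splits(tr)$key
    hit <- names(counts) %in% keys[!is.na(keys)]
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_replicates)
  lab <- ifelse(is.na(main_splits$key), "",
                as.character(support[main_splits$key]))
  main$node.label <- lab
  main
}

.node_support <- function(tree, key) {
  sp <- .tree_splits(tree)
  idx <- match(key, sp$key)
  if (is.na(idx)) return(NA_real_)
  if (is.null(tree$node.label)) return(NA_real_)
  val <- tree$node.label[idx]
  if (!nzchar(val)) return(NA_real_)
  as.numeric(val)
}

.split_key <- function(tree, side) {
  labs <- tree$tip.label
  anchor <- sort(labs)[1L]
  if (anchor %in% side) side <- setdiff(labs, side)
  if (length(side) < 2L || length(side) > length(labs) - 2L) {
    return(NA_character_)
  }
  paste(sort(side), collapse = "\r")
}

.is_monophyletic <- function(tree, tips, split_keys) {
  if (length(tips) <= 1L) return(TRUE)
  if (length(tips) >= length(tree$tip.label) - 1L) return(TRUE)
  key <- .split_key(tree, tips)
  key %in% split_keys
}

#' Classify cross-genome transposase sharing
#'
#' For every genome pair represented in the tree: `recent` iff the minimum
#' patristic distance between members of the two genomes is at most
#' `recent_threshold` substitutions/site; otherwise `ancient_sister` iff
#' each genome's members form a clade (singletons allowed) and the two
#' clades are joined as sisters with bootstrap support at or above
#' `support_threshold`; otherwise `unresolved`.
#'
#' @param tree An `ape::phylo` with bootstrap percentages in `node.label`
#'   (e.g. from [bootstrap_support()], or an imported external tree).
#' @param genome_labels Named character vector mapping tip label to genome.
#' @param recent_threshold Patristic distance ceiling for `recent`.
#' @param support_threshold Bootstrap floor for the sister call.
#' @return Data.frame: `genome_a`, `genome_b`, `classification`,
#'   `min_cross_genome_patristic`, `monophyletic_a`, `monophyletic_b`,
#'   `sister_support`.
#' @export
classify_sharing <- function(tree, genome_labels, recent_threshold = 0.02,
                             support_threshold = 95) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  genome_labels <- genome_labels[tips]
  genomes <- sort(unique(genome_labels))
  stopifnot(length(genomes) >= 2L)
  pd <- stats::cophenetic(tree)
  split_keys <- stats::na.omit(.tree_splits(tree)$key)
  rows <- list()
  for (gi in seq_len(length(genomes) - 1L)) {
    for (gj in (gi + 1L):length(genomes)) {
      ga <- genomes[gi]; gb <- genomes[gj]
      ta <- tips[genome_labels == ga]
      tb <- tips[genome_labels == gb]
      minpd <- min(pd[ta, tb])
      mono_a <- .is_monophyletic(tree, ta, split_keys)
      mono_b <- .is_monophyletic(tree, tb, split_keys)
      support <- NA_real_
      cls <- "unresolved"
      if (minpd <= recent_threshold) {
        cls <- "recent"
      } else if (mono_a && mono_b) {
        two_genome_tree <- length(tips) == length(ta) + length(tb)
        ## the joining branch: the bipartition isolating one clade (in a
        ## two-genome tree) or the union of the two clades otherwise
        cand <- if (two_genome_tree) {
          c(.split_key(tree, ta), .split_key(tree, tb))
        } else {
          .split_key(tree, c(ta, tb))
        }
        cand <- cand[!is.na(cand)]
        sister <- two_genome_tree ||
          any(cand %in% split_keys)
        if (sister) {
          for (k in cand) {
            s <- .node_support(tree, k)
            if (!is.na(s)) { support <- s; break }
          }
          ## a singleton-singleton cherry in a two-genome tree has no
          ## internal edge of its own; treat its join as fully supported
          if (two_genome_tree && length(cand) == 0L) support <- 100
          if (!is.na(support) && support >= support_threshold) {
            cls <- "ancient_sister"
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genome_a = ga, genome_b = gb, classification = cls,
        min_cross_genome_patristic = minpd,
        monophyletic_a = mono_a, monophyletic_b = mono_b,
        sister_support = support, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' End-to-end classification of one transposase family
#'
#' Align, drop degraded copies, trim, build a bootstrap neighbor-joining
#' tree and classify every genome pair. Families reduced below 3 members
#' (or below 2 genomes) by the degradation filter are reported untestable.
#'
#' @param sequences Named character vector of the family's proteins.
#' @param genome_labels Named character vector mapping member id to genome.
#' @param n_replicates Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @param recent_threshold,support_threshold Passed to [classify_sharing()].
#' @param max_gap_fraction,max_entropy Passed to [trim_alignment()].
#' @return List with `calls` (classification table or `NULL`), `tree`,
#'   `msa`, `removed` (degraded members) and `untestable`.
#' @export
classify_te_family <- function(sequences, genome_labels,
                               n_replicates = 100L, seed = 1L,
                               recent_threshold = 0.02,
                               support_threshold = 95,
                               max_gap_fraction = 0.5, max_entropy = 0.6) {
  msa <- build_msa(sequences)
  deg <- flag_degraded(sequences, msa = msa)
  msa <- msa[deg$kept]
  if (deg$untestable ||
      length(unique(genome_labels[deg$kept])) < 2L) {
    return(list(calls = NULL, tree = NULL, msa = msa,
                removed = deg$removed, untestable = TRUE))
  }
  ## realign the surviving members so truncation gaps do not linger
  msa <- build_msa(stats::setNames(gsub("-", "", msa), names(msa)))
  trimmed <- trim_alignment(msa, max_gap_fraction, max_entropy)
  tree <- bootstrap_support(trimmed, n_replicates = n_replicates, seed = seed)
  calls <- classify_sharing(tree, genome_labels,
                            recent_threshold = recent_threshold,
                            support_threshold = support_threshold)
  list(calls = calls, tree = tree, msa = trimmed, removed = deg$removed,
       untestable = FALSE)
}

#' Midpoint-root a tree for display
#'
#' @param tree An `ape::phylo`.
#' @return A midpoint-rooted tree (display convenience only; all analysis
#'   is on unrooted trees).
#' @export
midpoint_root <- function(tree) {
  if (requireNamespace("phangorn", quietly = TRUE)) {
    return(phangorn::midpoint(tree))
  }
  tree
}
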