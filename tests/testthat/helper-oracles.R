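# Independent oracles used by the tests; deliberately simple and separate
# from the package implementations they check.

# union-find connected components over character ids
uf_components <- function(ids, edge_a, edge_b) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edge_a)) {
    ra <- find(edge_a[k]); rb <- find(edge_b[k])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  vapply(ids, find, character(1))
}

# exhaustive affine-gap semi-global alignment score for two short sequences
# (free terminal gaps; plain R Gotoh, independent of the package's C++ kernel)
oracle_gotoh <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  S <- matrix(NEG, n + 1, m + 1); X <- S; Y <- S
  S[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(S[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend,
                     Y[i - 1, j] - gap_open - gap_extend)
      Y[i, j] <- max(S[i, j - 1] - gap_open - gap_extend,
                     X[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      S[i, j] <- sub[av[i - 1], bv[j - 1]] +
        max(S[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    }
  }
  max(S[n + 1, ], X[n + 1, ], Y[n + 1, ], S[, m + 1], X[, m + 1], Y[, m + 1])
}

# alignment score of an msa pair under the same model (terminal gaps free)
msa_pair_score <- function(row_a, row_b, sub, gap_open = 11, gap_extend = 1) {
  va <- strsplit(row_a, "")[[1]]; vb <- strsplit(row_b, "")[[1]]
  nga <- which(va != "-"); ngb <- which(vb != "-")
  from <- max(nga[1], ngb[1]); to <- min(nga[length(nga)], ngb[length(ngb)])
  score <- 0
  in_gap <- FALSE
  for (k in from:to) {
    if (va[k] == "-" && vb[k] == "-") next
    if (va[k] == "-" || vb[k] == "-") {
      score <- score - gap_extend - (if (in_gap) 0 else gap_open)
      in_gap <- TRUE
    } else {
      score <- score + sub[va[k], vb[k]]
      in_gap <- FALSE
    }
  }
  score
}

blosum62_test <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  e$BLOSUM62[aa, aa]
})

# random additive distance matrix from a random tree; returns both
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
  D <- stats::cophenetic(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

# quartet oracle: for an additive matrix the four-point condition names the
# true split of every quartet; check the tree induces the same splits
quartets_match <- function(tree, D) {
  labs <- rownames(D)
  pd <- stats::cophenetic(tree)[labs, labs]
  for (q in utils::combn(labs, 4, simplify = FALSE)) {
    sums <- c(D[q[1], q[2]] + D[q[3], q[4]],
              D[q[1], q[3]] + D[q[2], q[4]],
              D[q[1], q[4]] + D[q[2], q[3]])
    sums_t <- c(pd[q[1], q[2]] + pd[q[3], q[4]],
                pd[q[1], q[3]] + pd[q[2], q[4]],
                pd[q[1], q[4]] + pd[q[2], q[3]])
    if (which.min(sums) != which.min(sums_t)) return(FALSE)
  }
  TRUE
}

rand_aa_string <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}

rand_nt_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute an exact fraction of positions with different letters
mutate_exact <- function(s, frac, alphabet) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), round(frac * length(v)))
  for (i in idx) v[i] <- sample(setdiff(alphabet, v[i]), 1)
  paste(v, collapse = "")
}
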