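#' Read a FASTA file into a sequence table
#'
#' Sequences are returned in file order with residues uppercased. The first
#' whitespace-separated token of each header is the record id; the remainder
#' (possibly empty) is the description.
#'
#' @param path Path to a FASTA file (nucleotide or amino acid).
#' @return A data.frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  res <- toupper(as.character(set))
  if (any(nchar(res) == 0L)) {
    stop("record(s) with empty sequence: ",
         paste(ids[nchar(res) == 0L], collapse = ", "))
  }
  data.frame(id = ids, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param records data.frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) {
    records$description
  } else {
    rep("", nrow(records))
  }
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nchar(desc) > 0L,
                       paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read gene features from GFF3, with optional protein sequences
#'
#' Coordinates are 1-based inclusive as in GFF3. The feature class is derived
#' from the annotation: features typed `intron` become class `"intron"`; CDS
#' whose `product` attribute contains "transposase" (case-insensitively)
#' become `"transposase"`; remaining CDS become `"CDS"`; anything else is
#' `"other"`. Proteins are joined to CDS by shared id with the protein FASTA.
#'
#' @param path GFF3 file.
#' @param protein_fasta_path Optional protein FASTA whose ids match the GFF3
#'   `ID` attributes.
#' @param genome_id Genome label recorded for every feature; defaults to the
#'   file name without extension.
#' @return A data.frame of gene features with columns `feature_id`,
#'   `genome_id`, `contig_id`, `start`, `end`, `strand`, `feature_class`,
#'   `product`, `protein`.
#' @export
read_gff3 <- function(path, protein_fasta_path = NULL, genome_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(genome_id)) {
    genome_id <- tools::file_path_sans_ext(basename(path))
  }
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) >= 5L && any(raw[[5L]] < raw[[4L]])) {
    bad <- which(raw[[5L]] < raw[[4L]])[1L]
    stop("GFF3 feature with end < start (row ", bad, ")")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  product <- if ("product" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$product)
  } else {
    rep(NA_character_, length(gr))
  }
  product[is.na(product)] <- ""
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$ID)
  } else {
    rep(NA_character_, length(gr))
  }
  ids[is.na(ids)] <- paste0("feat", seq_along(gr))[is.na(ids)]
  class <- ifelse(type == "intron", "intron",
           ifelse(type == "CDS" & grepl("transposase", product,
                                        ignore.case = TRUE), "transposase",
           ifelse(type == "CDS", "CDS", "other")))
  feats <- data.frame(
    feature_id = ids,
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_class = class,
    product = product,
    protein = "",
    stringsAsFactors = FALSE
  )
  if (!is.null(protein_fasta_path)) {
    prots <- read_fasta(protein_fasta_path)
    idx <- match(feats$feature_id, prots$id)
    feats$protein <- ifelse(is.na(idx), "", prots$residues[idx])
    coding <- feats$feature_class %in% c("CDS", "transposase")
    missing <- coding & feats$protein == ""
    if (any(missing)) {
      warning("no protein sequence for CDS feature(s): ",
              paste(feats$feature_id[missing], collapse = ", "))
    }
  }
  validate_features(feats)
  feats
}

validate_features <- function(feats) {
  stopifnot(all(feats$start >= 1L), all(feats$end >= feats$start))
  coding <- feats$feature_class %in% c("CDS", "transposase")
  if (any(coding & !(feats$strand %in% c("+", "-")))) {
    stop("CDS/transposase feature without defined strand")
  }
  has_prot <- nchar(feats$protein) > 0L
  bad <- has_prot & (nchar(feats$protein) * 3L >
                       (feats$end - feats$start + 1L) + 3L)
  if (any(bad)) {
    stop("protein longer than its CDS allows: ",
         paste(feats$feature_id[bad], collapse = ", "))
  }
  invisible(feats)
}

#' Write gene features to GFF3 (and optionally their proteins to FASTA)
#'
#' @param feats Feature data.frame as returned by [read_gff3()].
#' @param path Output GFF3 path.
#' @param protein_fasta_path Optional path for a protein FASTA holding the
#'   non-empty `protein` entries keyed by `feature_id`.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(feats, path, protein_fasta_path = NULL) {
  type <- ifelse(feats$feature_class == "intron", "intron",
          ifelse(feats$feature_class %in% c("CDS", "transposase"), "CDS",
                 "region"))
  gr <- GenomicRanges::GRanges(
    seqnames = feats$contig_id,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = ifelse(feats$strand %in% c("+", "-"), feats$strand, "*")
  )
  gr$source <- "symbiocensus"
  gr$type <- type
  gr$phase <- ifelse(type == "CDS", 0L, NA_integer_)
  gr$ID <- feats$feature_id
  gr$product <- feats$product
  rtracklayer::export(gr, path, format = "gff3")
  if (!is.null(protein_fasta_path)) {
    keep <- nchar(feats$protein) > 0L
    write_fasta(data.frame(id = feats$feature_id[keep],
                           residues = feats$protein[keep],
                           stringsAsFactors = FALSE),
                protein_fasta_path)
  }
  invisible(path)
}

#' Construct a dense per-base depth track
#'
#' @param sample_id,reference_id Track identity.
#' @param depth Integer vector of per-position depths (1-based positions).
#' @return A `depth_track` list.
#' @export
depth_track <- function(sample_id, reference_id, depth) {
  depth <- as.integer(depth)
  if (any(depth < 0L)) stop("negative depth in track ", reference_id)
  structure(list(sample_id = sample_id, reference_id = reference_id,
                 depth = depth),
            class = "depth_track")
}

#' Read samtools-depth-style TSV into dense depth tracks
#'
#' Rows are (reference, position, depth), 1-based; positions absent from the
#' file have depth 0. An optional 4th column carries the sample id; otherwise
#' all rows belong to `sample_id`.
#'
#' @param path TSV path (no header).
#' @param reference_lengths Named integer vector of reference lengths.
#' @param sample_id Sample label used when the file has no sample column.
#' @return A list of [depth_track()] objects, one per (sample, reference)
#'   pair, covering every declared reference for every sample seen.
#' @export
read_depth_tsv <- function(path, reference_lengths, sample_id = "sample1") {
  stopifnot(file.exists(path), !is.null(names(reference_lengths)))
  info <- file.info(path)
  if (info$size == 0) {
    rows <- data.frame(ref = character(), pos = integer(), depth = integer(),
                       sample = character(), stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    rows <- data.frame(ref = as.character(raw[[1L]]),
                       pos = as.integer(raw[[2L]]),
                       depth = as.integer(raw[[3L]]),
                       stringsAsFactors = FALSE)
    rows$sample <- if (ncol(raw) >= 4L) as.character(raw[[4L]]) else sample_id
  }
  if (nrow(rows) > 0L) {
    unknown <- setdiff(unique(rows$ref), names(reference_lengths))
    if (length(unknown) > 0L) {
      stop("depth rows for undeclared reference(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(rows$depth < 0L)) stop("negative depth in ", path)
    over <- rows$pos > reference_lengths[rows$ref] | rows$pos < 1L
    if (any(over)) {
      stop("position out of range for reference ", rows$ref[which(over)[1L]],
           " (position ", rows$pos[which(over)[1L]], ")")
    }
  }
  samples <- unique(c(rows$sample, if (nrow(rows) == 0L) sample_id))
  tracks <- list()
  for (s in samples) {
    for (ref in names(reference_lengths)) {
      d <- integer(reference_lengths[[ref]])
      sel <- rows$sample == s & rows$ref == ref
      if (any(sel)) d[rows$pos[sel]] <- rows$depth[sel]
      tracks[[length(tracks) + 1L]] <- depth_track(s, ref, d)
    }
  }
  tracks
}

#' Write depth tracks as 4-column TSV (reference, position, depth, sample)
#'
#' Zero-depth positions are omitted (the read-side fill rule restores them).
#'
#' @param tracks List of [depth_track()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    nz <- which(tr$depth > 0L)
    if (length(nz) == 0L) next
    writeLines(paste(tr$reference_id, nz, tr$depth[nz], tr$sample_id,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Parse / serialize Newick trees
#'
#' Thin wrappers around the `ape` Newick machinery with an explicit
#' balance check so malformed strings fail with the offending position.
#'
#' @param text A Newick string.
#' @return For `read_newick`, an `ape::phylo` tree; for `write_newick`, a
#'   Newick string.
#' @export
read_newick <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at position ", i)
  }
  if (depth != 0L) stop("unbalanced '(' — ", depth, " unclosed at end of string")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  tree
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 12)
}
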