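#' Spot-by-gene count matrix
#'
#' Lightweight container for deduplicated UMI counts. Rows are barcoded
#' spots, columns are genes; counts are stored sparsely.
#'
#' @param counts matrix or sparse Matrix of non-negative integer counts,
#'   spots in rows and genes in columns.
#' @param barcodes character vector of unique spot barcodes, one per row.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column.
#' @return an object of class `CountMatrix` with fields `counts`
#'   (a `dgCMatrix`), `barcodes` and `gene_ids`.
#' @export
count_matrix <- function(counts, barcodes, gene_ids) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "CsparseMatrix"), "generalMatrix")
  barcodes <- as.character(barcodes)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(barcodes)) {
    stopf("count matrix has %d rows but %d barcodes", nrow(counts),
          length(barcodes))
  }
  if (ncol(counts) != length(gene_ids)) {
    stopf("count matrix has %d columns but %d gene ids", ncol(counts),
          length(gene_ids))
  }
  if (anyDuplicated(barcodes)) stopf("duplicate barcodes")
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stopf("counts must be non-negative integers")
  }
  dimnames(counts) <- list(barcodes, gene_ids)
  structure(list(counts = counts, barcodes = barcodes, gene_ids = gene_ids),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d spots x %d genes, %d nonzero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' Read a count matrix from a Matrix Market triplet directory
#'
#' Expects the 10x-style triplet `matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`. The on-disk orientation is inferred by matching the MTX
#' dimensions against the barcode and feature list lengths (the 10x
#' convention stores features in rows); the returned matrix is always
#' spots-by-genes. Indices are 1-based on disk, as the Matrix Market format
#' prescribes.
#'
#' @param directory_path directory containing the three files.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(directory_path) {
  paths <- file.path(directory_path, c("matrix.mtx", "barcodes.tsv",
                                       "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("missing file(s): %s", paste(missing, collapse = ", "))
  m <- Matrix::readMM(paths[1])
  barcodes <- readLines(paths[2])
  features <- readLines(paths[3])
  # features.tsv may carry extra columns (id, symbol); the id is column 1
  gene_ids <- vapply(strsplit(features, "\t"), `[`, character(1), 1L)
  nb <- length(barcodes); ng <- length(gene_ids)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)            # 10x convention: features x spots on disk
  } else if (nrow(m) == nb && ncol(m) == ng) {
    # already spots x genes
  } else {
    stopf("MTX dimensions %d x %d match neither %d barcodes x %d features nor its transpose",
          nrow(m), ncol(m), nb, ng)
  }
  count_matrix(m, barcodes, gene_ids)
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Emits `matrix.mtx` (features in rows, the 10x convention),
#' `barcodes.tsv` and `features.tsv` into `directory_path`, readable back
#' by [read_count_matrix()].
#'
#' @param matrix a [count_matrix()].
#' @param directory_path output directory (created if needed).
#' @export
write_count_matrix <- function(matrix, directory_path) {
  stopifnot(inherits(matrix, "CountMatrix"))
  if (!dir.exists(directory_path)) {
    ok <- dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory '%s'", directory_path)
  }
  Matrix::writeMM(Matrix::t(matrix$counts),
                  file.path(directory_path, "matrix.mtx"))
  writeLines(matrix$barcodes, file.path(directory_path, "barcodes.tsv"))
  writeLines(matrix$gene_ids, file.path(directory_path, "features.tsv"))
  invisible(NULL)
}

#' Read spot array positions
#'
#' Reads a Visium-style positions table (columns `barcode`, `in_tissue`,
#' `x`, `y`; integer array coordinates) and returns the geometry for
#' exactly the requested barcodes, in their order. Rows for barcodes not in
#' `barcodes` are tolerated with a warning; a requested barcode missing
#' from the file, or two spots sharing one array position, is an error.
#'
#' @param csv_path path to the CSV file.
#' @param barcodes barcodes that must be covered (usually from the count
#'   matrix).
#' @return a `data.frame` with columns `barcode`, `x`, `y`, `in_tissue`.
#' @export
read_spot_positions <- function(csv_path, barcodes) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("barcode", "in_tissue", "x", "y")
  if (!all(need %in% names(df))) {
    stopf("positions CSV must have columns %s", paste(need, collapse = ", "))
  }
  extra <- setdiff(df$barcode, barcodes)
  if (length(extra)) {
    warnf("ignoring %d position row(s) for barcodes absent from the matrix (e.g. '%s')",
          length(extra), extra[1])
    df <- df[df$barcode %in% barcodes, , drop = FALSE]
  }
  miss <- setdiff(barcodes, df$barcode)
  if (length(miss)) stopf("no position for barcode '%s'", miss[1])
  if (anyDuplicated(df$barcode)) stopf("duplicate position rows for barcode '%s'",
                                       df$barcode[duplicated(df$barcode)][1])
  key <- paste(df$x, df$y)
  if (anyDuplicated(key)) {
    stopf("two barcodes share array position (%s)",
          sub(" ", ", ", key[duplicated(key)][1]))
  }
  df <- df[match(barcodes, df$barcode), c("barcode", "x", "y", "in_tissue")]
  rownames(df) <- NULL
  df$x <- as.integer(df$x); df$y <- as.integer(df$y)
  df$in_tissue <- as.logical(df$in_tissue)
  df
}

#' Write spot array positions
#' @param geometry data.frame as returned by [read_spot_positions()].
#' @param csv_path output path.
#' @export
write_spot_positions <- function(geometry, csv_path) {
  utils::write.csv(geometry[, c("barcode", "in_tissue", "x", "y")],
                   csv_path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a gene annotation table
#'
#' Tab-separated columns: `gene_id`, `symbol`, `is_tf` (TRUE/FALSE),
#' `tf_family` (empty for non-TFs), `pathway_tags` and `term_ids`
#' (semicolon-separated sets, possibly empty). Every TF must carry a
#' family.
#'
#' @param tsv_path path to the TSV file.
#' @return a `data.frame`; `pathway_tags`/`term_ids` stay
#'   semicolon-encoded, use [annotation_genes_with_tag()] to expand them.
#' @export
read_gene_annotation <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_id", "symbol", "is_tf", "tf_family", "pathway_tags",
            "term_ids")
  if (!all(need %in% names(df))) {
    stopf("annotation TSV must have columns %s", paste(need, collapse = ", "))
  }
  df$is_tf <- as.logical(df$is_tf)
  validate_gene_annotation(df[, need])
}

validate_gene_annotation <- function(df) {
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene_id in annotation")
  bad <- df$is_tf & (is.na(df$tf_family) | df$tf_family == "")
  if (any(bad)) stopf("TF gene '%s' has no tf_family", df$gene_id[bad][1])
  df$pathway_tags[is.na(df$pathway_tags)] <- ""
  df$term_ids[is.na(df$term_ids)] <- ""
  rownames(df) <- NULL
  df
}

#' @rdname read_gene_annotation
#' @param annotation annotation data.frame.
#' @export
write_gene_annotation <- function(annotation, tsv_path) {
  utils::write.table(annotation, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}

#' Genes carrying a pathway tag or enrichment term
#'
#' @param annotation annotation data.frame.
#' @param tag pathway tag (e.g. `"catechin_synthesis"`).
#' @param column which set column to search, `"pathway_tags"` or
#'   `"term_ids"`.
#' @return character vector of gene ids.
#' @export
annotation_genes_with_tag <- function(annotation, tag,
                                      column = c("pathway_tags", "term_ids")) {
  column <- match.arg(column)
  sets <- strsplit(annotation[[column]], ";", fixed = TRUE)
  hit <- vapply(sets, function(s) tag %in% s, logical(1))
  annotation$gene_id[hit]
}

#' Read promoter sequences from FASTA
#'
#' One record per gene; the header token before the first whitespace is
#' the gene id. Sequences are uppercased and must use only A, C, G, T, N.
#'
#' @param fasta_path path to a FASTA file.
#' @return named character vector (gene id to sequence); empty with a
#'   warning when the file holds no records.
#' @export
read_promoters <- function(fasta_path) {
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) == 0L) {
    warnf("no promoter records in '%s'", fasta_path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) stopf("duplicate promoter gene id '%s'",
                                ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nchar(bad) > 0)) {
    stopf("promoter '%s' contains illegal character '%s'",
          ids[nchar(bad) > 0][1], substr(bad[nchar(bad) > 0][1], 1, 1))
  }
  if (any(nchar(seqs) < 1L)) stopf("promoter '%s' is empty",
                                   ids[nchar(seqs) < 1L][1])
  stats::setNames(seqs, ids)
}

#' Write promoter sequences to FASTA
#' @param promoters named character vector of sequences.
#' @param fasta_path output path.
#' @param width line-wrap width.
#' @export
write_promoters <- function(promoters, fasta_path, width = 70L) {
  set <- Biostrings::BStringSet(promoters)
  Biostrings::writeXStringSet(set, fasta_path, width = width)
  invisible(NULL)
}

#' Read a MEME-minimal motif library
#'
#' Parses the MEME minimal text format: a `MOTIF <name>` line followed by
#' a `letter-probability matrix:` header and `w` rows of four
#' probabilities (A, C, G, T order). Each row must sum to 1 within 1e-4
#' and is renormalized after the check. Motif names key TF families.
#'
#' @param meme_path path to the motif file.
#' @return a named list of PWMs; each PWM is a list with `name`, `probs`
#'   (4 x width matrix, rows A/C/G/T) and `width`.
#' @export
read_motifs <- function(meme_path) {
  lines <- readLines(meme_path)
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) stopf("no MOTIF entries in '%s'", meme_path)
  out <- list()
  for (i in seq_along(motif_at)) {
    start <- motif_at[i]
    end <- if (i < length(motif_at)) motif_at[i + 1] - 1L else length(lines)
    name <- strsplit(trimws(lines[start]), "\\s+")[[1]][2]
    if (is.na(name) || name == "") stopf("MOTIF line without a name")
    block <- lines[start:end]
    hdr <- grep("letter-probability matrix", block)
    if (!length(hdr)) stopf("motif '%s' has no letter-probability matrix", name)
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", block[hdr[1]]))
    if (is.na(w) || w < 1L) stopf("motif '%s' has width 0", name)
    rows <- block[-seq_len(hdr[1])]
    rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
    if (length(rows) < w) stopf("motif '%s' declares w=%d but has %d rows",
                                name, w, length(rows))
    probs <- t(vapply(rows[seq_len(w)], function(r) {
      v <- as.numeric(strsplit(trimws(r), "\\s+")[[1]])
      if (length(v) != 4L || anyNA(v)) stopf("motif '%s': bad probability row", name)
      v
    }, numeric(4)))
    sums <- rowSums(probs)
    if (any(abs(sums - 1) > 1e-4)) {
      stopf("motif '%s': probability row sums to %.4f", name,
            sums[abs(sums - 1) > 1e-4][1])
    }
    probs <- probs / sums
    pm <- t(probs)                       # 4 x w, rows A C G T
    rownames(pm) <- c("A", "C", "G", "T")
    if (name %in% names(out)) stopf("duplicate motif name '%s'", name)
    out[[name]] <- new_pwm(name, pm)
  }
  out
}

#' Write a motif library in MEME-minimal format
#' @param library named list of PWMs as from [read_motifs()].
#' @param meme_path output path.
#' @export
write_motifs <- function(library, meme_path) {
  con <- file(meme_path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", ""), con)
  for (pwm in library) {
    writeLines(sprintf("MOTIF %s", pwm$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       pwm$width), con)
    for (j in seq_len(pwm$width)) {
      writeLines(paste(sprintf("%.6f", pwm$probs[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(NULL)
}
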