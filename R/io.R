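#' Sparse cells-by-features count matrix
#'
#' Thin S3 container around a `Matrix::dgCMatrix` with rows = barcodes and
#' columns = features (genomic intervals encoded `chrom:start-end` for tile
#' and peak flavors, gene names for gene scores), plus the per-cell total
#' insertion depth cached at construction time.
#'
#' @param counts sparse (or dense) matrix, rows named by barcode, columns by
#'   feature.
#' @param flavor one of `"tile"`, `"peak"`, `"gene_score"`.
#' @param depth optional per-row depth; defaults to `rowSums(counts)`.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(counts, flavor = c("tile", "peak", "gene_score"),
                           depth = NULL) {
  flavor <- match.arg(flavor)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("feature_matrix requires row (barcode) and column (feature) names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stopf("feature_matrix labels must be unique")
  }
  if (any(counts@x < 0)) stopf("feature_matrix entries must be non-negative")
  depth <- depth %||% Matrix::rowSums(counts)
  if (length(depth) != nrow(counts)) stopf("depth length must match rows")
  structure(list(counts = counts, flavor = flavor,
                 depth = stats::setNames(as.numeric(depth), rownames(counts))),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$counts)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix [%s]> %d cells x %d features, %d nonzero\n",
              x$flavor, nrow(x$counts), ncol(x$counts),
              length(x$counts@x)))
  invisible(x)
}

#' Parse `chrom:start-end` feature labels into interval columns
#'
#' @param labels character vector of `chrom:start-end` strings (0-based
#'   half-open).
#' @return data.table with chrom, start, end, midpoint.
#' @export
parse_interval <- function(labels) {
  m <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
  bad <- lengths(m) != 4L
  if (any(bad)) stopf("unparseable interval label(s): %s",
                      paste(utils::head(labels[bad], 3), collapse = ", "))
  dt <- data.table::data.table(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)))
  if (any(dt$end <= dt$start)) stopf("interval with end <= start")
  dt[, midpoint := start + (end - start) %/% 2L]
  dt[]
}

#' Read a fragment file
#'
#' Reads a plain or gzipped 5-column TSV (chrom, start, end, barcode, count;
#' 0-based half-open) skipping leading `#` header lines, validates every
#' record, and optionally filters to a barcode whitelist.
#'
#' @param path fragment file.
#' @param barcode_whitelist optional character vector of barcodes to keep.
#' @return data.table of fragment records sorted as stored on disk.
#' @export
read_fragments <- function(path, barcode_whitelist = NULL) {
  if (!file.exists(path)) stopf("no such fragment file: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    first <- c(first, line)
  }
  close(con)
  n_header <- length(first)
  dt <- if (grepl("\\.gz$", path)) {
    # decompress through gzip so no optional helper package is needed
    data.table::fread(cmd = sprintf("gzip -dc %s", shQuote(path)),
                      skip = n_header, header = FALSE, sep = "\t",
                      colClasses = list(character = c(1, 4)))
  } else {
    data.table::fread(path, skip = n_header, header = FALSE, sep = "\t",
                      colClasses = list(character = c(1, 4)))
  }
  if (nrow(dt) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), barcode = character(),
                                  count = integer()))
  }
  if (ncol(dt) != 5L) {
    stopf("fragment file %s: expected 5 columns, found %d (first data line %d)",
          path, ncol(dt), n_header + 1L)
  }
  data.table::setnames(dt, c("chrom", "start", "end", "barcode", "count"))
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) |
                 !is.finite(dt$count) |
                 dt$start != floor(dt$start) | dt$end != floor(dt$end) |
                 dt$start < 0 | dt$end <= dt$start | dt$count < 1)
  if (length(bad)) {
    stopf("fragment file %s: malformed record at line %d", path,
          n_header + bad[1])
  }
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  dt[, count := as.integer(count)]
  if (!is.null(barcode_whitelist)) dt <- dt[barcode %in% barcode_whitelist]
  dt[]
}

#' Write a fragment table
#'
#' @param fragments data.table with chrom, start, end, barcode, count.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(fragments[, .(chrom, start, end, barcode, count)], path,
                     sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Write / read a feature matrix as MatrixMarket + TSV sidecars
#'
#' `write_matrix()` emits `matrix.mtx` (triplet format), `barcodes.tsv`
#' (barcode and cached depth), `features.tsv` and `meta.tsv` (flavor) under
#' `dir`; `read_matrix()` reverses it losslessly.
#'
#' @param matrix a [feature_matrix()].
#' @param dir directory to write into / read from.
#' @return `read_matrix()` returns a `feature_matrix`.
#' @export
write_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "feature_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(matrix$counts, file.path(dir, "matrix.mtx"))
  data.table::fwrite(
    data.table::data.table(barcode = rownames(matrix$counts),
                           depth = matrix$depth),
    file.path(dir, "barcodes.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(feature = colnames(matrix$counts)),
                     file.path(dir, "features.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(field = "flavor",
                                            value = matrix$flavor),
                     file.path(dir, "meta.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  bc <- data.table::fread(file.path(dir, "barcodes.tsv"))
  ft <- data.table::fread(file.path(dir, "features.tsv"),
                          colClasses = "character")
  meta <- data.table::fread(file.path(dir, "meta.tsv"))
  if (nrow(bc) != nrow(m) || nrow(ft) != ncol(m)) {
    stopf("matrix dimensions (%d x %d) disagree with sidecars (%d barcodes, %d features)",
          nrow(m), ncol(m), nrow(bc), nrow(ft))
  }
  rownames(m) <- bc$barcode
  colnames(m) <- ft$feature
  feature_matrix(m, flavor = meta[field == "flavor", value], depth = bc$depth)
}

#' Read ground-truth sidecar files
#'
#' Readers for the peak BED (with class/owner/motif/motif-strand columns),
#' gene TSV and cell TSV written by [write_truth()]. All intervals are
#' 0-based half-open, matching the fragment convention.
#'
#' @param path file path.
#' @return data.table.
#' @export
read_peaks_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  cn <- c("chrom", "start", "end", "class", "owner", "motif", "motif_strand")
  data.table::setnames(dt, cn[seq_len(ncol(dt))])
  for (col in intersect(c("owner", "motif", "motif_strand"), names(dt))) {
    dt[get(col) == ".", (col) := NA_character_]
  }
  dt[, summit := start + (end - start) %/% 2L]
  dt[, peak_id := sprintf("%s:%d-%d", chrom, start, end)]
  dt[]
}

#' @rdname read_peaks_bed
#' @export
read_genes_tsv <- function(path) data.table::fread(path, sep = "\t")

#' @rdname read_peaks_bed
#' @export
read_cells_tsv <- function(path) data.table::fread(path, sep = "\t")

#' Read JASPAR-style position weight matrices
#'
#' Parses the common JASPAR text layout: a `>name` header followed by four
#' lines `A [ n n ... ]`, `C [...]`, `G [...]`, `T [...]` (counts or
#' frequencies; brackets optional). Each matrix is column-normalized to
#' probabilities.
#'
#' @param path PWM text file.
#' @return named list of `pwm` objects (4 x L probability matrices with
#'   rownames ACGT and a `background` attribute).
#' @export
read_jaspar_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stopf("no '>' headers in PWM file %s", path)
  out <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    name <- sub("^>\\s*", "", lines[starts[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    block <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      as.numeric(strsplit(gsub("[][]", " ", l), "\\s+")[[1]] |>
                   (\(v) v[nzchar(v)])())
    })
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    out[[name]] <- pwm(mat, name = name)
  }
  out
}

#' Construct a PWM object
#'
#' @param mat 4 x L matrix of counts or probabilities, rows A, C, G, T.
#' @param name motif name.
#' @param background base composition (default uniform).
#' @return a `pwm`: column-stochastic probability matrix.
#' @export
pwm <- function(mat, name = "motif", background = rep(0.25, 4)) {
  if (nrow(mat) != 4L) stopf("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4L) stopf("PWM length must be >= 4")
  mat <- sweep(mat, 2L, colSums(mat), "/")
  if (any(abs(colSums(mat) - 1) > 1e-6)) stopf("PWM columns must sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(mat, name = name, background = background, class = "pwm")
}

#' Reassemble a truth catalog from files written by [write_truth()]
#'
#' Rebuilds the per-group open-peak map from the peak classes and the
#' (tissue, cell type) combinations present in the cell table.
#'
#' @param dir directory holding `peaks.bed`, `genes.tsv`, `cells.tsv`.
#' @return a `truth_catalog` (without the generating `sim_config`).
#' @export
read_truth <- function(dir) {
  peaks <- read_peaks_bed(file.path(dir, "peaks.bed"))
  genes <- read_genes_tsv(file.path(dir, "genes.tsv"))
  cells <- read_cells_tsv(file.path(dir, "cells.tsv"))
  groups <- unique(cells[, .(tissue, cell_type, group)])
  data.table::setorder(groups, group)
  open_peaks <- lapply(seq_len(nrow(groups)), function(g) {
    ti <- groups$tissue[g]; ty <- groups$cell_type[g]
    which(peaks$class == "housekeeping" |
            (peaks$class == "tissue" & peaks$owner == ti) |
            (peaks$class == "celltype" & peaks$owner == ty))
  })
  structure(list(peaks = peaks, genes = genes, groups = groups,
                 open_peaks = open_peaks, config = NULL),
            class = "truth_catalog")
}
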