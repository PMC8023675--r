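# Count-matrix input/output and gene-major chunk streaming. Genes are
# independent given the design and size factors, so fitting can stream over
# contiguous gene blocks; the on-disk backend re-reads the source file per
# chunk so that at most chunk_size x n_cells count values are resident.

#' Open a count matrix
#'
#' Reads a gene x cell matrix of non-negative integer counts from
#' MatrixMarket (`mtx`), 10x-style HDF5 (`10x-h5`) or TSV, returning a
#' `matrix_handle` that the fitting functions iterate over in gene chunks.
#' With `on_disk = TRUE` the counts stay in the file and each chunk is read on
#' demand; results are identical to the in-memory backend.
#'
#' Formats:
#' \describe{
#'   \item{mtx}{MatrixMarket coordinate integer, 1-based, general symmetry.
#'     Sidecar name files `features.tsv`/`genes.tsv` and `barcodes.tsv` in the
#'     same directory are used when present, else names `gene_0001...` /
#'     `cell_0001...` are synthesized. Unlisted coordinates are zeros.}
#'   \item{10x-h5}{HDF5 file with a CSC group (`data`, `indices`, `indptr`,
#'     `shape`, genes as the first shape dimension). Both the v2/v3 `matrix`
#'     group layout and a flat root layout are accepted; feature/barcode name
#'     arrays are read when present.}
#'   \item{tsv}{dense tab-separated values, gene rows, header = cell names,
#'     first column = gene names.}
#' }
#'
#' @param path file path.
#' @param format one of `"mtx"`, `"10x-h5"`, `"tsv"`; default guesses from
#'   the file extension.
#' @param on_disk keep the data on disk and read chunks lazily.
#' @return a `matrix_handle`.
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "10x-h5", "tsv"),
                        on_disk = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", h5 = "10x-h5", hdf5 = "10x-h5",
                     tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension of ", path))
  }
  meta <- switch(format,
    "mtx" = mtx_meta(path),
    "10x-h5" = h5_meta(path),
    "tsv" = tsv_meta(path))
  handle <- structure(list(
    n_genes = meta$n_genes, n_cells = meta$n_cells,
    gene_names = meta$gene_names, cell_names = meta$cell_names,
    backend = if (on_disk) "on-disk" else "in-memory",
    format = format, path = path, meta = meta$extra,
    data = NULL), class = "matrix_handle")
  if (!on_disk) {
    handle$data <- read_chunk(handle, seq_len(meta$n_genes), force_disk = TRUE)
  }
  handle
}

#' Wrap an in-memory matrix as a handle
#' @param counts gene x cell matrix or an existing `matrix_handle`.
#' @return a `matrix_handle` with the in-memory backend.
#' @export
as_matrix_handle <- function(counts) {
  if (inherits(counts, "matrix_handle")) return(counts)
  counts <- as.matrix(counts)
  validate_counts_matrix(counts, "in-memory matrix")
  gn <- rownames(counts) %||% sprintf("gene_%04d", seq_len(nrow(counts)))
  cn <- colnames(counts) %||% sprintf("cell_%04d", seq_len(ncol(counts)))
  if (anyDuplicated(gn)) stop("gene names must be unique")
  if (anyDuplicated(cn)) stop("cell names must be unique")
  structure(list(n_genes = nrow(counts), n_cells = ncol(counts),
                 gene_names = gn, cell_names = cn,
                 backend = "in-memory", format = "memory", path = NULL,
                 meta = NULL, data = unname(counts)),
            class = "matrix_handle")
}

#' @export
print.matrix_handle <- function(x, ...) {
  cat("<matrix_handle> ", x$n_genes, " genes x ", x$n_cells, " cells, ",
      x$backend, " (", x$format, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.matrix_handle <- function(x) c(x$n_genes, x$n_cells)

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_counts_matrix <- function(m, what, i_off = 0L) {
  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(what, " contains a negative or non-integer value at gene ",
         bad[1, 1] + i_off, ", cell ", bad[1, 2])
  }
  invisible(m)
}

# ---- format metadata ---------------------------------------------------

mtx_meta <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^%%MatrixMarket matrix coordinate (integer|real) general", hdr)) {
    stop("unsupported MatrixMarket header in ", path, ": ", hdr)
  }
  con <- file(path, "r"); on.exit(close(con))
  ln <- readLines(con, n = 1L)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!startsWith(ln, "%")) break
  }
  dims <- scan(text = ln, what = double(), quiet = TRUE)
  dir <- dirname(path)
  gene_names <- read_name_sidecar(file.path(dir, c("features.tsv", "genes.tsv")),
                                  dims[1], "gene")
  cell_names <- read_name_sidecar(file.path(dir, "barcodes.tsv"), dims[2], "cell")
  list(n_genes = as.integer(dims[1]), n_cells = as.integer(dims[2]),
       gene_names = gene_names, cell_names = cell_names,
       extra = list(nnz = dims[3]))
}

read_name_sidecar <- function(candidates, n, what) {
  for (f in candidates) {
    if (file.exists(f)) {
      nm <- utils::read.delim(f, header = FALSE, stringsAsFactors = FALSE)[[1]]
      if (length(nm) != n) {
        stop("name file ", f, " lists ", length(nm), " entries but the matrix has ",
             n, " ", what, "s")
      }
      return(as.character(nm))
    }
  }
  sprintf("%s_%04d", what, seq_len(n))
}

h5_meta <- function(path) {
  contents <- rhdf5::h5ls(path)
  grp <- if (any(contents$group == "/matrix" | contents$name == "matrix")) "matrix/" else ""
  shape <- as.integer(rhdf5::h5read(path, paste0(grp, "shape")))
  gene_names <- h5_names(path, paste0(grp, c("features/name", "features/id",
                                             "genes", "gene_names")),
                         shape[1], "gene")
  cell_names <- h5_names(path, paste0(grp, "barcodes"), shape[2], "cell")
  list(n_genes = shape[1], n_cells = shape[2],
       gene_names = gene_names, cell_names = cell_names,
       extra = list(group = grp))
}

h5_names <- function(path, candidates, n, what) {
  contents <- rhdf5::h5ls(path)
  present <- sub("^/", "", file.path(contents$group, contents$name))
  for (ds in candidates) {
    if (ds %in% present) {
      nm <- as.character(rhdf5::h5read(path, ds))
      if (length(nm) == n) return(nm)
      stop("name array ", ds, " lists ", length(nm), " entries but the matrix has ",
           n, " ", what, "s")
    }
  }
  sprintf("%s_%04d", what, seq_len(n))
}

tsv_meta <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  cell_names <- header[-1]
  first_col <- utils::read.delim(path, header = TRUE, colClasses = c("character", rep("NULL", length(cell_names))))[[1]]
  list(n_genes = length(first_col), n_cells = length(cell_names),
       gene_names = first_col, cell_names = cell_names, extra = NULL)
}

# ---- chunk reads -------------------------------------------------------

read_chunk <- function(handle, rows, force_disk = FALSE) {
  if (!force_disk && !is.null(handle$data)) {
    return(handle$data[rows, , drop = FALSE])
  }
  m <- switch(handle$format,
    "mtx" = read_chunk_mtx(handle, rows),
    "10x-h5" = read_chunk_h5(handle, rows),
    "tsv" = read_chunk_tsv(handle, rows),
    stop("no on-disk reader for format ", handle$format))
  validate_counts_matrix(m, handle$path, i_off = min(rows) - 1L)
  m
}

read_chunk_mtx <- function(handle, rows) {
  r0 <- min(rows); r1 <- max(rows)
  out <- matrix(0, nrow = length(rows), ncol = handle$n_cells)
  con <- file(handle$path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!startsWith(ln, "%")) break  # dimension line
  }
  repeat {
    block <- scan(con, what = double(), n = 3L * 100000L, quiet = TRUE)
    if (!length(block)) break
    trip <- matrix(block, ncol = 3L, byrow = TRUE)
    keep <- trip[, 1] >= r0 & trip[, 1] <= r1
    if (any(keep)) {
      tk <- trip[keep, , drop = FALSE]
      out[cbind(tk[, 1] - r0 + 1L, tk[, 2])] <-
        out[cbind(tk[, 1] - r0 + 1L, tk[, 2])] + tk[, 3]
    }
  }
  out
}

read_chunk_h5 <- function(handle, rows) {
  grp <- handle$meta$group
  r0 <- min(rows); r1 <- max(rows)
  indptr <- as.numeric(rhdf5::h5read(handle$path, paste0(grp, "indptr")))
  out <- matrix(0, nrow = length(rows), ncol = handle$n_cells)
  block <- 10000L
  for (c0 in seq(1L, handle$n_cells, by = block)) {
    c1 <- min(c0 + block - 1L, handle$n_cells)
    p0 <- indptr[c0] + 1; p1 <- indptr[c1 + 1]
    if (p1 < p0) next
    idx <- list(p0:p1)
    vals <- as.numeric(rhdf5::h5read(handle$path, paste0(grp, "data"), index = idx))
    ridx <- as.numeric(rhdf5::h5read(handle$path, paste0(grp, "indices"), index = idx)) + 1
    cols <- rep.int(c0:c1, diff(indptr[c0:(c1 + 1L)]))
    keep <- ridx >= r0 & ridx <= r1
    if (any(keep)) {
      out[cbind(ridx[keep] - r0 + 1L, cols[keep])] <- vals[keep]
    }
  }
  out
}

read_chunk_tsv <- function(handle, rows) {
  r0 <- min(rows)
  m <- utils::read.delim(handle$path, header = FALSE, skip = r0,
                         nrows = length(rows), row.names = 1L)
  as.matrix(unname(m))
}

# ---- streaming ---------------------------------------------------------

#' Iterate over contiguous gene chunks
#'
#' Returns a closure that yields successive `CountChunk`s — lists with `rows`
#' (gene indices), `counts` (genes x cells), `gene_names` — and `NULL` when
#' exhausted. Chunks are contiguous, in order, cover every gene exactly once,
#' and for on-disk handles at most `chunk_size * n_cells` count values are
#' resident at a time.
#'
#' @param handle a `matrix_handle` (or plain matrix).
#' @param chunk_size genes per chunk (>= 1).
#' @return function yielding chunks.
#' @export
chunk_iterator <- function(handle, chunk_size = 200L) {
  handle <- as_matrix_handle_lazy(handle)
  chunk_size <- max(1L, as.integer(chunk_size))
  starts <- seq(1L, handle$n_genes, by = chunk_size)
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(starts)) return(NULL)
    rows <- starts[i]:min(starts[i] + chunk_size - 1L, handle$n_genes)
    list(rows = rows, counts = read_chunk(handle, rows),
         gene_names = handle$gene_names[rows])
  }
}

as_matrix_handle_lazy <- function(x) {
  if (inherits(x, "matrix_handle")) x else as_matrix_handle(x)
}

#' Materialize all chunks of a matrix
#'
#' Convenience wrapper around [chunk_iterator()] that collects every chunk in
#' a list; intended for small matrices and tests. The last chunk may be short;
#' row-binding the chunks reproduces the matrix exactly.
#'
#' @inheritParams chunk_iterator
#' @return list of chunks.
#' @export
iter_chunks <- function(handle, chunk_size = 200L) {
  it <- chunk_iterator(handle, chunk_size)
  out <- list()
  repeat {
    ch <- it()
    if (is.null(ch)) break
    out[[length(out) + 1L]] <- ch
  }
  out
}

#' Stream per-cell column sums
#'
#' First streaming pass used for normed-sum size factors without loading the
#' matrix.
#'
#' @inheritParams chunk_iterator
#' @return numeric vector of per-cell totals.
#' @export
stream_colsums <- function(handle, chunk_size = 200L) {
  handle <- as_matrix_handle_lazy(handle)
  tot <- numeric(handle$n_cells)
  it <- chunk_iterator(handle, chunk_size)
  repeat {
    ch <- it()
    if (is.null(ch)) break
    tot <- tot + colSums(ch$counts)
  }
  tot
}

# ---- writers -----------------------------------------------------------

#' Write a per-gene results table as deterministic TSV
#'
#' Fixed column order (as supplied), floats formatted with `%.6g`, missing
#' values as `NA`; byte-identical across runs on identical inputs. Optional
#' comment header lines (prefixed `#`) record the run configuration.
#'
#' @param table data.frame/tibble of results.
#' @param path output file.
#' @param header character vector of comment lines (written as `# ...`).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, header = NULL) {
  table <- as.data.frame(table)
  fmt <- vapply(table, function(col) {
    if (is.double(col)) sprintf("%.6g", col)
    else if (is.logical(col)) ifelse(col, "TRUE", "FALSE")
    else as.character(col)
  }, FUN.VALUE = character(nrow(table)))
  if (nrow(table) == 1L) fmt <- matrix(fmt, nrow = 1L)
  if (nrow(table) == 0L) fmt <- matrix(character(0), ncol = ncol(table))
  fmt[is.na(as.matrix(table))] <- "NA"
  lines <- c(
    if (length(header)) paste0("# ", header),
    paste(names(table), collapse = "\t"),
    if (nrow(table)) apply(fmt, 1L, paste, collapse = "\t")
  )
  con <- file(path, "wb")  # binary mode: identical line endings everywhere
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a count matrix as MatrixMarket with name sidecars
#'
#' Coordinate integer format, 1-based, plus `features.tsv` and `barcodes.tsv`
#' next to the matrix file.
#'
#' @param counts gene x cell integer matrix.
#' @param path `.mtx` output path.
#' @return `path`, invisibly.
#' @export
write_mtx <- function(counts, path) {
  counts <- as.matrix(counts)
  nz <- which(counts != 0, arr.ind = TRUE)
  ord <- order(nz[, 2], nz[, 1])  # column-major, the conventional mtx order
  nz <- nz[ord, , drop = FALSE]
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(nrow(counts), ncol(counts), nrow(nz)),
             sprintf("%d %d %d", nz[, 1], nz[, 2], as.integer(counts[nz])))
  con <- file(path, "wb"); writeLines(lines, con); close(con)
  dir <- dirname(path)
  gn <- rownames(counts) %||% sprintf("gene_%04d", seq_len(nrow(counts)))
  cn <- colnames(counts) %||% sprintf("cell_%04d", seq_len(ncol(counts)))
  writeLines(gn, fp <- file(file.path(dir, "features.tsv"), "wb")); close(fp)
  writeLines(cn, fp <- file(file.path(dir, "barcodes.tsv"), "wb")); close(fp)
  invisible(path)
}

#' Write a count matrix as a 10x-style HDF5 file
#'
#' CSC layout under a `matrix` group with `data`, `indices`, `indptr`,
#' `shape`, `barcodes` and `features/{id,name}` arrays, genes as the first
#' shape dimension.
#'
#' @param counts gene x cell integer matrix.
#' @param path `.h5` output path.
#' @return `path`, invisibly.
#' @export
write_10x_h5 <- function(counts, path) {
  counts <- as.matrix(counts)
  sp <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "matrix")
  rhdf5::h5write(as.integer(sp@x), path, "matrix/data")
  rhdf5::h5write(as.integer(sp@i), path, "matrix/indices")
  rhdf5::h5write(as.integer(sp@p), path, "matrix/indptr")
  rhdf5::h5write(as.integer(dim(counts)), path, "matrix/shape")
  cn <- colnames(counts) %||% sprintf("cell_%04d", seq_len(ncol(counts)))
  gn <- rownames(counts) %||% sprintf("gene_%04d", seq_len(nrow(counts)))
  rhdf5::h5write(cn, path, "matrix/barcodes")
  rhdf5::h5createGroup(path, "matrix/features")
  rhdf5::h5write(gn, path, "matrix/features/id")
  rhdf5::h5write(gn, path, "matrix/features/name")
  rhdf5::H5close()
  invisible(path)
}
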