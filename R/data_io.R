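#' Read a feature-by-droplet count matrix
#'
#' Reads sparse counts either from a Matrix Market triplet directory
#' (`matrix.mtx`, `features.tsv`, `barcodes.tsv`, each optionally
#' gzip-compressed) or from a dense tab-separated file whose header row holds
#' droplet identifiers and whose first column holds feature identifiers.
#'
#' @param path For `format = "mtx_triplet"`, a directory containing the three
#'   companion files (or a path to the `matrix.mtx(.gz)` file itself, with the
#'   companions alongside). For `format = "dense_tsv"`, the TSV file.
#' @param format `"mtx_triplet"` or `"dense_tsv"`; `"auto"` picks by path.
#' @return A [`Matrix::dgCMatrix-class`] of non-negative integer counts with
#'   features as rows and droplets as columns, carrying feature and droplet
#'   identifiers as dimnames.
#' @export
read_counts <- function(path, format = c("auto", "mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx(\\.gz)?$", path))
      "mtx_triplet" else "dense_tsv"
  }
  m <- switch(format,
    mtx_triplet = read_mtx_triplet(path),
    dense_tsv = read_dense_tsv(path)
  )
  validate_counts(m)
  m
}

read_mtx_triplet <- function(path) {
  dir <- if (dir.exists(path)) path else dirname(path)
  locate <- function(stem) {
    for (f in file.path(dir, c(stem, paste0(stem, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    abort(sprintf("missing companion file '%s(.gz)' in %s", stem, dir),
          class = "dblkit_format_error")
  }
  mtx <- locate("matrix.mtx")
  feats <- locate("features.tsv")
  bars <- locate("barcodes.tsv")
  con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else mtx
  m <- Matrix::readMM(con)
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  read_ids <- function(f) {
    x <- readr::read_tsv(f, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
    as.character(x[[1]])
  }
  fid <- read_ids(feats)
  bid <- read_ids(bars)
  if (length(fid) != nrow(m) || length(bid) != ncol(m)) {
    abort(sprintf(
      "identifier files (%d features, %d barcodes) do not match matrix dims %d x %d",
      length(fid), length(bid), nrow(m), ncol(m)), class = "dblkit_format_error")
  }
  dimnames(m) <- list(fid, bid)
  m
}

read_dense_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  fid <- as.character(x[[1]])
  vals <- as.matrix(x[, -1, drop = FALSE])
  mode(vals) <- "double"
  m <- as(as(Matrix::Matrix(vals, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(fid, colnames(x)[-1])
  m
}

#' Validate a count matrix
#'
#' Checks the count-matrix contract: non-negative integral entries and unique
#' feature/droplet identifiers. Called by the readers and by pipeline entry
#' points; exported for use on matrices built in memory.
#'
#' @param counts feature x droplet matrix (sparse or dense).
#' @return `counts`, invisibly, coerced to `dgCMatrix`.
#' @export
validate_counts <- function(counts) {
  counts <- as_counts(counts)
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v)))) {
    abort("count matrix entries must be non-negative integers",
          class = "dblkit_validation_error")
  }
  for (ax in 1:2) {
    ids <- dimnames(counts)[[ax]]
    if (!is.null(ids) && anyDuplicated(ids)) {
      abort(sprintf("duplicate %s identifiers in count matrix",
                    c("feature", "droplet")[ax]),
            class = "dblkit_validation_error")
    }
  }
  invisible(counts)
}

as_counts <- function(counts) {
  m <- as(as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("feature%d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("droplet%d", seq_len(ncol(m)))
  m
}

#' Write a count matrix as a Matrix Market triplet directory
#'
#' @param counts feature x droplet count matrix.
#' @param dir output directory, created if needed.
#' @export
write_counts <- function(counts, dir) {
  counts <- as_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(id = rownames(counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(id = colnames(counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  invisible(dir)
}

#' Read an ATAC fragment file
#'
#' Parses a BED-like tab-separated fragment file (chrom, start, end, barcode,
#' and optionally a count column, which is ignored for positioning). Gzip
#' input is handled transparently. Coordinates follow the common
#' fragments-file convention: 0-based, half-open `[start, end)`.
#'
#' @param path fragment file (`.tsv`, `.bed`, possibly `.gz`).
#' @return A tibble with columns `chrom`, `start`, `end`, `barcode`, one row
#'   per fragment.
#' @export
read_fragments <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  lines <- readLines(con)
  if (inherits(con, "connection")) close(con)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), barcode = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    abort(sprintf("fragment line %d has fewer than 4 fields",
                  which(nf < 4)[1]), class = "dblkit_parse_error")
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("non-integer coordinates on fragment line %d", bad[1]),
          class = "dblkit_parse_error")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort(sprintf("fragment line %d has start >= end", bad[1]),
          class = "dblkit_parse_error")
  }
  if (any(start < 0)) {
    abort("negative fragment start coordinate", class = "dblkit_parse_error")
  }
  tibble(
    chrom = vapply(parts, `[[`, "", 1),
    start = start,
    end = end,
    barcode = vapply(parts, `[[`, "", 4)
  )
}

#' Construct a doublet score table
#'
#' @param droplet_id character droplet identifiers.
#' @param score doublet scores in `[0, 1]`.
#' @param threshold calling threshold; droplets with `score >= threshold` are
#'   classed as doublets.
#' @param ... further per-run metadata stored as attributes (e.g. the
#'   threshold search context).
#' @return A tibble of class `dblkit_scores` with columns `droplet_id`,
#'   `score`, `class`.
#' @export
score_table <- function(droplet_id, score, threshold, ...) {
  stopifnot(length(droplet_id) == length(score))
  if (length(score) && (any(!is.finite(score)) || any(score < 0 | score > 1))) {
    abort("scores must be finite and within [0, 1]",
          class = "dblkit_validation_error")
  }
  out <- tibble(
    droplet_id = as.character(droplet_id),
    score = as.numeric(score),
    class = factor(ifelse(score >= threshold, "doublet", "singlet"),
                   levels = c("singlet", "doublet"))
  )
  attr(out, "threshold") <- threshold
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("dblkit_scores", class(out))
  out
}

#' Write a score table to TSV
#'
#' Scores are written at full precision so that [read_scores()] reproduces the
#' table exactly; the threshold is stored in a header comment.
#'
#' @param table a `dblkit_scores` tibble from [score_table()] or
#'   [detect_doublets()].
#' @param path output file.
#' @export
write_scores <- function(table, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  thr <- attr(table, "threshold")
  # per-sample (split) runs carry one threshold per sample; record NA here
  if (length(thr) != 1) thr <- NA_real_
  writeLines(sprintf("# threshold=%s", format(thr, digits = 17)), con)
  writeLines("droplet_id\tscore\tclass", con)
  if (nrow(table)) {
    writeLines(sprintf("%s\t%s\t%s", table$droplet_id,
                       format(table$score, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       as.character(table$class)), con)
  }
  invisible(path)
}

#' Read a score table written by [write_scores()]
#' @param path TSV file.
#' @return a `dblkit_scores` tibble.
#' @export
read_scores <- function(path) {
  lines <- readLines(path)
  thr <- NA_real_
  if (length(lines) && grepl("^# threshold=", lines[1])) {
    raw <- sub("^# threshold=", "", lines[1])
    thr <- if (raw == "NA") NA_real_ else as.numeric(raw)
    lines <- lines[-1]
  }
  stopifnot(length(lines) >= 1, lines[1] == "droplet_id\tscore\tclass")
  lines <- lines[-1]
  if (!length(lines)) return(score_table(character(), numeric(), thr))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  score_table(vapply(parts, `[[`, "", 1),
              as.numeric(vapply(parts, `[[`, "", 2)), thr)
}

#' @export
print.dblkit_scores <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("# Doublet scores: %d droplets, %d called (threshold %.4g)\n",
              nrow(x), sum(x$class == "doublet"), thr))
  NextMethod()
}
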