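#' Read a sparse count matrix with TSV sidecars
#'
#' Reads a MatrixMarket file plus `features.tsv` / `cells.tsv` sidecars
#' (first column: identifier; further columns become feature/cell
#' metadata). MatrixMarket indices are 1-based in the file and converted
#' internally. Gzip-compressed inputs are handled transparently.
#'
#' @param mtx_path path to the `.mtx` (or `.mtx.gz`) file.
#' @param features_path,cells_path paths to the sidecar TSVs (no
#'   header).
#' @return An [count_matrix()] object.
#' @export
read_count_matrix <- function(mtx_path, features_path, cells_path) {
  for (p in c(mtx_path, features_path, cells_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(mtx_path)
  if (any(dim(m) == 0)) stop("empty matrix in ", mtx_path)
  feats <- read.table(features_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
  cells <- read.table(cells_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stop("dimension mismatch: ", nrow(feats), " features in sidecar vs ",
         nrow(m), " matrix rows")
  if (nrow(cells) != ncol(m))
    stop("dimension mismatch: ", nrow(cells), " cells in sidecar vs ",
         ncol(m), " matrix columns")
  fmeta <- if (ncol(feats) > 1) feats[, -1, drop = FALSE]
  cmeta <- if (ncol(cells) > 1) cells[, -1, drop = FALSE]
  if (!is.null(fmeta)) names(fmeta) <- paste0("V", seq_len(ncol(fmeta)))
  count_matrix(m, feature_ids = feats[[1]], cell_ids = cells[[1]],
               cell_meta = cmeta, feature_meta = fmeta)
}

#' Write a count matrix as MTX with TSV sidecars
#'
#' @param x an [count_matrix()] object.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the paths written (`mtx`, `features`, `cells`).
#' @export
write_count_matrix <- function(x, dir, prefix = "matrix") {
  stopifnot(inherits(x, "sct_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(mtx = file.path(dir, paste0(prefix, ".mtx")),
                features = file.path(dir, paste0(prefix, "_features.tsv")),
                cells = file.path(dir, paste0(prefix, "_cells.tsv")))
  Matrix::writeMM(x$counts, paths$mtx)
  fdf <- data.frame(id = x$feature_ids)
  if (!is.null(x$feature_meta)) fdf <- cbind(fdf, x$feature_meta)
  cdf <- data.frame(id = x$cell_ids)
  if (!is.null(x$cell_meta)) cdf <- cbind(cdf, x$cell_meta)
  write.table(fdf, paths$features, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cdf, paths$cells, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Read a BED file of intervals (0-based half-open)
#'
#' Minimal three-plus-column BED reader with per-line validation; a
#' malformed line raises an error naming its line number.
#'
#' @param path BED file path (plain or gzipped).
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) stop("malformed BED line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end)
      stop("malformed BED line ", i, ": bad coordinates '", p[2], "-", p[3], "'")
    out[[i]] <- data.frame(chrom = p[1], start = start, end = end,
                           name = if (length(p) >= 4) p[4] else NA_character_,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and
#'   optionally a name column (`name` or `peak_id`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  nm <- if (!is.null(intervals$name)) intervals$name
        else if (!is.null(intervals$peak_id)) intervals$peak_id
  df <- data.frame(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(nm)) df$name <- nm
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (one set per line: name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(p) {
    if (length(p) < 3) stop("malformed GMT line: '", p[1], "'")
    p[-(1:2)]
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Annotate peaks with distance to the nearest TSS
#'
#' Computes the signed distance from each peak midpoint to the nearest
#' transcription start site on the same chromosome and labels peaks
#' `proximal` when the absolute distance is at most `threshold_kb`
#' kilobases, `distal` otherwise. Peaks on chromosomes absent from the
#' TSS table get `NA` distance and label.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param tss data.frame of TSS records (`chrom`, `start`, `end`); the
#'   TSS position is taken as `start`.
#' @param threshold_kb proximal/distal cutoff in kb (default 2.5).
#' @return `peaks` with added `tss_distance` (signed, peak midpoint
#'   minus TSS) and `annotation` ("proximal"/"distal"/NA).
#' @export
annotate_peak_distance <- function(peaks, tss, threshold_kb = 2.5) {
  mid <- (peaks$start + peaks$end) %/% 2
  dist_out <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    sites <- sort(tss$start[tss$chrom == ch])
    if (!length(sites)) next
    idx <- which(peaks$chrom == ch)
    pos <- findInterval(mid[idx], sites)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(sites))
    d_lo <- mid[idx] - sites[lo]
    d_hi <- mid[idx] - sites[hi]
    d <- ifelse(pos == 0, d_hi,
                ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi))
    dist_out[idx] <- d
  }
  peaks$tss_distance <- dist_out
  peaks$annotation <- ifelse(is.na(dist_out), NA_character_,
                             ifelse(abs(dist_out) <= threshold_kb * 1000,
                                    "proximal", "distal"))
  peaks
}
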