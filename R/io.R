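# Readers and writers for the external formats the pipeline touches:
# Matrix Market bundles with features/barcodes sidecars and optional spot
# coordinates, BED peak files with a GC column, delimited gene-signature
# files and score tables, and the YAML run config. Readers validate and
# reject rather than coerce; writers emit files their readers accept and
# prefix a provenance header (package version, seed, config hash — never a
# timestamp, so outputs are checksum-stable).

provenance_header <- function(seed = NA, config_hash = NA) {
  sprintf("# flscape %s seed=%s config_hash=%s",
          as.character(utils::packageVersion("flscape")),
          as.character(seed), as.character(config_hash))
}

#' Write a Matrix Market bundle
#'
#' Writes `matrix.mtx` (features x barcodes, the CellRanger dialect),
#' `features.tsv`, `barcodes.tsv` and optionally `coords.tsv`
#' (barcode, array_row, array_col).
#'
#' @param counts Observations x features matrix (dense or sparse) with
#'   dimnames.
#' @param dir Output directory (created if absent).
#' @param coords Optional coordinates data frame.
#' @param seed,config_hash Provenance fields for the sidecar headers.
#' @return `dir`, invisibly.
#' @export
write_mtx_bundle <- function(counts, dir, coords = NULL, seed = NA,
                             config_hash = NA) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_validation("counts must carry both barcodes (rows) and features (columns) as dimnames")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as(Matrix::Matrix(Matrix::t(as(counts, "CsparseMatrix"))), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  hdr <- provenance_header(seed, config_hash)
  writeLines(c(hdr, rownames(m)), file.path(dir, "features.tsv"))
  writeLines(c(hdr, colnames(m)), file.path(dir, "barcodes.tsv"))
  if (!is.null(coords)) {
    con <- file(file.path(dir, "coords.tsv"), "w")
    writeLines(hdr, con)
    write.table(coords, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}

read_sidecar <- function(path) {
  x <- readLines(path)
  x[!startsWith(x, "#")]
}

#' Read a Matrix Market bundle
#'
#' Orientation is auto-detected from the sidecar lengths (both the
#' features x barcodes dialect and its transpose are accepted); the result
#' is always observations x features. Duplicate barcodes, dimension
#' mismatches and non-integer values (in `mode = "counts"`) or
#' non-binary values (in `mode = "binary"`) are rejected with classed
#' errors.
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and optionally `coords.tsv`.
#' @param mode `"counts"` (nonnegative integers) or `"binary"`.
#' @return dgCMatrix, observations x features, with attribute
#'   `orientation` recording the on-disk layout and attribute `coords` when
#'   a coordinates sidecar is present.
#' @export
read_mtx_bundle <- function(dir, mode = c("counts", "binary")) {
  mode <- match.arg(mode)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_missing_input(sprintf("missing input file(s): %s",
                               paste(missing, collapse = ", ")))
  m <- Matrix::readMM(paths[1L])
  # pattern/logical Matrix Market dialects carry no value slot; coerce
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  features <- read_sidecar(paths[2L])
  barcodes <- read_sidecar(paths[3L])
  if (anyDuplicated(barcodes))
    stop_flscape("duplicate barcodes in sidecar", class = "flscape_duplicate_barcode")
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    orientation <- "features_x_barcodes"
    dimnames(m) <- list(features, barcodes)
    m <- Matrix::t(m)
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    orientation <- "barcodes_x_features"
    dimnames(m) <- list(barcodes, features)
  } else {
    stop_flscape(sprintf(
      "matrix is %d x %d but sidecars have %d features / %d barcodes",
      nrow(m), ncol(m), length(features), length(barcodes)),
      class = "flscape_dim_mismatch")
  }
  m <- as(m, "CsparseMatrix")
  if (mode == "counts" && length(m@x) &&
      (any(m@x < 0) || any(m@x != round(m@x))))
    stop_flscape("non-integer or negative values where counts expected",
                 class = "flscape_noninteger")
  if (mode == "binary" && length(m@x) && !all(m@x %in% c(0, 1)))
    stop_flscape("non-binary values where a binary matrix was expected",
                 class = "flscape_nonbinary")
  cpath <- file.path(dir, "coords.tsv")
  if (file.exists(cpath)) {
    coords <- read.table(cpath, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
    if (!all(rownames(m) %in% coords$barcode))
      stop_flscape("coords sidecar does not cover all barcodes",
                   class = "flscape_dim_mismatch")
    attr(m, "coords") <- coords[match(rownames(m), coords$barcode), ,
                                drop = FALSE]
  }
  attr(m, "orientation") <- orientation
  m
}

#' Write peaks as BED with a GC column
#'
#' Columns: chrom, start, end, name, gc (0-based half-open intervals).
#'
#' @param peaks Data frame with `chrom`, `start`, `end`, optional `name`
#'   and `gc`.
#' @param path Output path.
#' @param seed,config_hash Provenance fields.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path, seed = NA, config_hash = NA) {
  if (is.null(peaks$name)) peaks$name <- sprintf("peak%05d", seq_len(nrow(peaks)))
  cols <- c("chrom", "start", "end", "name", if (!is.null(peaks$gc)) "gc")
  con <- file(path, "w")
  writeLines(provenance_header(seed, config_hash), con)
  write.table(peaks[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a BED peak file
#'
#' Intervals are 0-based half-open (`end > start` required; a violation is
#' reported with its line number). A numeric 5th column (or 4th when no
#' name column is present) is parsed as GC fraction and must lie in
#' `[0, 1]`. Unsorted input is preserved but flagged via the `sorted`
#' attribute.
#'
#' @param path BED path.
#' @return Data frame `chrom`, `start`, `end`, `name`, `gc` (when present),
#'   `width`, with attribute `sorted`.
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop_missing_input(sprintf("no such file: %s", path))
  lines <- readLines(path)
  data_idx <- which(!startsWith(lines, "#") & !startsWith(lines, "track") &
                      nzchar(lines))
  if (!length(data_idx)) stop_validation("empty BED file")
  parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop_validation(sprintf("line %d: fewer than 3 BED columns",
                            data_idx[which(ncols < 3L)[1L]]))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) | end <= start)
  if (length(bad))
    stop_validation(sprintf("line %d: invalid interval (end must exceed start)",
                            data_idx[bad[1L]]))
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  col4 <- if (all(ncols >= 4L)) vapply(parts, `[[`, "", 4L) else NULL
  col5 <- if (all(ncols >= 5L)) vapply(parts, `[[`, "", 5L) else NULL
  if (!is.null(col5)) {
    out$name <- col4
    out$gc <- as.numeric(col5)
  } else if (!is.null(col4)) {
    gc_try <- suppressWarnings(as.numeric(col4))
    if (all(is.finite(gc_try))) out$gc <- gc_try else out$name <- col4
  }
  if (!is.null(out$gc) && (any(!is.finite(out$gc)) | any(out$gc < 0 | out$gc > 1)))
    stop_validation("GC column outside [0, 1]")
  out$width <- out$end - out$start
  sorted <- identical(order(chrom, start), seq_along(chrom))
  if (!sorted) message("BED input is not coordinate-sorted; order preserved")
  attr(out, "sorted") <- sorted
  out
}

#' Write a gene signature file
#'
#' Tab-delimited with header `gene  direction` (`up`/`down`) and a
#' provenance header comment.
#'
#' @param sig A [gene_signature()].
#' @param path Output path.
#' @param seed,config_hash Provenance fields.
#' @return `path`, invisibly.
#' @export
write_signature_file <- function(sig, path, seed = NA, config_hash = NA) {
  df <- data.frame(
    gene = c(sig$up, sig$down),
    direction = c(rep("up", length(sig$up)), rep("down", length(sig$down))),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines(c(provenance_header(seed, config_hash),
               sprintf("# signature=%s provenance=%s", sig$name,
                       gsub("\n", " ", sig$provenance))), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a gene signature file
#'
#' @param path Tab-delimited file with columns `gene`, `direction`.
#' @param name Optional signature name (default: file base name).
#' @return A [gene_signature()]. An empty file yields an empty signature
#'   with a warning; an unknown direction token or a gene listed with
#'   conflicting directions is an error.
#' @export
read_signature_file <- function(path, name = NULL) {
  if (!file.exists(path)) stop_missing_input(sprintf("no such file: %s", path))
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) <= 1L || all(!nzchar(lines[-1L]))) {
    warning("empty signature file")
    return(suppressWarnings(gene_signature(name)))
  }
  df <- read.table(text = lines, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(df)))
    stop_validation("signature file must have columns gene, direction")
  bad <- setdiff(unique(df$direction), c("up", "down"))
  if (length(bad))
    stop_validation(sprintf("unknown direction token: '%s'", bad[1L]))
  conflict <- intersect(df$gene[df$direction == "up"],
                        df$gene[df$direction == "down"])
  if (length(conflict))
    stop_validation(sprintf("gene '%s' listed with conflicting directions",
                            conflict[1L]))
  gene_signature(name, up = df$gene[df$direction == "up"],
                 down = df$gene[df$direction == "down"],
                 provenance = sprintf("read from %s", basename(path)))
}

#' Write a delimited score/metadata table with provenance header
#'
#' @param df Data frame or matrix.
#' @param path Output path.
#' @param seed,config_hash Provenance fields.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(df, path, seed = NA, config_hash = NA) {
  if (is.matrix(df))
    df <- data.frame(id = rownames(df) %||% seq_len(nrow(df)), df,
                     stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, "w")
  writeLines(provenance_header(seed, config_hash), con)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML with `seed`, `thresholds`, `sizes`, `masks`, `paths`. Threshold
#' ranges are validated (e.g. fractions in `[0, 1]`).
#'
#' @param path YAML path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_missing_input(sprintf("no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  th <- cfg$thresholds %||% list()
  defaults <- list(signature_alpha = 0.05, sc_de_bonferroni = 0.05,
                   gsea_bh = 0.25, mito_max = 0.2, libsize_min = 1024,
                   tf_gate = 0.2, gene_min_spots = 10, gene_max_frac = 0.95,
                   anchor_quantile = 0.9)
  for (nm in names(defaults)) th[[nm]] <- th[[nm]] %||% defaults[[nm]]
  fracs <- c("signature_alpha", "sc_de_bonferroni", "gsea_bh", "mito_max",
             "tf_gate", "gene_max_frac", "anchor_quantile")
  for (nm in fracs)
    if (th[[nm]] < 0 || th[[nm]] > 1)
      stop_validation(sprintf("threshold '%s' outside [0, 1]", nm))
  if (th$libsize_min < 0 || th$gene_min_spots < 0)
    stop_validation("count thresholds must be nonnegative")
  cfg$thresholds <- th
  cfg$seed <- cfg$seed %||% 1L
  cfg$config_path <- path
  cfg$config_hash <- unname(tools::md5sum(path))
  structure(cfg, class = c("run_config", class(cfg)))
}
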