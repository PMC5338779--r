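#' Read a gene x sample expression table
#'
#' Reads a delimited text table (tab or comma; sniffed from the header line
#' unless `delim` is given) or a MatrixMarket triplet with gene/sample ID
#' sidecar files, and returns a validated [expr_mat]. Readers reject rather
#' than repair: duplicate gene IDs, negative values and non-numeric cells are
#' errors with coordinates, never silently collapsed or coerced.
#'
#' @param path Path to the table (or `.mtx` file).
#' @param unit Abundance unit of the stored values: `"counts"`, `"CPM"` or
#'   `"FPKM"`.
#' @param orientation `"genes_in_rows"` (default; first column = gene IDs,
#'   remaining columns = samples) or `"genes_in_cols"` (transposed layout,
#'   first column = sample IDs).
#' @param delim Optional explicit delimiter, `"\t"` or `","`.
#' @param genes_file,samples_file Sidecar files (one ID per line) required
#'   when `path` is a MatrixMarket `.mtx` file.
#' @return An [expr_mat].
#' @export
read_expression_table <- function(path, unit,
                                  orientation = c("genes_in_rows", "genes_in_cols"),
                                  delim = NULL, genes_file = NULL, samples_file = NULL) {
  orientation <- match.arg(orientation)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    return(read_expression_mtx(path, unit, genes_file, samples_file))
  }
  delim <- delim %||% sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) {
    abort(paste0("expression table '", path, "' needs an ID column plus at least one value column"),
          class = "channelscreen_format_error")
  }
  names(raw)[1] <- if (orientation == "genes_in_rows") "gene_id" else "sample_id"
  id <- raw[[1]]
  num <- raw[-1]
  for (j in names(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad) > 0) {
      abort(paste0("non-numeric cell '", num[[j]][bad[1]], "' at row ", bad[1] + 1,
                   " (", id[bad[1]], "), column '", j, "' of ", path),
            class = "channelscreen_parse_error")
    }
    num[[j]] <- v
  }
  tbl <- bind_cols(tibble(id = id), num)
  if (orientation == "genes_in_cols") {
    m <- as.matrix(tbl[-1])
    rownames(m) <- tbl$id
    m <- t(m)
    tbl <- bind_cols(tibble(id = rownames(m)), as_tibble(m))
  }
  names(tbl)[1] <- "gene_id"
  expr_mat(tbl, unit = unit)
}

read_expression_mtx <- function(path, unit, genes_file, samples_file) {
  if (is.null(genes_file) || is.null(samples_file)) {
    abort("MTX input requires genes_file and samples_file sidecars",
          class = "channelscreen_format_error")
  }
  m <- as.matrix(Matrix::readMM(path))
  genes <- readr::read_lines(genes_file)
  samples <- readr::read_lines(samples_file)
  if (nrow(m) != length(genes) || ncol(m) != length(samples)) {
    abort(paste0("MTX dimensions ", nrow(m), "x", ncol(m),
                 " do not match sidecars (", length(genes), " genes, ",
                 length(samples), " samples)"),
          class = "channelscreen_format_error")
  }
  rownames(m) <- genes
  colnames(m) <- samples
  expr_from_matrix(m, unit = unit)
}

#' Write an expression table as TSV
#'
#' Inverse of [read_expression_table()]; full double precision is kept so
#' that read-after-write reproduces the object within representation
#' precision (bit-exact for integer counts).
#'
#' @param x An [expr_mat].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_mat"))
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

sniff_delim <- function(path) {
  header <- readr::read_lines(path, n_max = 1)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else {
    abort(paste0("cannot detect delimiter (tab or comma) in '", path,
                 "'; pass delim explicitly"),
          class = "channelscreen_format_error")
  }
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id` plus any of `group` (`tumor`/`control`),
#' `isolate_id`, `subtype`, `region`; extra columns pass through. Region
#' labels are restricted to the seven anatomic compartments
#' (LE, IT, CT, PZ, PAN, HBV, MVP).
#'
#' @param path Path to a TSV/CSV file.
#' @param expr Optional [expr_mat]; if given, metadata must cover each of its
#'   samples exactly once.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path, expr = NULL) {
  meta <- readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE, progress = FALSE)
  validate_metadata(meta, expr)
}

validate_metadata <- function(meta, expr = NULL) {
  meta <- as_tibble(meta)
  if (!"sample_id" %in% names(meta)) {
    abort("metadata must have a sample_id column", class = "channelscreen_validation_error")
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicate sample_id in metadata", class = "channelscreen_validation_error")
  }
  if ("group" %in% names(meta) && !all(meta$group %in% .group_levels)) {
    abort("group must be 'tumor' or 'control'", class = "channelscreen_validation_error")
  }
  if ("region" %in% names(meta)) {
    bad <- setdiff(unique(meta$region[!is.na(meta$region)]), .region_levels)
    if (length(bad) > 0) {
      abort(paste0("unknown region label(s): ", paste(bad, collapse = ", "),
                   " (expected ", paste(.region_levels, collapse = "/"), ")"),
            class = "channelscreen_validation_error")
    }
  }
  if (!is.null(expr)) {
    missing <- setdiff(expr_samples(expr), meta$sample_id)
    if (length(missing) > 0) {
      abort(paste0("metadata missing sample(s): ", paste(missing, collapse = ", ")),
            class = "channelscreen_validation_error")
    }
  }
  meta
}
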