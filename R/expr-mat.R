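#' Expression matrix container
#'
#' An `expr_mat` is a wide tibble — one `gene_id` column followed by one
#' numeric column per sample — carrying a unit tag (`"counts"`, `"CPM"` or
#' `"FPKM"`). Downstream operations declare which units they accept, so the
#' tag travels with the data and unit mismatches fail loudly instead of
#' silently producing nonsense.
#'
#' @param x A data frame with a `gene_id` character column and numeric
#'   sample columns.
#' @param unit One of `"counts"`, `"CPM"`, `"FPKM"`.
#' @return A tibble of class `expr_mat` with a `unit` attribute.
#' @examples
#' m <- expr_mat(tibble::tibble(gene_id = c("A", "B"), s1 = c(0, 2), s2 = c(1, 3)),
#'               unit = "counts")
#' expr_unit(m)
#' @export
expr_mat <- function(x, unit) {
  unit <- match.arg(unit, .unit_levels)
  x <- as_tibble(x)
  if (!"gene_id" %in% names(x)) {
    abort("expression table must have a 'gene_id' column", class = "channelscreen_format_error")
  }
  x <- dplyr::relocate(x, "gene_id")
  x$gene_id <- as.character(x$gene_id)
  validate_expr_mat(x)
  structure(x, unit = unit, class = c("expr_mat", class(as_tibble(x))))
}

validate_expr_mat <- function(x) {
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene identifiers: ", paste(unique(dup), collapse = ", ")),
          class = "channelscreen_validation_error")
  }
  val_cols <- setdiff(names(x), "gene_id")
  if (length(val_cols) == 0) {
    abort("expression table has no sample columns", class = "channelscreen_format_error")
  }
  if (anyDuplicated(val_cols)) {
    abort("duplicate sample identifiers", class = "channelscreen_validation_error")
  }
  for (s in val_cols) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(paste0("non-numeric values in sample column '", s, "'"),
            class = "channelscreen_parse_error")
    }
    if (anyNA(v)) {
      abort(paste0("missing values in sample '", s, "' (gene ",
                   x$gene_id[which(is.na(v))[1]], "); absent genes must be explicit zeros"),
            class = "channelscreen_validation_error")
    }
    if (any(v < 0)) {
      i <- which(v < 0)[1]
      abort(paste0("negative value at gene '", x$gene_id[i], "', sample '", s, "'"),
            class = "channelscreen_format_error")
    }
  }
  invisible(x)
}

#' @rdname expr_mat
#' @export
expr_unit <- function(x) attr(x, "unit")

#' @rdname expr_mat
#' @export
expr_samples <- function(x) setdiff(names(x), "gene_id")

#' Convert an expr_mat to a plain numeric matrix (genes x samples)
#' @param x An `expr_mat`.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
expr_values <- function(x) {
  m <- as.matrix(as_tibble(x)[setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  m
}

#' Build an expr_mat from a numeric matrix
#' @param m Numeric matrix, genes in rows with rownames, samples in columns
#'   with colnames.
#' @inheritParams expr_mat
#' @export
expr_from_matrix <- function(m, unit) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  expr_mat(bind_cols(tibble(gene_id = rownames(m)), as_tibble(m)), unit = unit)
}

check_unit <- function(x, required, op) {
  if (!inherits(x, "expr_mat")) {
    abort(paste0(op, "() requires an expr_mat"), class = "channelscreen_validation_error")
  }
  if (!expr_unit(x) %in% required) {
    abort(paste0(op, "() requires unit ", paste(required, collapse = " or "),
                 ", got ", expr_unit(x)),
          class = "channelscreen_unit_error")
  }
  invisible(x)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat("# expr_mat [", nrow(x), " genes x ", length(expr_samples(x)),
      " samples], unit: ", expr_unit(x), "\n", sep = "")
  NextMethod()
}
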