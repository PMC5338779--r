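#' Read gene sets from a GMT file
#'
#' Standard Broad-dialect GMT: one set per line, tab-separated fields
#' `name`, `description`, then members. Duplicate members within a line are
#' collapsed with a warning; duplicate set names across lines are an error;
#' lines with fewer than three fields are a parse error naming the line.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors of class `gene_set_collection`,
#'   with a `provenance` attribute (the source path) and a tibble of set
#'   descriptions in attribute `descriptions`.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  desc <- character()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      abort(paste0("GMT line ", i, " has ", length(f),
                   " tab-separated field(s); need name, description, members"),
            class = "channelscreen_parse_error")
    }
    nm <- f[1]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort(paste0("GMT line ", i, " (set '", nm, "') has no members"),
            class = "channelscreen_validation_error")
    }
    if (anyDuplicated(members)) {
      warn(paste0("GMT set '", nm, "': duplicate members collapsed"))
      members <- unique(members)
    }
    if (nm %in% names(sets)) {
      abort(paste0("duplicate gene-set name '", nm, "' at GMT line ", i),
            class = "channelscreen_validation_error")
    }
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  structure(sets,
            provenance = path,
            descriptions = tibble(set = names(sets), description = unname(desc)),
            class = c("gene_set_collection", "list"))
}

#' Write gene sets to a GMT file
#' @param sets A named list of character vectors (or `gene_set_collection`).
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a gene -> family annotation table
#'
#' Two columns, `gene_id` and `family` (TSV/CSV). Each gene must map to
#' exactly one family.
#'
#' @param path Path to the annotation table.
#' @return A tibble with columns `gene_id`, `family`.
#' @export
read_family_annotation <- function(path) {
  fam <- readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "family") %in% names(fam))) {
    abort("family annotation needs columns gene_id and family",
          class = "channelscreen_format_error")
  }
  fam <- dplyr::distinct(as_tibble(fam)[c("gene_id", "family")])
  dup <- fam$gene_id[duplicated(fam$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("gene(s) annotated to more than one family: ",
                 paste(unique(dup), collapse = ", ")),
          class = "channelscreen_validation_error")
  }
  fam
}
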