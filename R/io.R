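#' Read and write region x gene matrices
#'
#' Delimited text with a header row of gene ids and a first column of region
#' ids; the dialect (tab or comma) is chosen by file extension (`.tsv` /
#' `.txt` = tab, `.csv` = comma).  Lines starting with `#` (provenance
#' headers) are ignored on read.  Round-trips are exact to the printed
#' precision (15 significant digits).
#'
#' @param x region x gene numeric matrix.
#' @param path file path.
#' @param header optional provenance comment line(s) written before the data.
#' @return `read_matrix` returns the matrix; `write_matrix` the path,
#'   invisibly.
#' @export
write_matrix <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  sep <- delim_for(path)
  writeLines(paste(c("region", colnames(x)), collapse = sep), con)
  body <- apply(x, 1, function(row)
    paste(formatC(row, digits = 15, format = "g"), collapse = sep))
  writeLines(paste(rownames(x), body, sep = sep), con)
  invisible(path)
}

delim_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  sep <- delim_for(path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  nfield <- lengths(regmatches(lines, gregexpr(sep, lines, fixed = TRUE))) + 1L
  if (length(unique(nfield)) > 1L) {
    bad <- which(nfield != nfield[1])[1]
    stop_invalid("ragged row at line ", bad, " of ", basename(path))
  }
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          check.names = FALSE, comment.char = "")
  if (anyDuplicated(names(df)[-1]))
    stop_invalid("duplicated gene column id in ", basename(path))
  if (anyDuplicated(df[[1]]))
    stop_invalid("duplicated region id in ", basename(path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene ids.  Set order is preserved; gene ids are
#' uppercased; duplicate genes within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @param universe gene universe for the resulting collection (default: the
#'   union of all genes in the file).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(gene_set_collection(setNames(list(), character(0)) , character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L)
    stop_invalid("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) {
    genes <- toupper(p[-(1:2)])
    if (anyDuplicated(genes))
      warning("duplicate genes in set '", p[1], "' deduplicated")
    unique(genes)
  })
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  gene_set_collection(sets, universe %||% unique(unlist(sets)))
}

#' Write a cohort to disk (donor TSVs + JSON manifest)
#'
#' @param cohort a `synthetic_cohort` (or list of [donor_expression()]).
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  donors <- if (inherits(cohort, "synthetic_cohort")) cohort$donors else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(donors))
  for (i in seq_along(donors)) {
    d <- donors[[i]]
    files[i] <- paste0(d$donor_id, ".tsv")
    write_matrix(d$values, file.path(dir, files[i]))
  }
  if (inherits(cohort, "synthetic_cohort"))
    write_atlas(cohort$atlas, file.path(dir, "atlas.csv"))
  manifest <- list(donors = vapply(donors, function(d) d$donor_id, character(1)),
                   files = files,
                   all_regions = donors[[1]]$all_regions,
                   atlas = if (inherits(cohort, "synthetic_cohort")) "atlas.csv"
                   else NULL)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  donors <- lapply(seq_along(manifest$donors), function(i) {
    vals <- read_matrix(file.path(dir, manifest$files[i]))
    donor_expression(manifest$donors[i], vals, manifest$all_regions)
  })
  atlas <- if (!is.null(manifest$atlas))
    read_atlas(file.path(dir, manifest$atlas)) else NULL
  structure(list(donors = donors, truth = NULL, atlas = atlas),
            class = "synthetic_cohort")
}

#' Write single-cell data as MatrixMarket + metadata TSV
#'
#' @param cells a `synthetic_cells` (or cell x gene matrix).
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_cells <- function(cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- if (inherits(cells, "synthetic_cells")) cells$values else cells
  Matrix::writeMM(Matrix::Matrix(vals, sparse = TRUE),
                  file.path(dir, "cells.mtx"))
  writeLines(colnames(vals), file.path(dir, "genes.txt"))
  meta <- data.frame(cell_id = rownames(vals),
                     cell_type = if (inherits(cells, "synthetic_cells"))
                       as.character(cells$cell_type) else NA_character_)
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cells
#' @export
read_cells <- function(dir) {
  vals <- as.matrix(Matrix::readMM(file.path(dir, "cells.mtx")))
  meta <- read.delim(file.path(dir, "metadata.tsv"), stringsAsFactors = FALSE)
  rownames(vals) <- meta$cell_id
  colnames(vals) <- readLines(file.path(dir, "genes.txt"))
  structure(list(values = vals, cell_type = factor(meta$cell_type),
                 latent = NULL),
            class = "synthetic_cells")
}

#' Write / read a long-format developmental expression table
#' @param dev data frame from [generate_development()].
#' @param path TSV path.
#' @export
write_development <- function(dev, path) {
  write.table(dev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_development
#' @export
read_development <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
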