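#' Read an LFQ abundance table
#'
#' Reads a tab-separated protein quantification table in the dialect of
#' MaxQuant `proteinGroups.txt`-style output: one row per protein group,
#' annotation columns, and one intensity column per sample identified by a
#' common prefix. Rows flagged in reverse-decoy or contaminant columns are
#' dropped when those columns exist. In raw-stage tables a `0` or blank
#' intensity means "not quantified" (the MaxQuant convention) and becomes a
#' masked missing value; at log2 and later stages only blank cells are
#' missing, so genuine zeros survive.
#'
#' @param path path to a tab-separated file. Lines starting with `#` are
#'   treated as comments (the package's own writers emit a `#` provenance
#'   header).
#' @param prefix prefix identifying intensity columns; the sample id is the
#'   column name with the prefix removed. Default `"LFQ intensity "`.
#' @param id_col,gene_col,desc_col annotation column names. When `id_col` is
#'   absent the reader falls back to `"Protein IDs"` / `"Majority protein
#'   IDs"`, and `gene_col` to `"Gene names"`, so both this package's own
#'   output and vendor exports parse without configuration.
#' @param stage the processing stage to tag the result with.
#' @return an [lfq_matrix].
#' @seealso [write_lfq_table()]
#' @export
read_lfq_table <- function(path, prefix = "LFQ intensity ",
                           id_col = "protein_id", gene_col = "gene_symbol",
                           desc_col = "description", stage = "raw") {
  stage <- match.arg(stage, lfq_stages())
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, na.strings = c("NA", "NaN")),
    error = function(e) stop_format("cannot parse '", path, "': ",
                                    conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) == 0)
    stop_format("no data rows in '", path, "'")

  int_cols <- grep(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", prefix)),
                   names(df), value = TRUE)
  if (!length(int_cols))
    stop_format("no intensity columns with prefix '", prefix, "' in '", path, "'")

  id_col <- pick_col(df, c(id_col, "Protein IDs", "Majority protein IDs"))
  if (is.null(id_col))
    stop_format("no protein identifier column in '", path, "'")
  gene_col <- pick_col(df, c(gene_col, "Gene names"))
  desc_col <- pick_col(df, c(desc_col, "Protein names"))

  # drop decoy / contaminant flagged rows when the columns exist
  for (flag in c("Reverse", "Potential contaminant", "Contaminant")) {
    if (flag %in% names(df)) df <- df[!(df[[flag]] %in% "+"), , drop = FALSE]
  }
  if (nrow(df) == 0) stop_format("all rows flagged as decoy/contaminant in '", path, "'")

  ids <- as.character(df[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_format("duplicate protein ids in '", path, "': ",
                paste(dup, collapse = ", "))

  vals <- as.matrix(df[, int_cols, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (stage == "raw") vals[!is.na(vals) & vals == 0] <- NA_real_
  colnames(vals) <- substring(int_cols, nchar(prefix) + 1L)
  rownames(vals) <- ids

  proteins <- data.frame(
    protein_id = ids,
    gene_symbol = if (is.null(gene_col)) ids else as.character(df[[gene_col]]),
    description = if (is.null(desc_col)) "" else as.character(df[[desc_col]]),
    stringsAsFactors = FALSE)
  lfq_matrix(vals, proteins, stage = stage)
}

pick_col <- function(df, candidates) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit)) hit[[1]] else NULL
}

#' Write an LFQ abundance table
#'
#' Writes the matrix in the tab-separated dialect [read_lfq_table()] reads,
#' preceded by a `#` provenance header recording the stage and any supplied
#' parameters. Raw-stage missing cells are written as `0` (the upstream
#' convention); later stages write blanks, keeping zero values unambiguous.
#'
#' @param x an [lfq_matrix].
#' @param path output path.
#' @param prefix intensity-column prefix, as in [read_lfq_table()].
#' @param provenance optional named list appended to the header line.
#' @return `path`, invisibly.
#' @export
write_lfq_table <- function(x, path, prefix = "LFQ intensity ",
                            provenance = list()) {
  stopifnot(inherits(x, "lfq_matrix"))
  header <- provenance_line(c(list(stage = x$stage), provenance))
  v <- x$values
  chr <- matrix(format_num(v), nrow(v), ncol(v))
  fill <- if (x$stage == "raw") "0" else ""
  chr[is.na(v)] <- fill
  out <- cbind(x$proteins, chr, stringsAsFactors = FALSE)
  names(out) <- c(names(x$proteins), paste0(prefix, colnames(v)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_num <- function(v) {
  # full double precision, locale-independent, no scientific surprise on read
  formatC(v, digits = 17, format = "g")
}

provenance_line <- function(fields) {
  paste0("# evlfq ", paste(names(fields),
                           vapply(fields, function(f) paste(format(f), collapse = ","),
                                  character(1)),
                           sep = "=", collapse = " "))
}

#' Read a sample-design table
#'
#' Reads a delimited file with columns `sample`, `condition` and optionally
#' `replicate` (a header is required; extra columns are ignored). Replicate
#' indices are assigned in file order within each condition when absent. The
#' resulting design is order-independent: shuffling the file rows yields the
#' same design up to row order, and consistency against a matrix is checked
#' at pipeline assembly via the sample ids.
#'
#' @param path path to a tab- or comma-separated file.
#' @return a [sample_design].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df)))
    stop_format("design file needs 'sample' and 'condition' columns")
  sample_design(df$sample, df$condition,
                replicate = if ("replicate" %in% names(df)) df$replicate)
}

#' Write a sample-design table
#'
#' @param design a [sample_design].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "sample_design"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(list(stage = "design")), con)
  utils::write.table(as.data.frame(design), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference identifier list
#'
#' Reads a plain-text list with one identifier per line, as exported from
#' extracellular-vesicle compendia such as ExoCarta or Vesiclepedia. Lines
#' starting with `#` are comments; identifiers are uppercased and
#' deduplicated so that set operations are case-insensitive.
#'
#' @param path path to the list.
#' @param name label for the reference set (defaults to the file name).
#' @return a list of class `reference_set` with elements `name` and
#'   `members` (sorted uppercase identifiers).
#' @export
read_reference <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  members <- sort(unique(toupper(lines)))
  if (!length(members))
    stop_format("no usable identifiers in '", path, "'")
  structure(list(name = name, members = members), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> '%s': %d identifiers\n", x$name,
              length(x$members)))
  invisible(x)
}

#' Apply an identifier mapping
#'
#' Applies a user-supplied two-column mapping (e.g. mouse gene symbol to
#' human equivalent) to a character vector of identifiers, verbatim; symbols
#' absent from the map pass through unchanged.
#'
#' @param ids character vector of identifiers.
#' @param map_path path to a two-column tab-separated file (from, to), no
#'   header required.
#' @return mapped character vector.
#' @export
map_identifiers <- function(ids, map_path) {
  if (!file.exists(map_path)) stop_format("file not found: ", map_path)
  m <- utils::read.table(map_path, header = FALSE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(m) < 2) stop_format("mapping file needs two columns")
  i <- match(ids, m[[1]])
  out <- ids
  out[!is.na(i)] <- m[[2]][i[!is.na(i)]]
  out
}
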