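#' Species tables
#'
#' A species table is the package's core container: one row per species (or
#' subspecies — subspecies are kept as independent records, never merged),
#' holding the taxon name, genus, maximum recorded shell length in mm, and
#' the shallowest/deepest recorded depth in m. Internally it is a plain
#' `data.frame` with class `"species_table"` and a `source` attribute giving
#' its provenance. The analysis variable throughout the package is
#' `log10(shell_length_mm)`; slopes and p-values are invariant to the log
#' base, and base 10 is the malacological convention.
#'
#' @param taxon_name character vector of unique taxon identifiers.
#' @param genus character vector of genus names.
#' @param shell_length_mm positive numeric, maximum recorded shell length (mm).
#' @param depth_min_m non-negative numeric, shallowest recorded depth (m).
#' @param depth_max_m non-negative numeric, deepest recorded depth (m);
#'   must be `>= depth_min_m` row-wise.
#' @param source character scalar provenance label.
#'
#' @return A `species_table` (a `data.frame` with the five columns above).
#' @examples
#' species_table(c("Conus alpha", "Conus beta"), c("Conus", "Conus"),
#'               c(45, 30), c(0, 300), c(150, 900))
#' @export
species_table <- function(taxon_name, genus, shell_length_mm,
                          depth_min_m, depth_max_m, source = "in-memory") {
  tab <- data.frame(
    taxon_name = as.character(taxon_name),
    genus = as.character(genus),
    shell_length_mm = as.numeric(shell_length_mm),
    depth_min_m = as.numeric(depth_min_m),
    depth_max_m = as.numeric(depth_max_m),
    stringsAsFactors = FALSE
  )
  validate_species_table(tab)
  attr(tab, "source") <- source
  class(tab) <- c("species_table", "data.frame")
  tab
}

validate_species_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  req <- c("taxon_name", "genus", "shell_length_mm", "depth_min_m", "depth_max_m")
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop("species table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(tab)) {
    if (any(!is.finite(tab$shell_length_mm)) || any(tab$shell_length_mm <= 0)) {
      stop("shell_length_mm must be positive and finite")
    }
    if (any(!is.finite(tab$depth_min_m)) || any(!is.finite(tab$depth_max_m)) ||
        any(tab$depth_min_m < 0) || any(tab$depth_min_m > tab$depth_max_m)) {
      stop("depth range must satisfy 0 <= depth_min_m <= depth_max_m")
    }
    if (anyDuplicated(tab$taxon_name)) {
      stop("taxon_name values must be unique within a table")
    }
  }
  invisible(tab)
}

#' Default column mapping for tab-separated species tables
#'
#' Maps the five logical fields onto header names. The defaults describe the
#' dialect this package writes; exports from other databases are adapted by
#' passing a modified map (a template for a Malacolog-style export ships in
#' `inst/extdata/s1_column_map.json`).
#'
#' @return Named character vector: logical field -> column header.
#' @export
default_column_map <- function() {
  c(taxon_name = "taxon", genus = "genus", shell_length_mm = "length_mm",
    depth_min_m = "depth_min_m", depth_max_m = "depth_max_m")
}

#' Read a species table from delimited text
#'
#' Reads a tab-separated UTF-8 file with one header row (lines starting with
#' `#` are ignored), validates each row, and drops — with a counted reason —
#' rows that are missing a field, fail numeric parsing, have a non-positive
#' shell length, or have an inverted depth range. Duplicate taxon names keep
#' the first occurrence with a warning. A summary of rows read / retained /
#' dropped is logged (suppress with `options(bathyrule.quiet = TRUE)`).
#'
#' @param path path to a delimited text file.
#' @param column_map named character vector mapping logical fields to column
#'   headers; see [default_column_map()].
#' @param sep field separator (tab).
#' @return A [species_table()] with a `drop_summary` attribute (named integer
#'   vector of drop reasons).
#' @export
read_species_table <- function(path, column_map = default_column_map(),
                               sep = "\t") {
  if (!file.exists(path)) stop("cannot read species table: no such file: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = "character",
                      fileEncoding = "UTF-8"),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  req <- c("taxon_name", "genus", "shell_length_mm", "depth_min_m", "depth_max_m")
  if (!all(req %in% names(column_map))) {
    stop("column_map must name all of: ", paste(req, collapse = ", "))
  }
  absent <- setdiff(unname(column_map[req]), names(raw))
  if (length(absent)) {
    stop("header is missing mapped column(s): ", paste(absent, collapse = ", "))
  }

  n_read <- nrow(raw)
  taxon <- trimws(raw[[column_map[["taxon_name"]]]])
  genus <- trimws(raw[[column_map[["genus"]]]])
  len <- suppressWarnings(as.numeric(raw[[column_map[["shell_length_mm"]]]]))
  dmin <- suppressWarnings(as.numeric(raw[[column_map[["depth_min_m"]]]]))
  dmax <- suppressWarnings(as.numeric(raw[[column_map[["depth_max_m"]]]]))

  drop <- c("missing field" = 0L, "non-numeric value" = 0L,
            "non-positive length" = 0L, "inverted depth range" = 0L,
            "duplicate taxon" = 0L)
  bad_missing <- is.na(taxon) | taxon == "" | is.na(genus) | genus == "" |
    raw[[column_map[["shell_length_mm"]]]] %in% c(NA, "") |
    raw[[column_map[["depth_min_m"]]]] %in% c(NA, "") |
    raw[[column_map[["depth_max_m"]]]] %in% c(NA, "")
  bad_numeric <- !bad_missing & (is.na(len) | is.na(dmin) | is.na(dmax))
  bad_len <- !bad_missing & !bad_numeric & len <= 0
  bad_depth <- !bad_missing & !bad_numeric & !bad_len & (dmin < 0 | dmin > dmax)
  keep <- !(bad_missing | bad_numeric | bad_len | bad_depth)
  drop["missing field"] <- sum(bad_missing)
  drop["non-numeric value"] <- sum(bad_numeric)
  drop["non-positive length"] <- sum(bad_len)
  drop["inverted depth range"] <- sum(bad_depth)

  taxon <- taxon[keep]; genus <- genus[keep]
  len <- len[keep]; dmin <- dmin[keep]; dmax <- dmax[keep]
  dup <- duplicated(taxon)
  if (any(dup)) {
    warning(sum(dup), " duplicate taxon name(s); keeping first occurrence")
    drop["duplicate taxon"] <- sum(dup)
    taxon <- taxon[!dup]; genus <- genus[!dup]
    len <- len[!dup]; dmin <- dmin[!dup]; dmax <- dmax[!dup]
  }
  if (!length(taxon)) stop("no valid rows retained from ", path)

  tab <- species_table(taxon, genus, len, dmin, dmax, source = path)
  attr(tab, "drop_summary") <- drop
  stage_log("read", "%d rows read, %d retained, %d dropped (%s)",
            n_read, nrow(tab), n_read - nrow(tab),
            paste(sprintf("%s: %d", names(drop), drop), collapse = "; "))
  tab
}

#' Write a species table as tab-separated text
#'
#' Writes the same dialect [read_species_table()] reads; a write-then-read
#' round trip reproduces the table field for field, and repeated writes of
#' the same table are byte-identical. Numeric fields are printed at full
#' precision (up to 15 significant digits).
#'
#' @param table a [species_table()].
#' @param path output file path.
#' @param column_map header names to use, as in [read_species_table()].
#' @return `path`, invisibly.
#' @export
write_species_table <- function(table, path, column_map = default_column_map()) {
  validate_species_table(table)
  out <- data.frame(
    a = table$taxon_name, b = table$genus,
    c = format(table$shell_length_mm, digits = 15, trim = TRUE,
               scientific = FALSE),
    d = format(table$depth_min_m, digits = 15, trim = TRUE, scientific = FALSE),
    e = format(table$depth_max_m, digits = 15, trim = TRUE, scientific = FALSE),
    stringsAsFactors = FALSE
  )
  names(out) <- unname(column_map[c("taxon_name", "genus", "shell_length_mm",
                                    "depth_min_m", "depth_max_m")])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  }
  invisible(path)
}

#' @export
print.species_table <- function(x, ...) {
  cat(sprintf("species_table: %d taxa, %d genera (source: %s)\n",
              nrow(x), length(unique(x$genus)),
              attr(x, "source") %||% "unknown"))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

# log10 shell sizes, the analysis scale used everywhere downstream
log_size <- function(table) log10(table$shell_length_mm)
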