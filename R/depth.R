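#' Depth classification rules
#'
#' Two schemes classify species as deep-sea or shallow-water from their
#' recorded depth ranges:
#'
#' * `midpoint`: a species is deep iff the midpoint of its depth range
#'   exceeds `boundary_m`; everything else is shallow. Total — no species is
#'   excluded. This liberal rule is the one under which the standard OLS test
#'   produces its false-positive artifact.
#' * `strict`: a species is shallow iff it was never recorded below
#'   `boundary_m` (`depth_max_m <= boundary_m`), deep iff it was only
#'   recorded below `deep_cutoff_m` (`depth_min_m > deep_cutoff_m`), and
#'   excluded otherwise. The cutoff is typically one of 200, 400, 600 or
#'   800 m, the boundary 200 m — the average Atlantic shelf limit and the
#'   base of the photic zone.
#'
#' At the boundary itself, shallow uses `<=` and deep uses strict `>`, so a
#' species recorded exactly at the boundary is shallow and never both.
#'
#' @param scheme `"midpoint"` or `"strict"`.
#' @param boundary_m shallow boundary in m (default 200).
#' @param deep_cutoff_m strict-scheme deep cutoff in m (`>= boundary_m`).
#' @return A `depth_rule` object.
#' @examples
#' depth_rule("strict", deep_cutoff_m = 400)
#' @export
depth_rule <- function(scheme = c("midpoint", "strict"), boundary_m = 200,
                       deep_cutoff_m = boundary_m) {
  scheme <- match.arg(scheme)
  stopifnot(boundary_m > 0, deep_cutoff_m > 0)
  if (scheme == "strict" && deep_cutoff_m < boundary_m) {
    stop("strict scheme requires deep_cutoff_m >= boundary_m")
  }
  structure(list(scheme = scheme, boundary_m = boundary_m,
                 deep_cutoff_m = deep_cutoff_m),
            class = "depth_rule")
}

#' @export
print.depth_rule <- function(x, ...) {
  if (x$scheme == "midpoint") {
    cat(sprintf("depth_rule: midpoint > %g m => deep, else shallow\n",
                x$boundary_m))
  } else {
    cat(sprintf(
      "depth_rule: strict; shallow = max depth <= %g m, deep = min depth > %g m\n",
      x$boundary_m, x$deep_cutoff_m))
  }
  invisible(x)
}

#' Depth-range midpoint
#'
#' The mean of a species' shallowest and deepest recorded depths, in m.
#'
#' @param table a [species_table()] (or any data frame with `depth_min_m`
#'   and `depth_max_m` columns).
#' @return Numeric vector of midpoints.
#' @export
depth_midpoint <- function(table) {
  (table$depth_min_m + table$depth_max_m) / 2
}

#' Classify species as deep, shallow or excluded
#'
#' Applies a [depth_rule()] to every record. Under the midpoint scheme the
#' categories `deep`/`shallow` partition the table; under the strict scheme
#' species recorded on both sides of the boundary/cutoff are `excluded`.
#'
#' @param table a [species_table()].
#' @param rule a [depth_rule()].
#' @return A data frame (`taxon_name`, `category`) with the rule attached as
#'   attribute `rule`; `category` is a factor with levels deep, shallow,
#'   excluded.
#' @export
classify_depth <- function(table, rule = depth_rule()) {
  validate_species_table(table)
  stopifnot(inherits(rule, "depth_rule"))
  if (rule$scheme == "midpoint") {
    cat_ <- ifelse(depth_midpoint(table) > rule$boundary_m, "deep", "shallow")
  } else {
    cat_ <- rep("excluded", nrow(table))
    cat_[table$depth_max_m <= rule$boundary_m] <- "shallow"
    cat_[table$depth_min_m > rule$deep_cutoff_m] <- "deep"
  }
  out <- data.frame(taxon_name = table$taxon_name,
                    category = factor(cat_, levels = c("deep", "shallow",
                                                       "excluded")),
                    stringsAsFactors = FALSE)
  attr(out, "rule") <- rule
  out
}

#' Exclude species by depth-range threshold
#'
#' Drops species whose ranges lie wholly (`range_min_exceeds`: minimum depth
#' beyond the threshold) or partly (`range_max_exceeds`: maximum depth beyond
#' the threshold) below `threshold_m` — used to remove abyssal (> 3000 m) or
#' bathypelagic (> 1000 m) species before the genus-level analysis. Two
#' exclusion counters are returned: `excluded_count` over all dropped species,
#' and, when `assignments` is supplied, `excluded_analysis_count` over dropped
#' species that were classified deep or shallow and whose genus had both a
#' deep and a shallow member (i.e. species that would otherwise have entered
#' the analysis).
#'
#' @param table a [species_table()].
#' @param mode `"range_min_exceeds"` or `"range_max_exceeds"`.
#' @param threshold_m positive depth threshold in m.
#' @param assignments optional result of [classify_depth()] on `table`, used
#'   for the analysis-scoped counter.
#' @return List with `table` (filtered [species_table()]), `excluded_count`,
#'   and `excluded_analysis_count` (NA when `assignments` is missing).
#' @export
exclude_by_depth <- function(table,
                             mode = c("range_min_exceeds", "range_max_exceeds"),
                             threshold_m, assignments = NULL) {
  validate_species_table(table)
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold_m), threshold_m > 0)
  drop <- if (mode == "range_min_exceeds") {
    table$depth_min_m > threshold_m
  } else {
    table$depth_max_m > threshold_m
  }
  n_analysis <- NA_integer_
  if (!is.null(assignments)) {
    cat_ <- assignments$category[match(table$taxon_name,
                                       assignments$taxon_name)]
    classified <- cat_ %in% c("deep", "shallow")
    two_sided <- vapply(
      split(cat_[classified], table$genus[classified]),
      function(v) any(v == "deep") && any(v == "shallow"), logical(1))
    in_analysis <- classified &
      table$genus %in% names(two_sided)[two_sided]
    n_analysis <- sum(drop & in_analysis)
  }
  kept <- table[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- class(table)
  attr(kept, "source") <- attr(table, "source")
  stage_log("exclude", "%s > %g m: %d species excluded (%s in analysis scope)",
            sub("range_|_exceeds", "", mode), threshold_m, sum(drop),
            ifelse(is.na(n_analysis), "NA", n_analysis))
  list(table = kept, excluded_count = sum(drop),
       excluded_analysis_count = n_analysis)
}
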