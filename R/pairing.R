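#' Group a classified species table into two-sided genera
#'
#' Keeps only genera containing at least one deep and one shallow species
#' (species classified `excluded` are dropped first). Each retained genus is
#' represented by its deep and shallow species subsets, carrying the log10
#' shell size and the depth-range midpoint of every member — everything the
#' pairing schemes and the permutation machinery need.
#'
#' @param table a [species_table()].
#' @param assignments result of [classify_depth()] on `table`.
#' @return A `genus_groups` object: named list (one element per genus, sorted
#'   by name) of lists with data frames `deep` and `shallow`, each with
#'   columns `taxon_name`, `log_size`, `midpoint_m`, `shell_length_mm`.
#' @export
group_into_genera <- function(table, assignments) {
  validate_species_table(table)
  cat_ <- as.character(
    assignments$category[match(table$taxon_name, assignments$taxon_name)])
  if (anyNA(cat_)) stop("assignments do not cover every record in the table")
  keep <- cat_ != "excluded"
  df <- data.frame(
    genus = table$genus[keep],
    taxon_name = table$taxon_name[keep],
    log_size = log10(table$shell_length_mm[keep]),
    midpoint_m = depth_midpoint(table)[keep],
    shell_length_mm = table$shell_length_mm[keep],
    category = cat_[keep],
    stringsAsFactors = FALSE
  )
  groups <- lapply(split(df, df$genus), function(g) {
    list(deep = g[g$category == "deep",
                  c("taxon_name", "log_size", "midpoint_m", "shell_length_mm")],
         shallow = g[g$category == "shallow",
                     c("taxon_name", "log_size", "midpoint_m",
                       "shell_length_mm")])
  })
  groups <- groups[vapply(groups, function(g) {
    nrow(g$deep) >= 1L && nrow(g$shallow) >= 1L
  }, logical(1))]
  groups <- groups[order(names(groups))]
  stage_log("group", "%d genera with both deep and shallow members",
            length(groups))
  structure(groups, class = "genus_groups")
}

#' @export
print.genus_groups <- function(x, ...) {
  nd <- vapply(x, function(g) nrow(g$deep), integer(1))
  ns <- vapply(x, function(g) nrow(g$shallow), integer(1))
  cat(sprintf("genus_groups: %d genera; deep species %d, shallow species %d\n",
              length(x), sum(nd), sum(ns)))
  invisible(x)
}

#' Filter genera on minimum species counts
#'
#' Retains genera with at least `min_deep` deep and `min_shallow` shallow
#' species. Counts are taken before any equalization, i.e. the filter is a
#' genus-inclusion criterion applied ahead of the balancing schemes; the 2/2
#' setting removes genera dominated by single isolated records.
#'
#' @param groups a `genus_groups` object from [group_into_genera()].
#' @param min_deep,min_shallow minimum species counts per side.
#' @return The filtered `genus_groups`.
#' @export
filter_min_counts <- function(groups, min_deep = 2L, min_shallow = 2L) {
  stopifnot(inherits(groups, "genus_groups"))
  keep <- vapply(groups, function(g) {
    nrow(g$deep) >= min_deep && nrow(g$shallow) >= min_shallow
  }, logical(1))
  out <- groups[keep]
  stage_log("filter", "min counts %d deep / %d shallow: %d of %d genera kept",
            min_deep, min_shallow, length(out), length(groups))
  structure(out, class = "genus_groups")
}

# Keep-priority orderings. Shallow species are kept shallowest-midpoint
# first, deep species deepest-midpoint first; ties broken by smaller shell
# length, then taxon name, so selection is deterministic.
keep_order_shallow <- function(df) {
  order(df$midpoint_m, df$shell_length_mm, df$taxon_name)
}
keep_order_deep <- function(df) {
  order(-df$midpoint_m, df$shell_length_mm, df$taxon_name)
}

#' Equalize deep and shallow species counts within a genus
#'
#' Trims the larger side to the size of the smaller so that both sides
#' contribute equally many species, removing the species that least separate
#' the two depth groups: when shallow outnumber deep, the shallow species
#' with the deepest range midpoints are removed (the shallowest are kept),
#' and vice versa when deep outnumber shallow. This greedy rule maximizes
#' the difference in mean depth-range midpoints between the retained deep
#' and shallow subsets over all equal-size subset pairs (the objective is a
#' sum of marginal terms, so keeping the extreme-midpoint species on each
#' side is optimal).
#'
#' @param deep,shallow data frames as stored in a `genus_groups` element.
#' @return List with trimmed `deep` and `shallow` data frames of equal size.
#' @export
equalize_counts <- function(deep, shallow) {
  stopifnot(nrow(deep) >= 1L, nrow(shallow) >= 1L)
  k <- min(nrow(deep), nrow(shallow))
  list(deep = deep[keep_order_deep(deep)[seq_len(k)], , drop = FALSE],
       shallow = shallow[keep_order_shallow(shallow)[seq_len(k)], ,
                         drop = FALSE])
}

#' Select the single most depth-separated deep/shallow pair
#'
#' Returns the one deep and one shallow species maximizing
#' (deep midpoint − shallow midpoint). The objective is separable, so this
#' is the deepest-midpoint deep species and the shallowest-midpoint shallow
#' species, with the same tie-breaks as [equalize_counts()].
#'
#' @inheritParams equalize_counts
#' @return List with one-row `deep` and `shallow` data frames.
#' @export
select_single_pair <- function(deep, shallow) {
  stopifnot(nrow(deep) >= 1L, nrow(shallow) >= 1L)
  list(deep = deep[keep_order_deep(deep)[1L], , drop = FALSE],
       shallow = shallow[keep_order_shallow(shallow)[1L], , drop = FALSE])
}

#' Build one (shallow, deep) log-size pair per genus
#'
#' Converts genus groups into the regression inputs: per genus, `x` is the
#' mean log10 shell length of the (possibly subset) shallow species and `y`
#' that of the deep species, means taken after the log transform to avoid
#' bias. Three balancing schemes are available:
#'
#' * `all_means` — means over all deep and all shallow congeners;
#' * `equalized` — means over equal-size subsets chosen by
#'   [equalize_counts()];
#' * `single_pair` — the single pair chosen by [select_single_pair()].
#'
#' @param groups a `genus_groups` object.
#' @param scheme balancing scheme.
#' @return A `genus_pairs` data frame: `genus`, `x` (shallow log10 size),
#'   `y` (deep log10 size), `n_shallow`, `n_deep` (counts used), `scheme`.
#' @examples
#' tab <- species_table(paste0("sp", 1:4), rep("Conus", 4),
#'                      c(10, 1000, 20, 80), c(0, 10, 500, 700),
#'                      c(100, 150, 900, 1200))
#' grp <- group_into_genera(tab, classify_depth(tab, depth_rule("strict")))
#' build_genus_pairs(grp, "all_means")
#' @export
build_genus_pairs <- function(groups,
                              scheme = c("all_means", "equalized",
                                         "single_pair")) {
  stopifnot(inherits(groups, "genus_groups"))
  scheme <- match.arg(scheme)
  rows <- lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    sel <- switch(scheme,
                  all_means = g,
                  equalized = equalize_counts(g$deep, g$shallow),
                  single_pair = select_single_pair(g$deep, g$shallow))
    data.frame(genus = gn,
               x = mean(sel$shallow$log_size),
               y = mean(sel$deep$log_size),
               n_shallow = nrow(sel$shallow),
               n_deep = nrow(sel$deep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||% data.frame(
    genus = character(), x = numeric(), y = numeric(),
    n_shallow = integer(), n_deep = integer())
  out$scheme <- rep(scheme, nrow(out))
  class(out) <- c("genus_pairs", "data.frame")
  out
}
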