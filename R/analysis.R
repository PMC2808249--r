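#' Specify a complete deep-vs-shallow size analysis
#'
#' Bundles every setting of one analysis run: the depth rule, an optional
#' abyssal/bathypelagic exclusion filter, the genus balancing scheme,
#' minimum per-genus species counts, and the permutation settings. The spec
#' is validated for internal consistency (e.g. an exclusion threshold must
#' exceed the deep cutoff, otherwise no deep species could remain).
#'
#' @param rule a [depth_rule()].
#' @param scheme pairing scheme, as in [build_genus_pairs()].
#' @param min_deep,min_shallow genus-inclusion minimum counts (1/1 = no
#'   filter).
#' @param exclude_mode `"none"`, `"range_min_exceeds"` or
#'   `"range_max_exceeds"`.
#' @param exclude_threshold_m threshold for the exclusion filter (m).
#' @param n_permutations permutation count for the SMA test.
#' @param seed integer seed for the permutation test.
#' @return An `analysis_spec` object.
#' @export
analysis_spec <- function(rule = depth_rule(), scheme = "all_means",
                          min_deep = 1L, min_shallow = 1L,
                          exclude_mode = c("none", "range_min_exceeds",
                                           "range_max_exceeds"),
                          exclude_threshold_m = 3000,
                          n_permutations = 100000L, seed = 1L) {
  exclude_mode <- match.arg(exclude_mode)
  stopifnot(inherits(rule, "depth_rule"), min_deep >= 1L, min_shallow >= 1L,
            n_permutations >= 1L)
  scheme <- match.arg(scheme, c("all_means", "equalized", "single_pair"))
  if (exclude_mode != "none" && rule$scheme == "strict" &&
      exclude_threshold_m <= rule$deep_cutoff_m) {
    stop("exclusion threshold must exceed the deep cutoff")
  }
  structure(list(rule = rule, scheme = scheme, min_deep = as.integer(min_deep),
                 min_shallow = as.integer(min_shallow),
                 exclude_mode = exclude_mode,
                 exclude_threshold_m = exclude_threshold_m,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "analysis_spec")
}

#' Run one end-to-end island-rule analysis
#'
#' Classifies the table under the spec's depth rule, applies any exclusion
#' filter, groups into two-sided genera, applies the minimum-count filter
#' and balancing scheme, then fits the SMA and OLS regressions and runs the
#' within-genus permutation test. Deterministic given the spec's seed.
#'
#' @param table a [species_table()].
#' @param spec an [analysis_spec()].
#' @param permute run the permutation test? (`FALSE` skips it, e.g. for
#'   slope-only table sweeps.)
#' @return An `analysis_result`: a list with `n` (genera), `sma`, `ols`
#'   ([ols_fit()]/[sma_fit()] objects), `perm` ([permutation_test()] object
#'   or `NULL`), `pairs`, `excluded_count`, `excluded_analysis_count`, and a
#'   `provenance` list recording every setting, the seed, the package
#'   version and an input checksum.
#' @examples
#' tab <- simulate_species_table(simulation_config(n_genera = 40, seed = 7))
#' res <- run_analysis(tab, analysis_spec(n_permutations = 999))
#' res$sma$slope
#' res$perm$p_two_tailed
#' @export
run_analysis <- function(table, spec = analysis_spec(), permute = TRUE) {
  validate_species_table(table)
  stopifnot(inherits(spec, "analysis_spec"))
  excl_n <- 0L
  excl_analysis <- NA_integer_
  work <- table
  if (spec$exclude_mode != "none") {
    assign0 <- classify_depth(work, spec$rule)
    ex <- exclude_by_depth(work, spec$exclude_mode, spec$exclude_threshold_m,
                           assignments = assign0)
    work <- ex$table
    excl_n <- ex$excluded_count
    excl_analysis <- ex$excluded_analysis_count
  }
  assignments <- classify_depth(work, spec$rule)
  groups <- group_into_genera(work, assignments)
  groups <- filter_min_counts(groups, spec$min_deep, spec$min_shallow)
  pairs <- build_genus_pairs(groups, spec$scheme)
  sma <- sma_fit(pairs)
  ols <- ols_fit(pairs)
  perm <- if (permute) {
    permutation_test(groups, spec$scheme,
                     n_permutations = spec$n_permutations, seed = spec$seed)
  }
  if (!is.null(perm)) perm$null_statistics <- NULL
  structure(list(
    n = nrow(pairs), sma = sma, ols = ols, perm = perm, pairs = pairs,
    excluded_count = excl_n, excluded_analysis_count = excl_analysis,
    provenance = list(
      rule = unclass(spec$rule), scheme = spec$scheme,
      min_deep = spec$min_deep, min_shallow = spec$min_shallow,
      exclude_mode = spec$exclude_mode,
      exclude_threshold_m = spec$exclude_threshold_m,
      n_permutations = spec$n_permutations, seed = spec$seed,
      source = attr(table, "source") %||% "unknown",
      input_checksum = sum(table$shell_length_mm) + sum(table$depth_max_m),
      n_input_species = nrow(table),
      package_version = as.character(utils::packageVersion("bathyrule")))),
    class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("island-rule analysis: n = %d genera (%s pairing)\n",
              x$n, x$provenance$scheme))
  cat(sprintf("  SMA slope b = %.3f", x$sma$slope))
  if (!is.null(x$perm)) {
    cat(sprintf("; permutation p = %.3f (%d permutations)",
                x$perm$p_two_tailed, x$perm$n_permutations))
  }
  cat("\n")
  cat(sprintf("  OLS slope b = %.3f; t-test p (H0 slope = 1) = %.4g\n",
              x$ols$slope, x$ols$p_value))
  invisible(x)
}

# Flatten an analysis_result to one result row.
result_record <- function(label, res) {
  data.frame(label = label, n = res$n,
             b_sma = res$sma$slope,
             p_perm = if (!is.null(res$perm)) res$perm$p_two_tailed
                      else NA_real_,
             b_ols = res$ols$slope, p_ols = res$ols$p_value,
             excluded = res$excluded_count, stringsAsFactors = FALSE)
}

#' Run a standard sweep of analysis settings
#'
#' Reproduces the structure of the standard result tables on any species
#' table:
#'
#' * `table1A` — strict rules at deep cutoffs 200/400/600/800 m crossed with
#'   the three balancing schemes (12 records, no count filter);
#' * `table1B` — the same 12 cells with the minimum 2 deep / 2 shallow
#'   genus filter;
#' * `table2` — abyssal/bathypelagic exclusions (min/max depth beyond
#'   3000 m and 1000 m) crossed with the strict 400 m no-filter analysis
#'   (part A) and the strict 200 m 2/2-filtered analysis (part B), 8
#'   records, all-means pairing;
#' * `fig1A` — the liberal midpoint rule with all-means pairing (OLS and
#'   SMA on the same 2-sided genera), 1 record.
#'
#' @param table a [species_table()].
#' @param suite one of `"table1A"`, `"table1B"`, `"table2"`, `"fig1A"`.
#' @param n_permutations permutations per cell (the sweeps run one
#'   permutation test per record; lower this for quick looks).
#' @param seed integer seed.
#' @param permute run permutation tests (slopes only when `FALSE`)?
#' @return A data frame of result records (`label`, `n`, `b_sma`, `p_perm`,
#'   `b_ols`, `p_ols`, `excluded`).
#' @export
run_table_suite <- function(table, suite = c("table1A", "table1B", "table2",
                                             "fig1A"),
                            n_permutations = 10000L, seed = 1L,
                            permute = TRUE) {
  suite <- match.arg(suite)
  cutoffs <- c(200, 400, 600, 800)
  schemes <- c("all_means", "equalized", "single_pair")
  recs <- list()
  if (suite %in% c("table1A", "table1B")) {
    mins <- if (suite == "table1B") 2L else 1L
    for (cut in cutoffs) {
      for (sch in schemes) {
        sp <- analysis_spec(depth_rule("strict", deep_cutoff_m = cut),
                            scheme = sch, min_deep = mins, min_shallow = mins,
                            n_permutations = n_permutations, seed = seed)
        recs[[length(recs) + 1L]] <- result_record(
          sprintf(">%dm/%s", cut, sch),
          run_analysis(table, sp, permute = permute))
      }
    }
  } else if (suite == "table2") {
    filt <- expand.grid(mode = c("range_min_exceeds", "range_max_exceeds"),
                        thr = c(3000, 1000), stringsAsFactors = FALSE)
    parts <- list(A = list(cut = 400, mins = 1L),
                  B = list(cut = 200, mins = 2L))
    for (p in names(parts)) {
      for (i in seq_len(nrow(filt))) {
        sp <- analysis_spec(
          depth_rule("strict", deep_cutoff_m = parts[[p]]$cut),
          scheme = "all_means", min_deep = parts[[p]]$mins,
          min_shallow = parts[[p]]$mins, exclude_mode = filt$mode[i],
          exclude_threshold_m = filt$thr[i],
          n_permutations = n_permutations, seed = seed)
        recs[[length(recs) + 1L]] <- result_record(
          sprintf("%s/%s>%dm", p, sub("range_|_exceeds", "", filt$mode[i]),
                  filt$thr[i]),
          run_analysis(table, sp, permute = permute))
      }
    }
  } else {
    sp <- analysis_spec(depth_rule("midpoint"), scheme = "all_means",
                        n_permutations = n_permutations, seed = seed)
    recs[[1L]] <- result_record("midpoint/all_means",
                                run_analysis(table, sp, permute = permute))
  }
  do.call(rbind, recs)
}

#' Read a genus-to-clade annotation file
#'
#' Two-column tab-separated text (`genus`, `clade`), used to split genus
#' pairs for [common_slope_test()] — e.g. Neogastropoda vs all other taxa.
#'
#' @param path path to the annotation TSV.
#' @return Data frame with `genus` and `clade` columns.
#' @export
read_clade_annotation <- function(path) {
  if (!file.exists(path)) stop("no such clade annotation file: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("genus", "clade") %in% names(ann))) {
    stop("clade annotation needs 'genus' and 'clade' columns")
  }
  ann
}

#' Split genus pairs by clade
#'
#' @param pairs a `genus_pairs` data frame.
#' @param annotation data frame from [read_clade_annotation()]; genera
#'   absent from it are pooled under `other_label`.
#' @param other_label label for unannotated genera.
#' @return Named list of `genus_pairs` data frames, ready for
#'   [common_slope_test()].
#' @export
split_pairs_by_clade <- function(pairs, annotation, other_label = "other") {
  lab <- annotation$clade[match(pairs$genus, annotation$genus)]
  lab[is.na(lab)] <- other_label
  split(as.data.frame(pairs), lab)
}

#' Serialize analysis results to JSON
#'
#' Writes one JSON record per analysis (method, slope, statistic, p, n plus
#' provenance) at full precision.
#'
#' @param results a data frame from [run_table_suite()] or a single
#'   `analysis_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  if (inherits(results, "analysis_result")) {
    out <- c(list(record = result_record("analysis", results)),
             list(provenance = results$provenance))
  } else {
    out <- list(records = results)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Diagnostic scatter plot of genus pairs
#'
#' Plots deep log size against shallow log size with the 1:1 null line and
#' the fitted SMA (solid) and OLS (dashed) lines.
#'
#' @param pairs a `genus_pairs` data frame.
#' @param ... passed to [plot()].
#' @return Invisibly, the fitted SMA and OLS objects.
#' @export
plot_genus_pairs <- function(pairs, ...) {
  sma <- sma_fit(pairs); ols <- ols_fit(pairs)
  plot(pairs$x, pairs$y,
       xlab = "shallow-water log10 shell length (mm)",
       ylab = "deep-sea log10 shell length (mm)", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::abline(sma$intercept, sma$slope, lty = 1)
  graphics::abline(ols$intercept, ols$slope, lty = 2)
  invisible(list(sma = sma, ols = ols))
}
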