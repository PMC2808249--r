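test_that("only genera with both deep and shallow members are retained", {
  tab <- toy_table()
  # strict rule at 200 m: Conus has 2 shallow + 1 deep; Oliva 1 + 1;
  # Natica has 1 shallow, 1 deep, 1 straddler (excluded)
  grp <- classified_groups(tab)
  expect_setequal(names(grp), c("Conus", "Oliva", "Natica"))
  expect_identical(nrow(grp$Conus$shallow), 2L)
  expect_identical(nrow(grp$Natica$deep), 1L)
  # drop all deep Conus records: genus must disappear
  tab2 <- tab[tab$taxon_name != "Conus gamma", ]
  class(tab2) <- class(tab)
  grp2 <- classified_groups(tab2)
  expect_false("Conus" %in% names(grp2))
})

test_that("pair means are means of log10 lengths, order-invariant", {
  grp <- classified_groups(toy_table())
  pairs <- build_genus_pairs(grp, "all_means")
  conus <- pairs[pairs$genus == "Conus", ]
  expect_equal(conus$x, mean(log10(c(10, 1000))))  # = 2
  expect_equal(conus$x, 2)
  expect_equal(conus$y, 2)                         # single deep sp., 100 mm
  # permutation invariance in species order
  tab <- toy_table()
  perm <- tab[rev(seq_len(nrow(tab))), ]
  class(perm) <- class(tab)
  pairs_rev <- build_genus_pairs(classified_groups(perm), "all_means")
  expect_equal(pairs_rev[order(pairs_rev$genus), c("x", "y")],
               pairs[order(pairs$genus), c("x", "y")],
               ignore_attr = TRUE)
})

test_that("equalization keeps the shallowest shallow / deepest deep species", {
  # worked example: 2 deep, 5 shallow; the 3 deepest-midpoint shallow
  # species must be removed, keeping midpoints {10, 50}
  deep <- data.frame(taxon_name = c("d1", "d2"), log_size = c(1, 2),
                     midpoint_m = c(500, 800), shell_length_mm = c(10, 100))
  shallow <- data.frame(taxon_name = paste0("s", 1:5), log_size = 1:5,
                        midpoint_m = c(10, 50, 90, 120, 180),
                        shell_length_mm = 10^(1:5))
  eq <- equalize_counts(deep, shallow)
  expect_setequal(eq$shallow$midpoint_m, c(10, 50))
  expect_identical(nrow(eq$deep), 2L)
  # vice versa: more deep than shallow keeps deepest-midpoint deep species
  deep3 <- data.frame(taxon_name = c("d1", "d2", "d3"), log_size = 1:3,
                      midpoint_m = c(300, 900, 1500),
                      shell_length_mm = c(10, 20, 30))
  sh1 <- shallow[1, ]
  eq2 <- equalize_counts(deep3, sh1)
  expect_identical(eq2$deep$midpoint_m, 1500)
  expect_identical(nrow(eq2$shallow), 1L)
  # equal counts: identity up to ordering
  eq3 <- equalize_counts(deep, shallow[1:2, ])
  expect_setequal(eq3$shallow$taxon_name, c("s1", "s2"))
  expect_setequal(eq3$deep$taxon_name, c("d1", "d2"))
})

test_that("greedy equalization matches brute-force subset enumeration", {
  set.seed(101)
  for (i in 1:60) {
    g <- random_genus(sample(1:5, 1), sample(1:5, 1))
    eq <- equalize_counts(g$deep, g$shallow)
    expect_identical(nrow(eq$deep), nrow(eq$shallow))
    expect_identical(nrow(eq$deep), min(nrow(g$deep), nrow(g$shallow)))
    expect_equal(mean(eq$deep$midpoint_m) - mean(eq$shallow$midpoint_m),
                 brute_force_best_diff(g$deep, g$shallow))
  }
})

test_that("single-pair selection matches exhaustive search over all pairs", {
  set.seed(202)
  for (i in 1:60) {
    g <- random_genus(sample(1:6, 1), sample(1:6, 1))
    sel <- select_single_pair(g$deep, g$shallow)
    best <- max(outer(g$deep$midpoint_m, g$shallow$midpoint_m, `-`))
    expect_equal(sel$deep$midpoint_m - sel$shallow$midpoint_m, best)
    expect_identical(nrow(sel$deep), 1L)
    expect_identical(nrow(sel$shallow), 1L)
  }
  # fixed example: maximal midpoint separation
  g <- list(deep = data.frame(taxon_name = c("d1", "d2"), log_size = 1:2,
                              midpoint_m = c(500, 800),
                              shell_length_mm = c(1, 2)),
            shallow = data.frame(taxon_name = c("s1", "s2"), log_size = 1:2,
                                 midpoint_m = c(10, 180),
                                 shell_length_mm = c(1, 2)))
  sel <- select_single_pair(g$deep, g$shallow)
  expect_identical(sel$deep$midpoint_m, 800)
  expect_identical(sel$shallow$midpoint_m, 10)
})

test_that("midpoint ties break deterministically by length then name", {
  deep <- data.frame(taxon_name = c("zz", "aa"), log_size = c(1, 1),
                     midpoint_m = c(700, 700), shell_length_mm = c(5, 5))
  shallow <- data.frame(taxon_name = c("s1", "s2"), log_size = c(1, 1),
                        midpoint_m = c(50, 50), shell_length_mm = c(9, 2))
  sel <- select_single_pair(deep, shallow)
  expect_identical(sel$deep$taxon_name, "aa")   # name breaks the tie
  expect_identical(sel$shallow$shell_length_mm, 2)  # length breaks the tie
})

test_that("minimum-count filter uses pre-equalization counts", {
  grp <- groups_from_sizes(
    deep_sizes = list(c(1, 2), c(1), c(1, 2, 3)),
    shallow_sizes = list(c(1), c(1, 2), c(1, 2)))
  expect_identical(length(filter_min_counts(grp, 1, 1)), 3L)
  expect_identical(names(filter_min_counts(grp, 2, 2)), "g3")
  expect_identical(length(filter_min_counts(grp, 2, 1)), 2L)
})

test_that("genus-pair counts never increase with the deep cutoff", {
  tab <- simulate_species_table(simulation_config(n_genera = 80, seed = 13,
                                                  deep_cutoff_m = 300,
                                                  straddle_frac = 0.2))
  for (scheme in c("all_means", "equalized", "single_pair")) {
    ns <- vapply(c(200, 400, 600, 800), function(cut) {
      grp <- classified_groups(tab, depth_rule("strict", deep_cutoff_m = cut))
      if (length(grp) < 1) return(0L)
      nrow(build_genus_pairs(grp, scheme))
    }, integer(1))
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("balanced schemes report equal counts and single pairs", {
  grp <- classified_groups(simulate_species_table(
    simulation_config(n_genera = 20, seed = 77)))
  eq <- build_genus_pairs(grp, "equalized")
  expect_true(all(eq$n_deep == eq$n_shallow))
  sp <- build_genus_pairs(grp, "single_pair")
  expect_true(all(sp$n_deep == 1L & sp$n_shallow == 1L))
})
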