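options(bathyrule.quiet = TRUE)

# A small hand-built table: 3 genera, mixed depth habits.
toy_table <- function() {
  species_table(
    taxon_name = c("Conus alpha", "Conus beta", "Conus gamma",
                   "Oliva alpha", "Oliva beta",
                   "Natica alpha", "Natica beta", "Natica gamma"),
    genus = c("Conus", "Conus", "Conus", "Oliva", "Oliva",
              "Natica", "Natica", "Natica"),
    shell_length_mm = c(10, 1000, 100, 50, 20, 30, 40, 25),
    depth_min_m = c(0, 10, 500, 0, 600, 5, 100, 900),
    depth_max_m = c(100, 150, 900, 180, 1400, 60, 500, 2500),
    source = "toy"
  )
}

# One random genus group pair (deep/shallow data frames) for scheme tests.
random_genus <- function(n_deep, n_shallow) {
  mk <- function(n, tag) {
    data.frame(taxon_name = paste0(tag, seq_len(n)),
               log_size = round(stats::rnorm(n, 1.2, 0.3), 3),
               midpoint_m = round(stats::runif(n, 0, 2000), 1),
               shell_length_mm = round(stats::rlnorm(n, 3, 1), 2),
               stringsAsFactors = FALSE)
  }
  list(deep = mk(n_deep, "d"), shallow = mk(n_shallow, "s"))
}

# genus_groups built straight from per-genus deep/shallow log-size vectors
# (midpoints fixed so selection schemes are deterministic).
groups_from_sizes <- function(deep_sizes, shallow_sizes) {
  stopifnot(length(deep_sizes) == length(shallow_sizes))
  gs <- lapply(seq_along(deep_sizes), function(i) {
    d <- deep_sizes[[i]]; s <- shallow_sizes[[i]]
    list(deep = data.frame(taxon_name = sprintf("g%d_d%d", i, seq_along(d)),
                           log_size = d,
                           midpoint_m = 1000 + seq_along(d),
                           shell_length_mm = 10^d,
                           stringsAsFactors = FALSE),
         shallow = data.frame(taxon_name = sprintf("g%d_s%d", i,
                                                   seq_along(s)),
                              log_size = s, midpoint_m = seq_along(s),
                              shell_length_mm = 10^s,
                              stringsAsFactors = FALSE))
  })
  names(gs) <- sprintf("g%d", seq_along(gs))
  structure(gs, class = "genus_groups")
}

# Brute-force maximizer of the mean-midpoint difference over all equal-size
# subset pairs; returns the best achievable objective value.
brute_force_best_diff <- function(deep, shallow) {
  k <- min(nrow(deep), nrow(shallow))
  best <- -Inf
  for (di in utils::combn(nrow(deep), k, simplify = FALSE)) {
    for (si in utils::combn(nrow(shallow), k, simplify = FALSE)) {
      best <- max(best, mean(deep$midpoint_m[di]) -
                    mean(shallow$midpoint_m[si]))
    }
  }
  best
}

classified_groups <- function(tab, rule = depth_rule("strict")) {
  group_into_genera(tab, classify_depth(tab, rule))
}

# Table with controlled depth geometry: every genus has 3 shallow (< 200 m)
# and 3 mesopelagic deep species (450-900 m), so all strict cutoffs <= 400 m
# and all abyssal/bathypelagic exclusions leave a usable analysis; a few
# abyssal extras give the exclusion filters something to drop.
mesopelagic_table <- function(n_genera = 12, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_genera), function(g) {
      n <- 3L
      dmin_d <- runif(n, 450, 600)
      dmin_s <- runif(n, 0, 40)
      data.frame(
        taxon_name = sprintf("T%02d_%s%d", g, rep(c("d", "s"), each = n),
                             rep(seq_len(n), 2)),
        genus = sprintf("T%02d", g),
        shell_length_mm = rlnorm(2 * n, 3, 0.8),
        depth_min_m = c(dmin_d, dmin_s),
        depth_max_m = c(dmin_d + runif(n, 100, 300),
                        dmin_s + runif(n, 20, 120)),
        stringsAsFactors = FALSE)
    })
    extras <- data.frame(
      taxon_name = c("T01_abyssal", "T02_abyssal"),
      genus = c("T01", "T02"), shell_length_mm = c(40, 55),
      depth_min_m = c(3200, 3400), depth_max_m = c(4000, 4100),
      stringsAsFactors = FALSE)
    df <- rbind(do.call(rbind, rows), extras)
    species_table(df$taxon_name, df$genus, df$shell_length_mm,
                  df$depth_min_m, df$depth_max_m, source = "mesopelagic")
  })
}
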