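#!/usr/bin/env Rscript
# Stage 4: statistical comparisons.
#
# Paired t-tests between GPS-only and dead-reckoned per-night metrics
# (path length, per-class proximity proportions), Welch t-tests between
# the two animals, and one-way land-use models (time ~ feature class)
# with Tukey HSD post hoc comparisons, building/road proportions
# log10(x+1)-transformed. All inputs come from the stage-3 tables.

library(badgerdr)

nm <- as.data.frame(data.table::fread("results/night_metrics.csv"))
px <- as.data.frame(data.table::fread("results/proximity.csv"))

rows <- list()
note <- function(name, t) {
  rows[[length(rows) + 1]] <<- data.frame(
    test = name, statistic = t$statistic, df_1 = t$df[1],
    df_2 = if (length(t$df) > 1) t$df[2] else NA_real_,
    p_value = t$p_value)
  cat(sprintf("%-34s t/F = %8.3f  df = %s  p = %.4g\n", name, t$statistic,
              paste(signif(t$df, 4), collapse = ","), t$p_value))
}

note("path: paired DR vs GPS",
     paired_comparison(nm$path_km_dr, nm$path_km_gps))
a1 <- nm$animal == 1
note("path GPS: Welch animal 1 vs 2",
     welch_comparison(nm$path_km_gps[a1], nm$path_km_gps[!a1]))
note("path DR: Welch animal 1 vs 2",
     welch_comparison(nm$path_km_dr[a1], nm$path_km_dr[!a1]))

for (cl in sort(unique(px$class))) {
  d <- px[px$class == cl, ]
  wide <- merge(d[d$source == "dr", c("animal", "night", "proportion")],
                d[d$source == "gps", c("animal", "night", "proportion")],
                by = c("animal", "night"), suffixes = c("_dr", "_gps"))
  note(sprintf("proximity %s: paired DR vs GPS", cl),
       paired_comparison(wide$proportion_dr, wide$proportion_gps))
}

landuse_rows <- list()
for (src in c("gps", "dr")) {
  d <- px[px$source == src, ]
  val <- d$proportion
  tcl <- d$class %in% c("building", "road")
  val[tcl] <- log10_plus_one(val[tcl])
  lu <- landuse_model(data.frame(value = val, class = d$class))
  cat(sprintf("land use (%s): F(%d, %d) = %.2f, p = %.3g\n", src,
              lu$df[1], lu$df[2], lu$F_statistic, lu$p_value))
  pw <- lu$pairwise
  pw$source <- src
  landuse_rows[[src]] <- pw
  rows[[length(rows) + 1]] <- data.frame(
    test = sprintf("land use one-way model (%s)", src),
    statistic = lu$F_statistic, df_1 = lu$df[1], df_2 = lu$df[2],
    p_value = lu$p_value)
}

data.table::fwrite(do.call(rbind, rows), "results/stats_tests.csv")
data.table::fwrite(do.call(rbind, landuse_rows), "results/landuse_tukey.csv")
cat("wrote results/stats_tests.csv and results/landuse_tukey.csv\n")
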