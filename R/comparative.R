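#' Aggregate per-specimen measurements to species level
#'
#' Computes per-species, per-sex arithmetic means of 1C genome size and a
#' per-species mean GC over all specimens, and attaches taxonomy and
#' karyotype annotations where available. Missing sexes are left `NA`.
#'
#' @param measurements data.frame with columns species, sex (`F`/`M`/
#'   `UNKNOWN`), c1_pg and optionally gc_percent.
#' @param taxonomy optional data.frame (species, family, subfamily).
#' @param karyotype optional data.frame (species, male_2n) with the male
#'   diploid chromosome-number group label.
#' @return data.frame of class-free species summaries: species, family,
#'   subfamily, n_female, n_male, mean_1C_female_pg, mean_1C_male_pg,
#'   mean_gc_percent, male_2n.
#' @export
aggregate_species <- function(measurements, taxonomy = NULL, karyotype = NULL) {
  stopifnot(is.data.frame(measurements))
  keep <- !is.na(measurements$species) & nzchar(measurements$species) &
    !is.na(measurements$c1_pg)
  dropped <- unique(measurements$species[!keep])
  if (length(dropped))
    message("aggregate_species: dropped species with no usable measurement: ",
            paste(dropped, collapse = ", "))
  m <- measurements[keep, , drop = FALSE]
  gs_assert(nrow(m) > 0, "no-measurements", "no usable measurements")

  one <- function(g) {
    f <- g[g$sex == "F", "c1_pg"]
    ml <- g[g$sex == "M", "c1_pg"]
    gc <- if ("gc_percent" %in% names(g)) g$gc_percent else NA_real_
    data.frame(species = g$species[1],
               n_female = length(f), n_male = length(ml),
               mean_1C_female_pg = if (length(f)) mean(f) else NA_real_,
               mean_1C_male_pg = if (length(ml)) mean(ml) else NA_real_,
               mean_gc_percent = if (all(is.na(gc))) NA_real_ else mean(gc, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(split(m, m$species), one))
  rownames(res) <- NULL
  res <- res[order(res$species), , drop = FALSE]

  res$family <- NA_character_
  res$subfamily <- NA_character_
  if (!is.null(taxonomy)) {
    i <- match(res$species, taxonomy$species)
    res$family <- taxonomy$family[i]
    if ("subfamily" %in% names(taxonomy)) res$subfamily <- taxonomy$subfamily[i]
  }
  res$male_2n <- NA_integer_
  if (!is.null(karyotype))
    res$male_2n <- karyotype$male_2n[match(res$species, karyotype$species)]
  res
}

#' Female-minus-male genome size differences per species
#'
#' For XX/X0 species the female minus male 1C difference estimates the DNA
#' content of the X chromosome; a negative difference (male larger) signals
#' intraspecific variation or method mixing.
#'
#' @param summaries data.frame with species, mean_1C_female_pg and
#'   mean_1C_male_pg (e.g. from [aggregate_species()]).
#' @param provenance one of `SAME_STUDY`, `CROSS_STUDY`, `CROSS_METHOD`, or a
#'   vector (recycled) tagging where each species' sex means came from.
#' @return data.frame species, delta_pg (F − M), provenance; one row per
#'   species with both sex means available.
#' @export
sex_differences <- function(summaries,
                            provenance = c("SAME_STUDY", "CROSS_STUDY",
                                           "CROSS_METHOD")) {
  stopifnot(is.data.frame(summaries))
  if (length(provenance) == 1 || identical(provenance,
                                           c("SAME_STUDY", "CROSS_STUDY", "CROSS_METHOD")))
    provenance <- match.arg(provenance)
  keep <- !is.na(summaries$mean_1C_female_pg) & !is.na(summaries$mean_1C_male_pg)
  prov <- rep_len(provenance, nrow(summaries))[keep]
  s <- summaries[keep, , drop = FALSE]
  data.frame(species = s$species,
             delta_pg = s$mean_1C_female_pg - s$mean_1C_male_pg,
             provenance = prov, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation on k−1 degrees
#' of freedom (the convention used for genome size vs chromosome-number
#' comparisons).
#'
#' @param values numeric trait values.
#' @param groups grouping key per value (e.g. chromosome number 2n).
#' @return A `gs_group_test` list: statistic, df, p_value, groups, corrected.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  gs_assert(length(unique(groups)) >= 2, "insufficient-groups",
            "need at least two groups")
  kt <- kruskal.test(values, factor(groups))
  structure(list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, groups = sort(unique(groups)),
                 corrected = FALSE, method = "Kruskal-Wallis"),
            class = "gs_group_test")
}

#' @export
print.gs_group_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, df %s, p = %.4g%s\n", x$method,
              x$statistic, ifelse(is.null(x$df), "-", format(x$df)),
              x$p_value, if (isTRUE(x$corrected)) " (Bonferroni)" else ""))
  invisible(x)
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests for every pair of groups
#' having at least `min_group_size` records. Exact p-values are used when
#' both groups have at most 8 observations and no ties; otherwise the
#' tie-corrected normal approximation. Each p-value is multiplied by the
#' number of pairs actually tested and capped at 1.
#'
#' @inheritParams kruskal_wallis
#' @param min_group_size minimum records for a group to enter (default 2,
#'   i.e. groups with more than one record).
#' @return Symmetric matrix of corrected p-values (diagonal `NA`), with
#'   attributes `n_pairs` (Bonferroni family size) and `group_sizes`.
#' @export
pairwise_mann_whitney_bonferroni <- function(values, groups,
                                             min_group_size = 2) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  sizes <- table(groups)
  elig <- names(sizes)[sizes >= min_group_size]
  gs_assert(length(elig) >= 2, "insufficient-groups",
            "fewer than two groups meet min_group_size")
  elig <- elig[order(suppressWarnings(as.numeric(elig)), elig, na.last = FALSE)]
  k <- length(elig)
  m <- k * (k - 1) / 2
  pm <- matrix(NA_real_, k, k, dimnames = list(elig, elig))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- values[groups == elig[i]]
    b <- values[groups == elig[j]]
    exact <- length(a) <= 8 && length(b) <= 8 && !any(duplicated(c(a, b)))
    p <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                      correct = !exact)$p.value)
    pm[i, j] <- pm[j, i] <- min(1, p * m)
  }
  attr(pm, "n_pairs") <- m
  attr(pm, "group_sizes") <- as.integer(sizes[elig])
  pm
}

#' Pearson correlation test
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return A `gs_group_test` with statistic r, df n−2 and two-sided t-based p.
#' @export
pearson_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  gs_assert(length(x) >= 3, "insufficient-data", "need at least 3 pairs")
  gs_assert(sd(x) > 0 && sd(y) > 0, "degenerate-input",
            "zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(statistic = unname(ct$estimate), df = unname(ct$parameter),
                 p_value = ct$p.value, groups = NULL, corrected = FALSE,
                 method = "Pearson correlation"),
            class = "gs_group_test")
}

#' GC-content contrasts among families
#'
#' One-way ANOVA of GC content across families, pairwise Mann-Whitney tests
#' (Bonferroni corrected), and a per-family summary table (N, max, min,
#' mean +/- sd).
#'
#' @param gc_table data.frame with columns family and gc (per specimen or
#'   per species), optionally sex.
#' @return list with `anova` (a `gs_group_test` holding F, df, p),
#'   `pairwise` (corrected p matrix) and `summary` (per-family table).
#' @export
gc_family_contrasts <- function(gc_table) {
  stopifnot(is.data.frame(gc_table), all(c("family", "gc") %in% names(gc_table)))
  g <- gc_table[!is.na(gc_table$gc) & !is.na(gc_table$family), , drop = FALSE]
  gs_assert(length(unique(g$family)) >= 2, "insufficient-groups",
            "need at least two families")
  fit <- aov(gc ~ family, data = transform(g, family = factor(family)))
  tab <- summary(fit)[[1]]
  an <- structure(list(statistic = tab[["F value"]][1],
                       df = tab[["Df"]], p_value = tab[["Pr(>F)"]][1],
                       groups = sort(unique(g$family)), corrected = FALSE,
                       method = "one-way ANOVA"),
                  class = "gs_group_test")
  pw <- pairwise_mann_whitney_bonferroni(g$gc, g$family, min_group_size = 2)
  sm <- do.call(rbind, lapply(split(g$gc, g$family), function(v)
    data.frame(n = length(v), max = max(v), min = min(v),
               mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_)))
  sm <- data.frame(family = rownames(sm), sm, row.names = NULL,
                   stringsAsFactors = FALSE)
  list(anova = an, pairwise = pw, summary = sm)
}
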