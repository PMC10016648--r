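make_meas <- function(species, sex, c1, gc = NA_real_) {
  data.frame(specimen_id = paste0("s", seq_along(species)), species = species,
             sex = sex, c1_pg = c1, gc_percent = gc, stringsAsFactors = FALSE)
}

test_that("aggregate_species takes per-sex arithmetic means", {
  m <- make_meas(rep("Bryodemella tuberculata", 2), c("F", "F"),
                 c(21.96, 21.88), c(42.0, 42.1))
  s <- aggregate_species(m)
  expect_equal(s$mean_1C_female_pg, 21.92)
  expect_true(is.na(s$mean_1C_male_pg))
  expect_equal(s$n_female, 2)
  expect_equal(s$mean_gc_percent, 42.05)
  # single-element mean; order invariance; optional karyotype
  m2 <- make_meas(c("a", "b", "b"), c("M", "F", "M"), c(5, 7, 6))
  s2 <- aggregate_species(m2)
  expect_equal(s2$mean_1C_male_pg[s2$species == "a"], 5)
  s2r <- aggregate_species(m2[3:1, ])
  expect_equal(s2, s2r)
  expect_true(all(is.na(s2$male_2n)))
  kar <- data.frame(species = "a", male_2n = 22)
  expect_equal(aggregate_species(m2, karyotype = kar)$male_2n,
               c(22, NA))
})

test_that("sex differences reproduce the six published worked values", {
  d <- sex_differences(printed_sex_fixture())
  expect_equal(d$delta_pg, c(2.52, 2.43, 2.25, 2.13, -0.21, -0.31),
               tolerance = 1e-9)
  # filter rule: species lacking a male mean are dropped
  s <- printed_sex_fixture()
  s$mean_1C_male_pg[1] <- NA
  expect_equal(nrow(sex_differences(s)), 5)
})

test_that("sex differences are antisymmetric under swapping sex labels", {
  s <- printed_sex_fixture()
  swapped <- transform(s, mean_1C_female_pg = mean_1C_male_pg,
                       mean_1C_male_pg = mean_1C_female_pg)
  expect_equal(sex_differences(swapped)$delta_pg,
               -sex_differences(s)$delta_pg)
})

test_that("Kruskal-Wallis: identical groups give H = 0, p = 1", {
  kw <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)
  expect_equal(kw$df, 1)
  expect_error(kruskal_wallis(1:5, rep("A", 5)), class = "insufficient-groups")
})

test_that("Kruskal-Wallis H matches the rank-variance oracle", {
  # fixed 3 groups x 4 values fixture, with ties
  v <- c(3.1, 4.2, 4.2, 5.0, 1.2, 2.2, 3.3, 3.1, 6.1, 7.0, 5.5, 6.6)
  g <- rep(c("a", "b", "c"), each = 4)
  expect_equal(kruskal_wallis(v, g)$statistic, kw_oracle_h(v, g),
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    sizes <- sample(2:5, 3, replace = TRUE)
    v <- round(rnorm(sum(sizes)), 1)  # rounding induces occasional ties
    g <- rep(letters[1:3], sizes)
    expect_equal(kruskal_wallis(v, g)$statistic, kw_oracle_h(v, g),
                 tolerance = 1e-12)
  }
})

test_that("pairwise Mann-Whitney matches exact enumeration and Bonferroni rules", {
  # two fully separated groups of 3: exact two-sided p = 0.1, one pair tested
  v <- c(1, 2, 3, 10, 11, 12); g <- rep(c("lo", "hi"), each = 3)
  pm <- pairwise_mann_whitney_bonferroni(v, g)
  expect_equal(pm["lo", "hi"], 0.1, tolerance = 1e-12)
  expect_equal(attr(pm, "n_pairs"), 1)
  # identical groups: corrected p = 1
  pm1 <- pairwise_mann_whitney_bonferroni(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(pm1["lo", "hi"], 1)
  # random small tie-free groups against the enumeration oracle
  set.seed(21)
  for (i in 1:15) {
    a <- runif(sample(2:5, 1)); b <- runif(sample(2:5, 1))
    pm2 <- pairwise_mann_whitney_bonferroni(c(a, b),
                                            rep(c("a", "b"), c(length(a), length(b))))
    expect_equal(pm2["a", "b"], mw_oracle_p(a, b), tolerance = 1e-12)
  }
})

test_that("Bonferroni family size counts only eligible pairs and caps at 1", {
  set.seed(4)
  v <- c(rnorm(4), rnorm(4, 2), rnorm(4, 4), rnorm(1))
  g <- rep(c("a", "b", "c", "singleton"), c(4, 4, 4, 1))
  pm <- pairwise_mann_whitney_bonferroni(v, g)
  expect_equal(dim(pm), c(3, 3))           # singleton group excluded
  expect_equal(attr(pm, "n_pairs"), 3)
  expect_true(all(pm[lower.tri(pm)] <= 1))
  expect_error(pairwise_mann_whitney_bonferroni(c(1, 2), c("a", "b")),
               class = "insufficient-groups")
  # corrected p is raw p times m, monotone in raw p
  raw <- suppressWarnings(wilcox.test(v[g == "a"], v[g == "b"],
                                      exact = TRUE)$p.value)
  expect_equal(pm["a", "b"], min(1, raw * 3), tolerance = 1e-12)
})

test_that("Pearson test: perfect lines, degenerate input, permutation null", {
  x <- 1:10
  expect_equal(pearson_test(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_test(x, -x)$statistic, -1)
  expect_error(pearson_test(x, rep(2, 10)), class = "degenerate-input")
  expect_error(pearson_test(1:2, 2:1), class = "insufficient-data")
  # analytic two-sided p vs a permutation null
  set.seed(31)
  y <- x + rnorm(10, 0, 4)
  pt <- pearson_test(x, y)
  r_obs <- abs(cor(x, y))
  perm <- replicate(20000, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= r_obs)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 20000)
  expect_lt(abs(pt$p_value - p_perm), 4 * mc_sd + 1e-3)
})

test_that("family GC contrasts: null gives flat ANOVA, shifts are detected", {
  g0 <- data.frame(family = rep(c("A", "B", "C"), each = 4),
                   gc = rep(c(38, 39, 40, 41), 3))
  r0 <- gc_family_contrasts(g0)
  expect_equal(r0$anova$statistic, 0, tolerance = 1e-12)
  expect_true(all(r0$pairwise[lower.tri(r0$pairwise)] == 1))
  expect_equal(sort(r0$summary$family), c("A", "B", "C"))
  expect_equal(r0$summary$mean, rep(39.5, 3))

  # power at a clear effect: 4 families, one shifted by 3 sd
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    d <- data.frame(family = rep(c("A", "B", "C", "D"), each = 8),
                    gc = rnorm(32, 40, 0.8) + rep(c(0, 0, 0, 2.4), each = 8))
    gc_family_contrasts(d)$anova$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("chromosome-number statistics run on the bundled species table", {
  tab <- orthoptera_species_table()
  expect_equal(nrow(tab), 50)
  males <- tab[!is.na(tab$c1_male_pg), ]
  kw <- kruskal_wallis(males$c1_male_pg, males$male_2n)
  expect_gt(kw$statistic, 0)
  expect_lt(kw$p_value, 0.05)
  pm <- pairwise_mann_whitney_bonferroni(males$c1_male_pg, males$male_2n)
  sizes <- table(males$male_2n)
  expect_equal(rownames(pm), names(sizes)[sizes >= 2])
})
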