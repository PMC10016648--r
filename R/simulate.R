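#' Configuration for a synthetic two-peak fluorescence histogram
#'
#' Defaults mirror a typical measurement run in this workflow: 4,000 recorded
#' particles split evenly between sample and standard, CVs at the reported
#' medians (2.31% for the AT-selective dye, 3.81% for the intercalating dye
#' — the default uses the AT-selective value), a 1024-channel histogram and a
#' small exponential debris background.
#'
#' @param standard_channel target mean channel of the standard peak.
#' @param true_ratio sample/standard genome-size (fluorescence) ratio.
#' @param cv_sample,cv_standard peak coefficients of variation in percent.
#' @param n_sample,n_standard particles per peak.
#' @param debris_fraction proportion of all recorded particles belonging to
#'   an exponential-decay debris background (0 disables).
#' @param n_bins number of histogram channels.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return list of class `histogram_sim_config`.
#' @export
histogram_sim_config <- function(standard_channel = 100, true_ratio = 2,
                                 cv_sample = 2.31, cv_standard = 2.31,
                                 n_sample = 2000, n_standard = 2000,
                                 debris_fraction = 0.02, n_bins = 1024,
                                 seed = 1L) {
  gs_assert(standard_channel > 0 && true_ratio > 0 && cv_sample > 0 &&
            cv_standard > 0, "invalid-argument",
            "channels, ratio and CVs must be positive")
  gs_assert(debris_fraction >= 0 && debris_fraction < 1, "invalid-argument",
            "debris_fraction must be in [0, 1)")
  structure(list(standard_channel = standard_channel, true_ratio = true_ratio,
                 cv_sample = cv_sample, cv_standard = cv_standard,
                 n_sample = n_sample, n_standard = n_standard,
                 debris_fraction = debris_fraction, n_bins = n_bins,
                 seed = as.integer(seed)),
            class = "histogram_sim_config")
}

#' Simulate a two-peak fluorescence histogram
#'
#' Particle fluorescences are drawn from two normal distributions — the
#' standard peak at `standard_channel` and the sample peak at
#' `standard_channel * true_ratio`, each with sd = mean x CV/100 — plus an
#' exponential debris background decaying from channel zero. Values are
#' binned into `n_bins` integer channels; out-of-range draws are clamped to
#' the edge channels so that particles are conserved exactly.
#'
#' @param cfg a [histogram_sim_config()].
#' @param dye dye label carried on the histogram.
#' @return An [fcm_histogram()] whose `meta` records the generating truth.
#' @export
simulate_histogram <- function(cfg, dye = c("AT_SELECTIVE", "INTERCALATING")) {
  stopifnot(inherits(cfg, "histogram_sim_config"))
  dye <- match.arg(dye)
  mu_std <- cfg$standard_channel
  mu_smp <- cfg$standard_channel * cfg$true_ratio
  sd_std <- mu_std * cfg$cv_standard / 100
  sd_smp <- mu_smp * cfg$cv_sample / 100
  top <- cfg$n_bins - 1
  if (mu_smp + 4 * sd_smp > top || mu_std + 4 * sd_std > top)
    gs_error("off-scale", "peak exceeds the histogram range (mean + 4 sd > top channel)")

  set.seed(cfg$seed)
  n_core <- cfg$n_sample + cfg$n_standard
  n_debris <- round(cfg$debris_fraction / (1 - cfg$debris_fraction) * n_core)
  v <- c(rnorm(cfg$n_standard, mu_std, sd_std),
         rnorm(cfg$n_sample, mu_smp, sd_smp),
         if (n_debris > 0) rexp(n_debris, rate = 3 / mu_std))
  ch <- pmin(pmax(round(v), 0), top)
  counts <- tabulate(ch + 1L, nbins = cfg$n_bins)
  fcm_histogram(0:top, counts, dye = dye,
                meta = list(sim = unclass(cfg), n_debris = n_debris))
}

#' Simulate a paired-dye ratio observation
#'
#' The intercalating-dye ratio is the true size ratio times multiplicative
#' lognormal noise; the AT-selective-dye ratio additionally carries the
#' base-composition factor from [forward_dye_ratio()].
#'
#' @param true_ratio true sample/standard genome-size ratio.
#' @param gc_sample sample GC content in percent (0-100, exclusive).
#' @param standard a [standard_ref()].
#' @param binding_length dye binding-site length (AT base pairs).
#' @param noise_cv multiplicative noise CV in percent (0 = noiseless).
#' @param seed integer RNG seed.
#' @return A [dye_pair()].
#' @export
simulate_dye_pair <- function(true_ratio, gc_sample,
                              standard = standard_ref(), binding_length = 4L,
                              noise_cv = 0, seed = 1L) {
  gs_assert(gc_sample > 0 && gc_sample < 100, "invalid-fraction",
            "gc_sample must be in (0, 100)")
  gs_assert(true_ratio > 0 && noise_cv >= 0, "invalid-argument",
            "true_ratio must be positive, noise_cv non-negative")
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + (noise_cv / 100)^2))
  noise <- function() if (sdlog > 0) exp(rnorm(1, 0, sdlog)) else 1
  p_st <- 1 - standard$gc_percent / 100
  p_s <- 1 - gc_sample / 100
  r_int <- true_ratio * noise()
  r_at <- true_ratio * forward_dye_ratio(p_s, p_st, binding_length) * noise()
  dye_pair(r_at, r_int, standard, binding_length)
}

#' Configuration for Brownian-motion trait simulation on a pure-birth tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate of the Yule tree.
#' @param root_state trait value at the root (picograms); default 6.19 pg, a
#'   realistic ancestral insect genome size for this group.
#' @param sigma2 Brownian rate (pg^2 per unit branch length).
#' @param seed integer RNG seed.
#' @param total_height optional tree height to rescale the simulated tree to
#'   before evolving the trait. Pure-birth tree height grows with the number
#'   of tips; fixing a common height makes estimator precision comparable
#'   across tree sizes in sample-size experiments. `NULL` (default) keeps
#'   the natural Yule scale.
#' @return list of class `bm_sim_config`.
#' @export
bm_sim_config <- function(n_tips, birth_rate = 1, root_state = 6.19,
                          sigma2 = 1, seed = 1L, total_height = NULL) {
  gs_assert(n_tips >= 2, "invalid-argument", "n_tips must be >= 2")
  gs_assert(sigma2 >= 0 && birth_rate > 0, "invalid-argument",
            "sigma2 must be >= 0 and birth_rate > 0")
  gs_assert(is.null(total_height) || total_height > 0, "invalid-argument",
            "total_height must be positive when given")
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 root_state = root_state, sigma2 = sigma2,
                 seed = as.integer(seed), total_height = total_height),
            class = "bm_sim_config")
}

#' Simulate a pure-birth tree and Brownian tip values
#'
#' Grows a Yule tree with [ape::rphylo()] and evolves the trait from the
#' root by independent normal increments with variance `sigma2 x branch
#' length` along every edge (preorder recursion), so tips inherit the exact
#' Brownian covariance structure the reconstruction assumes.
#'
#' @param cfg a [bm_sim_config()].
#' @return list with `tree` (phylo), `tips` (named numeric tip values) and
#'   `node_states` (true states at all nodes, tips first).
#' @export
simulate_tree_and_tips <- function(cfg) {
  stopifnot(inherits(cfg, "bm_sim_config"))
  set.seed(cfg$seed)
  tree <- ape::rphylo(cfg$n_tips, birth = cfg$birth_rate, death = 0)
  if (!is.null(cfg$total_height)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * cfg$total_height / h
  }
  n <- cfg$n_tips
  states <- numeric(n + tree$Nnode)
  states[n + 1L] <- cfg$root_state
  ord <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    len <- ord$edge.length[e]
    states[child] <- states[par] +
      if (cfg$sigma2 > 0 && len > 0) rnorm(1, 0, sqrt(cfg$sigma2 * len)) else 0
  }
  tips <- setNames(states[seq_len(n)], tree$tip.label)
  list(tree = tree, tips = tips, node_states = states)
}

#' Simulate a species table with group-structured genome sizes
#'
#' Draws per-species genome sizes from normal distributions whose means are
#' `base_mean + group_shifts[g]`, truncated below at 0.1 pg, and labels the
#' groups with chromosome numbers. Used for calibration and power checks of
#' the chromosome-number statistics.
#'
#' @param n_groups number of groups.
#' @param group_shifts numeric vector of per-group mean offsets (pg).
#' @param n_per_group species per group (scalar or vector).
#' @param base_mean baseline mean 1C size in pg.
#' @param sd within-group standard deviation in pg.
#' @param seed integer RNG seed.
#' @param two_n_labels chromosome-number labels; default 12, 14, 16, ...
#' @return data.frame with species, male_2n, c1_male_pg.
#' @export
make_species_table <- function(n_groups, group_shifts = rep(0, n_groups),
                               n_per_group = 10, base_mean = 10, sd = 1,
                               seed = 1L, two_n_labels = NULL) {
  gs_assert(length(group_shifts) == n_groups, "invalid-argument",
            "group_shifts must have n_groups entries")
  n_per_group <- rep_len(n_per_group, n_groups)
  if (is.null(two_n_labels)) two_n_labels <- seq(12, by = 2, length.out = n_groups)
  gs_assert(length(two_n_labels) == n_groups, "invalid-argument",
            "two_n_labels must have n_groups entries")
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_groups), function(g) {
    v <- pmax(0.1, rnorm(n_per_group[g], base_mean + group_shifts[g], sd))
    data.frame(species = sprintf("sp_g%d_%d", g, seq_len(n_per_group[g])),
               male_2n = two_n_labels[g], c1_male_pg = v,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
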