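#' Build a pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()].
#' Defaults embed the workflow's standard operating point: *Pisum sativum*
#' standard (2C = 9.09 pg, GC 38.50%), DAPI binding length 4, QC thresholds
#' CV <= 5% and >= 3000 particles.
#'
#' @param out_dir output directory (created if missing).
#' @param stages character subset of
#'   `c("simulate", "measure", "gc", "stats", "asr")`, executed in that
#'   order.
#' @param seed integer seed used for every stochastic stage.
#' @param standard list with `name`, `genome_size_2C_pg`, `gc_percent`.
#' @param standard_window channel window `c(lo, hi)` locating the standard
#'   peak (see [measure_histogram()]).
#' @param binding_length dye binding-site length for GC estimation.
#' @param qc list with `max_cv_percent`, `min_particles`.
#' @param histograms_dir directory of histogram TSVs plus a `manifest.csv`
#'   (columns file, specimen_id, species, sex, dye); filled by the simulate
#'   stage when that stage is run.
#' @param simulate list of generator settings for the simulate stage:
#'   `n_species`, `specimens_per_species`, `ratio_range`, `gc_range`,
#'   `cv_at`, `cv_intercalating`, `n_particles`, `standard_channel`.
#' @param tree path to a Newick tree for the asr stage (optional).
#' @param traits path to a species-means CSV (species, value) for the asr
#'   stage; defaults to species means computed by the gc stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "measure", "gc", "stats"),
                            seed = 1L,
                            standard = list(name = "Pisum sativum 'Ctirad'",
                                            genome_size_2C_pg = 9.09,
                                            gc_percent = 38.50),
                            standard_window = c(80, 120),
                            binding_length = 4L,
                            qc = list(max_cv_percent = 5, min_particles = 3000),
                            histograms_dir = NULL,
                            simulate = list(),
                            tree = NULL, traits = NULL) {
  all_stages <- c("simulate", "measure", "gc", "stats", "asr")
  gs_assert(all(stages %in% all_stages), "invalid-argument",
            paste("stages must be among:", paste(all_stages, collapse = ", ")))
  sim_defaults <- list(n_species = 4, specimens_per_species = 2,
                       ratio_range = c(0.5, 4), gc_range = c(36, 43),
                       cv_at = 2.31, cv_intercalating = 3.81,
                       n_particles = 4000, standard_channel = 100)
  simulate <- utils::modifyList(sim_defaults, simulate)
  structure(list(out_dir = out_dir,
                 stages = all_stages[all_stages %in% stages],
                 seed = as.integer(seed), standard = standard,
                 standard_window = standard_window,
                 binding_length = binding_length, qc = qc,
                 histograms_dir = histograms_dir, simulate = simulate,
                 tree = tree, traits = traits),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  gs_assert(file.exists(path), "file-not-found", paste("no such file:", path))
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the measurement-to-reconstruction pipeline
#'
#' Executes the configured stages in order — simulate (synthetic histogram
#' pairs + manifest), measure (peak fitting and internal-standard
#' calibration), gc (paired-dye GC estimation), stats (species aggregation,
#' sex differences, chromosome-number Kruskal-Wallis and pairwise
#' Mann-Whitney tests, family GC contrasts when annotations are present) and
#' asr (Brownian-motion ancestral state reconstruction on a supplied tree).
#' Each stage writes CSV outputs under `cfg$out_dir`; a JSON run report
#' records the configuration, seed, QC summary and an MD5 hash per output
#' file. Reruns with identical configuration and inputs reproduce identical
#' outputs.
#'
#' A stage failure is re-raised with the stage name (condition class
#' `stage-failure`) after a `FAILED_<stage>` marker is written; outputs of
#' completed stages are retained.
#'
#' @param cfg a [pipeline_config()].
#' @return The run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  std <- standard_ref(cfg$standard$name, cfg$standard$genome_size_2C_pg,
                      cfg$standard$gc_percent)
  state <- new.env(parent = emptyenv())
  state$files <- character(0)
  report <- list(package = "gsflow",
                 version = as.character(utils::packageVersion("gsflow")),
                 r_version = as.character(getRversion()),
                 seed = cfg$seed, stages = cfg$stages,
                 config = unclass(cfg), stage_status = list())

  log_line <- function(stage, msg)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    log_line(stage, "started")
    ok <- tryCatch({fun(); TRUE}, error = function(e) {
      writeLines(conditionMessage(e), file.path(cfg$out_dir,
                                                paste0("FAILED_", stage)))
      stop(errorCondition(sprintf("stage '%s' failed: %s", stage,
                                  conditionMessage(e)),
                          class = c("stage-failure", "gsflow_error",
                                    "error", "condition")))
    })
    report$stage_status[[stage]] <<- "ok"
    log_line(stage, "done")
  }
  out <- function(name) {
    p <- file.path(cfg$out_dir, name)
    state$files <- unique(c(state$files, p))
    p
  }

  run_stage("simulate", function() {
    hdir <- file.path(cfg$out_dir, "histograms")
    dir.create(hdir, showWarnings = FALSE)
    cfg$histograms_dir <<- hdir
    s <- cfg$simulate
    set.seed(cfg$seed)
    manifest <- list()
    p_st <- 1 - std$gc_percent / 100
    for (i in seq_len(s$n_species)) {
      ratio <- s$ratio_range[1] +
        (i - 1) / max(1, s$n_species - 1) * diff(s$ratio_range)
      gc_i <- s$gc_range[1] +
        (i - 1) / max(1, s$n_species - 1) * diff(s$gc_range)
      for (k in seq_len(s$specimens_per_species)) {
        id <- sprintf("sp%02d_%d", i, k)
        seeds <- cfg$seed + 1000L * i + 2L * k + c(0L, 1L)
        ratio_at <- ratio * forward_dye_ratio(1 - gc_i / 100, p_st,
                                              cfg$binding_length)
        specs <- list(
          AT_SELECTIVE = list(ratio = ratio_at, cv = s$cv_at, seed = seeds[1]),
          INTERCALATING = list(ratio = ratio, cv = s$cv_intercalating,
                               seed = seeds[2]))
        for (dye in names(specs)) {
          sp <- specs[[dye]]
          h <- simulate_histogram(histogram_sim_config(
            standard_channel = s$standard_channel, true_ratio = sp$ratio,
            cv_sample = sp$cv, cv_standard = sp$cv,
            n_sample = s$n_particles / 2, n_standard = s$n_particles / 2,
            seed = sp$seed), dye = dye)
          f <- sprintf("%s_%s.tsv", id, tolower(substr(dye, 1, 2)))
          write_histogram(h, file.path(hdir, f))
          manifest[[length(manifest) + 1L]] <-
            data.frame(file = f, specimen_id = id,
                       species = sprintf("synthsp_%02d", i), sex = "UNKNOWN",
                       dye = dye, true_ratio = sp$ratio, true_gc = gc_i,
                       stringsAsFactors = FALSE)
        }
      }
    }
    write.csv(do.call(rbind, manifest), file.path(hdir, "manifest.csv"),
              row.names = FALSE, quote = FALSE)
    state$files <- c(state$files, file.path(hdir, "manifest.csv"))
  })

  run_stage("measure", function() {
    hdir <- cfg$histograms_dir
    gs_assert(!is.null(hdir) && dir.exists(hdir), "file-not-found",
              "histograms_dir does not exist")
    man <- read.csv(file.path(hdir, "manifest.csv"), stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(man)), function(i) {
      h <- read_histogram(file.path(hdir, man$file[i]), dye = man$dye[i])
      measure_histogram(h, std, cfg$standard_window,
                        specimen_id = man$specimen_id[i],
                        species = man$species[i], sex = man$sex[i],
                        max_cv_percent = cfg$qc$max_cv_percent,
                        min_particles = cfg$qc$min_particles)
    })
    state$measurements <- do.call(rbind, rows)
    write_measurements(state$measurements, out("measurements.csv"))
  })

  run_stage("gc", function() {
    gs_assert(!is.null(state$measurements), "missing-stage",
              "gc stage needs measurements (run measure first)")
    state$gc <- gc_from_measurements(state$measurements, std,
                                     cfg$binding_length)
    write.csv(state$gc, out("gc.csv"), row.names = FALSE, quote = FALSE)
  })

  run_stage("stats", function() {
    gs_assert(!is.null(state$measurements), "missing-stage",
              "stats stage needs measurements (run measure first)")
    sums <- aggregate_species(state$measurements)
    if (!is.null(state$gc)) {
      spgc <- tapply(state$gc$gc_percent, state$gc$species, mean, na.rm = TRUE)
      sums$mean_gc_percent <- as.numeric(spgc[sums$species])
    }
    write.csv(sums, out("species_summaries.csv"), row.names = FALSE,
              quote = FALSE)
    sx <- sex_differences(sums)
    write.csv(sx, out("sex_differences.csv"), row.names = FALSE, quote = FALSE)
    if (any(!is.na(sums$male_2n)) &&
        length(unique(na.omit(sums$male_2n))) >= 2) {
      kw <- kruskal_wallis(sums$mean_1C_male_pg, sums$male_2n)
      write.csv(data.frame(test = "kruskal_wallis", statistic = kw$statistic,
                           df = kw$df, p_value = kw$p_value),
                out("kruskal_wallis.csv"), row.names = FALSE, quote = FALSE)
      pw <- pairwise_mann_whitney_bonferroni(sums$mean_1C_male_pg,
                                             sums$male_2n)
      write.csv(as.data.frame(pw), out("pairwise_mw.csv"), quote = FALSE)
    }
  })

  run_stage("asr", function() {
    gs_assert(!is.null(cfg$tree), "missing-stage", "asr stage needs a tree path")
    tree <- read_newick(cfg$tree)
    traits <- if (!is.null(cfg$traits)) {
      tt <- read.csv(cfg$traits, stringsAsFactors = FALSE)
      setNames(tt[[2]], tt[[1]])
    } else {
      gs_assert(!is.null(state$measurements), "missing-stage",
                "asr stage needs traits or upstream measurements")
      tapply(state$measurements$c1_pg, state$measurements$species, mean)
    }
    mp <- match_and_prune(tree, setNames(as.numeric(traits), names(traits)))
    res <- bm_asr(mp$tree, mp$tip_values)
    ann <- annotate_tree(mp$tree, res)
    write.csv(ann$node_table, out("asr_nodes.csv"), row.names = FALSE,
              quote = FALSE)
    writeLines(ann$newick, out("asr_annotated.tre"))
    state$asr <- res
  })

  existing <- state$files[file.exists(state$files)]
  report$outputs <- lapply(existing, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  if (!is.null(state$measurements)) {
    flagged <- sum(nzchar(state$measurements$qc_flags))
    report$qc <- list(n_measurements = nrow(state$measurements),
                      n_flagged = flagged)
  }
  if (!is.null(state$asr))
    report$asr <- list(root_estimate = state$asr$root_estimate,
                       sigma2_hat = state$asr$sigma2_hat)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(report)
}
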