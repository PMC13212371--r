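# End-to-end orchestration: phantom -> quantify -> cohort -> subtype -> fit,
# driven by a plain-text (YAML) config, with every output file hashed into a
# JSON run manifest so reruns under the same config are verifiably identical.

default_run_config <- function() {
  list(seed = 1L,
       stages = c("phantom", "quantify", "cohort", "subtype", "fit"),
       n = 2040L,
       n_subtype_arteries = 2000L,
       ladder = c(130, 200, 300, 400, 600, 800, 1000),
       target_spearman = 0.67,
       image = NULL, masks = NULL)
}

# demo phantom: one graded carotid insert, one uniform carotid insert and a
# uniform basilar insert, inside a 48 x 48 x 16 grid at 0.6 x 0.6 x 3 mm
demo_phantom_spec <- function(seed = 1L) {
  phantom_spec(list(
    calc_insert("ICA_left", center_mm = c(8, 8, 12), radii_mm = 4,
                hu_profile = hu_graded(900, 180)),
    calc_insert("ICA_right", center_mm = c(20, 8, 24), radii_mm = 3,
                hu_profile = hu_uniform(350)),
    calc_insert("basilar", center_mm = c(14, 20, 36),
                radii_mm = c(2, 2, 4), shape = "ellipsoid",
                hu_profile = hu_uniform(220))
  ), seed = seed)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and writes a JSON run
#' manifest recording the config, per-stage seeds, wall times, and an MD5
#' hash of every output file. Referenced input paths are checked before any
#' stage runs; a failing stage aborts with its name while earlier outputs
#' remain on disk.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized fields: `out_dir` (required), `seed`, `stages` (subset of
#'   phantom / quantify / cohort / subtype / fit), `n`, `n_subtype_arteries`,
#'   `ladder`, `target_spearman`, and optionally `image` plus `masks` (a
#'   named list of NIfTI paths) to quantify a real volume instead of the
#'   bundled demo phantom.
#' @return The manifest list, invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML file path")
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$out_dir)) stop("config must name an `out_dir`")
  bad <- setdiff(cfg$stages, c("phantom", "quantify", "cohort", "subtype", "fit"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  # pre-flight: every referenced input must exist before anything runs
  refs <- c(cfg$image, unlist(cfg$masks))
  missing <- refs[!vapply(refs, file.exists, logical(1))]
  if (length(missing))
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  if (!is.null(cfg$image) && is.null(cfg$masks))
    stop("an `image` needs accompanying `masks`")

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                   stages = list(), files = list())
  outputs <- character(0)
  seed <- as.integer(cfg$seed)
  phantom <- NULL

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s (earlier outputs retained)",
                   name, conditionMessage(e)), call. = FALSE))
    manifest$stages[[name]] <<- list(
      seed = substream_seed(seed, match(name, cfg$stages)),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    outputs <<- c(outputs, files)
  }

  if ("phantom" %in% cfg$stages) run_stage("phantom", function() {
    s <- substream_seed(seed, match("phantom", cfg$stages))
    phantom <<- generate_phantom(demo_phantom_spec(seed = s))
    unlist(write_phantom(phantom, file.path(cfg$out_dir, "phantom")))
  })

  if ("quantify" %in% cfg$stages) run_stage("quantify", function() {
    if (!is.null(cfg$image)) {
      grid <- read_volume_nifti(cfg$image)
      masks <- lapply(cfg$masks, function(p) {
        m <- RNifti::readNifti(p)
        array(m > 0, dim = dim(m)[1:3])
      })
      target <- list(grid = grid, masks = masks)
    } else {
      if (is.null(phantom)) {
        s <- substream_seed(seed, 1L)
        phantom <<- generate_phantom(demo_phantom_spec(seed = s))
      }
      target <- phantom
    }
    meas <- quantify_phantom(target, threshold_ladder(cfg$ladder))
    validate_measurements(meas)
    arts <- measurements_table(meas, participant_id = 1L)
    agg <- aggregate_participant(meas)
    p1 <- file.path(cfg$out_dir, "arteries.csv")
    p2 <- file.path(cfg$out_dir, "participant_aggregates.csv")
    utils::write.csv(arts, p1, row.names = FALSE)
    utils::write.csv(agg, p2, row.names = FALSE)
    c(p1, p2)
  })

  cohort <- NULL
  if ("cohort" %in% cfg$stages) run_stage("cohort", function() {
    s <- substream_seed(seed, match("cohort", cfg$stages))
    cohort <<- simulate_cohort(n = cfg$n, seed = s,
                               target_spearman = cfg$target_spearman)
    p1 <- file.path(cfg$out_dir, "cohort.csv")
    utils::write.csv(as.data.frame(cohort), p1, row.names = FALSE)
    gen <- attr(cohort, "generator")
    p2 <- file.path(cfg$out_dir, "cohort_generator.yaml")
    yaml::write_yaml(lapply(gen, function(x)
      if (is.numeric(x)) as.numeric(x) else x), p2)
    c(p1, p2)
  })

  if ("subtype" %in% cfg$stages) run_stage("subtype", function() {
    s <- substream_seed(seed, match("subtype", cfg$stages))
    arts <- simulate_subtype_arteries(cfg$n_subtype_arteries, seed = s)
    ds <- density_by_subtype(arts)
    tests <- pairwise_subtype_tests(arts)
    p1 <- file.path(cfg$out_dir, "subtype_summary.csv")
    p2 <- file.path(cfg$out_dir, "subtype_pairwise_tests.csv")
    utils::write.csv(ds$summary, p1, row.names = FALSE)
    utils::write.csv(tests, p2, row.names = FALSE)
    c(p1, p2)
  })

  if ("fit" %in% cfg$stages) run_stage("fit", function() {
    if (is.null(cohort)) stop("fit stage requires the cohort stage")
    eff <- default_effect_spec()
    ofit <- fit_proportional_odds(as.data.frame(cohort)[names(eff$beta)],
                                  cohort$density_category)
    otab <- data.frame(term = names(ofit$coefficients),
                       estimate = ofit$coefficients, or = ofit$or,
                       ci_low = ofit$or_ci[, "lower"],
                       ci_high = ofit$or_ci[, "upper"], p = ofit$p_value)
    lfit <- fit_linear_standardized(as.data.frame(cohort)[names(eff$beta)],
                                    cohort$ln_density)
    ltab <- data.frame(term = names(lfit$coefficients),
                       beta = lfit$coefficients,
                       ci_low = lfit$ci[, "lower"],
                       ci_high = lfit$ci[, "upper"], p = lfit$p_value)
    s <- substream_seed(seed, match("fit", cfg$stages))
    sp <- spearman_with_ci(cohort$ln_volume_plus1, cohort$ln_density, seed = s)
    stab <- data.frame(rho = sp$rho, ci_low = sp$ci_lower,
                       ci_high = sp$ci_upper, n = sp$n, n_boot = sp$n_boot)
    dist <- export_distributions(data.frame(
      stratum = "IAC",
      category = factor(DENSITY_CATEGORY_LABELS[cohort$density_category],
                        levels = DENSITY_CATEGORY_LABELS, ordered = TRUE)))
    paths <- file.path(cfg$out_dir, c("ordinal_fit.csv", "linear_fit.csv",
                                      "spearman.csv",
                                      "category_distribution.csv"))
    utils::write.csv(otab, paths[1], row.names = FALSE)
    utils::write.csv(ltab, paths[2], row.names = FALSE)
    utils::write.csv(stab, paths[3], row.names = FALSE)
    utils::write.csv(dist, paths[4], row.names = FALSE)
    paths
  })

  manifest$files <- as.list(tools::md5sum(outputs))
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

# stage contract: measurement invariants checked before any model fit
validate_measurements <- function(measurements) {
  for (m in measurements) {
    prof <- m$profile
    if (is.unsorted(rev(prof$voxel_count)))
      stop("voxel counts increase along the threshold ladder for ",
           m$artery_id)
    vv <- prof$volume_mm3[prof$voxel_count > 0] /
      prof$voxel_count[prof$voxel_count > 0]
    if ((length(vv) && max(vv) - min(vv) > 1e-9) ||
        any(prof$volume_mm3[prof$voxel_count == 0] != 0))
      stop("volume is not voxel_count x voxel volume for ", m$artery_id)
    pres <- !is.na(prof$mean_hu)
    if (any(prof$mean_hu[pres] < prof$threshold[pres]))
      stop("mean density below its threshold for ", m$artery_id)
  }
  invisible(TRUE)
}

#' Category-distribution tables per stratum
#'
#' Converts per-participant (or per-artery) maximum-density categories into
#' the percentage-composition bars used to display the density distribution:
#' within each stratum, the percentage of each of the seven categories,
#' summing to 100.
#'
#' @param data `data.frame` with a `category` column (factor over the seven
#'   density categories) and a `stratum` column.
#' @return `data.frame`: stratum, category, n, percent. Strata with no
#'   observations are emitted with `n = 0` and `percent = NA`.
#' @export
export_distributions <- function(data) {
  if (!all(c("category", "stratum") %in% names(data)))
    stop("`data` needs columns `category` and `stratum`")
  cat <- data$category
  if (!is.factor(cat))
    cat <- factor(cat, levels = DENSITY_CATEGORY_LABELS, ordered = TRUE)
  strata <- if (is.factor(data$stratum)) levels(data$stratum)
            else unique(data$stratum)
  out <- do.call(rbind, lapply(strata, function(s) {
    sel <- data$stratum == s & !is.na(cat)
    n <- table(cat[sel])
    tot <- sum(n)
    data.frame(stratum = s, category = factor(names(n), levels = levels(cat),
                                              ordered = TRUE),
               n = as.integer(n),
               percent = if (tot > 0) 100 * as.integer(n) / tot else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
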