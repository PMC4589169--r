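#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run: cohort size and composition,
#' acquisition geometry, RGB thresholds, vessel and lesion options, stepwise
#' criteria, and the single root seed all stage randomness derives from.
#' The default profile uses the standard acquisition constants (AT8/4G8
#' boxes, the 100 um^2 APP filter, 8 vessels per block, the ARWMC size
#' cutoffs) with a demo geometry of 144 px tiles at 435.2/144 um/px — the
#' same 1.7 mm^2 montage field as the full-resolution 512 px / 0.85 um/px
#' geometry, sampled coarsely enough that a full 36-case run takes minutes.
#'
#' @param outdir output directory.
#' @param n_cases,prop_ad cohort size and AD fraction (defaults 36, 23/36).
#' @param tile_px,pixel_size montage acquisition geometry (um/px).
#' @param thresholds named list with `at8` and `g48` [rgb_threshold()]s.
#' @param n_specks_g48 APP-like confounders painted per 4G8 montage.
#' @param vessel_n_per_block,vessel_pixel_size vessel sampling options.
#' @param lesion_field_mm,lesion_px_per_mm lesion mask geometry.
#' @param entry_p,removal_p stepwise criteria.
#' @param write_images write TIFF/PNG rasters to disk (CSV outputs are
#'   always written).
#' @param seed integer root seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("wmhpath_run_"),
                       n_cases = 36L, prop_ad = 23 / 36,
                       tile_px = 144L, pixel_size = 435.2 / 144,
                       thresholds = list(at8 = at8_threshold(),
                                         g48 = g48_threshold()),
                       n_specks_g48 = 3L,
                       vessel_n_per_block = 8L, vessel_pixel_size = 1.0,
                       lesion_field_mm = 80, lesion_px_per_mm = 2,
                       entry_p = 0.05, removal_p = 0.10,
                       write_images = FALSE,
                       seed = 1L) {
  cfg <- structure(
    list(outdir = outdir, n_cases = as.integer(n_cases), prop_ad = prop_ad,
         tile_px = as.integer(tile_px), pixel_size = pixel_size,
         thresholds = thresholds, n_specks_g48 = as.integer(n_specks_g48),
         vessel_n_per_block = as.integer(vessel_n_per_block),
         vessel_pixel_size = vessel_pixel_size,
         lesion_field_mm = lesion_field_mm,
         lesion_px_per_mm = lesion_px_per_mm,
         entry_p = entry_p, removal_p = removal_p,
         write_images = isTRUE(write_images), seed = as.integer(seed)),
    class = "run_config"
  )
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config object to validate.
#' @export
validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) stop("not a run_config")
  if (is.null(config$thresholds$at8) || is.null(config$thresholds$g48) ||
      !inherits(config$thresholds$at8, "rgb_threshold") ||
      !inherits(config$thresholds$g48, "rgb_threshold")) {
    stop("config must carry 'at8' and 'g48' rgb_threshold specs")
  }
  stopifnot(config$n_cases >= 1, config$tile_px > 0, config$pixel_size > 0,
            config$entry_p < config$removal_p, config$seed >= 0)
  invisible(config)
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param config a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- function(t) {
    rgb_threshold(unlist(t$r_range), unlist(t$g_range), unlist(t$b_range),
                  min_component_area =
                    if (is.null(t$min_component_area)) NA_real_
                    else t$min_component_area,
                  marker = t$marker)
  }
  y$thresholds <- list(at8 = thr(y$thresholds$at8),
                       g48 = thr(y$thresholds$g48))
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  y <- unclass(config)
  y$thresholds <- lapply(config$thresholds, function(t) {
    list(r_range = t$r_range, g_range = t$g_range, b_range = t$b_range,
         min_component_area =
           if (is.na(t$min_component_area)) NULL else t$min_component_area,
         marker = t$marker)
  })
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

# location-class multipliers on the regional burden (sulcus > gyral tip);
# chosen to average to 1 over the 4 locations of a section
.location_mult <- c(sulcus = 1.5, midsection = 1.0, gyrus = 0.5)

# deterministic sub-seed, kept well below 2^31
.sub_seed <- function(root, ...) {
  k <- c(...)
  (root * 97L + sum(k * seq_along(k) * 131L)) %% 1999999973L
}

.case_region_col <- function(tab, prefix, section) {
  region <- .section_region[[section]]
  tab[[paste0(prefix, "_", region)]]
}

# generate + quantify all montages of one case; returns per-location rows
.quantify_case_ihc <- function(cohort_row, case_i, config) {
  plan <- sampling_plan()
  rows <- vector("list", 2L * nrow(plan))
  ri <- 0L
  for (marker in c("AT8", "4G8")) {
    thr <- if (marker == "AT8") config$thresholds$at8 else config$thresholds$g48
    prefix <- if (marker == "AT8") "hptau" else "abeta"
    for (li in seq_len(nrow(plan))) {
      section <- plan$section[li]
      regional_pct <- .case_region_col(cohort_row, prefix, section)
      target <- min(0.3, regional_pct / 100 *
                      .location_mult[[plan$location_class[li]]])
      spec <- ihc_scene_spec(
        tile_px = config$tile_px, pixel_size = config$pixel_size,
        structure_kinds = if (marker == "AT8") c("tangle", "thread")
          else "plaque",
        target_fraction = target,
        n_specks = if (marker == "4G8") config$n_specks_g48 else 0L,
        marker = marker,
        seed = .sub_seed(config$seed, 1L, case_i, li,
                         if (marker == "AT8") 0L else 1L)
      )
      scene <- make_ihc_montage(spec)
      if (config$write_images) {
        dir <- file.path(config$outdir, "montages", cohort_row$id)
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        write_montage(scene$image,
                      file.path(dir, sprintf("%s_%s_%02d.tif", marker,
                                             section, li)))
      }
      ir <- quantify_ihc(scene$image, thr)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        case_id = cohort_row$id, section = section,
        location_class = plan$location_class[li], marker = marker,
        percent_area = ir$percent_area, positive_px = ir$positive_px,
        measured_px = ir$measured_px,
        true_fraction_pathological = scene$true_fraction_pathological,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# generate + measure the 40 vessels of one case
.measure_case_vessels <- function(cohort_row, case_i, config) {
  blocks <- c("prefrontal", "midfrontal", "temporal", "parietal", "occipital")
  block_region <- c(prefrontal = "frontal", midfrontal = "frontal",
                    temporal = "temporal", parietal = "parietal",
                    occipital = "occipital")
  rows <- list()
  for (bi in seq_along(blocks)) {
    region_si <- cohort_row[[paste0("si_", block_region[[blocks[bi]]])]]
    for (vi in seq_len(config$vessel_n_per_block)) {
      sd0 <- .sub_seed(config$seed, 2L, case_i, bi, vi)
      meas <- NULL
      for (try in 0:4) {
        res <- withr::with_seed(sd0 + try, {
          si_v <- min(max(region_si + stats::rnorm(1, 0, 0.04), 0.05), 0.85)
          d_ext <- stats::runif(1, 60, 250)
          list(spec = vessel_scene_spec(
            d_int = d_ext * (1 - si_v), d_ext = d_ext,
            eccentricity = stats::runif(1, 0, 0.3),
            rotation = stats::runif(1, 0, 180),
            pixel_size = config$vessel_pixel_size,
            seed = sd0 + try
          ))
        })
        scene <- make_vessel_image(res$spec)
        if (config$write_images) {
          dir <- file.path(config$outdir, "vessels", cohort_row$id)
          dir.create(dir, recursive = TRUE, showWarnings = FALSE)
          write_vessel_image(scene$image,
                             file.path(dir, sprintf("%s_%02d.tif",
                                                    blocks[bi], vi)))
        }
        meas <- tryCatch(measure_vessel(scene$image), error = function(e) NULL)
        if (!is.null(meas)) break
      }
      if (is.null(meas)) {
        stop("vessel measurement failed for ", cohort_row$id, " block ",
             blocks[bi], " vessel ", vi)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cohort_row$id, block = blocks[bi], vessel_id = vi,
        d_int = meas$d_int, d_ext = meas$d_ext, si = meas$si,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# lesion diameters realising a target ARWMC score
.diameters_for_score <- function(score) {
  switch(as.character(score),
    "0" = numeric(0),
    "1" = stats::runif(sample(1:3, 1), 4, 8),
    "2" = stats::runif(1, 12, 18),
    "3" = stats::runif(1, 22, 30)
  )
}

.score_case_wmh <- function(cohort_row, case_i, config) {
  regions <- c("frontal", "temporal", "parietal", "occipital")
  scores <- stats::setNames(integer(4), regions)
  for (ri in seq_along(regions)) {
    truth <- cohort_row[[paste0("arwmc_", regions[ri])]]
    sd0 <- .sub_seed(config$seed, 3L, case_i, ri)
    diams <- withr::with_seed(sd0, .diameters_for_score(truth))
    spec <- lesion_scene_spec(field_mm = config$lesion_field_mm,
                              lesion_diameters = diams,
                              px_per_mm = config$lesion_px_per_mm,
                              seed = sd0 + 1L)
    lm_ <- make_lesion_mask(spec)
    if (config$write_images) {
      dir <- file.path(config$outdir, "masks", cohort_row$id)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_lesion_mask(lm_, file.path(dir, paste0(regions[ri], ".png")))
    }
    scores[ri] <- score_region(census_lesions(lm_), regions[ri])$score
  }
  comb <- combine_scores(scores)
  data.frame(case_id = cohort_row$id,
             frontal = scores[["frontal"]], temporal = scores[["temporal"]],
             parietal = scores[["parietal"]], occipital = scores[["occipital"]],
             parieto_occipital = comb$regional[["parieto_occipital"]],
             total = comb$total, stringsAsFactors = FALSE)
}

# age-controlled one-tailed correlations + stepwise, on measured values
.analyze_cohort <- function(merged, config) {
  regions <- c("frontal", "temporal", "parietal", "occipital", "total")
  out <- list()
  add <- function(analysis, region, variable, res) {
    if (inherits(res, "error")) {
      res <- list(estimate = NA_real_, statistic = NA_real_, df = NA_real_,
                  p.value = NA_real_,
                  method = paste0("failed: ", conditionMessage(res)))
    }
    out[[length(out) + 1L]] <<- data.frame(
      analysis = analysis, region = region, variable = variable,
      estimate = res$estimate, statistic = res$statistic, df = res$df,
      p = res$p.value, method = res$method, stringsAsFactors = FALSE
    )
  }
  try_corr <- function(...) tryCatch(partial_corr(...), error = function(e) e)
  for (r in regions) {
    # parietal/occipital ARWMC enter through the combined parieto-occipital
    wmh_col <- switch(r,
      parietal = "arwmc_meas_parieto_occipital",
      occipital = "arwmc_meas_parieto_occipital",
      paste0("arwmc_meas_", r))
    wmh <- merged[[wmh_col]]
    add("correlation", r, "hptau",
        try_corr(merged[[paste0("hptau_meas_", r)]], wmh,
                 covariates = merged$age, method = "spearman",
                 alternative = "greater"))
    add("correlation", r, "abeta",
        try_corr(merged[[paste0("abeta_meas_", r)]], wmh,
                 covariates = merged$age, method = "spearman",
                 alternative = "greater"))
    add("correlation", r, "si",
        try_corr(merged[[paste0("si_meas_", r)]], wmh,
                 covariates = merged$age, method = "pearson",
                 alternative = "greater"))
  }
  corr <- do.call(rbind, out)

  # group contrasts with normality routing
  contrasts <- list()
  for (v in c("hptau_meas_total", "abeta_meas_total", "si_meas_total",
              "arwmc_meas_total")) {
    x <- merged[[v]][merged$group == "AD"]
    y <- merged[[v]][merged$group == "control"]
    route <- route_test(x, y)
    if (route$route == "parametric") {
      r <- pooled_t(x, y)
      contrasts[[v]] <- data.frame(variable = v, test = "pooled_t",
                                   statistic = r$t, df = r$df, p = r$p,
                                   route = route$route,
                                   stringsAsFactors = FALSE)
    } else {
      r <- mann_whitney_u(x, y)
      contrasts[[v]] <- data.frame(variable = v, test = "mann_whitney_u",
                                   statistic = r$U, df = NA_real_, p = r$p,
                                   route = route$route,
                                   stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, contrasts)

  # stepwise per region: ARWMC ~ hptau + abeta + si + age
  steps <- list()
  for (r in regions) {
    wmh_col <- switch(r,
      parietal = "arwmc_meas_parieto_occipital",
      occipital = "arwmc_meas_parieto_occipital",
      paste0("arwmc_meas_", r))
    dat <- data.frame(
      wmh = merged[[wmh_col]],
      hptau = merged[[paste0("hptau_meas_", r)]],
      abeta = merged[[paste0("abeta_meas_", r)]],
      si = merged[[paste0("si_meas_", r)]],
      age = merged$age
    )
    sm <- tryCatch(
      stepwise_forward(dat, "wmh", c("hptau", "abeta", "si", "age"),
                       entry_p = config$entry_p,
                       removal_p = config$removal_p),
      error = function(e) NULL)
    steps[[r]] <- if (is.null(sm)) data.frame(
      region = r, selected = NA_character_, r_squared = NA_real_,
      f_statistic = NA_real_, model_p = NA_real_, n = NA_integer_,
      stringsAsFactors = FALSE
    ) else data.frame(
      region = r,
      selected = paste(sm$selected, collapse = "+"),
      r_squared = sm$r_squared, f_statistic = sm$f_statistic,
      model_p = sm$model_p, n = sm$n, stringsAsFactors = FALSE
    )
  }
  steps <- do.call(rbind, steps)
  list(correlations = corr, contrasts = contrasts, stepwise = steps)
}

#' Run the full synthetic study pipeline
#'
#' Stages, executed in order and each failing fast with a stage-named error:
#' `generate` (Gaussian-copula cohort truth), `quantify_ihc` (paint and
#' quantify 24 AT8 + 24 4G8 montages per case, aggregate to regional and
#' total burden), `measure_vessels` (render and measure 8 vessels per
#' white-matter block, pool to regional/total SI), `score_wmh` (generate and
#' rate lesion masks per region, combine to the parieto-occipital and total
#' ARWMC scores), `analyze` (routing-based group contrasts, age-controlled
#' one-tailed partial correlations, forward stepwise regression). All CSV
#' outputs land in `config$outdir`; a JSON manifest records the config,
#' checksums and versions. Identical config + seed reproduce byte-identical
#' CSVs.
#'
#' @param config a [run_config()].
#' @return the run manifest (class `run_manifest`), invisibly; its
#'   `results` field holds the analysis tables.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  cohort <- stage("generate", {
    cc <- cohort_config(n_cases = config$n_cases, prop_ad = config$prop_ad,
                        seed = .sub_seed(config$seed, 0L, 0L))
    make_cohort(cc)
  })
  emit(as.data.frame(cohort), "cohort_truth.csv")

  ihc <- stage("quantify_ihc", {
    per_loc <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
      .quantify_case_ihc(cohort[i, ], i, config)
    }))
    reg <- do.call(rbind, lapply(split(per_loc,
                                       list(per_loc$case_id, per_loc$marker),
                                       drop = TRUE), function(d) {
      agg <- aggregate_case(d)
      data.frame(case_id = d$case_id[1], marker = d$marker[1],
                 t(agg$regional), total = agg$total,
                 stringsAsFactors = FALSE)
    }))
    rownames(reg) <- NULL
    reg <- reg[order(reg$case_id, reg$marker), ]
    list(per_loc = per_loc, regional = reg)
  })
  emit(ihc$per_loc, "ihc_per_location.csv")
  emit(ihc$regional, "ihc_regional.csv")

  vessels <- stage("measure_vessels", {
    per_vessel <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
      .measure_case_vessels(cohort[i, ], i, config)
    }))
    reg <- do.call(rbind, lapply(split(per_vessel, per_vessel$case_id),
                                 function(d) {
      agg <- aggregate_si(d[, c("block", "si")],
                          n_per_block = config$vessel_n_per_block)
      data.frame(case_id = d$case_id[1], t(agg$regional), total = agg$total,
                 stringsAsFactors = FALSE)
    }))
    rownames(reg) <- NULL
    list(per_vessel = per_vessel, regional = reg)
  })
  emit(vessels$per_vessel, "vessels.csv")
  emit(vessels$regional, "si_regional.csv")

  wmh <- stage("score_wmh", {
    do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
      .score_case_wmh(cohort[i, ], i, config)
    }))
  })
  emit(wmh, "arwmc_scores.csv")

  results <- stage("analyze", {
    merged <- data.frame(id = cohort$id, group = cohort$group,
                         age = cohort$age, stringsAsFactors = FALSE)
    for (r in c("frontal", "temporal", "parietal", "occipital", "total")) {
      at8 <- ihc$regional[ihc$regional$marker == "AT8", ]
      g48 <- ihc$regional[ihc$regional$marker == "4G8", ]
      merged[[paste0("hptau_meas_", r)]] <-
        at8[[r]][match(merged$id, at8$case_id)]
      merged[[paste0("abeta_meas_", r)]] <-
        g48[[r]][match(merged$id, g48$case_id)]
      merged[[paste0("si_meas_", r)]] <-
        vessels$regional[[r]][match(merged$id, vessels$regional$case_id)]
    }
    mwm <- match(merged$id, wmh$case_id)
    merged$arwmc_meas_frontal <- wmh$frontal[mwm]
    merged$arwmc_meas_temporal <- wmh$temporal[mwm]
    merged$arwmc_meas_parieto_occipital <- wmh$parieto_occipital[mwm]
    merged$arwmc_meas_total <- wmh$total[mwm]
    res <- .analyze_cohort(merged, config)
    res$merged <- merged
    res
  })
  emit(results$correlations, "analysis_correlations.csv")
  emit(results$contrasts, "analysis_contrasts.csv")
  emit(results$stepwise, "analysis_stepwise.csv")
  emit(results$merged, "case_measures.csv")

  manifest <- structure(
    list(
      package = "wmhpath",
      version = as.character(utils::packageVersion("wmhpath")),
      seed = config$seed,
      config = unclass(config)[setdiff(names(config), "thresholds")],
      thresholds = lapply(config$thresholds, unclass),
      outputs = stats::setNames(as.character(tools::md5sum(outputs)),
                                basename(outputs)),
      timestamp = format(Sys.time(), tz = "UTC"),
      results = list(correlations = results$correlations,
                     contrasts = results$contrasts,
                     stepwise = results$stepwise)
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "results")],
    file.path(config$outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Write a complete synthetic study to disk
#'
#' Emits a ready-to-analyse synthetic dataset: the cohort CSV plus, for each
#' case, 24 AT8 and 24 4G8 montage TIFFs, 40 vessel TIFFs and 4 lesion-mask
#' PNGs (all with JSON scale sidecars). The default mirrors the reference
#' study design: 36 cases, 23 of them AD.
#'
#' @param outdir target directory.
#' @param seed root seed.
#' @param n_cases,prop_ad cohort composition.
#' @param ... further arguments to [run_config()].
#' @return the run manifest, invisibly.
#' @export
make_demo_dataset <- function(outdir, seed = 1L, n_cases = 36L,
                              prop_ad = 23 / 36, ...) {
  cfg <- run_config(outdir = outdir, n_cases = n_cases, prop_ad = prop_ad,
                    write_images = TRUE, seed = seed, ...)
  run_pipeline(cfg)
}
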