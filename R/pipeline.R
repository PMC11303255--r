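#' Analyze one net-periphery profile end to end
#'
#' The per-cell analysis chain: choose the hole-count-maximizing threshold
#' (40--66% of the unsaturated WFA peak), detect holes at least 0.5 µm wide,
#' and classify per-hole occupancy for every marker channel.
#'
#' @param profile A [line_profile()] with a `WFA` channel plus markers.
#' @param channels Marker channels (default: all non-WFA).
#' @param f_min,f_max,f_step Threshold sweep (fractions of unsaturated peak).
#' @param w_min Minimum hole width, µm.
#' @param k_sigma Occupancy prominence criterion, noise-sd units.
#' @param saturation_level Saturation intensity.
#' @return A list: `threshold` (a `threshold_result`), `holes` (a
#'   `hole_set`), `calls` (an `occupancy_calls` tibble).
#' @export
analyze_net_profile <- function(profile, channels = NULL, f_min = 0.40,
                                f_max = 0.66, f_step = 0.01, w_min = 0.5,
                                k_sigma = 3.0, saturation_level = 4095) {
  thr <- select_threshold(profile, "WFA", f_min, f_max, f_step, w_min,
                          saturation_level)
  holes <- detect_holes(profile, "WFA", thr$threshold, w_min)
  calls <- classify_occupancy(holes, profile, channels, k_sigma)
  list(threshold = thr, holes = holes, calls = calls)
}

#' Measure cohort occupancy through the full pipeline
#'
#' Runs [analyze_net_profile()] on every cell of a synthetic (or measured)
#' cohort and summarizes the occupancy combinatorics. Cells whose analysis
#' fails are skipped with a warning; the run errors only if all fail.
#'
#' @param profiles A list of [line_profile()]s (e.g. from
#'   [simulate_cohort()], taking `$profile` of each element).
#' @inheritParams analyze_net_profile
#' @return A list: `summary` (an `occupancy_table`), `holes` (tibble with
#'   `cell` column), `calls` (tibble with `cell`), `thresholds` (tibble of
#'   per-cell threshold fractions, the logged paper-gap parameter).
#' @export
measure_cohort_occupancy <- function(profiles, channels = NULL, ...) {
  results <- purrr::imap(profiles, function(p, idx) {
    tryCatch(analyze_net_profile(p, channels, ...), error = function(e) {
      warning(sprintf("cell %s failed: %s", idx, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all cells failed", call. = FALSE)
  results <- results[ok]
  cells <- seq_along(profiles)[ok]
  holes <- purrr::map2_dfr(results, cells, function(r, id) {
    dplyr::mutate(tibble::as_tibble(r$holes), cell = id, .before = 1)
  })
  calls <- purrr::map2_dfr(results, cells, function(r, id) {
    dplyr::mutate(tibble::as_tibble(r$calls), cell = id, .before = 1)
  })
  thresholds <- purrr::map2_dfr(results, cells, function(r, id) {
    tibble::tibble(cell = id, fraction = r$threshold$fraction_of_peak,
                   threshold = r$threshold$threshold,
                   unsaturated_peak = r$threshold$unsaturated_peak,
                   n_holes = r$threshold$n_holes)
  })
  list(summary = occupancy_summary(calls), holes = holes, calls = calls,
       thresholds = thresholds)
}

#' Run the hole-occupancy pipeline from a run configuration
#'
#' Orchestrates synthesize -> (render/extract) -> detect -> classify ->
#' summarize for a synthetic cohort and, when `out_dir` is set, writes the
#' holes table, occupancy calls, per-cell threshold log, and summary JSON.
#' `route = "image"` renders each net as a 2D image and extracts the profile
#' along the true contour before detection (the full imaging pipeline);
#' `route = "profile"` synthesizes the 1D profile directly.
#'
#' @param config A list (or YAML file read by [read_run_config()]) with
#'   elements `preset` (an [occupancy_presets()] name) or `occupancy`
#'   (an [occupancy_profile()]), `n_cells`, `seed`, optional `spec`
#'   (a [net_spec()]), `route`, `out_dir`, and analysis parameter overrides
#'   (`f_min`, `f_max`, `w_min`, `k_sigma`).
#' @return As [measure_cohort_occupancy()], invisibly when writing.
#' @export
run_holes_pipeline <- function(config) {
  stopifnot(is.list(config))
  occ <- config$occupancy %||% occupancy_presets(config$preset)
  spec <- config$spec %||% net_spec(snr = config$snr %||% 10)
  n_cells <- config$n_cells %||% 40
  seed <- config$seed %||% 1
  route <- config$route %||% "profile"
  profiles <- if (route == "image") {
    seeds <- with_rng(seed, sample.int(.Machine$integer.max - 1L, n_cells))
    lapply(seeds, function(sd) {
      syn <- simulate_net_image(spec, occ, sd)
      extract_profile(syn$image, syn$contour)
    })
  } else {
    lapply(simulate_cohort(spec, occ, n_cells, seed), `[[`, "profile")
  }
  res <- measure_cohort_occupancy(
    profiles, channels = occ$channels,
    f_min = config$f_min %||% 0.40, f_max = config$f_max %||% 0.66,
    w_min = config$w_min %||% 0.5, k_sigma = config$k_sigma %||% 3.0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(res$holes, file.path(config$out_dir, "holes.csv"))
    readr::write_csv(res$calls, file.path(config$out_dir, "occupancy_calls.csv"))
    readr::write_csv(res$thresholds, file.path(config$out_dir, "thresholds.csv"))
    jsonlite::write_json(
      list(config = config[setdiff(names(config), c("occupancy", "spec"))],
           cohort = res$summary$cohort, pooled = res$summary$pooled),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

#' Run the pericellular coverage/puncta pipeline for labelled groups
#'
#' Synthesizes one pericellular image per cell for each group (group
#' parameters: `band_coverage`, `n_puncta`, `contact_frac`), measures
#' astrocytic band coverage, pericellular puncta and astrocyte contacts
#' through [soma_mask()], [pericellular_band()], [coverage()],
#' [find_maxima()] and [puncta_with_astro_contact()], and aggregates per
#' group.
#'
#' @param config A list: `groups` (named list of parameter lists),
#'   `n_cells`, `seed`, optional `band_width`, `prominence`, `out_dir`.
#' @return A list: `per_cell` (tibble), `groups` (a `group_summary`).
#' @export
run_pericellular_pipeline <- function(config) {
  stopifnot(is.list(config), length(config$groups) >= 1)
  n_cells <- config$n_cells %||% 10
  band_width <- config$band_width %||% 0.8
  prominence <- config$prominence %||% 500
  seeds <- with_rng(config$seed %||% 1,
                    sample.int(.Machine$integer.max - 1L,
                               n_cells * length(config$groups)))
  k <- 0L
  per_cell <- purrr::imap_dfr(config$groups, function(gp, gname) {
    purrr::map_dfr(seq_len(n_cells), function(ci) {
      k <<- k + 1L
      syn <- simulate_pericellular_image(
        soma_radius = gp$soma_radius %||% 5,
        band_coverage = gp$band_coverage %||% 0.4,
        n_puncta = gp$n_puncta %||% 30,
        contact_frac = gp$contact_frac,
        band_width = band_width, seed = seeds[k])
      img <- syn$image
      soma <- soma_mask(img, "soma")
      band <- pericellular_band(soma, band_width)
      astro <- img_channel(img, "astro") >
        otsu_threshold(img_channel(img, "astro"))
      perim <- syn$truth$perimeter
      cov <- coverage(band, list(astro = astro), perim)
      pts <- find_maxima(img_channel(img, "puncta"), prominence,
                         pixel_size = img$pixel_size)
      pband <- pericellular_puncta(pts, band, perim)
      contacts <- puncta_with_astro_contact(pts, astro)
      tibble::tibble(
        group = gname, cell = ci,
        coverage_um = cov$normalized_um[cov$marker == "astro"],
        puncta_per_um = pband$per_um,
        contact_frac = if (nrow(contacts)) mean(contacts$contact) else NA_real_)
    })
  })
  out <- list(per_cell = per_cell,
              groups = summarize_groups(per_cell, group_col = "group"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(per_cell, file.path(config$out_dir, "pericellular_cells.csv"))
    readr::write_csv(out$groups$summary,
                     file.path(config$out_dir, "pericellular_groups.csv"))
  }
  out
}

#' Summarize per-cell metrics by group
#'
#' Mean, sd and n per metric per group (the mean ± s.d. convention of the
#' figure panels); per-cell values are retained for external statistics —
#' no hypothesis testing is performed here.
#'
#' @param per_cell Tibble with one row per cell: a group column plus numeric
#'   metric columns.
#' @param group_col Name of the group column.
#' @param grouping Optional named vector or two-column table mapping cell
#'   ids to group labels when `per_cell` lacks a group column; every cell
#'   must map to a known label.
#' @return A list of class `group_summary`: `summary` (group, metric, mean,
#'   sd, n) and `per_cell` (the input, with groups attached).
#' @export
summarize_groups <- function(per_cell, group_col = "group", grouping = NULL) {
  per_cell <- tibble::as_tibble(per_cell)
  if (!is.null(grouping)) {
    map <- if (is.data.frame(grouping)) {
      stats::setNames(grouping[[2]], grouping[[1]])
    } else grouping
    if (!"cell" %in% names(per_cell)) stop("`per_cell` needs a cell column",
                                           call. = FALSE)
    lab <- map[as.character(per_cell$cell)]
    if (anyNA(lab)) stop("unknown group label for some cells", call. = FALSE)
    per_cell[[group_col]] <- unname(lab)
  }
  if (!group_col %in% names(per_cell)) {
    stop("no '", group_col, "' column and no `grouping` supplied", call. = FALSE)
  }
  metrics <- names(per_cell)[vapply(per_cell, is.numeric, logical(1))]
  metrics <- setdiff(metrics, c("cell", group_col))
  if (!length(metrics)) stop("no numeric metric columns", call. = FALSE)
  long <- tidyr::pivot_longer(per_cell, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data[[group_col]], .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)), .groups = "drop")
  structure(list(summary = summary, per_cell = per_cell),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @rdname summarize_groups
#' @param x A `group_summary`.
#' @param ... Unused.
#' @export
tidy.group_summary <- function(x, ...) x$summary

#' Read a YAML run configuration
#'
#' @param path YAML file with the fields of [run_holes_pipeline()] /
#'   [run_pericellular_pipeline()].
#' @return A config list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
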