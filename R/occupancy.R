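#' Classify per-hole marker occupancy
#'
#' A hole is called occupied by a channel when that channel shows a clearly
#' distinguishable peak between the two flanking WFA peaks: operationally, a
#' local maximum inside the hole interval whose prominence over the higher
#' of the two channel values at the hole boundaries is at least `k_sigma`
#' times the channel's robust noise sd. The noise sd is estimated from the
#' median absolute deviation of lag-`noise_lag` differences over the whole
#' profile (`mad(diff(v, lag)) / sqrt(2)`): the MAD keeps smooth structure
#' from inflating the estimate, and the lag (default 3 samples) keeps the
#' short-range correlation that band averaging and sub-pixel interpolation
#' imprint on extracted profiles from deflating it. For uncorrelated
#' samples the lag is immaterial.
#'
#' @param holes A `hole_set` from [detect_holes()].
#' @param profile The [line_profile()] the holes were detected on.
#' @param channels Marker channels to classify; default: all non-WFA channels.
#' @param k_sigma Prominence criterion in noise-sd units (default 3).
#' @param noise_lag Sample lag for the difference-based noise estimate.
#' @return A tibble of class `occupancy_calls` with columns `hole`,
#'   `channel`, `present`, `peak_s`, `prominence`; attributes record
#'   `k_sigma` and the per-channel noise sd actually used.
#' @export
classify_occupancy <- function(holes, profile, channels = NULL, k_sigma = 3.0,
                               noise_lag = 3L) {
  if (is.null(channels)) channels <- setdiff(profile_channels(profile), "WFA")
  stopifnot(all(channels %in% profile_channels(profile)), k_sigma >= 0,
            noise_lag >= 1)
  L <- profile_perimeter(profile)
  s <- profile$s
  noise_sd <- vapply(channels, function(ch) {
    stats::mad(diff(profile[[ch]], lag = noise_lag)) / sqrt(2)
  }, numeric(1))

  one <- function(k, ch) {
    v <- profile[[ch]]
    a <- holes$start[k]; w <- holes$width[k]
    rel <- (s - a) %% L
    inside <- rel > 0 & rel < w
    if (!any(inside)) {
      return(tibble::tibble(hole = holes$hole[k], channel = ch,
                            present = FALSE, peak_s = NA_real_,
                            prominence = NA_real_))
    }
    vmax <- max(v[inside])
    peak_s <- s[inside][which.max(v[inside])]
    bound <- max(profile_value_at(profile, ch, a),
                 profile_value_at(profile, ch, (a + w) %% L))
    prom <- vmax - bound
    tibble::tibble(hole = holes$hole[k], channel = ch,
                   present = prom > 0 & prom >= k_sigma * noise_sd[ch],
                   peak_s = peak_s, prominence = prom)
  }
  grid <- tidyr::expand_grid(k = seq_len(nrow(holes)), ch = channels)
  out <- purrr::map2_dfr(grid$k, grid$ch, one)
  attr(out, "k_sigma") <- k_sigma
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("occupancy_calls", class(out))
  out
}

# Combination label of one hole given its per-channel presence flags,
# using the same "A+B" / "none" convention as occupancy_profile().
combo_of <- function(present, channels) {
  sel <- channels[present]
  if (length(sel) == 0) "none" else paste(sel, collapse = "+")
}

#' Summarize cohort occupancy combinatorics
#'
#' Takes per-hole occupancy calls from one or more cells and reports, per
#' cell and pooled over holes, the percentage of holes in every combination
#' category: the mutually exclusive partition over channel combinations
#' (type `"exclusive"`; sums to 100 per cell), per-channel marginals (type
#' `"contains"`: holes containing the channel regardless of co-occupants),
#' intersections of channel pairs and of the full channel set (type
#' `"contains"`), and the derived union `"any"` and complement `"none"`
#' (type `"derived"`; `any = 100 - none`). The cohort summary is the
#' per-cell mean and sd, the headline statistic of occupancy panels.
#'
#' @param calls An `occupancy_calls` tibble, or a bind of several with a
#'   `cell` column identifying the source net.
#' @param channels Channel ordering for labels; default: order of appearance.
#' @return A list of class `occupancy_table`: `per_cell` (cell, combination,
#'   type, pct), `cohort` (combination, type, mean, sd, n_cells), `pooled`
#'   (combination, type, pct), plus `channels` and `n_holes`.
#' @export
occupancy_summary <- function(calls, channels = NULL) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) stop("no occupancy calls supplied", call. = FALSE)
  if (!"cell" %in% names(calls)) calls$cell <- 1L
  if (is.null(channels)) channels <- unique(calls$channel)
  stopifnot(all(calls$channel %in% channels))

  wide <- tidyr::pivot_wider(calls[c("cell", "hole", "channel", "present")],
                             names_from = "channel", values_from = "present")
  if (anyNA(wide[channels])) {
    stop("every hole needs a call for every channel", call. = FALSE)
  }
  pm <- as.matrix(wide[channels])
  wide$combo <- apply(pm, 1, combo_of, channels = channels)

  categories <- function(sub) {
    m <- as.matrix(sub[channels])
    n <- nrow(sub)
    excl <- vapply(combination_labels(channels),
                   function(lb) mean(sub$combo == lb) * 100, numeric(1))
    marg <- vapply(channels, function(ch) mean(m[, ch]) * 100, numeric(1))
    pairs <- utils::combn(channels, min(2, length(channels)), simplify = FALSE)
    inter <- if (length(channels) >= 2) {
      sets <- pairs
      if (length(channels) > 2) sets <- c(sets, list(channels))
      stats::setNames(
        vapply(sets, function(cc) mean(rowSums(m[, cc, drop = FALSE]) ==
                                         length(cc)) * 100, numeric(1)),
        vapply(sets, paste, character(1), collapse = "&"))
    } else numeric(0)
    none <- mean(rowSums(m) == 0) * 100
    dplyr::bind_rows(
      tibble::tibble(combination = names(excl), type = "exclusive",
                     pct = unname(excl)),
      tibble::tibble(combination = channels, type = "contains",
                     pct = unname(marg)),
      if (length(inter)) tibble::tibble(combination = names(inter),
                                        type = "contains", pct = unname(inter)),
      tibble::tibble(combination = c("any", "none"), type = "derived",
                     pct = c(100 - none, none))
    )
  }

  per_cell <- dplyr::group_modify(dplyr::group_by(wide, .data$cell),
                                  function(d, g) categories(d))
  per_cell <- dplyr::ungroup(per_cell)
  cohort <- dplyr::summarise(
    dplyr::group_by(per_cell, .data$combination, .data$type),
    mean = mean(.data$pct), sd = stats::sd(.data$pct),
    n_cells = dplyr::n(), .groups = "drop")
  pooled <- categories(wide)

  structure(
    list(per_cell = per_cell, cohort = cohort, pooled = pooled,
         channels = channels, n_holes = nrow(wide)),
    class = "occupancy_table"
  )
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("<occupancy_table> %d holes, %d cells, channels: %s\n",
              x$n_holes, length(unique(x$per_cell$cell)),
              paste(x$channels, collapse = ", ")))
  print(x$cohort)
  invisible(x)
}

#' Look up one occupancy percentage
#'
#' @param table An `occupancy_table`.
#' @param combination Combination label (e.g. `"AldheGFP"`,
#'   `"AldheGFP&vGlut1"`, `"any"`).
#' @param type Category type the label belongs to.
#' @param source `"pooled"` (percentage over all holes) or `"cohort"`
#'   (mean of per-cell percentages).
#' @return A single percentage.
#' @export
occupancy_pct <- function(table, combination,
                          type = c("contains", "derived", "exclusive"),
                          source = c("pooled", "cohort")) {
  type <- match.arg(type)
  source <- match.arg(source)
  tb <- if (source == "pooled") table$pooled else table$cohort
  row <- tb[tb$combination == combination & tb$type == type, ]
  if (nrow(row) != 1) {
    stop("combination '", combination, "' (type ", type, ") not found",
         call. = FALSE)
  }
  unname(if (source == "pooled") row$pct else row$mean)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an occupancy table
#'
#' @param x An `occupancy_table`.
#' @param ... Unused.
#' @return The cohort tibble (combination, type, mean, sd, n_cells).
#' @export
tidy.occupancy_table <- function(x, ...) x$cohort

#' @rdname tidy.occupancy_table
#' @export
glance.occupancy_table <- function(x, ...) {
  tibble::tibble(
    n_holes = x$n_holes,
    n_cells = length(unique(x$per_cell$cell)),
    n_channels = length(x$channels),
    pct_any = occupancy_pct(x, "any", "derived"),
    pct_none = occupancy_pct(x, "none", "derived")
  )
}

#' Plot cohort occupancy percentages
#'
#' Bar chart (mean ± sd across cells) of the per-channel marginals, the
#' full-set intersection, and the derived any/none categories — the layout
#' of a published occupancy panel.
#'
#' @param object An `occupancy_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_table <- function(object, ...) {
  full <- paste(object$channels, collapse = "&")
  keep <- dplyr::filter(
    object$cohort,
    (.data$type == "contains" & .data$combination %in%
       c(object$channels, full)) | .data$type == "derived")
  keep$combination <- factor(keep$combination,
                             levels = c(object$channels, full, "any", "none"))
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$combination, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "% of PNN holes")
}
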