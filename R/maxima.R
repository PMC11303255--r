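#' Prominence-based detection of puncta (find maxima)
#'
#' Detects local intensity maxima whose prominence — the height of the
#' maximum above the highest saddle connecting it to any higher maximum —
#' is at least `prominence`. This is the flood-from-maximum ("noise
#' tolerance") semantics under which the published prominence settings of
#' 500 (vGlut1) and 2,000 (vGAT) on a 12-bit scale are meaningful: starting
#' from each candidate maximum in descending intensity order, the region of
#' pixels reachable without descending below `value - prominence`
#' (8-connected) is flooded; a candidate whose flood reaches strictly higher
#' ground, or which lies inside the flood of a higher maximum, is rejected.
#' Plateau maxima are reported once at the plateau centroid. Ties between
#' equal maxima connected within one flood band are broken by processing
#' order (intensity descending, then row-major position).
#'
#' @param channel Numeric intensity matrix.
#' @param prominence Minimum prominence (> 0), intensity units.
#' @param pixel_size µm/px used for the physical coordinates of the output.
#' @return A tibble of class `puncta_set` with columns `x`, `y` (µm, pixel
#'   centres), `row`, `col` (plateau centroid, 1-based), `value`.
#' @export
find_maxima <- function(channel, prominence, pixel_size = 1) {
  stopifnot(is.matrix(channel), prominence > 0)
  nr <- nrow(channel); nc <- ncol(channel)
  empty <- tibble::tibble(x = numeric(), y = numeric(), row = numeric(),
                          col = numeric(), value = numeric())
  attr(empty, "prominence") <- prominence
  class(empty) <- c("puncta_set", class(empty))
  if (length(unique(as.vector(channel))) < 2) return(empty)

  # candidate pixels: >= all 8 neighbours (computed against a -Inf pad)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- channel
  nbmax <- matrix(-Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbmax <- pmax(nbmax, pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)])
  }
  cand <- channel >= nbmax

  # 8-connected neighbours of a set of linear indices (vectorized frontier)
  neighbours_of <- function(idx) {
    i <- ((idx - 1) %% nr) + 1; j <- ((idx - 1) %/% nr) + 1
    out <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      out <- c(out, (jj[ok] - 1L) * nr + ii[ok])
    }
    unique(out)
  }

  # group candidates into equal-value plateaus (8-connected)
  plateau_id <- matrix(0L, nr, nc)
  n_plat <- 0L
  plat_rows <- list()
  for (p0 in which(cand)) {
    if (plateau_id[p0] != 0L) next
    n_plat <- n_plat + 1L
    v0 <- channel[p0]
    plateau_id[p0] <- n_plat
    members <- p0
    frontier <- p0
    while (length(frontier)) {
      nbr <- neighbours_of(frontier)
      nbr <- nbr[plateau_id[nbr] == 0L & cand[nbr] & channel[nbr] == v0]
      plateau_id[nbr] <- n_plat
      members <- c(members, nbr)
      frontier <- nbr
    }
    plat_rows[[n_plat]] <- members
  }
  if (n_plat == 0) return(empty)

  plat_val <- vapply(plat_rows, function(m) channel[m[1]], numeric(1))
  plat_seed <- vapply(plat_rows, min, numeric(1))
  ord <- order(-plat_val, plat_seed)

  owner <- matrix(0L, nr, nc)   # which candidate's flood claimed each pixel
  accepted <- logical(n_plat)
  for (pi in ord) {
    members <- plat_rows[[pi]]
    if (length(members) == nr * nc) next       # constant region = no punctum
    if (any(owner[members] != 0L)) next        # inside a higher max's band
    v0 <- plat_val[pi]
    lo <- v0 - prominence
    # flood pixels with value > lo, 8-connected, from the plateau; reaching
    # strictly higher ground, or territory flooded by an earlier (higher or
    # equal) maximum, means that maximum connects within this band
    owner[members] <- pi
    rejected <- FALSE
    frontier <- members
    while (length(frontier)) {
      nbr <- neighbours_of(frontier)
      nbr <- nbr[channel[nbr] > lo]
      if (any(owner[nbr] != 0L & owner[nbr] != pi)) rejected <- TRUE
      nbr <- nbr[owner[nbr] == 0L]
      if (length(nbr)) {
        owner[nbr] <- pi
        if (any(channel[nbr] > v0)) rejected <- TRUE
      }
      frontier <- nbr
    }
    accepted[pi] <- !rejected
  }

  keep <- which(accepted)
  if (!length(keep)) return(empty)
  rows <- vapply(plat_rows[keep], function(m) mean(((m - 1) %% nr) + 1), numeric(1))
  cols <- vapply(plat_rows[keep], function(m) mean(((m - 1) %/% nr) + 1), numeric(1))
  out <- tibble::tibble(
    x = (cols - 0.5) * pixel_size,
    y = (rows - 0.5) * pixel_size,
    row = rows, col = cols,
    value = plat_val[keep]
  )
  out <- out[order(-out$value, out$row, out$col), ]
  attr(out, "prominence") <- prominence
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("puncta_set", class(out))
  out
}
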