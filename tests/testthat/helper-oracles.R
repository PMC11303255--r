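# Independent reference implementations used as oracles.

# Naive circular run-length hole scan: walk the rotated boolean vector
# sample by sample, collect below-threshold runs, interpolate boundaries.
oracle_holes <- function(v, L, threshold, w_min = 0.5) {
  n <- length(v)
  ds <- L / n
  s <- (seq_len(n) - 1) * ds
  below <- v < threshold
  if (!any(below)) {
    return(data.frame(start = numeric(), end = numeric(), width = numeric()))
  }
  if (all(below)) return(data.frame(start = 0, end = 0, width = L))
  st <- which(!below)[1]
  idx <- c(st:n, seq_len(st - 1))          # original indices in rotated order
  brot <- below[idx]
  runs <- list()
  r0 <- NA
  for (r in seq_len(n)) {
    if (brot[r] && is.na(r0)) r0 <- r
    if (!brot[r] && !is.na(r0)) {
      runs[[length(runs) + 1]] <- c(r0, r - 1)
      r0 <- NA
    }
  }
  if (!is.na(r0)) runs[[length(runs) + 1]] <- c(r0, n)
  rows <- lapply(runs, function(rr) {
    i0 <- idx[rr[1]]; i1 <- idx[rr[2]]
    ip <- if (i0 == 1) n else i0 - 1
    iq <- if (i1 == n) 1 else i1 + 1
    f0 <- (v[ip] - threshold) / (v[ip] - v[i0])
    f1 <- (threshold - v[i1]) / (v[iq] - v[i1])
    start <- (s[ip] + f0 * ds) %% L
    end <- (s[i1] + f1 * ds) %% L
    c(start, end, (end - start) %% L)
  })
  m <- do.call(rbind, rows)
  m <- m[m[, 3] >= w_min, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2], width = m[, 3])
}

# 8-connected component of `mask` containing `seed_idx`, computed by
# morphological reachability: grow the seed by 3x3 dilation clipped to the
# mask until a fixed point (EBImage as the morphology engine).
reach8 <- function(mask, seed_idx) {
  brush <- EBImage::makeBrush(3, "box")
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  comp[seed_idx] <- TRUE
  repeat {
    grown <- EBImage::imageData(EBImage::dilate(EBImage::Image(comp * 1),
                                                brush)) > 0
    grown <- grown & mask
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

# Exhaustive prominence-maxima reference: for each local-max plateau, take
# the 8-connected component of {value > v0 - prominence} containing it and
# accept iff the component holds nothing higher, breaking ties among equal
# maxima by seed order.
oracle_maxima <- function(m, prominence) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  nbmax <- matrix(-Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbmax <- pmax(nbmax, pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)])
  }
  cand <- m >= nbmax
  plateaus <- list()
  remaining <- cand
  while (any(remaining)) {
    seed <- which(remaining)[1]
    members <- which(reach8(remaining & m == m[seed], seed))
    plateaus[[length(plateaus) + 1]] <- list(value = m[seed], members = members)
    remaining[members] <- FALSE
  }
  if (!length(plateaus)) return(data.frame(row = numeric(), col = numeric(),
                                           value = numeric()))
  seeds <- vapply(plateaus, function(p) min(p$members), numeric(1))
  vals <- vapply(plateaus, function(p) p$value, numeric(1))
  ord <- order(-vals, seeds)
  acc <- logical(length(plateaus))
  for (i in ord) {
    p <- plateaus[[i]]
    if (length(p$members) == nr * nc) next
    comp <- reach8(m > p$value - prominence, p$members[1])
    if (max(m[comp]) > p$value) next
    # equal maxima sharing the band: first by (value desc, seed asc) wins
    rivals <- which(vals == p$value &
                      vapply(plateaus, function(q) comp[q$members[1]], logical(1)))
    if (min(seeds[rivals]) < seeds[i]) next
    acc[i] <- TRUE
  }
  keep <- plateaus[acc]
  data.frame(
    row = vapply(keep, function(p) mean(((p$members - 1) %% nr) + 1), numeric(1)),
    col = vapply(keep, function(p) mean(((p$members - 1) %/% nr) + 1), numeric(1)),
    value = vapply(keep, function(p) p$value, numeric(1))
  )
}

# Rectangular-trough test profile: troughs given as (start, width, floor)
# fractions of the peak, on a circle of length L sampled at ds.
make_trough_profile <- function(troughs, L = 50, ds = 0.031, peak = 3000) {
  n <- round(L / ds)
  s <- (seq_len(n) - 1) * (L / n)
  v <- rep(peak, n)
  for (k in seq_len(nrow(troughs))) {
    rel <- (s - troughs$start[k]) %% L
    v[rel < troughs$width[k]] <- troughs$floor[k] * peak
  }
  line_profile(s, list(WFA = v), L)
}

# add a Gaussian bump (circular) to one channel of a profile
add_bump <- function(profile, channel, center, amp, sigma) {
  L <- profile_perimeter(profile)
  d <- abs(profile$s - center) %% L
  d <- pmin(d, L - d)
  profile[[channel]] <- profile[[channel]] + amp * exp(-d^2 / (2 * sigma^2))
  profile
}
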