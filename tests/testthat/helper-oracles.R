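# Independent brute-force oracles, written as literal transcriptions of the
# definitions. They deliberately share no code with the package internals:
# everything is per-cell loops and explicit counting.

# Bioclim oracle: one cell at a time, from 12-month vectors.
oracle_bioclim_cell <- function(tmin, tmax, prec) {
  tavg <- (tmin + tmax) / 2
  qs <- lapply(1:12, function(q) {
    idx <- c(q, q %% 12 + 1, (q + 1) %% 12 + 1)
    list(t = mean(tavg[idx]), p = sum(prec[idx]))
  })
  qt <- sapply(qs, `[[`, "t")
  qp <- sapply(qs, `[[`, "p")
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  wet <- which(qp == max(qp))[1]
  dry <- which(qp == min(qp))[1]
  hot <- which(qt == max(qt))[1]
  cold <- which(qt == min(qt))[1]
  b05 <- max(tmax); b06 <- min(tmin); b07 <- b05 - b06
  b02 <- mean(tmax - tmin)
  c(
    Bio01 = mean(tavg),
    Bio02 = b02,
    Bio03 = if (b07 > 0) 100 * b02 / b07 else NA_real_,
    Bio04 = 100 * sd_pop(tavg),
    Bio05 = b05, Bio06 = b06, Bio07 = b07,
    Bio08 = qt[wet], Bio09 = qt[dry], Bio10 = qt[hot], Bio11 = qt[cold],
    Bio12 = sum(prec),
    Bio13 = max(prec), Bio14 = min(prec),
    Bio15 = if (mean(prec) > 1e-12) 100 * sd_pop(prec) / mean(prec) else 0,
    Bio16 = qp[wet], Bio17 = qp[dry], Bio18 = qp[hot], Bio19 = qp[cold]
  )
}

# GDD5 oracle: explicit daily loop, each day carrying its month's mean.
oracle_gdd5_cell <- function(tmin, tmax, base = 5) {
  dim_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  total <- 0
  for (m in 1:12) {
    tmean <- (tmin[m] + tmax[m]) / 2
    for (d in seq_len(dim_days[m])) total <- total + max(0, tmean - base)
  }
  total
}

# Rank AUC oracle: double loop over all presence/background pairs.
oracle_auc <- function(pres, bg) {
  wins <- 0
  for (a in pres) for (b in bg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pres) * length(bg))
}

# MESS oracle: per-point per-variable explicit counting.
oracle_mess_point <- function(ref, p) {
  vars <- colnames(ref)
  sims <- sapply(vars, function(v) {
    rv <- ref[, v]
    mn <- min(rv); mx <- max(rv)
    if (mx == mn) return(if (p[v] == mn) 100 else 0)
    f <- 100 * sum(rv < p[v]) / length(rv)
    if (f == 0) 100 * (p[v] - mn) / (mx - mn)
    else if (f <= 50) 2 * f
    else if (f < 100) 2 * (100 - f)
    else 100 * (mx - p[v]) / (mx - mn)
  })
  list(mess = min(sims), mod = vars[which.min(sims)])
}

# Point-in-cell binning oracle: scan every cell's rectangle.
oracle_bin_point <- function(spec, px, py) {
  ymax <- spec$ymin + spec$nrow * spec$cellsize
  for (cc in seq_len(spec$ncol)) {
    for (rr in seq_len(spec$nrow)) {
      x0 <- spec$xmin + (cc - 1) * spec$cellsize
      y1 <- ymax - (rr - 1) * spec$cellsize
      y0 <- y1 - spec$cellsize
      if (px >= x0 && px < x0 + spec$cellsize && py >= y0 && py < y1) {
        return(as.integer((cc - 1) * spec$nrow + rr))
      }
    }
  }
  NA_integer_
}

# Training-presence threshold oracle: sort and index.
oracle_threshold <- function(p, percentile = 10) {
  s <- sort(p)
  n <- length(p)
  # smallest k such that keeping values >= s[k] retains >= (100-percentile)%
  for (k in seq_len(n)) {
    if (sum(p >= s[k]) < ceiling((1 - percentile / 100) * n)) {
      return(s[k - 1])
    }
  }
  s[n]
}

# Bilinear oracle: two-pass 1D linear interpolation with stats::approx.
oracle_bilinear_point <- function(layer, coarse_spec, x, y) {
  cs <- coarse_spec$cellsize
  xc <- coarse_spec$xmin + (seq_len(coarse_spec$ncol) - 0.5) * cs
  yc <- (coarse_spec$ymin + coarse_spec$nrow * cs) -
    (seq_len(coarse_spec$nrow) - 0.5) * cs   # row 1 = north
  x <- min(max(x, xc[1]), xc[length(xc)])
  y <- min(max(y, yc[length(yc)]), yc[1])
  # interpolate along columns first (per row), then across rows
  rowvals <- sapply(seq_len(coarse_spec$nrow), function(r) {
    stats::approx(xc, layer[r, ], xout = x)$y
  })
  stats::approx(rev(yc), rev(rowvals), xout = y)$y
}

# Jolliffe B2 oracle: independent transcription with princomp-style steps.
oracle_b2 <- function(x, lambda0 = 0.70) {
  keep <- colnames(x)
  repeat {
    if (length(keep) < 2) break
    cm <- cor(x[, keep, drop = FALSE])
    eg <- eigen(cm, symmetric = TRUE)
    if (min(eg$values) >= lambda0) break
    low_order <- order(eg$values)
    gone <- character()
    for (k in low_order) {
      if (eg$values[k] >= lambda0) next
      loads <- abs(eg$vectors[, k])
      names(loads) <- keep
      loads <- loads[!names(loads) %in% gone]
      if (!length(loads)) next
      best <- loads[loads == max(loads)]
      gone <- c(gone, sort(names(best))[1])
    }
    keep <- setdiff(keep, gone)
  }
  keep
}
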