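# Independent brute-force enumerators for the texture matrices. These are
# deliberately naive (explicit loops over pixel pairs, run scans and flood
# fills) so they share no code with the package's vectorised engine.

brute_glcm <- function(grid, n_bins, offset) {
  nr <- nrow(grid); nc <- ncol(grid)
  counts <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- grid[r, c]; b <- grid[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

brute_glcm_features <- function(P) {
  n <- nrow(P)
  ent <- 0; con <- 0; ene <- 0; hom <- 0; mx <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      p <- P[i, j]
      if (p > 0) ent <- ent - p * log2(p)
      con <- con + p * (i - j)^2
      ene <- ene + p^2
      hom <- hom + p / (1 + abs(i - j))
      if (p > mx) mx <- p
    }
  }
  c(Entropy = ent, Contrast = con, Energy = ene, Homogeneity = hom,
    MaximumProbability = mx)
}

# Walk each maximal line of a direction, collecting (level, length) runs.
brute_runs <- function(grid, offset) {
  nr <- nrow(grid); nc <- ncol(grid)
  dr <- offset[1]; dc <- offset[2]
  starts <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      pr <- r - dr; pc <- c - dc
      inside <- pr >= 1 && pr <= nr && pc >= 1 && pc <= nc
      if (!inside) starts[[length(starts) + 1]] <- c(r, c)
    }
  }
  runs <- NULL
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur_lev <- NA; cur_len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- grid[r, c]
      if (!is.na(v) && !is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lev)) runs <- rbind(runs, c(cur_lev, cur_len))
        cur_lev <- v; cur_len <- if (is.na(v)) 0 else 1
      }
      r <- r + dr; c <- c + dc
    }
    if (!is.na(cur_lev)) runs <- rbind(runs, c(cur_lev, cur_len))
  }
  runs
}

brute_glrlm <- function(grid, n_bins, offset) {
  runs <- brute_runs(grid, offset)
  if (is.null(runs)) return(NULL)
  R <- matrix(0, n_bins, max(runs[, 2]))
  for (k in seq_len(nrow(runs))) {
    R[runs[k, 1], runs[k, 2]] <- R[runs[k, 1], runs[k, 2]] + 1
  }
  R
}

brute_rlm_features <- function(R, n_px) {
  n_runs <- sum(R)
  sre <- 0; lre <- 0; gln <- 0; rln <- 0
  for (i in seq_len(nrow(R))) {
    row_tot <- 0
    for (j in seq_len(ncol(R))) {
      sre <- sre + R[i, j] / j^2
      lre <- lre + R[i, j] * j^2
      row_tot <- row_tot + R[i, j]
    }
    gln <- gln + row_tot^2
  }
  for (j in seq_len(ncol(R))) {
    col_tot <- 0
    for (i in seq_len(nrow(R))) col_tot <- col_tot + R[i, j]
    rln <- rln + col_tot^2
  }
  c(ShortRunEmphasis = sre / n_runs, LongRunEmphasis = lre / n_runs,
    GrayLevelNonUniformity = gln / n_runs,
    RunLengthNonUniformity = rln / n_runs, RunPercentage = n_runs / n_px)
}

# 8-connected flood fill, one zone at a time.
brute_zones <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  seen <- matrix(FALSE, nr, nc)
  zones <- NULL
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (seen[r0, c0] || is.na(grid[r0, c0])) next
      lev <- grid[r0, c0]
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        size <- size + 1
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r <- p[1] + dr; c <- p[2] + dc
          if (r < 1 || r > nr || c < 1 || c > nc) next
          if (seen[r, c] || is.na(grid[r, c]) || grid[r, c] != lev) next
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
      zones <- rbind(zones, c(lev, size))
    }
  }
  zones
}

brute_glszm <- function(grid, n_bins) {
  z <- brute_zones(grid)
  S <- matrix(0, n_bins, max(z[, 2]))
  for (k in seq_len(nrow(z))) S[z[k, 1], z[k, 2]] <- S[z[k, 1], z[k, 2]] + 1
  S
}

brute_szm_features <- function(S, n_px) {
  n_z <- sum(S)
  sae <- 0; lae <- 0; zsn <- 0; zent <- 0
  for (i in seq_len(nrow(S))) {
    for (s in seq_len(ncol(S))) {
      sae <- sae + S[i, s] / s^2
      lae <- lae + S[i, s] * s^2
      p <- S[i, s] / n_z
      if (p > 0) zent <- zent - p * log2(p)
    }
  }
  for (s in seq_len(ncol(S))) {
    tot <- 0
    for (i in seq_len(nrow(S))) tot <- tot + S[i, s]
    zsn <- zsn + tot^2
  }
  c(SmallAreaEmphasis = sae / n_z, LargeAreaEmphasis = lae / n_z,
    SizeZoneNonUniformity = zsn / n_z, ZonePercentage = n_z / n_px,
    ZoneEntropy = zent)
}

# Random discretised ROI on a small grid: integer labels with a random
# irregular mask (at least `min_px` pixels).
random_disc_roi <- function(max_side = 8, n_bins = 4, min_px = 4) {
  nr <- sample(2:max_side, 1); nc <- sample(2:max_side, 1)
  repeat {
    mask <- matrix(runif(nr * nc) < 0.75, nr, nc)
    if (sum(mask) >= min_px) break
  }
  grid <- matrix(NA_integer_, nr, nc)
  grid[mask] <- sample.int(n_bins, sum(mask), replace = TRUE)
  structure(list(grid = grid, n_bins = n_bins,
                 bin_edges = seq(0, n_bins)), class = "disc_roi")
}

# Small single-study fixture with a ring mask, built in code.
make_test_study <- function(seed = 1, n = 48, noise = 1, iph = FALSE) {
  set.seed(seed)
  mask <- matrix(FALSE, n, n)
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  d2 <- (rr - n / 2)^2 + (cc - n / 2)^2
  outer <- d2 <= 100
  lumen <- d2 <= 25
  img_mat <- matrix(95, n, n) + noise * matrix(rnorm(n * n), n, n)
  muscle <- d2_from(rr, cc, 6, 6) <= 9
  gm <- d2_from(rr, cc, n - 6, n - 6) <= 16
  img_mat[muscle] <- 100 + rnorm(sum(muscle), 0, 0.5)
  if (iph) {
    px <- which(outer & !lumen)[1:5]
    img_mat[px] <- 200
  }
  img <- roi_image(img_mat, 0.3, 2)
  list(patient_id = "test01", label = "asymptomatic",
       images = list(T1 = img, T2 = img, CE_T1 = img),
       masks = list(lumen = lumen, outer_wall = outer,
                    plaque_roi = outer & !lumen, muscle_ref = muscle,
                    grey_matter_ref = gm))
}

d2_from <- function(rr, cc, r0, c0) (rr - r0)^2 + (cc - c0)^2

dim_pad <- function(m) {
  # run/zone matrices may differ in trailing all-zero columns
  if (is.null(m)) return(m)
  while (ncol(m) > 1 && all(m[, ncol(m)] == 0)) m <- m[, -ncol(m), drop = FALSE]
  unname(m)
}
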