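# Independent brute-force oracles used to check the package's operations.
# These deliberately use naive per-pixel / per-frame computations, not the
# vectorized implementations under test.

# Li-Lee cross entropy of a threshold, computed per pixel.
li_cross_entropy <- function(v, t) {
  below <- v[v <= t]; above <- v[v > t]
  term <- function(x) {
    s <- sum(x)
    if (s <= 0) 0 else s * log(mean(x))
  }
  -(term(below) + term(above))
}

# Exhaustive Li threshold over all 256 8-bit levels.
li_oracle <- function(crop) {
  v <- as.numeric(crop)
  eta <- vapply(0:255, function(t) li_cross_entropy(v, t), numeric(1L))
  (0:255)[which.min(eta)]
}

# Exhaustive Otsu threshold over all 255 candidate levels, per pixel.
otsu_oracle <- function(crop8) {
  v <- as.numeric(crop8)
  wvar <- vapply(0:254, function(t) {
    b <- v[v <= t]; f <- v[v > t]
    if (length(b) == 0L || length(f) == 0L) return(Inf)
    pvar <- function(x) mean((x - mean(x))^2)
    (length(b) * pvar(b) + length(f) * pvar(f)) / length(v)
  }, numeric(1L))
  (0:254)[which.min(wvar)]
}

# Stack-based per-pixel flood fill; returns components as lists of sorted
# linear indices.
flood_fill_oracle <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  comps <- list()
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    px <- integer()
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      px <- c(px, (p[2L] - 1L) * H + p[1L])
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        if (connectivity == 4L && abs(dr) + abs(dc) != 1L) next
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r < 1L || r > H || c < 1L || c > W) next
        if (mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(px)
  }
  comps
}

# Naive run-length scan for sub-cutoff episodes.
runs_oracle <- function(below) {
  out <- NULL
  i <- 1L
  n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1L]) j <- j + 1L
      out <- rbind(out, c(start = i, end = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Numerical minimization of RMSD over rotation space (Euler angles),
# independent of the closed-form superposition.
rotation_rmsd_oracle <- function(a, b, n_starts = 12L) {
  A <- sweep(a, 2L, colMeans(a))
  B <- sweep(b, 2L, colMeans(b))
  euler <- function(th) {
    cx <- cos(th[1L]); sx <- sin(th[1L])
    cy <- cos(th[2L]); sy <- sin(th[2L])
    cz <- cos(th[3L]); sz <- sin(th[3L])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
    Rz %*% Ry %*% Rx
  }
  obj <- function(th) sqrt(mean(rowSums((A - B %*% t(euler(th)))^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    th0 <- runif(3L, -pi, pi)
    fit <- optim(th0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

random_rigid_transform <- function() {
  th <- runif(3L, -pi, pi)
  cx <- cos(th[1L]); sx <- sin(th[1L])
  cy <- cos(th[2L]); sy <- sin(th[2L])
  cz <- cos(th[3L]); sz <- sin(th[3L])
  R <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L) %*%
       matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L) %*%
       matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  list(R = R, t = runif(3L, -10, 10))
}

# Match detected circles against planted GUVs; returns recall/precision at
# the given center and relative-radius tolerances.
match_detections <- function(det, truth, center_tol = 2, radius_tol = 0.1) {
  matched <- 0L
  used <- rep(FALSE, nrow(det))
  for (g in seq_len(nrow(truth))) {
    d <- sqrt((det$center_row - truth$center_row[g])^2 +
              (det$center_col - truth$center_col[g])^2)
    i <- which(!used & d <= center_tol &
               abs(det$radius - truth$radius[g]) <=
                 radius_tol * truth$radius[g])
    if (length(i) > 0L) { matched <- matched + 1L; used[i[1L]] <- TRUE }
  }
  list(recall = matched / nrow(truth),
       precision = if (nrow(det) > 0L) matched / nrow(det) else 0)
}

# Pooled scene-recovery measurement shared by unit and acceptance tests.
measure_scene_recovery <- function(seeds, params = pipeline_params(),
                                   two_channel = TRUE) {
  n_pos <- 0L; n_guv <- 0L; n_col <- 0L; n_max <- 0L
  t_pos <- 0L; t_col <- 0L; t_max <- 0L
  for (s in seeds) {
    sp <- if (two_channel)
      sample_scene_spec(s, channels = c("proteinA", "proteinB"))
    else sample_scene_spec(s)
    sc <- generate_guv_scene(sp)
    det <- detect_guvs(sc$image, r_min = 8, r_max = 18)
    q <- quantify_scene(sc$image, det, params = params)
    sa <- q$summary[q$summary$channel == "proteinA", ]
    n_pos <- n_pos + sa$n_positive; n_guv <- n_guv + sa$n_guvs
    t_pos <- t_pos + round(sc$truth$proportion_with_puncta[["proteinA"]] *
                           nrow(sc$truth$guvs))
    if (two_channel) {
      n_col <- n_col + sum(q$coloc$n_colocalized)
      n_max <- n_max + sum(q$coloc$n_max)
      t_col <- t_col + sum(sc$truth$colocalization$n_colocalized)
      t_max <- t_max + sum(sc$truth$colocalization$n_max)
    }
  }
  list(proportion = n_pos / n_guv, truth_proportion = t_pos / n_guv,
       coloc = if (n_max > 0) n_col / n_max else NA_real_,
       truth_coloc = if (t_max > 0) t_col / t_max else NA_real_)
}
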