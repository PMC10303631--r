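# Brute-force oracles for the texture families and first-order
# statistics: naive enumeration with explicit loops, written separately
# from the package kernels so that agreement is a meaningful check.

oracle_offsets <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
      out[[length(out) + 1]] <- c(dx, dy, dz)
    }
  }
  out
}

in_grid <- function(v, dm) {
  all(v >= 1) && all(v <= dm)
}

# ---- GLCM ------------------------------------------------------------------

oracle_glcm_matrix <- function(lev, off, ng) {
  dm <- dim(lev)
  C <- matrix(0, ng, ng)
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    a <- lev[x, y, z]
    if (a == 0) next
    for (s in c(1, -1)) { # count both directions: symmetric matrix
      v <- c(x, y, z) + s * off
      if (!in_grid(v, dm)) next
      b <- lev[v[1], v[2], v[3]]
      if (b == 0) next
      C[a, b] <- C[a, b] + 1
    }
  }
  C
}

oracle_glcm_features_from_P <- function(P, ng) {
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  vx <- 0; vy <- 0
  for (i in 1:ng) {
    vx <- vx + (i - mux)^2 * px[i]
    vy <- vy + (i - muy)^2 * py[i]
  }
  psum <- numeric(2 * ng); pdif <- numeric(ng) # index k+1 for pdif (k>=0)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  ent <- function(v) { s <- 0; for (p in v) if (p > 0) s <- s - p * log2(p); s }
  hx <- ent(px); hy <- ent(py); hxy <- ent(as.vector(P))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  da <- 0
  for (k in 0:(ng - 1)) da <- da + k * pdif[k + 1]
  feats <- c(
    Autocorrelation = 0, JointAverage = 0, ClusterProminence = 0,
    ClusterShade = 0, ClusterTendency = 0, Contrast = 0, Correlation = 0,
    DifferenceAverage = da, DifferenceEntropy = ent(pdif),
    DifferenceVariance = 0, JointEnergy = 0, JointEntropy = hxy,
    Imc1 = 0, Imc2 = 0, Idm = 0, Idmn = 0, Id = 0, Idn = 0,
    InverseVariance = 0, MaximumProbability = max(P), SumAverage = 0,
    SumEntropy = ent(psum), SumSquares = 0, MCC = 0)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    feats["Autocorrelation"] <- feats["Autocorrelation"] + i * j * p
    feats["JointAverage"] <- feats["JointAverage"] + i * p
    cdev <- i + j - mux - muy
    feats["ClusterProminence"] <- feats["ClusterProminence"] + cdev^4 * p
    feats["ClusterShade"] <- feats["ClusterShade"] + cdev^3 * p
    feats["ClusterTendency"] <- feats["ClusterTendency"] + cdev^2 * p
    feats["Contrast"] <- feats["Contrast"] + (i - j)^2 * p
    feats["JointEnergy"] <- feats["JointEnergy"] + p^2
    feats["Idm"] <- feats["Idm"] + p / (1 + (i - j)^2)
    feats["Idmn"] <- feats["Idmn"] + p / (1 + ((i - j) / ng)^2)
    feats["Id"] <- feats["Id"] + p / (1 + abs(i - j))
    feats["Idn"] <- feats["Idn"] + p / (1 + abs(i - j) / ng)
    if (i != j) {
      feats["InverseVariance"] <- feats["InverseVariance"] + p / (i - j)^2
    }
    feats["SumSquares"] <- feats["SumSquares"] + (i - mux)^2 * p
  }
  for (k in 0:(ng - 1)) {
    feats["DifferenceVariance"] <- feats["DifferenceVariance"] +
      (k - da)^2 * pdif[k + 1]
  }
  for (k in 2:(2 * ng)) {
    feats["SumAverage"] <- feats["SumAverage"] + k * psum[k]
  }
  feats["Correlation"] <- if (vx > 0 && vy > 0) {
    (feats[["Autocorrelation"]] - mux * muy) / sqrt(vx * vy)
  } else 1
  feats["Imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  feats["Imc2"] <- sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0))
  present <- which(px > 0)
  if (length(present) > 1) {
    np <- length(present)
    Q <- matrix(0, np, np)
    for (ii in seq_len(np)) for (jj in seq_len(np)) {
      for (kk in seq_len(np)) {
        Q[ii, jj] <- Q[ii, jj] +
          P[present[ii], present[kk]] * P[present[jj], present[kk]] /
          (px[present[ii]] * py[present[kk]])
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    feats["MCC"] <- sqrt(max(ev[2], 0))
  } else {
    feats["MCC"] <- 1
  }
  feats
}

oracle_glcm <- function(lev, ng, distance = 1) {
  acc <- NULL; ndir <- 0
  for (off in oracle_offsets()) {
    C <- oracle_glcm_matrix(lev, off * distance, ng)
    if (sum(C) == 0) next
    f <- oracle_glcm_features_from_P(C / sum(C), ng)
    acc <- if (is.null(acc)) f else acc + f
    ndir <- ndir + 1
  }
  if (ndir == 0) {
    h <- numeric(ng)
    for (v in lev[lev > 0]) h[v] <- h[v] + 1
    C <- diag(h, nrow = ng)
    acc <- oracle_glcm_features_from_P(C / sum(C), ng)
    ndir <- 1
  }
  acc / ndir
}

# ---- GLRLM -----------------------------------------------------------------

oracle_glrlm_matrix <- function(lev, off, ng) {
  dm <- dim(lev)
  runs <- list()
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    g <- lev[x, y, z]
    if (g == 0) next
    prev <- c(x, y, z) - off
    if (in_grid(prev, dm) && lev[prev[1], prev[2], prev[3]] == g) next
    len <- 1
    cur <- c(x, y, z) + off
    while (in_grid(cur, dm) && lev[cur[1], cur[2], cur[3]] == g) {
      len <- len + 1
      cur <- cur + off
    }
    runs[[length(runs) + 1]] <- c(g, len)
  }
  lmax <- max(dm)
  R <- matrix(0, ng, lmax)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

oracle_glrlm_features_from_R <- function(R, np) {
  ng <- nrow(R); lmax <- ncol(R)
  nr <- sum(R)
  f <- c(ShortRunEmphasis = 0, LongRunEmphasis = 0,
         GrayLevelNonUniformity = 0, GrayLevelNonUniformityNormalized = 0,
         RunLengthNonUniformity = 0, RunLengthNonUniformityNormalized = 0,
         RunPercentage = nr / np, GrayLevelVariance = 0, RunVariance = 0,
         RunEntropy = 0, LowGrayLevelRunEmphasis = 0,
         HighGrayLevelRunEmphasis = 0, ShortRunLowGrayLevelEmphasis = 0,
         ShortRunHighGrayLevelEmphasis = 0, LongRunLowGrayLevelEmphasis = 0,
         LongRunHighGrayLevelEmphasis = 0)
  mug <- 0; mur <- 0
  for (i in 1:ng) for (j in 1:lmax) {
    p <- R[i, j] / nr
    mug <- mug + i * p
    mur <- mur + j * p
    f["ShortRunEmphasis"] <- f["ShortRunEmphasis"] + p / j^2
    f["LongRunEmphasis"] <- f["LongRunEmphasis"] + p * j^2
    f["LowGrayLevelRunEmphasis"] <- f["LowGrayLevelRunEmphasis"] + p / i^2
    f["HighGrayLevelRunEmphasis"] <- f["HighGrayLevelRunEmphasis"] + p * i^2
    f["ShortRunLowGrayLevelEmphasis"] <-
      f["ShortRunLowGrayLevelEmphasis"] + p / (i^2 * j^2)
    f["ShortRunHighGrayLevelEmphasis"] <-
      f["ShortRunHighGrayLevelEmphasis"] + p * i^2 / j^2
    f["LongRunLowGrayLevelEmphasis"] <-
      f["LongRunLowGrayLevelEmphasis"] + p * j^2 / i^2
    f["LongRunHighGrayLevelEmphasis"] <-
      f["LongRunHighGrayLevelEmphasis"] + p * i^2 * j^2
    if (p > 0) f["RunEntropy"] <- f["RunEntropy"] - p * log2(p)
  }
  for (i in 1:ng) {
    si <- sum(R[i, ])
    f["GrayLevelNonUniformity"] <- f["GrayLevelNonUniformity"] + si^2 / nr
    f["GrayLevelNonUniformityNormalized"] <-
      f["GrayLevelNonUniformityNormalized"] + si^2 / nr^2
    f["GrayLevelVariance"] <- f["GrayLevelVariance"] +
      (i - mug)^2 * si / nr
  }
  for (j in 1:lmax) {
    sj <- sum(R[, j])
    f["RunLengthNonUniformity"] <- f["RunLengthNonUniformity"] + sj^2 / nr
    f["RunLengthNonUniformityNormalized"] <-
      f["RunLengthNonUniformityNormalized"] + sj^2 / nr^2
    f["RunVariance"] <- f["RunVariance"] + (j - mur)^2 * sj / nr
  }
  f
}

oracle_glrlm <- function(lev, ng) {
  np <- sum(lev > 0)
  acc <- NULL
  for (off in oracle_offsets()) {
    f <- oracle_glrlm_features_from_R(oracle_glrlm_matrix(lev, off, ng), np)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / 13
}

# ---- GLSZM -----------------------------------------------------------------

oracle_zones <- function(lev) {
  dm <- dim(lev)
  seen <- array(FALSE, dm)
  zones <- list()
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    g <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        w <- v + c(dx, dy, dz)
        if (!in_grid(w, dm)) next
        if (!seen[w[1], w[2], w[3]] && lev[w[1], w[2], w[3]] == g) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  zones
}

oracle_glszm <- function(lev, ng) {
  zones <- oracle_zones(lev)
  np <- sum(lev > 0)
  nz <- length(zones)
  g <- vapply(zones, `[`, numeric(1), 1)
  s <- vapply(zones, `[`, numeric(1), 2)
  f <- c(SmallAreaEmphasis = 0, LargeAreaEmphasis = 0,
         GrayLevelNonUniformity = 0, GrayLevelNonUniformityNormalized = 0,
         SizeZoneNonUniformity = 0, SizeZoneNonUniformityNormalized = 0,
         ZonePercentage = nz / np, GrayLevelVariance = 0, ZoneVariance = 0,
         ZoneEntropy = 0, LowGrayLevelZoneEmphasis = 0,
         HighGrayLevelZoneEmphasis = 0, SmallAreaLowGrayLevelEmphasis = 0,
         SmallAreaHighGrayLevelEmphasis = 0,
         LargeAreaLowGrayLevelEmphasis = 0,
         LargeAreaHighGrayLevelEmphasis = 0)
  for (k in seq_len(nz)) {
    p <- 1 / nz
    f["SmallAreaEmphasis"] <- f["SmallAreaEmphasis"] + p / s[k]^2
    f["LargeAreaEmphasis"] <- f["LargeAreaEmphasis"] + p * s[k]^2
    f["LowGrayLevelZoneEmphasis"] <-
      f["LowGrayLevelZoneEmphasis"] + p / g[k]^2
    f["HighGrayLevelZoneEmphasis"] <-
      f["HighGrayLevelZoneEmphasis"] + p * g[k]^2
    f["SmallAreaLowGrayLevelEmphasis"] <-
      f["SmallAreaLowGrayLevelEmphasis"] + p / (g[k]^2 * s[k]^2)
    f["SmallAreaHighGrayLevelEmphasis"] <-
      f["SmallAreaHighGrayLevelEmphasis"] + p * g[k]^2 / s[k]^2
    f["LargeAreaLowGrayLevelEmphasis"] <-
      f["LargeAreaLowGrayLevelEmphasis"] + p * s[k]^2 / g[k]^2
    f["LargeAreaHighGrayLevelEmphasis"] <-
      f["LargeAreaHighGrayLevelEmphasis"] + p * g[k]^2 * s[k]^2
  }
  mug <- 0; mus <- 0
  for (i in 1:ng) mug <- mug + i * sum(g == i) / nz
  for (sv in unique(s)) mus <- mus + sv * sum(s == sv) / nz
  for (i in 1:ng) {
    ni <- sum(g == i)
    f["GrayLevelNonUniformity"] <- f["GrayLevelNonUniformity"] + ni^2 / nz
    f["GrayLevelNonUniformityNormalized"] <-
      f["GrayLevelNonUniformityNormalized"] + ni^2 / nz^2
    f["GrayLevelVariance"] <- f["GrayLevelVariance"] + (i - mug)^2 * ni / nz
  }
  for (sv in unique(s)) {
    ns <- sum(s == sv)
    f["SizeZoneNonUniformity"] <- f["SizeZoneNonUniformity"] + ns^2 / nz
    f["SizeZoneNonUniformityNormalized"] <-
      f["SizeZoneNonUniformityNormalized"] + ns^2 / nz^2
    f["ZoneVariance"] <- f["ZoneVariance"] + (sv - mus)^2 * ns / nz
  }
  for (i in 1:ng) for (sv in unique(s)) {
    nc <- sum(g == i & s == sv)
    if (nc > 0) {
      p <- nc / nz
      f["ZoneEntropy"] <- f["ZoneEntropy"] - p * log2(p)
    }
  }
  f
}

# ---- NGTDM -----------------------------------------------------------------

oracle_ngtdm <- function(lev, ng) {
  dm <- dim(lev)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    g <- lev[x, y, z]
    if (g == 0) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      v <- c(x + dx, y + dy, z + dz)
      if (!in_grid(v, dm)) next
      h <- lev[v[1], v[2], v[3]]
      if (h > 0) nb <- c(nb, h)
    }
    if (length(nb) == 0) next
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  nvp <- sum(n_i)
  if (nvp == 0) {
    return(c(Coarseness = 1e6, Contrast = 0, Busyness = 0, Complexity = 0,
             Strength = 0))
  }
  p_i <- n_i / nvp
  ngp <- sum(p_i > 0)
  co_den <- 0; for (i in 1:ng) co_den <- co_den + p_i[i] * s_i[i]
  coars <- if (co_den > 0) min(1 / co_den, 1e6) else 1e6
  contr <- 0
  if (ngp > 1) {
    acc <- 0
    for (i in 1:ng) for (j in 1:ng) acc <- acc + p_i[i] * p_i[j] * (i - j)^2
    contr <- acc / (ngp * (ngp - 1)) * sum(s_i) / nvp
  }
  busy_den <- 0; compl <- 0; stren <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (p_i[i] > 0 && p_i[j] > 0) {
      busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
      compl <- compl + abs(i - j) *
        (p_i[i] * s_i[i] + p_i[j] * s_i[j]) / (p_i[i] + p_i[j])
      stren <- stren + (p_i[i] + p_i[j]) * (i - j)^2
    }
  }
  c(Coarseness = coars, Contrast = contr,
    Busyness = if (busy_den > 0) co_den / busy_den else 0,
    Complexity = compl / nvp,
    Strength = if (sum(s_i) > 0) stren / sum(s_i) else 0)
}

# ---- GLDM ------------------------------------------------------------------

oracle_gldm <- function(lev, ng, alpha = 0) {
  dm <- dim(lev)
  P <- matrix(0, ng, 27)
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    g <- lev[x, y, z]
    if (g == 0) next
    d <- 0
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      v <- c(x + dx, y + dy, z + dz)
      if (!in_grid(v, dm)) next
      h <- lev[v[1], v[2], v[3]]
      if (h > 0 && abs(h - g) <= alpha) d <- d + 1
    }
    P[g, d + 1] <- P[g, d + 1] + 1
  }
  nz <- sum(P)
  f <- c(SmallDependenceEmphasis = 0, LargeDependenceEmphasis = 0,
         GrayLevelNonUniformity = 0, DependenceNonUniformity = 0,
         DependenceNonUniformityNormalized = 0, GrayLevelVariance = 0,
         DependenceVariance = 0, DependenceEntropy = 0,
         LowGrayLevelEmphasis = 0, HighGrayLevelEmphasis = 0,
         SmallDependenceLowGrayLevelEmphasis = 0,
         SmallDependenceHighGrayLevelEmphasis = 0,
         LargeDependenceLowGrayLevelEmphasis = 0,
         LargeDependenceHighGrayLevelEmphasis = 0)
  mug <- 0; mud <- 0
  for (i in 1:ng) for (j in 1:27) {
    p <- P[i, j] / nz
    mug <- mug + i * p
    mud <- mud + j * p
    f["SmallDependenceEmphasis"] <- f["SmallDependenceEmphasis"] + p / j^2
    f["LargeDependenceEmphasis"] <- f["LargeDependenceEmphasis"] + p * j^2
    f["LowGrayLevelEmphasis"] <- f["LowGrayLevelEmphasis"] + p / i^2
    f["HighGrayLevelEmphasis"] <- f["HighGrayLevelEmphasis"] + p * i^2
    f["SmallDependenceLowGrayLevelEmphasis"] <-
      f["SmallDependenceLowGrayLevelEmphasis"] + p / (i^2 * j^2)
    f["SmallDependenceHighGrayLevelEmphasis"] <-
      f["SmallDependenceHighGrayLevelEmphasis"] + p * i^2 / j^2
    f["LargeDependenceLowGrayLevelEmphasis"] <-
      f["LargeDependenceLowGrayLevelEmphasis"] + p * j^2 / i^2
    f["LargeDependenceHighGrayLevelEmphasis"] <-
      f["LargeDependenceHighGrayLevelEmphasis"] + p * i^2 * j^2
    if (p > 0) {
      f["DependenceEntropy"] <- f["DependenceEntropy"] - p * log2(p)
    }
  }
  for (i in 1:ng) {
    si <- sum(P[i, ])
    f["GrayLevelNonUniformity"] <- f["GrayLevelNonUniformity"] + si^2 / nz
    f["GrayLevelVariance"] <- f["GrayLevelVariance"] + (i - mug)^2 * si / nz
  }
  for (j in 1:27) {
    sj <- sum(P[, j])
    f["DependenceNonUniformity"] <- f["DependenceNonUniformity"] + sj^2 / nz
    f["DependenceNonUniformityNormalized"] <-
      f["DependenceNonUniformityNormalized"] + sj^2 / nz^2
    f["DependenceVariance"] <- f["DependenceVariance"] +
      (j - mud)^2 * sj / nz
  }
  f
}

# ---- first order -----------------------------------------------------------

# percentile by explicit linear interpolation between order statistics
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(xs[n])
  xs[lo + 1] + (h - lo) * (xs[lo + 2] - xs[lo + 1])
}

oracle_firstorder <- function(x, lev_in, ng, spacing = c(1, 1, 1)) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  p10 <- oracle_percentile(x, 0.10)
  p90 <- oracle_percentile(x, 0.90)
  rx <- x[x >= p10 & x <= p90]
  h <- numeric(ng)
  for (v in lev_in) h[v] <- h[v] + 1
  p <- h / n
  ent <- 0; unif <- 0
  for (q in p) {
    if (q > 0) ent <- ent - q * log2(q)
    unif <- unif + q^2
  }
  c(Energy = sum(x^2), TotalEnergy = prod(spacing) * sum(x^2),
    Entropy = ent, Minimum = min(x), `10Percentile` = p10,
    `90Percentile` = p90, Maximum = max(x), Mean = mu,
    Median = oracle_percentile(x, 0.5),
    InterquartileRange = oracle_percentile(x, 0.75) -
      oracle_percentile(x, 0.25),
    Range = max(x) - min(x), MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(rx - mean(rx))) / length(rx),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2, Uniformity = unif)
}

# ---- fixture builders ------------------------------------------------------

# quantized VOI straight from a level array (0 = outside mask)
qvoi_from_levels <- function(lev, ng = max(lev)) {
  structure(list(levels = lev, ng = as.integer(ng),
                 mask = voi_mask(lev > 0), spacing = c(1, 1, 1)),
            class = "quantized_voi")
}

random_qvoi <- function(dim = c(5, 5, 3), ng = 4, p_mask = 0.85) {
  m <- array(stats::runif(prod(dim)) < p_mask, dim)
  if (!any(m)) m[1] <- TRUE
  lev <- array(0L, dim)
  lev[m] <- sample.int(ng, sum(m), replace = TRUE)
  qvoi_from_levels(lev, ng)
}

# package-vs-oracle comparison across all five texture families
compare_families <- function(qv, tol = 1e-10) {
  lev <- qv$levels
  ng <- qv$ng
  checks <- list(
    glcm = list(got = glcm_features(qv), want = oracle_glcm(lev, ng)),
    glrlm = list(got = glrlm_features(qv), want = oracle_glrlm(lev, ng)),
    glszm = list(got = glszm_features(qv), want = oracle_glszm(lev, ng)),
    ngtdm = list(got = ngtdm_features(qv), want = oracle_ngtdm(lev, ng)),
    gldm = list(got = gldm_features(qv), want = oracle_gldm(lev, ng)))
  errs <- vapply(names(checks), function(fam) {
    got <- unlist(checks[[fam]]$got)
    names(got) <- sub(paste0("^", fam, "/"), "", names(got))
    want <- checks[[fam]]$want
    max(abs(got[names(want)] - want))
  }, numeric(1))
  errs
}

# small deterministic ball mask for shape checks
ball_mask <- function(radius, spacing = c(1, 1, 1)) {
  n <- 2 * radius + 5
  cen <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  voi_mask(array((g$x - cen)^2 + (g$y - cen)^2 + (g$z - cen)^2 <= radius^2,
                 c(n, n, n)), spacing)
}
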