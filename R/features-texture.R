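glcm_feature_names <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC")

glrlm_feature_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage",
  "GrayLevelVariance", "RunVariance", "RunEntropy",
  "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
  "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
  "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")

glszm_feature_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage",
  "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
  "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
  "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")

ngtdm_feature_names <- c(
  "Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

gldm_feature_names <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

# crop the level grid to the mask bounding box (speed only)
qv_cropped <- function(qvoi) {
  list(levels = crop_to_bbox(qvoi$levels, qvoi$mask$data), ng = qvoi$ng)
}

xlog2 <- function(p) ifelse(p > 0, log2(p), 0) # 0*log(0) = 0 convention

# ---- GLCM ------------------------------------------------------------------

# per-Ng cache of index vectors and distance weights used by every
# co-occurrence matrix of the same size
glcm_cache_env <- new.env(parent = emptyenv())
glcm_cache <- function(ng) {
  key <- as.character(ng)
  cc <- glcm_cache_env[[key]]
  if (is.null(cc)) {
    iv <- rep(seq_len(ng), times = ng)
    jv <- rep(seq_len(ng), each = ng)
    d <- iv - jv
    cc <- list(
      iv = iv, jv = jv, ij = iv * jv, sum_group = iv + jv,
      dif_group = abs(d), w_contrast = d^2,
      w_idm = 1 / (1 + d^2), w_idmn = 1 / (1 + (d / ng)^2),
      w_id = 1 / (1 + abs(d)), w_idn = 1 / (1 + abs(d) / ng),
      w_invvar = ifelse(d == 0, 0, 1 / ifelse(d == 0, 1, d^2)),
      k_sum = 2:(2 * ng), k_dif = 0:(ng - 1))
    glcm_cache_env[[key]] <- cc
  }
  cc
}

ent2 <- function(p) { # -sum p log2 p over positive entries
  p <- p[p > 0]
  -sum(p * log2(p))
}

# all 24 features of one normalized symmetric co-occurrence matrix
glcm_features_from_matrix <- function(P, ng) {
  cc <- glcm_cache(ng)
  pvec <- as.vector(P)
  px <- .rowSums(P, ng, ng)
  py <- .colSums(P, ng, ng)
  lev <- seq_len(ng)
  mux <- sum(lev * px)
  muy <- sum(lev * py)
  sigx <- sqrt(sum((lev - mux)^2 * px))
  sigy <- sqrt(sum((lev - muy)^2 * py))
  # diagonal/antidiagonal marginals (all groups present in the grouping
  # vector, so rowsum returns the full k range in order)
  p_sum <- as.numeric(rowsum(pvec, cc$sum_group))
  p_dif <- as.numeric(rowsum(pvec, cc$dif_group))
  da <- sum(cc$k_dif * p_dif)

  hx <- ent2(px)
  hy <- ent2(py)
  hxy <- ent2(pvec)
  pxpy <- px[cc$iv] * py[cc$jv]
  pos <- pvec > 0
  hxy1 <- -sum(pvec[pos] * log2(pxpy[pos]))
  hxy2 <- ent2(pxpy)

  present <- which(px > 0)
  if (length(present) > 1) {
    # Q = Dx^-1 P Dy^-1 P' is similar to S S' with S = Dx^-1/2 P Dy^-1/2,
    # so its eigenvalues come from a symmetric PSD problem
    S <- P[present, present, drop = FALSE] /
      sqrt(outer(px[present], py[present]))
    ev <- eigen(tcrossprod(S), symmetric = TRUE,
                only.values = TRUE)$values
    mcc <- sqrt(max(ev[2], 0))
  } else {
    mcc <- 1
  }

  cs <- cc$sum_group - mux - muy
  c(Autocorrelation = sum(cc$ij * pvec),
    JointAverage = sum(cc$iv * pvec),
    ClusterProminence = sum(cs^4 * pvec),
    ClusterShade = sum(cs^3 * pvec),
    ClusterTendency = sum(cs^2 * pvec),
    Contrast = sum(cc$w_contrast * pvec),
    Correlation = if (sigx * sigy > 0)
      (sum(cc$ij * pvec) - mux * muy) / (sigx * sigy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = ent2(p_dif),
    DifferenceVariance = sum((cc$k_dif - da)^2 * p_dif),
    JointEnergy = sum(pvec^2),
    JointEntropy = hxy,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)),
    Idm = sum(cc$w_idm * pvec),
    Idmn = sum(cc$w_idmn * pvec),
    Id = sum(cc$w_id * pvec),
    Idn = sum(cc$w_idn * pvec),
    InverseVariance = sum(cc$w_invvar * pvec),
    MaximumProbability = max(pvec),
    SumAverage = sum(cc$k_sum * p_sum),
    SumEntropy = ent2(p_sum),
    SumSquares = sum((cc$iv - mux)^2 * pvec),
    MCC = mcc)
}

#' Gray-level co-occurrence matrix (GLCM) features
#'
#' Symmetric co-occurrence matrices are accumulated over the 13 unique 3D
#' direction offsets at the given voxel distance, each normalized, and
#' the 24 features averaged over directions with at least one voxel pair.
#' If no direction holds a pair (e.g. a single-voxel VOI), the matrix
#' degenerates to self co-occurrence of the level histogram, which yields
#' the documented degenerate values (Contrast 0, JointEnergy 1,
#' Correlation 1).
#'
#' @param qvoi A [discretize()]d VOI.
#' @param distance Voxel distance of the offsets (default 1).
#' @return A 1-row tibble with 24 columns named `glcm/<name>`.
#' @export
glcm_features <- function(qvoi, distance = 1) {
  if (distance < 1) {
    stop_dynomics("`distance` must be >= 1", class = "dynomics_type_error")
  }
  qc <- qv_cropped(qvoi)
  ng <- qc$ng
  counts <- cpp_glcm(as.integer(qc$levels), dim(qc$levels), ng,
                     as.integer(distance))
  counts <- array(counts, c(ng, ng, 13))
  acc <- NULL
  ndir <- 0
  for (d in 1:13) {
    C <- matrix(counts[, , d], ng, ng)
    C <- C + t(C) # symmetrize
    tot <- sum(C)
    if (tot == 0) next
    f <- glcm_features_from_matrix(C / tot, ng)
    acc <- if (is.null(acc)) f else acc + f
    ndir <- ndir + 1
  }
  if (ndir == 0) {
    # no neighboring pairs: self co-occurrence of the level histogram
    h <- tabulate(qc$levels[qc$levels > 0], nbins = ng)
    C <- diag(h, nrow = ng)
    acc <- glcm_features_from_matrix(C / sum(C), ng)
    ndir <- 1
  }
  as_feature_row(acc / ndir, "glcm")
}

# ---- GLRLM -----------------------------------------------------------------

glrlm_features_from_matrix <- function(R, np) {
  ng <- nrow(R)
  lmax <- ncol(R)
  nr <- sum(R)
  sg <- rowSums(R)
  sr <- colSums(R)
  i <- seq_len(ng)
  j <- seq_len(lmax)
  p <- R / nr
  pg <- sg / nr
  pr <- sr / nr
  mug <- sum(i * pg)
  mur <- sum(j * pr)
  jm <- matrix(j, ng, lmax, byrow = TRUE)
  im <- matrix(i, ng, lmax)
  c(ShortRunEmphasis = sum(pr / j^2),
    LongRunEmphasis = sum(pr * j^2),
    GrayLevelNonUniformity = sum(sg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(sg^2) / nr^2,
    RunLengthNonUniformity = sum(sr^2) / nr,
    RunLengthNonUniformityNormalized = sum(sr^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(pg * (i - mug)^2),
    RunVariance = sum(pr * (j - mur)^2),
    RunEntropy = -sum(p * xlog2(p)),
    LowGrayLevelRunEmphasis = sum(pg / i^2),
    HighGrayLevelRunEmphasis = sum(pg * i^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (im^2 * jm^2)),
    ShortRunHighGrayLevelEmphasis = sum(p * im^2 / jm^2),
    LongRunLowGrayLevelEmphasis = sum(p * jm^2 / im^2),
    LongRunHighGrayLevelEmphasis = sum(p * im^2 * jm^2))
}

#' Gray-level run-length matrix (GLRLM) features
#'
#' Run-length matrices are built along each of the 13 unique 3D
#' directions; the 16 features are averaged over directions.
#'
#' @param qvoi A [discretize()]d VOI.
#' @return A 1-row tibble with 16 columns named `glrlm/<name>`.
#' @export
glrlm_features <- function(qvoi) {
  qc <- qv_cropped(qvoi)
  ng <- qc$ng
  np <- sum(qc$levels > 0)
  lmax <- max(dim(qc$levels))
  counts <- cpp_glrlm(as.integer(qc$levels), dim(qc$levels), ng)
  counts <- array(counts, c(ng, lmax, 13))
  acc <- NULL
  for (d in 1:13) {
    f <- glrlm_features_from_matrix(matrix(counts[, , d], ng, lmax), np)
    acc <- if (is.null(acc)) f else acc + f
  }
  as_feature_row(acc / 13, "glrlm")
}

# ---- GLSZM -----------------------------------------------------------------

#' Gray-level size-zone matrix (GLSZM) features
#'
#' A zone is a 26-connected set of voxels sharing the same gray level;
#' one merged zone matrix `P(g, s)` is built for the whole VOI.
#'
#' @param qvoi A [discretize()]d VOI.
#' @return A 1-row tibble with 16 columns named `glszm/<name>`.
#' @export
glszm_features <- function(qvoi) {
  qc <- qv_cropped(qvoi)
  zones <- cpp_glszm(as.integer(qc$levels), dim(qc$levels), qc$ng)
  g <- zones[, 1]
  s <- zones[, 2]
  np <- sum(qc$levels > 0)
  nz <- length(g)
  p <- rep(1 / nz, nz) # each zone contributes one matrix count
  # marginals over gray level and size
  sg <- tapply(rep(1, nz), factor(g, levels = seq_len(qc$ng)), sum,
               default = 0)
  ss <- tapply(rep(1, nz), factor(s, levels = sort(unique(s))), sum,
               default = 0)
  svals <- sort(unique(s))
  pg <- as.numeric(sg) / nz
  ps <- as.numeric(ss) / nz
  ivals <- seq_len(qc$ng)
  mug <- sum(ivals * pg)
  mus <- sum(svals * ps)
  # matrix-cell probabilities (for entropy and joint emphases, collapse
  # duplicate (g, s) cells)
  cell <- tapply(rep(1, nz), interaction(g, s, drop = TRUE), sum)
  pcell <- as.numeric(cell) / nz
  vals <- c(
    SmallAreaEmphasis = sum(p / s^2),
    LargeAreaEmphasis = sum(p * s^2),
    GrayLevelNonUniformity = sum(as.numeric(sg)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(as.numeric(sg)^2) / nz^2,
    SizeZoneNonUniformity = sum(as.numeric(ss)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(as.numeric(ss)^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(pg * (ivals - mug)^2),
    ZoneVariance = sum(ps * (svals - mus)^2),
    ZoneEntropy = -sum(pcell * xlog2(pcell)),
    LowGrayLevelZoneEmphasis = sum(p / g^2),
    HighGrayLevelZoneEmphasis = sum(p * g^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (g^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = sum(p * g^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = sum(p * s^2 / g^2),
    LargeAreaHighGrayLevelEmphasis = sum(p * g^2 * s^2))
  as_feature_row(vals, "glszm")
}

# ---- NGTDM -----------------------------------------------------------------

#' Neighborhood gray-tone difference matrix (NGTDM) features
#'
#' For each gray level `i`, `s_i` sums the absolute difference between
#' the level and the mean level of each voxel's in-mask 26-neighborhood;
#' voxels without in-mask neighbors are excluded. Degenerate-case
#' conventions: Contrast 0 when a single level is present, Busyness and
#' Strength 0 and Coarseness 1e6 when their denominators vanish.
#'
#' @param qvoi A [discretize()]d VOI.
#' @return A 1-row tibble with 5 columns named `ngtdm/<name>`.
#' @export
ngtdm_features <- function(qvoi) {
  qc <- qv_cropped(qvoi)
  m <- cpp_ngtdm(as.integer(qc$levels), dim(qc$levels), qc$ng)
  n_i <- m[, 1]
  s_i <- m[, 2]
  nvp <- sum(n_i)
  if (nvp == 0) {
    vals <- c(Coarseness = 1e6, Contrast = 0, Busyness = 0, Complexity = 0,
              Strength = 0)
    return(as_feature_row(vals, "ngtdm"))
  }
  p_i <- n_i / nvp
  ivals <- seq_len(qc$ng)
  ngp <- sum(p_i > 0)
  act <- which(p_i > 0)

  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  coarseness <- min(coarseness, 1e6)

  contrast <- if (ngp > 1) {
    (sum(outer(p_i, p_i) * outer(ivals, ivals, "-")^2) /
       (ngp * (ngp - 1))) * (sum(s_i) / nvp)
  } else 0

  busy_den <- sum(abs(outer(ivals[act] * p_i[act], ivals[act] * p_i[act],
                            "-")))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0

  complexity <- if (length(act) > 0) {
    pi_a <- p_i[act]; si_a <- s_i[act]; iv <- ivals[act]
    sum(abs(outer(iv, iv, "-")) *
          (outer(pi_a * si_a, pi_a * si_a, "+")) /
          outer(pi_a, pi_a, "+")) / nvp
  } else 0

  strength <- if (sum(s_i) > 0) {
    pi_a <- p_i[act]; iv <- ivals[act]
    sum(outer(pi_a, pi_a, "+") * outer(iv, iv, "-")^2) / sum(s_i)
  } else 0

  vals <- c(Coarseness = coarseness, Contrast = contrast,
            Busyness = busyness, Complexity = complexity,
            Strength = strength)
  as_feature_row(vals, "ngtdm")
}

# ---- GLDM ------------------------------------------------------------------

#' Gray-level dependence matrix (GLDM) features
#'
#' A 26-neighbor is dependent on the center voxel when their levels
#' differ by at most `alpha`. The dependence size of a voxel is the
#' dependent-neighbor count plus one (the center), so isolated voxels
#' occupy the smallest dependence column and the matrix has no empty
#' zeroth column.
#'
#' @param qvoi A [discretize()]d VOI.
#' @param alpha Dependence threshold on level difference (default 0).
#' @return A 1-row tibble with 14 columns named `gldm/<name>`.
#' @export
gldm_features <- function(qvoi, alpha = 0) {
  if (alpha < 0) {
    stop_dynomics("`alpha` must be >= 0", class = "dynomics_type_error")
  }
  qc <- qv_cropped(qvoi)
  P <- cpp_gldm(as.integer(qc$levels), dim(qc$levels), qc$ng,
                as.integer(alpha))
  # dependence size = neighbor count + 1 -> columns 1..27
  ng <- qc$ng
  nd <- ncol(P)
  nz <- sum(P)
  i <- seq_len(ng)
  j <- seq_len(nd) # dependence sizes
  p <- P / nz
  sg <- rowSums(P)
  sd_ <- colSums(P)
  pg <- sg / nz
  pd <- sd_ / nz
  mug <- sum(i * pg)
  mud <- sum(j * pd)
  im <- matrix(i, ng, nd)
  jm <- matrix(j, ng, nd, byrow = TRUE)
  vals <- c(
    SmallDependenceEmphasis = sum(pd / j^2),
    LargeDependenceEmphasis = sum(pd * j^2),
    GrayLevelNonUniformity = sum(sg^2) / nz,
    DependenceNonUniformity = sum(sd_^2) / nz,
    DependenceNonUniformityNormalized = sum(sd_^2) / nz^2,
    GrayLevelVariance = sum(pg * (i - mug)^2),
    DependenceVariance = sum(pd * (j - mud)^2),
    DependenceEntropy = -sum(p * xlog2(p)),
    LowGrayLevelEmphasis = sum(pg / i^2),
    HighGrayLevelEmphasis = sum(pg * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (im^2 * jm^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * im^2 / jm^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * jm^2 / im^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * im^2 * jm^2))
  as_feature_row(vals, "gldm")
}
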