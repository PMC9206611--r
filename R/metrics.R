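#' Overlap metrics: Dice and Jaccard
#'
#' Dice(A,B) = 2|A int B| / (|A| + |B|); Jac(A,B) = |A int B| / |A un B|.
#' When both maps are empty the metrics are defined as 1 (a diagnostic message
#' is emitted); empty-vs-nonempty gives 0.
#'
#' @param a,b binary arrays of identical shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  check_labels(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) { message("dice: both label maps empty; returning 1"); return(1) }
  2 * sum(a * b) / (sa + sb)
}

#' @rdname dice
#' @export
jaccard <- function(a, b) {
  check_labels(a, b)
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) { message("jaccard: both label maps empty; returning 1"); return(1) }
  inter / uni
}

check_labels <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("label maps must have identical shape")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) stop("label maps must be binary")
}

# shift a 3D array by one voxel along an axis; vacated entries become 0
# (out-of-grid neighbours count as background, so the grid edge is surface)
shift3 <- function(m, ax, by) {
  d <- dim(m)
  out <- array(0, d)
  n <- d[ax]
  src <- if (by == 1) 2:n else 1:(n - 1)
  dst <- if (by == 1) 1:(n - 1) else 2:n
  if (ax == 1) out[dst, , ] <- m[src, , ]
  else if (ax == 2) out[, dst, ] <- m[, src, ]
  else out[, , dst] <- m[, , src]
  out
}

# boundary voxels by 6-connectivity erosion difference
boundary_voxels <- function(a) {
  er <- a > 0
  for (ax in 1:3) for (by in c(-1, 1)) er <- er & (shift3(a, ax, by) > 0)
  which(a > 0 & !er, arr.ind = TRUE)
}

#' Average symmetric surface distance (mm)
#'
#' Surfaces are the boundary voxels (6-connectivity erosion difference) at
#' their physical coordinates; the ASSD is the mean of the two directed mean
#' nearest-surface distances.
#'
#' @param a,b binary arrays of identical shape (both non-empty).
#' @param spacing voxel spacing in mm.
#' @return scalar distance in mm.
#' @export
assd <- function(a, b, spacing = c(1, 1, 1)) {
  check_labels(a, b)
  if (sum(a) == 0 || sum(b) == 0) stop("assd: label map is empty")
  spacing <- rep_len(as.numeric(spacing), 3L)
  pa <- sweep(boundary_voxels(a), 2, spacing, "*")
  pb <- sweep(boundary_voxels(b), 2, spacing, "*")
  (mean(nn_dist(pa, pb)) + mean(nn_dist(pb, pa))) / 2
}

# chunked brute-force nearest-neighbour distances from rows of A to rows of B
nn_dist <- function(A, B, chunk = 512L) {
  nb <- nrow(B)
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ak <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ak^2), rep(1, nb)) - 2 * Ak %*% t(B) +
      outer(rep(1, e - s + 1L), b2)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Structural similarity index for 3D volumes
#'
#' Mean local SSIM with a 3D Gaussian window (sigma = 1.5 voxels), constants
#' K1 = 0.01 and K2 = 0.03, and data range taken from the reference volume
#' \code{ref} (max - min) unless supplied.
#'
#' @param ref reference (ground-truth) volume: 3D array or \code{prost_volume}.
#' @param x volume under test, same shape.
#' @param sigma Gaussian window sigma in voxels.
#' @param K1,K2 stability constants.
#' @param data_range optional fixed dynamic range.
#' @return scalar in [-1, 1] (1 for identical volumes).
#' @export
ssim <- function(ref, x, sigma = 1.5, K1 = 0.01, K2 = 0.03, data_range = NULL) {
  ref <- if (inherits(ref, "prost_volume")) ref$data else ref
  x <- if (inherits(x, "prost_volume")) x$data else x
  if (!identical(dim(ref), dim(x))) stop("volumes must have identical shape")
  if (is.null(data_range)) {
    data_range <- max(ref) - min(ref)
    if (data_range <= 0) stop("constant reference volume: data range is zero")
  }
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  mu1 <- gaussian_smooth3d(ref, sigma); mu2 <- gaussian_smooth3d(x, sigma)
  s11 <- gaussian_smooth3d(ref * ref, sigma) - mu1^2
  s22 <- gaussian_smooth3d(x * x, sigma) - mu2^2
  s12 <- gaussian_smooth3d(ref * x, sigma) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Evaluate a registration result against its case ground truth
#'
#' Computes Dice, Jaccard, ASSD (mm) and SSIM between the warped atlas
#' (labels/volume) and the target (labels/volume), together with the case's
#' projection angles.
#'
#' @param result a \code{registration_result} from \code{\link{register_case}}
#'   (or any list with \code{warped_volume} and \code{warped_labels}).
#' @param case the \code{registration_case} it was computed from.
#' @return one-row data.frame (a \code{MetricsRecord}).
#' @export
evaluate_case <- function(result, case) {
  wl <- result$warped_labels
  wv <- if (inherits(result$warped_volume, "prost_volume"))
    result$warped_volume$data else result$warped_volume
  tl <- case$target$labels
  d <- dice(wl, tl); j <- jaccard(wl, tl)
  data.frame(case_id = case$seed,
             theta_ap = case$geom_ap$lao_rao_deg,
             theta_lat = case$geom_lat$lao_rao_deg,
             dice = d, jaccard = j,
             assd_mm = assd(wl, tl, case$spec$spacing),
             ssim = ssim(case$target$data, wv))
}

#' Sensitivity of registration accuracy to projection-angle error
#'
#' Re-registers each case with both input geometries offset by Delta-theta and
#' tabulates the mean metrics per offset, emulating an uncertainty on the
#' calibrated LAO/RAO angle.
#'
#' @param model a trained \code{prost_model}.
#' @param cases list of \code{registration_case}.
#' @param delta_deg numeric vector of angle offsets (degrees).
#' @return data.frame: one row per offset with mean dice/jaccard/assd/ssim.
#' @export
angle_sensitivity_sweep <- function(model, cases, delta_deg = seq(-10, 10, by = 5)) {
  rows <- lapply(delta_deg, function(dd) {
    met <- lapply(cases, function(case) {
      pc <- perturb_case_geometry(case, dd)
      evaluate_case(register_case(model, pc), case)
    })
    met <- do.call(rbind, met)
    data.frame(delta_deg = dd, dice = mean(met$dice), jaccard = mean(met$jaccard),
               assd_mm = mean(met$assd_mm), ssim = mean(met$ssim))
  })
  do.call(rbind, rows)
}

perturb_case_geometry <- function(case, delta_deg) {
  bump <- function(g) {
    g$lao_rao_deg <- ((g$lao_rao_deg + delta_deg + 180) %% 360) - 180
    g
  }
  case$geom_ap <- bump(case$geom_ap)
  case$geom_lat <- bump(case$geom_lat)
  case
}

#' Median Dice over a grid of biplanar angle combinations
#'
#' Bins evaluated cases by their (theta_AP, theta_LAT) pair and reports the
#' median Dice per bin, as in generalised-geometry evaluations.
#'
#' @param model trained \code{prost_model}.
#' @param cases list of \code{registration_case} (generalised mode).
#' @param bin_deg bin width in degrees (default 4).
#' @return list with \code{dice} (matrix, NA for empty bins) and the bin
#'   breaks for both axes.
#' @export
biplane_angle_grid <- function(model, cases, bin_deg = 4) {
  res <- vapply(cases, function(case)
    evaluate_case(register_case(model, case), case)$dice, numeric(1))
  th_ap <- vapply(cases, function(cs) cs$geom_ap$lao_rao_deg, numeric(1))
  th_lat <- vapply(cases, function(cs) cs$geom_lat$lao_rao_deg, numeric(1))
  br_ap <- seq(floor(min(th_ap)), ceiling(max(th_ap)) + bin_deg, by = bin_deg)
  br_lat <- seq(floor(min(th_lat)), ceiling(max(th_lat)) + bin_deg, by = bin_deg)
  ia <- cut(th_ap, br_ap, include.lowest = TRUE)
  il <- cut(th_lat, br_lat, include.lowest = TRUE)
  m <- matrix(NA_real_, nlevels(ia), nlevels(il),
              dimnames = list(levels(ia), levels(il)))
  for (lv in split(seq_along(res), list(ia, il), drop = TRUE)) {
    m[ia[lv[1]], il[lv[1]]] <- stats::median(res[lv])
  }
  list(dice = m, breaks_ap = br_ap, breaks_lat = br_lat)
}

#' Write a metrics table as CSV
#'
#' One row per case with stable column order
#' (case_id, theta_ap, theta_lat, dice, jaccard, assd_mm, ssim).
#'
#' @param metrics data.frame from \code{\link{evaluate_case}} rows.
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(metrics, path) {
  cols <- c("case_id", "theta_ap", "theta_lat", "dice", "jaccard", "assd_mm", "ssim")
  utils::write.csv(metrics[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Paired t-test between two metrics tables
#'
#' Plumbing utility: paired two-sided t-test on a shared metric column of two
#' per-case metrics tables (matched by case_id).
#'
#' @param m1,m2 metrics data.frames.
#' @param metric column name (default "dice").
#' @return the \code{htest} object from \code{\link[stats]{t.test}}.
#' @export
paired_metric_ttest <- function(m1, m2, metric = "dice") {
  j <- merge(m1, m2, by = "case_id", suffixes = c("_1", "_2"))
  stats::t.test(j[[paste0(metric, "_1")]], j[[paste0(metric, "_2")]], paired = TRUE)
}
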