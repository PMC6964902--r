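# AR overlay of CBCT-frame structures onto the endoscopic image, sphere
# detection, target registration error (TRE) in millimeters, and the
# protocol statistics (summary, spatial error maps, one-way ANOVA with
# Tukey-Kramer post-hoc comparisons).
#
# TRE here is the 2D overlay error in the image re-expressed in object-plane
# millimeters through the known 2-mm sphere diameter:
#   TRE[mm] = TRE[px] * diameter[mm] / diameter[px],
# with diameter[px] taken from the detected REAL sphere (the physical sphere
# anchors the millimeter scale).  This is not the 3D fiducial-based TRE of
# the point-registration literature.

#' Overlay CBCT-frame spheres onto the endoscopic view
#'
#' Maps each sphere center through the fusion chain
#' `T_CP = T_PO^-1 (T_MO T_CM)` (see [patient_to_camera()]) into the camera
#' frame and projects it; the circle radius follows the projected diameter.
#' Structures that land behind the camera are dropped (their count is
#' reported in the `n_dropped` attribute).
#'
#' @param structures data.frame with columns `sphere_id, x, y, z` (mm, CBCT
#'   frame) and `diameter_mm` (default 2 if absent).
#' @param TPO,TMO,TCM The current patient pose (`O <- P`), tracked EM pose
#'   (`O <- M`) and hand-eye calibration (`M <- C`).
#' @param K A [camera_intrinsics()].
#' @param clip_to_image Drop circles whose center is outside the sensor.
#' @return data.frame `sphere_id, u, v, r_px, source = "overlay"`.
#' @export
overlay_structures <- function(structures, TPO, TMO, TCM, K,
                               clip_to_image = FALSE) {
  TCP <- patient_to_camera(TPO, TMO, TCM)      # P <- C
  T_cp <- invert_transform(TCP)                # C <- P
  ctr <- transform_points(T_cp, as.matrix(structures[, c("x", "y", "z")]))
  dia <- if ("diameter_mm" %in% names(structures)) structures$diameter_mm
         else rep(2, nrow(structures))
  keep <- which(ctr[, 3] > 0)
  out <- do.call(rbind, lapply(keep, function(i)
    project_sphere(K, ctr[i, ], dia[i] / 2)))
  if (is.null(out)) out <- matrix(numeric(0), 0, 3)
  res <- data.frame(sphere_id = structures$sphere_id[keep],
                    u = out[, 1], v = out[, 2], r_px = out[, 3],
                    source = "overlay", stringsAsFactors = FALSE)
  if (clip_to_image && nrow(res))
    res <- res[res$u >= 0 & res$u < K$width & res$v >= 0 & res$v < K$height, ,
               drop = FALSE]
  attr(res, "n_dropped") <- nrow(structures) - length(keep)
  res
}

#' Detect spheres in a rendered endoscopic image
#'
#' Intensity threshold, connected components, size/circularity filtering,
#' then sub-pixel center by intensity-weighted centroid.  The reported
#' radius is the anti-aliased area estimator `sqrt(sum(I)/pi)` over the
#' component (the boundary circle fit is used for the circularity gate,
#' where boundary-pixel quantization does not matter).
#'
#' @param image Grayscale matrix (height x width, values in [0, 1]).
#' @param threshold Binarization threshold.
#' @param min_area_px,max_area_px Component size gates.
#' @param min_circularity Minimum `4 pi A / P^2`-style roundness (computed
#'   from the boundary circle fit residual); blobs failing it are flagged
#'   ambiguous and excluded.
#' @return data.frame `sphere_id, u, v, r_px, source = "real"`; zero rows on
#'   a blank image.  Ambiguous (overlapping) blobs are counted in the
#'   `n_ambiguous` attribute.
#' @export
detect_spheres <- function(image, threshold = 0.5, min_area_px = 4,
                           max_area_px = Inf, min_circularity = 0.6) {
  stopifnot(is.matrix(image))
  bw <- image > threshold
  if (!any(bw)) {
    out <- data.frame(sphere_id = character(0), u = numeric(0), v = numeric(0),
                      r_px = numeric(0), source = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_ambiguous") <- 0L
    return(out)
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(bw), nrow = nrow(image)))
  nlab <- max(lab)
  rows <- list(); n_amb <- 0L
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area_px || nrow(idx) > max_area_px) next
    # 0-based pixel coordinates: u = col - 1, v = row - 1
    w <- image[idx]
    u <- sum((idx[, 2] - 1) * w) / sum(w)
    v <- sum((idx[, 1] - 1) * w) / sum(w)
    r_area <- sqrt(sum(w) / pi)
    # boundary pixels: component pixels with a 4-neighbor outside
    bset <- bset_boundary(lab, l, idx)
    circ <- circle_fit(bset[, 2] - 1, bset[, 1] - 1)
    roundness <- 1 - min(1, circ$rms / max(circ$r, 1))
    if (roundness < min_circularity) { n_amb <- n_amb + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      sphere_id = sprintf("D%03d", l), u = u, v = v, r_px = r_area,
      source = "real", stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sphere_id = character(0), u = numeric(0), v = numeric(0),
               r_px = numeric(0), source = character(0), stringsAsFactors = FALSE)
  attr(out, "n_ambiguous") <- n_amb
  out
}

bset_boundary <- function(lab, l, idx) {
  h <- nrow(lab); w <- ncol(lab)
  on_b <- apply(idx, 1L, function(p) {
    r <- p[1]; c_ <- p[2]
    r == 1L || r == h || c_ == 1L || c_ == w ||
      lab[r - 1L, c_] != l || lab[r + 1L, c_] != l ||
      lab[r, c_ - 1L] != l || lab[r, c_ + 1L] != l
  })
  idx[on_b, , drop = FALSE]
}

# Kasa algebraic circle fit; returns center, radius, RMS radial residual.
circle_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  s <- qr.solve(A, b)
  r <- sqrt(s[3] + s[1]^2 + s[2]^2)
  list(cx = s[1], cy = s[2], r = r,
       rms = sqrt(mean((sqrt((x - s[1])^2 + (y - s[2])^2) - r)^2)))
}

#' Pair real and overlaid circles
#'
#' Mutual-nearest-neighbor pairing with a maximum-distance gate; unpaired
#' circles on either side are returned separately.
#'
#' @param real,overlay data.frames with columns `u, v, r_px` (and
#'   `sphere_id`).
#' @param max_distance_px Gate (default 50 px).
#' @return List: `pairs` (data.frame with both centers, the real diameter
#'   and the pixel offset), `unpaired_real`, `unpaired_overlay`.
#' @export
match_circles <- function(real, overlay, max_distance_px = 50) {
  if (!nrow(real) || !nrow(overlay))
    return(list(pairs = data.frame(), unpaired_real = real,
                unpaired_overlay = overlay))
  D <- outer(real$u, overlay$u, "-")^2 + outer(real$v, overlay$v, "-")^2
  D <- sqrt(D)
  nn_r <- apply(D, 1L, which.min)   # nearest overlay for each real
  nn_o <- apply(D, 2L, which.min)   # nearest real for each overlay
  rows <- list()
  used_o <- logical(nrow(overlay))
  for (i in seq_len(nrow(real))) {
    j <- nn_r[i]
    if (nn_o[j] == i && D[i, j] <= max_distance_px) {
      used_o[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        real_id = real$sphere_id[i], overlay_id = overlay$sphere_id[j],
        u_real = real$u[i], v_real = real$v[i],
        u_ovl = overlay$u[j], v_ovl = overlay$v[j],
        diameter_px = 2 * real$r_px[i], offset_px = D[i, j],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else data.frame()
  paired_r <- if (nrow(pairs)) real$sphere_id %in% pairs$real_id else
    rep(FALSE, nrow(real))
  list(pairs = pairs,
       unpaired_real = real[!paired_r, , drop = FALSE],
       unpaired_overlay = overlay[!used_o, , drop = FALSE])
}

#' Pixel-to-millimeter TRE conversion
#'
#' `TRE[mm] = TRE[px] * diameter[mm] / diameter[px]`, with the pixel diameter
#' taken from the detected real sphere.
#'
#' @param offset_px Center distance real vs overlay (px).
#' @param diameter_px Detected diameter of the real sphere (px), > 0.
#' @param diameter_mm Physical sphere diameter (mm), default 2.
#' @export
compute_tre <- function(offset_px, diameter_px, diameter_mm = 2) {
  if (any(diameter_px <= 0)) stop("compute_tre: non-positive pixel diameter")
  offset_px * diameter_mm / diameter_px
}

#' Evaluate the accuracy protocol: per-frame overlay vs reality
#'
#' Runs the full navigation chain on every frame of a simulated protocol:
#' the patient pose `T_PO` is re-estimated from the grid border markers
#' against the CBCT-time virtual reference grid, the EM pose `T_MO` is
#' fitted from the EM disc observations, the CBCT-frame spheres are overlaid
#' through `T_CP = T_PO^-1 (T_MO T_CM)`, and each overlaid circle is paired
#' with the corresponding real circle.
#'
#' @param protocol A [run_accuracy_protocol()] bundle.
#' @param tcm The hand-eye transform to use (defaults to the bundle's ground
#'   truth; pass a calibrated estimate to evaluate the full pipeline).
#' @param intrinsics Intrinsics used by the overlay path (defaults to the
#'   bundle's true intrinsics; pass a mismatched model to study calibration
#'   residuals).
#' @param real_source `"ground_truth"` takes the real circles from the
#'   simulator's exact projections; `"detect"` runs [detect_spheres()] on
#'   rendered frames (requires `render = TRUE` bundles).
#' @param max_match_px Pairing gate passed to [match_circles()].
#' @return data.frame of TRE records: `sphere_id, distance_mm,
#'   position_index, u_real, v_real, u_ovl, v_ovl, diameter_px, tre_mm`.
#' @export
evaluate_accuracy <- function(protocol, tcm = protocol$tcm_true,
                              intrinsics = protocol$intrinsics,
                              real_source = c("ground_truth", "detect"),
                              max_match_px = 50) {
  stopifnot(inherits(protocol, "accuracy_protocol"))
  real_source <- match.arg(real_source)
  vrg <- build_vrg(protocol$reference$obs)   # CBCT frame := OTS frame at CBCT time
  structures <- protocol$phantom$spheres
  ctr <- transform_points(protocol$reference$pose,
                          as.matrix(structures[, c("x", "y", "z")]))
  structures[, c("x", "y", "z")] <- unclass(ctr)
  em <- protocol$em_disc
  recs <- list()
  for (fr in protocol$frames) {
    pp <- estimate_patient_pose(vrg, fr$grid_obs)
    if (pp$tracking_lost) next
    em_vis <- fr$em_obs[fr$em_obs$visible, , drop = FALSE]
    TMO <- register_point_sets(
      as.matrix(em[match(em_vis$marker_id, em$marker_id), c("x", "y", "z")]),
      as.matrix(em_vis[, c("x", "y", "z")]),
      source = "M", target = "O")$transform
    ovl <- overlay_structures(structures, pp$TPO, TMO, tcm, intrinsics)
    real <- if (real_source == "ground_truth") {
      data.frame(sphere_id = fr$ground_truth$sphere_id,
                 u = fr$ground_truth$u, v = fr$ground_truth$v,
                 r_px = fr$ground_truth$r_px, source = "real",
                 stringsAsFactors = FALSE)
    } else {
      if (is.null(fr$image))
        stop("evaluate_accuracy: real_source = 'detect' needs a rendered bundle")
      detect_spheres(fr$image)
    }
    m <- match_circles(real, ovl, max_distance_px = max_match_px)
    if (!nrow(m$pairs)) next
    recs[[length(recs) + 1L]] <- data.frame(
      sphere_id = m$pairs$real_id, distance_mm = fr$distance_mm,
      position_index = fr$position_index,
      u_real = m$pairs$u_real, v_real = m$pairs$v_real,
      u_ovl = m$pairs$u_ovl, v_ovl = m$pairs$v_ovl,
      diameter_px = m$pairs$diameter_px,
      tre_mm = compute_tre(m$pairs$offset_px, m$pairs$diameter_px),
      stringsAsFactors = FALSE)
  }
  if (!length(recs)) stop("evaluate_accuracy: no paired circles in any frame")
  do.call(rbind, recs)
}

#' Summarize TRE records
#'
#' Overall and per-distance statistics (mean, SD with the n-1 denominator,
#' median, quartiles by linear interpolation between order statistics, min,
#' max), a binned spatial error map over image coordinates, and the one-way
#' ANOVA with Tukey-Kramer post-hoc comparison across working distances.
#'
#' @param records TRE records from [evaluate_accuracy()].
#' @param K Intrinsics (for the image extent and the circular field mask).
#' @param heatmap_bins Bins per image axis (default 8).
#' @return Object of class `tre_summary`: `overall` and `per_distance`
#'   statistics, `heatmap` (list: `mean_mm`, `count`, `valid` - bins with
#'   centers outside the circular endoscopic field are invalid; valid empty
#'   bins hold NA, not zero), and `anova` (from [anova_tukey()], NULL with a
#'   single distance group).
#' @export
summarize_tre <- function(records, K, heatmap_bins = 8L) {
  if (!nrow(records)) stop("summarize_tre: no records")
  stats_of <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(x), mean = mean(x), sd = sd(x),
               median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x))
  }
  per <- do.call(rbind, lapply(split(records$tre_mm, records$distance_mm), stats_of))
  per <- cbind(distance_mm = as.numeric(rownames(per)), per)
  rownames(per) <- NULL
  heat <- tre_heatmap(records, K, bins = heatmap_bins)
  anova <- if (length(unique(records$distance_mm)) >= 2L &&
               all(table(records$distance_mm) >= 2L))
    anova_tukey(split(records$tre_mm, records$distance_mm)) else NULL
  structure(list(overall = stats_of(records$tre_mm), per_distance = per,
                 heatmap = heat, anova = anova),
            class = "tre_summary")
}

#' @export
print.tre_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("TRE overall: %.3f +/- %.3f mm, median %.3f mm, IQR %.3f-%.3f mm, max %.3f mm (n = %d)\n",
              o$mean, o$sd, o$median, o$q1, o$q3, o$max, o$n))
  cat("per working distance:\n")
  print(round(x$per_distance, 4))
  if (!is.null(x$anova))
    cat(sprintf("one-way ANOVA across distances: F = %.3f, p = %.3g\n",
                x$anova$F, x$anova$p))
  invisible(x)
}

#' Binned spatial TRE map
#'
#' Mean TRE per image bin (binned on the real-circle position).  Bins whose
#' center lies outside the inscribed circular endoscopic field are marked
#' invalid; valid but empty bins are NA.
#'
#' @param records TRE records.
#' @param K Intrinsics.
#' @param bins Bins per axis.
#' @return List `mean_mm` (bins x bins, row = v bin), `count`, `valid`,
#'   `u_breaks`, `v_breaks`.
#' @export
tre_heatmap <- function(records, K, bins = 8L) {
  ub <- seq(0, K$width, length.out = bins + 1L)
  vb <- seq(0, K$height, length.out = bins + 1L)
  iu <- pmin(pmax(findInterval(records$u_real, ub, rightmost.closed = TRUE), 1L), bins)
  iv <- pmin(pmax(findInterval(records$v_real, vb, rightmost.closed = TRUE), 1L), bins)
  mean_mm <- matrix(NA_real_, bins, bins)
  count <- matrix(0L, bins, bins)
  for (k in seq_len(nrow(records))) {
    count[iv[k], iu[k]] <- count[iv[k], iu[k]] + 1L
  }
  agg <- tapply(records$tre_mm, list(iv, iu), mean)
  mean_mm[cbind(as.integer(rep(rownames(agg), ncol(agg))),
                as.integer(rep(colnames(agg), each = nrow(agg))))] <- as.numeric(agg)
  uc <- (head(ub, -1) + tail(ub, -1)) / 2
  vc <- (head(vb, -1) + tail(vb, -1)) / 2
  rad <- min(K$width, K$height) / 2
  valid <- outer((vc - K$height / 2)^2, (uc - K$width / 2)^2, "+") <= rad^2
  list(mean_mm = mean_mm, count = count, valid = valid,
       u_breaks = ub, v_breaks = vb)
}

#' One-way ANOVA with Tukey-Kramer post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA across the groups, followed by Tukey's honest
#' significant differences; with unequal group sizes `TukeyHSD()` applies the
#' Tukey-Kramer correction via the studentized-range distribution.
#'
#' @param groups Named list (or split()) of numeric vectors, >= 2 groups of
#'   >= 2 values each.
#' @param conf_level Confidence level of the pairwise intervals.
#' @return List: `F`, `p`, `df`, and `pairwise` (data.frame `pair, mean_diff,
#'   lwr, upr, p_adj, significant`).
#' @export
anova_tukey <- function(groups, conf_level = 0.95) {
  if (length(groups) < 2L) stop("anova_tukey: need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("anova_tukey: every group needs at least 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, 1L))))
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  pv <- tab[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = conf_level)$group
  pw <- data.frame(pair = rownames(tk), mean_diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"],
                   significant = tk[, "p adj"] < 1 - conf_level,
                   row.names = NULL, stringsAsFactors = FALSE)
  list(F = Fv, p = pv,
       df = c(between = tab$Df[1], within = tab$Df[2]),
       pairwise = pw)
}

#' Plot helpers for a TRE summary
#'
#' `plot_tre_boxplots()` draws the per-distance boxplots;
#' `plot_tre_heatmap()` draws the binned spatial error map (invalid bins
#' blank).  Both draw on the active graphics device.
#'
#' @param records TRE records.
#' @param summary A [summarize_tre()] result.
#' @export
plot_tre_boxplots <- function(records) {
  graphics::boxplot(tre_mm ~ distance_mm, data = records,
                    xlab = "working distance (mm)", ylab = "TRE (mm)",
                    col = "grey85", main = "Overlay error vs working distance")
  invisible(NULL)
}

#' @rdname plot_tre_boxplots
#' @export
plot_tre_heatmap <- function(summary) {
  h <- summary$heatmap
  m <- h$mean_mm
  m[!h$valid] <- NA
  graphics::image(x = h$u_breaks, y = h$v_breaks,
                  z = t(m), ylim = rev(range(h$v_breaks)),
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  xlab = "u (px)", ylab = "v (px)",
                  main = "Mean TRE (mm) over the image")
  invisible(NULL)
}
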