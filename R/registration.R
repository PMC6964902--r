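# Rigid point-set registration (Kabsch / Procrustes with reflection guard),
# the virtual reference grid (VRG), and marker-based motion compensation.

# Least-squares rigid fit dst ~ R src + t.  Returns R, t, fre (RMS residual).
kabsch_fit <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # reflection guard
  t_ <- cd - as.numeric(R %*% cs)
  res <- sweep(src %*% t(R), 2, t_, "+") - dst
  list(R = R, t = t_, fre = sqrt(mean(rowSums(res^2))))
}

#' Rigid point-set registration
#'
#' Closed-form least-squares rigid fit of two point sets matched by id
#' (centroid subtraction, SVD of the cross-covariance with a determinant
#' correction guarding against reflections).  The fiducial registration error
#' (FRE) is the RMS residual after alignment.
#'
#' @param src,dst n x 3 matrices (mm).  Rows are matched by `ids` if given,
#'   else by row order.  At least 3 non-collinear common points are required.
#' @param ids Optional character vector of point ids (same ids in both sets
#'   are matched; either set may contain extra points).
#' @param dst_ids Ids for `dst` when they differ from `ids` in order/content.
#' @param source,target Frame labels of the returned transform.
#' @return List: `transform` (a `rigid_transform`, `target <- source`),
#'   `fre_mm`, `n_points`.
#' @export
register_point_sets <- function(src, dst, ids = NULL, dst_ids = ids,
                                source = "src", target = "dst") {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!is.null(ids)) {
    common <- intersect(ids, dst_ids)
    if (length(common) < 3L)
      stop("register_point_sets: fewer than 3 common point ids")
    src <- src[match(common, ids), , drop = FALSE]
    dst <- dst[match(common, dst_ids), , drop = FALSE]
  }
  if (nrow(src) != nrow(dst)) stop("register_point_sets: size mismatch")
  if (nrow(src) < 3L) stop("register_point_sets: at least 3 points required")
  # collinearity check: rank of the centered configuration
  sv <- svd(sweep(src, 2, colMeans(src)))$d
  if (sv[2] < arnav_tolerances()$collinear * max(sv[1], 1))
    stop("register_point_sets: degenerate (collinear) configuration")
  fit <- kabsch_fit(src, dst)
  list(transform = rigid_transform(fit$R, fit$t, source = source, target = target),
       fre_mm = fit$fre, n_points = nrow(src))
}

#' Marker observations of an optical tracking system
#'
#' One OTS frame: identified markers with 3D positions in the OTS/world frame
#' and visibility flags.
#'
#' @param marker_id Character labels.
#' @param positions n x 3 matrix (mm, OTS frame).
#' @param visible Logical vector (default all `TRUE`).
#' @return A data.frame with columns `marker_id, x, y, z, visible`.
#' @export
marker_observations <- function(marker_id, positions, visible = TRUE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, length(marker_id) == nrow(positions))
  visible <- rep_len(visible, nrow(positions))
  if (any(visible & !stats::complete.cases(positions)))
    stop("marker_observations: visible marker with non-finite position")
  data.frame(marker_id = as.character(marker_id),
             x = positions[, 1], y = positions[, 2], z = positions[, 3],
             visible = visible, stringsAsFactors = FALSE)
}

#' Build the virtual reference grid at CBCT time
#'
#' Stores the reference configuration of the patient-surface markers as seen
#' by the OTS at CBCT acquisition.  If the markers are hybrid
#' (optical + radiopaque) their CBCT-frame coordinates may be supplied, in
#' which case the OTS-to-CBCT co-registration is estimated by
#' [register_point_sets()]; otherwise the OTS frame at acquisition time *is*
#' the CBCT frame (the tracker is rigidly integrated with the C-arm).
#'
#' @param obs [marker_observations()] at CBCT time (>= 3 visible markers).
#' @param hybrid_cbct_positions Optional n x 3 matrix of the same markers in
#'   the CBCT frame, with rownames or `hybrid_ids` giving marker ids.
#' @param hybrid_ids Marker ids for `hybrid_cbct_positions`.
#' @return Object of class `virtual_reference_grid`: `reference` (data.frame
#'   of reference positions), `cbct_from_ots` (`P <- O` transform),
#'   `registration_fre_mm`.
#' @export
build_vrg <- function(obs, hybrid_cbct_positions = NULL, hybrid_ids = NULL) {
  vis <- obs[obs$visible, , drop = FALSE]
  if (nrow(vis) < 3L) stop("build_vrg: fewer than 3 visible markers")
  pos <- as.matrix(vis[, c("x", "y", "z")])
  sv <- svd(sweep(pos, 2, colMeans(pos)))$d
  if (sv[2] < arnav_tolerances()$collinear * max(sv[1], 1))
    stop("build_vrg: collinear reference markers")
  fre <- 0
  if (is.null(hybrid_cbct_positions)) {
    cbct_from_ots <- transform_identity("O", "P")
  } else {
    hp <- as.matrix(hybrid_cbct_positions)
    if (is.null(hybrid_ids)) hybrid_ids <- rownames(hp)
    if (is.null(hybrid_ids)) hybrid_ids <- vis$marker_id[seq_len(nrow(hp))]
    reg <- register_point_sets(pos, hp, ids = vis$marker_id, dst_ids = hybrid_ids,
                               source = "O", target = "P")
    cbct_from_ots <- reg$transform
    fre <- reg$fre_mm
  }
  structure(list(reference = vis, cbct_from_ots = cbct_from_ots,
                 registration_fre_mm = fre),
            class = "virtual_reference_grid")
}

#' Estimate the current patient pose from tracked markers
#'
#' Fits the rigid motion of the currently visible VRG markers relative to
#' their CBCT-time reference configuration and composes it with the stored
#' OTS-to-CBCT registration, yielding the patient pose `T_PO` (`O <- P`) that
#' motion-compensates the CBCT model.  The current FRE is reported as a
#' tracking-quality indicator.
#'
#' @param vrg A [build_vrg()] result.
#' @param obs Current [marker_observations()].
#' @return List: `TPO` (`O <- P`), `fre_mm`, `n_markers`, `tracking_lost`
#'   (TRUE with `TPO = NULL` when fewer than 3 shared markers are visible).
#' @export
estimate_patient_pose <- function(vrg, obs) {
  stopifnot(inherits(vrg, "virtual_reference_grid"))
  vis <- obs[obs$visible, , drop = FALSE]
  common <- intersect(vrg$reference$marker_id, vis$marker_id)
  if (length(common) < 3L)
    return(list(TPO = NULL, fre_mm = NA_real_, n_markers = length(common),
                tracking_lost = TRUE))
  ref <- as.matrix(vrg$reference[match(common, vrg$reference$marker_id),
                                 c("x", "y", "z")])
  cur <- as.matrix(vis[match(common, vis$marker_id), c("x", "y", "z")])
  reg <- register_point_sets(ref, cur, source = "Oref", target = "O")
  # patient point p_P -> reference OTS coords (inverse co-registration)
  # -> current OTS coords (fitted motion)
  TPO <- compose_transforms(
    rigid_transform(reg$transform$rotation, reg$transform$translation,
                    source = "P0", target = "O"),
    rigid_transform(t(vrg$cbct_from_ots$rotation),
                    as.numeric(-t(vrg$cbct_from_ots$rotation) %*%
                                 vrg$cbct_from_ots$translation),
                    source = "P", target = "P0"))
  list(TPO = TPO, fre_mm = reg$fre_mm, n_markers = length(common),
       tracking_lost = FALSE)
}
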