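#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R (det +1; reflections excluded to preserve
#' chirality) and translation minimizing the RMSD between the mobile frame's
#' fit particles and the reference coordinates.
#'
#' @param mobile an sk_frame, or an N x 3 coordinate matrix
#' @param ref an sk_alignment_ref (see [alignment_reference()]), or an
#'   N x 3 reference coordinate matrix when `fit` is given
#' @param fit optional index vector of fit particles (when `ref` is a bare
#'   matrix of the fit coordinates, `fit` indexes the mobile coordinates)
#' @return list(R, t, rmsd): the transform x' = x %*% t(R) + t and the fit
#'   RMSD in nm after superposition
#' @export
kabsch_superpose <- function(mobile, ref, fit = NULL) {
  mob_all <- if (inherits(mobile, "sk_frame")) mobile$positions else as.matrix(mobile)
  if (inherits(ref, "sk_alignment_ref")) {
    fit <- ref$fit
    ref_fit <- ref$coords[fit, , drop = FALSE]
  } else {
    ref_fit <- as.matrix(ref)
    if (is.null(fit)) fit <- seq_len(nrow(mob_all))
  }
  P <- mob_all[fit, , drop = FALSE]
  if (nrow(P) != nrow(ref_fit)) stop("fit particle counts differ")
  if (nrow(P) < 3L) stop("need at least 3 fit particles")
  cm_p <- colMeans(P)
  cm_q <- colMeans(ref_fit)
  Pc <- sweep(P, 2, cm_p)
  Qc <- sweep(ref_fit, 2, cm_q)
  sv <- svd(crossprod(Pc, Qc))         # H = P^T Q
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) fit particle set; superposition is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cm_q - as.numeric(R %*% cm_p)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(R = R, t = tvec, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords N x 3 matrix
#' @param tr transform list(R, t) from [kabsch_superpose()]
#' @return transformed N x 3 matrix
#' @export
apply_transform <- function(coords, tr) {
  sweep(as.matrix(coords) %*% t(tr$R), 2, tr$t, `+`)
}

#' Alignment reference
#'
#' Reference coordinates plus the fit selection (e.g. protein backbone) used
#' to superpose every analysed frame before RMSD and density accumulation.
#'
#' @param coords N x 3 reference coordinate matrix (nm), full system
#' @param fit sk_selection or index vector of fit particles (>= 3,
#'   non-collinear)
#' @return an "sk_alignment_ref"
#' @export
alignment_reference <- function(coords, fit) {
  coords <- as.matrix(coords)
  idx <- if (inherits(fit, "sk_selection")) fit$indices else fit
  if (length(idx) < 3L) stop("alignment needs at least 3 fit particles")
  fc <- sweep(coords[idx, , drop = FALSE], 2,
              colMeans(coords[idx, , drop = FALSE]))
  if (svd(fc)$d[2] < 1e-10) {
    stop("fit particles are collinear; alignment is not unique")
  }
  structure(list(coords = coords, fit = idx), class = "sk_alignment_ref")
}

#' RMSD time series after per-frame superposition
#'
#' Each frame is superposed onto the reference on the fit selection; the
#' RMSD is then reported over the report selection (which may differ, e.g.
#' fit on the full backbone, report on the cavity helices).
#'
#' @param traj an sk_trajectory
#' @param ref an sk_alignment_ref
#' @param report sk_selection or index vector to measure RMSD over; defaults
#'   to the fit selection
#' @return data.frame(time, rmsd) in ns and nm
#' @export
rmsd_series <- function(traj, ref, report = NULL) {
  stopifnot(inherits(traj, "sk_trajectory"), inherits(ref, "sk_alignment_ref"))
  rep_idx <- if (is.null(report)) ref$fit
  else if (inherits(report, "sk_selection")) report$indices else report
  if (length(rep_idx) == 0L) stop("report selection is empty")
  ref_rep <- ref$coords[rep_idx, , drop = FALSE]
  out <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- get_frame(traj, i)
    tr <- kabsch_superpose(fr, ref)
    moved <- apply_transform(fr$positions[rep_idx, , drop = FALSE], tr)
    sqrt(mean(rowSums((moved - ref_rep)^2)))
  }, numeric(1))
  data.frame(time = traj$times, rmsd = out)
}
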