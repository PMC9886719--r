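#' Eigenvalue normalization of a connectome
#'
#' Divides every element of the connectivity matrix A by
#' (largest absolute eigenvalue of A) + 1. The normalized matrix defines a
#' stable discrete-time linear system x(t+1) = A_norm x(t): its spectral
#' radius is lambda_max / (lambda_max + 1) < 1. A zero matrix maps to a
#' zero matrix (lambda_max = 0, divisor 1).
#'
#' @param C a [connectome].
#' @return object of class `normalized_connectome`: `A_norm`, `lambda_max`,
#'   the eigendecomposition of `A_norm` (`evals`, `evecs`), plus the
#'   subject id, timepoint and parcel ids carried through.
#' @export
normalize_connectome <- function(C) {
  stopifnot(inherits(C, "connectome"))
  W <- C$W
  if (any(!is.finite(W))) stop("non-finite entries in connectome")
  # A and A / (lambda_max + 1) share eigenvectors, so one decomposition
  # serves both the normalization and the downstream modal computation
  e <- eigen(W, symmetric = TRUE)
  lambda_max <- max(abs(e$values))
  structure(
    list(A_norm = W / (lambda_max + 1), lambda_max = lambda_max,
         evals = e$values / (lambda_max + 1), evecs = e$vectors,
         parcel_ids = C$parcel_ids, subject_id = C$subject_id,
         timepoint = C$timepoint),
    class = "normalized_connectome"
  )
}

#' Per-parcel modal controllability
#'
#' For the normalized adjacency A_norm with orthonormal eigendecomposition
#' A_norm = V diag(xi) V', the modal controllability of parcel i is
#'
#'   phi_i = sum_j (1 - xi_j^2) * v_ij^2
#'
#' Parcels with high phi preferentially steer the system's fast-decaying
#' (difficult-to-reach) modes. Because rows of V have unit norm, phi_i is a
#' convex combination of (1 - xi_j^2) and lies in (0, 1]; it is invariant
#' to eigenvector sign and to the basis chosen inside degenerate
#' eigenspaces.
#'
#' @param N a [normalize_connectome()] result, or a symmetric numeric
#'   matrix with spectral radius < 1.
#' @return object of class `controllability_profile`: `phi` (named by
#'   parcel id), `parcel_ids`, `subject_id`, `timepoint`.
#' @export
modal_controllability <- function(N) {
  if (inherits(N, "normalized_connectome")) {
    xi <- N$evals
    V <- N$evecs
    parcel_ids <- N$parcel_ids
    subject_id <- N$subject_id
    timepoint <- N$timepoint
  } else if (is.matrix(N)) {
    A <- N
    if (nrow(A) != ncol(A)) stop("matrix must be square")
    if (max(abs(A - t(A))) > 1e-8) stop("asymmetric input matrix")
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    xi <- e$values
    V <- e$vectors
    parcel_ids <- seq_len(nrow(A))
    subject_id <- "S1"
    timepoint <- "T1"
  } else {
    stop("input must be a normalized_connectome or a matrix")
  }
  if (max(abs(xi)) >= 1) {
    stop("spectral radius >= 1: normalize the connectome first")
  }
  phi <- as.vector(V^2 %*% (1 - xi^2))
  names(phi) <- parcel_ids
  structure(
    list(phi = phi, parcel_ids = parcel_ids, subject_id = subject_id,
         timepoint = timepoint),
    class = "controllability_profile"
  )
}

#' Network-averaged modal controllability
#'
#' Unweighted arithmetic mean of phi over all member parcels of a named
#' network — one summary value per subject-timepoint per network.
#'
#' @param P a [modal_controllability()] profile.
#' @param D a [network_definition].
#' @param network network label to average over.
#' @return scalar mean controllability.
#' @export
network_mean_controllability <- function(P, D, network) {
  stopifnot(inherits(P, "controllability_profile"))
  members <- network_members(D, network)
  missing <- setdiff(members, P$parcel_ids)
  if (length(missing) > 0) {
    stop("network '", network, "' parcels absent from profile: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  mean(P$phi[as.character(members)])
}

#' Group-level controllability topography
#'
#' Averages phi across subjects at each parcel and ranks the parcel means
#' (1 = smallest, ties averaged), as used to compare the spatial
#' distribution of controllability between timepoints.
#'
#' @param profiles list of [modal_controllability()] profiles over the same
#'   parcel set.
#' @return object of class `topography_map`: data.frame with `parcel_id`,
#'   `mean_phi`, `rank`.
#' @export
group_topography <- function(profiles) {
  if (length(profiles) == 0) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, TRUE, "controllability_profile")))
  ids <- profiles[[1]]$parcel_ids
  for (p in profiles) {
    if (!identical(p$parcel_ids, ids)) stop("mismatched parcel sets")
  }
  phi_mat <- vapply(profiles, function(p) p$phi, numeric(length(ids)))
  mean_phi <- rowMeans(as.matrix(phi_mat))
  out <- data.frame(parcel_id = ids, mean_phi = unname(mean_phi),
                    rank = rank(mean_phi))
  structure(out, class = c("topography_map", "data.frame"))
}

#' Spearman similarity of two topography maps
#'
#' Rank correlation (average ranks for ties) between the per-parcel group
#' means of two maps, with the t-approximation p-value on n - 2 df.
#'
#' @param M1,M2 [group_topography()] maps over the same parcel set.
#' @return list with `rho`, `p`, `n`.
#' @export
topography_similarity <- function(M1, M2) {
  stopifnot(inherits(M1, "topography_map"), inherits(M2, "topography_map"))
  if (!identical(M1$parcel_id, M2$parcel_id)) {
    M2 <- M2[match(M1$parcel_id, M2$parcel_id), ]
    if (any(is.na(M2$parcel_id))) stop("mismatched parcel sets")
  }
  spearman_stat(M1$mean_phi, M2$mean_phi)
}
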