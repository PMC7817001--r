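#' Spatial clustering of localizations into oligomers
#'
#' Groups blinks into oligomer clusters by single-linkage connectivity: two
#' blinks belong to the same cluster iff they are connected by a chain of
#' blinks with pairwise distance strictly below \code{gap}. Implemented with
#' a gap-sized grid hash so only neighboring cells are compared; exact for
#' any input.
#'
#' @param table localization table (columns \code{x_nm}, \code{y_nm}).
#' @param gap connectivity distance, nm (default 50).
#' @return integer vector of cluster labels (1-based, numbered by first
#'   occurrence); length 0 for an empty table.
#' @export
cluster_spatial <- function(table, gap = 50) {
  stopifnot(gap > 0)
  if (nrow(table) == 0L) return(integer(0))
  .cluster_spatial_cpp(as.numeric(table$x_nm), as.numeric(table$y_nm), gap)
}

#' Intensity clustering of one oligomer's blinks
#'
#' Assigns blinks to individual dye molecules by clustering in the
#' \eqn{(N_x, N_y)} intensity plane: single-linkage agglomeration cut so
#' that the closest-pair distance between any two resulting groups exceeds
#' \code{delta_p} photons (clusters exactly \code{delta_p} apart are still
#' merged). Deterministic; group labels are numbered by lowest member row.
#'
#' @param N_x,N_y observed channel intensities, photons.
#' @param delta_p minimum inter-group separation, photons; the empirical
#'   default rule is \code{300 + N_max/100} (see
#'   \code{\link{acquisition_model}}).
#' @return integer vector of group labels.
#' @export
cluster_intensity <- function(N_x, N_y, delta_p) {
  stopifnot(delta_p > 0, length(N_x) == length(N_y))
  if (length(N_x) == 0L) return(integer(0))
  .cluster_threshold_cpp(as.numeric(N_x), as.numeric(N_y), delta_p,
                         strict = FALSE)
}

#' Per-molecule group statistics
#'
#' For each intensity group \eqn{i} with \eqn{m_i} member blinks, computes
#' the mean position \eqn{(\bar x_i, \bar y_i)}, the mean squared per-blink
#' precision \eqn{\hat\sigma_i^2 = m_i^{-1}\sum_j s_j^2} and the variance of
#' the mean position \eqn{\hat z_i = \hat\sigma_i^2 / m_i}.
#'
#' @param table localization table rows of one oligomer.
#' @param labels integer group labels from \code{\link{cluster_intensity}}.
#' @return data.frame with one row per group: \code{group}, \code{m},
#'   \code{x_bar}, \code{y_bar}, \code{sigma2_hat}, \code{z_hat}.
#' @export
protomer_groups <- function(table, labels) {
  stopifnot(nrow(table) == length(labels))
  g <- sort(unique(labels))
  fac <- factor(labels, levels = g)
  m <- tabulate(fac, nbins = length(g))
  s2 <- as.vector(tapply(table$sj_nm^2, fac, mean))
  data.frame(group = g, m = m,
             x_bar = as.vector(tapply(table$x_nm, fac, mean)),
             y_bar = as.vector(tapply(table$y_nm, fac, mean)),
             sigma2_hat = s2,
             z_hat = s2 / m)
}

#' Eligibility of one oligomer
#'
#' An oligomer is eligible for size estimation iff its blinks fall into
#' exactly \code{n} well-separated intensity groups; oligomers with merged
#' or missing groups are rejected, which protects the fit from spurious
#' averaged positions. When ground-truth molecule ids are available,
#' \code{all_correct} reports whether every group is pure (one molecule per
#' group, distinct across groups).
#'
#' @param groups data.frame from \code{\link{protomer_groups}}.
#' @param n expected number of protomers.
#' @param labels the blink-level group labels.
#' @param molecule_id optional ground-truth molecule ids per blink.
#' @return list with \code{eligible}, \code{n_found}, \code{all_correct}
#'   (NA without ground truth) and \code{groups}.
#' @export
check_eligibility <- function(groups, n, labels = NULL, molecule_id = NULL) {
  n_found <- nrow(groups)
  all_correct <- NA
  if (!is.null(molecule_id) && !is.null(labels)) {
    per_group <- tapply(molecule_id, labels, function(v) length(unique(v)))
    firsts <- tapply(molecule_id, labels, function(v) v[1])
    all_correct <- all(per_group == 1L) && !anyDuplicated(firsts)
  }
  list(eligible = n_found == n, n_found = n_found,
       all_correct = all_correct, groups = groups)
}

#' Batch blink assignment over a whole localization table
#'
#' Runs the intensity clustering and eligibility check for every oligomer in
#' the table (rows are grouped by \code{oligomer_id}) and returns group
#' statistics for the eligible ones. This is the production path; the
#' per-oligomer functions above expose the same operations for inspection.
#'
#' @param table localization table with an \code{oligomer_id} column (from
#'   the simulator's ground truth or from \code{\link{cluster_spatial}}).
#' @param acq an \code{\link{acquisition_model}} (supplies \code{delta_p}).
#' @param n expected number of protomers per oligomer.
#' @param delta_p override for the intensity separation, photons.
#' @return list with \code{per_oligomer} (data.frame: \code{oligomer_id},
#'   \code{n_found}, \code{eligible}, \code{all_correct}) and \code{groups}
#'   (data.frame for eligible oligomers only, \code{n} rows each:
#'   \code{oligomer_id}, \code{x_bar}, \code{y_bar}, \code{z_hat},
#'   \code{m}).
#' @export
assign_blinks <- function(table, acq, n, delta_p = acq$delta_p) {
  if (nrow(table) == 0L) {
    return(list(per_oligomer = data.frame(oligomer_id = integer(),
                                          n_found = integer(),
                                          eligible = logical(),
                                          all_correct = logical()),
                groups = data.frame(oligomer_id = integer(), x_bar = numeric(),
                                    y_bar = numeric(), z_hat = numeric(),
                                    m = integer())))
  }
  if (is.unsorted(table$oligomer_id))
    table <- table[order(table$oligomer_id), ]
  has_truth <- "molecule_id" %in% names(table)
  mol <- if (has_truth) as.integer(table$molecule_id) else
    integer(nrow(table))
  res <- .assign_batch_cpp(as.integer(table$oligomer_id),
                           as.numeric(table$Nx_photons),
                           as.numeric(table$Ny_photons),
                           as.numeric(table$x_nm), as.numeric(table$y_nm),
                           as.numeric(table$sj_nm),
                           mol, has_truth, delta_p, as.integer(n))
  per <- data.frame(oligomer_id = res$oligomer_id, n_found = res$n_found,
                    eligible = res$eligible, all_correct = res$all_correct)
  groups <- data.frame(
    oligomer_id = rep(res$oligomer_id[res$eligible_index], each = n),
    x_bar = res$xbar, y_bar = res$ybar, z_hat = res$zhat, m = res$m)
  list(per_oligomer = per, groups = groups)
}
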