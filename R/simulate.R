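#' Oligomer simulation specification
#'
#' Describes the ground-truth population: regular polygons with \code{n}
#' protomers, each protomer carrying at most one dye molecule. Side length
#' \code{l} and circumscribed-circle radius \code{R} are related by
#' \eqn{l = 2R\sin(\pi/n)}; give exactly one of the two.
#'
#' @param n protomers per oligomer (integer >= 3).
#' @param l side length, nm (exclusive with \code{R}).
#' @param R circumscribed-circle radius, nm (exclusive with \code{l}).
#' @param n_oligomers number of oligomers to simulate.
#' @param labeling_efficiency probability that a protomer carries a
#'   detectable fluorophore, in [0, 1].
#' @param tilt_alpha tilt of the oligomerization plane out of the focal
#'   plane, radians in [0, pi/2); applied as \eqn{y' = y\cos\alpha} about
#'   each oligomer's center.
#' @param blink_mean,blink_sd distribution mean and sd of the log-normal
#'   blink-count statistics (localizations per molecule).
#' @return an object of class \code{oligomer_spec}.
#' @examples
#' oligomer_spec(n = 4, l = 5, n_oligomers = 1000)
#' @export
oligomer_spec <- function(n = 4, l = NULL, R = NULL, n_oligomers = 1000,
                          labeling_efficiency = 1, tilt_alpha = 0,
                          blink_mean = 6.4, blink_sd = 5) {
  stopifnot(n >= 3, n == round(n))
  if (is.null(l) == is.null(R))
    stop("give exactly one of `l` (side length) or `R` (radius)")
  if (is.null(R)) R <- l / (2 * sin(pi / n))
  if (is.null(l)) l <- 2 * R * sin(pi / n)
  stopifnot(l > 0, n_oligomers >= 1,
            labeling_efficiency >= 0, labeling_efficiency <= 1,
            tilt_alpha >= 0, tilt_alpha < pi / 2,
            blink_mean > 0, blink_sd > 0)
  structure(list(n = as.integer(n), l = l, R = R,
                 n_oligomers = as.integer(n_oligomers),
                 labeling_efficiency = labeling_efficiency,
                 tilt_alpha = tilt_alpha,
                 blink_mean = blink_mean, blink_sd = blink_sd),
            class = "oligomer_spec")
}

#' @export
print.oligomer_spec <- function(x, ...) {
  cat(sprintf(
    "Oligomer spec: %d-mer, side %.4g nm (R = %.4g nm), %d oligomers\n",
    x$n, x$l, x$R, x$n_oligomers))
  cat(sprintf("  labeling efficiency %.2f, tilt %.1f deg, blinks ~ logN(mean %.1f, sd %.1f)\n",
              x$labeling_efficiency, x$tilt_alpha * 180 / pi,
              x$blink_mean, x$blink_sd))
  invisible(x)
}

#' Corner positions of a regular polygon
#'
#' @param n number of corners (>= 3).
#' @param l side length, nm (exclusive with \code{R}).
#' @param R circumscribed-circle radius, nm.
#' @param center numeric length-2 center position, nm.
#' @param angle in-plane rotation of the first corner, radians.
#' @return an \code{n x 2} matrix of corner coordinates; adjacent corners are
#'   \code{l} apart.
#' @examples
#' make_polygon(4, l = 5)  # square on a circle of radius 5/sqrt(2)
#' @export
make_polygon <- function(n, l = NULL, R = NULL, center = c(0, 0), angle = 0) {
  if (n < 3) stop("a polygon needs at least 3 corners")
  if (is.null(l) == is.null(R))
    stop("give exactly one of `l` or `R`")
  if (is.null(R)) R <- l / (2 * sin(pi / n))
  phi <- angle + (seq_len(n)) * 2 * pi / n
  cbind(x = center[1] + R * cos(phi), y = center[2] + R * sin(phi))
}

#' Tilt positions out of the focal plane
#'
#' A tilt of the oligomerization plane by \eqn{\alpha} about the x-axis
#' through the oligomer center compresses the projected y-coordinates:
#' \eqn{y' = y_c + (y - y_c)\cos\alpha}. x is unchanged.
#'
#' @param positions matrix with columns x, y (nm).
#' @param alpha tilt angle, radians.
#' @param center length-2 center the tilt pivots about; defaults to the
#'   column means of \code{positions}.
#' @return the transformed positions.
#' @export
apply_tilt <- function(positions, alpha, center = colMeans(positions)) {
  positions[, 2] <- center[2] + (positions[, 2] - center[2]) * cos(alpha)
  positions
}

#' Simulate a localization table under the full forward model
#'
#' For each oligomer a regular polygon is placed at a well-separated grid
#' position with random in-plane orientation and optional out-of-plane tilt.
#' Each protomer is labeled with probability \code{labeling_efficiency};
#' labeled protomers receive a fixed random dipole and a log-normal blink
#' count. Every blink passes through the photon noise chain
#' (\code{\link{draw_emission}}); blinks below the detection threshold are
#' discarded, and surviving blinks are displaced from the true protomer
#' position by independent per-axis Gaussian localization errors with the
#' per-blink precision estimate as standard deviation.
#'
#' Oligomer centers sit on a square grid with spacing
#' \code{max(100 * R, 200)} nm so spatial clusters never overlap and
#' ground-truth grouping is unambiguous.
#'
#' @param spec an \code{\link{oligomer_spec}}.
#' @param acq an \code{\link{acquisition_model}}.
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   so the table is reproducible.
#' @return a data.frame (class \code{localization_table}) with columns
#'   \code{oligomer_id}, \code{molecule_id}, \code{x_nm}, \code{y_nm},
#'   \code{Nx_photons}, \code{Ny_photons}, \code{Ntotal_photons},
#'   \code{sj_nm} and the diagnostic \code{dx_true_nm}. Rows are sorted by
#'   \code{oligomer_id}. Oligomers whose blinks are all discarded contribute
#'   no rows.
#' @export
simulate_dataset <- function(spec, acq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  R <- spec$R
  N_oligo <- spec$n_oligomers

  # grid of oligomer centers, spacing >> cluster extent
  k <- ceiling(sqrt(N_oligo))
  spacing <- max(100 * R, 200)
  idx <- seq_len(N_oligo) - 1L
  cx <- (idx %% k) * spacing
  cy <- (idx %/% k) * spacing
  angle <- stats::runif(N_oligo, 0, 2 * pi)

  # protomer (molecule) level
  oligo_of_mol <- rep.int(seq_len(N_oligo), rep.int(n, N_oligo))
  corner <- rep.int(seq_len(n), N_oligo)
  phic <- angle[oligo_of_mol] + corner * 2 * pi / n
  px <- cx[oligo_of_mol] + R * cos(phic)
  py <- cy[oligo_of_mol] + R * sin(phic) * cos(spec$tilt_alpha)

  labeled <- stats::runif(N_oligo * n) < spec$labeling_efficiency
  mol <- which(labeled)
  if (length(mol) == 0L) return(empty_localization_table())

  dip <- sample_dipole(length(mol))
  m_i <- draw_blink_count(length(mol), spec$blink_mean, spec$blink_sd)

  # blink level
  bmol <- rep.int(seq_along(mol), m_i)  # index into `mol`
  em <- draw_emission(list(phi = dip$phi[bmol], theta = dip$theta[bmol]), acq)
  keep <- em$accepted
  if (!any(keep)) return(empty_localization_table())
  bm <- bmol[keep]
  sj <- em$dx[keep]
  gmol <- mol[bm]
  out <- data.frame(
    oligomer_id = oligo_of_mol[gmol],
    molecule_id = gmol,
    x_nm = px[gmol] + stats::rnorm(length(bm), 0, sj),
    y_nm = py[gmol] + stats::rnorm(length(bm), 0, sj),
    Nx_photons = em$N_x_obs[keep],
    Ny_photons = em$N_y_obs[keep],
    Ntotal_photons = em$N_total[keep],
    sj_nm = sj,
    dx_true_nm = em$dx_true[keep])
  class(out) <- c("localization_table", "data.frame")
  out
}

empty_localization_table <- function() {
  out <- data.frame(oligomer_id = integer(), molecule_id = integer(),
                    x_nm = numeric(), y_nm = numeric(),
                    Nx_photons = numeric(), Ny_photons = numeric(),
                    Ntotal_photons = numeric(), sj_nm = numeric(),
                    dx_true_nm = numeric())
  class(out) <- c("localization_table", "data.frame")
  out
}

loc_required_cols <- c("x_nm", "y_nm", "Nx_photons", "Ny_photons",
                       "Ntotal_photons", "sj_nm")

#' Write / read a localization table as CSV
#'
#' Plain-text interchange format: one row per blink, header mandatory,
#' numeric columns rounded to 6 decimal places (writer/reader round-trip is
#' bit-exact at that precision). Ground-truth columns (\code{oligomer_id},
#' \code{molecule_id}) are optional on read — real data lack them.
#'
#' @param table a localization table data.frame.
#' @param path file path.
#' @return \code{read_localizations} returns the table;
#'   \code{write_localizations} returns \code{path} invisibly.
#' @export
write_localizations <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, format = "f", digits = 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(loc_required_cols, names(df))
  if (length(missing))
    stop("localization table lacks columns: ", paste(missing, collapse = ", "))
  class(df) <- c("localization_table", "data.frame")
  df
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("Localization table: %d blinks", nrow(x)))
  if ("oligomer_id" %in% names(x) && nrow(x))
    cat(sprintf(", %d oligomers", length(unique(x$oligomer_id))))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
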