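#' Levenberg-Marquardt settings for the geometric circle fit
#'
#' @param lambda0 initial damping factor.
#' @param lambda_up factor applied to the damping after a rejected step
#'   (> 1).
#' @param lambda_down factor applied after an accepted step (< 1).
#' @param tol_step stop when the accepted parameter step norm falls below
#'   this value, nm.
#' @param max_iter iteration cap.
#' @return a list of class \code{lm_settings}.
#' @export
lm_settings <- function(lambda0 = 1e-3, lambda_up = 10, lambda_down = 0.1,
                        tol_step = 1e-10, max_iter = 200) {
  stopifnot(lambda0 > 0, lambda_up > 1, lambda_down > 0, lambda_down < 1,
            tol_step > 0, max_iter >= 1)
  structure(list(lambda0 = lambda0, lambda_up = lambda_up,
                 lambda_down = lambda_down, tol_step = tol_step,
                 max_iter = as.integer(max_iter)),
            class = "lm_settings")
}

#' Initial guess for the circle fit
#'
#' The center starts at the unweighted mean of the per-protomer mean
#' positions (each protomer counts once, regardless of its blink count). The
#' radius starts at half the RMS distance of the means from that center —
#' deliberately below the radius the fit will converge to for near-regular
#' configurations, since the objective prefers approaches from small radii.
#'
#' @param x,y coordinates of the per-protomer mean positions, nm.
#' @return list with \code{a0}, \code{b0}, \code{R0} and \code{degenerate}
#'   (TRUE when all points coincide, i.e. \code{R0 == 0}).
#' @export
initial_guess <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points to fit a circle")
  a0 <- mean(x); b0 <- mean(y)
  R0 <- 0.5 * sqrt(mean((x - a0)^2 + (y - b0)^2))
  list(a0 = a0, b0 = b0, R0 = R0, degenerate = R0 < 1e-12)
}

#' Geometric circle fit by Levenberg-Marquardt
#'
#' Minimizes the geometric objective
#' \deqn{S(a, b, R) = \sum_i \left(\sqrt{(x_i - a)^2 + (y_i - b)^2} -
#'   R\right)^2}
#' over center \eqn{(a, b)} and radius \eqn{R \ge 0} with a damped
#' Gauss-Newton (Levenberg-Marquardt) iteration on the normal equations
#' \eqn{(D^T D + \lambda I)d = -D^T f}: a step is accepted only if it
#' decreases \eqn{S} (then \eqn{\lambda} shrinks), otherwise \eqn{\lambda}
#' grows and the step is retried. Negative trial radii are reflected.
#' Degenerate inputs (coincident or collinear points) are flagged via
#' \code{converged = FALSE} rather than silently fitted.
#'
#' @param x,y the points to fit — normally the per-protomer mean positions.
#' @param init optional list with \code{a0}, \code{b0}, \code{R0}; defaults
#'   to \code{\link{initial_guess}}.
#' @param settings an \code{\link{lm_settings}} object.
#' @return an object of class \code{circle_fit}: list with \code{a},
#'   \code{b}, \code{r_hat}, \code{S}, \code{iterations}, \code{converged},
#'   \code{lambda_final}.
#' @examples
#' sq <- make_polygon(4, R = 4)
#' fit_circle_lm(sq[, 1], sq[, 2])  # r_hat = 4, S = 0
#' @export
fit_circle_lm <- function(x, y, init = NULL, settings = lm_settings()) {
  if (length(x) < 3) stop("need at least 3 points to fit a circle")
  if (is.null(init)) init <- initial_guess(x, y)
  if (isTRUE(init$degenerate)) {
    out <- list(a = init$a0, b = init$b0, r_hat = 0, S = 0, iterations = 0L,
                converged = FALSE, lambda_final = settings$lambda0)
    class(out) <- "circle_fit"
    return(out)
  }
  out <- .fit_circle_cpp(as.numeric(x), as.numeric(y),
                         init$a0, init$b0, init$R0,
                         settings$lambda0, settings$lambda_up,
                         settings$lambda_down, settings$tol_step,
                         settings$max_iter)
  class(out) <- "circle_fit"
  out
}

#' Naive circle fit to all raw blink coordinates
#'
#' The same objective and optimizer as \code{\link{fit_circle_lm}}, applied
#' to every blink without molecule assignment. Provided for comparison: the
#' blink-count heterogeneity across protomers pulls the fit toward the
#' heavily-blinking corners and typically yields much worse radius
#' estimates than the grouped fit.
#'
#' @param table localization table rows of one oligomer.
#' @inheritParams fit_circle_lm
#' @return a \code{circle_fit} object.
#' @export
fit_circle_all_blinks <- function(table, init = NULL,
                                  settings = lm_settings()) {
  fit_circle_lm(table$x_nm, table$y_nm, init = init, settings = settings)
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: center (%.4g, %.4g) nm, r_hat = %.4g nm\n",
              x$a, x$b, x$r_hat))
  cat(sprintf("  S = %.4g, %d iterations, converged: %s\n",
              x$S, x$iterations, x$converged))
  invisible(x)
}

# Batch fits over the eligible groups from assign_blinks(); blocks of n
# consecutive rows per oligomer.
fit_circles <- function(groups, n, settings = lm_settings()) {
  res <- .fit_circles_batch_cpp(as.numeric(groups$x_bar),
                                as.numeric(groups$y_bar), as.integer(n),
                                settings$lambda0, settings$lambda_up,
                                settings$lambda_down, settings$tol_step,
                                settings$max_iter)
  data.frame(oligomer_id = groups$oligomer_id[seq(1, nrow(groups), by = n)],
             a = res$a, b = res$b, r_hat = res$r_hat, S = res$S,
             iterations = res$iterations, converged = res$converged)
}
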