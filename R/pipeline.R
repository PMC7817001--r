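#' Full size-estimation pipeline on one localization table
#'
#' Runs assignment (intensity clustering + eligibility), per-oligomer
#' Levenberg-Marquardt circle fits on the group means, the second-order bias
#' correction and the population aggregation on a localization table.
#' Oligomer identity is taken from the \code{oligomer_id} column when
#' present (the simulator's ground truth — simulated oligomers are placed
#' far apart by construction); otherwise blinks are first grouped spatially
#' with \code{\link{cluster_spatial}}.
#'
#' @param table a localization table.
#' @param acq the \code{\link{acquisition_model}} used (supplies
#'   \code{delta_p}).
#' @param n protomers per oligomer.
#' @param nominal_l optional nominal side length, nm, for relative errors.
#' @param method population estimator, \code{"median"} or \code{"mean"}.
#' @param n_boot bootstrap samples for the 95\% CI of the estimator; 0
#'   disables the interval.
#' @param gap spatial connectivity distance, nm, used only when the table
#'   has no \code{oligomer_id} column.
#' @param delta_p override for the intensity-group separation, photons.
#' @param settings \code{\link{lm_settings}} for the circle fits.
#' @param n_simulated optional total number of simulated oligomers, used as
#'   the denominator of the eligibility fraction (oligomers with no
#'   surviving blinks leave no rows); defaults to the number of oligomer ids
#'   present.
#' @return list of class \code{size_analysis}:
#'   \describe{
#'     \item{estimates}{per-oligomer data.frame: \code{oligomer_id},
#'       \code{r_hat}, \code{r_corr}, \code{l_hat}, \code{discriminant_ok},
#'       \code{converged}, \code{S}.}
#'     \item{assignment}{per-oligomer eligibility data.frame.}
#'     \item{population}{the \code{\link{aggregate_size}} result plus
#'       \code{ci_low}/\code{ci_high}.}
#'     \item{counts}{named vector of stage counts: simulated, with_rows,
#'       eligible, converged, corrected.}
#'     \item{fractions}{eligible fraction and (when ground truth is
#'       present) fraction of eligible oligomers with all blinks correctly
#'       assigned.}
#'   }
#' @export
size_oligomers <- function(table, acq, n, nominal_l = NULL,
                           method = c("median", "mean"), n_boot = 1000,
                           gap = 50, delta_p = acq$delta_p,
                           settings = lm_settings(), n_simulated = NULL) {
  method <- match.arg(method)
  if (!"oligomer_id" %in% names(table)) {
    table$oligomer_id <- cluster_spatial(table, gap)
    table <- table[order(table$oligomer_id), ]
  }
  asg <- assign_blinks(table, acq, n, delta_p = delta_p)
  n_with_rows <- nrow(asg$per_oligomer)
  if (is.null(n_simulated)) n_simulated <- n_with_rows
  n_eligible <- sum(asg$per_oligomer$eligible)
  if (n_eligible == 0L) stop("no eligible oligomers")

  fits <- fit_circles(asg$groups, n, settings = settings)
  z_sum <- rowsum_block(asg$groups$z_hat, n)
  keep <- fits$converged & fits$r_hat > 0
  corr <- correct_radius(pmax(fits$r_hat, .Machine$double.eps), z_sum, n)
  corr$r_corr[!keep] <- NA_real_
  corr$l_hat[!keep] <- NA_real_
  est <- data.frame(oligomer_id = fits$oligomer_id, r_hat = fits$r_hat,
                    r_corr = corr$r_corr, l_hat = corr$l_hat,
                    discriminant_ok = corr$discriminant_ok & keep,
                    converged = fits$converged, S = fits$S)
  pop <- aggregate_size(est$l_hat, method = method, nominal_l = nominal_l)
  if (n_boot > 0) {
    ci <- bootstrap_ci(est$l_hat, method = method, n_boot = n_boot)
    pop$ci_low <- ci[1]; pop$ci_high <- ci[2]
  } else {
    pop$ci_low <- pop$ci_high <- NA_real_
  }
  eligible_correct <- asg$per_oligomer$all_correct[asg$per_oligomer$eligible]
  list(estimates = est, assignment = asg$per_oligomer, population = pop,
       counts = c(simulated = n_simulated, with_rows = n_with_rows,
                  eligible = n_eligible, converged = sum(keep),
                  corrected = sum(est$discriminant_ok)),
       fractions = c(
         eligible = n_eligible / n_simulated,
         correct = if (all(is.na(eligible_correct))) NA_real_ else
           mean(eligible_correct, na.rm = TRUE))) -> out
  class(out) <- "size_analysis"
  out
}

# per-oligomer sums over blocks of n consecutive group rows
rowsum_block <- function(v, n) {
  if (length(v) == 0L) return(numeric(0))
  colSums(matrix(v, nrow = n))
}

#' Experiment configuration for parameter sweeps
#'
#' Declares a simulation-and-analysis experiment: base acquisition and
#' oligomer parameters plus one swept parameter. Defaults mirror the
#' standard study conditions: pixel 100 nm, sigma_PSF 160 nm, 10 nm
#' precision cutoff, blink statistics log-normal(mean 6.4, sd 5) and the
#' delta_p rule 300 + N_max/100.
#'
#' @param acq base \code{\link{acquisition_model}}.
#' @param oligomer base \code{\link{oligomer_spec}}.
#' @param sweep_param one of \code{"N_max"}, \code{"b"},
#'   \code{"labeling_efficiency"}, \code{"side_length"}, \code{"n"},
#'   \code{"tilt_alpha"}, \code{"N_oligo"}; or \code{"none"} for a single
#'   run.
#' @param sweep_values numeric vector of values for the swept parameter.
#' @param seed base integer seed; each sweep value gets an independent,
#'   reproducible sub-stream.
#' @param method population estimator.
#' @param n_boot bootstrap samples per sweep value.
#' @return list of class \code{experiment_config}.
#' @export
experiment_config <- function(acq, oligomer, sweep_param = "none",
                              sweep_values = NA, seed = 0,
                              method = c("median", "mean"), n_boot = 1000) {
  method <- match.arg(method)
  ok <- c("none", "N_max", "b", "labeling_efficiency", "side_length", "n",
          "tilt_alpha", "N_oligo")
  if (!sweep_param %in% ok)
    stop("sweep_param must be one of: ", paste(ok, collapse = ", "))
  if (oligomer$n_oligomers < 1) stop("n_oligomers must be positive")
  structure(list(acq = acq, oligomer = oligomer, sweep_param = sweep_param,
                 sweep_values = sweep_values, seed = as.integer(seed),
                 method = method, n_boot = n_boot),
            class = "experiment_config")
}

# independent, reproducible per-sweep-value seeds below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + 7919 * i) %% 2147483629)
}

apply_sweep_value <- function(config, value) {
  acq <- config$acq
  sp <- config$oligomer
  switch(config$sweep_param,
    none = NULL,
    N_max = {
      acq <- acquisition_model(N_max = value, b = acq$b, a = acq$a,
                               sigma_psf = acq$sigma_psf,
                               dx_max = acq$dx_max)
    },
    b = {
      acq <- acquisition_model(N_max = acq$N_max, b = value, a = acq$a,
                               sigma_psf = acq$sigma_psf,
                               dx_max = acq$dx_max, delta_p = acq$delta_p)
    },
    labeling_efficiency = sp$labeling_efficiency <- value,
    side_length = {
      sp$l <- value
      sp$R <- value / (2 * sin(pi / sp$n))
    },
    n = {
      sp$n <- as.integer(value)
      sp$l <- 2 * sp$R * sin(pi / sp$n)  # fixed circumscribed radius
    },
    tilt_alpha = sp$tilt_alpha <- value,
    N_oligo = sp$n_oligomers <- as.integer(value))
  list(acq = acq, oligomer = sp)
}

#' Run a sweep experiment
#'
#' For every sweep value: simulate a fresh data set (independent seeded
#' sub-stream), run the full pipeline (\code{\link{size_oligomers}}) and
#' collect the population statistics. Deterministic given the config seed.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param verbose print one progress line per sweep value.
#' @return object of class \code{sweep_result}: a list with \code{summary}
#'   (one data.frame row per sweep value: value, counts, eligible and
#'   correct-assignment fractions, median and mean side length, signed and
#'   absolute relative errors, CI bounds, excluded-discriminant count) and
#'   \code{config}.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  values <- if (config$sweep_param == "none") NA else config$sweep_values
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    pars <- apply_sweep_value(config, values[i])
    sp <- pars$oligomer; acq <- pars$acq
    tbl <- simulate_dataset(sp, acq, seed = derive_seed(config$seed, i))
    res <- size_oligomers(tbl, acq, sp$n, nominal_l = sp$l,
                          method = config$method, n_boot = config$n_boot,
                          n_simulated = sp$n_oligomers)
    med <- stats::median(res$estimates$l_hat, na.rm = TRUE)
    mn <- mean(res$estimates$l_hat, na.rm = TRUE)
    rows[[i]] <- data.frame(
      value = values[i],
      n_simulated = sp$n_oligomers,
      n_eligible = res$counts[["eligible"]],
      n_corrected = res$counts[["corrected"]],
      n_excluded_discriminant = res$counts[["converged"]] -
        res$counts[["corrected"]],
      eligible_fraction = res$fractions[["eligible"]],
      correct_fraction = res$fractions[["correct"]],
      L_median = med, L_mean = mn,
      L_hat = res$population$L_hat,
      epsilon_signed = res$population$epsilon_signed,
      epsilon_abs = res$population$epsilon_l,
      ci_low = res$population$ci_low, ci_high = res$population$ci_high)
    if (verbose)
      cat(sprintf("%s = %g: eligible %.3f, L_hat %.4f, eps %.2e\n",
                  config$sweep_param, values[i],
                  rows[[i]]$eligible_fraction, rows[[i]]$L_hat,
                  rows[[i]]$epsilon_signed))
  }
  out <- list(summary = do.call(rbind, rows), config = config)
  class(out) <- "sweep_result"
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep of %s over %d value(s)\n", x$config$sweep_param,
              nrow(x$summary)))
  print.data.frame(x$summary[, c("value", "eligible_fraction", "L_hat",
                                 "epsilon_signed", "ci_low", "ci_high")],
                   digits = 5)
  invisible(x)
}

#' Write sweep results to disk
#'
#' Writes a CSV of the per-value summary, a JSON with the same content plus
#' the configuration scalars, and optionally binned side-length histogram
#' counts for the last analyzed data set (display clipping, if any, is the
#' plot reader's business — statistics always use the full distribution).
#'
#' @param result a \code{sweep_result}.
#' @param dir output directory (created if needed).
#' @param histogram optional numeric vector of per-oligomer side lengths to
#'   bin (e.g. \code{analysis$estimates$l_hat}).
#' @param breaks histogram breaks passed to \code{hist()}.
#' @return invisibly, the paths written.
#' @export
report_sweep <- function(result, dir, histogram = NULL, breaks = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "sweep_summary.csv")
  utils::write.csv(result$summary, csv, row.names = FALSE)
  js <- file.path(dir, "sweep_summary.json")
  cfg <- result$config
  jsonlite::write_json(
    list(sweep_param = cfg$sweep_param, seed = cfg$seed,
         method = cfg$method,
         acquisition = unclass(cfg$acq), oligomer = unclass(cfg$oligomer),
         summary = result$summary),
    js, auto_unbox = TRUE, digits = NA)
  paths <- c(csv, js)
  if (!is.null(histogram)) {
    h <- graphics::hist(histogram[!is.na(histogram)], breaks = breaks,
                        plot = FALSE)
    hp <- file.path(dir, "side_length_histogram.csv")
    utils::write.csv(data.frame(bin_low = utils::head(h$breaks, -1),
                                bin_high = h$breaks[-1], count = h$counts),
                     hp, row.names = FALSE)
    paths <- c(paths, hp)
  }
  invisible(paths)
}
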