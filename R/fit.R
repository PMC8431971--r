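#' Fit grid for pair-override scans
#'
#' Candidate well depths and pair Rmin values for the grid stage of the fit.
#' Defaults span 5.0 to 14.0 kcal/mol in 0.1 steps and 2.7 to 2.8 Angstrom in
#' 0.01 steps, so that parameters quoted at 0.1 kcal/mol / 0.01 Angstrom
#' precision are representable grid points.
#'
#' @param eps_values well-depth magnitudes, kcal/mol.
#' @param rmin_values pair Rmin values, Angstrom.
#' @return An object of class `fit_grid`.
#' @export
fit_grid <- function(eps_values = seq(5.0, 14.0, by = 0.1),
                     rmin_values = seq(2.7, 2.8, by = 0.01)) {
  if (length(eps_values) == 0L || length(rmin_values) == 0L)
    stop("fit grid must be nonempty")
  structure(list(eps_values = as.numeric(eps_values),
                 rmin_values = as.numeric(rmin_values)),
            class = "fit_grid")
}

kT_room <- 0.593  # kcal/mol

#' Weighted mismatch between two energy curves
#'
#' Both curves are first shifted so that the energy at the largest scanned
#' distance is zero (scans report the change in potential energy relative to
#' the dissociated pair), then the weighted sum of squared differences is
#' taken. Scheme `"uniform"` weights every point 1; `"close_range"` uses
#' normalized Boltzmann weights `w(r) = exp(-E_ref(r)/kT)` with kT = 0.593
#' kcal/mol, which emphasizes the well region and suppresses both the steep
#' repulsive wall and the flat tail.
#'
#' @param mm,ref [as_energy_curve()] objects on identical distance grids.
#' @param weight_scheme `"close_range"` (default) or `"uniform"`.
#' @param anchor shift both curves to zero at the largest distance before
#'   comparing (default `TRUE`); set `FALSE` to compare absolute energies.
#' @return scalar objective (kcal^2/mol^2); 0 iff the shifted curves agree.
#' @export
fit_objective <- function(mm, ref, weight_scheme = c("close_range", "uniform"),
                          anchor = TRUE) {
  weight_scheme <- match.arg(weight_scheme)
  if (length(mm$distances) != length(ref$distances) ||
      any(abs(mm$distances - ref$distances) > 1e-9))
    stop("curves are not on the same distance grid")
  e_mm <- mm$energies
  e_ref <- ref$energies
  if (anchor) {
    e_mm <- e_mm - e_mm[length(e_mm)]
    e_ref <- e_ref - e_ref[length(e_ref)]
  }
  w <- curve_weights(e_ref, weight_scheme)
  sum(w * (e_mm - e_ref)^2)
}

curve_weights <- function(e_ref, weight_scheme) {
  if (weight_scheme == "uniform") return(rep(1, length(e_ref)))
  w <- exp(-e_ref / kT_room)
  w / sum(w) * length(e_ref)
}

## install the fitted pair override, preserving overrides for other pairs
merge_override <- function(params, ov_row) {
  ov <- params$overrides
  keep <- !((ov$type_a %in% c(ov_row$type_a, ov_row$type_b)) &
            (ov$type_b %in% c(ov_row$type_a, ov_row$type_b)))
  with_override(params, rbind(ov[keep, , drop = FALSE], ov_row))
}

mm_curve_for <- function(eps, rmin, configs, mol, ion_type, params,
                         pair_types) {
  ov <- data.frame(type_a = pair_types[1], type_b = pair_types[2],
                   well_depth = eps, rmin = rmin)
  energy_curve(configs, mol, merge_override(params, ov), ion_type)
}

## Precompute the parts of the scan energy that do not depend on the fitted
## pair override: Coulomb over all atoms and LJ over atoms outside the fitted
## type pair. The candidate curve is then base + sum over pair atoms of
## eps*((rmin/r)^12 - 2*(rmin/r)^6), one cheap vector expression per
## candidate.
scan_cache <- function(mol, configs, params, ion_type, pair_types,
                       ion_charge = 1) {
  a <- mol$atoms
  xyz <- coords(mol)
  ion <- as.matrix(configs[, c("x", "y", "z")])
  r <- sqrt(outer(rowSums(xyz^2), rep(1, nrow(ion))) +
            outer(rep(1, nrow(xyz)), rowSums(ion^2)) -
            2 * xyz %*% t(ion))                      # natoms x nconfigs
  q <- vapply(a$name, function(nm) lookup_charge(params, mol$label, nm),
              numeric(1))
  coul <- colSums(params$coulomb_constant * q * ion_charge / r)
  pair_idx <- which(a$type == pair_types[1] | a$type == pair_types[2])
  ov <- params$overrides
  keep <- !((ov$type_a %in% pair_types) & (ov$type_b %in% pair_types))
  base_no_ov <- with_override(params, ov[keep, , drop = FALSE])
  lj_other <- rep(0, nrow(ion))
  for (i in setdiff(seq_len(nrow(a)), pair_idx)) {
    p <- combine_lj(a$type[i], ion_type, base_no_ov)
    x6 <- (p[["rmin"]] / r[i, ])^6
    lj_other <- lj_other + p[["well_depth"]] * (x6^2 - 2 * x6)
  }
  list(base = coul + lj_other, r_pair = r[pair_idx, , drop = FALSE])
}

cached_curve <- function(cache, eps, rmin) {
  e <- cache$base
  for (i in seq_len(nrow(cache$r_pair))) {
    x6 <- (rmin / cache$r_pair[i, ])^6
    e <- e + eps * (x6^2 - 2 * x6)
  }
  e
}

cached_objective <- function(cache, eps, rmin, e_ref_shifted, w) {
  e <- cached_curve(cache, eps, rmin)
  e <- e - e[length(e)]
  sum(w * (e - e_ref_shifted)^2)
}

sulfur_pair <- function(mol, ion_type) {
  s <- mol$atoms$type[mol$atoms$element == "S"][1]
  if (is.na(s)) stop("no sulfur atom in geometry; supply pair_types")
  c(s, ion_type)
}

#' Grid search for a pair-specific Lennard-Jones override
#'
#' Evaluates the rigid-dimer molecular-mechanics curve for every
#' (well depth, Rmin) candidate in the grid, with the override applied to the
#' sulfur-ion type pair, and returns the candidate minimizing
#' [fit_objective()] against the reference curve. Ties are broken
#' deterministically in favour of the smallest well depth, then the smallest
#' Rmin.
#'
#' @param ref reference [as_energy_curve()]; its distances define the scan.
#' @param mol a [molecule_geometry()].
#' @param ion_type LJ type label of the ion.
#' @param params base [parameter_set()] (any existing override for the fitted
#'   pair is replaced during the scan).
#' @param grid a [fit_grid()].
#' @param weight_scheme see [fit_objective()].
#' @param pair_types the fitted type pair; default (sulfur type, `ion_type`).
#' @param anchor_atom passed to [build_approach_series()].
#' @return An object of class `nbfix_fit`; see [nbfix_fit()].
#' @export
grid_fit <- function(ref, mol, ion_type = "SOD", params = default_parameter_set(),
                     grid = fit_grid(), weight_scheme = c("close_range", "uniform"),
                     pair_types = NULL, anchor_atom = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  if (length(grid$eps_values) == 0L) stop("empty fit grid")
  if (is.null(pair_types)) pair_types <- sulfur_pair(mol, ion_type)
  r <- ref$distances
  configs <- build_approach_series(mol, r_start = min(r), r_end = max(r),
                                   step = if (length(r) > 1) diff(r)[1] else 0.1,
                                   anchor_atom = anchor_atom)
  if (nrow(configs) != length(r) || any(abs(configs$distance - r) > 1e-8))
    configs <- approach_at(mol, r, anchor_atom)

  cache <- scan_cache(mol, configs, params, ion_type, pair_types)
  e_ref <- ref$energies - ref$energies[length(ref$energies)]
  w <- curve_weights(e_ref, weight_scheme)
  cand <- expand.grid(eps = grid$eps_values, rmin = grid$rmin_values,
                      KEEP.OUT.ATTRS = FALSE)
  obj <- vapply(seq_len(nrow(cand)), function(i)
    cached_objective(cache, cand$eps[i], cand$rmin[i], e_ref, w),
    numeric(1))
  # deterministic tie-break: lowest objective, then lowest eps, then lowest rmin
  ord <- order(obj, cand$eps, cand$rmin)
  best <- ord[1]
  new_nbfix_fit(eps = cand$eps[best], rmin = cand$rmin[best],
                objective = obj[best], ref = ref, mol = mol,
                ion_type = ion_type, params = params, grid = grid,
                weight_scheme = weight_scheme, pair_types = pair_types,
                configs = configs, refined = FALSE, call = sys.call())
}

approach_at <- function(mol, distances, anchor_atom = NULL) {
  base <- build_approach_series(mol, r_start = min(distances),
                                r_end = min(distances) + 1, step = 1,
                                anchor_atom = anchor_atom)
  anchor_i <- which(mol$atoms$element == "S")[1]
  if (!is.null(anchor_atom)) anchor_i <- match(anchor_atom, mol$atoms$name)
  anchor <- coords(mol)[anchor_i, ]
  dir <- (c(base$x[1], base$y[1], base$z[1]) - anchor) / base$distance[1]
  pos <- t(anchor + t(outer(distances, dir)))
  data.frame(distance = distances, x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

new_nbfix_fit <- function(eps, rmin, objective, ref, mol, ion_type, params,
                          grid, weight_scheme, pair_types, configs, refined,
                          call) {
  ov <- data.frame(type_a = pair_types[1], type_b = pair_types[2],
                   well_depth = eps, rmin = rmin)
  mm <- energy_curve(configs, mol, merge_override(params, ov), ion_type)
  e_mm <- mm$energies - mm$energies[length(mm$energies)]
  e_ref <- ref$energies - ref$energies[length(ref$energies)]
  structure(list(best = ov, objective = objective,
                 residuals = e_mm - e_ref,
                 weights = curve_weights(e_ref, weight_scheme),
                 grid = grid, weight_scheme = weight_scheme,
                 refined = refined, ref = ref, mm_curve = mm,
                 mol = mol, ion_type = ion_type, params = params,
                 pair_types = pair_types, configs = configs, call = call),
            class = "nbfix_fit")
}

#' Fit a pair-specific Lennard-Jones correction to a reference curve
#'
#' The main fitting interface: a grid search over the candidate
#' (well depth, Rmin) values ([grid_fit()]) followed, by default, by a
#' derivative-free simplex refinement ([refine_fit()]). Returns a classed
#' model object supporting [print()], [summary()], [coef()], [predict()],
#' [residuals()] and [plot()].
#'
#' @inheritParams grid_fit
#' @param refine run the continuous refinement stage after the grid search.
#' @return An object of class `nbfix_fit` with components `best` (the fitted
#'   override row), `objective`, `residuals` (mm - ref after tail-anchoring),
#'   `mm_curve`, `ref`, `grid`, `weight_scheme`, `refined`.
#' @examples
#' mol <- analog_geometry("methylthioethane")
#' ref <- make_reference_curve(ref_model_params(), mol = mol)
#' fit <- nbfix_fit(ref, mol, grid = fit_grid(seq(5, 14, 0.5), seq(2.7, 2.8, 0.05)))
#' coef(fit)
#' @export
nbfix_fit <- function(ref, mol, ion_type = "SOD",
                      params = default_parameter_set(), grid = fit_grid(),
                      weight_scheme = c("close_range", "uniform"),
                      pair_types = NULL, anchor_atom = NULL, refine = TRUE) {
  fit <- grid_fit(ref, mol, ion_type, params, grid, weight_scheme,
                  pair_types, anchor_atom)
  if (refine) fit <- refine_fit(fit)
  fit$call <- sys.call()
  fit
}

#' Continuous refinement of a grid fit
#'
#' Polishes the grid optimum with a Nelder-Mead simplex on the same
#' objective, box-constrained to the grid bounds extended by one grid step on
#' each side (candidates outside the box score infinitely). The result never
#' has a worse objective than the seed.
#'
#' @param seed_result an `nbfix_fit` from [grid_fit()].
#' @param reltol relative convergence tolerance on the objective.
#' @return An `nbfix_fit` with `refined = TRUE`.
#' @export
refine_fit <- function(seed_result, reltol = 1e-12) {
  stopifnot(inherits(seed_result, "nbfix_fit"))
  f <- seed_result
  ev <- f$grid$eps_values; rv <- f$grid$rmin_values
  step_e <- if (length(ev) > 1) min(diff(sort(ev))) else 0.1
  step_r <- if (length(rv) > 1) min(diff(sort(rv))) else 0.01
  lo <- c(min(ev) - step_e, min(rv) - step_r)
  hi <- c(max(ev) + step_e, max(rv) + step_r)
  cache <- scan_cache(f$mol, f$configs, f$params, f$ion_type, f$pair_types)
  e_ref <- f$ref$energies - f$ref$energies[length(f$ref$energies)]
  w <- curve_weights(e_ref, f$weight_scheme)
  obj <- function(p) {
    if (any(p < lo) || any(p > hi)) return(Inf)
    cached_objective(cache, p[1], p[2], e_ref, w)
  }
  start <- c(f$best$well_depth, f$best$rmin)
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = 2000))
  # a second pass from the first optimum tightens convergence of the simplex
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(reltol = reltol, maxit = 2000))
  if (opt2$value < opt$value) opt <- opt2
  if (opt$value <= f$objective) {
    out <- new_nbfix_fit(opt$par[1], opt$par[2], opt$value, f$ref, f$mol,
                         f$ion_type, f$params, f$grid, f$weight_scheme,
                         f$pair_types, f$configs, refined = TRUE,
                         call = f$call)
  } else {
    out <- f
  }
  out$refined <- TRUE
  out
}

#' Locate the minimum of an energy curve
#'
#' Interpolates the minimum of a sampled curve. For coarsely sampled curves
#' a parabola is fitted through the lowest point and its two neighbours; for
#' densely sampled curves (5 points or more) the parabolic estimate is
#' polished by minimizing a cubic-spline interpolant over the bracketing
#' interval, which removes the bias a symmetric parabola picks up on an
#' asymmetric potential well. When the lowest point sits on a boundary of
#' the scan (e.g. a monotone curve) the endpoint is returned verbatim with
#' `boundary = TRUE`.
#'
#' @param curve an [as_energy_curve()] object with at least 3 points.
#' @return list with `location` (Angstrom), `depth` (kcal/mol), `boundary`.
#' @export
curve_minimum <- function(curve) {
  r <- curve$distances; e <- curve$energies
  n <- length(r)
  if (n < 3L) stop("curve_minimum needs at least 3 points")
  i <- which.min(e)
  if (i == 1L || i == n)
    return(list(location = r[i], depth = e[i], boundary = TRUE))
  if (n >= 5L) {
    sf <- stats::splinefun(r, e)
    opt <- stats::optimize(sf, interval = c(r[i - 1L], r[i + 1L]),
                           tol = 1e-10)
    return(list(location = opt$minimum, depth = opt$objective,
                boundary = FALSE))
  }
  x <- r[(i - 1):(i + 1)]; y <- e[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(y ~ x + I(x^2)))
  if (!is.finite(co[3]) || co[3] <= 0)
    return(list(location = r[i], depth = e[i], boundary = FALSE))
  loc <- -co[2] / (2 * co[3])
  list(location = unname(loc),
       depth = unname(co[1] - co[2]^2 / (4 * co[3])),
       boundary = FALSE)
}

#' @export
coef.nbfix_fit <- function(object, ...)
  c(well_depth = object$best$well_depth, rmin = object$best$rmin)

#' @export
residuals.nbfix_fit <- function(object, ...) object$residuals

#' @export
fitted.nbfix_fit <- function(object, ...) object$mm_curve$energies

#' Predict the corrected molecular-mechanics curve of a fit
#'
#' @param object an `nbfix_fit`.
#' @param distances anchor-ion distances at which to evaluate; defaults to the
#'   distances of the fitted reference curve.
#' @param ... unused.
#' @return An [as_energy_curve()] labelled `mm_nbfix`.
#' @export
predict.nbfix_fit <- function(object, distances = NULL, ...) {
  if (is.null(distances)) return(object$mm_curve)
  cfg <- approach_at(object$mol, distances)
  energy_curve(cfg, object$mol,
               merge_override(object$params, object$best), object$ion_type)
}

#' @export
print.nbfix_fit <- function(x, ...) {
  cat("Pair-specific Lennard-Jones (NBFIX) fit\n")
  cat(sprintf("  pair:       %s-%s (%s)\n", x$pair_types[1], x$pair_types[2],
              x$mol$label))
  cat(sprintf("  well depth: %.4g kcal/mol (dialect: -%.4g)\n",
              x$best$well_depth, x$best$well_depth))
  cat(sprintf("  Rmin:       %.4g Angstrom\n", x$best$rmin))
  cat(sprintf("  objective:  %.6g (%s weights%s)\n", x$objective,
              x$weight_scheme, if (x$refined) ", refined" else ", grid only"))
  invisible(x)
}

#' @export
summary.nbfix_fit <- function(object, ...) {
  mn <- curve_minimum(object$mm_curve)
  mr <- curve_minimum(object$ref)
  out <- list(fit = object,
              mm_min = mn, ref_min = mr,
              rms_resid = sqrt(mean(object$residuals^2)),
              max_abs_resid = max(abs(object$residuals)))
  class(out) <- "summary.nbfix_fit"
  out
}

#' @export
print.summary.nbfix_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  curve minimum (mm_nbfix): %.3f kcal/mol at %.3f A\n",
              x$mm_min$depth, x$mm_min$location))
  cat(sprintf("  curve minimum (reference): %.3f kcal/mol at %.3f A\n",
              x$ref_min$depth, x$ref_min$location))
  cat(sprintf("  residuals: rms %.4g, max |.| %.4g kcal/mol\n",
              x$rms_resid, x$max_abs_resid))
  invisible(x)
}

#' Plot a pair-override fit
#'
#' Draws the reference curve, the uncorrected molecular-mechanics curve and
#' the fitted (override) curve, all anchored to zero at the largest scanned
#' distance.
#'
#' @param x an `nbfix_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.nbfix_fit <- function(x, ...) {
  r <- x$ref$distances
  shift <- function(e) e - e[length(e)]
  base <- energy_curve(x$configs, x$mol,
                       with_override(x$params, empty_overrides()), x$ion_type)
  y <- cbind(shift(x$ref$energies), shift(base$energies),
             shift(x$mm_curve$energies))
  graphics::matplot(r, y, type = "l", lty = c(1, 2, 1), lwd = c(2, 1, 2),
                    col = c("blue", "red", "darkorange"),
                    xlab = "S - ion distance (Angstrom)",
                    ylab = "relative energy (kcal/mol)", ...)
  graphics::legend("bottomright", c("reference", "mm default", "mm NBFIX"),
                   lty = c(1, 2, 1), lwd = c(2, 1, 2),
                   col = c("blue", "red", "darkorange"), bty = "n")
  invisible(x)
}
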