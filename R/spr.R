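#' Surface plasmon resonance: 1:1 Langmuir kinetics with mass transport
#'
#' Simulation and global fitting of concentration-series sensorgrams under
#' the mass-transport-limited 1:1 binding model
#' `dR/dt = (ka C (Rmax - R) - kd R) / (1 + ka (Rmax - R) / kt)`,
#' integrated through an association phase (constant injected concentration C)
#' and a dissociation phase (C = 0). As `kt -> Inf` the model reduces to the
#' closed-form 1:1 solution `R(t) = Req (1 - exp(-(ka C + kd) t))` with
#' `Req = Rmax C / (C + Kd)`.
#'
#' @name spr_kinetics
NULL

#' Model response curve for one analyte concentration
#'
#' @param ka association rate constant, 1/(M s).
#' @param kd dissociation rate constant, 1/s.
#' @param Rmax surface capacity, RU.
#' @param kt mass-transport coefficient, RU/(M s); `Inf` disables transport
#'   limitation.
#' @param conc injected analyte concentration, M.
#' @param times output time grid, s (strictly increasing, starting at 0).
#' @param t_assoc association time, s; beyond it the concentration is 0.
#' @param R0 response at t = 0 (RU).
#' @param rtol,atol integration tolerances.
#' @return numeric vector of responses (RU) on `times`.
#' @export
model_response <- function(ka, kd, Rmax, conc, times, t_assoc,
                           kt = 1e7, R0 = 0, rtol = 1e-8, atol = 1e-10) {
  stopifnot(ka > 0, kd >= 0, Rmax > 0, t_assoc > 0)
  deriv <- function(t, y, parms) {
    C <- if (t <= t_assoc) conc else 0
    free <- max(Rmax - y[1L], 0)
    num <- ka * C * free - kd * y[1L]
    den <- if (is.finite(kt)) 1 + ka * free / kt else 1
    list(num / den)
  }
  # integrate the two phases separately so the injection stop is a hard event
  t1 <- times[times <= t_assoc]
  t2 <- times[times > t_assoc]
  out <- numeric(0)
  y_end <- R0
  if (length(t1)) {
    grid <- unique(c(0, t1))
    sol <- deSolve::lsoda(y = c(R = R0), times = grid, func = deriv,
                          parms = NULL, rtol = rtol, atol = atol)
    out <- sol[match(t1, grid), 2L]
    y_end <- sol[nrow(sol), 2L]
  }
  if (length(t2)) {
    grid <- unique(c(t_assoc, t2))
    sol <- deSolve::lsoda(y = c(R = y_end), times = grid, func = deriv,
                          parms = NULL, rtol = rtol, atol = atol)
    out <- c(out, sol[match(t2, grid), 2L])
  }
  as.numeric(out)
}

# vectorized variant: one state per concentration, shared time grid;
# returns a length(times) x length(concs) matrix stacked column-wise
model_response_multi <- function(ka, kd, Rmax, concs, times, t_assoc,
                                 kt = 1e7, rtol = 1e-8, atol = 1e-10) {
  nc <- length(concs)
  deriv <- function(t, y, parms) {
    C <- if (t <= t_assoc) concs else rep(0, nc)
    free <- pmax(Rmax - y, 0)
    num <- ka * C * free - kd * y
    den <- if (is.finite(kt)) 1 + ka * free / kt else rep(1, nc)
    list(num / den)
  }
  t1 <- times[times <= t_assoc]
  t2 <- times[times > t_assoc]
  out <- NULL
  y_end <- rep(0, nc)
  if (length(t1)) {
    grid <- unique(c(0, t1))
    sol <- deSolve::lsoda(y = y_end, times = grid, func = deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    out <- sol[match(t1, grid), -1L, drop = FALSE]
    y_end <- sol[nrow(sol), -1L]
  }
  if (length(t2)) {
    grid <- unique(c(t_assoc, t2))
    sol <- deSolve::lsoda(y = y_end, times = grid, func = deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    out <- rbind(out, sol[match(t2, grid), -1L, drop = FALSE])
  }
  out
}

#' The Biacore-style injection series used for the concentration presets
#' @keywords internal
.SPR_SERIES <- list(
  full = c(1000, 500, 250, 125, 62.5, 31.3, 15.6, 7.8, 7.8, 3.9, 1.95,
           0.98, 0.98, 0.48, 0.24, 0.12) * 1e-9,
  high_affinity = c(1.95, 0.98, 0.98, 0.48, 0.24, 0.12, 0) * 1e-9,
  reduced_affinity = c(62.5, 31.3, 15.6, 7.8, 7.8, 3.9, 1.95, 0.98, 0.98,
                       0.48, 0.24, 0.12) * 1e-9
)

#' Concentration presets for sensorgram series
#'
#' `"high_affinity"` is the low-concentration window used for tight binders
#' (<= 1.95 nM, duplicates included, plus a zero-concentration blank);
#' `"reduced_affinity"` is the <= 62.5 nM window; `"full"` is the complete
#' injection series.
#'
#' @param name preset name.
#' @return concentrations in M.
#' @export
spr_concentration_preset <- function(name = c("high_affinity",
                                              "reduced_affinity", "full")) {
  .SPR_SERIES[[match.arg(name)]]
}

#' Generate a noisy synthetic sensorgram series
#'
#' Numerically integrated mass-transport 1:1 curves plus seeded Gaussian
#' noise; bit-identical for identical specs.
#'
#' @param ka,kd,Rmax,kt kinetic parameters (see [model_response()]).
#' @param concentrations analyte concentrations, M.
#' @param t_assoc,t_dissoc phase durations, s.
#' @param dt time step of the output grid, s.
#' @param noise_sd Gaussian noise s.d., RU.
#' @param seed integer seed for the noise stream.
#' @return data.frame (long format): `curve_id`, `concentration_M`, `time_s`,
#'   `response_RU`; attribute `spec` records the generating parameters.
#' @export
generate_sensorgrams <- function(ka = 1e6, kd = 1.32e-3, Rmax = 50,
                                 kt = 1e7,
                                 concentrations = spr_concentration_preset("high_affinity"),
                                 t_assoc = 240, t_dissoc = 240, dt = 1,
                                 noise_sd = 0.5, seed = 1L) {
  stopifnot(ka > 0, kd > 0, Rmax > 0, kt > 0, t_assoc > 0, t_dissoc > 0)
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  curves <- lapply(seq_along(concentrations), function(i) {
    resp <- if (concentrations[i] == 0) rep(0, length(times))
    else model_response(ka, kd, Rmax, concentrations[i], times, t_assoc,
                        kt = kt)
    data.frame(curve_id = i, concentration_M = concentrations[i],
               time_s = times, response_RU = resp)
  })
  out <- do.call(rbind, curves)
  if (noise_sd > 0) {
    rng <- local({
      set.seed(as.integer(seed))
      stats::rnorm(nrow(out), sd = noise_sd)
    })
    out$response_RU <- out$response_RU + rng
  }
  attr(out, "spec") <- list(ka = ka, kd = kd, Rmax = Rmax, kt = kt,
                            t_assoc = t_assoc, t_dissoc = t_dissoc,
                            noise_sd = noise_sd, seed = seed)
  out
}

#' Double referencing of a sensorgram
#'
#' `corrected = sample - surface_control - mean(buffer blanks)`, the standard
#' correction removing bulk refractive-index steps and systematic drift.
#' Curves on different time grids are resampled by linear interpolation onto
#' the sample grid.
#'
#' @param sample data.frame with `time_s`, `response_RU`.
#' @param surface_control same layout (reference flow cell).
#' @param buffer_blanks list of data.frames (analyte-free injections); may be
#'   empty, in which case only the control is subtracted (with a warning).
#' @return data.frame `time_s`, `response_RU` (corrected).
#' @export
double_reference <- function(sample, surface_control, buffer_blanks = list()) {
  tgrid <- sample$time_s
  interp <- function(df) stats::approx(df$time_s, df$response_RU, xout = tgrid,
                                       rule = 2)$y
  corr <- sample$response_RU - interp(surface_control)
  if (length(buffer_blanks)) {
    bl <- rowMeans(do.call(cbind, lapply(buffer_blanks, interp)))
    corr <- corr - bl
  } else {
    warning("no buffer blanks supplied; control-only correction applied")
  }
  data.frame(time_s = tgrid, response_RU = corr)
}

#' Global 1:1 Langmuir fit of a sensorgram series
#'
#' Shared `ka`, `kd`, `Rmax` (and optionally `kt`) are fit across all curves
#' by Levenberg-Marquardt least squares on log-scale parameters.
#' Initialization combines a data-driven start (terminal dissociation decay
#' for `kd`, max response for `Rmax`) with an optional log-grid multistart
#' over `ka` in [1e3, 1e8] and `kd` in [1e-5, 1e-1]; the fit is deterministic
#' for a given configuration. The refractive-index (bulk) term is fixed at
#' zero and `kt` is fixed at 1e7 RU/(M s) unless `fix_kt = FALSE`.
#'
#' @param curves data.frame as from [generate_sensorgrams()] (columns
#'   `curve_id`, `concentration_M`, `time_s`, `response_RU`).
#' @param t_assoc association time, s.
#' @param fix_kt keep the transport coefficient fixed at `kt0`?
#' @param kt0 initial/fixed transport coefficient, RU/(M s).
#' @param multistart number of additional log-grid starts per axis (0 = only
#'   the data-driven start).
#' @param rtol integration tolerance used inside the fit.
#' @return list of class `kinetic_fit`: `ka`, `kd`, `Kd` (= kd/ka exactly),
#'   `Rmax`, `kt`, `residual_sse`, `per_curve_rmse`, `converged`.
#' @export
global_fit <- function(curves, t_assoc = 240, fix_kt = TRUE, kt0 = 1e7,
                       multistart = 2, rtol = 1e-8) {
  ids <- unique(curves$curve_id)
  conc <- vapply(ids, function(i)
    curves$concentration_M[curves$curve_id == i][1L], 0)
  use <- conc > 0
  if (sum(use) < 3L)
    stop("need >= 3 non-zero analyte concentrations for a global fit")
  if (max(conc[use]) / min(conc[use]) < 10)
    stop("concentration series must span at least 10-fold")
  sub <- curves[curves$curve_id %in% ids[use], , drop = FALSE]

  # all curves of a Biacore series share one clock; when they do, the whole
  # series is integrated as one vector ODE (much cheaper inside the fit)
  grids <- lapply(ids[use], function(i) sub$time_s[sub$curve_id == i])
  common_grid <- length(unique(vapply(grids, length, 0L))) == 1L &&
    all(vapply(grids[-1L], function(g) isTRUE(all.equal(g, grids[[1L]])), TRUE))
  predict_all <- function(ka, kd, Rmax, kt) {
    if (common_grid) {
      as.numeric(model_response_multi(ka, kd, Rmax, conc[use], grids[[1L]],
                                      t_assoc, kt = kt, rtol = rtol))
    } else {
      unlist(lapply(ids[use], function(i) {
        ci <- sub[sub$curve_id == i, , drop = FALSE]
        model_response(ka, kd, Rmax, ci$concentration_M[1L], ci$time_s,
                       t_assoc, kt = kt, rtol = rtol)
      }))
    }
  }
  obs <- unlist(lapply(ids[use], function(i)
    sub$response_RU[sub$curve_id == i]))

  # data-driven starts
  Rmax0 <- max(obs) * 1.2
  tail_kd <- {
    i <- ids[use][which.max(conc[use])]
    ci <- sub[sub$curve_id == i & sub$time_s > t_assoc, , drop = FALSE]
    pos <- ci$response_RU > max(ci$response_RU, 1e-6) * 0.05
    if (sum(pos) > 10) {
      f <- stats::lm(log(ci$response_RU[pos]) ~ ci$time_s[pos])
      max(min(-stats::coef(f)[2L], 0.1), 1e-5)
    } else 1e-3
  }
  starts <- list(c(log(1e6), log(tail_kd)))
  if (multistart > 0) {
    ka_grid <- 10^seq(3, 8, length.out = multistart + 1L)
    kd_grid <- 10^seq(-5, -1, length.out = multistart + 1L)
    for (ka0 in ka_grid) for (kd0 in kd_grid)
      starts[[length(starts) + 1L]] <- c(log(ka0), log(kd0))
  }
  resid_fn <- function(par) {
    ka <- exp(par[1L]); kd <- exp(par[2L]); Rmax <- exp(par[3L])
    kt <- if (fix_kt) kt0 else exp(par[4L])
    pred <- tryCatch(suppressWarnings(predict_all(ka, kd, Rmax, kt)),
                     error = function(e) NULL)
    if (is.null(pred) || length(pred) != length(obs) || !all(is.finite(pred)))
      return(rep(1e6, length(obs)))  # infeasible trial; steer away
    pred - obs
  }
  best <- NULL
  for (s in starts) {
    par0 <- c(s, log(Rmax0), if (!fix_kt) log(kt0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("global fit failed to converge from any start")
  p <- best$fit$par
  ka <- exp(p[1L]); kd <- exp(p[2L]); Rmax <- exp(p[3L])
  kt <- if (fix_kt) kt0 else exp(p[4L])
  res <- best$fit$fvec
  splits <- rep(ids[use], vapply(ids[use], function(i)
    sum(sub$curve_id == i), 0L))
  per_curve <- vapply(split(res, splits), function(r) sqrt(mean(r^2)), 0)
  structure(list(ka = ka, kd = kd, Kd = kd / ka, Rmax = Rmax, kt = kt,
                 fixed_kt = fix_kt, residual_sse = sum(res^2),
                 per_curve_rmse = per_curve,
                 converged = best$fit$info %in% 1:4,
                 n_curves = sum(use)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 Langmuir fit (%d curves): ka %.3g 1/(M s), kd %.3g 1/s, Kd %.3g M\n",
              x$n_curves, x$ka, x$kd, x$Kd))
  cat(sprintf("Rmax %.1f RU, kt %s, SSE %.3g RU^2, converged: %s\n",
              x$Rmax, if (x$fixed_kt) sprintf("%.1g (fixed)", x$kt)
              else sprintf("%.3g (fitted)", x$kt),
              x$residual_sse, x$converged))
  invisible(x)
}
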