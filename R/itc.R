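#' Parameters of a one-set-of-sites ITC experiment
#'
#' Bundles the thermodynamic parameters and injection schedule of a
#' perfusion-cell titration: `n` identical independent sites per
#' macromolecule, association constant `K` (1/M; `Kd = 1/K`), molar
#' enthalpy `delta_H` (cal per mol of injectant), cell volume `V0` (L),
#' cell concentration `Mt0` (M), syringe concentration `X0` (M) and the
#' injection volumes (L). `heat_offset` (cal/mol injectant) models the
#' heat-of-dilution baseline.
#'
#' @param n sites per macromolecule (> 0).
#' @param K association constant, 1/M (> 0).
#' @param delta_H cal/mol of injectant.
#' @param V0 cell volume in L (default 200 uL, a standard low-volume cell).
#' @param Mt0 cell (macromolecule) concentration, M.
#' @param X0 syringe (injectant) concentration, M.
#' @param injection_volumes vector of injection volumes in L (default
#'   nineteen 2.0 uL injections).
#' @param temperature K (default 293.15, i.e. 20 C).
#' @param heat_offset cal/mol injectant added to every injection.
#' @return An `itc_params` list.
#' @export
itc_params <- function(n = 1, K, delta_H, V0 = 200e-6, Mt0 = 30e-6,
                       X0 = 300e-6, injection_volumes = rep(2.0e-6, 19L),
                       temperature = 293.15, heat_offset = 0) {
  stopifnot(n > 0, K > 0, V0 > 0, Mt0 > 0, X0 > 0,
            all(injection_volumes > 0))
  structure(list(n = n, K = K, delta_H = delta_H, V0 = V0, Mt0 = Mt0,
                 X0 = X0, injection_volumes = injection_volumes,
                 temperature = temperature, heat_offset = heat_offset),
            class = "itc_params")
}

# Running total concentrations in a perfusion cell after a cumulative
# injected volume dV: injected material displaces cell contents, giving the
# standard corrections Mt = Mt0 (1 - dV/2V0)/(1 + dV/2V0) and
# Xt = X0 (dV/V0)/(1 + dV/2V0).
running_concentrations <- function(params, cum_volume) {
  f <- cum_volume / params$V0
  list(Mt = params$Mt0 * (1 - f / 2) / (1 + f / 2),
       Xt = params$X0 * f / (1 + f / 2))
}

#' Cumulative heat of a one-set-of-sites titration
#'
#' Closed-form cumulative heat content of the cell after a given injection,
#' with `Xt`, `Mt` the running total ligand and macromolecule
#' concentrations corrected for displaced volume:
#' `Q = (n Mt dH V0 / 2) (1 + Xt/(n Mt) + 1/(n K Mt)
#'        - sqrt((1 + Xt/(n Mt) + 1/(n K Mt))^2 - 4 Xt/(n Mt)))`.
#'
#' @param params an [itc_params()] object.
#' @param after_injection injection index (0 = before the first injection;
#'   defaults to the full schedule).
#' @return Cumulative heat(s) Q in cal, one per requested index.
#' @export
one_site_cumulative_heat <- function(params,
                                     after_injection =
                                       seq_along(params$injection_volumes)) {
  stopifnot(inherits(params, "itc_params"))
  if (any(after_injection < 0) ||
      any(after_injection > length(params$injection_volumes)))
    stop("injection index outside the schedule")
  vapply(after_injection, function(i) {
    if (i == 0) return(0)
    rc <- running_concentrations(params,
                                 sum(params$injection_volumes[seq_len(i)]))
    with(params, {
      a <- 1 + rc$Xt / (n * rc$Mt) + 1 / (n * K * rc$Mt)
      disc <- a^2 - 4 * rc$Xt / (n * rc$Mt)
      if (disc < 0) stop("negative discriminant in binding polynomial")
      (n * rc$Mt * delta_H * V0 / 2) * (a - sqrt(disc))
    })
  }, numeric(1L))
}

#' Per-injection heats of a one-set-of-sites titration
#'
#' Differences of [one_site_cumulative_heat()] with the displaced-volume
#' correction `dQ_i = Q_i - Q_{i-1} + (dV_i/V0)(Q_i + Q_{i-1})/2` (material
#' pushed out of an overfilled cell carries the average heat content), plus
#' the dilution offset `heat_offset * X0 * dV_i`.
#'
#' @param params an [itc_params()] object.
#' @return numeric vector of per-injection heats in cal.
#' @export
injection_heats <- function(params) {
  idx <- seq_along(params$injection_volumes)
  Q <- one_site_cumulative_heat(params, c(0L, idx))
  dv <- params$injection_volumes
  dQ <- Q[idx + 1L] - Q[idx] +
    (dv / params$V0) * (Q[idx + 1L] + Q[idx]) / 2
  dQ + params$heat_offset * params$X0 * dv
}

#' Simulate an ITC thermogram
#'
#' Forward one-set-of-sites model heats plus i.i.d. Gaussian noise. An
#' optional small pre-injection (0.4 uL by default, a standard practice to
#' purge the syringe tip) can be prepended; its heat is simulated like any
#' other and it is flagged for exclusion by [fit_one_site()].
#'
#' @param params an [itc_params()] object.
#' @param noise_sd Gaussian noise standard deviation in ucal (>= 0).
#' @param seed integer RNG seed for reproducibility.
#' @param first_small_injection prepend a purge injection of this volume
#'   in L (`NULL` to disable; default 0.4 uL).
#' @return A `thermogram`: list with `data` (data.frame: `injection`,
#'   `volume` L, `heat_ucal`, `ndh` cal/mol injectant, `exclude`) and
#'   `meta` (V0, Mt0, X0, temperature).
#' @export
simulate_thermogram <- function(params, noise_sd = 0, seed = 1L,
                                first_small_injection = 0.4e-6) {
  stopifnot(inherits(params, "itc_params"), noise_sd >= 0)
  p <- params
  first_excluded <- FALSE
  if (!is.null(first_small_injection) && first_small_injection > 0) {
    p$injection_volumes <- c(first_small_injection, p$injection_volumes)
    first_excluded <- TRUE
  }
  q_cal <- injection_heats(p)
  set.seed(as.integer(seed))
  heat_ucal <- q_cal * 1e6 + rnorm(length(q_cal), 0, noise_sd)
  dv <- p$injection_volumes
  thermogram(data.frame(injection = seq_along(dv), volume = dv,
                        heat_ucal = heat_ucal,
                        exclude = c(first_excluded,
                                    rep(FALSE, length(dv) - 1L))),
             meta = list(V0 = p$V0, Mt0 = p$Mt0, X0 = p$X0,
                         temperature = p$temperature,
                         truth = params))
}

#' Construct a thermogram object
#'
#' @param data data.frame with columns `injection` (strictly increasing),
#'   `volume` (L, > 0), `heat_ucal`; an optional logical `exclude` marks
#'   injections left out of fits (e.g. the purge injection).
#' @param meta list with at least `V0`, `Mt0`, `X0` (L, M, M).
#' @return A `thermogram` object; `ndh` (cal/mol injectant) is derived.
#' @export
thermogram <- function(data, meta) {
  need <- c("injection", "volume", "heat_ucal")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("thermogram lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(diff(data$injection) <= 0))
    stop("injection indices must be strictly increasing")
  if (any(data$volume <= 0)) stop("injection volumes must be positive")
  for (k in c("V0", "Mt0", "X0"))
    if (is.null(meta[[k]])) stop("thermogram metadata lacks ", k)
  if (is.null(data$exclude)) data$exclude <- FALSE
  data$ndh <- data$heat_ucal * 1e-6 / (data$volume * meta$X0)
  structure(list(data = data, meta = meta), class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("ITC thermogram: %d injections, cell %.0f uM / syringe %.0f uM in %.0f uL\n",
              nrow(x$data), x$meta$Mt0 * 1e6, x$meta$X0 * 1e6,
              x$meta$V0 * 1e6))
  invisible(x)
}

#' Read / write thermograms as delimited text plus JSON metadata
#'
#' CSV columns: `injection`, `volume_uL`, `heat_ucal` (and optional
#' `exclude`); the JSON sidecar holds `V0_uL`, `Mt0_uM`, `X0_uM`,
#' `temperature_K`.
#'
#' @param csv_path CSV file of injections.
#' @param meta_path JSON metadata file (default: `csv_path` with a
#'   `.json` extension).
#' @return A `thermogram` object.
#' @export
read_thermogram <- function(csv_path,
                            meta_path = sub("\\.[^.]+$", ".json",
                                            csv_path)) {
  d <- utils::read.csv(csv_path)
  m <- jsonlite::fromJSON(meta_path)
  thermogram(data.frame(injection = d$injection,
                        volume = d$volume_uL * 1e-6,
                        heat_ucal = d$heat_ucal,
                        exclude = if (!is.null(d$exclude))
                          as.logical(d$exclude) else FALSE),
             meta = list(V0 = m$V0_uL * 1e-6, Mt0 = m$Mt0_uM * 1e-6,
                         X0 = m$X0_uM * 1e-6,
                         temperature = m$temperature_K %||% 293.15))
}

#' @rdname read_thermogram
#' @param tg a `thermogram` object to write.
#' @export
write_thermogram <- function(tg, csv_path,
                             meta_path = sub("\\.[^.]+$", ".json",
                                             csv_path)) {
  utils::write.csv(data.frame(injection = tg$data$injection,
                              volume_uL = tg$data$volume * 1e6,
                              heat_ucal = tg$data$heat_ucal,
                              exclude = tg$data$exclude),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(list(V0_uL = tg$meta$V0 * 1e6,
                            Mt0_uM = tg$meta$Mt0 * 1e6,
                            X0_uM = tg$meta$X0 * 1e6,
                            temperature_K = tg$meta$temperature),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Fit the one-set-of-sites binding model to a thermogram
#'
#' Levenberg-Marquardt least squares on the per-injection heats with free
#' parameters (n, K, delta_H, heat offset); K is fitted on the log scale.
#' Default initial values follow standard thermogram heuristics: offset
#' from the final plateau, delta_H from the first included injection, n
#' from the molar ratio at the half-height of the transition, and K from
#' an assumed mid-range sigmoidicity. The first (purge) injection is
#' excluded by default. A Wiseman c-value (`n K Mt0`) outside [1, 1000]
#' is recorded as a low-information warning.
#'
#' @param tg a `thermogram`.
#' @param init optional [itc_params()] with starting values.
#' @param exclude_first drop the first injection (default TRUE).
#' @return An `itc_fit` object with estimates (`n_hat`, `K_hat`, `Kd_uM`,
#'   `delta_H_hat`, `offset_hat`), standard errors, `rss`, `converged`,
#'   `c_value` and fit warnings. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @export
fit_one_site <- function(tg, init = NULL, exclude_first = TRUE) {
  stopifnot(inherits(tg, "thermogram"))
  d <- tg$data
  use <- !d$exclude
  # the purge injection is the conventional exclusion; drop the first
  # injection only when no purge is flagged
  if (exclude_first && !any(d$exclude)) use[1L] <- FALSE
  if (sum(use) < 6L) stop("need at least 6 usable injections")
  obs <- d$heat_ucal
  vols <- d$volume
  make_params <- function(n, K, dH, off) {
    itc_params(n = n, K = K, delta_H = dH, V0 = tg$meta$V0,
               Mt0 = tg$meta$Mt0, X0 = tg$meta$X0,
               injection_volumes = vols,
               temperature = tg$meta$temperature %||% 293.15,
               heat_offset = off)
  }
  model_ucal <- function(n, K, dH, off)
    injection_heats(make_params(n, K, dH, off)) * 1e6
  if (is.null(init)) {
    ndh <- d$ndh[use]
    mr <- cumsum(vols * tg$meta$X0)[use] / (tg$meta$V0 * tg$meta$Mt0)
    off0 <- mean(tail(ndh, 3L))
    dH0 <- ndh[1L] - off0
    if (abs(dH0) < 1e-9) dH0 <- if (off0 < 0) -1000 else 1000
    half <- off0 + dH0 / 2
    cross <- which(if (dH0 < 0) ndh > half else ndh < half)[1L]
    n0 <- if (is.na(cross)) 1 else max(0.2, min(5, mr[cross]))
    K0 <- 50 / (n0 * tg$meta$Mt0)   # assume mid-range c ~ 50
    init <- make_params(n0, K0, dH0, off0)
  }
  resid_fn <- function(p) {
    obs[use] - model_ucal(abs(p[["n"]]) + 1e-12,
                          exp(p[["logK"]]), p[["dH"]], p[["off"]])[use]
  }
  # multi-start over the sigmoidicity guess: the K heuristic is the least
  # reliable initial value, so try a small c grid and keep the best RSS
  starts <- lapply(c(1, 0.1, 10), function(scale)
    c(n = init$n, logK = log(init$K * scale), dH = init$delta_H,
      off = init$heat_offset))
  fit <- NULL
  for (par0 in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$info %in% 1:4 &&
        (is.null(fit) || cand$deviance < fit$deviance - 1e-12))
      fit <- cand
  }
  converged <- !is.null(fit)
  warnings <- character()
  if (!converged)
    return(structure(list(converged = FALSE, warnings = "fit did not converge",
                          thermogram = tg), class = "itc_fit"))
  p <- fit$par
  n_hat <- abs(p[["n"]]); K_hat <- exp(p[["logK"]])
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4L),
                                              names(par0)))
  c_value <- n_hat * K_hat * tg$meta$Mt0
  if (is.finite(c_value) && (c_value < 1 || c_value > 1000))
    warnings <- c(warnings, sprintf(
      "c-value %.3g outside [1, 1000]: low-information titration regime",
      c_value))
  est <- list(n_hat = n_hat, K_hat = K_hat,
              Kd_uM = 1e6 / K_hat,
              delta_H_hat = p[["dH"]], offset_hat = p[["off"]])
  fitted_ucal <- model_ucal(n_hat, K_hat, p[["dH"]], p[["off"]])
  structure(c(est, list(
    se = list(n = se[["n"]],
              Kd_uM = if (is.finite(se[["logK"]]))
                (1e6 / K_hat) * se[["logK"]] else NA_real_,
              delta_H = se[["dH"]], offset = se[["off"]]),
    rss = sum(resid_fn(p)^2), converged = TRUE, c_value = c_value,
    warnings = warnings, used = use, fitted_ucal = fitted_ucal,
    thermogram = tg)), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!x$converged) {
    cat("One-set-of-sites ITC fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("One-set-of-sites ITC fit (%d injections used)\n",
              sum(x$used)))
  cat(sprintf("  n      = %.3f\n  Kd     = %.3g uM\n  dH     = %.3g cal/mol\n  offset = %.3g cal/mol\n",
              x$n_hat, x$Kd_uM, x$delta_H_hat, x$offset_hat))
  if (length(x$warnings)) cat("  warning:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  if (!object$converged) return(print(object))
  est <- data.frame(
    estimate = c(object$n_hat, object$Kd_uM, object$delta_H_hat,
                 object$offset_hat),
    se = c(object$se$n, object$se$Kd_uM, object$se$delta_H,
           object$se$offset),
    row.names = c("n", "Kd_uM", "delta_H", "offset"))
  cat("One-set-of-sites ITC fit\n")
  print(est)
  cat(sprintf("c-value %.3g, RSS %.4g ucal^2\n", object$c_value,
              object$rss))
  invisible(est)
}

#' @export
coef.itc_fit <- function(object, ...) {
  if (!object$converged) stop("fit did not converge")
  c(n = object$n_hat, K = object$K_hat, Kd_uM = object$Kd_uM,
    delta_H = object$delta_H_hat, offset = object$offset_hat)
}

#' @export
fitted.itc_fit <- function(object, ...) object$fitted_ucal

#' @export
residuals.itc_fit <- function(object, ...) {
  object$thermogram$data$heat_ucal - object$fitted_ucal
}

#' @export
predict.itc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  stopifnot(inherits(newdata, "thermogram"))
  p <- itc_params(n = object$n_hat, K = object$K_hat,
                  delta_H = object$delta_H_hat, V0 = newdata$meta$V0,
                  Mt0 = newdata$meta$Mt0, X0 = newdata$meta$X0,
                  injection_volumes = newdata$data$volume,
                  heat_offset = object$offset_hat)
  injection_heats(p) * 1e6
}

#' @export
plot.itc_fit <- function(x, ...) {
  d <- x$thermogram$data
  mr <- cumsum(d$volume * x$thermogram$meta$X0) /
    (x$thermogram$meta$V0 * x$thermogram$meta$Mt0)
  plot(mr, d$ndh, xlab = "molar ratio (injectant/cell)",
       ylab = "heat (cal/mol injectant)",
       pch = ifelse(x$used, 19, 1), ...)
  if (x$converged)
    lines(mr, x$fitted_ucal * 1e-6 / (d$volume * x$thermogram$meta$X0),
          col = 2)
  invisible(x)
}

#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 0,
                             ...) {
  if (!object$converged) stop("fit did not converge")
  if (!is.null(seed)) set.seed(seed)
  tg <- object$thermogram
  p <- itc_params(n = object$n_hat, K = object$K_hat,
                  delta_H = object$delta_H_hat, V0 = tg$meta$V0,
                  Mt0 = tg$meta$Mt0, X0 = tg$meta$X0,
                  injection_volumes = tg$data$volume,
                  heat_offset = object$offset_hat)
  lapply(seq_len(nsim), function(i)
    simulate_thermogram(p, noise_sd = noise_sd,
                        seed = sample.int(.Machine$integer.max, 1L),
                        first_small_injection = NULL))
}

#' Fold reduction in affinity relative to wild type
#'
#' `Kd_mutant / Kd_wildtype`, the convention for reporting mutant binding
#' panels. A non-binding mutant (no converged fit possible, passed as
#' `NULL`) is reported as the sentinel `"ND"` (not determined), never as
#' infinity.
#'
#' @param fit_mutant an `itc_fit`, or `NULL` for a non-binder.
#' @param fit_wildtype a converged `itc_fit`.
#' @return numeric ratio, or the character `"ND"` for a non-binder.
#' @export
fold_reduction <- function(fit_mutant, fit_wildtype) {
  stopifnot(inherits(fit_wildtype, "itc_fit"))
  if (!fit_wildtype$converged) stop("wild-type fit did not converge")
  if (is.null(fit_mutant)) return("ND")
  stopifnot(inherits(fit_mutant, "itc_fit"))
  if (!fit_mutant$converged) stop("mutant fit did not converge")
  fit_mutant$Kd_uM / fit_wildtype$Kd_uM
}

#' Average replicate dissociation constants
#'
#' Arithmetic mean and half-range across replicate fits, the convention
#' for reporting duplicate titrations as `mean +/- half-range`.
#'
#' @param fits list of converged `itc_fit` objects.
#' @return list with `Kd_uM` (mean) and `half_range_uM`.
#' @export
average_replicates <- function(fits) {
  kds <- vapply(fits, function(f) {
    if (!f$converged) stop("unconverged replicate")
    f$Kd_uM
  }, numeric(1L))
  list(Kd_uM = mean(kds), half_range_uM = diff(range(kds)) / 2)
}
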