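#' @title Steady-state and inhibition kinetics
#'
#' @description
#' Initial velocities are obtained from absorbance slopes via Beer-Lambert,
#' fitted to the Michaelis-Menten model `v = kcat*S/(Km + S)` and, in the
#' presence of an inhibitor at concentration `Ic`, to the competitive
#' `v = kcat*S / (Km*(1 + Ic/Ki) + S)` or non-competitive
#' `v = kcat*S / ((1 + Ic/Ki)*(Km + S))` rate laws by a single global
#' nonlinear least-squares fit across all inhibitor series. Model
#' discrimination uses small-sample-corrected AIC (AICc), with
#' Lineweaver-Burk double-reciprocal plots as the classical diagnostic:
#' competitive series share the y-intercept `1/kcat`, non-competitive series
#' share the x-intercept `-1/Km`.
#'
#' Units: substrate and inhibitor concentrations in mM, velocities in
#' mM/min, or in s^-1 (turnover) when normalised by enzyme concentration;
#' `kcat` then carries the velocity's unit and `Km`/`Ki` are in mM.
#' @name kinetics
NULL

#' Assay specification for absorbance-to-rate conversion
#'
#' @param extinction molar extinction coefficient of the monitored product,
#'   1/(M cm)
#' @param wavelength monitoring wavelength, nm (bookkeeping only)
#' @param path_length optical path, cm
#' @param enzyme_concentration molar enzyme concentration; when given,
#'   velocities are also expressed as turnover in 1/s
#' @return an object of class `assay_spec`
#' @export
assay_spec <- function(extinction, wavelength = NA_real_, path_length = 1,
                       enzyme_concentration = NULL) {
  if (!is.numeric(extinction) || extinction <= 0)
    stop("extinction coefficient must be > 0", call. = FALSE)
  if (path_length <= 0) stop("path length must be > 0", call. = FALSE)
  structure(list(extinction = extinction, wavelength = wavelength,
                 path_length = path_length,
                 enzyme_concentration = enzyme_concentration),
            class = "assay_spec")
}

#' Convert an absorbance slope to an initial velocity
#'
#' Beer-Lambert: `v = slope / (extinction * path)`.
#'
#' @param slope absorbance change per minute
#' @param assay an [assay_spec()]
#' @return list with `M_per_min`, `mM_per_min` and, when the enzyme
#'   concentration is known, `turnover_per_s`
#' @export
rate_from_absorbance <- function(slope, assay) {
  stopifnot(inherits(assay, "assay_spec"))
  v <- slope / (assay$extinction * assay$path_length)   # M/min
  out <- list(M_per_min = v, mM_per_min = 1e3 * v)
  if (!is.null(assay$enzyme_concentration))
    out$turnover_per_s <- v / 60 / assay$enzyme_concentration
  out
}

#' Extinction coefficient from a spectrum point
#'
#' Inverse Beer-Lambert: `extinction = A / (concentration * path)`.
#'
#' @param absorbance measured absorbance
#' @param concentration molar concentration of the absorbing species
#' @param path_length optical path, cm
#' @return extinction coefficient, 1/(M cm)
#' @export
extinction_from_spectrum <- function(absorbance, concentration,
                                     path_length = 1) {
  if (concentration <= 0)
    stop("concentration must be > 0", call. = FALSE)
  absorbance / (concentration * path_length)
}

.kin_cols <- c("substrate_mM", "inhibitor_mM", "velocity")

.check_kinetic_data <- function(data, need_inhibitor = FALSE) {
  stopifnot(is.data.frame(data))
  if (!"inhibitor_mM" %in% names(data)) data$inhibitor_mM <- 0
  missing <- setdiff(.kin_cols, names(data))
  if (length(missing))
    stop("kinetic table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(data$substrate_mM <= 0))
    stop("substrate concentrations must be > 0", call. = FALSE)
  if (any(data$inhibitor_mM < 0))
    stop("inhibitor concentrations must be >= 0", call. = FALSE)
  if (need_inhibitor && !any(data$inhibitor_mM == 0))
    stop("inhibition fits need an uninhibited (Ic = 0) series", call. = FALSE)
  data
}

.r_squared <- function(observed, fitted) {
  1 - sum((observed - fitted)^2) / sum((observed - mean(observed))^2)
}

# Levenberg-Marquardt least squares via minpack.lm::nls.lm. Gaussian
# log-likelihood, AICc (k counts the residual variance) and Jacobian-based
# standard errors are computed from the solution; a parameter pinned at a
# bound can make the Jacobian rank-deficient, in which case the standard
# errors are reported as NA rather than failing the fit.
.ls_fit <- function(model_fn, start, data, lower, upper) {
  resid_fn <- function(par) data$velocity - model_fn(par, data)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4)
    stop("nonlinear least squares did not converge: ", fit$message,
         call. = FALSE)
  est <- fit$par
  n <- nrow(data)
  p <- length(est)
  rss <- sum(fit$fvec^2)
  sigma2 <- rss / (n - p)
  se <- tryCatch(sqrt(diag(sigma2 * chol2inv(chol(fit$hessian / 2)))),
                 error = function(e) rep(NA_real_, p))
  names(se) <- names(est)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- p + 1L
  aicc <- 2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
  fitted <- model_fn(est, data)
  list(coef = unlist(est), se = se, fitted = fitted,
       r_squared = .r_squared(data$velocity, fitted),
       rss = rss, aicc = aicc, converged = TRUE, fit = fit)
}

#' Fit the Michaelis-Menten model
#'
#' Nonlinear least squares with starting values `Km = median(S)`,
#' `kcat = 1.2 * max(v)`. Standard errors come from the Jacobian-based
#' parameter covariance at the optimum; 95% limits are `+/- 1.96 se`.
#'
#' @param data data frame with columns `substrate_mM` and `velocity`
#'   (an `inhibitor_mM` column, if present, is ignored — the model is shared
#'   across series)
#' @return an object of class `mal_mm_fit`: `kcat`, `Km`, `se`,
#'   `r_squared`, `aicc`, `converged`, `valid`, and the underlying `fit`
#' @export
fit_michaelis_menten <- function(data) {
  data <- .check_kinetic_data(data)
  if (length(unique(data$substrate_mM)) < 4L)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  start <- list(kcat = 1.2 * max(data$velocity),
                Km = stats::median(data$substrate_mM))
  fit <- tryCatch(
    .ls_fit(function(par, d)
              par$kcat * d$substrate_mM / (par$Km + d$substrate_mM),
            start, data,
            lower = c(kcat = 1e-12, Km = 1e-12),
            upper = c(kcat = Inf, Km = Inf)),
    error = function(e) stop("Michaelis-Menten fit failed: ",
                             conditionMessage(e), call. = FALSE))
  structure(list(kcat = unname(fit$coef["kcat"]), Km = unname(fit$coef["Km"]),
                 se = fit$se, r_squared = fit$r_squared, aicc = fit$aicc,
                 converged = fit$converged,
                 valid = all(fit$coef > 0), fit = fit$fit),
            class = "mal_mm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mal_mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: kcat %.3g +/- %.2g, Km %.3g +/- %.2g mM, R2 %.4f\n",
              x$kcat, x$se["kcat"], x$Km, x$se["Km"], x$r_squared))
  invisible(x)
}

.inhibition_model_fn <- function(model) {
  switch(model,
    competitive = function(par, d)
      par$kcat * d$substrate_mM /
        (par$Km * (1 + d$inhibitor_mM / par$Ki) + d$substrate_mM),
    noncompetitive = function(par, d)
      par$kcat * d$substrate_mM /
        ((1 + d$inhibitor_mM / par$Ki) * (par$Km + d$substrate_mM)))
}

.KI_UPPER <- 1e8   # mM; a fit pinned here signals no measurable inhibition

#' Globally fit an inhibition model
#'
#' One nonlinear least-squares fit of `kcat`, `Km` and `Ki` across all
#' (substrate, inhibitor) points. A fitted `Ki` at the upper bound (1e8 mM)
#' is flagged as a no-inhibition indication. With a single inhibitor level
#' (Ic = 0 only) `Ki` is unidentifiable: the fit degenerates to
#' Michaelis-Menten and is flagged.
#'
#' @param data data frame with `substrate_mM`, `inhibitor_mM`, `velocity`
#' @param model `"competitive"` or `"noncompetitive"`
#' @return an object of class `mal_inhibition_fit`: `model`, `kcat`, `Km`,
#'   `Ki`, `se`, `global_r_squared`, `aicc`, flags `ki_identifiable` and
#'   `no_inhibition`, and the underlying `fit`
#' @export
fit_inhibition <- function(data, model = c("competitive", "noncompetitive")) {
  model <- match.arg(model)
  data <- .check_kinetic_data(data, need_inhibitor = TRUE)
  if (length(unique(data$inhibitor_mM)) < 2L) {
    mm <- fit_michaelis_menten(data)
    return(structure(list(model = model, kcat = mm$kcat, Km = mm$Km,
                          Ki = NA_real_, se = mm$se,
                          global_r_squared = mm$r_squared, aicc = mm$aicc,
                          ki_identifiable = FALSE, no_inhibition = NA,
                          fit = mm$fit),
                     class = "mal_inhibition_fit"))
  }
  if (length(unique(data$substrate_mM)) < 4L)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  start <- list(kcat = 1.2 * max(data$velocity),
                Km = stats::median(data$substrate_mM),
                Ki = stats::median(data$inhibitor_mM[data$inhibitor_mM > 0]))
  fit <- tryCatch(
    .ls_fit(.inhibition_model_fn(model), start, data,
            lower = c(kcat = 1e-12, Km = 1e-12, Ki = 1e-12),
            upper = c(kcat = Inf, Km = Inf, Ki = .KI_UPPER)),
    error = function(e) stop(model, " inhibition fit failed: ",
                             conditionMessage(e), call. = FALSE))
  est <- fit$coef
  structure(list(model = model,
                 kcat = unname(est["kcat"]), Km = unname(est["Km"]),
                 Ki = unname(est["Ki"]), se = fit$se,
                 global_r_squared = fit$r_squared,
                 aicc = fit$aicc, ki_identifiable = TRUE,
                 no_inhibition = unname(est["Ki"]) >= 0.99 * .KI_UPPER,
                 fit = fit$fit),
            class = "mal_inhibition_fit")
}

#' @export
print.mal_inhibition_fit <- function(x, ...) {
  cat(sprintf("%s inhibition fit: kcat %.3g, Km %.3g mM, Ki %.3g mM, global R2 %.4f\n",
              x$model, x$kcat, x$Km, x$Ki, x$global_r_squared))
  invisible(x)
}

#' Discriminate the inhibition mechanism
#'
#' Fits plain Michaelis-Menten (parameters shared across all inhibitor
#' series), competitive and non-competitive models, and selects by smallest
#' AICc. `"none"` is declared when neither inhibition model improves AICc
#' over plain Michaelis-Menten by more than `aicc_margin`, or when the best
#' inhibition fit runs to the no-inhibition boundary.
#'
#' @param data data frame with `substrate_mM`, `inhibitor_mM`, `velocity`
#' @param aicc_margin required AICc improvement over the no-inhibition model
#' @return a `mal_inhibition_fit` whose `model` is the selected mechanism
#'   (possibly `"none"`), with an `aicc_table` attribute listing all models
#' @export
classify_inhibition <- function(data, aicc_margin = 2) {
  data <- .check_kinetic_data(data, need_inhibitor = TRUE)
  mm <- fit_michaelis_menten(data)
  comp <- fit_inhibition(data, "competitive")
  nonc <- fit_inhibition(data, "noncompetitive")
  aicc <- c(none = mm$aicc, competitive = comp$aicc,
            noncompetitive = nonc$aicc)
  best_inh <- if (comp$aicc <= nonc$aicc) comp else nonc
  chosen <- if (isTRUE(best_inh$no_inhibition) ||
                mm$aicc - best_inh$aicc <= aicc_margin) {
    structure(list(model = "none", kcat = mm$kcat, Km = mm$Km,
                   Ki = Inf, se = mm$se, global_r_squared = mm$r_squared,
                   aicc = mm$aicc, ki_identifiable = FALSE,
                   no_inhibition = TRUE, fit = mm$fit),
              class = "mal_inhibition_fit")
  } else best_inh
  attr(chosen, "aicc_table") <- aicc
  chosen
}

#' Lineweaver-Burk double-reciprocal series
#'
#' For each inhibitor level, fits `1/v ~ 1/S` by ordinary least squares and
#' reports slope, y-intercept and x-intercept. Non-positive velocities are
#' excluded with a warning. The intercept pattern is labelled: a common
#' y-intercept across inhibitor levels indicates competitive inhibition, a
#' common x-intercept non-competitive inhibition.
#'
#' @param data data frame with `substrate_mM`, `inhibitor_mM`, `velocity`
#' @param tol relative spread below which intercepts count as common
#' @return an object of class `mal_lb`: per-level data frame (`inhibitor_mM`,
#'   `slope`, `y_intercept`, `x_intercept`, `n`) with attributes
#'   `y_intercept_spread`, `x_intercept_spread` and `pattern`
#' @export
lineweaver_burk <- function(data, tol = 1e-6) {
  data <- .check_kinetic_data(data)
  bad <- data$velocity <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive velocities excluded from ",
            "double-reciprocal analysis", call. = FALSE)
    data <- data[!bad, , drop = FALSE]
  }
  levels <- sort(unique(data$inhibitor_mM))
  rows <- lapply(levels, function(ic) {
    d <- data[data$inhibitor_mM == ic, , drop = FALSE]
    fit <- stats::lm(I(1 / velocity) ~ I(1 / substrate_mM), data = d)
    b <- unname(stats::coef(fit))
    data.frame(inhibitor_mM = ic, slope = b[2], y_intercept = b[1],
               x_intercept = -b[1] / b[2], n = nrow(d))
  })
  series <- do.call(rbind, rows)
  rel_spread <- function(x)
    if (length(x) < 2L) 0 else diff(range(x)) / max(abs(x))
  ys <- rel_spread(series$y_intercept)
  xs <- rel_spread(series$x_intercept)
  pattern <- if (nrow(series) < 2L) "single series"
    else if (ys <= tol) "competitive (common y-intercept)"
    else if (xs <= tol) "noncompetitive (common x-intercept)"
    else "mixed or noisy"
  structure(series, class = c("mal_lb", "data.frame"),
            y_intercept_spread = ys, x_intercept_spread = xs,
            pattern = pattern)
}

#' Plot Lineweaver-Burk series
#'
#' @param x a `mal_lb` object
#' @param data the kinetic data the series were fitted from (points)
#' @param ... passed to [graphics::plot()]
#' @export
plot.mal_lb <- function(x, data = NULL, ...) {
  xr <- c(0, max(1 / 1e-9, 1.2 / min(x$x_intercept)))
  if (!is.null(data)) xr <- range(0, 1 / data$substrate_mM)
  graphics::plot(NA, xlim = xr,
                 ylim = range(0, x$y_intercept + x$slope * xr[2]),
                 xlab = "1/[S] (1/mM)", ylab = "1/v", ...)
  for (i in seq_len(nrow(x)))
    graphics::abline(x$y_intercept[i], x$slope[i], col = i)
  if (!is.null(data))
    graphics::points(1 / data$substrate_mM, 1 / data$velocity,
                     col = as.integer(factor(data$inhibitor_mM)))
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat turnover number (or a `mal_mm_fit`, in which case `Km` is
#'   taken from the fit)
#' @param Km Michaelis constant, mM
#' @return `kcat/Km` to 3 significant figures
#' @export
efficiency <- function(kcat, Km = NULL) {
  if (inherits(kcat, "mal_mm_fit")) {
    Km <- kcat$Km; kcat <- kcat$kcat
  }
  signif(kcat / Km, 3)
}

#' Fold change between two constants
#'
#' @param a,b values to compare
#' @return `a / b`
#' @export
fold_change <- function(a, b) {
  if (any(b == 0)) stop("fold change undefined for zero reference",
                        call. = FALSE)
  a / b
}

#' Read a kinetics table
#'
#' Delimited file with columns `substrate_mM`, `inhibitor_mM`, `velocity`
#' and optionally `replicate`; the separator is taken from the file
#' extension (`.tsv` = tab, otherwise comma).
#'
#' @param path input file
#' @return data frame
#' @export
read_kinetics <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  .check_kinetic_data(utils::read.table(path, header = TRUE, sep = sep,
                                        stringsAsFactors = FALSE))
}

#' Write an inhibition fit report as JSON
#'
#' @param fit a `mal_inhibition_fit` or `mal_mm_fit`
#' @param path output JSON path
#' @return the fit, invisibly
#' @export
write_fit_report <- function(fit, path) {
  report <- list(model = fit$model %||% "michaelis-menten",
                 kcat = fit$kcat, Km = fit$Km, Ki = fit$Ki,
                 se = as.list(fit$se),
                 conf95 = as.list(1.96 * fit$se),
                 global_r_squared = fit$global_r_squared %||% fit$r_squared,
                 aicc = as.list(attr(fit, "aicc_table") %||% fit$aicc))
  report$Ki <- if (is.null(report$Ki) || !is.finite(report$Ki)) NULL else report$Ki
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(fit)
}
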