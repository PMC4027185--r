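#' Michaelis-Menten velocity
#'
#' @param Vmax Maximal velocity (uM s^-1).
#' @param Km Michaelis constant (mM), > 0.
#' @param S Substrate concentration (mM), >= 0; vectorised.
#' @return Initial velocity `Vmax * S / (Km + S)`.
#' @export
mm_velocity <- function(Vmax, Km, S) {
  if (any(Km <= 0)) abort("Km must be > 0")
  if (any(S < 0)) abort("S must be >= 0")
  Vmax * S / (Km + S)
}

#' Read a velocity table
#'
#' TSV with columns `enzyme`, `S_mM`, `v_uM_per_s` and optionally
#' `replicate`. Comma decimal separators are accepted on input (values are
#' normalised to dot decimals).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `enzyme`, `S`, `v`, `replicate`.
#' @export
read_velocity_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = "character")
  num <- function(x) as.numeric(gsub(",", ".", x, fixed = TRUE))
  tibble(
    enzyme = df$enzyme,
    S = num(df$S_mM),
    v = num(df$v_uM_per_s),
    replicate = if ("replicate" %in% names(df)) {
      as.integer(df$replicate)
    } else 1L
  )
}

#' Fit the Michaelis-Menten equation by nonlinear least squares
#'
#' Initialisation: `Vmax0 = max(v)`, `Km0 = S` at the observation whose
#' velocity is nearest `Vmax0 / 2`. On failure, up to two jittered restarts
#' are attempted (deterministic given `data` and `restart_seed`).
#'
#' @param data A tibble with columns `S` (mM) and `v` (uM s^-1); a
#'   `replicate` column is carried through but not used in the loss.
#' @param enzyme Optional enzyme label stored in the fit.
#' @param restart_seed Seed for jittered restarts.
#' @return An object of class `mm_fit` with fields `Km`, `Vmax`, `Km_se`,
#'   `Vmax_se`, `kcat`, `kcat_se`, `kcat_over_Km`, `rss`, `n_points`,
#'   `converged`, `detectable`.
#' @export
fit_mm <- function(data, enzyme = NA_character_, restart_seed = 1L) {
  if (length(unique(data$S)) < 3) {
    abort("need at least 3 distinct substrate concentrations")
  }
  if (any(data$S <= 0)) abort("substrate concentrations must be > 0")
  if (any(data$v < 0)) abort("velocities must be >= 0")
  v0 <- max(data$v)
  km0 <- data$S[which.min(abs(data$v - v0 / 2))]
  starts <- list(c(Vmax = v0, Km = km0))
  withr::with_seed(restart_seed, {
    for (k in 1:2) {
      starts[[k + 1]] <- c(
        Vmax = v0 * exp(rnorm(1, 0, 0.3)),
        Km = km0 * exp(rnorm(1, 0, 0.5))
      )
    }
  })
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ Vmax * S / (Km + S), data = data,
        start = as.list(st),
        lower = c(Vmax = 0, Km = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(
      list(enzyme = enzyme, Km = NA_real_, Vmax = NA_real_,
           Km_se = NA_real_, Vmax_se = NA_real_, kcat = NA_real_,
           kcat_se = NA_real_, kcat_over_Km = NA_real_, rss = NA_real_,
           n_points = nrow(data), converged = FALSE, detectable = TRUE,
           data = data),
      class = "mm_fit"
    ))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  structure(
    list(
      enzyme = enzyme,
      Km = unname(est["Km"]), Vmax = unname(est["Vmax"]),
      Km_se = unname(se["Km"]), Vmax_se = unname(se["Vmax"]),
      kcat = NA_real_, kcat_se = NA_real_, kcat_over_Km = NA_real_,
      rss = sum(stats::resid(fit)^2),
      n_points = nrow(data),
      converged = fit$convInfo$isConv %||% TRUE,
      detectable = TRUE,
      data = data
    ),
    class = "mm_fit"
  )
}

#' Represent an enzyme with activity below assay background
#'
#' Undetectable activity is a distinct state, never coded as zero
#' parameters.
#'
#' @param enzyme Enzyme label.
#' @return An `mm_fit` with `detectable = FALSE` and `NA` parameters.
#' @export
undetectable_fit <- function(enzyme) {
  structure(
    list(enzyme = enzyme, Km = NA_real_, Vmax = NA_real_, Km_se = NA_real_,
         Vmax_se = NA_real_, kcat = NA_real_, kcat_se = NA_real_,
         kcat_over_Km = NA_real_, rss = NA_real_, n_points = 0L,
         converged = NA, detectable = FALSE, data = NULL),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!isTRUE(x$detectable)) {
    cat(sprintf("<mm_fit> %s  activity below background (undetectable)\n",
                x$enzyme))
    return(invisible(x))
  }
  cat(sprintf(
    "<mm_fit> %s  Km = %.4g mM (se %.2g), Vmax = %.4g uM/s (se %.2g)%s\n",
    x$enzyme %||% "", x$Km, x$Km_se, x$Vmax, x$Vmax_se,
    if (!is.na(x$kcat)) {
      sprintf(", kcat = %.4g /s, kcat/Km = %.4g /s/uM", x$kcat,
              x$kcat_over_Km)
    } else ""
  ))
  invisible(x)
}

#' Catalytic efficiency from kcat and Km
#'
#' `Km` is in mM and the efficiency is reported per uM, so the ratio
#' carries a factor of 1000: `kcat / (Km * 1000)`.
#'
#' @param kcat Turnover number (s^-1); vectorised.
#' @param Km_mM Michaelis constant in mM.
#' @return Efficiency in s^-1 uM^-1.
#' @export
catalytic_efficiency <- function(kcat, Km_mM) {
  if (any(Km_mM <= 0)) abort("Km must be > 0")
  kcat / (Km_mM * 1000)
}

#' Populate kcat and kcat/Km on a fit
#'
#' `kcat` is either supplied directly or derived as `Vmax / [E]` from the
#' enzyme molar concentration (both in uM and uM s^-1, giving s^-1).
#'
#' @param fit An `mm_fit`.
#' @param kcat Optional turnover number (s^-1).
#' @param enzyme_conc_uM Optional enzyme molar concentration (uM).
#' @return The fit with `kcat` and `kcat_over_Km` populated.
#' @export
derive_efficiency <- function(fit, kcat = NULL, enzyme_conc_uM = NULL) {
  if (!isTRUE(fit$detectable)) return(fit)
  if (is.null(kcat)) {
    if (is.null(enzyme_conc_uM)) {
      abort("supply kcat directly or enzyme_conc_uM to derive it from Vmax")
    }
    kcat <- fit$Vmax / enzyme_conc_uM
  }
  fit$kcat <- kcat
  fit$kcat_over_Km <- catalytic_efficiency(kcat, fit$Km)
  fit
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("Km", "Vmax"),
    estimate = c(x$Km, x$Vmax),
    std.error = c(x$Km_se, x$Vmax_se)
  )
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble(
    enzyme = x$enzyme, Km = x$Km, Km_se = x$Km_se, Vmax = x$Vmax,
    Vmax_se = x$Vmax_se, kcat = x$kcat, kcat_over_Km = x$kcat_over_Km,
    rss = x$rss, n_points = x$n_points, converged = x$converged,
    detectable = x$detectable
  )
}

#' @export
autoplot.mm_fit <- function(object, ...) {
  if (!isTRUE(object$detectable) || is.null(object$data)) {
    abort("nothing to plot for an undetectable fit")
  }
  grid <- tibble(S = seq(min(object$data$S), max(object$data$S),
                         length.out = 200))
  grid$v <- mm_velocity(object$Vmax, object$Km, grid$S)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$S, y = .data$v)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      title = object$enzyme %||% "Michaelis-Menten fit",
      subtitle = sprintf("Km = %.4g mM, Vmax = %.4g uM/s", object$Km,
                         object$Vmax),
      x = "[S] (mM)", y = "v (uM/s)"
    ) +
    ggplot2::theme_minimal()
}

#' Kinetics summary table over several fits
#'
#' Mirrors the usual kinetic-parameter table layout (Km +/- se, Vmax +/-
#' se, kcat, kcat/Km); undetectable enzymes print `U`.
#'
#' @param fits List of `mm_fit` objects.
#' @return A tibble, one row per enzyme.
#' @export
kinetics_table <- function(fits) {
  bind_rows(lapply(fits, function(f) {
    if (!isTRUE(f$detectable)) {
      tibble(enzyme = f$enzyme, Km = "U", Vmax = "U", kcat = "U",
             kcat_over_Km = "U")
    } else {
      tibble(
        enzyme = f$enzyme,
        Km = sprintf("%.4f ± %.3f", f$Km, f$Km_se),
        Vmax = sprintf("%.4f ± %.4f", f$Vmax, f$Vmax_se),
        kcat = if (is.na(f$kcat)) NA_character_ else sprintf("%.1f", f$kcat),
        kcat_over_Km = if (is.na(f$kcat_over_Km)) NA_character_ else {
          sprintf("%.3f", f$kcat_over_Km)
        }
      )
    }
  }))
}

#' Compare a kinetic parameter between two groups of fits
#'
#' Equal-variance two-sample Student's t-test on the chosen parameter
#' across replicate fits.
#'
#' @param fits_a,fits_b Lists of `mm_fit` objects (>= 2 each).
#' @param parameter `"Km"` or `"Vmax"`.
#' @return A tibble with `statistic`, `p.value`, `df`, `estimate_a`,
#'   `estimate_b`.
#' @export
compare_fits <- function(fits_a, fits_b, parameter = c("Km", "Vmax")) {
  parameter <- match.arg(parameter)
  xa <- vapply(fits_a, function(f) f[[parameter]], numeric(1))
  xb <- vapply(fits_b, function(f) f[[parameter]], numeric(1))
  if (length(xa) < 2 || length(xb) < 2) {
    abort("need at least 2 fits per group")
  }
  tt <- t.test(xa, xb, var.equal = TRUE)
  tibble(
    parameter = parameter,
    statistic = unname(tt$statistic),
    p.value = tt$p.value,
    df = unname(tt$parameter),
    estimate_a = mean(xa),
    estimate_b = mean(xb)
  )
}

#' Initial slope of a linear time course
#'
#' Least-squares slope of `signal ~ time`, optionally converted to a
#' concentration rate by a user-supplied extinction coefficient
#' (slope / epsilon).
#'
#' @param time,signal Numeric vectors.
#' @param extinction_coeff Optional coefficient dividing the slope.
#' @return The slope (or converted rate).
#' @export
initial_slope <- function(time, signal, extinction_coeff = NULL) {
  sl <- unname(coef(stats::lm(signal ~ time))[2])
  if (!is.null(extinction_coeff)) sl <- sl / extinction_coeff
  sl
}
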