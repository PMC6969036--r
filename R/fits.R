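#' Subtract control-well binding from an ELISA dataset
#'
#' Specific binding is the raw response minus the response of matched
#' control (carrier-protein-only) wells; negative differences are clipped
#' to zero with a warning.
#'
#' @param data Tibble with columns `concentration_nM`, `response`, and
#'   `control_response` (same length).
#' @return Tibble with columns `concentration_nM`, `response` (now
#'   specific), the control column removed.
#' @export
#' @examples
#' d <- tibble::tibble(concentration_nM = c(1, 2),
#'                     response = c(0.5, 0.9),
#'                     control_response = c(0.1, 0.1))
#' specific_binding(d)
specific_binding <- function(data) {
  need <- c("concentration_nM", "response", "control_response")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("`data` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  spec <- data$response - data$control_response
  if (any(spec < 0)) {
    warning(sum(spec < 0), " point(s) with control > response clipped to 0",
            call. = FALSE)
    spec <- pmax(spec, 0)
  }
  out <- tibble::as_tibble(data)
  out$response <- spec
  out$control_response <- NULL
  out
}

validate_binding_data <- function(data) {
  need <- c("concentration_nM", "response")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("`data` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$concentration_nM <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  invisible(data)
}

#' Fit the Hill-Langmuir saturation-binding model
#'
#' Unweighted least-squares fit of `B = Bmax * c / (Kd + c)` (Hill
#' coefficient fixed at 1) by Levenberg-Marquardt, initialised at
#' `Bmax0 = max(response)`, `Kd0 = median(concentration)`. Replicate wells
#' may simply be stacked as extra rows (pooled fit).
#'
#' The fit is reported as non-converged when the optimizer fails, when the
#' data do not approach saturation (fitted Kd far beyond the measured
#' concentration range), or when the Kd standard error exceeds the
#' estimate — the regime where only the ratio Bmax/Kd (initial slope) is
#' identified, as with a binder whose saturation curve is never obtained.
#'
#' @param data Tibble with columns `concentration_nM`, `response`
#'   (specific binding; apply [specific_binding()] first if control wells
#'   were measured). At least 3 distinct concentrations.
#' @return A `binding_fit` object: list with `kd` (nM), `bmax`,
#'   `kd_stderr`, `rss`, `converged`, `diagnostic`, `n`, `data`.
#'   Supports [tidy()], [glance()], `predict()`, and [ggplot2::autoplot()].
#' @export
#' @examples
#' d <- simulate_binding_curve(kd = 10, bmax = 2,
#'                             concentrations = 2^(0:7) * 0.25)
#' fit_hill_langmuir(d)
fit_hill_langmuir <- function(data) {
  validate_binding_data(data)
  if (length(unique(data$concentration_nM)) < 3) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  start <- list(bmax = max(data$response),
                kd = stats::median(data$concentration_nM))
  if (start$bmax <= 0) start$bmax <- 1e-6
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ bmax * concentration_nM / (kd + concentration_nM),
      data = data, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) e
  )
  out <- list(n = nrow(data), data = tibble::as_tibble(data))
  if (inherits(fit, "error")) {
    out <- c(out, list(kd = NA_real_, bmax = NA_real_, kd_stderr = NA_real_,
                       rss = NA_real_, converged = FALSE,
                       diagnostic = paste("optimizer failure:",
                                          conditionMessage(fit))))
    return(structure(out, class = "binding_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(bmax = NA_real_, kd = NA_real_))
  rss <- sum(stats::resid(fit)^2)
  diagnostic <- ""
  converged <- TRUE
  if (!is.finite(est[["kd"]]) || est[["kd"]] <= 0 || est[["bmax"]] <= 0) {
    converged <- FALSE
    diagnostic <- "non-physical estimate: Kd and Bmax must be positive"
  } else if (est[["kd"]] > 50 * max(data$concentration_nM)) {
    converged <- FALSE
    diagnostic <- "saturation not reached: fitted Kd far beyond measured range"
  } else if (is.na(se[["kd"]]) || se[["kd"]] > abs(est[["kd"]])) {
    converged <- FALSE
    diagnostic <- "Kd not identified: standard error exceeds estimate"
  }
  structure(c(out, list(kd = unname(est[["kd"]]), bmax = unname(est[["bmax"]]),
                        kd_stderr = unname(se[["kd"]]), rss = rss,
                        converged = converged, diagnostic = diagnostic)),
            class = "binding_fit")
}

#' Predict binding response from a fitted model
#'
#' @param object A converged `binding_fit`.
#' @param concentration_nM Non-negative concentrations (nM).
#' @param ... Unused.
#' @return Predicted responses `Bmax * c / (Kd + c)`.
#' @export
predict.binding_fit <- function(object, concentration_nM, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  if (any(concentration_nM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  object$bmax * concentration_nM / (object$kd + concentration_nM)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit> Hill-Langmuir saturation binding\n")
  if (x$converged) {
    cat(sprintf("  Kd = %.4g nM (SE %.3g), Bmax = %.4g, RSS = %.3g, n = %d\n",
                x$kd, x$kd_stderr, x$bmax, x$rss, x$n))
  } else {
    cat("  NOT converged:", x$diagnostic, "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_hill_langmuir
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(term = c("kd", "bmax"),
                 estimate = c(x$kd, x$bmax),
                 std.error = c(x$kd_stderr, NA_real_))
}

#' @rdname fit_hill_langmuir
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, bmax = x$bmax, kd_stderr = x$kd_stderr,
                 rss = x$rss, converged = x$converged, n = x$n)
}

validate_unfolding_data <- function(data) {
  need <- c("time_min", "fluorescence")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("`data` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$time_min < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(data$time_min, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  invisible(data)
}

#' Fit a thermal-unfolding half-life
#'
#' Isothermal unfolding monitored by a hydrophobicity-sensing dye produces
#' a rising fluorescence time course. The half-life is estimated by an
#' unweighted least-squares fit of the rectangular-hyperbola form
#' `F(t) = F0 + (Fmax - F0) * t / (t_half + t)` — the time-domain analogue
#' of the saturation-binding equation, with a baseline `F0` because raw
#' fluorescence has nonzero background. At `t = t_half` the fitted curve
#' passes exactly through `(F0 + Fmax) / 2`.
#'
#' @param data Tibble with columns `time_min` (strictly increasing,
#'   `>= 4` points including one near 0) and `fluorescence`.
#' @return A `half_life_fit` object: list with `t_half` (min), `f0`,
#'   `fmax`, `rss`, `converged`, `diagnostic`, `n`, `data`. Supports
#'   [tidy()], [glance()], and [ggplot2::autoplot()].
#' @export
#' @examples
#' d <- simulate_unfolding_curve(t_half = 1.68, f0 = 0, fmax = 1,
#'                               times = seq(0, 5, 0.25))
#' fit_half_life(d)
fit_half_life <- function(data) {
  validate_unfolding_data(data)
  if (nrow(data) < 4) stop("need at least 4 time points", call. = FALSE)
  out <- list(n = nrow(data), data = tibble::as_tibble(data))
  fail <- function(msg) {
    structure(c(out, list(t_half = NA_real_, f0 = NA_real_, fmax = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          diagnostic = msg)),
              class = "half_life_fit")
  }
  f <- data$fluorescence
  if (stats::sd(f) == 0) return(fail("constant fluorescence: no unfolding signal"))
  if (stats::cor(data$time_min, f) < 0) {
    return(fail("declining fluorescence: not an unfolding curve"))
  }
  start <- list(f0 = f[1], fmax = f[length(f)],
                t_half = stats::median(data$time_min))
  if (start$t_half <= 0) start$t_half <- max(data$time_min) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fluorescence ~ f0 + (fmax - f0) * time_min / (t_half + time_min),
      data = data, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(fail(paste("optimizer failure:", conditionMessage(fit))))
  }
  est <- stats::coef(fit)
  if (!is.finite(est[["t_half"]]) || est[["t_half"]] <= 0) {
    return(fail("non-physical estimate: half-life must be positive"))
  }
  structure(c(out, list(t_half = unname(est[["t_half"]]),
                        f0 = unname(est[["f0"]]),
                        fmax = unname(est[["fmax"]]),
                        rss = sum(stats::resid(fit)^2),
                        converged = TRUE, diagnostic = "")),
            class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat("<half_life_fit> thermal-unfolding half-life\n")
  if (x$converged) {
    cat(sprintf("  t1/2 = %.4g min, F0 = %.4g, Fmax = %.4g, RSS = %.3g, n = %d\n",
                x$t_half, x$f0, x$fmax, x$rss, x$n))
  } else {
    cat("  NOT converged:", x$diagnostic, "\n")
  }
  invisible(x)
}

#' @rdname fit_half_life
#' @param x A `half_life_fit`.
#' @param ... Unused.
#' @export
tidy.half_life_fit <- function(x, ...) {
  tibble::tibble(term = c("t_half", "f0", "fmax"),
                 estimate = c(x$t_half, x$f0, x$fmax))
}

#' @rdname fit_half_life
#' @export
glance.half_life_fit <- function(x, ...) {
  tibble::tibble(t_half = x$t_half, f0 = x$f0, fmax = x$fmax,
                 rss = x$rss, converged = x$converged, n = x$n)
}

#' Read assay CSVs
#'
#' `read_binding_csv()` expects columns `concentration_nM`, `response`,
#' and optionally `control_response`; `read_unfolding_csv()` expects
#' `time_min`, `fluorescence`.
#'
#' @param path CSV path.
#' @return A tibble in the corresponding fit's input format.
#' @export
read_binding_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_binding_data(df)
  df
}

#' @rdname read_binding_csv
#' @export
read_unfolding_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_unfolding_data(df)
  df
}
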