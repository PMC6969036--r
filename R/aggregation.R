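#' Summarise aggregation rates from cell counts
#'
#' Converts per-replicate counts of aggregate-bearing cells into
#' percentage rates and per-construct mean with SEM (sample SD / sqrt(n)).
#' The counting protocol scores at least 100 cells per dish, so replicates
#' with `n_total < 100` are kept but flagged with a protocol warning.
#'
#' @param obs Tibble (or data frame) with columns `construct_id`,
#'   `replicate`, `n_aggregated`, `n_total`.
#' @return Tibble with one row per construct: `construct_id`,
#'   `n_replicates`, `mean_rate` (percent), `sem` (percent; `NA` with a
#'   warning flag when a construct has a single replicate), `warnings`.
#' @export
#' @examples
#' obs <- tibble::tibble(construct_id = "A", replicate = 1:3,
#'                       n_aggregated = c(10, 20, 15), n_total = 200)
#' aggregation_summary(obs)
aggregation_summary <- function(obs) {
  need <- c("construct_id", "replicate", "n_aggregated", "n_total")
  if (!is.data.frame(obs) || !all(need %in% names(obs))) {
    stop("`obs` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(obs$n_aggregated < 0) || any(obs$n_total <= 0)) {
    stop("counts must satisfy 0 <= n_aggregated and n_total > 0",
         call. = FALSE)
  }
  if (any(obs$n_aggregated > obs$n_total)) {
    stop("n_aggregated exceeds n_total for construct(s): ",
         paste(unique(obs$construct_id[obs$n_aggregated > obs$n_total]),
               collapse = ", "), call. = FALSE)
  }
  obs |>
    tibble::as_tibble() |>
    dplyr::mutate(rate = 100 * .data$n_aggregated / .data$n_total,
                  undercounted = .data$n_total < 100) |>
    dplyr::group_by(.data$construct_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_rate = mean(.data$rate),
      sem = if (dplyr::n() > 1) stats::sd(.data$rate) / sqrt(dplyr::n())
            else NA_real_,
      warnings = paste(c(
        if (any(.data$undercounted)) "fewer than 100 cells counted in >=1 replicate",
        if (dplyr::n() == 1) "single replicate: SEM undefined"
      ), collapse = "; "),
      .groups = "drop"
    )
}

#' Pearson correlation with t-based and permutation p-values
#'
#' Sample Pearson r with the exact t transform
#' `t = r * sqrt(n-2) / sqrt(1-r^2)` against a t distribution with `n-2`
#' degrees of freedom (two-tailed), optionally augmented by a seeded
#' permutation test on |r|.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, each with nonzero
#'   variance.
#' @param n_perm Number of permutations for the permutation p-value
#'   (0 = skip; use at least 10^4 for a stable estimate).
#' @param seed Integer seed for the permutation test (required when
#'   `n_perm > 0` for reproducibility).
#' @return One-row tibble: `r`, `p_t`, `p_perm` (`NA` if skipped), `n`.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3), c(1, 3, 2))
pearson_cor <- function(x, y, n_perm = 0, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p_t <- r_to_p(r, n)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("supply `seed` when n_perm > 0", call. = FALSE)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    r_null <- vapply(seq_len(n_perm),
                     function(i) stats::cor(x, sample(y)), numeric(1))
    p_perm <- (1 + sum(abs(r_null) >= abs(r))) / (n_perm + 1)
  }
  tibble::tibble(r = r, p_t = p_t, p_perm = p_perm, n = n)
}

#' Two-tailed p-value from a Pearson r and sample size
#'
#' Closed-form consistency check of the t transform; reproduces the
#' printed p-values of the charge-vs-aggregation correlations from their
#' (r, n) pairs alone.
#'
#' @param r Pearson correlation.
#' @param n Number of paired observations (`n >= 3`).
#' @return Two-tailed p-value from t with `n - 2` degrees of freedom.
#' @export
#' @examples
#' r_to_p(0.6168, 17)
r_to_p <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Correlate construct charge (or pI) with aggregation rate
#'
#' Pairs screening records with per-construct mean aggregation rates by id
#' and computes the Pearson correlation between the signed net charge at
#' `ph` (or the pI when `ph = "pI"`) and the mean aggregation percentage.
#' The signed-charge convention means a positive r indicates that less
#' negative constructs aggregate more.
#'
#' @param records Screening tibble from [screen_constructs()].
#' @param summaries Summary tibble from [aggregation_summary()].
#' @param ph pH of the charge column to use, or `"pI"`.
#' @inheritParams pearson_cor
#' @return One-row tibble as from [pearson_cor()] plus columns `axis` and
#'   `n_unmatched`; unmatched ids are reported in a message.
#' @export
correlate_charge_aggregation <- function(records, summaries, ph = 6.6,
                                         n_perm = 0, seed = NULL) {
  axis <- if (identical(ph, "pI")) "pI" else charge_col(ph)
  if (!axis %in% names(records)) {
    stop("records have no column '", axis, "'", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(records, "id", value = dplyr::all_of(axis)),
    dplyr::select(summaries, id = "construct_id", "mean_rate"),
    by = "id"
  )
  n_unmatched <- (nrow(records) - nrow(joined)) +
    (nrow(summaries) - nrow(joined))
  if (n_unmatched > 0) {
    message(n_unmatched, " id(s) present in only one input were dropped")
  }
  if (nrow(joined) < 3) {
    stop("fewer than 3 matched construct ids", call. = FALSE)
  }
  out <- pearson_cor(joined$value, joined$mean_rate,
                     n_perm = n_perm, seed = seed)
  dplyr::mutate(out, axis = axis, n_unmatched = n_unmatched)
}

#' Ellipsoid tumour volume from calliper measurements
#'
#' `(pi/6) * length * width^2`, the standard calliper formula for
#' subcutaneous xenografts.
#'
#' @param length,width Calliper dimensions in mm (vectors recycle);
#'   `length >= width` expected (a warning is raised otherwise, and the
#'   value still computed).
#' @return Volume in cubic millimetres.
#' @export
#' @examples
#' tumour_volume(6, 5)
tumour_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) {
    stop("dimensions must be positive", call. = FALSE)
  }
  if (any(length < width)) {
    warning("length < width: check measurement orientation", call. = FALSE)
  }
  (pi / 6) * length * width^2
}

#' Read an aggregation count table from CSV
#'
#' Expected columns: `construct_id`, `replicate`, `n_aggregated`,
#' `n_total` (header required).
#'
#' @param path CSV path.
#' @return Tibble of per-replicate observations.
#' @export
read_aggregation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "replicate", "n_aggregated", "n_total")
  if (!all(need %in% names(df))) {
    stop("aggregation CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}
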