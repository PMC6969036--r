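#' Simulate an scFv-like construct panel
#'
#' Generates `n` sequences from a fixed scFv-like framework whose variable
#' windows (CDR-like stretches, marked `x` in the framework string) are
#' sampled from `residue_freq`. Every generated core is fused with the
#' s3Flag (N) and HA (C) tags by default, mirroring a tag-fusion screening
#' panel. Deterministic given `seed`.
#'
#' @param n Number of constructs (default 17, the size of a typical
#'   aggregation-screening panel).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param framework Template string: fixed residues plus `x` at variable
#'   positions. The default is a miniature VH-linker-VL skeleton with
#'   three variable windows.
#' @param residue_freq Named probability vector over the 20 residues for
#'   variable positions (must sum to 1); default slightly enriched in
#'   D/E/G/S/Y as in antigen-binding loops.
#' @param n_tags,c_tags Tags fused to every core (default s3Flag / HA);
#'   use `character()` for bare cores.
#' @return Tibble with columns `id`, `sequence`, `free_n_term`,
#'   `free_c_term` — directly consumable by [screen_constructs()].
#' @export
#' @examples
#' simulate_scfv_set(n = 3, seed = 1)
simulate_scfv_set <- function(n = 17, seed,
                              framework = paste0(
                                "EVQLVESGGGLVQPGGSLRLSCAAS", strrep("x", 8),
                                "WVRQAPGKGLEWV", strrep("x", 10),
                                "RFTISRDNSKNTLYLQMNSLRAEDTAVYYCAK",
                                strrep("x", 12),
                                "WGQGTLVTVSSGGGGSGGGGSGGGGS",
                                "DIQMTQSPSSLSASVGDRVTITC"),
                              residue_freq = NULL,
                              n_tags = "s3Flag", c_tags = "HA") {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!nzchar(framework)) stop("empty framework", call. = FALSE)
  if (n == 0) {
    return(tibble::tibble(id = character(0), sequence = character(0),
                          free_n_term = logical(0), free_c_term = logical(0)))
  }
  if (is.null(residue_freq)) {
    residue_freq <- stats::setNames(rep(1, 20), AA_ALPHABET20)
    residue_freq[c("D", "E", "G", "S", "Y")] <- 3
    residue_freq <- residue_freq / sum(residue_freq)
  }
  if (abs(sum(residue_freq) - 1) > 1e-9 || any(residue_freq < 0)) {
    stop("`residue_freq` must be non-negative and sum to 1", call. = FALSE)
  }
  if (!all(names(residue_freq) %in% AA_ALPHABET20)) {
    stop("`residue_freq` names must be standard residues", call. = FALSE)
  }
  tmpl <- strsplit(framework, "", fixed = TRUE)[[1]]
  var_idx <- which(tmpl == "x")
  fixed <- tmpl[tmpl != "x"]
  if (length(fixed) > 0) validate_peptide(paste(fixed, collapse = ""))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cores <- vapply(seq_len(n), function(i) {
    s <- tmpl
    if (length(var_idx) > 0) {
      s[var_idx] <- sample(names(residue_freq), length(var_idx),
                           replace = TRUE, prob = residue_freq)
    }
    paste(s, collapse = "")
  }, character(1))
  fusions <- purrr::imap(cores, function(core, i) {
    build_fusion(core, n_tags = n_tags, c_tags = c_tags,
                 core_id = sprintf("scFv%02d", i),
                 id = paste(c(n_tags, sprintf("scFv%02d", i), c_tags),
                            collapse = "-"))
  })
  as_construct_table(fusions)
}

#' Simulate aggregation counts with a controlled charge-aggregation link
#'
#' For each construct the true aggregation rate is
#' `clip(intercept + slope * charge@charge_ph + noise, 0, 100)` percent,
#' then discretised into `n_replicates` binomial counts over `n_total`
#' cells. A positive `slope` on the signed charge makes less-negative
#' constructs aggregate more — the structure of a charge-vs-aggregation
#' screening panel.
#'
#' @param constructs Anything [as_construct_table()] accepts.
#' @param seed Integer seed.
#' @param intercept Baseline aggregation (percent) at zero net charge.
#' @param slope Percent aggregation per elementary charge.
#' @param noise_sd SD of Gaussian noise on the percentage scale.
#' @param charge_ph pH at which the driving charge is computed.
#' @param n_replicates,n_total Replicates per construct and cells counted
#'   per replicate.
#' @param pka A [pka_set()].
#' @return Tibble of per-replicate observations (`construct_id`,
#'   `replicate`, `n_aggregated`, `n_total`) with the per-construct true
#'   rates attached as attribute `true_rates`.
#' @export
simulate_aggregation_data <- function(constructs, seed,
                                      intercept = 38, slope = 3,
                                      noise_sd = 3, charge_ph = 6.6,
                                      n_replicates = 3, n_total = 200,
                                      pka = pka_default()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  tab <- as_construct_table(constructs)
  charges <- purrr::pmap_dbl(tab, function(id, sequence, free_n_term,
                                           free_c_term) {
    net_charge(sequence, charge_ph, pka = pka,
               n_term = free_n_term, c_term = free_c_term)
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  true_rate <- pmin(pmax(intercept + slope * charges +
                           stats::rnorm(nrow(tab), 0, noise_sd), 0), 100)
  obs <- tidyr::expand_grid(construct_id = tab$id,
                            replicate = seq_len(n_replicates))
  obs$n_total <- n_total
  obs$n_aggregated <- stats::rbinom(
    nrow(obs), size = n_total,
    prob = rep(true_rate, each = n_replicates) / 100
  )
  out <- obs[, c("construct_id", "replicate", "n_aggregated", "n_total")]
  attr(out, "true_rates") <- stats::setNames(true_rate, tab$id)
  attr(out, "charges") <- stats::setNames(charges, tab$id)
  out
}

#' Simulate a saturation-binding curve
#'
#' Responses follow `B = Bmax * c / (Kd + c)` plus Gaussian noise with SD
#' `noise_sd * Bmax`; `noise_sd = 0` gives the exact model values.
#'
#' @param kd Dissociation constant (nM), > 0.
#' @param bmax Maximal response, > 0.
#' @param concentrations Concentrations in nM; default an 8-point two-fold
#'   dilution series descending from 36 nM (spanning roughly 0.28-36 nM).
#' @param noise_sd Noise SD as a fraction of `bmax` (>= 0).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Tibble with `concentration_nM`, `response`.
#' @export
#' @examples
#' simulate_binding_curve(kd = 12.18, bmax = 1)
simulate_binding_curve <- function(kd, bmax,
                                   concentrations = 36 / 2^(7:0),
                                   noise_sd = 0, seed = NULL) {
  stopifnot(kd > 0, bmax > 0)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  resp <- bmax * concentrations / (kd + concentrations)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("supply `seed` when noise_sd > 0", call. = FALSE)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    resp <- resp + stats::rnorm(length(resp), 0, noise_sd * bmax)
  }
  tibble::tibble(concentration_nM = concentrations, response = resp)
}

#' Simulate a thermal-unfolding fluorescence time course
#'
#' `F(t) = F0 + (Fmax - F0) * t / (t_half + t)` plus Gaussian noise with
#' SD `noise_sd * Fmax`.
#'
#' @param t_half Half-life in minutes, > 0.
#' @param f0,fmax Baseline and plateau fluorescence.
#' @param times Time points in minutes (non-negative, strictly
#'   increasing); default 0-5 min every 0.25 min.
#' @param noise_sd Noise SD as a fraction of `fmax` (>= 0).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Tibble with `time_min`, `fluorescence`.
#' @export
#' @examples
#' simulate_unfolding_curve(t_half = 1.68, f0 = 0, fmax = 1)
simulate_unfolding_curve <- function(t_half, f0 = 0, fmax = 1,
                                     times = seq(0, 5, 0.25),
                                     noise_sd = 0, seed = NULL) {
  stopifnot(t_half > 0)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  fl <- f0 + (fmax - f0) * times / (t_half + times)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("supply `seed` when noise_sd > 0", call. = FALSE)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    fl <- fl + stats::rnorm(length(fl), 0, noise_sd * abs(fmax))
  }
  tibble::tibble(time_min = times, fluorescence = fl)
}
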