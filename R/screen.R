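#' STAND designation criteria
#'
#' A construct is designated a STAND (ultra-stable cytoplasmic antibody)
#' when its isoelectric point is at most `max_pi` AND its net charge at
#' `charge_ph` is at most `max_charge` (both inclusive). The defaults —
#' pI of at most 5.5 and charge of at most -6 e at pH 6.6 — bracket the
#' published successful constructs (fusion pIs 4.48-5.08, charges -6.1 to
#' -7.1 e at pH 6.6) and exclude the published failures; both thresholds
#' are plain parameters and should be tuned to the screening problem.
#'
#' @param max_pi Maximum pI (pH units).
#' @param max_charge Maximum (i.e. most positive admissible) net charge at
#'   `charge_ph`, in elementary-charge units; must be negative.
#' @param charge_ph pH at which the charge criterion applies.
#' @return A `stand_criteria` list.
#' @export
stand_criteria <- function(max_pi = 5.5, max_charge = -6.0, charge_ph = 6.6) {
  if (!is.numeric(charge_ph) || charge_ph < 0 || charge_ph > 14) {
    stop("`charge_ph` must lie in [0, 14]", call. = FALSE)
  }
  if (!is.numeric(max_charge) || max_charge >= 0) {
    stop("`max_charge` must be negative", call. = FALSE)
  }
  structure(list(max_pi = max_pi, max_charge = max_charge,
                 charge_ph = charge_ph),
            class = "stand_criteria")
}

#' Screen constructs for STAND designation
#'
#' Evaluates each construct's pI (bisection) and net charge at the report
#' pH set, then applies the [stand_criteria()]. The default report pH set
#' {6.6, 7.03, 7.4} spans the physiological cytoplasmic range; only
#' `criteria$charge_ph` enters the designation.
#'
#' @param constructs Anything [as_construct_table()] accepts: a tibble with
#'   `id`/`sequence` columns (ids must be unique), a `fusion_construct`, or
#'   a list of them.
#' @param pka A [pka_set()].
#' @param criteria A [stand_criteria()].
#' @param ph Report pH set; `criteria$charge_ph` is added if missing.
#' @return A tibble with one row per construct, input order preserved:
#'   `id`, `length`, `pI`, one `charge_<ph>` column per report pH,
#'   `is_stand`, `warnings`. A construct with undefined pI gets `pI = NA`,
#'   `is_stand = FALSE`, and a warning string.
#' @export
#' @examples
#' screen_constructs(tibble::tibble(
#'   id = c("s3Flag", "HA"),
#'   sequence = c("DYKDHDGDYKDHDIDYKDDDDK", "YPYDVPDYA")
#' ))
screen_constructs <- function(constructs, pka = pka_default(),
                              criteria = stand_criteria(),
                              ph = c(6.6, 7.03, 7.4)) {
  stopifnot(inherits(pka, "pka_set"), inherits(criteria, "stand_criteria"))
  tab <- as_construct_table(constructs)
  if (anyDuplicated(tab$id)) {
    stop("duplicate construct ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  ph <- sort(unique(c(ph, criteria$charge_ph)))
  if (nrow(tab) == 0L) {
    out <- tibble::tibble(id = character(0), length = integer(0),
                          pI = numeric(0))
    for (p in ph) out[[charge_col(p)]] <- numeric(0)
    out$is_stand <- logical(0)
    out$warnings <- character(0)
    return(out)
  }
  rows <- purrr::pmap(tab, function(id, sequence, free_n_term, free_c_term) {
    charges <- net_charge(sequence, ph, pka = pka,
                          n_term = free_n_term, c_term = free_c_term)
    warn <- character(0)
    pI <- tryCatch(
      isoelectric_point(sequence, pka = pka,
                        n_term = free_n_term, c_term = free_c_term),
      standr_pi_undefined = function(e) {
        warn <<- c(warn, "pI undefined")
        NA_real_
      })
    q_crit <- charges[match(criteria$charge_ph, ph)]
    is_stand <- !is.na(pI) && pI <= criteria$max_pi &&
      q_crit <= criteria$max_charge
    row <- tibble::tibble(id = id, length = nchar(sequence), pI = pI)
    for (i in seq_along(ph)) row[[charge_col(ph[i])]] <- charges[i]
    row$is_stand <- is_stand
    row$warnings <- paste(warn, collapse = "; ")
    row
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pka_name") <- pka$name
  attr(out, "criteria") <- criteria
  out
}

charge_col <- function(ph) paste0("charge_", format(ph, trim = TRUE))

#' Enumerate and rank tag combinations for a core sequence
#'
#' Exhaustively enumerates ordered tag subsets at each terminus (up to
#' `max_tags_per_terminus` tags per side, no tag reuse within a side),
#' screens every resulting fusion, and ranks candidates by net charge at
#' the criterion pH ascending (most negative first), breaking ties by pI
#' ascending and then lexicographic id. The ranking is invariant to the
#' library's row order.
#'
#' @inheritParams build_fusion
#' @inheritParams screen_constructs
#' @param max_tags_per_terminus Maximum tags per terminus (0, 1, or 2);
#'   0 returns only the bare core.
#' @return Screening tibble (as from [screen_constructs()]) with a leading
#'   `rank` column, ordered best-first.
#' @export
suggest_tag_combinations <- function(core, library = builtin_tags(),
                                     pka = pka_default(),
                                     criteria = stand_criteria(),
                                     max_tags_per_terminus = 2,
                                     core_id = "scFv") {
  validate_tag_library(library)
  if (nrow(library) == 0L) stop("empty tag library", call. = FALSE)
  if (max_tags_per_terminus > 2) {
    stop("`max_tags_per_terminus` must be at most 2", call. = FALSE)
  }
  side_options <- function(allowed) {
    opts <- list(character(0))
    if (max_tags_per_terminus >= 1) {
      opts <- c(opts, as.list(allowed))
    }
    if (max_tags_per_terminus >= 2 && length(allowed) >= 2) {
      pairs <- expand.grid(a = allowed, b = allowed,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      opts <- c(opts, purrr::map2(pairs$a, pairs$b, c))
    }
    opts
  }
  n_allowed <- sort(library$name[library$positions %in% c("N", "either")])
  c_allowed <- sort(library$name[library$positions %in% c("C", "either")])
  combos <- tidyr::expand_grid(n = side_options(n_allowed),
                               c = side_options(c_allowed))
  fusions <- purrr::map2(combos$n, combos$c, function(nt, ct) {
    build_fusion(core, n_tags = nt, c_tags = ct, library = library,
                 core_id = core_id)
  })
  rec <- screen_constructs(fusions, pka = pka, criteria = criteria)
  qcol <- charge_col(criteria$charge_ph)
  rec <- dplyr::arrange(rec, .data[[qcol]], .data$pI, .data$id)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(rec))), rec)
}

#' Write a screening report as annotated TSV
#'
#' Numeric columns are written with 2 decimals; the pKa-set name and the
#' designation criteria are echoed as `#`-prefixed header comment lines so
#' a report is self-describing.
#'
#' @param records Screening tibble from [screen_constructs()].
#' @param path Output path.
#' @param pka,criteria Echoed in the header; default to the attributes
#'   stored on `records` and fall back to the package defaults.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(records, path,
                                pka = NULL, criteria = NULL) {
  pka_name <- if (!is.null(pka)) pka$name else
    attr(records, "pka_name") %||% pka_default()$name
  criteria <- criteria %||% attr(records, "criteria") %||% stand_criteria()
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(
    paste0("# pka_set: ", pka_name),
    sprintf("# criteria: max_pi=%.2f max_charge=%.2f charge_ph=%.2f",
            criteria$max_pi, criteria$max_charge, criteria$charge_ph)
  ), con)
  out <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, 2)))
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a screening report TSV
#'
#' @param path Report path written by [write_screen_report()].
#' @return The records tibble (comment lines dropped).
#' @export
read_screen_report <- function(path) {
  tibble::as_tibble(
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
  )
}
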