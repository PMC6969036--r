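#' @keywords internal
#' @noRd
AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

# Validate and upper-case a peptide sequence; returns the residue vector.
# `lenient` maps ambiguity letters (B,J,O,U,X,Z) to non-ionizable placeholders
# with a warning instead of rejecting.
validate_peptide <- function(sequence, lenient = FALSE) {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence)) {
    stop("`sequence` must be a single character string", call. = FALSE)
  }
  seq_up <- toupper(sequence)
  aa <- strsplit(seq_up, "", fixed = TRUE)[[1]]
  if (length(aa) == 0L) stop("empty sequence", call. = FALSE)
  bad <- which(!aa %in% AA_ALPHABET20)
  if (length(bad) > 0L) {
    ambiguous <- c("B", "J", "O", "U", "X", "Z")
    if (lenient && all(aa[bad] %in% ambiguous)) {
      warning("treating ambiguous residue(s) ",
              paste(unique(aa[bad]), collapse = ","),
              " at position(s) ", paste(bad, collapse = ","),
              " as non-ionizable", call. = FALSE)
    } else {
      stop("invalid residue '", aa[bad[1]], "' at position ", bad[1],
           call. = FALSE)
    }
  }
  aa
}

#' Count ionizable groups in a peptide
#'
#' Decomposes a sequence into the counts that drive the
#' Henderson-Hasselbalch net-charge sum: one count per ionizable side chain
#' (D, E, H, C, Y, K, R) plus 0/1 for each enabled free terminus.
#'
#' @param sequence Single amino-acid string (one-letter code,
#'   case-insensitive).
#' @param n_term,c_term Logical; whether the free N-/C-terminus contributes
#'   its ionizable group. Internal junctions of a fusion have no free
#'   termini, so tag segments inside a construct are counted with both set
#'   to `FALSE`.
#' @param lenient If `TRUE`, ambiguity letters (B,J,O,U,X,Z) are treated as
#'   non-ionizable with a warning instead of an error.
#' @return A tibble with columns `group` (`D,E,H,C,Y,K,R,Nterm,Cterm`),
#'   `count`, and `sign`.
#' @export
#' @examples
#' ionizable_composition("DYKDHDGDYKDHDIDYKDDDDK")
ionizable_composition <- function(sequence, n_term = TRUE, c_term = TRUE,
                                  lenient = FALSE) {
  aa <- validate_peptide(sequence, lenient = lenient)
  ionizable <- c("D", "E", "H", "C", "Y", "K", "R")
  sign <- c(D = -1, E = -1, H = +1, C = -1, Y = -1, K = +1, R = +1)
  counts <- vapply(ionizable, function(g) sum(aa == g), integer(1))
  tibble::tibble(
    group = c(ionizable, "Nterm", "Cterm"),
    count = c(counts, as.integer(n_term), as.integer(c_term)),
    sign  = c(unname(sign), +1L, -1L)
  )
}

# Henderson-Hasselbalch fractional charge of one group class.
hh_charge <- function(ph, pka, sign) {
  ifelse(sign > 0, 1 / (1 + 10^(ph - pka)), -1 / (1 + 10^(pka - ph)))
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch summation over all ionizable groups: each basic
#' group contributes `+1/(1+10^(pH-pKa))`, each acidic group
#' `-1/(1+10^(pKa-pH))`. Free termini contribute one basic (alpha-amine)
#' and one acidic (alpha-carboxyl) group when enabled. The result is in
#' elementary-charge units (e) and is non-increasing in pH.
#'
#' @inheritParams ionizable_composition
#' @param ph Numeric vector of pH values in \[0, 14\].
#' @param pka A [pka_set()]; defaults to [pka_default()].
#' @return Numeric vector of net charges, one per element of `ph`.
#' @export
#' @examples
#' net_charge("DYKDHDGDYKDHDIDYKDDDDK", ph = c(6.6, 7.03, 7.4))
net_charge <- function(sequence, ph, pka = pka_default(),
                       n_term = TRUE, c_term = TRUE, lenient = FALSE) {
  stopifnot(inherits(pka, "pka_set"))
  if (!is.numeric(ph) || length(ph) == 0L) {
    stop("`ph` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(ph)) || any(ph < 0) || any(ph > 14)) {
    stop("`ph` must lie in [0, 14]", call. = FALSE)
  }
  comp <- ionizable_composition(sequence, n_term = n_term, c_term = c_term,
                                lenient = lenient)
  pka_of <- c(pka$side_chain_pka, Nterm = pka$n_term_pka,
              Cterm = pka$c_term_pka)
  comp$pka <- unname(pka_of[comp$group])
  vapply(ph, function(p) {
    sum(comp$count * hh_charge(p, comp$pka, comp$sign))
  }, numeric(1))
}

#' Net charge versus pH curve
#'
#' Evaluates the net charge on a pH grid and returns a `charge_profile`
#' tibble (one row per grid point). The profile is strictly decreasing in
#' pH whenever the peptide has at least one ionizable group. If the charge
#' changes sign on the grid's span the isoelectric point is solved by
#' bisection and attached; otherwise `pI` is `NA`.
#'
#' @inheritParams net_charge
#' @param ph Sorted numeric grid in \[0, 14\]; default `seq(0, 14, 0.1)`.
#' @param id Label stored with the profile (defaults to the sequence
#'   itself, truncated).
#' @return A tibble of class `charge_profile` with columns `ph` and
#'   `net_charge`, and attributes `sequence_id`, `pI`, `termini`,
#'   `pka_name`.
#' @export
#' @examples
#' prof <- charge_curve("YPYDVPDYA")
#' attr(prof, "pI")
charge_curve <- function(sequence, ph = seq(0, 14, by = 0.1),
                         pka = pka_default(), n_term = TRUE, c_term = TRUE,
                         id = NULL) {
  if (length(ph) == 0L) stop("empty pH grid", call. = FALSE)
  if (is.unsorted(ph, strictly = TRUE)) {
    stop("`ph` grid must be strictly increasing", call. = FALSE)
  }
  q <- net_charge(sequence, ph, pka = pka, n_term = n_term, c_term = c_term)
  pI <- tryCatch(
    isoelectric_point(sequence, pka = pka, n_term = n_term, c_term = c_term),
    error = function(e) NA_real_
  )
  if (is.null(id)) {
    id <- if (nchar(sequence) > 16) paste0(substr(sequence, 1, 13), "...") else sequence
  }
  out <- tibble::tibble(ph = ph, net_charge = q)
  structure(out,
            class = c("charge_profile", class(out)),
            sequence_id = id,
            pI = pI,
            termini = c(n_term = n_term, c_term = c_term),
            pka_name = pka$name)
}

#' Isoelectric point by bisection
#'
#' Solves `net_charge(sequence, pH) == 0` on pH \[0, 14\]. The net charge
#' is strictly decreasing in pH for any peptide with an ionizable group,
#' so when a sign change exists the root is unique and bisection is
#' guaranteed to find it.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units (default `1e-3`). The
#'   returned value keeps full solver precision; round for reporting.
#' @return The pI in pH units.
#' @section Errors: If the charge never changes sign on \[0, 14\] (e.g. a
#'   pure poly-acid with termini disabled) the pI is undefined and an error
#'   of class `standr_pi_undefined` is thrown, distinct from invalid-input
#'   errors.
#' @export
#' @examples
#' isoelectric_point("DYKDHDGDYKDHDIDYKDDDDK")
isoelectric_point <- function(sequence, pka = pka_default(),
                              n_term = TRUE, c_term = TRUE, tol = 1e-3) {
  comp <- ionizable_composition(sequence, n_term = n_term, c_term = c_term)
  pi_undefined <- function(msg) {
    stop(structure(class = c("standr_pi_undefined", "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  if (sum(comp$count) == 0) {
    pi_undefined("pI undefined: sequence has no ionizable groups")
  }
  f <- function(p) net_charge(sequence, p, pka = pka,
                              n_term = n_term, c_term = c_term)
  lo <- 0; hi <- 14
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo == 0) return(lo)
  if (f_hi == 0) return(hi)
  if (f_lo < 0 || f_hi > 0) {
    pi_undefined(paste0("pI undefined: net charge does not change sign",
                        " on [0, 14] for this sequence/termini choice"))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
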