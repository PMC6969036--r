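#' Built-in epitope-tag library
#'
#' The peptide tags used for cytoplasmic-antibody charge engineering. The
#' s3Flag tag (the 22-residue Sigma triple-Flag variant) and the HA tag
#' are the acidic, low-pI tags whose fusion converts an aggregation-prone
#' scFv into a STAND; T7/His6/myc are the conventional tags used as
#' comparators. The myc sequence is the community-standard EQKLISEEDL and
#' is flagged `inferred` in `provenance`; the T7 sequence is reconstructed
#' from its coding primer (`derived-from-primer`). EGFP is deliberately
#' absent: supply it as a user sequence if needed.
#'
#' @return A tibble (tag library) with columns `name`, `sequence`,
#'   `positions` (`"N"`, `"C"`, or `"either"`), `provenance`.
#' @export
#' @examples
#' builtin_tags()
builtin_tags <- function() {
  tibble::tribble(
    ~name,     ~sequence,                  ~positions, ~provenance,
    "s3Flag",  "DYKDHDGDYKDHDIDYKDDDDK",   "either",   "published",
    "flag",    "DYKDDDDK",                 "either",   "published",
    "HA",      "YPYDVPDYA",                "either",   "published",
    "T7",      "MASMTGGQQMG",              "N",        "derived-from-primer",
    "His6",    "HHHHHH",                   "either",   "published",
    "myc",     "EQKLISEEDL",               "either",   "inferred"
  )
}

#' Look up a tag in a library
#'
#' @param name Tag name.
#' @param library Tag library tibble (columns `name`, `sequence`,
#'   `positions`); defaults to [builtin_tags()].
#' @return One-row tibble for the tag.
#' @export
tag_lookup <- function(name, library = builtin_tags()) {
  validate_tag_library(library)
  hit <- library[library$name == name, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("tag '", name, "' not found in library (available: ",
         paste(library$name, collapse = ", "), ")", call. = FALSE)
  }
  hit
}

validate_tag_library <- function(library) {
  need <- c("name", "sequence", "positions")
  if (!is.data.frame(library) || !all(need %in% names(library))) {
    stop("tag library must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(library$name)) {
    stop("duplicate tag names in library", call. = FALSE)
  }
  if (nrow(library) > 0 && any(nchar(library$sequence) == 0)) {
    stop("empty tag sequence in library", call. = FALSE)
  }
  invisible(library)
}

#' Read / write a tag library as CSV
#'
#' Columns `name`, `sequence`, `positions` (and optionally `provenance`,
#' defaulting to `"user"`).
#'
#' @param path File path.
#' @param library Tag library tibble.
#' @return `read_tag_library()` a tibble; `write_tag_library()` `path`
#'   invisibly.
#' @export
read_tag_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"provenance" %in% names(df)) df$provenance <- "user"
  df$sequence <- toupper(df$sequence)
  validate_tag_library(df)
  purrr::walk(df$sequence, validate_peptide)
  tibble::as_tibble(df)
}

#' @rdname read_tag_library
#' @export
write_tag_library <- function(library, path) {
  validate_tag_library(library)
  utils::write.csv(library, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_fusion_construct <- function(id, segments, free_n_term, free_c_term) {
  structure(
    list(id = id, segments = segments,
         free_n_term = free_n_term, free_c_term = free_c_term),
    class = "fusion_construct"
  )
}

#' Assemble a tag-fusion construct
#'
#' Builds an ordered-segment fusion `n_tags... core ...c_tags` with
#' optional explicit linker segments at each junction. Segments are
#' concatenated directly: internal junctions contribute no terminal
#' ionizable groups, and only the outermost termini can be free
#' (both free by default, as for a cytoplasmically expressed construct).
#'
#' @param core Core amino-acid sequence (e.g. an scFv).
#' @param n_tags,c_tags Character vector of tag names resolved in
#'   `library`, N-terminal tags listed outermost-first and C-terminal tags
#'   innermost-first.
#' @param linkers Optional single linker sequence (e.g. `"GS"`) inserted at
#'   every tag junction, or `NULL` for direct concatenation.
#' @param library Tag library tibble; defaults to [builtin_tags()].
#' @param core_id Label for the core segment.
#' @param id Construct id; by default derived deterministically from the
#'   segment names (e.g. `"s3Flag-scFv-HA"`).
#' @param free_n_term,free_c_term Whether the outer termini are free.
#' @return A `fusion_construct` object.
#' @section Errors: A tag whose `positions` entry excludes the requested
#'   terminus is rejected.
#' @export
#' @examples
#' fc <- build_fusion(strrep("A", 10), n_tags = "s3Flag", c_tags = "HA",
#'                    core_id = "toy")
#' fusion_sequence(fc)
build_fusion <- function(core, n_tags = character(), c_tags = character(),
                         linkers = NULL, library = builtin_tags(),
                         core_id = "scFv", id = NULL,
                         free_n_term = TRUE, free_c_term = TRUE) {
  validate_peptide(core)
  validate_tag_library(library)
  check_pos <- function(tag_name, where) {
    tag <- tag_lookup(tag_name, library)
    if (!tag$positions %in% c(where, "either")) {
      stop("tag '", tag_name, "' is not allowed at the ", where,
           "-terminus (positions: ", tag$positions, ")", call. = FALSE)
    }
    tag
  }
  n_specs <- purrr::map(n_tags, check_pos, where = "N")
  c_specs <- purrr::map(c_tags, check_pos, where = "C")
  seg_names <- c(purrr::map_chr(n_specs, "name"), core_id,
                 purrr::map_chr(c_specs, "name"))
  seg_seqs  <- c(purrr::map_chr(n_specs, "sequence"), toupper(core),
                 purrr::map_chr(c_specs, "sequence"))
  if (!is.null(linkers)) {
    validate_peptide(linkers)
    k <- length(seg_seqs)
    if (k > 1) {
      names_i <- character(0); seqs_i <- character(0)
      for (i in seq_len(k)) {
        names_i <- c(names_i, seg_names[i])
        seqs_i <- c(seqs_i, seg_seqs[i])
        if (i < k) {
          names_i <- c(names_i, "linker")
          seqs_i <- c(seqs_i, toupper(linkers))
        }
      }
      seg_names <- names_i; seg_seqs <- seqs_i
    }
  }
  segments <- tibble::tibble(segment = seg_names, sequence = seg_seqs)
  if (is.null(id)) id <- paste(seg_names[seg_names != "linker"], collapse = "-")
  new_fusion_construct(id, segments, free_n_term, free_c_term)
}

#' Flatten a fusion construct to its full peptide sequence
#'
#' @param construct A `fusion_construct`.
#' @return Single amino-acid string; its length is the sum of the segment
#'   lengths.
#' @export
fusion_sequence <- function(construct) {
  stopifnot(inherits(construct, "fusion_construct"))
  paste(construct$segments$sequence, collapse = "")
}

#' @export
print.fusion_construct <- function(x, ...) {
  cat("<fusion_construct>", x$id, "\n")
  cat("  segments:", paste(sprintf("%s(%d)", x$segments$segment,
                                   nchar(x$segments$sequence)),
                           collapse = " - "), "\n")
  cat(sprintf("  length %d aa; free termini N=%s C=%s\n",
              nchar(fusion_sequence(x)), x$free_n_term, x$free_c_term))
  invisible(x)
}

#' Coerce constructs to a screening table
#'
#' Accepts a tibble with `id` and `sequence` columns, a single
#' `fusion_construct`, or a list of them, and returns the uniform
#' tibble the screening functions consume.
#'
#' @param x Constructs in any accepted form.
#' @return Tibble with columns `id`, `sequence`, `free_n_term`,
#'   `free_c_term`.
#' @export
as_construct_table <- function(x) {
  if (inherits(x, "fusion_construct")) x <- list(x)
  if (is.data.frame(x)) {
    if (!all(c("id", "sequence") %in% names(x))) {
      stop("construct table needs `id` and `sequence` columns", call. = FALSE)
    }
    out <- tibble::as_tibble(x)
    if (!"free_n_term" %in% names(out)) out$free_n_term <- TRUE
    if (!"free_c_term" %in% names(out)) out$free_c_term <- TRUE
    out$sequence <- toupper(out$sequence)
  } else if (is.list(x) && all(purrr::map_lgl(x, inherits, "fusion_construct"))) {
    out <- tibble::tibble(
      id = purrr::map_chr(x, "id"),
      sequence = purrr::map_chr(x, fusion_sequence),
      free_n_term = purrr::map_lgl(x, "free_n_term"),
      free_c_term = purrr::map_lgl(x, "free_c_term")
    )
  } else {
    stop("cannot interpret `x` as constructs", call. = FALSE)
  }
  purrr::walk(out$sequence, validate_peptide)
  out[, c("id", "sequence", "free_n_term", "free_c_term")]
}
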