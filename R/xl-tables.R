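#' @importFrom rlang .data
NULL

xl_mandatory_cols <- c("protein_a", "residue_a", "restype_a",
                       "protein_b", "residue_b", "restype_b",
                       "chemistry", "condition")

#' Read a cross-link identification table
#'
#' Reads the package's TSV dialect for residue-pair cross-link
#' identifications. Mandatory columns: `protein_a`, `residue_a`,
#' `restype_a`, `protein_b`, `residue_b`, `restype_b`, `chemistry`,
#' `condition`. Optional columns (`score`, `intermolecular`, anything else)
#' are preserved. Residue positions are 1-based.
#'
#' @param path Path to a TSV file.
#' @return A tibble of cross-link records.
#' @export
read_xl_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(xl_mandatory_cols, names(tbl))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(tbl$residue_a < 1 | tbl$residue_b < 1)
  if (length(bad) > 0) {
    stop("residue position < 1 at line ", bad[1] + 1L,
         " (positions are 1-based)")
  }
  if (!"intermolecular" %in% names(tbl)) tbl$intermolecular <- "ambiguous"
  tibble::as_tibble(tbl)
}

#' Write a cross-link table
#'
#' @param records Tibble of cross-link records.
#' @param path Output TSV path.
#' @return `records`, invisibly.
#' @export
write_xl_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(records)
}

#' Validate cross-link records against a chemistry registry
#'
#' Flags records whose residue types are incompatible with the reactive
#' pair of their chemistry (in either end order).
#'
#' @param records Tibble of cross-link records.
#' @param registry Named list of [crosslinker_spec] objects
#'   (default [xl_chemistries()]).
#' @return `records` with a logical `valid` column added.
#' @export
validate_xl_records <- function(records, registry = xl_chemistries()) {
  ok <- purrr::pmap_lgl(
    list(records$restype_a, records$restype_b, records$chemistry),
    function(ra, rb, chem) {
      spec <- registry[[chem]]
      if (is.null(spec)) return(FALSE)
      (ra %in% spec$reactive_a && rb %in% spec$reactive_b) ||
        (ra %in% spec$reactive_b && rb %in% spec$reactive_a)
    }
  )
  dplyr::mutate(records, valid = ok)
}

# Canonical unordered pair order: by (protein, residue) lexicographically.
canonicalize_pairs <- function(records) {
  swap <- records$protein_a > records$protein_b |
    (records$protein_a == records$protein_b &
       records$residue_a > records$residue_b)
  out <- records
  ab <- list(c("protein_a", "protein_b"), c("residue_a", "residue_b"),
             c("restype_a", "restype_b"))
  for (cols in ab) {
    if (all(cols %in% names(records))) {
      out[[cols[1]]] <- ifelse(swap, records[[cols[2]]], records[[cols[1]]])
      out[[cols[2]]] <- ifelse(swap, records[[cols[1]]], records[[cols[2]]])
    }
  }
  out
}

#' Deduplicate cross-link records to unique residue pairs
#'
#' Collapses records to unique unordered residue pairs per chemistry and
#' condition: (a, b) and (b, a) are the same pair, and repeated
#' identifications of the same pair (different peptides, charge states,
#' replicates) collapse to one row with a record count.
#'
#' @param records Tibble of cross-link records.
#' @param by Additional grouping columns beyond the pair itself; default
#'   `c("chemistry", "condition")`.
#' @return Tibble of unique pairs with an `n_records` count.
#' @export
xl_deduplicate <- function(records, by = c("chemistry", "condition")) {
  canon <- canonicalize_pairs(records)
  keys <- c("protein_a", "residue_a", "protein_b", "residue_b",
            intersect(by, names(canon)))
  canon |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      restype_a = dplyr::first(.data$restype_a),
      restype_b = dplyr::first(.data$restype_b),
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Domain map for DnaJB8
#'
#' Default 1-based inclusive domain intervals for the 232-residue Hsp40
#' co-chaperone DnaJB8: J-domain (JD) 1-82, glycine/phenylalanine-rich
#' (G/F) 83-139, serine/threonine-rich (S/T) 140-169, C-terminal domain
#' (CTD) 170-232. The G/F <-> S/T boundary is approximate (not precisely
#' annotated) and configurable.
#'
#' @param gf_st_boundary Last residue of the G/F region (default 139).
#' @return Tibble with columns `domain`, `start`, `end` and attribute
#'   `approximate_boundaries`.
#' @export
dnajb8_domains <- function(gf_st_boundary = 139) {
  stopifnot(gf_st_boundary > 83, gf_st_boundary < 169)
  out <- tibble::tibble(
    domain = c("JD", "G/F", "S/T", "CTD"),
    start = c(1L, 83L, gf_st_boundary + 1L, 170L),
    end = c(82L, as.integer(gf_st_boundary), 169L, 232L)
  )
  attr(out, "approximate_boundaries") <- "G/F-S/T"
  out
}

domain_of <- function(residues, domain_map) {
  idx <- vapply(residues, function(r) {
    hit <- which(domain_map$start <= r & r <= domain_map$end)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  ifelse(is.na(idx), "unassigned", domain_map$domain[idx])
}

#' Classify residue pairs by domain
#'
#' Labels each pair `"X-Y"` (en dash) with X, Y the domains of the two
#' residues, alphabetically ordered so classification is symmetric:
#' a JD-to-CTD link is always labelled `"CTD–JD"`. Residues outside every
#' interval classify as `"unassigned"`. When `subfeatures` is supplied
#' (e.g. a putative helix H5 inside the G/F region), pairs touching a
#' sub-feature get an extra annotation column.
#'
#' @param pairs Tibble with `residue_a`, `residue_b` columns.
#' @param domain_map Tibble as from [dnajb8_domains()].
#' @param subfeatures Optional tibble with `feature`, `start`, `end`.
#' @return `pairs` with `domain_a`, `domain_b`, `class` (and `subfeature`)
#'   columns added.
#' @export
classify_pairs <- function(pairs, domain_map = dnajb8_domains(),
                           subfeatures = NULL) {
  da <- domain_of(pairs$residue_a, domain_map)
  db <- domain_of(pairs$residue_b, domain_map)
  cls <- purrr::map2_chr(da, db, function(x, y) {
    paste(sort(c(x, y)), collapse = "–")
  })
  out <- dplyr::mutate(pairs, domain_a = da, domain_b = db, class = cls)
  if (!is.null(subfeatures)) {
    hit <- function(r) {
      f <- subfeatures$feature[subfeatures$start <= r & r <= subfeatures$end]
      if (length(f) == 0) NA_character_ else paste(f, collapse = ",")
    }
    fa <- vapply(pairs$residue_a, hit, character(1))
    fb <- vapply(pairs$residue_b, hit, character(1))
    out$subfeature <- ifelse(
      is.na(fa) & is.na(fb), NA_character_,
      paste0(ifelse(is.na(fa), "", fa), "|", ifelse(is.na(fb), "", fb))
    )
  }
  out
}

#' Build a cross-link contact map
#'
#' Deduplicates records, classifies pairs by domain, and tallies pairs per
#' domain class. Per-class counts always sum to the total number of unique
#' pairs.
#'
#' @param records Tibble of cross-link records.
#' @param domain_map Tibble as from [dnajb8_domains()].
#' @param by Grouping passed to [xl_deduplicate()].
#' @param subfeatures Optional sub-feature tibble (see [classify_pairs()]).
#' @return An object of class `xl_contact_map`: list with `pairs` (classified
#'   unique pairs), `class_counts`, and `domain_map`.
#' @export
xl_contact_map <- function(records, domain_map = dnajb8_domains(),
                           by = c("chemistry", "condition"),
                           subfeatures = NULL) {
  pairs <- xl_deduplicate(records, by = by)
  # self-links are not contacts: the diagonal is excluded
  pairs <- pairs[!(pairs$protein_a == pairs$protein_b &
                     pairs$residue_a == pairs$residue_b), , drop = FALSE]
  pairs <- classify_pairs(pairs, domain_map, subfeatures)
  counts <- pairs |>
    dplyr::count(.data$class, name = "n_pairs") |>
    dplyr::arrange(.data$class)
  structure(
    list(pairs = pairs, class_counts = counts, domain_map = domain_map),
    class = "xl_contact_map"
  )
}

#' @export
print.xl_contact_map <- function(x, ...) {
  cat("<xl_contact_map> ", nrow(x$pairs), " unique pairs\n", sep = "")
  print(x$class_counts)
  invisible(x)
}

#' @rdname xl_contact_map
#' @param object An `xl_contact_map`.
#' @param ... Unused.
#' @method autoplot xl_contact_map
#' @export
autoplot.xl_contact_map <- function(object, ...) {
  p <- object$pairs
  lo <- pmin(p$residue_a, p$residue_b)
  hi <- pmax(p$residue_a, p$residue_b)
  df <- tibble::tibble(i = c(lo, hi), j = c(hi, lo),
                       class = rep(p$class, 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue", colour = "domain class",
                  title = "Cross-link contact map") +
    ggplot2::theme_minimal()
}

#' Compare cross-link pairs between two conditions
#'
#' Partitions the union of unique pairs seen in two condition tags into
#' `shared`, `a_only`, and `b_only`, with domain classes attached. The three
#' sets are disjoint and exhaustive.
#'
#' @param records Tibble of cross-link records.
#' @param cond_a,cond_b Condition tags present in `records$condition`.
#' @param domain_map Tibble as from [dnajb8_domains()].
#' @return Tibble of unique pairs with a `status` column
#'   (`shared` / `a_only` / `b_only`).
#' @export
compare_conditions <- function(records, cond_a, cond_b,
                               domain_map = dnajb8_domains()) {
  for (cond in c(cond_a, cond_b)) {
    if (!cond %in% records$condition) stop("unknown condition tag: ", cond)
  }
  pairs <- xl_deduplicate(records, by = "condition")
  key <- function(p) paste(p$protein_a, p$residue_a, p$protein_b, p$residue_b)
  a <- pairs[pairs$condition == cond_a, ]
  b <- pairs[pairs$condition == cond_b, ]
  all_pairs <- dplyr::distinct(
    dplyr::bind_rows(a, b),
    .data$protein_a, .data$residue_a, .data$protein_b, .data$residue_b,
    .keep_all = TRUE
  )
  in_a <- key(all_pairs) %in% key(a)
  in_b <- key(all_pairs) %in% key(b)
  all_pairs$status <- dplyr::case_when(
    in_a & in_b ~ "shared",
    in_a ~ "a_only",
    TRUE ~ "b_only"
  )
  all_pairs$condition <- NULL
  classify_pairs(all_pairs, domain_map)
}

#' Monolink frequency per residue
#'
#' Counts single-ended (monolink) modifications per residue and chemistry,
#' optionally comparing two conditions residue-by-residue. Near-identical
#' monolink frequencies across conditions indicate that surface reactivity
#' is unchanged and that differences in cross-link yield reflect contact
#' changes, not labelling artefacts.
#'
#' @param monolinks Tibble with `residue`, `chemistry`, `condition` columns.
#' @param cond_a,cond_b Optional pair of condition tags to compare.
#' @return Counts per (residue, chemistry, condition); when comparing,
#'   a wide tibble with per-residue counts in each condition and their
#'   difference.
#' @export
monolink_frequency <- function(monolinks, cond_a = NULL, cond_b = NULL) {
  counts <- monolinks |>
    dplyr::count(.data$residue, .data$chemistry, .data$condition,
                 name = "n")
  if (is.null(cond_a) || is.null(cond_b)) return(counts)
  counts |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(difference = .data[[cond_a]] - .data[[cond_b]]) |>
    dplyr::arrange(.data$residue)
}

#' Overlap of cross-links with covarying residue pairs
#'
#' A cross-link pair (i, j) overlaps the covariation signal if some
#' covarying pair with probability >= `prob_threshold` lies within
#' `window` residues of it on both coordinates (in either orientation).
#'
#' @param pairs Tibble with `residue_a`, `residue_b` (unique cross-link
#'   pairs), or an `xl_contact_map`.
#' @param covar_table Tibble with columns `i`, `j`, `probability`.
#' @param prob_threshold Probability cutoff (default 0.7).
#' @param window Residue window (default 2, i.e. +/-2).
#' @return List with `per_pair` (pairs with logical `overlaps`), `count`,
#'   and `fraction`.
#' @export
covariation_overlap <- function(pairs, covar_table, prob_threshold = 0.7,
                                window = 2) {
  if (window < 0) stop("window must be >= 0")
  if (inherits(pairs, "xl_contact_map")) pairs <- pairs$pairs
  stopifnot(all(covar_table$probability >= 0 & covar_table$probability <= 1))
  cov <- covar_table[covar_table$probability >= prob_threshold, ]
  hits <- purrr::map2_lgl(pairs$residue_a, pairs$residue_b, function(a, b) {
    any((abs(cov$i - a) <= window & abs(cov$j - b) <= window) |
          (abs(cov$i - b) <= window & abs(cov$j - a) <= window))
  })
  list(
    per_pair = dplyr::mutate(pairs, overlaps = hits),
    count = sum(hits),
    fraction = if (nrow(pairs) == 0) NA_real_ else mean(hits)
  )
}
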