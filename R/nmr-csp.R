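#' Read an HSQC peak list
#'
#' TSV with columns `assignment` (residue number, optionally with residue
#' type, e.g. `"K34"` or `"34"`), `dH_ppm`, `dN_ppm`.
#'
#' @param path TSV path.
#' @return Tibble with `assignment`, `residue`, `restype`, `dH_ppm`,
#'   `dN_ppm`.
#' @export
read_peaklist <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("assignment", "dH_ppm", "dN_ppm"), names(tbl))
  if (length(missing) > 0) {
    stop("missing peak-list column(s): ", paste(missing, collapse = ", "))
  }
  parse_peak_assignments(tibble::as_tibble(tbl))
}

parse_peak_assignments <- function(tbl) {
  a <- as.character(tbl$assignment)
  tbl$residue <- as.integer(gsub("[^0-9]", "", a))
  restype <- gsub("[^A-Za-z]", "", a)
  tbl$restype <- ifelse(nzchar(restype), toupper(restype), NA_character_)
  tbl
}

#' Match peaks between two HSQC peak lists
#'
#' When both lists carry shared assignments, peaks are matched by
#' assignment key. Otherwise matching is greedy nearest-neighbour within a
#' tolerance ellipse in (dH, dN) space (each axis scaled by its tolerance),
#' ascending by scaled distance, each peak matched at most once.
#'
#' @param reference,titrated Peak-list tibbles (see [read_peaklist()]).
#' @param tol_h,tol_n Matching tolerances in ppm for 1H and 15N
#'   (defaults 0.05 and 0.5).
#' @return List with `matched` (tibble with reference and titrated shifts
#'   side by side), `unmatched_reference`, `unmatched_titrated`.
#' @export
match_peaks <- function(reference, titrated, tol_h = 0.05, tol_n = 0.5) {
  stopifnot(nrow(reference) > 0, nrow(titrated) > 0)
  if ("assignment" %in% names(reference) &&
      "assignment" %in% names(titrated) &&
      length(intersect(reference$assignment, titrated$assignment)) > 0) {
    matched <- dplyr::inner_join(
      reference, titrated,
      by = "assignment", suffix = c("_ref", "_titr")
    )
    un_ref <- reference[!reference$assignment %in% titrated$assignment, ]
    un_titr <- titrated[!titrated$assignment %in% reference$assignment, ]
    return(list(matched = matched, unmatched_reference = un_ref,
                unmatched_titrated = un_titr))
  }
  # scaled distances between all peak pairs
  dh <- outer(reference$dH_ppm, titrated$dH_ppm, `-`) / tol_h
  dn <- outer(reference$dN_ppm, titrated$dN_ppm, `-`) / tol_n
  d2 <- dh^2 + dn^2
  cand <- which(d2 <= 1, arr.ind = TRUE)
  ord <- order(d2[cand])
  cand <- cand[ord, , drop = FALSE]
  used_ref <- logical(nrow(reference))
  used_titr <- logical(nrow(titrated))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_ref[i] && !used_titr[j]) {
      used_ref[i] <- TRUE; used_titr[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  idx <- do.call(rbind, pairs)
  if (is.null(idx)) idx <- matrix(integer(), ncol = 2)
  ref_m <- reference[idx[, 1], , drop = FALSE]
  titr_m <- titrated[idx[, 2], , drop = FALSE]
  names(titr_m) <- paste0(names(titr_m), "_titr")
  names(ref_m) <- paste0(names(ref_m), "_ref")
  matched <- dplyr::bind_cols(ref_m, titr_m)
  # unify column naming with the assignment-join branch
  if ("assignment_ref" %in% names(matched)) {
    matched <- dplyr::rename(matched, assignment = "assignment_ref")
  }
  list(
    matched = matched,
    unmatched_reference = reference[!used_ref, , drop = FALSE],
    unmatched_titrated = titrated[!used_titr, , drop = FALSE]
  )
}

#' Combined chemical shift perturbation
#'
#' Per-residue combined 1H/15N displacement
#' \eqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}}
#' with nitrogen scaling \eqn{\alpha} (default 0.14, the standard amide
#' convention).
#'
#' @param matched Matched-pair tibble from [match_peaks()] (columns
#'   `dH_ppm_ref`, `dH_ppm_titr`, `dN_ppm_ref`, `dN_ppm_titr`).
#' @param n_scale Nitrogen scaling factor (default 0.14).
#' @return Tibble of class `csp_profile` with `residue`, `restype`,
#'   `delta_h`, `delta_n`, `csp` (ppm).
#' @export
csp <- function(matched, n_scale = 0.14) {
  col <- function(...) {
    for (nm in c(...)) if (nm %in% names(matched)) return(matched[[nm]])
    NULL
  }
  res <- col("residue_ref", "residue")
  rt <- col("restype_ref", "restype")
  dh <- matched$dH_ppm_titr - matched$dH_ppm_ref
  dn <- matched$dN_ppm_titr - matched$dN_ppm_ref
  out <- tibble::tibble(
    residue = res,
    restype = rt %||% NA_character_,
    delta_h = dh,
    delta_n = dn,
    csp = sqrt(dh^2 + (n_scale * dn)^2)
  )
  attr(out, "n_scale") <- n_scale
  class(out) <- c("csp_profile", class(out))
  out
}

#' Call perturbed residues from a CSP profile
#'
#' Under the `"mean"` rule the threshold is the mean CSP over non-proline
#' residues; under a fixed rule it is the supplied value in ppm (e.g.
#' 0.005 ppm). Residues are flagged when CSP strictly exceeds the
#' threshold.
#'
#' @param profile A `csp_profile` from [csp()].
#' @param rule `"mean"` or a numeric fixed threshold in ppm.
#' @return `profile` with `threshold` and logical `perturbed` columns.
#' @export
call_perturbed <- function(profile, rule = "mean") {
  stopifnot(nrow(profile) > 0)
  if (identical(rule, "mean")) {
    non_pro <- is.na(profile$restype) | profile$restype != "P"
    threshold <- mean(profile$csp[non_pro])
  } else {
    stopifnot(is.numeric(rule), rule >= 0)
    threshold <- rule
  }
  dplyr::mutate(profile, threshold = threshold,
                perturbed = .data$csp > threshold)
}

#' Per-residue CSP trajectories across a titration series
#'
#' Combines CSP profiles computed at increasing molar ratios into
#' per-residue trajectories and flags non-monotonic ones for review
#' (fast-exchange titrations should shift monotonically with ligand).
#'
#' @param profiles Named list of `csp_profile` objects; names are molar
#'   ratios (e.g. `"0.125"`, `"2"`), coerced to numeric for ordering.
#' @return List with `trajectories` (tibble: residue x ratio CSP) and
#'   `non_monotonic` (residues whose CSP is not non-decreasing in ratio,
#'   beyond a 1e-9 slack).
#' @export
titration_series <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  ratios <- as.numeric(names(profiles))
  stopifnot(!anyNA(ratios))
  common <- Reduce(intersect, lapply(profiles, `[[`, "residue"))
  all_res <- Reduce(union, lapply(profiles, `[[`, "residue"))
  missing <- setdiff(all_res, common)
  if (length(missing) > 0) {
    stop("residue(s) missing at some titration point: ",
         paste(sort(missing), collapse = ", "))
  }
  long <- purrr::imap_dfr(profiles, function(p, ratio) {
    tibble::tibble(residue = p$residue, ratio = as.numeric(ratio),
                   csp = p$csp)
  }) |>
    dplyr::arrange(.data$residue, .data$ratio)
  non_mono <- long |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(mono = all(diff(.data$csp) >= -1e-9),
                     .groups = "drop") |>
    dplyr::filter(!.data$mono) |>
    dplyr::pull(.data$residue)
  list(trajectories = long, non_monotonic = non_mono)
}

#' Plot a CSP profile as a per-residue bar chart
#'
#' @param profile A `csp_profile`, optionally after [call_perturbed()].
#' @return A ggplot object.
#' @export
plot_csp <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$residue,
                                             y = .data$csp)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "residue", y = "combined CSP (ppm)",
                  title = "Chemical shift perturbation") +
    ggplot2::theme_minimal()
  if ("threshold" %in% names(profile)) {
    p <- p + ggplot2::geom_hline(yintercept = profile$threshold[1],
                                 colour = "red", linetype = 2)
  }
  p
}
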