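#' Default per-residue charge rule
#'
#' D/E = -1, K/R = +1, all else 0. Histidine is uncharged by default
#' (pH 7.4 convention); pass `histidine = 0.1` or `0.5` for partial
#' protonation.
#'
#' @param histidine Charge assigned to histidine (default 0).
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
charge_rule <- function(histidine = 0) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- stats::setNames(rep(0, length(aa)), aa)
  ch[c("D", "E")] <- -1
  ch[c("K", "R")] <- 1
  ch["H"] <- histidine
  ch
}

#' Net charge per residue (NCPR) profile
#'
#' Sliding-window mean of per-residue charges: the average charge over a
#' `window`-residue window, reported at the window start (1-based) or
#' centre. Values lie in \[-1, 1\].
#'
#' @param sequence Protein sequence (one-letter codes, single string).
#' @param window Window size in residues (default 10).
#' @param rule Named charge vector (default [charge_rule()]).
#' @param align `"start"` (default) or `"center"` window alignment.
#' @param permissive Treat non-standard residues as charge 0 instead of
#'   erroring.
#' @return Tibble with `position`, `ncpr`; attributes `window`, `align`.
#' @export
#' @examples
#' ncpr("KKKKKDDDDD", window = 10)$ncpr # 0
ncpr <- function(sequence, window = 10, rule = charge_rule(),
                 align = c("start", "center"), permissive = FALSE) {
  align <- match.arg(align)
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (window < 1 || window > n) stop("window must be in [1, sequence length]")
  unknown <- setdiff(unique(aa), names(rule))
  if (length(unknown) > 0) {
    if (!permissive) {
      stop("non-standard residue(s): ", paste(unknown, collapse = ", "))
    }
    rule[unknown] <- 0
  }
  charges <- unname(rule[aa])
  cs <- c(0, cumsum(charges))
  vals <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  pos <- if (align == "start") seq_len(n - window + 1) else
    seq_len(n - window + 1) + floor((window - 1) / 2)
  out <- tibble::tibble(position = pos, ncpr = vals)
  attr(out, "window") <- window
  attr(out, "align") <- align
  out
}

#' Contiguous charge blocks in an NCPR profile
#'
#' Maximal runs of consecutive positions whose NCPR magnitude is at least
#' `threshold`, with a consistent sign, ordered and non-overlapping. These
#' are the charge blocks whose complementarity (a basic block on one domain
#' facing an acidic block on another) underlies electrostatic domain-domain
#' contacts.
#'
#' @param profile Tibble from [ncpr()] (columns `position`, `ncpr`).
#' @param threshold Magnitude cutoff in (0, 1\].
#' @return Tibble with `start`, `end` (positions), `sign` (`"+"`/`"-"`),
#'   `mean_ncpr`.
#' @export
charge_blocks <- function(profile, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  s <- sign(profile$ncpr) * (abs(profile$ncpr) >= threshold)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  if (!any(keep)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          sign = character(), mean_ncpr = numeric()))
  }
  tibble::tibble(
    start = profile$position[starts[keep]],
    end = profile$position[ends[keep]],
    sign = ifelse(r$values[keep] > 0, "+", "-"),
    mean_ncpr = purrr::map2_dbl(starts[keep], ends[keep],
                                ~ mean(profile$ncpr[.x:.y]))
  )
}

#' Plot an NCPR profile
#'
#' @param profile Tibble from [ncpr()].
#' @param domain_map Optional domain map for shading.
#' @return A ggplot object.
#' @export
plot_ncpr <- function(profile, domain_map = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position,
                                             y = .data$ncpr))
  if (!is.null(domain_map)) {
    p <- p + ggplot2::geom_rect(
      data = domain_map, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -1, ymax = 1, fill = .data$domain),
      alpha = 0.15
    )
  }
  p +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_col(ggplot2::aes(fill = NULL),
                      fill = ifelse(profile$ncpr >= 0, "firebrick",
                                    "steelblue")) +
    ggplot2::labs(x = "residue (window start)", y = "NCPR",
                  title = "Net charge per residue") +
    ggplot2::theme_minimal()
}
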