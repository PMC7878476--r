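#' Monoisotopic atomic masses
#'
#' Returns the table of monoisotopic atomic masses (IUPAC, Da) used for all
#' mass accounting in the package. `D` denotes deuterium (2H); the H/D mass
#' difference (1.0062767 Da) drives the light/heavy precursor deltas of
#' isotope-labelled cross-linkers.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' atomic_masses()[["O"]]
atomic_masses <- function() {
  c(
    H = 1.00782503207,
    D = 2.01410177785,
    C = 12.0,
    N = 14.0030740048,
    O = 15.9949146196,
    S = 31.97207100,
    P = 30.97376163
  )
}

#' Parse an elemental formula
#'
#' Parses a Hill-style formula string such as `"C6H14N4O2"` into named
#' element counts. An empty string is the empty composition.
#'
#' @param formula Formula string, or an already-named numeric vector of
#'   element counts (returned unchanged after validation).
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) && length(formula) > 0) {
      stop("numeric formula must be a named vector of element counts")
    }
    if (any(formula < 0)) stop("element counts must be >= 0")
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1)
  if (!nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("malformed formula: ", formula)
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.numeric(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  tapply(counts, elems, sum)[unique(elems)]
}

#' Monoisotopic mass of an elemental composition
#'
#' @param formula Formula string (e.g. `"H2O"`) or named count vector.
#' @return Mass in Da; the empty composition has mass 0.
#' @export
#' @examples
#' formula_mass("H2O")      # 18.010565
#' formula_mass("C2H3NO")   # carbamidomethyl, 57.02146
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0) return(0)
  masses <- atomic_masses()
  unknown <- setdiff(names(counts), names(masses))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  sum(counts * masses[names(counts)])
}

#' Define a cross-linker chemistry
#'
#' A chemistry bundles everything the pipeline needs to know about one
#' cross-linking reagent: which residues it joins, the elemental composition
#' added by the bridge, how many waters are lost on reaction, how many H->D
#' substitutions the heavy isotopologue carries, the single-ended (monolink)
#' product compositions, and the distance bound within which a cross-link is
#' considered geometrically satisfied.
#'
#' @param name Chemistry name.
#' @param reactive_a,reactive_b Character vectors of one-letter residue codes
#'   for the two reactive ends.
#' @param bridge Elemental formula added upon cross-linking (may be `""` for
#'   a zero-length coupler such as DMTMM).
#' @param water_loss Number of waters lost per cross-linking reaction.
#' @param label_count Number of H->D substitutions in the heavy form.
#' @param monolinks Named list of single-ended products, each a
#'   `list(formula =, water_loss =)`.
#' @param max_distance Distance bound in Angstrom for satisfaction scoring.
#' @return An object of class `crosslinker_spec`.
#' @export
crosslinker_spec <- function(name, reactive_a, reactive_b, bridge = "",
                             water_loss = 0L, label_count = 0L,
                             monolinks = list(), max_distance) {
  stopifnot(length(reactive_a) > 0, length(reactive_b) > 0,
            label_count >= 0, max_distance > 0)
  structure(
    list(
      name = name,
      reactive_a = reactive_a,
      reactive_b = reactive_b,
      bridge = bridge,
      water_loss = water_loss,
      label_count = label_count,
      monolinks = monolinks,
      max_distance = max_distance
    ),
    class = "crosslinker_spec"
  )
}

#' @export
print.crosslinker_spec <- function(x, ...) {
  cat("<crosslinker_spec> ", x$name, "\n", sep = "")
  cat("  reactive: {", paste(x$reactive_a, collapse = ","), "} x {",
      paste(x$reactive_b, collapse = ","), "}\n", sep = "")
  cat("  crosslink mass shift: ",
      format(crosslink_mass_shift(x), digits = 9), " Da\n", sep = "")
  ml <- monolink_mass_shifts(x)
  if (length(ml)) {
    cat("  monolinks: ",
        paste(sprintf("%s = %.6f Da", names(ml), ml), collapse = "; "),
        "\n", sep = "")
  }
  cat("  heavy/light delta: ", format(heavy_light_delta(x), digits = 8),
      " Da\n  max distance: ", x$max_distance, " A\n", sep = "")
  invisible(x)
}

#' Built-in cross-linker chemistry registry
#'
#' Three chemistries commonly combined in XL-MS of charge-rich proteins:
#'
#' * **ADH** (adipic acid dihydrazide): links carboxylate pairs (D/E x D/E)
#'   through a 6-carbon bridge, losing two waters; used as an h8/d8 isotope
#'   pair (8 deuteriums). Acid-acid satisfaction bound 21 Angstrom.
#' * **DMTMM**: zero-length coupling of lysine amines to carboxylates by
#'   direct amide bond formation with loss of one water; no monolink
#'   product. Acid-lysine bound 16 Angstrom.
#' * **DSS** (disuccinimidyl suberate): lysine-lysine NHS-ester linker,
#'   h12/d12 pair; hydrolyzed and aminolyzed monolink products. The distance
#'   bound is configurable; the default 30 Angstrom follows the common
#'   Calpha-Calpha convention for DSS.
#'
#' @param dss_max_distance Distance bound for DSS (Angstrom).
#' @param n_terminal_amine Treat the protein N-terminus as an additional
#'   amine-reactive site for DSS/DMTMM (adds `"^"` to the reactive sets).
#'   Off by default.
#' @return Named list of [crosslinker_spec] objects (`adh`, `dmtmm`, `dss`).
#' @export
#' @examples
#' xl_chemistries()$adh
xl_chemistries <- function(dss_max_distance = 30, n_terminal_amine = FALSE) {
  amine <- if (n_terminal_amine) c("K", "^") else "K"
  list(
    adh = crosslinker_spec(
      name = "adh",
      reactive_a = c("D", "E"), reactive_b = c("D", "E"),
      bridge = "C6H14N4O2", water_loss = 2L, label_count = 8L,
      monolinks = list(hydrolyzed = list(formula = "C6H14N4O2", water_loss = 1L)),
      max_distance = 21
    ),
    dmtmm = crosslinker_spec(
      name = "dmtmm",
      reactive_a = amine, reactive_b = c("D", "E"),
      bridge = "", water_loss = 1L, label_count = 0L,
      monolinks = list(),
      max_distance = 16
    ),
    dss = crosslinker_spec(
      name = "dss",
      reactive_a = amine, reactive_b = amine,
      bridge = "C8H10O2", water_loss = 0L, label_count = 12L,
      monolinks = list(
        hydrolyzed = list(formula = "C8H12O3", water_loss = 0L),
        aminolyzed = list(formula = "C8H13NO2", water_loss = 0L)
      ),
      max_distance = dss_max_distance
    )
  )
}

#' Cross-link mass shift of a chemistry
#'
#' Mass added to the cross-linked peptide pair: the bridge composition minus
#' the waters lost in the coupling reaction. Negative for zero-length
#' couplers (DMTMM: net loss of one water).
#'
#' @param spec A [crosslinker_spec].
#' @return Mass shift in Da.
#' @export
#' @examples
#' crosslink_mass_shift(xl_chemistries()$adh)   # 138.09055
#' crosslink_mass_shift(xl_chemistries()$dmtmm) # -18.010565
crosslink_mass_shift <- function(spec) {
  stopifnot(inherits(spec, "crosslinker_spec"))
  formula_mass(spec$bridge) - spec$water_loss * formula_mass("H2O")
}

#' Monolink mass shifts of a chemistry
#'
#' One mass per single-ended (monolink) product composition, e.g. the
#' hydrolyzed product in which one reactive end coupled to the protein and
#' the other quenched with water.
#'
#' @param spec A [crosslinker_spec].
#' @return Named numeric vector of mass shifts in Da (empty for chemistries
#'   with no monolink product, such as DMTMM).
#' @export
#' @examples
#' monolink_mass_shifts(xl_chemistries()$adh) # hydrolyzed = 156.1011
monolink_mass_shifts <- function(spec) {
  stopifnot(inherits(spec, "crosslinker_spec"))
  vapply(spec$monolinks, function(m) {
    formula_mass(m$formula) - m$water_loss * formula_mass("H2O")
  }, numeric(1))
}

#' Heavy/light precursor mass difference
#'
#' The precursor mass difference between the deuterated (heavy) and
#' protonated (light) forms of an isotope-coded cross-linker:
#' `label_count * (m(D) - m(H))`.
#'
#' @param spec A [crosslinker_spec].
#' @return Delta in Da.
#' @export
#' @examples
#' heavy_light_delta(xl_chemistries()$adh) # 8.05021 for ADH-h8/d8
heavy_light_delta <- function(spec) {
  stopifnot(inherits(spec, "crosslinker_spec"))
  m <- atomic_masses()
  spec$label_count * (m[["D"]] - m[["H"]])
}

#' Relative mass error in parts per million
#'
#' @param observed,theoretical Masses in Da; `theoretical` must be > 0.
#' @return Signed ppm error `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be > 0")
  1e6 * (observed - theoretical) / theoretical
}
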