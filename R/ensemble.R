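#' Read a multi-MODEL PDB file as a structure ensemble
#'
#' Thin wrapper over [bio3d::read.pdb()] that converts each MODEL into a
#' tidy coordinate tibble (`residue`, `restype`, `atom`, `x`, `y`, `z`) and
#' returns them as a `structure_ensemble`.
#'
#' @param path PDB file path (single- or multi-MODEL).
#' @param chain Optional chain id to keep (default: first chain).
#' @return A `structure_ensemble` (list of model tibbles).
#' @export
read_ensemble_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  keep <- which(at$chain == chain & at$type == "ATOM")
  n_models <- dim(pdb$xyz)[1]
  models <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    tibble::tibble(
      residue = at$resno[keep],
      restype = bio3d::aa321(at$resid[keep]),
      atom = at$elety[keep],
      x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3]
    )
  })
  as_structure_ensemble(models)
}

#' Assemble a structure ensemble from model tibbles or bead chains
#'
#' @param models List of coordinate tibbles (columns `residue`, `x`, `y`,
#'   `z`; optionally `restype`, `atom`).
#' @return A `structure_ensemble`.
#' @export
as_structure_ensemble <- function(models) {
  stopifnot(length(models) >= 1)
  models <- lapply(models, tibble::as_tibble)
  structure(models, class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("<structure_ensemble> ", length(x), " model(s), ",
      length(unique(x[[1]]$residue)), " residues\n", sep = "")
  invisible(x)
}

# Coordinates of one residue under an atom rule with fallback:
#  CA -> CA; CB -> CB else CA (glycine); terminal -> side-chain terminal
#  atom of the reactive group (NZ/OD/OE...) else CB else CA.
atom_rule_coords <- function(model, residue, atom_rule = "CA") {
  rows <- model[model$residue == residue, , drop = FALSE]
  if (nrow(rows) == 0) stop("residue ", residue, " not present in model")
  if (!"atom" %in% names(rows)) {
    return(as.numeric(rows[1, c("x", "y", "z")]))
  }
  order <- switch(atom_rule,
    CA = "CA",
    CB = c("CB", "CA"),
    terminal = c("NZ", "OE2", "OE1", "OD2", "OD1", "CB", "CA"),
    stop("unknown atom rule: ", atom_rule)
  )
  for (a in order) {
    hit <- which(rows$atom == a)
    if (length(hit) > 0) return(as.numeric(rows[hit[1], c("x", "y", "z")]))
  }
  stop("no atom matching rule '", atom_rule, "' (or fallback) for residue ",
       residue)
}

#' Euclidean distance between two residues in a model
#'
#' @param model Coordinate tibble (one structure model or bead chain).
#' @param residue_a,residue_b Residue numbers.
#' @param atom_rule `"CA"`, `"CB"` (falls back to CA), or `"terminal"`
#'   (reactive side-chain terminal atom, falling back to CB then CA).
#' @return Distance in Angstrom.
#' @export
pair_distance <- function(model, residue_a, residue_b, atom_rule = "CA") {
  pa <- atom_rule_coords(model, residue_a, atom_rule)
  pb <- atom_rule_coords(model, residue_b, atom_rule)
  sqrt(sum((pa - pb)^2))
}

#' Is a cross-link satisfied by a model?
#'
#' A link is satisfied when the inter-residue distance is within (inclusive)
#' the distance bound of its chemistry: 21 Angstrom for acid-acid (ADH),
#' 16 Angstrom for acid-lysine (DMTMM) under the package defaults.
#'
#' @param link One-row tibble (or list) with `residue_a`, `residue_b`,
#'   `chemistry`.
#' @param model Coordinate tibble.
#' @param registry Chemistry registry (default [xl_chemistries()]).
#' @param atom_rule See [pair_distance()].
#' @return Logical.
#' @export
xl_satisfied <- function(link, model, registry = xl_chemistries(),
                         atom_rule = "CA") {
  spec <- registry[[link$chemistry[1]]]
  if (is.null(spec)) stop("chemistry not registered: ", link$chemistry[1])
  pair_distance(model, link$residue_a[1], link$residue_b[1], atom_rule) <=
    spec$max_distance
}

# distance matrix (models x links); NA where a residue is missing
link_distance_matrix <- function(links, ensemble, atom_rule) {
  vapply(seq_along(ensemble), function(m) {
    model <- ensemble[[m]]
    vapply(seq_len(nrow(links)), function(l) {
      tryCatch(
        pair_distance(model, links$residue_a[l], links$residue_b[l],
                      atom_rule),
        error = function(e) NA_real_
      )
    }, numeric(1))
  }, numeric(nrow(links)))
}

#' Score cross-link satisfaction over a structural ensemble
#'
#' Evaluates every link against every model with chemistry-specific distance
#' bounds (inclusive), reporting per-model satisfied counts, the per-link
#' fraction of models satisfying it, the histogram of satisfied counts over
#' the ensemble, and the best model(s). Models missing a linked residue
#' count that link as unsatisfiable (FALSE) and are flagged.
#'
#' @param links Tibble with `residue_a`, `residue_b`, `chemistry`.
#' @param ensemble A `structure_ensemble` (or list of coordinate tibbles).
#' @param registry Chemistry registry (default [xl_chemistries()]).
#' @param atom_rule See [pair_distance()].
#' @return Object of class `xl_satisfaction`: list with `per_model`,
#'   `per_link`, `matrix` (links x models logical), `histogram`,
#'   `best_models`, `flagged_models`.
#' @export
score_ensemble <- function(links, ensemble, registry = xl_chemistries(),
                           atom_rule = "CA") {
  if (length(ensemble) == 0) stop("empty ensemble")
  if (nrow(links) == 0) stop("empty link list")
  bounds <- vapply(links$chemistry, function(chem) {
    spec <- registry[[chem]]
    if (is.null(spec)) stop("chemistry not registered: ", chem)
    spec$max_distance
  }, numeric(1))
  dmat <- link_distance_matrix(links, ensemble, atom_rule)
  dmat <- matrix(dmat, nrow = nrow(links))
  sat <- !is.na(dmat) & dmat <= bounds
  counts <- colSums(sat)
  hist <- tabulate(counts + 1L, nbins = nrow(links) + 1L)
  names(hist) <- 0:nrow(links)
  best <- which(counts == max(counts))
  structure(
    list(
      per_model = tibble::tibble(model = seq_along(ensemble),
                                 n_satisfied = counts,
                                 n_links = nrow(links)),
      per_link = dplyr::mutate(
        links,
        max_distance = bounds,
        fraction_satisfied = rowMeans(sat)
      ),
      matrix = sat,
      histogram = hist,
      best_models = best,
      flagged_models = which(colSums(is.na(dmat)) > 0)
    ),
    class = "xl_satisfaction"
  )
}

#' @export
print.xl_satisfaction <- function(x, ...) {
  nm <- nrow(x$per_model)
  cat("<xl_satisfaction> ", nm, " model(s) x ", nrow(x$per_link),
      " link(s)\n", sep = "")
  best <- x$best_models[1]
  cat("  best model ", best, ": ", x$per_model$n_satisfied[best], "/",
      x$per_link |> nrow(), " links satisfied",
      if (length(x$best_models) > 1)
        paste0(" (", length(x$best_models), "-way tie)") else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname score_ensemble
#' @param x An `xl_satisfaction` object.
#' @param ... Unused.
#' @method tidy xl_satisfaction
#' @export
tidy.xl_satisfaction <- function(x, ...) x$per_link

#' @rdname score_ensemble
#' @method glance xl_satisfaction
#' @export
glance.xl_satisfaction <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$per_model),
    n_links = nrow(x$per_link),
    best_model = x$best_models[1],
    best_satisfied = max(x$per_model$n_satisfied),
    n_best_ties = length(x$best_models),
    mean_satisfied = mean(x$per_model$n_satisfied)
  )
}

#' @rdname score_ensemble
#' @param object An `xl_satisfaction` object.
#' @method autoplot xl_satisfaction
#' @export
autoplot.xl_satisfaction <- function(object, ...) {
  df <- tibble::tibble(
    n_satisfied = as.integer(names(object$histogram)),
    n_models = as.numeric(object$histogram)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_satisfied,
                                   y = .data$n_models)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cross-links satisfied", y = "models",
                  title = "Ensemble cross-link satisfaction") +
    ggplot2::theme_minimal()
}

#' Satisfied-count curves across a range of distance thresholds
#'
#' Robustness check for the chemistry distance bounds: recomputes per-model
#' satisfied counts at each threshold (applied to all links alike).
#' Counts are non-decreasing in the threshold.
#'
#' @param links Tibble with `residue_a`, `residue_b`.
#' @param ensemble A `structure_ensemble`.
#' @param thresholds Ascending positive thresholds in Angstrom.
#' @param atom_rule See [pair_distance()].
#' @return Tibble with `threshold`, `model`, `n_satisfied`.
#' @export
threshold_sensitivity <- function(links, ensemble, thresholds,
                                  atom_rule = "CA") {
  if (any(thresholds < 0)) stop("thresholds must be non-negative")
  stopifnot(!is.unsorted(thresholds))
  dmat <- matrix(link_distance_matrix(links, ensemble, atom_rule),
                 nrow = nrow(links))
  purrr::map_dfr(thresholds, function(th) {
    tibble::tibble(
      threshold = th,
      model = seq_along(ensemble),
      n_satisfied = colSums(!is.na(dmat) & dmat <= th)
    )
  })
}
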