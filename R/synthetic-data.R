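#' Seed derivation for generator streams
#'
#' Each generator derives its own RNG stream from (seed, stage name), so
#' adding a generator to a workflow never perturbs the fixtures produced by
#' another. The derived seed is a deterministic 31-bit hash.
#'
#' @param seed Integer master seed.
#' @param stage Stage name (character).
#' @return Integer seed below 2^31.
#' @export
stream_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) %% 1000003) * 2017 + h) %% .Machine$integer.max
}

#' Generate a self-avoiding random bead chain
#'
#' Random walk with a fixed 3.8 Angstrom step (the Calpha virtual bond)
#' rejecting any placement closer than `min_dist` to an existing bead;
#' dead ends trigger a restart. Used as the ground-truth compact
#' conformation from which cross-links are planted.
#'
#' @param n Number of beads (>= 2).
#' @param seed Integer seed.
#' @param min_dist Minimum pairwise distance (Angstrom, default 3.5).
#' @param bond Step length (default 3.8).
#' @param max_attempts Chain-level restart cap.
#' @return A `bead_chain`.
#' @export
gen_chain <- function(n, seed = 1, min_dist = 3.5, bond = 3.8,
                      max_attempts = 200) {
  stopifnot(n >= 2)
  set.seed(stream_seed(seed, "gen_chain"))
  for (attempt in seq_len(max_attempts)) {
    X <- matrix(NA_real_, n, 3)
    X[1, ] <- 0
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:60) {
        u <- stats::rnorm(3)
        step <- bond * u / sqrt(sum(u^2))
        cand <- X[i - 1, ] + step
        prev <- X[seq_len(i - 2), , drop = FALSE]
        if (nrow(prev) == 0 ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_dist) {
          X[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(bead_chain(X))
  }
  stop("could not build a self-avoiding chain of length ", n,
       " after ", max_attempts, " attempts")
}

#' Jittered structural ensemble around a base conformation
#'
#' Each model is the base plus independent per-coordinate Gaussian jitter,
#' emulating a conformational ensemble spread around one fold.
#'
#' @param base A `bead_chain` or coordinate tibble.
#' @param n_models Number of models (>= 1).
#' @param jitter Gaussian jitter SD in Angstrom (>= 0).
#' @param seed Integer seed.
#' @return A `structure_ensemble`.
#' @export
gen_ensemble <- function(base, n_models, jitter = 1, seed = 1) {
  stopifnot(n_models >= 1, jitter >= 0)
  set.seed(stream_seed(seed, "gen_ensemble"))
  X <- as_coord_matrix(base)
  n <- nrow(X)
  models <- lapply(seq_len(n_models), function(m) {
    Xm <- X + matrix(stats::rnorm(n * 3, sd = jitter), n, 3)
    tibble::tibble(residue = seq_len(n),
                   x = Xm[, 1], y = Xm[, 2], z = Xm[, 3])
  })
  as_structure_ensemble(models)
}

#' Plant cross-links with known ground truth on a model
#'
#' Samples `n_true` residue pairs whose distance in the source model is
#' within the chemistry bound and `n_decoy` pairs beyond the bound plus a
#' 2 Angstrom margin; residue types are rewritten to be compatible with the
#' chemistry's reactive pair. The returned table carries the planted truth
#' label, enabling label round-trip tests of satisfaction scoring.
#'
#' @param model Coordinate tibble or `bead_chain` (the ground-truth
#'   conformation).
#' @param chemistry A [crosslinker_spec] or registry name.
#' @param n_true,n_decoy Numbers of satisfied / unsatisfiable pairs.
#' @param seed Integer seed.
#' @param min_separation Minimum |i - j| sequence separation (default 3).
#' @param condition Condition tag for the records.
#' @param registry Chemistry registry used when `chemistry` is a name.
#' @return Tibble of cross-link records with a logical `planted_true`
#'   column.
#' @export
plant_crosslinks <- function(model, chemistry, n_true, n_decoy, seed = 1,
                             min_separation = 3, condition = "synthetic",
                             registry = xl_chemistries()) {
  spec <- if (inherits(chemistry, "crosslinker_spec")) chemistry else
    registry[[chemistry]]
  if (is.null(spec)) stop("chemistry not registered: ", chemistry)
  set.seed(stream_seed(seed, "plant_crosslinks"))
  X <- as_coord_matrix(model)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  sep_ok <- abs(idx[, 1] - idx[, 2]) >= min_separation
  d <- D[idx]
  true_pool <- which(sep_ok & d <= spec$max_distance)
  decoy_pool <- which(sep_ok & d > spec$max_distance + 2)
  if (length(true_pool) < n_true || length(decoy_pool) < n_decoy) {
    stop("infeasible request: ", length(true_pool), " candidate true and ",
         length(decoy_pool), " candidate decoy pairs available")
  }
  pick_true <- if (n_true > 0) sample(true_pool, n_true) else integer(0)
  pick_decoy <- if (n_decoy > 0) sample(decoy_pool, n_decoy) else integer(0)
  rows <- c(pick_true, pick_decoy)
  ra <- sample(spec$reactive_a, length(rows), replace = TRUE)
  rb <- sample(spec$reactive_b, length(rows), replace = TRUE)
  tibble::tibble(
    protein_a = "synthetic", residue_a = idx[rows, 1], restype_a = ra,
    protein_b = "synthetic", residue_b = idx[rows, 2], restype_b = rb,
    chemistry = spec$name, condition = condition,
    score = NA_real_, intermolecular = "intra",
    distance = d[rows],
    planted_true = rep(c(TRUE, FALSE), c(n_true, n_decoy))
  )
}

#' Simulate an FP titration curve
#'
#' Exact one-site ligand-depletion signal plus seeded additive Gaussian
#' noise on mP. The defaults mirror a standard plate-based design: 0.2 uM
#' tracer, two-fold dilution series from a 150 uM top dose plus a zero
#' point, triplicate wells, sigma = 5 mP.
#'
#' @param kd Ground-truth dissociation constant (uM, > 0).
#' @param tracer Tracer concentration (uM).
#' @param top_dose Top titrant concentration (uM).
#' @param n_points Number of non-zero two-fold dilutions.
#' @param plateaus Named numeric: `free` and `bound` polarizations (mP).
#' @param sigma Gaussian noise SD (mP).
#' @param replicates Replicate wells per concentration.
#' @param seed Integer seed.
#' @return Tibble (`conc_uM`, `mP`, `replicate`) with `tracer_conc`,
#'   `kd_true` attributes.
#' @export
gen_fp_curve <- function(kd, tracer = 0.2, top_dose = 150, n_points = 12,
                         plateaus = c(free = 50, bound = 200), sigma = 5,
                         replicates = 3, seed = 1) {
  stopifnot(kd > 0, n_points >= 2)
  set.seed(stream_seed(seed, "gen_fp_curve"))
  conc <- c(top_dose / 2^(seq_len(n_points) - 1), 0)
  fb <- fraction_bound_one_site(tracer, conc, kd)
  mp_true <- plateaus[["free"]] + (plateaus[["bound"]] - plateaus[["free"]]) * fb
  out <- tidyr::expand_grid(
    tibble::tibble(conc_uM = conc, mp_true = mp_true),
    replicate = seq_len(replicates)
  )
  out$mP <- out$mp_true + stats::rnorm(nrow(out), sd = sigma)
  out$mp_true <- NULL
  attr(out, "tracer_conc") <- tracer
  attr(out, "kd_true") <- kd
  out
}

#' Simulate a competition FP titration curve
#'
#' Tracer preincubated with competitor 1 (known `kd1`) titrated with
#' competitor 2 (`kd2`), through the full two-competitor equilibrium, plus
#' Gaussian noise.
#'
#' @param kd1,kd2 Dissociation constants (uM).
#' @param comp1_conc Fixed competitor-1 concentration (uM).
#' @param tracer Tracer concentration (uM).
#' @param top_dose,n_points Titration design for competitor 2.
#' @param plateaus Named numeric: `free`, `bound1`, `bound2` (mP).
#' @param sigma Gaussian noise SD (mP).
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return Tibble (`conc_uM`, `mP`, `replicate`).
#' @export
gen_competition_curve <- function(kd1, kd2, comp1_conc = 3.125,
                                  tracer = 0.2, top_dose = 150,
                                  n_points = 12,
                                  plateaus = c(free = 50, bound1 = 150,
                                               bound2 = 250),
                                  sigma = 5, replicates = 3, seed = 1) {
  stopifnot(kd1 > 0, kd2 > 0)
  set.seed(stream_seed(seed, "gen_competition_curve"))
  conc <- c(top_dose / 2^(seq_len(n_points) - 1), 0)
  mp_true <- vapply(conc, function(h) {
    eq <- competitive_equilibrium(tracer, comp1_conc, h, kd1, kd2)
    fp_signal(eq, as.list(plateaus))
  }, numeric(1))
  out <- tidyr::expand_grid(
    tibble::tibble(conc_uM = conc, mp_true = mp_true),
    replicate = seq_len(replicates)
  )
  out$mP <- out$mp_true + stats::rnorm(nrow(out), sd = sigma)
  out$mp_true <- NULL
  attr(out, "tracer_conc") <- tracer
  out
}

#' Simulate an HSQC titration peak-list pair
#'
#' Reference peaks drawn uniformly from plausible amide ranges
#' (1H 6-10 ppm, 15N 100-135 ppm); the titrated list adds planted combined
#' shifts (random direction in the scaled (H, N) plane, so the combined
#' CSP equals the planted magnitude) to the `perturbed_set`, plus optional
#' small jitter on every peak. A fraction of residues are labelled proline
#' and receive no planted shift.
#'
#' @param n_residues Number of peaks.
#' @param perturbed_set Residue numbers receiving planted shifts.
#' @param magnitudes Planted combined-CSP magnitudes (ppm), recycled.
#' @param seed Integer seed.
#' @param jitter Jitter SD applied to all titrated peaks (ppm, on the
#'   combined scale; default 0).
#' @param n_scale Nitrogen scaling used to embed the planted magnitude.
#' @param proline_fraction Fraction of unperturbed residues labelled "P".
#' @return List with `reference` and `titrated` peak-list tibbles and
#'   `truth` (the planted set).
#' @export
gen_peaklists <- function(n_residues, perturbed_set = integer(),
                          magnitudes = 0.02, seed = 1, jitter = 0,
                          n_scale = 0.14, proline_fraction = 0.05) {
  stopifnot(all(perturbed_set %in% seq_len(n_residues)))
  set.seed(stream_seed(seed, "gen_peaklists"))
  res <- seq_len(n_residues)
  restype <- sample(setdiff(strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]], ""),
                    n_residues, replace = TRUE)
  n_pro <- round(proline_fraction * n_residues)
  pro_candidates <- setdiff(res, perturbed_set)
  if (n_pro > 0 && length(pro_candidates) >= n_pro) {
    restype[sample(pro_candidates, n_pro)] <- "P"
  }
  ref <- tibble::tibble(
    assignment = paste0(restype, res),
    residue = res,
    restype = restype,
    dH_ppm = stats::runif(n_residues, 6, 10),
    dN_ppm = stats::runif(n_residues, 100, 135)
  )
  titr <- ref
  mags <- rep(magnitudes, length.out = length(perturbed_set))
  for (k in seq_along(perturbed_set)) {
    i <- which(res == perturbed_set[k])
    phi <- stats::runif(1, 0, 2 * pi)
    titr$dH_ppm[i] <- titr$dH_ppm[i] + mags[k] * cos(phi)
    titr$dN_ppm[i] <- titr$dN_ppm[i] + mags[k] * sin(phi) / n_scale
  }
  if (jitter > 0) {
    phi <- stats::runif(n_residues, 0, 2 * pi)
    amp <- abs(stats::rnorm(n_residues, sd = jitter))
    titr$dH_ppm <- titr$dH_ppm + amp * cos(phi)
    titr$dN_ppm <- titr$dN_ppm + amp * sin(phi) / n_scale
  }
  list(reference = ref, titrated = titr, truth = perturbed_set)
}
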