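#' Construct a bead chain
#'
#' @param coords n x 3 numeric matrix of bead coordinates (Angstrom), one
#'   bead per residue.
#' @param domain Optional per-bead domain labels.
#' @param rigid_groups Optional list of integer vectors; beads in a group
#'   move only as a rigid body during [collapse_chain()].
#' @return Tibble of class `bead_chain` with columns `residue`, `x`, `y`,
#'   `z` (and `domain`), carrying `rigid_groups` as an attribute.
#' @export
bead_chain <- function(coords, domain = NULL, rigid_groups = list()) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, all(is.finite(coords)))
  n <- nrow(coords)
  if (length(rigid_groups) > 1) {
    all_idx <- unlist(rigid_groups)
    if (anyDuplicated(all_idx)) {
      stop("conflicting rigid-group membership: a bead may belong to at most one group")
    }
  }
  out <- tibble::tibble(
    residue = seq_len(n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  if (!is.null(domain)) out$domain <- domain
  attr(out, "rigid_groups") <- rigid_groups
  class(out) <- c("bead_chain", class(out))
  out
}

chain_coords <- function(chain) {
  cbind(chain$x, chain$y, chain$z)
}

#' Build a near-extended bead chain
#'
#' One bead per residue on a gentle helix with a rise of ~3.5 Angstrom per
#' residue and consecutive-bead separation of ~3.8 Angstrom (the Calpha
#' virtual bond length), giving an end-to-end distance close to the fully
#' expanded value of 3.5 Angstrom per residue. The slight off-axis lateral
#' displacement avoids the degenerate collinear start.
#'
#' @param n_residues Number of beads (>= 2).
#' @param domain_map Optional domain map tibble ([dnajb8_domains()]) used to
#'   label beads.
#' @param rigid_templates Optional list of `list(indices =, coords =)`
#'   entries; each template's internal geometry replaces the helix for
#'   those beads (translated into place) and the beads become a rigid group.
#' @return A `bead_chain`.
#' @export
build_expanded_chain <- function(n_residues, domain_map = NULL,
                                 rigid_templates = NULL) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  i <- seq_len(n_residues) - 1
  rise <- 3.5
  dtheta <- 0.6
  radius <- sqrt(3.8^2 - rise^2) / (2 * sin(dtheta / 2))
  coords <- cbind(radius * cos(i * dtheta), radius * sin(i * dtheta),
                  i * rise)
  rigid_groups <- list()
  if (!is.null(rigid_templates)) {
    for (tpl in rigid_templates) {
      idx <- tpl$indices
      tc <- tpl$coords
      stopifnot(length(idx) == nrow(tc))
      shift <- coords[idx[1], ] - tc[1, ]
      coords[idx, ] <- sweep(tc, 2, shift, `+`)
      rigid_groups <- c(rigid_groups, list(as.integer(idx)))
    }
  }
  domain <- NULL
  if (!is.null(domain_map)) {
    domain <- domain_of(seq_len(n_residues), domain_map)
  }
  bead_chain(coords, domain = domain, rigid_groups = rigid_groups)
}

#' Define a distance-restraint set
#'
#' Flat-bottom upper-bound restraints: zero energy when the bead pair is
#' within `upper_bound`, quadratic penalty outside. Cross-link-derived
#' restraints use the chemistry bounds (acid-acid 21, acid-lysine 16
#' Angstrom).
#'
#' @param residue_a,residue_b Bead indices.
#' @param upper_bound Upper bounds in Angstrom (> 0), recycled.
#' @param weight Restraint weights, recycled (default 1).
#' @return Tibble with class `restraint_set`.
#' @export
restraint_set <- function(residue_a, residue_b, upper_bound, weight = 1) {
  stopifnot(all(upper_bound > 0))
  out <- tibble::tibble(
    residue_a = as.integer(residue_a),
    residue_b = as.integer(residue_b),
    upper_bound = as.numeric(upper_bound),
    weight = as.numeric(weight)
  )
  class(out) <- c("restraint_set", class(out))
  out
}

# Energy and gradient of the coarse-grained model.
# Terms: harmonic bonds (r0 = 3.8 A), flat-bottom restraints,
# soft-sphere repulsion between non-bonded pairs closer than sigma.
collapse_energy <- function(X, restraints, k_bond = 100, k_rep = 10,
                            sigma = 4, r0 = 3.8, grad = FALSE) {
  n <- nrow(X)
  E <- 0
  G <- if (grad) matrix(0, n, 3) else NULL
  pair_i <- seq_len(n - 1)
  pair_j <- pair_i + 1L
  pair_k <- rep(k_bond, n - 1)
  pair_ref <- rep(r0, n - 1)
  pair_flat <- rep(FALSE, n - 1)
  if (nrow(restraints) > 0) {
    pair_i <- c(pair_i, restraints$residue_a)
    pair_j <- c(pair_j, restraints$residue_b)
    pair_k <- c(pair_k, restraints$weight)
    pair_ref <- c(pair_ref, restraints$upper_bound)
    pair_flat <- c(pair_flat, rep(TRUE, nrow(restraints)))
  }
  # soft-sphere repulsion: non-bonded pairs with d < sigma
  D <- as.matrix(stats::dist(X))
  close <- which(upper.tri(D) & D < sigma, arr.ind = TRUE)
  if (nrow(close) > 0) {
    close <- close[abs(close[, 1] - close[, 2]) > 1, , drop = FALSE]
  }
  if (nrow(close) > 0) {
    # repulsion is k_rep*(sigma - d)^2 for d < sigma: same quadratic form
    # with reference sigma, one-sided on the other flank
    pair_i <- c(pair_i, close[, 1])
    pair_j <- c(pair_j, close[, 2])
    pair_k <- c(pair_k, rep(k_rep, nrow(close)))
    pair_ref <- c(pair_ref, rep(sigma, nrow(close)))
    pair_flat <- c(pair_flat, rep(NA, nrow(close)))  # NA = lower flank
  }
  dvec <- X[pair_i, , drop = FALSE] - X[pair_j, , drop = FALSE]
  d <- pmax(sqrt(rowSums(dvec^2)), 1e-9)
  dev <- d - pair_ref
  act <- ifelse(is.na(pair_flat), dev < 0, !pair_flat | dev > 0)
  E <- sum(pair_k[act] * dev[act]^2)
  if (grad && any(act)) {
    coef <- 2 * pair_k[act] * dev[act] / d[act]
    gi <- dvec[act, , drop = FALSE] * coef
    idx <- c(pair_i[act], pair_j[act])
    acc <- rowsum(rbind(gi, -gi), group = idx)
    rows <- as.integer(rownames(acc))
    G[rows, ] <- G[rows, ] + acc
  }
  if (grad) list(E = E, G = G) else list(E = E)
}

rodrigues <- function(axis, angle) {
  if (angle == 0) return(diag(3))
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Apply a steepest-descent step of size eta; rigid groups move by the
# aggregate force (translation) and torque (exact rotation), so their
# internal geometry is preserved to machine precision.
apply_step <- function(X, G, eta, rigid_groups, free_idx) {
  Xn <- X
  Xn[free_idx, ] <- X[free_idx, , drop = FALSE] -
    eta * G[free_idx, , drop = FALSE]
  for (g in rigid_groups) {
    Fg <- -colSums(G[g, , drop = FALSE])
    centroid <- colMeans(X[g, , drop = FALSE])
    rel <- sweep(X[g, , drop = FALSE], 2, centroid)
    tau <- colSums(cbind(
      rel[, 2] * (-G[g, 3]) - rel[, 3] * (-G[g, 2]),
      rel[, 3] * (-G[g, 1]) - rel[, 1] * (-G[g, 3]),
      rel[, 1] * (-G[g, 2]) - rel[, 2] * (-G[g, 1])
    ))
    inertia <- sum(rel^2) + 1e-9
    tau_norm <- sqrt(sum(tau^2))
    angle <- eta * tau_norm / inertia
    R <- if (tau_norm > 0) rodrigues(tau, angle) else diag(3)
    Xn[g, ] <- sweep(rel %*% t(R), 2, centroid + eta * Fg / length(g), `+`)
  }
  Xn
}

minimize_once <- function(X0, restraints, rigid_groups, max_iter, tol,
                          ...) {
  n <- nrow(X0)
  if (length(rigid_groups) == 0) {
    # all beads free: two-stage quasi-Newton with analytic gradient.
    # Stage 1 folds the chain under bonds + restraints alone (repulsion
    # off), so restraints can pull the chain past itself; stage 2 turns
    # the soft-sphere repulsion back on to resolve clashes.
    fn <- function(p, k_rep) {
      collapse_energy(matrix(p, n, 3), restraints, k_rep = k_rep, ...)$E
    }
    gr <- function(p, k_rep) {
      as.vector(collapse_energy(matrix(p, n, 3), restraints,
                                k_rep = k_rep, grad = TRUE, ...)$G)
    }
    s1 <- stats::optim(
      par = as.vector(X0), fn = fn, gr = gr, k_rep = 0,
      method = "L-BFGS-B",
      control = list(maxit = max_iter, factr = 10, pgtol = tol)
    )
    s2 <- stats::optim(
      par = s1$par, fn = fn, gr = gr, k_rep = 10,
      method = "L-BFGS-B",
      control = list(maxit = max_iter, factr = 10, pgtol = tol)
    )
    X <- matrix(s2$par, n, 3)
    eg <- collapse_energy(X, restraints, grad = TRUE, ...)
    return(list(X = X, energy = eg$E,
                n_iter = s1$counts[["function"]] + s2$counts[["function"]],
                grad_norm = sqrt(sum(eg$G^2))))
  }
  # rigid groups present: projected steepest descent with backtracking,
  # rigid bodies updated by exact translation + rotation
  free_idx <- setdiff(seq_len(n), unlist(rigid_groups))
  X <- X0
  eg <- collapse_energy(X, restraints, grad = TRUE, ...)
  eta <- 1e-3
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    gnorm <- sqrt(sum(eg$G^2))
    if (gnorm < tol) break
    accepted <- FALSE
    for (bt in 1:40) {
      Xt <- apply_step(X, eg$G, eta, rigid_groups, free_idx)
      et <- collapse_energy(Xt, restraints, grad = FALSE, ...)
      if (et$E < eg$E) {
        X <- Xt
        eg <- collapse_energy(X, restraints, grad = TRUE, ...)
        eta <- eta * 1.5
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) break
  }
  list(X = X, energy = eg$E, n_iter = iter,
       grad_norm = sqrt(sum(eg$G^2)))
}

#' Collapse a bead chain under distance restraints
#'
#' Deterministic restraint-driven compaction: steepest-descent minimization
#' (with backtracking line search, so energy is non-increasing over
#' accepted steps) of flat-bottom upper-bound restraints plus harmonic
#' bonds at 3.8 Angstrom and soft-sphere repulsion (sigma = 4 Angstrom).
#' Seeded random restarts (small coordinate jitter of the start) escape
#' trapped conformations; the best-energy result is returned. Beads in
#' rigid groups move only as rigid bodies.
#'
#' @param chain A `bead_chain`.
#' @param restraints A [restraint_set()].
#' @param seed Integer seed controlling restart jitter (deterministic).
#' @param max_iter Maximum minimizer iterations per restart.
#' @param tolerance Gradient-norm stopping tolerance; the default 0 lets
#'   the minimizer run to its machine-precision energy-decrease criterion,
#'   which parks active restraints inside their bounds rather than a few
#'   1e-6 Angstrom outside.
#' @param n_restarts Number of seeded restarts (default 5).
#' @param jitter Restart jitter amplitude in Angstrom.
#' @return List of class `xl_collapse`: `chain` (collapsed `bead_chain`),
#'   `summary` (per-restart tibble), `best_restart`.
#' @export
collapse_chain <- function(chain, restraints, seed = 1, max_iter = 500,
                           tolerance = 0, n_restarts = 5, jitter = 3) {
  X0 <- chain_coords(chain)
  n <- nrow(X0)
  if (nrow(restraints) > 0 &&
      any(restraints$residue_a > n | restraints$residue_b > n |
            restraints$residue_a < 1 | restraints$residue_b < 1)) {
    stop("restraint references bead outside chain")
  }
  rigid_groups <- attr(chain, "rigid_groups") %||% list()
  rg0 <- radius_of_gyration(X0)
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    Xs <- X0
    if (r > 1) {
      set.seed((seed + r * 7919L) %% .Machine$integer.max)
      Xs <- X0 + matrix(stats::rnorm(n * 3, sd = jitter), n, 3)
    }
    runs[[r]] <- minimize_once(Xs, restraints, rigid_groups,
                               max_iter, tolerance)
  }
  energies <- vapply(runs, `[[`, numeric(1), "energy")
  best <- which.min(energies)
  Xf <- runs[[best]]$X
  out_chain <- bead_chain(Xf,
                          domain = if ("domain" %in% names(chain)) chain$domain,
                          rigid_groups = rigid_groups)
  summary <- tibble::tibble(
    restart = seq_len(n_restarts),
    energy = energies,
    n_iter = vapply(runs, `[[`, numeric(1), "n_iter"),
    grad_norm = vapply(runs, `[[`, numeric(1), "grad_norm")
  )
  structure(
    list(
      chain = out_chain,
      summary = summary,
      best_restart = best,
      rg_initial_nm = rg0,
      rg_final_nm = radius_of_gyration(Xf),
      restraint_satisfaction = restraint_satisfaction(out_chain, restraints)
    ),
    class = "xl_collapse"
  )
}

#' @export
print.xl_collapse <- function(x, ...) {
  cat("<xl_collapse> Rg ", round(x$rg_initial_nm, 2), " -> ",
      round(x$rg_final_nm, 2), " nm; restraints satisfied: ",
      round(100 * x$restraint_satisfaction, 1), "%\n", sep = "")
  invisible(x)
}

#' Fraction of restraints satisfied by a chain
#'
#' @param chain A `bead_chain` (or n x 3 coordinate matrix).
#' @param restraints A [restraint_set()].
#' @param tol Numerical slack in Angstrom (default 1e-6): a minimizer
#'   parks active restraints exactly on the flat-bottom boundary, so the
#'   comparison must absorb floating-point round-off there.
#' @return Fraction in \[0, 1\] of restraints whose bead-pair distance is
#'   within (inclusive) the upper bound; `NaN` for an empty set.
#' @export
restraint_satisfaction <- function(chain, restraints, tol = 1e-6) {
  X <- if (is.matrix(chain)) chain else chain_coords(chain)
  if (nrow(restraints) == 0) return(NaN)
  d <- sqrt(rowSums((X[restraints$residue_a, , drop = FALSE] -
                       X[restraints$residue_b, , drop = FALSE])^2))
  mean(d <= restraints$upper_bound + tol)
}

#' Write a bead chain as a CA-only PDB file
#'
#' @param chain A `bead_chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    chain$residue, chain$residue, chain$x, chain$y, chain$z
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
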