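simple_model <- function(coords) {
  tibble::tibble(residue = seq_len(nrow(coords)),
                 x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

test_that("pair distances are Euclidean with atom-rule fallback", {
  m <- simple_model(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(pair_distance(m, 1, 2), 5)
  expect_equal(pair_distance(m, 1, 1), 0)
  expect_error(pair_distance(m, 1, 99), "99")

  # atom-aware model: CB rule falls back to CA for glycine
  m2 <- tibble::tibble(
    residue = c(1, 1, 2), restype = c("K", "K", "G"),
    atom = c("CA", "CB", "CA"),
    x = c(0, 1, 10), y = 0, z = 0
  )
  expect_equal(pair_distance(m2, 1, 2, atom_rule = "CB"), 9)
  expect_equal(pair_distance(m2, 1, 2, atom_rule = "CA"), 10)

  # random pairs match direct norm computation
  set.seed(3)
  X <- matrix(rnorm(30 * 3, sd = 10), 30, 3)
  m3 <- simple_model(X)
  for (k in 1:10) {
    ij <- sample.int(30, 2)
    expect_equal(pair_distance(m3, ij[1], ij[2]),
                 sqrt(sum((X[ij[1], ] - X[ij[2], ])^2)))
  }
})

test_that("satisfaction is inclusive at the chemistry bound", {
  place <- function(d) simple_model(rbind(c(0, 0, 0), c(d, 0, 0)))
  link <- function(chem) tibble::tibble(residue_a = 1, residue_b = 2,
                                        chemistry = chem)
  expect_true(xl_satisfied(link("adh"), place(20.9)))
  expect_true(xl_satisfied(link("adh"), place(21.0)))
  expect_false(xl_satisfied(link("adh"), place(21.1)))
  expect_true(xl_satisfied(link("dmtmm"), place(16.0)))
  expect_false(xl_satisfied(link("dmtmm"), place(16.01)))
})

test_that("ensemble scoring equals the brute-force double loop", {
  ch <- gen_chain(40, seed = 11)
  ens <- gen_ensemble(ch, n_models = 30, jitter = 3, seed = 11)
  links <- plant_crosslinks(ch, "dmtmm", n_true = 10, n_decoy = 10,
                            seed = 11)
  rep <- score_ensemble(links, ens)
  oracle <- oracle_satisfaction(links, ens, rep$per_link$max_distance)
  expect_identical(unname(rep$matrix), unname(oracle))
  expect_equal(rep$per_model$n_satisfied, colSums(oracle))
  expect_equal(rep$per_link$fraction_satisfied, rowMeans(oracle))
  # histogram mass conservation
  expect_equal(sum(rep$histogram), length(ens))
  # best models are the argmax set
  expect_equal(rep$best_models,
               which(colSums(oracle) == max(colSums(oracle))))
})

test_that("scoring handles planted all-true and degenerate inputs", {
  ch <- gen_chain(30, seed = 2)
  links <- plant_crosslinks(ch, "dmtmm", n_true = 5, n_decoy = 0, seed = 2)
  rep <- score_ensemble(links, as_structure_ensemble(list(ch)))
  expect_equal(rep$per_model$n_satisfied, 5L)
  expect_equal(rep$per_link$fraction_satisfied, rep(1, 5))
  expect_error(score_ensemble(links[0, ], as_structure_ensemble(list(ch))))
  expect_error(score_ensemble(links, structure(list(),
                                              class = "structure_ensemble")))
})

test_that("satisfaction is invariant under rigid motion and shrinks on expansion", {
  ch <- gen_chain(30, seed = 4)
  links <- plant_crosslinks(ch, "dmtmm", n_true = 6, n_decoy = 6, seed = 4)
  X <- cbind(ch$x, ch$y, ch$z)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  moved <- simple_model(sweep(X %*% R, 2, c(5, -3, 12), `+`))
  rep2 <- score_ensemble(links, as_structure_ensemble(
    list(tibble::as_tibble(ch), moved)))
  expect_equal(rep2$matrix[, 1], rep2$matrix[, 2])

  scaled <- simple_model(X * 10)
  rep3 <- score_ensemble(links, as_structure_ensemble(
    list(tibble::as_tibble(ch), scaled)))
  expect_true(rep3$per_model$n_satisfied[2] <= rep3$per_model$n_satisfied[1])
})

test_that("models missing a linked residue are flagged, not dropped", {
  ch <- gen_chain(30, seed = 6)
  links <- plant_crosslinks(ch, "dmtmm", n_true = 4, n_decoy = 0, seed = 6)
  partial <- tibble::as_tibble(ch)[1:10, ]
  rep <- score_ensemble(links, as_structure_ensemble(
    list(tibble::as_tibble(ch), partial)))
  expect_equal(rep$flagged_models, 2L)
  expect_equal(nrow(rep$per_model), 2)
})

test_that("threshold sensitivity curves are monotone and match brute force", {
  ch <- gen_chain(25, seed = 8)
  ens <- gen_ensemble(ch, n_models = 5, jitter = 2, seed = 8)
  links <- plant_crosslinks(ch, "dmtmm", n_true = 5, n_decoy = 5, seed = 8)
  ths <- c(0, 5, 10, 16, 25, 1e6)
  out <- threshold_sensitivity(links, ens, ths)
  expect_equal(out$n_satisfied[out$threshold == 0], rep(0L, 5),
               ignore_attr = TRUE)
  expect_equal(out$n_satisfied[out$threshold == 1e6], rep(10L, 5),
               ignore_attr = TRUE)
  for (m in 1:5) {
    curve <- out$n_satisfied[out$model == m]
    expect_true(all(diff(curve) >= 0))
    for (k in seq_along(ths)) {
      oracle <- oracle_satisfaction(links, ens, rep(ths[k], nrow(links)))
      expect_equal(curve[k], sum(oracle[, m]))
    }
  }
  expect_error(threshold_sensitivity(links, ens, c(-1, 5)))
})

test_that("multi-MODEL PDB files round-trip through the reader", {
  ch1 <- gen_chain(15, seed = 21)
  ch2 <- gen_chain(15, seed = 22)
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c()
  for (m in list(ch1, ch2)) {
    lines <- c(lines, sprintf("MODEL     %4d", length(lines)))
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      m$residue, m$residue, m$x, m$y, m$z))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  ens <- read_ensemble_pdb(path)
  expect_length(ens, 2)
  expect_equal(ens[[1]]$residue, 1:15)
  expect_equal(ens[[1]]$x, ch1$x, tolerance = 1e-3)
  expect_equal(ens[[2]]$z, ch2$z, tolerance = 1e-3)
})
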