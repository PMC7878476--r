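test_that("peak lists parse assignments and match by key", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    assignment = c("K34", "E208", "P100"),
    dH_ppm = c(8.1, 7.5, 8.8), dN_ppm = c(120, 115, 128)
  ), path)
  pl <- read_peaklist(path)
  expect_equal(pl$residue, c(34L, 208L, 100L))
  expect_equal(pl$restype, c("K", "E", "P"))

  m <- match_peaks(pl, pl)
  expect_equal(nrow(m$matched), 3)
  expect_equal(nrow(m$unmatched_reference), 0)
  prof <- csp(m$matched)
  expect_equal(prof$csp, rep(0, 3))
})

test_that("combined CSP follows the scaled-nitrogen formula", {
  matched <- tibble::tibble(
    residue_ref = 1:3, restype_ref = c("A", "A", "A"),
    dH_ppm_ref = c(8, 8, 8), dN_ppm_ref = c(120, 120, 120),
    dH_ppm_titr = c(8.01, 8, 8.03), dN_ppm_titr = c(120, 120.1, 120.2)
  )
  prof <- csp(matched, n_scale = 0.14)
  expect_equal(prof$csp[1], 0.01)
  expect_equal(prof$csp[2], 0.014)
  expect_equal(prof$csp[3], sqrt(0.03^2 + (0.14 * 0.2)^2))
})

test_that("CSP is symmetric in which list is the reference", {
  pl <- gen_peaklists(40, perturbed_set = c(5, 10), magnitudes = 0.05,
                      seed = 41)
  fwd <- csp(match_peaks(pl$reference, pl$titrated)$matched)
  rev <- csp(match_peaks(pl$titrated, pl$reference)$matched)
  expect_equal(fwd$csp, rev$csp)
})

test_that("nearest-neighbour matching without assignments is greedy-optimal", {
  pl <- gen_peaklists(50, perturbed_set = sample(1:50, 8), magnitudes = 0.03,
                      seed = 42)
  ref <- dplyr::select(pl$reference, -assignment, -residue, -restype)
  titr <- dplyr::select(pl$titrated, -assignment, -residue, -restype)
  m <- match_peaks(ref, titr, tol_h = 0.05, tol_n = 0.5)
  # brute force: greedy over exhaustively enumerated scaled distances
  d2 <- outer(ref$dH_ppm, titr$dH_ppm, `-`)^2 / 0.05^2 +
    outer(ref$dN_ppm, titr$dN_ppm, `-`)^2 / 0.5^2
  expected <- 0
  taken_r <- c(); taken_t <- c()
  ord <- order(d2)
  for (k in ord) {
    if (d2[k] > 1) break
    ij <- arrayInd(k, dim(d2))
    if (!(ij[1] %in% taken_r) && !(ij[2] %in% taken_t)) {
      taken_r <- c(taken_r, ij[1]); taken_t <- c(taken_t, ij[2])
      expected <- expected + 1
    }
  }
  expect_equal(nrow(m$matched), expected)
  # a peak moved far beyond tolerance goes unmatched
  titr2 <- titr
  titr2$dH_ppm[1] <- titr2$dH_ppm[1] + 3
  m2 <- match_peaks(ref[1, ], titr2[1, ])
  expect_equal(nrow(m2$matched), 0)
  expect_equal(nrow(m2$unmatched_reference), 1)
})

test_that("perturbed-residue calling honours mean and fixed rules", {
  prof <- csp(tibble::tibble(
    residue_ref = 1:10, restype_ref = c(rep("A", 9), "P"),
    dH_ppm_ref = 8, dN_ppm_ref = 120,
    dH_ppm_titr = 8 + c(rep(0.002, 9), 0.002), dN_ppm_titr = 120
  ))
  # all equal: strict > flags none under the mean rule
  called <- call_perturbed(prof, "mean")
  expect_false(any(called$perturbed))

  prof2 <- prof
  prof2$csp[3] <- prof2$csp[3] * 10
  called2 <- call_perturbed(prof2, "mean")
  expect_equal(which(called2$perturbed), 3L)

  # mean excludes prolines: brute-force recomputation
  expect_equal(called2$threshold[1],
               mean(prof2$csp[prof2$restype != "P"]))
})

test_that("planted large shifts are recovered at the fixed threshold", {
  truth <- sort(sample(1:70, 17))
  pl <- gen_peaklists(70, perturbed_set = truth, magnitudes = 0.05,
                      seed = 43, jitter = 0.0005)
  m <- match_peaks(pl$reference, pl$titrated)
  called <- call_perturbed(csp(m$matched), 0.005)
  expect_equal(sort(called$residue[called$perturbed]), truth)
  expect_equal(sum(called$perturbed), 17)
})

test_that("titration series tracks trajectories and flags gaps", {
  ratios <- c(0, 0.125, 0.25, 0.5, 1, 2)
  base <- gen_peaklists(30, perturbed_set = integer(), seed = 44)
  profiles <- lapply(ratios, function(r) {
    titr <- base$reference
    # planted linear-in-ratio shift on residues 5 and 12
    titr$dH_ppm[c(5, 12)] <- titr$dH_ppm[c(5, 12)] + 0.01 * r
    csp(match_peaks(base$reference, titr)$matched)
  })
  names(profiles) <- ratios
  out <- titration_series(profiles)
  expect_equal(out$non_monotonic, integer(0) + numeric(0))
  traj5 <- out$trajectories[out$trajectories$residue == 5, ]
  fit <- lm(csp ~ ratio, data = traj5)
  expect_equal(unname(coef(fit)["ratio"]), 0.01, tolerance = 1e-6)
  traj7 <- out$trajectories[out$trajectories$residue == 7, ]
  expect_equal(traj7$csp, rep(0, length(ratios)))

  # missing residue at one point is reported
  broken <- profiles
  broken[["2"]] <- broken[["2"]][broken[["2"]]$residue != 12, ]
  expect_error(titration_series(broken), "12")
})
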