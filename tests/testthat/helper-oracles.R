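# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and set operations only.

# unique unordered pair keys of a record table
oracle_pair_keys <- function(records, with = c("chemistry", "condition")) {
  keys <- character(nrow(records))
  for (r in seq_len(nrow(records))) {
    ends <- sort(c(
      paste(records$protein_a[r], records$residue_a[r]),
      paste(records$protein_b[r], records$residue_b[r])
    ))
    extra <- vapply(with, function(col) as.character(records[[col]][r]),
                    character(1))
    keys[r] <- paste(c(ends, extra), collapse = "|")
  }
  keys
}

oracle_dedup_count <- function(records, with = c("chemistry", "condition")) {
  length(unique(oracle_pair_keys(records, with)))
}

# domain lookup by linear interval scan
oracle_domain <- function(res, domain_map) {
  for (k in seq_len(nrow(domain_map))) {
    if (res >= domain_map$start[k] && res <= domain_map$end[k]) {
      return(domain_map$domain[k])
    }
  }
  "unassigned"
}

oracle_class <- function(a, b, domain_map) {
  paste(sort(c(oracle_domain(a, domain_map),
               oracle_domain(b, domain_map))), collapse = "–")
}

# per-model satisfied counts by explicit double loop over models and links
oracle_satisfaction <- function(links, ensemble, bounds) {
  n_links <- nrow(links)
  sat <- matrix(FALSE, n_links, length(ensemble))
  for (m in seq_along(ensemble)) {
    mod <- ensemble[[m]]
    for (l in seq_len(n_links)) {
      pa <- mod[mod$residue == links$residue_a[l], c("x", "y", "z")]
      pb <- mod[mod$residue == links$residue_b[l], c("x", "y", "z")]
      d <- sqrt(sum((as.numeric(pa[1, ]) - as.numeric(pb[1, ]))^2))
      sat[l, m] <- d <= bounds[l]
    }
  }
  sat
}

# exact complex concentration by bisection on the one-site mass balance
oracle_one_site_bisection <- function(tracer, ligand, kd,
                                      tol = 1e-12) {
  if (ligand == 0 || tracer == 0) return(0)
  f <- function(c) c * kd - (tracer - c) * (ligand - c)
  lo <- 0
  hi <- min(tracer, ligand)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# sliding window means by explicit loop
oracle_window_means <- function(charges, window) {
  n <- length(charges)
  vapply(seq_len(n - window + 1), function(i) {
    mean(charges[i:(i + window - 1)])
  }, numeric(1))
}

# covariation overlap by exhaustive double loop
oracle_covar_overlap <- function(pairs, covar, thr, window) {
  hits <- logical(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs$residue_a[p]; b <- pairs$residue_b[p]
    for (q in seq_len(nrow(covar))) {
      if (covar$probability[q] < thr) next
      i <- covar$i[q]; j <- covar$j[q]
      if ((abs(i - a) <= window && abs(j - b) <= window) ||
          (abs(i - b) <= window && abs(j - a) <= window)) {
        hits[p] <- TRUE
        break
      }
    }
  }
  hits
}

# random cross-link record table over a small residue range
random_xl_records <- function(n, n_res = 232, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    protein_a = "p1",
    residue_a = sample.int(n_res, n, replace = TRUE),
    restype_a = sample(c("D", "E", "K"), n, replace = TRUE),
    protein_b = "p1",
    residue_b = sample.int(n_res, n, replace = TRUE),
    restype_b = sample(c("D", "E", "K"), n, replace = TRUE),
    chemistry = sample(c("adh", "dmtmm"), n, replace = TRUE),
    condition = sample(c("PBS_150mM", "PBS_285mM"), n, replace = TRUE)
  )
}
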