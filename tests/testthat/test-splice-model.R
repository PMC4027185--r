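test_that("extract_site_window concatenates flank and exon per convention", {
  acc <- site_window_spec("acceptor", exonic_len = 3, intronic_len = 5)
  expect_equal(
    extract_site_window("CCCAAA", upstream_flank = "GGGTTTAG",
                        site_type = "acceptor", spec = acc),
    "TTTAGCCC"
  )
  don <- site_window_spec("donor")
  expect_equal(
    extract_site_window("CCCAAG", downstream_flank = "GTAAGTCCC",
                        site_type = "donor", spec = don),
    "AAGGTAAGT"
  )
  expect_error(
    extract_site_window("CCCAAG", downstream_flank = "GTAA",
                        site_type = "donor", spec = don),
    "deficit"
  )
})

test_that("default window conventions give widths 9 and 23", {
  expect_equal(site_window_spec("donor")$width, 9L)
  expect_equal(site_window_spec("acceptor")$width, 23L)
})

test_that("singleton-constraint model equals the closed-form weight matrix", {
  set.seed(21)
  spec <- site_window_spec("donor", exonic_len = 2, intronic_len = 4)
  wins <- sim_splice_windows(site_signal_params("donor")[1:6, ], 400,
                             seed = 31)
  m <- train_maxent(wins, spec = spec, constraints = "singleton")
  # exhaustive over all 4^6 windows against an independent count-based WMM
  diffs <- vapply(all_windows_chr(6), function(win) {
    score_site(m, win) - oracle_wmm_score(wins, win)
  }, numeric(1))
  expect_lt(max(abs(diffs)), 1e-9)
})

test_that("identical training windows concentrate the fitted distribution", {
  spec <- site_window_spec("donor", exonic_len = 1, intronic_len = 3)
  wins <- rep("ACGT", 200)
  m <- train_maxent(wins, spec = spec, constraints = "chain")
  # with n=200 and pseudocount 0.5 per pair cell the exact closed form is
  # marg1 * prod(pair/marg): (202/208) * (200.5/202)^3
  p_modal <- 2^(score_site(m, "ACGT") + 4 * log2(0.25))
  expect_equal(p_modal, (202 / 208) * (200.5 / 202)^3, tolerance = 1e-10)
  expect_gt(p_modal, 0.9)
  expect_true(m$fit$converged)
})

test_that("chain model recovers generating adjacent-pair marginals", {
  # first-order-dependent generator: strong A->C, C->G, G->T, T->A coupling
  w <- 6
  pair <- matrix(0.025, 4, 4, dimnames = list(.BASES, .BASES))
  pair["A", "C"] <- pair["C", "G"] <- pair["G", "T"] <- pair["T", "A"] <- 0.175
  dist <- make_window_dist(pairs = rep(list(pair), w - 1))
  wins <- sim_splice_windows(dist, 5000, seed = 77)
  spec <- site_window_spec("donor", exonic_len = 3, intronic_len = 3)
  m <- train_maxent(wins, spec = spec, constraints = "chain")
  for (i in seq_len(w - 1)) {
    expect_lt(max(abs(m$signal$pairs[[i]] - pair / sum(pair))), 0.02)
  }
})

test_that("score is zero when signal equals background", {
  spec <- site_window_spec("donor", exonic_len = 2, intronic_len = 2)
  wins <- sim_splice_windows(matrix(0.25, 4, 4), 500, seed = 3)
  m <- train_maxent(wins, background_windows = wins, spec = spec,
                    constraints = "chain")
  for (win in c("ACGT", "TTTT", "GATC")) {
    expect_equal(score_site(m, win), 0.0)
  }
})

test_that("modal-window score has the closed singleton form", {
  # deterministic marginals: base k modal with probability p at every position
  spec <- site_window_spec("donor", exonic_len = 2, intronic_len = 2)
  wins <- sim_splice_windows(
    matrix(rep(c(0.85, 0.05, 0.05, 0.05), 4), 4, byrow = TRUE), 3000,
    seed = 13
  )
  m <- train_maxent(wins, spec = spec, constraints = "singleton")
  p_hat <- vapply(1:4, function(p) {
    (sum(substr(wins, p, p) == "A") + 0.5) / (length(wins) + 2)
  }, numeric(1))
  expect_equal(score_site(m, "AAAA"), sum(log2(4 * p_hat)), tolerance = 1e-12)
})

test_that("IPF-fitted table matches marginals and maximises entropy", {
  set.seed(8)
  w <- 4
  spec <- site_window_spec("donor", exonic_len = 2, intronic_len = 2)
  wins <- replicate(300, random_seq(w))
  subsets <- list(1L, 2L, 3L, 4L, c(2L, 3L))
  m <- train_maxent(wins, spec = spec, constraints = subsets, tol = 1e-10)
  expect_true(m$fit$converged)
  # fitted subset marginals equal empirical (pseudocounted) marginals
  tab <- m$signal$table
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  idx_mat <- matrix(match(.chars(paste(wins, collapse = "")), .BASES),
                    ncol = w, byrow = TRUE)
  subkey <- function(mat, s) {
    k <- mat[, s[1]]
    if (length(s) > 1) {
      for (j in 2:length(s)) k <- k + (mat[, s[j]] - 1L) * 4L^(j - 1L)
    }
    k
  }
  alpha <- 0.5 * 4^2   # pseudo-mass implied by pc = 0.5 at the largest subset
  for (s in subsets) {
    cells <- 4^length(s)
    fitted_marg <- as.vector(rowsum(tab, subkey(grid, s)))
    emp <- (tabulate(subkey(idx_mat, s), nbins = cells) + alpha / cells) /
      (length(wins) + alpha)
    expect_equal(fitted_marg, emp, tolerance = 1e-8)
  }
  # maximum-entropy property: fitted entropy >= empirical entropy
  expect_gte(model_entropy(m) + 1e-9, empirical_entropy(wins))
})

test_that("fitted entropy is at least the empirical entropy on small toys", {
  set.seed(19)
  for (w in c(3, 4, 6)) {
    spec <- site_window_spec("donor", exonic_len = 1, intronic_len = w - 1)
    wins <- replicate(150, paste(
      sample(.BASES, w, replace = TRUE, prob = c(.5, .2, .2, .1)),
      collapse = ""
    ))
    for (constraints in list("singleton", "chain")) {
      m <- train_maxent(wins, spec = spec, constraints = constraints)
      expect_gte(model_entropy(m) + 1e-9, empirical_entropy(wins))
    }
  }
})

test_that("adding constraints never increases fitted entropy", {
  set.seed(23)
  w <- 4
  spec <- site_window_spec("donor", exonic_len = 2, intronic_len = 2)
  wins <- replicate(400, paste(
    sample(.BASES, w, replace = TRUE, prob = c(.4, .3, .2, .1)), collapse = ""
  ))
  singletons <- as.list(1:4)
  nested <- list(
    singletons,
    c(singletons, list(c(1L, 2L))),
    c(singletons, list(c(1L, 2L), c(2L, 3L))),
    c(singletons, list(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
  )
  ent <- vapply(nested, function(cs) {
    model_entropy(train_maxent(wins, spec = spec, constraints = cs,
                               tol = 1e-10))
  }, numeric(1))
  expect_true(all(diff(ent) <= 1e-8))
  # chain closed form agrees with IPF under the same constraints
  m_chain <- train_maxent(wins, spec = spec, constraints = "chain")
  expect_equal(model_entropy(m_chain), ent[4], tolerance = 1e-6)
})

test_that("chain evaluation agrees with IPF full-table probabilities", {
  set.seed(29)
  w <- 4
  spec <- site_window_spec("donor", exonic_len = 2, intronic_len = 2)
  wins <- replicate(300, paste(
    sample(.BASES, w, replace = TRUE, prob = c(.4, .1, .3, .2)), collapse = ""
  ))
  m_chain <- train_maxent(wins, spec = spec, constraints = "chain")
  m_ipf <- train_maxent(
    wins, spec = spec,
    constraints = c(as.list(1:4), list(c(1L, 2L), c(2L, 3L), c(3L, 4L))),
    tol = 1e-12, max_iter = 500
  )
  for (win in sample(all_windows_chr(w), 40)) {
    expect_equal(score_site(m_chain, win), score_site(m_ipf, win),
                 tolerance = 1e-6)
  }
})

test_that("classify_strength applies the cutoff semantics", {
  expect_equal(classify_strength(8.0, c(3, 6))$label, "strong")
  expect_equal(classify_strength(2.9, c(3, 6))$label, "weak")
  expect_equal(classify_strength(4.5, c(3, 6))$label, "intermediate")
  expect_equal(classify_strength(6.0, c(3, 6))$label, "strong")
  expect_error(classify_strength(1, c(6, 3)), "cutoffs")
})

test_that("model files round-trip exactly", {
  m <- ss_test_models()$acceptor
  f1 <- withr::local_tempfile(fileext = ".model")
  f2 <- withr::local_tempfile(fileext = ".model")
  write_splice_model(m, f1)
  m2 <- read_splice_model(f1)
  write_splice_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  wins <- sim_splice_windows(site_signal_params("acceptor"), 25, seed = 4)
  expect_identical(score_sites(m, wins)$score, score_sites(m2, wins)$score)
})

test_that("training-parameter recovery holds on data resampled from a fit", {
  m <- ss_test_models()$donor
  wins <- sim_splice_windows(m$signal, 4000, seed = 55)
  m2 <- train_maxent(wins, spec = m$spec, constraints = "chain")
  for (i in seq_along(m$signal$pairs)) {
    expect_lt(max(abs(m$signal$pairs[[i]] - m2$signal$pairs[[i]])), 0.03)
  }
})
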