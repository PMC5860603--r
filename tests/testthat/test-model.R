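test_that("emission log density has the closed-form special cases", {
  em <- mixture_emission(array(1, c(1, 1, 1)), array(0, c(1, 1, 1)),
                         matrix(1 / (2 * pi)))
  tr <- transition_model(1, matrix(1), 10)
  p <- saga_params(em, tr)
  expect_equal(emission_log_density(p, 1, 0), 0)         # peak density 1
  # two identical components with weights 1/2 collapse to one
  em2 <- mixture_emission(array(0.5, c(1, 1, 2)),
                          array(1.3, c(1, 1, 2)),
                          matrix(c(0.7, 0.7), 1, 2))
  em1 <- mixture_emission(array(1, c(1, 1, 1)), array(1.3, c(1, 1, 1)),
                          matrix(0.7))
  p2 <- saga_params(em2, tr); p1 <- saga_params(em1, tr)
  expect_equal(emission_log_density(p2, 1, 0.4),
               emission_log_density(p1, 1, 0.4), tolerance = 1e-12)
  # all tracks missing: empty product
  pm <- rand_params(2, T_ = 3, C = 2, seed = 5)
  expect_identical(emission_log_density(pm, 1, c(NA, NA, NA)), 0)
  expect_error(emission_log_density(pm, 1, c(1, Inf, 0)), "non-finite")
})

test_that("emission log density matches direct summation on random mixtures", {
  p <- rand_params(3, T_ = 2, C = 3, seed = 9)
  for (i in 1:20) {
    x <- rand_obs(1, 2, missing = 0.2, seed = i)[1, ]
    ours <- sapply(1:3, function(l) emission_log_density(p, l, x))
    expect_equal(ours, log(oracle_row_density(p, x)), tolerance = 1e-12)
  }
})

test_that("mixture cdf is a valid CDF agreeing with quadrature", {
  p <- rand_params(2, T_ = 1, C = 3, seed = 4)
  expect_equal(mixture_cdf(saga_params(
    mixture_emission(array(1, c(1, 1, 1)), array(2, c(1, 1, 1)), matrix(4)),
    transition_model(1, matrix(1), 10)), 1, 1, 2), 0.5)
  expect_equal(mixture_cdf(p, 1, 1, -1e9), 0, tolerance = 1e-12)
  expect_equal(mixture_cdf(p, 1, 1, 1e9), 1, tolerance = 1e-12)
  xs <- seq(-6, 6, length.out = 25)
  expect_true(all(diff(mixture_cdf(p, 2, 1, xs)) >= 0))
  dens <- function(x) sapply(x, function(xx)
    sum(p$emission$weights[1, 1, ] *
          dnorm(xx, p$emission$means[1, 1, ], sqrt(p$emission$variances[1, ]))))
  for (q in c(-2, 0, 1.5)) {
    quad <- integrate(dens, -50, q, rel.tol = 1e-9)$value
    expect_equal(mixture_cdf(p, 1, 1, q), quad, tolerance = 1e-6)
  }
})

test_that("forward-backward is exact against path enumeration", {
  for (seed in 1:25) {
    set.seed(seed + 1000)
    K <- sample(2:3, 1); C <- sample(1:2, 1); n <- sample(3:6, 1)
    p <- rand_params(K, T_ = 2, C = C, seed = seed)
    x <- rand_obs(n, 2, missing = 0.15, seed = seed + 500)
    or <- oracle_enumerate(x, p)
    fb <- forward_backward(x, p)
    expect_equal(fb$loglik, or$loglik, tolerance = 1e-10)
    expect_equal(fb$loglik_backward, or$loglik, tolerance = 1e-9)
    expect_equal(unname(rowSums(fb$gamma)), rep(1, n), tolerance = 1e-9)
    expect_equal(sum(fb$xi), n - 1, tolerance = 1e-9)
    ok <- rowSums(!is.na(x)) > 0
    r <- fb$resp
    for (t in 1:2) {
      obs <- !is.na(x[, t])
      if (any(obs))
        expect_equal(apply(r[obs, , t, , drop = FALSE], c(1, 2), sum),
                     fb$gamma[obs, , drop = FALSE], tolerance = 1e-9)
    }
  }
})

test_that("degenerate chains have closed-form posteriors", {
  # K = 1: gamma is 1 and the log-likelihood is the emission sum
  p1 <- rand_params(1, T_ = 2, C = 2, seed = 2)
  x <- rand_obs(8, 2, missing = 0.2, seed = 3)
  fb <- forward_backward(x, p1)
  expect_equal(unname(fb$gamma[, 1]), rep(1, 8))
  E <- sapply(seq_len(8), function(i) emission_log_density(p1, 1, x[i, ]))
  expect_equal(fb$loglik, sum(E), tolerance = 1e-10)
  # symmetric two-label model: gamma = 1/2 everywhere
  em <- mixture_emission(array(1, c(2, 1, 1)), array(0, c(2, 1, 1)),
                         matrix(1))
  tr <- transition_model(c(0.5, 0.5), matrix(0.5, 2, 2), 10)
  fb <- forward_backward(matrix(rnorm(6), 6, 1), saga_params(em, tr))
  expect_equal(unname(fb$gamma), matrix(0.5, 6, 2), tolerance = 1e-12)
})

test_that("viterbi attains the enumerated optimum and honors min length", {
  p1 <- rand_params(1, T_ = 1, seed = 1)
  v <- viterbi(matrix(rnorm(5), 5, 1), p1)
  expect_equal(v$path, rep(1L, 5))
  for (seed in 1:15) {
    K <- 2
    p <- rand_params(K, T_ = 1, C = 1, seed = seed)
    x <- rand_obs(5, 1, missing = 0, seed = seed + 50)
    or <- oracle_enumerate(x, p)
    v <- viterbi(x, p)
    expect_equal(v$score, or$best, tolerance = 1e-10)
    # the returned path attains the optimum under the oracle's scoring
    score_path <- function(path) {
      lp <- log(p$transitions$initial[path[1]]) +
        log(oracle_row_density(p, x[1, ])[path[1]])
      for (j in 2:length(path))
        lp <- lp + log(p$transitions$A[path[j - 1], path[j]]) +
          log(oracle_row_density(p, x[j, ])[path[j]])
      lp
    }
    expect_equal(score_path(v$path), or$best, tolerance = 1e-10)
  }
  # hard minimum length: interior runs of the decoded path are >= m
  for (seed in 1:10) {
    p <- rand_params(2, T_ = 1, C = 1, m = 3, seed = seed)
    x <- rand_obs(9, 1, missing = 0, seed = seed + 99)
    v <- viterbi(x, p)
    r <- rle(v$path)
    interior <- r$lengths[-c(1, length(r$lengths))]
    if (length(interior)) expect_true(all(interior >= 3))
  }
})

test_that("min-length models are exact against the phase-aware oracle", {
  for (seed in 1:10) {
    p <- rand_params(2, T_ = 1, C = 1, m = 2, seed = seed)
    x <- rand_obs(6, 1, missing = 0.1, seed = seed + 7)
    or <- oracle_enumerate(x, p)
    fb <- forward_backward(x, p, responsibilities = FALSE)
    v <- viterbi(x, p)
    expect_equal(fb$loglik, or$loglik, tolerance = 1e-10)
    expect_equal(v$score, or$best, tolerance = 1e-10)
    expect_lte(v$score, fb$loglik + 1e-12)
  }
})

test_that("model parameters round-trip bit-exactly through text", {
  for (seed in 1:5) {
    p <- rand_params(3, T_ = 2, C = 2, m = 2, seed = seed,
                     resolution = 10)
    f <- tempfile()
    write_saga_params(p, f)
    q <- read_saga_params(f)
    expect_identical(q$emission$weights, p$emission$weights)
    expect_identical(q$emission$means, p$emission$means)
    expect_identical(q$emission$variances, p$emission$variances)
    expect_identical(q$transitions$A, unname(p$transitions$A))
    expect_identical(q$transitions$initial, p$transitions$initial)
    expect_identical(q$resolution, p$resolution)
    # byte-stable re-write
    f2 <- tempfile()
    write_saga_params(q, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("sampled segment lengths are geometric with mean L", {
  # m = 1, C = 1: plain Gaussian HMM; segment lengths from the
  # generative model follow a geometric law with mean L
  L <- 8
  spec <- simulation_spec(num_labels = 2, num_tracks = 1,
                          chrom_lengths = c(s = 8.2e5), resolution = 1,
                          expected_length = L, missing_rate = 0, seed = 99)
  par <- random_params(spec)
  sim <- simulate_genome(par, spec)
  lens <- rle(sim$labels$s)$lengths
  lens <- lens[-length(lens)]                  # last run truncated
  expect_gt(length(lens), 1e5)
  # chi-square goodness of fit against Geometric(1/L), binned tail
  brk <- c(seq_len(30), Inf)
  obs <- table(cut(lens, c(0, brk)))
  pr <- diff(c(0, pgeom(brk - 1, 1 / L)))
  keep <- pr > 1e-6
  chi <- suppressWarnings(chisq.test(as.numeric(obs[keep]), p = pr[keep],
                                     rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)
})
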