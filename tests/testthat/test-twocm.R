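sig_df <- function(values, chrom = "chr1", spacing = 35) {
  data.frame(chrom = chrom, position = seq_along(values) * spacing,
             signal = values)
}

test_that("1-SD filter and sign capping follow the genome-wide statistics", {
  # sample SD of (-3,-3,3,3) is 3.46; every probe is within 1 SD
  expect_error(filter_and_cap(sig_df(c(-3, -3, 3, 3))), "empty series")
  # only the extreme probes of (-5,0,0,5) survive, capped to their sign
  cs <- filter_and_cap(sig_df(c(-5, 0, 0, 5)))
  expect_equal(cs$capped, c(-1, 1))
  expect_equal(cs$position, c(1, 4) * 35)
  expect_error(filter_and_cap(sig_df(rep(2, 10))), "SD = 0")
  expect_error(filter_and_cap(sig_df(5)), "at least 2")
})

test_that("transition statistic contrasts the n-probe flanks", {
  # maximal contrast at the junction of homogeneous blocks
  cs <- make_capped(c(rep(-1, 48), rep(1, 48)))
  d <- transition_statistic(cs, 48)
  expect_equal(d[48], 2)
  expect_true(all(is.na(d[-48])))          # flanks undefined elsewhere

  expect_equal(unique(transition_statistic(make_capped(rep(1, 200)), 48)[
    48:152]), 0)

  # half-mixed left flank vs homogeneous right flank
  cs2 <- make_capped(c(rep(1, 24), rep(-1, 24), rep(1, 48)))
  expect_equal(transition_statistic(cs2, 48)[48], 1)

  # statistic never crosses chromosomes
  two <- rbind(make_capped(rep(1, 30), chrom = "chr1"),
               make_capped(rep(-1, 30), chrom = "chr2"))
  class(two) <- c("capped_series", "data.frame")
  expect_true(all(is.na(transition_statistic(two, 20))))
})

test_that("permutation preserves the value multiset and is uniform", {
  cs <- make_capped(rep(c(1, -1), 500))
  set.seed(1)
  p <- permute_series(cs)
  expect_equal(sort(p$capped), sort(cs$capped))
  expect_equal(p$position, cs$position)
  one <- make_capped(1)
  expect_equal(permute_series(one)$capped, 1)

  # fraction of +1 in a fixed window of 48 over 100 permutations matches
  # the hypergeometric expectation 0.5 (binomial-scale error)
  set.seed(7)
  fr <- vapply(1:100, function(i)
    mean(permute_series(cs)$capped[1:48] == 1), numeric(1))
  se <- sqrt(0.25 / (48 * 100))
  expect_lt(abs(mean(fr) - 0.5), 5 * se)
})

test_that("calibration separates structured series from shuffled ones", {
  pl <- planted_signal(n_domains = 12, domain_probes = 150, mean_abs = 1,
                       noise_sd = 0.6, seed = 4)
  series <- filter_and_cap(pl$signals)
  params <- twocm_params(n_permutations = 50)
  cal <- calibrate_2cm(series, params, seed = 4)
  expect_equal(cal$selected$p_value, 0)
  expect_gt(cal$selected$real_count, cal$report$mean_permuted_count * 10)

  # an i.i.d. shuffle of the same series is not significant
  set.seed(99)
  shuffled <- permute_series(series)
  err <- tryCatch(calibrate_2cm(shuffled, params, seed = 5),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_true(err$report$p_value >= params$alpha)
})

test_that("run collapse keeps the max-d probe, leftmost on ties", {
  cs <- make_capped(rep(1, 10))
  d <- c(NA, 0.9, 1.4, 1.4, 0.2, NA, 0.9, NA, NA, NA)
  expect_equal(collapse_transitions(cs, d, 0.8), c(3L, 7L))
  expect_equal(collapse_transitions(cs, d, 2), integer(0))
})

test_that("sliding-window implementation matches the brute-force scan", {
  set.seed(31)
  for (rep in 1:10) {
    L <- sample(120:500, 1)
    n <- sample(c(5L, 10L, 24L), 1)
    vals <- sample(c(-1, 1), L, replace = TRUE,
                   prob = c(0.5, 0.5))
    # occasionally inject block structure so transitions exist
    if (rep %% 2 == 0) vals[1:(L %/% 2)] <- 1
    cs <- make_capped(vals)
    dc <- runif(1, 0.3, 1.2)
    bf <- brute_force_transitions(cs, n, dc)
    d <- transition_statistic(cs, n)
    expect_equal(d, bf$d)
    expect_identical(collapse_transitions(cs, d, dc), bf$transitions)
  }
})

test_that("domain assembly tiles the span and merges same-state segments", {
  # zero transitions: one whole-span open domain
  set.seed(1)
  sigs <- data.frame(chrom = "chr1",
                     position = seq(1, by = 35, length.out = 50),
                     signal = 0.3 + rnorm(50, 0, 0.1))
  cs <- filter_and_cap(sigs)
  doms <- assemble_domains_2cm(cs, integer(0), sigs)
  expect_equal(nrow(doms), 1)
  expect_equal(doms$state, "open")
  expect_equal(c(doms$start, doms$end), c(sigs$position[1] - 1,
                                          sigs$position[50]))

  # one transition between a negative block and a positive block:
  # (closed, open).  Noise keeps the SD filter non-degenerate.
  vals <- c(rnorm(60, -2, 1), rnorm(60, 2, 1))
  sigs2 <- sig_df(vals)
  series2 <- filter_and_cap(sigs2)
  d <- transition_statistic(series2, 20)
  tr <- collapse_transitions(series2, d, 1.5)
  doms2 <- assemble_domains_2cm(series2, tr, sigs2)
  expect_equal(doms2$state, c("closed", "open"))
  expect_equal(doms2$start[2], doms2$end[1])
  expect_equal(doms2$end[2], max(sigs2$position))
})

test_that("2CM fit recovers planted domains and obeys its invariants", {
  pl <- planted_signal(n_domains = 20, domain_probes = 430, mean_abs = 0.8,
                       noise_sd = 0.8, seed = 8)
  fit <- segment_2cm(pl$signals, twocm_params(n_permutations = 30), seed = 8)
  d <- fit$domains

  # partition of the probe-covered span, no same-state neighbours
  expect_equal(d$start[-1], d$end[-nrow(d)])
  expect_true(all(d$state[-1] != d$state[-nrow(d)]))
  expect_equal(d$start[1], pl$signals$position[1] - 1)
  expect_equal(d$end[nrow(d)], max(pl$signals$position))

  # bp agreement with the planted truth (SNR 1)
  L <- max(pl$truth$end)
  pos0 <- 0:(L - 1)
  agree <- mean(state_at(d, pos0) == state_at(pl$truth, pos0), na.rm = TRUE)
  expect_gt(agree, 0.9)

  # raising the cutoff never increases the supra-cutoff probe count
  # (the count the permutation calibration compares)
  series <- fit$series
  dstat <- transition_statistic(series, 48)
  counts <- vapply(c(0.5, 0.8, 1.1, 1.5, 1.9),
                   function(dc) sum(dstat >= dc, na.rm = TRUE), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("high-SNR boundaries are recovered within n retained probes", {
  # noiseless two-valued input is degenerate under the 1-SD filter (every
  # deviation sits at exactly one SD), so use a high-SNR noisy series
  pl <- planted_signal(n_domains = 8, domain_probes = 200, mean_abs = 1,
                       noise_sd = 0.5, seed = 2)
  fit <- segment_2cm(pl$signals, twocm_params(n_permutations = 20), seed = 2)
  retention <- nrow(fit$series) / nrow(pl$signals)
  tol_bp <- 48 / retention * 35           # 48 retained probes in bp
  true_bounds <- pl$truth$start[-1]
  rec_bounds <- fit$domains$start[-1]
  expect_gt(length(rec_bounds), 0)
  for (b in rec_bounds) expect_lt(min(abs(true_bounds - b)), tol_bp)
})
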