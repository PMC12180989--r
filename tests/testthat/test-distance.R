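ranges_fix <- structure(list(dose = c(100, 2000), fractions = c(1, 35),
                             rx_isodose_line_pct = c(50, 100),
                             icd_weight = c(0, 1)),
                        class = "scaling_ranges")

rx <- function(d, f) list(dose_per_fraction_cgy = d, n_fractions = f)

test_that("prescription distance matches its closed form and metric axioms", {
  expect_equal(rx_distance(rx(200, 30), rx(200, 30), ranges_fix), 0)
  expect_equal(rx_distance(rx(200, 30), rx(300, 30), ranges_fix), 100 / 1900)

  withr::with_seed(42, {
    for (i in 1:200) {
      p <- rx(runif(1, 100, 2000), sample(1:35, 1))
      q <- rx(runif(1, 100, 2000), sample(1:35, 1))
      s <- rx(runif(1, 100, 2000), sample(1:35, 1))
      dpq <- rx_distance(p, q, ranges_fix)
      expect_equal(dpq, rx_distance(q, p, ranges_fix))
      expect_lte(dpq, rx_distance(p, s, ranges_fix) + rx_distance(s, q, ranges_fix) + 1e-12)
      expect_equal(dpq, brute_rx_dist(p, q, ranges_fix))
    }
  })

  degen <- ranges_fix
  degen$dose <- c(200, 200)
  expect_error(rx_distance(rx(200, 30), rx(300, 30), degen), "degenerate")
  expect_equal(rx_distance(rx(200, 30), rx(200, 20), degen), 10 / 34)
})

test_that("Gower distance handles identity, the maximal case and one mismatch", {
  u <- list(technique = "IMRT", energy = "6x", intent = "curative",
            age_group = "adult", rx_isodose_line_pct = 100, icd_weight = 0.5)
  expect_equal(gower_distance(u, u, ranges_fix), 0)

  v <- list(technique = "3D", energy = "10x", intent = "palliative",
            age_group = "pediatric", rx_isodose_line_pct = 50, icd_weight = 1)
  u2 <- u
  u2$icd_weight <- 0
  expect_equal(gower_distance(u2, v, ranges_fix), 1)

  w <- u
  w$energy <- "10x"
  expect_equal(gower_distance(u, w, ranges_fix), 1 / 6)
})

test_that("Gower implementation agrees with a brute-force oracle and daisy", {
  vocab <- list(technique = c("IMRT", "3D", "SBRT_SRT"),
                energy = c("6x", "10x", "6fff", "4e"),
                intent = c("curative", "palliative"),
                age_group = c("adult", "pediatric"))
  withr::with_seed(7, {
    pairs <- lapply(1:300, function(i) {
      mk <- function() {
        out <- lapply(vocab, function(v) sample(v, 1))
        out$rx_isodose_line_pct <- runif(1, 50, 100)
        out$icd_weight <- runif(1)
        out
      }
      list(u = mk(), v = mk(), w = setNames(runif(6, 0.5, 2),
        c("technique", "energy", "intent", "age_group", "rx_isodose_line_pct", "icd_weight")))
    })
  })
  for (p in pairs) {
    expect_equal(gower_distance(p$u, p$v, ranges_fix),
                 brute_gower(p$u, p$v, ranges_fix), tolerance = 1e-14)
    expect_equal(gower_distance(p$u, p$v, ranges_fix, p$w),
                 brute_gower(p$u, p$v, ranges_fix, p$w), tolerance = 1e-14)
  }

  skip_if_not_installed("cluster")
  # cross-check against cluster::daisy, whose numeric ranges come from the
  # data it sees: hand it the same ranges by appending two anchor rows
  for (p in pairs[1:25]) {
    anchor <- function(iso, icd) {
      out <- lapply(vocab, function(v) v[1])
      out$rx_isodose_line_pct <- iso
      out$icd_weight <- icd
      out
    }
    df <- do.call(rbind, lapply(list(p$u, p$v, anchor(50, 0), anchor(100, 1)),
                                as.data.frame, stringsAsFactors = FALSE))
    for (f in names(vocab)) df[[f]] <- factor(df[[f]], levels = vocab[[f]])
    dz <- as.matrix(cluster::daisy(df, metric = "gower"))[1, 2]
    expect_equal(gower_distance(p$u, p$v, ranges_fix), dz, tolerance = 1e-12)
  }
})

test_that("R statistic is zero on well-matched queries and equals the exhaustive oracle", {
  coh <- toy_cohort(
    toy_records(5, 200, 30),
    toy_records(5, 1200, 4, technique = "IMRT", id_prefix = "S")
  )
  q <- toy_cohort(toy_records(1, 200, 30))[1, ]
  expect_equal(r_statistic(q, coh, nu = 0.5), 0)    # k = 5 exact matches

  eng <- engineer_cohort(generate_cohort(default_specs()$thoracic, seed = 21))
  coh50 <- apply_icd_weights(utils::head(eng, 50))
  qs <- apply_icd_weights(eng[101:105, ], reference = coh50)
  for (i in seq_len(nrow(qs))) {
    expect_equal(r_statistic(qs[i, ], coh50, nu = 0.1),
                 brute_knn_stat(qs[i, ], coh50, 0.1, "r"), tolerance = 1e-12)
  }
})

test_that("F statistic equals the brute-force two-stage oracle on a small cohort", {
  raw <- generate_cohort(default_specs()$brain, seed = 22)
  coh30 <- apply_icd_weights(utils::head(engineer_cohort(raw), 30))
  qs <- coh30[c(1, 10, 25), ]
  qs$record_id <- paste0("Q", 1:3)
  for (i in seq_len(nrow(qs))) {
    for (mu in c(0.05, 0.2, 0.6)) {
      expect_equal(f_statistic(qs[i, ], coh30, mu = mu),
                   brute_knn_stat(qs[i, ], coh30, mu, "f"), tolerance = 1e-12)
    }
  }
  ident <- toy_cohort(toy_records(8, 200, 30))
  expect_equal(f_statistic(ident[1, ], ident, mu = 0.5), 0)
})

test_that("R and F shrink when exact duplicates of the query join the cohort", {
  raw <- generate_cohort(default_specs()$thoracic, seed = 23)
  coh <- apply_icd_weights(utils::head(engineer_cohort(raw), 60))
  q <- coh[7, ]
  q$record_id <- "QRY"
  r0 <- r_statistic(q, coh, nu = 0.2)
  f0 <- f_statistic(q, coh, mu = 0.2)
  dup <- q
  dup$record_id <- "DUP"
  dup$replication_weight <- 10L
  coh2 <- dplyr::bind_rows(coh, dup)
  expect_lte(r_statistic(q, coh2, nu = 0.2), r0 + 1e-12)
  expect_lte(f_statistic(q, coh2, mu = 0.2), f0 + 1e-12)
})

test_that("mean pairwise distances: degenerate, two-record and banded cases", {
  same <- toy_cohort(toy_records(6, 200, 30))
  mp0 <- mean_pairwise(same)
  expect_equal(mp0$tau, 0)
  expect_equal(mp0$theta, 0)
  expect_error(mean_pairwise(same[1, ]), "at least 2")

  two <- toy_cohort(toy_records(1, 200, 30), toy_records(1, 300, 30))
  # the pair's own ranges: dose span 100, fraction span 0 -> theta = 1
  expect_equal(mean_pairwise(two)$theta, 1)

  coh <- engineer_cohort(generate_cohort(default_specs()$thoracic, seed = 24))
  for (part in partition_by_technique(coh)) {
    mp <- mean_pairwise(part)
    expect_gt(mp$tau, 0.01); expect_lt(mp$tau, 0.8)
    expect_gt(mp$theta, 0.01); expect_lt(mp$theta, 0.8)
  }
})

test_that("mean pairwise agrees with the expanded brute force, exact and subsampled", {
  raw <- generate_cohort(default_specs()$brain, seed = 25)
  coh <- apply_icd_weights(utils::head(engineer_cohort(raw), 40))
  coh$replication_weight <- withr::with_seed(1, sample.int(3, 40, replace = TRUE))
  ex <- expand_weights(coh)
  ranges <- rx_ranges(coh)
  n <- nrow(ex)
  ds <- gs <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ds <- c(ds, brute_rx_dist(ex[i, ], ex[j, ], ranges))
    gs <- c(gs, brute_gower(ex[i, ], ex[j, ], ranges))
  }
  mp <- mean_pairwise(coh)
  expect_equal(mp$theta, mean(ds), tolerance = 1e-12)
  expect_equal(mp$tau, mean(gs), tolerance = 1e-12)

  sub <- mean_pairwise(coh, exact_unique_limit = 0, n_subsample = 2e5, seed = 3)
  se <- stats::sd(ds) / sqrt(2e5)
  expect_lt(abs(sub$theta - mean(ds)), 3 * se + 1e-3)
})

test_that("replication weights behave exactly like duplicated records", {
  raw <- generate_cohort(default_specs()$thoracic, seed = 26)
  coh <- apply_icd_weights(utils::head(engineer_cohort(raw), 50))
  coh$replication_weight <- withr::with_seed(2, sample.int(4, 50, replace = TRUE))
  dup <- expand_weights(coh)
  q <- coh[13, ]
  q$record_id <- "QRY"
  ranges <- rx_ranges(coh)
  for (fr in c(0.02, 0.1, 0.3)) {
    k_w <- max(1, floor(fr * sum(coh$replication_weight) + 0.5))
    nu_dup <- k_w / nrow(dup)   # same absolute neighbour count on both forms
    expect_equal(r_statistic(q, coh, fr, ranges), r_statistic(q, dup, nu_dup, ranges),
                 tolerance = 1e-12)
    expect_equal(f_statistic(q, coh, fr, ranges), f_statistic(q, dup, nu_dup, ranges),
                 tolerance = 1e-12)
  }
  expect_equal(mean_pairwise(coh), mean_pairwise(dup), tolerance = 1e-12)
})
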