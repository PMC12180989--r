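#' Min-max scaling ranges for the distance metrics
#'
#' Dose per fraction (hundreds of cGy) and fraction number (units to tens)
#' live on incommensurate scales, so both axes of the prescription distance
#' are min-max scaled to \[0, 1\] by the *historical cohort's* ranges (never
#' by the query record). The numeric Gower features (Rx isodose line,
#' diagnostic-code weight) are range-normalised the same way.
#'
#' @param cohort An engineered cohort tibble.
#' @return A `scaling_ranges` list with `dose`, `fractions`,
#'   `rx_isodose_line_pct` and `icd_weight` elements, each `c(min, max)`.
#' @export
rx_ranges <- function(cohort) {
  rng <- function(x) range(x, na.rm = TRUE)
  structure(
    list(
      dose = rng(cohort$dose_per_fraction_cgy),
      fractions = rng(as.numeric(cohort$n_fractions)),
      rx_isodose_line_pct = if (all(is.na(cohort$rx_isodose_line_pct))) c(0, 0)
        else rng(cohort$rx_isodose_line_pct),
      icd_weight = if (is.null(cohort$icd_weight)) c(0, 1) else rng(cohort$icd_weight)
    ),
    class = "scaling_ranges"
  )
}

# Scaled coordinate; degenerate range with differing values is an error for
# the prescription axes (caller checks), 0 when values all equal.
.scale01 <- function(x, rng) {
  span <- rng[2] - rng[1]
  if (span == 0) return(rep(0, length(x)))
  (x - rng[1]) / span
}

#' Prescription (Rx) distance
#'
#' Euclidean distance between two prescriptions in the min-max-scaled
#' (dose per fraction, number of fractions) plane. Symmetric, zero iff the
#' scaled coordinates coincide, and bounded by sqrt(2) for prescriptions
#' inside the cohort's ranges.
#'
#' @param p,q Prescriptions: lists or one-row data frames with
#'   `dose_per_fraction_cgy` and `n_fractions`.
#' @param ranges A [rx_ranges()] object from the historical cohort.
#' @return Non-negative numeric distance.
#' @export
rx_distance <- function(p, q, ranges) {
  for (ax in c("dose", "fractions")) {
    field <- if (ax == "dose") "dose_per_fraction_cgy" else "n_fractions"
    if (ranges[[ax]][2] == ranges[[ax]][1] && any(p[[field]] != q[[field]])) {
      abort(paste0("degenerate cohort range for ", field,
                   " but prescriptions differ on it"))
    }
  }
  dd <- .scale01(p$dose_per_fraction_cgy, ranges$dose) -
    .scale01(q$dose_per_fraction_cgy, ranges$dose)
  df <- .scale01(as.numeric(p$n_fractions), ranges$fractions) -
    .scale01(as.numeric(q$n_fractions), ranges$fractions)
  sqrt(dd^2 + df^2)
}

# Vectorised prescription distance from one query to every cohort row.
.rx_dist_vec <- function(query, cohort, ranges) {
  rx_distance(
    list(dose_per_fraction_cgy = query$dose_per_fraction_cgy,
         n_fractions = query$n_fractions),
    list(dose_per_fraction_cgy = cohort$dose_per_fraction_cgy,
         n_fractions = cohort$n_fractions),
    ranges
  )
}

#' Gower distance between two clinical feature vectors
#'
#' The feature distance works on the mixed-type vector (technique, energy,
#' intent, age group; Rx isodose line, diagnostic-code weight): categorical
#' features contribute a 0/1 mismatch indicator, numeric features the
#' absolute difference divided by the cohort range (clamped to \[0, 1\] for
#' queries outside the historical range; a degenerate numeric range falls
#' back to the mismatch indicator). The distance is the feature-weighted
#' mean of these per-feature dissimilarities, so it lies in \[0, 1\].
#'
#' @param u,v Feature vectors: lists or one-row data frames with the six
#'   feature fields (fully populated, post-imputation).
#' @param ranges A [rx_ranges()] object.
#' @param weights Named positive feature weights; default 1 for each of the
#'   six features.
#' @return Numeric in \[0, 1\].
#' @export
gower_distance <- function(u, v, ranges, weights = NULL) {
  w <- gower_feature_weights(weights)
  total <- sum(w)
  s <- 0
  for (f in .gower_categorical) s <- s + w[[f]] * as.numeric(u[[f]] != v[[f]])
  for (f in .gower_numeric) {
    rng <- ranges[[f]]
    span <- rng[2] - rng[1]
    contrib <- if (span == 0) as.numeric(u[[f]] != v[[f]])
      else pmin(abs(u[[f]] - v[[f]]) / span, 1)
    s <- s + w[[f]] * contrib
  }
  s / total
}

gower_feature_weights <- function(weights = NULL) {
  w <- setNames(rep(1, length(.gower_features)), .gower_features)
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), .gower_features)
    if (length(bad) > 0) abort(paste0("unknown Gower feature(s): ", paste(bad, collapse = ", ")))
    w[names(weights)] <- weights
  }
  if (any(w < 0) || sum(w) <= 0) abort("Gower feature weights must be positive in total")
  w
}

# Vectorised Gower distance from one query row to every cohort row.
.gower_dist_vec <- function(query, cohort, ranges, weights = NULL) {
  gower_distance(
    query[.gower_features],
    as.list(cohort[.gower_features]),
    ranges, weights
  )
}

# Replication-weight-aware distance profile of one query against a cohort,
# aggregated into groups of equal prescription distance. Records tied at the
# neighbourhood boundary are included pro rata by replication weight (for
# copies of one record this is exactly the duplicated-cohort semantics; for
# distinct tied records it avoids an arbitrary ordering and lets weighting —
# e.g. time scaling — shift the neighbourhood's feature composition).
.query_profile <- function(query, cohort, ranges, gower_weights = NULL) {
  d_rx <- .rx_dist_vec(query, cohort, ranges)
  d_gw <- .gower_dist_vec(query, cohort, ranges, gower_weights)
  ord <- order(d_rx, method = "radix")
  d_rx <- d_rx[ord]
  d_gw <- d_gw[ord]
  w <- as.numeric(cohort$replication_weight[ord])
  grp <- cumsum(c(TRUE, d_rx[-1] != d_rx[-length(d_rx)]))
  gw_sum <- as.numeric(rowsum(w, grp))
  gd <- d_rx[!duplicated(grp)]
  g_gw_mean <- as.numeric(rowsum(w * d_gw, grp)) / gw_sum
  list(
    cw = cumsum(gw_sum),
    cum_rx = cumsum(gw_sum * gd),
    cum_gw = cumsum(gw_sum * g_gw_mean),
    gd = gd,
    g_gw_mean = g_gw_mean
  )
}

# Mean over the k nearest expanded copies: whole equal-distance groups while
# they fit, then a pro-rata share of the boundary group.
.knn_mean <- function(cum, cw, gmean, k) {
  j <- findInterval(k - 1e-9, cw) + 1L
  if (j > length(cw)) j <- length(cw)
  prev_cw <- if (j > 1L) cw[j - 1L] else 0
  prev_cum <- if (j > 1L) cum[j - 1L] else 0
  (prev_cum + (k - prev_cw) * gmean[j]) / k
}

# Neighbour count from a percentage of the effective database size.
.neighbour_count <- function(frac, s_eff) {
  if (frac <= 0 || frac > 1) abort("neighbourhood fraction must lie in (0, 1]")
  min(max(1, round_half_up(frac * s_eff)), s_eff)
}

#' R statistic: prescription distance to the historical database
#'
#' Measures how dissimilar a new prescription is from historically treated
#' prescriptions: the mean [rx_distance()] from the query to its `k` nearest
#' historical prescriptions, where `k` is the fraction `nu` of the effective
#' database size (replication weights counting as copies),
#' `k = max(1, round(nu * S))`.
#'
#' @param new A single record (one-row tibble).
#' @param cohort The engineered historical cohort (same technique).
#' @param nu Fraction of the historical database in (0, 1].
#' @param ranges Optionally precomputed [rx_ranges()].
#' @return Non-negative numeric; 0 when the database holds at least `k`
#'   copies of the exact prescription.
#' @export
r_statistic <- function(new, cohort, nu, ranges = rx_ranges(cohort)) {
  if (nrow(cohort) == 0) abort("empty cohort")
  prof <- .query_profile(new, cohort, ranges)
  k <- .neighbour_count(nu, sum(cohort$replication_weight))
  .knn_mean(prof$cum_rx, prof$cw, prof$gd, k)
}

#' F statistic: feature distance among similar prescriptions
#'
#' Measures how atypical a record's clinical features are *for its
#' prescription*: the mean [gower_distance()] between the query's feature
#' vector and the feature vectors of the `k'` historical records nearest in
#' prescription distance (the "similar or same Rx" neighbourhood),
#' `k' = max(1, round(mu * S))`.
#'
#' @inheritParams r_statistic
#' @param mu Fraction of the historical database in (0, 1].
#' @param gower_weights Optional named feature weights.
#' @return Numeric in \[0, 1\].
#' @export
f_statistic <- function(new, cohort, mu, ranges = rx_ranges(cohort),
                        gower_weights = NULL) {
  if (nrow(cohort) == 0) abort("empty cohort")
  prof <- .query_profile(new, cohort, ranges, gower_weights)
  k <- .neighbour_count(mu, sum(cohort$replication_weight))
  .knn_mean(prof$cum_gw, prof$cw, prof$g_gw_mean, k)
}

#' Mean pairwise feature and prescription distances (tau, theta)
#'
#' The cohort-level dispersion constants that anchor the flagging
#' thresholds: `theta` is the mean [rx_distance()] and `tau` the mean
#' [gower_distance()] over all unordered pairs of effective records
#' (replication weights expand to duplicates; pairs of copies of one record
#' contribute distance 0).
#'
#' `tau` is always computed exactly through a per-feature decomposition of
#' the pair sum (category weight totals for categorical features, sorted
#' prefix sums for numeric ones). `theta` is computed exactly over unique
#' prescription pairs whenever the cohort has at most `exact_unique_limit`
#' distinct prescriptions or at most 5000 effective records; beyond that a
#' seeded uniform subsample of at least `n_subsample` pairs is used.
#'
#' @param cohort An engineered cohort tibble with at least 2 effective
#'   records.
#' @param gower_weights Optional named feature weights.
#' @param exact_unique_limit Unique-prescription cap for the exact `theta`
#'   path.
#' @param n_subsample Number of sampled pairs on the subsampled path.
#' @param seed Seed for the subsampled path.
#' @return A list with elements `tau` and `theta`.
#' @export
mean_pairwise <- function(cohort, gower_weights = NULL,
                          exact_unique_limit = 2000, n_subsample = 1e6,
                          seed = 1) {
  w <- as.numeric(cohort$replication_weight)
  W <- sum(w)
  if (W < 2) abort("mean_pairwise needs at least 2 effective records")
  n_pairs <- W * (W - 1) / 2
  ranges <- rx_ranges(cohort)
  gw <- gower_feature_weights(gower_weights)

  # tau: per-feature exact pair sums.
  pair_sum <- 0
  for (f in .gower_categorical) {
    wc <- tapply(w, cohort[[f]], sum)
    pair_sum <- pair_sum + gw[[f]] * (W^2 - sum(wc^2)) / 2
  }
  for (f in .gower_numeric) {
    rng <- ranges[[f]]
    span <- rng[2] - rng[1]
    if (span > 0) {
      ord <- order(cohort[[f]])
      x <- cohort[[f]][ord]
      wx <- w[ord]
      cw <- cumsum(wx)
      cs <- cumsum(wx * x)
      j <- seq_along(x)[-1]
      s <- sum(wx[j] * (x[j] * cw[j - 1] - cs[j - 1]))
      pair_sum <- pair_sum + gw[[f]] * s / span
    }
  }
  tau <- pair_sum / sum(gw) / n_pairs

  # theta: exact over unique prescriptions, else seeded pair subsampling.
  key <- paste(cohort$dose_per_fraction_cgy, cohort$n_fractions)
  uniq <- !duplicated(key)
  m <- sum(uniq)
  if (m <= exact_unique_limit || W <= 5000) {
    du <- .scale01(cohort$dose_per_fraction_cgy[uniq], ranges$dose)
    fu <- .scale01(as.numeric(cohort$n_fractions[uniq]), ranges$fractions)
    wu <- as.numeric(tapply(w, key, sum)[key[uniq]])
    dmat <- as.matrix(stats::dist(cbind(du, fu)))
    theta <- sum((wu %o% wu) * dmat) / 2 / n_pairs
  } else {
    theta <- withr::with_seed(seed, {
      i <- sample.int(W, n_subsample, replace = TRUE)
      j <- sample.int(W, n_subsample, replace = TRUE)
      keep <- i != j
      idx <- findInterval(c(i[keep], j[keep]) - 0.5, cumsum(w)) + 1L
      half <- length(idx) / 2
      a <- idx[seq_len(half)]
      b <- idx[half + seq_len(half)]
      ds <- .scale01(cohort$dose_per_fraction_cgy, ranges$dose)
      fs <- .scale01(as.numeric(cohort$n_fractions), ranges$fractions)
      mean(sqrt((ds[a] - ds[b])^2 + (fs[a] - fs[b])^2))
    })
  }
  list(tau = unname(tau), theta = unname(theta))
}
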