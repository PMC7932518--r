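# Shared fixture builders. Everything is generated in code at test time;
# nothing binary ships with the package.

# two texture classes with disjoint per-channel intensity mixtures
two_class_specs <- function(noise_sd = 40) {
  list(
    texture_spec(
      levels = list(cbind(c(3000, 9000), c(0.8, 0.2)),
                    cbind(c(2000, 6000), c(0.3, 0.7))),
      density = 0.2, radius_range = c(4, 7), noise_sd = noise_sd,
      label = "classA"),
    texture_spec(
      levels = list(cbind(c(3000, 9000), c(0.2, 0.8)),
                    cbind(c(2000, 6000), c(0.7, 0.3))),
      density = 0.2, radius_range = c(4, 7), noise_sd = noise_sd,
      label = "classB"))
}

# small on-disk dataset: n stacks per class, 2 channels, 60x60x6
make_texture_dataset <- function(dir, n_per_class = 4, seed = 1,
                                 shape = c(60L, 60L, 6L)) {
  generate_texture_dataset(two_class_specs(), n_per_class, dir,
                           shape = shape, seed = seed)
}

# small trained model for reuse across tests (cached per session)
cached_model_env <- new.env()
get_small_model <- function() {
  if (!is.null(cached_model_env$model)) {
    return(list(model = cached_model_env$model,
                dataset = cached_model_env$dataset))
  }
  dir <- file.path(tempdir(), "pvx-model-fixture")
  ds <- make_texture_dataset(dir, n_per_class = 4, seed = 11)
  cfg <- pvx_config(k_p = 4L, k_sv = 5L, k_m = 6L,
                    sv_size = c(5L, 5L, 2L), mv_size = c(2L, 2L, 1L),
                    n_train = 6L)
  model <- train_model(ds, cfg, seed = 5)
  cached_model_env$model <- model
  cached_model_env$dataset <- ds
  list(model = model, dataset = ds)
}

# random label-0..k category stack
random_category_stack <- function(dim_yxz, k, seed) {
  with_seed_test(seed, array(sample(0:k, prod(dim_yxz), replace = TRUE),
                             dim_yxz))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# independent brute-force MCT oracle: plain correlation over every candidate
mct_oracle <- function(plane, n_candidates = 256L) {
  v <- as.numeric(plane)
  cand <- seq(min(v), max(v), length.out = n_candidates)
  best_r <- -Inf
  best_t <- NA_real_
  for (T in cand) {
    m <- as.numeric(v >= T)
    if (length(unique(m)) < 2L) next
    r <- suppressWarnings(cor(m, v))
    if (is.finite(r) && r > best_r + 1e-12) { best_r <- r; best_t <- T }
  }
  best_t
}

# independent knee-point oracle: literal loop-based evaluation of the
# curvature + angle rules
knee_oracle <- function(N, n_keep = 5) {
  M <- length(N)
  dF <- rep(NA_real_, M)
  for (m in 2:(M - 1)) dF[m] <- N[m - 1] + N[m + 1] - 2 * N[m]
  if (all(dF[!is.na(dF)] == 0)) return(NULL)
  ord <- order(dF, decreasing = TRUE, na.last = TRUE)
  cut <- dF[ord[min(n_keep, sum(!is.na(dF)))]]
  best_angle <- -Inf; best_m <- NA
  for (m in 2:(M - 1)) {
    if (is.na(dF[m]) || dF[m] < cut) next
    dl <- abs(N[m] - N[m - 1]); dr <- abs(N[m + 1] - N[m])
    if (dl == 0 || dr == 0) next
    a <- atan(1 / dl) + atan(1 / dr)
    if (a > best_angle) { best_angle <- a; best_m <- m }
  }
  if (!is.finite(best_angle)) return(NULL)
  N[best_m]
}

# random monotone non-decreasing cluster-count curve with a knee
random_knee_curve <- function(seed) {
  with_seed_test(seed, {
    len <- sample(8:20, 1)
    slow <- cumsum(sample(0:2, len, replace = TRUE, prob = c(.5, .4, .1))) + 1
    fast <- slow[len] + cumsum(sample(5:40, 5, replace = TRUE))
    c(slow, fast)
  })
}
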