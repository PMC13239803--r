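#' Simulation configuration for synthetic multimodal datasets
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults emulate a multimodal brain-imaging study of cognitive aging:
#' five modalities sharing low-rank subject structure, sparse spatial maps,
#' scanner-level location/scale batch effects, a CDR-SOB-like target driven
#' by a small subset of components, diagnosis bands derived from the target,
#' and a binary genetic-risk carrier label driven by one designated
#' component.
#'
#' @param N number of subjects (must be at least `2 * K_true`).
#' @param M number of modalities.
#' @param features_m integer vector of length `M`: feature count per
#'   modality. Feature counts are configuration, not claims about any real
#'   preprocessing pipeline.
#' @param K_true number of latent components generating the data.
#' @param sparsity fraction of nonzero features per spatial-map column.
#' @param snr per-modality signal-to-noise variance ratio of the feature
#'   matrices (var(signal)/var(noise)); noise SDs are set from the realized
#'   signal variance so the empirical ratio matches within sampling error.
#' @param n_sites number of imaging sites (at least 3); site sizes are drawn
#'   from a symmetric Dirichlet-multinomial. All subjects at one site share a
#'   scanner.
#' @param n_scanners number of scanner manufacturers.
#' @param beta_support number of components with nonzero target coefficient.
#' @param target_mean,target_sd location/scale of the affine map of the raw
#'   linear score onto the CDR-SOB scale before clipping to \[0, 18\] and
#'   rounding to half points.
#' @param target_r2 fraction of raw target variance explained by the latent
#'   linear predictor (the known R-squared ceiling before rescaling).
#' @param carrier_component index of the component driving the carrier label.
#' @param carrier_slope logistic slope of carrier probability on the
#'   (unit-variance) designated loading.
#' @param carrier_prevalence marginal carrier probability.
#' @param batch_gamma_sd SD of additive scanner offsets, in units of the
#'   per-modality feature SD.
#' @param batch_delta_sd SD of log multiplicative scanner factors.
#' @param csf_fraction fraction of subjects with a CSF draw.
#' @param csf_r_abeta,csf_r_ptau planted correlation of CSF amyloid-beta 42
#'   and phosphorylated tau 181 with the carrier component's loading.
#' @param modality_weights optional `M x K_true` nonnegative matrix of
#'   per-component modality weights; by default each component is active in
#'   a random nonempty subset of modalities.
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the configuration including the seed.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(N = 400, M = 5,
                              features_m = rep(2000L, M),
                              K_true = 6, sparsity = 0.15, snr = 5,
                              n_sites = 12, n_scanners = 3,
                              beta_support = 3,
                              target_mean = 3.5, target_sd = 3,
                              target_r2 = 0.8,
                              carrier_component = 2, carrier_slope = 5,
                              carrier_prevalence = 0.35,
                              batch_gamma_sd = 0.1, batch_delta_sd = 0.05,
                              csf_fraction = 0.6,
                              csf_r_abeta = 0.3, csf_r_ptau = -0.4,
                              modality_weights = NULL,
                              seed = 1) {
  if (length(features_m) != M) {
    stop("`features_m` must have one entry per modality (length M)")
  }
  if (N < 2 * K_true) stop("need N >= 2 * K_true")
  if (snr <= 0) stop("snr must be positive")
  if (n_sites < 3) stop("need at least 3 sites")
  if (K_true > min(features_m)) {
    stop("K_true may not exceed any modality's feature count")
  }
  if (beta_support > K_true) stop("beta_support may not exceed K_true")
  if (carrier_component > K_true) stop("carrier_component out of range")
  if (!is.null(modality_weights)) {
    modality_weights <- as.matrix(modality_weights)
    if (!all(dim(modality_weights) == c(M, K_true))) {
      stop("modality_weights must be M x K_true")
    }
    if (any(modality_weights < 0)) stop("modality_weights must be >= 0")
  }
  codes <- c("GM", "CT", "PSA", "AMY", "TAU")
  modalities <- if (M <= 5) codes[seq_len(M)] else
    c(codes, paste0("MOD", seq_len(M - 5)))
  structure(list(
    N = as.integer(N), M = as.integer(M),
    features_m = as.integer(features_m), K_true = as.integer(K_true),
    sparsity = sparsity, snr = snr, n_sites = as.integer(n_sites),
    n_scanners = as.integer(n_scanners),
    beta_support = as.integer(beta_support),
    target_mean = target_mean, target_sd = target_sd,
    target_r2 = target_r2,
    carrier_component = as.integer(carrier_component),
    carrier_slope = carrier_slope,
    carrier_prevalence = carrier_prevalence,
    batch_gamma_sd = batch_gamma_sd, batch_delta_sd = batch_delta_sd,
    csf_fraction = csf_fraction,
    csf_r_abeta = csf_r_abeta, csf_r_ptau = csf_r_ptau,
    modality_weights = modality_weights,
    modalities = modalities, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic multimodal dataset with known ground truth
#'
#' Draws shared subject loadings, sparse per-modality spatial maps and
#' nonnegative per-component modality weights; builds each modality as the
#' low-rank product plus scanner batch effects and Gaussian noise scaled to
#' the requested signal-to-noise ratio; derives the continuous target from a
#' subset of loadings, diagnosis bands from the target via [band_cdr_sob()],
#' the carrier label from a logistic model on one designated loading, and
#' optional CSF biomarker values correlated with that same loading.
#'
#' The generating ground truth (loadings, maps, weights, target
#' coefficients, noise SDs, batch parameters, empirical SNR and target
#' correlation ceiling) is stored in `$truth` so downstream recovery can be
#' scored exactly.
#'
#' @param config a [simulation_config()].
#' @return object of class `multimodal_dataset`: list with `X` (named list
#'   of subjects-by-features matrices), `pheno` (data.frame with
#'   subject_id, age, sex, target, site, scanner, diagnosis, carrier and CSF
#'   columns) and `truth`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$N; M <- config$M; K <- config$K_true
  P <- config$features_m
  subject_id <- sprintf("S%04d", seq_len(N))

  ## Latent subject loadings
  Z <- matrix(stats::rnorm(N * K), N, K,
              dimnames = list(subject_id, paste0("C", seq_len(K))))

  ## Per-component modality weights: each component active in a random
  ## nonempty modality subset unless supplied explicitly.
  W <- config$modality_weights
  if (is.null(W)) {
    W <- matrix(0, M, K)
    for (k in seq_len(K)) {
      n_active <- sample.int(M, 1L)
      act <- sample.int(M, n_active)
      W[act, k] <- stats::runif(n_active, 0.5, 1.5)
    }
  }
  rownames(W) <- config$modalities

  ## Sparse spatial maps: hard-zeroed random support, two-sided Gamma values
  maps <- vector("list", M)
  for (m in seq_len(M)) {
    S <- matrix(0, P[m], K)
    nnz <- max(1L, round(config$sparsity * P[m]))
    for (k in seq_len(K)) {
      idx <- sample.int(P[m], nnz)
      S[idx, k] <- sample(c(-1, 1), nnz, replace = TRUE) *
        stats::rgamma(nnz, shape = 3, rate = 1)
    }
    rownames(S) <- sprintf("F%05d", seq_len(P[m]))
    maps[[m]] <- S
  }
  names(maps) <- config$modalities

  ## Sites and scanners: site sizes Dirichlet-multinomial; one scanner per
  ## site, every scanner level represented.
  p_site <- stats::rgamma(config$n_sites, shape = 5)
  p_site <- p_site / sum(p_site)
  site <- sample(seq_len(config$n_sites), N, replace = TRUE, prob = p_site)
  ## guarantee every site has at least 2 subjects (splits and ComBat need it)
  for (s in seq_len(config$n_sites)) {
    short <- 2L - sum(site == s)
    if (short > 0) {
      donors <- which(tabulate(site, config$n_sites) > 2)
      take <- which(site %in% donors)[seq_len(short)]
      site[take] <- s
    }
  }
  scanner_of_site <- c(seq_len(config$n_scanners),
                       sample.int(config$n_scanners,
                                  config$n_sites - config$n_scanners,
                                  replace = TRUE))
  scanner_of_site <- scanner_of_site[sample.int(config$n_sites)]
  scanner <- scanner_of_site[site]
  site <- sprintf("site%02d", site)
  scanner <- c("SiemensLike", "GELike", "PhilipsLike",
               sprintf("Vendor%d", seq_len(max(0, config$n_scanners - 3))))[scanner]

  ## Assemble modalities: signal + batch effects + scaled Gaussian noise
  X <- vector("list", M)
  noise_sd <- numeric(M)
  empirical_snr <- numeric(M)
  gamma_list <- vector("list", M)
  delta_list <- vector("list", M)
  scanner_levels <- sort(unique(scanner))
  for (m in seq_len(M)) {
    signal <- Z %*% (t(maps[[m]]) * W[m, ])
    v_sig <- stats::var(as.vector(signal))
    noise_sd[m] <- sqrt(v_sig / config$snr)
    noise <- matrix(stats::rnorm(N * P[m], sd = noise_sd[m]), N, P[m])
    empirical_snr[m] <- v_sig / stats::var(as.vector(noise))
    sd_m <- sqrt(v_sig + noise_sd[m]^2)
    gam <- matrix(stats::rnorm(length(scanner_levels) * P[m],
                               sd = config$batch_gamma_sd * sd_m),
                  length(scanner_levels), P[m],
                  dimnames = list(scanner_levels, NULL))
    del <- matrix(exp(stats::rnorm(length(scanner_levels) * P[m],
                                   sd = config$batch_delta_sd)),
                  length(scanner_levels), P[m],
                  dimnames = list(scanner_levels, NULL))
    Xm <- inject_batch_effects(signal + noise, scanner, gam, del)
    dimnames(Xm) <- list(subject_id, rownames(maps[[m]]))
    X[[m]] <- Xm
    gamma_list[[m]] <- gam
    delta_list[[m]] <- del
  }
  names(X) <- config$modalities

  ## Target: linear in a component subset, rescaled to the CDR-SOB range,
  ## clipped and rounded to half points.
  supp <- seq_len(config$beta_support)
  beta <- numeric(K)
  beta[supp] <- sample(c(-1, 1), length(supp), replace = TRUE) *
    stats::runif(length(supp), 0.5, 1.5)
  lin <- as.vector(Z %*% beta)
  tnoise_sd <- sqrt(stats::var(lin) * (1 - config$target_r2) / config$target_r2)
  raw <- lin + stats::rnorm(N, sd = tnoise_sd)
  target <- config$target_mean +
    config$target_sd * (raw - mean(raw)) / stats::sd(raw)
  target <- pmin(pmax(target, 0), 18)
  target <- round(target * 2) / 2
  diagnosis <- band_cdr_sob(target)
  ## correlation ceiling after rescale/clip/round, from the stored truth
  target_r_ceiling <- stats::cor(lin, target)

  ## Carrier: logistic in the designated component's loading
  zc <- as.vector(scale(Z[, config$carrier_component]))
  a0 <- stats::uniroot(function(a) {
    mean(stats::plogis(a + config$carrier_slope * zc)) -
      config$carrier_prevalence
  }, c(-30, 30))$root
  carrier <- stats::rbinom(N, 1L, stats::plogis(a0 + config$carrier_slope * zc))

  ## Demographics (not wired into the target: the generator's R^2 ceiling
  ## stays exact, and demographics act as a weak comparator)
  age <- round(stats::rnorm(N, 73, 7), 1)
  sex <- sample(c("F", "M"), N, replace = TRUE)

  ## CSF biomarkers correlated with the carrier component's loading
  has_csf <- stats::rbinom(N, 1L, config$csf_fraction) == 1L
  mk_csf <- function(rho, mu, sdv) {
    z <- rho * zc + sqrt(1 - rho^2) * stats::rnorm(N)
    mu + sdv * z
  }
  csf_abeta42 <- ifelse(has_csf, round(mk_csf(config$csf_r_abeta, 1000, 300), 1), NA)
  csf_ptau181 <- ifelse(has_csf, round(mk_csf(config$csf_r_ptau, 25, 8), 2), NA)
  csf_offset_days <- ifelse(has_csf, round(stats::rnorm(N, 0, 150)), NA)

  pheno <- data.frame(
    subject_id = subject_id, age = age, sex = sex,
    target = target, site = site, scanner = scanner,
    diagnosis = as.character(diagnosis), carrier = carrier,
    csf_abeta42 = csf_abeta42, csf_ptau181 = csf_ptau181,
    csf_offset_days = csf_offset_days,
    stringsAsFactors = FALSE
  )

  truth <- list(
    loadings_true = Z, maps_true = maps, modality_weights_true = W,
    beta_true = beta, noise_sd_per_modality = noise_sd,
    empirical_snr = empirical_snr,
    batch_gamma = gamma_list, batch_delta = delta_list,
    carrier_component_index = config$carrier_component,
    carrier_intercept = a0,
    target_linear = lin, target_noise_sd = tnoise_sd,
    target_r_ceiling = target_r_ceiling
  )

  structure(list(X = X, pheno = pheno, truth = truth, config = config),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("multimodal_dataset:", nrow(x$pheno), "subjects,",
      length(x$X), "modalities\n")
  for (m in names(x$X)) cat("  ", m, ":", ncol(x$X[[m]]), "features\n")
  cat("  diagnosis:",
      paste(names(table(x$pheno$diagnosis)),
            table(x$pheno$diagnosis), collapse = ", "), "\n")
  if (!is.null(x$truth)) cat("  ground truth stored (K_true =",
                             ncol(x$truth$loadings_true), ")\n")
  invisible(x)
}

#' Apply location/scale batch effects to a feature matrix
#'
#' `X'[i, j] = (X[i, j] + gamma[scanner(i), j]) * delta[scanner(i), j]`.
#' With `gamma = 0` and `delta = 1` the matrix is returned unchanged. This
#' is the confound that harmonization must later remove.
#'
#' @param X subjects-by-features matrix.
#' @param scanner per-subject batch labels; every level must be a row of
#'   `gamma` and `delta`.
#' @param gamma additive offsets, batch-levels-by-features (rownames are the
#'   batch levels); a scalar or per-level vector is recycled across features.
#' @param delta multiplicative factors, same shape rules; must be positive.
#' @return matrix of the same shape as `X`.
#' @export
inject_batch_effects <- function(X, scanner, gamma, delta) {
  X <- as.matrix(X)
  scanner <- as.character(scanner)
  levels_ <- unique(scanner)
  expand <- function(v, nm) {
    if (is.matrix(v)) return(v)
    v <- rep_len(v, length(nm))
    matrix(rep(v, ncol(X)), length(nm), ncol(X), dimnames = list(nm, NULL))
  }
  gamma <- expand(gamma, levels_)
  delta <- expand(delta, levels_)
  if (is.null(rownames(gamma)) || is.null(rownames(delta))) {
    stop("gamma and delta must have batch levels as rownames")
  }
  missing_lv <- setdiff(levels_, intersect(rownames(gamma), rownames(delta)))
  if (length(missing_lv)) {
    stop("unknown scanner level(s): ", paste(missing_lv, collapse = ", "))
  }
  if (any(delta <= 0)) stop("delta must be positive")
  ridx <- match(scanner, rownames(gamma))
  out <- (X + gamma[ridx, , drop = FALSE]) *
    delta[match(scanner, rownames(delta)), , drop = FALSE]
  dimnames(out) <- dimnames(X)
  out
}

#' Site-grouped train/validation/test split
#'
#' Partitions subjects into splits such that all subjects from a given site
#' land in the same split, preventing site-related leakage. Sites are
#' shuffled (seeded) and each is assigned greedily to the split whose
#' subject count is furthest below its target.
#'
#' @param site per-subject site labels.
#' @param fractions target subject fractions, must sum to 1; names default
#'   to `train`, `val`, `test` for three splits.
#' @param seed integer seed for the site shuffle.
#' @return object of class `split_assignment`: list with `split` (factor per
#'   subject), `sites` (named character: split of each site) and `fractions`.
#' @export
grouped_split <- function(site, fractions = c(train = 0.70, val = 0.15, test = 0.15),
                          seed = 1) {
  site <- as.character(site)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n_split <- length(fractions)
  if (is.null(names(fractions))) {
    names(fractions) <- if (n_split == 3) c("train", "val", "test") else
      paste0("split", seq_len(n_split))
  }
  sites <- unique(site)
  if (length(sites) < n_split) stop("fewer distinct sites than splits")
  site_n <- table(site)[sites]
  N <- length(site)
  set.seed(seed)
  ord <- sample.int(length(sites))
  target <- fractions * N
  filled <- numeric(n_split)
  assign_of_site <- character(length(sites))
  names(assign_of_site) <- sites
  for (s in sites[ord]) {
    deficit <- target - filled
    j <- which.max(deficit)
    assign_of_site[s] <- names(fractions)[j]
    filled[j] <- filled[j] + site_n[[s]]
  }
  split <- factor(assign_of_site[site], levels = names(fractions))
  structure(list(split = split, sites = assign_of_site,
                 fractions = fractions, seed = seed),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  tb <- table(x$split)
  cat("split_assignment:",
      paste(names(tb), tb, sep = "=", collapse = ", "),
      sprintf("(fractions %s)\n",
              paste(round(tb / sum(tb), 3), collapse = "/")))
  invisible(x)
}
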