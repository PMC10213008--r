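#' Configuration of the synthetic family-GWAS generator
#'
#' Describes a population of nuclear four-member families (two parents, two
#' children) genotyped on a panel of block-correlated SNPs, with an ACE
#' phenotype. Defaults reproduce the reference simulation design: 250
#' MZ-twin families, 50 SNPs in blocks of 6, 4, 6, 4 and 30 with minor
#' allele frequencies 0.2, 0.4, 0.4, 0.25 and 0.25, within-block genotype
#' correlation 0.7, the first SNP of each of the first four blocks causal,
#' variance components (4, 1, 1) and no covariates.
#'
#' The per-SNP heritability parameter `h` is calibrated so that each causal
#' SNP explains `h / (sigma_a2 + sigma_c2 + sigma_e2)` percent of the total
#' trait variability (see [causal_effect_size()] for the alternative
#' scaling).
#'
#' @param m Number of families.
#' @param block_sizes Integer vector of SNP-block sizes (sums to `p_g`).
#' @param block_mafs Minor allele frequency per block, in (0, 0.5].
#' @param within_block_corr Target Pearson correlation between the 0/1
#'   allele indicators of two SNPs in the same block (binary scale).
#' @param h Per-SNP heritability parameter (>= 0); `h = 0` means no causal
#'   SNPs.
#' @param causal_positions Indices of causal SNPs; default the first SNP of
#'   each of the first four blocks.
#' @param varcomp ACE variance components of the error term.
#' @param family_type_mix Named probability vector over family types
#'   (`MZ`, `DZ`, `adopted`, `non_twin_sibs`, `mixed_adopted_bio`);
#'   default all-MZ.
#' @param include_covariates If `TRUE`, add a binary `sex` and a standard
#'   normal `age_std` covariate with effects 1 and 0.5.
#' @param h_convention `"total_variance"` (default) or `"error_scaled"`;
#'   see [causal_effect_size()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(m = 250L,
                       block_sizes = c(6L, 4L, 6L, 4L, 30L),
                       block_mafs = c(0.2, 0.4, 0.4, 0.25, 0.25),
                       within_block_corr = 0.7,
                       h = 10,
                       causal_positions = NULL,
                       varcomp = variance_components(4, 1, 1),
                       family_type_mix = c(MZ = 1),
                       include_covariates = FALSE,
                       h_convention = c("total_variance", "error_scaled")) {
  h_convention <- match.arg(h_convention)
  stopifnot(m >= 1, length(block_sizes) == length(block_mafs),
            all(block_sizes >= 1),
            all(block_mafs > 0 & block_mafs <= 0.5),
            within_block_corr >= 0, within_block_corr < 1,
            h >= 0)
  varcomp <- as_varcomp(varcomp)
  p_g <- sum(block_sizes)
  block_of <- rep(seq_along(block_sizes), block_sizes)
  block_starts <- cumsum(c(1L, utils::head(block_sizes, -1L)))
  if (is.null(causal_positions)) {
    causal_positions <- block_starts[seq_len(min(4L, length(block_sizes)))]
    if (h == 0) causal_positions <- integer()
  }
  if (length(causal_positions) &&
      (min(causal_positions) < 1 || max(causal_positions) > p_g)) {
    stop("causal_positions out of range")
  }
  types <- c("MZ", "DZ", "adopted", "non_twin_sibs", "mixed_adopted_bio")
  if (is.null(names(family_type_mix)) ||
      !all(names(family_type_mix) %in% types)) {
    stop("family_type_mix must be named with known family types")
  }
  family_type_mix <- family_type_mix / sum(family_type_mix)
  structure(list(m = as.integer(m), block_sizes = as.integer(block_sizes),
                 block_mafs = block_mafs,
                 within_block_corr = within_block_corr,
                 h = h, causal_positions = as.integer(causal_positions),
                 varcomp = varcomp, family_type_mix = family_type_mix,
                 include_covariates = include_covariates,
                 h_convention = h_convention,
                 p_g = p_g, block_of = block_of,
                 block_starts = block_starts),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: m = %d families, %d SNPs in blocks (%s), h = %g\n",
              x$m, x$p_g, paste(x$block_sizes, collapse = ","), x$h))
  invisible(x)
}

# ---- correlated-Bernoulli calibration -----------------------------------

# Probability that two equicorrelated standard normals both fall below q.
binorm_orthant <- function(q, rho) {
  if (rho <= 0) return(stats::pnorm(q)^2)
  stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((q - rho * z) / sqrt(1 - rho^2))
  }, -10, q, rel.tol = 1e-10)$value
}

# Pearson correlation of two Bernoulli(maf) indicators under a Gaussian
# copula with latent correlation rho.
binary_pair_corr <- function(rho, maf) {
  q <- stats::qnorm(maf)
  (binorm_orthant(q, rho) - maf^2) / (maf * (1 - maf))
}

the_corr_cache <- new.env(parent = emptyenv())

# Latent equicorrelation such that the binary-scale correlation hits the
# target; solved once per (maf, target) by bisection on the orthant
# probability.
calibrate_latent_corr <- function(maf, target) {
  if (target <= 0) return(0)
  key <- sprintf("%.10g|%.10g", maf, target)
  hit <- get0(key, envir = the_corr_cache)
  if (!is.null(hit)) return(hit)
  root <- stats::uniroot(function(r) binary_pair_corr(r, maf) - target,
                         c(1e-8, 1 - 1e-8), tol = 1e-9)$root
  assign(key, root, envir = the_corr_cache)
  root
}

#' Simulate haplotype-like parental allele vectors
#'
#' Draws 0/1 vectors of length `p_g` with independent blocks; within a
#' block, entries are Bernoulli(MAF) indicators coupled through an
#' equicorrelated Gaussian copula whose latent correlation is calibrated so
#' the correlation of the binary indicators matches
#' `config$within_block_corr`.
#'
#' @param config A [sim_config()].
#' @param n Number of vectors to draw.
#' @return An `n x p_g` 0/1 integer matrix.
#' @export
simulate_parent_alleles <- function(config, n = 1L) {
  stopifnot(inherits(config, "sim_config"))
  out <- matrix(0L, n, config$p_g)
  col0 <- 0L
  for (b in seq_along(config$block_sizes)) {
    k <- config$block_sizes[b]
    maf <- config$block_mafs[b]
    rho <- calibrate_latent_corr(maf, config$within_block_corr)
    z <- sqrt(rho) * stats::rnorm(n) +
      sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
    out[, col0 + seq_len(k)] <- (z < stats::qnorm(maf)) + 0L
    col0 <- col0 + k
  }
  out
}

#' Simulate the genotypes of nuclear families
#'
#' Each parent's genotype is the sum of two independent allele vectors
#' (its haplotypes). Children inherit one haplotype from each parent:
#' MZ twins share the same transmitted pair (identical genotypes), DZ twins
#' and non-twin siblings draw transmissions independently, adopted children
#' are built from fresh haplotypes unrelated to the rearing parents, and in
#' mixed families child 1 is biological, child 2 adopted.
#'
#' @param config A [sim_config()].
#' @param n_families Number of families (default `config$m`).
#' @param family_types Optional character vector of types; drawn from
#'   `config$family_type_mix` when omitted.
#' @return A list with `genotypes` (list of `4 x p_g` matrices ordered
#'   father, mother, child 1, child 2) and `family_types`.
#' @export
simulate_family_genotypes <- function(config, n_families = config$m,
                                      family_types = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- as.integer(n_families)
  if (is.null(family_types)) {
    family_types <- sample(names(config$family_type_mix), m, replace = TRUE,
                           prob = config$family_type_mix)
  }
  stopifnot(length(family_types) == m)
  p_g <- config$p_g
  H <- simulate_parent_alleles(config, 4L * m)     # parental haplotypes
  i0 <- (seq_len(m) - 1L) * 4L
  pickf1 <- sample(0:1, m, TRUE); pickm1 <- sample(0:1, m, TRUE)
  pickf2 <- sample(0:1, m, TRUE); pickm2 <- sample(0:1, m, TRUE)
  # fresh haplotypes for adopted children (unused rows cost little)
  HA <- simulate_parent_alleles(config, 4L * m)
  genotypes <- vector("list", m)
  for (i in seq_len(m)) {
    f <- H[i0[i] + 1L, ] + H[i0[i] + 2L, ]
    mo <- H[i0[i] + 3L, ] + H[i0[i] + 4L, ]
    type <- family_types[i]
    c1 <- H[i0[i] + 1L + pickf1[i], ] + H[i0[i] + 3L + pickm1[i], ]
    c2 <- switch(type,
                 MZ = c1,
                 DZ = ,
                 non_twin_sibs = H[i0[i] + 1L + pickf2[i], ] +
                   H[i0[i] + 3L + pickm2[i], ],
                 adopted = HA[i0[i] + 3L, ] + HA[i0[i] + 4L, ],
                 mixed_adopted_bio = HA[i0[i] + 3L, ] + HA[i0[i] + 4L, ])
    if (type == "adopted") c1 <- HA[i0[i] + 1L, ] + HA[i0[i] + 2L, ]
    G <- rbind(f, mo, c1, c2)
    dimnames(G) <- NULL
    genotypes[[i]] <- G
  }
  list(genotypes = genotypes, family_types = family_types)
}

#' Causal SNP effect size from the heritability parameter
#'
#' Under the default `"total_variance"` convention the coefficient is
#' `sqrt(h / (100 * 2 * maf * (1 - maf)))`, so that a causal SNP with
#' genotype variance `2 maf (1 - maf)` contributes
#' `h / (sigma_a2 + sigma_c2 + sigma_e2)` percent of the total trait
#' variability when the error variance sums to that total. The
#' `"error_scaled"` convention divides additionally by the variance sum,
#' `sqrt(h / (100 * (sigma_a2 + sigma_c2 + sigma_e2) * 2 * maf * (1 - maf)))`,
#' giving effects smaller by the square root of the variance total.
#'
#' @param h Heritability parameter (>= 0).
#' @param maf Minor allele frequency in (0, 1).
#' @param varcomp ACE variance components.
#' @param convention `"total_variance"` or `"error_scaled"`.
#' @return Non-negative effect size.
#' @export
causal_effect_size <- function(h, maf, varcomp = variance_components(4, 1, 1),
                               convention = c("total_variance",
                                              "error_scaled")) {
  convention <- match.arg(convention)
  if (maf <= 0 || maf >= 1) stop("maf must lie strictly in (0, 1)")
  if (h < 0) stop("h must be non-negative")
  vc <- as_varcomp(varcomp)
  denom <- 100 * 2 * maf * (1 - maf)
  if (convention == "error_scaled") {
    denom <- denom * (vc$sigma_a2 + vc$sigma_c2 + vc$sigma_e2)
  }
  sqrt(h / denom)
}

sim_beta_g <- function(config) {
  beta <- numeric(config$p_g)
  if (length(config$causal_positions)) {
    mafs <- config$block_mafs[config$block_of[config$causal_positions]]
    beta[config$causal_positions] <-
      mapply(causal_effect_size, h = config$h, maf = mafs,
             MoreArgs = list(varcomp = config$varcomp,
                             convention = config$h_convention))
  }
  beta
}

#' Simulate ACE phenotypes for given family genotypes
#'
#' Generates `y_i = G_i beta_g + C_i beta_c + a_i + c_i 1 + e_i` with
#' `a_i ~ N(0, sigma_a2 Phi_i)`, a scalar shared-environment draw
#' `c_i ~ N(0, sigma_c2)` and `e_i ~ N(0, sigma_e2 I)`. The intercept is 0.
#'
#' @param genotypes List of `4 x p_g` genotype matrices.
#' @param beta_g SNP effect vector of length `p_g`.
#' @param family_types Character vector of family types (determines
#'   `Phi_i`).
#' @param config A [sim_config()] (supplies the variance components).
#' @param C Optional list of covariate matrices; `covariate_effects` their
#'   coefficients.
#' @param covariate_effects Numeric vector, one per covariate column.
#' @return A list of per-family phenotype vectors (length 4 each).
#' @export
simulate_phenotypes <- function(genotypes, beta_g, family_types, config,
                                C = NULL, covariate_effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- length(genotypes)
  if (length(beta_g) != config$p_g) stop("beta_g has wrong length")
  vc <- config$varcomp
  phis <- lapply(unique(family_types), build_kinship_matrix)
  names(phis) <- unique(family_types)
  Ls <- lapply(phis, function(phi) {
    ev <- eigen(phi, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(phi))
  })
  ys <- vector("list", m)
  for (i in seq_len(m)) {
    ni <- nrow(genotypes[[i]])
    a <- sqrt(vc$sigma_a2) *
      as.vector(Ls[[family_types[i]]] %*% stats::rnorm(ni))
    ci <- stats::rnorm(1, 0, sqrt(vc$sigma_c2))
    e <- stats::rnorm(ni, 0, sqrt(vc$sigma_e2))
    y <- as.vector(genotypes[[i]] %*% beta_g) + a + ci + e
    if (!is.null(C)) y <- y + as.vector(C[[i]] %*% covariate_effects)
    ys[[i]] <- y
  }
  ys
}

#' Simulate a complete pedigree dataset
#'
#' Draws genotypes and phenotypes per the configuration and assembles a
#' [fam_dataset()]. The generating truth (causal indices, effect sizes,
#' variance components) is attached as attribute `"truth"`.
#'
#' @param config A [sim_config()].
#' @return A `fam_dataset`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gg <- simulate_family_genotypes(config)
  beta_g <- sim_beta_g(config)
  Cmats <- NULL; ceff <- NULL; cnames <- character()
  if (config$include_covariates) {
    cnames <- c("sex", "age_std")
    ceff <- c(1, 0.5)
    Cmats <- lapply(seq_len(config$m), function(i) {
      cbind(sex = c(0, 1, stats::rbinom(2, 1, 0.5)),
            age_std = stats::rnorm(4))
    })
  }
  ys <- simulate_phenotypes(gg$genotypes, beta_g, gg$family_types, config,
                            C = Cmats, covariate_effects = ceff)
  snp_ids <- sprintf("snp_%02d", seq_len(config$p_g))
  fams <- lapply(seq_len(config$m), function(i) {
    family_block(family_id = sprintf("fam_%04d", i),
                 y = ys[[i]],
                 G = gg$genotypes[[i]],
                 phi = build_kinship_matrix(gg$family_types[i]),
                 C = if (is.null(Cmats)) NULL else Cmats[[i]],
                 roles = c("father", "mother", "child", "child"),
                 family_type = gg$family_types[i])
  })
  ds <- fam_dataset(fams, snp_ids = snp_ids, covariate_names = cnames)
  attr(ds, "truth") <- list(causal = config$causal_positions,
                            beta_g = beta_g,
                            covariate_effects = ceff,
                            varcomp = config$varcomp,
                            config = config)
  ds
}

#' Selection accuracy metrics against the generating truth
#'
#' Computes, for a selected index set: TP, the proportion of causal SNPs
#' detected; TN, the proportion of non-causal SNPs left undetected; RTP,
#' the proportion of causal blocks in which at least one SNP (causal or a
#' correlated neighbour) was detected; and RTN, the proportion of SNPs in
#' the signal-free blocks (those containing no causal SNP) left undetected.
#'
#' @param selected Integer vector of selected SNP indices.
#' @param config The generating [sim_config()].
#' @return A one-row data frame with columns `tp`, `tn`, `rtp`, `rtn` and
#'   `n_selected`.
#' @export
compute_metrics <- function(selected, config) {
  stopifnot(inherits(config, "sim_config"))
  selected <- unique(as.integer(selected))
  if (length(selected) && (min(selected) < 1 || max(selected) > config$p_g)) {
    stop("selected indices out of range")
  }
  causal <- config$causal_positions
  noncausal <- setdiff(seq_len(config$p_g), causal)
  causal_blocks <- unique(config$block_of[causal])
  null_blocks <- setdiff(seq_along(config$block_sizes), causal_blocks)
  null_snps <- which(config$block_of %in% null_blocks)
  tp <- if (length(causal)) mean(causal %in% selected) else NA_real_
  tn <- if (length(noncausal)) {
    1 - length(intersect(selected, noncausal)) / length(noncausal)
  } else NA_real_
  rtp <- if (length(causal_blocks)) {
    mean(vapply(causal_blocks, function(b) {
      any(selected %in% which(config$block_of == b))
    }, TRUE))
  } else NA_real_
  rtn <- if (length(null_snps)) {
    1 - length(intersect(selected, null_snps)) / length(null_snps)
  } else NA_real_
  data.frame(tp = tp, tn = tn, rtp = rtp, rtn = rtn,
             n_selected = length(selected))
}
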