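#' One nuclear pedigree's data block
#'
#' Bundles the phenotype vector, genotype matrix (0/1/2 minor-allele counts),
#' optional covariates and the relatedness matrix of a single family.
#'
#' @param family_id Identifier (character or numeric).
#' @param y Numeric phenotype vector of length `n_i`.
#' @param G Integer matrix `n_i x p_g` with entries in 0, 1, 2.
#' @param phi Symmetric relatedness matrix `n_i x n_i`, unit diagonal.
#' @param C Optional numeric covariate matrix `n_i x p` (default none).
#' @param roles Character vector of member roles, each of `"father"`,
#'   `"mother"`, `"child"`.
#' @param family_type Optional family-type label (e.g. `"MZ"`), kept for
#'   bookkeeping and serialization.
#' @return An object of class `family_block`.
#' @export
family_block <- function(family_id, y, G, phi, C = NULL,
                         roles = NULL, family_type = NA_character_) {
  y <- as.numeric(y)
  G <- as.matrix(G)
  n_i <- length(y)
  if (n_i < 1) stop("family must contain at least one individual")
  if (nrow(G) != n_i) stop("nrow(G) must equal length(y)")
  if (anyNA(G)) stop("missing genotypes are not allowed")
  if (!all(G %in% 0:2)) stop("genotypes must be coded 0/1/2")
  phi <- as.matrix(phi)
  if (!isSymmetric(phi, tol = 1e-8) || nrow(phi) != n_i) {
    stop("phi must be a symmetric n_i x n_i matrix")
  }
  if (any(abs(diag(phi) - 1) > 1e-8)) stop("phi must have unit diagonal")
  if (any(phi < -1e-8 | phi > 1 + 1e-8)) stop("phi entries must lie in [0, 1]")
  if (!is.null(C)) {
    C <- as.matrix(C)
    if (nrow(C) != n_i) stop("nrow(C) must equal length(y)")
    storage.mode(C) <- "double"
  }
  if (is.null(roles)) roles <- rep("child", n_i)
  if (length(roles) != n_i || !all(roles %in% c("father", "mother", "child"))) {
    stop("roles must be father/mother/child, one per individual")
  }
  structure(list(family_id = family_id, y = y, G = G, C = C, phi = phi,
                 roles = roles, family_type = family_type, n_i = n_i),
            class = "family_block")
}

#' Pedigree dataset
#'
#' An ordered collection of [family_block()]s sharing the same SNP panel and
#' covariate set.
#'
#' @param families List of `family_block` objects.
#' @param snp_ids Character vector of SNP labels (length `p_g`).
#' @param covariate_names Character vector of covariate labels (length `p`,
#'   possibly empty).
#' @return An object of class `fam_dataset` with elements `families`,
#'   `snp_ids`, `covariate_names`, `m` (number of families) and `n`
#'   (total individuals).
#' @export
fam_dataset <- function(families, snp_ids = NULL, covariate_names = NULL) {
  if (!length(families)) stop("dataset must contain at least one family")
  if (!all(vapply(families, inherits, TRUE, "family_block"))) {
    stop("families must be a list of family_block objects")
  }
  p_g <- ncol(families[[1]]$G)
  p_c <- if (is.null(families[[1]]$C)) 0L else ncol(families[[1]]$C)
  for (f in families) {
    if (ncol(f$G) != p_g) stop("all families must have the same number of SNPs")
    pc_f <- if (is.null(f$C)) 0L else ncol(f$C)
    if (pc_f != p_c) stop("all families must have the same covariates")
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(p_g))
  if (length(snp_ids) != p_g) stop("snp_ids length must match genotype columns")
  if (is.null(covariate_names)) {
    covariate_names <- if (p_c) paste0("cov_", seq_len(p_c)) else character()
  }
  if (length(covariate_names) != p_c) {
    stop("covariate_names length must match covariate columns")
  }
  structure(list(families = families,
                 snp_ids = as.character(snp_ids),
                 covariate_names = as.character(covariate_names),
                 m = length(families),
                 n = sum(vapply(families, function(f) f$n_i, 1L))),
            class = "fam_dataset")
}

#' @export
print.fam_dataset <- function(x, ...) {
  cat(sprintf("fam_dataset: %d families, %d individuals, %d SNPs, %d covariates\n",
              x$m, x$n, length(x$snp_ids), length(x$covariate_names)))
  invisible(x)
}

n_snps <- function(dataset) length(dataset$snp_ids)

# ---- internal design machinery ------------------------------------------

# Stack the fixed-effect design of the whole dataset and index families by
# shared covariance structure, so per-family 4x4 solves can be batched.
# Columns of X are [intercept | SNPs | covariates].
ds_design <- function(dataset) {
  p_g <- length(dataset$snp_ids)
  p_c <- length(dataset$covariate_names)
  p <- 1L + p_g + p_c
  n <- dataset$n
  X <- matrix(0, n, p)
  y <- numeric(n)
  fam_of_row <- integer(n)
  row0 <- 0L
  fam_rows <- vector("list", dataset$m)
  keys <- character(dataset$m)
  for (i in seq_len(dataset$m)) {
    f <- dataset$families[[i]]
    idx <- row0 + seq_len(f$n_i)
    X[idx, 1] <- 1
    X[idx, 1 + seq_len(p_g)] <- f$G
    if (p_c) X[idx, 1 + p_g + seq_len(p_c)] <- f$C
    y[idx] <- f$y
    fam_of_row[idx] <- i
    fam_rows[[i]] <- idx
    keys[i] <- paste0(f$n_i, "|",
                      paste(signif(f$phi[upper.tri(f$phi, diag = FALSE)], 10),
                            collapse = ","))
    row0 <- row0 + f$n_i
  }
  groups <- lapply(split(seq_len(dataset$m), keys), function(fams) {
    k <- dataset$families[[fams[1]]]$n_i
    # rows[s, i]: stacked row index of member s in the i-th family of group
    rows <- vapply(fams, function(i) fam_rows[[i]], integer(k))
    if (k == 1L) rows <- matrix(rows, nrow = 1L)
    list(fams = fams, k = k, rows = rows,
         phi = dataset$families[[fams[1]]]$phi)
  })
  list(X = X, y = y, p = p, p_g = p_g, p_c = p_c, n = n,
       fam_rows = fam_rows, groups = unname(groups),
       gcols = 1L + seq_len(p_g),
       ccols = if (p_c) 1L + p_g + seq_len(p_c) else integer())
}

# Sufficient statistics per covariance group: member-pair crossproducts that
# do not depend on the variance components. For a group with k members,
# Cst[[s]][[t]] = Xs' Xt, ust[[s]][[t]] = Xs' yt, wst[s,t] = ys . yt.
ds_suffstats <- function(design) {
  lapply(design$groups, function(g) {
    k <- g$k
    Xs <- lapply(seq_len(k), function(s) design$X[g$rows[s, ], , drop = FALSE])
    ys <- lapply(seq_len(k), function(s) design$y[g$rows[s, ]])
    Cst <- vector("list", k); ust <- vector("list", k)
    wst <- matrix(0, k, k)
    for (s in seq_len(k)) {
      Cst[[s]] <- vector("list", k); ust[[s]] <- vector("list", k)
      for (t in seq_len(k)) {
        if (t >= s) Cst[[s]][[t]] <- crossprod(Xs[[s]], Xs[[t]])
        ust[[s]][[t]] <- crossprod(Xs[[s]], ys[[t]])
        wst[s, t] <- sum(ys[[s]] * ys[[t]])
      }
    }
    list(k = k, m_g = length(g$fams), phi = g$phi, Cst = Cst, ust = ust,
         wst = wst)
  })
}

# Accumulate A = sum_i Xi' Vi^-1 Xi, b = sum_i Xi' Vi^-1 yi,
# yVy = sum_i yi' Vi^-1 yi and sum log det Vi, given variance components.
ds_accumulate <- function(suff, varcomp) {
  p <- nrow(suff[[1]]$Cst[[1]][[1]])
  A <- matrix(0, p, p); b <- numeric(p); yVy <- 0; logdet <- 0
  Vinv_list <- vector("list", length(suff))
  for (gi in seq_along(suff)) {
    sg <- suff[[gi]]
    V <- assemble_covariance(varcomp, sg$phi)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vinv <- chol2inv(R)
    Vinv_list[[gi]] <- Vinv
    logdet <- logdet + sg$m_g * 2 * sum(log(diag(R)))
    k <- sg$k
    for (s in seq_len(k)) {
      for (t in seq_len(k)) {
        w <- Vinv[s, t]
        if (w == 0) next
        if (t >= s) {
          A <- A + w * sg$Cst[[s]][[t]]
          if (t > s) A <- A + w * t(sg$Cst[[s]][[t]])
        }
        b <- b + w * sg$ust[[s]][[t]]
        yVy <- yVy + w * sg$wst[s, t]
      }
    }
  }
  list(A = A, b = as.numeric(b), yVy = yVy, logdet = logdet,
       Vinv = Vinv_list)
}
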