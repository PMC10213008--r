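#' Expected-relatedness (kinship) matrix for a nuclear family
#'
#' Builds the matrix \eqn{\Phi} whose entries are twice the kinship
#' coefficient between pairs of family members, used as the polygenic
#' correlation structure of the ACE model. Rows/columns are ordered
#' father, mother, child 1, child 2 for the standard four-member pedigree.
#'
#' Twice the kinship coefficient is 1/2 for a parent and a biological child,
#' 1/2 for full siblings or dizygotic (DZ) twins, 1 for monozygotic (MZ)
#' twins, and 0 for any pair involving an adopted child (or the two parents,
#' assumed unrelated).
#'
#' @param family_type One of `"MZ"`, `"DZ"`, `"adopted"`, `"non_twin_sibs"`,
#'   `"mixed_adopted_bio"`. `"non_twin_sibs"` is structurally identical to
#'   `"DZ"`; `"mixed_adopted_bio"` has one biological child (index 3) and one
#'   adopted child (index 4).
#' @param n_members Number of family members. 4 is the standard pedigree
#'   (two parents, two children); 2 (parents only) and 3 (parents plus one
#'   child) are also supported.
#' @return A symmetric `n_members` x `n_members` matrix with unit diagonal.
#' @examples
#' build_kinship_matrix("MZ", 4)
#' build_kinship_matrix("adopted", 4)  # identity
#' @export
build_kinship_matrix <- function(family_type, n_members = 4L) {
  family_type <- match.arg(family_type,
                           c("MZ", "DZ", "adopted", "non_twin_sibs",
                             "mixed_adopted_bio"))
  if (!n_members %in% 2:4) {
    stop("n_members must be 2, 3 or 4 (parents plus up to two children)")
  }
  if (n_members < 4L && family_type == "mixed_adopted_bio") {
    stop("mixed_adopted_bio requires 4 members")
  }
  phi <- diag(n_members)
  if (n_members == 2L) return(phi)  # parents only, unrelated
  # parent-child entries
  pc <- switch(family_type,
               adopted = 0,
               mixed_adopted_bio = c(1 / 2, 0),
               1 / 2)
  if (family_type == "mixed_adopted_bio") {
    phi[1:2, 3] <- phi[3, 1:2] <- pc[1]
    phi[1:2, 4] <- phi[4, 1:2] <- pc[2]
    phi[3, 4] <- phi[4, 3] <- 0
    return(phi)
  }
  for (child in seq(3L, n_members)) {
    phi[1:2, child] <- phi[child, 1:2] <- pc
  }
  if (n_members == 4L) {
    cc <- switch(family_type, MZ = 1, DZ = 1 / 2, non_twin_sibs = 1 / 2,
                 adopted = 0)
    phi[3, 4] <- phi[4, 3] <- cc
  }
  phi
}

#' Assemble the ACE covariance matrix of one family
#'
#' Computes \eqn{V = \sigma_a^2 \Phi + \sigma_c^2 11' + \sigma_e^2 I}: an
#' additive-polygenic component proportional to the relatedness matrix, a
#' shared-environment component constant within the family, and an
#' individual-level residual component.
#'
#' @param varcomp A [variance_components()] object or a list/vector with
#'   elements `sigma_a2`, `sigma_c2`, `sigma_e2`.
#' @param phi Symmetric relatedness matrix with unit diagonal, as from
#'   [build_kinship_matrix()].
#' @return The covariance matrix, symmetric and positive definite whenever
#'   `sigma_e2 > 0`.
#' @export
assemble_covariance <- function(varcomp, phi) {
  vc <- as_varcomp(varcomp)
  phi <- as.matrix(phi)
  if (!isSymmetric(phi, tol = 1e-8)) stop("phi must be symmetric")
  n <- nrow(phi)
  vc$sigma_a2 * phi + vc$sigma_c2 * matrix(1, n, n) + vc$sigma_e2 * diag(n)
}

#' Variance components of the ACE model
#'
#' @param sigma_a2 Additive polygenic variance (>= 0).
#' @param sigma_c2 Shared-environment variance (>= 0).
#' @param sigma_e2 Unique-environment (residual) variance (> 0).
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(sigma_a2, sigma_c2, sigma_e2) {
  stopifnot(is.finite(sigma_a2), is.finite(sigma_c2), is.finite(sigma_e2),
            sigma_a2 >= 0, sigma_c2 >= 0, sigma_e2 > 0)
  structure(list(sigma_a2 = sigma_a2, sigma_c2 = sigma_c2,
                 sigma_e2 = sigma_e2),
            class = "variance_components")
}

as_varcomp <- function(x) {
  if (inherits(x, "variance_components")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) || !all(c("sigma_a2", "sigma_c2", "sigma_e2") %in%
                                names(x))) {
    if (length(x) != 3) stop("varcomp must have 3 components")
    names(x) <- c("sigma_a2", "sigma_c2", "sigma_e2")
  }
  variance_components(x[["sigma_a2"]], x[["sigma_c2"]], x[["sigma_e2"]])
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("ACE variance components: sigma_a2 = %.4g, sigma_c2 = %.4g, sigma_e2 = %.4g\n",
              x$sigma_a2, x$sigma_c2, x$sigma_e2))
  invisible(x)
}
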