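#' Write a pedigree dataset as a wide genotype CSV
#'
#' One row per individual with columns `family_id`, `individual_id`,
#' `role`, `zygosity` (the family type), `phenotype`, any covariates, then
#' the SNP columns (0/1/2).
#'
#' @param dataset A [fam_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "fam_dataset"))
  rows <- lapply(dataset$families, function(f) {
    base <- data.frame(family_id = rep(as.character(f$family_id), f$n_i),
                       individual_id = paste0(f$family_id, "_",
                                              seq_len(f$n_i)),
                       role = f$roles,
                       zygosity = rep(as.character(f$family_type), f$n_i),
                       phenotype = f$y)
    if (length(dataset$covariate_names)) {
      cv <- as.data.frame(f$C)
      names(cv) <- dataset$covariate_names
      base <- cbind(base, cv)
    }
    gg <- as.data.frame(f$G)
    names(gg) <- dataset$snp_ids
    cbind(base, gg)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a wide genotype CSV into a pedigree dataset
#'
#' Expects columns `family_id`, `individual_id`, `role`, `phenotype`, an
#' optional `zygosity` column, the named covariate columns, and all
#' remaining columns as SNP genotypes coded 0/1/2. Missing genotypes are an
#' error. The per-family relatedness matrix is built from the roles and the
#' family type (from `zygosity` or the `family_types` map).
#'
#' @param path CSV file path.
#' @param covariates Character vector naming the covariate columns
#'   (default none).
#' @param family_types Optional named vector mapping `family_id` to a type
#'   in `MZ`, `DZ`, `adopted`, `non_twin_sibs`, `mixed_adopted_bio`;
#'   overrides the `zygosity` column.
#' @return A [fam_dataset()].
#' @export
read_genotype_csv <- function(path, covariates = character(),
                              family_types = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  required <- c("family_id", "individual_id", "role", "phenotype")
  if (!all(required %in% names(df))) {
    stop("genotype CSV must contain columns: ",
         paste(required, collapse = ", "))
  }
  meta <- c(required, "zygosity", covariates)
  snp_cols <- setdiff(names(df), meta)
  if (!length(snp_cols)) stop("no SNP columns found")
  G_all <- as.matrix(df[, snp_cols, drop = FALSE])
  if (anyNA(G_all)) stop("missing genotypes are not allowed")
  fams <- lapply(split(seq_len(nrow(df)), factor(df$family_id,
                                                 unique(df$family_id))),
                 function(idx) {
    fid <- df$family_id[idx[1]]
    type <- if (!is.null(family_types)) {
      unname(family_types[as.character(fid)])
    } else if ("zygosity" %in% names(df)) {
      df$zygosity[idx[1]]
    } else NA_character_
    if (is.na(type)) {
      stop("family type unknown for family ", fid,
           ": provide a zygosity column or a family_types map")
    }
    roles <- df$role[idx]
    family_block(fid, df$phenotype[idx], G_all[idx, , drop = FALSE],
                 build_family_phi(roles, type),
                 C = if (length(covariates)) {
                   as.matrix(df[idx, covariates, drop = FALSE])
                 } else NULL,
                 roles = roles, family_type = type)
  })
  fam_dataset(unname(fams), snp_ids = snp_cols,
              covariate_names = covariates)
}

# Relatedness matrix for an arbitrary subset of a nuclear family given
# member roles; children ordered as they appear.
build_family_phi <- function(roles, type) {
  n <- length(roles)
  child_idx <- which(roles == "child")
  phi <- diag(n)
  pc <- if (type == "adopted") 0 else 1 / 2
  for (ci in seq_along(child_idx)) {
    child_pc <- if (type == "mixed_adopted_bio" && ci == 2L) 0 else pc
    for (p in which(roles %in% c("father", "mother"))) {
      phi[p, child_idx[ci]] <- phi[child_idx[ci], p] <- child_pc
    }
  }
  if (length(child_idx) == 2L) {
    cc <- switch(type, MZ = 1, DZ = 1 / 2, non_twin_sibs = 1 / 2, 0)
    phi[child_idx[1], child_idx[2]] <- phi[child_idx[2], child_idx[1]] <- cc
  }
  phi
}

#' Read a PLINK-style additive `.raw` genotype file
#'
#' Whitespace-separated file with header `FID IID PAT MAT SEX PHENOTYPE`
#' followed by SNP_allele columns in additive 0/1/2 coding. Individuals
#' are grouped into nuclear families by `FID`; rows with `PAT = MAT = 0`
#' are taken as parents, the rest as children. `SEX` is carried as a
#' covariate. The family type must be supplied via `family_types` (a named
#' map from FID); families missing from the map default to `"DZ"` with a
#' message, since the `.raw` format carries no zygosity information.
#'
#' @param path File path.
#' @param family_types Optional named character vector keyed by FID.
#' @return A [fam_dataset()].
#' @export
read_plink_raw <- function(path, family_types = NULL) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(required %in% names(df))) {
    stop(".raw file must contain the header FID IID PAT MAT SEX PHENOTYPE")
  }
  snp_cols <- setdiff(names(df), required)
  if (!length(snp_cols)) stop("no SNP columns found")
  defaulted <- FALSE
  fams <- lapply(split(seq_len(nrow(df)), factor(df$FID, unique(df$FID))),
                 function(idx) {
    fid <- as.character(df$FID[idx[1]])
    is_parent <- df$PAT[idx] == 0 & df$MAT[idx] == 0
    if (sum(!is_parent) &&
        !all(df$PAT[idx][!is_parent] %in% df$IID[idx][is_parent] |
             df$PAT[idx][!is_parent] == 0)) {
      stop("family ", fid, " is not a nuclear pedigree")
    }
    ord <- idx[order(!is_parent)]
    roles <- ifelse(df$PAT[ord] == 0 & df$MAT[ord] == 0,
                    ifelse(df$SEX[ord] == 1, "father", "mother"), "child")
    type <- if (!is.null(family_types) &&
                as.character(fid) %in% names(family_types)) {
      unname(family_types[as.character(fid)])
    } else {
      defaulted <<- TRUE
      "DZ"
    }
    G <- as.matrix(df[ord, snp_cols, drop = FALSE])
    if (anyNA(G)) stop("missing genotypes are not allowed")
    family_block(fid, df$PHENOTYPE[ord], G, build_family_phi(roles, type),
                 C = matrix(as.numeric(df$SEX[ord]), ncol = 1),
                 roles = roles, family_type = type)
  })
  if (defaulted) {
    message("family types not supplied for some FIDs; defaulting to DZ")
  }
  fam_dataset(unname(fams), snp_ids = snp_cols, covariate_names = "SEX")
}
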