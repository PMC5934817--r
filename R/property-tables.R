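# Per-residue physicochemical scales and residue-pair distance matrices.
# Residue order everywhere: ACDEFGHIKLMNPQRSTVWY.

.aa <- function(...) {
  v <- c(...)
  names(v) <- AA_ALPHABET20
  v
}

# Kyte-Doolittle hydropathy
.KD_HYDROPHOBICITY <- .aa(
  1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
  1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)

# Hopp-Woods hydrophilicity
.HW_HYDROPHILICITY <- .aa(
  -0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
  -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3)

# side-chain mass (Da)
.SIDE_CHAIN_MASS <- .aa(
  15, 47, 59, 73, 91, 1, 82, 57, 73, 57,
  75, 58, 42, 72, 101, 31, 45, 43, 130, 107)

# normalized van der Waals volume
.VDW_VOLUME <- .aa(
  1.00, 2.43, 2.78, 3.78, 5.89, 0.00, 4.66, 4.00, 4.77, 4.00,
  4.43, 2.95, 2.72, 3.95, 6.13, 1.60, 2.60, 3.00, 8.08, 6.47)

# Grantham polarity
.POLARITY <- .aa(
  8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
  5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2)

# Grantham composition (non-carbon atoms in side chain / carbons)
.GRANTHAM_COMPOSITION <- .aa(
  0.00, 2.75, 1.38, 0.92, 0.00, 0.74, 0.58, 0.00, 0.33, 0.00,
  0.00, 1.33, 0.39, 0.89, 0.65, 1.42, 0.71, 0.00, 0.13, 0.20)

# Grantham side-chain volume
.GRANTHAM_VOLUME <- .aa(
  31, 55, 54, 83, 132, 3, 96, 111, 119, 111,
  105, 56, 32.5, 85, 124, 32, 61, 84, 170, 136)

# polarizability
.POLARIZABILITY <- .aa(
  0.046, 0.128, 0.105, 0.151, 0.290, 0.000, 0.230, 0.186, 0.219, 0.186,
  0.221, 0.134, 0.131, 0.180, 0.291, 0.062, 0.108, 0.140, 0.409, 0.298)

# formal side-chain charge at pH 7 (His half-protonated)
.CHARGE <- .aa(
  0, 0, -1, -1, 0, 0, 0.5, 0, 1, 0,
  0, 0, 0, 0, 1, 0, 0, 0, 0, 0)

# Chou-Fasman alpha-helix propensity
.HELIX_PROPENSITY <- .aa(
  1.42, 0.70, 1.01, 1.51, 1.13, 0.57, 1.00, 1.08, 1.16, 1.21,
  1.45, 0.67, 0.57, 1.11, 0.98, 0.77, 0.83, 1.06, 1.08, 0.69)

# maximum solvent-accessible surface area (A^2)
.SOLVENT_ACCESS <- .aa(
  115, 135, 150, 190, 210, 75, 195, 175, 200, 170,
  185, 160, 145, 180, 225, 115, 140, 155, 255, 230)

# standardized hydropathy scale shared by the profile similarity
.PROFILE_HYD <- {
  h <- .KD_HYDROPHOBICITY
  (h - mean(h)) / sd(h)
}
.PROFILE_RANGE <- max(.PROFILE_HYD) - min(.PROFILE_HYD)

# hydropathy lookup by character code (fast path for aligned strings)
.HYD_BY_BYTE <- {
  v <- rep(NA_real_, 128L)
  v[utf8ToInt(paste(AA_ALPHABET20, collapse = ""))] <- .PROFILE_HYD
  v
}
.GAP_BYTE <- utf8ToInt("-")

# three-class groupings behind the CTD encoding, class order 1/2/3
.CTD_CLASSES <- list(
  hydrophobicity    = c("RKEDQN",   "GASTPHY",          "CLVIMFW"),
  vdw_volume        = c("GASTPD",   "NVEQIL",           "MHKFRYW"),
  polarity          = c("LIFWCMVY", "PATGS",            "HQRKNED"),
  polarizability    = c("GASDT",    "CPNVEQIL",         "KMHFRYW"),
  charge            = c("KR",       "ANCQGHILMFPSTWYV", "DE"),
  secondary_struct  = c("EALMQKRH", "VIYCWFT",          "GNPSD"),
  solvent_access    = c("ALFCGIVW", "RKQEND",           "MSPTHY"))

#' Per-residue physicochemical property table
#'
#' The seven numeric per-residue scales used by the autocorrelation
#' descriptors and the physicochemical profile (hydrophobicity, normalized
#' van der Waals volume, polarity, polarizability, charge, alpha-helix
#' propensity, solvent accessibility), in the fixed residue order
#' \code{ACDEFGHIKLMNPQRSTVWY}.
#'
#' @param standardized standardize each scale to mean 0, sd 1 over the 20
#'   residues (the form the descriptors consume).
#' @return a 20 x 7 numeric matrix, residues in rows.
#' @export
#' @examples
#' aaPropertyTable()["W", "hydrophobicity"]
aaPropertyTable <- function(standardized = FALSE) {
  m <- cbind(hydrophobicity = .KD_HYDROPHOBICITY,
             vdw_volume = .VDW_VOLUME,
             polarity = .POLARITY,
             polarizability = .POLARIZABILITY,
             charge = .CHARGE,
             secondary_struct = .HELIX_PROPENSITY,
             solvent_access = .SOLVENT_ACCESS)
  if (standardized) m[, ] <- scale(m)
  m
}

#' Residue-pair physicochemical distance matrices
#'
#' Symmetric zero-diagonal 20 x 20 distance matrices used by the
#' quasi-sequence-order descriptor. \code{"schneider_wrede"} is the
#' physicochemical distance built as the root-mean-square difference of
#' standardized hydrophobicity, hydrophilicity and side-chain mass;
#' \code{"grantham"} applies Grantham's composition/polarity/volume formula
#' \eqn{D = \rho [\alpha(c_1-c_2)^2 + \beta(p_1-p_2)^2 +
#' \gamma(v_1-v_2)^2]^{1/2}} with \eqn{\alpha = 1.833}, \eqn{\beta = 0.1018},
#' \eqn{\gamma = 0.000399} and \eqn{\rho} scaled so the mean off-diagonal
#' distance is 100.
#'
#' @param type which matrix.
#' @return 20 x 20 numeric matrix with dimnames \code{ACDEFGHIKLMNPQRSTVWY}.
#' @export
#' @examples
#' d <- aaDistanceMatrix("grantham")
#' all(diag(d) == 0)
aaDistanceMatrix <- function(type = c("schneider_wrede", "grantham")) {
  type <- match.arg(type)
  if (type == "schneider_wrede") {
    props <- scale(cbind(.KD_HYDROPHOBICITY, .HW_HYDROPHILICITY,
                         .SIDE_CHAIN_MASS))
    d <- as.matrix(stats::dist(props)) / sqrt(ncol(props))
  } else {
    alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399
    dc <- outer(.GRANTHAM_COMPOSITION, .GRANTHAM_COMPOSITION, "-")
    dp <- outer(.POLARITY, .POLARITY, "-")
    dv <- outer(.GRANTHAM_VOLUME, .GRANTHAM_VOLUME, "-")
    d <- sqrt(alpha * dc^2 + beta * dp^2 + gamma * dv^2)
    off <- d[upper.tri(d)]
    d <- d * (100 / mean(off))
  }
  dimnames(d) <- list(AA_ALPHABET20, AA_ALPHABET20)
  d
}

# class index (1/2/3) of each residue under each CTD attribute
.ctdClassIndex <- function() {
  vapply(.CTD_CLASSES, function(classes) {
    idx <- integer(20L)
    for (k in 1:3)
      idx[match(strsplit(classes[k], "")[[1]], AA_ALPHABET20)] <- k
    idx
  }, integer(20L))
}
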