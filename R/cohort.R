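#' Construct an eye cohort
#'
#' A cohort bundles the circumpapillary thickness profiles of a set of eyes
#' (one row per eye, one column per angular position) with the per-eye
#' covariates used by the compensation pipeline.  Profiles are sampled on a
#' circle, so column `p0` is angularly adjacent to the last column: all
#' downstream operations treat the index arithmetic as circular.
#'
#' The angular convention is that column `p0` sits at the temporal horizontal
#' position with indices increasing through superior, nasal and inferior back
#' to temporal (TSNIT unrolling).  This convention only fixes the orientation
#' of plots and of the simulator's peak angles; no computation depends on it.
#'
#' @param profiles numeric matrix, eyes in rows and angular positions in
#'   columns, thickness in micrometers.  Row names are taken as eye ids when
#'   `covariates` lacks an `eye_id` column order match.
#' @param covariates data frame with columns `eye_id`, `age` (years),
#'   `gender` (`"M"`/`"F"`), `axial_length` (mm), `disc_fovea_distance` (mm),
#'   `disc_fovea_angle` (degrees), `quality_score`, `label`
#'   (`"normal"`/`"glaucoma"`), in the same order as the profile rows.
#' @return An object of class `rnfl_cohort`: a list with elements `profiles`
#'   (matrix), `covariates` (data frame) and `P` (profile length).
#' @export
cohort <- function(profiles, covariates) {
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "double"
  stopifnot(is.data.frame(covariates))
  required <- c("eye_id", "age", "gender", "axial_length",
                "disc_fovea_distance", "disc_fovea_angle",
                "quality_score", "label")
  missing_cols <- setdiff(required, names(covariates))
  if (length(missing_cols))
    stop("covariates table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(profiles) != nrow(covariates))
    stop("profiles has ", nrow(profiles), " rows but covariates has ",
         nrow(covariates))
  covariates$eye_id <- as.character(covariates$eye_id)
  if (anyDuplicated(covariates$eye_id))
    stop("duplicated eye_id in cohort: ",
         paste(unique(covariates$eye_id[duplicated(covariates$eye_id)]),
               collapse = ", "))
  if (any(!is.finite(profiles)) || any(profiles < 0))
    stop("profile values must be finite and non-negative")
  bad_label <- setdiff(unique(covariates$label), c("normal", "glaucoma"))
  if (length(bad_label))
    stop("labels must be 'normal' or 'glaucoma'; found: ",
         paste(bad_label, collapse = ", "))
  rownames(profiles) <- covariates$eye_id
  structure(list(profiles = profiles,
                 covariates = covariates,
                 P = ncol(profiles)),
            class = "rnfl_cohort")
}

#' @export
print.rnfl_cohort <- function(x, ...) {
  tab <- table(x$covariates$label)
  cat("rnfl_cohort: ", nrow(x$profiles), " eyes, P = ", x$P, "\n", sep = "")
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of eyes in a cohort
#' @param x an `rnfl_cohort`
#' @return integer count of eyes
#' @export
n_eyes <- function(x) nrow(x$profiles)

#' Subset a cohort by record index
#' @param x an `rnfl_cohort`
#' @param i integer or logical index over eyes
#' @param ... ignored
#' @return the subsetted `rnfl_cohort`
#' @export
`[.rnfl_cohort` <- function(x, i, ...) {
  cohort(x$profiles[i, , drop = FALSE], x$covariates[i, , drop = FALSE])
}

#' Circular profile index helper
#'
#' Maps arbitrary integer offsets onto the valid 1..P column range so that
#' index `P + 1` wraps to 1 and index 0 wraps to `P`.
#'
#' @param i integer vector of (possibly out-of-range) 1-based indices
#' @param P profile length
#' @return indices wrapped into `1..P`
#' @export
wrap_index <- function(i, P) ((i - 1) %% P) + 1

#' Angular position of each profile point
#' @param P profile length
#' @return numeric vector of length `P`: degrees on the scan circle for the
#'   1-based point index, starting at 0 (temporal) and increasing superiorly.
#' @export
profile_angles <- function(P) 360 * (seq_len(P) - 1) / P

#' Read a cohort from its two CSV tables
#'
#' The on-disk representation is two comma-separated UTF-8 tables with header
#' rows: a wide profile table (`eye_id,p0,...,p{P-1}`, micrometers) and a
#' covariate table (`eye_id,age,gender,axial_length,disc_fovea_distance,
#' disc_fovea_angle,quality_score,label`).  The two tables are joined on
#' `eye_id`; record order follows the profile table.
#'
#' @param profiles_path path to the profile CSV
#' @param covariates_path path to the covariate CSV
#' @return an [cohort()] object
#' @export
read_cohort <- function(profiles_path, covariates_path) {
  prof <- utils::read.csv(profiles_path, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  cov <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
  if (names(prof)[1] != "eye_id")
    stop("profiles table must start with an eye_id column")
  ids <- as.character(prof$eye_id)
  vals <- prof[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]))
      if (length(bad))
        stop("non-numeric thickness at row ", bad[1],
             ", column ", names(vals)[j])
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  cov$eye_id <- as.character(cov$eye_id)
  missing_in_cov <- setdiff(ids, cov$eye_id)
  if (length(missing_in_cov))
    stop("eye_id missing from covariates table: ",
         paste(missing_in_cov, collapse = ", "))
  missing_in_prof <- setdiff(cov$eye_id, ids)
  if (length(missing_in_prof))
    stop("eye_id missing from profiles table: ",
         paste(missing_in_prof, collapse = ", "))
  cov <- cov[match(ids, cov$eye_id), , drop = FALSE]
  rownames(cov) <- NULL
  cohort(m, cov)
}

#' Write a cohort to its two CSV tables
#'
#' Inverse of [read_cohort()]; profile values are written with full double
#' precision so a read/write round trip is exact.
#'
#' @param x an `rnfl_cohort`
#' @param profiles_path output path for the profile CSV
#' @param covariates_path output path for the covariate CSV
#' @return invisibly, the two paths
#' @export
write_cohort <- function(x, profiles_path, covariates_path) {
  stopifnot(inherits(x, "rnfl_cohort"))
  write_profile_csv(x$profiles, x$covariates$eye_id, profiles_path)
  cov <- x$covariates
  for (j in seq_along(cov))
    if (is.double(cov[[j]])) cov[[j]] <- sprintf("%.17g", cov[[j]])
  utils::write.csv(cov, covariates_path, row.names = FALSE, quote = FALSE)
  invisible(c(profiles_path, covariates_path))
}

# full-precision profile-table writer shared by write_cohort and the
# compensate command; %.17g round-trips doubles exactly
write_profile_csv <- function(m, ids, path) {
  ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  prof <- data.frame(eye_id = ids, ch, check.names = FALSE,
                     stringsAsFactors = FALSE)
  names(prof) <- c("eye_id", paste0("p", seq_len(ncol(m)) - 1))
  utils::write.csv(prof, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop low-quality scans
#'
#' Scans whose quality score falls below the threshold are removed; the
#' conventional acquisition cutoff of 15 is the default.  Records with a
#' score exactly at the threshold are kept.
#'
#' @param x an `rnfl_cohort`
#' @param min_quality minimum acceptable quality score (dimensionless)
#' @return the filtered cohort, order preserved, with attribute `n_removed`
#'   giving the number of discarded records
#' @export
filter_quality <- function(x, min_quality = 15) {
  stopifnot(inherits(x, "rnfl_cohort"), min_quality >= 0)
  keep <- x$covariates$quality_score >= min_quality
  out <- cohort(x$profiles[keep, , drop = FALSE],
                x$covariates[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Littmann-Bennett ocular magnification factor
#'
#' The Littmann formula with Bennett's axial-length approximation,
#' `q = 0.01306 * (axial_length - 1.82)`, converts measured distances on a
#' fundus image to true retinal distances via `t = p * q * s` (with `s` the
#' camera scaling).  Used when fundus-measured covariates such as the
#' disc-fovea distance must be corrected for eye size.
#'
#' @param axial_length axial length in mm; must lie in (15, 35)
#' @return the dimensionless magnification factor `q`
#' @export
littmann_bennett_factor <- function(axial_length) {
  if (any(!is.finite(axial_length)) ||
      any(axial_length <= 15) || any(axial_length >= 35))
    stop("axial_length must lie in (15, 35) mm")
  0.01306 * (axial_length - 1.82)
}
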