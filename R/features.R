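#' Canonical feature names
#'
#' The 44 features in report order: 24 texture (six Haralick statistics for
#' each displacement (1,1,1), (1,0,0), (0,1,0), (0,0,1)), 6 morphological,
#' 9 ellipsoid-fitting, 5 posterior acoustic.
#'
#' @return character vector of length 44.
#' @export
feature_names <- function() {
  tex <- unlist(lapply(texture_displacements(), function(d) {
    paste0("T_", c("ASM", "Con", "I", "E", "D", "Cor"),
           sprintf("(%s)", paste(d, collapse = ",")))
  }))
  c(tex,
    c("M_V", "M_A", "M_Rm", "M_Rstd", "M_Cc", "M_Cd"),
    c("E_A", "E_S", "E_V", "E_RO", "E_RI", "E_R", "E_ROa", "E_RIa", "E_Ra"),
    c("P_std", "P_Rstd", "P_Sstd", "P_Sm", "P_Rm"))
}

#' Feature family of each feature
#'
#' @return named character vector mapping each of the 44 feature names to
#'   `"texture"`, `"morphology"`, `"ellipsoid"` or `"posterior"`.
#' @export
feature_families <- function() {
  fn <- feature_names()
  fam <- c(rep("texture", 24), rep("morphology", 6),
           rep("ellipsoid", 9), rep("posterior", 5))
  names(fam) <- fn
  fam
}

#' Extract the full 44-feature vector of a case
#'
#' Runs the four feature families on a co-registered volume/mask pair.
#' Deterministic given its inputs. Features whose definition degenerates on
#' the given case (e.g. a constant-gray lesion has no `P_Rstd`) are `NA`
#' with a warning; such cases are rejected by the classifier.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [lesion_mask()] of identical shape.
#' @param config thresholds, see [grading_config()]: uses `sliver_min_size`,
#'   `angularity_threshold`, `posterior_fraction`, `posterior_height_cap`,
#'   `mesh_smooth_iter`.
#' @return named numeric vector of length 44 (see [feature_names()]).
#' @export
extract_features <- function(volume, mask, config = grading_config()) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "lesion_mask"))
  if (!identical(dim(volume$data), dim(mask$data))) {
    stop("volume and mask shapes differ", call. = FALSE)
  }
  tex <- texture_features(volume, mask)
  mor <- morphology_features(mask, smooth_iter = config$mesh_smooth_iter)
  ell <- ellipsoid_features(mask,
                            min_size = config$sliver_min_size,
                            angularity_threshold = config$angularity_threshold,
                            smooth_iter = config$mesh_smooth_iter,
                            lesion_area = mor[["M_A"]])
  post <- build_posterior(mask, target = config$posterior_fraction,
                          height_cap = config$posterior_height_cap)
  pac <- posterior_features(volume, mask, post)
  out <- c(tex, mor, ell, pac)
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Grade-group comparison of feature values
#'
#' For each feature, tests the difference between low- and high-grade
#' groups: Lilliefors-corrected Kolmogorov-Smirnov normality test on each
#' group at alpha = 0.05; if both groups are normal, a two-sided Welch
#' t-test, otherwise a two-sided Mann-Whitney U test. Cases with a missing
#' value are excluded from that feature's test only. A feature constant in
#' both groups gets p = 1 with a note.
#'
#' @param features data frame or matrix with the 44 feature columns (extra
#'   columns such as `case_id` are ignored).
#' @param labels factor/character of "low"/"high" per row.
#' @param alpha normality-test level (default 0.05).
#' @return data frame with one row per feature: summary statistics per
#'   group (mean, sd, median), the test used, and the p-value.
#' @export
compare_groups <- function(features, labels, alpha = 0.05) {
  fn <- feature_names()
  features <- as.data.frame(features, check.names = FALSE, optional = TRUE)
  stopifnot(all(fn %in% colnames(features)))
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("low", "high")), length(labels) == nrow(features))
  if (min(table(labels)) < 3) stop("need at least 3 cases per group",
                                   call. = FALSE)
  is_normal <- function(x) {
    if (length(x) < 5 || stats::sd(x) == 0) return(FALSE)
    ok <- tryCatch(nortest::lillie.test(x)$p.value, error = function(e) 0)
    ok > alpha
  }
  rows <- lapply(fn, function(f) {
    x <- as.numeric(features[[f]])
    keep <- !is.na(x)
    lo <- x[keep & labels == "low"]
    hi <- x[keep & labels == "high"]
    base <- data.frame(
      feature = f, family = unname(feature_families()[f]),
      n_low = length(lo), n_high = length(hi),
      mean_low = mean(lo), sd_low = stats::sd(lo), median_low = stats::median(lo),
      mean_high = mean(hi), sd_high = stats::sd(hi),
      median_high = stats::median(hi), stringsAsFactors = FALSE)
    if (length(unique(c(lo, hi))) == 1L) {
      base$test <- "none (constant)"
      base$p_value <- 1
      return(base)
    }
    if (is_normal(lo) && is_normal(hi)) {
      base$test <- "t-test"
      base$p_value <- stats::t.test(lo, hi)$p.value
    } else {
      base$test <- "Mann-Whitney U"
      base$p_value <- suppressWarnings(stats::wilcox.test(lo, hi)$p.value)
    }
    base
  })
  do.call(rbind, rows)
}
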