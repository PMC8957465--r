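#' Synthetic cohort specification
#'
#' Describes the joint cohort to simulate: how many joints of each type, the
#' pathology grade distribution per soft-tissue lesion (assigned by seeded
#' permutation, not sampling, so the specified counts are reproduced
#' verbatim), the pre/post-synovectomy synovial volume model, the bleed-count
#' model, and per-arm mis-grading rates for the two MRI measurement arms.
#'
#' The three detection methods (pathology, conventional MRI, Canny-based MRI)
#' are modeled as three measurement arms over the same joints, so per-level
#' detection-rate comparisons share one denominator; use
#' [cohort_long()] for the one-row-per-arm view.
#'
#' @param joints_per_type named integer vector with entries `knee`, `ankle`,
#'   `elbow`, `hip`.
#' @param grade_distributions named list (per lesion) of named count vectors;
#'   names are grade labels (`"0"` to `"3"`, or a combined `"2-3"` bin).
#' @param volume_model list with `pre_mean` (mm^3), `pre_cv` (lognormal
#'   coefficient of variation), `reduction` (post/pre factor in (0, 1]),
#'   `post_cv` (residual lognormal CV of the post volume).
#' @param bleed_model list with `pre_mean`, `post_mean` (bleeds per 6
#'   months) and `dispersion` (1 = Poisson; > 1 = negative binomial).
#' @param arm_error named vector `c(conventional =, canny =)` of per-joint
#'   probabilities that an arm's soft-tissue grade is shifted by one level.
#' @param rs_joints number of joints in the radiation-synovectomy-treated
#'   subgroup carrying the pre/post volume comparison.
#' @param n_patients number of patients the joints are distributed over.
#' @param skip_sum_check character vector of lesions exempt from the
#'   grade-count/joint-total consistency check (needed when a specified
#'   distribution does not sum to the joint total).
#' @param seed master seed; all stage draws derive from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(joints_per_type = c(knee = 84L, ankle = 38L,
                                            elbow = 10L, hip = 14L),
                        grade_distributions = list(
                          effusion = c(`0` = 14L, `1` = 59L, `2-3` = 37L),
                          synovial_hyperplasia = c(`0` = 15L, `1` = 50L,
                                                   `2` = 27L, `3` = 54L),
                          hemosiderin = c(`0` = 36L, `1` = 46L, `2` = 22L,
                                          `3` = 44L)),
                        volume_model = list(pre_mean = 30000, pre_cv = 0.20,
                                            reduction = 0.7, post_cv = 0.20),
                        bleed_model = list(pre_mean = 4.0, post_mean = 1.2,
                                           dispersion = 1),
                        arm_error = c(conventional = 0.25, canny = 0.04),
                        rs_joints = 42L, n_patients = 60L,
                        skip_sum_check = character(),
                        seed = 20201L) {
  if (any(joints_per_type < 0)) stopf("joint counts must be nonnegative")
  for (lesion in names(grade_distributions)) {
    if (any(grade_distributions[[lesion]] < 0))
      stopf("grade counts for '%s' must be nonnegative", lesion)
  }
  vm <- volume_model
  if (!(vm$reduction > 0 && vm$reduction <= 1))
    stopf("volume reduction factor must lie in (0, 1]")
  if (vm$pre_mean <= 0) stopf("pre-surgery volume mean must be positive")
  structure(list(joints_per_type = joints_per_type,
                 grade_distributions = grade_distributions,
                 volume_model = volume_model, bleed_model = bleed_model,
                 arm_error = arm_error, rs_joints = as.integer(rs_joints),
                 n_patients = as.integer(n_patients),
                 skip_sum_check = skip_sum_check, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The study's default cohort
#'
#' The published cohort verbatim: 146 joints (84 knee, 38 ankle, 10 elbow,
#' 14 hip) over 60 patients; pathology grade counts of (14, 59, 37) for
#' effusion scores (0, 1, 2-3), (15, 50, 27, 54) for synovial hyperplasia
#' scores 0-3 and (36, 46, 22, 44) for hemosiderin scores 0-3; a 42-joint
#' radiation-synovectomy subgroup. The effusion counts sum to 110 and the
#' hemosiderin counts to 148 - neither equals 146; the distributions are kept
#' verbatim rather than reconciled, and the sum-consistency check is disabled
#' for exactly those two lesions (joints beyond the effusion counts stay
#' ungraded `NA`; the two hemosiderin grades in excess are dropped from the
#' last bin with a warning at generation time).
#'
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function() {
  cohort_spec(skip_sum_check = c("effusion", "hemosiderin"))
}

lesion_names <- c("effusion", "synovial_hyperplasia", "hemosiderin")
arm_names <- c("pathology", "conventional", "canny")

# expand a named count vector like c(`0`=14, `1`=59, `2-3`=37) into a vector
# of numeric grades; a combined "a-b" bin is split evenly, low grade first
expand_grades <- function(counts) {
  out <- integer(0)
  for (lab in names(counts)) {
    k <- counts[[lab]]
    if (grepl("-|~", lab)) {
      pair <- as.integer(strsplit(lab, "-|~")[[1]])
      out <- c(out, rep(pair[1], ceiling(k / 2)), rep(pair[2], floor(k / 2)))
    } else {
      out <- c(out, rep(as.integer(lab), k))
    }
  }
  out
}

# MRI arms mis-grade by under-detection: a hit joint's grade drops one level
# (clamped at 0). Downward bias reflects missed small lesions, the mechanism
# that separates a method arm's detection rates from pathology; symmetric
# errors would leave per-level rates nearly unchanged.
shift_grades <- function(grades, p_err, seed) {
  with_seed(seed, {
    hit <- stats::runif(length(grades)) < p_err
    out <- grades
    idx <- which(hit & !is.na(grades))
    out[idx] <- pmax(grades[idx] - 1L, 0L)
    out
  })
}

#' Generate a synthetic cohort table
#'
#' One row per joint. Pathology grades are assigned by seeded permutation of
#' the exact counts in the spec; the conventional and Canny MRI arms re-grade
#' each joint with their respective mis-grading probabilities. Pre-surgery
#' synovial volumes are lognormal around `pre_mean`; post volumes are
#' `pre * reduction * exp(noise)` with mean-one lognormal noise. Bleed counts
#' pre/post are Poisson (or negative binomial when `dispersion > 1`).
#' Everything is a pure function of the spec, including its seed.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` of class `cohort_table` with columns `patient_id`,
#'   `joint_type`, `rs_treated`, `<lesion>_<arm>` grade columns,
#'   `volume_pre`, `volume_post` (mm^3), `bleeds_pre`, `bleeds_post`; the
#'   spec is attached as attribute `spec`.
#' @examples
#' co <- make_cohort(default_cohort_spec())
#' table(co$joint_type)
#' grade_counts(co, "synovial_hyperplasia")
#' @export
make_cohort <- function(spec = default_cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec()")
  n <- sum(spec$joints_per_type)
  joint_type <- rep(names(spec$joints_per_type), spec$joints_per_type)
  patient_id <- sprintf("P%03d", sort(rep_len(seq_len(spec$n_patients), n)))
  df <- data.frame(patient_id = patient_id, joint_type = joint_type,
                   stringsAsFactors = FALSE)

  for (lesion in names(spec$grade_distributions)) {
    counts <- spec$grade_distributions[[lesion]]
    grades <- expand_grades(counts)
    if (length(grades) != n) {
      if (!(lesion %in% spec$skip_sum_check))
        stopf("grade counts for '%s' sum to %d but the cohort has %d joints",
              lesion, length(grades), n)
      if (length(grades) < n) {
        grades <- c(grades, rep(NA_integer_, n - length(grades)))
      } else {
        warning(sprintf(
          "grade counts for '%s' sum to %d > %d joints; dropping %d from the last bin",
          lesion, length(grades), n, length(grades) - n), call. = FALSE)
        grades <- grades[seq_len(n)]
      }
    }
    path <- with_seed(derive_seed(spec$seed, paste0("grades_", lesion)),
                      sample(grades))
    df[[paste0(lesion, "_pathology")]] <- path
    df[[paste0(lesion, "_conventional")]] <-
      shift_grades(path, spec$arm_error[["conventional"]],
                   derive_seed(spec$seed, paste0("conv_", lesion)))
    df[[paste0(lesion, "_canny")]] <-
      shift_grades(path, spec$arm_error[["canny"]],
                   derive_seed(spec$seed, paste0("canny_", lesion)))
  }

  vm <- spec$volume_model
  sdlog_pre <- sqrt(log(1 + vm$pre_cv^2))
  sdlog_post <- sqrt(log(1 + vm$post_cv^2))
  df$volume_pre <- with_seed(derive_seed(spec$seed, "volume_pre"),
    stats::rlnorm(n, log(vm$pre_mean) - sdlog_pre^2 / 2, sdlog_pre))
  noise <- with_seed(derive_seed(spec$seed, "volume_post"),
    stats::rlnorm(n, -sdlog_post^2 / 2, sdlog_post))
  df$volume_post <- df$volume_pre * vm$reduction * noise

  bm <- spec$bleed_model
  rcount <- function(mu, label) with_seed(derive_seed(spec$seed, label), {
    if (is.null(bm$dispersion) || bm$dispersion <= 1) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, mu = mu, size = mu / (bm$dispersion - 1))
    }
  })
  df$bleeds_pre <- rcount(bm$pre_mean, "bleeds_pre")
  df$bleeds_post <- rcount(bm$post_mean, "bleeds_post")

  rs_idx <- with_seed(derive_seed(spec$seed, "rs_subgroup"),
                      sample.int(n, min(spec$rs_joints, n)))
  df$rs_treated <- seq_len(n) %in% rs_idx

  structure(df, spec = spec, class = c("cohort_table", "data.frame"))
}

#' Tabulate grades of one lesion in one arm
#'
#' @param cohort a `cohort_table`.
#' @param lesion one of `"effusion"`, `"synovial_hyperplasia"`,
#'   `"hemosiderin"`.
#' @param arm one of `"pathology"`, `"conventional"`, `"canny"`.
#' @param levels grade levels to tabulate (default 0:3).
#' @return named integer vector of counts over graded (non-`NA`) joints.
#' @export
grade_counts <- function(cohort, lesion, arm = "pathology", levels = 0:3) {
  col <- paste0(lesion, "_", arm)
  if (!col %in% names(cohort)) stopf("no column '%s' in the cohort", col)
  g <- cohort[[col]]
  vapply(levels, function(l) sum(g == l, na.rm = TRUE), integer(1)) |>
    stats::setNames(as.character(levels))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d joints (%s), %d RS-treated\n",
              nrow(x),
              paste(sprintf("%d %s", table(x$joint_type)[unique(x$joint_type)],
                            unique(x$joint_type)), collapse = ", "),
              sum(x$rs_treated)))
  invisible(x)
}

#' Long (one row per joint and arm) view of a cohort
#'
#' The fixed-header exchange format: columns `patient_id`, `joint_type`,
#' `arm`, the three lesion grades, volumes and bleed counts.
#'
#' @param cohort a `cohort_table`.
#' @return a plain `data.frame`.
#' @export
cohort_long <- function(cohort) {
  out <- do.call(rbind, lapply(arm_names, function(arm) {
    d <- data.frame(patient_id = cohort$patient_id,
                    joint_type = cohort$joint_type, arm = arm,
                    stringsAsFactors = FALSE)
    for (lesion in lesion_names) d[[lesion]] <- cohort[[paste0(lesion, "_", arm)]]
    d$volume_pre <- cohort$volume_pre
    d$volume_post <- cohort$volume_post
    d$bleeds_pre <- cohort$bleeds_pre
    d$bleeds_post <- cohort$bleeds_post
    d$rs_treated <- cohort$rs_treated
    d
  }))
  rownames(out) <- NULL
  out
}

#' Read and write cohort tables as TSV
#'
#' `write_cohort()` writes the long per-arm format; `read_cohort()` reads it
#' back and reassembles the wide `cohort_table` (without the generating
#' spec).
#'
#' @param cohort a `cohort_table`.
#' @param path TSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort_long(cohort), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "joint_type", "arm", lesion_names,
            "volume_pre", "volume_post", "bleeds_pre", "bleeds_post")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols))
    stopf("cohort file lacks columns: %s", paste(missing_cols, collapse = ", "))
  base <- long[long$arm == "pathology",
               setdiff(names(long), c("arm", lesion_names))]
  names(base) <- sub("^", "", names(base))
  df <- base
  for (arm in intersect(arm_names, unique(long$arm))) {
    sub <- long[long$arm == arm, ]
    for (lesion in lesion_names) {
      df[[paste0(lesion, "_", arm)]] <- sub[[lesion]]
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("cohort_table", "data.frame"))
}
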