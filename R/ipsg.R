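#' IPSG MRI score card
#'
#' The additive IPSG (International Prophylaxis Study Group) MRI score of one
#' joint: three soft-tissue lesions graded 0-3 (effusion/hemorrhage, synovial
#' hyperplasia, hemosiderin deposition, subtotal 0-9) and eight binary
#' osteochondral items (bone erosion, subchondral cysts, cartilage damage,
#' subtotal 0-8), for a maximum total of 17.
#'
#' @param effusion,synovial_hyperplasia,hemosiderin integer grades 0-3.
#' @param erosion_any_surface 0/1, any surface erosion of the subchondral
#'   cortex or joint margin.
#' @param erosion_ge_half_of_bone 0/1, erosion of at least 50% of a single
#'   bone.
#' @param cyst_single 0/1, at least one subchondral cyst.
#' @param cyst_extensive 0/1, cysts in more than 2 bones or more than 1/3 of
#'   a single bone.
#' @param cartilage_any_damage 0/1, cartilage damage anywhere.
#' @param cartilage_ge_half_volume 0/1, loss of at least 50% of cartilage
#'   volume in a single bone.
#' @param cartilage_focal_full_thickness 0/1, focal full-thickness loss in at
#'   least one bone.
#' @param cartilage_full_thickness_ge_half_surface 0/1, full-thickness loss
#'   over at least 50% of a single bone's surface.
#' @return list of class `ipsg_card`.
#' @examples
#' total_score(ipsg_card(effusion = 2, synovial_hyperplasia = 1,
#'                       hemosiderin = 3, erosion_any_surface = 1,
#'                       cartilage_any_damage = 1))
#' @export
ipsg_card <- function(effusion = 0L, synovial_hyperplasia = 0L,
                      hemosiderin = 0L,
                      erosion_any_surface = 0L, erosion_ge_half_of_bone = 0L,
                      cyst_single = 0L, cyst_extensive = 0L,
                      cartilage_any_damage = 0L, cartilage_ge_half_volume = 0L,
                      cartilage_focal_full_thickness = 0L,
                      cartilage_full_thickness_ge_half_surface = 0L) {
  card <- list(effusion = effusion,
               synovial_hyperplasia = synovial_hyperplasia,
               hemosiderin = hemosiderin,
               erosion_any_surface = erosion_any_surface,
               erosion_ge_half_of_bone = erosion_ge_half_of_bone,
               cyst_single = cyst_single, cyst_extensive = cyst_extensive,
               cartilage_any_damage = cartilage_any_damage,
               cartilage_ge_half_volume = cartilage_ge_half_volume,
               cartilage_focal_full_thickness = cartilage_focal_full_thickness,
               cartilage_full_thickness_ge_half_surface =
                 cartilage_full_thickness_ge_half_surface)
  card <- lapply(card, as.integer)
  validate_card(card)
  structure(card, class = "ipsg_card")
}

soft_tissue_items <- c("effusion", "synovial_hyperplasia", "hemosiderin")
osteochondral_items <- c("erosion_any_surface", "erosion_ge_half_of_bone",
                         "cyst_single", "cyst_extensive",
                         "cartilage_any_damage", "cartilage_ge_half_volume",
                         "cartilage_focal_full_thickness",
                         "cartilage_full_thickness_ge_half_surface")

validate_card <- function(card) {
  for (f in soft_tissue_items) {
    v <- card[[f]]
    if (is.na(v) || v < 0L || v > 3L)
      stopf("grade out of range for '%s': %s (must be 0-3)", f, v)
  }
  for (f in osteochondral_items) {
    v <- card[[f]]
    if (is.na(v) || !v %in% c(0L, 1L))
      stopf("binary item out of range for '%s': %s (must be 0/1)", f, v)
  }
  invisible(card)
}

#' Total and subtotal IPSG scores
#'
#' @param card an [ipsg_card()].
#' @return named numeric vector `(total, soft_tissue, osteochondral)`;
#'   `total = soft_tissue + osteochondral`, bounded by 17 = 9 + 8.
#' @export
total_score <- function(card) {
  if (!inherits(card, "ipsg_card")) card <- do.call(ipsg_card, as.list(card))
  validate_card(card)
  soft <- sum(unlist(card[soft_tissue_items]))
  osteo <- sum(unlist(card[osteochondral_items]))
  c(total = soft + osteo, soft_tissue = soft, osteochondral = osteo)
}

#' @export
print.ipsg_card <- function(x, ...) {
  ts <- total_score(x)
  cat(sprintf("<ipsg_card> total %d (soft tissue %d / osteochondral %d)\n",
              ts[["total"]], ts[["soft_tissue"]], ts[["osteochondral"]]))
  cat(sprintf("  effusion %d, hyperplasia %d, hemosiderin %d\n",
              x$effusion, x$synovial_hyperplasia, x$hemosiderin))
  on <- osteochondral_items[unlist(x[osteochondral_items]) == 1L]
  if (length(on)) cat("  osteochondral:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Area-fraction grade thresholds
#'
#' Maps a lesion's area fraction of the joint region to the small/medium/
#' large grades 1-3. The qualitative IPSG sizes carry no published numeric
#' cuts; the defaults (floor 0.01, cuts 0.05 and 0.15) are package
#' conventions for the phantom geometry, not clinical definitions, and are
#' fully configurable.
#'
#' @param floor fraction below which the grade is 0.
#' @param cut1 small/medium boundary.
#' @param cut2 medium/large boundary.
#' @return list of class `grade_thresholds`.
#' @export
grade_thresholds <- function(floor = 0.01, cut1 = 0.05, cut2 = 0.15) {
  if (!(0 <= floor && floor < cut1 && cut1 < cut2 && cut2 < 1))
    stopf("need 0 <= floor < cut1 < cut2 < 1 (got %g, %g, %g)",
          floor, cut1, cut2)
  structure(list(floor = floor, cut1 = cut1, cut2 = cut2),
            class = "grade_thresholds")
}

#' Grade from an area fraction
#'
#' Piecewise-constant, half-open intervals: `< floor` gives 0,
#' `[floor, cut1)` gives 1, `[cut1, cut2)` gives 2, `>= cut2` gives 3.
#'
#' @param area_fraction lesion area / joint-region area, in `[0, 1]`
#'   (vectorized).
#' @param thresholds a [grade_thresholds()] object.
#' @return integer grade(s) 0-3.
#' @export
grade_from_fraction <- function(area_fraction, thresholds = grade_thresholds()) {
  if (any(is.na(area_fraction)) || any(area_fraction < 0 | area_fraction > 1))
    stopf("area_fraction must lie in [0, 1]")
  g <- integer(length(area_fraction))
  g[area_fraction >= thresholds$floor] <- 1L
  g[area_fraction >= thresholds$cut1] <- 2L
  g[area_fraction >= thresholds$cut2] <- 3L
  g
}

# boundary pixels of a logical mask: mask pixels with a non-mask 4-neighbor
# (or on the raster border)
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[1L + seq_len(nr), 1L + seq_len(nc)] <- mask
  inner <- p[seq_len(nr), 1L + seq_len(nc)] & p[2L + seq_len(nr), 1L + seq_len(nc)] &
           p[1L + seq_len(nr), seq_len(nc)] & p[1L + seq_len(nr), 2L + seq_len(nc)]
  mask & !inner
}

#' Score a joint from lesion masks
#'
#' Computes an [ipsg_card()] from binary lesion masks. Soft-tissue grades
#' come from area fractions relative to the joint region via
#' [grade_from_fraction()]. Osteochondral binaries come from mask-overlap
#' rules:
#' \itemize{
#'   \item erosion touching the cortical boundary of any bone sets
#'     `erosion_any_surface`; erosion covering at least 50% of one bone sets
#'     `erosion_ge_half_of_bone`;
#'   \item any cyst component inside a bone sets `cyst_single`; cysts in
#'     more than 2 bones or more than 1/3 of a single bone set
#'     `cyst_extensive`;
#'   \item any cartilage-damage pixel sets `cartilage_any_damage`; damage of
#'     at least 50% of one bone's cartilage sets `cartilage_ge_half_volume`;
#'     full-thickness damage anywhere sets `cartilage_focal_full_thickness`
#'     and, over at least 50% of one bone's cartilage,
#'     `cartilage_full_thickness_ge_half_surface`.
#' }
#'
#' @param masks either a `phantom_image` (its ground-truth masks are used) or
#'   a named list of logical matrices sharing dimensions:
#'   `joint_region` (required, nonempty), and optionally `effusion`,
#'   `synovium`, `hemosiderin`, `bones` (list, one mask per bone), `erosion`,
#'   `cyst`, `cartilage` (list per bone), `cartilage_damage`,
#'   `cartilage_full_thickness`.
#' @param thresholds a [grade_thresholds()] object.
#' @return an [ipsg_card()].
#' @export
score_from_masks <- function(masks, thresholds = grade_thresholds()) {
  if (inherits(masks, "phantom_image")) masks <- masks$masks
  jr <- masks$joint_region
  if (is.null(jr) || !any(jr)) stopf("empty joint region: nothing to score")
  dims <- dim(jr)
  all_masks <- c(masks[!vapply(masks, is.list, logical(1))],
                 masks$bones, masks$cartilage)
  for (m in all_masks) {
    if (!is.null(m) && !all(dim(m) == dims))
      stopf("mask dimensions differ from the joint region")
  }
  area <- sum(jr)
  frac <- function(m) if (is.null(m)) 0 else sum(m) / area
  card <- list(
    effusion = grade_from_fraction(min(frac(masks$effusion), 1), thresholds),
    synovial_hyperplasia = grade_from_fraction(min(frac(masks$synovium), 1),
                                               thresholds),
    hemosiderin = grade_from_fraction(min(frac(masks$hemosiderin), 1),
                                      thresholds))

  bones <- masks$bones %||% list()
  erosion <- masks$erosion
  card$erosion_any_surface <- 0L; card$erosion_ge_half_of_bone <- 0L
  if (!is.null(erosion) && any(erosion) && length(bones)) {
    touches <- vapply(bones, function(b) any(erosion & mask_boundary(b)),
                      logical(1))
    card$erosion_any_surface <- as.integer(any(touches))
    halves <- vapply(bones, function(b) sum(erosion & b) >= 0.5 * sum(b),
                     logical(1))
    card$erosion_ge_half_of_bone <- as.integer(any(halves))
  }

  cyst <- masks$cyst
  card$cyst_single <- 0L; card$cyst_extensive <- 0L
  if (!is.null(cyst) && any(cyst) && length(bones)) {
    in_bone <- vapply(bones, function(b) any(cyst & b), logical(1))
    card$cyst_single <- as.integer(any(in_bone))
    over_third <- vapply(bones, function(b) sum(cyst & b) > sum(b) / 3,
                         logical(1))
    card$cyst_extensive <- as.integer(sum(in_bone) > 2L || any(over_third))
  }

  cart <- masks$cartilage %||% list()
  dmg <- masks$cartilage_damage
  ft <- masks$cartilage_full_thickness
  card$cartilage_any_damage <- as.integer(!is.null(dmg) && any(dmg))
  card$cartilage_ge_half_volume <- 0L
  card$cartilage_focal_full_thickness <- as.integer(!is.null(ft) && any(ft))
  card$cartilage_full_thickness_ge_half_surface <- 0L
  if (!is.null(dmg) && length(cart)) {
    half_vol <- vapply(cart, function(cb) sum(cb) > 0 &&
                         sum(dmg & cb) >= 0.5 * sum(cb), logical(1))
    card$cartilage_ge_half_volume <- as.integer(any(half_vol))
  }
  if (!is.null(ft) && length(cart)) {
    half_surf <- vapply(cart, function(cb) sum(cb) > 0 &&
                          sum(ft & cb) >= 0.5 * sum(cb), logical(1))
    card$cartilage_full_thickness_ge_half_surface <- as.integer(any(half_surf))
  }
  do.call(ipsg_card, card)
}
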