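# Label fusion, left-right operations and regional volumetry.

#' Anatomical label scheme
#'
#' Table mapping label IDs to names, hemisphere, left/right partner and
#' lobar group.  The partner relation must be a symmetric involution with
#' partners on opposite hemispheres; pairing is an explicit table (never
#' parity arithmetic on IDs) because real schemes break ID parity, e.g. an
#' unpaired corpus callosum sitting between paired ventricle IDs.
#'
#' @param entries data.frame with columns `id`, `name`,
#'   `hemisphere` (one of `"left"`, `"right"`, `"none"`), `partner_id`
#'   (`NA` for unpaired), and optionally `lobe`.
#' @return A `label_scheme` object (validated data.frame).
#' @export
label_scheme <- function(entries) {
  entries <- as.data.frame(entries)
  need <- c("id", "name", "hemisphere", "partner_id")
  if (!all(need %in% names(entries)))
    stop("label_scheme: need columns ", paste(need, collapse = ", "))
  if (!"lobe" %in% names(entries)) entries$lobe <- NA_character_
  entries$id <- as.integer(entries$id)
  entries$partner_id <- as.integer(entries$partner_id)
  if (anyDuplicated(entries$id)) stop("label_scheme: duplicate label IDs")
  if (!all(entries$hemisphere %in% c("left", "right", "none")))
    stop("label_scheme: hemisphere must be left/right/none")
  for (i in seq_len(nrow(entries))) {
    p <- entries$partner_id[i]
    if (is.na(p)) next
    j <- match(p, entries$id)
    if (is.na(j))
      stop("label_scheme: partner ", p, " of label ", entries$id[i],
           " is not in the scheme")
    if (is.na(entries$partner_id[j]) || entries$partner_id[j] != entries$id[i])
      stop("label_scheme: partner relation is not an involution at label ",
           entries$id[i])
    if (!(entries$hemisphere[i] %in% c("left", "right")) ||
        entries$hemisphere[j] == entries$hemisphere[i])
      stop("label_scheme: partners ", entries$id[i], "/", p,
           " must lie on opposite hemispheres")
  }
  structure(entries, class = c("label_scheme", "data.frame"))
}

scheme_pairs <- function(scheme) {
  left <- scheme[scheme$hemisphere == "left" & !is.na(scheme$partner_id), ]
  data.frame(region = sub("[._ ]?left$", "", left$name),
             left_id = left$id, right_id = left$partner_id,
             stringsAsFactors = FALSE)
}

#' Majority-vote label fusion
#'
#' Per-voxel most frequent label across a stack of co-registered label
#' maps; ties are broken deterministically toward the smallest label ID.
#'
#' @param maps List of [label_map()]s on one common grid.
#' @return The fused [label_map()].
#' @export
majority_vote <- function(maps) {
  if (length(maps) < 1) stop("majority_vote: need at least one map")
  for (m in maps[-1])
    if (!same_grid(maps[[1]], m))
      stop("majority_vote: all maps must share one grid")
  if (length(maps) == 1) return(maps[[1]])
  stack <- vapply(maps, function(m) as.vector(m$data),
                  integer(length(maps[[1]]$data)))
  ids <- sort(unique(as.vector(stack)))
  counts <- vapply(ids, function(id) rowSums(stack == id),
                   numeric(nrow(stack)))
  win <- ids[max.col(counts, ties.method = "first")]
  label_map(array(as.integer(win), dim = grid_dim(maps[[1]])),
            maps[[1]]$spacing, maps[[1]]$origin)
}

#' Left-right flip of a label map with partner-ID swap
#'
#' Mirrors the map along the left-right axis and replaces every hemispheric
#' label by its partner from the scheme, so a flipped map remains
#' anatomically consistent (a left structure stays named "left" on the new
#' left side).  Unpaired labels are kept.  Applying the operation twice
#' restores the original map exactly.
#'
#' @param labels A [label_map()].
#' @param scheme A [label_scheme()] covering every hemispheric ID present.
#' @return The flipped-and-swapped [label_map()].
#' @export
flip_labels_lr <- function(labels, scheme) {
  stopifnot(inherits(labels, "label_map"), inherits(scheme, "label_scheme"))
  present <- setdiff(unique(as.vector(labels$data)), 0L)
  hemi <- scheme$id[scheme$hemisphere %in% c("left", "right")]
  missing_partner <- intersect(present,
                               scheme$id[scheme$id %in% hemi &
                                         is.na(scheme$partner_id)])
  unknown_hemi <- setdiff(present, c(scheme$id, 0L))
  if (length(unknown_hemi))
    stop("flip_labels_lr: label ID(s) ", paste(unknown_hemi, collapse = ", "),
         " not in scheme")
  if (length(missing_partner))
    stop("flip_labels_lr: hemispheric label ID(s) ",
         paste(missing_partner, collapse = ", "), " have no partner")
  flipped <- flip_lr(labels)
  lut <- seq_len(max(c(flipped$data, scheme$id)) + 1L) - 1L
  swap <- !is.na(scheme$partner_id)
  lut[scheme$id[swap] + 1L] <- scheme$partner_id[swap]
  flipped$data <- array(as.integer(lut[flipped$data + 1L]),
                        dim = dim(flipped$data))
  flipped
}

#' Volumetric asymmetry coefficient
#'
#' `S = 2 |V_L - V_R| / (V_L + V_R)`, the normalized left-right volume
#' difference: 0 for equal volumes, 2 when one side is absent.
#'
#' @param v_left,v_right Left and right volumes (any common unit).
#' @return S in `[0, 2]`, or `NA` when both volumes are zero.
#' @export
asymmetry_coefficient <- function(v_left, v_right) {
  if (v_left < 0 || v_right < 0)
    stop("asymmetry_coefficient: volumes must be non-negative")
  tot <- v_left + v_right
  ifelse(tot > 0, 2 * abs(v_left - v_right) / tot, NA_real_)
}

#' Regional volumes of a label map
#'
#' Volume of every label as voxel count times voxel physical volume,
#' reported in cm^3.  With a list of maps (a cohort) the per-label mean and
#' SD across subjects are added.
#'
#' @param labels A [label_map()] or a list of label maps on equal grids.
#' @param include_background Include label 0 (default FALSE).
#' @return data.frame with columns `label`, `volume_cm3` (single map) or
#'   `label`, `mean_cm3`, `sd_cm3` (cohort).
#' @export
region_volumes <- function(labels, include_background = FALSE) {
  if (inherits(labels, "label_map")) {
    voxvol <- prod(labels$spacing) / 1000          # mm^3 -> cm^3
    tab <- table(factor(as.vector(labels$data)))
    out <- data.frame(label = as.integer(names(tab)),
                      volume_cm3 = as.numeric(tab) * voxvol)
    if (!include_background) out <- out[out$label != 0L, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  per <- lapply(labels, region_volumes, include_background = include_background)
  ids <- sort(unique(unlist(lapply(per, `[[`, "label"))))
  mat <- vapply(per, function(p) {
    v <- stats::setNames(rep(0, length(ids)), ids)
    v[as.character(p$label)] <- p$volume_cm3
    v
  }, numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  data.frame(label = ids,
             mean_cm3 = rowMeans(mat),
             sd_cm3 = apply(mat, 1, stats::sd))
}

#' Lobar volumes as proportions of intracranial volume
#'
#' Masks the label map with a binary brain mask, groups labels by the
#' scheme's lobar grouping, and reports each group's in-mask volume as a
#' percentage of the mask volume.
#'
#' @param labels A [label_map()].
#' @param mask A binary [label_map()] (non-zero = in mask) on the same grid.
#' @param scheme A [label_scheme()] with a `lobe` column.
#' @return data.frame with columns `lobe` and `percent_icv`.
#' @export
icv_proportions <- function(labels, mask, scheme) {
  if (!same_grid(labels, mask))
    stop("icv_proportions: labels and mask must share a grid")
  m <- as.vector(mask$data) != 0L
  if (!any(m)) stop("icv_proportions: empty mask")
  lab <- as.vector(labels$data)[m]
  lobes <- stats::setNames(scheme$lobe, scheme$id)
  grp <- lobes[as.character(lab)]
  keep <- !is.na(grp)
  tab <- tapply(rep(1L, sum(keep)), grp[keep], sum)
  data.frame(lobe = names(tab),
             percent_icv = 100 * as.numeric(tab) / sum(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-pair asymmetry report
#'
#' Computes left and right volumes and the asymmetry coefficient S for
#' every paired region of the scheme.
#'
#' @param labels A [label_map()].
#' @param scheme A [label_scheme()].
#' @return An `asymmetry_report`: data.frame with columns `region`,
#'   `v_left_cm3`, `v_right_cm3`, `S`, plus attributes `max_S` / `min_S`.
#' @export
asymmetry_report <- function(labels, scheme) {
  vols <- region_volumes(labels, include_background = TRUE)
  getv <- function(id) {
    i <- match(id, vols$label)
    if (is.na(i)) 0 else vols$volume_cm3[i]
  }
  pairs <- scheme_pairs(scheme)
  out <- data.frame(region = pairs$region,
                    v_left_cm3 = vapply(pairs$left_id, getv, 0),
                    v_right_cm3 = vapply(pairs$right_id, getv, 0))
  out$S <- mapply(asymmetry_coefficient, out$v_left_cm3, out$v_right_cm3)
  structure(out, class = c("asymmetry_report", "data.frame"),
            max_S = suppressWarnings(max(out$S, na.rm = TRUE)),
            min_S = suppressWarnings(min(out$S, na.rm = TRUE)))
}
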