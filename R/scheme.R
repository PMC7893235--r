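#' Landmark scheme
#'
#' A landmark scheme fixes the identity, ordering and annotation of every
#' landmark digitised on a specimen: its type (fixed anatomical landmark,
#' curve semilandmark or surface semilandmark), the skull module it belongs
#' to, whether it lies on the midline (sagittal) plane, its bilateral partner
#' (if any) and, for curve semilandmarks, the ordered curve it slides along.
#'
#' Landmark order everywhere in the package is the scheme order; files are
#' re-sorted against the scheme on read so that Procrustes arithmetic always
#' sees consistent configurations.
#'
#' @param ids character vector of unique landmark identifiers.
#' @param type one of `"fixed"`, `"curve"`, `"surface"` per landmark.
#' @param module module label per landmark.
#' @param midline logical per landmark; midline landmarks must be unpaired.
#' @param pair identifier of the bilateral partner, `NA` if unpaired. The
#'   pairing must be an involution with no fixed points.
#' @param side `"right"`, `"left"` or `"mid"`; if `NULL` it is derived:
#'   midline landmarks are `"mid"`, the first-listed member of each pair is
#'   `"right"`.
#' @param curve curve label per landmark (`NA` for landmarks that are not
#'   curve semilandmarks). Every curve semilandmark must belong to exactly
#'   one curve with at least 3 members.
#' @param curve_pos integer position along the curve.
#' @return an object of class `landmark_scheme`, a data frame with one row
#'   per landmark in scheme order.
#' @export
landmarkScheme <- function(ids, type = "fixed", module = "all",
                           midline = FALSE, pair = NA_character_,
                           side = NULL, curve = NA_character_,
                           curve_pos = NA_integer_) {
  k <- length(ids)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicated landmark ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  info <- data.frame(
    id = ids,
    type = rep_len(as.character(type), k),
    module = rep_len(as.character(module), k),
    midline = rep_len(as.logical(midline), k),
    pair = rep_len(as.character(pair), k),
    curve = rep_len(as.character(curve), k),
    curve_pos = rep_len(as.integer(curve_pos), k),
    stringsAsFactors = FALSE
  )
  if (!all(info$type %in% c("fixed", "curve", "surface"))) {
    stop("landmark type must be one of 'fixed', 'curve', 'surface'")
  }
  if (is.null(side)) {
    side <- rep("right", k)
    side[info$midline] <- "mid"
    paired <- which(!is.na(info$pair))
    seen <- character(0)
    for (i in paired) {
      if (info$pair[i] %in% seen) side[i] <- "left"
      seen <- c(seen, info$id[i])
    }
  }
  info$side <- rep_len(as.character(side), k)

  ## pairing must be an involution without fixed points
  paired <- !is.na(info$pair)
  if (any(paired)) {
    if (!all(info$pair[paired] %in% info$id)) {
      stop("pair refers to unknown landmark id")
    }
    idx <- match(info$pair[paired], info$id)
    back <- info$pair[idx]
    if (any(info$pair[paired] == info$id[paired])) {
      stop("a landmark cannot be paired with itself")
    }
    if (any(is.na(back)) || any(back != info$id[paired])) {
      stop("pairing is not an involution")
    }
  }
  if (any(info$midline & paired)) {
    stop("midline landmarks must be unpaired")
  }
  ## curve membership: every curve semilandmark on exactly one curve, >= 3 members
  iscurve <- info$type == "curve"
  if (any(iscurve & is.na(info$curve))) {
    stop("curve semilandmarks must carry a curve label")
  }
  if (any(iscurve)) {
    sizes <- table(info$curve[iscurve])
    if (any(sizes < 3)) {
      stop("every curve needs at least 3 semilandmarks; offending: ",
           paste(names(sizes)[sizes < 3], collapse = ", "))
    }
    if (any(is.na(info$curve_pos[iscurve]))) {
      info$curve_pos[iscurve] <- stats::ave(
        seq_len(sum(iscurve)), info$curve[iscurve], FUN = seq_along)
    }
  }
  class(info) <- c("landmark_scheme", "data.frame")
  info
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", nrow(x), "landmarks,",
      length(unique(x$module)), "modules\n")
  cat("  types:  ", paste(sprintf("%s=%d", names(table(x$type)),
                                  table(x$type)), collapse = ", "), "\n")
  cat("  midline:", sum(x$midline), " paired:", sum(!is.na(x$pair)), "\n")
  invisible(x)
}

schemeModules <- function(scheme) unique(scheme$module)

#' Validate the module partition of a scheme
#'
#' Report-only check of the module labelling: lists the modules with their
#' landmark counts and collects violations (unlabelled landmarks, empty
#' module label set).
#'
#' @param scheme a [landmarkScheme()] object.
#' @return a list with elements `valid` (logical), `modules` (data frame of
#'   module, n_landmarks), and `violations` (character vector).
#' @export
validatePartition <- function(scheme) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  violations <- character(0)
  lab <- scheme$module
  unlab <- is.na(lab) | !nzchar(lab)
  if (any(unlab)) {
    violations <- c(violations, paste0(
      "unlabelled landmarks: ", paste(scheme$id[unlab], collapse = ", ")))
  }
  mods <- table(lab[!unlab])
  if (length(mods) == 0) {
    violations <- c(violations, "empty module label set")
  }
  list(
    valid = length(violations) == 0,
    modules = data.frame(module = names(mods),
                         n_landmarks = as.integer(mods),
                         stringsAsFactors = FALSE),
    violations = violations
  )
}

#' Specimen dataset
#'
#' A collection of landmark configurations sharing one scheme. Coordinates
#' are stored as a k x 3 x n array in scheme order; absent landmarks (partial
#' specimens) are `NA` with a parallel presence mask. A module counts as
#' present in a specimen only when all its landmarks are present.
#'
#' @param coords k x 3 x n numeric array (or a k x 3 matrix for a single
#'   specimen) in scheme landmark order.
#' @param scheme a [landmarkScheme()].
#' @param specimens character vector of specimen identifiers.
#' @param retrodeformed logical per specimen.
#' @return an object of class `specimen_dataset`.
#' @export
specimenDataset <- function(coords, scheme, specimens = NULL,
                            retrodeformed = FALSE) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  k <- nrow(scheme)
  if (dim(coords)[1] != k) {
    stop("coords have ", dim(coords)[1], " landmarks but scheme has ", k)
  }
  n <- dim(coords)[3]
  if (n < 1) stop("dataset needs at least one specimen")
  if (is.null(specimens)) specimens <- sprintf("spec%03d", seq_len(n))
  dimnames(coords) <- list(scheme$id, c("x", "y", "z"), specimens)
  present <- apply(!is.na(coords[, 1, , drop = FALSE]), c(1, 3), all)
  dim(present) <- c(k, n)
  dimnames(present) <- list(scheme$id, specimens)
  bad <- apply(coords, 3, function(m) any(!is.finite(m) & !is.na(m)))
  if (any(bad)) {
    stop("non-finite coordinates in specimens: ",
         paste(specimens[bad], collapse = ", "))
  }
  structure(list(
    coords = coords,
    present = present,
    scheme = scheme,
    specimens = specimens,
    retrodeformed = rep_len(retrodeformed, n)
  ), class = "specimen_dataset")
}

#' @export
print.specimen_dataset <- function(x, ...) {
  n <- length(x$specimens)
  comp <- sum(apply(x$present, 2, all))
  cat("Specimen dataset:", n, "specimens (", comp, "complete ),",
      nrow(x$scheme), "landmarks\n")
  invisible(x)
}

nSpecimens <- function(dataset) length(dataset$specimens)

#' Which modules are present (complete) in each specimen
#'
#' @param dataset a `specimen_dataset`.
#' @return logical matrix, modules x specimens.
#' @export
modulePresence <- function(dataset) {
  mods <- schemeModules(dataset$scheme)
  out <- vapply(mods, function(m) {
    idx <- dataset$scheme$module == m
    apply(dataset$present[idx, , drop = FALSE], 2, all)
  }, logical(nSpecimens(dataset)))
  t(matrix(out, ncol = length(mods),
           dimnames = list(dataset$specimens, mods)))
}

#' Subset a dataset by landmarks and/or specimens
#'
#' @param dataset a `specimen_dataset`.
#' @param landmarks landmark ids (or logical/integer index into scheme rows).
#' @param specimens specimen ids (or index).
#' @return a `specimen_dataset` on the reduced scheme. Pairs whose partner is
#'   dropped become unpaired; curves reduced below 3 members are degraded to
#'   surface semilandmarks.
#' @export
subsetDataset <- function(dataset, landmarks = NULL, specimens = NULL) {
  coords <- dataset$coords
  scheme <- dataset$scheme
  retro <- dataset$retrodeformed
  if (!is.null(landmarks)) {
    if (is.character(landmarks)) landmarks <- match(landmarks, scheme$id)
    scheme <- scheme[landmarks, , drop = FALSE]
    scheme$pair[!(scheme$pair %in% scheme$id)] <- NA_character_
    iscurve <- scheme$type == "curve"
    if (any(iscurve)) {
      sizes <- table(scheme$curve[iscurve])
      small <- names(sizes)[sizes < 3]
      degr <- iscurve & scheme$curve %in% small
      scheme$type[degr] <- "surface"
      scheme$curve[degr] <- NA_character_
    }
    class(scheme) <- c("landmark_scheme", "data.frame")
    coords <- coords[landmarks, , , drop = FALSE]
  }
  ids <- dataset$specimens
  if (!is.null(specimens)) {
    if (is.character(specimens)) specimens <- match(specimens, ids)
    coords <- coords[, , specimens, drop = FALSE]
    ids <- ids[specimens]
    retro <- retro[specimens]
  }
  specimenDataset(coords, scheme, ids, retro)
}

#' Restrict a dataset to one module, keeping specimens where it is complete
#'
#' @param dataset a `specimen_dataset`.
#' @param module module label.
#' @return a `specimen_dataset` holding only that module's landmarks and the
#'   specimens in which the module is complete.
#' @export
moduleDataset <- function(dataset, module) {
  idx <- which(dataset$scheme$module == module)
  if (length(idx) == 0) stop("unknown module: ", module)
  pres <- apply(dataset$present[idx, , drop = FALSE], 2, all)
  if (!any(pres)) stop("module ", module, " is absent from every specimen")
  subsetDataset(dataset, landmarks = idx, specimens = which(pres))
}

## landmark indices of the analysis side (midline + right), scheme order
analysisSideIndex <- function(scheme) {
  which(scheme$side %in% c("mid", "right"))
}
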