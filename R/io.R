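#' Read landmark data
#'
#' Reads a specimen dataset from either the Rohlf TPS interchange format
#' (`LM3=`/`ID=` records, complete specimens only) or the canonical long
#' table (columns `specimen, landmark_id, x, y, z`; missing rows become
#' absent landmarks, which is how partial specimens are represented).
#'
#' Rows are re-ordered against the scheme; file order never matters.
#'
#' @param path file path (or a connection already open for reading).
#' @param dialect `"long_table"` (default) or `"tps"`.
#' @param scheme a [landmarkScheme()]; if `NULL`, a minimal scheme (all
#'   fixed landmarks, one module, no pairing) is inferred from the ids found.
#' @param sep field separator for the long table; `","` default, `"\t"`
#'   accepted.
#' @return a [specimenDataset()].
#' @export
readLandmarks <- function(path, dialect = c("long_table", "tps"),
                          scheme = NULL, sep = ",") {
  dialect <- match.arg(dialect)
  if (dialect == "tps") {
    readLandmarksTPS(path, scheme)
  } else {
    readLandmarksLong(path, scheme, sep)
  }
}

readLandmarksLong <- function(path, scheme = NULL, sep = ",") {
  tab <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("specimen", "landmark_id", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("long table must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(tab$specimen, tab$landmark_id)
  if (anyDuplicated(key)) {
    stop("duplicate (specimen, landmark_id) rows: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  }
  if (is.null(scheme)) {
    scheme <- landmarkScheme(unique(tab$landmark_id))
  }
  unknown <- setdiff(unique(tab$landmark_id), scheme$id)
  if (length(unknown)) {
    stop("landmark ids not in scheme: ", paste(unknown, collapse = ", "))
  }
  specs <- unique(tab$specimen)
  k <- nrow(scheme)
  coords <- array(NA_real_, c(k, 3, length(specs)))
  li <- match(tab$landmark_id, scheme$id)
  si <- match(tab$specimen, specs)
  for (d in 1:3) {
    v <- tab[[c("x", "y", "z")[d]]]
    if (!is.numeric(v)) stop("non-numeric coordinate column ", c("x", "y", "z")[d])
    coords[cbind(li, d, si)] <- v
  }
  specimenDataset(coords, scheme, specs)
}

readLandmarksTPS <- function(path, scheme = NULL) {
  lines <- readLines(path)
  blocks <- list(); ids <- character(0)
  i <- 1; nb <- 0
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    m <- regmatches(ln, regexec("^LM(3?)\\s*=\\s*([0-9]+)$", ln, ignore.case = TRUE))[[1]]
    if (length(m) == 0) {
      stop("TPS parse error at line ", i, ": expected LM3= record, got '", ln, "'")
    }
    if (m[2] != "3") {
      stop("TPS dimensionality error at line ", i,
           ": 2D record (LM=) not supported, need LM3=")
    }
    k <- as.integer(m[3])
    xyz <- matrix(NA_real_, k, 3)
    for (j in seq_len(k)) {
      if (i + j > length(lines)) {
        stop("TPS parse error: unexpected end of file in block starting line ", i)
      }
      parts <- strsplit(trimws(lines[i + j]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 3 || anyNA(vals)) {
        stop("TPS parse error at line ", i + j,
             ": expected 3 numeric coordinates, got '", lines[i + j], "'")
      }
      xyz[j, ] <- vals
    }
    i <- i + k + 1
    id <- sprintf("specimen%03d", nb + 1)
    if (i <= length(lines)) {
      idm <- regmatches(trimws(lines[i]),
                        regexec("^ID\\s*=\\s*(.+)$", trimws(lines[i]), ignore.case = TRUE))[[1]]
      if (length(idm)) { id <- trimws(idm[2]); i <- i + 1 }
    }
    nb <- nb + 1
    blocks[[nb]] <- xyz
    ids[nb] <- id
  }
  if (nb == 0) stop("TPS parse error: no LM3= blocks found")
  ks <- vapply(blocks, nrow, integer(1))
  if (length(unique(ks)) != 1) {
    stop("TPS blocks disagree on landmark count: ", paste(unique(ks), collapse = ", "))
  }
  if (anyDuplicated(ids)) stop("duplicate specimen ids in TPS file")
  if (is.null(scheme)) scheme <- landmarkScheme(sprintf("lm%03d", seq_len(ks[1])))
  if (nrow(scheme) != ks[1]) {
    stop("TPS blocks have ", ks[1], " landmarks but scheme has ", nrow(scheme))
  }
  coords <- array(unlist(blocks), c(ks[1], 3, nb))
  ## TPS lists coordinates landmark-by-landmark: unlist of k x 3 matrices is fine
  for (b in seq_len(nb)) coords[, , b] <- blocks[[b]]
  specimenDataset(coords, scheme, ids)
}

#' Write landmark data
#'
#' Inverse of [readLandmarks()]. The long table omits rows for absent
#' landmarks; the TPS dialect has no missing-value convention, so writing a
#' partial specimen as TPS is an error.
#'
#' @param dataset a [specimenDataset()].
#' @param path output file path.
#' @param dialect `"long_table"` or `"tps"`.
#' @param sep long-table field separator.
#' @export
writeLandmarks <- function(dataset, path, dialect = c("long_table", "tps"),
                           sep = ",") {
  dialect <- match.arg(dialect)
  if (dialect == "tps") {
    if (!all(dataset$present)) {
      stop("TPS cannot represent absent landmarks; use the long_table dialect")
    }
    con <- file(path, "w"); on.exit(close(con))
    k <- nrow(dataset$scheme)
    for (s in seq_along(dataset$specimens)) {
      writeLines(sprintf("LM3=%d", k), con)
      m <- dataset$coords[, , s]
      writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
      writeLines(sprintf("ID=%s", dataset$specimens[s]), con)
    }
  } else {
    fmt <- function(v) sprintf("%.17g", v)   # round-trips doubles exactly
    rows <- do.call(rbind, lapply(seq_along(dataset$specimens), function(s) {
      keep <- dataset$present[, s]
      data.frame(specimen = dataset$specimens[s],
                 landmark_id = dataset$scheme$id[keep],
                 x = fmt(dataset$coords[keep, 1, s]),
                 y = fmt(dataset$coords[keep, 2, s]),
                 z = fmt(dataset$coords[keep, 3, s]),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

#' Write / read a landmark scheme as a YAML sidecar
#'
#' The sidecar records, per landmark id: type, module, midline flag,
#' bilateral pair, side, and curve membership, in scheme order.
#'
#' @param scheme a [landmarkScheme()].
#' @param path file path.
#' @export
writeScheme <- function(scheme, path) {
  obj <- list(landmarks = lapply(seq_len(nrow(scheme)), function(i) {
    r <- scheme[i, ]
    x <- list(id = r$id, type = r$type, module = r$module,
              midline = r$midline, side = r$side)
    if (!is.na(r$pair)) x$pair <- r$pair
    if (!is.na(r$curve)) { x$curve <- r$curve; x$curve_pos <- r$curve_pos }
    x
  }))
  yaml::write_yaml(obj, path)
  invisible(NULL)
}

#' @rdname writeScheme
#' @return `readScheme` returns a [landmarkScheme()].
#' @export
readScheme <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$landmarks)) stop("scheme file has no 'landmarks' entry")
  g <- function(f, default) {
    vapply(obj$landmarks, function(x) {
      v <- x[[f]]
      if (is.null(v)) default else v
    }, default)
  }
  landmarkScheme(
    ids = g("id", NA_character_),
    type = g("type", "fixed"),
    module = g("module", "all"),
    midline = g("midline", FALSE),
    pair = g("pair", NA_character_),
    side = g("side", NA_character_),
    curve = g("curve", NA_character_),
    curve_pos = as.integer(g("curve_pos", NA_integer_))
  )
}

#' Read / write module hypothesis sets
#'
#' A hypothesis set is a named list of module assignments over the landmark
#' ids of a scheme, stored as YAML: each hypothesis maps module names to the
#' landmark ids they contain.
#'
#' @param path YAML file path.
#' @param scheme a [landmarkScheme()] used to validate coverage.
#' @return a named list of named character vectors (landmark id -> module).
#' @export
readHypotheses <- function(path, scheme = NULL) {
  obj <- yaml::read_yaml(path)
  hyps <- lapply(obj, function(h) {
    assign <- character(0)
    for (mod in names(h)) {
      ids <- as.character(h[[mod]])
      assign[ids] <- mod
    }
    assign
  })
  if (!is.null(scheme)) {
    for (nm in names(hyps)) {
      miss <- setdiff(scheme$id, names(hyps[[nm]]))
      if (length(miss)) {
        stop("hypothesis '", nm, "' leaves landmarks unassigned: ",
             paste(utils::head(miss, 5), collapse = ", "))
      }
    }
  }
  hyps
}

#' @rdname readHypotheses
#' @param hypotheses named list of assignments (landmark id -> module label).
#' @export
writeHypotheses <- function(hypotheses, path) {
  obj <- lapply(hypotheses, function(assign) {
    split(names(assign), assign)
  })
  yaml::write_yaml(obj, path)
  invisible(NULL)
}
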