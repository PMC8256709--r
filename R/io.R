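# Plain-text interchange formats: columnar profile files and the
# directory-based scan container (index.csv + one profile file per pixel).

#' Read and write 1D profile files
#'
#' Profiles are stored as plain columnar text with a header line
#' `# q_nm^-1 I sigma` and one row per q value (two columns when no
#' uncertainty is recorded, three when it is). The round trip is lossless;
#' strictly increasing q is enforced on read.
#'
#' @param path File path.
#' @param profile A [qprofile].
#' @param modality Modality tag to attach on read (`"saxs"`/`"waxs"`);
#'   default from the file header when present.
#' @return `read_profile` returns a [qprofile]; `write_profile` returns
#'   `path` invisibly.
#' @export
read_profile <- function(path, modality = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty profile file: ", path)
  header <- grepl("^\\s*#", lines)
  if (is.null(modality)) {
    m <- regmatches(lines[header], regexpr("modality=(saxs|waxs)", lines[header]))
    modality <- if (length(m)) sub("modality=", "", m[[1]]) else "saxs"
  }
  dat_lines <- which(!header & nzchar(trimws(lines)))
  if (length(dat_lines) == 0) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines[dat_lines]), "\\s+")
  ncols <- lengths(fields)
  if (any(ncols < 2 | ncols > 3)) {
    stop("parse error at line ", dat_lines[which(ncols < 2 | ncols > 3)[1]],
         ": expected 2 or 3 columns")
  }
  num <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(num, function(v) any(is.na(v)), TRUE))
  if (length(bad)) {
    stop("parse error at line ", dat_lines[bad[1]], ": non-numeric value")
  }
  q <- vapply(num, `[[`, 0, 1L)
  I <- vapply(num, `[[`, 0, 2L)
  if (any(!is.finite(I))) {
    stop("parse error at line ", dat_lines[which(!is.finite(I))[1]],
         ": NaN intensity")
  }
  nd <- which(diff(q) <= 0)
  if (length(nd)) {
    stop("parse error at line ", dat_lines[nd[1] + 1],
         ": q not strictly increasing")
  }
  sigma <- if (all(ncols == 3)) vapply(num, `[[`, 0, 3L) else NULL
  qprofile(q, I, sigma = sigma, modality = modality)
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "qprofile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# q_nm^-1 I sigma  modality=%s", profile$modality), con)
  if (is.null(profile$sigma)) {
    writeLines(sprintf("%.10g %.10g", profile$q, profile$intensity), con)
  } else {
    writeLines(sprintf("%.10g %.10g %.10g", profile$q, profile$intensity,
                       profile$sigma), con)
  }
  invisible(path)
}

.truth_to_json <- function(truth) {
  jsonlite::toJSON(list(step = unclass(truth$step),
                        waxs_peaks = truth$waxs_peaks,
                        background = truth$background,
                        count_scale = truth$count_scale,
                        seed = truth$seed),
                   auto_unbox = TRUE, digits = NA)
}

.truth_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  ground_truth(step = do.call(step_params, as.list(x$step)),
               waxs_peaks = as.data.frame(x$waxs_peaks),
               background = unlist(x$background),
               count_scale = x$count_scale,
               seed = x$seed)
}

#' Write and read a scan grid as a directory container
#'
#' The canonical interchange layout: a directory holding `index.csv`
#' (columns `row`, `col`, `x_um`, `y_um`, `path`, `truth_json`) plus one
#' columnar profile file per pixel.
#'
#' @param grid A [scan_grid].
#' @param dir Directory path (created if needed).
#' @return `write_scan` returns `dir` invisibly; `read_scan` a
#'   [scan_grid].
#' @export
write_scan <- function(grid, dir) {
  stopifnot(inherits(grid, "scan_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- grid$index
  idx$path <- sprintf("profile_r%03d_c%03d.txt", idx$row, idx$col)
  idx$truth_json <- vapply(grid$truths, function(tr) {
    if (is.null(tr)) "" else as.character(.truth_to_json(tr))
  }, "")
  for (i in seq_len(nrow(idx))) {
    write_profile(get_profile(grid, i), file.path(dir, idx$path[i]))
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  meta <- list(modality = grid$modality, n_rows = grid$n_rows,
               n_cols = grid$n_cols, step_um = grid$step_um,
               noise = grid$noise, seed = grid$seed)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "scan.json"))
  invisible(dir)
}

#' @rdname write_scan
#' @export
read_scan <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"),
                         colClasses = c(truth_json = "character"))
  meta <- jsonlite::fromJSON(file.path(dir, "scan.json"))
  profs <- lapply(idx$path, function(p) read_profile(file.path(dir, p),
                                                     modality = meta$modality))
  q <- profs[[1]]$q
  intensity <- do.call(rbind, lapply(profs, function(p) {
    if (!isTRUE(all.equal(p$q, q))) stop("inconsistent q grids in ", dir)
    p$intensity
  }))
  truths <- lapply(idx$truth_json, function(tj) {
    if (is.na(tj) || !nzchar(tj)) NULL else .truth_from_json(tj)
  })
  structure(list(q = q, intensity = intensity,
                 index = idx[, c("row", "col", "x_um", "y_um")],
                 truths = truths, modality = meta$modality,
                 n_rows = meta$n_rows, n_cols = meta$n_cols,
                 step_um = meta$step_um, noise = meta$noise,
                 seed = meta$seed),
            class = "scan_grid")
}

#' Fold a 2D detector frame into azimuthally segmented 1D profiles
#'
#' Radial regrouping of a plain 2D intensity array with beam-centre and
#' geometry metadata into `n_segments` azimuthal segment profiles on a
#' common q grid. Segment 1 starts at the +horizontal axis and segments
#' proceed counter-clockwise. The full-azimuth average is the pixel-count
#' weighted mean over segments and equals the direct radial average.
#'
#' @param frame Numeric matrix of intensities (rows = detector y).
#' @param center Beam centre `c(x, y)` in pixel coordinates (x along
#'   columns); must lie inside the frame.
#' @param pixel_mm Pixel pitch in mm.
#' @param dist_mm Sample-detector distance in mm.
#' @param lambda_nm X-ray wavelength in nm.
#' @param n_segments Number of azimuthal segments (>= 1; beamline default
#'   16).
#' @param n_qbins Number of radial q bins.
#' @return A list with `segments` (list of [qprofile]s), `counts`
#'   (segments x bins pixel counts), and `average` (full-azimuth
#'   [qprofile]).
#' @export
fold_azimuthal <- function(frame, center, pixel_mm, dist_mm, lambda_nm,
                           n_segments = 16L, n_qbins = 200L) {
  stopifnot(is.matrix(frame), n_segments >= 1)
  if (center[1] < 1 || center[1] > ncol(frame) ||
      center[2] < 1 || center[2] > nrow(frame)) {
    stop("beam center outside the frame")
  }
  xx <- matrix(rep(seq_len(ncol(frame)), each = nrow(frame)), nrow(frame))
  yy <- matrix(rep(seq_len(nrow(frame)), ncol(frame)), nrow(frame))
  dx <- xx - center[1]
  dy <- yy - center[2]
  r_mm <- sqrt(dx^2 + dy^2) * pixel_mm
  theta <- atan(r_mm / dist_mm) / 2
  qv <- 4 * pi * sin(theta) / lambda_nm
  phi <- atan2(dy, dx) %% (2 * pi)
  seg <- pmin(floor(phi / (2 * pi) * n_segments) + 1L, n_segments)

  ok <- qv > 0
  edges <- seq(min(qv[ok]), max(qv), length.out = n_qbins + 1L)
  bin <- pmin(findInterval(qv, edges, rightmost.closed = TRUE), n_qbins)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  counts <- matrix(0, n_segments, n_qbins)
  sums <- matrix(0, n_segments, n_qbins)
  key <- (seg - 1L) * n_qbins + bin
  tab_n <- tabulate(key[ok], nbins = n_segments * n_qbins)
  agg <- rowsum(as.numeric(frame[ok]), group = key[ok])
  tab_s <- numeric(n_segments * n_qbins)
  tab_s[as.integer(rownames(agg))] <- agg[, 1]
  counts[] <- matrix(tab_n, n_segments, n_qbins, byrow = TRUE)
  sums[] <- matrix(tab_s, n_segments, n_qbins, byrow = TRUE)

  segments <- lapply(seq_len(n_segments), function(s) {
    have <- counts[s, ] > 0
    qprofile(centers[have], sums[s, have] / counts[s, have],
             modality = "saxs")
  })
  tot_n <- colSums(counts)
  have <- tot_n > 0
  average <- qprofile(centers[have], colSums(sums)[have] / tot_n[have],
                      modality = "saxs")
  list(segments = segments, counts = counts, average = average,
       q = centers)
}
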