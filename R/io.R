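# Readers and writers for every external format the pipeline touches:
# wide coordinate CSV, ASCII PLY/OBJ meshes, PLINK .eigenvec, ADMIXTURE .Q,
# template JSON, and per-vertex scalar maps (PLY + CSV).
# All readers validate rather than silently reorder or truncate.

#' Write a cohort of landmark configurations to wide CSV
#'
#' One row per individual: `id, x1, y1, z1, ..., xL, yL, zL` (1-based landmark
#' indices in the header).
#'
#' @param shapes `n x L x 3` array with ids in `dimnames[[1]]`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_shapes <- function(shapes, path) {
  m <- shapes_to_matrix(shapes)
  L <- ncol(m) / 3L
  hdr <- as.vector(t(outer(seq_len(L), c("x", "y", "z"),
                           function(i, a) paste0(a, i))))
  df <- data.frame(id = rownames(m), m, stringsAsFactors = FALSE)
  colnames(df) <- c("id", hdr)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort of landmark configurations
#'
#' Accepts either a wide CSV written by [write_shapes()] or a directory of
#' per-individual ASCII PLY/OBJ meshes whose vertex count matches the
#' template (vertices are taken in file order; template correspondence is
#' assumed, as for registered scans).
#'
#' @param path CSV file or mesh directory.
#' @param template Optional `face_template`; when given, the landmark count is
#'   validated against it.
#' @return `n x L x 3` array with ids in rownames.
#' @export
read_shapes <- function(path, template = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(ply|obj)$", full.names = TRUE))
    if (length(files) == 0L) stop("no .ply/.obj meshes found in ", path)
    ids <- sub("\\.(ply|obj)$", "", basename(files))
    if (anyDuplicated(ids)) stop("duplicate id: ", ids[duplicated(ids)][1L])
    configs <- lapply(files, read_mesh_vertices)
    Ls <- vapply(configs, nrow, integer(1L))
    if (!is.null(template)) {
      bad <- which(Ls != nrow(template$coordinates))
      if (length(bad))
        stop("vertex count mismatch for '", ids[bad[1L]], "': got ",
             Ls[bad[1L]], ", template has ", nrow(template$coordinates))
    }
    if (length(unique(Ls)) != 1L)
      stop("inconsistent vertex counts across meshes")
    return(stack_configs(configs, ids))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 4L || (ncol(df) - 1L) %% 3L != 0L)
    stop("expected 1 + 3L columns, got ", ncol(df),
         if (!is.null(template))
           paste0(" (expected ", 1L + 3L * nrow(template$coordinates), ")"))
  L <- (ncol(df) - 1L) %/% 3L
  if (!is.null(template) && L != nrow(template$coordinates))
    stop("CSV has ", L, " landmarks, template has ",
         nrow(template$coordinates))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate id: ", ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric coordinate values in ", path)
  rownames(m) <- ids
  matrix_to_shapes(m)
}

# Minimal ASCII PLY / OBJ vertex reader (template correspondence assumed).
read_mesh_vertices <- function(file) {
  ext <- tolower(tools::file_ext(file))
  lines <- readLines(file, warn = FALSE)
  if (ext == "obj") {
    v <- lines[startsWith(lines, "v ")]
    if (length(v) == 0L) stop("no vertices in OBJ file ", file)
    m <- do.call(rbind, lapply(strsplit(trimws(v), "\\s+"), function(p)
      as.numeric(p[2:4])))
  } else {
    if (!identical(trimws(lines[1L]), "ply")) stop(file, " is not a PLY file")
    end <- match("end_header", trimws(lines))
    if (is.na(end)) stop("PLY header not terminated in ", file)
    fmt <- grep("^format", lines[1:end], value = TRUE)
    if (!any(grepl("ascii", fmt))) stop("only ASCII PLY is supported: ", file)
    vline <- grep("^element vertex", lines[1:end], value = TRUE)
    nv <- as.integer(strsplit(trimws(vline[1L]), "\\s+")[[1L]][3L])
    body <- lines[(end + 1L):(end + nv)]
    m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(p)
      as.numeric(p[1:3])))
  }
  if (anyNA(m)) stop("non-numeric vertex coordinates in ", file)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Read genetic PC scores in PLINK .eigenvec dialect
#'
#' Whitespace-delimited, optional header line, columns `FID IID PC1..PCK` or
#' `IID PC1..PCK`. Ids are taken from IID; column order is preserved.
#'
#' @param path File path.
#' @return `n x K` numeric matrix, ids in rownames, columns `PC1..PCK`.
#' @export
read_eigenvec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty .eigenvec file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  first <- toks[[1L]]
  header <- startsWith(first[1L], "#") ||
    any(grepl("^PC[0-9]+$", first, ignore.case = TRUE))
  if (header) toks <- toks[-1L]
  if (length(toks) == 0L) stop("no data rows in ", path)
  widths <- lengths(toks)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, " (line ",
         which(widths != widths[1L])[1L] + header, ")")
  w <- widths[1L]
  # detect FID column: two leading non-numeric fields vs one
  lead2 <- suppressWarnings(is.na(as.numeric(toks[[1L]][2L])))
  id_col <- if (lead2) 2L else 1L
  nK <- w - id_col
  if (nK < 1L) stop("no PC columns in ", path)
  scores <- matrix(NA_real_, length(toks), nK)
  for (i in seq_along(toks)) {
    v <- suppressWarnings(as.numeric(toks[[i]][(id_col + 1L):w]))
    if (anyNA(v))
      stop("non-numeric PC score on line ", i + as.integer(header),
           " of ", path)
    scores[i, ] <- v
  }
  rownames(scores) <- vapply(toks, `[[`, character(1L), id_col)
  colnames(scores) <- paste0("PC", seq_len(nK))
  scores
}

#' Read admixture proportions in ADMIXTURE .Q dialect
#'
#' One whitespace-delimited row of proportions per individual, no ids in the
#' file; ids are supplied in file order. Rows whose sum deviates from 1 by
#' more than `1e-3` are rejected; smaller deviations are renormalized.
#'
#' @param path File path.
#' @param ids Character vector of individual ids, one per row.
#' @param region_names Optional column labels.
#' @return `n x R` matrix with rows summing to 1, ids in rownames.
#' @export
read_q <- function(path, ids, region_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != length(ids))
    stop("Q file has ", length(lines), " rows but ", length(ids),
         " ids were supplied")
  toks <- strsplit(trimws(lines), "\\s+")
  if (length(unique(lengths(toks))) != 1L) stop("ragged rows in ", path)
  q <- do.call(rbind, lapply(toks, as.numeric))
  if (anyNA(q)) stop("non-numeric proportion in ", path)
  if (any(q < 0) || any(q > 1))
    stop("admixture proportions must lie in [0, 1]")
  s <- rowSums(q)
  bad <- which(abs(s - 1) > 1e-3)
  if (length(bad))
    stop("row ", bad[1L], " sums to ", format(s[bad[1L]]),
         "; must be within 1e-3 of 1")
  q <- q / s
  rownames(q) <- ids
  if (!is.null(region_names)) {
    if (length(region_names) != ncol(q))
      stop("expected ", ncol(q), " region names")
    colnames(q) <- region_names
  }
  q
}

#' Write a Q matrix in ADMIXTURE .Q dialect
#' @param q `n x R` matrix of proportions.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_q <- function(q, path) {
  utils::write.table(format(q, digits = 6, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genetic PC scores in PLINK .eigenvec dialect
#' @param pcs `n x K` matrix, ids in rownames.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_eigenvec <- function(pcs, path) {
  df <- data.frame(FID = rownames(pcs), IID = rownames(pcs), pcs)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write / read a landmark template as JSON
#'
#' Template JSON stores coordinates, triangulation and the bilateral pairing
#' (1-based indices) in a diff-friendly form.
#'
#' @param template A `face_template`.
#' @param path JSON file.
#' @return `path` invisibly / a `face_template`.
#' @export
write_template <- function(template, path) {
  obj <- list(coordinates = unname(template$coordinates),
              triangles = unname(template$triangles),
              pairing = template$pairing,
              grid = as.list(template$grid), extent = template$extent)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- as.matrix(obj$coordinates)
  colnames(coords) <- c("x", "y", "z")
  tpl <- structure(list(coordinates = coords,
                        triangles = matrix(as.integer(obj$triangles),
                                           ncol = 3L),
                        pairing = as.integer(obj$pairing),
                        grid = c(nr = as.integer(obj$grid$nr),
                                 nc = as.integer(obj$grid$nc)),
                        extent = obj$extent),
                   class = "face_template")
  validate_template(tpl, tol = 1e-9)
  tpl
}

#' Export a per-landmark scalar map
#'
#' Writes both an ASCII PLY with a per-vertex `quality` property (colourable
#' in any mesh viewer) and a CSV `(landmark, value)` table.
#'
#' @param template A `face_template` providing geometry and triangulation.
#' @param values Numeric vector of length L.
#' @param path Base path; `.ply` and `.csv` are appended.
#' @param allow_nan Permit NaN/NA values (default FALSE).
#' @return Named character vector of written paths, invisibly.
#' @export
write_scalar_map <- function(template, values, path, allow_nan = FALSE) {
  L <- nrow(template$coordinates)
  if (length(values) != L)
    stop("expected ", L, " values, got ", length(values))
  if (!allow_nan && anyNA(values))
    stop("scalar map contains NaN/NA; pass allow_nan = TRUE to permit")
  ply <- paste0(path, ".ply")
  csv <- paste0(path, ".csv")
  co <- template$coordinates
  tr <- template$triangles
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", L),
           "property float x", "property float y", "property float z",
           "property float quality",
           paste("element face", nrow(tr)),
           "property list uchar int vertex_indices", "end_header")
  vb <- sprintf("%.9g %.9g %.9g %.9g", co[, 1L], co[, 2L], co[, 3L], values)
  fb <- sprintf("3 %d %d %d", tr[, 1L] - 1L, tr[, 2L] - 1L, tr[, 3L] - 1L)
  writeLines(c(hdr, vb, fb), ply)
  utils::write.csv(data.frame(landmark = seq_len(L), value = values), csv,
                   row.names = FALSE, quote = FALSE)
  invisible(c(ply = ply, csv = csv))
}

#' Read a scalar map CSV written by [write_scalar_map()]
#' @param path CSV path.
#' @return Numeric vector of per-landmark values.
#' @export
read_scalar_map <- function(path) {
  df <- utils::read.csv(path)
  df$value[order(df$landmark)]
}

#' Write a full synthetic cohort to a directory
#'
#' Emits `shapes.csv`, `covariates.csv`, `cohort.Q`, `cohort.eigenvec`,
#' `template.json` and `regions.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_shapes(cohort$shapes, file.path(dir, "shapes.csv"))
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  write_q(cohort$q, file.path(dir, "cohort.Q"))
  write_eigenvec(cohort$pcs, file.path(dir, "cohort.eigenvec"))
  write_template(cohort$template, file.path(dir, "template.json"))
  utils::write.csv(data.frame(id = cohort$covariates$id,
                              region = as.character(cohort$true_region)),
                   file.path(dir, "regions.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
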